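# Orchestration: dataset simulation to disk, end-to-end analysis, and report
# rendering. These functions (plus the thin wrapper in inst/cli/faimsvoc.R)
# are the run-level interface; every step is also callable on in-memory
# objects.

#' Write a simulated cohort to disk in the package interchange format
#'
#' Writes one matrix CSV per (sample, replicate, polarity)
#' (`<id>_rep<r>_<polarity>.csv`), `metadata.csv`, `truth.json` (planted
#' pixels per class effect) and the archived generator configuration
#' (`sim_config.json`).
#'
#' @param config a [sim_config()]
#' @param out_dir output directory
#' @param seed generator seed (default: config's)
#' @param force overwrite a non-empty existing directory (default FALSE)
#' @return the `faims_cohort`, invisibly
#' @export
faims_simulate <- function(config = sim_config(), out_dir, seed = config$seed,
                           force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force)
    stop_fv("faims_simulate: %s exists and is not empty (use force = TRUE)", out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(config, seed)
  for (sid in names(cohort$runs)) {
    for (run in cohort$runs[[sid]]) {
      for (pol in c("positive", "negative")) {
        write_scan(run[[pol]],
                   file.path(out_dir, sprintf("%s_rep%d_%s.csv", sid,
                                              run$replicate_index, pol)))
      }
    }
  }
  write_metadata(cohort$metadata, file.path(out_dir, "metadata.csv"))
  jsonlite::write_json(cohort$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- unclass(cohort$config)
  cfg$seed <- seed
  jsonlite::write_json(cfg, file.path(out_dir, "sim_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(cohort)
}

#' Read a cohort back from the interchange format
#'
#' @param dir directory written by [faims_simulate()] (or hand-assembled in
#'   the same layout)
#' @param geometry optional `c(n_df, n_cv)` to enforce on every scan
#' @return a `faims_cohort` (without ground truth unless `truth.json` exists)
#' @export
read_cohort <- function(dir, geometry = NULL) {
  meta <- read_metadata(file.path(dir, "metadata.csv"))
  files <- list.files(dir, pattern = "_rep[0-9]+_(positive|negative)\\.csv$")
  if (!length(files)) stop_fv("read_cohort: no scan files in %s", dir)
  info <- regmatches(files, regexec("^(.*)_rep([0-9]+)_(positive|negative)\\.csv$", files))
  tab <- do.call(rbind, lapply(info, function(x)
    data.frame(file = x[1], sid = x[2], rep = as.integer(x[3]), pol = x[4],
               stringsAsFactors = FALSE)))
  runs <- lapply(meta$sample_id, function(sid) {
    sub <- tab[tab$sid == sid, ]
    if (!nrow(sub)) stop_fv("read_cohort: no scans for sample %s", sid)
    lapply(sort(unique(sub$rep)), function(r) {
      get_scan <- function(pol) {
        f <- sub$file[sub$rep == r & sub$pol == pol]
        if (length(f) != 1)
          stop_fv("read_cohort: sample %s replicate %d: expected one %s scan, found %d",
                  sid, r, pol, length(f))
        read_scan(file.path(dir, f), pol, geometry = geometry)
      }
      instrument_run(sid, r, get_scan("positive"), get_scan("negative"))
    })
  })
  names(runs) <- meta$sample_id
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) jsonlite::read_json(truth_path, simplifyVector = TRUE) else list()
  n_df <- length(runs[[1]][[1]]$positive$df_axis)
  n_cv <- length(runs[[1]][[1]]$positive$cv_axis)
  cfg_path <- file.path(dir, "sim_config.json")
  config <- if (file.exists(cfg_path)) {
    cf <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
    cf$peaks <- as.data.frame(cf$peaks)
    structure(cf, class = "sim_config")
  } else {
    list(n_df = n_df, n_cv = n_cv, replicates = max(tab$rep))
  }
  structure(list(runs = runs, metadata = meta, truth = truth, config = config),
            class = "faims_cohort")
}

#' Run the full analysis pipeline on a cohort
#'
#' Selects the configured replicate, combines polarities, fits the label-blind
#' background mask, and runs tenfold cross-validation with in-fold rank-sum
#' selection for every requested comparison x classifier family x feature
#' count, reporting AUC (95% CI, permutation p), Youden operating point and
#' predictive values per cell, with the best AUC per comparison flagged.
#'
#' @param cohort a `faims_cohort`, or a directory for [read_cohort()]
#' @param comparisons comparison specs (default [builtin_comparisons()]);
#'   unresolvable comparisons are skipped with a message
#' @param families,ks classifier families and feature counts to cross
#' @param replicate replicate carried to analysis (default 2)
#' @param mask_quantile background-mask quantile (default 0.5)
#' @param n_folds,seed cross-validation settings
#' @param n_boot,n_perm inference settings
#' @param out_dir if given, writes `report.csv`, `report.json`, per-best-model
#'   feature-map TSVs and a run log there
#' @return a `faims_analysis`: list with `report` (data.frame), `results`
#'   (named `cv_result`s), `mask`, `feature_ids`, `geometry`, `settings`
#' @export
faims_analyze <- function(cohort, comparisons = builtin_comparisons(),
                          families = .classifier_families, ks = c(100, 50, 20),
                          replicate = 2, mask_quantile = 0.5, n_folds = 10,
                          seed = 1L, n_boot = 2000, n_perm = 10000,
                          out_dir = NULL) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  X_full <- cohort_matrix(cohort, replicate)
  mask <- fit_background_mask(X_full, quantile = mask_quantile,
                              provenance = "all samples (label-blind)")
  X <- apply_mask(X_full, mask)
  res <- run_all(X, cohort$metadata, comparisons = comparisons,
                 families = families, ks = ks, n_folds = n_folds, seed = seed,
                 n_boot = n_boot, n_perm = n_perm)
  n_df <- cohort$config$n_df; n_cv <- cohort$config$n_cv
  out <- structure(list(report = res$report, results = res$results,
                        mask = mask, feature_ids = mask$retained,
                        geometry = c(n_df = n_df, n_cv = n_cv),
                        settings = list(replicate = replicate,
                                        mask_quantile = mask_quantile,
                                        n_folds = n_folds, seed = seed,
                                        n_boot = n_boot, n_perm = n_perm,
                                        ks = ks, families = families)),
                   class = "faims_analysis")
  if (!is.null(out_dir)) write_analysis(out, out_dir)
  out
}

#' @export
print.faims_analysis <- function(x, ...) {
  cat(sprintf("<faims_analysis> %d comparisons, %d result cells\n",
              length(unique(x$report$comparison)), nrow(x$report)))
  best <- x$report[x$report$best, c("comparison", "family", "k", "auc")]
  best$auc <- round_half_up(best$auc, 2)
  print(best, row.names = FALSE)
  invisible(x)
}

write_analysis <- function(analysis, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(analysis$report, file.path(out_dir, "report.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(report = analysis$report,
                            settings = analysis$settings,
                            mask = list(retained = length(analysis$mask$retained),
                                        of = analysis$mask$n_features,
                                        rule = analysis$mask$rule)),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  # feature map of the best model per comparison
  for (cid in unique(analysis$report$comparison)) {
    row <- analysis$report[analysis$report$comparison == cid &
                             analysis$report$best, ][1, ]
    cv <- analysis$results[[paste(cid, row$family, row$k, sep = ":")]]
    sel <- sort(unique(unlist(cv$selected)))
    fm <- feature_map_coordinates(sel, analysis$geometry["n_df"],
                                  analysis$geometry["n_cv"])
    utils::write.table(fm, file.path(out_dir, sprintf("features_%s.tsv", cid)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(out_dir)
}

#' Render a human-readable summary of an analysis run
#'
#' Produces a markdown table mirroring the published classification-table
#' columns (best algorithm, feature count, AUC with 95% CI, p, sensitivity,
#' specificity, PPV, NPV; display rounded half-up to 2 decimals) plus one
#' feature-map and one ROC image per completed comparison.
#'
#' @param x a `faims_analysis`, or a run directory written by
#'   [faims_analyze()] (markdown only in that case)
#' @param out_dir directory for `report.md` and images (default: none, the
#'   markdown is only returned)
#' @return the markdown report as a character vector of lines, invisibly
#' @export
faims_report <- function(x, out_dir = NULL) {
  if (is.character(x)) {
    rep_df <- utils::read.csv(file.path(x, "report.csv"), stringsAsFactors = FALSE)
    analysis <- NULL
  } else {
    rep_df <- x$report
    analysis <- x
  }
  fmt <- function(v) sprintf("%.2f", round_half_up(v, 2))
  lines <- c("# FAIMS VOC classification report", "",
             "| Comparison | Best algorithm | Features | AUC (95% CI) | P | Sensitivity | Specificity | PPV | NPV |",
             "|---|---|---|---|---|---|---|---|---|")
  for (cid in unique(rep_df$comparison)) {
    sub <- rep_df[rep_df$comparison == cid, ]
    b <- sub[which(sub$best)[1], ]
    if (is.na(b$comparison)) {
      lines <- c(lines, sprintf("| %s | skipped | | | | | | | |", cid))
      next
    }
    incomplete <- if (isTRUE(b$incomplete)) " (incomplete)" else ""
    lines <- c(lines, sprintf(
      "| %s%s | %s | %d | %s (%s-%s) | %s | %s | %s | %s | %s |",
      cid, incomplete, gsub("_", " ", b$family), b$k,
      fmt(b$auc), fmt(b$ci_low), fmt(b$ci_high),
      ifelse(b$p_value < 0.001, "<0.001", fmt(b$p_value)),
      fmt(b$sensitivity), fmt(b$specificity), fmt(b$ppv), fmt(b$npv)))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(lines, file.path(out_dir, "report.md"))
    if (!is.null(analysis)) {
      for (cid in unique(rep_df$comparison)) {
        b <- rep_df[rep_df$comparison == cid & rep_df$best, ][1, ]
        cv <- analysis$results[[paste(cid, b$family, b$k, sep = ":")]]
        ok <- !is.na(cv$scores$score)
        roc <- roc_auc(cv$scores$score[ok], cv$scores$label[ok], cv$positive)
        grDevices::png(file.path(out_dir, sprintf("roc_%s.png", cid)),
                       width = 600, height = 600)
        plot_roc(roc, main = sprintf("%s: %s (%d features), AUC %.2f",
                                     cid, cv$family, cv$k, roc$auc))
        grDevices::dev.off()
        sel <- sort(unique(unlist(cv$selected)))
        grDevices::png(file.path(out_dir, sprintf("features_%s.png", cid)),
                       width = 900, height = 450)
        plot_feature_map(sel, analysis$geometry["n_df"],
                         analysis$geometry["n_cv"],
                         main = sprintf("%s: selected feature locations", cid))
        grDevices::dev.off()
      }
    }
  }
  invisible(lines)
}

#' Plot a ROC curve
#' @param roc result of [roc_auc()]
#' @param ... passed to [graphics::plot()]
#' @return NULL, invisibly
#' @export
plot_roc <- function(roc, ...) {
  graphics::plot(roc$curve$fpr, roc$curve$tpr, type = "s",
                 xlab = "1 - specificity", ylab = "Sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(NULL)
}

#' Plot selected feature locations on the two dispersion-plot panels
#' @param indices flat feature indices
#' @param n_df,n_cv geometry
#' @param main overall title
#' @return NULL, invisibly
#' @export
plot_feature_map <- function(indices, n_df = 51, n_cv = 512, main = "") {
  fm <- feature_map_coordinates(indices, n_df, n_cv)
  op <- graphics::par(mfrow = c(1, 2), oma = c(0, 0, 2, 0))
  on.exit(graphics::par(op))
  for (pol in c("positive", "negative")) {
    sub <- fm[fm$polarity == pol, ]
    graphics::plot(sub$cv_volts, sub$df_percent, pch = 16, cex = 0.6,
                   xlim = c(6, -6), ylim = c(0, 100),
                   xlab = "Compensation voltage (V)",
                   ylab = "Dispersion field (%)",
                   main = sprintf("%s polarity (%d features)", pol, nrow(sub)))
  }
  graphics::mtext(main, outer = TRUE)
  invisible(NULL)
}

#' Re-run the pipeline on an externally supplied raw dataset
#'
#' The study's printed AUCs were produced from its raw instrument exports,
#' which ship as supplementary material, with unstated seeds and
#' hyperparameters; they are therefore reproducible only from that file and
#' only within stochastic tolerance. Given a directory containing the raw
#' scans and metadata in the package interchange format (see
#' [read_cohort()]), this runs the identical pipeline and returns the
#' analysis for side-by-side comparison with the printed table.
#'
#' @param data_dir directory with the converted supplementary dataset
#' @param ... passed to [faims_analyze()]
#' @return a `faims_analysis`
#' @export
reproduce_supplementary <- function(data_dir, ...) {
  if (missing(data_dir) || !dir.exists(data_dir))
    stop_fv(paste0("reproduce_supplementary: supply the directory holding the ",
                   "study's raw VOC dataset converted to the package ",
                   "interchange format (per-run matrix CSVs + metadata.csv); ",
                   "it is not distributed with the package"))
  faims_analyze(read_cohort(data_dir), ...)
}
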