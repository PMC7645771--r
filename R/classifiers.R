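# Pluggable classifier backends behind a single fit/predict contract.
#
# The four families compared by the pipeline are random forest, Gaussian
# process, support vector machine and sparse (L1) logistic regression. Each
# backend takes a training matrix/labels plus a test matrix and returns a
# probability-like score in [0,1] per test sample, oriented so that higher
# means more like the positive class. Hyperparameters are declarative and
# overridable; stochastic fits are seeded.

.classifier_families <- c("random_forest", "gaussian_process",
                          "support_vector_machine", "sparse_logistic_regression")

#' Declare a classifier to be used inside cross-validation
#'
#' Defaults: random forest with 1000 trees; SVM with a radial kernel and
#' probability-calibrated scores; Gaussian process with a radial kernel
#' (automatic bandwidth); sparse logistic regression = L1-penalised logistic
#' with the penalty chosen by inner 5-fold cross-validation.
#'
#' @param family one of `"random_forest"`, `"gaussian_process"`,
#'   `"support_vector_machine"`, `"sparse_logistic_regression"`
#' @param hyper named list of hyperparameter overrides (`ntree`, `cost`,
#'   `sigma`, `inner_nfolds`, `lambda`)
#' @param seed integer seed for the stochastic parts of the fit
#' @return an object of class `classifier_spec`
#' @export
classifier_spec <- function(family = .classifier_families, hyper = list(),
                            seed = 1L) {
  family <- match.arg(family)
  structure(list(family = family, hyper = hyper, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Fit a classifier on training data and score test samples
#'
#' @param spec a `classifier_spec`
#' @param x_train,x_test numeric matrices with identical columns
#' @param y_train factor of two levels for the training rows
#' @param positive which level of `y_train` counts as positive; scores are
#'   the predicted probability of this level
#' @param seed seed for this particular fit (defaults to the spec's seed)
#' @return numeric vector of scores in [0,1], one per test row
#' @export
fit_predict <- function(spec, x_train, y_train, x_test,
                        positive = levels(y_train)[1], seed = spec$seed) {
  stopifnot(inherits(spec, "classifier_spec"))
  y_train <- droplevels(as.factor(y_train))
  if (nlevels(y_train) != 2)
    stop_fv("fit_predict: training labels must have exactly 2 classes")
  if (!positive %in% levels(y_train))
    stop_fv("fit_predict: positive class '%s' not in labels", positive)
  x_train <- as.matrix(x_train); x_test <- as.matrix(x_test)
  h <- spec$hyper
  scores <- with_seed(seed, switch(
    spec$family,
    random_forest = {
      fit <- randomForest::randomForest(x = x_train, y = y_train,
                                        ntree = h$ntree %||% 1000)
      stats::predict(fit, x_test, type = "prob")[, positive]
    },
    gaussian_process = {
      # kernlab announces its bandwidth estimation on stdout; keep runs quiet
      utils::capture.output(fit <- suppressMessages(
        kernlab::gausspr(x = x_train, y = y_train, kernel = "rbfdot",
                         kpar = h$kpar %||% "automatic")
      ))
      kernlab::predict(fit, x_test, type = "probabilities")[, positive]
    },
    support_vector_machine = .svm_scores(x_train, y_train, x_test, positive, h),
    sparse_logistic_regression = .sparse_logistic_scores(x_train, y_train,
                                                         x_test, positive, h)
  ))
  pmin(1, pmax(0, as.numeric(scores)))
}

# Radial-kernel SVM with Platt-scaled probabilities; if the internal
# probability calibration cannot be fitted (tiny training folds), fall back
# to a logistic squashing of the decision values, oriented to the positive
# class.
.svm_scores <- function(x_train, y_train, x_test, positive, h) {
  prob_fit <- tryCatch(
    e1071::svm(x = x_train, y = y_train, kernel = "radial",
               cost = h$cost %||% 1, probability = TRUE),
    error = function(e) NULL)
  if (!is.null(prob_fit)) {
    pr <- tryCatch({
      pred <- stats::predict(prob_fit, x_test, probability = TRUE)
      attr(pred, "probabilities")[, positive]
    }, error = function(e) NULL)
    if (!is.null(pr) && !anyNA(pr)) return(pr)
  }
  fit <- e1071::svm(x = x_train, y = y_train, kernel = "radial",
                    cost = h$cost %||% 1)
  pred <- stats::predict(fit, x_test, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  # column name "A/B" means positive decision values favour class A
  parts <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]]
  s <- if (parts[1] == positive) dv[, 1] else -dv[, 1]
  stats::plogis(s)
}

# L1-penalised logistic regression; lambda picked by inner k-fold CV on the
# training fold when it is big enough, otherwise the 1-SE lambda of a plain
# path fit on deviance is approximated by a mid-path value.
.sparse_logistic_scores <- function(x_train, y_train, x_test, positive, h) {
  y01 <- as.integer(y_train == positive)
  if (ncol(x_train) < 2) {  # glmnet requires >= 2 columns
    x_train <- cbind(x_train, 0)
    x_test <- cbind(x_test, 0)
  }
  lam <- h$lambda
  if (is.null(lam)) {
    nf <- min(h$inner_nfolds %||% 5, min(table(y01)))
    if (nf >= 3) {
      cvfit <- glmnet::cv.glmnet(x_train, y01, family = "binomial",
                                 alpha = 1, nfolds = nf)
      lam <- cvfit$lambda.min
    } else {
      fit0 <- glmnet::glmnet(x_train, y01, family = "binomial", alpha = 1)
      lam <- fit0$lambda[ceiling(length(fit0$lambda) / 2)]
    }
  }
  fit <- glmnet::glmnet(x_train, y01, family = "binomial", alpha = 1,
                        lambda = lam)
  as.numeric(stats::predict(fit, x_test, type = "response"))
}
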