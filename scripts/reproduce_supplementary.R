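#!/usr/bin/env Rscript
# Re-run the full classification pipeline on the study's raw VOC dataset.
#
# The published AUCs were computed from the raw two-polarity instrument
# exports distributed as supplementary material, with unstated random seeds
# and classifier hyperparameters; they are therefore not reproducible from
# the package alone, and a rerun on the raw data is expected to agree only
# within stochastic tolerance (about +/- 0.10 on each AUC).
#
# Usage:
#   Rscript scripts/reproduce_supplementary.R <data_dir> <out_dir> [seed]
#
# <data_dir> must hold the dataset converted to the package interchange
# format: one matrix CSV per (sample, replicate, polarity) named
# <id>_rep<r>_<polarity>.csv plus metadata.csv (see ?read_cohort).

suppressPackageStartupMessages(library(faimsvoc))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 2)
  stop("usage: Rscript scripts/reproduce_supplementary.R <data_dir> <out_dir> [seed]")
seed <- if (length(args) >= 3) as.integer(args[3]) else 1L

an <- reproduce_supplementary(args[1], seed = seed, out_dir = args[2])
faims_report(an, out_dir = args[2])
print(an)
cat("full report written to", args[2], "\n")
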