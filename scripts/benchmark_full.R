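#!/usr/bin/env Rscript
# Full-scale missing-data strategy benchmark: 500 subjects x 10
# biomarkers, 3 subtypes (fractions 4/9, 3/9, 2/9), event levels (1,2,3)
# with ceiling 5, unit noise; 150 and 2000 cells deleted (3% and 40%).
# This is a multi-hour single-CPU run; results land in
# results/benchmark_full.csv (per-replicate rows) and *_summary.csv.
#
#   Rscript scripts/benchmark_full.R --seed 1 --reps 3 \
#       --out results/benchmark_full.csv

suppressPackageStartupMessages({
  library(optparse)
  library(mdsustain)
})

p <- OptionParser()
p <- add_option(p, "--seed", type = "integer", default = 1L)
p <- add_option(p, "--reps", type = "integer", default = 3L)
p <- add_option(p, "--startpoints", type = "integer", default = 25L)
p <- add_option(p, "--out", type = "character",
                default = "results/benchmark_full.csv")
opt <- parse_args(p)

dir.create(dirname(opt$out), showWarnings = FALSE, recursive = TRUE)
set.seed(opt$seed)

strategies <- list(
  missingStrategy("uniform"),
  missingStrategy("deletion"),
  missingStrategy("mean"),
  missingStrategy("knn", knnK = 5, knnFeatures = "summary_stats"),
  missingStrategy("knn", knnK = 5, knnFeatures = "zscored"))

opts <- sustainOptions(nStartpoints = opt$startpoints)

report <- runBenchmark(strategies, missingCounts = c(150L, 2000L),
                       reps = opt$reps, J = 500L, I = 10L, C = 3L,
                       levels = c(1, 2, 3), zMax = 5, opts = opts)
write.csv(report, opt$out, row.names = FALSE)
summ <- summarizeBenchmark(report)
write.csv(summ, sub("\\.csv$", "_summary.csv", opt$out), row.names = FALSE)
print(summ, digits = 4)
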