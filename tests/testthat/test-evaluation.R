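test_that("Kendall similarity: identity, reversal, adjacent swap, oracle", {
  expect_equal(sequenceSimilarity(1:5, 1:5), 1)
  expect_equal(sequenceSimilarity(1:5, 5:1), 0)
  # one adjacent transposition among N = 30 events: 1 - 1/435
  a <- 1:30
  b <- a; b[10:11] <- b[11:10]
  expect_equal(sequenceSimilarity(a, b), 1 - 1 / 435)
  set.seed(3)
  for (rep in 1:10) {
    N <- sample(3:8, 1)
    x <- sample.int(N); y <- sample.int(N)
    expect_equal(sequenceSimilarity(x, y), naiveKendall(x, y))
    expect_equal(sequenceSimilarity(x, y), sequenceSimilarity(y, x))
    expect_equal(sequenceSimilarity(x, x), 1)
  }
  expect_error(sequenceSimilarity(1:4, c(1, 2, 3, 5)), "same event set")
})

test_that("cluster matching recovers identity, swaps, and enumerated optima", {
  lab <- c(1, 1, 2, 2, 3, 3)
  expect_equal(matchClusters(lab, lab, 3), 1:3)
  swapped <- c(2, 2, 1, 1, 3, 3)
  expect_equal(matchClusters(swapped, lab, 3), c(2L, 1L, 3L))
  # a confusion structure whose optimum is verified by brute force here
  est <- c(1, 1, 1, 2, 2, 3, 3, 3, 3)
  tru <- c(2, 2, 3, 3, 3, 1, 1, 2, 1)
  conf <- table(est, tru)
  perms <- rbind(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  scores <- apply(perms, 1, function(p) sum(conf[cbind(1:3, p)]))
  expect_equal(matchClusters(est, tru, 3),
               as.integer(perms[which.max(scores), ]))
})

test_that("subtype accuracy counts matched agreements and excludes stage 0", {
  est <- c(1, 1, 2, 2, 1)
  tru <- c(2, 2, 1, 1, 1)
  m <- matchClusters(est, tru, 2)
  expect_equal(subtypeAccuracy(est, tru, m), 80)
  # invariance under relabeling of the estimate
  relab <- c(2, 2, 1, 1, 2)
  m2 <- matchClusters(relab, tru, 2)
  expect_equal(subtypeAccuracy(relab, tru, m2),
               subtypeAccuracy(est, tru, m))
  expect_equal(subtypeAccuracy(c(1, 1, 1, 2), c(1, 1, 2, 2), 1:2), 75)
  # stage-0 subjects drop out of scoring
  expect_equal(subtypeAccuracy(c(1, 1, 1, 2), c(1, 1, 2, 2), 1:2,
                               estStage = c(1, 0, 3, 2)), 100 * 2 / 3)
  expect_error(subtypeAccuracy(1, 1, 1, estStage = 0L), "no scored")
})

test_that("staging error: hand cases and symmetry", {
  expect_equal(stagingError(1:5, 1:5)$mean[1], 0)
  expect_equal(stagingError(1:5, 1:5)$sd[1], 0)
  expect_equal(stagingError(2:6, 1:5)$mean[1], 1)
  st <- stagingError(c(0, 2, 5, 9), c(0, 1, 3, 6))  # diffs 0 1 2 3
  expect_equal(st$mean[1], 1.5)
  expect_equal(st$sd[1], sd(c(0, 1, 2, 3)))
  expect_equal(stagingError(c(5, 1), c(2, 4))[, c("mean", "sd")],
               stagingError(c(2, 4), c(5, 1))[, c("mean", "sd")])
  bys <- stagingError(c(1, 2, 3, 4), c(1, 3, 3, 8), bySubtype = c(1, 1, 2, 2))
  expect_equal(bys$mean, c(mean(c(0, 1, 0, 4)), 0.5, 2))
  expect_error(stagingError(integer(0), integer(0)), "nonempty")
})

test_that("longitudinal consistency follows the progression rules", {
  cfg <- tinyConfig(list(c(1, 2), 1), zMax = 5)
  model <- subtypeModel(cfg, rbind(c(1, 2, 3), c(3, 1, 2)),
                        fractions = c(0.5, 0.5))
  mk <- function(stagePoint, subtype) {
    # a sharply staged synthetic subject at the given subtype/stage
    x <- vapply(1:2, function(i)
      trajectoryValue(sequences(model)[subtype, ], cfg, i,
                      stagePoint + 0.5), numeric(1))
    matrix(x, 1, dimnames = list("s1", NULL))
  }
  base <- subjectPosteriors(mk(2, 1), model)
  same <- subjectPosteriors(mk(3, 1), model)
  lc <- longitudinalConsistency(base, list(same))
  expect_equal(lc$byVisit$subtypeConsistencyPct, 100)
  expect_equal(lc$byVisit$stageConsistencyPct, 100)
  # identical posteriors are trivially consistent
  lc2 <- longitudinalConsistency(base, list(base))
  expect_equal(lc2$byVisit$subtypeConsistencyPct, 100)
  expect_equal(lc2$byVisit$stageConsistencyPct, 100)
  expect_equal(lc2$byVisit$ciOverlapPct, 100)
  # regression to an earlier stage violates the stage rule
  earlier <- subjectPosteriors(mk(1, 1), model)
  lc3 <- longitudinalConsistency(base, list(earlier))
  expect_equal(lc3$byVisit$stageConsistencyPct, 0)
  # progressing out of normal appearing is subtype-consistent
  na0 <- subjectPosteriors(matrix(c(0, 0), 1,
                                  dimnames = list("s1", NULL)), model)
  expect_true(normalAppearing(na0))
  lc4 <- longitudinalConsistency(na0, list(subjectPosteriors(mk(3, 2),
                                                             model)))
  expect_equal(lc4$byVisit$subtypeConsistencyPct, 100)
})

test_that("modality ablation: no-op group, full mask, membership oracle", {
  set.seed(19)
  m <- simulateModel(C = 2, I = 4, levels = c(1, 2), zMax = 5)
  sim <- simulateSubjects(m, J = 40)
  groups <- list(none = character(0),
                 mri = biomarkerNames(modelConfig(m))[1:2],
                 all = biomarkerNames(modelConfig(m)))
  ab <- modalityAblation(sim$data, m, groups)
  expect_equal(ab$pctSameSubtype[ab$modality == "none"], 100)
  expect_equal(ab$meanStageDiff[ab$modality == "none"], 0)
  # masking everything collapses the posterior to the prior:
  # every subject's ML subtype is the largest-fraction subtype
  post <- subjectPosteriors(matrix(NA_real_, 40, 4,
                                   dimnames = list(rownames(sim$data),
                                                   NULL)), m)
  expect_true(all(mlSubtype(post) == which.max(fractions(m))))
  # coverage column equals an independent membership loop
  masked <- sim$data; masked[, 1:2] <- NA
  postM <- subjectPosteriors(masked, m)
  full <- subjectPosteriors(sim$data, m)
  cs <- credibleSets(postM, 0.95)
  hits <- 0
  for (j in 1:40) {
    inSet <- FALSE
    for (r in seq_len(nrow(cs[[j]])))
      if (cs[[j]]$subtype[r] == mlSubtype(full)[j] &&
          cs[[j]]$stage[r] == mlStage(full)[j]) inSet <- TRUE
    hits <- hits + inSet
  }
  expect_equal(ab$ciCoveragePct[ab$modality == "mri"], 100 * hits / 40)
  expect_error(modalityAblation(sim$data, m, list(x = "nope")),
               "unknown biomarker")
})

test_that("the benchmark harness emits the expected schema and determinism", {
  strategies <- list(missingStrategy("uniform"), missingStrategy("mean"))
  opts <- sustainOptions(nStartpoints = 2, nSplitStartpoints = 1,
                         nSplitTrials = 1)
  set.seed(23)
  rep1 <- runBenchmark(strategies, missingCounts = 30L, reps = 1,
                       J = 60, I = 3, C = 2, levels = c(1, 2),
                       opts = opts)
  expect_setequal(rep1$strategy, c("full_data", "uniform", "mean"))
  expect_equal(nrow(rep1), 3L)
  expect_true(all(c("kendall_mean", "subtype_accuracy_pct", "staging_mae",
                    "staging_sd", "missing_frac") %in% colnames(rep1)))
  expect_true(all(rep1$kendall_mean >= 0 & rep1$kendall_mean <= 1))
  expect_true(all(rep1$subtype_accuracy_pct >= 0 &
                    rep1$subtype_accuracy_pct <= 100))
  set.seed(23)
  rep2 <- runBenchmark(strategies, missingCounts = 30L, reps = 1,
                       J = 60, I = 3, C = 2, levels = c(1, 2),
                       opts = opts)
  expect_identical(rep1, rep2)
  summ <- summarizeBenchmark(rep1)
  expect_equal(nrow(summ), 3L)
  md <- benchmarkMarkdown(summ)
  expect_equal(length(md), 2L + nrow(summ))
  expect_match(md[1], "^\\| Strategy \\|")
  expect_true(all(grepl("^\\|", md)))
})

test_that("a failed strategy cell is recorded as NA, not an error", {
  # every subject has a missing entry: deletion removes everyone
  x <- matrix(rnorm(30), 10, 3)
  x[cbind(1:10, rep(1:3, length.out = 10))] <- NA
  expect_error(applyStrategy(x, missingStrategy("deletion")),
               "every subject")
  # the harness converts such failures into an NA row
  strategies <- list(missingStrategy("deletion"))
  opts <- sustainOptions(nStartpoints = 1, nSplitStartpoints = 1,
                         nSplitTrials = 1)
  set.seed(29)
  rep1 <- runBenchmark(strategies, missingCounts = 150L, reps = 1,
                       J = 50, I = 3, C = 2, levels = 1, opts = opts)
  del <- rep1[rep1$strategy == "deletion", ]
  expect_true(is.na(del$kendall_mean) || del$n_fit < 50)
})
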