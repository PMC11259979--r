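# helper: marginal log likelihood of a single-sequence model with unit
# weights, used to score candidate orderings independently of the greedy
seqLL <- function(data, ordering, config) {
  totalLogLikelihood(data, subtypeModel(config, ordering, fractions = 1))
}

test_that("a fully forced ordering is returned immediately", {
  cfg <- biomarkerConfig("bm", list(c(1, 2, 3)), zMax = 5)
  set.seed(1)
  x <- matrix(rnorm(20, 1), 20, 1)
  res <- optimizeSequence(x, cfg, opts = sustainOptions(nStartpoints = 2))
  expect_identical(res$ordering, 1:3)
  expect_true(validSequence(res$ordering, cfg))
})

test_that("greedy search equals exhaustive search on small instances", {
  set.seed(7)
  configs <- list(
    tinyConfig(list(1, 1), zMax = c(5, 4)),              # 2 orderings
    tinyConfig(list(c(1, 2), 1), zMax = c(5, 4)),        # 3 orderings
    tinyConfig(list(1, 1, 2), zMax = c(5, 4, 5))         # 6 orderings
  )
  for (cfg in configs) {
    truthOrd <- randomSequence(cfg)
    model <- subtypeModel(cfg, truthOrd, fractions = 1)
    sim <- simulateSubjects(model, J = 50)
    sim$data <- sim$data / 10 + matrix(rnorm(length(sim$data), 0, 0.1),
                                       nrow(sim$data))
    for (rep in 1:2) {
      x <- sim$data + matrix(rnorm(length(sim$data), 0, 0.5),
                             nrow(sim$data))
      all <- naiveAllSequences(cfg)
      lls <- apply(all, 1, function(o) seqLL(x, o, cfg))
      res <- optimizeSequence(x, cfg,
                              opts = sustainOptions(nStartpoints = 3))
      expect_equal(res$logLik, max(lls), tolerance = 1e-10)
    }
  }
})

test_that("greedy with data simulated from a known 2-event order recovers it", {
  set.seed(13)
  cfg <- tinyConfig(list(1, 1), zMax = c(5, 5), sigma = 0.1)
  truthOrd <- c(1L, 2L)
  model <- subtypeModel(cfg, truthOrd, fractions = 1)
  sim <- simulateSubjects(model, J = 50)
  res <- optimizeSequence(sim$data, cfg,
                          opts = sustainOptions(nStartpoints = 4))
  all <- naiveAllSequences(cfg)
  lls <- apply(all, 1, function(o) seqLL(sim$data, o, cfg))
  expect_identical(res$ordering, all[which.max(lls), ])
  expect_identical(res$ordering, truthOrd)
})

test_that("EM with one subtype reduces to plain sequence optimisation", {
  set.seed(17)
  cfg <- tinyConfig(list(c(1, 2), 1), zMax = 5)
  model0 <- subtypeModel(cfg, randomSequence(cfg), fractions = 1)
  x <- matrix(rnorm(40, 1, 2), 20, 2)
  em <- fitEM(x, model0, opts = sustainOptions(nStartpoints = 1))
  expect_equal(fractions(em$model), 1)
  direct <- optimizeSequence(x, cfg, init = sequences(model0)[1, ],
                             opts = sustainOptions(nStartpoints = 1))
  expect_equal(em$logLik, direct$logLik, tolerance = 1e-9)
})

test_that("EM log likelihood is monotone nondecreasing on every run", {
  set.seed(19)
  for (rep in 1:3) {
    m <- simulateModel(C = 2, I = 3, levels = c(1, 2), zMax = 5)
    sim <- simulateSubjects(m, J = 60)
    init <- subtypeModel(modelConfig(m),
                         rbind(randomSequence(modelConfig(m)),
                               randomSequence(modelConfig(m))))
    em <- fitEM(sim$data, init, opts = sustainOptions(nStartpoints = 1))
    expect_true(all(diff(em$trace) >= -1e-8))
  }
})

test_that("EM recovers fractions of a well-separated 2-subtype mixture", {
  set.seed(23)
  cfg <- biomarkerConfig(paste0("bm", 1:5), c(1, 2), zMax = 5,
                         sigma = 0.5)
  repeat {
    s1 <- randomSequence(cfg)
    s2 <- randomSequence(cfg)
    if (sequenceSimilarity(s1, s2) < 0.6) break
  }
  truth <- subtypeModel(cfg, rbind(s1, s2), fractions = c(0.65, 0.35))
  sim <- simulateSubjects(truth, J = 200)
  init <- subtypeModel(cfg, rbind(randomSequence(cfg),
                                  randomSequence(cfg)))
  em <- fitEM(sim$data, init, opts = sustainOptions(nStartpoints = 1))
  f <- sort(fractions(em$model), decreasing = TRUE)
  expect_lt(max(abs(f - c(0.65, 0.35))), 0.1)
})

test_that("hierarchical fitting is likelihood-monotone in C and sized cMax", {
  set.seed(29)
  m <- simulateModel(C = 1, I = 3, levels = c(1, 2), zMax = 5)
  sim <- simulateSubjects(m, J = 80)
  opts <- sustainOptions(nStartpoints = 3, nSplitStartpoints = 2,
                         nSplitTrials = 2, nMCMC = 10)
  fits <- fitSustain(sim$data, modelConfig(m), cMax = 2, opts = opts,
                     mcmc = FALSE)
  expect_length(fits, 2L)
  expect_gte(logLik(fits[[2]]), logLik(fits[[1]]) - 1e-6)
  expect_equal(nSubtypes(fits[[1]]), 1L)
  expect_equal(nSubtypes(fits[[2]]), 2L)
})

test_that("MCMC accepts everything when the data are fully missing", {
  set.seed(31)
  cfg <- tinyConfig(list(c(1, 2), 1), zMax = 5)
  model <- subtypeModel(cfg, randomSequence(cfg), fractions = 1)
  x <- matrix(NA_real_, 5, 2)
  fit <- mcmcUncertainty(x, model, sustainOptions(nMCMC = 500))
  expect_equal(mcmcTrace(fit)$acceptanceRate, 1)
})

test_that("positional variance rows sum to 1; forced order gives identity", {
  set.seed(37)
  cfg <- biomarkerConfig("bm", list(c(1, 2, 3)), zMax = 5)
  model <- subtypeModel(cfg, 1:3, fractions = 1)
  x <- matrix(rnorm(30, 1), 30, 1)
  fit <- mcmcUncertainty(x, model, sustainOptions(nMCMC = 200))
  pv <- positionalVariance(fit)[[1]]
  expect_equal(unname(rowSums(pv)), rep(1, 3))
  expect_equal(unname(pv), diag(3))  # only one valid sequence exists
  # a multi-biomarker model: rows still sum to 1
  m2 <- simulateModel(C = 2, I = 3, levels = c(1, 2), zMax = 5)
  sim <- simulateSubjects(m2, J = 40)
  fit2 <- mcmcUncertainty(sim$data, m2, sustainOptions(nMCMC = 300))
  for (pv2 in positionalVariance(fit2))
    expect_equal(unname(rowSums(pv2)), rep(1, nEvents(m2)))
})

test_that("identical seed, options and data give identical fits", {
  m <- simulateModel(C = 2, I = 3, levels = c(1, 2), zMax = 5)
  set.seed(43)
  sim <- simulateSubjects(m, J = 50)
  opts <- sustainOptions(nStartpoints = 3, nSplitStartpoints = 2,
                         nSplitTrials = 2, nMCMC = 200, seed = 99)
  f1 <- fitSustain(sim$data, modelConfig(m), cMax = 2, opts = opts)
  f2 <- fitSustain(sim$data, modelConfig(m), cMax = 2, opts = opts)
  expect_identical(sequences(mlModel(f1[[2]])),
                   sequences(mlModel(f2[[2]])))
  expect_identical(fractions(mlModel(f1[[2]])),
                   fractions(mlModel(f2[[2]])))
  expect_identical(logLik(f1[[2]]), logLik(f2[[2]]))
  expect_identical(mcmcTrace(f1[[2]])$logLik, mcmcTrace(f2[[2]])$logLik)
  expect_identical(positionalVariance(f1[[2]]),
                   positionalVariance(f2[[2]]))
})

test_that("single-subtype sequence recovery at moderate noise", {
  set.seed(47)
  cfg <- biomarkerConfig(paste0("bm", 1:4), c(1, 2), zMax = 5,
                         sigma = 0.25)
  truthOrd <- randomSequence(cfg)
  truth <- subtypeModel(cfg, truthOrd, fractions = 1)
  sim <- simulateSubjects(truth, J = 300)
  res <- optimizeSequence(sim$data, cfg,
                          opts = sustainOptions(nStartpoints = 5))
  expect_identical(res$ordering, truthOrd)
})
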