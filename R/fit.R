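# Model estimation: greedy multi-start sequence optimisation, EM over
# subtype memberships, hierarchical cluster splitting for C = 1..cMax,
# and Metropolis-Hastings sampling of positional uncertainty.

#' Fitting options
#'
#' @param nStartpoints greedy random restarts for top-level sequence
#'   optimisation.
#' @param nSplitStartpoints restarts used inside cluster-split
#'   initialisation (per half of a split).
#' @param nEMIterMax cap on EM iterations.
#' @param emTol EM stops when the log-likelihood gain falls below this.
#' @param nMCMC Metropolis-Hastings iterations for uncertainty estimation.
#' @param nSplitTrials random bipartitions tried when splitting a cluster.
#' @param fracSd standard deviation of the Gaussian perturbation used as
#'   the mixture-fraction proposal (perturb, clip at 0, renormalise).
#' @param mcmcThin keep every \code{mcmcThin}-th sequence sample;
#'   \code{NULL} stores about 1000 samples.
#' @param maxGreedyPass cap on hill-climb sweeps over the events.
#' @param seed if non-NULL, \code{set.seed} is called at the start of
#'   \code{\link{fitSustain}} so a whole fit is reproducible.
#' @return A named list of options.
#' @export
sustainOptions <- function(nStartpoints = 25L, nSplitStartpoints = 5L,
                           nEMIterMax = 100L, emTol = 1e-6,
                           nMCMC = 1e5, nSplitTrials = 5L,
                           fracSd = 0.01, mcmcThin = NULL,
                           maxGreedyPass = 100L, seed = NULL) {
  stopifnot(nStartpoints >= 1, nSplitStartpoints >= 1, nEMIterMax >= 1,
            emTol > 0, nMCMC >= 1, nSplitTrials >= 1, fracSd > 0,
            maxGreedyPass >= 1)
  list(nStartpoints = as.integer(nStartpoints),
       nSplitStartpoints = as.integer(nSplitStartpoints),
       nEMIterMax = as.integer(nEMIterMax), emTol = emTol,
       nMCMC = as.integer(nMCMC), nSplitTrials = as.integer(nSplitTrials),
       fracSd = fracSd, mcmcThin = mcmcThin,
       maxGreedyPass = as.integer(maxGreedyPass), seed = seed)
}

# weighted marginal log likelihood of one sequence (internal)
.seqLogLik <- function(data, ordering, config, weights, logPrior) {
  ev <- .eventVectors(config)
  .cppSeqLogLik(data, .orderingToPositions(ordering), ev$bio0, ev$z,
                ev$zmax, ev$sigma, ev$logu, logPrior, weights)
}

#' Greedy multi-start sequence optimisation
#'
#' From each of \code{nStartpoints} random valid orderings (plus an
#' optional supplied start), hill-climbs by remove-and-reinsert moves:
#' each event in turn is tried at every reinsertion position that respects
#' within-biomarker level order and moved to the best strictly improving
#' one, sweeping until no move improves the weighted log likelihood.
#'
#' @param data subjects x biomarkers matrix, NA = missing.
#' @param config a \linkS4class{BiomarkerConfig}.
#' @param weights per-subject nonnegative weights (EM responsibilities);
#'   default 1 for every subject.
#' @param opts \code{\link{sustainOptions}}.
#' @param missingMode see \code{\link{observationDensity}}.
#' @param init optional ordering used as the first startpoint.
#' @param stagePrior prior over stages; default uniform.
#' @param nStartpoints overrides \code{opts$nStartpoints}.
#' @return list with \code{ordering} (the best sequence found) and
#'   \code{logLik} (its weighted log likelihood).
#' @export
optimizeSequence <- function(data, config, weights = NULL,
                             opts = sustainOptions(),
                             missingMode = c("uniform", "none"),
                             init = NULL, stagePrior = NULL,
                             nStartpoints = opts$nStartpoints) {
  data <- .checkData(data, config)
  missingMode <- .checkMissingMode(data, missingMode)
  N <- nEvents(config)
  if (is.null(weights)) weights <- rep(1, nrow(data))
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (is.null(stagePrior)) stagePrior <- rep(1 / (N + 1), N + 1)
  logPrior <- log(stagePrior)
  ev <- .eventVectors(config)
  best <- NULL
  for (s in seq_len(nStartpoints)) {
    ord0 <- if (s == 1L && !is.null(init)) as.integer(init)
            else randomSequence(config)
    if (!validSequence(ord0, config)) stop("invalid starting sequence")
    res <- .cppGreedyClimb(data, as.numeric(weights), ord0, ev$bio0, ev$z,
                           ev$zmax, ev$sigma, ev$logu, logPrior,
                           opts$maxGreedyPass)
    if (is.null(best) || res$logLik > best$logLik) best <- res
  }
  list(ordering = as.integer(best$ordering), logLik = best$logLik)
}

# E-step: per-subject per-subtype marginal log likelihood (J x C),
# excluding the fraction factor
.subtypeLogLik <- function(data, model) {
  C <- nSubtypes(model)
  logPrior <- log(model@stagePrior)
  ev <- .eventVectors(model@config)
  a <- matrix(0, nrow(data), C)
  for (c in seq_len(C)) {
    pos <- .orderingToPositions(model@sequences[c, ])
    S <- .cppStageLogLik(data, pos, ev$bio0, ev$z, ev$zmax, ev$sigma,
                         ev$logu)
    a[, c] <- .logSumExpRows(sweep(S, 2L, logPrior, "+"))
  }
  a
}

#' EM over subtype memberships and sequences
#'
#' Alternates (a) responsibilities
#' \eqn{r_{jc} \propto f_c \sum_k P(k) L_c(j,k)}, (b) fraction updates
#' \eqn{f_c \leftarrow \mathrm{mean}_j r_{jc}}, and (c) per-subtype
#' hill-climbing of each sequence under weights \eqn{r_{jc}}, until the
#' log-likelihood gain falls below \code{emTol} or the iteration cap.
#' The log likelihood is nondecreasing across iterations.  If a cluster
#' empties (all responsibilities ~0) its sequence is re-seeded at random
#' with a warning.
#'
#' @param data subjects x biomarkers matrix, NA = missing.
#' @param model initial \linkS4class{SubtypeModel} (defines C).
#' @param opts \code{\link{sustainOptions}}.
#' @param missingMode see \code{\link{observationDensity}}.
#' @return list with \code{model}, \code{logLik} and \code{trace} (the
#'   per-iteration log-likelihood path).
#' @export
fitEM <- function(data, model, opts = sustainOptions(),
                  missingMode = c("uniform", "none")) {
  data <- .checkData(data, model@config)
  missingMode <- .checkMissingMode(data, missingMode)
  validObject(model)
  C <- nSubtypes(model)
  J <- nrow(data)
  logPrior <- log(model@stagePrior)
  trace <- numeric(0)
  llPrev <- -Inf
  for (iter in seq_len(opts$nEMIterMax)) {
    a <- .subtypeLogLik(data, model)
    aw <- sweep(a, 2L, log(model@fractions), "+")
    llRow <- .logSumExpRows(aw)
    ll <- sum(llRow)
    trace <- c(trace, ll)
    if (ll - llPrev < opts$emTol && iter > 1L) break
    llPrev <- ll
    r <- exp(aw - llRow)
    f <- colMeans(r)
    sq <- model@sequences
    for (c in seq_len(C)) {
      if (sum(r[, c]) < 1e-8) {
        warning(sprintf("subtype %d emptied during EM; re-seeding", c))
        sq[c, ] <- randomSequence(model@config)
        f[c] <- 1 / J
        next
      }
      res <- optimizeSequence(data, model@config, weights = r[, c],
                              opts = opts, missingMode = missingMode,
                              init = sq[c, ], stagePrior = model@stagePrior,
                              nStartpoints = 1L)
      sq[c, ] <- res$ordering
    }
    f <- pmax(f, 1e-12)
    f <- f / sum(f)
    model <- subtypeModel(model@config, sq, fractions = f,
                          stagePrior = model@stagePrior)
  }
  aw <- sweep(.subtypeLogLik(data, model), 2L, log(model@fractions), "+")
  ll <- sum(.logSumExpRows(aw))
  if (ll != trace[length(trace)]) trace <- c(trace, ll)
  list(model = model, logLik = ll, trace = trace)
}

# split one cluster's subjects into two nonempty halves at random,
# fit each half's sequence, and refine with a 2-subtype EM on the subset
.splitCluster <- function(dataSub, config, opts, missingMode, stagePrior) {
  J <- nrow(dataSub)
  best <- NULL
  for (trial in seq_len(opts$nSplitTrials)) {
    repeat {
      grp <- runif(J) < 0.5
      if (any(grp) && any(!grp)) break
    }
    s1 <- optimizeSequence(dataSub[grp, , drop = FALSE], config,
                           opts = opts, missingMode = missingMode,
                           stagePrior = stagePrior,
                           nStartpoints = opts$nSplitStartpoints)
    s2 <- optimizeSequence(dataSub[!grp, , drop = FALSE], config,
                           opts = opts, missingMode = missingMode,
                           stagePrior = stagePrior,
                           nStartpoints = opts$nSplitStartpoints)
    init <- subtypeModel(config, rbind(s1$ordering, s2$ordering),
                         fractions = c(mean(grp), mean(!grp)),
                         stagePrior = stagePrior)
    em <- fitEM(dataSub, init, opts = opts, missingMode = missingMode)
    if (is.null(best) || em$logLik > best$logLik) best <- em
  }
  best
}

#' Hierarchical SuStaIn fit for C = 1..cMax subtypes
#'
#' The single-subtype model is fitted by greedy multi-start sequence
#' optimisation.  Each larger model is initialised from the previous one
#' by splitting every cluster in turn (random bipartitions of its
#' ML-assigned subjects, a 2-subtype EM inside the cluster, keeping the
#' best split), then refitted by full EM on all subjects; the best
#' initialisation wins.  Positional uncertainty is estimated by MCMC when
#' \code{mcmc = TRUE}.
#'
#' @param data subjects x biomarkers matrix, NA = missing.
#' @param config a \linkS4class{BiomarkerConfig}.
#' @param cMax largest number of subtypes to fit.
#' @param opts \code{\link{sustainOptions}}.
#' @param missingMode see \code{\link{observationDensity}}.
#' @param mcmc run \code{\link{mcmcUncertainty}} on each fitted model.
#' @return A list of \linkS4class{SustainFit}, element C holding the
#'   C-subtype fit.  Fewer elements (with a warning) if some cluster can
#'   no longer be split.
#' @export
fitSustain <- function(data, config, cMax = 1L, opts = sustainOptions(),
                       missingMode = c("uniform", "none"), mcmc = TRUE) {
  data <- .checkData(data, config)
  missingMode <- .checkMissingMode(data, missingMode)
  if (!is.null(opts$seed)) set.seed(opts$seed)
  N <- nEvents(config)
  stagePrior <- rep(1 / (N + 1), N + 1)
  fits <- vector("list", 0L)
  s1 <- optimizeSequence(data, config, opts = opts,
                         missingMode = missingMode,
                         stagePrior = stagePrior)
  model <- subtypeModel(config, s1$ordering, fractions = 1,
                        stagePrior = stagePrior)
  fits[[1L]] <- .makeFit(data, model, s1$logLik, opts, missingMode, mcmc)
  for (C in seq_len(cMax)[-1L]) {
    prev <- fits[[C - 1L]]@model
    assign <- mlSubtype(subjectPosteriors(data, prev, missingMode))
    bestCand <- NULL
    for (c in seq_len(nSubtypes(prev))) {
      idx <- which(assign == c)
      if (length(idx) < 2L) next
      sp <- .splitCluster(data[idx, , drop = FALSE], config, opts,
                          missingMode, stagePrior)
      sq <- rbind(prev@sequences[-c, , drop = FALSE],
                  sp$model@sequences)
      fprev <- prev@fractions
      f0 <- c(fprev[-c], fprev[c] * sp$model@fractions)
      init <- subtypeModel(config, sq, fractions = f0 / sum(f0),
                           stagePrior = stagePrior)
      em <- fitEM(data, init, opts = opts, missingMode = missingMode)
      if (is.null(bestCand) || em$logLik > bestCand$logLik) bestCand <- em
    }
    if (is.null(bestCand)) {
      warning(sprintf(
        "no cluster of the %d-subtype model could be split; stopping",
        C - 1L))
      break
    }
    fits[[C]] <- .makeFit(data, bestCand$model, bestCand$logLik, opts,
                          missingMode, mcmc)
  }
  fits
}

.makeFit <- function(data, model, logLik, opts, missingMode, mcmc) {
  fit <- new("SustainFit", model = model, logLik = logLik, mcmc = list(),
             positionalVariance = list(), options = opts)
  if (mcmc) fit <- mcmcUncertainty(data, fit, opts, missingMode)
  fit
}

#' Metropolis-Hastings uncertainty estimation
#'
#' Samples event orderings and mixture fractions around a fitted model:
#' each iteration proposes moving one randomly chosen event of one
#' randomly chosen subtype to a random valid position, jointly with a
#' Gaussian perturb-clip-renormalise move on the fractions, accepted with
#' probability \eqn{\min(1, L_{new}/L_{old})} on the total data
#' likelihood.  Returns per-subtype positional frequency matrices (rows =
#' events in config order, columns = positions; rows sum to 1), the
#' likelihood and fraction traces, and thinned sequence samples.  If a
#' sampled state beats the stored ML model, the fit is re-selected to it.
#'
#' @param data subjects x biomarkers matrix, NA = missing.
#' @param fit a \linkS4class{SustainFit} (or \linkS4class{SubtypeModel}).
#' @param opts \code{\link{sustainOptions}}.
#' @param missingMode see \code{\link{observationDensity}}.
#' @return The \linkS4class{SustainFit} with \code{mcmc} and
#'   \code{positionalVariance} slots filled.
#' @export
mcmcUncertainty <- function(data, fit, opts = sustainOptions(),
                            missingMode = c("uniform", "none")) {
  if (is(fit, "SubtypeModel"))
    fit <- new("SustainFit", model = fit,
               logLik = totalLogLikelihood(data, fit, missingMode),
               mcmc = list(), positionalVariance = list(), options = opts)
  model <- fit@model
  data <- .checkData(data, model@config)
  missingMode <- .checkMissingMode(data, missingMode)
  if (opts$nMCMC < 1) stop("nMCMC must be at least 1")
  N <- nEvents(model@config)
  C <- nSubtypes(model)
  ev <- .eventVectors(model@config)
  thin <- opts$mcmcThin
  if (is.null(thin)) thin <- max(1L, as.integer(opts$nMCMC %/% 1000L))
  res <- .cppMCMC(data, model@sequences, model@fractions, ev$bio0, ev$z,
                  ev$zmax, ev$sigma, ev$logu, log(model@stagePrior),
                  opts$nMCMC, opts$fracSd, as.integer(thin))
  et <- eventTable(model@config)
  pv <- lapply(res$posCount, function(m) {
    m <- m / opts$nMCMC
    dimnames(m) <- list(paste0(et$name, "[", et$z, "]"),
                        as.character(seq_len(N)))
    m
  })
  keep <- seq_len(res$nKept)
  samples <- res$seqSamples
  if (res$nKept > 0) samples <- samples[keep, , , drop = FALSE]
  fit@mcmc <- list(logLik = as.numeric(res$logLik),
                   fractions = res$fractions,
                   acceptanceRate = res$accepted / opts$nMCMC,
                   seqSamples = samples, thin = thin)
  fit@positionalVariance <- pv
  if (res$bestLogLik > fit@logLik + 1e-9) {
    fit@model <- subtypeModel(model@config, res$bestOrderings,
                              fractions = res$bestFractions,
                              stagePrior = model@stagePrior)
    fit@logLik <- res$bestLogLik
  }
  fit
}
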