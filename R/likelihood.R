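# Data likelihood of the Z-score event-sequence model.  A subject at
# model timeline coordinate t has biomarker i distributed Normal(g_i(t),
# sigma_i) where g_i is the piecewise-linear trajectory through the
# biomarker's events; a missing observation contributes the constant
# uniform density 1/zMax_i instead, so it is inert in the posterior.
# Stage k occupies [k, k+1] on the [0, N+1] timeline and its integral is
# approximated by a midpoint evaluation at t = k + 0.5.

# validate a subjects-x-biomarkers matrix against a config
.checkData <- function(data, config) {
  if (!is.matrix(data)) data <- as.matrix(data)
  if (!is.numeric(data)) stop("data must be a numeric matrix")
  if (ncol(data) != nBiomarkers(config))
    stop(sprintf("data has %d columns but config has %d biomarkers",
                 ncol(data), nBiomarkers(config)))
  if (any(is.infinite(data)))
    stop("observed values must be finite (use NA for missing)")
  if (is.null(rownames(data)) && nrow(data) > 0)
    rownames(data) <- as.character(seq_len(nrow(data)))
  data
}

.checkMissingMode <- function(data, missingMode) {
  missingMode <- match.arg(missingMode, c("uniform", "none"))
  if (missingMode == "none" && anyNA(data))
    stop("data contain missing values but missingMode is 'none'; ",
         "apply a missing-data strategy first or use 'uniform'")
  missingMode
}

#' Piecewise-linear trajectory value
#'
#' Evaluates \eqn{g_i(t)}: the linear interpolation through the anchor
#' (0, 0), each of biomarker \eqn{i}'s events at its sequence position,
#' and the anchor \eqn{(N+1, z_{max})}.
#'
#' @param ordering integer event ordering (see \code{\link{eventTable}}).
#' @param config a \linkS4class{BiomarkerConfig}.
#' @param biomarker biomarker index or name.
#' @param t timeline coordinate(s) in \code{[0, N+1]}.
#' @return Numeric vector of trajectory values, nondecreasing in \code{t}.
#' @examples
#' cfg <- biomarkerConfig("bm", list(c(1, 2, 3)), zMax = 5)
#' trajectoryValue(1:3, cfg, "bm", c(0, 1.5, 4))
#' @export
trajectoryValue <- function(ordering, config, biomarker, t) {
  if (!validSequence(ordering, config)) stop("invalid event ordering")
  if (is.character(biomarker))
    biomarker <- match(biomarker, config@names)
  if (is.na(biomarker) || biomarker < 1 ||
      biomarker > nBiomarkers(config))
    stop("unknown biomarker")
  N <- nEvents(config)
  if (any(t < 0 | t > N + 1)) stop("t must lie in [0, N+1]")
  et <- eventTable(config)
  positions <- .orderingToPositions(ordering)
  ev <- which(et$biomarker == biomarker)
  p <- positions[ev]
  o <- order(p)
  xs <- c(0, p[o], N + 1)
  ys <- c(0, et$z[ev][o], config@zMax[biomarker])
  approx(xs, ys, xout = t, method = "linear", ties = "ordered")$y
}

#' Observation density under the trajectory model
#'
#' \eqn{P(x_{ij} \mid t)}: the normal density around \eqn{g_i(t)} for an
#' observed value, or the constant \eqn{1/z_{max,i}} for a missing value
#' under the uniform missing-data model.
#'
#' @param x observed Z-score, or NA for missing.
#' @param biomarker biomarker index or name.
#' @param t timeline coordinate(s).
#' @param ordering integer event ordering.
#' @param config a \linkS4class{BiomarkerConfig}.
#' @param missingMode \code{"uniform"} marginalises missing values with the
#'   uniform density; \code{"none"} treats a missing value as a contract
#'   violation (for use after deletion or imputation).
#' @return Density value(s), one per element of \code{t}.
#' @export
observationDensity <- function(x, biomarker, t, ordering, config,
                               missingMode = c("uniform", "none")) {
  missingMode <- match.arg(missingMode)
  if (is.character(biomarker)) biomarker <- match(biomarker, config@names)
  if (is.na(biomarker) || biomarker < 1 || biomarker > nBiomarkers(config))
    stop("unknown biomarker")
  if (is.na(x)) {
    if (missingMode == "none")
      stop("missing value under missingMode 'none'")
    return(rep(1 / config@zMax[biomarker], length(t)))
  }
  g <- trajectoryValue(ordering, config, biomarker, t)
  dnorm(x, mean = g, sd = config@sigma[biomarker])
}

#' Per-stage marginal likelihoods for one sequence
#'
#' Entry \eqn{(j, k)} approximates the stage-\eqn{k} integral of
#' \eqn{\prod_i P(x_{ij} \mid t)} over \eqn{t \in [k, k+1]} (midpoint
#' quadrature, interval width 1), excluding the stage-prior factor.
#'
#' @param data subjects x biomarkers numeric matrix, NA = missing.
#' @param ordering integer event ordering.
#' @param config a \linkS4class{BiomarkerConfig}.
#' @param missingMode see \code{\link{observationDensity}}.
#' @param log return log likelihoods instead of natural scale.
#' @return Numeric matrix, subjects x stages \code{0..N}.
#' @export
stageLikelihoods <- function(data, ordering, config,
                             missingMode = c("uniform", "none"),
                             log = FALSE) {
  data <- .checkData(data, config)
  missingMode <- .checkMissingMode(data, missingMode)
  if (!validSequence(ordering, config)) stop("invalid event ordering")
  N <- nEvents(config)
  if (nrow(data) == 0L) {
    out <- matrix(numeric(0), 0L, N + 1L)
    colnames(out) <- as.character(0:N)
    return(out)
  }
  ev <- .eventVectors(config)
  S <- .cppStageLogLik(data, .orderingToPositions(ordering), ev$bio0,
                       ev$z, ev$zmax, ev$sigma, ev$logu)
  dimnames(S) <- list(rownames(data), as.character(0:N))
  if (log) S else exp(S)
}

# log-sum-exp over the last dimension of a matrix, rowwise
.logSumExpRows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Total data log likelihood of a subtype model
#'
#' \eqn{\log \prod_j \sum_c f_c \sum_k P(k) \, L_c(j, k)} where
#' \eqn{L_c(j, k)} are the per-stage marginal likelihoods of subtype
#' \eqn{c}'s sequence.  Accumulated in log space.
#'
#' @param data subjects x biomarkers numeric matrix, NA = missing.
#' @param model a \linkS4class{SubtypeModel}.
#' @param missingMode see \code{\link{observationDensity}}.
#' @return Log likelihood in nats.
#' @export
totalLogLikelihood <- function(data, model,
                               missingMode = c("uniform", "none")) {
  data <- .checkData(data, model@config)
  missingMode <- .checkMissingMode(data, missingMode)
  validObject(model)
  if (nrow(data) == 0L) return(0)
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
  sum(.logSumExpRows(sweep(a, 2L, log(model@fractions), "+")))
}

#' Posterior subtype and stage probabilities per subject
#'
#' For each subject the joint table proportional to
#' \eqn{f_c \, P(k) \, L_c(j, k)}, normalised to sum to 1, with
#' maximum-likelihood (subtype, stage) assignments taken over the joint
#' table (ties resolved to the lowest subtype, then lowest stage).
#' Subjects whose ML stage is 0 are flagged normal appearing.
#'
#' @inheritParams totalLogLikelihood
#' @return A \linkS4class{SubjectPosteriors}.
#' @export
subjectPosteriors <- function(data, model,
                              missingMode = c("uniform", "none")) {
  data <- .checkData(data, model@config)
  missingMode <- .checkMissingMode(data, missingMode)
  validObject(model)
  C <- nSubtypes(model)
  N <- nEvents(model@config)
  J <- nrow(data)
  logPrior <- log(model@stagePrior)
  logf <- log(model@fractions)
  ev <- .eventVectors(model@config)
  logJoint <- array(0, dim = c(J, C, N + 1L))
  for (c in seq_len(C)) {
    pos <- .orderingToPositions(model@sequences[c, ])
    S <- .cppStageLogLik(data, pos, ev$bio0, ev$z, ev$zmax, ev$sigma,
                         ev$logu)
    logJoint[, c, ] <- sweep(S, 2L, logPrior, "+") + logf[c]
  }
  prob <- array(0, dim = dim(logJoint))
  mlSub <- integer(J)
  mlStg <- integer(J)
  for (j in seq_len(J)) {
    tab <- logJoint[j, , , drop = FALSE]
    dim(tab) <- c(C, N + 1L)
    m <- max(tab)
    p <- exp(tab - m)
    p <- p / sum(p)
    prob[j, , ] <- p
    # ML over the joint table; lowest subtype then lowest stage on ties
    best <- which(p == max(p), arr.ind = TRUE)
    best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE]
    mlSub[j] <- best[1L, 1L]
    mlStg[j] <- best[1L, 2L] - 1L
  }
  new("SubjectPosteriors", prob = prob,
      subjectIds = if (J > 0) rownames(data) else character(0),
      mlSubtype = mlSub, mlStage = mlStg,
      normalAppearing = mlStg == 0L)
}

#' Smallest credible set of (subtype, stage) cells
#'
#' Cells are taken in decreasing probability order until the cumulative
#' probability reaches \code{mass}; equal probabilities are ordered by
#' subtype then stage index, making the set deterministic and of minimal
#' size.
#'
#' @param prob a normalised subtypes x stages probability matrix (one
#'   subject's posterior table).
#' @param mass target cumulative probability in (0, 1].
#' @return A data.frame with columns \code{subtype}, \code{stage} (0-based)
#'   and \code{prob}, in decreasing probability order.
#' @export
credibleSet <- function(prob, mass = 0.95) {
  if (!is.matrix(prob)) stop("prob must be a subtypes x stages matrix")
  if (!is.numeric(mass) || length(mass) != 1L || mass <= 0 || mass > 1)
    stop("mass must lie in (0, 1]")
  idx <- expand.grid(subtype = seq_len(nrow(prob)),
                     stage = seq_len(ncol(prob)) - 1L)
  p <- as.vector(prob)
  o <- order(-p, idx$subtype, idx$stage)
  cs <- cumsum(p[o])
  m <- which(cs >= mass - 1e-12)[1L]
  if (is.na(m)) m <- length(o)
  keep <- o[seq_len(m)]
  data.frame(subtype = idx$subtype[keep], stage = idx$stage[keep],
             prob = p[keep])
}

#' Credible sets for every subject of a posterior object
#'
#' @param post a \linkS4class{SubjectPosteriors}.
#' @param mass target cumulative probability.
#' @return A list of per-subject credible-set data.frames
#'   (see \code{\link{credibleSet}}).
#' @export
credibleSets <- function(post, mass = 0.95) {
  d <- dim(post@prob)
  lapply(seq_len(d[1L]), function(j) {
    tab <- post@prob[j, , , drop = FALSE]
    dim(tab) <- d[2:3]
    credibleSet(tab, mass)
  })
}
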