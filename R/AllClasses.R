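#' Per-biomarker Z-score event configuration
#'
#' Describes the event grid of the piecewise-linear Z-score progression
#' model: for each biomarker, the increasing Z-score thresholds at which
#' events occur, the trajectory ceiling \code{zMax}, and the observation
#' noise \code{sigma}.  The total number of model events is
#' \eqn{N = \sum_i R_i} where \eqn{R_i} is the number of levels of
#' biomarker \eqn{i}; the model timeline is \eqn{[0, N+1]} with one stage
#' per event plus stage 0.
#'
#' @slot names character vector of biomarker identifiers.
#' @slot eventLevels list of increasing numeric Z-score thresholds, one
#'   vector per biomarker; all levels must lie strictly between 0 and the
#'   biomarker's \code{zMax}.
#' @slot zMax numeric vector of trajectory ceilings (Z units).
#' @slot sigma numeric vector of observation noise standard deviations
#'   (Z units).
#' @export
setClass("BiomarkerConfig",
  representation(names = "character", eventLevels = "list",
                 zMax = "numeric", sigma = "numeric"))

setValidity("BiomarkerConfig", function(object) {
  msg <- character()
  I <- length(object@names)
  if (I < 1L) msg <- c(msg, "at least one biomarker is required")
  if (anyDuplicated(object@names))
    msg <- c(msg, "biomarker names must be unique")
  if (length(object@eventLevels) != I || length(object@zMax) != I ||
      length(object@sigma) != I)
    msg <- c(msg, "eventLevels, zMax and sigma must match names in length")
  else {
    if (any(object@zMax <= 0)) msg <- c(msg, "zMax must be positive")
    if (any(object@sigma <= 0)) msg <- c(msg, "sigma must be positive")
    for (i in seq_len(I)) {
      lv <- object@eventLevels[[i]]
      if (length(lv) < 1L)
        msg <- c(msg, sprintf("biomarker '%s' has no event levels",
                              object@names[i]))
      else {
        if (any(diff(lv) <= 0))
          msg <- c(msg, sprintf(
            "event levels of '%s' must be strictly increasing",
            object@names[i]))
        if (any(lv <= 0) || any(lv >= object@zMax[i]))
          msg <- c(msg, sprintf(
            "event levels of '%s' must lie in (0, zMax)", object@names[i]))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a biomarker configuration
#'
#' @param names character vector of biomarker identifiers.
#' @param eventLevels numeric vector (recycled to every biomarker) or list
#'   of per-biomarker increasing Z-score thresholds.
#' @param zMax trajectory ceiling(s), recycled across biomarkers.
#' @param sigma observation noise standard deviation(s), recycled across
#'   biomarkers.  Defaults to 1: the data are control-referenced Z-scores.
#' @return A \linkS4class{BiomarkerConfig}.
#' @examples
#' cfg <- biomarkerConfig(paste0("bm", 1:3), c(1, 2, 3), zMax = 5)
#' nEvents(cfg)
#' @export
biomarkerConfig <- function(names, eventLevels, zMax, sigma = 1) {
  I <- length(names)
  if (!is.list(eventLevels)) eventLevels <- rep(list(eventLevels), I)
  new("BiomarkerConfig", names = as.character(names),
      eventLevels = lapply(eventLevels, as.numeric),
      zMax = rep_len(as.numeric(zMax), I),
      sigma = rep_len(as.numeric(sigma), I))
}

#' Mixture of ordered event sequences
#'
#' A fitted or generating SuStaIn model: \code{C} subtype event sequences
#' over a shared \linkS4class{BiomarkerConfig}, mixture fractions
#' \eqn{f_c}, and a prior over the \eqn{N+1} model stages.  Each sequence
#' is stored as a permutation of the config's event indices (see
#' \code{\link{eventTable}}); position \eqn{p} on the timeline holds the
#' event at column \eqn{p}.
#'
#' @slot config the shared \linkS4class{BiomarkerConfig}.
#' @slot sequences integer matrix, one row per subtype, row \eqn{c} a
#'   permutation of \code{seq_len(nEvents(config))}.
#' @slot fractions numeric mixture weights summing to 1.
#' @slot stagePrior numeric prior over stages \code{0..N} summing to 1.
#' @export
setClass("SubtypeModel",
  representation(config = "BiomarkerConfig", sequences = "matrix",
                 fractions = "numeric", stagePrior = "numeric"))

setValidity("SubtypeModel", function(object) {
  msg <- character()
  N <- nEvents(object@config)
  sq <- object@sequences
  if (!is.numeric(sq) || ncol(sq) != N)
    msg <- c(msg, sprintf("sequences must have %d columns", N))
  else {
    for (c in seq_len(nrow(sq)))
      if (!validSequence(sq[c, ], object@config))
        msg <- c(msg, sprintf("row %d is not a valid event sequence", c))
  }
  if (length(object@fractions) != nrow(sq))
    msg <- c(msg, "one fraction per sequence required")
  if (any(object@fractions < 0) ||
      abs(sum(object@fractions) - 1) > 1e-9)
    msg <- c(msg, "fractions must be nonnegative and sum to 1")
  if (length(object@stagePrior) != N + 1L)
    msg <- c(msg, sprintf("stagePrior must have length %d", N + 1L))
  else if (any(object@stagePrior < 0) ||
           abs(sum(object@stagePrior) - 1) > 1e-9)
    msg <- c(msg, "stagePrior must be nonnegative and sum to 1")
  if (length(msg)) msg else TRUE
})

#' Construct a subtype model
#'
#' @param config a \linkS4class{BiomarkerConfig}.
#' @param sequences integer matrix (subtypes x events) of event orderings,
#'   or a single integer vector for a one-subtype model.
#' @param fractions mixture fractions; default uniform over subtypes.
#' @param stagePrior prior over stages \code{0..N}; default uniform
#'   \code{1/(N+1)}.
#' @return A \linkS4class{SubtypeModel}.
#' @export
subtypeModel <- function(config, sequences, fractions = NULL,
                         stagePrior = NULL) {
  if (is.vector(sequences)) sequences <- matrix(sequences, nrow = 1L)
  sequences <- matrix(as.integer(sequences), nrow = nrow(sequences))
  C <- nrow(sequences)
  N <- nEvents(config)
  if (is.null(fractions)) fractions <- rep(1 / C, C)
  if (is.null(stagePrior)) stagePrior <- rep(1 / (N + 1), N + 1)
  new("SubtypeModel", config = config, sequences = sequences,
      fractions = as.numeric(fractions),
      stagePrior = as.numeric(stagePrior))
}

#' Per-subject posteriors over subtype and stage
#'
#' Joint posterior tables \eqn{P(c, k \mid x_j)} for each subject, with
#' maximum-likelihood assignments.  Subjects whose ML stage is 0 are
#' flagged "normal appearing": they show no detectable abnormality and are
#' not subtypable.
#'
#' @slot prob numeric array subjects x subtypes x stages (stage dimension
#'   indexes stages \code{0..N}); each subject's table sums to 1.
#' @slot subjectIds character subject identifiers.
#' @slot mlSubtype integer ML subtype per subject (ties: lowest index).
#' @slot mlStage integer ML stage per subject, in \code{0..N}.
#' @slot normalAppearing logical, TRUE where ML stage is 0.
#' @export
setClass("SubjectPosteriors",
  representation(prob = "array", subjectIds = "character",
                 mlSubtype = "integer", mlStage = "integer",
                 normalAppearing = "logical"))

setValidity("SubjectPosteriors", function(object) {
  d <- dim(object@prob)
  J <- d[1L]
  if (length(object@subjectIds) != J || length(object@mlSubtype) != J ||
      length(object@mlStage) != J || length(object@normalAppearing) != J)
    return("per-subject slots must match the first dimension of prob")
  if (J > 0) {
    sums <- apply(object@prob, 1L, sum)
    if (any(abs(sums - 1) > 1e-6))
      return("each subject's posterior table must sum to 1")
  }
  TRUE
})

#' A fitted SuStaIn model with uncertainty
#'
#' @slot model the maximum-likelihood \linkS4class{SubtypeModel}.
#' @slot logLik total data log likelihood at the ML model (nats).
#' @slot mcmc list with elements \code{logLik} (trace), \code{fractions}
#'   (iterations x subtypes), \code{acceptanceRate}, and \code{seqSamples}
#'   (thinned sequence draws, samples x subtypes x positions); empty list
#'   if MCMC was not run.
#' @slot positionalVariance list of per-subtype event-by-position
#'   frequency matrices (rows = events in config order, columns = timeline
#'   positions); rows sum to 1.
#' @slot options the \code{\link{sustainOptions}} used for the fit.
#' @export
setClass("SustainFit",
  representation(model = "SubtypeModel", logLik = "numeric",
                 mcmc = "list", positionalVariance = "list",
                 options = "list"))
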