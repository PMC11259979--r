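# Synthetic-data generator: ground-truth subtype/stage/sequence structure
# and biomarker matrices matching the benchmark design (500 subjects, 10
# biomarkers, 3 subtypes with fractions 4/9, 3/9, 2/9, event levels
# (1,2,3) with ceiling 5, unit noise, uniform stages, MCAR missingness).

#' Benchmark mixture fractions
#'
#' \eqn{f_c = (2 + (C - c)) / (2C + \sum_{c'}(C - c'))}; for three
#' subtypes this gives (4/9, 3/9, 2/9).
#'
#' @param C number of subtypes.
#' @return Numeric vector of fractions summing to 1.
#' @export
subtypeFractions <- function(C) {
  stopifnot(C >= 1)
  c <- seq_len(C)
  (2 + (C - c)) / (2 * C + sum(C - c))
}

#' Simulate a generating subtype model
#'
#' Draws an independent uniform-random valid event ordering per subtype
#' over \code{I} biomarkers sharing the given event levels and ceiling,
#' with identity noise structure (independent unit-variance biomarkers by
#' default) and the benchmark mixture fractions.
#'
#' @param C subtype count.
#' @param I biomarker count.
#' @param levels Z-score event levels shared by every biomarker.
#' @param zMax trajectory ceiling shared by every biomarker.
#' @param sigma observation noise standard deviation.
#' @return A \linkS4class{SubtypeModel}.
#' @export
simulateModel <- function(C = 3L, I = 10L, levels = c(1, 2, 3), zMax = 5,
                          sigma = 1) {
  stopifnot(C >= 1, I >= 1)
  config <- biomarkerConfig(sprintf("bm%02d", seq_len(I)), levels,
                            zMax = zMax, sigma = sigma)
  sequences <- t(vapply(seq_len(C), function(c) randomSequence(config),
                        integer(nEvents(config))))
  subtypeModel(config, sequences, fractions = subtypeFractions(C))
}

#' Simulate subjects from a subtype model
#'
#' Each subject draws a subtype with probabilities \eqn{f_c} and a stage
#' uniformly on \code{0..N}; observations are
#' \eqn{x_{ij} = g_i(t) + \epsilon}, \eqn{\epsilon \sim N(0, \sigma_i)},
#' with \eqn{t} the stage midpoint \eqn{k + 0.5} (the same timepoint the
#' likelihood quadrature uses) or, with \code{continuousTime = TRUE}, a
#' uniform draw within the stage interval.
#'
#' @param model a generating \linkS4class{SubtypeModel}.
#' @param J number of subjects.
#' @param continuousTime sample t uniformly within each stage instead of
#'   at its midpoint.
#' @return list with \code{data} (J x I matrix, fully observed),
#'   \code{subtype} and \code{stage} (ground-truth labels), and
#'   \code{model}.
#' @export
simulateSubjects <- function(model, J = 500L, continuousTime = FALSE) {
  stopifnot(J >= 1)
  validObject(model)
  config <- model@config
  N <- nEvents(config)
  I <- nBiomarkers(config)
  C <- nSubtypes(model)
  subtype <- sample.int(C, J, replace = TRUE, prob = model@fractions)
  stage <- sample.int(N + 1L, J, replace = TRUE) - 1L
  ev <- .eventVectors(config)
  # trajectory values at the N+1 stage midpoints, per subtype
  G <- lapply(seq_len(C), function(c)
    .cppTrajMatrix(.orderingToPositions(model@sequences[c, ]), ev$bio0,
                   ev$z, ev$zmax))
  data <- matrix(0, J, I,
                 dimnames = list(sprintf("subj%04d", seq_len(J)),
                                 config@names))
  for (j in seq_len(J)) {
    if (continuousTime) {
      t <- stage[j] + runif(1)
      g <- vapply(seq_len(I), function(i)
        trajectoryValue(model@sequences[subtype[j], ], config, i, t),
        numeric(1))
    } else {
      g <- G[[subtype[j]]][, stage[j] + 1L]
    }
    data[j, ] <- g + rnorm(I, 0, config@sigma)
  }
  list(data = data, subtype = subtype, stage = stage, model = model)
}

#' Delete cells completely at random
#'
#' Exactly \code{nMissing} distinct cells, chosen uniformly without
#' replacement over the whole matrix, are set to NA; all other values are
#' preserved.
#'
#' @param data subjects x biomarkers matrix.
#' @param nMissing number of cells to delete, in \code{0..(J*I)}.
#' @return The matrix with \code{nMissing} additional NA cells.
#' @export
injectMissingness <- function(data, nMissing) {
  total <- length(data)
  if (nMissing < 0 || nMissing > total)
    stop("nMissing must lie in [0, J*I]")
  if (nMissing == 0L) return(data)
  cells <- sample.int(total, nMissing)
  data[cells] <- NA_real_
  data
}
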