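# The four benchmarked missing-data strategies.  "uniform" is the
# model-side approach (missing entries marginalised with a uniform
# density) and leaves the data untouched; the other three are data
# transforms that produce a complete matrix for a standard fit.

#' Specify a missing-data handling strategy
#'
#' @param kind one of \code{"uniform"} (marginalise missing entries in the
#'   likelihood; the data pass through unchanged), \code{"deletion"}
#'   (drop every subject with any missing biomarker), \code{"mean"}
#'   (column-mean imputation) or \code{"knn"} (K-nearest-neighbour
#'   imputation).
#' @param knnK neighbour count for \code{"knn"}.
#' @param knnFeatures neighbour feature space for \code{"knn"}:
#'   \code{"summary_stats"} compares subjects by the (mean, range, sd) of
#'   their observed values; \code{"zscored"} compares the Z-score rows
#'   directly over pairwise-complete coordinates.
#' @return A list of class \code{"missingStrategy"}.
#' @export
missingStrategy <- function(kind = c("uniform", "deletion", "mean", "knn"),
                            knnK = 5L,
                            knnFeatures = c("summary_stats", "zscored")) {
  kind <- match.arg(kind)
  knnFeatures <- match.arg(knnFeatures)
  if (kind == "knn" && knnK < 1) stop("knnK must be at least 1")
  structure(list(kind = kind, knnK = as.integer(knnK),
                 knnFeatures = knnFeatures), class = "missingStrategy")
}

#' Apply a missing-data strategy to a data matrix
#'
#' @param data subjects x biomarkers matrix, NA = missing.
#' @param strategy a \code{\link{missingStrategy}}.
#' @return list with \code{data} (the transformed matrix), \code{kept}
#'   (row indices retained; all rows except under deletion) and
#'   \code{missingMode} (\code{"uniform"} for the uniform strategy,
#'   \code{"none"} otherwise) to pass to the fitting functions.
#' @export
applyStrategy <- function(data, strategy) {
  stopifnot(inherits(strategy, "missingStrategy"))
  if (!is.matrix(data) || !is.numeric(data))
    stop("data must be a numeric matrix")
  switch(strategy$kind,
    uniform = list(data = data, kept = seq_len(nrow(data)),
                   missingMode = "uniform"),
    deletion = {
      kept <- which(complete.cases(data))
      if (length(kept) == 0L)
        stop("deletion removed every subject")
      list(data = data[kept, , drop = FALSE], kept = kept,
           missingMode = "none")
    },
    mean = {
      out <- data
      for (i in seq_len(ncol(data))) {
        obs <- !is.na(data[, i])
        if (!any(obs))
          stop(sprintf("column %d has no observed values to impute from", i))
        out[!obs, i] <- mean(data[obs, i])
      }
      list(data = out, kept = seq_len(nrow(data)), missingMode = "none")
    },
    knn = list(data = knnImpute(data, strategy$knnK, strategy$knnFeatures),
               kept = seq_len(nrow(data)), missingMode = "none"))
}

#' K-nearest-neighbour imputation
#'
#' Each missing cell \eqn{(j, i)} is replaced by the mean of biomarker
#' \eqn{i} over the \eqn{k} subjects nearest to subject \eqn{j} among
#' those with biomarker \eqn{i} observed.  Distances are Euclidean in the
#' chosen feature space; all lookups read the original (pre-imputation)
#' matrix, so the order in which cells are visited cannot matter.
#'
#' Feature spaces: \code{"summary_stats"} represents each subject by the
#' mean, range and standard deviation of its observed values (range and
#' sd are 0 for a single observed value); \code{"zscored"} uses the raw
#' Z-score rows, with distances over the coordinates observed in both
#' subjects scaled by \eqn{\sqrt{I / n_{shared}}} so that pairs with
#' different overlap are comparable.  Distance ties are broken towards
#' the lower subject index.
#'
#' @param data subjects x biomarkers matrix, NA = missing.
#' @param k neighbour count; if fewer neighbours are eligible for a cell,
#'   all eligible ones are used with a warning.
#' @param features \code{"summary_stats"} or \code{"zscored"}.
#' @return The matrix with every NA imputed.
#' @export
knnImpute <- function(data, k = 5L,
                      features = c("summary_stats", "zscored")) {
  features <- match.arg(features)
  if (k < 1) stop("k must be at least 1")
  J <- nrow(data)
  I <- ncol(data)
  out <- data
  obs <- !is.na(data)
  if (any(colSums(obs) == 0L))
    stop("a biomarker with no observed values cannot be imputed")
  feat <- NULL
  if (features == "summary_stats") {
    feat <- t(vapply(seq_len(J), function(j) {
      v <- data[j, obs[j, ]]
      if (length(v) == 0L) return(c(NA_real_, NA_real_, NA_real_))
      c(mean(v), diff(range(v)), if (length(v) > 1L) sd(v) else 0)
    }, numeric(3)))
  }
  missCells <- which(!obs, arr.ind = TRUE)
  # row-major over missing cells; reads are from the original matrix
  missCells <- missCells[order(missCells[, 1L], missCells[, 2L]), ,
                         drop = FALSE]
  for (r in seq_len(nrow(missCells))) {
    j <- missCells[r, 1L]
    i <- missCells[r, 2L]
    eligible <- setdiff(which(obs[, i]), j)
    if (features == "summary_stats") {
      if (anyNA(feat[j, ])) {
        warning(sprintf(
          "subject %d has no observed values; using the column mean", j))
        out[j, i] <- mean(data[eligible, i])
        next
      }
      ok <- eligible[!is.na(feat[eligible, 1L])]
      d <- sqrt(colSums((t(feat[ok, , drop = FALSE]) - feat[j, ])^2))
    } else {
      ok <- eligible
      d <- vapply(ok, function(jj) {
        shared <- obs[j, ] & obs[jj, ]
        n <- sum(shared)
        if (n == 0L) return(Inf)
        sqrt(sum((data[j, shared] - data[jj, shared])^2) * I / n)
      }, numeric(1))
    }
    if (length(ok) == 0L)
      stop(sprintf("no eligible neighbour for subject %d biomarker %d",
                   j, i))
    kUse <- k
    if (length(ok) < k) {
      warning(sprintf(
        "only %d eligible neighbours (< k = %d) for subject %d biomarker %d",
        length(ok), k, j, i))
      kUse <- length(ok)
    }
    nn <- ok[order(d, ok)][seq_len(kUse)]
    out[j, i] <- mean(data[nn, i])
  }
  out
}
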