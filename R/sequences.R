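# Event sequences are permutations of the config's event indices (see
# eventTable()); validity requires each biomarker's events to appear in
# increasing level order, so that the trajectory is monotone.

#' Check an event ordering for validity
#'
#' @param ordering integer vector giving the event index at each timeline
#'   position \code{1..N}.
#' @param config the \linkS4class{BiomarkerConfig} the events refer to.
#' @return TRUE if \code{ordering} is a permutation of all events with
#'   every biomarker's events in increasing level order.
#' @export
validSequence <- function(ordering, config) {
  N <- nEvents(config)
  ordering <- as.integer(ordering)
  if (length(ordering) != N || anyNA(ordering) ||
      !setequal(ordering, seq_len(N)))
    return(FALSE)
  et <- eventTable(config)
  for (i in seq_len(nBiomarkers(config))) {
    lv <- et$level[ordering][et$biomarker[ordering] == i]
    if (is.unsorted(lv, strictly = TRUE)) return(FALSE)
  }
  TRUE
}

#' Draw a uniformly random valid event ordering
#'
#' Samples a uniform permutation of the events and then sorts each
#' biomarker's events into level order within the positions they occupy,
#' which yields a uniform draw over valid orderings.
#'
#' @param config a \linkS4class{BiomarkerConfig}.
#' @return An integer ordering (event index per position).
#' @export
randomSequence <- function(config) {
  et <- eventTable(config)
  N <- nEvents(config)
  ordering <- sample.int(N)
  for (i in seq_len(nBiomarkers(config))) {
    at <- which(et$biomarker[ordering] == i)
    ordering[at] <- et$event[et$biomarker == i]
  }
  ordering
}

#' Enumerate all valid event orderings
#'
#' Intended for small configurations (the count grows as the multinomial
#' coefficient \eqn{N! / \prod_i R_i!}).
#'
#' @param config a \linkS4class{BiomarkerConfig}.
#' @param limit abort if more than this many orderings exist.
#' @return A matrix with one valid ordering per row.
#' @export
allSequences <- function(config, limit = 1e5) {
  et <- eventTable(config)
  N <- nEvents(config)
  R <- lengths(config@eventLevels)
  count <- exp(lgamma(N + 1) - sum(lgamma(R + 1)))
  if (count > limit || factorial(N) > 1e6)
    stop("too many valid orderings to enumerate (", format(count), ")")
  # assign biomarker labels to positions in all distinct ways, then place
  # each biomarker's events in level order
  slots <- rep(seq_along(R), R)
  perms <- unique(.permutations(slots))
  out <- matrix(0L, nrow(perms), N)
  for (r in seq_len(nrow(perms))) {
    ordering <- integer(N)
    for (i in seq_along(R))
      ordering[perms[r, ] == i] <- et$event[et$biomarker == i]
    out[r, ] <- ordering
  }
  out
}

# all permutations of a (possibly multiset) vector, as rows
.permutations <- function(x) {
  n <- length(x)
  if (n == 1L) return(matrix(x, 1L, 1L))
  out <- NULL
  for (i in seq_len(n)) {
    rest <- .permutations(x[-i])
    out <- rbind(out, cbind(x[i], rest))
  }
  out
}

# positions[e] = timeline position of event e
.orderingToPositions <- function(ordering) {
  positions <- integer(length(ordering))
  positions[ordering] <- seq_along(ordering)
  positions
}

# internal: flat event attribute vectors for the C++ kernels
.eventVectors <- function(config) {
  et <- eventTable(config)
  list(bio0 = as.integer(et$biomarker - 1L), z = as.numeric(et$z),
       zmax = as.numeric(config@zMax), sigma = as.numeric(config@sigma),
       logu = -log(as.numeric(config@zMax)))
}
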