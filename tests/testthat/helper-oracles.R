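# Independent reference implementations used as oracles: deliberately
# naive (explicit loops, natural-scale products) and sharing no code with
# the package internals.

# piecewise-linear trajectory by explicit segment search
naiveTrajectory <- function(ordering, config, i, t) {
  et <- eventTable(config)
  N <- nrow(et)
  pos <- integer(N)
  pos[ordering] <- seq_len(N)
  mine <- which(et$biomarker == i)
  xs <- c(0, sort(pos[mine]), N + 1)
  ys <- c(0, et$z[mine][order(pos[mine])], zMax(config)[[i]])
  sapply(t, function(tt) {
    seg <- max(which(xs <= tt))
    if (seg == length(xs)) return(ys[length(ys)])
    ys[seg] + (ys[seg + 1] - ys[seg]) * (tt - xs[seg]) /
      (xs[seg + 1] - xs[seg])
  })
}

# stage likelihood by direct product over biomarkers at the midpoint
naiveStageLik <- function(x, ordering, config, k) {
  t <- k + 0.5
  p <- 1
  for (i in seq_len(nBiomarkers(config))) {
    if (is.na(x[i])) {
      p <- p * 1 / zMax(config)[[i]]
    } else {
      g <- naiveTrajectory(ordering, config, i, t)
      p <- p * dnorm(x[i], g, sigmaNoise(config)[[i]])
    }
  }
  p
}

# Eq.-style total log likelihood by triple loop on the natural scale
naiveTotalLogLik <- function(data, model) {
  config <- modelConfig(model)
  N <- nEvents(config)
  total <- 0
  for (j in seq_len(nrow(data))) {
    pj <- 0
    for (c in seq_len(nSubtypes(model))) {
      for (k in 0:N) {
        pj <- pj + fractions(model)[c] * stagePrior(model)[k + 1] *
          naiveStageLik(data[j, ], sequences(model)[c, ], config, k)
      }
    }
    total <- total + log(pj)
  }
  total
}

# per-subject joint posterior by direct normalisation
naivePosterior <- function(x, model) {
  config <- modelConfig(model)
  N <- nEvents(config)
  tab <- matrix(0, nSubtypes(model), N + 1)
  for (c in seq_len(nSubtypes(model)))
    for (k in 0:N)
      tab[c, k + 1] <- fractions(model)[c] * stagePrior(model)[k + 1] *
        naiveStageLik(x, sequences(model)[c, ], config, k)
  tab / sum(tab)
}

# Kendall similarity by explicit pair counting
naiveKendall <- function(a, b) {
  N <- length(a)
  posA <- integer(N); posA[a] <- seq_len(N)
  posB <- integer(N); posB[b] <- seq_len(N)
  disc <- 0
  for (e in 1:(N - 1)) {
    for (f in (e + 1):N) {
      if (sign(posA[e] - posA[f]) != sign(posB[e] - posB[f]))
        disc <- disc + 1
    }
  }
  1 - disc / choose(N, 2)
}

# recursive enumeration of valid orderings (events of each biomarker in
# level order), independent of the package's allSequences()
naiveAllSequences <- function(config) {
  et <- eventTable(config)
  res <- list()
  extend <- function(prefix, nextLevel) {
    if (length(prefix) == nrow(et)) {
      res[[length(res) + 1]] <<- prefix
      return(invisible(NULL))
    }
    for (i in seq_len(nBiomarkers(config))) {
      if (nextLevel[i] <= sum(et$biomarker == i)) {
        e <- et$event[et$biomarker == i & et$level == nextLevel[i]]
        nl <- nextLevel
        nl[i] <- nl[i] + 1
        extend(c(prefix, e), nl)
      }
    }
  }
  extend(integer(0), rep(1L, nBiomarkers(config)))
  do.call(rbind, res)
}

# a tiny two-biomarker configuration used across tests
tinyConfig <- function(levels = list(c(1, 2), c(1)), zMax = 5, sigma = 1)
  biomarkerConfig(paste0("bm", seq_along(levels)), levels, zMax, sigma)
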