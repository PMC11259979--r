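# Evaluation metrics against simulation ground truth, longitudinal
# consistency rules, modality ablation, and the benchmark harness that
# compares the missing-data strategies.

#' Kendall similarity between two event sequences
#'
#' \eqn{1 - d / \binom{N}{2}} where \eqn{d} is the number of event pairs
#' ordered differently by the two sequences: 1 for identical orderings,
#' 0 for a full reversal.
#'
#' @param est,truth integer orderings over the same event set.
#' @return Similarity in \code{[0, 1]}.
#' @export
sequenceSimilarity <- function(est, truth) {
  est <- as.integer(est)
  truth <- as.integer(truth)
  if (length(est) != length(truth) || !setequal(est, truth))
    stop("sequences must order the same event set")
  N <- length(est)
  if (N < 2L) return(1)
  p1 <- .orderingToPositions(est)
  p2 <- .orderingToPositions(truth)
  disc <- 0L
  for (e in seq_len(N - 1L)) {
    f <- (e + 1L):N
    disc <- disc + sum((p1[e] - p1[f]) * (p2[e] - p2[f]) < 0)
  }
  1 - disc / (N * (N - 1) / 2)
}

#' Match estimated clusters to true clusters
#'
#' Finds the bijection between estimated and true cluster labels that
#' maximises the agreement count, by enumeration over the \eqn{C!}
#' permutations of the confusion matrix.
#'
#' @param est,truth integer cluster labels in \code{1..C} over the same
#'   subjects.
#' @param C cluster count.
#' @return Integer permutation \code{m}: estimated cluster \code{c}
#'   corresponds to true cluster \code{m[c]}.
#' @export
matchClusters <- function(est, truth, C) {
  if (length(est) != length(truth))
    stop("label vectors must cover the same subjects")
  if (any(c(est, truth) < 1) || any(c(est, truth) > C))
    stop("labels must lie in 1..C")
  if (C > 8L) stop("cluster matching by enumeration supports C <= 8")
  conf <- matrix(0L, C, C)
  for (j in seq_along(est))
    conf[est[j], truth[j]] <- conf[est[j], truth[j]] + 1L
  perms <- .permutations(seq_len(C))
  scores <- apply(perms, 1L, function(p)
    sum(conf[cbind(seq_len(C), p)]))
  as.integer(perms[which.max(scores), ])
}

#' Subtyping accuracy
#'
#' Percentage of scored subjects whose matched estimated subtype equals
#' the ground-truth subtype.  Normal-appearing subjects (estimated ML
#' stage 0) are excluded when \code{excludeStage0} is set and
#' \code{estStage} is supplied, since stage-0 subjects are not subtypable.
#'
#' @param est,truth integer subtype labels over the same subjects.
#' @param matching permutation from \code{\link{matchClusters}}.
#' @param excludeStage0 drop subjects with estimated ML stage 0.
#' @param estStage estimated ML stages (required for the exclusion).
#' @return Accuracy in percent.
#' @export
subtypeAccuracy <- function(est, truth, matching = seq_len(max(est, truth)),
                            excludeStage0 = TRUE, estStage = NULL) {
  if (length(est) != length(truth))
    stop("label vectors must cover the same subjects")
  score <- rep(TRUE, length(est))
  if (excludeStage0 && !is.null(estStage)) score <- estStage > 0L
  if (!any(score)) stop("no scored subjects: accuracy undefined")
  100 * mean(matching[est[score]] == truth[score])
}

#' Staging error
#'
#' Mean and standard deviation across individuals of the absolute
#' difference between estimated and true stage (sample SD, n-1
#' denominator), optionally stratified by true subtype.
#'
#' @param est,truth integer stage vectors of equal length.
#' @param bySubtype optional true-subtype labels for stratified rows.
#' @return A data.frame with columns \code{subtype} ("all" plus one row
#'   per stratum when \code{bySubtype} is given), \code{n}, \code{mean}
#'   and \code{sd}.
#' @export
stagingError <- function(est, truth, bySubtype = NULL) {
  if (length(est) != length(truth) || length(est) == 0L)
    stop("stage vectors must be nonempty and of equal length")
  err <- abs(est - truth)
  out <- data.frame(subtype = "all", n = length(err), mean = mean(err),
                    sd = if (length(err) > 1L) sd(err) else NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(bySubtype)) {
    for (s in sort(unique(bySubtype))) {
      e <- err[bySubtype == s]
      out <- rbind(out, data.frame(
        subtype = as.character(s), n = length(e), mean = mean(e),
        sd = if (length(e) > 1L) sd(e) else NA_real_,
        stringsAsFactors = FALSE))
    }
  }
  out
}

# marginal probability of each subject's ML subtype
.mlSubtypeProb <- function(post) {
  d <- dim(post@prob)
  vapply(seq_len(d[1L]), function(j)
    sum(post@prob[j, post@mlSubtype[j], ]), numeric(1))
}

#' Longitudinal consistency of subtype and stage assignments
#'
#' A follow-up visit is subtype-consistent if the subject keeps its
#' baseline ML subtype or progressed to a subtype from normal appearing
#' (baseline ML stage 0); stage-consistent if the follow-up ML stage is
#' at least the baseline ML stage; and CI-overlapping if the credible
#' sets of the two visits share at least one (subtype, stage) cell.
#'
#' @param baseline a \linkS4class{SubjectPosteriors}.
#' @param followups list of \linkS4class{SubjectPosteriors} over the same
#'   subjects in the same order.
#' @param mass credible-set mass.
#' @param probBins cut points for stratifying subtype consistency by the
#'   baseline ML-subtype probability.
#' @return list with \code{byVisit} (per-visit percentages) and
#'   \code{byProbability} (subtype consistency pooled over visits within
#'   baseline-probability bins).
#' @export
longitudinalConsistency <- function(baseline, followups, mass = 0.95,
                                    probBins = c(0, 0.5, 0.7, 0.9, 1)) {
  if (is(followups, "SubjectPosteriors")) followups <- list(followups)
  csBase <- credibleSets(baseline, mass)
  pML <- .mlSubtypeProb(baseline)
  byVisit <- NULL
  binLab <- levels(cut(0.5, probBins, include.lowest = TRUE))
  binHit <- setNames(numeric(length(binLab)), binLab)
  binTot <- binHit
  for (v in seq_along(followups)) {
    fu <- followups[[v]]
    if (!identical(subjectIds(fu), subjectIds(baseline)))
      stop("follow-up subjects do not match baseline")
    subCons <- normalAppearing(baseline) |
      (mlSubtype(fu) == mlSubtype(baseline))
    stgCons <- mlStage(fu) >= mlStage(baseline)
    csFu <- credibleSets(fu, mass)
    overlap <- vapply(seq_along(csFu), function(j) {
      a <- paste(csBase[[j]]$subtype, csBase[[j]]$stage)
      b <- paste(csFu[[j]]$subtype, csFu[[j]]$stage)
      any(a %in% b)
    }, logical(1))
    byVisit <- rbind(byVisit, data.frame(
      visit = v, n = length(subCons),
      subtypeConsistencyPct = 100 * mean(subCons),
      stageConsistencyPct = 100 * mean(stgCons),
      ciOverlapPct = 100 * mean(overlap)))
    bins <- cut(pML, probBins, include.lowest = TRUE)
    for (b in binLab) {
      at <- which(bins == b)
      binHit[b] <- binHit[b] + sum(subCons[at])
      binTot[b] <- binTot[b] + length(at)
    }
  }
  byProb <- data.frame(bin = binLab, n = as.integer(binTot),
                       subtypeConsistencyPct = 100 * binHit /
                         pmax(binTot, 1))
  byProb$subtypeConsistencyPct[binTot == 0] <- NA_real_
  list(byVisit = byVisit, byProbability = byProb)
}

#' Modality ablation
#'
#' Measures how much each modality contributes to subtyping and staging:
#' the modality's biomarkers are masked (treated as missing under the
#' uniform model) and the re-assignments are compared to the full-data
#' assignments used as a proxy ground truth.
#'
#' @param data subjects x biomarkers matrix.
#' @param model a fitted \linkS4class{SubtypeModel}.
#' @param groups named list mapping each modality to biomarker names or
#'   column indices.
#' @param mass credible-set mass for the coverage column.
#' @return data.frame per modality: \code{pctSameSubtype} (% of subjects
#'   keeping their full-data ML subtype), \code{meanStageDiff} (mean
#'   absolute ML-stage change) and \code{ciCoveragePct} (% of subjects
#'   whose full-data ML cell lies in the ablated credible set).
#' @export
modalityAblation <- function(data, model, groups, mass = 0.95) {
  data <- .checkData(data, model@config)
  full <- subjectPosteriors(data, model, "uniform")
  out <- NULL
  for (g in names(groups)) {
    cols <- groups[[g]]
    if (is.character(cols)) {
      bad <- setdiff(cols, model@config@names)
      if (length(bad))
        stop("unknown biomarker(s) in group '", g, "': ",
             paste(bad, collapse = ", "))
      cols <- match(cols, model@config@names)
    } else if (length(cols) && (any(cols < 1) ||
                                any(cols > nBiomarkers(model@config))))
      stop("biomarker index out of range in group '", g, "'")
    masked <- data
    if (length(cols)) masked[, cols] <- NA_real_
    post <- subjectPosteriors(masked, model, "uniform")
    cs <- credibleSets(post, mass)
    cover <- vapply(seq_along(cs), function(j)
      any(cs[[j]]$subtype == mlSubtype(full)[j] &
            cs[[j]]$stage == mlStage(full)[j]), logical(1))
    out <- rbind(out, data.frame(
      modality = g, nBiomarkers = length(cols),
      pctSameSubtype = 100 * mean(mlSubtype(post) == mlSubtype(full)),
      meanStageDiff = mean(abs(mlStage(post) - mlStage(full))),
      ciCoveragePct = 100 * mean(cover)))
  }
  out
}

# evaluate one fitted model against simulation truth
.evaluateFit <- function(fit, truthModel, trueSubtype, trueStage, data,
                         missingMode, excludeStage0 = TRUE) {
  model <- mlModel(fit)
  C <- nSubtypes(model)
  post <- subjectPosteriors(data, model, missingMode)
  m <- matchClusters(mlSubtype(post), trueSubtype, C)
  kend <- vapply(seq_len(C), function(c)
    sequenceSimilarity(sequences(model)[c, ],
                       sequences(truthModel)[m[c], ]), numeric(1))
  acc <- subtypeAccuracy(mlSubtype(post), trueSubtype, m,
                         excludeStage0 = excludeStage0,
                         estStage = mlStage(post))
  st <- stagingError(mlStage(post), trueStage)
  list(kendall = kend, kendallMean = mean(kend), accuracy = acc,
       stagingMean = st$mean[1L], stagingSd = st$sd[1L], matching = m,
       posteriors = post)
}

#' Benchmark missing-data strategies on synthetic data
#'
#' For each replicate: simulates a generating model and subject matrix,
#' injects each requested number of MCAR missing cells, applies each
#' strategy, fits a model with the true number of subtypes, and scores
#' sequence similarity (Kendall, per matched cluster and averaged),
#' subtyping accuracy and staging error against the ground truth.  A
#' full-data row (no cells deleted) is always included.  A strategy that
#' fails on a dataset (e.g. deletion removing almost every subject) is
#' recorded as a failed cell with NA metrics.
#'
#' @param strategies list of \code{\link{missingStrategy}} objects.
#' @param missingCounts numbers of cells to delete (e.g. \code{c(150,
#'   2000)} on the 500 x 10 design: 3\% and 40\%).
#' @param reps replicate count.
#' @param J,I,C,levels,zMax,sigma simulation design passed to
#'   \code{\link{simulateModel}} / \code{\link{simulateSubjects}}.
#' @param opts \code{\link{sustainOptions}} for the fits.
#' @param excludeStage0 see \code{\link{subtypeAccuracy}}.
#' @return data.frame with one row per (strategy, missing count,
#'   replicate) plus full-data rows: columns \code{strategy},
#'   \code{missing_n}, \code{missing_frac}, \code{rep},
#'   \code{kendall_mean}, \code{subtype_accuracy_pct},
#'   \code{staging_mae}, \code{staging_sd}, \code{n_fit} (subjects the
#'   model was fitted on) and \code{log_lik}.
#' @export
runBenchmark <- function(strategies, missingCounts, reps = 1L,
                         J = 500L, I = 10L, C = 3L, levels = c(1, 2, 3),
                         zMax = 5, sigma = 1, opts = sustainOptions(),
                         excludeStage0 = TRUE) {
  rows <- NULL
  stratLabel <- function(s)
    if (s$kind == "knn") paste0("knn_", s$knnFeatures) else s$kind
  for (rep in seq_len(reps)) {
    truth <- simulateModel(C = C, I = I, levels = levels, zMax = zMax,
                           sigma = sigma)
    sim <- simulateSubjects(truth, J = J)
    evalCell <- function(label, missN, dataIn, kept, missingMode) {
      fit <- tryCatch({
        fits <- fitSustain(dataIn, truth@config, cMax = C, opts = opts,
                           missingMode = missingMode, mcmc = FALSE)
        if (length(fits) < C) stop("could not fit ", C, " subtypes")
        fits[[C]]
      }, error = function(e) e)
      if (inherits(fit, "error"))
        return(data.frame(strategy = label, missing_n = missN,
                          missing_frac = missN / (J * I), rep = rep,
                          kendall_mean = NA_real_,
                          subtype_accuracy_pct = NA_real_,
                          staging_mae = NA_real_, staging_sd = NA_real_,
                          n_fit = nrow(dataIn), log_lik = NA_real_))
      ev <- .evaluateFit(fit, truth, sim$subtype[kept], sim$stage[kept],
                         dataIn, missingMode, excludeStage0)
      data.frame(strategy = label, missing_n = missN,
                 missing_frac = missN / (J * I), rep = rep,
                 kendall_mean = ev$kendallMean,
                 subtype_accuracy_pct = ev$accuracy,
                 staging_mae = ev$stagingMean, staging_sd = ev$stagingSd,
                 n_fit = nrow(dataIn), log_lik = logLik(fit))
    }
    rows <- rbind(rows, evalCell("full_data", 0L, sim$data,
                                 seq_len(J), "none"))
    for (missN in missingCounts) {
      masked <- injectMissingness(sim$data, missN)
      for (s in strategies) {
        ap <- tryCatch(applyStrategy(masked, s), error = function(e) e)
        if (inherits(ap, "error")) {
          rows <- rbind(rows, data.frame(
            strategy = stratLabel(s), missing_n = missN,
            missing_frac = missN / (J * I), rep = rep,
            kendall_mean = NA_real_, subtype_accuracy_pct = NA_real_,
            staging_mae = NA_real_, staging_sd = NA_real_, n_fit = 0L,
            log_lik = NA_real_))
          next
        }
        rows <- rbind(rows, evalCell(stratLabel(s), missN, ap$data,
                                     ap$kept, ap$missingMode))
      }
    }
  }
  rownames(rows) <- NULL
  rows
}

#' Aggregate a benchmark report over replicates
#'
#' @param report output of \code{\link{runBenchmark}}.
#' @return data.frame of per-(strategy, missing count) means and standard
#'   deviations over replicates.
#' @export
summarizeBenchmark <- function(report) {
  key <- interaction(report$strategy, report$missing_n, drop = TRUE)
  out <- NULL
  for (k in levels(key)) {
    r <- report[key == k, ]
    out <- rbind(out, data.frame(
      strategy = r$strategy[1L], missing_n = r$missing_n[1L],
      missing_frac = r$missing_frac[1L], reps = nrow(r),
      failed = sum(is.na(r$kendall_mean)),
      kendall_mean = mean(r$kendall_mean, na.rm = TRUE),
      subtype_accuracy_pct = mean(r$subtype_accuracy_pct, na.rm = TRUE),
      staging_mae = mean(r$staging_mae, na.rm = TRUE),
      staging_sd = mean(r$staging_sd, na.rm = TRUE)))
  }
  out[order(out$missing_n, out$strategy), ]
}

#' Render an aggregated benchmark as a Markdown table
#'
#' @param summary output of \code{\link{summarizeBenchmark}}.
#' @return Character vector of Markdown lines (failed cells shown blank).
#' @export
benchmarkMarkdown <- function(summary) {
  fmt <- function(x, d = 2)
    ifelse(is.na(x) | !is.finite(x), "", formatC(x, digits = d,
                                                 format = "f"))
  lines <- c(
    "| Strategy | Missing | Kendall | Subtype % correct | Stage mean diff (SD) |",
    "|---|---|---|---|---|")
  for (r in seq_len(nrow(summary))) {
    stage <- if (is.na(summary$staging_mae[r])) "" else
      sprintf("%s (%s)", fmt(summary$staging_mae[r]),
              fmt(summary$staging_sd[r]))
    lines <- c(lines, sprintf(
      "| %s | %s%% | %s | %s | %s |",
      summary$strategy[r], round(100 * summary$missing_frac[r]),
      fmt(summary$kendall_mean[r]),
      fmt(summary$subtype_accuracy_pct[r]), stage))
  }
  lines
}
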