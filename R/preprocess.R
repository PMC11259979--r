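# Control-referenced preprocessing: per-biomarker linear covariate
# correction estimated in controls, Z-scoring against the control
# residual distribution, sign flipping for biomarkers that decrease with
# disease, and derivation of the event grid from the corrected Z-scores.

#' Fit the control-referenced covariate model
#'
#' For each biomarker, an ordinary least squares regression on the
#' control subjects only; covariates whose coefficient fails a two-sided
#' t-test at \code{alpha} are dropped in a single backward pass
#' (optionally iterated) and the model refitted on the retained set.  The
#' mean and SD of the control residuals are stored for Z-scoring.
#'
#' @param raw subjects x biomarkers data.frame or matrix of raw values
#'   (NA = missing).
#' @param covariates subjects x covariates data.frame (numeric columns).
#' @param controlFlag logical per subject, TRUE for controls.
#' @param directions named vector of +1/-1 per biomarker: -1 flips
#'   biomarkers that decrease with disease so that corrected Z-scores
#'   increase with progression.  Default +1 for all.
#' @param alpha per-coefficient significance threshold for covariate
#'   retention.
#' @param covariateMap optional named list restricting each biomarker to a
#'   subset of covariate names (e.g. intracranial volume only for imaging
#'   markers).
#' @param iterate drop nonsignificant covariates one at a time, refitting
#'   until all retained covariates are significant, instead of the
#'   default single pass.
#' @return list of class \code{"covariateModel"}: per biomarker the
#'   retained covariates and coefficients, control residual mean/SD and
#'   direction.
#' @export
fitCovariateModel <- function(raw, covariates, controlFlag,
                              directions = NULL, alpha = 0.05,
                              covariateMap = NULL, iterate = FALSE) {
  raw <- as.data.frame(raw)
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(raw) == nrow(covariates),
            length(controlFlag) == nrow(raw))
  if (is.null(directions))
    directions <- setNames(rep(1, ncol(raw)), colnames(raw))
  if (!all(directions %in% c(-1, 1)))
    stop("directions must be +1 or -1")
  models <- list()
  for (bm in colnames(raw)) {
    covs <- if (!is.null(covariateMap) && !is.null(covariateMap[[bm]]))
      covariateMap[[bm]] else colnames(covariates)
    ctl <- which(controlFlag & !is.na(raw[[bm]]) &
                   complete.cases(covariates[covs]))
    if (length(ctl) < 2L)
      stop("need at least 2 complete control subjects for ", bm)
    fitOnce <- function(keep) {
      df <- data.frame(.y = raw[[bm]][ctl], covariates[ctl, keep,
                                                       drop = FALSE])
      fit <- lm(.y ~ ., data = df)
      if (any(is.na(coef(fit))))
        stop("collinear covariates for ", bm, ": ",
             paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
      fit
    }
    coefP <- function(fit) {
      cf <- summary(fit)$coefficients
      setNames(cf[, 4L], rownames(cf))[-1L]
    }
    keep <- covs
    fit <- fitOnce(keep)
    repeat {
      p <- coefP(fit)
      drop <- intersect(names(p)[p >= alpha], keep)
      if (!length(drop)) break
      if (iterate) drop <- names(which.max(p[drop]))
      keep <- setdiff(keep, drop)
      if (length(keep)) fit <- fitOnce(keep)
      else {
        fit <- lm(.y ~ 1, data = data.frame(.y = raw[[bm]][ctl]))
        break
      }
      if (!iterate) break
    }
    m0 <- list(coef = coef(fit), covariates = keep)
    resid <- raw[[bm]][ctl] -
      .predictBiomarker(m0, covariates[ctl, , drop = FALSE])
    models[[bm]] <- list(
      biomarker = bm, covariates = keep, coef = coef(fit),
      controlMean = mean(resid), controlSd = sd(resid),
      direction = unname(directions[bm]))
    if (models[[bm]]$controlSd <= 0 || !is.finite(models[[bm]]$controlSd))
      stop("degenerate control residuals for ", bm)
  }
  structure(list(models = models, alpha = alpha), class = "covariateModel")
}

.predictBiomarker <- function(m, covariates) {
  pred <- rep(m$coef[["(Intercept)"]], nrow(covariates))
  for (cv in m$covariates) pred <- pred + m$coef[[cv]] * covariates[[cv]]
  pred
}

#' Covariate-correct and Z-score a raw biomarker table
#'
#' Residualises each biomarker against its retained covariates and
#' standardises against the control residual distribution:
#' \eqn{z = \mathrm{direction} \times (\mathrm{residual} - \mu_{ctl}) /
#' \sigma_{ctl}}.  Missing raw cells stay missing; a subject with a
#' missing retained covariate gets NA for that biomarker (with a
#' message).
#'
#' @param raw subjects x biomarkers table of raw values.
#' @param covariates subjects x covariates table.
#' @param model a \code{"covariateModel"} from
#'   \code{\link{fitCovariateModel}}.
#' @return Numeric matrix of Z-scores (subjects x biomarkers), rownames
#'   taken from \code{raw}.
#' @export
correctAndZscore <- function(raw, covariates, model) {
  stopifnot(inherits(model, "covariateModel"))
  raw <- as.data.frame(raw)
  covariates <- as.data.frame(covariates)
  bad <- setdiff(names(model$models), colnames(raw))
  if (length(bad)) stop("raw table lacks biomarker(s): ",
                        paste(bad, collapse = ", "))
  out <- matrix(NA_real_, nrow(raw), length(model$models),
                dimnames = list(rownames(raw), names(model$models)))
  for (bm in names(model$models)) {
    m <- model$models[[bm]]
    covOk <- complete.cases(covariates[m$covariates])
    if (any(!covOk & !is.na(raw[[bm]])))
      message(sum(!covOk & !is.na(raw[[bm]])), " subject(s) lost ", bm,
              " to missing covariates")
    ok <- !is.na(raw[[bm]]) & covOk
    resid <- raw[[bm]][ok] - .predictBiomarker(m, covariates[ok, ,
                                                             drop = FALSE])
    out[ok, bm] <- m$direction * (resid - m$controlMean) / m$controlSd
  }
  out
}

# round half away from zero (round() rounds half to even)
.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Derive the event configuration from Z-scored data
#'
#' Sets each biomarker's ceiling to the rounded 95th percentile of its
#' observed Z-scores (linear-interpolation quantile, halves rounded away
#' from zero) and keeps the candidate event levels strictly below the
#' ceiling.  Biomarkers whose ceiling does not exceed the smallest
#' candidate level carry no usable events and are excluded with a
#' warning.
#'
#' @param z subjects x biomarkers matrix of Z-scores, NA = missing.
#' @param candidateLevels event levels considered, in increasing order.
#' @param minObs minimum observed values required per biomarker.
#' @param sigma observation noise assigned to every biomarker.
#' @return A \linkS4class{BiomarkerConfig} over the retained biomarkers.
#' @export
deriveEventConfig <- function(z, candidateLevels = c(1, 2, 3, 5),
                              minObs = 20L, sigma = 1) {
  if (is.null(colnames(z)))
    colnames(z) <- sprintf("bm%02d", seq_len(ncol(z)))
  keepNames <- character(0)
  levelsList <- list()
  zmaxKeep <- numeric(0)
  for (i in seq_len(ncol(z))) {
    v <- z[, i][!is.na(z[, i])]
    if (length(v) < minObs)
      stop(sprintf("biomarker '%s' has fewer than %d observed values",
                   colnames(z)[i], minObs))
    zm <- .roundHalfAway(quantile(v, 0.95, names = FALSE, type = 7))
    lv <- candidateLevels[candidateLevels < zm]
    if (length(lv) == 0L) {
      warning(sprintf(
        "biomarker '%s' is uninformative (ceiling %g); excluded",
        colnames(z)[i], zm))
      next
    }
    keepNames <- c(keepNames, colnames(z)[i])
    levelsList <- c(levelsList, list(lv))
    zmaxKeep <- c(zmaxKeep, zm)
  }
  if (!length(keepNames)) stop("no informative biomarkers")
  biomarkerConfig(keepNames, levelsList, zMax = zmaxKeep, sigma = sigma)
}
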