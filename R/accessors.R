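#' @rdname BiomarkerConfig-class
#' @export
setMethod("nBiomarkers", "BiomarkerConfig",
          function(object) length(object@names))

#' @rdname BiomarkerConfig-class
#' @export
setMethod("nEvents", "BiomarkerConfig",
          function(object) sum(lengths(object@eventLevels)))

#' @rdname BiomarkerConfig-class
#' @export
setMethod("biomarkerNames", "BiomarkerConfig", function(object) object@names)

#' @rdname BiomarkerConfig-class
#' @export
setMethod("eventLevels", "BiomarkerConfig",
          function(object) setNames(object@eventLevels, object@names))

#' @rdname BiomarkerConfig-class
#' @export
setMethod("zMax", "BiomarkerConfig",
          function(object) setNames(object@zMax, object@names))

#' @rdname BiomarkerConfig-class
#' @export
setMethod("sigmaNoise", "BiomarkerConfig",
          function(object) setNames(object@sigma, object@names))

#' Enumerate the model events of a configuration
#'
#' Events are enumerated biomarker by biomarker in config order, levels in
#' increasing order; this fixed enumeration is how sequences refer to
#' events.
#'
#' @param config a \linkS4class{BiomarkerConfig}.
#' @return A data.frame with one row per event: \code{event} (index),
#'   \code{biomarker} (index), \code{name}, \code{level} (index within the
#'   biomarker) and \code{z} (the Z-score threshold).
#' @export
eventTable <- function(config) {
  R <- lengths(config@eventLevels)
  data.frame(
    event = seq_len(sum(R)),
    biomarker = rep(seq_along(R), R),
    name = rep(config@names, R),
    level = unlist(lapply(R, seq_len), use.names = FALSE),
    z = unlist(config@eventLevels, use.names = FALSE))
}

setMethod("show", "BiomarkerConfig", function(object) {
  cat(sprintf("BiomarkerConfig: %d biomarkers, %d Z-score events\n",
              nBiomarkers(object), nEvents(object)))
  et <- eventTable(object)
  lv <- vapply(object@eventLevels, function(x)
    paste(format(x, trim = TRUE), collapse = ","), "")
  cat(sprintf("  %s: levels (%s), zMax %g, sigma %g\n",
              object@names, lv, object@zMax, object@sigma), sep = "")
  invisible(et)
})

#' @rdname SubtypeModel-class
#' @param object a \linkS4class{SubtypeModel}.
#' @export
setMethod("nSubtypes", "SubtypeModel",
          function(object) nrow(object@sequences))

#' @rdname SubtypeModel-class
#' @export
setMethod("nEvents", "SubtypeModel", function(object) nEvents(object@config))

#' @rdname SubtypeModel-class
#' @export
setMethod("sequences", "SubtypeModel", function(object) object@sequences)

#' @rdname SubtypeModel-class
#' @export
setMethod("fractions", "SubtypeModel", function(object) object@fractions)

#' @rdname SubtypeModel-class
#' @export
setMethod("stagePrior", "SubtypeModel", function(object) object@stagePrior)

#' @rdname SubtypeModel-class
#' @export
setMethod("modelConfig", "SubtypeModel", function(object) object@config)

setMethod("show", "SubtypeModel", function(object) {
  N <- nEvents(object@config)
  cat(sprintf("SubtypeModel: %d subtype(s), %d events (%d biomarkers)\n",
              nSubtypes(object), N, nBiomarkers(object@config)))
  et <- eventTable(object@config)
  for (c in seq_len(nSubtypes(object))) {
    ord <- object@sequences[c, ]
    lab <- paste0(et$name[ord], "[", et$z[ord], "]")
    cat(sprintf("  subtype %d (f = %.3f): %s\n", c, object@fractions[c],
                paste(head(lab, 6L), collapse = " -> ")))
    if (N > 6L) cat("    ...\n")
  }
  invisible(NULL)
})

#' @rdname SubjectPosteriors-class
#' @param object a \linkS4class{SubjectPosteriors}.
#' @export
setMethod("mlSubtype", "SubjectPosteriors", function(object) object@mlSubtype)

#' @rdname SubjectPosteriors-class
#' @export
setMethod("mlStage", "SubjectPosteriors", function(object) object@mlStage)

#' @rdname SubjectPosteriors-class
#' @export
setMethod("normalAppearing", "SubjectPosteriors",
          function(object) object@normalAppearing)

#' @rdname SubjectPosteriors-class
#' @export
setMethod("posteriorArray", "SubjectPosteriors", function(object) object@prob)

#' @rdname SubjectPosteriors-class
#' @export
setMethod("subjectIds", "SubjectPosteriors", function(object) object@subjectIds)

setMethod("show", "SubjectPosteriors", function(object) {
  d <- dim(object@prob)
  cat(sprintf(
    "SubjectPosteriors: %d subjects, %d subtype(s), stages 0..%d\n",
    d[1L], d[2L], d[3L] - 1L))
  cat(sprintf("  normal appearing (ML stage 0): %d\n",
              sum(object@normalAppearing)))
  invisible(NULL)
})

#' @rdname SustainFit-class
#' @param object a \linkS4class{SustainFit}.
#' @export
setMethod("positionalVariance", "SustainFit",
          function(object) object@positionalVariance)

#' @rdname SustainFit-class
#' @export
setMethod("mcmcTrace", "SustainFit", function(object) object@mcmc)

#' @rdname SustainFit-class
#' @export
setMethod("modelConfig", "SustainFit",
          function(object) object@model@config)

#' @rdname SustainFit-class
#' @export
setMethod("nSubtypes", "SustainFit",
          function(object) nSubtypes(object@model))

#' Extract the ML model from a fit
#' @param object a \linkS4class{SustainFit}.
#' @return The maximum-likelihood \linkS4class{SubtypeModel}.
#' @export
setGeneric("mlModel", function(object) standardGeneric("mlModel"))

#' @rdname mlModel
#' @export
setMethod("mlModel", "SustainFit", function(object) object@model)

#' @importFrom stats logLik
#' @export
setMethod("logLik", "SustainFit", function(object, ...) object@logLik)

setMethod("show", "SustainFit", function(object) {
  cat(sprintf("SustainFit: %d subtype(s), log likelihood %.4f\n",
              nSubtypes(object@model), object@logLik))
  if (length(object@mcmc))
    cat(sprintf("  MCMC: %d iterations, acceptance rate %.3f\n",
                length(object@mcmc$logLik), object@mcmc$acceptanceRate))
  show(object@model)
  invisible(NULL)
})
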