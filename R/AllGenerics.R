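#' @rdname BiomarkerConfig-class
#' @param object,x a package object.
#' @export
setGeneric("nEvents", function(object) standardGeneric("nEvents"))

#' @rdname BiomarkerConfig-class
#' @export
setGeneric("nBiomarkers", function(object) standardGeneric("nBiomarkers"))

#' @rdname BiomarkerConfig-class
#' @export
setGeneric("biomarkerNames",
           function(object) standardGeneric("biomarkerNames"))

#' @rdname BiomarkerConfig-class
#' @export
setGeneric("eventLevels", function(object) standardGeneric("eventLevels"))

#' @rdname BiomarkerConfig-class
#' @export
setGeneric("zMax", function(object) standardGeneric("zMax"))

#' @rdname BiomarkerConfig-class
#' @export
setGeneric("sigmaNoise", function(object) standardGeneric("sigmaNoise"))

#' @rdname SubtypeModel-class
#' @export
setGeneric("nSubtypes", function(object) standardGeneric("nSubtypes"))

#' @rdname SubtypeModel-class
#' @export
setGeneric("sequences", function(object) standardGeneric("sequences"))

#' @rdname SubtypeModel-class
#' @export
setGeneric("fractions", function(object) standardGeneric("fractions"))

#' @rdname SubtypeModel-class
#' @export
setGeneric("stagePrior", function(object) standardGeneric("stagePrior"))

#' @rdname SubtypeModel-class
#' @export
setGeneric("modelConfig", function(object) standardGeneric("modelConfig"))

#' @rdname SubjectPosteriors-class
#' @export
setGeneric("mlSubtype", function(object) standardGeneric("mlSubtype"))

#' @rdname SubjectPosteriors-class
#' @export
setGeneric("mlStage", function(object) standardGeneric("mlStage"))

#' @rdname SubjectPosteriors-class
#' @export
setGeneric("normalAppearing",
           function(object) standardGeneric("normalAppearing"))

#' @rdname SubjectPosteriors-class
#' @export
setGeneric("posteriorArray",
           function(object) standardGeneric("posteriorArray"))

#' @rdname SubjectPosteriors-class
#' @export
setGeneric("subjectIds", function(object) standardGeneric("subjectIds"))

#' @rdname SustainFit-class
#' @export
setGeneric("positionalVariance",
           function(object) standardGeneric("positionalVariance"))

#' @rdname SustainFit-class
#' @export
setGeneric("mcmcTrace", function(object) standardGeneric("mcmcTrace"))
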