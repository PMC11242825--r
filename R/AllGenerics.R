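#' @rdname AlleleDistanceMatrix-class
#' @param object,x an object.
#' @export
setGeneric("locus", function(x) standardGeneric("locus"))

#' @rdname AlleleDistanceMatrix-class
#' @export
setGeneric("distValues", function(x) standardGeneric("distValues"))

#' @rdname AlleleDistanceMatrix-class
#' @export
setGeneric("alleleIds", function(x) standardGeneric("alleleIds"))

#' @rdname HaplotypeRegistry-class
#' @export
setGeneric("haplotypeIds", function(x) standardGeneric("haplotypeIds"))

#' @rdname HaplotypeRegistry-class
#' @export
setGeneric("haplotypeTable", function(x) standardGeneric("haplotypeTable"))

#' @rdname SlaAnalysis-class
#' @export
setGeneric("groupTable", function(x) standardGeneric("groupTable"))

#' @rdname SlaAnalysis-class
#' @export
setGeneric("correlationTable", function(x) standardGeneric("correlationTable"))

#' @rdname SlaAnalysis-class
#' @export
setGeneric("analysisSeries", function(x) standardGeneric("analysisSeries"))

#' @rdname SlaAnalysis-class
#' @export
setGeneric("analysisParams", function(x) standardGeneric("analysisParams"))

#' @rdname SubstitutionModel-class
#' @export
setGeneric("gammaShape", function(x) standardGeneric("gammaShape"))

#' @rdname SubstitutionModel-class
#' @export
setGeneric("equilibriumFrequencies",
           function(x) standardGeneric("equilibriumFrequencies"))
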