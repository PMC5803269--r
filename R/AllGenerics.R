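#' @include AllClasses.R
NULL

#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @export
setGeneric("exprScale", function(x) standardGeneric("exprScale"))

#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @export
setGeneric("filterLowExpression",
           function(x, threshold = 0.1, maxLowSamples = 2)
               standardGeneric("filterLowExpression"))

#' @export
setGeneric("logTransform", function(x, pseudocount = 1)
    standardGeneric("logTransform"))

#' @export
setGeneric("uniprotFilter", function(x, annotation)
    standardGeneric("uniprotFilter"))

#' @export
setGeneric("meanVarianceWeights", function(x, span = 0.5)
    standardGeneric("meanVarianceWeights"))

#' @export
setGeneric("residualNormalize", function(x, annotation, minGenes = 10L)
    standardGeneric("residualNormalize"))

#' @export
setGeneric("metafeatureScore", function(x, geneSet, center = FALSE)
    standardGeneric("metafeatureScore"))

#' @export
setGeneric("signatureTable", function(object) standardGeneric("signatureTable"))

#' @export
setGeneric("fcSet", function(object) standardGeneric("fcSet"))

#' @export
setGeneric("pvalSet", function(object) standardGeneric("pvalSet"))

#' @export
setGeneric("markerSets", function(object) standardGeneric("markerSets"))

#' @export
setGeneric("mixingProportions", function(object)
    standardGeneric("mixingProportions"))

#' @export
setGeneric("traitEffects", function(object) standardGeneric("traitEffects"))

#' @export
setGeneric("scoreValues", function(object) standardGeneric("scoreValues"))

#' @export
setGeneric("nGenesUsed", function(object) standardGeneric("nGenesUsed"))
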