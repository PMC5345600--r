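#' @include AllClasses.R
NULL

#' @export
setGeneric("phenotype", function(x, ...) standardGeneric("phenotype"))

#' @export
setGeneric("cytotype", function(x, ...) standardGeneric("cytotype"))

#' @export
setGeneric("alleleCalls", function(x, ...) standardGeneric("alleleCalls"))

#' @export
setGeneric("markerNames", function(x, ...) standardGeneric("markerNames"))

#' @export
setGeneric("diagnosticAlleles", function(x, ...) standardGeneric("diagnosticAlleles"))

#' @export
setGeneric("hybridGroups", function(x, ...) standardGeneric("hybridGroups"))

#' @export
setGeneric("filterHybridSamples", function(x, maxMissing = 2, ...)
    standardGeneric("filterHybridSamples"))

#' @export
setGeneric("adjustedResiduals", function(x, ...) standardGeneric("adjustedResiduals"))
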