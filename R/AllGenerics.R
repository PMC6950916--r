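#' @include AllClasses.R
NULL

#' @export
setGeneric("totalCount", function(x) standardGeneric("totalCount"))

#' @export
setGeneric("nPositions", function(x) standardGeneric("nPositions"))

#' @export
setGeneric("profileData", function(x) standardGeneric("profileData"))

#' @export
setGeneric("shifts", function(x) standardGeneric("shifts"))

#' @export
setGeneric("cnccValues", function(x) standardGeneric("cnccValues"))

#' @export
setGeneric("argmaxShift", function(x) standardGeneric("argmaxShift"))

#' @export
setGeneric("endKind", function(x) standardGeneric("endKind"))

#' @export
setGeneric("overhangLength", function(x) standardGeneric("overhangLength"))

#' @export
setGeneric("siteTable", function(x) standardGeneric("siteTable"))

#' @export
setGeneric("filterSites", function(x, minReads) standardGeneric("filterSites"))

#' @export
setGeneric("regionRanges", function(x) standardGeneric("regionRanges"))

#' @export
setGeneric("regionWidths", function(x) standardGeneric("regionWidths"))
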