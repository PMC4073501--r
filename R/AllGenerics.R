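#' @export
setGeneric("probeMap", function(x) standardGeneric("probeMap"))

#' @export
setGeneric("log2Ratios", function(x) standardGeneric("log2Ratios"))

#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @export
setGeneric("regions", function(x) standardGeneric("regions"))

#' @export
setGeneric("carriers", function(x) standardGeneric("carriers"))

#' @export
setGeneric("groupSizes", function(x) standardGeneric("groupSizes"))
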