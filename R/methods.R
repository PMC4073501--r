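#' @describeIn AcghSet probe map as a `GRanges`.
#' @param x an `AcghSet` or `CnvrSet`.
#' @export
setMethod("probeMap", "AcghSet",
          function(x) SummarizedExperiment::rowRanges(x))

#' @describeIn AcghSet log2-ratio matrix (probes x samples).
#' @export
setMethod("log2Ratios", "AcghSet",
          function(x) SummarizedExperiment::assay(x, "log2"))

#' @describeIn AcghSet named character vector sample id -> group label.
#' @export
setMethod("sampleGroups", "AcghSet", function(x)
  setNames(as.character(SummarizedExperiment::colData(x)$group), colnames(x)))

setMethod("show", "AcghSet", function(object) {
  cat("AcghSet:", nrow(object), "probes x", ncol(object), "samples\n")
  g <- table(sampleGroups(object))
  cat("groups:", paste(names(g), g, sep = "=", collapse = ", "), "\n")
  cat("chromosomes:",
      paste(GenomeInfoDb::seqlevels(probeMap(object)), collapse = ", "), "\n")
})

#' @describeIn CnvrSet CNVR intervals as a `GRanges`.
#' @param x a `CnvrSet`.
#' @export
setMethod("regions", "CnvrSet", function(x) x@regions)

#' @describeIn CnvrSet carrier sample ids, one character vector per region.
#' @export
setMethod("carriers", "CnvrSet", function(x) x@carriers)

#' @describeIn CnvrSet named integer vector of group sizes.
#' @export
setMethod("groupSizes", "CnvrSet", function(x) x@groupSizes)

#' @export
setMethod("length", "CnvrSet", function(x) length(x@regions))

setMethod("show", "CnvrSet", function(object) {
  st <- table(factor(object@regions$state, c("gain", "loss", "both")))
  cat("CnvrSet:", length(object), "CNVRs (",
      paste(names(st), st, sep = "=", collapse = ", "), ")\n")
  cat("groups:", paste(names(object@groupSizes), object@groupSizes,
                       sep = "=", collapse = ", "), "\n")
  if (length(object))
    cat("total length:", sum(IRanges::width(object@regions)), "bp\n")
})
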