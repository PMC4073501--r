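#' AcghSet: probes x samples log2-ratio container
#'
#' `AcghSet` extends `RangedSummarizedExperiment`: rows are array probes
#' (a `GRanges` probe map, sorted and non-overlapping within chromosome),
#' the single assay `"log2"` holds per-probe log2(test/reference) values,
#' and `colData` carries the sample's population group label.
#'
#' @slot .. see `RangedSummarizedExperiment`.
#' @aliases AcghSet-class
#' @exportClass AcghSet
setClass("AcghSet", contains = "RangedSummarizedExperiment")

setValidity("AcghSet", function(object) {
  msg <- NULL
  if (!"log2" %in% names(SummarizedExperiment::assays(object)))
    msg <- c(msg, "assay 'log2' is required")
  else {
    m <- SummarizedExperiment::assay(object, "log2")
    if (!is.numeric(m)) msg <- c(msg, "assay 'log2' must be numeric")
    else if (any(!is.finite(m))) msg <- c(msg, "log2 ratios must be finite")
  }
  if (!"group" %in% names(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData column 'group' is required")
  rr <- SummarizedExperiment::rowRanges(object)
  if (!"probe_id" %in% names(S4Vectors::mcols(rr)))
    msg <- c(msg, "rowRanges must carry a 'probe_id' column")
  if (is.null(msg)) TRUE else msg
})

#' Construct an AcghSet
#'
#' @param probes `GRanges` probe map with an mcols column `probe_id`.
#' @param log2ratios numeric matrix, one row per probe, one column per
#'   sample; finite values; column names are sample ids.
#' @param groups named character vector mapping sample id to group label;
#'   must cover all columns of `log2ratios`.
#' @return An [AcghSet-class] object.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 101), width = 60),
#'                              probe_id = c("p1", "p2"))
#' m <- cbind(s1 = c(0, 0.1), s2 = c(-1, -0.9))
#' AcghSet(gr, m, c(s1 = "taurine", s2 = "yak"))
#' @export
AcghSet <- function(probes, log2ratios, groups) {
  log2ratios <- as.matrix(log2ratios)
  if (length(probes) != nrow(log2ratios))
    stop("value count per sample (", nrow(log2ratios),
         ") must equal probe count (", length(probes), ")")
  if (is.null(colnames(log2ratios))) stop("log2ratios needs sample column names")
  groups <- .checkGroups(groups)
  missing <- setdiff(colnames(log2ratios), names(groups))
  if (length(missing))
    stop("samples without group assignment: ", paste(missing, collapse = ", "))
  cd <- S4Vectors::DataFrame(group = unname(groups[colnames(log2ratios)]),
                             row.names = colnames(log2ratios))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2 = log2ratios), rowRanges = probes, colData = cd)
  methods::new("AcghSet", se)
}

#' CnvrSet: copy number variable regions with carriers
#'
#' Holds the disjoint CNVR intervals of one group (or of a cross-group
#' merge) as a `GRanges` with per-region state, carrier count and frequency,
#' together with the carrier sample ids per region and the sizes of the
#' sample groups the frequencies are computed against.
#'
#' @slot regions `GRanges` with mcols `cnvr_id`, `state` (gain/loss/both),
#'   `n_carriers`, `frequency`, and `groups` (comma-joined provenance labels).
#' @slot carriers list of character vectors, one per region.
#' @slot groupSizes named integer vector: samples per group label.
#' @aliases CnvrSet-class
#' @exportClass CnvrSet
setClass("CnvrSet",
         representation(regions = "GRanges", carriers = "list",
                        groupSizes = "integer"))

setValidity("CnvrSet", function(object) {
  msg <- NULL
  r <- object@regions
  need <- c("cnvr_id", "state", "n_carriers", "frequency", "groups")
  miss <- setdiff(need, names(S4Vectors::mcols(r)))
  if (length(miss))
    msg <- c(msg, paste("regions missing mcols:", paste(miss, collapse = ", ")))
  else {
    if (!all(r$state %in% c("gain", "loss", "both")))
      msg <- c(msg, "state must be gain, loss or both")
    if (any(r$frequency <= 0 | r$frequency > 1))
      msg <- c(msg, "frequency must be in (0, 1]")
    if (length(object@carriers) != length(r))
      msg <- c(msg, "one carrier vector per region required")
    else if (length(r) &&
             any(vapply(object@carriers, anyDuplicated, 0L) > 0))
      msg <- c(msg, "carrier lists must not contain duplicates")
  }
  if (is.null(names(object@groupSizes)))
    msg <- c(msg, "groupSizes must be named")
  if (is.null(msg)) TRUE else msg
})

#' Construct a CnvrSet
#'
#' @param regions `GRanges` with the mcols documented in [CnvrSet-class].
#' @param carriers list of character vectors of carrier sample ids.
#' @param groupSizes named integer vector of group sizes.
#' @return A [CnvrSet-class] object.
#' @export
CnvrSet <- function(regions, carriers, groupSizes) {
  methods::new("CnvrSet", regions = regions, carriers = as.list(carriers),
               groupSizes = setNames(as.integer(groupSizes),
                                     names(groupSizes)))
}
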