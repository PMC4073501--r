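# mean Ct per sample for one assay; replicates averaged first
.meanCt <- function(wells, assay) {
  w <- wells[wells$assay == assay & is.finite(wells$ct), , drop = FALSE]
  tapply(w$ct, w$sample, mean)
}

#' Relative copy number by the delta-delta-Ct method
#'
#' Per sample: `dCt = mean Ct(target) - mean Ct(control gene)` (technical
#' replicates averaged first), `ddCt = dCt(sample) - dCt(calibrator)`, and
#' relative copy number `RCN = 2^-ddCt`, so the two-copy calibrator sits at
#' RCN 1 by construction and each copy doubling subtracts one cycle from
#' the expected ddCt. Assumes amplification efficiency 2.
#'
#' @param wells Ct table (`sample`, `assay`, `ct`, one row per replicate),
#'   e.g. from [simulateQpcr()] or [readWells()].
#' @param calibrator sample id of the two-copy reference; must have both
#'   assays measured.
#' @param controlAssay internal-control gene assay name (e.g. `"BTF3"`).
#' @param targetAssay target assay name; default: the single non-control
#'   assay present.
#' @param gainCut,lossCut RCN cutoffs passed to [classifyType()].
#' @return `data.frame`: `sample`, `dct`, `ddct`, `rcn`, `type`. Samples
#'   missing the control assay are skipped with a warning.
#' @export
relativeCopyNumber <- function(wells, calibrator, controlAssay,
                               targetAssay = NULL, gainCut = 1.4,
                               lossCut = 0.6) {
  if (is.null(targetAssay)) {
    targetAssay <- setdiff(unique(wells$assay), controlAssay)
    if (length(targetAssay) != 1)
      stop("targetAssay must be given when several non-control assays exist")
  }
  tgt <- .meanCt(wells, targetAssay)
  ctl <- .meanCt(wells, controlAssay)
  if (!calibrator %in% names(tgt) || !calibrator %in% names(ctl))
    stop("calibrator '", calibrator,
         "' lacks target or control measurements")
  noCtl <- setdiff(names(tgt), names(ctl))
  if (length(noCtl))
    warning("skipping sample(s) without control assay: ",
            paste(noCtl, collapse = ", "))
  samples <- intersect(names(tgt), names(ctl))
  dct <- tgt[samples] - ctl[samples]
  ddct <- dct - dct[[calibrator]]
  rcn <- 2^(-ddct)
  data.frame(sample = samples, dct = unname(dct), ddct = unname(ddct),
             rcn = unname(rcn),
             type = classifyType(unname(rcn), gainCut, lossCut),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify relative copy number against the two-copy reference
#'
#' @param rcn positive relative copy number(s), 1 = two copies.
#' @param gainCut RCN at or above which a sample is typed `gain`
#'   (default 1.4, below the 1.5 expected for three copies, widened for
#'   replicate noise).
#' @param lossCut RCN at or below which a sample is typed `loss`
#'   (default 0.6, above the 0.5 expected for one copy).
#' @return character vector in `{gain, loss, normal}`.
#' @export
classifyType <- function(rcn, gainCut = 1.4, lossCut = 0.6) {
  if (!(lossCut < 1 && 1 < gainCut))
    stop("cutoffs must satisfy lossCut < 1 < gainCut")
  if (any(rcn <= 0)) stop("rcn must be positive")
  ifelse(rcn >= gainCut, "gain", ifelse(rcn <= lossCut, "loss", "normal"))
}

#' Expression fold change by the delta-delta-Ct method
#'
#' Mathematically the ddCt chain of [relativeCopyNumber()] with an
#' expression normaliser gene (e.g. GAPDH) in place of the copy-number
#' control: fold = `2^-ddCt` against the calibrator.
#'
#' @param wells Ct table as in [relativeCopyNumber()].
#' @param calibrator calibrator sample id.
#' @param normalizerAssay normaliser gene assay name.
#' @param targetAssay expression target assay name (default: the single
#'   other assay).
#' @return `data.frame`: `sample`, `dct`, `ddct`, `fold`.
#' @export
expressionFoldChange <- function(wells, calibrator, normalizerAssay,
                                 targetAssay = NULL) {
  est <- relativeCopyNumber(wells, calibrator, normalizerAssay, targetAssay)
  data.frame(sample = est$sample, dct = est$dct, ddct = est$ddct,
             fold = est$rcn, stringsAsFactors = FALSE)
}

#' Compare expression fold changes between CNV types
#'
#' Two-sided Welch t-tests on every pair of types with at least two samples
#' each; types with fewer samples are skipped with a warning. Two groups
#' with identical constant values compare at t = 0, p = 1.
#'
#' @param values numeric fold changes (or any per-sample quantity).
#' @param types character vector of CNV types aligned with `values`.
#' @return `data.frame`: `type1`, `type2`, `n1`, `n2`, `t`, `df`, `p`.
#' @export
compareGroups <- function(values, types) {
  if (length(values) != length(types)) stop("values/types length mismatch")
  lev <- sort(unique(types))
  counts <- table(factor(types, lev))
  small <- names(counts)[counts < 2]
  if (length(small))
    warning("type(s) with < 2 samples skipped: ",
            paste(small, collapse = ", "))
  lev <- setdiff(lev, small)
  if (length(lev) < 2) return(data.frame(
    type1 = character(0), type2 = character(0), n1 = integer(0),
    n2 = integer(0), t = numeric(0), df = numeric(0), p = numeric(0)))
  pairs <- combn(lev, 2)
  out <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- values[types == pairs[1, i]]
    b <- values[types == pairs[2, i]]
    if (sd(a) == 0 && sd(b) == 0) {
      tt <- list(statistic = if (mean(a) == mean(b)) 0 else Inf,
                 parameter = length(a) + length(b) - 2,
                 p.value = if (mean(a) == mean(b)) 1 else 0)
    } else tt <- t.test(a, b)
    data.frame(type1 = pairs[1, i], type2 = pairs[2, i],
               n1 = length(a), n2 = length(b),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
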