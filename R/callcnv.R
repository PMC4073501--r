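#' Call CNVs from segments by the mean-ratio / minimum-probe rule
#'
#' A segment qualifies as a CNV when its mean log2 ratio is at least
#' `threshold` in absolute value (inclusive) and it spans at least
#' `minProbes` consecutive probes. Adjacent qualifying segments of the same
#' state within a sample and chromosome (no probes between them) are merged
#' into one call, with a probe-count-weighted mean. Calls carry only the
#' direction (gain/loss), not an integer copy number.
#'
#' @param segments segment `data.frame` from [segmentSamples()].
#' @param threshold log2-ratio magnitude cutoff, inclusive (default 0.5,
#'   must be > 0).
#' @param minProbes minimum consecutive probes (default 5, must be >= 1).
#' @param genome optional genome layout supplying `seqinfo` for the result.
#' @return `GRanges` of calls (1-based closed, first to last member probe)
#'   with mcols `sample`, `state`, `mean_log2`, `n_probes`.
#' @export
callCnvs <- function(segments, threshold = 0.5, minProbes = 5,
                     genome = NULL) {
  if (threshold <= 0) stop("threshold must be > 0")
  if (minProbes < 1) stop("minProbes must be >= 1")
  need <- c("sample", "chrom", "start_probe", "end_probe", "start_bp",
            "end_bp", "n_probes", "mean_log2")
  if (!all(need %in% names(segments)))
    stop("segments needs columns: ", paste(need, collapse = ", "))
  seg <- segments[order(segments$sample, segments$chrom,
                        segments$start_probe), , drop = FALSE]
  seg$state <- ifelse(seg$mean_log2 >= threshold, "gain",
                      ifelse(seg$mean_log2 <= -threshold, "loss", NA))
  seg <- seg[!is.na(seg$state) & seg$n_probes >= minProbes, , drop = FALSE]
  if (nrow(seg)) {
    # merge runs of adjacent qualifying same-state segments
    newRun <- c(TRUE, !(seg$sample[-1] == seg$sample[-nrow(seg)] &
                        seg$chrom[-1] == seg$chrom[-nrow(seg)] &
                        seg$state[-1] == seg$state[-nrow(seg)] &
                        seg$start_probe[-1] == seg$end_probe[-nrow(seg)] + 1))
    run <- cumsum(newRun)
    seg <- do.call(rbind, lapply(split(seg, run), function(d) data.frame(
      sample = d$sample[1], chrom = d$chrom[1],
      start_bp = d$start_bp[1], end_bp = d$end_bp[nrow(d)],
      state = d$state[1],
      mean_log2 = sum(d$mean_log2 * d$n_probes) / sum(d$n_probes),
      n_probes = sum(d$n_probes), stringsAsFactors = FALSE)))
  }
  si <- if (is.null(genome)) NULL else .layoutSeqinfo(.checkLayout(genome))
  gr <- GenomicRanges::GRanges(
    if (nrow(seg)) seg$chrom else character(0),
    IRanges::IRanges(start = if (nrow(seg)) seg$start_bp else integer(0),
                     end = if (nrow(seg)) seg$end_bp else integer(0)),
    seqinfo = si)
  gr$sample <- if (nrow(seg)) seg$sample else character(0)
  gr$state <- if (nrow(seg)) seg$state else character(0)
  gr$mean_log2 <- if (nrow(seg)) seg$mean_log2 else numeric(0)
  gr$n_probes <- if (nrow(seg)) as.integer(seg$n_probes) else integer(0)
  names(gr) <- NULL
  gr
}

#' Type one sample over a region against the two-copy reference
#'
#' Returns `"gain"` or `"loss"` if any of the sample's calls of that state
#' overlaps the region, `"normal"` if none does (same copy state as the
#' reference), and `"both"` with a warning when gain and loss calls both
#' overlap it.
#'
#' @param calls call `GRanges` from [callCnvs()].
#' @param region a length-1 `GRanges`.
#' @param sample sample id to type.
#' @return one of `"gain"`, `"loss"`, `"normal"`, `"both"`.
#' @export
genotypeSampleRegion <- function(calls, region, sample) {
  if (length(region) != 1) stop("region must be a single interval")
  mine <- calls[calls$sample == sample]
  hit <- mine[IRanges::overlapsAny(mine, region)]
  states <- unique(hit$state)
  if (all(c("gain", "loss") %in% states)) {
    warning("sample ", sample, " has both gain and loss calls over region")
    return("both")
  }
  if ("gain" %in% states) return("gain")
  if ("loss" %in% states) return("loss")
  "normal"
}
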