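#' Describe a genome layout
#'
#' A genome layout is an ordered table of chromosome names and lengths, with
#' an optional mitochondrial contig flagged by name. All coordinates in the
#' package are 0-based half-open on disk and 1-based closed inside R
#' (`GRanges` convention); lengths are in base pairs.
#'
#' @param chrom character vector of unique chromosome names.
#' @param length integer-ish vector of chromosome lengths in bp, all > 0.
#' @param mito name of the mitochondrial contig (flagged "M"), or `NA` if the
#'   layout has none.
#' @return A `data.frame` with columns `chrom`, `length`, `is_mito`.
#' @examples
#' genomeLayout(c("chr1", "chrM"), c(1e6, 16000), mito = "chrM")
#' @export
genomeLayout <- function(chrom, length, mito = NA_character_) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (length(chrom) != base::length(length))
    stop("chrom and length differ in length")
  if (any(!is.finite(length)) || any(length <= 0))
    stop("chromosome lengths must be positive")
  if (!is.na(mito) && !mito %in% chrom)
    stop("mitochondrial contig '", mito, "' not among chromosome names")
  data.frame(chrom = chrom, length = length,
             is_mito = !is.na(mito) & chrom == mito,
             stringsAsFactors = FALSE)
}

#' Default desk-scale genome layout
#'
#' Five 10-Mb autosomes plus a 16-kb mitochondrial contig: a scaled-down
#' stand-in for a multi-chromosome bovine assembly that preserves
#' multi-chromosome structure at desk-scale runtime.
#'
#' @return A genome layout `data.frame` (see [genomeLayout()]).
#' @export
defaultGenome <- function() {
  genomeLayout(c(paste0("chr", 1:5), "chrM"),
               c(rep(10e6, 5), 16e3), mito = "chrM")
}

# Seqinfo for GRanges built from a genome layout
.layoutSeqinfo <- function(genome) {
  Seqinfo(seqnames = genome$chrom, seqlengths = as.integer(genome$length))
}

.checkLayout <- function(genome) {
  if (!is.data.frame(genome) ||
      !all(c("chrom", "length") %in% names(genome)))
    stop("genome must be a layout data.frame with columns chrom, length")
  if (is.null(genome$is_mito)) genome$is_mito <- FALSE
  genome
}

.checkSeed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("seed must be a single finite number")
  as.integer(seed)
}

# group assignment: named character vector sample -> group
.checkGroups <- function(groups) {
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be a named vector: names are sample ids")
  if (anyDuplicated(names(groups))) stop("duplicate sample ids in groups")
  g <- as.character(groups)
  names(g) <- names(groups)
  g
}
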