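#' Intersect CNVRs with gene/QTL intervals by overlap fraction
#'
#' For every CNVR/feature pair with any overlap, computes the overlap in
#' base pairs and its fraction of the FEATURE length; a feature is a
#' positive hit of the CNVR when that fraction strictly exceeds
#' `minFraction` (the ">50%" containment rule: a feature overlapped at
#' exactly half is not positive). The summary counts CNVRs with at least
#' one positive gene or QTL and tallies positive QTLs by trait class.
#'
#' @param cnvrs a [CnvrSet-class] (or a `GRanges` with a `cnvr_id` mcol).
#' @param features `GRanges` from [makeFeatures()] (mcols `feature_id`,
#'   `kind`, and `class` for QTLs). Chromosome names must all be known to
#'   the CNVR set; unmatched names are an error listing the offenders.
#' @param minFraction positivity cutoff on the feature-length fraction,
#'   strict (default 0.5).
#' @return list with `hits` (`data.frame`: `cnvr_id`, `feature_id`, `kind`,
#'   `overlap_bp`, `fraction`, `positive`) and `summary` (list: `n_cnvrs`,
#'   `n_gene_cnvrs`, `pct_gene_cnvrs`, `n_qtl_cnvrs`, `pct_qtl_cnvrs`,
#'   `n_genes`, `n_qtls`, `qtl_class_counts`).
#' @export
overlapFeatures <- function(cnvrs, features, minFraction = 0.5) {
  r <- if (methods::is(cnvrs, "CnvrSet")) regions(cnvrs) else cnvrs
  if (!"cnvr_id" %in% names(mcols(r))) stop("cnvrs must carry cnvr_id")
  known <- unique(as.character(seqnames(r)))
  if (length(GenomeInfoDb::seqlevels(r)))
    known <- union(known, GenomeInfoDb::seqlevels(r))
  bad <- setdiff(unique(as.character(seqnames(features))), known)
  if (length(bad))
    stop("feature chromosome name(s) not found in CNVR set: ",
         paste(bad, collapse = ", "))
  hits <- GenomicRanges::findOverlaps(r, features, ignore.strand = TRUE)
  q <- queryHits(hits); s <- subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(granges(r)[q],
                                           granges(features)[s]))
  # sum overlap bp per (cnvr, feature) pair before taking the fraction
  key <- paste(q, s, sep = "_")
  ovSum <- tapply(ov, key, sum)
  first <- !duplicated(key)
  q1 <- q[first]; s1 <- s[first]
  ovTot <- as.numeric(ovSum[paste(q1, s1, sep = "_")])
  frac <- ovTot / IRanges::width(features)[s1]
  hitsDf <- data.frame(
    cnvr_id = r$cnvr_id[q1],
    feature_id = features$feature_id[s1],
    kind = features$kind[s1],
    class = if ("class" %in% names(mcols(features)))
      features$class[s1] else NA_character_,
    overlap_bp = ovTot, fraction = frac,
    positive = frac > minFraction,
    stringsAsFactors = FALSE)
  pos <- hitsDf[hitsDf$positive, , drop = FALSE]
  nC <- length(r)
  nGeneC <- length(unique(pos$cnvr_id[pos$kind == "gene"]))
  nQtlC <- length(unique(pos$cnvr_id[pos$kind == "QTL"]))
  qtlTab <- table(pos$class[pos$kind == "QTL"])
  list(hits = hitsDf,
       summary = list(
         n_cnvrs = nC,
         n_gene_cnvrs = nGeneC,
         pct_gene_cnvrs = if (nC) 100 * nGeneC / nC else 0,
         n_qtl_cnvrs = nQtlC,
         pct_qtl_cnvrs = if (nC) 100 * nQtlC / nC else 0,
         n_genes = length(unique(pos$feature_id[pos$kind == "gene"])),
         n_qtls = length(unique(pos$feature_id[pos$kind == "QTL"])),
         qtl_class_counts = setNames(as.integer(qtlTab), names(qtlTab))))
}
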