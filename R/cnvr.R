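#' Aggregate one group's CNV calls into CNVRs
#'
#' CNVRs are the connected components of the interval-overlap graph over a
#' group's calls (transitive union): every maximal run of mutually or
#' transitively overlapping calls becomes one region spanning their union.
#' Overlap means at least one shared base; bookended intervals do not merge.
#' Per region, the state is `gain`/`loss` when all member calls agree and
#' `both` when carriers include at least one of each; frequency is carrier
#' count over the group size (all samples of the group, carriers or not).
#'
#' @param calls `GRanges` of calls from [callCnvs()] (or CNVRs re-fed as
#'   calls; the operation is idempotent).
#' @param groupSamples character vector of all sample ids in the group.
#' @param groupName group label recorded as provenance.
#' @return a [CnvrSet-class].
#' @export
buildCnvrs <- function(calls, groupSamples, groupName = "group") {
  groupSamples <- unique(as.character(groupSamples))
  bad <- setdiff(unique(calls$sample), groupSamples)
  if (length(bad))
    stop("call samples outside the group: ", paste(bad, collapse = ", "))
  red <- GenomicRanges::reduce(calls, min.gapwidth = 0L,
                               ignore.strand = TRUE)
  red <- sort(red)
  hits <- GenomicRanges::findOverlaps(red, calls)
  carr <- vector("list", length(red))
  state <- character(length(red))
  for (i in seq_along(red)) {
    members <- subjectHits(hits)[queryHits(hits) == i]
    carr[[i]] <- sort(unique(calls$sample[members]))
    st <- unique(calls$state[members])
    state[i] <- if (all(c("gain", "loss") %in% st) || "both" %in% st)
      "both" else st[1]
  }
  nC <- lengths(carr)
  red$cnvr_id <- sprintf("%s_CNVR%d", groupName, seq_along(red))
  red$state <- state
  red$n_carriers <- as.integer(nC)
  red$frequency <- nC / length(groupSamples)
  red$groups <- groupName
  CnvrSet(red, carr, setNames(length(groupSamples), groupName))
}

#' Merge CNVR sets across groups
#'
#' Overlap components across all groups' CNVRs (transitive union, >= 1
#' shared base) become the merged CNVR set. Each merged region records which
#' groups contributed (a group shares a merged CNVR iff one of its CNVRs
#' overlaps it), the union of carriers, and frequency over the pooled sample
#' count.
#'
#' @param setList named list of [CnvrSet-class] objects, one per group.
#' @return a [CnvrSet-class]; per-region provenance in mcols `groups`
#'   (comma-joined). Use [vennCounts()] for the Venn accounting.
#' @export
mergeGroups <- function(setList) {
  if (!length(setList)) stop("at least one group CNVR set required")
  if (is.null(names(setList)) || any(!nzchar(names(setList))))
    names(setList) <- paste0("group", seq_along(setList))
  all <- NULL; prov <- character(0); st <- character(0)
  carrAll <- list()
  for (g in names(setList)) {
    r <- regions(setList[[g]])
    gr <- granges(r)
    all <- if (is.null(all)) gr else c(all, gr)
    prov <- c(prov, rep(g, length(r)))
    st <- c(st, r$state)
    carrAll <- c(carrAll, carriers(setList[[g]]))
  }
  red <- sort(GenomicRanges::reduce(all, min.gapwidth = 0L,
                                    ignore.strand = TRUE))
  hits <- GenomicRanges::findOverlaps(red, all)
  nTotal <- sum(vapply(setList, function(x) sum(groupSizes(x)), 0L))
  carr <- vector("list", length(red))
  state <- character(length(red)); groupsOf <- character(length(red))
  for (i in seq_along(red)) {
    members <- subjectHits(hits)[queryHits(hits) == i]
    carr[[i]] <- sort(unique(unlist(carrAll[members])))
    sts <- unique(st[members])
    state[i] <- if (all(c("gain", "loss") %in% sts) || "both" %in% sts)
      "both" else sts[1]
    groupsOf[i] <- paste(names(setList)[names(setList) %in%
                                          unique(prov[members])],
                         collapse = ",")
  }
  red$cnvr_id <- sprintf("CNVR%d", seq_along(red))
  red$state <- state
  red$n_carriers <- lengths(carr)
  red$frequency <- lengths(carr) / nTotal
  red$groups <- groupsOf
  gs <- unlist(lapply(setList, groupSizes))
  names(gs) <- names(setList)
  CnvrSet(red, carr, gs)
}

#' Venn accounting of a merged CNVR set
#'
#' @param x merged [CnvrSet-class] from [mergeGroups()].
#' @return named integer vector: merged CNVR count per group combination
#'   (comma-joined labels), plus attribute `"per_group"` with the number of
#'   merged CNVRs each group shares.
#' @export
vennCounts <- function(x) {
  prov <- regions(x)$groups
  counts <- table(prov)
  out <- setNames(as.integer(counts), names(counts))
  perGroup <- vapply(names(groupSizes(x)), function(g)
    sum(vapply(strsplit(prov, ","), function(p) g %in% p, TRUE)), 0L)
  attr(out, "per_group") <- perGroup
  out
}

#' Summarise a CNVR set (Table-1 style accounting)
#'
#' @param x a [CnvrSet-class].
#' @param genome genome layout giving the assembly length for the percent
#'   column.
#' @return one-row `data.frame`: `samples`, `cnvrs`, `avg` (CNVRs per
#'   sample), `unique` (single-carrier CNVRs), `gain`, `loss`, `both`,
#'   `total_bp` (CNVRs are disjoint, so lengths sum), `pct_genome`.
#' @export
summarizeCnvrs <- function(x, genome) {
  genome <- .checkLayout(genome)
  glen <- sum(genome$length)
  if (glen <= 0) stop("genome length must be positive")
  r <- regions(x)
  nS <- sum(groupSizes(x))
  st <- factor(r$state, c("gain", "loss", "both"))
  data.frame(
    samples = nS,
    cnvrs = length(r),
    avg = if (nS) length(r) / nS else 0,
    unique = sum(r$n_carriers == 1),
    gain = sum(st == "gain"), loss = sum(st == "loss"),
    both = sum(st == "both"),
    total_bp = if (length(r)) sum(IRanges::width(r)) else 0,
    pct_genome = 100 * (if (length(r)) sum(IRanges::width(r)) else 0) / glen)
}

#' Per-chromosome CNVR coverage
#'
#' @param x a [CnvrSet-class].
#' @param genome genome layout.
#' @return `data.frame` (`chrom`, `covered_bp`, `pct`), one row per
#'   chromosome of the layout, ranked by descending coverage.
#' @export
chromCoverage <- function(x, genome) {
  genome <- .checkLayout(genome)
  r <- regions(x)
  cov <- setNames(numeric(nrow(genome)), genome$chrom)
  if (length(r)) {
    byChrom <- tapply(IRanges::width(r), as.character(seqnames(r)), sum)
    cov[names(byChrom)] <- byChrom
  }
  out <- data.frame(chrom = genome$chrom, covered_bp = unname(cov),
                    pct = 100 * unname(cov) / genome$length)
  out[order(-out$pct, out$chrom), ]
}
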