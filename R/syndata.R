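#' Simulate an array probe layout
#'
#' Tiles each chromosome with short oligo probes at jittered spacing:
#' successive probe starts are separated by gaps drawn uniformly on
#' [0.5, 1.5] x `meanSpacing` (floored at the probe length so probes never
#' overlap), emulating an evenly distributed aCGH design. A mitochondrial
#' contig (flagged in the layout) receives exactly `mitoProbes` evenly
#' spaced probes regardless of spacing.
#'
#' @param genome genome layout from [genomeLayout()].
#' @param meanSpacing mean probe start-to-start spacing in bp (default 3364).
#' @param probeLen probe length in bp, typically in 50-75 (default 60).
#' @param seed integer seed; the layout is deterministic given the seed.
#' @param mitoProbes probe count on the mitochondrial contig (default 5).
#' @return `GRanges` probe map, sorted, non-overlapping within chromosome,
#'   with mcols column `probe_id`.
#' @examples
#' g <- genomeLayout("chr1", 1e6)
#' length(makeProbes(g, meanSpacing = 3364, seed = 1))  # ~ 297
#' @export
makeProbes <- function(genome, meanSpacing = 3364, probeLen = 60, seed = 1,
                       mitoProbes = 5) {
  genome <- .checkLayout(genome)
  if (meanSpacing <= probeLen) stop("meanSpacing must exceed probeLen")
  set.seed(.checkSeed(seed))
  chroms <- character(0); starts <- numeric(0)
  for (i in seq_len(nrow(genome))) {
    len <- genome$length[i]
    if (len < probeLen)
      stop("chromosome ", genome$chrom[i], " (", len,
           " bp) is shorter than one probe (", probeLen, " bp)")
    if (genome$is_mito[i]) {
      s <- unique(round(seq(1, len - probeLen + 1, length.out = mitoProbes)))
      if (length(s) < mitoProbes)
        stop("mitochondrial contig too short for ", mitoProbes, " probes")
    } else {
      ndraw <- ceiling(len / (0.45 * meanSpacing)) + 2
      gaps <- pmax(probeLen, runif(ndraw, 0.5, 1.5) * meanSpacing)
      s <- 1 + round(cumsum(c(0, gaps)))
      s <- s[s + probeLen - 1 <= len]
    }
    chroms <- c(chroms, rep(genome$chrom[i], length(s)))
    starts <- c(starts, s)
  }
  gr <- GenomicRanges::GRanges(
    factor(chroms, levels = genome$chrom),
    IRanges::IRanges(start = starts, width = probeLen),
    seqinfo = .layoutSeqinfo(genome))
  gr$probe_id <- paste0(as.character(seqnames(gr)), "_p",
                        unlist(lapply(split(seq_along(gr), seqnames(gr)),
                                      seq_along), use.names = FALSE))
  gr
}

#' Describe a planted-event design
#'
#' Counts and size/copy-number distributions for planted copy-number events
#' at three sharing scopes: `shared-all` events are placed identically in
#' every sample, `group` events identically in every member of one group,
#' `private` events in exactly one sample. Copy number 2 is background;
#' planted events carry 0, 1 (losses), 3 or 4 (gains) copies. Default copy
#' weights are loss-heavy (losses about three times as frequent as gains,
#' as aCGH panels typically show).
#'
#' @param nShared number of shared-all events.
#' @param nGroup number of events per group.
#' @param nPrivate number of private events per sample.
#' @param lenRange min/max event length in bp.
#' @param cnProbs named probability weights over copy numbers 0, 1, 3, 4.
#' @param mitoCn optional named vector group -> mitochondrial copy number;
#'   groups listed get a whole-contig event of that copy number in every
#'   member (emulating group-level mitochondrial copy shifts).
#' @return list of class `eventDesign`.
#' @export
eventDesign <- function(nShared = 3, nGroup = 3, nPrivate = 2,
                        lenRange = c(24000, 75000),
                        cnProbs = c(`0` = 0.15, `1` = 0.45,
                                    `3` = 0.20, `4` = 0.20),
                        mitoCn = NULL) {
  stopifnot(nShared >= 0, nGroup >= 0, nPrivate >= 0,
            length(lenRange) == 2, lenRange[1] <= lenRange[2])
  if (!all(names(cnProbs) %in% c("0", "1", "3", "4")))
    stop("cnProbs names must be among 0, 1, 3, 4 (2 is background)")
  structure(list(nShared = nShared, nGroup = nGroup, nPrivate = nPrivate,
                 lenRange = lenRange, cnProbs = cnProbs / sum(cnProbs),
                 mitoCn = mitoCn),
            class = "eventDesign")
}

# TRUE where candidate [start,end] overlaps an existing event of any sample
# in `samples` (truth is the accumulating event data.frame)
.truthOverlaps <- function(truth, samples, chrom, start, end) {
  if (!nrow(truth)) return(FALSE)
  sel <- truth$sample %in% samples & truth$chrom == chrom
  any(truth$start[sel] <= end & truth$end[sel] >= start)
}

#' Plant copy-number events into samples
#'
#' Draws non-overlapping ground-truth events per the design. Events are
#' placed shared-all first, then group, then private; a candidate colliding
#' with an already placed event (in any sample that would carry it) is
#' redrawn elsewhere, so the first-placed event wins and the final per-sample
#' event sets are non-overlapping.
#'
#' @param genome genome layout.
#' @param groups named character vector sample id -> group label.
#' @param design an [eventDesign()].
#' @param seed integer seed.
#' @param maxTries placement retries before giving up.
#' @return `data.frame` with columns `sample`, `group`, `chrom`, `start`,
#'   `end` (1-based closed bp), `cn`, `scope`.
#' @export
plantEvents <- function(genome, groups, design = eventDesign(), seed = 1,
                        maxTries = 1000) {
  genome <- .checkLayout(genome)
  groups <- .checkGroups(groups)
  if (!length(groups)) stop("at least one sample required")
  set.seed(.checkSeed(seed))
  auto <- genome[!genome$is_mito, , drop = FALSE]
  if (design$lenRange[1] > max(auto$length))
    stop("requested event length ", design$lenRange[1],
         " exceeds every chromosome length")
  cnPool <- as.integer(names(design$cnProbs))
  truth <- data.frame(sample = character(0), group = character(0),
                      chrom = character(0), start = numeric(0),
                      end = numeric(0), cn = integer(0),
                      scope = character(0), stringsAsFactors = FALSE)
  place <- function(samples, scope) {
    cn <- sample(cnPool, 1, prob = design$cnProbs)
    for (try in seq_len(maxTries)) {
      len <- round(runif(1, design$lenRange[1], design$lenRange[2]))
      ok <- auto$length >= len
      if (!any(ok)) stop("event length ", len, " longer than any chromosome")
      ci <- sample(which(ok), 1, prob = auto$length[ok])
      start <- floor(runif(1, 1, auto$length[ci] - len + 1))
      end <- start + len - 1
      if (!.truthOverlaps(truth, samples, auto$chrom[ci], start, end)) {
        truth <<- rbind(truth, data.frame(
          sample = samples, group = unname(groups[samples]),
          chrom = auto$chrom[ci], start = start, end = end,
          cn = cn, scope = scope, stringsAsFactors = FALSE))
        return(invisible(NULL))
      }
    }
    stop("could not place a ", scope, " event after ", maxTries, " tries")
  }
  for (i in seq_len(design$nShared)) place(names(groups), "shared-all")
  for (g in unique(groups))
    for (i in seq_len(design$nGroup))
      place(names(groups)[groups == g], "group")
  for (s in names(groups))
    for (i in seq_len(design$nPrivate)) place(s, "private")
  if (!is.null(design$mitoCn)) {
    mito <- genome[genome$is_mito, , drop = FALSE]
    if (!nrow(mito)) stop("design has mitoCn but layout has no mito contig")
    for (g in names(design$mitoCn)) {
      cn <- as.integer(design$mitoCn[[g]])
      if (cn == 2) next
      members <- names(groups)[groups == g]
      truth <- rbind(truth, data.frame(
        sample = members, group = g, chrom = mito$chrom[1],
        start = 1, end = mito$length[1], cn = cn, scope = "group",
        stringsAsFactors = FALSE))
    }
  }
  rownames(truth) <- NULL
  truth
}

#' Simulate log2-ratio profiles over a probe map
#'
#' The expected value at a probe is `log2(CN/2)` where CN is the planted
#' copy number at the probe midpoint (2 elsewhere); homozygous deletions
#' (CN = 0) are floored at `cnFloor` log2 units, as saturating arrays are.
#' Independent Gaussian noise of standard deviation `noiseSd` is added per
#' probe.
#'
#' @param probes `GRanges` probe map from [makeProbes()].
#' @param truth event `data.frame` from [plantEvents()] (may have 0 rows).
#' @param groups named character vector sample id -> group label.
#' @param noiseSd per-probe noise standard deviation in log2 units (>= 0).
#' @param seed integer seed.
#' @param cnFloor log2 expectation assigned to CN = 0 probes (default -3).
#' @return an [AcghSet-class].
#' @export
simulateRatios <- function(probes, truth, groups, noiseSd = 0.2, seed = 1,
                           cnFloor = -3) {
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  groups <- .checkGroups(groups)
  set.seed(.checkSeed(seed))
  mid <- floor((start(probes) + end(probes)) / 2)
  chrom <- as.character(seqnames(probes))
  n <- length(probes)
  m <- matrix(0, n, length(groups),
              dimnames = list(NULL, names(groups)))
  for (s in names(groups)) {
    ev <- truth[truth$sample == s, , drop = FALSE]
    mu <- numeric(n)
    for (k in seq_len(nrow(ev))) {
      hit <- chrom == ev$chrom[k] & mid >= ev$start[k] & mid <= ev$end[k]
      mu[hit] <- if (ev$cn[k] == 0) cnFloor else log2(ev$cn[k] / 2)
    }
    m[, s] <- mu + rnorm(n, 0, noiseSd)
  }
  AcghSet(probes, m, groups)
}

#' Simulate gene and QTL annotation intervals
#'
#' Random (possibly overlapping) intervals labelled `gene` or `QTL`;
#' QTLs carry a trait class drawn from the six conventional classes
#' (exterior, health, meat-carcass, milk, production, reproduction).
#'
#' @param genome genome layout.
#' @param nGenes,nQtls interval counts (>= 0).
#' @param geneLenRange,qtlLenRange min/max lengths in bp.
#' @param seed integer seed.
#' @return sorted `GRanges` with mcols `feature_id`, `kind`, `name`, `class`
#'   (`NA` for genes).
#' @export
makeFeatures <- function(genome, nGenes = 300, nQtls = 150,
                         geneLenRange = c(5e3, 5e4),
                         qtlLenRange = c(5e4, 5e5), seed = 1) {
  genome <- .checkLayout(genome)
  stopifnot(nGenes >= 0, nQtls >= 0)
  set.seed(.checkSeed(seed))
  auto <- genome[!genome$is_mito, , drop = FALSE]
  qtlClasses <- c("exterior", "health", "meat-carcass", "milk",
                  "production", "reproduction")
  drawOne <- function(lenRange) {
    len <- min(round(runif(1, lenRange[1], lenRange[2])), max(auto$length))
    ok <- auto$length >= len
    ci <- sample(which(ok), 1, prob = auto$length[ok])
    start <- floor(runif(1, 1, auto$length[ci] - len + 1))
    c(ci = ci, start = start, end = start + len - 1)
  }
  rows <- lapply(seq_len(nGenes + nQtls), function(i)
    drawOne(if (i <= nGenes) geneLenRange else qtlLenRange))
  if (!length(rows)) {
    return(GenomicRanges::GRanges(seqinfo = .layoutSeqinfo(genome),
                                  feature_id = character(0),
                                  kind = character(0), name = character(0),
                                  class = character(0)))
  }
  rows <- do.call(rbind, rows)
  kind <- rep(c("gene", "QTL"), c(nGenes, nQtls))
  gr <- GenomicRanges::GRanges(
    factor(auto$chrom[rows[, "ci"]], levels = genome$chrom),
    IRanges::IRanges(rows[, "start"], rows[, "end"]),
    seqinfo = .layoutSeqinfo(genome))
  gr$feature_id <- paste0(ifelse(kind == "gene", "gene", "qtl"),
                          c(seq_len(nGenes), seq_len(nQtls)))
  gr$kind <- kind
  gr$name <- toupper(gr$feature_id)
  gr$class <- ifelse(kind == "QTL",
                     sample(qtlClasses, nGenes + nQtls, replace = TRUE),
                     NA_character_)
  sort(gr)
}

#' Default effect specifications for the five growth traits
#'
#' Plausible overall means and residual standard deviations for body height,
#' body length, heart girth and hucklebone width (cm) and body weight (kg)
#' in adult Chinese beef cattle, with genotype effects concentrated on body
#' length and heart girth (loss carriers larger, gain carriers smaller) and
#' modest farm/breed effects.
#'
#' @param farms,breeds,genotypes factor level names.
#' @return named list of per-trait effect specs usable by
#'   [simulatePhenotypes()].
#' @export
defaultTraitSpecs <- function(farms = c("farmA", "farmB", "farmC"),
                              breeds = c("Qinchuan", "Jiaxian", "Nanyang"),
                              genotypes = c("gain", "loss", "normal")) {
  eff <- function(levels, values) setNames(values[seq_along(levels)], levels)
  spread <- function(levels, step)
    eff(levels, step * (seq_along(levels) - mean(seq_along(levels))))
  mk <- function(mu, sd, gEff) list(
    mu = mu, sd = sd,
    farm = spread(farms, sd / 4), breed = spread(breeds, sd / 4),
    genotype = setNames(gEff[c("gain", "loss", "normal")][
      match(genotypes, c("gain", "loss", "normal"))], genotypes))
  list(
    body_height = mk(126.7, 6.0, c(gain = 0, loss = 0, normal = 0)),
    body_length = mk(139.9, 10.1, c(gain = -6.0, loss = 5.3, normal = 0)),
    heart_girth = mk(174.5, 10.0, c(gain = -4.6, loss = 1.5, normal = 0)),
    hucklebone_width = mk(21.3, 4.6, c(gain = 1.9, loss = -0.9, normal = 0)),
    body_weight = mk(368.5, 59.7, c(gain = -13.8, loss = 16.6, normal = 0)))
}

#' Simulate phenotypes under the additive fixed-effects trait model
#'
#' Each trait value is drawn as
#' `Y = mu + farm effect + genotype effect + breed effect + N(0, sd)`,
#' the model the association stage fits. The true effects are attached as
#' attribute `"effects"` for recovery testing.
#'
#' @param records `data.frame` with columns `sample`, `farm`, `breed`,
#'   `genotype`; every value must be a level named in the trait specs.
#' @param traits named list of per-trait specs, each a list with `mu`,
#'   `sd`, and named effect vectors `farm`, `breed`, `genotype`
#'   (see [defaultTraitSpecs()]).
#' @param seed integer seed.
#' @return `data.frame` of `records` plus one column per trait.
#' @export
simulatePhenotypes <- function(records, traits = defaultTraitSpecs(),
                               seed = 1) {
  need <- c("sample", "farm", "breed", "genotype")
  if (!all(need %in% names(records)))
    stop("records needs columns: ", paste(need, collapse = ", "))
  set.seed(.checkSeed(seed))
  out <- records[, need, drop = FALSE]
  for (tn in names(traits)) {
    sp <- traits[[tn]]
    for (fac in c("farm", "breed", "genotype")) {
      bad <- setdiff(unique(records[[fac]]), names(sp[[fac]]))
      if (length(bad))
        stop("unknown ", fac, " level(s) for trait ", tn, ": ",
             paste(bad, collapse = ", "))
    }
    out[[tn]] <- sp$mu + unname(sp$farm[records$farm]) +
      unname(sp$genotype[records$genotype]) +
      unname(sp$breed[records$breed]) +
      rnorm(nrow(records), 0, sp$sd)
  }
  attr(out, "effects") <- traits
  out
}

#' Simulate a qPCR Ct table from known copy numbers
#'
#' Target-assay Ct decreases by one cycle per copy-number doubling:
#' `Ct = baseCt - log2(CN/2) + noise`; the control-gene Ct is independent
#' of copy number. A CN = 0 target never amplifies and is reported at the
#' configured ceiling cycle. The calibrator sample must carry 2 copies.
#'
#' @param cn named integer vector sample id -> copy number at the assayed
#'   locus.
#' @param calibrator sample id used downstream as the two-copy reference.
#' @param baseCt target-assay Ct of a two-copy sample (cycles).
#' @param controlCt control-gene Ct (cycles).
#' @param repSd replicate noise sd in cycles (>= 0).
#' @param nReps technical replicates per well (>= 1).
#' @param seed integer seed.
#' @param noAmpCt ceiling Ct reported for CN = 0 targets.
#' @param targetAssay,controlAssay assay names in the output table.
#' @return `data.frame` with columns `sample`, `assay`, `role`
#'   (target/control), `rep`, `ct`.
#' @export
simulateQpcr <- function(cn, calibrator, baseCt = 25, controlCt = 20,
                         repSd = 0, nReps = 3, seed = 1, noAmpCt = 40,
                         targetAssay = "target", controlAssay = "BTF3") {
  if (nReps < 1) stop("nReps must be >= 1")
  if (repSd < 0) stop("repSd must be >= 0")
  if (is.null(names(cn))) stop("cn must be named by sample id")
  if (!calibrator %in% names(cn)) stop("calibrator absent from cn")
  if (cn[[calibrator]] != 2) stop("calibrator must have copy number 2")
  set.seed(.checkSeed(seed))
  rows <- lapply(names(cn), function(s) {
    tgt <- if (cn[[s]] == 0) rep(noAmpCt, nReps)
           else baseCt - log2(cn[[s]] / 2) + rnorm(nReps, 0, repSd)
    ctl <- controlCt + rnorm(nReps, 0, repSd)
    data.frame(sample = s,
               assay = rep(c(targetAssay, controlAssay), each = nReps),
               role = rep(c("target", "control"), each = nReps),
               rep = rep(seq_len(nReps), 2), ct = c(tgt, ctl),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Recall and precision of CNV calls against planted truth
#'
#' A planted event counts as recovered when a call of the matching state
#' (losses for CN < 2, gains for CN > 2) in the same sample covers at least
#' `minCover` of its bases; a call counts as correct when at least
#' `minCover` of its bases lie inside matching truth events of its sample.
#'
#' @param truth truth `data.frame` from [plantEvents()].
#' @param calls call `GRanges` from [callCnvs()].
#' @param minCover required covered fraction on each side (default 0.5).
#' @return list with `recall`, `precision`, `n_events`, `n_calls`.
#' @export
eventRecovery <- function(truth, calls, minCover = 0.5) {
  truthState <- ifelse(truth$cn < 2, "loss", "gain")
  covered <- function(chrom, s1, e1, sample, state) {
    # fraction of [s1, e1] covered by matching calls
    sel <- calls$sample == sample & calls$state == state &
      as.character(seqnames(calls)) == chrom
    if (!any(sel)) return(0)
    cs <- pmax(start(calls)[sel], s1)
    ce <- pmin(end(calls)[sel], e1)
    keep <- ce >= cs
    if (!any(keep)) return(0)
    sum(ce[keep] - cs[keep] + 1) / (e1 - s1 + 1)  # calls are disjoint
  }
  rec <- vapply(seq_len(nrow(truth)), function(i)
    covered(truth$chrom[i], truth$start[i], truth$end[i],
            truth$sample[i], truthState[i]) >= minCover, TRUE)
  prec <- vapply(seq_along(calls), function(i) {
    sel <- truth$sample == calls$sample[i] &
      truthState == calls$state[i] &
      truth$chrom == as.character(seqnames(calls))[i]
    if (!any(sel)) return(FALSE)
    cs <- pmax(truth$start[sel], start(calls)[i])
    ce <- pmin(truth$end[sel], end(calls)[i])
    keep <- ce >= cs
    if (!any(keep)) return(FALSE)
    sum(ce[keep] - cs[keep] + 1) / IRanges::width(calls)[i] >= minCover
  }, TRUE)
  list(recall = if (nrow(truth)) mean(rec) else NA_real_,
       precision = if (length(calls)) mean(prec) else NA_real_,
       n_events = nrow(truth), n_calls = length(calls))
}
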