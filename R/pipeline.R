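#' Build and validate a run configuration
#'
#' Central parameter container for [runAll()]. Unknown keys are rejected;
#' every parameter is range-checked here, before any computation.
#'
#' @param genome genome layout (default [defaultGenome()]).
#' @param groups named character vector sample id -> group label; the
#'   default is a 12-sample panel in the 3 bovine groups (7 taurine, 2 yak,
#'   3 buffalo), the paper-like proportions at desk scale.
#' @param design planted-event design from [eventDesign()]; the default
#'   adds the group-level mitochondrial copy shift (taurine gain, yak and
#'   buffalo loss).
#' @param meanSpacing,probeLen probe layout parameters in bp.
#' @param noiseSd per-probe log2 noise sd.
#' @param penalty segmentation penalty, `"auto"` or a number >= 0.
#' @param threshold CNV-calling log2 cutoff (> 0).
#' @param minProbes minimum probes per CNV (>= 1).
#' @param minFraction feature positivity fraction in (0, 1).
#' @param nGenes,nQtls simulated annotation sizes.
#' @param nPerm indicator-value permutations (>= 1).
#' @param alpha significance level in (0, 1).
#' @param seed master seed; stage seeds are derived from it.
#' @param verbose emit stage-tagged progress to stderr.
#' @return validated config list of class `cnvherdConfig`.
#' @export
runConfig <- function(genome = defaultGenome(),
                      groups = NULL,
                      design = NULL,
                      meanSpacing = 3364, probeLen = 60,
                      noiseSd = 0.2, penalty = "auto",
                      threshold = 0.5, minProbes = 5, minFraction = 0.5,
                      nGenes = 300, nQtls = 150,
                      nPerm = 199, alpha = 0.05,
                      seed = 1, verbose = FALSE) {
  if (is.null(groups))
    groups <- setNames(c(rep("taurine", 7), rep("yak", 2),
                         rep("buffalo", 3)),
                       c(paste0("tau", 1:7), paste0("yak", 1:2),
                         paste0("buf", 1:3)))
  if (is.null(design))
    design <- eventDesign(mitoCn = c(taurine = 3, yak = 1, buffalo = 1)[
      intersect(c("taurine", "yak", "buffalo"), unique(groups))])
  stopifnot(meanSpacing > probeLen, probeLen > 0, noiseSd >= 0,
            threshold > 0, minProbes >= 1,
            minFraction > 0, minFraction < 1,
            nGenes >= 0, nQtls >= 0, nPerm >= 1,
            alpha > 0, alpha < 1)
  if (!identical(penalty, "auto") &&
      (!is.numeric(penalty) || penalty < 0))
    stop("penalty must be 'auto' or a nonnegative number")
  structure(list(genome = .checkLayout(genome),
                 groups = .checkGroups(groups), design = design,
                 meanSpacing = meanSpacing, probeLen = probeLen,
                 noiseSd = noiseSd, penalty = penalty,
                 threshold = threshold, minProbes = minProbes,
                 minFraction = minFraction, nGenes = nGenes,
                 nQtls = nQtls, nPerm = nPerm, alpha = alpha,
                 seed = .checkSeed(seed), verbose = isTRUE(verbose)),
            class = "cnvherdConfig")
}

#' Read a run configuration from YAML
#'
#' Scalar parameters of [runConfig()] may be set; unknown keys are
#' rejected. `groups` may be given as a mapping sample -> group.
#'
#' @param path YAML file path.
#' @return validated config from [runConfig()].
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  allowed <- c("meanSpacing", "probeLen", "noiseSd", "penalty",
               "threshold", "minProbes", "minFraction", "nGenes",
               "nQtls", "nPerm", "alpha", "seed", "verbose", "groups")
  bad <- setdiff(names(y), allowed)
  if (length(bad))
    stop(path, ": unknown config key(s): ", paste(bad, collapse = ", "))
  if (!is.null(y$groups)) y$groups <- unlist(y$groups)
  do.call(runConfig, y)
}

.stage <- function(name, verbose, expr) {
  if (verbose) message("[", name, "] ...")
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full pipeline on a simulated experiment
#'
#' Simulate probes, truth events, log2 ratios, features, qPCR and
#' phenotypes; then normalise, segment, call CNVs, build per-group CNVRs,
#' merge across groups, annotate, cluster, score indicator values, estimate
#' qPCR copy numbers at a planted locus, and fit the trait association.
#' Fully reproducible for a fixed seed. If `outdir` is given, every stage
#' output is written there (probes/features/calls/CNVRs as BED-like TSV,
#' ratios as TSV matrix, wells/phenotypes as CSV) along with a run report.
#'
#' @param config a `cnvherdConfig` from [runConfig()].
#' @param outdir optional output directory (created if missing).
#' @return list with all stage outputs and `report` (counts per stage,
#'   parameters, seed).
#' @export
runAll <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "cnvherdConfig"))
  v <- config$verbose
  seed <- config$seed
  probes <- .stage("simulate", v, makeProbes(
    config$genome, config$meanSpacing, config$probeLen, seed = seed))
  truth <- .stage("simulate", v, plantEvents(
    config$genome, config$groups, config$design, seed = seed + 1))
  acgh <- .stage("simulate", v, simulateRatios(
    probes, truth, config$groups, config$noiseSd, seed = seed + 2))
  features <- .stage("simulate", v, makeFeatures(
    config$genome, config$nGenes, config$nQtls, seed = seed + 3))
  segs <- .stage("segment", v,
                 segmentSamples(normalizeRatios(acgh), config$penalty))
  calls <- .stage("call", v, callCnvs(
    segs, config$threshold, config$minProbes, genome = config$genome))
  groupsOf <- config$groups
  sets <- .stage("cnvr", v, {
    out <- list()
    for (g in unique(groupsOf)) {
      members <- names(groupsOf)[groupsOf == g]
      out[[g]] <- buildCnvrs(calls[calls$sample %in% members], members, g)
    }
    out
  })
  merged <- .stage("cnvr", v, mergeGroups(sets))
  ann <- .stage("annotate", v,
                overlapFeatures(merged, features, config$minFraction))
  pm <- .stage("groups", v, presenceMatrix(merged, names(groupsOf)))
  tree <- .stage("groups", v, if (length(groupsOf) >= 2 && ncol(pm) > 0)
    clusterSamples(pm) else NULL)
  iv <- .stage("groups", v, if (ncol(pm) > 0)
    indval(pm, groupsOf, nPerm = config$nPerm, seed = seed + 4) else NULL)
  # qPCR at the most widely shared planted autosomal locus
  qpcrOut <- .stage("qpcr", v, {
    auto <- truth[!truth$chrom %in%
                    config$genome$chrom[config$genome$is_mito], ,
                  drop = FALSE]
    if (nrow(auto)) {
      key <- paste(auto$chrom, auto$start, auto$end, auto$cn)
      top <- names(sort(table(key), decreasing = TRUE))[1]
      locus <- auto[match(top, key), ]
      cn <- setNames(rep(2L, length(groupsOf)), names(groupsOf))
      hit <- auto$chrom == locus$chrom & auto$start <= locus$end &
        auto$end >= locus$start
      cn[auto$sample[hit]] <- auto$cn[hit]
      cn <- c(cn, reference = 2L)  # two-copy reference bull as calibrator
      calib <- "reference"
      wells <- simulateQpcr(cn, calib, repSd = 0.05, seed = seed + 5)
      list(locus = locus, wells = wells,
           estimates = relativeCopyNumber(wells, calib, "BTF3"))
    } else NULL
  })
  # trait association against the qPCR-typed genotypes
  assocOut <- .stage("assoc", v, if (!is.null(qpcrOut)) {
    est <- qpcrOut$estimates
    est <- est[est$sample %in% names(groupsOf), , drop = FALSE]
    types <- setNames(est$type, est$sample)
    n <- length(types)
    recs <- data.frame(sample = names(types),
                       farm = paste0("farm", seq_len(n) %% 2 + 1),
                       breed = unname(groupsOf[names(types)]),
                       genotype = unname(types),
                       stringsAsFactors = FALSE)
    specs <- defaultTraitSpecs(farms = unique(recs$farm),
                               breeds = unique(recs$breed),
                               genotypes = unique(recs$genotype))
    pheno <- simulatePhenotypes(recs, specs, seed = seed + 6)
    tab <- tryCatch(assocTable(pheno, alpha = config$alpha),
                    error = function(e) NULL)
    list(pheno = pheno, table = tab)
  } else NULL)
  report <- list(
    seed = seed,
    parameters = config[c("meanSpacing", "probeLen", "noiseSd", "penalty",
                          "threshold", "minProbes", "minFraction",
                          "nPerm", "alpha")],
    counts = list(probes = length(probes), truth_events = nrow(truth),
                  samples = length(groupsOf), segments = nrow(segs),
                  calls = length(calls),
                  cnvrs_per_group = vapply(sets, length, 0L),
                  merged_cnvrs = length(merged),
                  annotation_hits = nrow(ann$hits)))
  out <- list(probes = probes, truth = truth, acgh = acgh,
              features = features, segments = segs, calls = calls,
              groupSets = sets, merged = merged, annotation = ann,
              presence = pm, tree = tree, indval = iv, qpcr = qpcrOut,
              assoc = assocOut, report = report)
  if (!is.null(outdir)) .writeRunOutputs(out, config, outdir)
  out
}

.writeRunOutputs <- function(out, config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  f <- function(x) file.path(outdir, x)
  p <- list(threshold = config$threshold, minProbes = config$minProbes)
  seed <- config$seed
  writeGenome(config$genome, f("genome.tsv"), seed = seed)
  writeProbes(out$probes, f("probes.tsv"), seed = seed)
  writeTruth(out$truth, f("truth.tsv"), seed = seed)
  writeRatios(out$acgh, f("ratios.tsv"), seed = seed)
  writeFeatures(out$features, f("features.tsv"), seed = seed)
  writeCalls(out$calls, f("calls.tsv"), p, seed)
  for (g in names(out$groupSets))
    writeCnvrs(out$groupSets[[g]], f(paste0("cnvrs_", g, ".tsv")), p, seed)
  writeCnvrs(out$merged, f("cnvrs_merged.tsv"), p, seed)
  .writeTable(out$annotation$hits, f("annotation_hits.tsv"),
              .fileHeader(list(minFraction = config$minFraction), seed))
  if (!is.null(out$indval))
    .writeTable(out$indval, f("indval.tsv"),
                .fileHeader(list(nPerm = config$nPerm), seed))
  if (!is.null(out$qpcr)) {
    writeWells(out$qpcr$wells, f("qpcr_wells.csv"), seed = seed)
    .writeTable(out$qpcr$estimates, f("qpcr_estimates.csv"),
                .fileHeader(seed = seed), sep = ",")
  }
  if (!is.null(out$assoc)) {
    writePhenotypes(out$assoc$pheno, f("phenotypes.csv"), seed = seed)
    if (!is.null(out$assoc$table))
      .writeTable(out$assoc$table, f("assoc_table.tsv"),
                  .fileHeader(list(alpha = config$alpha), seed))
  }
  rep <- out$report
  writeLines(c(.fileHeader(rep$parameters, rep$seed),
               paste0(names(unlist(rep$counts)), "\t",
                      unlist(rep$counts))),
             f("run_report.tsv"))
  invisible(outdir)
}
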