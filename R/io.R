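# ---- shared helpers ---------------------------------------------------------
# Every writer puts a comment header with tool version, parameters and seed;
# every reader skips '#' lines and validates field counts line by line.
# Genomic records are 0-based half-open on disk, 1-based closed in R.

.fileHeader <- function(params = list(), seed = NULL, extra = character(0)) {
  p <- if (length(params))
    paste(names(params), unlist(params), sep = "=", collapse = " ")
  else "-"
  c(paste0("#cnvherd ", as.character(packageVersion("cnvherd")),
           " | params: ", p, " | seed: ",
           if (is.null(seed)) "NA" else seed),
    extra)
}

.writeTable <- function(df, path, comment, sep = "\t") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(comment, con)
  write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE,
              col.names = TRUE)
}

# read a delimited file with per-line field-count validation; returns the
# data.frame plus the comment lines as attribute "comments"
.readTable <- function(path, sep, required, numericCols = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  isComment <- startsWith(lines, "#")
  body <- which(!isComment & nzchar(lines))
  if (!length(body)) stop(path, ": no header line found")
  split1 <- strsplit(lines[body], sep, fixed = TRUE)
  headerFields <- split1[[1]]
  nf <- length(headerFields)
  for (k in seq_along(body)[-1]) {
    if (length(split1[[k]]) != nf)
      stop(path, ": line ", body[k], " has ", length(split1[[k]]),
           " fields, expected ", nf, " (", lines[body[k]], ")")
  }
  df <- as.data.frame(do.call(rbind, split1[-1]), stringsAsFactors = FALSE)
  if (!nrow(df)) df <- as.data.frame(matrix(character(0), 0, nf),
                                     stringsAsFactors = FALSE)
  names(df) <- headerFields
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  for (cc in intersect(numericCols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (nrow(df) && anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop(path, ": line ", body[bad + 1], ": non-numeric value '",
           df[[cc]][bad], "' in column ", cc)
    }
    df[[cc]] <- v
  }
  attr(df, "comments") <- lines[isComment]
  df
}

.checkBed <- function(df, path) {
  bad <- which(df$end <= df$start)
  if (length(bad))
    stop(path, ": record ", bad[1], " (", df$chrom[bad[1]], ":",
         df$start[bad[1]], "-", df$end[bad[1]],
         ") has end <= start (0-based half-open required)")
}

# ---- genome layout ----------------------------------------------------------

#' Read / write a genome layout table
#'
#' TSV with columns `chrom`, `length` and optional `is_mito` (0/1).
#' @param path file path.
#' @param genome genome layout `data.frame`.
#' @param seed seed recorded in the header comment.
#' @return `readGenome`: a genome layout `data.frame`.
#' @export
readGenome <- function(path) {
  df <- .readTable(path, "\t", c("chrom", "length"), "length")
  mito <- if ("is_mito" %in% names(df)) df$chrom[df$is_mito == "1"][1]
          else NA_character_
  genomeLayout(df$chrom, df$length, mito = mito)
}

#' @rdname readGenome
#' @export
writeGenome <- function(genome, path, seed = NULL) {
  genome <- .checkLayout(genome)
  out <- data.frame(chrom = genome$chrom, length = genome$length,
                    is_mito = as.integer(genome$is_mito))
  .writeTable(out, path, .fileHeader(seed = seed))
  invisible(path)
}

# ---- probes and features (BED-like) -----------------------------------------

#' Read / write a probe map (BED-like TSV, 0-based half-open)
#'
#' Columns `chrom`, `start`, `end`, `name`.
#' @param path file path.
#' @param probes probe `GRanges` from [makeProbes()].
#' @param params,seed recorded in the header comment.
#' @return `readProbes`: a probe `GRanges`.
#' @export
readProbes <- function(path) {
  df <- .readTable(path, "\t", c("chrom", "start", "end", "name"),
                   c("start", "end"))
  .checkBed(df, path)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1, df$end))
  gr$probe_id <- df$name
  gr
}

#' @rdname readProbes
#' @export
writeProbes <- function(probes, path, params = list(), seed = NULL) {
  df <- data.frame(chrom = as.character(seqnames(probes)),
                   start = start(probes) - 1, end = end(probes),
                   name = probes$probe_id)
  .writeTable(df, path, .fileHeader(params, seed))
  invisible(path)
}

#' Read / write feature intervals (BED-like TSV with kind/class)
#'
#' Columns `chrom`, `start`, `end`, `name`, `kind`, `class`.
#' @param path file path.
#' @param features feature `GRanges` from [makeFeatures()].
#' @param params,seed recorded in the header comment.
#' @return `readFeatures`: a feature `GRanges`.
#' @export
readFeatures <- function(path) {
  df <- .readTable(path, "\t",
                   c("chrom", "start", "end", "name", "kind", "class"),
                   c("start", "end"))
  .checkBed(df, path)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1, df$end))
  gr$feature_id <- df$name
  gr$kind <- df$kind
  gr$name <- toupper(df$name)
  gr$class <- ifelse(df$class == ".", NA_character_, df$class)
  gr
}

#' @rdname readFeatures
#' @export
writeFeatures <- function(features, path, params = list(), seed = NULL) {
  df <- data.frame(chrom = as.character(seqnames(features)),
                   start = start(features) - 1, end = end(features),
                   name = features$feature_id, kind = features$kind,
                   class = ifelse(is.na(features$class), ".",
                                  features$class))
  .writeTable(df, path, .fileHeader(params, seed))
  invisible(path)
}

# ---- ratio matrix -----------------------------------------------------------

#' Read / write log2-ratio profiles (TSV matrix)
#'
#' One row per probe aligned with the probe map, one column per sample,
#' header row of sample ids.
#' @param path ratio matrix path.
#' @param x an [AcghSet-class].
#' @param probes probe `GRanges` the rows align to.
#' @param groups named vector sample id -> group label.
#' @param params,seed recorded in the header comment.
#' @return `readRatios`: an [AcghSet-class].
#' @export
readRatios <- function(path, probes, groups) {
  df <- .readTable(path, "\t", character(0))
  m <- as.matrix(df)
  mode(m) <- "numeric"
  if (anyNA(m)) stop(path, ": non-numeric or missing ratio values")
  if (nrow(m) != length(probes))
    stop(path, ": ", nrow(m), " rows but probe map has ", length(probes),
         " probes")
  AcghSet(probes, m, groups)
}

#' @rdname readRatios
#' @export
writeRatios <- function(x, path, params = list(), seed = NULL) {
  .writeTable(as.data.frame(log2Ratios(x)), path, .fileHeader(params, seed))
  invisible(path)
}

# ---- CNV calls --------------------------------------------------------------

#' Read / write CNV calls (BED-like TSV)
#'
#' Columns `chrom`, `start`, `end`, `sample`, `state`, `mean_log2`,
#' `n_probes`.
#' @param path file path.
#' @param calls call `GRanges` from [callCnvs()].
#' @param params,seed recorded in the header comment.
#' @return `readCalls`: a call `GRanges`.
#' @export
readCalls <- function(path) {
  df <- .readTable(path, "\t",
                   c("chrom", "start", "end", "sample", "state",
                     "mean_log2", "n_probes"),
                   c("start", "end", "mean_log2", "n_probes"))
  .checkBed(df, path)
  bad <- which(!df$state %in% c("gain", "loss"))
  if (length(bad))
    stop(path, ": record ", bad[1], ": state must be gain or loss")
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1, df$end))
  gr$sample <- df$sample
  gr$state <- df$state
  gr$mean_log2 <- df$mean_log2
  gr$n_probes <- as.integer(df$n_probes)
  gr
}

#' @rdname readCalls
#' @export
writeCalls <- function(calls, path, params = list(), seed = NULL) {
  df <- data.frame(chrom = as.character(seqnames(calls)),
                   start = start(calls) - 1, end = end(calls),
                   sample = calls$sample, state = calls$state,
                   mean_log2 = calls$mean_log2, n_probes = calls$n_probes)
  .writeTable(df, path, .fileHeader(params, seed))
  invisible(path)
}

# ---- CNVRs ------------------------------------------------------------------

#' Read / write a CNVR set (BED-like TSV)
#'
#' Columns `chrom`, `start`, `end`, `id`, `state`, `n_carriers`,
#' `frequency`, `groups`, `carriers` (comma-joined sample ids); group sizes
#' travel in a machine-readable comment line so the round trip is lossless.
#' @param path file path.
#' @param x a [CnvrSet-class].
#' @param params,seed recorded in the header comment.
#' @return `readCnvrs`: a [CnvrSet-class].
#' @export
readCnvrs <- function(path) {
  df <- .readTable(path, "\t",
                   c("chrom", "start", "end", "id", "state", "n_carriers",
                     "frequency", "groups", "carriers"),
                   c("start", "end", "n_carriers", "frequency"))
  .checkBed(df, path)
  gsLine <- grep("^#groupSizes:", attr(df, "comments"), value = TRUE)
  if (!length(gsLine)) stop(path, ": missing #groupSizes: comment line")
  parts <- strsplit(sub("^#groupSizes:\\s*", "", gsLine[1]), ",")[[1]]
  kv <- strsplit(parts, "=")
  gs <- setNames(as.integer(vapply(kv, `[`, "", 2)),
                 vapply(kv, `[`, "", 1))
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1, df$end))
  gr$cnvr_id <- df$id
  gr$state <- df$state
  gr$n_carriers <- as.integer(df$n_carriers)
  gr$frequency <- df$frequency
  gr$groups <- df$groups
  CnvrSet(gr, lapply(strsplit(df$carriers, ","), sort), gs)
}

#' @rdname readCnvrs
#' @export
writeCnvrs <- function(x, path, params = list(), seed = NULL) {
  r <- regions(x)
  df <- data.frame(chrom = as.character(seqnames(r)),
                   start = start(r) - 1, end = end(r), id = r$cnvr_id,
                   state = r$state, n_carriers = r$n_carriers,
                   frequency = r$frequency, groups = r$groups,
                   carriers = vapply(carriers(x), paste, "",
                                     collapse = ","))
  gs <- paste0("#groupSizes: ",
               paste(names(groupSizes(x)), groupSizes(x), sep = "=",
                     collapse = ","))
  .writeTable(df, path, .fileHeader(params, seed, extra = gs))
  invisible(path)
}

# ---- truth events -----------------------------------------------------------

#' Read / write planted ground-truth events (TSV, 0-based half-open)
#' @param path file path.
#' @param truth truth `data.frame` from [plantEvents()].
#' @param params,seed recorded in the header comment.
#' @return `readTruth`: a truth `data.frame` (1-based closed coordinates).
#' @export
readTruth <- function(path) {
  df <- .readTable(path, "\t",
                   c("sample", "group", "chrom", "start", "end", "cn",
                     "scope"), c("start", "end", "cn"))
  .checkBed(df, path)
  df$start <- df$start + 1
  df$cn <- as.integer(df$cn)
  attr(df, "comments") <- NULL
  df
}

#' @rdname readTruth
#' @export
writeTruth <- function(truth, path, params = list(), seed = NULL) {
  out <- truth
  out$start <- out$start - 1
  .writeTable(out, path, .fileHeader(params, seed))
  invisible(path)
}

# ---- qPCR wells and phenotypes (CSV) ----------------------------------------

#' Read / write qPCR Ct tables (CSV)
#'
#' Columns `sample`, `assay`, `role`, `rep`, `ct`.
#' @param path file path.
#' @param wells wells `data.frame` from [simulateQpcr()].
#' @param params,seed recorded in the header comment.
#' @return `readWells`: a wells `data.frame`.
#' @export
readWells <- function(path) {
  df <- .readTable(path, ",", c("sample", "assay", "role", "ct"),
                   c("ct"))
  if (nrow(df) && any(df$ct <= 0))
    stop(path, ": Ct values must be positive")
  attr(df, "comments") <- NULL
  df
}

#' @rdname readWells
#' @export
writeWells <- function(wells, path, params = list(), seed = NULL) {
  .writeTable(wells, path, .fileHeader(params, seed), sep = ",")
  invisible(path)
}

#' Read / write phenotype tables (CSV)
#'
#' Columns `sample`, `farm`, `breed`, `genotype`, then one column per
#' trait (numeric; empty for missing).
#' @param path file path.
#' @param pheno phenotype `data.frame` from [simulatePhenotypes()].
#' @param params,seed recorded in the header comment.
#' @return `readPhenotypes`: a phenotype `data.frame`.
#' @export
readPhenotypes <- function(path) {
  df <- .readTable(path, ",", c("sample", "farm", "breed", "genotype"))
  for (cc in setdiff(names(df), c("sample", "farm", "breed", "genotype"))) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    v[df[[cc]] %in% c("", "NA")] <- NA
    df[[cc]] <- v
  }
  attr(df, "comments") <- NULL
  df
}

#' @rdname readPhenotypes
#' @export
writePhenotypes <- function(pheno, path, params = list(), seed = NULL) {
  .writeTable(pheno, path, .fileHeader(params, seed), sep = ",")
  invisible(path)
}
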