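#' Sample x CNVR presence matrix
#'
#' @param x a [CnvrSet-class].
#' @param samples character vector of all sample ids (rows); every carrier
#'   in the CNVR set must be listed.
#' @return binary integer matrix, samples as rows, CNVR ids as columns;
#'   entry 1 iff the sample carries the CNVR. Zero columns are allowed
#'   (an empty CNVR set gives a zero-width matrix).
#' @export
presenceMatrix <- function(x, samples) {
  samples <- as.character(samples)
  carr <- carriers(x)
  unknown <- setdiff(unique(unlist(carr)), samples)
  if (length(unknown))
    stop("carrier sample(s) not in sample list: ",
         paste(unknown, collapse = ", "))
  ids <- regions(x)$cnvr_id
  m <- matrix(0L, length(samples), length(ids),
              dimnames = list(samples, ids))
  for (j in seq_along(carr)) m[carr[[j]], j] <- 1L
  m
}

#' Jaccard distances between binary sample profiles
#'
#' Distance = 1 - |intersection| / |union| over carried CNVRs. A pair of
#' all-zero profiles (no CNVRs carried) is at distance 0; an all-zero
#' profile is at distance 1 from any non-identical profile (documented
#' convention, since the Jaccard ratio is undefined on empty unions).
#'
#' @param m binary matrix, samples as rows.
#' @return a `dist` object.
#' @export
jaccardDist <- function(m) {
  m <- (as.matrix(m) != 0) * 1
  inter <- m %*% t(m)
  sizes <- rowSums(m)
  un <- outer(sizes, sizes, "+") - inter
  d <- ifelse(un == 0, 0, 1 - inter / un)
  stats::as.dist(d)
}

#' Cluster samples on their CNVR presence profiles
#'
#' Deterministic agglomerative hierarchical clustering of the binary
#' presence profiles; with the defaults, Jaccard distance and average
#' linkage.
#'
#' @param m presence matrix from [presenceMatrix()] (>= 2 samples).
#' @param distance `"jaccard"` (see [jaccardDist()]) or any
#'   [stats::dist()] method name.
#' @param linkage agglomeration method for [stats::hclust()].
#' @return an `hclust` tree.
#' @export
clusterSamples <- function(m, distance = "jaccard", linkage = "average") {
  if (nrow(m) < 2) stop("need at least 2 samples to cluster")
  d <- if (identical(distance, "jaccard")) jaccardDist(m)
       else stats::dist(m, method = distance)
  stats::hclust(d, method = linkage)
}

#' Indicator-value statistics for group-indicative CNVRs
#'
#' Classic indicator-value analysis (Dufrene-Legendre form with square-root
#' scaling) on binary presence: for CNVR j and group g, specificity
#' `A_g = mean presence in g / sum over groups of mean presence` and
#' fidelity `B_g = fraction of group-g samples carrying j`; the statistic is
#' `max_g sqrt(A_g * B_g)` and the best group the argmax. Significance is a
#' group-label permutation test:
#' `p = (1 + #permutations with statistic >= observed) / (nPerm + 1)`.
#' An all-zero column scores statistic 0 with p = 1.
#'
#' @param m presence matrix from [presenceMatrix()].
#' @param groups named character vector sample id -> group (>= 2 non-empty
#'   groups covering the rows of `m`).
#' @param nPerm number of label permutations (default 999).
#' @param seed integer seed; results are reproducible given the seed.
#' @param adjust p-value adjustment method passed to [stats::p.adjust()]
#'   (default `"none"`, mirroring per-test alpha practice; `"BH"`
#'   available).
#' @param exact enumerate all distinct group assignments instead of
#'   sampling permutations (feasible only for small panels); the p-value is
#'   then the exact fraction of assignments, the observed one included,
#'   whose statistic reaches the observed value.
#' @return `data.frame`: `cnvr_id`, `group` (best), `A`, `B`, `stat`, `p`
#'   (and `p_adj` when `adjust != "none"`).
#' @export
indval <- function(m, groups, nPerm = 999, seed = 1, adjust = "none",
                   exact = FALSE) {
  # used only in exact mode: all distinct arrangements of the label multiset
  .labelArrangements <- function(lab) {
    n <- length(lab)
    rec <- function(remaining) {
      if (!length(remaining)) return(matrix(character(0), 0, 1))
      lv <- sort(unique(remaining))
      out <- NULL
      for (l in lv) {
        rest <- remaining[-match(l, remaining)]
        sub <- rec(rest)
        out <- cbind(out, rbind(rep(l, ncol(sub)), sub))
      }
      out
    }
    if (n > 10) stop("exact enumeration limited to <= 10 samples")
    rec(as.character(lab))
  }
  groups <- .checkGroups(groups)
  m <- as.matrix(m)
  if (is.null(rownames(m))) stop("presence matrix must have sample rownames")
  miss <- setdiff(rownames(m), names(groups))
  if (length(miss))
    stop("samples without group: ", paste(miss, collapse = ", "))
  lab <- factor(unname(groups[rownames(m)]))
  if (nlevels(lab) < 2) stop("need >= 2 groups")
  if (any(table(lab) == 0)) stop("every group must be non-empty")
  set.seed(.checkSeed(seed))
  statFor <- function(labels) {
    gm <- rowsum(m, labels) / as.vector(table(labels))  # groups x cnvrs
    tot <- colSums(gm)
    A <- sweep(gm, 2, ifelse(tot == 0, 1, tot), "/")
    A[, tot == 0] <- 0
    sqrt(A * gm)  # B equals mean presence for binary data
  }
  colMax <- function(x) {
    cm <- x[1, ]
    for (r in seq_len(nrow(x))[-1]) cm <- pmax(cm, x[r, ])
    cm
  }
  obs <- statFor(lab)
  best <- apply(obs, 2, which.max)
  stat <- obs[cbind(best, seq_len(ncol(m)))]
  if (exact) {
    perms <- .labelArrangements(lab)
    geq <- rep(0L, ncol(m))
    for (i in seq_len(ncol(perms)))
      geq <- geq + (colMax(statFor(perms[, i])) >= stat - 1e-12)
    p <- geq / ncol(perms)
  } else {
    geq <- rep(0L, ncol(m))
    for (b in seq_len(nPerm)) {
      geq <- geq + (colMax(statFor(sample(lab))) >= stat - 1e-12)
    }
    p <- (1 + geq) / (nPerm + 1)
  }
  zero <- colSums(m) == 0
  stat[zero] <- 0; p[zero] <- 1
  gm <- rowsum(m, lab) / as.vector(table(lab))
  out <- data.frame(
    cnvr_id = colnames(m), group = levels(lab)[best],
    A = {tot <- colSums(gm); ifelse(tot == 0, 0,
          gm[cbind(best, seq_len(ncol(m)))] / tot)},
    B = gm[cbind(best, seq_len(ncol(m)))],
    stat = stat, p = p, stringsAsFactors = FALSE, row.names = NULL)
  if (!identical(adjust, "none")) out$p_adj <- p.adjust(out$p, adjust)
  out
}
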