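# Independent brute-force oracles used across the suite. These never call
# the code paths they check.

# exact segmentation objective by exhaustive enumeration over all 2^(n-1)
# breakpoint patterns (feasible for n <= 12)
bruteForceSegObjective <- function(values, penalty) {
  n <- length(values)
  best <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    bounds <- c(0, cuts, n)
    obj <- penalty * (length(bounds) - 1)
    for (k in seq_len(length(bounds) - 1)) {
      seg <- values[(bounds[k] + 1):bounds[k + 1]]
      obj <- obj + sum((seg - mean(seg))^2)
    }
    if (obj < best) best <- obj
  }
  best
}

# transitive overlap closure of 1-based closed intervals by repeated
# pairwise merging (quadratic, order-free)
bruteForceClosure <- function(df) {
  # df: chrom, start, end; returns merged components as a data.frame
  comp <- seq_len(nrow(df))
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(df))) for (j in seq_len(nrow(df))) {
      if (comp[i] != comp[j] && df$chrom[i] == df$chrom[j] &&
          df$start[i] <= df$end[j] && df$end[i] >= df$start[j]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- do.call(rbind, lapply(unique(comp), function(cc) {
    sel <- comp == cc
    data.frame(chrom = df$chrom[which(sel)[1]],
               start = min(df$start[sel]), end = max(df$end[sel]),
               members = I(list(which(sel))))
  }))
  out[order(out$chrom, out$start), ]
}

# per-base overlap count between two 1-based closed intervals
perBaseOverlap <- function(s1, e1, s2, e2) {
  sum(seq(s1, e1) %in% seq(s2, e2))
}

# exact IndVal p-value for one binary column by enumerating all distinct
# assignments of samples to groups of the given sizes
exactIndvalP <- function(presence, labels) {
  statOf <- function(lab) {
    lv <- sort(unique(lab))
    A <- vapply(lv, function(g) mean(presence[lab == g]), 0)
    tot <- sum(A)
    if (tot == 0) return(0)
    max(sqrt((A / tot) * A))
  }
  obs <- statOf(labels)
  perms <- unique(combinat_perms(labels))
  cnt <- sum(vapply(perms, function(p) statOf(p) >= obs - 1e-12, TRUE))
  cnt / length(perms)
}

# all distinct permutations of a label multiset (small n only)
combinat_perms <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (l in unique(x)) {
    rest <- x[-match(l, x)]
    out <- c(out, lapply(combinat_perms(rest), function(p) c(l, p)))
  }
  unique(out)
}

# small synthetic call GRanges builder
makeCalls <- function(chrom, start, end, sample, state,
                      mean_log2 = NULL, n_probes = 6L) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  gr$sample <- sample
  gr$state <- state
  gr$mean_log2 <- if (is.null(mean_log2))
    ifelse(state == "gain", 1, -1) else mean_log2
  gr$n_probes <- as.integer(rep(n_probes, length.out = length(gr)))
  gr
}
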