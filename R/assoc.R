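#' Fit the additive fixed-effects growth-trait model
#'
#' Ordinary least squares for `trait = mu + farm + genotype + breed + error`
#' with crossed fixed factors (treatment coding internally; results do not
#' depend on the reference level). Records missing the trait or any factor
#' are dropped listwise for that trait. Factors observed at a single level
#' drop out of the design (the model reduces, e.g. to one-way in genotype).
#' Aliased (perfectly confounded) levels are an explicit error naming the
#' offending coefficients.
#'
#' @param records phenotype `data.frame` with columns `farm`, `breed`,
#'   `genotype` and the trait.
#' @param trait trait column name.
#' @return object of class `cnvAssocFit`: list with the `lm` fit, the
#'   trait name, the modelled data and the factor levels used.
#' @export
fitModel <- function(records, trait) {
  need <- c("farm", "breed", "genotype", trait)
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records missing column(s): ", paste(miss, collapse = ", "))
  d <- records[, need]
  names(d)[4] <- "y"
  d <- d[complete.cases(d), , drop = FALSE]
  if (!nrow(d)) stop("no complete records for trait ", trait)
  for (f in c("farm", "breed", "genotype")) d[[f]] <- factor(d[[f]])
  terms <- c("farm", "genotype", "breed")
  terms <- terms[vapply(terms, function(f) nlevels(d[[f]]) > 1, TRUE)]
  form <- stats::as.formula(paste("y ~",
                                  if (length(terms))
                                    paste(terms, collapse = " + ")
                                  else "1"))
  fit <- lm(form, data = d)
  if (anyNA(coef(fit))) {
    aliased <- names(coef(fit))[is.na(coef(fit))]
    stop("aliased (confounded) model term(s): ",
         paste(aliased, collapse = ", "),
         "; genotype cannot be separated from farm/breed in these data")
  }
  structure(list(fit = fit, trait = trait, data = d,
                 levels = lapply(d[c("farm", "breed", "genotype")], levels)),
            class = "cnvAssocFit")
}

#' @export
print.cnvAssocFit <- function(x, ...) {
  cat("cnvAssocFit:", x$trait, "~ farm + genotype + breed,",
      nrow(x$data), "records\n")
  print(summary(x$fit)$coefficients)
  invisible(x)
}

# contrast row giving the LSM of one genotype level: the average
# model-matrix row over the Cartesian grid of farm x breed levels
.lsmContrast <- function(object, level) {
  lv <- object$levels
  grid <- expand.grid(farm = factor(lv$farm, lv$farm),
                      breed = factor(lv$breed, lv$breed),
                      genotype = factor(level, lv$genotype),
                      KEEP.OUT.ATTRS = FALSE)
  mm <- model.matrix(stats::delete.response(stats::terms(object$fit)), grid)
  colMeans(mm)
}

#' Least-squares means of the CNV genotype levels
#'
#' LSM of a genotype level = average model prediction over the Cartesian
#' grid of farm x breed levels with genotype fixed at that level, equal
#' weights per cell; the standard error comes from the corresponding linear
#' contrast and the coefficient covariance matrix. In a balanced design
#' this equals the raw genotype group mean.
#'
#' @param object a `cnvAssocFit` from [fitModel()].
#' @return `data.frame`: `genotype`, `n`, `lsm`, `se`.
#' @export
lsm <- function(object) {
  stopifnot(inherits(object, "cnvAssocFit"))
  V <- vcov(object$fit)
  b <- coef(object$fit)
  rows <- lapply(object$levels$genotype, function(g) {
    cvec <- .lsmContrast(object, g)
    data.frame(genotype = g, n = sum(object$data$genotype == g),
               lsm = sum(cvec * b),
               se = sqrt(drop(t(cvec) %*% V %*% cvec)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pairwise genotype comparisons with significance letters
#'
#' t-tests on LSM contrasts between genotype levels, using the residual
#' degrees of freedom of the fit; no multiplicity correction by default
#' (per-test alpha, as superscript-letter tables conventionally report),
#' Benjamini-Hochberg available. Letters are assigned so that two levels
#' share a letter if and only if they are not significantly different at
#' `alpha`; letters are ordered by descending LSM ("a" = largest).
#'
#' @param object a `cnvAssocFit` from [fitModel()].
#' @param alpha significance level (default 0.05).
#' @param adjust p-value adjustment method for [stats::p.adjust()]
#'   (default `"none"`).
#' @return list with `pairs` (`data.frame`: `level1`, `level2`, `estimate`,
#'   `se`, `t`, `df`, `p`) and `letters` (named character vector per
#'   genotype level).
#' @export
compareLevels <- function(object, alpha = 0.05, adjust = "none") {
  stopifnot(inherits(object, "cnvAssocFit"))
  lev <- object$levels$genotype
  if (length(lev) < 2) stop("need >= 2 genotype levels to compare")
  V <- vcov(object$fit)
  b <- coef(object$fit)
  df <- df.residual(object$fit)
  pairs <- combn(lev, 2)
  res <- lapply(seq_len(ncol(pairs)), function(i) {
    cvec <- .lsmContrast(object, pairs[1, i]) -
      .lsmContrast(object, pairs[2, i])
    est <- sum(cvec * b)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    tval <- if (se > 0) est / se else 0
    data.frame(level1 = pairs[1, i], level2 = pairs[2, i],
               estimate = est, se = se, t = tval, df = df,
               p = if (se > 0) 2 * pt(-abs(tval), df) else 1,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_used <- p.adjust(res$p, adjust)
  letters <- .assignLetters(lev, res, alpha, lsm(object))
  res$p_used <- NULL
  list(pairs = res, letters = letters)
}

# letters from maximal cliques of the not-significantly-different graph
.assignLetters <- function(levels, pairs, alpha, lsmTab) {
  ns <- pairs[pairs$p_used >= alpha, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    ns[, c("level1", "level2")], directed = FALSE,
    vertices = data.frame(name = levels))
  cliques <- igraph::max_cliques(g)
  cliqueLevels <- lapply(cliques, function(cl)
    igraph::V(g)$name[as.integer(cl)])
  # order cliques by the largest member LSM so "a" marks the top group
  ord <- order(-vapply(cliqueLevels, function(cl)
    max(lsmTab$lsm[match(cl, lsmTab$genotype)]), 0))
  cliqueLevels <- cliqueLevels[ord]
  out <- setNames(rep("", length(levels)), levels)
  for (i in seq_along(cliqueLevels))
    for (lv in cliqueLevels[[i]])
      out[lv] <- paste0(out[lv], letters[i])
  out
}

#' Trait-by-genotype association table
#'
#' Fits the additive model per trait and reports N, LSM, SE and
#' significance letters per genotype level, the shape of a growth-trait
#' association table.
#'
#' @param records phenotype `data.frame` (see [fitModel()]).
#' @param traits trait column names (default: all non-factor columns).
#' @param alpha significance level for the letters.
#' @return `data.frame` with one row per genotype x trait.
#' @export
assocTable <- function(records, traits = NULL, alpha = 0.05) {
  if (is.null(traits))
    traits <- setdiff(names(records),
                      c("sample", "farm", "breed", "genotype"))
  rows <- lapply(traits, function(tr) {
    f <- fitModel(records, tr)
    tab <- lsm(f)
    tab$letter <- if (length(f$levels$genotype) > 1)
      unname(compareLevels(f, alpha)$letters[tab$genotype]) else "a"
    tab$trait <- tr
    tab
  })
  do.call(rbind, rows)[, c("trait", "genotype", "n", "lsm", "se", "letter")]
}
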