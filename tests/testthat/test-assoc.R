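balancedRecords <- function(reps = 2) {
  d <- expand.grid(farm = c("f1", "f2", "f3"), breed = c("b1", "b2"),
                   genotype = c("gain", "loss", "normal"),
                   rep = seq_len(reps), stringsAsFactors = FALSE)
  d$sample <- paste0("s", seq_len(nrow(d)))
  d
}

traitSpec <- function(mu = 100, sd = 0,
                      farm = c(f1 = -2, f2 = 0, f3 = 2),
                      breed = c(b1 = -1, b2 = 1),
                      genotype = c(gain = -4, loss = 6, normal = 0)) {
  list(t1 = list(mu = mu, sd = sd, farm = farm, breed = breed,
                 genotype = genotype))
}

test_that("noiseless fits recover planted effects exactly", {
  ph <- simulatePhenotypes(balancedRecords(), traitSpec(), seed = 1)
  f <- fitModel(ph, "t1")
  co <- coef(f$fit)
  expect_equal(unname(co[["genotypeloss"]]), 10)   # 6 - (-4)
  expect_equal(unname(co[["genotypenormal"]]), 4)
  expect_equal(unname(co[["farmf3"]]), 4)
  expect_equal(unname(co[["breedb2"]]), 2)
  # zero noise: LSM = mu + genotype effect + mean farm + mean breed effect
  tab <- suppressWarnings(lsm(f))  # zero-residual fit warns in summary.lm
  expect_equal(setNames(tab$lsm, tab$genotype),
               c(gain = 96, loss = 106, normal = 100))
})

test_that("single-farm single-breed data reduce to a one-way model", {
  d <- data.frame(farm = "f1", breed = "b1",
                  genotype = rep(c("gain", "loss", "normal"), each = 4),
                  t1 = c(1, 2, 3, 4, 11, 12, 13, 14, 6, 7, 8, 9))
  f <- fitModel(d, "t1")
  co <- coef(f$fit)
  expect_equal(unname(co[["genotypeloss"]]),
               mean(d$t1[d$genotype == "loss"]) -
                 mean(d$t1[d$genotype == "gain"]))
  tab <- lsm(f)
  expect_equal(setNames(tab$lsm, tab$genotype),
               c(gain = 2.5, loss = 12.5, normal = 7.5))
})

test_that("balanced-design LSM equals raw genotype means", {
  ph <- simulatePhenotypes(balancedRecords(3), traitSpec(sd = 5), seed = 9)
  tab <- lsm(fitModel(ph, "t1"))
  raw <- tapply(ph$t1, ph$genotype, mean)
  expect_equal(setNames(tab$lsm, tab$genotype), raw[tab$genotype],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("unbalanced LSM matches the prediction-grid oracle and emmeans", {
  set.seed(21)
  d <- balancedRecords(4)
  d <- d[-sample(nrow(d), 20), ]  # knock out rows to unbalance
  ph <- simulatePhenotypes(d, traitSpec(sd = 3), seed = 2)
  f <- fitModel(ph, "t1")
  tab <- lsm(f)
  # brute-force oracle: average lm predictions over the farm x breed grid
  grid <- expand.grid(farm = levels(factor(ph$farm)),
                      breed = levels(factor(ph$breed)),
                      stringsAsFactors = FALSE)
  for (g in tab$genotype) {
    grid$genotype <- g
    expect_equal(tab$lsm[tab$genotype == g],
                 mean(predict(f$fit, newdata = grid)), tolerance = 1e-10)
  }
  skip_if_not_installed("emmeans")
  em <- as.data.frame(emmeans::emmeans(f$fit, "genotype"))
  expect_equal(tab$lsm, em$emmean, tolerance = 1e-8)
  expect_equal(tab$se, em$SE, tolerance = 1e-8)
})

test_that("LSM is invariant to factor level ordering", {
  ph <- simulatePhenotypes(balancedRecords(2), traitSpec(sd = 2), seed = 5)
  f1 <- fitModel(ph, "t1")
  ph2 <- ph
  ph2$genotype <- factor(ph2$genotype,
                         levels = c("normal", "loss", "gain"))
  ph2$farm <- factor(ph2$farm, levels = c("f3", "f1", "f2"))
  f2 <- fitModel(ph2, "t1")
  a <- lsm(f1); b <- lsm(f2)
  b <- b[match(a$genotype, b$genotype), ]
  expect_equal(a$lsm, b$lsm, tolerance = 1e-10)
  expect_equal(a$se, b$se, tolerance = 1e-10)
})

test_that("confounded genotype is an explicit aliasing error", {
  d <- data.frame(farm = rep(c("f1", "f2"), each = 4),
                  breed = "b1",
                  genotype = rep(c("gain", "loss"), each = 4),
                  t1 = rnorm(8))
  expect_error(fitModel(d, "t1"), "aliased")
})

test_that("pairwise comparisons are symmetric and letters partition levels", {
  set.seed(6)
  d <- balancedRecords(20)
  ph <- simulatePhenotypes(
    d, traitSpec(sd = 1, genotype = c(gain = -8, loss = 8, normal = 0)),
    seed = 3)
  f <- fitModel(ph, "t1")
  cmp <- compareLevels(f)
  # strongly separated levels each get their own letter
  expect_identical(sort(unname(cmp$letters)), c("a", "b", "c"))
  expect_identical(cmp$letters[["loss"]], "a")  # largest LSM gets "a"
  expect_true(all(cmp$pairs$p < 0.05))
  # symmetric: estimate flips sign when the pair is reversed
  cmpP <- cmp$pairs
  expect_equal(abs(cmpP$estimate[cmpP$level1 == "gain" &
                                   cmpP$level2 == "loss"]),
               abs(cmpP$estimate[cmpP$level1 == "loss" |
                                   cmpP$level2 == "loss"][1]))

  # identical populations share one letter
  ph0 <- simulatePhenotypes(
    d, traitSpec(sd = 1, genotype = c(gain = 0, loss = 0, normal = 0)),
    seed = 8)
  cmp0 <- compareLevels(fitModel(ph0, "t1"))
  expect_identical(unname(cmp0$letters), c("a", "a", "a"))
})

test_that("mixed significance letterings match the admissible grouping oracle", {
  # construct LSM separations so gain < normal < loss with only the
  # extremes significantly different: letters must overlap in the middle
  set.seed(14)
  d <- balancedRecords(6)
  ph <- simulatePhenotypes(
    d, traitSpec(sd = 4, genotype = c(gain = -3, loss = 3, normal = 0)),
    seed = 4)
  f <- fitModel(ph, "t1")
  cmp <- compareLevels(f)
  sig <- function(l1, l2) {
    p <- cmp$pairs
    any(p$p[(p$level1 == l1 & p$level2 == l2) |
              (p$level1 == l2 & p$level2 == l1)] < 0.05)
  }
  lt <- cmp$letters
  for (l1 in names(lt)) for (l2 in names(lt)) {
    if (l1 < l2) {
      shares <- length(intersect(strsplit(lt[[l1]], "")[[1]],
                                 strsplit(lt[[l2]], "")[[1]])) > 0
      expect_identical(shares, !sig(l1, l2))
    }
  }
})

test_that("noisy-effects estimates land within 2 SE most of the time", {
  inside <- 0
  nrep <- 30
  for (seed in seq_len(nrep)) {
    d <- balancedRecords(12)  # 216 records
    d <- d[-sample(nrow(d), 16), ]
    ph <- simulatePhenotypes(d, traitSpec(sd = 6), seed = seed)
    f <- fitModel(ph, "t1")
    co <- summary(f$fit)$coefficients
    est <- co["genotypeloss", "Estimate"]
    se <- co["genotypeloss", "Std. Error"]
    inside <- inside + (abs(est - 10) <= 2 * se)
  }
  expect_gte(inside / nrep, 0.9)
})

test_that("the association table reports every trait and level", {
  d <- balancedRecords(4)
  ph <- simulatePhenotypes(d, defaultTraitSpecs(
    farms = c("f1", "f2", "f3"), breeds = c("b1", "b2")), seed = 2)
  tab <- assocTable(ph)
  expect_identical(nrow(tab), 15L)  # 5 traits x 3 genotypes
  expect_setequal(unique(tab$trait),
                  c("body_height", "body_length", "heart_girth",
                    "hucklebone_width", "body_weight"))
  expect_true(all(tab$se > 0))
  expect_true(all(nzchar(tab$letter)))
})
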