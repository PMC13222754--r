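test_that("conflict-tactics recoding collapses 0/7/8 and keeps 1-6", {
  expect_identical(recode_ctspc(7L), 0L)
  expect_identical(recode_ctspc(8L), 0L)
  expect_identical(recode_ctspc(0L), 0L)
  expect_identical(recode_ctspc(0:8), c(0L, 1:6, 0L, 0L))
  expect_true(is.na(recode_ctspc(NA_integer_)))
  expect_error(recode_ctspc(9, item = "nv1"), "nv1")
  expect_error(recode_ctspc(-1), "Illegal")
})

test_that("reverse coding maps endpoints and is an involution", {
  expect_equal(reverse_code(1, 1, 4), 4)
  expect_equal(reverse_code(2.5, 1, 4), 2.5)
  expect_equal(reverse_code(0, 0, 6), 6)
  for (x in seq(0, 6, by = 0.25)) {
    expect_equal(reverse_code(reverse_code(x, 0, 6), 0, 6), x)
  }
  expect_error(reverse_code(5, 1, 4), "outside")
})

test_that("composite scoring averages, enforces the missing-item rule and is bounded", {
  expect_equal(score_composite(c(0, 1, 2), 3), 1.0)
  expect_equal(score_composite(c(2, 2, 2)), 2.0)
  expect_true(is.na(score_composite(c(1, NA, 2), min_items = 3)))
  expect_equal(score_composite(c(1, NA, 2), min_items = 2), 1.5)
  expect_warning(out <- score_composite(numeric(0)), "Empty")
  expect_true(is.na(out))
  set.seed(1)
  for (r in 1:20) {
    x <- runif(5, 0, 6)
    expect_equal(score_composite(x), score_composite(sample(x)))
    expect_gte(score_composite(x), min(x))
    expect_lte(score_composite(x), max(x))
  }
})

test_that("omega matches the one-factor closed form and its limits", {
  lam <- 0.7
  set.seed(2024)
  n <- 20000
  f <- rnorm(n)
  X <- sapply(1:3, function(j) lam * f + sqrt(1 - lam^2) * rnorm(n))
  om <- mcdonalds_omega(X)
  expect_equal(om$omega, (3 * lam)^2 / ((3 * lam)^2 + 3 * (1 - lam^2)),
               tolerance = 0.02)
  expect_identical(om$flag, "ok")

  Xind <- matrix(rnorm(20000 * 4), ncol = 4)
  expect_lt(abs(mcdonalds_omega(Xind)$omega), 0.03)

  Xsame <- matrix(rep(rnorm(100), 3), ncol = 3)
  om1 <- mcdonalds_omega(Xsame)
  expect_equal(om1$omega, 1)
  expect_identical(om1$flag, "near_singular")
})

test_that("omega equals alpha for tau-equivalent items at the population covariance", {
  lam <- 0.6
  p <- 4
  R <- matrix(lam^2, p, p)
  diag(R) <- 1
  om <- mcdonalds_omega(covmat = R, n_obs = 10000)
  alpha <- p * lam^2 / (1 + (p - 1) * lam^2)  # independent closed form
  expect_equal(om$omega, alpha, tolerance = 1e-6)
})

test_that("Spearman-Brown split-half behaves at its anchors", {
  # population r solving 2r/(1+r) = 0.55
  r_pop <- 0.55 / (2 - 0.55)
  set.seed(55)
  n <- 50000
  z <- rnorm(n)
  x1 <- sqrt(r_pop) * z + sqrt(1 - r_pop) * rnorm(n)
  x2 <- sqrt(r_pop) * z + sqrt(1 - r_pop) * rnorm(n)
  sb <- split_half_spearman_brown(x1, x2)
  expect_equal(sb$reliability, 0.55, tolerance = 0.02)
  x <- rnorm(100)
  expect_equal(split_half_spearman_brown(x, x)$reliability, 1)
  expect_identical(split_half_spearman_brown(x, rep(1, 100))$flag,
                   "zero_variance")
})

test_that("group descriptives reproduce brute-force ANOVA arithmetic", {
  sc <- data.frame(person_id = 1:6, wave = 3,
                   group = rep(c("A", "B", "C"), each = 2),
                   irr = c(1, 2, 2, 3, 3, 4))
  d <- describe_by_group(sc, "irr", 3)
  # explicit sum-of-squares decomposition
  x <- sc$irr; g <- sc$group
  gm <- mean(x)
  ssb <- sum(tapply(x, g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(x, g, function(v) sum((v - mean(v))^2)))
  F_oracle <- (ssb / 2) / (ssw / 3)
  expect_equal(d$F, F_oracle, tolerance = 1e-12)

  sc2 <- data.frame(person_id = 1:6, wave = 3,
                    group = rep(c("A", "B"), each = 3),
                    irr = rep(c(1, 2, 3), 2))
  d2 <- describe_by_group(sc2, "irr", 3)
  expect_equal(d2$F, 0)
  expect_equal(d2$p, 1)

  sc3 <- data.frame(person_id = 1:6, wave = 3,
                    group = rep(c("A", "B"), each = 3),
                    irr = rep(c(0, 1), each = 3))
  d3 <- describe_by_group(sc3, "irr", 3)
  expect_identical(d3$flag, "zero_within_variance")
  expect_equal(d3$p, 0)
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(9)
  sc <- data.frame(person_id = 1:40, wave = 3,
                   group = rep(c("A", "B"), each = 20),
                   irr = rnorm(40, mean = rep(c(0, 0.4), each = 20)))
  d <- describe_by_group(sc, "irr", 3)
  tt <- t.test(irr ~ group, data = sc, var.equal = TRUE)
  expect_equal(d$F, unname(tt$statistic)^2, tolerance = 1e-10)
})

test_that("pearson matrix is symmetric with unit diagonal and matches direct arithmetic", {
  sc <- data.frame(person_id = 1:5, wave = 3, group = "A",
                   irr = c(1, 2, 3, 4, 5), pstr = c(2, 1, 4, 3, 5))
  R <- pearson_matrix(sc, 3, vars = c("irr", "pstr"))
  x <- sc$irr; y <- sc$pstr
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(R["irr", "pstr"], r_oracle, tolerance = 1e-12)
  expect_equal(diag(R), c(irr = 1, pstr = 1))
  expect_equal(R, t(R))
})

test_that("item scoring produces bounded composites with the right reversals", {
  truth <- default_truth("shared", n_per_group = c(G1 = 150, G2 = 60,
                                                   G3 = 60))
  panel <- simulate_panel(truth, seed = 77, items = TRUE)
  scored <- score_items(panel$items)
  expect_true(all(scored$wave %in% c(3, 5, 9)))
  rng <- list(irr = c(0, 2), pstr = c(1, 4), nVio = c(0, 6),
              psyAgg = c(0, 6), phyAs = c(0, 6), neg = c(0, 6),
              cAtt = c(1, 4), cPra = c(1, 4))
  for (v in names(rng)) {
    x <- scored[[v]]
    expect_true(all(is.na(x) | (x >= rng[[v]][1] & x <= rng[[v]][2])),
                label = paste("bounds for", v))
  }
  # cultural scores constant across waves within person
  spread <- tapply(scored$cAtt, scored$person_id,
                   function(v) diff(range(v)))
  expect_true(all(spread == 0, na.rm = TRUE))
  # nVio reversal: scored nVio correlates positively with the generator's
  # reverse-coded composite
  merged <- merge(scored, panel$scores,
                  by = c("person_id", "wave"), suffixes = c("_it", "_tr"))
  expect_gt(cor(merged$nVio_it, merged$nVio_tr,
                use = "complete.obs"), 0.5)
})

test_that("simulated item batteries reach study-like reliabilities", {
  truth <- default_truth("shared", n_per_group = c(G1 = 800, G2 = 60,
                                                   G3 = 60))
  panel <- simulate_panel(truth, seed = 5, items = TRUE)
  rel <- reliability_table(panel$items[panel$items$group == "G1", ])
  om <- rel$omega[rel$scale %in% c("irr", "pstr", "nVio", "psyAgg",
                                   "phyAs", "neg")]
  expect_true(all(om > 0.55 & om < 0.92))
  sb <- rel$split_half[rel$scale == "cultural"]
  expect_gt(sb, 0.3)
  expect_lt(sb, 0.75)
})
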