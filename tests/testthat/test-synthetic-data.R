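test_that("truth scenarios have the promised structure", {
  tn <- default_truth("null")
  Bn <- tn$per_group$G1$B
  expect_true(all(Bn[row(Bn) != col(Bn)] == 0))
  expect_true(all(tn$per_group$G1$Sigma_zeta[upper.tri(Bn)] == 0))

  ts <- default_truth("shared")
  expect_equal(ts$per_group$G1$B, ts$per_group$G2$B)
  expect_equal(ts$per_group$G1$B, ts$per_group$G3$B)
  offd <- ts$per_group$G1$B[row(Bn) != col(Bn)]
  nz <- abs(offd[offd != 0])
  expect_true(all(nz >= 0.05 & nz <= 0.30))

  td <- default_truth("group_divergent")
  dB <- td$per_group$G2$B - td$per_group$G1$B
  expect_equal(sum(dB != 0), 2)
  expect_true(all(abs(dB[dB != 0]) >= 0.2))
  # stationarity in every scenario and group
  for (tr in list(tn, ts, td)) {
    for (g in tr$groups) {
      expect_lt(max(Mod(eigen(tr$per_group[[g]]$B)$values)), 1)
    }
  }
})

test_that("the generator is bit-reproducible under a fixed seed", {
  truth <- default_truth("shared", n_per_group = c(G1 = 80, G2 = 60,
                                                   G3 = 60))
  p1 <- simulate_panel(truth, seed = 42, items = TRUE)
  p2 <- simulate_panel(truth, seed = 42, items = TRUE)
  expect_identical(p1$scores, p2$scores)
  expect_identical(p1$items, p2$items)
  p3 <- simulate_panel(truth, seed = 43)
  expect_false(identical(p1$scores$irr, p3$scores$irr))
})

test_that("generator moments match the analytic stationary covariance", {
  truth <- default_truth("shared", n_per_group = c(G1 = 5000, G2 = 60,
                                                   G3 = 60))
  tg <- truth$per_group$G1
  panel <- simulate_panel(truth, seed = 314)
  sc <- panel$scores[panel$scores$group == "G1", ]
  y3 <- as.matrix(sc[sc$wave == 3, panelnet_nodes()])
  # truncated-series oracle for S
  S_oracle <- lyapunov_series(tg$B, tg$Sigma_zeta, kmax = 50)
  target <- S_oracle + tg$Sigma_b
  expect_lt(max(abs(cov(y3) - target)), 0.08 * max(diag(target)))
  expect_lt(max(abs(colMeans(y3) - tg$mu)), 0.05)
})

test_that("null truth yields no lag-1 cross-covariance in person-centered data", {
  truth <- default_truth("null", n_per_group = c(G1 = 5000, G2 = 60,
                                                 G3 = 60))
  panel <- simulate_panel(truth, seed = 99)
  sc <- panel$scores[panel$scores$group == "G1", ]
  nodes <- panelnet_nodes()
  wide <- lapply(c(3, 5, 9), function(w)
    as.matrix(sc[sc$wave == w, nodes]))
  pm <- (wide[[1]] + wide[[2]] + wide[[3]]) / 3
  w1 <- wide[[1]] - pm; w2 <- wide[[2]] - pm
  cc <- cov(w2, w1)
  offdiag <- cc[row(cc) != col(cc)]
  expect_lt(max(abs(offdiag)), 0.04 * max(diag(cov(w1))))
})

test_that("likert discretization counts thresholds strictly below x", {
  expect_identical(discretize_likert(0, c(-0.5, 0.5)), 1L)
  expect_identical(discretize_likert(-2, c(-0.5, 0.5)), 0L)
  expect_identical(discretize_likert(c(-1, 0, 1), c(-0.5, 0.5)),
                   c(0L, 1L, 2L))
  expect_error(discretize_likert(0, c(0.5, -0.5)), "increasing")
  set.seed(7)
  x <- rnorm(20000)
  f <- tabulate(discretize_likert(x, c(-0.43, 0.43)) + 1L, 3) / 20000
  # oracle: normal CDF at the thresholds
  expect_equal(f, c(pnorm(-0.43), pnorm(0.43) - pnorm(-0.43),
                    1 - pnorm(0.43)), tolerance = 0.02)
})

test_that("monotone dropout hits the configured attrition rates", {
  truth <- default_truth("shared", n_per_group = c(G1 = 4000, G2 = 3000,
                                                   G3 = 3000))
  panel <- simulate_panel(truth, seed = 8)
  panel <- apply_missingness(panel, seed = 8)
  sc <- panel$scores
  obs <- tapply(!is.na(sc$irr), sc$wave, mean)
  expect_equal(unname(obs["3"]), 1)
  expect_equal(unname(obs["5"]), 1 - 0.0143, tolerance = 0.015)
  expect_equal(unname(obs["9"]), (1 - 0.0143) * (1 - 0.0984),
               tolerance = 0.015)
  # monotone: missing at 5 implies missing at 9
  m5 <- sc$person_id[sc$wave == 5 & is.na(sc$irr)]
  expect_true(all(is.na(sc$irr[sc$wave == 9 & sc$person_id %in% m5])))
  # inclusion rule: exactly the persons with >= 2 observed irritability waves
  irr_w <- tapply(!is.na(sc$irr), sc$person_id, sum)
  expect_identical(panel$inclusion$included,
                   unname(as.integer(irr_w[panel$inclusion$person_id]) >= 2L))
})

test_that("degenerate retention keeps or removes everyone", {
  truth <- default_truth("shared", n_per_group = c(G1 = 100, G2 = 60,
                                                   G3 = 60))
  truth$retention <- c(r35 = 1, r59 = 1)
  panel <- apply_missingness(simulate_panel(truth, seed = 1), truth, 1)
  expect_true(all(panel$inclusion$included))
  truth$retention <- c(r35 = 0, r59 = 1)
  panel0 <- apply_missingness(simulate_panel(truth, seed = 1), truth, 1)
  sc <- panel0$scores
  expect_true(all(is.na(sc$irr[sc$wave %in% c(5, 9)])))
  expect_false(any(panel0$inclusion$included))
})
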