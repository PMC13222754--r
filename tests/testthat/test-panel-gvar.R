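test_that("the stationary covariance solves the Lyapunov equation", {
  Q <- diag(c(1, 2, 0.5))
  expect_equal(stationary_within_cov(matrix(0, 3, 3), Q), Q,
               ignore_attr = TRUE)
  expect_equal(stationary_within_cov(matrix(0.5), matrix(1))[1, 1], 4 / 3)
  set.seed(44)
  B <- matrix(rnorm(16, sd = 0.2), 4)
  B <- B * (0.8 / max(Mod(eigen(B)$values)))
  Q <- random_pd_cov(4, seed = 6)
  S <- stationary_within_cov(B, Q)
  expect_lt(max(abs(S - lyapunov_series(B, Q))), 1e-8)
  expect_error(stationary_within_cov(diag(1.01, 3), diag(3)),
               "stationary")
})

test_that("the implied covariance has the promised block structure", {
  p <- 3
  Sz <- random_pd_cov(p, seed = 2)
  Sig <- implied_covariance(list(B = matrix(0, p, p), Sigma_zeta = Sz,
                                 Sigma_b = matrix(0, p, p)), waves = 3)
  bd <- matrix(0, 9, 9)
  for (t in 0:2) bd[t * p + 1:p, t * p + 1:p] <- Sz
  expect_equal(Sig, bd, ignore_attr = TRUE)
  Sb <- matrix(0.3, p, p) + diag(0.2, p)
  Sig2 <- implied_covariance(list(B = matrix(0, p, p), Sigma_zeta = diag(p),
                                  Sigma_b = Sb), waves = 3)
  expect_equal(Sig2[4:6, 1:3], Sb)
  expect_equal(Sig2[7:9, 1:3], Sb)
  # symmetric PD across random stable parameter draws
  for (seed in 1:5) {
    set.seed(seed)
    B <- matrix(rnorm(16, sd = 0.25), 4)
    B <- B * (0.7 / max(Mod(eigen(B)$values)))
    Sig3 <- implied_covariance(list(B = B,
                                    Sigma_zeta = random_pd_cov(4, seed),
                                    Sigma_b = random_pd_cov(4, seed + 50) / 4),
                               waves = 3)
    expect_equal(Sig3, t(Sig3))
    expect_gt(min(eigen(Sig3, symmetric = TRUE)$values), 0)
  }
})

test_that("implied covariance matches generator moments (round trip)", {
  truth <- balanced_gvar_truth(n = 20000)
  tg <- truth$per_group$G1
  sc <- simulate_group_scores(truth, seed = 202)
  Y <- panelnet:::scores_to_wide(sc, panelnet_nodes(), c(3, 5, 9))
  Sig_emp <- cov(Y)
  Sig_th <- implied_covariance(list(B = tg$B, Sigma_zeta = tg$Sigma_zeta,
                                    Sigma_b = tg$Sigma_b), waves = 3)
  expect_lt(max(abs(Sig_emp - Sig_th)), 0.06 * max(diag(Sig_th)))
})

test_that("the optimizer improves on its starting values and fits recover truth", {
  truth <- balanced_gvar_truth(n = 800)
  sc <- simulate_group_scores(truth, seed = 9)
  fit <- fit_panel_gvar(sc)
  expect_true(fit$converged)
  # optimizer contract: discrepancy at optimum <= discrepancy at start
  Y <- panelnet:::scores_to_wide(sc, panelnet_nodes(), c(3, 5, 9))
  Y <- Y[complete.cases(Y), ]
  start <- panelnet:::gvar_moment_start(Y, 6, 3)
  u <- panelnet:::theta_unpack(start, 6)
  Sn <- crossprod(scale(Y, scale = FALSE)) / nrow(Y)
  f_start <- panelnet:::cpp_gvar_eval(u$B, u$dz, u$Oz, u$db, u$Ob, Sn, 3L,
                                      FALSE, FALSE)$f
  expect_lte(fit$F_value, f_start + 1e-10)
  tg <- truth$per_group$G1
  expect_lt(mean(abs(fit$B - tg$B)), 0.06)
  expect_lt(abs(fit$B["pstr", "irr"] - 0.4), 0.12)
  # pooling: one lag-1 structure by construction
  expect_equal(dim(fit$B), c(6L, 6L))
})

test_that("self-consistency: refitting data simulated from the fitted model", {
  truth <- balanced_gvar_truth(n = 700)
  fit <- fit_panel_gvar(simulate_group_scores(truth, seed = 31))
  truth2 <- truth
  truth2$per_group$G1$B <- fit$B
  truth2$per_group$G1$Sigma_zeta <- fit$Sigma_zeta
  truth2$per_group$G1$Sigma_b <- fit$Sigma_b
  truth2$per_group$G1$S <- fit$S
  truth2$per_group$G1$n <- 20000
  refit <- fit_panel_gvar(simulate_group_scores(truth2, seed = 32))
  expect_lt(mean(abs(refit$B - fit$B)), 0.02)
  expect_lt(mean(abs(refit$Omega_zeta - fit$Omega_zeta)), 0.02)
})

test_that("pruning removes parameters without increasing the likelihood", {
  truth <- balanced_gvar_truth(n = 800)
  sc <- simulate_group_scores(truth, seed = 13)
  fit <- fit_panel_gvar(sc)
  pr <- prune(fit, alpha = 0.01)
  expect_lte(pr$loglik, fit$loglik + 1e-6)
  expect_gt(pr$df, fit$df)
  expect_lt(pr$nfree, fit$nfree)
  # fixed parameters are exactly zero
  expect_true(all(pr$B[!pr$pattern$B] == 0))
  expect_true(all(pr$Omega_zeta[!pr$pattern$Oz & upper.tri(pr$B)] == 0))
  # remaining structural parameters are all significant at alpha
  left <- pr$pval$B[pr$pattern$B]
  expect_true(all(left < 0.01, na.rm = TRUE))
  # degenerate threshold: nothing pruned
  pr1 <- prune(fit, alpha = 1)
  expect_identical(pr1$nfree, fit$nfree)
  expect_identical(pr1$B, fit$B)
})

test_that("fit indices reduce to their closed-form arithmetic", {
  dummy <- list(n = 1001, loglik = -1000, df = 50, Sn = diag(2))
  fi <- fit_indices(dummy, saturated_loglik = -950,
                    baseline_loglik = -1450, baseline_df = 60)
  expect_equal(fi$chisq, 100)
  expect_equal(fi$rmsea, sqrt(50 / (50 * 1000)))
  expect_equal(fi$cfi, 1 - 50 / 940, tolerance = 1e-12)
  expect_equal(fi$tli, ((1000 / 60) - 2) / ((1000 / 60) - 1),
               tolerance = 1e-12)
  # a model matching the saturated likelihood with zero df is perfect
  sat <- list(n = 500, loglik = -800, df = 0, Sn = diag(2))
  fi0 <- fit_indices(sat, saturated_loglik = -800,
                     baseline_loglik = -900, baseline_df = 10)
  expect_equal(fi0$chisq, 0)
  expect_equal(fi0$cfi, 1)
  expect_equal(fi0$rmsea, 0)
  expect_identical(fi0$tli_flag, "undefined_df0")
})

test_that("temporal standardization has the right limits and unit invariance", {
  truth <- balanced_gvar_truth(n = 600)
  sc <- simulate_group_scores(truth, seed = 3)
  fit <- fit_panel_gvar(sc)
  Bs <- temporal_std(fit)
  # scalar AR(1) identity on the diagonal: unchanged
  expect_equal(diag(Bs), diag(fit$B), tolerance = 1e-12)
  zero <- fit; zero$B <- matrix(0, 6, 6); zero$S <- diag(6)
  expect_true(all(temporal_std(zero) == 0))
  # unit-variance stationary process: standardized equals raw
  unit <- list(B = fit$B, S = diag(6))
  expect_equal(temporal_std(unit), fit$B, tolerance = 1e-12,
               ignore_attr = TRUE)
  # invariance to rescaling the composites
  sc2 <- sc
  sc2$irr <- sc2$irr * 10
  fit2 <- fit_panel_gvar(sc2)
  expect_equal(temporal_std(fit2), Bs, tolerance = 0.02)
})

test_that("bootstrap summaries are deterministic and respect the stability boundary", {
  truth <- balanced_gvar_truth(n = 300)
  sc <- simulate_group_scores(truth, seed = 21)
  b1 <- bootstrap_edges(sc, R = 2, seed = 7, control = list(min_n = 100))
  b2 <- bootstrap_edges(sc, R = 2, seed = 7, control = list(min_n = 100))
  expect_identical(b1$edges, b2$edges)

  fit <- prune(fit_panel_gvar(sc), alpha = 0.01)
  boots <- b1
  boots$edges$inclusion <- rep(1, nrow(boots$edges))
  st <- stable_network(fit, boots)
  expect_identical(st$B, fit$B)
  boots$edges$inclusion <- rep(0, nrow(boots$edges))
  st0 <- stable_network(fit, boots)
  expect_true(all(st0$B == 0) && all(st0$Omega_zeta == 0))
  # boundary inclusive: inclusion exactly 0.5 survives
  boots$edges$inclusion <- rep(c(0.5, 0.49), length.out = nrow(boots$edges))
  st5 <- stable_network(fit, boots, threshold = 0.5)
  kept <- st5$stable$stable
  expect_identical(kept, boots$edges$inclusion >= 0.5)
})
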