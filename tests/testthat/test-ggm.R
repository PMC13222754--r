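test_that("partial correlations match the residual-regression oracle", {
  expect_equal(partial_correlations(diag(3)), matrix(0, 3, 3),
               ignore_attr = TRUE)
  S2 <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(partial_correlations(S2)[1, 2], 0.5)
  S3 <- matrix(c(2, 0.8, 0.5,
                 0.8, 1.5, 0.6,
                 0.5, 0.6, 1.2), 3)
  P <- partial_correlations(S3)
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(P[i, j], pcor_by_residual_regression(S3, i, j),
                 tolerance = 1e-10)
  }
  expect_error(partial_correlations(matrix(c(1, 1, 1, 1), 2)), "singular")
})

test_that("partial correlations commute with node permutation", {
  S <- random_pd_cov(5, seed = 11)
  P <- partial_correlations(S)
  pm <- c(3, 1, 5, 2, 4)
  expect_equal(partial_correlations(S[pm, pm]), P[pm, pm],
               tolerance = 1e-12)
})

test_that("glasso hits its unpenalized and fully-penalized limits", {
  S <- cov2cor(random_pd_cov(4, seed = 3))
  expect_lt(max(abs(glasso(S, 0)$K - solve(S))), 1e-6)
  lam_max <- max(abs(S[upper.tri(S)]))
  K <- glasso(S, lam_max + 1e-8)$K
  expect_true(all(K[upper.tri(K)] == 0))
  expect_error(glasso(S, -0.1), "lambda")
})

test_that("glasso solutions satisfy the KKT optimality conditions", {
  # Independent oracle: stationarity of the penalized likelihood requires
  # W_ij = S_ij + lambda sign(K_ij) on active edges, |W_ij - S_ij| <= lambda
  # on zero edges, W_ii = S_ii.
  for (seed in c(5, 17)) {
    S <- cov2cor(random_pd_cov(6, seed = seed))
    for (lam in c(0.05, 0.15)) {
      fit <- glasso(S, lam)
      W <- solve(fit$K)
      act <- abs(fit$K) > 1e-8 & row(S) != col(S)
      zer <- abs(fit$K) <= 1e-8
      if (any(act)) {
        expect_lt(max(abs((W - S - lam * sign(fit$K))[act])), 1e-6)
      }
      if (any(zer)) expect_lt(max(abs((W - S)[zer])) - lam, 1e-8)
      expect_lt(max(abs(diag(W) - diag(S))), 1e-6)
    }
  }
})

test_that("the glasso path is monotone in sparsity", {
  fx <- fixture_ggm8()
  set.seed(21)
  X <- rmvn_chol(400, fx$chol)
  S <- cor(X)
  lams <- exp(seq(log(0.5), log(0.01), length.out = 40))
  path <- panelnet:::cpp_glasso_path(S, lams, FALSE, 1e-7, 500L)
  Es <- sapply(seq_along(lams), function(i)
    panelnet:::edge_count(path$K[, , i]))
  # decreasing lambda: edge count non-decreasing (rare one-edge ties allowed)
  expect_true(all(diff(Es) >= -1))
  expect_gt(Es[length(Es)], Es[1])
})

test_that("EBIC reduces to its arithmetic definition", {
  expect_equal(ebic(-100, 3, 1000, 8, 0.5),
               200 + 3 * log(1000) + 6 * log(8))
  expect_equal(ebic(-50, 0, 100, 5, 0.5), 100)
  expect_equal(ebic(-50, 4, 100, 5, 0), 100 + 4 * log(100))
})

test_that("network estimation is deterministic and names degenerate nodes", {
  fx <- fixture_ggm8()
  set.seed(12)
  X <- rmvn_chol(900, fx$chol)
  colnames(X) <- paste0("v", 1:8)
  sc <- data.frame(person_id = 1:900, group = "G1", wave = 3, X)
  n1 <- estimate_ggm(sc, "G1", 3, nodes = colnames(X), nlambda = 40)
  n2 <- estimate_ggm(sc, "G1", 3, nodes = colnames(X), nlambda = 40)
  expect_identical(n1$lambda, n2$lambda)
  expect_identical(n1$pcor, n2$pcor)
  expect_equal(n1$E, sum(n1$pcor[upper.tri(n1$pcor)] != 0))
  expect_equal(n1$pcor, t(n1$pcor))
  expect_true(all(diag(n1$pcor) == 0))
  sc$v3 <- 1
  expect_error(estimate_ggm(sc, "G1", 3, nodes = colnames(X)), "v3")
})

test_that("estimation at the population covariance recovers truth as lambda -> 0", {
  fx <- fixture_ggm8()
  # data engineered to have sample covariance exactly equal to the
  # population matrix
  set.seed(31)
  n <- 600
  Z <- scale(matrix(rnorm(n * 8), n))
  Z <- Z %*% solve(chol(cov(Z)))
  X <- Z %*% fx$chol
  fit <- panelnet:::ggm_from_matrix(X, lambda_grid = 1e-7)
  expect_lt(max(abs(fit$pcor - fx$Omega)), 1e-3)
})
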