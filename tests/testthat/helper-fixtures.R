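# Fixtures built in code: known GGM populations and well-conditioned
# GVAR truths used across the unit and acceptance tests.

# Random positive-definite covariance with names.
random_pd_cov <- function(p, seed) {
  set.seed(seed)
  A <- matrix(rnorm(p * p, sd = 0.5), p, p)
  S <- crossprod(A) + diag(p)
  dimnames(S) <- list(paste0("v", 1:p), paste0("v", 1:p))
  S
}

# Partial-correlation oracle: correlation of residuals after regressing
# each of i, j on all remaining variables (population-level, from cov).
pcor_by_residual_regression <- function(cov, i, j) {
  others <- setdiff(seq_len(ncol(cov)), c(i, j))
  if (length(others) == 0) return(stats::cov2cor(cov)[i, j])
  Soo <- cov[others, others, drop = FALSE]
  bi <- solve(Soo, cov[others, i])
  bj <- solve(Soo, cov[others, j])
  vi <- cov[i, i] - crossprod(cov[others, i], bi)
  vj <- cov[j, j] - crossprod(cov[others, j], bj)
  cij <- cov[i, j] - crossprod(cov[others, i], bj)
  as.numeric(cij / sqrt(vi * vj))
}

# Frozen sparse 8-node GGM truth for edge-recovery tests.
fixture_ggm8 <- function() {
  p <- 8
  edges <- rbind(c(1, 2), c(3, 4), c(5, 6), c(7, 8), c(2, 5), c(4, 7))
  vals <- c(0.3, 0.28, -0.3, 0.28, 0.25, -0.25)
  Om <- matrix(0, p, p)
  for (i in seq_len(nrow(edges))) {
    Om[edges[i, 1], edges[i, 2]] <- vals[i]
    Om[edges[i, 2], edges[i, 1]] <- vals[i]
  }
  K <- -Om
  diag(K) <- 1
  Sigma <- stats::cov2cor(solve(K))
  list(Omega = Om, Sigma = Sigma, chol = chol(Sigma))
}

# 6-node population with every partial correlation 0.15: non-degenerate
# edge statistics for permutation-test calibration.
fixture_dense6 <- function() {
  p <- 6
  Om <- matrix(0.15, p, p)
  diag(Om) <- 0
  K <- -Om
  diag(K) <- 1
  Sigma <- stats::cov2cor(solve(K))
  list(Omega = Om, Sigma = Sigma, chol = chol(Sigma))
}

rmvn_chol <- function(n, ch) matrix(rnorm(n * ncol(ch)), n) %*% ch

# Well-conditioned (unit-scale) GVAR truth: autoregressive 0.3 on every
# node, one strong cross-lagged edge pstr <- irr, mild contemporaneous and
# between-person structure. `strong` sets the pstr <- irr coefficient.
balanced_gvar_truth <- function(n = 1000, strong = 0.4) {
  nodes <- panelnet_nodes()
  p <- length(nodes)
  B <- diag(0.3, p)
  dimnames(B) <- list(nodes, nodes)
  B["pstr", "irr"] <- strong
  Oz <- matrix(0, p, p, dimnames = list(nodes, nodes))
  Oz["irr", "pstr"] <- Oz["pstr", "irr"] <- 0.2
  Oz["psyAgg", "phyAs"] <- Oz["phyAs", "psyAgg"] <- 0.2
  Ob <- matrix(0, p, p, dimnames = list(nodes, nodes))
  Ob["irr", "pstr"] <- Ob["pstr", "irr"] <- 0.2
  Sz <- panelnet:::calibrate_innovations(
    B, panelnet:::pcor_to_cov(Oz, rep(1, p)), rep(1, p))
  base <- default_truth("shared", n_per_group = c(G1 = n))
  tg <- base$per_group$G1
  tg$B <- B
  tg$Sigma_zeta <- Sz
  tg$Sigma_b <- panelnet:::pcor_to_cov(Ob, rep(sqrt(0.4), p))
  tg$S <- stationary_within_cov(B, Sz)
  tg$mu <- setNames(rep(0, p), nodes)
  tg$n <- n
  base$per_group <- list(G1 = tg)
  base$groups <- "G1"
  base
}

# One-group scores from a truth object.
simulate_group_scores <- function(truth, seed, group = "G1") {
  panel <- simulate_panel(truth, seed = seed)
  panel$scores[panel$scores$group == group, , drop = FALSE]
}

# Truncated-series oracle for the stationary covariance.
lyapunov_series <- function(B, Q, kmax = 200) {
  S <- Q
  Bk <- B
  for (k in seq_len(kmax)) {
    S <- S + Bk %*% Q %*% t(Bk)
    Bk <- Bk %*% B
  }
  S
}
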