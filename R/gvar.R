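# Pooled-lag panel graphical VAR. Parameters: temporal matrix B (directed,
# row = outcome at t, column = predictor at t-1), contemporaneous
# partial-correlation network of the innovations, and a between-person
# partial-correlation network, each network carried by a precision matrix
# K = D (I - Omega) D with D = diag(exp(delta)). Estimation maximizes the
# Gaussian likelihood of the stacked p*T observation vector with a
# saturated mean structure; the compiled back-end supplies the discrepancy,
# analytic gradient and expected information.

#' Stationary within-person covariance of a lag-1 VAR
#'
#' Solves the discrete Lyapunov equation `S = B S B' + Sigma_zeta`.
#'
#' @param B Temporal (lag-1 regression) matrix, spectral radius < 1.
#' @param Sigma_zeta Positive-definite innovation covariance.
#' @return Symmetric positive-definite stationary covariance.
#' @export
stationary_within_cov <- function(B, Sigma_zeta) {
  B <- as.matrix(B); Sigma_zeta <- as.matrix(Sigma_zeta)
  rad <- max(Mod(eigen(B, only.values = TRUE)$values))
  if (rad >= 1) stop("Spectral radius of B is ", round(rad, 4),
                     " >= 1; process is not stationary.", call. = FALSE)
  if (inherits(tryCatch(chol(Sigma_zeta), error = function(e) e), "error")) {
    stop("Sigma_zeta must be positive definite.", call. = FALSE)
  }
  S <- cpp_lyap(B, Sigma_zeta)
  dimnames(S) <- dimnames(B)
  S
}

#' Implied covariance of the stacked panel observation vector
#'
#' Block (t, s) with t >= s equals `B^(t-s) S + Sigma_b`, where S is the
#' stationary within-person covariance; the between-person component is
#' constant across wave pairs.
#'
#' @param params List with `B`, `Sigma_zeta`, `Sigma_b` (or a
#'   `panel_gvar_fit`).
#' @param waves Number of waves T.
#' @return Symmetric positive-definite `(p*T) x (p*T)` matrix.
#' @export
implied_covariance <- function(params, waves = 3) {
  B <- as.matrix(params$B)
  S <- stationary_within_cov(B, params$Sigma_zeta)
  Sb <- as.matrix(params$Sigma_b)
  p <- ncol(B)
  C <- vector("list", waves)
  C[[1]] <- S
  if (waves > 1) for (k in 2:waves) C[[k]] <- B %*% C[[k - 1]]
  Sig <- matrix(0, p * waves, p * waves)
  for (t in seq_len(waves)) {
    for (s in seq_len(t)) {
      blk <- C[[t - s + 1]] + Sb
      Sig[((t - 1) * p + 1):(t * p), ((s - 1) * p + 1):(s * p)] <- blk
      if (s != t) {
        Sig[((s - 1) * p + 1):(s * p), ((t - 1) * p + 1):(t * p)] <- t(blk)
      }
    }
  }
  0.5 * (Sig + t(Sig))
}

# ---- parameter bookkeeping -------------------------------------------------

tri_pairs <- function(p) which(upper.tri(diag(p)), arr.ind = TRUE)

theta_pack <- function(B, dz, Oz, db, Ob) {
  ut <- upper.tri(Oz)
  c(as.vector(B), dz, Oz[ut], db, Ob[ut])
}

theta_unpack <- function(theta, p) {
  m <- p * (p - 1) / 2
  B <- matrix(theta[1:(p^2)], p, p)
  i <- p^2
  dz <- theta[(i + 1):(i + p)]; i <- i + p
  Oz <- matrix(0, p, p); Oz[upper.tri(Oz)] <- theta[(i + 1):(i + m)]
  Oz <- Oz + t(Oz); i <- i + m
  db <- theta[(i + 1):(i + p)]; i <- i + p
  Ob <- matrix(0, p, p); Ob[upper.tri(Ob)] <- theta[(i + 1):(i + m)]
  Ob <- Ob + t(Ob)
  list(B = B, dz = dz, Oz = Oz, db = db, Ob = Ob)
}

saturated_pattern <- function(p) {
  list(B = matrix(TRUE, p, p),
       Oz = matrix(TRUE, p, p) & upper.tri(diag(p)) | lower.tri(diag(p)),
       Ob = matrix(TRUE, p, p) & upper.tri(diag(p)) | lower.tri(diag(p)))
}

pattern_pack <- function(pattern, p) {
  ut <- upper.tri(diag(p))
  c(as.vector(pattern$B), rep(TRUE, p), pattern$Oz[ut], rep(TRUE, p),
    pattern$Ob[ut])
}

cov_to_kparams <- function(Sigma) {
  K <- chol2inv(chol(Sigma))
  d <- sqrt(diag(K))
  O <- -K / tcrossprod(d)
  diag(O) <- 0
  O[O > 0.95] <- 0.95
  O[O < -0.95] <- -0.95
  list(delta = log(d), Omega = 0.5 * (O + t(O)))
}

kparams_to_cov <- function(delta, Omega) {
  d <- exp(delta)
  M <- -Omega
  diag(M) <- 1
  K <- diag(d) %*% M %*% diag(d)
  chol2inv(chol(0.5 * (K + t(K))))
}

ensure_pd <- function(M, floor_frac = 0.02) {
  M <- 0.5 * (M + t(M))
  e <- eigen(M, symmetric = TRUE)
  fl <- floor_frac * mean(diag(M))
  e$values[e$values < fl] <- fl
  e$vectors %*% diag(e$values) %*% t(e$vectors)
}

# Moment-based starting values from the wide data matrix (n x pT).
gvar_moment_start <- function(Y, p, T) {
  n <- nrow(Y)
  Yw <- array(Y, c(n, p, T))
  M <- apply(Yw, c(1, 2), mean)
  W <- Yw - array(rep(M, T), c(n, p, T))
  X <- do.call(rbind, lapply(seq_len(T - 1), function(t) W[, , t]))
  Z <- do.call(rbind, lapply(seq_len(T - 1), function(t) W[, , t + 1]))
  B0 <- t(solve(crossprod(X) + diag(1e-8, p), crossprod(X, Z)))
  rad <- max(Mod(eigen(B0, only.values = TRUE)$values))
  if (rad > 0.9) B0 <- B0 * (0.9 / rad)
  resid <- Z - X %*% t(B0)
  Sz0 <- ensure_pd(stats::cov(resid))
  S0 <- cpp_lyap(B0, Sz0)
  C1 <- B0 %*% S0; C2 <- B0 %*% C1
  wbar_cov <- (3 * S0 + 2 * (C1 + t(C1)) + (C2 + t(C2))) / 9
  Sb0 <- ensure_pd(stats::cov(M) - wbar_cov, floor_frac = 0.05)
  kz <- cov_to_kparams(Sz0)
  kb <- cov_to_kparams(Sb0)
  theta_pack(B0, kz$delta, kz$Omega, kb$delta, kb$Omega)
}

# Core fit given the ML sample covariance of the stacked vector.
fit_gvar_core <- function(Sn, n, nodes, pattern, start_theta, waves = 3,
                          control = list()) {
  p <- length(nodes)
  free <- pattern_pack(pattern, p)
  base <- numeric(length(free))
  theta0 <- start_theta
  theta0[!free] <- 0
  maxit <- control$maxit %||% 600

  eval_at <- function(theta, grad = FALSE, info = FALSE) {
    pars <- theta_unpack(theta, p)
    cpp_gvar_eval(pars$B, pars$dz, pars$Oz, pars$db, pars$Ob, Sn,
                  as.integer(waves), grad, info)
  }
  fn <- function(tf) {
    th <- base; th[free] <- tf
    eval_at(th)$f
  }
  gr <- function(tf) {
    th <- base; th[free] <- tf
    ev <- eval_at(th, grad = TRUE)
    if (!isTRUE(ev$ok)) return(rep(0, sum(free)))
    ev$grad[free]
  }
  opt <- stats::optim(theta0[free], fn, gr, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-12))
  if (opt$convergence != 0 || opt$value >= 1e9) {
    opt2 <- stats::nlminb(opt$par, fn, gr,
                          control = list(iter.max = maxit))
    if (opt2$objective <= opt$value) {
      opt <- list(par = opt2$par, value = opt2$objective,
                  convergence = opt2$convergence)
    }
  }
  theta <- base; theta[free] <- opt$par
  ev <- eval_at(theta, grad = TRUE, info = TRUE)
  if (!isTRUE(ev$ok)) {
    stop("Panel GVAR optimization ended in an infeasible region (gradient ",
         "norm unavailable).", call. = FALSE)
  }
  gnorm <- sqrt(sum(ev$grad[free]^2))
  converged <- opt$convergence == 0 || gnorm < 1e-4

  se <- rep(NA_real_, length(theta))
  Ifree <- ev$info[free, free, drop = FALSE]
  Vf <- tryCatch(solve((n / 2) * Ifree), error = function(e) {
    MASS::ginv((n / 2) * Ifree)
  })
  se[free] <- sqrt(pmax(diag(Vf), 0))
  pval <- rep(NA_real_, length(theta))
  pval[free] <- 2 * stats::pnorm(-abs(theta[free] / se[free]))

  pars <- theta_unpack(theta, p)
  dimnames(pattern$B) <- dimnames(pattern$Oz) <- dimnames(pattern$Ob) <-
    list(nodes, nodes)
  dimnames(pars$B) <- list(nodes, nodes)
  dimnames(pars$Oz) <- list(nodes, nodes)
  dimnames(pars$Ob) <- list(nodes, nodes)
  Sigma_zeta <- kparams_to_cov(pars$dz, pars$Oz)
  Sigma_b <- kparams_to_cov(pars$db, pars$Ob)
  dimnames(Sigma_zeta) <- dimnames(Sigma_b) <- list(nodes, nodes)
  S <- stationary_within_cov(pars$B, Sigma_zeta)
  d <- p * waves
  F_model <- ev$f
  loglik <- -(n / 2) * (F_model + d * log(2 * pi))
  nfree <- sum(free)
  df <- d * (d + 1) / 2 - nfree

  sep <- theta_unpack(ifelse(is.na(se), NA_real_, se), p)
  pvp <- theta_unpack(ifelse(is.na(pval), NA_real_, pval), p)
  shape_named <- function(M) { dimnames(M) <- list(nodes, nodes); M }

  structure(list(
    nodes = nodes, waves = waves, n = n, Sn = Sn,
    pattern = pattern, theta = theta, free = free,
    B = pars$B, Omega_zeta = pars$Oz, Omega_b = pars$Ob,
    delta_zeta = pars$dz, delta_b = pars$db,
    Sigma_zeta = Sigma_zeta, Sigma_b = Sigma_b, S = S,
    se = list(B = shape_named(sep$B), Omega_zeta = shape_named(sep$Oz),
              Omega_b = shape_named(sep$Ob)),
    pval = list(B = shape_named(pvp$B), Omega_zeta = shape_named(pvp$Oz),
                Omega_b = shape_named(pvp$Ob)),
    F_value = F_model, loglik = loglik, df = df, nfree = nfree,
    converged = converged, grad_norm = gnorm,
    control = control), class = "panel_gvar_fit")
}

#' Fit a pooled-lag panel graphical VAR for one group
#'
#' Maximizes the Gaussian likelihood of the stacked observation vector
#' (all nodes at all waves) under the stationarity-constrained implied
#' covariance: one temporal matrix pooled across consecutive wave pairs, a
#' contemporaneous innovation network and a between-person network. The
#' mean structure is saturated (sample means), so the reported discrepancy
#' concerns the covariance structure. Complete-case on the stacked vector
#' by default. Starting values come from lag-1 moment regressions on
#' person-centered data.
#'
#' @param scores Scored table for one group (long; columns `person_id`,
#'   `wave`, node columns).
#' @param nodes Node columns (default the six composites).
#' @param pattern Optional free/fixed pattern (list of logical matrices
#'   `B`, `Oz`, `Ob`); default saturated.
#' @param start Optional starting parameter vector.
#' @param waves Wave labels, in temporal order.
#' @param control List: `maxit` (default 600), `min_n` (default 100).
#' @return Object of class `"panel_gvar_fit"` with estimates, standard
#'   errors (expected-information Wald), log-likelihood, df and
#'   convergence information. See [fit_indices()], [prune()],
#'   [bootstrap_edges()].
#' @export
fit_panel_gvar <- function(scores, nodes = panelnet_nodes(), pattern = NULL,
                           start = NULL, waves = c(3, 5, 9),
                           control = list()) {
  Y <- scores_to_wide(scores, nodes, waves)
  Y <- Y[stats::complete.cases(Y), , drop = FALSE]
  n <- nrow(Y)
  min_n <- control$min_n %||% 100
  if (n < min_n) stop("Need >= ", min_n, " complete cases; have ", n, ".",
                      call. = FALSE)
  p <- length(nodes); T <- length(waves)
  Yc <- scale(Y, scale = FALSE)
  Sn <- crossprod(Yc) / n
  if (inherits(tryCatch(chol(Sn), error = function(e) e), "error")) {
    warning("Sample covariance not positive definite; ridge added.",
            call. = FALSE)
    Sn <- Sn + diag(1e-6 * mean(diag(Sn)), ncol(Sn))
  }
  if (is.null(pattern)) pattern <- saturated_pattern(p)
  if (is.null(start)) start <- gvar_moment_start(Y, p, T)
  fit <- fit_gvar_core(Sn, n, nodes, pattern, start, waves = T,
                       control = control)
  fit$mu <- stats::setNames(rowMeans(matrix(colMeans(Y), p, T)), nodes)
  fit
}

# Long scores -> wide n x (p*T) matrix, wave-major column blocks.
scores_to_wide <- function(scores, nodes, waves) {
  ids <- unique(scores$person_id)
  p <- length(nodes); T <- length(waves)
  Y <- matrix(NA_real_, length(ids), p * T,
              dimnames = list(ids, paste(rep(nodes, T),
                                         rep(waves, each = p), sep = ".")))
  for (t in seq_along(waves)) {
    sub <- scores[scores$wave == waves[t], c("person_id", nodes)]
    Y[match(sub$person_id, ids), ((t - 1) * p + 1):(t * p)] <-
      as.matrix(sub[, nodes])
  }
  Y
}

#' @export
print.panel_gvar_fit <- function(x, ...) {
  fi <- fit_indices(x)
  cat(sprintf(
    "Panel GVAR: %d nodes x %d waves, n = %d, free = %d, df = %d\n",
    length(x$nodes), x$waves, x$n, x$nfree, x$df))
  cat(sprintf(
    "  chisq = %.2f, CFI = %.3f, TLI = %.3f, RMSEA = %.3f%s\n",
    fi$chisq, fi$cfi, fi$tli, fi$rmsea,
    if (!x$converged) "  [NOT CONVERGED]" else ""))
  invisible(x)
}

#' SEM fit indices for a panel GVAR fit
#'
#' Likelihood-ratio chi-square against the saturated covariance, with CFI,
#' TLI and RMSEA. The baseline model is the independence model with free
#' variances (and saturated means), the same for all groups.
#'
#' @param fit A `"panel_gvar_fit"`.
#' @param saturated_loglik,baseline_loglik,baseline_df Optional overrides;
#'   computed from the fit's sample covariance when omitted.
#' @return List with `chisq`, `df`, `cfi`, `tli`, `rmsea`,
#'   `chisq_baseline`, `df_baseline`, and `tli_flag` when TLI is undefined.
#' @export
fit_indices <- function(fit, saturated_loglik = NULL,
                        baseline_loglik = NULL, baseline_df = NULL) {
  n <- fit$n
  d <- nrow(fit$Sn)
  ldSn <- determinant(fit$Sn, logarithm = TRUE)$modulus[1]
  F_sat <- ldSn + d
  if (is.null(saturated_loglik)) {
    saturated_loglik <- -(n / 2) * (F_sat + d * log(2 * pi))
  }
  if (is.null(baseline_loglik)) {
    F_base <- sum(log(diag(fit$Sn))) + d
    baseline_loglik <- -(n / 2) * (F_base + d * log(2 * pi))
  }
  if (is.null(baseline_df)) baseline_df <- d * (d + 1) / 2 - d
  chisq_m <- max(2 * (saturated_loglik - fit$loglik), 0)
  df_m <- fit$df
  chisq_b <- max(2 * (saturated_loglik - baseline_loglik), 0)
  df_b <- baseline_df
  if (df_m == 0) {
    return(list(chisq = chisq_m, df = 0, cfi = 1, tli = NA_real_,
                rmsea = 0, chisq_baseline = chisq_b, df_baseline = df_b,
                tli_flag = "undefined_df0"))
  }
  num_m <- max(chisq_m - df_m, 0)
  num_b <- max(chisq_b - df_b, num_m, 0)
  cfi <- if (num_b == 0) 1 else 1 - num_m / num_b
  rb <- chisq_b / df_b
  rm_ <- chisq_m / df_m
  tli <- if (rb == 1) NA_real_ else (rb - rm_) / (rb - 1)
  rmsea <- sqrt(max(chisq_m - df_m, 0) / (df_m * (n - 1)))
  list(chisq = chisq_m, df = df_m, cfi = cfi, tli = tli, rmsea = rmsea,
       chisq_baseline = chisq_b, df_baseline = df_b, tli_flag = NULL)
}

#' Stepwise pruning of nonsignificant network parameters
#'
#' Iteratively fixes to zero every free structural parameter (temporal
#' edges including autoregressive diagonals, contemporaneous and
#' between-person partial correlations) whose Wald p-value is at or above
#' `alpha`, refits, and repeats until nothing is removable. Variances
#' (precision scales) always stay free. Model df increases with each
#' removal round.
#'
#' @param fit A converged `"panel_gvar_fit"`.
#' @param alpha Pruning level (default 0.01).
#' @param max_rounds Safety cap on removal rounds.
#' @return The pruned `"panel_gvar_fit"` (with `prune_rounds` recorded).
#' @export
prune <- function(fit, alpha = 0.01, max_rounds = 25) {
  if (alpha >= 1) { fit$prune_rounds <- 0L; return(fit) }
  rounds <- 0L
  repeat {
    pat <- fit$pattern
    ut <- upper.tri(diag(length(fit$nodes)))
    rem_B <- pat$B & !is.na(fit$pval$B) & fit$pval$B >= alpha
    rem_Oz <- pat$Oz & ut & !is.na(fit$pval$Omega_zeta) &
      fit$pval$Omega_zeta >= alpha
    rem_Ob <- pat$Ob & ut & !is.na(fit$pval$Omega_b) &
      fit$pval$Omega_b >= alpha
    if (!any(rem_B) && !any(rem_Oz) && !any(rem_Ob)) break
    if (rounds >= max_rounds) break
    pat$B[rem_B] <- FALSE
    pat$Oz[rem_Oz | t(rem_Oz)] <- FALSE
    pat$Ob[rem_Ob | t(rem_Ob)] <- FALSE
    new_fit <- tryCatch(
      fit_gvar_core(fit$Sn, fit$n, fit$nodes, pat, fit$theta,
                    waves = fit$waves, control = fit$control),
      error = function(e) NULL)
    if (is.null(new_fit) || !new_fit$converged) {
      warning("Pruning refit failed; returning last converged model.",
              call. = FALSE)
      break
    }
    new_fit$mu <- fit$mu
    fit <- new_fit
    rounds <- rounds + 1L
  }
  fit$prune_rounds <- rounds
  fit
}

# Canonical edge bookkeeping for bootstrap/stability summaries.
gvar_edge_frame <- function(nodes) {
  p <- length(nodes)
  tp <- expand.grid(to = nodes, from = nodes, KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE)[, c("from", "to")]
  ut <- tri_pairs(p)
  und <- data.frame(from = nodes[ut[, 1]], to = nodes[ut[, 2]],
                    stringsAsFactors = FALSE)
  rbind(
    data.frame(kind = ifelse(tp$from == tp$to, "autoregressive", "temporal"),
               tp, stringsAsFactors = FALSE),
    data.frame(kind = "contemporaneous", und, stringsAsFactors = FALSE),
    data.frame(kind = "between", und, stringsAsFactors = FALSE))
}

# Nonzero-and-free indicator vector aligned with gvar_edge_frame (the
# temporal block is traversed column-major: outcome fastest, predictor
# slowest, matching vec(B)).
gvar_edge_indicator <- function(fit, tol = 1e-10) {
  p <- length(fit$nodes)
  ut <- upper.tri(diag(p))
  c(as.vector(fit$pattern$B & abs(fit$B) > tol),
    (fit$pattern$Oz & abs(fit$Omega_zeta) > tol)[ut],
    (fit$pattern$Ob & abs(fit$Omega_b) > tol)[ut])
}

gvar_edge_estimates <- function(fit) {
  p <- length(fit$nodes)
  ut <- upper.tri(diag(p))
  c(as.vector(fit$B), fit$Omega_zeta[ut], fit$Omega_b[ut])
}

#' Case-bootstrap edge stability for the panel GVAR
#'
#' Resamples persons with replacement (all of a person's waves travel
#' together), refits and prunes the model on each resample, and reports
#' the proportion of resamples in which each edge is retained (free and
#' nonzero after pruning).
#'
#' @param scores Scored table for one group.
#' @param nodes Node columns.
#' @param R Number of bootstrap resamples.
#' @param alpha Pruning level used within each resample.
#' @param seed Integer seed (deterministic resampling).
#' @param threshold Stability threshold recorded in the summary
#'   (inclusion >= threshold counts as stable; default 0.5).
#' @param control Fit control list.
#' @return Object of class `"bootstrap_summary"`: `edges` data frame
#'   (kind, from, to, inclusion), `R`, `n_success`, `threshold`, `seed`.
#' @export
bootstrap_edges <- function(scores, nodes = panelnet_nodes(), R = 1000,
                            alpha = 0.01, seed = 1L, threshold = 0.5,
                            control = list()) {
  Y <- scores_to_wide(scores, nodes, c(3, 5, 9))
  Y <- Y[stats::complete.cases(Y), , drop = FALSE]
  n <- nrow(Y)
  p <- length(nodes)
  start <- gvar_moment_start(Y, p, 3)
  set.seed(derive_seed(seed, "bootstrap"))
  idx <- matrix(sample.int(n, n * R, replace = TRUE), n, R)
  ef <- gvar_edge_frame(nodes)
  counts <- numeric(nrow(ef))
  n_success <- 0L
  for (r in seq_len(R)) {
    Yr <- Y[idx[, r], , drop = FALSE]
    Src <- crossprod(scale(Yr, scale = FALSE)) / n
    res <- tryCatch({
      f <- fit_gvar_core(Src, n, nodes, saturated_pattern(p), start,
                         control = control)
      prune(f, alpha = alpha)
    }, error = function(e) NULL, warning = function(w) NULL)
    if (is.null(res)) next
    counts <- counts + gvar_edge_indicator(res)
    n_success <- n_success + 1L
  }
  if (n_success == 0L) stop("All bootstrap replicates failed.",
                            call. = FALSE)
  ef$inclusion <- counts / n_success
  structure(list(edges = ef, R = R, n_success = n_success,
                 threshold = threshold, seed = seed, nodes = nodes),
            class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf(
    "Bootstrap edge stability: %d/%d successful resamples, threshold %.2f\n",
    x$n_success, x$R, x$threshold))
  cat(sprintf("  %d of %d edges stable (inclusion >= threshold)\n",
              sum(x$edges$inclusion >= x$threshold), nrow(x$edges)))
  invisible(x)
}

#' Stability-masked network estimates
#'
#' Sets to zero every edge whose bootstrap inclusion proportion is below
#' the threshold; estimates of surviving edges are unchanged. The boundary
#' is inclusive: inclusion exactly at the threshold counts as stable.
#'
#' @param fit A (typically pruned) `"panel_gvar_fit"`.
#' @param boots Matching [bootstrap_edges()] summary.
#' @param threshold Stability threshold (default the summary's).
#' @return List of class `"stable_gvar"` with masked `B`, `Omega_zeta`,
#'   `Omega_b` and the stability indicator per edge.
#' @export
stable_network <- function(fit, boots, threshold = boots$threshold) {
  stopifnot(identical(fit$nodes, boots$nodes))
  ef <- boots$edges
  stable <- ef$inclusion >= threshold
  p <- length(fit$nodes)
  B <- fit$B; Oz <- fit$Omega_zeta; Ob <- fit$Omega_b
  tempo <- ef$kind %in% c("temporal", "autoregressive")
  Bmask <- matrix(stable[tempo], p, p)  # vec(B) order: outcome fastest
  B <- B * Bmask
  ut <- tri_pairs(p)
  zmask <- matrix(FALSE, p, p)
  zmask[ut] <- stable[ef$kind == "contemporaneous"]
  Oz <- Oz * (zmask | t(zmask))
  bmask <- matrix(FALSE, p, p)
  bmask[ut] <- stable[ef$kind == "between"]
  Ob <- Ob * (bmask | t(bmask))
  structure(list(nodes = fit$nodes, B = B, Omega_zeta = Oz, Omega_b = Ob,
                 threshold = threshold, stable = cbind(ef, stable = stable)),
            class = "stable_gvar")
}

#' Standardized temporal network
#'
#' Rescales the temporal matrix to a correlation-like scale:
#' `std(i <- j) = B_ij * sqrt(S_jj / S_ii)` with S the stationary
#' within-person covariance, so the result is invariant to the units of
#' the composites and reduces to the lag-1 autocorrelation for a diagonal
#' model.
#'
#' @param fit A `"panel_gvar_fit"` (or list with `B` and `S`).
#' @return Directed edge matrix on the standardized scale.
#' @export
temporal_std <- function(fit) {
  s <- sqrt(diag(fit$S))
  Bs <- fit$B * outer(1 / s, s)
  dimnames(Bs) <- dimnames(fit$B)
  Bs
}
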