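#' Partial correlations from a covariance matrix
#'
#' Standardizes the negative inverse covariance: with `K = solve(cov)`,
#' edge(i,j) = -K_ij / sqrt(K_ii K_jj), zero diagonal.
#'
#' @param cov Positive-definite covariance matrix.
#' @return Symmetric partial-correlation matrix with zero diagonal.
#' @export
partial_correlations <- function(cov) {
  cov <- as.matrix(cov)
  rc <- rcond(cov)
  ch <- tryCatch(chol(cov), error = function(e) NULL)
  if (is.null(ch) || rc < 1e-12) {
    stop("Covariance is singular or near-singular (rcond = ",
         format(rc, digits = 3), ").", call. = FALSE)
  }
  K <- chol2inv(ch)
  d <- sqrt(diag(K))
  P <- -K / tcrossprod(d)
  diag(P) <- 0
  dimnames(P) <- dimnames(cov)
  0.5 * (P + t(P))
}

#' Graphical lasso
#'
#' L1-penalized Gaussian likelihood estimation of a sparse precision
#' matrix: maximizes `log det K - tr(S K) - lambda * sum_{i!=j} |K_ij|`
#' by block coordinate descent. At `lambda = 0` the exact inverse of `S`
#' is returned; for `lambda >= max |off-diagonal S|` the precision is
#' diagonal (empty graph).
#'
#' @param S Sample covariance (typically a correlation matrix).
#' @param lambda Penalty, `>= 0`.
#' @param penalize_diag Penalize the diagonal as well (default `FALSE`,
#'   the usual convention for partial-correlation networks).
#' @param tol Convergence tolerance (relative to the mean absolute
#'   off-diagonal of `S`).
#' @param maxit Maximum number of sweeps.
#' @return List with precision `K`, working covariance `W`, `lambda`,
#'   `iterations`, `converged`.
#' @export
glasso <- function(S, lambda, penalize_diag = FALSE, tol = 1e-7,
                   maxit = 500) {
  S <- as.matrix(S)
  if (lambda < 0) stop("lambda must be >= 0.", call. = FALSE)
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) {
    if (lambda == 0) stop("S is not positive definite at lambda = 0.",
                          call. = FALSE)
    warning("S not positive definite; adding a small ridge.", call. = FALSE)
    S <- S + diag(1e-4 * mean(diag(S)), ncol(S))
    ch <- chol(S)
  }
  if (lambda == 0) {
    K <- chol2inv(ch)
    dimnames(K) <- dimnames(S)
    return(list(K = K, W = S, lambda = 0, iterations = 0L,
                converged = TRUE))
  }
  fit <- cpp_glasso(S, lambda, penalize_diag, tol, as.integer(maxit))
  if (!fit$converged) {
    stop("Graphical lasso did not converge at lambda = ", lambda,
         " within ", fit$iterations, " sweeps.", call. = FALSE)
  }
  dimnames(fit$K) <- dimnames(S)
  list(K = fit$K, W = fit$W, lambda = lambda,
       iterations = fit$iterations, converged = TRUE)
}

#' Extended Bayesian information criterion
#'
#' `-2 loglik + E log(n) + 4 gamma E log(p)` for a Gaussian graphical
#' model with `E` estimated edges.
#'
#' @param loglik Model log-likelihood.
#' @param E Number of nonzero upper-triangle edges.
#' @param n Sample size.
#' @param p Number of nodes.
#' @param gamma EBIC sparsity weight (`0` gives ordinary BIC).
#' @return EBIC value.
#' @export
ebic <- function(loglik, E, n, p, gamma) {
  stopifnot(n > 0, p >= 2, gamma >= 0)
  -2 * loglik + E * log(n) + 4 * gamma * E * log(p)
}

# Gaussian log-likelihood of precision K against sample covariance S
# (additive constant -n p log(2 pi)/2 dropped; cancels in EBIC comparisons).
ggm_loglik <- function(K, S, n) {
  (n / 2) * (determinant(K, logarithm = TRUE)$modulus[1] - sum(S * K))
}

edge_count <- function(K, tol = 1e-10) {
  sum(abs(K[upper.tri(K)]) > tol)
}

# Core estimator on a complete numeric matrix (persons x nodes).
ggm_from_matrix <- function(X, gamma = 0.5, nlambda = 100,
                            lambda_min_ratio = 0.01, lambda_grid = NULL,
                            tol = 1e-7, maxit = 500) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  sds <- apply(X, 2, stats::sd)
  if (any(sds < 1e-10)) {
    stop("Near-constant node(s): ",
         paste(colnames(X)[sds < 1e-10], collapse = ", "), call. = FALSE)
  }
  Z <- scale(X)
  S <- stats::cor(Z)
  if (is.null(lambda_grid)) {
    lmax <- max(abs(S[upper.tri(S)]))
    lambda_grid <- exp(seq(log(lmax), log(lambda_min_ratio * lmax),
                           length.out = nlambda))
  }
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  path <- cpp_glasso_path(S, lambda_grid, FALSE, tol, as.integer(maxit))
  if (!any(path$converged == 1)) {
    stop("Graphical lasso failed to converge on the whole lambda grid.",
         call. = FALSE)
  }
  m <- length(lambda_grid)
  crit <- rep(Inf, m); Es <- integer(m)
  for (i in seq_len(m)) {
    if (path$converged[i] != 1) next
    K <- path$K[, , i]
    Es[i] <- edge_count(K)
    crit[i] <- ebic(ggm_loglik(K, S, n), Es[i], n, p, gamma)
  }
  # minimum EBIC; ties broken towards the sparser (then more penalized) model
  best <- which(crit <= min(crit) + 1e-9)
  best <- best[order(Es[best], -lambda_grid[best])][1]
  K <- path$K[, , best]
  dimnames(K) <- dimnames(S)
  Kz <- K
  Kz[abs(Kz) <= 1e-10] <- 0
  d <- sqrt(diag(K))
  P <- -Kz / tcrossprod(d)
  diag(P) <- 0
  P <- 0.5 * (P + t(P))
  list(pcor = P, K = K, lambda = lambda_grid[best], gamma = gamma,
       n = n, E = Es[best], ebic = crit[best], lambda_grid = lambda_grid,
       ebic_path = crit, S = S)
}

#' Estimate a regularized cross-sectional network
#'
#' Fits the graphical lasso along a log-spaced penalty grid to the
#' within-group, within-wave standardized composites, selects the penalty
#' minimizing the EBIC and reports the selected partial-correlation
#' network. Complete-case by default; variables are z-scored within the
#' group-wave cell before estimation because the L1 penalty is not
#' scale-free.
#'
#' @param scores Scored table (long, one row per person and wave).
#' @param group,wave Cell to estimate.
#' @param nodes Node columns (default: six composites plus the two
#'   time-invariant cultural-belonging nodes).
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param nlambda,lambda_min_ratio Penalty grid: `nlambda` log-spaced
#'   values spanning `[lambda_min_ratio * lambda_max, lambda_max]`.
#' @param lambda_grid Optional explicit grid (overrides the above).
#' @return Object of class `"ggm_network"`: `nodes`, `pcor`, `lambda`,
#'   `gamma`, `n`, `E` (selected edges), `group`, `wave`.
#' @export
estimate_ggm <- function(scores, group, wave,
                         nodes = intersect(panelnet_nodes(TRUE),
                                           names(scores)),
                         gamma = 0.5, nlambda = 100,
                         lambda_min_ratio = 0.01, lambda_grid = NULL) {
  d <- scores[scores$group == group & scores$wave == wave, nodes,
              drop = FALSE]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) < 10 * length(nodes)) {
    stop("Need at least ", 10 * length(nodes), " complete cases; have ",
         nrow(d), ".", call. = FALSE)
  }
  fit <- ggm_from_matrix(d, gamma = gamma, nlambda = nlambda,
                         lambda_min_ratio = lambda_min_ratio,
                         lambda_grid = lambda_grid)
  structure(c(fit, list(nodes = nodes, group = group, wave = wave)),
            class = "ggm_network")
}

#' @export
print.ggm_network <- function(x, ...) {
  cat(sprintf(
    "GGM (%s, wave %s): %d nodes, %d edges, lambda = %.4f, gamma = %.2f, n = %d\n",
    x$group %||% "-", x$wave %||% "-", ncol(x$pcor), x$E, x$lambda,
    x$gamma, x$n))
  invisible(x)
}

#' Edge list of a network matrix
#'
#' @param net A `"ggm_network"` or a symmetric edge matrix.
#' @return Data frame with `from`, `to`, `weight` (upper triangle).
#' @export
ggm_edge_table <- function(net) {
  P <- if (inherits(net, "ggm_network")) net$pcor else as.matrix(net)
  labs <- colnames(P) %||% paste0("V", seq_len(ncol(P)))
  ut <- which(upper.tri(P), arr.ind = TRUE)
  data.frame(from = labs[ut[, 1]], to = labs[ut[, 2]],
             weight = P[ut])
}
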