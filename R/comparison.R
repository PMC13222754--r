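# Permutation comparisons of network edges between groups and waves.
# Two-sided statistics on absolute edge differences (AED), add-one
# permutation p-values, Holm adjustment reported alongside raw p.

p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*",
         ifelse(p < 0.10, "^", ""))))
}

#' Absolute edge differences between two networks
#'
#' @param netA,netB `"ggm_network"` objects or symmetric edge matrices
#'   with identical node sets and ordering.
#' @return Matrix of entrywise `|w_A - w_B|`.
#' @export
edge_differences <- function(netA, netB) {
  A <- if (inherits(netA, "ggm_network")) netA$pcor else as.matrix(netA)
  B <- if (inherits(netB, "ggm_network")) netB$pcor else as.matrix(netB)
  la <- colnames(A); lb <- colnames(B)
  if (!is.null(la) && !is.null(lb) && !identical(la, lb)) {
    stop("Node sets differ: ",
         paste(union(setdiff(la, lb), setdiff(lb, la)), collapse = ", "),
         call. = FALSE)
  }
  if (!all(dim(A) == dim(B))) stop("Edge matrices have different sizes.",
                                   call. = FALSE)
  abs(A - B)
}

#' Cross-sectional network estimator configurations
#'
#' `ggm_estimator()` returns the EBIC graphical-lasso estimator used for
#' the study networks; `pcor_estimator()` returns the unregularized
#' (saturated) partial-correlation estimator. Both map a complete
#' persons-by-nodes matrix to a partial-correlation matrix and are meant
#' to be fixed before any permutation testing.
#'
#' @param gamma,nlambda,lambda_min_ratio See [estimate_ggm()].
#' @return A function `X -> partial correlation matrix`.
#' @export
ggm_estimator <- function(gamma = 0.5, nlambda = 100,
                          lambda_min_ratio = 0.01) {
  function(X) ggm_from_matrix(X, gamma = gamma, nlambda = nlambda,
                              lambda_min_ratio = lambda_min_ratio)$pcor
}

#' @rdname ggm_estimator
#' @export
pcor_estimator <- function() {
  function(X) partial_correlations(stats::cor(as.matrix(X)))
}

as_node_matrix <- function(data, nodes = NULL) {
  X <- as.matrix(if (is.null(nodes)) data else data[, nodes, drop = FALSE])
  X[stats::complete.cases(X), , drop = FALSE]
}

edge_table_from <- function(obs, netA, netB, p, p_adj, n_perm, seed) {
  labs <- colnames(obs) %||% paste0("V", seq_len(ncol(obs)))
  ut <- which(upper.tri(obs), arr.ind = TRUE)
  data.frame(
    from = labs[ut[, 1]], to = labs[ut[, 2]],
    est_A = netA[ut], est_B = netB[ut], AED = obs[ut],
    p = p[ut], p_holm = p_adj, stars = p_stars(p[ut]),
    n_perm = n_perm, seed = seed, stringsAsFactors = FALSE)
}

#' Network comparison test between two groups
#'
#' Estimates one network per group, takes the absolute edge difference
#' (AED) per edge, and builds the permutation null by repeatedly shuffling
#' group labels over persons and re-estimating both networks. Per-edge
#' p-values use the add-one rule, `p = (1 + #{AED_perm >= AED_obs}) /
#' (1 + n_perm)`; the omnibus statistic is the maximum AED.
#'
#' @param dataA,dataB Persons-by-nodes matrices (or data frames) on the
#'   identical node set; incomplete rows are dropped.
#' @param estimator Estimator function (see [ggm_estimator()]); fixed
#'   before testing.
#' @param n_perm Number of permutations.
#' @param seed Integer seed; results are deterministic given the seed.
#' @param max_fail_frac Abort if more than this fraction of permutation
#'   re-estimations fail.
#' @return Object of class `"edge_comparison"`: `edges` (from, to, est_A,
#'   est_B, AED, p, p_holm, stars), `omnibus` (max AED and its p), counts.
#' @export
nct_edges <- function(dataA, dataB, estimator = ggm_estimator(),
                      n_perm = 1000, seed = 1L, max_fail_frac = 0.05) {
  XA <- as_node_matrix(dataA); XB <- as_node_matrix(dataB)
  if (!identical(colnames(XA), colnames(XB))) {
    stop("Samples must share the identical node set and order.",
         call. = FALSE)
  }
  netA <- estimator(XA); netB <- estimator(XB)
  obs <- abs(netA - netB)
  pool <- rbind(XA, XB)
  nA <- nrow(XA); n <- nrow(pool)
  set.seed(derive_seed(seed, "nct_edges"))
  counts <- matrix(0, nrow(obs), ncol(obs))
  omn_count <- 0
  omn_obs <- max(obs[upper.tri(obs)])
  fails <- 0L; succ <- 0L
  for (b in seq_len(n_perm)) {
    pm <- sample.int(n)
    d <- tryCatch(
      abs(estimator(pool[pm[seq_len(nA)], , drop = FALSE]) -
            estimator(pool[pm[(nA + 1):n], , drop = FALSE])),
      error = function(e) NULL)
    if (is.null(d)) { fails <- fails + 1L; next }
    succ <- succ + 1L
    counts <- counts + (d >= obs - 1e-12)
    omn_count <- omn_count + (max(d[upper.tri(d)]) >= omn_obs - 1e-12)
  }
  if (fails > max_fail_frac * n_perm) {
    stop("Estimator failed in ", fails, " of ", n_perm,
         " permutations; aborting.", call. = FALSE)
  }
  p <- (1 + counts) / (1 + succ)
  ut <- upper.tri(obs)
  p_adj <- holm_adjust(p[ut])
  edges <- edge_table_from(obs, netA, netB, p, p_adj, succ, seed)
  structure(list(edges = edges, netA = netA, netB = netB,
                 omnibus = list(stat = omn_obs,
                                p = (1 + omn_count) / (1 + succ)),
                 n_perm = succ, n_failed = fails, seed = seed),
            class = "edge_comparison")
}

#' @export
print.edge_comparison <- function(x, ...) {
  cat(sprintf(
    "Edge comparison: %d edges, %d permutations; omnibus max AED = %.3f (p = %.3f)\n",
    nrow(x$edges), x$n_perm, x$omnibus$stat, x$omnibus$p))
  sig <- x$edges[x$edges$p < 0.05, , drop = FALSE]
  if (nrow(sig)) print(sig[, c("from", "to", "AED", "p", "stars")],
                       row.names = FALSE)
  invisible(x)
}

#' Network comparison test between two waves (paired permutation)
#'
#' Compares edge weights between two timepoints within one sample using
#' persons measured at both waves. The null swaps each person's pair of
#' wave labels independently with probability one half, preserving the
#' within-person dependence under exchangeability of the waves. This
#' paired scheme is an approximation documented as this package's own
#' reconstruction.
#'
#' @param data Scored table (long) for one group.
#' @param waveX,waveY The two waves to compare.
#' @param nodes Node columns.
#' @inheritParams nct_edges
#' @param min_overlap Minimum persons with both waves complete.
#' @return `"edge_comparison"` object.
#' @export
nct_waves <- function(data, waveX, waveY,
                      nodes = intersect(panelnet_nodes(TRUE), names(data)),
                      estimator = ggm_estimator(), n_perm = 1000,
                      seed = 1L, max_fail_frac = 0.05, min_overlap = 100) {
  dx <- data[data$wave == waveX, c("person_id", nodes)]
  dy <- data[data$wave == waveY, c("person_id", nodes)]
  ids <- intersect(dx$person_id[stats::complete.cases(dx[, nodes])],
                   dy$person_id[stats::complete.cases(dy[, nodes])])
  if (length(ids) < min_overlap) {
    stop("Only ", length(ids), " persons complete at both waves; need >= ",
         min_overlap, ".", call. = FALSE)
  }
  XA <- as.matrix(dx[match(ids, dx$person_id), nodes])
  XB <- as.matrix(dy[match(ids, dy$person_id), nodes])
  netA <- estimator(XA); netB <- estimator(XB)
  obs <- abs(netA - netB)
  n <- length(ids)
  set.seed(derive_seed(seed, "nct_waves"))
  counts <- matrix(0, nrow(obs), ncol(obs))
  omn_obs <- max(obs[upper.tri(obs)]); omn_count <- 0
  fails <- 0L; succ <- 0L
  for (b in seq_len(n_perm)) {
    sw <- stats::runif(n) < 0.5
    Xa <- XA; Xb <- XB
    Xa[sw, ] <- XB[sw, ]; Xb[sw, ] <- XA[sw, ]
    d <- tryCatch(abs(estimator(Xa) - estimator(Xb)),
                  error = function(e) NULL)
    if (is.null(d)) { fails <- fails + 1L; next }
    succ <- succ + 1L
    counts <- counts + (d >= obs - 1e-12)
    omn_count <- omn_count + (max(d[upper.tri(d)]) >= omn_obs - 1e-12)
  }
  if (fails > max_fail_frac * n_perm) {
    stop("Estimator failed in ", fails, " of ", n_perm,
         " permutations; aborting.", call. = FALSE)
  }
  p <- (1 + counts) / (1 + succ)
  p_adj <- holm_adjust(p[upper.tri(p)])
  edges <- edge_table_from(obs, netA, netB, p, p_adj, succ, seed)
  structure(list(edges = edges, netA = netA, netB = netB,
                 omnibus = list(stat = omn_obs,
                                p = (1 + omn_count) / (1 + succ)),
                 n_perm = succ, n_failed = fails, seed = seed),
            class = "edge_comparison")
}

#' Permutation test of longitudinal (panel GVAR) edge differences
#'
#' Compares edges of two groups' pruned panel GVAR networks. The observed
#' difference per edge comes from the per-group pruned fits, with an edge
#' absent from a pruned network contributing 0. The null permutes whole
#' persons (all waves travel together) between the groups and refits and
#' prunes both models per permutation. Two-sided add-one p-values.
#'
#' @param panelA,panelB Scored tables (long) for the two groups.
#' @param nodes Node columns.
#' @param edges Optional data frame (kind, from, to) restricting the
#'   report; default all structural edges.
#' @param n_perm Number of permutations.
#' @param alpha Pruning level used in every fit.
#' @param seed Integer seed.
#' @param max_fail_frac Abort threshold on permutation fit failures.
#' @param control Fit control list.
#' @return Data frame of class `"gvar_edge_comparison"` with kind, from,
#'   to, est_A, est_B, AED, p, p_holm, stars.
#' @export
permutation_edge_test_longitudinal <- function(panelA, panelB,
                                               nodes = panelnet_nodes(),
                                               edges = NULL, n_perm = 500,
                                               alpha = 0.01, seed = 1L,
                                               max_fail_frac = 0.10,
                                               control = list()) {
  YA <- scores_to_wide(panelA, nodes, c(3, 5, 9))
  YB <- scores_to_wide(panelB, nodes, c(3, 5, 9))
  YA <- YA[stats::complete.cases(YA), , drop = FALSE]
  YB <- YB[stats::complete.cases(YB), , drop = FALSE]
  nA <- nrow(YA); nB <- nrow(YB)
  p <- length(nodes)
  fit_one <- function(Y) {
    Sn <- crossprod(scale(Y, scale = FALSE)) / nrow(Y)
    st <- gvar_moment_start(Y, p, 3)
    f <- fit_gvar_core(Sn, nrow(Y), nodes, saturated_pattern(p), st,
                       control = control)
    prune(f, alpha = alpha)
  }
  fitA <- fit_one(YA); fitB <- fit_one(YB)
  estA <- gvar_edge_estimates(fitA) * gvar_edge_indicator(fitA)
  estB <- gvar_edge_estimates(fitB) * gvar_edge_indicator(fitB)
  obs <- abs(estA - estB)
  ef <- gvar_edge_frame(nodes)
  pool <- rbind(YA, YB)
  set.seed(derive_seed(seed, "gvar_perm"))
  counts <- numeric(length(obs))
  fails <- 0L; succ <- 0L
  for (b in seq_len(n_perm)) {
    pm <- sample.int(nA + nB)
    d <- tryCatch({
      fa <- fit_one(pool[pm[seq_len(nA)], , drop = FALSE])
      fb <- fit_one(pool[pm[(nA + 1):(nA + nB)], , drop = FALSE])
      abs(gvar_edge_estimates(fa) * gvar_edge_indicator(fa) -
            gvar_edge_estimates(fb) * gvar_edge_indicator(fb))
    }, error = function(e) NULL, warning = function(w) NULL)
    if (is.null(d)) { fails <- fails + 1L; next }
    succ <- succ + 1L
    counts <- counts + (d >= obs - 1e-12)
  }
  if (fails > max_fail_frac * n_perm) {
    stop("Panel GVAR failed in ", fails, " of ", n_perm,
         " permutations; aborting.", call. = FALSE)
  }
  pv <- (1 + counts) / (1 + succ)
  out <- cbind(ef, est_A = estA, est_B = estB, AED = obs, p = pv,
               p_holm = holm_adjust(pv), stars = p_stars(pv),
               n_perm = succ, seed = seed)
  if (!is.null(edges)) {
    key <- paste(out$kind, out$from, out$to)
    out <- out[key %in% paste(edges$kind, edges$from, edges$to), ,
               drop = FALSE]
  }
  class(out) <- c("gvar_edge_comparison", "data.frame")
  out
}

#' Holm step-down adjustment of p-values
#'
#' @param pvals Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values (monotone, each `>=` its raw p, capped at 1).
#' @export
holm_adjust <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  stats::p.adjust(pvals, method = "holm")
}
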