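# Synthetic three-group, three-wave panel generator. Ground truth is a
# lag-1 graphical VAR per group with a between-person random level:
#   y_it = mu_g + b_i + w_it,  b_i ~ N(0, Sigma_b),
#   w_i,t+1 = B w_it + zeta,   zeta ~ N(0, Sigma_zeta),
# with w at the first wave drawn from the stationary distribution
# S = B S B' + Sigma_zeta, so three waves suffice without burn-in.

# Deterministic substream seeds so stages are independently reproducible.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

rmvn <- function(n, Sigma) {
  p <- ncol(Sigma)
  matrix(stats::rnorm(n * p), n, p) %*% chol(Sigma)
}

# Symmetric partial-correlation pattern -> covariance with given sds.
pcor_to_cov <- function(Omega, sds) {
  K <- -Omega
  diag(K) <- 1
  S <- solve(K)
  D <- diag(sds / sqrt(diag(S)), nrow(S))
  S <- D %*% S %*% D
  dimnames(S) <- dimnames(Omega)
  0.5 * (S + t(S))
}

# Rescale an innovation covariance so the stationary variances hit targets.
calibrate_innovations <- function(B, Sigma_zeta, target_var) {
  for (i in 1:30) {
    S <- cpp_lyap(B, Sigma_zeta)
    D <- diag(sqrt(target_var / diag(S)), nrow(B))
    Sigma_zeta <- D %*% Sigma_zeta %*% D
  }
  dimnames(Sigma_zeta) <- dimnames(B)
  Sigma_zeta
}

#' Ground truth for the synthetic panel study
#'
#' Builds the generative parameters for three groups of the study's sizes
#' (1167/614/627) under one of three scenarios: `"shared"` (identical
#' temporal and contemporaneous structure in all groups, cross-lagged
#' edges of magnitude 0.05--0.30), `"group_divergent"` (two named temporal
#' edges shifted by 0.25 in the second group), and `"null"` (no
#' cross-variable temporal, contemporaneous or between-person edges;
#' autoregressive stability retained).
#'
#' @param scenario One of `"shared"`, `"group_divergent"`, `"null"`.
#' @param n_per_group Integer vector of group sizes.
#' @return Object of class `"study_truth"`: node labels, per-group `B`,
#'   `Sigma_zeta`, `Sigma_b`, `mu`, stationary `S`, measurement config,
#'   retention probabilities and scenario metadata.
#' @export
default_truth <- function(scenario = c("shared", "group_divergent", "null"),
                          n_per_group = c(G1 = 1167, G2 = 614, G3 = 627)) {
  scenario <- match.arg(scenario)
  nodes <- panelnet_nodes()
  p <- length(nodes)

  B <- matrix(0, p, p, dimnames = list(nodes, nodes))
  diag(B) <- c(0.25, 0.25, 0.25, 0.25, 0.25, 0.10)
  if (scenario != "null") {
    B["irr", "phyAs"] <- 0.18
    B["irr", "nVio"] <- 0.07
    B["pstr", "irr"] <- 0.08
    B["psyAgg", "irr"] <- -0.25
    B["phyAs", "irr"] <- -0.20
    B["nVio", "neg"] <- 0.25
  }

  Oz <- matrix(0, p, p, dimnames = list(nodes, nodes))
  Ob <- matrix(0, p, p, dimnames = list(nodes, nodes))
  if (scenario != "null") {
    set_edge <- function(M, i, j, v) { M[i, j] <- v; M[j, i] <- v; M }
    Oz <- set_edge(Oz, "irr", "pstr", 0.20)
    Oz <- set_edge(Oz, "irr", "psyAgg", 0.15)
    Oz <- set_edge(Oz, "irr", "phyAs", 0.12)
    Oz <- set_edge(Oz, "irr", "neg", 0.12)
    Oz <- set_edge(Oz, "psyAgg", "phyAs", 0.25)
    Oz <- set_edge(Oz, "pstr", "psyAgg", 0.10)
    Oz <- set_edge(Oz, "nVio", "neg", -0.10)
    Ob <- set_edge(Ob, "irr", "pstr", 0.25)
    Ob <- set_edge(Ob, "psyAgg", "phyAs", 0.30)
    Ob <- set_edge(Ob, "irr", "psyAgg", 0.15)
    Ob <- set_edge(Ob, "nVio", "neg", -0.15)
  }

  total_sd <- c(irr = 0.45, pstr = 0.60, nVio = 1.10, psyAgg = 1.00,
                phyAs = 0.90, neg = 0.45)
  within_share <- 2 / 3
  S_target <- within_share * total_sd^2
  Sigma_zeta0 <- pcor_to_cov(Oz, rep(1, p))
  Sigma_b <- pcor_to_cov(Ob, sqrt((1 - within_share)) * total_sd)

  mu <- rbind(
    G1 = c(0.95, 2.20, 2.45, 2.35, 1.30, 0.35),
    G2 = c(0.90, 2.15, 2.30, 2.15, 1.05, 0.30),
    G3 = c(0.85, 2.10, 2.60, 1.95, 0.90, 0.30))
  colnames(mu) <- nodes

  groups <- names(n_per_group)
  if (is.null(groups)) groups <- paste0("G", seq_along(n_per_group))
  per_group <- list()
  divergent_edges <- NULL
  for (gi in seq_along(groups)) {
    Bg <- B
    if (scenario == "group_divergent" && gi == 2L) {
      Bg["irr", "pstr"] <- B["irr", "pstr"] + 0.25
      Bg["neg", "pstr"] <- B["neg", "pstr"] + 0.25
      divergent_edges <- data.frame(
        kind = "temporal", from = c("pstr", "pstr"), to = c("irr", "neg"),
        delta = 0.25)
    }
    Sz <- calibrate_innovations(Bg, Sigma_zeta0, S_target)
    Sg <- cpp_lyap(Bg, Sz)
    dimnames(Sg) <- list(nodes, nodes)
    per_group[[groups[gi]]] <- list(
      B = Bg, Sigma_zeta = Sz, Sigma_b = Sigma_b, S = Sg,
      mu = mu[min(gi, nrow(mu)), ], n = unname(n_per_group[gi]))
  }

  measurement <- list(
    irr = list(loadings = c(0.70, 0.77, 0.73),
               thresholds = c(0.25, 1.15), code0 = 0L),
    pstr = list(loadings = c(0.60, 0.65, 0.55, 0.62),
                thresholds = c(-1.2, 0, 1.2), code0 = 1L, flip = TRUE),
    nVio = list(loadings = c(0.62, 0.68, 0.58, 0.64),
                thresholds = c(-0.3, 0.5, 1.0, 1.5, 2.0, 2.5), ctspc = TRUE),
    psyAgg = list(loadings = c(0.58, 0.64, 0.56, 0.62, 0.54),
                  thresholds = c(-0.3, 0.5, 1.0, 1.5, 2.0, 2.5), ctspc = TRUE),
    phyAs = list(loadings = c(0.62, 0.66, 0.60, 0.64, 0.58),
                 thresholds = c(0.0, 0.7, 1.2, 1.7, 2.2, 2.7), ctspc = TRUE),
    neg = list(loadings = c(0.65, 0.70, 0.62, 0.67, 0.60),
               thresholds = c(0.6, 1.2, 1.7, 2.2, 2.7, 3.2), ctspc = TRUE),
    # latent correlation chosen so the discretized items correlate ~ 0.38,
    # i.e. a Spearman-Brown split-half reliability of ~ 0.55
    cult = list(r = 0.443, b_loading = 0.30,
                thresholds = c(-1.5, -0.5, 0.6)))

  structure(list(
    nodes = nodes, groups = groups, scenario = scenario,
    per_group = per_group, measurement = measurement,
    retention = c(r35 = 1 - 0.0143, r59 = 1 - 0.0984),
    total_sd = total_sd, divergent_edges = divergent_edges),
    class = "study_truth")
}

#' @export
print.study_truth <- function(x, ...) {
  cat(sprintf("Study truth ('%s'): %d nodes, groups %s (n = %s)\n",
              x$scenario, length(x$nodes), paste(x$groups, collapse = "/"),
              paste(vapply(x$per_group, `[[`, 0, "n"), collapse = "/")))
  invisible(x)
}

#' Assign a value to an ordered Likert category
#'
#' Returns the number of thresholds strictly below `x`, so categories are
#' contiguous integers starting at 0.
#'
#' @param x Numeric vector.
#' @param thresholds Strictly increasing numeric vector of cutpoints.
#' @return Integer categories in `0:length(thresholds)`.
#' @export
discretize_likert <- function(x, thresholds) {
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing.", call. = FALSE)
  }
  out <- rowSums(outer(x, thresholds, ">"))
  out[is.na(x)] <- NA_integer_
  as.integer(out)
}

#' Simulate a three-wave panel from ground truth
#'
#' Draws each person's between-person level, initializes the within-person
#' process at its stationary distribution and propagates it across waves
#' 3, 5 and 9. Optionally also generates Likert item responses (with the
#' conflict-tactics 0/7/8 zero-codes) and the two baseline cultural items.
#'
#' @param truth A [default_truth()] object.
#' @param seed Integer master seed; bit-identical output under the same
#'   seed.
#' @param items If `TRUE`, also emit a long item-response table.
#' @return Object of class `"simulated_panel"` with `scores` (long data
#'   frame), optional `items`, `truth` and per-person `latent` components.
#' @export
simulate_panel <- function(truth, seed = 1L, items = FALSE) {
  stopifnot(inherits(truth, "study_truth"))
  for (g in truth$groups) {
    rad <- max(Mod(eigen(truth$per_group[[g]]$B, only.values = TRUE)$values))
    if (rad >= 1) stop("Non-stationary temporal matrix in group ", g,
                       " (spectral radius ", round(rad, 3), ").",
                       call. = FALSE)
  }
  set.seed(derive_seed(seed, "panel"))
  nodes <- truth$nodes
  waves <- c(3L, 5L, 9L)
  scores <- list()
  latent <- list()
  for (g in truth$groups) {
    tg <- truth$per_group[[g]]
    n <- tg$n
    b <- rmvn(n, tg$Sigma_b)
    w <- array(NA_real_, c(n, length(nodes), 3))
    w[, , 1] <- rmvn(n, tg$S)
    for (t in 2:3) {
      w[, , t] <- w[, , t - 1] %*% t(tg$B) + rmvn(n, tg$Sigma_zeta)
    }
    ids <- sprintf("%s_%04d", g, seq_len(n))
    # baseline cultural belonging: shared person-level factor plus noise
    mc <- truth$measurement$cult
    zb <- b[, "psyAgg"] / sqrt(tg$Sigma_b["psyAgg", "psyAgg"])
    re <- (mc$r - mc$b_loading^2) / (1 - mc$b_loading^2)
    e <- rmvn(n, matrix(c(1, re, re, 1), 2))
    cl <- mc$b_loading * cbind(zb, zb) + sqrt(1 - mc$b_loading^2) * e
    catt_cont <- 2.5 + 0.7 * cl[, 1]
    cpra_cont <- 2.5 + 0.7 * cl[, 2]
    for (t in 1:3) {
      y <- sweep(w[, , t] + b, 2, tg$mu, "+")
      colnames(y) <- nodes
      scores[[length(scores) + 1]] <- data.frame(
        person_id = ids, group = g, wave = waves[t], y,
        cAtt = catt_cont, cPra = cpra_cont, row.names = NULL)
    }
    latent[[g]] <- list(b = b, w = w, cultural = cl, ids = ids)
  }
  scores <- do.call(rbind, scores)
  scores <- scores[order(scores$person_id, scores$wave), ]
  rownames(scores) <- NULL
  out <- structure(list(scores = scores, truth = truth, latent = latent,
                        items = NULL, seed = seed),
                   class = "simulated_panel")
  if (items) out$items <- simulate_items(out, derive_seed(seed, "items"))
  out
}

# Item responses from the continuous composites via a one-factor
# measurement model per scale and wave, discretized to Likert codes.
simulate_items <- function(panel, seed) {
  set.seed(seed)
  truth <- panel$truth
  scales <- panelnet_scales()
  rows <- list()
  sc <- panel$scores
  for (nm in panelnet_nodes()) {
    def <- scales[[nm]]
    mc <- truth$measurement[[nm]]
    lam <- mc$loadings
    for (g in truth$groups) {
      tg <- truth$per_group[[g]]
      idx <- sc$group == g
      tot_sd <- sqrt(tg$S[nm, nm] + tg$Sigma_b[nm, nm])
      eta <- (sc[[nm]][idx] - tg$mu[nm]) / tot_sd
      if (nm == "nVio") eta <- -eta  # items keyed to raw (un-reversed) frequency
      n <- length(eta)
      for (j in seq_along(lam)) {
        x <- lam[j] * eta + sqrt(1 - lam[j]^2) * stats::rnorm(n)
        cat_ <- discretize_likert(x, mc$thresholds)
        raw <- cat_
        if (isTRUE(mc$ctspc)) {
          z <- which(!is.na(cat_) & cat_ == 0L)
          raw[z] <- sample(c(0L, 7L, 8L), length(z), replace = TRUE,
                           prob = c(0.5, 0.15, 0.35))
        }
        if (isTRUE(mc$flip)) raw <- 4L - cat_  # agreement scale, 1..4 raw
        if (!is.null(mc$code0) && mc$code0 == 1L && !isTRUE(mc$flip)) {
          raw <- cat_ + 1L
        }
        rows[[length(rows) + 1]] <- data.frame(
          person_id = sc$person_id[idx], group = g, wave = sc$wave[idx],
          instrument = def$instrument, item_id = def$items[j],
          raw_code = raw, row.names = NULL)
      }
    }
  }
  # cultural items at wave 0, one record per person
  mc <- truth$measurement$cult
  for (g in truth$groups) {
    lat <- panel$latent[[g]]
    for (j in 1:2) {
      cat_ <- discretize_likert(lat$cultural[, j], mc$thresholds)
      rows[[length(rows) + 1]] <- data.frame(
        person_id = lat$ids, group = g, wave = 0L,
        instrument = "CULT", item_id = paste0("cult", j),
        raw_code = 4L - cat_, row.names = NULL)
    }
  }
  items <- do.call(rbind, rows)
  rownames(items) <- NULL
  items
}

#' Apply monotone wave dropout and the inclusion filter
#'
#' Persons drop out between waves with the configured retention
#' probabilities and stay missing at all later waves. The inclusion flag
#' marks persons with irritability observed at two or more waves; flagged
#' persons are retained, not dropped.
#'
#' @param panel A [simulate_panel()] object.
#' @param truth Truth object carrying `retention`; defaults to the panel's.
#' @param seed Integer seed.
#' @return The panel with missingness applied to `scores` (and `items` if
#'   present), a logical `included` column, and an `inclusion` data frame.
#' @export
apply_missingness <- function(panel, truth = panel$truth, seed = 1L) {
  ret <- truth$retention
  stopifnot(all(ret > 0 | ret == 0), all(ret <= 1))
  set.seed(derive_seed(seed, "missingness"))
  sc <- panel$scores
  ids <- unique(sc$person_id)
  keep5 <- stats::runif(length(ids)) < ret[["r35"]]
  keep9 <- keep5 & (stats::runif(length(ids)) < ret[["r59"]])
  miss5 <- ids[!keep5]
  miss9 <- ids[!keep9]
  node_cols <- intersect(c(panelnet_nodes(TRUE)), names(sc))
  sc[sc$wave == 5 & sc$person_id %in% miss5, node_cols] <- NA
  sc[sc$wave == 9 & sc$person_id %in% miss9, node_cols] <- NA
  if (!is.null(panel$items)) {
    it <- panel$items
    drop <- (it$wave == 5 & it$person_id %in% miss5) |
      (it$wave == 9 & it$person_id %in% miss9)
    panel$items <- it[!drop, , drop = FALSE]
  }
  irr_waves <- tapply(!is.na(sc$irr), sc$person_id, sum)
  inclusion <- data.frame(person_id = names(irr_waves),
                          n_irr_waves = as.integer(irr_waves),
                          included = as.integer(irr_waves) >= 2L)
  sc$included <- inclusion$included[match(sc$person_id, inclusion$person_id)]
  panel$scores <- sc
  panel$inclusion <- inclusion
  panel
}

#' @export
print.simulated_panel <- function(x, ...) {
  cat(sprintf("Simulated panel ('%s'): %d persons x %d waves%s\n",
              x$truth$scenario, length(unique(x$scores$person_id)),
              length(unique(x$scores$wave)),
              if (!is.null(x$items)) " (with items)" else ""))
  invisible(x)
}
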