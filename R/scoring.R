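#' Scale definitions for the parenting/irritability battery
#'
#' Returns the registry of composite scales: the child-irritability items
#' (3-point, 0--2), the four parent-child conflict-tactics subscales
#' (frequency codes recoded to 0--6, non-violent discipline reverse-coded so
#' that higher means fewer non-violent discipline occurrences), the
#' aggravation-in-parenting stress items (4-point, reverse-coded so that
#' higher means more stress), and the two single-item cultural-belonging
#' variables measured once at baseline (wave 0).
#'
#' @return A named list; each element describes one scale: `instrument`,
#'   `items`, `range` (per-item legal range after recoding), `recode`
#'   (`"ctspc"` or `"none"`), `reverse` (`"composite"`, `"item"` or
#'   `"none"`), and `waves`.
#' @export
panelnet_scales <- function() {
  list(
    irr = list(instrument = "CBCL_IRR", items = c("cbcl1", "cbcl2", "cbcl3"),
               range = c(0, 2), recode = "none", reverse = "none",
               waves = c(3, 5, 9)),
    pstr = list(instrument = "APS", items = paste0("aps", 1:4),
                range = c(1, 4), recode = "none", reverse = "item",
                waves = c(3, 5, 9)),
    nVio = list(instrument = "CTSPC", items = paste0("nv", 1:4),
                range = c(0, 6), recode = "ctspc", reverse = "composite",
                waves = c(3, 5, 9)),
    psyAgg = list(instrument = "CTSPC", items = paste0("pa", 1:5),
                  range = c(0, 6), recode = "ctspc", reverse = "none",
                  waves = c(3, 5, 9)),
    phyAs = list(instrument = "CTSPC", items = paste0("ph", 1:5),
                 range = c(0, 6), recode = "ctspc", reverse = "none",
                 waves = c(3, 5, 9)),
    neg = list(instrument = "CTSPC", items = paste0("ng", 1:5),
               range = c(0, 6), recode = "ctspc", reverse = "none",
               waves = c(3, 5, 9)),
    cAtt = list(instrument = "CULT", items = "cult1",
                range = c(1, 4), recode = "none", reverse = "item",
                waves = 0),
    cPra = list(instrument = "CULT", items = "cult2",
                range = c(1, 4), recode = "none", reverse = "item",
                waves = 0)
  )
}

#' Node labels of the six-variable panel network
#' @param cultural If `TRUE`, append the two baseline cultural-belonging
#'   nodes used in the cross-sectional networks.
#' @return Character vector of node labels.
#' @export
panelnet_nodes <- function(cultural = FALSE) {
  nodes <- c("irr", "pstr", "nVio", "psyAgg", "phyAs", "neg")
  if (cultural) nodes <- c(nodes, "cAtt", "cPra")
  nodes
}

#' Recode conflict-tactics frequency responses
#'
#' Raw responses use codes 0--8 where 1--6 are ascending frequency bins,
#' 7 means "not in the past year, but it happened before" and 8 means "this
#' has never happened". Codes 0, 7 and 8 all map to frequency 0; codes
#' 1--6 are kept as-is.
#'
#' @param raw_code Integer vector of raw codes in 0--8 (`NA` allowed).
#' @param item Optional item label used in error messages.
#' @return Integer vector of frequency scores in 0--6.
#' @export
recode_ctspc <- function(raw_code, item = NULL) {
  bad <- !is.na(raw_code) & (raw_code < 0 | raw_code > 8 |
                               raw_code != round(raw_code))
  if (any(bad)) {
    stop("Illegal conflict-tactics code(s) ",
         paste(unique(raw_code[bad]), collapse = ", "),
         if (!is.null(item)) paste0(" for item '", item, "'"),
         "; legal codes are 0-8.", call. = FALSE)
  }
  out <- raw_code
  out[!is.na(out) & out %in% c(0, 7, 8)] <- 0L
  out
}

#' Reverse-code a score on a bounded scale
#'
#' Maps `score` to `lo + hi - score`, so applying the function twice is the
#' identity.
#'
#' @param score Numeric vector within `[lo, hi]` (`NA` allowed).
#' @param lo,hi Scale endpoints.
#' @return Reversed scores.
#' @export
reverse_code <- function(score, lo, hi) {
  stopifnot(is.numeric(lo), is.numeric(hi), lo < hi)
  bad <- !is.na(score) & (score < lo | score > hi)
  if (any(bad)) {
    stop("Score(s) outside [", lo, ", ", hi, "]: ",
         paste(utils::head(unique(score[bad]), 5), collapse = ", "),
         call. = FALSE)
  }
  lo + hi - score
}

#' Composite score as the mean of item scores
#'
#' Averages the non-missing items when at least `min_items` of them are
#' present; otherwise returns `NA`. The result is bounded by the minimum
#' and maximum of its inputs and is invariant to item order.
#'
#' @param items Numeric vector of item scores on a common scale.
#' @param min_items Minimum number of non-missing items required
#'   (default: all items).
#' @return Scalar composite or `NA`.
#' @export
score_composite <- function(items, min_items = length(items)) {
  if (length(items) == 0L) {
    warning("Empty item vector; composite is missing.", call. = FALSE)
    return(NA_real_)
  }
  k <- sum(!is.na(items))
  if (k < min_items) return(NA_real_)
  mean(items, na.rm = TRUE)
}

#' McDonald's omega from a one-factor model
#'
#' Fits a single-factor model by maximum likelihood (via [stats::factanal],
#' i.e. in the correlation metric of the standardized items) and returns
#' omega = (sum of loadings)^2 / ((sum of loadings)^2 + sum of uniquenesses).
#' Unlike Cronbach's alpha, omega does not assume tau-equivalent (equal)
#' loadings.
#'
#' @param item_matrix Numeric matrix, persons in rows, items (>= 3) in
#'   columns; rows with missing values are dropped. Alternatively `NULL`
#'   when `covmat` is given.
#' @param n_min Minimum number of complete rows required.
#' @param covmat Optional item covariance/correlation matrix fitted
#'   directly (with `n_obs`), e.g. a population matrix.
#' @param n_obs Nominal sample size accompanying `covmat`.
#' @return List of class `"reliability"` with `omega`, `n_used`,
#'   `loadings`, `uniquenesses` and a `flag` (`"ok"`, `"heywood"` or
#'   `"near_singular"`). Heywood cases (uniqueness at the boundary) are
#'   flagged, not silently clamped.
#' @export
mcdonalds_omega <- function(item_matrix, n_min = 50, covmat = NULL,
                            n_obs = NULL) {
  if (!is.null(covmat)) {
    R <- stats::cov2cor(as.matrix(covmat))
    n <- n_obs %||% 1000L
  } else {
    X <- as.matrix(item_matrix)
    if (ncol(X) < 3) stop("omega needs at least 3 items.", call. = FALSE)
    X <- X[stats::complete.cases(X), , drop = FALSE]
    n <- nrow(X)
    if (n < n_min) stop("omega needs >= ", n_min, " complete rows.",
                        call. = FALSE)
    R <- stats::cor(X)
  }
  # Degenerate limit: (numerically) perfectly correlated items.
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < 1e-8) {
    return(structure(list(omega = 1, n_used = n, loadings = NULL,
                          uniquenesses = NULL, flag = "near_singular"),
                     class = "reliability"))
  }
  fit <- tryCatch(
    stats::factanal(covmat = R, factors = 1, n.obs = n),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(omega = NA_real_, n_used = n, loadings = NULL,
                          uniquenesses = NULL, flag = "nonconvergence"),
                     class = "reliability"))
  }
  lam <- as.numeric(fit$loadings)
  if (sum(lam) < 0) lam <- -lam  # sign convention
  th <- fit$uniquenesses
  omega <- sum(lam)^2 / (sum(lam)^2 + sum(th))
  flag <- if (any(th <= 0.005 + 1e-8)) "heywood" else "ok"
  structure(list(omega = omega, n_used = n, loadings = lam,
                 uniquenesses = th, flag = flag),
            class = "reliability")
}

#' @export
print.reliability <- function(x, ...) {
  cat(sprintf("McDonald's omega = %.3f (n = %d, %s)\n",
              x$omega, x$n_used, x$flag))
  invisible(x)
}

#' Spearman-Brown corrected split-half reliability
#'
#' Correlates the two halves and applies the Spearman-Brown step-up
#' 2r / (1 + r) for the full-length test.
#'
#' @param x1,x2 Numeric vectors, the two half-test scores.
#' @return List with `reliability`, `r`, `n_used`, `flag`
#'   (`"ok"`, `"negative_r"` or `"zero_variance"`).
#' @export
split_half_spearman_brown <- function(x1, x2) {
  ok <- !is.na(x1) & !is.na(x2)
  x1 <- x1[ok]; x2 <- x2[ok]
  n <- length(x1)
  if (n < 10) stop("Need >= 10 paired observations.", call. = FALSE)
  if (stats::sd(x1) == 0 || stats::sd(x2) == 0) {
    return(list(reliability = NA_real_, r = NA_real_, n_used = n,
                flag = "zero_variance"))
  }
  r <- stats::cor(x1, x2)
  rel <- 2 * r / (1 + r)
  flag <- "ok"
  if (r < 0) { rel <- 0; flag <- "negative_r" }
  list(reliability = rel, r = r, n_used = n, flag = flag)
}

# Recode/reverse one scale's item matrix (persons x items) to scoring scale.
prepare_items <- function(X, def) {
  X <- as.matrix(X)
  if (def$recode == "ctspc") {
    for (j in seq_len(ncol(X))) X[, j] <- recode_ctspc(X[, j],
                                                       colnames(X)[j])
  } else {
    rng <- def$range
    bad <- !is.na(X) & (X < rng[1] | X > rng[2])
    if (any(bad)) stop("Item value(s) outside [", rng[1], ", ", rng[2],
                       "] for instrument ", def$instrument, call. = FALSE)
  }
  if (def$reverse == "item") {
    rng <- def$range
    X[] <- reverse_code(as.numeric(X), rng[1], rng[2])
  }
  X
}

#' Score an item-response table into composites
#'
#' Turns a long item-response table into one row per person and wave with
#' the six network composites plus the baseline cultural-belonging
#' variables (carried to every wave as time-invariant scores).
#'
#' @param items Data frame with columns `person_id`, `group`, `wave`,
#'   `instrument`, `item_id`, `raw_code` (empty/`NA` = missing).
#' @param min_items Named list or single integer: minimum non-missing items
#'   per composite (default: all items of the scale, since prorating
#'   changes composite variance).
#' @return Data frame (one row per person x wave in waves 3/5/9) with
#'   columns `person_id`, `group`, `wave` and the scale scores.
#' @export
score_items <- function(items, min_items = NULL) {
  req <- c("person_id", "group", "wave", "instrument", "item_id", "raw_code")
  if (!all(req %in% names(items))) {
    stop("items table must have columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  dup <- duplicated(items[, c("person_id", "wave", "item_id")])
  if (any(dup)) stop("Duplicate (person, wave, item) records.", call. = FALSE)
  scales <- panelnet_scales()
  persons <- unique(items[, c("person_id", "group")])
  waves <- c(3L, 5L, 9L)
  out <- expand.grid(person_id = persons$person_id, wave = waves,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$group <- persons$group[match(out$person_id, persons$person_id)]
  out <- out[, c("person_id", "group", "wave")]

  get_min <- function(nm, k) {
    if (is.null(min_items)) return(k)
    if (is.list(min_items)) return(min_items[[nm]] %||% k)
    min(min_items, k)
  }

  for (nm in names(scales)) {
    def <- scales[[nm]]
    sub <- items[items$instrument == def$instrument &
                   items$item_id %in% def$items, , drop = FALSE]
    scores <- rep(NA_real_, nrow(out))
    target_waves <- if (identical(def$waves, 0)) 0 else waves
    for (w in target_waves) {
      sw <- sub[sub$wave == w, , drop = FALSE]
      if (nrow(sw) == 0) next
      wide <- matrix(NA_real_, nrow(persons), length(def$items),
                     dimnames = list(persons$person_id, def$items))
      ij <- cbind(match(sw$person_id, persons$person_id),
                  match(sw$item_id, def$items))
      wide[ij] <- sw$raw_code
      wide <- prepare_items(wide, def)
      k <- get_min(nm, length(def$items))
      comp <- apply(wide, 1, score_composite, min_items = k)
      if (def$reverse == "composite") {
        comp <- reverse_code(comp, def$range[1], def$range[2])
      }
      rows <- if (w == 0) rep(TRUE, nrow(out)) else out$wave == w
      scores[rows] <- comp[match(out$person_id[rows], persons$person_id)]
    }
    out[[nm]] <- scores
  }
  out
}

#' Reliability report for scored scales
#'
#' McDonald's omega per multi-item scale and wave, and the Spearman-Brown
#' split-half reliability for the two-item cultural-belonging pair.
#'
#' @param items Long item-response table (see [score_items()]).
#' @return Data frame with `scale`, `wave`, `omega`, `split_half`,
#'   `n_used`, `flag`.
#' @export
reliability_table <- function(items) {
  scales <- panelnet_scales()
  rows <- list()
  persons <- unique(items$person_id)
  for (nm in setdiff(names(scales), c("cAtt", "cPra"))) {
    def <- scales[[nm]]
    for (w in def$waves) {
      sw <- items[items$instrument == def$instrument &
                    items$item_id %in% def$items & items$wave == w, ,
                  drop = FALSE]
      if (nrow(sw) == 0) next
      wide <- matrix(NA_real_, length(persons), length(def$items),
                     dimnames = list(persons, def$items))
      wide[cbind(match(sw$person_id, persons),
                 match(sw$item_id, def$items))] <- sw$raw_code
      wide <- prepare_items(wide, def)
      om <- tryCatch(mcdonalds_omega(wide), error = function(e) NULL)
      if (is.null(om)) next
      rows[[length(rows) + 1]] <- data.frame(
        scale = nm, wave = w, omega = om$omega, split_half = NA_real_,
        n_used = om$n_used, flag = om$flag)
    }
  }
  cult <- items[items$instrument == "CULT" & items$wave == 0, , drop = FALSE]
  if (nrow(cult) > 0) {
    x1 <- cult$raw_code[cult$item_id == "cult1"][
      match(persons, cult$person_id[cult$item_id == "cult1"])]
    x2 <- cult$raw_code[cult$item_id == "cult2"][
      match(persons, cult$person_id[cult$item_id == "cult2"])]
    sb <- tryCatch(split_half_spearman_brown(x1, x2), error = function(e) NULL)
    if (!is.null(sb)) {
      rows[[length(rows) + 1]] <- data.frame(
        scale = "cultural", wave = 0, omega = NA_real_,
        split_half = sb$reliability, n_used = sb$n_used, flag = sb$flag)
    }
  }
  do.call(rbind, rows)
}

#' Group descriptives with a one-way ANOVA
#'
#' Per-group n, mean and SD of one composite at one wave, with the classic
#' one-way analysis-of-variance F test of group differences (listwise
#' deletion on the variable).
#'
#' @param scores Scored table (see [score_items()] or [simulate_panel()]).
#' @param variable Column name of the composite.
#' @param wave Wave to describe.
#' @return List of class `"group_descriptives"`: `table` (group, n, mean,
#'   sd), `F`, `df`, `p`, `flag`.
#' @export
describe_by_group <- function(scores, variable, wave) {
  d <- scores[scores$wave == wave & !is.na(scores[[variable]]), ,
              drop = FALSE]
  d$group <- factor(as.character(d$group))
  counts <- table(d$group)
  drop <- names(counts)[counts < 2]
  if (length(drop) > 0) {
    warning("Dropping group(s) with < 2 observations: ",
            paste(drop, collapse = ", "), call. = FALSE)
    d <- d[!(as.character(d$group) %in% drop), , drop = FALSE]
    d$group <- droplevels(d$group)
  }
  if (nlevels(d$group) < 2) stop("Need >= 2 groups with >= 2 observations.",
                                 call. = FALSE)
  x <- d[[variable]]
  tab <- do.call(rbind, lapply(levels(d$group), function(g) {
    xs <- x[d$group == g]
    data.frame(group = g, n = length(xs), mean = mean(xs), sd = stats::sd(xs))
  }))
  within_var <- sum((tab$n - 1) * tab$sd^2)
  flag <- if (within_var == 0) "zero_within_variance" else "ok"
  if (flag == "ok") {
    av <- stats::anova(stats::lm(x ~ group, data = d))
    Fv <- av$`F value`[1]; p <- av$`Pr(>F)`[1]; dfv <- av$Df
  } else {
    Fv <- Inf; p <- 0; dfv <- c(nlevels(d$group) - 1,
                                nrow(d) - nlevels(d$group))
  }
  structure(list(table = tab, F = Fv, df = dfv, p = p, flag = flag,
                 variable = variable, wave = wave),
            class = "group_descriptives")
}

#' @export
print.group_descriptives <- function(x, ...) {
  cat(sprintf("%s at wave %s: F(%d, %d) = %.3f, p = %.4g%s\n", x$variable,
              x$wave, x$df[1], x$df[2], x$F, x$p,
              if (x$flag != "ok") paste0(" [", x$flag, "]") else ""))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Bivariate Pearson correlations of the composites at one wave
#'
#' Pairwise-complete by default; entries undefined because of a constant
#' variable are flagged via the `"constant"` attribute.
#'
#' @param scores Scored table.
#' @param wave Wave to use.
#' @param vars Variables (default: the six network nodes present).
#' @param use Missing-data policy passed to [stats::cor].
#' @return Correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(scores, wave,
                           vars = intersect(panelnet_nodes(TRUE),
                                            names(scores)),
                           use = "pairwise.complete.obs") {
  d <- scores[scores$wave == wave, vars, drop = FALSE]
  const <- vapply(d, function(v) stats::sd(v, na.rm = TRUE) == 0 ||
                    all(is.na(v)), logical(1))
  R <- suppressWarnings(stats::cor(as.matrix(d), use = use))
  diag(R) <- 1
  attr(R, "constant") <- names(const)[const]
  attr(R, "n") <- colSums(!is.na(d))
  R
}

`%||%` <- function(a, b) if (is.null(a)) b else a
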