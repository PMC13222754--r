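# CSV interfaces. Scores: one row per person x wave, empty field = missing.
# Items: long format person_id,group,wave,instrument,item_id,raw_code, or a
# wide format with column names INSTRUMENT.item.wave.

#' Read a long item-response CSV
#'
#' @param path CSV with header
#'   `person_id,group,wave,instrument,item_id,raw_code`; empty = missing.
#' @return Item-response data frame.
#' @export
read_items_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("", "NA"))
  req <- c("person_id", "group", "wave", "instrument", "item_id", "raw_code")
  if (!all(req %in% names(d))) {
    stop("Malformed items file; expected header ",
         paste(req, collapse = ","), call. = FALSE)
  }
  d
}

#' Read wide-format items
#'
#' Wide columns follow the convention `INSTRUMENT.item.wave`, e.g.
#' `CTSPC.nv1.3`; remaining columns must include `person_id` and `group`.
#'
#' @param path CSV path.
#' @return Long item-response data frame.
#' @export
read_items_wide_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("", "NA"))
  stopifnot(all(c("person_id", "group") %in% names(d)))
  cols <- setdiff(names(d), c("person_id", "group"))
  parts <- strsplit(cols, ".", fixed = TRUE)
  ok <- lengths(parts) == 3
  if (!all(ok)) stop("Wide item columns must be INSTRUMENT.item.wave; bad: ",
                     paste(cols[!ok], collapse = ", "), call. = FALSE)
  out <- lapply(seq_along(cols), function(i) {
    data.frame(person_id = d$person_id, group = d$group,
               wave = as.integer(parts[[i]][3]),
               instrument = parts[[i]][1], item_id = parts[[i]][2],
               raw_code = d[[cols[i]]], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Read a scored panel CSV
#'
#' @param path CSV with header `person_id,group,wave,<score columns>`;
#'   empty fields are missing.
#' @param groups Optional allowed group labels; others are rejected.
#' @param waves Allowed wave codes.
#' @return Scored data frame.
#' @export
read_scores_csv <- function(path, groups = NULL, waves = c(0, 3, 5, 9)) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("", "NA"))
  req <- c("person_id", "group", "wave")
  if (!all(req %in% names(d))) {
    stop("Malformed scores file; need columns ", paste(req, collapse = ","),
         call. = FALSE)
  }
  bad_wave <- which(!(d$wave %in% waves))
  if (length(bad_wave)) {
    stop("Bad wave code at data line(s) ",
         paste(utils::head(bad_wave, 5), collapse = ", "),
         " (allowed: ", paste(waves, collapse = "/"), ").", call. = FALSE)
  }
  if (!is.null(groups)) {
    bad <- which(!(d$group %in% groups))
    if (length(bad)) {
      stop("Unknown group label(s) ",
           paste(unique(d$group[bad]), collapse = ", "),
           " at data line(s) ", paste(utils::head(bad, 5), collapse = ", "),
           call. = FALSE)
    }
  }
  num_cols <- setdiff(names(d), req)
  for (cl in num_cols) d[[cl]] <- as.numeric(d[[cl]])
  d
}

#' Write a scored panel CSV (lossless round trip with [read_scores_csv()])
#'
#' @param scores Scored data frame.
#' @param path Output path.
#' @export
write_scores_csv <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE, na = "")
  invisible(path)
}

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

ggm_to_list <- function(net) {
  list(nodes = net$nodes, group = net$group, wave = net$wave,
       lambda = net$lambda, gamma = net$gamma, n = net$n, E = net$E,
       pcor = unname(apply(net$pcor, 1, as.numeric, simplify = FALSE)))
}

gvar_to_list <- function(fit, fi = NULL, boots = NULL, stable = NULL) {
  out <- list(
    nodes = fit$nodes, n = fit$n, df = fit$df, nfree = fit$nfree,
    converged = fit$converged, loglik = fit$loglik,
    mu = as.list(fit$mu),
    temporal = unname(apply(fit$B, 1, as.numeric, simplify = FALSE)),
    temporal_std = unname(apply(temporal_std(fit), 1, as.numeric,
                                simplify = FALSE)),
    contemporaneous = unname(apply(fit$Omega_zeta, 1, as.numeric,
                                   simplify = FALSE)),
    between = unname(apply(fit$Omega_b, 1, as.numeric, simplify = FALSE)),
    pattern_temporal = unname(apply(fit$pattern$B, 1, as.logical,
                                    simplify = FALSE)))
  if (!is.null(fi)) out$fit_indices <- fi[c("chisq", "df", "cfi", "tli",
                                            "rmsea")]
  if (!is.null(boots)) {
    out$bootstrap <- list(R = boots$R, n_success = boots$n_success,
                          threshold = boots$threshold,
                          inclusion = boots$edges$inclusion)
  }
  if (!is.null(stable)) {
    out$stable_temporal <- unname(apply(stable$B, 1, as.numeric,
                                        simplify = FALSE))
  }
  out
}
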