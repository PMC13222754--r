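# Study orchestration: simulate or ingest -> inclusion filter -> score ->
# descriptives -> 9 cross-sectional networks + comparisons -> 3 panel GVAR
# models with bootstrap stability -> longitudinal edge comparisons ->
# structured report. Stages cache their outputs so a run is resumable and
# each stage is independently reproducible from the master seed.

#' Build a study configuration
#'
#' @param input `"simulate"` or `"csv"`.
#' @param scenario Generator scenario for simulate mode.
#' @param n_per_group Group sizes for simulate mode.
#' @param scores_file,items_file Input paths for csv mode.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param out_dir Output directory.
#' @param gamma,nlambda,lambda_min_ratio Cross-sectional estimator
#'   settings.
#' @param prune_alpha Pruning level for the panel GVAR.
#' @param R_boot Bootstrap resamples per group.
#' @param n_perm Permutations per comparison.
#' @param paper_scale If `TRUE`, raise `R_boot` and `n_perm` to 1000
#'   (the study-scale values); desk defaults are reduced.
#' @param with_items Simulate item-level responses too (enables the
#'   reliability stage).
#' @param resume Reuse cached stage outputs when the configuration
#'   matches.
#' @param verbose Print stage progress.
#' @return A `study_config` list.
#' @export
study_config <- function(input = c("simulate", "csv"), scenario = "shared",
                         n_per_group = c(G1 = 1167, G2 = 614, G3 = 627),
                         scores_file = NULL, items_file = NULL, seed = 1L,
                         out_dir = file.path(tempdir(), "panelnet_out"),
                         gamma = 0.5, nlambda = 100,
                         lambda_min_ratio = 0.01, prune_alpha = 0.01,
                         R_boot = 200, n_perm = 200, paper_scale = FALSE,
                         with_items = FALSE, resume = TRUE,
                         verbose = FALSE) {
  input <- match.arg(input)
  if (paper_scale) { R_boot <- 1000; n_perm <- 1000 }
  if (input == "csv" && is.null(scores_file) && is.null(items_file)) {
    stop("csv input needs scores_file or items_file.", call. = FALSE)
  }
  if (input == "csv") {
    for (f in c(scores_file, items_file)) {
      if (!is.null(f) && !file.exists(f)) stop("File not found: ", f,
                                               call. = FALSE)
    }
  }
  structure(list(
    input = input, scenario = scenario, n_per_group = n_per_group,
    scores_file = scores_file, items_file = items_file, seed = seed,
    out_dir = out_dir, gamma = gamma, nlambda = nlambda,
    lambda_min_ratio = lambda_min_ratio, prune_alpha = prune_alpha,
    R_boot = R_boot, n_perm = n_perm, with_items = with_items,
    resume = resume, verbose = verbose), class = "study_config")
}

# Small deterministic hash of the configuration (provenance + cache key).
config_hash <- function(config) {
  s <- jsonlite::toJSON(config[setdiff(names(config),
                                       c("out_dir", "verbose", "resume"))],
                        auto_unbox = TRUE, digits = 12)
  v <- utf8ToInt(s)
  h <- 0
  for (x in v) h <- (h * 131 + x) %% 2147483647
  sprintf("%08x", as.integer(h))
}

run_stage <- function(name, config, fun) {
  cache <- file.path(config$out_dir, "cache", paste0(name, ".rds"))
  hash <- config_hash(config)
  if (config$resume && file.exists(cache)) {
    obj <- readRDS(cache)
    if (identical(obj$hash, hash)) {
      if (config$verbose) message("stage ", name, ": cached")
      return(obj$value)
    }
  }
  if (config$verbose) message("stage ", name, ": running")
  t0 <- proc.time()[3]
  value <- fun()
  dir.create(dirname(cache), recursive = TRUE, showWarnings = FALSE)
  saveRDS(list(hash = hash, value = value), cache)
  manifest <- file.path(config$out_dir, "manifest.json")
  done <- if (file.exists(manifest)) {
    jsonlite::read_json(manifest, simplifyVector = TRUE)$stages
  } else character()
  write_json(list(config_hash = hash,
                  stages = union(done, name),
                  seconds = round(proc.time()[3] - t0, 2)), manifest)
  value
}

#' Run the full study pipeline
#'
#' Executes, in order: data ingest or simulation, the inclusion filter
#' (irritability observed at two or more waves), scoring (csv items mode),
#' descriptives and reliabilities, nine cross-sectional networks (three
#' groups by three waves, eight nodes), pairwise group and wave network
#' comparison tests, three panel GVAR models with pruning, fit indices,
#' bootstrap stability and stability-masked networks, and the longitudinal
#' permutation edge comparisons. Outputs are written under
#' `config$out_dir` and returned as a structured report.
#'
#' @param config A [study_config()].
#' @return List of class `"study_report"`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  data_stage <- run_stage("data", config, function() {
    if (config$input == "simulate") {
      truth <- default_truth(config$scenario,
                             n_per_group = config$n_per_group)
      panel <- simulate_panel(truth, seed = seed,
                              items = config$with_items)
      panel <- apply_missingness(panel, seed = seed)
      list(scores = panel$scores, items = panel$items,
           inclusion = panel$inclusion, truth = truth)
    } else {
      items <- if (!is.null(config$items_file)) {
        read_items_csv(config$items_file)
      }
      scores <- if (!is.null(config$scores_file)) {
        read_scores_csv(config$scores_file)
      } else {
        score_items(items)
      }
      irr_waves <- tapply(!is.na(scores$irr), scores$person_id, sum)
      inclusion <- data.frame(person_id = names(irr_waves),
                              n_irr_waves = as.integer(irr_waves),
                              included = as.integer(irr_waves) >= 2L)
      list(scores = scores, items = items, inclusion = inclusion,
           truth = NULL)
    }
  })

  inc <- data_stage$inclusion
  keep <- inc$person_id[inc$included]
  scores <- data_stage$scores[data_stage$scores$person_id %in% keep, ,
                              drop = FALSE]
  groups <- sort(unique(as.character(scores$group)))
  waves <- c(3, 5, 9)
  nodes6 <- panelnet_nodes()
  nodes8 <- intersect(panelnet_nodes(TRUE), names(scores))

  descriptives <- run_stage("descriptives", config, function() {
    desc <- list()
    for (v in nodes6) {
      for (w in waves) {
        d <- describe_by_group(scores, v, w)
        desc[[paste0(v, "_w", w)]] <- list(
          variable = v, wave = w, F = d$F, p = d$p,
          groups = d$table)
      }
    }
    cors <- lapply(waves, function(w) pearson_matrix(scores, w,
                                                     vars = nodes8))
    names(cors) <- paste0("wave", waves)
    rel <- if (!is.null(data_stage$items)) {
      reliability_table(data_stage$items[
        data_stage$items$person_id %in% keep, , drop = FALSE])
    }
    list(anova = desc, correlations = cors, reliability = rel,
         n_included = length(keep), n_total = nrow(inc))
  })

  ggms <- run_stage("ggm", config, function() {
    out <- list()
    for (g in groups) {
      for (w in waves) {
        out[[paste(g, w, sep = "_")]] <- estimate_ggm(
          scores, g, w, nodes = nodes8, gamma = config$gamma,
          nlambda = config$nlambda,
          lambda_min_ratio = config$lambda_min_ratio)
      }
    }
    out
  })

  est <- ggm_estimator(gamma = config$gamma, nlambda = config$nlambda,
                       lambda_min_ratio = config$lambda_min_ratio)

  nct_groups <- run_stage("nct_groups", config, function() {
    out <- list()
    pairs <- utils::combn(groups, 2, simplify = FALSE)
    for (pr in pairs) {
      for (w in waves) {
        dA <- scores[scores$group == pr[1] & scores$wave == w, nodes8]
        dB <- scores[scores$group == pr[2] & scores$wave == w, nodes8]
        key <- paste(pr[1], pr[2], "w", w, sep = "_")
        out[[key]] <- nct_edges(dA, dB, estimator = est,
                                n_perm = config$n_perm,
                                seed = derive_seed(seed, key))
      }
    }
    out
  })

  nct_wave_pairs <- run_stage("nct_waves", config, function() {
    out <- list()
    wp <- list(c(3, 5), c(5, 9), c(3, 9))
    for (g in groups) {
      for (pr in wp) {
        key <- paste(g, "w", pr[1], pr[2], sep = "_")
        out[[key]] <- nct_waves(
          scores[scores$group == g, , drop = FALSE], pr[1], pr[2],
          nodes = nodes8, estimator = est, n_perm = config$n_perm,
          seed = derive_seed(seed, key))
      }
    }
    out
  })

  gvars <- run_stage("gvar", config, function() {
    out <- list()
    for (g in groups) {
      sg <- scores[scores$group == g, , drop = FALSE]
      fit <- fit_panel_gvar(sg, nodes = nodes6)
      pruned <- prune(fit, alpha = config$prune_alpha)
      fi <- fit_indices(pruned)
      boots <- bootstrap_edges(sg, nodes = nodes6, R = config$R_boot,
                               alpha = config$prune_alpha,
                               seed = derive_seed(seed, paste0("boot_", g)))
      out[[g]] <- list(fit = fit, pruned = pruned, fit_indices = fi,
                       boots = boots,
                       stable = stable_network(pruned, boots))
    }
    out
  })

  gvar_comparisons <- run_stage("gvar_compare", config, function() {
    out <- list()
    pairs <- utils::combn(groups, 2, simplify = FALSE)
    for (pr in pairs) {
      key <- paste("gvar", pr[1], pr[2], sep = "_")
      out[[paste(pr, collapse = "_")]] <- permutation_edge_test_longitudinal(
        scores[scores$group == pr[1], , drop = FALSE],
        scores[scores$group == pr[2], , drop = FALSE],
        nodes = nodes6, n_perm = config$n_perm,
        alpha = config$prune_alpha, seed = derive_seed(seed, key))
    }
    out
  })

  report <- structure(list(
    provenance = list(config_hash = config_hash(config), seed = seed,
                      version = as.character(utils::packageVersion("panelnet")),
                      scenario = if (config$input == "simulate")
                        config$scenario else "csv"),
    inclusion = list(n_total = nrow(inc), n_included = length(keep)),
    descriptives = descriptives,
    ggm = ggms, nct_groups = nct_groups, nct_waves = nct_wave_pairs,
    gvar = gvars, gvar_comparisons = gvar_comparisons,
    config = config), class = "study_report")
  write_report(report, config$out_dir)
  report
}

#' Write a study report to disk
#'
#' Emits `report.json`, `scores.csv`-style stage outputs, per-network JSON
#' and edge CSVs, and per-comparison CSVs under `dir`.
#'
#' @param report A `"study_report"`.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_json(list(
    n_included = report$descriptives$n_included,
    anova = lapply(report$descriptives$anova, function(a) {
      list(variable = a$variable, wave = a$wave, F = a$F, p = a$p,
           groups = a$groups)
    })), file.path(dir, "descriptives.json"))
  if (!is.null(report$descriptives$reliability)) {
    write_json(report$descriptives$reliability,
               file.path(dir, "reliability.json"))
  }
  for (key in names(report$ggm)) {
    net <- report$ggm[[key]]
    write_json(ggm_to_list(net), file.path(dir, paste0("ggm_", key, ".json")))
    utils::write.csv(ggm_edge_table(net),
                     file.path(dir, paste0("edges_", key, ".csv")),
                     row.names = FALSE)
  }
  for (g in names(report$gvar)) {
    gv <- report$gvar[[g]]
    write_json(gvar_to_list(gv$pruned, gv$fit_indices, gv$boots, gv$stable),
               file.path(dir, paste0("gvar_", g, ".json")))
    ef <- gv$boots$edges
    ef$estimate <- c(gvar_edge_estimates(gv$pruned))
    ef$stable <- ef$inclusion >= gv$boots$threshold
    utils::write.csv(ef, file.path(dir, paste0("gvar_", g, "_edges.csv")),
                     row.names = FALSE)
  }
  for (key in names(report$nct_groups)) {
    utils::write.csv(report$nct_groups[[key]]$edges,
                     file.path(dir, paste0("comparison_", key, ".csv")),
                     row.names = FALSE)
  }
  for (key in names(report$nct_waves)) {
    utils::write.csv(report$nct_waves[[key]]$edges,
                     file.path(dir, paste0("comparison_waves_", key, ".csv")),
                     row.names = FALSE)
  }
  for (key in names(report$gvar_comparisons)) {
    utils::write.csv(report$gvar_comparisons[[key]],
                     file.path(dir, paste0("comparison_gvar_", key, ".csv")),
                     row.names = FALSE)
  }
  body <- report_body(report)
  write_json(body, file.path(dir, "report.json"))
  invisible(dir)
}

# Deterministic JSON-serializable body of the report (no timestamps).
report_body <- function(report) {
  list(
    provenance = report$provenance,
    inclusion = report$inclusion,
    n_networks_cross_sectional = length(report$ggm),
    n_networks_longitudinal = length(report$gvar),
    descriptives = list(
      n_included = report$descriptives$n_included,
      anova = lapply(report$descriptives$anova, function(a) {
        list(variable = a$variable, wave = a$wave, F = a$F, p = a$p)
      })),
    ggm = lapply(report$ggm, ggm_to_list),
    gvar = lapply(report$gvar, function(gv) {
      gvar_to_list(gv$pruned, gv$fit_indices, gv$boots, gv$stable)
    }),
    nct_groups = lapply(report$nct_groups, function(x) {
      list(omnibus = x$omnibus, edges = x$edges)
    }),
    gvar_comparisons = lapply(report$gvar_comparisons, function(x) {
      as.list(x[, c("kind", "from", "to", "AED", "p")])
    }))
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf(
    "Study report: %d/%d persons included; %d cross-sectional + %d longitudinal networks\n",
    x$inclusion$n_included, x$inclusion$n_total, length(x$ggm),
    length(x$gvar)))
  invisible(x)
}
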