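#' Configuration for a full study run
#'
#' Collects every tunable of the end-to-end pipeline with one explicit
#' seed per stochastic stage, so a run is reproducible from the config
#' alone.  The config round-trips losslessly through JSON.
#'
#' @param correlation_method `"pearson"` (default) or `"polychoric"`.
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param n_lambda,lambda_min_ratio Penalty-grid settings.
#' @param bootstrap_B Bootstrap resamples (default 1000).
#' @param drop_proportions Case-dropping grid.
#' @param nct_n_perm NCT permutations per wave pair (default 1000).
#' @param nct_pairs Wave pairs for the NCT; NULL = all pairs.
#' @param time_codes Slope time codes (default 0:3).
#' @param seeds Named list of per-stage seeds (`layout`, `bootstrap`,
#'   `nct`).
#' @param output_dir Directory for the report bundle, or NULL to skip
#'   writing files.
#' @return A `run_config` list.
#' @export
run_config <- function(correlation_method = "pearson", gamma = 0.5,
                       n_lambda = 100, lambda_min_ratio = 0.01,
                       bootstrap_B = 1000,
                       drop_proportions = seq(0.05, 0.75, 0.05),
                       nct_n_perm = 1000, nct_pairs = NULL,
                       time_codes = 0:3,
                       seeds = list(layout = 1, bootstrap = 2, nct = 3),
                       output_dir = NULL) {
  structure(list(correlation_method = correlation_method, gamma = gamma,
                 n_lambda = n_lambda,
                 lambda_min_ratio = lambda_min_ratio,
                 bootstrap_B = bootstrap_B,
                 drop_proportions = drop_proportions,
                 nct_n_perm = nct_n_perm, nct_pairs = nct_pairs,
                 time_codes = time_codes, seeds = seeds,
                 output_dir = output_dir),
            class = "run_config")
}

#' Run the full longitudinal network study on a panel
#'
#' Executes the complete analysis sequence on a 4-wave item panel: scale
#' scores and reliability, one EBIC-glasso network per wave on that wave's
#' complete cases, a shared Fruchterman-Reingold layout, strength and
#' bridge centrality tables, bootstrap stability per wave, the paired
#' Network Comparison Test over the requested wave pairs with Bonferroni
#' correction, and the OLS-slope change-trajectory network.  Stage
#' failures are caught and reported per stage; downstream stages that
#' depend on a failed stage are skipped.
#'
#' When `config$output_dir` is set the bundle is also written to disk:
#' per-wave edge lists and network JSONs, layout JSON, centrality CSVs,
#' stability JSON, NCT summary CSV, the slope network, and a manifest
#' recording every seed, sample size and selected penalty.
#'
#' @param panel An [item_panel()].
#' @param config A [run_config()].
#' @param stability Run the (comparatively slow) bootstrap stability stage
#'   (default TRUE).
#' @return A `study_report` list with elements `scores`, `alpha`,
#'   `networks`, `layout`, `centrality`, `stability`, `comparison`,
#'   `slopes`, `slope_network`, `manifest`, `errors`.
#' @export
run_study <- function(panel, config = run_config(), stability = TRUE) {
  validate_panel(panel)
  est <- default_estimator(config$correlation_method, config$gamma,
                           config$n_lambda, config$lambda_min_ratio)
  waves <- intersect(WAVES, unique(panel$wave))
  errors <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  scores <- run_stage("scores", total_scores(panel))
  alpha <- run_stage("alpha", {
    out <- list()
    for (w in waves) {
      x <- complete_cases(panel, w)
      out[[w]] <- c(phq = cronbach_alpha(x[, 1:9]),
                    gad = cronbach_alpha(x[, 10:16]))
    }
    out
  })

  networks <- list()
  for (w in waves)
    networks[[w]] <- run_stage(paste0("network_", w), {
      x <- complete_cases(panel, w)
      estimate_network(x, est)
    })
  ok_nets <- Filter(Negate(is.null), networks)

  layout <- if (length(ok_nets) > 0)
    run_stage("layout", fr_layout(ok_nets, seed = config$seeds$layout))
  centrality <- list()
  for (w in names(ok_nets))
    centrality[[w]] <- run_stage(paste0("centrality_", w),
                                 bridge_centrality(networks[[w]]))

  stab <- NULL
  if (stability && length(ok_nets) > 0) {
    stab <- list()
    for (w in names(ok_nets))
      stab[[w]] <- run_stage(paste0("stability_", w), {
        x <- complete_cases(panel, w)
        bootstrap_stability(x, B = config$bootstrap_B,
                            seed = config$seeds$bootstrap,
                            config = est,
                            drop_proportions = config$drop_proportions)
      })
  }

  comparison <- if (length(waves) >= 2)
    run_stage("comparison",
              compare_waves(panel, pairs = config$nct_pairs,
                            n_perm = config$nct_n_perm,
                            seed = config$seeds$nct, config = est))

  slopes <- run_stage("slopes",
                      ols_slopes(panel, waves,
                                 config$time_codes[seq_along(waves)]))
  slope_net <- if (!is.null(slopes))
    run_stage("slope_network",
              slope_network(slopes, gamma = config$gamma,
                            n_lambda = config$n_lambda,
                            lambda_min_ratio = config$lambda_min_ratio))

  manifest <- list(
    waves = waves,
    n_per_wave = sapply(waves, function(w)
      tryCatch(attr(complete_cases(panel, w), "n"),
               error = function(e) 0L)),
    lambda_selected = sapply(names(ok_nets), function(w)
      networks[[w]]$lambda_selected),
    slope_n = if (!is.null(slopes)) nrow(slopes) else NA_integer_,
    config = unclass(config))

  report <- structure(list(scores = scores, alpha = alpha,
                           networks = networks, layout = layout,
                           centrality = centrality, stability = stab,
                           comparison = comparison, slopes = slopes,
                           slope_network = slope_net,
                           manifest = manifest, errors = errors),
                      class = "study_report")
  if (!is.null(config$output_dir))
    write_study_bundle(report, config$output_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> ", length(Filter(Negate(is.null), x$networks)),
      " wave networks", if (!is.null(x$slope_network))
        " + slope network", "\n", sep = "")
  if (length(x$errors) > 0)
    cat("  failed stages:", paste(names(x$errors), collapse = ", "), "\n")
  invisible(x)
}

# serialize one network to a plain list for JSON output
network_to_list <- function(net) {
  list(nodes = net$nodes, weights = unname(net$weights),
       partition = as.list(net$partition), n = net$n,
       lambda_selected = net$lambda_selected)
}

#' Write a study report bundle to disk
#'
#' Edge lists (6 decimal places), network/layout/stability JSONs
#' (unrounded), centrality and NCT summary CSVs, and a manifest JSON.
#'
#' @param report A `study_report` from [run_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_bundle <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (w in names(report$networks)) {
    net <- report$networks[[w]]
    if (is.null(net)) next
    write_edge_list(net, file.path(dir, paste0("network_", w, ".csv")))
    jsonlite::write_json(network_to_list(net),
                         file.path(dir, paste0("network_", w, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(report$layout))
    jsonlite::write_json(report$layout, file.path(dir, "layout.json"),
                         auto_unbox = TRUE, digits = NA)
  for (w in names(report$centrality))
    if (!is.null(report$centrality[[w]]))
      write.csv(report$centrality[[w]],
                file.path(dir, paste0("centrality_", w, ".csv")),
                row.names = FALSE)
  if (!is.null(report$stability)) {
    cs <- lapply(Filter(Negate(is.null), report$stability),
                 function(s) as.list(s$cs))
    jsonlite::write_json(cs, file.path(dir, "stability_cs.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(report$comparison))
    write.csv(report$comparison$summary,
              file.path(dir, "nct_summary.csv"), row.names = FALSE)
  if (!is.null(report$slope_network)) {
    write_edge_list(report$slope_network,
                    file.path(dir, "network_slopes.csv"))
    jsonlite::write_json(network_to_list(report$slope_network),
                         file.path(dir, "network_slopes.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
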