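# default estimator configuration shared by bootstrap, NCT and run_study
default_estimator <- function(method = "pearson", gamma = 0.5,
                              n_lambda = 100, lambda_min_ratio = 0.01) {
  list(method = method, gamma = gamma, n_lambda = n_lambda,
       lambda_min_ratio = lambda_min_ratio)
}

# one full correlation -> EBIC-glasso estimation under a config
estimate_network <- function(x, config = default_estimator(),
                             partition = NULL) {
  R <- correlation_matrix(x, method = config$method)
  ebic_glasso(R, n = nrow(x), gamma = config$gamma,
              n_lambda = config$n_lambda,
              lambda_min_ratio = config$lambda_min_ratio,
              partition = partition)
}

#' Bootstrap edge accuracy
#'
#' Nonparametric bootstrap of the edge weights: rows are resampled with
#' replacement `B` times, the whole estimation pipeline (correlation plus
#' EBIC-glasso) is re-run on every resample, and 2.5th/97.5th percentile
#' intervals are formed per edge.  Resamples on which estimation fails are
#' dropped and counted; more than 10% failures aborts.
#'
#' @param x Item-score matrix.
#' @param B Number of resamples (>= 100).
#' @param seed Integer seed.
#' @param config Estimator configuration from `default_estimator()`.
#' @return Data frame `node_i, node_j, estimate, lower, upper` over all
#'   node pairs; attributes `B_effective` and `failures`.
#' @export
edge_bootstrap <- function(x, B = 1000, seed = 1,
                           config = default_estimator()) {
  if (B < 100) stop("B must be at least 100")
  set.seed(seed)
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  point <- estimate_network(x, config, partition = NA)
  idx <- which(upper.tri(point$weights), arr.ind = TRUE)
  draws <- matrix(NA_real_, B, nrow(idx))
  failures <- 0
  for (b in seq_len(B)) {
    rows <- sample.int(n, n, replace = TRUE)
    net_b <- tryCatch(estimate_network(x[rows, , drop = FALSE], config,
                                       partition = NA),
                      error = function(e) NULL)
    if (is.null(net_b)) { failures <- failures + 1; next }
    draws[b, ] <- net_b$weights[idx]
  }
  if (failures > 0.1 * B)
    stop("estimation failed on ", failures, " of ", B, " resamples")
  qs <- apply(draws, 2, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  out <- data.frame(node_i = rownames(point$weights)[idx[, 1]],
                    node_j = colnames(point$weights)[idx[, 2]],
                    estimate = point$weights[idx],
                    lower = qs[1, ], upper = qs[2, ],
                    stringsAsFactors = FALSE)
  attr(out, "B_effective") <- B - failures
  attr(out, "failures") <- failures
  out
}

#' Case-dropping bootstrap of centrality stability
#'
#' For each drop proportion q, draws `B` subsamples retaining
#' `(1-q) * n` rows, recomputes the requested centralities on each, and
#' records their Spearman correlation with the full-sample centralities.
#'
#' @param x Item-score matrix (nodes must carry a two-community partition
#'   when bridge indices are requested).
#' @param drop_proportions Grid of drop proportions in (0, 0.8]; default
#'   0.05 to 0.75 in steps of 0.05.
#' @param B Subsamples per proportion (default 1000).
#' @param seed Integer seed.
#' @param kinds Centrality kinds among `"strength"`, `"bridge_strength"`,
#'   `"bridge_betweenness"`, `"bridge_closeness"`.
#' @param config Estimator configuration.
#' @return Long data frame `kind, drop, replicate, correlation`;
#'   attribute `failures` counts dropped subsamples.
#' @export
case_drop_bootstrap <- function(x,
                                drop_proportions = seq(0.05, 0.75, 0.05),
                                B = 1000, seed = 1,
                                kinds = c("strength",
                                          "bridge_betweenness"),
                                config = default_estimator()) {
  if (any(drop_proportions <= 0 | drop_proportions > 0.8))
    stop("drop proportions must lie in (0, 0.8]")
  allowed <- c("strength", "bridge_strength", "bridge_betweenness",
               "bridge_closeness")
  kinds <- match.arg(kinds, allowed, several.ok = TRUE)
  set.seed(seed)
  x <- as.matrix(x)
  n <- nrow(x)
  need_bridge <- any(kinds != "strength")
  partition <- if (need_bridge) NULL else NA

  cent_of <- function(net) {
    if (need_bridge) {
      tab <- bridge_centrality(net)
      sapply(kinds, function(k) tab[[k]])
    } else {
      matrix(strength_centrality(net), ncol = 1,
             dimnames = list(NULL, "strength"))
    }
  }
  full <- cent_of(estimate_network(x, config, partition))

  res <- list()
  failures <- 0
  for (q in drop_proportions) {
    keep_n <- max(3, round((1 - q) * n))
    for (b in seq_len(B)) {
      rows <- sample.int(n, keep_n)
      cent <- tryCatch(
        cent_of(estimate_network(x[rows, , drop = FALSE], config,
                                 partition)),
        error = function(e) NULL)
      if (is.null(cent)) { failures <- failures + 1; next }
      for (k in seq_along(kinds)) {
        r <- suppressWarnings(cor(full[, k], cent[, k],
                                  method = "spearman"))
        res[[length(res) + 1]] <- data.frame(
          kind = kinds[k], drop = q, replicate = b,
          correlation = if (is.na(r)) 0 else r,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, res)
  attr(out, "failures") <- failures
  out
}

#' Correlation-stability (CS) coefficient
#'
#' The largest drop proportion q in the grid at which at least `prob` of
#' the bootstrap correlations with the full-sample centrality are still at
#' least `cor_threshold`; 0 when no grid point qualifies.  Values above
#' 0.25 are conventionally read as minimally stable, above 0.5 as stable.
#'
#' @param curves Output of [case_drop_bootstrap()].
#' @param cor_threshold Correlation level (default 0.7).
#' @param prob Required probability (default 0.95).
#' @return Named numeric vector, one CS per centrality kind.
#' @export
cs_coefficient <- function(curves, cor_threshold = 0.7, prob = 0.95) {
  kinds <- unique(curves$kind)
  sapply(setNames(kinds, kinds), function(k) {
    sub <- curves[curves$kind == k, ]
    qs <- sort(unique(sub$drop))
    ok <- vapply(qs, function(q) {
      r <- sub$correlation[sub$drop == q]
      mean(r >= cor_threshold) >= prob
    }, logical(1))
    if (!any(ok)) 0 else max(qs[ok])
  })
}

#' Full bootstrap stability report
#'
#' Runs [edge_bootstrap()] and [case_drop_bootstrap()] and summarizes the
#' CS coefficients.
#'
#' @param x Item-score matrix.
#' @param B Resamples for both bootstraps.
#' @param seed Integer seed.
#' @param kinds Centrality kinds for the case-dropping bootstrap.
#' @param config Estimator configuration.
#' @param drop_proportions Case-dropping grid.
#' @return A `stability_report` list: `edges`, `curves`, `cs`, `B`, `seed`.
#' @export
bootstrap_stability <- function(x, B = 1000, seed = 1,
                                kinds = c("strength",
                                          "bridge_betweenness"),
                                config = default_estimator(),
                                drop_proportions = seq(0.05, 0.75,
                                                       0.05)) {
  edges <- edge_bootstrap(x, B = B, seed = seed, config = config)
  curves <- case_drop_bootstrap(x, drop_proportions = drop_proportions,
                                B = B, seed = seed + 1L, kinds = kinds,
                                config = config)
  structure(list(edges = edges, curves = curves,
                 cs = cs_coefficient(curves), B = B, seed = seed),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("<stability_report> B = ", x$B, "\n  CS coefficients: ",
      paste(names(x$cs), format(x$cs, digits = 2), sep = "=",
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
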