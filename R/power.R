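#' Simulation-based sample-size recommendation for GGM estimation
#'
#' For each candidate sample size n: a fresh sparse ground-truth network
#' (p nodes, the given edge density) is generated per replicate, n ordinal
#' observations are sampled from it, the network is re-estimated with
#' EBIC-glasso, and the edge-recovery sensitivity (true edges recovered /
#' true edges) is recorded.  The probability q(n) that sensitivity reaches
#' the `sensitivity` target is estimated by the replicate fraction, a
#' monotone (isotonic) curve is fitted to q(n), and the recommendation is
#' the smallest candidate whose fitted q(n) reaches `assurance`.  A coarse
#' grid is scanned first, then refined around the crossing.
#'
#' @param p Node count (default 16).
#' @param density True edge density (default 0.2).
#' @param sensitivity Performance target s in (0,1) (default 0.6).
#' @param assurance Required probability of reaching it (default 0.8).
#' @param candidate_range Interval of sample sizes searched (default
#'   50-1000).
#' @param n_coarse Coarse grid size (default 10).
#' @param n_refine Refinement grid size inside the crossing interval
#'   (default 8).
#' @param replicates Replicates per candidate (default 100).
#' @param config Estimator configuration (see [edge_bootstrap()]).
#' @param generator Arguments passed on to [generate_true_network()]
#'   (weight scheme, thresholds, ...).
#' @param seed Integer seed.
#' @return A `power_recommendation` list: `n_recommended`, `curve` (data
#'   frame candidate/stage/q_raw/q_fitted), `replicates_total`, `spec`.
#' @export
recommend_sample_size <- function(p = 16, density = 0.2,
                                  sensitivity = 0.6, assurance = 0.8,
                                  candidate_range = c(50, 1000),
                                  n_coarse = 10, n_refine = 8,
                                  replicates = 100,
                                  config = default_estimator(),
                                  generator = list(), seed = 1) {
  if (sensitivity <= 0 || sensitivity >= 1) stop("sensitivity in (0,1)")
  if (assurance <= 0 || assurance >= 1) stop("assurance in (0,1)")
  if (candidate_range[1] <= 0 || diff(candidate_range) <= 0)
    stop("candidate_range must be a positive ordered interval")
  set.seed(seed)

  q_at <- function(n) {
    hits <- logical(replicates)
    for (r in seq_len(replicates)) {
      gen_args <- c(list(p = p, density = density,
                         seed = sample.int(.Machine$integer.max, 1)),
                    generator)
      model <- do.call(generate_true_network, gen_args)
      x <- sample_wave(model, n)
      net <- tryCatch(estimate_network(x, config, partition = NA),
                      error = function(e) NULL)
      if (is.null(net)) next
      truth <- true_adjacency(model)
      est <- net$weights != 0
      up <- upper.tri(truth)
      true_edges <- sum(truth[up])
      hits[r] <- if (true_edges == 0) TRUE else
        sum(est[up] & truth[up]) / true_edges >= sensitivity
    }
    mean(hits)
  }

  coarse <- unique(round(seq(candidate_range[1], candidate_range[2],
                             length.out = n_coarse)))
  q_coarse <- vapply(coarse, q_at, numeric(1))
  fit_c <- stats::isoreg(coarse, q_coarse)$yf

  cross <- which(fit_c >= assurance)
  if (length(cross) == 0)
    stop("assurance level unreachable in candidate_range; maximum ",
         "attained probability ", format(max(fit_c), digits = 3))
  hi <- coarse[cross[1]]
  lo <- if (cross[1] == 1) candidate_range[1] else coarse[cross[1] - 1]

  refined <- setdiff(unique(round(seq(lo, hi, length.out = n_refine + 2))),
                     coarse)
  q_refined <- vapply(refined, q_at, numeric(1))

  cand <- c(coarse, refined)
  qs <- c(q_coarse, q_refined)
  ord <- order(cand)
  cand <- cand[ord]; qs <- qs[ord]
  stage <- ifelse(cand %in% refined, "refined", "coarse")
  fitted <- stats::isoreg(cand, qs)$yf
  rec <- cand[which(fitted >= assurance)[1]]

  structure(list(n_recommended = rec,
                 curve = data.frame(candidate = cand, stage = stage,
                                    q_raw = qs, q_fitted = fitted),
                 replicates_total = replicates * length(cand),
                 spec = list(p = p, density = density,
                             sensitivity = sensitivity,
                             assurance = assurance,
                             candidate_range = candidate_range,
                             replicates = replicates, seed = seed)),
            class = "power_recommendation")
}

#' @export
print.power_recommendation <- function(x, ...) {
  s <- x$spec
  cat("<power_recommendation> p = ", s$p, ", density = ", s$density,
      ", sensitivity >= ", s$sensitivity, " with probability ",
      s$assurance, "\n", sep = "")
  cat("  recommended sample size:", x$n_recommended, "\n")
  invisible(x)
}
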