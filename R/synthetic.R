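#' Generate a sparse ground-truth partial-correlation network
#'
#' Builds the `true_model` every synthetic cohort is sampled from.  A
#' random graph with exactly `round(density * p(p-1)/2)` edges receives raw
#' precision weights drawn uniformly from `weight_range` (sign chosen so
#' that `prop_positive` of the implied partial correlations are positive);
#' the precision diagonal is set to 1.5 times the absolute row sum (floored
#' at 1), which guarantees positive definiteness by diagonal dominance, and
#' the matrix is standardized so off-diagonals are (negated) partial
#' correlations.  A uniform-shrinkage loop further enforces a minimum
#' eigenvalue margin as a safety net.
#'
#' Ordinal items arise by thresholding the implied latent Gaussian;
#' default cut points sit at latent quantiles 0.55/0.80/0.93, mimicking the
#' right-skewed category frequencies of low-prevalence symptoms.
#'
#' @param p Number of nodes (>= 3); the 16-node default matches a 9 + 7
#'   depression/anxiety item set.
#' @param density Fraction of possible edges present, in (0, 1); density
#'   0.2 at p = 16 gives 24 edges.
#' @param weight_range Interval for the raw absolute precision weights.
#' @param prop_positive Fraction of edges with positive partial
#'   correlation (default 0.9, the empirical norm for symptom networks).
#' @param threshold_quantiles Latent quantiles of the three ordinal cut
#'   points (shared by all items by default).
#' @param wave_effects 4 x p matrix of additive latent mean shifts per wave
#'   (default all zero).
#' @param dropout_age_effect Log-odds of dropping out per year of age
#'   (used by [generate_cohort()]).
#' @param eig_margin Minimum eigenvalue required of the standardized
#'   precision.
#' @param seed Integer seed.
#' @return A `true_model` list: `nodes`, `true_partial` (p x p), `precision`
#'   (standardized), `sigma` (implied latent correlation matrix),
#'   `density`, `thresholds` (p x 3), `wave_effects`, `dropout_age_effect`,
#'   `seed`.
#' @export
generate_true_network <- function(p = 16, density = 0.2,
                                  weight_range = c(0.5, 1),
                                  prop_positive = 0.9,
                                  threshold_quantiles = c(0.55, 0.80, 0.93),
                                  wave_effects = NULL,
                                  dropout_age_effect = 0.1,
                                  eig_margin = 0.01, seed = 1) {
  if (p < 3) stop("p must be at least 3")
  if (density < 0 || density >= 1) stop("density must be in [0, 1)")
  if (diff(weight_range) < 0 || min(weight_range) < 0)
    stop("weight_range must be an ordered non-negative interval")
  set.seed(seed)
  nodes <- if (p == 16) symptom_nodes() else paste0("V", seq_len(p))

  n_pairs <- p * (p - 1) / 2
  m <- round(density * n_pairs)
  K <- diag(p)
  if (m > 0) {
    pairs <- which(upper.tri(K), arr.ind = TRUE)
    sel <- pairs[sample.int(n_pairs, m), , drop = FALSE]
    wts <- runif(m, weight_range[1], weight_range[2]) *
      sample(c(1, -1), m, replace = TRUE,
             prob = c(prop_positive, 1 - prop_positive))
    # negative precision entry <=> positive partial correlation
    K[sel] <- -wts
    K <- K + t(K) - diag(diag(K))
    diag(K) <- pmax(1.5 * (rowSums(abs(K)) - abs(diag(K))), 1)
    # standardize the precision; uniform shrinkage until the eigenvalue
    # margin holds (diagonal dominance normally makes this a no-op)
    for (attempt in 1:50) {
      Ks <- K / sqrt(outer(diag(K), diag(K)))
      if (min(eigen(Ks, symmetric = TRUE, only.values = TRUE)$values) >
            eig_margin) break
      off <- K - diag(diag(K))
      K <- diag(diag(K)) + 0.9 * off
      if (attempt == 50)
        stop("could not reach positive definiteness within weight_range")
    }
    K <- Ks
  }
  true_partial <- -K
  diag(true_partial) <- 0
  sigma <- solve(K)
  sigma <- sigma / sqrt(outer(diag(sigma), diag(sigma)))
  sigma <- (sigma + t(sigma)) / 2
  dimnames(K) <- dimnames(sigma) <- dimnames(true_partial) <-
    list(nodes, nodes)

  thresholds <- matrix(rep(qnorm(threshold_quantiles), each = p), p, 3,
                       dimnames = list(nodes, NULL))
  if (is.null(wave_effects))
    wave_effects <- matrix(0, 4, p, dimnames = list(WAVES, nodes))

  structure(list(nodes = nodes, true_partial = true_partial, precision = K,
                 sigma = sigma, density = density, thresholds = thresholds,
                 wave_effects = wave_effects,
                 dropout_age_effect = dropout_age_effect, seed = seed),
            class = "true_model")
}

#' @export
print.true_model <- function(x, ...) {
  tp <- x$true_partial
  cat("<true_model> p = ", length(x$nodes), ", ",
      sum(tp[upper.tri(tp)] != 0), " true edges (density ",
      format(x$density, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' True adjacency of a ground-truth model
#'
#' @param model A `true_model`.
#' @return Logical p x p matrix, TRUE where a true edge exists.
#' @export
true_adjacency <- function(model) {
  A <- model$true_partial != 0
  diag(A) <- FALSE
  A
}

#' Sample one wave of ordinal responses from a true model
#'
#' Draws latent vectors from the zero-mean Gaussian implied by the model's
#' partial-correlation structure, adds the wave's latent mean shifts, and
#' discretizes each coordinate into \{0,1,2,3\} by the item thresholds.
#'
#' @param model A `true_model`.
#' @param n Number of respondents (> 0).
#' @param wave Wave label selecting the row of `wave_effects`.
#' @param seed Integer seed, or NULL to draw from the current RNG stream.
#' @return Integer n x p matrix of item scores.
#' @export
sample_wave <- function(model, n, wave = "T1", seed = NULL) {
  if (n <= 0) stop("n must be positive")
  if (!is.null(seed)) set.seed(seed)
  p <- length(model$nodes)
  mu <- model$wave_effects[wave, ]
  Z <- MASS::mvrnorm(n, mu = mu, Sigma = model$sigma)
  if (n == 1) Z <- matrix(Z, 1, p)
  X <- matrix(0L, n, p, dimnames = list(NULL, model$nodes))
  for (k in seq_len(p))
    X[, k] <- as.integer(findInterval(Z[, k], model$thresholds[k, ]))
  X
}

#' Default wave drift for a 16-node depression/anxiety cohort
#'
#' Small positive latent drift on the sadness and guilt items and small
#' negative drift on all anxiety items across waves, emulating the typical
#' centrality shift over a treatment course; magnitudes configurable.
#'
#' @param drift Latent shift per wave step (default 0.08).
#' @return 4 x 16 matrix of latent mean shifts.
#' @export
default_wave_effects <- function(drift = 0.08) {
  nodes <- symptom_nodes()
  we <- matrix(0, 4, 16, dimnames = list(WAVES, nodes))
  step <- 0:3
  we[, c("Sdn", "Glt")] <- drift * step
  we[, GAD_NODES] <- -drift * step
  we
}

#' Specify a synthetic cohort
#'
#' Defaults reproduce the shape of a 4-wave IVF-ET cohort: 343 baseline
#' participants, per-wave retention 343/269/261/212 with 210 completing all
#' four waves, age ~ N(30.68, 4.10) years, and older participants more
#' likely to drop out (log-odds 0.1 per year).
#'
#' @param n_baseline Baseline sample size.
#' @param retention Named per-wave target complete-case counts.
#' @param n_completers Target number of participants observed at all four
#'   waves; set equal to `retention["T4"]` for strictly monotone dropout.
#' @param age_mean,age_sd Age distribution in years.
#' @param dropout_age_effect Log-odds per year of age on dropping out
#'   between consecutive waves.
#' @param wave_effects 4 x p latent mean shifts; default
#'   [default_wave_effects()].
#' @param model A `true_model`, or NULL to generate one from `seed`.
#' @param seed Integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_baseline = 343,
                        retention = c(T1 = 343, T2 = 269, T3 = 261,
                                      T4 = 212),
                        n_completers = 210, age_mean = 30.68,
                        age_sd = 4.10, dropout_age_effect = 0.1,
                        wave_effects = default_wave_effects(),
                        model = NULL, seed = 1) {
  retention <- retention[WAVES]
  if (any(is.na(retention))) stop("retention must name waves T1..T4")
  if (any(diff(retention) > 0))
    stop("retention must be non-increasing across waves")
  if (n_baseline < retention[1]) stop("n_baseline below T1 retention")
  if (n_completers > retention[4] || n_completers < 0)
    stop("n_completers must be in [0, retention at T4]")
  if (is.null(model))
    model <- generate_true_network(dropout_age_effect = dropout_age_effect,
                                   wave_effects = wave_effects, seed = seed)
  structure(list(n_baseline = n_baseline, retention = retention,
                 n_completers = n_completers, age_mean = age_mean,
                 age_sd = age_sd, dropout_age_effect = dropout_age_effect,
                 wave_effects = wave_effects, model = model, seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic 4-wave cohort
#'
#' Produces an [item_panel()] with exactly the target complete-case count
#' at every wave.  Dropout between consecutive waves is sampled from an
#' age-dependent logistic retention model (positive `dropout_age_effect`
#' makes older participants more likely to leave), then randomly trimmed or
#' re-retained to hit the targets exactly.  Dropout is monotone except
#' that, when `n_completers < retention["T4"]`, the difference is realized
#' by early droppers who skip T2 but return for T3 and T4, so the number of
#' all-wave completers is exactly `n_completers`.
#'
#' @param spec A [cohort_spec()].
#' @return An [item_panel()]; attribute `presence` is the logical
#'   participant x wave observation matrix, attribute `model` the
#'   generating `true_model`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_baseline
  model <- spec$model
  model$wave_effects <- spec$wave_effects
  ages <- rnorm(n, spec$age_mean, spec$age_sd)
  ids <- sprintf("P%04d", seq_len(n))

  n_int <- spec$retention[4] - spec$n_completers
  # monotone presence targets; intermittent participants are added back at
  # T3/T4 afterwards
  mono_target <- spec$retention - c(0, 0, n_int, n_int)

  present <- matrix(FALSE, n, 4, dimnames = list(ids, WAVES))
  present[sample.int(n, mono_target[1]), 1] <- TRUE
  for (k in 2:4) {
    cand <- which(present[, k - 1])
    target <- mono_target[k]
    if (target > length(cand)) stop("retention targets unreachable")
    base_rate <- target / length(cand)
    eta <- log(base_rate / (1 - base_rate)) -
      spec$dropout_age_effect * (ages[cand] - mean(ages))
    keep <- cand[runif(length(cand)) < plogis(eta)]
    if (length(keep) > target) {
      keep <- sample(keep, target)
    } else if (length(keep) < target) {
      extra <- sample(setdiff(cand, keep), target - length(keep))
      keep <- c(keep, extra)
    }
    present[keep, k] <- TRUE
  }
  if (n_int > 0) {
    # early droppers who skip T2 but come back: present T1, T3, T4
    pool <- which(present[, 1] & !present[, 2])
    if (length(pool) < n_int) stop("retention targets unreachable")
    back <- sample(pool, n_int)
    present[back, 3] <- TRUE
    present[back, 4] <- TRUE
  }

  rows <- list()
  for (k in 1:4) {
    idx <- which(present[, k])
    X <- sample_wave(model, length(idx), WAVES[k])
    df <- data.frame(participant_id = ids[idx], wave = WAVES[k],
                     age = ages[idx], stringsAsFactors = FALSE)
    df[, ITEM_COLS] <- X
    rows[[k]] <- df
  }
  panel <- item_panel(do.call(rbind, rows))
  attr(panel, "presence") <- present
  attr(panel, "model") <- model
  panel
}
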