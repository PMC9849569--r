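#' Per-participant OLS slopes of item scores across waves
#'
#' For every participant observed (with complete items) at all requested
#' waves, fits the closed-form least-squares slope of each item's score on
#' the wave time code:
#' \deqn{\beta = \sum_t (t - \bar t)(y_t - \bar y) / \sum_t (t - \bar t)^2.}
#' The slope score is the linear change of that symptom over the treatment
#' course for that individual.  Participants missing any requested wave are
#' excluded (the count is reported).
#'
#' @param panel An [item_panel()].
#' @param waves Wave labels to use (default all four).
#' @param time_codes Numeric time codes, one per wave (default 0,1,2,3 —
#'   equally spaced occasions).  Affine re-coding rescales all slopes by a
#'   common factor and leaves the slope network unchanged.
#' @return Numeric matrix, complete-case participants x items; attribute
#'   `n_excluded` counts participants dropped for missing waves,
#'   `time_codes` records the coding.
#' @export
ols_slopes <- function(panel, waves = WAVES,
                       time_codes = seq_along(waves) - 1) {
  if (length(waves) < 2) stop("need at least 2 waves")
  if (length(time_codes) != length(waves))
    stop("one time code per wave required")
  mats <- lapply(waves, function(w) complete_cases(panel, w))
  ids <- Reduce(intersect, lapply(mats, rownames))
  all_ids <- unique(panel$participant_id)
  if (length(ids) == 0) stop("no participant complete at all waves")
  t <- time_codes
  tc <- t - mean(t)
  denom <- sum(tc^2)
  p <- ncol(mats[[1]])
  slopes <- matrix(0, length(ids), p,
                   dimnames = list(ids, colnames(mats[[1]])))
  for (w in seq_along(waves))
    slopes <- slopes + tc[w] * mats[[w]][ids, , drop = FALSE]
  slopes <- slopes / denom
  attr(slopes, "n_excluded") <- length(all_ids) - length(ids)
  attr(slopes, "time_codes") <- setNames(t, waves)
  slopes
}

#' Change-trajectory network
#'
#' Estimates a Gaussian graphical model on the per-participant slope
#' scores: Pearson correlations of the slopes (slopes are continuous, so
#' the polychoric option does not apply) followed by EBIC-glasso with the
#' same penalty-selection parameters as the cross-sectional networks.  An
#' edge links two symptoms whose *changes* over the treatment course
#' co-occur across participants.
#'
#' @param slopes Slope matrix from [ols_slopes()].
#' @param gamma,n_lambda,lambda_min_ratio EBIC-glasso settings (same
#'   defaults as [ebic_glasso()]).
#' @param partition Community partition (NULL derives from node labels,
#'   NA for none).
#' @return A [symptom_network()]; items with constant slopes are dropped
#'   from estimation with a warning and re-inserted as isolated nodes.
#' @export
slope_network <- function(slopes, gamma = 0.5, n_lambda = 100,
                          lambda_min_ratio = 0.01, partition = NULL) {
  slopes <- as.matrix(slopes)
  if (nrow(slopes) < 3 * ncol(slopes))
    warning("fewer than 3 rows per node; slope network may be unstable")
  sds <- apply(slopes, 2, sd)
  const <- sds == 0
  if (any(const))
    warning("constant slope column(s) dropped: ",
            paste(colnames(slopes)[const], collapse = ", "))
  active <- slopes[, !const, drop = FALSE]
  R <- pearson_matrix(active)
  net <- ebic_glasso(R, n = nrow(slopes), gamma = gamma,
                     n_lambda = n_lambda,
                     lambda_min_ratio = lambda_min_ratio, partition = NA)
  nodes <- colnames(slopes)
  w <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  w[!const, !const] <- net$weights
  symptom_network_maybe(w, partition, nrow(slopes), net$lambda_selected)
}
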