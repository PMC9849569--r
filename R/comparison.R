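#' Paired Network Comparison Test
#'
#' Permutation test of network invariance between two conditions measured
#' on the same participants (e.g. two waves of a panel).  Two global
#' statistics are tested: structure invariance
#' \eqn{M = \max_{i<j} |w^A_{ij} - w^B_{ij}|} and global-strength
#' invariance \eqn{S = |\,\|W^A\|_1 - \|W^B\|_1\,|} (absolute difference of
#' the networks' global strengths).  The null distribution preserves
#' within-participant dependence: each permutation independently swaps a
#' participant's two response vectors between conditions with probability
#' 1/2 and re-estimates both networks.  p-values use the add-one estimator
#' \eqn{(1 + \#\{stat_{perm} \ge stat_{obs}\}) / (1 + n_{perm})}.
#' Edge-level differences are tested with the same permutation draws and
#' Holm-corrected across the edges nonzero in at least one observed
#' network.
#'
#' @param dataA,dataB Item-score matrices of the same participants,
#'   row-aligned (row i of both is the same person).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param config Estimator configuration (see [edge_bootstrap()]).
#' @param min_pairs Minimum number of paired rows (default 50).
#' @param test_edges Run the edge-level tests (default TRUE).
#' @return An `nct_result` list: `M`, `S`, `p_M`, `p_S`, `edge_tests`
#'   (data frame with observed differences, raw and Holm-corrected
#'   p-values), `networks`, `n_perm`, `n_pairs`, `seed`, `paired = TRUE`.
#' @export
nct_paired <- function(dataA, dataB, n_perm = 1000, seed = 1,
                       config = default_estimator(), min_pairs = 50,
                       test_edges = TRUE) {
  dataA <- as.matrix(dataA)
  dataB <- as.matrix(dataB)
  if (!all(dim(dataA) == dim(dataB)))
    stop("paired matrices must have identical dimensions")
  n <- nrow(dataA)
  if (n < min_pairs)
    stop("need at least ", min_pairs, " paired participants, got ", n)
  set.seed(seed)

  netA <- estimate_network(dataA, config, partition = NA)
  netB <- estimate_network(dataB, config, partition = NA)
  diff_obs <- netA$weights - netB$weights
  up <- upper.tri(diff_obs)
  M_obs <- max(abs(diff_obs[up]))
  S_obs <- abs(global_strength(netA) - global_strength(netB))

  idx <- which(up, arr.ind = TRUE)
  tested <- netA$weights[up] != 0 | netB$weights[up] != 0

  M_null <- S_null <- numeric(n_perm)
  edge_geq <- numeric(sum(up))
  max_retries <- 5L
  for (b in seq_len(n_perm)) {
    for (attempt in seq_len(max_retries)) {
      swap <- runif(n) < 0.5
      permA <- dataA; permB <- dataB
      permA[swap, ] <- dataB[swap, ]
      permB[swap, ] <- dataA[swap, ]
      fit <- tryCatch({
        nA <- estimate_network(permA, config, partition = NA)
        nB <- estimate_network(permB, config, partition = NA)
        list(nA = nA, nB = nB)
      }, error = function(e) NULL)
      if (!is.null(fit)) break
    }
    if (is.null(fit)) stop("estimation kept failing under permutation")
    dperm <- fit$nA$weights - fit$nB$weights
    M_null[b] <- max(abs(dperm[up]))
    S_null[b] <- abs(global_strength(fit$nA) - global_strength(fit$nB))
    edge_geq <- edge_geq + (abs(dperm[up]) >= abs(diff_obs[up]) - 1e-12)
  }

  p_M <- (1 + sum(M_null >= M_obs - 1e-12)) / (1 + n_perm)
  p_S <- (1 + sum(S_null >= S_obs - 1e-12)) / (1 + n_perm)

  edge_tests <- NULL
  if (test_edges) {
    p_raw <- (1 + edge_geq) / (1 + n_perm)
    edge_tests <- data.frame(
      node_i = rownames(diff_obs)[idx[, 1]],
      node_j = colnames(diff_obs)[idx[, 2]],
      weight_A = netA$weights[up], weight_B = netB$weights[up],
      difference = diff_obs[up], tested = tested,
      p = ifelse(tested, p_raw, NA_real_),
      stringsAsFactors = FALSE)
    edge_tests$p_holm <- NA_real_
    edge_tests$p_holm[tested] <- stats::p.adjust(p_raw[tested],
                                                 method = "holm")
  }

  structure(list(M = M_obs, S = S_obs, p_M = p_M, p_S = p_S,
                 edge_tests = edge_tests,
                 networks = list(A = netA, B = netB),
                 null_M = M_null, null_S = S_null,
                 n_perm = n_perm, n_pairs = n, seed = seed,
                 paired = TRUE),
            class = "nct_result")
}

#' @export
print.nct_result <- function(x, ...) {
  cat("<nct_result> paired NCT, n = ", x$n_pairs, " pairs, ",
      x$n_perm, " permutations\n", sep = "")
  cat(sprintf("  structure invariance   M = %.4f, p = %.4f\n", x$M, x$p_M))
  cat(sprintf("  global strength        S = %.4f, p = %.4f\n", x$S, x$p_S))
  if (!is.null(x$edge_tests)) {
    sig <- sum(x$edge_tests$p_holm < 0.05, na.rm = TRUE)
    cat("  edges significant after Holm correction:", sig, "\n")
  }
  invisible(x)
}

#' Compare networks across panel waves
#'
#' Runs the paired [nct_paired()] for every requested wave pair on the
#' participants with complete data at both waves, and applies a Bonferroni
#' correction across the pairs.
#'
#' @param panel An [item_panel()].
#' @param pairs List of 2-element wave-label vectors; default all 6 pairs
#'   of the four waves.
#' @param n_perm Permutations per pair.
#' @param seed Integer seed (incremented per pair).
#' @param alpha Family significance level (default 0.05); each pair is
#'   tested at `alpha / length(pairs)`.
#' @param config Estimator configuration.
#' @param ... Passed to [nct_paired()].
#' @return A `wave_comparison` list: `results` (named `nct_result` list),
#'   `summary` data frame (pair, n pairs, M, p_M, S, p_S, Bonferroni
#'   threshold, significance flags), `alpha`, `alpha_corrected`.
#' @export
compare_waves <- function(panel, pairs = NULL, n_perm = 1000, seed = 1,
                          alpha = 0.05, config = default_estimator(),
                          ...) {
  waves <- intersect(WAVES, unique(panel$wave))
  if (length(waves) < 2) stop("need at least 2 waves")
  if (is.null(pairs)) {
    cmb <- utils::combn(waves, 2)
    pairs <- lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
  }
  alpha_c <- alpha / length(pairs)
  results <- list()
  rows <- list()
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    a <- complete_cases(panel, pr[1])
    b <- complete_cases(panel, pr[2])
    common <- intersect(rownames(a), rownames(b))
    res <- nct_paired(a[common, , drop = FALSE],
                      b[common, , drop = FALSE],
                      n_perm = n_perm, seed = seed + i - 1L,
                      config = config, ...)
    key <- paste(pr, collapse = "-")
    results[[key]] <- res
    rows[[i]] <- data.frame(pair = key, n_pairs = res$n_pairs,
                            M = res$M, p_M = res$p_M,
                            S = res$S, p_S = res$p_S,
                            stringsAsFactors = FALSE)
  }
  summary <- do.call(rbind, rows)
  summary$alpha_corrected <- alpha_c
  summary$structure_significant <- summary$p_M < alpha_c
  summary$strength_significant <- summary$p_S < alpha_c
  structure(list(results = results, summary = summary, alpha = alpha,
                 alpha_corrected = alpha_c),
            class = "wave_comparison")
}

#' @export
print.wave_comparison <- function(x, ...) {
  cat("<wave_comparison> ", nrow(x$summary), " wave pairs, Bonferroni ",
      "threshold ", format(x$alpha_corrected, digits = 4), "\n", sep = "")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
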