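#' Construct a symptom network
#'
#' A weighted undirected network whose edge weights are regularized partial
#' correlations, with a two-community (depression/anxiety) node partition.
#'
#' @param weights Symmetric p x p weight matrix, zero diagonal, entries in
#'   \[-1, 1\]; dimnames give the node labels.
#' @param partition Named community vector as from [community_partition()];
#'   if NULL it is derived from the node labels.
#' @param n Sample size the network was estimated on (NA if unknown).
#' @param lambda_selected Penalty selected by EBIC (NA if not applicable).
#' @return A `symptom_network` object.
#' @export
symptom_network <- function(weights, partition = NULL, n = NA_real_,
                            lambda_selected = NA_real_) {
  weights <- as.matrix(weights)
  p <- nrow(weights)
  if (ncol(weights) != p) stop("weight matrix must be square")
  if (is.null(rownames(weights)))
    rownames(weights) <- colnames(weights) <- paste0("V", seq_len(p))
  if (max(abs(weights - t(weights))) > 1e-8)
    stop("weight matrix must be symmetric")
  weights <- (weights + t(weights)) / 2
  if (any(abs(diag(weights)) > 1e-12)) stop("diagonal must be zero")
  diag(weights) <- 0
  if (max(abs(weights)) > 1 + 1e-8)
    stop("edge weights must lie in [-1, 1]")
  if (is.null(partition)) partition <- community_partition(rownames(weights))
  if (!setequal(names(partition), rownames(weights)))
    stop("partition nodes do not match weight matrix nodes")
  if (length(unique(partition)) != 2)
    stop("partition must have exactly two non-empty communities")
  structure(list(nodes = rownames(weights), weights = weights,
                 partition = partition[rownames(weights)], n = n,
                 lambda_selected = lambda_selected),
            class = "symptom_network")
}

#' @export
print.symptom_network <- function(x, ...) {
  cat("<symptom_network> p = ", length(x$nodes), " nodes, E = ",
      edge_count(x), " edges, n = ", x$n, "\n", sep = "")
  if (!is.na(x$lambda_selected))
    cat("  lambda selected by EBIC: ",
        format(x$lambda_selected, digits = 4), "\n", sep = "")
  cat("  global strength: ", format(global_strength(x), digits = 4), "\n",
      sep = "")
  invisible(x)
}

#' Number of edges in a network
#'
#' Strictly nonzero upper-triangle entries of the weight matrix.
#'
#' @param net A [symptom_network()].
#' @return Integer edge count.
#' @export
edge_count <- function(net) {
  w <- net$weights
  sum(w[upper.tri(w)] != 0)
}

#' Global strength of a network
#'
#' The overall connectivity: the sum of absolute edge weights over all
#' unique node pairs.  This is the quantity the Network Comparison Test's
#' global strength invariance statistic S compares between networks.
#'
#' @param net A [symptom_network()].
#' @return Non-negative scalar.
#' @export
global_strength <- function(net) {
  w <- net$weights
  sum(abs(w[upper.tri(w)]))
}

#' Single graphical lasso fit
#'
#' L1-penalized Gaussian maximum likelihood for the precision matrix: the
#' maximizer of \eqn{\ell(K) - (n/2)\lambda \sum_{i \ne j} |K_{ij}|} with
#' \eqn{\ell(K) = (n/2)(\log\det K - \mathrm{tr}(RK))}, solved by block
#' coordinate descent.  The additive likelihood constant is omitted
#' throughout; it cancels in model selection.
#'
#' @param R Correlation (or covariance) matrix, positive semi-definite;
#'   `lambda = 0` additionally requires positive definiteness.
#' @param lambda Penalty, >= 0.
#' @param tolerance Convergence tolerance on the mean parameter change,
#'   relative to the average absolute off-diagonal of `R`.
#' @param max_iterations Outer-loop iteration cap.
#' @return List with `K` (precision), `W` (estimated covariance),
#'   `iterations`, `converged`.
#' @export
graphical_lasso <- function(R, lambda, tolerance = 1e-4,
                            max_iterations = 200) {
  R <- as.matrix(R)
  if (lambda < 0) stop("lambda must be non-negative")
  if (lambda == 0 && min(eigen(R, symmetric = TRUE,
                               only.values = TRUE)$values) <= 1e-10)
    stop("lambda = 0 requires a positive-definite input matrix")
  fit <- cpp_glasso(R, lambda, tolerance, max_iterations)
  if (!fit$converged)
    stop("graphical lasso did not converge in ", fit$iterations,
         " iterations (lambda = ", lambda, ")")
  dimnames(fit$K) <- dimnames(fit$W) <- dimnames(R)
  fit
}

#' Extended Bayesian information criterion for a glasso fit
#'
#' EBIC = -2 l + E log(n) + 4 E gamma log(p), where l is the profiled
#' Gaussian log-likelihood of the fitted precision matrix (constants
#' omitted), E the number of nonzero partial correlations and p the number
#' of nodes.  gamma = 0 recovers the ordinary BIC.
#'
#' @param fit Result of [graphical_lasso()] (needs `K`), or a list with
#'   elements `K` and the input matrix `R` supplied separately.
#' @param R The correlation matrix the fit was computed on.
#' @param n Sample size.
#' @param gamma EBIC hyperparameter, >= 0.
#' @param zero_tol Threshold below which a partial correlation counts as
#'   zero.
#' @return List with `ebic`, `loglik`, `edges`.
#' @export
ebic <- function(fit, R, n, gamma = 0.5, zero_tol = 1e-8) {
  K <- fit$K
  p <- nrow(K)
  ll <- (n / 2) * (determinant(K, logarithm = TRUE)$modulus[1] -
                     sum(R * K))
  w <- precision_to_partial(K, zero_tol)
  E <- sum(w[upper.tri(w)] != 0)
  list(ebic = -2 * ll + E * log(n) + 4 * E * gamma * log(p),
       loglik = ll, edges = E)
}

#' Convert a precision matrix to partial correlations
#'
#' \eqn{w_{ij} = -K_{ij} / \sqrt{K_{ii} K_{jj}}}, zero diagonal; entries
#' with \eqn{|w| <} `zero_tol` are set to exactly zero.
#'
#' @param K Symmetric positive-definite precision matrix.
#' @param zero_tol Hard-zero threshold.
#' @return Partial-correlation matrix with the dimnames of `K`.
#' @export
precision_to_partial <- function(K, zero_tol = 1e-8) {
  d <- sqrt(diag(K))
  w <- -K / outer(d, d)
  diag(w) <- 0
  w[abs(w) < zero_tol] <- 0
  dimnames(w) <- dimnames(K)
  w
}

#' EBIC-selected graphical lasso network
#'
#' Fits the graphical lasso over a descending log-spaced penalty grid from
#' \eqn{\lambda_{max}} (the largest absolute off-diagonal correlation, at
#' which the estimated graph is empty) down to
#' \eqn{\lambda_{max} \cdot} `lambda_min_ratio`, selects the penalty
#' minimizing the EBIC, and returns the selected model's partial
#' correlations as a [symptom_network()].
#'
#' @param R Correlation matrix (e.g. from [pearson_matrix()]).
#' @param n Sample size used to compute `R`.
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param n_lambda Grid size (default 100).
#' @param lambda_min_ratio Smallest penalty as a fraction of
#'   \eqn{\lambda_{max}} (default 0.01).
#' @param partition Community partition; NULL derives it from node labels,
#'   NA skips the two-community requirement (plain network).
#' @param tolerance,max_iterations Passed to the glasso solver.
#' @param stop_after Early-termination window: the descent down the grid
#'   stops once the EBIC has not improved for this many consecutive grid
#'   points (the criterion is near-unimodal along the path); 0 disables
#'   and forces the full grid.
#' @return A [symptom_network()] with attribute `path` holding the lambda
#'   grid, per-lambda EBIC, log-likelihood and edge counts (only the
#'   portion of the grid actually visited).
#' @export
ebic_glasso <- function(R, n, gamma = 0.5, n_lambda = 100,
                        lambda_min_ratio = 0.01, partition = NULL,
                        tolerance = 1e-4, max_iterations = 200,
                        stop_after = 30L) {
  R <- as.matrix(R)
  nodes <- rownames(R)
  lam_max <- max(abs(R[upper.tri(R)]))
  if (lam_max < 1e-12) {
    # uncorrelated input: the empty network at any positive penalty
    w <- matrix(0, nrow(R), ncol(R), dimnames = dimnames(R))
    net <- symptom_network_maybe(w, partition, n, 0)
    attr(net, "path") <- NULL
    return(net)
  }
  lambdas <- exp(seq(log(lam_max), log(lam_max * lambda_min_ratio),
                     length.out = n_lambda))
  path <- cpp_ebic_glasso_path(R, n, gamma, lambdas, tolerance,
                               max_iterations, 1e-8,
                               as.integer(stop_after))
  w <- path$partial
  dimnames(w) <- dimnames(R)
  net <- symptom_network_maybe(w, partition, n, path$lambda_selected)
  attr(net, "path") <- data.frame(lambda = as.numeric(path$lambda),
                                  ebic = as.numeric(path$ebic),
                                  loglik = as.numeric(path$loglik),
                                  edges = as.integer(path$edges),
                                  converged = as.logical(path$converged))
  net
}

# wrap in symptom_network when a two-community partition applies, else a
# bare network object with the same fields
symptom_network_maybe <- function(w, partition, n, lambda) {
  if (identical(partition, NA)) {
    structure(list(nodes = rownames(w), weights = w, partition = NULL,
                   n = n, lambda_selected = lambda),
              class = "symptom_network")
  } else {
    symptom_network(w, partition, n, lambda)
  }
}

#' Fruchterman-Reingold layout shared across networks
#'
#' Computes one force-directed node placement from the element-wise mean of
#' the absolute weight matrices of the supplied networks, so that several
#' waves of the same panel share a fixed, comparable layout.  The
#' implementation is deterministic: nodes are initialized on a circle in
#' sorted-label order with a seed-derived rotation, so the same seed always
#' yields the same coordinates and the result does not depend on node input
#' order.
#'
#' @param nets A [symptom_network()] or list of them (shared node set).
#' @param seed Integer seed controlling the initial rotation.
#' @param niter Iterations of the force simulation (default 300).
#' @return Data frame `node, x, y` with coordinates rescaled to the unit
#'   square.
#' @export
fr_layout <- function(nets, seed = 1, niter = 300) {
  if (inherits(nets, "symptom_network")) nets <- list(nets)
  nodes <- nets[[1]]$nodes
  for (nt in nets)
    if (!identical(sort(nt$nodes), sort(nodes)))
      stop("all networks must share one node set")
  p <- length(nodes)
  A <- matrix(0, p, p, dimnames = list(nodes, nodes))
  for (nt in nets) A <- A + abs(nt$weights[nodes, nodes])
  A <- A / length(nets)

  # deterministic circular start in sorted-label order
  ord <- order(nodes)
  ang <- 2 * pi * (seq_len(p) - 1) / p + 2 * pi * ((seed %% 360) / 360)
  pos <- matrix(0, p, 2)
  pos[ord, 1] <- cos(ang)
  pos[ord, 2] <- sin(ang)

  k <- sqrt(1 / p)              # ideal pairwise distance in the unit frame
  maxstep <- 0.1
  for (it in seq_len(niter)) {
    disp <- matrix(0, p, 2)
    for (i in seq_len(p)) {
      d <- sweep(pos, 2, pos[i, ])          # vectors towards other nodes
      dist2 <- pmax(rowSums(d^2), 1e-12)
      dist <- sqrt(dist2)
      rep_f <- k^2 / dist2                  # repulsion from every node
      att_f <- A[i, ] * dist / k            # attraction along edges
      f <- att_f - rep_f
      f[i] <- 0
      disp[i, ] <- colSums(d * f / dist)
    }
    step <- maxstep * (1 - (it - 1) / niter)
    len <- pmax(sqrt(rowSums(disp^2)), 1e-12)
    pos <- pos + disp / len * pmin(len, step)
  }
  # rescale to the unit square
  for (j in 1:2) {
    rng <- range(pos[, j])
    pos[, j] <- if (diff(rng) < 1e-12) 0.5 else (pos[, j] - rng[1]) / diff(rng)
  }
  data.frame(node = nodes, x = pos[, 1], y = pos[, 2],
             stringsAsFactors = FALSE)
}

#' Write a network as an edge list
#'
#' Plain-text edge list `node_i, node_j, weight` (upper triangle, nonzero
#' edges only, weights printed with 6 decimals), the same dialect used for
#' published supplementary edge-weight tables.
#'
#' @param net A [symptom_network()].
#' @param path Output CSV path.
#' @param all_pairs Write all node pairs including zero edges (default
#'   FALSE).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path, all_pairs = FALSE) {
  w <- net$weights
  idx <- which(upper.tri(w), arr.ind = TRUE)
  df <- data.frame(node_i = rownames(w)[idx[, 1]],
                   node_j = colnames(w)[idx[, 2]],
                   weight = w[idx], stringsAsFactors = FALSE)
  if (!all_pairs) df <- df[df$weight != 0, , drop = FALSE]
  df$weight <- sprintf("%.6f", df$weight)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a network from an edge-list table
#'
#' Reads a `node_i, node_j, weight` CSV (for instance a supplementary
#' edge-weight table of a published network) into a [symptom_network()].
#' Pairs not listed get weight zero.
#'
#' @param path Edge-list CSV path.
#' @param nodes Node labels fixing order and the full node set; defaults to
#'   [symptom_nodes()].
#' @param partition Community partition; NULL derives it from `nodes`.
#' @param n Sample size to record (optional).
#' @return A [symptom_network()].
#' @export
read_edge_list <- function(path, nodes = symptom_nodes(), partition = NULL,
                           n = NA_real_) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("node_i", "node_j", "weight")
  if (!all(need %in% names(df)))
    stop("edge list must have columns node_i, node_j, weight")
  unknown <- setdiff(unique(c(df$node_i, df$node_j)), nodes)
  if (length(unknown) > 0)
    stop("edge list mentions unknown nodes: ",
         paste(unknown, collapse = ", "))
  w <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(df))) {
    w[df$node_i[r], df$node_j[r]] <- df$weight[r]
    w[df$node_j[r], df$node_i[r]] <- df$weight[r]
  }
  symptom_network(w, partition = partition, n = n)
}
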