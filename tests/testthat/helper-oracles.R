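# Independent oracles used by the unit and acceptance tests.  These stay
# deliberately naive (generic optimizers, exhaustive enumeration) and never
# share code with the implementation they check.

# Proximal-gradient maximizer of the penalized Gaussian log-likelihood
#   log det K - tr(RK) - lambda * sum_{i != j} |K_ij|
# with backtracking line search; small p only.
prox_gradient_glasso <- function(R, lambda, max_iter = 200000,
                                 kkt_tol = 1e-7) {
  p <- nrow(R)
  soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)
  obj <- function(K) {
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    2 * sum(log(diag(ch))) - sum(R * K) -
      lambda * (sum(abs(K)) - sum(abs(diag(K))))
  }
  # KKT residual of  max  log det K - tr(RK) - lambda ||offdiag(K)||_1
  kkt <- function(K) {
    G <- solve(K) - R
    r <- 0
    for (i in seq_len(p)) for (j in seq_len(p)) {
      r <- max(r, if (i == j) abs(G[i, j]) else
        if (K[i, j] != 0) abs(G[i, j] - lambda * sign(K[i, j])) else
          max(abs(G[i, j]) - lambda, 0))
    }
    r
  }
  K <- diag(p)
  f_old <- obj(K)
  for (it in seq_len(max_iter)) {
    grad <- solve(K) - R
    step <- 1
    repeat {
      cand <- K + step * grad
      off <- soft(cand, step * lambda)
      diag(off) <- diag(cand)            # diagonal unpenalized
      cand <- (off + t(off)) / 2
      f_new <- obj(cand)
      if (is.finite(f_new) && f_new >= f_old - 1e-14) break
      step <- step / 2
      if (step < 1e-16) break
    }
    moved <- max(abs(cand - K))
    K <- cand
    f_old <- f_new
    if (it %% 50 == 0 || moved < 1e-12) {
      if (kkt(K) < kkt_tol) break
      if (moved < 1e-14) break           # stalled at numerical precision
    }
  }
  K
}

# random positive-definite correlation matrix
random_pd_corr <- function(p, seed) {
  set.seed(seed)
  A <- matrix(rnorm(p * p), p)
  S <- crossprod(A) + diag(p) * 0.5
  d <- sqrt(diag(S))
  S / outer(d, d)
}

# exhaustive shortest-path distances by enumerating all simple paths
brute_force_distances <- function(len) {
  p <- nrow(len)
  best <- matrix(Inf, p, p)
  diag(best) <- 0
  paths_from <- function(v, target, visited, acc) {
    if (v == target) {
      best[acc$s, target] <<- min(best[acc$s, target], acc$d)
      return(invisible())
    }
    for (u in seq_len(p)) {
      if (visited[u] || !is.finite(len[v, u])) next
      vis <- visited; vis[u] <- TRUE
      paths_from(u, target, vis,
                 list(s = acc$s, d = acc$d + len[v, u]))
    }
  }
  for (s in seq_len(p - 1))
    for (t in (s + 1):p) {
      vis <- rep(FALSE, p); vis[s] <- TRUE
      paths_from(s, t, vis, list(s = s, d = 0))
      best[t, s] <- best[s, t]
    }
  best
}

# enumerate all simple paths between two nodes; returns list of vertex
# sequences
all_simple_paths <- function(len, s, t) {
  p <- nrow(len)
  out <- list()
  walk <- function(v, visited, path) {
    if (v == t) {
      out[[length(out) + 1]] <<- path
      return(invisible())
    }
    for (u in seq_len(p)) {
      if (visited[u] || !is.finite(len[v, u])) next
      vis <- visited; vis[u] <- TRUE
      walk(u, vis, c(path, u))
    }
  }
  vis <- rep(FALSE, p); vis[s] <- TRUE
  walk(s, vis, s)
  out
}

path_length <- function(len, path) {
  if (length(path) < 2) return(0)
  sum(len[cbind(path[-length(path)], path[-1])])
}

# brute-force bridge betweenness: fractional count of shortest paths
# between cross-community pairs passing through each intermediate node
brute_force_bridge_betweenness <- function(weights, communities,
                                           fractional = TRUE) {
  p <- nrow(weights)
  len <- 1 / abs(weights)
  len[weights == 0] <- Inf
  diag(len) <- Inf
  bb <- numeric(p)
  for (s in seq_len(p - 1)) {
    for (t in (s + 1):p) {
      if (communities[s] == communities[t]) next
      paths <- all_simple_paths(len, s, t)
      if (length(paths) == 0) next
      lens <- vapply(paths, function(pa) path_length(len, pa), numeric(1))
      dmin <- min(lens)
      shortest <- paths[abs(lens - dmin) < 1e-9]
      for (v in seq_len(p)) {
        if (v == s || v == t) next
        hits <- sum(vapply(shortest, function(pa) v %in% pa, logical(1)))
        if (hits == 0) next
        bb[v] <- bb[v] + if (fractional) hits / length(shortest) else 1
      }
    }
  }
  bb
}

# brute-force bridge closeness from the enumerated distances
brute_force_bridge_closeness <- function(weights, communities) {
  len <- 1 / abs(weights)
  len[weights == 0] <- Inf
  diag(len) <- Inf
  d <- brute_force_distances(len)
  vapply(seq_len(nrow(weights)), function(i) {
    dd <- d[i, communities != communities[i]]
    if (all(!is.finite(dd))) 0 else {
      r <- 1 / mean(dd)
      if (is.finite(r)) r else 0
    }
  }, numeric(1))
}

# random sparse two-community symptom network for property tests
random_symptom_network <- function(p, seed, density = 0.5) {
  set.seed(seed)
  nodes <- paste0("N", seq_len(p))
  w <- matrix(0, p, p, dimnames = list(nodes, nodes))
  up <- which(upper.tri(w))
  on <- up[runif(length(up)) < density]
  w[on] <- runif(length(on), -0.6, 0.6)
  w <- w + t(w)
  part <- setNames(rep(c("depression", "anxiety"),
                       c(ceiling(p / 2), floor(p / 2))), nodes)
  symptom_network(w, partition = part)
}
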