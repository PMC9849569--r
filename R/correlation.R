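#' Pearson correlation matrix of an item-score matrix
#'
#' Product-moment correlations, the default input to network estimation.
#' Ordinal 0-3 items with skewed margins attenuate Pearson correlations
#' relative to the latent scale; [polychoric_matrix()] is the latent-scale
#' alternative.
#'
#' @param x Numeric matrix, participants x items.
#' @return Correlation matrix with class attribute recording
#'   `method = "pearson"` and `n = nrow(x)`.
#' @export
pearson_matrix <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("need at least 3 rows")
  sds <- apply(x, 2, sd)
  if (any(sds == 0))
    stop("constant column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  R <- cor(x)
  structure(R, method = "pearson", n = nrow(x))
}

# Bivariate standard normal CDF P(X <= h, Y <= k) at correlation rho, by
# Gauss-Legendre quadrature of d/dr Phi2 = phi2(h,k;r) over r in [0, rho]
# (Drezner-Wesolowsky identity).  Accurate to ~1e-7 for |rho| <= 0.99.
pbinorm <- function(h, k, rho) {
  if (abs(rho) < 1e-12) return(pnorm(h) * pnorm(k))
  rho <- max(min(rho, 0.9999), -0.9999)
  gl <- gauss_legendre_32
  r <- rho / 2 * (gl$nodes + 1)          # map [-1,1] -> [0, rho]
  wgt <- gl$weights * rho / 2
  dens <- exp(-(h^2 - 2 * r * h * k + k^2) / (2 * (1 - r^2))) /
    (2 * pi * sqrt(1 - r^2))
  pnorm(h) * pnorm(k) + sum(wgt * dens)
}

# 32-point Gauss-Legendre rule on [-1, 1]
gauss_legendre_32 <- local({
  # roots of P_32 via Newton from Chebyshev starting values
  n <- 32
  x <- cos(pi * (4 * seq_len(n) - 1) / (4 * n + 2))
  for (it in 1:100) {
    p0 <- rep(1, n); p1 <- x
    for (k in 2:n) {
      p2 <- ((2 * k - 1) * x * p1 - (k - 1) * p0) / k
      p0 <- p1; p1 <- p2
    }
    dp <- n * (x * p1 - p0) / (x^2 - 1)
    x_new <- x - p1 / dp
    if (max(abs(x_new - x)) < 1e-15) { x <- x_new; break }
    x <- x_new
  }
  p0 <- rep(1, n); p1 <- x
  for (k in 2:n) {
    p2 <- ((2 * k - 1) * x * p1 - (k - 1) * p0) / k
    p0 <- p1; p1 <- p2
  }
  dp <- n * (x * p1 - p0) / (x^2 - 1)
  list(nodes = x, weights = 2 / ((1 - x^2) * dp^2))
})

# thresholds for one ordinal margin: inverse-normal of cumulative
# proportions; categories are the sorted observed values
marginal_thresholds <- function(v) {
  tab <- table(factor(v, levels = sort(unique(v))))
  cum <- cumsum(tab) / sum(tab)
  qnorm(cum[-length(cum)])
}

# two-step ML polychoric correlation for one ordinal pair
polychoric_pair <- function(x, y, clamp = 0.999) {
  tx <- c(-Inf, marginal_thresholds(x), Inf)
  ty <- c(-Inf, marginal_thresholds(y), Inf)
  xf <- factor(x, levels = sort(unique(x)))
  yf <- factor(y, levels = sort(unique(y)))
  counts <- table(xf, yf)
  nr <- nrow(counts); nc <- ncol(counts)
  negll <- function(rho) {
    # rectangle probabilities from the CDF at the threshold grid
    cdf <- matrix(0, nr + 1, nc + 1)
    for (i in seq_len(nr + 1))
      for (j in seq_len(nc + 1))
        cdf[i, j] <- if (is.infinite(tx[i]) && tx[i] < 0 ||
                         is.infinite(ty[j]) && ty[j] < 0) 0 else
          if (is.infinite(tx[i]) && is.infinite(ty[j])) 1 else
            if (is.infinite(tx[i])) pnorm(ty[j]) else
              if (is.infinite(ty[j])) pnorm(tx[i]) else
                pbinorm(tx[i], ty[j], rho)
    pr <- cdf[-1, -1, drop = FALSE] + cdf[-(nr + 1), -(nc + 1), drop = FALSE] -
      cdf[-1, -(nc + 1), drop = FALSE] - cdf[-(nr + 1), -1, drop = FALSE]
    pr <- pmax(pr, 1e-12)
    -sum(counts * log(pr))
  }
  opt <- optimize(negll, c(-clamp, clamp))
  rho <- opt$minimum
  clamped <- FALSE
  # optimize() never returns the exact interval ends; treat near-boundary
  # optima as boundary estimates
  if (abs(rho) > clamp - 1e-3) {
    rho <- sign(rho) * clamp
    clamped <- TRUE
  }
  list(rho = rho, clamped = clamped)
}

#' Polychoric correlation matrix of an ordinal item-score matrix
#'
#' Pairwise two-step maximum-likelihood polychoric correlations: per-item
#' thresholds from the marginal category proportions via the inverse normal
#' CDF, then a one-dimensional likelihood maximization over the latent
#' correlation of each pair.  The assembled matrix is repaired to the
#' nearest positive semi-definite correlation matrix when needed.
#'
#' @param x Integer matrix, participants x items; every item needs at least
#'   two observed categories.
#' @param clamp Boundary estimates (degenerate tables) are clamped to
#'   +/- `clamp` and flagged (default 0.999).
#' @param epsilon Eigenvalue floor used by the PSD repair.
#' @return Correlation matrix with attributes `method = "polychoric"`,
#'   `n`, and `clamped` (logical matrix of flagged pairs).
#' @export
polychoric_matrix <- function(x, clamp = 0.999, epsilon = 1e-6) {
  x <- as.matrix(x)
  p <- ncol(x)
  ncat <- apply(x, 2, function(v) length(unique(v[!is.na(v)])))
  if (any(ncat < 2))
    stop("item(s) with fewer than 2 observed categories: ",
         paste(colnames(x)[ncat < 2], collapse = ", "))
  R <- diag(p)
  flagged <- matrix(FALSE, p, p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      est <- polychoric_pair(x[, i], x[, j], clamp)
      R[i, j] <- R[j, i] <- est$rho
      flagged[i, j] <- flagged[j, i] <- est$clamped
    }
  }
  dimnames(R) <- list(colnames(x), colnames(x))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < epsilon) R <- nearest_psd(R, epsilon)
  structure(R, method = "polychoric", n = nrow(x), clamped = flagged)
}

#' Nearest positive semi-definite correlation matrix
#'
#' Eigenvalue clipping at `epsilon` followed by rescaling to unit diagonal;
#' idempotent on matrices that already satisfy the constraint.
#'
#' @param R Symmetric matrix.
#' @param epsilon Eigenvalue floor (default 1e-6).
#' @return Repaired unit-diagonal matrix.
#' @export
nearest_psd <- function(R, epsilon = 1e-6) {
  R <- as.matrix(R)
  if (max(abs(R - t(R))) > 1e-8) stop("input must be symmetric")
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= epsilon) return(R)
  vals <- pmax(e$values, epsilon)
  out <- e$vectors %*% diag(vals) %*% t(e$vectors)
  d <- sqrt(diag(out))
  out <- out / outer(d, d)
  out <- (out + t(out)) / 2
  diag(out) <- 1
  dimnames(out) <- dimnames(R)
  out
}

#' Correlation matrix dispatcher
#'
#' @param x Item-score matrix.
#' @param method `"pearson"` (default) or `"polychoric"`.
#' @param ... Passed to the chosen estimator.
#' @return Correlation matrix.
#' @export
correlation_matrix <- function(x, method = c("pearson", "polychoric"),
                               ...) {
  method <- match.arg(method)
  switch(method,
         pearson = pearson_matrix(x),
         polychoric = polychoric_matrix(x, ...))
}
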