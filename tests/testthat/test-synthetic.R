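test_that("true network has the exact requested edge count and a PD precision", {
  m <- generate_true_network(p = 16, density = 0.2, seed = 4)
  up <- upper.tri(m$true_partial)
  expect_equal(sum(m$true_partial[up] != 0), 24)  # round(0.2 * 120)
  expect_gt(min(eigen(m$precision, only.values = TRUE)$values), 0)

  empty <- generate_true_network(p = 8, density = 0, seed = 4)
  expect_equal(sum(empty$true_partial != 0), 0)
  expect_equal(empty$precision, diag(8), ignore_attr = TRUE)
})

test_that("stored partial correlations equal brute-force partials from the implied covariance", {
  m <- generate_true_network(p = 5, density = 0.4, seed = 11)
  # invert the implied covariance and recompute partial correlations
  K <- solve(m$sigma)
  d <- sqrt(diag(K))
  partial <- -K / outer(d, d)
  diag(partial) <- 0
  expect_equal(partial, m$true_partial, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("sampling respects thresholds, independence and determinism", {
  m <- generate_true_network(p = 5, density = 0.2, seed = 2)
  # push one item's thresholds to +Inf: that item becomes constant 0
  m$thresholds[2, ] <- Inf
  x <- sample_wave(m, 500, seed = 7)
  expect_equal(var(x[, 2]), 0)
  expect_true(all(x %in% 0:3))

  # a pair with zero latent correlation stays uncorrelated
  m2 <- generate_true_network(p = 6, density = 0.1, seed = 3)
  zero_pairs <- which(abs(m2$sigma) < 1e-12 & upper.tri(m2$sigma),
                      arr.ind = TRUE)
  x2 <- sample_wave(m2, 5000, seed = 8)
  if (nrow(zero_pairs) > 0) {
    i <- zero_pairs[1, 1]; j <- zero_pairs[1, 2]
    expect_lt(abs(cor(x2[, i], x2[, j])), 3 / sqrt(5000))
  }

  expect_identical(sample_wave(m, 50, seed = 99),
                   sample_wave(m, 50, seed = 99))
  expect_error(sample_wave(m, 0), "positive")
})

test_that("cohort hits the wave targets exactly with age-dependent dropout", {
  panel <- generate_cohort(cohort_spec(seed = 5))
  targets <- c(T1 = 343, T2 = 269, T3 = 261, T4 = 212)
  for (w in names(targets))
    expect_equal(attr(complete_cases(panel, w), "n"), unname(targets[w]))
  pres <- attr(panel, "presence")
  expect_equal(sum(rowSums(pres) == 4), 210)
})

test_that("dropout is age-directed when the effect is positive and centered when zero", {
  diffs_pos <- diffs_null <- numeric(10)
  for (s in 1:10) {
    pan <- generate_cohort(cohort_spec(n_baseline = 150,
                                       retention = c(T1 = 150, T2 = 120,
                                                     T3 = 100, T4 = 80),
                                       n_completers = 80,
                                       dropout_age_effect = 0.15,
                                       seed = s))
    pres <- attr(pan, "presence")
    age <- tapply(pan$age, pan$participant_id, function(a) a[1])
    age <- age[rownames(pres)]
    diffs_pos[s] <- mean(age[!pres[, 4]]) - mean(age[pres[, 4]])

    pan0 <- generate_cohort(cohort_spec(n_baseline = 150,
                                        retention = c(T1 = 150, T2 = 120,
                                                      T3 = 100, T4 = 80),
                                        n_completers = 80,
                                        dropout_age_effect = 0,
                                        seed = s))
    pres0 <- attr(pan0, "presence")
    age0 <- tapply(pan0$age, pan0$participant_id, function(a) a[1])
    age0 <- age0[rownames(pres0)]
    diffs_null[s] <- mean(age0[!pres0[, 4]]) - mean(age0[pres0[, 4]])
  }
  expect_gte(mean(diffs_pos > 0), 0.9)
  # null effect: difference centered on zero
  expect_lt(abs(mean(diffs_null)), 1)
})

test_that("missingness is monotone apart from the designated intermittent returners", {
  panel <- generate_cohort(cohort_spec(seed = 9))
  pres <- attr(panel, "presence")
  # returners: absent at some wave then present later
  returner <- apply(pres, 1, function(r) any(diff(r) > 0))
  expect_equal(sum(returner), 2)   # retention[T4] - n_completers
  strict <- generate_cohort(cohort_spec(n_completers = 212, seed = 9))
  pres2 <- attr(strict, "presence")
  expect_false(any(apply(pres2, 1, function(r) any(diff(r) > 0))))
  expect_equal(sum(rowSums(pres2) == 4), 212)
})

test_that("network estimation recovers the true structure on synthetic data", {
  # the headline generator/estimator compatibility check at large n
  sens <- spec <- numeric(5)
  for (s in 1:5) {
    m <- generate_true_network(seed = 100 + s)
    x <- sample_wave(m, 2000, seed = 200 + s)
    net <- ebic_glasso(pearson_matrix(x), n = 2000)
    tr <- true_adjacency(m)
    up <- upper.tri(tr)
    est <- net$weights != 0
    sens[s] <- sum(est[up] & tr[up]) / sum(tr[up])
    spec[s] <- sum(!est[up] & !tr[up]) / sum(!tr[up])
  }
  expect_gte(mean(sens), 0.8)
  expect_gte(mean(spec), 0.8)
})
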