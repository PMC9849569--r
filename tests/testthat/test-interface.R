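fast_config <- function(dir = NULL) {
  run_config(bootstrap_B = 100, drop_proportions = c(0.1, 0.3),
             nct_n_perm = 40, output_dir = dir)
}

test_that("run_study produces the full bundle shape on a synthetic cohort", {
  panel <- small_cohort(seed = 81)
  rep1 <- run_study(panel, fast_config(), stability = FALSE)
  expect_length(rep1$networks, 4)
  for (net in rep1$networks) expect_length(net$nodes, 16)
  expect_length(rep1$slope_network$nodes, 16)
  expect_equal(nrow(rep1$layout), 16)
  expect_equal(nrow(rep1$comparison$summary), 6)
  expect_length(rep1$errors, 0)
  expect_equal(unname(rep1$manifest$n_per_wave),
               c(120L, 100L, 90L, 80L), ignore_attr = TRUE)
  # scale scores and reliability present for every wave
  expect_length(rep1$alpha, 4)
  expect_true(all(vapply(rep1$alpha, function(a) all(a > 0 & a <= 1),
                         logical(1))))
})

test_that("two runs with the same config write byte-identical bundles", {
  panel <- small_cohort(seed = 82)
  d1 <- file.path(tempdir(), "bundle1")
  d2 <- file.path(tempdir(), "bundle2")
  run_study(panel, fast_config(d1), stability = FALSE)
  run_study(panel, fast_config(d2), stability = FALSE)
  files <- list.files(d1)
  expect_true(length(files) > 5)
  for (f in setdiff(files, "manifest.json")) {
    b1 <- readBin(file.path(d1, f), "raw", file.size(file.path(d1, f)))
    b2 <- readBin(file.path(d2, f), "raw", file.size(file.path(d2, f)))
    expect_identical(b1, b2)
  }
  # manifests agree on everything except the output path itself
  m1 <- jsonlite::read_json(file.path(d1, "manifest.json"),
                            simplifyVector = TRUE)
  m2 <- jsonlite::read_json(file.path(d2, "manifest.json"),
                            simplifyVector = TRUE)
  m1$config$output_dir <- m2$config$output_dir <- NULL
  expect_identical(m1, m2)
})

test_that("stage failures are isolated and reported by name", {
  panel <- small_cohort(seed = 83)
  # break one wave: constant item => pearson fails for that wave only
  idx <- panel$wave == "T2"
  panel$phq1[idx] <- 1L
  rep1 <- run_study(panel, fast_config(), stability = FALSE)
  expect_true("network_T2" %in% names(rep1$errors))
  expect_false(is.null(rep1$networks$T1))
  expect_null(rep1$networks$T2)
  # downstream comparison depends on the broken wave and is reported too
  expect_true("comparison" %in% names(rep1$errors))
  expect_null(rep1$comparison)
})

test_that("a drift-free cohort from one fixed truth shows no spurious wave differences", {
  # zero wave drift: all waves sampled from the same model; the NCT should
  # find nothing after Bonferroni in the vast majority of cohorts
  clean <- 0
  for (s in 1:6) {
    spec <- cohort_spec(n_baseline = 150,
                        retention = c(T1 = 150, T2 = 140, T3 = 130,
                                      T4 = 120),
                        n_completers = 120,
                        wave_effects = matrix(0, 4, 16,
                                              dimnames = list(WAVES,
                                                              symptom_nodes())),
                        seed = 600 + s)
    panel <- generate_cohort(spec)
    cw <- compare_waves(panel, n_perm = 120, seed = s,
                        config = symptomnet:::default_estimator(gamma = 0))
    clean <- clean + (!any(cw$summary$structure_significant) &&
                        !any(cw$summary$strength_significant))
  }
  expect_gte(clean, 5)
})

test_that("the run config records every seed and round-trips through JSON", {
  cfg <- fast_config()
  expect_setequal(names(cfg$seeds), c("layout", "bootstrap", "nct"))
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(unclass(cfg), f, auto_unbox = TRUE, digits = NA,
                       null = "null")
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$bootstrap_B, cfg$bootstrap_B)
  expect_equal(back$drop_proportions, cfg$drop_proportions)
  expect_equal(back$seeds$nct, cfg$seeds$nct)
})
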