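# Small panel fixtures built in code.

# minimal panel: given a matrix of item scores per participant-wave row
make_panel <- function(ids, waves, scores, age = 30) {
  df <- data.frame(participant_id = ids, wave = waves, age = age,
                   stringsAsFactors = FALSE)
  scores <- matrix(scores, nrow = length(ids), ncol = 16,
                   dimnames = NULL)
  df[, c(paste0("phq", 1:9), paste0("gad", 1:7))] <- scores
  item_panel(df, validate = FALSE)
}

# a small but well-behaved cohort for pipeline tests: strong structure,
# quick to estimate
small_cohort <- function(seed = 1, n = c(T1 = 120, T2 = 100, T3 = 90,
                                         T4 = 80), completers = 78) {
  spec <- cohort_spec(n_baseline = unname(n[1]), retention = n,
                      n_completers = completers, seed = seed)
  generate_cohort(spec)
}
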