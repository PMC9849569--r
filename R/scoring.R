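#' Questionnaire total scores and clinical cutoff flags
#'
#' Sums the nine depression items (PHQ-9 total, 0-27) and the seven
#' anxiety items (GAD-7 total, 0-21) for every participant-wave and flags
#' totals at or above the clinical cutoff of 10.  A participant with any
#' missing item on a scale at a wave gets no score for that scale-wave.
#'
#' @param panel An [item_panel()].
#' @param cutoff Clinical cutoff applied to both totals (default 10).
#' @return Data frame `participant_id, wave, phq_total, phq_above_cutoff,
#'   gad_total, gad_above_cutoff`; totals are NA where items are missing.
#' @export
total_scores <- function(panel, cutoff = 10) {
  phq <- as.matrix(panel[, paste0("phq", 1:9)])
  gad <- as.matrix(panel[, paste0("gad", 1:7)])
  phq_total <- ifelse(apply(is.na(phq), 1, any), NA_integer_,
                      rowSums(phq))
  gad_total <- ifelse(apply(is.na(gad), 1, any), NA_integer_,
                      rowSums(gad))
  data.frame(participant_id = panel$participant_id, wave = panel$wave,
             phq_total = as.integer(phq_total),
             phq_above_cutoff = phq_total >= cutoff,
             gad_total = as.integer(gad_total),
             gad_above_cutoff = gad_total >= cutoff,
             stringsAsFactors = FALSE)
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability
#' \deqn{\alpha = \frac{k}{k-1}\left(1 - \frac{\sum_i V(x_i)}{V(\sum_i x_i)}\right)}
#' with sample (n-1 denominator) variances throughout.
#'
#' @param x Numeric matrix, respondents x items (>= 2 of each).
#' @return Scalar alpha.
#' @export
cronbach_alpha <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 items")
  if (nrow(x) < 2) stop("need at least 2 respondents")
  if (anyNA(x)) stop("complete cases required")
  k <- ncol(x)
  v_items <- sum(apply(x, 2, var))
  v_total <- var(rowSums(x))
  if (v_total == 0) stop("zero total-score variance: alpha undefined")
  (k / (k - 1)) * (1 - v_items / v_total)
}
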