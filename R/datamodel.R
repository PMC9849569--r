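#' @useDynLib symptomnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor cov dnorm pnorm qnorm rnorm runif rbinom plogis
#'   optimize setNames sd var quantile
#' @importFrom utils read.csv write.csv head
NULL

# Canonical node order: PHQ-9 depression items then GAD-7 anxiety items.
# Short reference names follow the usual symptom-network convention.
PHQ_NODES <- c("Anh", "Sdn", "Slp", "Enr", "App", "Glt", "Cnc", "Mtr", "Scd")
GAD_NODES <- c("Nrv", "Cnt", "Wrr", "Rlx", "Rst", "Irr", "Afr")
WAVES <- c("T1", "T2", "T3", "T4")
ITEM_COLS <- c(paste0("phq", 1:9), paste0("gad", 1:7))

#' Canonical symptom node labels
#'
#' Sixteen node labels in the fixed canonical order: the nine PHQ-9
#' depression items (Anh, Sdn, Slp, Enr, App, Glt, Cnc, Mtr, Scd) followed
#' by the seven GAD-7 anxiety items (Nrv, Cnt, Wrr, Rlx, Rst, Irr, Afr).
#' All matrices produced by the package use this order.
#'
#' @return Character vector of length 16.
#' @export
symptom_nodes <- function() c(PHQ_NODES, GAD_NODES)

#' Depression/anxiety community partition
#'
#' Fixed two-community assignment of the 16 symptom nodes: PHQ-9 items to
#' the depression community, GAD-7 items to the anxiety community.
#'
#' @param nodes Node labels; defaults to [symptom_nodes()].
#' @return Named character vector mapping node label to community.
#' @export
community_partition <- function(nodes = symptom_nodes()) {
  part <- ifelse(nodes %in% PHQ_NODES, "depression",
          ifelse(nodes %in% GAD_NODES, "anxiety", NA_character_))
  if (anyNA(part)) stop("unknown node labels: ",
                        paste(nodes[is.na(part)], collapse = ", "))
  setNames(part, nodes)
}

#' Construct an item panel
#'
#' An `item_panel` is a long-format table with one row per participant-wave:
#' columns `participant_id`, `wave` (one of T1-T4), `age` (years, optional
#' covariate, may be NA) and the 16 item scores `phq1..phq9, gad1..gad7`,
#' each an integer in 0-3 or NA for a missing response.  A participant with
#' no row at a wave is treated as absent (dropped out) at that wave.
#'
#' @param df Data frame with the columns above.
#' @param validate Run [validate_panel()] on the result (default TRUE).
#' @return The data frame with class `item_panel`.
#' @export
item_panel <- function(df, validate = TRUE) {
  needed <- c("participant_id", "wave", "age", ITEM_COLS)
  if (!"age" %in% names(df)) df$age <- NA_real_
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0)
    stop("panel is missing columns: ", paste(missing_cols, collapse = ", "))
  df <- df[, needed]
  df$participant_id <- as.character(df$participant_id)
  df$wave <- as.character(df$wave)
  class(df) <- c("item_panel", "data.frame")
  if (validate) validate_panel(df) else df
}

#' Validate an item panel
#'
#' Checks the panel invariants: every item score is an integer in 0-3 or
#' NA, wave labels are among T1-T4, and no participant appears twice at the
#' same wave.  Violations are reported with the offending row indices.
#'
#' @param panel An [item_panel()].
#' @return The panel, unchanged, if valid; otherwise an error listing every
#'   violating row.
#' @export
validate_panel <- function(panel) {
  problems <- character(0)
  bad_wave <- which(!panel$wave %in% WAVES)
  if (length(bad_wave) > 0)
    problems <- c(problems, paste0("unknown wave label in rows: ",
                                   paste(bad_wave, collapse = ", ")))
  scores <- as.matrix(panel[, ITEM_COLS])
  ok <- is.na(scores) | (scores %in% 0:3 & scores == round(scores))
  bad_rows <- which(apply(!ok, 1, any))
  if (length(bad_rows) > 0)
    problems <- c(problems, paste0("item score outside {0,1,2,3} in rows: ",
                                   paste(bad_rows, collapse = ", ")))
  key <- paste(panel$participant_id, panel$wave)
  dup <- which(duplicated(key))
  if (length(dup) > 0)
    problems <- c(problems,
                  paste0("duplicate participant-wave pairs (rows ",
                         paste(dup, collapse = ", "), "): ",
                         paste(unique(key[dup]), collapse = ", ")))
  if (length(problems) > 0)
    stop("invalid item panel:\n  ", paste(problems, collapse = "\n  "))
  panel
}

#' Complete cases at one wave
#'
#' Returns the item-score matrix of all participants with a fully observed
#' response vector at the given wave (listwise deletion; the estimation
#' sample size therefore varies by wave).
#'
#' @param panel An [item_panel()].
#' @param wave Wave label, one of `"T1".."T4"`.
#' @return Integer matrix (participants x 16) with participant ids as row
#'   names; attribute `n` records the number of rows.
#' @export
complete_cases <- function(panel, wave) {
  if (!wave %in% panel$wave) stop("wave ", wave, " not present in panel")
  rows <- panel[panel$wave == wave, , drop = FALSE]
  scores <- as.matrix(rows[, ITEM_COLS])
  keep <- !apply(is.na(scores), 1, any)
  if (!any(keep)) stop("no complete cases at wave ", wave)
  out <- scores[keep, , drop = FALSE]
  storage.mode(out) <- "integer"
  rownames(out) <- rows$participant_id[keep]
  colnames(out) <- symptom_nodes()
  attr(out, "n") <- nrow(out)
  attr(out, "wave") <- wave
  out
}

#' Read an item panel from CSV
#'
#' Expects the canonical wide dialect: one row per participant-wave with a
#' mandatory header `participant_id, wave, age, phq1..phq9, gad1..gad7`;
#' an empty field is a missing value.
#'
#' @param path CSV file path.
#' @param validate Validate the parsed panel (default TRUE).
#' @return An [item_panel()].
#' @export
read_panel <- function(path, validate = TRUE) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(participant_id = "character",
                                wave = "character"))
  item_panel(df, validate = validate)
}

#' Write an item panel to CSV
#'
#' Inverse of [read_panel()]: canonical column order, mandatory header,
#' empty field for missing values, UTF-8.
#'
#' @param panel An [item_panel()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  write.csv(as.data.frame(panel), path, row.names = FALSE, quote = FALSE,
            na = "")
  invisible(path)
}

#' @export
print.item_panel <- function(x, ...) {
  cat("<item_panel> ", length(unique(x$participant_id)), " participants, ",
      nrow(x), " participant-wave rows\n", sep = "")
  tab <- table(factor(x$wave, levels = WAVES))
  cat("  rows per wave:", paste(names(tab), tab, sep = "=", collapse = " "),
      "\n")
  invisible(x)
}

# integer codes 0..3 for the four equally spaced assessment occasions
wave_code <- function(wave) match(wave, WAVES) - 1L
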