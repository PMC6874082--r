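# CSV and JSON I/O with strict schema validation. Numeric formatting in
# derived CSVs is pinned (adjustments with 6 decimals) so file-level diffs
# are meaningful across runs.

trial_cols <- c("participant_id", "school", "condition", "block_position",
                "round", "E1", "X", "E2", "true_count")

participant_cols <- c("participant_id", "school", "age", "gender",
                      "household", "cohabiting_aunts_uncles", "block_order")

validate_trials <- function(trials, max_round = 5L) {
  if (!all(trial_cols %in% names(trials))) {
    stop_format(sprintf("trial table must have columns: %s",
                        paste(trial_cols, collapse = ", ")))
  }
  bad_row <- function(cond, what) {
    i <- which(cond)
    if (length(i)) {
      stop_format(sprintf("%s at data row %d", what, i[1]))
    }
  }
  for (col in c("E1", "X", "E2")) {
    v <- trials[[col]]
    bad_row(is.na(v) | v < 1 | v != round(v),
            sprintf("%s must be a positive integer", col))
  }
  bad_row(trials$X == trials$E1, "X must differ from E1")
  bad_row(!trials$condition %in% c("peer", "adult"),
          "condition must be 'peer' or 'adult'")
  bad_row(!trials$block_position %in% c(1L, 2L),
          "block_position must be 1 or 2")
  bad_row(is.na(trials$round) | trials$round < 1 | trials$round > max_round,
          sprintf("round must lie in 1..%d", max_round))
  bad_row(is.na(trials$true_count) | trials$true_count < 1,
          "true_count must be a positive integer")
  invisible(trials)
}

#' Read and write trial tables
#'
#' One row per participant x condition x round with columns
#' `participant_id`, `school`, `condition`, `block_position`, `round`,
#' `E1`, `X`, `E2`, `true_count`. Both directions validate the schema
#' strictly (positive integer estimates, `X != E1`, closed vocabularies)
#' and report the first offending data row.
#'
#' @param trials Trial tibble.
#' @param path CSV path.
#' @param max_round Largest admissible round index (default 5).
#' @return `write_trials()` returns `path` invisibly; `read_trials()` the
#'   validated tibble.
#' @export
write_trials <- function(trials, path, max_round = 5L) {
  trials <- as_tibble(trials)[, trial_cols]
  validate_trials(trials, max_round)
  readr::write_csv(trials, path)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path, max_round = 5L) {
  if (!file.exists(path)) stop_format(sprintf("trials file not found: %s", path))
  trials <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    school = readr::col_character(),
    condition = readr::col_character(),
    block_position = readr::col_integer(),
    round = readr::col_integer(),
    E1 = readr::col_double(),
    X = readr::col_double(),
    E2 = readr::col_double(),
    true_count = readr::col_integer()
  ), progress = FALSE)
  validate_trials(trials, max_round)
  trials$E1 <- as.integer(trials$E1)
  trials$X <- as.integer(trials$X)
  trials$E2 <- as.integer(trials$E2)
  trials
}

validate_participants <- function(p, age_range = c(11L, 15L)) {
  if (!all(participant_cols %in% names(p))) {
    stop_format(sprintf("participants table must have columns: %s",
                        paste(participant_cols, collapse = ", ")))
  }
  bad_row <- function(cond, what) {
    i <- which(cond)
    if (length(i)) stop_format(sprintf("%s at data row %d", what, i[1]))
  }
  bad_row(!p$household %in% c("nuclear", "extended"),
          "household must be 'nuclear' or 'extended'")
  bad_row(!p$gender %in% c("male", "female"),
          "gender must be 'male' or 'female'")
  bad_row(!p$block_order %in% c("peer_first", "adult_first"),
          "block_order must be 'peer_first' or 'adult_first'")
  bad_row(is.na(p$age) | p$age < age_range[1] | p$age > age_range[2],
          sprintf("age must lie in %d..%d", age_range[1], age_range[2]))
  bad_row(duplicated(p$participant_id), "duplicated participant_id")
  invisible(p)
}

#' Read and write participant profiles
#'
#' Columns `participant_id`, `school`, `age`, `gender`, `household`,
#' `cohabiting_aunts_uncles`, `block_order`, validated against the closed
#' vocabularies and the 11--15 age support.
#'
#' @param profiles Profile tibble from [sample_cohort()].
#' @param path CSV path.
#' @param age_range Admissible age bounds.
#' @return `write_participants()` returns `path` invisibly;
#'   `read_participants()` the validated tibble.
#' @export
write_participants <- function(profiles, path, age_range = c(11L, 15L)) {
  profiles <- as_tibble(profiles)[, participant_cols]
  validate_participants(profiles, age_range)
  readr::write_csv(profiles, path)
  invisible(path)
}

#' @rdname write_participants
#' @export
read_participants <- function(path, age_range = c(11L, 15L)) {
  if (!file.exists(path)) {
    stop_format(sprintf("participants file not found: %s", path))
  }
  p <- readr::read_csv(path, col_types = readr::cols(
    participant_id = readr::col_character(),
    school = readr::col_character(),
    age = readr::col_integer(),
    gender = readr::col_character(),
    household = readr::col_character(),
    cohabiting_aunts_uncles = readr::col_logical(),
    block_order = readr::col_character()
  ), progress = FALSE)
  validate_participants(p, age_range)
  p
}

#' Write adjustment records and participant summaries
#'
#' Adjustment records are written with `s` fixed to 6 decimals; summaries
#' with `S_peer`/`S_adult` fixed to 6 decimals, so repeated runs under the
#' same seed produce byte-identical files.
#'
#' @param records Adjustment records from [compute_adjustments()].
#' @param summaries [participant_summaries()] output.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_adjustments <- function(records, path) {
  out <- as_tibble(records)
  out$s <- formatC(out$s, digits = 6, format = "f")
  out$category <- as.character(out$category)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_adjustments
#' @export
write_summaries <- function(summaries, path) {
  out <- as_tibble(summaries)
  for (col in c("S_peer", "S_adult")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         formatC(out[[col]], digits = 6, format = "f"))
  }
  readr::write_csv(out, path)
  invisible(path)
}

write_results_json <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = 10,
                       null = "null", pretty = TRUE)
  invisible(path)
}
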