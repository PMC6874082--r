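# Measurement layer: per-round adjustment s, heuristic classification,
# validity filtering, per-participant condition means S, and accuracy
# deviations. Category boundaries are exact equality tests: s is a ratio of
# integer differences, so s == 0 and s == 1 are exact in floating point.

.categories <- c("contrarian", "stay", "compromise", "copy", "overshoot")

#' Per-round adjustment toward social information
#'
#' `s = (E2 - E1) / (X - E1)`: the fraction of the distance from the first
#' estimate toward the displayed social information covered by the second
#' estimate. Vectorised.
#'
#' @param E1,X,E2 Integer first estimate, displayed social information and
#'   second estimate; `X` must differ from `E1` everywhere.
#' @return Numeric adjustment(s).
#' @examples
#' adjustment_s(40, 50, 45) # 0.5
#' @export
adjustment_s <- function(E1, X, E2) {
  if (any(X == E1)) {
    stop_undefined_adjustment("adjustment undefined where X equals E1")
  }
  (E2 - E1) / (X - E1)
}

#' Classify an adjustment into a heuristic category
#'
#' `stay` at s = 0, `copy` at s = 1, `compromise` on 0 < s < 1,
#' `contrarian` below 0 and `overshoot` above 1. Boundaries are exact
#' (no epsilon), which is well defined because s is a ratio of integers.
#'
#' @param s Numeric adjustment(s), finite.
#' @return Factor with levels contrarian, stay, compromise, copy,
#'   overshoot.
#' @export
classify_adjustment <- function(s) {
  if (!is.numeric(s) || any(!is.finite(s))) {
    stop_invalid("`s` must be finite numeric")
  }
  out <- ifelse(s < 0, "contrarian",
                ifelse(s == 0, "stay",
                       ifelse(s < 1, "compromise",
                              ifelse(s == 1, "copy", "overshoot"))))
  factor(out, levels = .categories)
}

#' Score a trial table with adjustments, categories and validity
#'
#' Adds `s`, `category` and `valid` columns to a trial table under the
#' chosen policy (see [filter_valid()]).
#'
#' @param trials Trial table with columns `E1`, `X`, `E2`.
#' @param policy Validity policy: `"omit"` (default), `"include"` or
#'   `"clip"`.
#' @return The scored tibble of adjustment records.
#' @export
compute_adjustments <- function(trials, policy = c("omit", "include", "clip")) {
  policy <- match.arg(policy)
  if (!all(c("E1", "X", "E2") %in% names(trials))) {
    stop_invalid("`trials` must contain E1, X and E2 columns")
  }
  records <- dplyr::mutate(as_tibble(trials),
                           s = adjustment_s(.data$E1, .data$X, .data$E2),
                           category = classify_adjustment(.data$s))
  filter_valid(records, policy)
}

#' Apply a validity policy to adjustment records
#'
#' `omit` (default) marks rounds with s < 0 or s > 1 invalid, reproducing
#' the primary filtering rule; `include` keeps every round; `clip`
#' replaces s by the nearest value in \[0, 1\] (re-classifying the clipped
#' rounds) and keeps everything, mirroring the robustness recoding.
#'
#' @param records Tibble carrying an `s` column.
#' @param policy `"omit"`, `"include"` or `"clip"`.
#' @return `records` with `valid` (and, under `clip`, modified `s` and
#'   `category`).
#' @export
filter_valid <- function(records, policy = c("omit", "include", "clip")) {
  if (is.character(policy) && length(policy) == 1L &&
      !policy %in% c("omit", "include", "clip")) {
    stop_invalid(sprintf("unknown filter policy '%s'", policy))
  }
  policy <- match.arg(policy)
  if (!"s" %in% names(records)) {
    stop_invalid("`records` must carry an `s` column")
  }
  records <- as_tibble(records)
  if (policy == "clip") {
    records$s <- pmin(1, pmax(0, records$s))
    records$category <- classify_adjustment(records$s)
    records$valid <- TRUE
  } else if (policy == "include") {
    records$valid <- TRUE
  } else {
    records$valid <- records$s >= 0 & records$s <= 1
  }
  if (!"category" %in% names(records)) {
    records$category <- classify_adjustment(records$s)
  }
  records
}

#' Per-participant condition means of the adjustment
#'
#' Averages valid rounds per participant and condition into `S_peer` and
#' `S_adult`. A condition with no valid rounds yields `NA` (that
#' participant contributes no row for the condition downstream).
#'
#' @param records Adjustment records from [compute_adjustments()] (must
#'   carry `participant_id`, `condition`, `s`, `valid`).
#' @return Tibble with `participant_id`, `S_peer`, `S_adult`,
#'   `n_valid_peer`, `n_valid_adult`.
#' @export
participant_summaries <- function(records) {
  need <- c("participant_id", "condition", "s", "valid")
  if (!all(need %in% names(records))) {
    stop_invalid("`records` must carry participant_id, condition, s, valid")
  }
  long <- records |>
    dplyr::group_by(.data$participant_id, .data$condition) |>
    dplyr::summarise(
      n_valid = sum(.data$valid),
      S = ifelse(sum(.data$valid) > 0, mean(.data$s[.data$valid]), NA_real_),
      .groups = "drop"
    )
  wide <- tidyr::pivot_wider(long, names_from = "condition",
                             values_from = c("S", "n_valid"),
                             names_sep = "_")
  for (col in c("S_peer", "S_adult")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  for (col in c("n_valid_peer", "n_valid_adult")) {
    if (!col %in% names(wide)) wide[[col]] <- 0L
    wide[[col]][is.na(wide[[col]])] <- 0L
    wide[[col]] <- as.integer(wide[[col]])
  }
  wide[, c("participant_id", "S_peer", "S_adult",
           "n_valid_peer", "n_valid_adult")]
}

#' Predicted second estimate under a weight S
#'
#' The convex combination `(1 - S) * E1 + S * X`.
#'
#' @param E1,X Integer estimates.
#' @param S Weight in \[0, 1\].
#' @return Real predicted second estimate(s).
#' @export
predicted_second_estimate <- function(E1, X, S) {
  if (any(!is.finite(S)) || any(S < 0) || any(S > 1)) {
    stop_invalid("`S` must lie in [0, 1]")
  }
  (1 - S) * E1 + S * X
}

#' Heuristic category frequencies
#'
#' Pools classified rounds (both conditions by default sit in the same
#' table) and reports category proportions. The denominator is either all
#' classified rounds (`all_rounds`, default) or only rounds with
#' 0 <= s <= 1 (`valid_rounds`); both are exposed because observed
#' percentages depend on this choice.
#'
#' @param records Records carrying `s` and `category`.
#' @param pooling `"all_rounds"` or `"valid_rounds"`.
#' @return Tibble with `category`, `n`, `proportion` (all five categories
#'   always present).
#' @export
heuristic_frequencies <- function(records,
                                  pooling = c("all_rounds", "valid_rounds")) {
  pooling <- match.arg(pooling)
  if (!"category" %in% names(records) || nrow(records) == 0L) {
    stop_invalid("`records` must be non-empty classified adjustment records")
  }
  if (pooling == "valid_rounds") {
    records <- records[records$s >= 0 & records$s <= 1, ]
    if (nrow(records) == 0L) {
      stop_invalid("no rounds remain under valid_rounds pooling")
    }
  }
  counts <- table(factor(records$category, levels = .categories))
  tibble(
    category = factor(.categories, levels = .categories),
    n = as.integer(counts),
    proportion = as.numeric(counts) / nrow(records)
  )
}

#' Long table of deviations from the true count
#'
#' Two rows per trial (`period` first/second) with the deviation of the
#' corresponding estimate from the true count; feeds the accuracy mixed
#' model.
#'
#' @param trials Trial table with `E1`, `E2`, `true_count`.
#' @param signed If `FALSE` (default) absolute deviations; if `TRUE`
#'   signed `estimate - true_count`.
#' @return Long tibble with the trial identifiers plus `period` and
#'   `deviation`.
#' @export
deviation_table <- function(trials, signed = FALSE) {
  need <- c("E1", "E2", "true_count")
  if (!all(need %in% names(trials))) {
    stop_invalid("`trials` must contain E1, E2 and true_count")
  }
  dev <- function(est) {
    if (signed) est - trials$true_count else abs(est - trials$true_count)
  }
  keep <- intersect(c("participant_id", "school", "condition", "round",
                      "true_count"), names(trials))
  base <- as_tibble(trials)[, keep]
  dplyr::bind_rows(
    dplyr::mutate(base, period = "first", deviation = dev(trials$E1)),
    dplyr::mutate(base, period = "second", deviation = dev(trials$E2))
  )
}
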