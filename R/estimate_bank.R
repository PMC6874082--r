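# Pre-recorded estimate bank: the pool of first estimates (collected without
# social information) from which displayed values are drawn by nearest-target
# snapping. Default construction mirrors the original sample: 24 adults and
# 14 students, each completing 6 iterations of the 5 rounds, i.e. 144 adult
# and 84 student estimates per round.

new_estimate_bank <- function(entries, schedule = NULL,
                              provenance = c("simulated", "loaded")) {
  provenance <- match.arg(provenance)
  structure(
    list(entries = entries, provenance = provenance),
    schedule = schedule,
    class = "estimate_bank"
  )
}

#' Build a simulated pre-recorded estimate bank
#'
#' Each simulated bank member produces one first estimate per round and
#' iteration from the first-estimate model (no social information, no
#' feedback; iterations are independent draws). Adults and students share
#' the same estimation model unless separate parameter sets are supplied.
#'
#' @param schedule Stimulus schedule from [make_stimulus_schedule()]; the
#'   bank stores it so downstream sessions see the same true counts.
#' @param n_adults,n_students Number of bank members per source type
#'   (defaults 24 and 14).
#' @param n_iterations Iterations of the round schedule per member
#'   (default 6).
#' @param params [agent_params()] for adult members.
#' @param student_params Optional separate parameters for student members;
#'   defaults to `params`.
#' @param seed Optional seed.
#' @return An `estimate_bank` whose `entries` tibble has columns `round`,
#'   `source_type` (`adult`/`student`) and `estimate`.
#' @examples
#' bank <- build_bank(make_stimulus_schedule(seed = 1), seed = 2)
#' bank_counts(bank, 1) # 144 adult, 84 student
#' @export
build_bank <- function(schedule, n_adults = 24, n_students = 14,
                       n_iterations = 6, params = agent_params(),
                       student_params = params, seed = NULL) {
  n_adults <- check_scalar_count(n_adults, "n_adults", min = 0L)
  n_students <- check_scalar_count(n_students, "n_students", min = 0L)
  n_iterations <- check_scalar_count(n_iterations, "n_iterations")
  if (n_adults + n_students < 1L) {
    stop_invalid("the bank needs at least one member")
  }
  if (!is.data.frame(schedule) || !all(c("round_index", "true_count") %in% names(schedule))) {
    stop_invalid("`schedule` must come from make_stimulus_schedule()")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  one_source <- function(n_members, src, p) {
    if (n_members == 0L) return(NULL)
    # members x iterations independent draws per round, vectorised
    tc <- rep(schedule$true_count, each = n_members * n_iterations)
    tibble(
      round = rep(schedule$round_index, each = n_members * n_iterations),
      source_type = src,
      estimate = first_estimate(tc, p)
    )
  }
  entries <- dplyr::bind_rows(
    one_source(n_adults, "adult", params),
    one_source(n_students, "student", student_params)
  )
  new_estimate_bank(entries, schedule = schedule, provenance = "simulated")
}

#' @export
print.estimate_bank <- function(x, ...) {
  n <- table(x$entries$source_type)
  rounds <- sort(unique(x$entries$round))
  cat(sprintf(
    "<estimate_bank> %s; rounds %s; %s entries (%s)\n",
    x$provenance, paste(range(rounds), collapse = "-"),
    nrow(x$entries),
    paste(sprintf("%s %s", n, names(n)), collapse = ", ")
  ))
  invisible(x)
}

#' Entry counts per source for one round
#'
#' @param bank An `estimate_bank`.
#' @param round_index Round to count (must exist in the bank).
#' @return Named integer vector `c(n_adult, n_student)`.
#' @export
bank_counts <- function(bank, round_index) {
  stopifnot(inherits(bank, "estimate_bank"))
  round_index <- check_scalar_count(round_index, "round_index")
  if (!round_index %in% bank$entries$round) {
    stop_invalid(sprintf("round %d is not present in the bank", round_index))
  }
  e <- bank$entries[bank$entries$round == round_index, ]
  c(n_adult = sum(e$source_type == "adult"),
    n_student = sum(e$source_type == "student"))
}

#' Candidate estimates for one (round, source) cell
#'
#' @inheritParams bank_counts
#' @param source_type `"adult"` or `"student"`.
#' @return Integer vector of candidate estimates (possibly with repeats;
#'   the bank is a multiset).
#' @export
bank_entries <- function(bank, round_index, source_type = c("adult", "student")) {
  source_type <- match.arg(source_type)
  stopifnot(inherits(bank, "estimate_bank"))
  round_index <- check_scalar_count(round_index, "round_index")
  e <- bank$entries
  out <- e$estimate[e$round == round_index & e$source_type == source_type]
  if (length(out) == 0L) {
    stop_invalid(sprintf("bank has no %s entries for round %d",
                         source_type, round_index))
  }
  out
}

# round -> list(adult = ..., student = ...) numeric vectors for the hot loop
split_bank <- function(bank) {
  stopifnot(inherits(bank, "estimate_bank"))
  e <- bank$entries
  lapply(sort(unique(e$round)), function(r) {
    list(
      adult = as.numeric(e$estimate[e$round == r & e$source_type == "adult"]),
      student = as.numeric(e$estimate[e$round == r & e$source_type == "student"])
    )
  })
}

#' Save or load an estimate bank as CSV
#'
#' The on-disk format has columns `round`, `source_type` (`adult` or
#' `student`) and `estimate` (positive integer). `save_bank()` then
#' `load_bank()` reproduces the bank's entries exactly; the attached
#' schedule is not serialised, so sessions using a loaded bank must be
#' given a schedule explicitly.
#'
#' @param bank An `estimate_bank`.
#' @param path CSV file path.
#' @return `save_bank()` returns `path` invisibly; `load_bank()` returns an
#'   `estimate_bank` with provenance `"loaded"`.
#' @export
save_bank <- function(bank, path) {
  stopifnot(inherits(bank, "estimate_bank"))
  readr::write_csv(bank$entries, path)
  invisible(path)
}

#' @rdname save_bank
#' @export
load_bank <- function(path) {
  if (!file.exists(path)) {
    stop_format(sprintf("bank file not found: %s", path))
  }
  e <- readr::read_csv(path, col_types = readr::cols(
    round = readr::col_integer(),
    source_type = readr::col_character(),
    estimate = readr::col_double()
  ), progress = FALSE)
  if (!identical(names(e), c("round", "source_type", "estimate"))) {
    stop_format("bank CSV must have columns round, source_type, estimate")
  }
  bad_src <- which(!e$source_type %in% c("adult", "student"))
  if (length(bad_src)) {
    stop_format(sprintf("unknown source_type %s at data row %d",
                        e$source_type[bad_src[1]], bad_src[1]))
  }
  bad_est <- which(is.na(e$estimate) | e$estimate < 1 |
                     e$estimate != round(e$estimate))
  if (length(bad_est)) {
    stop_format(sprintf("estimate must be a positive integer at data row %d",
                        bad_est[1]))
  }
  bad_round <- which(is.na(e$round) | e$round < 1)
  if (length(bad_round)) {
    stop_format(sprintf("invalid round at data row %d", bad_round[1]))
  }
  e$estimate <- as.integer(e$estimate)
  new_estimate_bank(as_tibble(e), schedule = NULL, provenance = "loaded")
}
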