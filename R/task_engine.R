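# Task engine: stimulus schedule, target-value rule, nearest-bank selection
# of displayed social information, payoffs, and the per-participant session.

# cosmetic species labels; a different species is shown in every round only to
# prevent image memory, so labels carry no behavioural meaning
.species_pool <- c(
  "ants", "bees", "butterflies", "crabs", "deer", "fish", "flamingos",
  "geese", "goats", "penguins", "seals", "sheep", "starlings", "zebras"
)

#' Relative displacement schedule for displayed social information
#'
#' The round-wise relative offsets \eqn{\Delta} used to place the target
#' social-information value 15--25\% away from a participant's first
#' estimate. The default is the fixed five-round schedule
#' (0.25, 0.15, 0.20, 0.15, 0.25).
#'
#' @param deltas Numeric vector of offsets, each in \[0.15, 0.25\].
#' @return The validated numeric schedule.
#' @examples
#' delta_schedule()
#' @export
delta_schedule <- function(deltas = c(0.25, 0.15, 0.20, 0.15, 0.25)) {
  if (!is.numeric(deltas) || length(deltas) < 1L || anyNA(deltas)) {
    stop_invalid("`deltas` must be a non-empty numeric vector")
  }
  if (any(deltas < 0.15 - 1e-12) || any(deltas > 0.25 + 1e-12)) {
    stop_invalid("every delta must lie in [0.15, 0.25]")
  }
  deltas
}

#' Generate a stimulus schedule
#'
#' Draws one stimulus per round: an integer true animal count uniform on
#' `true_count_min:true_count_max` (default 50--60), a distinct cosmetic
#' species label, and the 6-second display duration. Deterministic given
#' `seed`.
#'
#' @param n_rounds Number of rounds (default 5).
#' @param true_count_min,true_count_max Inclusive bounds of the true count.
#' @param seed Optional integer seed; if `NULL` the ambient RNG is used.
#' @return A tibble with columns `round_index`, `true_count`,
#'   `species_label`, `display_seconds`.
#' @examples
#' make_stimulus_schedule(seed = 1)
#' @export
make_stimulus_schedule <- function(n_rounds = 5, true_count_min = 50,
                                   true_count_max = 60, seed = NULL) {
  n_rounds <- check_scalar_count(n_rounds, "n_rounds")
  true_count_min <- check_scalar_count(true_count_min, "true_count_min")
  true_count_max <- check_scalar_count(true_count_max, "true_count_max")
  if (true_count_max < true_count_min) {
    stop_invalid("`true_count_max` must be >= `true_count_min`")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  species <- if (n_rounds <= length(.species_pool)) {
    sample(.species_pool, n_rounds)
  } else {
    # distinctness kept by suffixing when more rounds than base labels
    paste0(sample(.species_pool, n_rounds, replace = TRUE), "_", seq_len(n_rounds))
  }
  tibble(
    round_index = seq_len(n_rounds),
    true_count = sample(true_count_min:true_count_max, n_rounds, replace = TRUE),
    species_label = species,
    display_seconds = 6L
  )
}

# scalar core; may consume one uniform when E1 equals the true count
target_value_impl <- function(E1, true_count, delta) {
  if (E1 < true_count) {
    E1 * (1 + delta)
  } else if (E1 > true_count) {
    E1 * (1 - delta)
  } else if (runif(1) < 0.5) {
    E1 * (1 - delta)
  } else {
    E1 * (1 + delta)
  }
}

#' Target social-information value
#'
#' Computes the target value X' toward which displayed social information is
#' steered: `E1 * (1 + delta)` when the first estimate is below the true
#' count, `E1 * (1 - delta)` when above, and a fair coin flip between the
#' two when the first estimate is exactly correct. X' is kept real-valued;
#' the bank-snapping step ([select_social_info()]) produces the integer
#' actually displayed.
#'
#' @param E1 First estimate (positive integer).
#' @param true_count True animal count.
#' @param delta Relative offset in (0, 1), from the round's
#'   [delta_schedule()].
#' @return The real-valued target X'.
#' @examples
#' target_social_value(100, 150, 0.25) # 125
#' @export
target_social_value <- function(E1, true_count, delta) {
  if (length(E1) != 1L || !is_wholenumber(E1) || E1 < 1) {
    stop_invalid("`E1` must be a single integer >= 1")
  }
  true_count <- check_scalar_count(true_count, "true_count")
  if (length(delta) != 1L || !is.numeric(delta) || delta <= 0 || delta >= 1) {
    stop_invalid("`delta` must be a single number in (0, 1)")
  }
  target_value_impl(as.numeric(E1), as.numeric(true_count), delta)
}

# nearest-candidate snap: candidates equal to E1 are excluded so that the
# adjustment s = (E2 - E1)/(X - E1) is always defined; exact-distance ties
# are broken by a uniform draw
pick_nearest_impl <- function(candidates, target, E1) {
  candidates <- candidates[candidates != E1]
  if (length(candidates) == 0L) {
    stop_no_social("no candidate social information differs from E1")
  }
  d <- abs(candidates - target)
  tied <- candidates[d <= min(d) + 1e-9]
  if (length(tied) == 1L) tied else tied[sample.int(length(tied), 1L)]
}

#' Select displayed social information from the estimate bank
#'
#' Computes the target value X' via [target_social_value()] and returns the
#' bank candidate closest to it. Candidates equal to `E1` are excluded
#' before the search (keeping the adjustment statistic defined); exact ties
#' are broken by a uniform draw from the ambient RNG.
#'
#' @inheritParams target_social_value
#' @param candidates Integer multiset of pre-recorded first estimates for
#'   this round and source type.
#' @return The selected integer X, never equal to `E1`.
#' @examples
#' select_social_info(100, 150, 0.25, candidates = c(110, 124, 130)) # 124
#' @export
select_social_info <- function(E1, true_count, delta, candidates) {
  if (!is_wholenumber(candidates) || any(candidates < 1)) {
    stop_invalid("`candidates` must be positive integers")
  }
  target <- target_social_value(E1, true_count, delta)
  as.integer(pick_nearest_impl(as.numeric(candidates), target, as.numeric(E1)))
}

#' Points earned by an estimate
#'
#' 100 points for an exactly correct estimate, minus 5 points per animal of
#' absolute error, floored at 0 (so any error of 20 or more earns nothing).
#' Vectorised over `estimate` and `true_count`.
#'
#' @param estimate Positive integer estimate(s).
#' @param true_count Positive integer true count(s).
#' @return Integer points in 0--100.
#' @examples
#' payoff_points(55, 55) # 100
#' payoff_points(45, 55) # 50
#' @export
payoff_points <- function(estimate, true_count) {
  if (!is_wholenumber(estimate) || any(estimate < 1)) {
    stop_invalid("`estimate` must be positive integers")
  }
  if (!is_wholenumber(true_count) || any(true_count < 1)) {
    stop_invalid("`true_count` must be positive integers")
  }
  as.integer(pmax(0, 100 - 5 * abs(estimate - true_count)))
}

#' Convert task points to compensation items
#'
#' Participants receive two items for participating plus one bonus item for
#' every completed 20 points earned (floor division).
#'
#' @param points Integer points in 0--100.
#' @return A tibble with columns `points`, `bonus_items`, `total_items`.
#' @examples
#' bonus_items(50) # 2 bonus items, 4 total
#' @export
bonus_items <- function(points) {
  if (!is_wholenumber(points) || any(points < 0) || any(points > 100)) {
    stop_invalid("`points` must be integers in [0, 100]")
  }
  points <- as.integer(points)
  tibble(points = points,
         bonus_items = points %/% 20L,
         total_items = points %/% 20L + 2L)
}

# Fast inner loop shared by run_session() and simulate_experiment().
# `bank_split` is the list produced by split_bank(); profile fields are
# pre-extracted scalars. Uses the ambient RNG throughout.
session_impl <- function(participant_id, school, block_order, extended,
                         params, bank_split, schedule, deltas) {
  n_rounds <- nrow(schedule)
  conds <- if (identical(block_order, "adult_first")) {
    c("adult", "peer")
  } else {
    c("peer", "adult")
  }
  n <- 2L * n_rounds
  condition <- character(n); block_position <- integer(n)
  round_idx <- integer(n); E1v <- integer(n); Xv <- integer(n)
  E2v <- integer(n); tcv <- integer(n)
  k <- 0L
  for (b in 1:2) {
    cond <- conds[b]
    adult <- cond == "adult"
    src <- if (adult) "adult" else "student"
    for (r in seq_len(n_rounds)) {
      tc <- schedule$true_count[r]
      E1 <- draw_first_estimate(tc, params)
      target <- target_value_impl(E1, tc, deltas[r])
      X <- pick_nearest_impl(bank_split[[r]][[src]], target, E1)
      s_star <- draw_heuristic_s(adult, extended, params)
      E2 <- max(1, round(E1 + s_star * (X - E1)))
      k <- k + 1L
      condition[k] <- cond; block_position[k] <- b; round_idx[k] <- r
      E1v[k] <- E1; Xv[k] <- X; E2v[k] <- E2; tcv[k] <- tc
    }
  }
  tibble(
    participant_id = participant_id, school = school,
    condition = condition, block_position = block_position,
    round = round_idx, E1 = E1v, X = Xv, E2 = E2v, true_count = tcv
  )
}

#' Run one participant's full session
#'
#' Plays both blocks (peer and adult, ordered by the profile's
#' `block_order`) of `nrow(schedule)` rounds each. Within a round the agent
#' produces a first estimate, the engine selects displayed social
#' information via the target-value rule and nearest-bank snap, and the
#' agent produces a second estimate. No feedback state is carried between
#' rounds.
#'
#' @param profile One-row participant tibble as produced by
#'   [sample_cohort()].
#' @param params [agent_params()] governing estimation and adjustment.
#' @param bank An [build_bank()] estimate bank covering every
#'   (round, source) pair.
#' @param schedule Stimulus schedule; defaults to the one the bank was
#'   built against.
#' @param deltas Displacement schedule, one entry per round.
#' @param seed Optional seed; if `NULL` the ambient RNG is used.
#' @return A tibble of `2 * nrow(schedule)` trial records with columns
#'   `participant_id`, `school`, `condition`, `block_position`, `round`,
#'   `E1`, `X`, `E2`, `true_count`.
#' @export
run_session <- function(profile, params, bank,
                        schedule = attr(bank, "schedule"),
                        deltas = delta_schedule(), seed = NULL) {
  if (!is.data.frame(profile) || nrow(profile) != 1L) {
    stop_invalid("`profile` must be a one-row data frame")
  }
  if (is.null(schedule)) {
    stop_invalid("no `schedule` supplied and the bank carries none")
  }
  if (length(deltas) != nrow(schedule)) {
    stop_invalid("`deltas` must have one entry per schedule round")
  }
  deltas <- delta_schedule(deltas)
  if (!is.null(seed)) withr::local_seed(seed)
  session_impl(
    participant_id = profile$participant_id,
    school = profile$school,
    block_order = profile$block_order,
    extended = identical(profile$household, "extended"),
    params = params,
    bank_split = split_bank(bank),
    schedule = schedule,
    deltas = deltas
  )
}
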