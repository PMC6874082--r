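# Synthetic cohort: demographics with exact margins and a heuristic-mixture
# behavioural model producing first and second estimates.
#
# First estimates follow a lognormal ratio model, E1 = round(true * exp(z)),
# z ~ N(bias_mu, bias_sigma); the default bias_mu is log(0.9) - sigma^2/2 so
# the expected ratio E1/true is exactly 0.90 (about 10% underestimation).
#
# Second estimates draw an adjustment heuristic per trial: stay (s = 0),
# copy (s = 1), contrarian (fixed s < 0), overshoot (fixed s > 1), or
# compromise with s from a Beta law on (0, 1) parameterised by mean and
# precision. The adult condition raises adjustments through a stay->copy
# probability swap plus `adult_shift` on the compromise mean; extended
# households add `household_shift` (0 by default, the null the experiment
# failed to reject).

as_condition_pair <- function(x, name) {
  if (length(x) == 1L && is.null(names(x))) {
    x <- c(peer = unname(x), adult = unname(x))
  }
  if (length(x) != 2L || !all(c("peer", "adult") %in% names(x))) {
    stop_invalid(sprintf("`%s` must be a scalar or a named c(peer=, adult=) pair", name))
  }
  if (!is.numeric(x) || any(x < 0) || any(x > 1)) {
    stop_invalid(sprintf("`%s` must contain probabilities in [0, 1]", name))
  }
  x[c("peer", "adult")]
}

#' Generative behaviour parameters for synthetic participants
#'
#' Defaults are calibrated analytically so that, after the default validity
#' filter, the expected mean adjustment is 43.7\% toward peer-sourced and
#' 47.5\% toward adult-sourced social information, pooled stay/copy rates
#' are 27\%/18\%, contrarian and overshoot rates are 2.2\% and 5.6\%, and
#' first estimates undershoot the true count by 10\% on average.
#'
#' @param bias_sigma SD of the log-ratio log(E1/true) (default 0.15).
#' @param bias_mu Mean of the log-ratio; default `log(0.9) - bias_sigma^2/2`
#'   so the expected ratio is exactly 0.90.
#' @param p_stay,p_copy Per-condition probabilities of the stay (s = 0) and
#'   copy (s = 1) heuristics, as `c(peer=, adult=)` (scalars are recycled).
#' @param p_contrarian,p_overshoot Probabilities of the discarded extremes
#'   (s < 0 and s > 1); scalars or per-condition pairs.
#' @param compromise_shape Two positive Beta shape parameters of the
#'   compromise law on (0, 1).
#' @param adult_shift Additive shift of the compromise mean in the adult
#'   condition.
#' @param household_shift Additive shift of the compromise mean for
#'   extended households (default 0: no household effect).
#' @param contrarian_s,overshoot_s Fixed adjustment values of the two
#'   extreme heuristics (defaults -0.2 and 1.2; these rounds are discarded
#'   by the default filter, so only their rates matter).
#' @return An object of class `agent_params`.
#' @examples
#' p <- agent_params()
#' expected_adjustment(p, "adult") # 0.475
#' @export
agent_params <- function(bias_sigma = 0.15,
                         bias_mu = log(0.9) - bias_sigma^2 / 2,
                         p_stay = c(peer = 0.285, adult = 0.255),
                         p_copy = c(peer = 0.165, adult = 0.195),
                         p_contrarian = 0.022,
                         p_overshoot = 0.056,
                         compromise_shape = c(2.52, 2.48),
                         adult_shift = 0.0107,
                         household_shift = 0,
                         contrarian_s = -0.2,
                         overshoot_s = 1.2) {
  if (!is.numeric(bias_sigma) || length(bias_sigma) != 1L || bias_sigma < 0) {
    stop_invalid("`bias_sigma` must be a single non-negative number")
  }
  if (!is.numeric(bias_mu) || length(bias_mu) != 1L) {
    stop_invalid("`bias_mu` must be a single number")
  }
  p_stay <- as_condition_pair(p_stay, "p_stay")
  p_copy <- as_condition_pair(p_copy, "p_copy")
  p_contrarian <- as_condition_pair(p_contrarian, "p_contrarian")
  p_overshoot <- as_condition_pair(p_overshoot, "p_overshoot")
  tot <- p_stay + p_copy + p_contrarian + p_overshoot
  if (any(tot > 1 + 1e-12)) {
    stop_invalid("mixture probabilities must sum to at most 1 per condition")
  }
  if (!is.numeric(compromise_shape) || length(compromise_shape) != 2L ||
      any(compromise_shape <= 0)) {
    stop_invalid("`compromise_shape` must be two positive numbers")
  }
  if (contrarian_s >= 0) stop_invalid("`contrarian_s` must be negative")
  if (overshoot_s <= 1) stop_invalid("`overshoot_s` must exceed 1")
  mu0 <- compromise_shape[1] / sum(compromise_shape)
  # compromise mean per (condition, household) cell, validated up front
  mu <- outer(
    c(peer = 0, adult = adult_shift),
    c(nuclear = 0, extended = household_shift), "+"
  ) + mu0
  if (any(mu <= 0) || any(mu >= 1)) {
    stop_invalid("shifted compromise means must stay inside (0, 1)")
  }
  params <- structure(
    list(
      bias_mu = bias_mu, bias_sigma = bias_sigma,
      p_stay = p_stay, p_copy = p_copy,
      p_contrarian = p_contrarian, p_overshoot = p_overshoot,
      compromise_shape = compromise_shape,
      adult_shift = adult_shift, household_shift = household_shift,
      contrarian_s = contrarian_s, overshoot_s = overshoot_s,
      # precomputed for the per-trial draw
      .nu = sum(compromise_shape),
      .mu = mu,
      .cum = rbind(peer = cumsum(c(p_stay["peer"], p_copy["peer"],
                                   p_contrarian["peer"], p_overshoot["peer"])),
                   adult = cumsum(c(p_stay["adult"], p_copy["adult"],
                                    p_contrarian["adult"], p_overshoot["adult"])))
    ),
    class = "agent_params"
  )
  ea <- vapply(c("peer", "adult"), function(cond) {
    vapply(c("nuclear", "extended"), function(h) {
      expected_adjustment(params, cond, h, policy = "include")
    }, numeric(1))
  }, numeric(2))
  if (any(ea < 0) || any(ea > 1)) {
    stop_invalid("expected adjustment must lie in [0, 1] for every condition")
  }
  params
}

#' @export
print.agent_params <- function(x, ...) {
  cat("<agent_params>\n")
  cat(sprintf("  first estimate: log-ratio N(%.4f, %.3f) => E[E1/true] = %.3f\n",
              x$bias_mu, x$bias_sigma, exp(x$bias_mu + x$bias_sigma^2 / 2)))
  for (cond in c("peer", "adult")) {
    cat(sprintf(
      "  %s: stay %.3f copy %.3f contrarian %.3f overshoot %.3f | E[S | 0<=s<=1] = %.3f\n",
      cond, x$p_stay[cond], x$p_copy[cond], x$p_contrarian[cond],
      x$p_overshoot[cond], expected_adjustment(x, cond)
    ))
  }
  invisible(x)
}

compromise_mean <- function(params, condition, household) {
  params$.mu[condition, if (identical(household, "extended")) "extended" else "nuclear"]
}

#' Analytic expected adjustment of the heuristic mixture
#'
#' Closed-form expectation of the per-round adjustment `s` under the
#' generative mixture, before integer rounding of estimates. With the
#' default `"omit"` policy this is the expectation conditional on a valid
#' round (0 <= s <= 1), i.e. the quantity the per-participant mean `S`
#' estimates.
#'
#' @param params [agent_params()].
#' @param condition `"peer"` or `"adult"`.
#' @param household `"nuclear"` or `"extended"`.
#' @param policy Validity policy, as in [filter_valid()].
#' @return The expected adjustment (a single number).
#' @export
expected_adjustment <- function(params, condition = c("peer", "adult"),
                                household = c("nuclear", "extended"),
                                policy = c("omit", "include", "clip")) {
  condition <- match.arg(condition)
  household <- match.arg(household)
  policy <- match.arg(policy)
  p_st <- params$p_stay[condition]
  p_cp <- params$p_copy[condition]
  p_co <- params$p_contrarian[condition]
  p_ov <- params$p_overshoot[condition]
  p_cm <- 1 - p_st - p_cp - p_co - p_ov
  mu <- compromise_mean(params, condition, household)
  unname(switch(policy,
    omit = (p_cp + p_cm * mu) / (p_st + p_cp + p_cm),
    include = p_cp + p_cm * mu + p_co * params$contrarian_s +
      p_ov * params$overshoot_s,
    clip = p_cp + p_cm * mu + p_ov
  ))
}

#' Draw first estimates
#'
#' `E1 = max(1, round(true_count * exp(z)))` with
#' `z ~ N(bias_mu, bias_sigma)`. Vectorised over `true_count`; uses the
#' ambient RNG.
#'
#' @param true_count Positive integer true count(s).
#' @param params [agent_params()].
#' @return Integer first estimate(s), always >= 1.
#' @export
first_estimate <- function(true_count, params = agent_params()) {
  if (!is_wholenumber(true_count) || any(true_count < 1)) {
    stop_invalid("`true_count` must be positive integers")
  }
  as.integer(pmax(1, round(true_count *
                             exp(rnorm(length(true_count), params$bias_mu,
                                       params$bias_sigma)))))
}

# scalar fast path used in the session loop (no validation)
draw_first_estimate <- function(true_count, params) {
  max(1, round(true_count * exp(rnorm(1, params$bias_mu, params$bias_sigma))))
}

# draw one intended adjustment s* from the condition-specific mixture
draw_heuristic_s <- function(adult, extended, params) {
  cum <- params$.cum[if (adult) "adult" else "peer", ]
  u <- runif(1)
  if (u < cum[1]) return(0)
  if (u < cum[2]) return(1)
  if (u < cum[3]) return(params$contrarian_s)
  if (u < cum[4]) return(params$overshoot_s)
  mu <- params$.mu[if (adult) "adult" else "peer",
                   if (extended) "extended" else "nuclear"]
  rbeta(1, mu * params$.nu, (1 - mu) * params$.nu)
}

#' Draw a second estimate from the heuristic mixture
#'
#' Draws an adjustment heuristic (stay, copy, compromise, contrarian or
#' overshoot) from the condition-specific mixture and returns
#' `E2 = round(E1 + s* (X - E1))`, clamped to at least 1. Uses the ambient
#' RNG.
#'
#' @param E1 First estimate (positive integer).
#' @param X Displayed social information, `X != E1`.
#' @param condition `"peer"` or `"adult"`.
#' @param params [agent_params()].
#' @param household `"nuclear"` or `"extended"` (affects the compromise
#'   mean only through `household_shift`).
#' @return Integer second estimate >= 1.
#' @export
second_estimate <- function(E1, X, condition = c("peer", "adult"),
                            params = agent_params(),
                            household = c("nuclear", "extended")) {
  condition <- match.arg(condition)
  household <- match.arg(household)
  if (length(E1) != 1L || !is_wholenumber(E1) || E1 < 1) {
    stop_invalid("`E1` must be a single integer >= 1")
  }
  if (length(X) != 1L || !is_wholenumber(X) || X < 1) {
    stop_invalid("`X` must be a single integer >= 1")
  }
  if (X == E1) {
    stop_invalid("`X` must differ from `E1` (adjustment undefined otherwise)")
  }
  s_star <- draw_heuristic_s(condition == "adult", household == "extended", params)
  as.integer(max(1, round(E1 + s_star * (X - E1))))
}

#' Cohort composition and behaviour configuration
#'
#' Margins are exact by construction (deterministic counts, randomised
#' cross-tabulation). The default reproduces the 256 analysable
#' participants of the study design: 148 extended- and 108
#' nuclear-household adolescents aged 11--15 across two schools.
#'
#' @param n_participants Cohort size (default 256).
#' @param school_counts Named participant counts per school (must sum to
#'   `n_participants`).
#' @param household_counts Named counts for `nuclear` and `extended`.
#' @param gender_counts Named counts for `male` and `female`.
#' @param age_mean,age_sd Targets of the discretised normal age draw.
#' @param age_range Inclusive integer age support (default 11--15).
#' @param p_aunts_uncles Probability that aunts/uncles cohabit (recorded
#'   for household-coding robustness checks; no behavioural effect).
#' @param params [agent_params()].
#' @param seed Optional default seed used by [sample_cohort()].
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 256,
                          school_counts = c(school_A = 149, school_B = 107),
                          household_counts = c(nuclear = 108, extended = 148),
                          gender_counts = c(male = 125, female = 131),
                          age_mean = 13.38, age_sd = 0.88,
                          age_range = c(11L, 15L),
                          p_aunts_uncles = 0.25,
                          params = agent_params(),
                          seed = NULL) {
  n_participants <- check_scalar_count(n_participants, "n_participants")
  check_counts <- function(x, name, vocab = NULL) {
    if (!is_wholenumber(x) || any(x < 0) || is.null(names(x))) {
      stop_invalid(sprintf("`%s` must be named non-negative integer counts", name))
    }
    if (!is.null(vocab) && !setequal(names(x), vocab)) {
      stop_invalid(sprintf("`%s` must be named %s", name,
                           paste(vocab, collapse = ", ")))
    }
    if (sum(x) != n_participants) {
      stop_invalid(sprintf("`%s` must sum to n_participants (%d)", name,
                           n_participants))
    }
    x
  }
  school_counts <- check_counts(school_counts, "school_counts")
  household_counts <- check_counts(household_counts, "household_counts",
                                   c("nuclear", "extended"))
  gender_counts <- check_counts(gender_counts, "gender_counts",
                                c("male", "female"))
  if (!inherits(params, "agent_params")) {
    stop_invalid("`params` must come from agent_params()")
  }
  structure(
    list(
      n_participants = n_participants, school_counts = school_counts,
      household_counts = household_counts, gender_counts = gender_counts,
      age_mean = age_mean, age_sd = age_sd,
      age_range = as.integer(age_range),
      p_aunts_uncles = p_aunts_uncles,
      params = params, seed = seed
    ),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "<cohort_config> n = %d; schools %s; households %s; ages %d-%d (target mean %.2f)\n",
    x$n_participants,
    paste(sprintf("%s=%d", names(x$school_counts), x$school_counts), collapse = " "),
    paste(sprintf("%s=%d", names(x$household_counts), x$household_counts), collapse = " "),
    x$age_range[1], x$age_range[2], x$age_mean
  ))
  invisible(x)
}

# ages on an integer support by rejection-sampled rounded normal draws;
# exact moments are not enforced, only the support
draw_ages <- function(n, mean, sd, range) {
  out <- integer(0)
  while (length(out) < n) {
    x <- round(rnorm(n, mean, sd))
    out <- c(out, x[x >= range[1] & x <= range[2]])
  }
  as.integer(out[seq_len(n)])
}

#' Sample a cohort of participant profiles
#'
#' Demographic margins (school, household, gender) are exact; their
#' cross-tabulation is randomised by independent permutation. Block order
#' alternates by enrolment index (odd index peer-first), giving a
#' deterministic counterbalance.
#'
#' @param config [cohort_config()].
#' @param seed Seed; defaults to the config's own.
#' @return A tibble with columns `participant_id`, `school`, `age`,
#'   `gender`, `household`, `cohabiting_aunts_uncles`, `block_order`.
#' @export
sample_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) withr::local_seed(seed)
  n <- config$n_participants
  margin <- function(counts) sample(rep(names(counts), counts))
  tibble(
    participant_id = sprintf("P%04d", seq_len(n)),
    school = margin(config$school_counts),
    age = draw_ages(n, config$age_mean, config$age_sd, config$age_range),
    gender = margin(config$gender_counts),
    household = margin(config$household_counts),
    cohabiting_aunts_uncles = runif(n) < config$p_aunts_uncles,
    block_order = ifelse(seq_len(n) %% 2L == 1L, "peer_first", "adult_first")
  )
}

#' Simulate a full experiment
#'
#' Samples a cohort (unless one is supplied), then runs every participant's
#' two-block session against the estimate bank, producing one trial record
#' per participant, condition and round. The cohort profiles are attached
#' as the `"profiles"` attribute (see [cohort_profiles()]).
#'
#' @param config [cohort_config()].
#' @param bank [build_bank()] estimate bank.
#' @param deltas Displacement schedule (default [delta_schedule()]).
#' @param seed Optional seed for the whole simulation.
#' @param schedule Stimulus schedule; defaults to the bank's own.
#' @param cohort Optional pre-sampled cohort tibble; when `NULL` a cohort
#'   is drawn from `config`.
#' @return Trial tibble (`n_participants * 2 * n_rounds` rows).
#' @export
simulate_experiment <- function(config, bank, deltas = delta_schedule(),
                                seed = NULL, schedule = attr(bank, "schedule"),
                                cohort = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (is.null(schedule)) {
    stop_invalid("no `schedule` supplied and the bank carries none")
  }
  deltas <- delta_schedule(deltas)
  if (length(deltas) != nrow(schedule)) {
    stop_invalid("`deltas` must have one entry per schedule round")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  if (is.null(cohort)) cohort <- sample_cohort(config, seed = NULL)
  bank_split <- split_bank(bank)
  params <- config$params
  sessions <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    sessions[[i]] <- session_impl(
      participant_id = cohort$participant_id[i],
      school = cohort$school[i],
      block_order = cohort$block_order[i],
      extended = cohort$household[i] == "extended",
      params = params, bank_split = bank_split,
      schedule = schedule, deltas = deltas
    )
  }
  trials <- dplyr::bind_rows(sessions)
  attr(trials, "profiles") <- cohort
  trials
}

#' Cohort profiles attached to a simulated trial table
#'
#' @param trials A trial table from [simulate_experiment()].
#' @return The participant profile tibble.
#' @export
cohort_profiles <- function(trials) {
  p <- attr(trials, "profiles")
  if (is.null(p)) {
    stop_invalid("`trials` carries no attached cohort profiles")
  }
  p
}
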