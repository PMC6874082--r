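# Shared fixtures: reduced cohorts and banks so unit tests stay fast while
# keeping the full design structure (two schools, both household types,
# both genders, counterbalanced blocks).

small_cohort_config <- function(n = 24, params = agent_params()) {
  a <- round(0.58 * n)
  nuc <- round(0.42 * n)
  m <- n %/% 2L
  cohort_config(
    n_participants = n,
    school_counts = c(school_A = a, school_B = n - a),
    household_counts = c(nuclear = nuc, extended = n - nuc),
    gender_counts = c(male = m, female = n - m),
    params = params
  )
}

make_test_bank <- function(seed = 1, n_adults = 6, n_students = 4,
                           n_iterations = 2, params = agent_params()) {
  schedule <- make_stimulus_schedule(seed = seed)
  build_bank(schedule, n_adults, n_students, n_iterations,
             params = params, seed = seed + 1L)
}

sim_small <- function(n = 24, seed = 5, params = agent_params()) {
  bank <- make_test_bank(seed)
  simulate_experiment(small_cohort_config(n, params = params), bank,
                      seed = seed + 2L)
}

# adjustment records for one participant from raw s values per condition
records_from_s <- function(s_peer, s_adult, id = "p1", policy = "omit") {
  filter_valid(
    tibble::tibble(
      participant_id = id,
      condition = c(rep("peer", length(s_peer)), rep("adult", length(s_adult))),
      round = c(seq_along(s_peer), seq_along(s_adult)),
      s = c(s_peer, s_adult),
      category = classify_adjustment(c(s_peer, s_adult))
    ),
    policy
  )
}
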