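test_that("cohort margins are exact and profiles well-formed", {
  cfg <- cohort_config()
  cohort <- sample_cohort(cfg, seed = 1)
  expect_equal(nrow(cohort), 256)
  expect_equal(sum(cohort$household == "extended"), 148)
  expect_equal(sum(cohort$household == "nuclear"), 108)
  expect_equal(unname(table(cohort$school)[c("school_A", "school_B")]),
               c(149L, 107L), ignore_attr = TRUE)
  expect_equal(sum(cohort$gender == "female"), 131)
  expect_true(all(cohort$age >= 11 & cohort$age <= 15))
  expect_equal(sum(cohort$block_order == "peer_first"), 128)
  # alternating counterbalance is deterministic
  expect_equal(cohort$block_order[1:4],
               c("peer_first", "adult_first", "peer_first", "adult_first"))
  expect_identical(cohort, sample_cohort(cfg, seed = 1))
})

test_that("tiny cohorts keep every configured margin", {
  cfg <- cohort_config(n_participants = 2,
                       school_counts = c(s1 = 1, s2 = 1),
                       household_counts = c(nuclear = 1, extended = 1),
                       gender_counts = c(male = 1, female = 1))
  cohort <- sample_cohort(cfg, seed = 2)
  expect_setequal(cohort$gender, c("male", "female"))
  expect_setequal(cohort$household, c("nuclear", "extended"))
  expect_error(cohort_config(n_participants = 3,
                             school_counts = c(s1 = 1, s2 = 1)),
               class = "beastsim_invalid_argument")
})

test_that("agent parameter validation rejects impossible mixtures", {
  expect_error(agent_params(p_stay = 0.7, p_copy = 0.4),
               class = "beastsim_invalid_argument")
  expect_error(agent_params(compromise_shape = c(-1, 2)),
               class = "beastsim_invalid_argument")
  expect_error(agent_params(contrarian_s = 0.1),
               class = "beastsim_invalid_argument")
  expect_error(agent_params(overshoot_s = 0.9),
               class = "beastsim_invalid_argument")
})

test_that("first estimates follow the lognormal ratio model with ~10% undershoot", {
  # deterministic limit: zero dispersion, bias log 0.9
  p0 <- agent_params(bias_sigma = 0, bias_mu = log(0.9))
  expect_equal(withr::with_seed(1, first_estimate(55, p0)), 50L)
  # floor at one for extreme negative draws
  pneg <- agent_params(bias_sigma = 0, bias_mu = -15)
  expect_equal(withr::with_seed(1, first_estimate(50, pneg)), 1L)
  # mean ratio at defaults
  ratio <- withr::with_seed(2, {
    tc <- sample(50:60, 1e5, replace = TRUE)
    mean(first_estimate(tc, agent_params()) / tc)
  })
  expect_equal(ratio, 0.90, tolerance = 0.01)
})

test_that("degenerate heuristic mixtures pin the second estimate", {
  p_copy1 <- agent_params(p_stay = 0, p_copy = 1, p_contrarian = 0,
                          p_overshoot = 0)
  p_stay1 <- agent_params(p_stay = 1, p_copy = 0, p_contrarian = 0,
                          p_overshoot = 0)
  withr::with_seed(3, {
    for (i in 1:20) {
      E1 <- sample(30:80, 1)
      X <- E1 + sample(c(-12:-3, 3:12), 1)
      expect_equal(second_estimate(E1, X, "peer", p_copy1), X)
      expect_equal(second_estimate(E1, X, "adult", p_stay1), E1)
    }
  })
  expect_error(second_estimate(50, 50, "peer"),
               class = "beastsim_invalid_argument")
})

test_that("realised adjustments match the analytic mixture means, adult above peer", {
  # closed-form filtered means of the default mixture:
  #   peer : (.165 + .472 * .504)  / .922 = 0.436972...
  #   adult: (.195 + .472 * .5147) / .922 = 0.474987...
  params <- agent_params()
  expect_equal(expected_adjustment(params, "peer"), 0.4369718, tolerance = 1e-6)
  expect_equal(expected_adjustment(params, "adult"), 0.4749874, tolerance = 1e-6)
  sim_mean <- function(cond) {
    withr::with_seed(4, {
      s <- replicate(1e4, {
        E1 <- sample(40:70, 1)
        X <- E1 + sample(c(-15:-5, 5:15), 1)
        (second_estimate(E1, X, cond, params) - E1) / (X - E1)
      })
      mean(s[s >= 0 & s <= 1])
    })
  }
  m_peer <- sim_mean("peer")
  m_adult <- sim_mean("adult")
  expect_equal(m_peer, 0.4370, tolerance = 0.015)
  expect_equal(m_adult, 0.4750, tolerance = 0.015)
  expect_gt(m_adult, m_peer)
})

test_that("simulated experiments have one record per participant, condition and round", {
  bank <- make_test_bank(seed = 20)
  trials <- simulate_experiment(cohort_config(), bank, seed = 21)
  expect_equal(nrow(trials), 2560)
  expect_equal(nrow(dplyr::distinct(trials, participant_id, condition, round)),
               2560)
  expect_identical(
    trials,
    simulate_experiment(cohort_config(), bank, seed = 21),
    ignore_attr = FALSE
  )
  profiles <- cohort_profiles(trials)
  expect_equal(nrow(profiles), 256)
})

test_that("a zero household shift leaves behaviour identical across household types", {
  trials <- sim_small(n = 128, seed = 30)
  adj <- compute_adjustments(trials)
  profiles <- cohort_profiles(trials)
  merged <- dplyr::inner_join(adj, profiles, by = "participant_id")
  means <- tapply(merged$s[merged$valid], merged$household[merged$valid], mean)
  expect_lt(abs(means[["extended"]] - means[["nuclear"]]), 0.03)
})
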