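test_that("the paired test matches a first-principles computation", {
  summ <- tibble::tibble(S_peer = c(0.3, 0.2, 0.1),
                         S_adult = c(0.4, 0.2, 0.3))
  # differences (0.1, 0.0, 0.2): mean 0.1, sd 0.1, t = 0.1 / (0.1 / sqrt(3))
  res <- paired_test(summ)
  expect_equal(res$t_statistic, sqrt(3), tolerance = 1e-12)
  expect_equal(res$degrees_of_freedom, 2L)
  expect_equal(res$cohens_d, 1)
  expect_equal(res$p_value, 2 * pt(-sqrt(3), 2), tolerance = 1e-12)

  # brute-force agreement on random small inputs
  withr::with_seed(6, {
    for (i in 1:20) {
      n <- sample(3:10, 1)
      sp <- runif(n); sa <- runif(n)
      res <- paired_test(tibble::tibble(S_peer = sp, S_adult = sa))
      d <- sa - sp
      t_manual <- mean(d) / (sd(d) / sqrt(n))
      expect_equal(res$t_statistic, t_manual, tolerance = 1e-12)
      expect_equal(res$p_value, 2 * pt(-abs(t_manual), n - 1),
                   tolerance = 1e-12)
      expect_equal(res$cohens_d, mean(d) / sd(d), tolerance = 1e-12)
    }
  })
})

test_that("degenerate and incomplete pairings are handled", {
  zero <- paired_test(tibble::tibble(S_peer = c(0.4, 0.5, 0.6),
                                     S_adult = c(0.4, 0.5, 0.6)))
  expect_equal(zero$t_statistic, 0)
  expect_equal(zero$cohens_d, 0)
  expect_true(zero$degenerate)

  with_na <- paired_test(tibble::tibble(S_peer = c(0.3, 0.2, 0.1, 0.5),
                                        S_adult = c(0.4, NA, 0.3, 0.6)))
  expect_equal(with_na$n_pairs, 3L)
  expect_equal(with_na$degrees_of_freedom, 2L)
  expect_error(paired_test(tibble::tibble(S_peer = 0.5, S_adult = 0.6)),
               class = "beastsim_insufficient_data")
})

test_that("the fixed-effects-only model matches a normal-equations oracle", {
  withr::with_seed(7, {
    n <- 16
    profiles <- tibble::tibble(
      participant_id = sprintf("p%02d", 1:n),
      school = rep(c("A", "B"), each = n / 2),
      age = sample(11:15, n, replace = TRUE),
      gender = sample(c("male", "female"), n, replace = TRUE),
      household = sample(c("nuclear", "extended"), n, replace = TRUE),
      cohabiting_aunts_uncles = FALSE,
      block_order = "peer_first"
    )
    summ <- tibble::tibble(participant_id = profiles$participant_id,
                           S_peer = runif(n), S_adult = runif(n),
                           n_valid_peer = 5L, n_valid_adult = 5L)
  })
  fit <- fit_adjustment_lmm(summ, profiles, include_random = FALSE)
  # oracle: solve the normal equations on the long design matrix
  long <- rbind(
    data.frame(S = summ$S_peer, adult = 0, profiles),
    data.frame(S = summ$S_adult, adult = 1, profiles)
  )
  X <- cbind(1,
             model_type = long$adult,
             household_type = as.integer(long$household == "extended"),
             gender = as.integer(long$gender == "female"),
             age = long$age,
             interaction = long$adult * (long$household == "extended"))
  beta <- solve(t(X) %*% X, t(X) %*% long$S)[, 1]
  co <- fit$coefficients
  expect_equal(co$estimate[co$term == "(Intercept)"], beta[[1]], tolerance = 1e-8)
  expect_equal(co$estimate[co$term == "model_type"], beta[["model_type"]],
               tolerance = 1e-8)
  expect_equal(co$estimate[co$term == "household_type"],
               beta[["household_type"]], tolerance = 1e-8)
  expect_equal(co$estimate[co$term == "gender"], beta[["gender"]],
               tolerance = 1e-8)
  expect_equal(co$estimate[co$term == "age"], beta[["age"]], tolerance = 1e-8)
  expect_equal(co$estimate[co$term == "model_type:household_type"],
               beta[["interaction"]], tolerance = 1e-8)
})

test_that("constant adjustment data yields a flat model", {
  profiles <- sample_cohort(small_cohort_config(16), seed = 8)
  summ <- tibble::tibble(participant_id = profiles$participant_id,
                         S_peer = 0.4, S_adult = 0.4,
                         n_valid_peer = 5L, n_valid_adult = 5L)
  fit <- suppressWarnings(fit_adjustment_lmm(summ, profiles,
                                             include_random = FALSE))
  co <- fit$coefficients
  expect_equal(co$estimate[co$term == "(Intercept)"], 0.4, tolerance = 1e-10)
  slopes <- co$estimate[co$term != "(Intercept)"]
  expect_true(all(abs(slopes) < 1e-10))
})

test_that("the mixed model recovers a sharpened condition effect with the right signs", {
  # sharp generator so one medium cohort suffices: far more stays under
  # peer, far more copies under adult
  params <- agent_params(p_stay = c(peer = 0.45, adult = 0.10),
                         p_copy = c(peer = 0.10, adult = 0.45),
                         adult_shift = 0)
  trials <- sim_small(n = 128, seed = 50, params = params)
  profiles <- cohort_profiles(trials)
  adj <- compute_adjustments(trials)
  summ <- participant_summaries(adj)

  m1 <- suppressWarnings(fit_adjustment_lmm(summ, profiles))
  co <- m1$coefficients
  expect_true(m1$converged)
  expect_gt(co$estimate[co$term == "model_type"], 0)
  expect_lt(co$p_value[co$term == "model_type"], 0.01)
  expect_equal(m1$n_observations, sum(!is.na(summ$S_peer)) +
                 sum(!is.na(summ$S_adult)))

  stay <- fit_stay_glmm(adj, profiles)
  expect_lt(stay$coefficients$estimate[stay$coefficients$term == "model_type"], 0)
  expect_lt(stay$coefficients$p_value[stay$coefficients$term == "model_type"],
            0.01)
  copy <- fit_copy_glmm(adj, profiles)
  expect_gt(copy$coefficients$estimate[copy$coefficients$term == "model_type"], 0)
  expect_lt(copy$coefficients$p_value[copy$coefficients$term == "model_type"],
            0.01)
})

test_that("constant binary outcomes are flagged instead of fitted", {
  params <- agent_params(p_stay = 0, p_copy = 0, p_contrarian = 0,
                         p_overshoot = 0)
  trials <- sim_small(n = 8, seed = 60, params = params)
  adj <- compute_adjustments(trials)
  fit <- fit_stay_glmm(adj, cohort_profiles(trials))
  expect_false(fit$converged)
  expect_match(fit$note, "constant")
})

test_that("second estimates improve accuracy: negative period effect", {
  trials <- sim_small(n = 96, seed = 70)
  fit <- fit_accuracy_lmm(deviation_table(trials))
  co <- fit$coefficients
  expect_lt(co$estimate[co$term == "period"], 0)
  expect_lt(co$p_value[co$term == "period"], 0.001)

  # no adjustment at all: the period effect vanishes
  frozen <- trials
  frozen$E2 <- frozen$E1
  fit0 <- suppressWarnings(fit_accuracy_lmm(deviation_table(frozen)))
  expect_lt(abs(fit0$coefficients$estimate[fit0$coefficients$term == "period"]),
            1e-8)

  # a single participant cannot support the nested structure
  one <- trials[trials$participant_id == trials$participant_id[1], ]
  res <- suppressWarnings(fit_accuracy_lmm(deviation_table(one)))
  expect_false(isTRUE(res$converged) && is.null(res$note) && !res$singular)
})

test_that("the recovery harness calibrates means, rates and null rejections", {
  cfg <- small_cohort_config(64)
  rec <- recovery_harness(cfg, n_replicates = 12, seed = 80)
  s <- rec$summary
  expect_equal(s$mean_S_peer, s$expected_S_peer, tolerance = 0.02)
  expect_equal(s$mean_S_adult, s$expected_S_adult, tolerance = 0.02)
  expect_lt(abs(s$rate_contrarian - 0.022), 0.01)
  expect_lt(abs(s$rate_overshoot - 0.056), 0.01)
  expect_equal(nrow(rec$replicates), 12)
  # deterministic under the same master seed
  rec2 <- recovery_harness(cfg, n_replicates = 12, seed = 80)
  expect_identical(rec$replicates, rec2$replicates)
})
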