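# Parameter-recovery, calibration and power harness: simulates replicate
# experiments end to end and compares what the measurement and inference
# chain recovers against the generator's analytic expectations.

#' Simulate replicate experiments and summarise recovery
#'
#' For each replicate, builds a fresh schedule, estimate bank and cohort,
#' simulates the full experiment, scores adjustments under the chosen
#' policy and records (a) cohort means of `S_peer` and `S_adult`, (b)
#' pooled contrarian/overshoot rates, and (c) optionally the paired test
#' and the adjustment LMM's `model_type` and interaction terms. The
#' summary reports bias and RMSE of the recovered means against the
#' analytic mixture expectation ([expected_adjustment()]) and rejection
#' rates at `alpha` (power when the corresponding generator effect is
#' non-zero, type-I error when it is zero).
#'
#' @param config [cohort_config()].
#' @param n_replicates Number of replicate experiments (default 50).
#' @param alpha Nominal test level (default 0.05).
#' @param seed Optional master seed; each replicate gets child seeds.
#' @param deltas Displacement schedule.
#' @param models Which analyses to run per replicate: any of `"paired"`,
#'   `"adjustment"`; use `character(0)` for measurement-only replicates.
#' @param filter_policy Validity policy for scoring.
#' @param n_rounds,true_count_min,true_count_max Task parameters.
#' @param bank_n_adults,bank_n_students,bank_n_iterations Bank structure.
#' @param drop_school Passed to [fit_adjustment_lmm()].
#' @return Object of class `beast_recovery`: a list with `replicates`
#'   (one tibble row per replicate) and `summary`.
#' @export
recovery_harness <- function(config, n_replicates = 50, alpha = 0.05,
                             seed = NULL, deltas = delta_schedule(),
                             models = c("paired", "adjustment"),
                             filter_policy = "omit",
                             n_rounds = 5, true_count_min = 50,
                             true_count_max = 60,
                             bank_n_adults = 24, bank_n_students = 14,
                             bank_n_iterations = 6, drop_school = FALSE) {
  stopifnot(inherits(config, "cohort_config"))
  n_replicates <- check_scalar_count(n_replicates, "n_replicates")
  if (length(models)) models <- match.arg(models, several.ok = TRUE)
  if (!is.null(seed)) withr::local_seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)

  rows <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    s <- spawn_seeds(rep_seeds[i], c("schedule", "bank", "simulate"))
    schedule <- make_stimulus_schedule(n_rounds, true_count_min,
                                       true_count_max, seed = s["schedule"])
    bank <- build_bank(schedule, bank_n_adults, bank_n_students,
                       bank_n_iterations, params = config$params,
                       seed = s["bank"])
    trials <- simulate_experiment(config, bank, deltas, seed = s["simulate"])
    adj <- compute_adjustments(trials, policy = filter_policy)
    summ <- participant_summaries(adj)
    freq <- heuristic_frequencies(adj, pooling = "all_rounds")
    row <- tibble(
      replicate = i, seed = rep_seeds[i],
      mean_S_peer = mean(summ$S_peer, na.rm = TRUE),
      mean_S_adult = mean(summ$S_adult, na.rm = TRUE),
      rate_contrarian = freq$proportion[freq$category == "contrarian"],
      rate_overshoot = freq$proportion[freq$category == "overshoot"]
    )
    if ("paired" %in% models) {
      pt <- paired_test(summ)
      row$p_paired <- pt$p_value
      row$cohens_d <- pt$cohens_d
    }
    if ("adjustment" %in% models) {
      m1 <- suppressWarnings(
        fit_adjustment_lmm(summ, cohort_profiles(trials),
                           drop_school = drop_school)
      )
      if (m1$converged && !is.null(m1$coefficients)) {
        co <- m1$coefficients
        pick <- function(term, what) co[[what]][co$term == term]
        row$est_model_type <- pick("model_type", "estimate")
        row$p_model_type <- pick("model_type", "p_value")
        row$est_interaction <- pick("model_type:household_type", "estimate")
        row$p_interaction <- pick("model_type:household_type", "p_value")
        row$singular <- m1$singular
      } else {
        row$est_model_type <- NA_real_
        row$p_model_type <- NA_real_
        row$est_interaction <- NA_real_
        row$p_interaction <- NA_real_
        row$singular <- NA
      }
    }
    rows[[i]] <- row
  }
  reps <- dplyr::bind_rows(rows)

  # cohort-composition-weighted analytic expectations
  w_ext <- config$household_counts["extended"] / config$n_participants
  expect_S <- vapply(c("peer", "adult"), function(cond) {
    (1 - w_ext) * expected_adjustment(config$params, cond, "nuclear") +
      w_ext * expected_adjustment(config$params, cond, "extended")
  }, numeric(1))
  # expected pooled extreme rates (conditions weighted equally by design)
  expect_rate <- function(p) unname(mean(p[c("peer", "adult")]))

  summary <- list(
    n_replicates = n_replicates, alpha = alpha,
    expected_S_peer = unname(expect_S["peer"]),
    expected_S_adult = unname(expect_S["adult"]),
    mean_S_peer = mean(reps$mean_S_peer),
    mean_S_adult = mean(reps$mean_S_adult),
    bias_S_peer = mean(reps$mean_S_peer) - unname(expect_S["peer"]),
    bias_S_adult = mean(reps$mean_S_adult) - unname(expect_S["adult"]),
    rmse_S_peer = sqrt(mean((reps$mean_S_peer - expect_S["peer"])^2)),
    rmse_S_adult = sqrt(mean((reps$mean_S_adult - expect_S["adult"])^2)),
    expected_rate_contrarian = expect_rate(config$params$p_contrarian),
    expected_rate_overshoot = expect_rate(config$params$p_overshoot),
    rate_contrarian = mean(reps$rate_contrarian),
    rate_overshoot = mean(reps$rate_overshoot)
  )
  if ("paired" %in% models) {
    summary$reject_paired <- mean(reps$p_paired < alpha)
  }
  if ("adjustment" %in% models) {
    ok <- is.finite(reps$p_model_type)
    summary$n_model_fits <- sum(ok)
    summary$mean_est_model_type <- mean(reps$est_model_type[ok])
    summary$mean_est_interaction <- mean(reps$est_interaction[ok])
    summary$reject_model_type <- mean(reps$p_model_type[ok] < alpha)
    summary$reject_interaction <- mean(reps$p_interaction[ok] < alpha)
  }
  structure(list(replicates = reps, summary = summary, models = models),
            class = "beast_recovery")
}

#' @export
print.beast_recovery <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<recovery harness> %d replicates, alpha = %.3f\n",
              s$n_replicates, s$alpha))
  cat(sprintf("  S_peer : recovered %.4f vs expected %.4f (bias %+.4f, RMSE %.4f)\n",
              s$mean_S_peer, s$expected_S_peer, s$bias_S_peer, s$rmse_S_peer))
  cat(sprintf("  S_adult: recovered %.4f vs expected %.4f (bias %+.4f, RMSE %.4f)\n",
              s$mean_S_adult, s$expected_S_adult, s$bias_S_adult, s$rmse_S_adult))
  cat(sprintf("  extreme rates: contrarian %.4f (exp %.4f), overshoot %.4f (exp %.4f)\n",
              s$rate_contrarian, s$expected_rate_contrarian,
              s$rate_overshoot, s$expected_rate_overshoot))
  if (!is.null(s$reject_paired)) {
    cat(sprintf("  paired-test rejection rate: %.3f\n", s$reject_paired))
  }
  if (!is.null(s$reject_model_type)) {
    cat(sprintf("  LMM rejection: model_type %.3f, interaction %.3f (over %d fits)\n",
                s$reject_model_type, s$reject_interaction, s$n_model_fits))
  }
  invisible(x)
}
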