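# Statistical layer: paired comparison of S_peer vs S_adult, the condition-
# level linear mixed model, round-level stay/copy logistic mixed models, and
# the first-vs-second accuracy mixed model. Fixed-effect coding follows the
# analysis convention: model_type peer = 0 / adult = 1, household_type
# nuclear = 0 / extended = 1, gender male = 0 / female = 1. Coefficient
# p-values are Wald (normal approximation) for both LMMs and GLMMs.

#' Paired comparison of condition-level adjustment means
#'
#' Classic two-sided paired t-test on `S_adult - S_peer` over participants
#' with both condition means defined, with paired Cohen's d
#' (mean difference / SD of differences).
#'
#' @param summaries Output of [participant_summaries()].
#' @return Object of class `beast_paired_test` with fields `t_statistic`,
#'   `degrees_of_freedom`, `p_value`, `cohens_d`, `mean_peer`,
#'   `mean_adult`, `n_pairs`, `degenerate`.
#' @export
paired_test <- function(summaries) {
  if (!all(c("S_peer", "S_adult") %in% names(summaries))) {
    stop_invalid("`summaries` must carry S_peer and S_adult")
  }
  ok <- is.finite(summaries$S_peer) & is.finite(summaries$S_adult)
  peer <- summaries$S_peer[ok]
  adult <- summaries$S_adult[ok]
  n <- length(peer)
  if (n < 2L) {
    stop_insufficient("paired test needs at least 2 complete pairs")
  }
  d <- adult - peer
  degenerate <- sd(d) == 0
  if (degenerate) {
    t_stat <- 0; p <- 1; d_cohen <- 0
  } else {
    tt <- stats::t.test(adult, peer, paired = TRUE)
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
    d_cohen <- mean(d) / sd(d)
  }
  structure(
    list(
      t_statistic = t_stat, degrees_of_freedom = n - 1L, p_value = p,
      cohens_d = d_cohen, mean_peer = mean(peer), mean_adult = mean(adult),
      n_pairs = n, degenerate = degenerate
    ),
    class = "beast_paired_test"
  )
}

#' @export
print.beast_paired_test <- function(x, ...) {
  cat(sprintf(
    "Paired t-test, S_adult vs S_peer: t = %.3f, d.f. = %d, P = %.4g\n",
    x$t_statistic, x$degrees_of_freedom, x$p_value
  ))
  cat(sprintf("  mean S_peer = %.4f, mean S_adult = %.4f, Cohen's d = %.3f (n = %d pairs)\n",
              x$mean_peer, x$mean_adult, x$cohens_d, x$n_pairs))
  if (x$degenerate) cat("  note: zero-variance differences (degenerate)\n")
  invisible(x)
}

new_model_fit <- function(model_name, coefficients = NULL,
                          n_observations = NA_integer_,
                          n_participants = NA_integer_,
                          random_effect_variances = numeric(0),
                          singular = FALSE, converged = TRUE,
                          note = NULL, fit = NULL) {
  structure(
    list(
      model_name = model_name, coefficients = coefficients,
      n_observations = n_observations, n_participants = n_participants,
      random_effect_variances = random_effect_variances,
      singular = singular, converged = converged, note = note, fit = fit
    ),
    class = "beast_model_fit"
  )
}

#' @export
print.beast_model_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<model fit: %s>  n = %s, N = %s%s%s\n",
              x$model_name, x$n_observations, x$n_participants,
              if (x$singular) " [singular]" else "",
              if (!x$converged) " [not converged]" else ""))
  if (!is.null(x$coefficients)) {
    print(as.data.frame(x$coefficients), digits = digits)
  }
  if (length(x$random_effect_variances)) {
    cat("random-effect variances:\n")
    print(round(x$random_effect_variances, 6))
  }
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

coef_tibble <- function(est, se, stat, p, stat_name = "statistic") {
  out <- tibble(term = names(est), estimate = unname(est),
                std_error = unname(se), statistic = unname(stat),
                p_value = unname(p))
  attr(out, "stat_name") <- stat_name
  out
}

ranef_variances <- function(fit) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  setNames(vc$vcov, ifelse(is.na(vc$grp), "Residual", vc$grp))
}

lmer_wald <- function(fit) {
  co <- summary(fit)$coefficients
  coef_tibble(setNames(co[, "Estimate"], rownames(co)),
              co[, "Std. Error"], co[, "t value"],
              2 * pnorm(-abs(co[, "t value"])), "t")
}

glmer_wald <- function(fit) {
  co <- summary(fit)$coefficients
  coef_tibble(setNames(co[, "Estimate"], rownames(co)),
              co[, "Std. Error"], co[, "z value"],
              co[, "Pr(>|z|)"], "z")
}

convergence_note <- function(fit) {
  msgs <- fit@optinfo$conv$lme4$messages
  if (length(msgs)) paste(unlist(msgs), collapse = "; ") else NULL
}

# Long model frame: one row per defined (participant, condition) S value,
# with the numeric predictor coding used throughout.
adjustment_model_data <- function(summaries, profiles) {
  need <- c("participant_id", "school", "household", "gender", "age")
  if (!all(need %in% names(profiles))) {
    stop_invalid("`profiles` must carry participant_id, school, household, gender, age")
  }
  long <- tidyr::pivot_longer(
    summaries[, c("participant_id", "S_peer", "S_adult")],
    cols = c("S_peer", "S_adult"), names_to = "condition",
    names_prefix = "S_", values_to = "S"
  )
  long <- long[is.finite(long$S), ]
  dat <- dplyr::inner_join(long, as_tibble(profiles), by = "participant_id")
  code_predictors(dat)
}

code_predictors <- function(dat) {
  dplyr::mutate(dat,
                model_type = as.integer(.data$condition == "adult"),
                household_type = as.integer(.data$household == "extended"),
                gender_code = as.integer(.data$gender == "female"))
}

fixed_rhs <- "model_type * household_type + gender_code + age"

rename_terms <- function(coefs) {
  coefs$term <- sub("gender_code", "gender", coefs$term)
  coefs
}

#' Linear mixed model of condition-level mean adjustments
#'
#' Fits `S ~ model_type * household_type + gender + age` with random
#' intercepts for participant nested in school, on the long table of
#' defined condition means (at most two rows per participant). With only
#' two schools the school variance component is weakly identified; singular
#' fits are tolerated and flagged, and `drop_school = TRUE` removes the
#' school intercept. `include_random = FALSE` reduces the model to ordinary
#' least squares with identical fixed effects.
#'
#' @param summaries [participant_summaries()] output.
#' @param profiles Participant profiles (see [sample_cohort()]).
#' @param include_random Fit random intercepts (default `TRUE`).
#' @param drop_school Drop the school-level intercept.
#' @return A `beast_model_fit`.
#' @export
fit_adjustment_lmm <- function(summaries, profiles, include_random = TRUE,
                               drop_school = FALSE) {
  dat <- adjustment_model_data(summaries, profiles)
  n_obs <- nrow(dat)
  n_part <- dplyr::n_distinct(dat$participant_id)
  if (!include_random) {
    fit <- stats::lm(stats::as.formula(paste("S ~", fixed_rhs)), data = dat)
    co <- summary(fit)$coefficients
    coefs <- coef_tibble(setNames(co[, 1], rownames(co)), co[, 2], co[, 3],
                         co[, 4], "t")
    return(new_model_fit("adjustment_ols", rename_terms(coefs), n_obs, n_part,
                         fit = fit))
  }
  re <- if (drop_school) "(1 | participant_id)" else "(1 | school/participant_id)"
  form <- stats::as.formula(paste("S ~", fixed_rhs, "+", re))
  fit <- tryCatch(
    suppressMessages(lme4::lmer(form, data = dat, REML = TRUE)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(new_model_fit("adjustment_lmm", converged = FALSE,
                         n_observations = n_obs, n_participants = n_part,
                         note = conditionMessage(fit)))
  }
  singular <- lme4::isSingular(fit, tol = 1e-5)
  if (singular) {
    warning("adjustment LMM: singular fit (a variance component is zero)",
            call. = FALSE)
  }
  new_model_fit("adjustment_lmm", rename_terms(lmer_wald(fit)), n_obs, n_part,
                ranef_variances(fit), singular = singular,
                note = convergence_note(fit), fit = fit)
}

fit_binary_glmm <- function(dat, outcome, model_name) {
  n_obs <- nrow(dat)
  n_part <- dplyr::n_distinct(dat$participant_id)
  y <- dat[[outcome]]
  if (length(unique(y)) < 2L) {
    return(new_model_fit(model_name, converged = FALSE,
                         n_observations = n_obs, n_participants = n_part,
                         note = "outcome is constant; model degenerate"))
  }
  form <- stats::as.formula(paste(outcome, "~", fixed_rhs,
                                  "+ (1 | school/participant_id)"))
  fit <- tryCatch(
    suppressMessages(lme4::glmer(
      form, data = dat, family = stats::binomial(),
      control = lme4::glmerControl(optimizer = "bobyqa")
    )),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(new_model_fit(model_name, converged = FALSE,
                         n_observations = n_obs, n_participants = n_part,
                         note = conditionMessage(fit)))
  }
  singular <- lme4::isSingular(fit, tol = 1e-5)
  new_model_fit(model_name, rename_terms(glmer_wald(fit)), n_obs, n_part,
                ranef_variances(fit), singular = singular,
                converged = is.null(convergence_note(fit)),
                note = convergence_note(fit), fit = fit)
}

glmm_data <- function(adjustments, profiles, rounds = c("valid", "all")) {
  rounds <- match.arg(rounds)
  need <- c("participant_id", "condition", "s")
  if (!all(need %in% names(adjustments))) {
    stop_invalid("`adjustments` must carry participant_id, condition and s")
  }
  dat <- as_tibble(adjustments)
  if (rounds == "valid") dat <- dat[dat$s >= 0 & dat$s <= 1, ]
  dat$stay <- as.integer(dat$s == 0)
  dat$copy <- as.integer(dat$s == 1)
  dat <- dplyr::inner_join(
    dat[, c("participant_id", "condition", "round", "stay", "copy")],
    as_tibble(profiles), by = "participant_id"
  )
  code_predictors(dat)
}

#' Logistic mixed models for stay and copy decisions
#'
#' Round-level logistic GLMMs for the decision to stay with the first
#' estimate (s = 0) and the decision to copy the social information
#' (s = 1), with the same fixed effects and random structure as the
#' adjustment model. By default only rounds with 0 <= s <= 1 enter
#' (`rounds = "valid"`); `rounds = "all"` keeps every defined round.
#' Degenerate outcomes (constant) and non-convergence are reported as
#' flagged results rather than errors.
#'
#' @param adjustments Adjustment records from [compute_adjustments()].
#' @param profiles Participant profiles.
#' @param rounds `"valid"` (default) or `"all"`.
#' @return A `beast_model_fit`.
#' @export
fit_stay_glmm <- function(adjustments, profiles, rounds = c("valid", "all")) {
  fit_binary_glmm(glmm_data(adjustments, profiles, rounds), "stay", "stay_glmm")
}

#' @rdname fit_stay_glmm
#' @export
fit_copy_glmm <- function(adjustments, profiles, rounds = c("valid", "all")) {
  fit_binary_glmm(glmm_data(adjustments, profiles, rounds), "copy", "copy_glmm")
}

#' Accuracy mixed model: first vs second estimates
#'
#' Linear mixed model of deviations from the true count on estimate period
#' (first = 0, second = 1), with period nested in participant nested in
#' school as random intercepts. A negative period coefficient means second
#' estimates sit closer to the truth.
#'
#' @param deviations Long table from [deviation_table()].
#' @return A `beast_model_fit`.
#' @export
fit_accuracy_lmm <- function(deviations) {
  need <- c("participant_id", "school", "period", "deviation")
  if (!all(need %in% names(deviations))) {
    stop_invalid("`deviations` must carry participant_id, school, period, deviation")
  }
  dat <- dplyr::mutate(as_tibble(deviations),
                       period_code = as.integer(.data$period == "second"))
  n_obs <- nrow(dat)
  n_part <- dplyr::n_distinct(dat$participant_id)
  fit <- tryCatch(
    suppressMessages(lme4::lmer(
      deviation ~ period_code + (1 | school / participant_id / period),
      data = dat
    )),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(new_model_fit("accuracy_lmm", converged = FALSE,
                         n_observations = n_obs, n_participants = n_part,
                         note = conditionMessage(fit)))
  }
  singular <- lme4::isSingular(fit, tol = 1e-5)
  coefs <- lmer_wald(fit)
  coefs$term <- sub("period_code", "period", coefs$term)
  new_model_fit("accuracy_lmm", coefs, n_obs, n_part, ranef_variances(fit),
                singular = singular, note = convergence_note(fit), fit = fit)
}

model_fit_to_list <- function(x) {
  list(
    model_name = x$model_name,
    converged = x$converged,
    singular = x$singular,
    n_observations = x$n_observations,
    n_participants = x$n_participants,
    coefficients = if (is.null(x$coefficients)) NULL else
      as.data.frame(x$coefficients),
    random_effect_variances = as.list(x$random_effect_variances),
    note = x$note
  )
}
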