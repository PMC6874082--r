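# Run configuration: one YAML document (task / bank / cohort / agent /
# analysis sections plus a master seed) fully determines a run; the master
# seed spawns labelled child seeds per pipeline stage (see spawn_seeds()).

#' Default run configuration
#'
#' The configuration encoding the study conditions: the five-round task
#' with the fixed displacement schedule and 50--60 true counts, the
#' 24 + 14 member bank with 6 iterations, the 256-participant cohort, and
#' the default analysis settings (omit filter, alpha 0.05).
#'
#' @param seed Master seed (default 20191121).
#' @return An object of class `run_config`: a named list with `seed`,
#'   `task`, `bank`, `cohort` (a [cohort_config()]) and `analysis`.
#' @export
default_run_config <- function(seed = 20191121) {
  new_run_config(list(seed = seed))
}

config_defaults <- function() {
  list(
    seed = 20191121,
    task = list(
      n_rounds = 5L,
      deltas = c(0.25, 0.15, 0.20, 0.15, 0.25),
      true_count_min = 50L,
      true_count_max = 60L
    ),
    bank = list(n_adults = 24L, n_students = 14L, n_iterations = 6L),
    cohort = list(
      n_participants = 256L,
      school_counts = list(school_A = 149L, school_B = 107L),
      household_counts = list(nuclear = 108L, extended = 148L),
      gender_counts = list(male = 125L, female = 131L),
      age_mean = 13.38, age_sd = 0.88, age_range = c(11L, 15L),
      p_aunts_uncles = 0.25
    ),
    agent = list(),
    analysis = list(filter_policy = "omit", alpha = 0.05,
                    drop_school = FALSE, glmm_rounds = "valid")
  )
}

# count maps are replaced wholesale, not merged key-by-key
.replace_keys <- c("school_counts", "household_counts", "gender_counts")

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (nm %in% .replace_keys) {
      base[[nm]] <- override[[nm]]
    } else if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

new_run_config <- function(override = list()) {
  cfg <- merge_config(config_defaults(), override)
  params <- do.call(agent_params, lapply(cfg$agent, function(x) {
    if (is.list(x)) unlist(x) else x
  }))
  ch <- cfg$cohort
  cohort <- cohort_config(
    n_participants = ch$n_participants,
    school_counts = unlist(ch$school_counts),
    household_counts = unlist(ch$household_counts),
    gender_counts = unlist(ch$gender_counts),
    age_mean = ch$age_mean, age_sd = ch$age_sd,
    age_range = unlist(ch$age_range),
    p_aunts_uncles = ch$p_aunts_uncles,
    params = params
  )
  cfg$task$deltas <- delta_schedule(unlist(cfg$task$deltas))
  if (cfg$task$n_rounds != length(cfg$task$deltas)) {
    stop_invalid("task: n_rounds must equal the length of the delta schedule")
  }
  structure(
    list(seed = cfg$seed, task = cfg$task, bank = cfg$bank,
         cohort = cohort, analysis = cfg$analysis),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Unspecified keys fall back to [default_run_config()]. The recognised
#' sections are `seed`, `task` (`n_rounds`, `deltas`, `true_count_min`,
#' `true_count_max`), `bank` (`n_adults`, `n_students`, `n_iterations`),
#' `cohort` (composition and margins), `agent` (any [agent_params()]
#' argument) and `analysis` (`filter_policy`, `alpha`, `drop_school`,
#' `glmm_rounds`).
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop_format(sprintf("config file not found: %s", path))
  }
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop_format(sprintf("malformed YAML in %s: %s", path, conditionMessage(e)))
  })
  if (is.null(raw)) raw <- list()
  known <- names(config_defaults())
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop_format(sprintf("unknown config section(s): %s",
                        paste(unknown, collapse = ", ")))
  }
  new_run_config(raw)
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> seed %s; %d rounds, deltas %s; bank %d+%d x %d\n",
              x$seed, x$task$n_rounds,
              paste(format(x$task$deltas), collapse = "/"),
              x$bank$n_adults, x$bank$n_students, x$bank$n_iterations))
  print(x$cohort)
  invisible(x)
}

config_hash <- function(config) rlang::hash(config)
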