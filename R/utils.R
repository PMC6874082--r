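# Internal condition classes and small shared helpers.

stop_invalid <- function(msg, ...) {
  abort(msg, class = "beastsim_invalid_argument", ...)
}

stop_format <- function(msg, ...) {
  abort(msg, class = "beastsim_format_error", ...)
}

stop_no_social <- function(msg, ...) {
  abort(msg, class = "beastsim_no_valid_social_info", ...)
}

stop_insufficient <- function(msg, ...) {
  abort(msg, class = "beastsim_insufficient_data", ...)
}

stop_undefined_adjustment <- function(msg, ...) {
  abort(msg, class = "beastsim_undefined_adjustment", ...)
}

# TRUE for vectors of whole numbers (integer or integer-valued double)
is_wholenumber <- function(x, tol = 1e-8) {
  is.numeric(x) && all(is.finite(x)) && all(abs(x - round(x)) < tol)
}

check_scalar_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is_wholenumber(x) || x < min) {
    stop_invalid(sprintf("`%s` must be a single integer >= %d, got %s",
                         name, min, deparse(substitute(x))))
  }
  as.integer(x)
}

#' Spawn labelled child seeds from a master seed
#'
#' Derives a deterministic set of child seeds from one master seed so that
#' pipeline stages (schedule, bank, cohort, sessions, harness) can be re-run
#' independently while remaining jointly reproducible. The ambient RNG state
#' is left untouched.
#'
#' @param seed Master seed (single integer).
#' @param labels Character vector naming the children.
#' @return Named integer vector of child seeds, one per label.
#' @examples
#' spawn_seeds(42, c("bank", "cohort"))
#' @export
spawn_seeds <- function(seed, labels) {
  if (length(seed) != 1L || !is_wholenumber(seed)) {
    stop_invalid("`seed` must be a single integer")
  }
  if (!is.character(labels) || length(labels) < 1L) {
    stop_invalid("`labels` must be a non-empty character vector")
  }
  s <- withr::with_seed(as.integer(seed),
                        sample.int(.Machine$integer.max - 1L, length(labels)))
  setNames(as.integer(s), labels)
}

# Standard child-seed labels used by the pipeline entry points.
pipeline_seeds <- function(seed) {
  spawn_seeds(seed, c("schedule", "bank", "cohort", "sessions", "harness"))
}
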