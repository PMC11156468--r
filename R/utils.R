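#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible stage seed from a master seed
#'
#' A single session- or pipeline-level seed is split into independent
#' per-stage streams so that re-running one stage does not perturb the
#' random numbers consumed by another. The derived seed is a deterministic
#' hash of the master seed and the stage label, kept below 2^31.
#'
#' @param seed Integer master seed.
#' @param stage Character stage label (e.g. "schedule", "agent", "spikes").
#' @return An integer seed in [0, 2^31 - 2].
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 48271 + h * 16807) %% 2147483563)
}

# Run expr with a temporarily-set RNG state; restores the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

# Error constructors: configuration vs structural problems are distinguished
# so callers (and tests) can match on class.
config_error <- function(field, msg) {
  stop(structure(class = c("xmodal_config_error", "error", "condition"),
                 list(message = sprintf("invalid configuration field '%s': %s",
                                        field, msg),
                      call = sys.call(-1), field = field)))
}

structural_error <- function(msg) {
  stop(structure(class = c("xmodal_structural_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    config_error(field, "must be a probability in [0, 1]")
  invisible(x)
}

check_window <- function(w, field) {
  if (!is.numeric(w) || length(w) != 2L || any(is.na(w)) || w[1] > w[2])
    config_error(field, "must be an ordered numeric pair")
  invisible(w)
}

is_trial_table <- function(x) {
  is.data.frame(x) &&
    all(c("block_index", "block_rule", "trial_index", "trial_in_block",
          "modality", "stim_onset", "licks") %in% names(x))
}

assert_trial_table <- function(x) {
  if (!is_trial_table(x))
    structural_error("expected a trial table (see generate_schedule())")
  invisible(x)
}
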