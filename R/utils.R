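stopf <- function(fmt, ..., class = NULL) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "sbdar_error")))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is_scalar_number(x)) {
    stopf("`%s` must be a single finite number", name, class = "sbdar_validation")
  }
  if (x < lower || x > upper) {
    stopf("`%s` = %g is outside [%g, %g]", name, x, lower, upper,
          class = "sbdar_validation")
  }
  invisible(x)
}

# Deterministic stage-seed derivation from one user-facing seed; values are
# kept below 2^31 - 1 so they remain valid R integers.
derive_seed <- function(seed, stage) {
  offsets <- c(scene = 101L, movement = 131L, noise = 151L, eemd = 211L,
               cohort = 401L, profile = 503L)
  if (!stage %in% names(offsets)) stopf("unknown seed stage '%s'", stage)
  as.integer((as.double(seed) * 7919 + offsets[[stage]]) %% 2147483647)
}

# Run a pipeline stage, prefixing any error with the stage name while
# preserving condition classes so callers can still test for them.
run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(sprintf("[%s] %s", name, conditionMessage(e)),
                        class = unique(c(class(e)[class(e) != "condition"],
                                         "sbdar_stage_error"))))
  })
}
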