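# Condition helpers -------------------------------------------------------
#
# All user-facing failures are classed conditions so callers (and the CLI)
# can distinguish bad input (exit code 2) from computation failures (3).

abort <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c(class, "mixo_error")))
}

abort_validation <- function(msg, ...) {
  abort("mixo_validation_error", msg, ...)
}

abort_config <- function(msg, ...) {
  abort(c("mixo_config_error", "mixo_validation_error"), msg, ...)
}

abort_mixing <- function(msg, ...) {
  abort(c("mixo_mixing_error", "mixo_validation_error"), msg, ...)
}

abort_io <- function(msg, ...) {
  abort(c("mixo_io_error", "mixo_validation_error"), msg, ...)
}

warn_mixo <- function(msg, ...) {
  warning(warningCondition(sprintf(msg, ...), class = "mixo_warning"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  })
  set.seed(seed)
  force(code)
}

check_number <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort_validation("`%s` must be a single non-missing number", name)
  }
  if (finite && !is.finite(x)) {
    abort_validation("`%s` must be finite", name)
  }
  if (positive && x <= 0) {
    abort_validation("`%s` must be > 0 (got %g)", name, x)
  }
  invisible(x)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort_validation("%s is missing required column(s): %s",
                     what, paste(missing, collapse = ", "))
  }
  invisible(df)
}
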