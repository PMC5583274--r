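# Internal helpers shared across modules.

# Run code with a temporarily fixed RNG state; the caller's stream is untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

stop_mrmqc <- function(msg, class) {
  abort(msg, class = c(class, "mrmqc_error"))
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop_mrmqc(
      sprintf("`%s` must be a single number in [%s, %s].", name, lower, upper),
      "mrmqc_validation_error"
    )
  }
  invisible(x)
}

# Coefficient of variation in percent; NA-safe for the degenerate all-missing case.
cv_pct <- function(x) {
  m <- mean(x, na.rm = TRUE)
  if (!is.finite(m) || m == 0) return(NA_real_)
  100 * sd(x, na.rm = TRUE) / m
}

# log2 with explicit propagation of non-positive areas to NA (never -Inf).
log2_area <- function(x) {
  out <- ifelse(is.na(x) | x <= 0, NA_real_, x)
  log2(out)
}
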