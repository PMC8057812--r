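# internal helpers shared across modules

#' Evaluate code under a temporary RNG seed
#'
#' Runs \code{code} with the global RNG seeded to \code{seed} and restores the
#' previous RNG state afterwards, so that seeded rendering/simulation never
#' perturbs the caller's random stream.
#'
#' @param seed integer scalar.
#' @param code expression to evaluate.
#' @return The value of \code{code}.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# scalar validators: fail loudly with the argument name in the message
check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
  ok_lo <- if (strict_lower) x > lower else x >= lower
  ok_hi <- if (strict_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi) {
    stop(sprintf(
      "'%s' = %g is outside the allowed range %s%g, %g%s", name, x,
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]"
    ), call. = FALSE)
  }
  x
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be TRUE or FALSE", name), call. = FALSE)
  }
  x
}

check_point <- function(x, name) {
  if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x))) {
    stop(sprintf("'%s' must be a finite (x, y) pair", name), call. = FALSE)
  }
  as.numeric(x)
}

# smallest signed angular difference a - b, wrapped to (-pi, pi]
ang_diff <- function(a, b) {
  atan2(sin(a - b), cos(a - b))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
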