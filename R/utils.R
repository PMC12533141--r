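## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library code never perturbs the
#' caller's random stream. All stochastic stages route their randomness
#' through this helper, which is what makes cohorts and training runs
#' reproducible from a single master seed.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
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
  force(code)
}

## Deterministic child-seed derivation. Keeps every derived seed inside the
## 32-bit integer range regardless of the master seed's magnitude.
child_seed <- function(master, index, salt = 0L) {
  s <- (as.double(master) %% 2147480000) + 1
  v <- (s * 48271 + as.double(index) * 7919 + as.double(salt) * 104729) %% 2147483629
  as.integer(v)
}

stop_if_not_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                      strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (strict_lower && x <= lower) {
    stop(sprintf("`%s` must be > %g", name, lower), call. = FALSE)
  }
  if (!strict_lower && x < lower) {
    stop(sprintf("`%s` must be >= %g", name, lower), call. = FALSE)
  }
  if (x > upper) stop(sprintf("`%s` must be <= %g", name, upper), call. = FALSE)
  invisible(x)
}

## Linear interpolation over NA runs with edge values held; errors when
## nothing is left to interpolate from.
interp_na <- function(x) {
  ok <- is.finite(x)
  if (all(ok)) return(x)
  if (!any(ok)) stop("no valid samples left to interpolate from", call. = FALSE)
  idx <- seq_along(x)
  stats::approx(idx[ok], x[ok], xout = idx, method = "linear", rule = 2)$y
}
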