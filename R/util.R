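# Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Trapezoidal integral
#' @param x strictly increasing abscissae
#' @param y ordinates
#' @return numeric scalar
#' @keywords internal
#' @noRd
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# Cumulative trapezoidal integral, same length as x (first element 0).
cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((y[-1] + y[-n]) * diff(x) / 2))
}

# Geometric (log-spaced) grid. Endpoints included.
geom_grid <- function(lo, hi, n) {
  stopifnot(lo > 0, hi > lo, n >= 2)
  exp(seq(log(lo), log(hi), length.out = n))
}

# Run code with a local RNG state so callers' streams are not disturbed.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

stop_domain <- function(...) stop(..., call. = FALSE)

assert_scalar_num <- function(x, name, lower = -Inf, allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_domain(sprintf("'%s' must be a single non-missing number", name))
  if (!allow_inf && !is.finite(x))
    stop_domain(sprintf("'%s' must be finite", name))
  if (x < lower)
    stop_domain(sprintf("'%s' must be >= %g (got %g)", name, lower, x))
  invisible(x)
}

# Smallest nu with cumulative Poisson mass >= 1 - eps (and at least 1).
poisson_truncation <- function(lambda, eps = 1e-9) {
  if (lambda <= 0) return(0L)
  nu <- stats::qpois(eps, lambda, lower.tail = FALSE)
  nu <- as.integer(nu) + 2L  # guard against qpois edge behaviour
  while (stats::ppois(nu, lambda) < 1 - eps) nu <- nu + 1L
  nu
}
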