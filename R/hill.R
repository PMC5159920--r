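#' Four-parameter Hill dose-response function
#'
#' Evaluates `f(x) = a + b * x^n / (k^n + x^n)`, the generic sigmoidal
#' dose-response used throughout the package: `a` is the basal response at
#' zero dose, `b` the dynamic range (maximum minus basal), `k` the
#' half-maximal dose, and `n` the Hill coefficient controlling steepness.
#' `n > 1` is an ultrasensitive (switch-like) response, `n = 1` Michaelian,
#' `n < 1` negative cooperativity.
#'
#' The ratio is computed in log space via
#' `exp(n * (log(x) - log(k)))`, with `x = 0` short-circuited to `a`, so the
#' evaluation is overflow-free even for very steep curves (e.g. `n = 100`).
#'
#' @param x Dose(s), non-negative numeric vector (same units as `k`).
#' @param a Basal response, `a >= 0`.
#' @param b Dynamic range (maximum minus basal), `b >= 0`.
#' @param k Half-maximal dose, `k > 0`.
#' @param n Hill coefficient, `n > 0`.
#'
#' @return Numeric vector of responses, same length as `x`. `hill(0) = a`,
#'   `hill(k) = a + b/2`, and `hill(x) -> a + b` as `x -> Inf`.
#' @export
#' @examples
#' hill(8.33, a = 0.1, b = 0.9, k = 8.33, n = 4) # 0.55 = a + b/2
#' hill(0, a = 0.1, b = 0.9, k = 8.33, n = 4) # 0.1 = a
hill <- function(x, a, b, k, n) {
  check_hill_params(a, b, k, n)
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)) || any(x < 0)) {
    abort("`x` must be a finite, non-negative numeric vector.")
  }
  out <- numeric(length(x))
  pos <- x > 0
  if (any(pos)) {
    # logistic form of the Hill ratio: x^n/(k^n + x^n) = plogis(n*(log x - log k))
    z <- n * (log(x[pos]) - log(k))
    out[pos] <- a + b * stats::plogis(z)
  }
  out[!pos] <- a
  out
}

#' Validate Hill parameters
#'
#' @param a,b,k,n Scalar Hill parameters (see [hill()]).
#' @return Invisibly, a named numeric vector `c(a, b, k, n)`.
#' @export
check_hill_params <- function(a, b, k, n) {
  p <- c(a = a, b = b, k = k, n = n)
  if (length(p) != 4 || anyNA(p) || any(!is.finite(p))) {
    abort("Hill parameters a, b, k, n must be finite scalars.")
  }
  if (a < 0) abort("Hill parameter `a` must be >= 0.")
  if (b < 0) abort("Hill parameter `b` must be >= 0.")
  if (k <= 0) abort("Hill parameter `k` must be > 0.")
  if (n <= 0) abort("Hill parameter `n` must be > 0.")
  invisible(p)
}
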