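#' Decreasing Hill inhibition arm
#'
#' Constructs one inhibitory arm of the loop: a decreasing Hill-type
#' dose-response
#' \deqn{g(x) = \frac{\gamma}{\delta^h + x^h}, \qquad x \ge 0,}
#' the standard sigmoid form for inhibitory biological interactions.
#' `gamma` sets the maximal output (attained at `x = 0`, where
#' `g(0) = gamma / delta^h`), `delta` is the half-inhibition scale (at
#' `x = delta` the output is half its maximum), and `h` is the Hill
#' coefficient controlling steepness.
#'
#' `h` may be any real number greater than or equal to 1; values below 1
#' are rejected because they make the derivative of `g` unbounded at 0.
#'
#' @param gamma Positive real. Maximal output parameter (dimensionless
#'   concentration units).
#' @param delta Positive real. Half-inhibition scale, in the units of the
#'   input `x`.
#' @param h Real `>= 1`. Hill coefficient (dimensionless).
#'
#' @return An object of class `"hill_arm"`.
#' @examples
#' arm <- hill_arm(gamma = 3, delta = 1, h = 2)
#' hill(arm, 0)    # maximum: gamma / delta^h = 3
#' hill(arm, 1)    # half-maximum: 1.5
#' @export
hill_arm <- function(gamma, delta, h) {
  stopifnot(is.numeric(gamma), length(gamma) == 1L, is.finite(gamma),
            is.numeric(delta), length(delta) == 1L, is.finite(delta),
            is.numeric(h),     length(h) == 1L,     is.finite(h))
  if (gamma <= 0) stop("'gamma' must be > 0, got ", gamma)
  if (delta <= 0) stop("'delta' must be > 0, got ", delta)
  if (h < 1)      stop("'h' must be >= 1, got ", h)
  structure(list(gamma = as.numeric(gamma),
                 delta = as.numeric(delta),
                 h     = as.numeric(h)),
            class = "hill_arm")
}

#' Evaluate a decreasing Hill arm
#'
#' Computes `g(x) = gamma / (delta^h + x^h)`. Strictly decreasing on
#' `x >= 0`, bounded in `(0, gamma / delta^h]`.
#'
#' @param arm A [hill_arm()].
#' @param x Numeric vector of nonnegative inputs.
#' @return Numeric vector of the same length as `x`.
#' @export
hill <- function(arm, x) {
  stopifnot(inherits(arm, "hill_arm"), is.numeric(x))
  if (any(x < 0, na.rm = TRUE)) stop("hill() is defined for x >= 0 only")
  arm$gamma / (arm$delta^arm$h + x^arm$h)
}

#' Derivative of a decreasing Hill arm
#'
#' `g'(x) = -gamma * h * x^(h-1) / (delta^h + x^h)^2`, which is finite for
#' all `x >= 0` when `h >= 1` (for `h = 1` the limit at 0 is
#' `-gamma / delta^2`; R's `0^0 == 1` convention yields it directly).
#'
#' @inheritParams hill
#' @return Numeric vector of derivatives, all `<= 0`.
#' @export
hill_deriv <- function(arm, x) {
  stopifnot(inherits(arm, "hill_arm"), is.numeric(x))
  if (any(x < 0, na.rm = TRUE)) stop("hill_deriv() is defined for x >= 0 only")
  -arm$gamma * arm$h * x^(arm$h - 1) / (arm$delta^arm$h + x^arm$h)^2
}

#' Maximum of a Hill arm
#'
#' The supremum of `g` on `x >= 0`, attained at `x = 0`:
#' `gamma / delta^h`.
#'
#' @inheritParams hill
#' @return A positive scalar.
#' @export
hill_max <- function(arm) {
  stopifnot(inherits(arm, "hill_arm"))
  arm$gamma / arm$delta^arm$h
}

#' @export
print.hill_arm <- function(x, ...) {
  cat(sprintf("Decreasing Hill arm: g(x) = %.6g / (%.6g^%.6g + x^%.6g)  [max %.6g]\n",
              x$gamma, x$delta, x$h, x$h, hill_max(x)))
  invisible(x)
}
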