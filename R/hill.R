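#' Shifted Hill regulation factor
#'
#' Sigmoidal factor by which a regulator `Y` scales the synthesis or
#' degradation of its target:
#' \deqn{H_s(Y; S, \lambda, n) = 1 + (\lambda - 1)\frac{Y^n}{S^n + Y^n}}
#' The factor equals 1 when `Y = 0` and saturates at the fold change
#' `lambda` as `Y` grows; `lambda > 1` is activation, `lambda < 1`
#' inhibition, `lambda = 1` no regulation.
#'
#' @param Y regulator level(s), non-negative numeric (vectorized).
#' @param S half-saturation threshold, `> 0` (concentration units).
#' @param lambda fold change at saturation, `> 0`.
#' @param n Hill exponent, integer `>= 1` (cooperativity).
#' @return the regulation factor, bounded between `min(1, lambda)` and
#'   `max(1, lambda)`.
#' @examples
#' shifted_hill(0, 1, 2, 4)        # 1: no regulator present
#' shifted_hill(1, 1, 2, 4)        # (1 + 2)/2: half saturation
#' shifted_hill(1e6, 1, 0.1, 2)    # ~0.1: saturated inhibition
#' @export
shifted_hill <- function(Y, S, lambda, n) {
  if (any(Y < 0)) stop("regulator level Y must be non-negative")
  if (S <= 0) stop("threshold S must be positive")
  if (n < 1) stop("Hill exponent n must be >= 1")
  Yn <- (Y / S)^n
  1 + (lambda - 1) * Yn / (1 + Yn)
}

# dHs/dY, same domain checks as shifted_hill; vectorized in Y.
# At Y = 0 with n >= 2 the derivative vanishes (Y^n is flat at the origin);
# n = 1 gives (lambda-1)/S.
shifted_hill_deriv <- function(Y, S, lambda, n) {
  if (any(Y < 0)) stop("regulator level Y must be non-negative")
  if (S <= 0) stop("threshold S must be positive")
  u <- (Y / S)^n
  denom <- (1 + u)^2
  # d/dY [u/(1+u)] with u = (Y/S)^n: n u / (Y (1+u)^2); handle Y = 0.
  out <- numeric(length(Y))
  pos <- Y > 0
  out[pos] <- (lambda - 1) * n * u[pos] / (Y[pos] * denom[pos])
  if (any(!pos)) out[!pos] <- if (n == 1) (lambda - 1) / S else 0
  out
}
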