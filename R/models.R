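# Bolus-transit model functions: exponentially modified Gaussian (EMG) and
# gamma variate (GVF), with analytic first derivatives.

# Scaled complementary error function erfcx(x) = exp(x^2) * erfc(x), stable
# for large positive x where the naive product overflows.  Below x = 6 the
# direct product is exact to double precision (exp(36) is representable);
# above, the asymptotic expansion 1/(x sqrt(pi)) * sum (-1)^n (2n-1)!!/(2x^2)^n
# has relative error < 1e-9 at x = 6 and improves rapidly.
erfcx_scaled <- function(x) {
  stopifnot(all(x >= 0))
  out <- numeric(length(x))
  lo <- x < 6
  if (any(lo)) {
    xl <- x[lo]
    # erfc via pnorm: erfc(x) = 2 * pnorm(-x * sqrt(2))
    out[lo] <- exp(xl^2) * 2 * stats::pnorm(-xl * sqrt(2))
  }
  if (any(!lo)) {
    xh <- x[!lo]
    # s = sum_{n>=0} (-1)^n (2n-1)!! / (2x^2)^n
    inv2x2 <- 1 / (2 * xh^2)
    s <- rep(1, length(xh))
    term <- rep(1, length(xh))
    for (n in 1:10) {
      term <- term * (-(2 * n - 1)) * inv2x2
      s <- s + term
    }
    out[!lo] <- s / (xh * sqrt(pi))
  }
  out
}

#' Evaluate the exponentially modified Gaussian model
#'
#' The EMG is the convolution of a Gaussian bolus (location `b`, width `c`)
#' with a one-sided exponential dispersion kernel (decay time `d`), scaled so
#' that the peak height approaches `a` in the narrow-kernel limit:
#' \deqn{F(t) = \frac{a c \sqrt{2\pi}}{2d}
#'   \exp\!\Big(\frac{b-t}{d} + \frac{c^2}{2d^2}\Big)
#'   \Big[\mathrm{sgn}(d) - \mathrm{erf}\Big(\frac{b-t}{\sqrt{2}c} +
#'   \frac{c}{\sqrt{2}d}\Big)\Big]}
#' with the standard normalized error function. Evaluation is numerically
#' stabilized through the scaled complementary error function so that no
#' overflow occurs far into the tails.
#'
#' @param params numeric vector `(a, b, c, d)`: amplitude (intensity),
#'   Gaussian center (s), Gaussian width (s), exponential decay time (s).
#'   Requires `c > 0` and `d != 0`; the physiological branch uses `d > 0`.
#' @param t numeric vector of times (s).
#' @return numeric vector of model intensities, same length as `t`.
#' @seealso [gvf_eval()], [emg_deriv()]
#' @export
emg_eval <- function(params, t) {
  params <- check_emg_params(params)
  a <- params[1]; b <- params[2]; cc <- params[3]; d <- params[4]
  # sgn(d) - erf(u) = erfc(sgn(d) * u) for both signs of d; with
  # u = (b-t)/(sqrt(2) c) + c/(sqrt(2) d) the exponent identity
  # E - u^2 = -(t-b)^2 / (2 c^2) holds, giving the stable form
  # F = (a c sqrt(2*pi) / (2|d|)) * exp(-(t-b)^2/(2c^2)) * erfcx(w),  w >= 0.
  u <- (b - t) / (sqrt(2) * cc) + cc / (sqrt(2) * d)
  w <- sign(d) * u
  k <- a * cc * sqrt(2 * pi) / (2 * abs(d))
  out <- numeric(length(t))
  pos <- w >= 0
  if (any(pos)) {
    out[pos] <- k * exp(-(t[pos] - b)^2 / (2 * cc^2)) * erfcx_scaled(w[pos])
  }
  if (any(!pos)) {
    e <- (b - t[!pos]) / d + cc^2 / (2 * d^2)
    out[!pos] <- k * exp(e) * (2 * stats::pnorm(-w[!pos] * sqrt(2)))
  }
  out
}

#' Analytic first derivative of the EMG model
#'
#' Uses the closed form `F'(t) = (a exp(-(t-b)^2/(2 c^2)) - F(t)) / d`,
#' obtained by differentiating the stabilized EMG expression.
#'
#' @inheritParams emg_eval
#' @return numeric vector of slopes (intensity / s).
#' @export
emg_deriv <- function(params, t) {
  params <- check_emg_params(params)
  a <- params[1]; b <- params[2]; cc <- params[3]; d <- params[4]
  (a * exp(-(t - b)^2 / (2 * cc^2)) - emg_eval(params, t)) / d
}

check_emg_params <- function(params) {
  params <- as.numeric(params)
  if (length(params) != 4L || anyNA(params)) {
    stop("EMG parameters must be a numeric vector (a, b, c, d)", call. = FALSE)
  }
  if (params[3] <= 0) stop("EMG width parameter c must be > 0", call. = FALSE)
  if (params[4] == 0) stop("EMG decay parameter d must be nonzero", call. = FALSE)
  params
}

#' Evaluate the gamma variate model
#'
#' `G(t) = A t^a exp(-t / b)`, the classic bolus-passage model, defined for
#' `t >= 0` with `A, a, b > 0`. The peak sits at `t = a b` with height
#' `A (a b)^a e^{-a}`.
#'
#' @param params numeric vector `(A, a, b)`: scale, shape exponent, decay
#'   time (s).
#' @param t numeric vector of times (s), all `>= 0`.
#' @return numeric vector of model intensities.
#' @export
gvf_eval <- function(params, t) {
  params <- check_gvf_params(params)
  if (any(t < 0)) stop("gamma variate model is defined on t >= 0", call. = FALSE)
  A <- params[1]; a <- params[2]; b <- params[3]
  A * t^a * exp(-t / b)
}

#' Analytic first derivative of the gamma variate model
#'
#' `G'(t) = A exp(-t/b) t^(a-1) (a - t/b)`. At `t = 0` the limit is 0 for
#' `a > 1`, `A` for `a = 1`, and diverges for `a < 1`.
#'
#' @inheritParams gvf_eval
#' @return numeric vector of slopes (intensity / s).
#' @export
gvf_deriv <- function(params, t) {
  params <- check_gvf_params(params)
  if (any(t < 0)) stop("gamma variate model is defined on t >= 0", call. = FALSE)
  A <- params[1]; a <- params[2]; b <- params[3]
  out <- A * exp(-t / b) * t^(a - 1) * (a - t / b)
  at0 <- t == 0
  if (any(at0)) {
    out[at0] <- if (a > 1) 0 else if (a == 1) A else Inf
  }
  out
}

check_gvf_params <- function(params) {
  params <- as.numeric(params)
  if (length(params) != 3L || anyNA(params)) {
    stop("GVF parameters must be a numeric vector (A, a, b)", call. = FALSE)
  }
  if (any(params <= 0)) stop("GVF parameters A, a, b must all be > 0", call. = FALSE)
  params
}

# Evaluate the enhancement component of either model on model-local time
# (time since onset for GVF; absolute time for EMG, whose location parameter
# absorbs the onset). GVF is 0 before onset.
model_component <- function(model_kind, params, t_local) {
  if (model_kind == "EMG") {
    emg_eval(params, t_local)
  } else {
    v <- numeric(length(t_local))
    nn <- t_local >= 0
    v[nn] <- gvf_eval(params, t_local[nn])
    v
  }
}

model_component_deriv <- function(model_kind, params, t_local) {
  if (model_kind == "EMG") {
    emg_deriv(params, t_local)
  } else {
    v <- numeric(length(t_local))
    nn <- t_local >= 0
    v[nn] <- gvf_deriv(params, t_local[nn])
    v
  }
}
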