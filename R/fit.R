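# Levenberg-Marquardt fitting of perfusion models to measured curves.

#' Options controlling curve fitting
#'
#' @param max_iter maximum Levenberg-Marquardt iterations per start.
#' @param tolerance relative tolerance on the sum of squares (`ftol`).
#' @param n_restarts number of deterministically jittered restarts tried
#'   after a failed start.
#' @param k_sigma,m_baseline baseline-detection settings forwarded to
#'   [detect_baseline_end()] when the curve carries no `t0_index`.
#' @return a list of class `ceus_fit_options`.
#' @export
fit_options <- function(max_iter = 200, tolerance = 1e-10, n_restarts = 4,
                        k_sigma = 3, m_baseline = 5) {
  structure(list(max_iter = as.integer(max_iter), tolerance = tolerance,
                 n_restarts = as.integer(n_restarts), k_sigma = k_sigma,
                 m_baseline = as.integer(m_baseline)),
            class = "ceus_fit_options")
}

n_params <- function(model_kind) if (model_kind == "EMG") 4L else 3L

new_failed_fit <- function(model_kind, reason, n_obs) {
  structure(list(model_kind = model_kind, params = rep(NA_real_, n_params(model_kind)),
                 baseline = NA_real_, t_onset = NA_real_, converged = FALSE,
                 adj_r2 = NA_real_, residual_norm = NA_real_, n_obs = n_obs,
                 reason = reason),
            class = "ceus_fit")
}

#' Fit a perfusion model to a measured curve
#'
#' Least-squares fit of the EMG or gamma variate model by the
#' Levenberg-Marquardt algorithm (via [minpack.lm::nls.lm()]). The baseline
#' level is estimated as the mean of the samples up to the detected baseline
#' end and subtracted before fitting. The gamma variate model, which starts
#' at zero, is evaluated on time since the baseline end (`t_onset`); the EMG
#' model is fitted on the absolute time axis, its location parameter `b`
#' absorbing the onset. Parameters are restricted to the physiological
#' positive branch (`a, c, d > 0` for EMG; `A, a, b > 0` for GVF).
#'
#' A fit is reported non-converged when the iteration limit is hit on every
#' start, residuals become non-finite, the curve shows no enhancement, or
#' the fitted peak lies outside the acquisition window. Failed fits carry a
#' `reason` and `NA` parameters; they are never silently dropped.
#'
#' @param curve a [perfusion_curve()] with at least `p + 2` samples
#'   (`p` = number of model parameters).
#' @param model_kind `"EMG"` or `"GVF"`.
#' @param options a [fit_options()] list.
#' @return an object of class `ceus_fit`: fields `model_kind`, `params`
#'   (`(a,b,c,d)` or `(A,a,b)`), `baseline`, `t_onset`, `converged`,
#'   `adj_r2`, `residual_norm`, `n_obs`, `reason`.
#' @export
fit_curve <- function(curve, model_kind = c("EMG", "GVF"), options = fit_options()) {
  stopifnot(inherits(curve, "perfusion_curve"))
  model_kind <- match.arg(model_kind)
  p <- n_params(model_kind)
  tt <- curve$times
  y <- curve$intensities
  n <- length(y)
  if (n <= p + 1L) {
    stop(sprintf("need more than %d samples to fit %s (adjusted R^2 undefined)",
                 p + 1L, model_kind), call. = FALSE)
  }

  if (is.null(curve$t0_index)) {
    curve <- tryCatch(
      detect_baseline_end(curve, k_sigma = options$k_sigma, m = options$m_baseline),
      ceus_no_enhancement = function(e) NULL)
    if (is.null(curve)) return(new_failed_fit(model_kind, "no_enhancement", n))
  }
  i0 <- curve$t0_index
  baseline <- mean(y[seq_len(i0)])
  t_onset <- if (model_kind == "GVF") tt[i0] else 0
  t_local <- tt - t_onset
  ydev <- y - baseline
  if (max(ydev) <= 0) return(new_failed_fit(model_kind, "no_enhancement", n))

  start0 <- init_params(model_kind, t_local, ydev, i0)
  lower <- if (model_kind == "EMG") c(1e-8, -Inf, 1e-8, 1e-8) else rep(1e-8, 3)

  resid_fun <- function(par) {
    r <- ydev - model_component(model_kind, par, t_local)
    r[!is.finite(r)] <- 1e6
    r
  }

  # a candidate solution is accepted only if its fitted peak lies strictly
  # inside the acquisition window; degenerate ramp-like optima (peak at the
  # window edge) trigger the jittered restarts instead of being kept
  grid <- seq(tt[1], tt[n], length.out = 2001L)
  peak_interior <- function(par) {
    imax <- which.max(model_component(model_kind, par, grid - t_onset))
    imax > 1L && imax < length(grid)
  }

  best <- NULL       # best interior-peak solution
  best_edge <- NULL  # best convergent solution with an edge peak
  jitters <- restart_jitter(p, options$n_restarts)
  for (k in seq_len(options$n_restarts + 1L)) {
    start <- pmax(start0 * jitters[[k]][["mult"]], lower)
    res <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = lower, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = options$max_iter, ftol = options$tolerance,
                           ptol = options$tolerance)),
      error = function(e) NULL)
    if (is.null(res)) next
    ok <- res$info %in% 1:4 && all(is.finite(res$par)) && all(is.finite(res$fvec))
    if (!ok) next
    ss <- sum(res$fvec^2)
    if (peak_interior(res$par)) {
      if (is.null(best) || ss < best$ss) best <- list(par = res$par, ss = ss)
      break # first interior-peak solution wins further restarts
    }
    if (is.null(best_edge) || ss < best_edge$ss) best_edge <- list(par = res$par, ss = ss)
  }
  if (is.null(best)) {
    reason <- if (is.null(best_edge)) "no_convergence" else "peak_outside_window"
    return(new_failed_fit(model_kind, reason, n))
  }

  par <- unname(best$par)
  fitted <- baseline + model_component(model_kind, par, t_local)
  adj <- tryCatch(adjusted_r2(y, fitted, p), error = function(e) NA_real_)
  structure(list(model_kind = model_kind, params = par, baseline = baseline,
                 t_onset = t_onset, converged = TRUE, adj_r2 = adj,
                 residual_norm = sqrt(best$ss), n_obs = n, reason = "ok"),
            class = "ceus_fit")
}

# Data-driven starting values (documented in the methods vignette):
# amplitude from the observed peak, location from the observed peak time,
# width a quarter of the enhancement duration (time span above 25% of the
# peak), decay from the 63% post-peak decay time (fallback: a quarter of
# the post-onset duration).
init_params <- function(model_kind, t_local, ydev, i0) {
  ip <- which.max(ydev)
  peak <- ydev[ip]
  tp <- max(t_local[ip], t_local[2] - t_local[1])
  dur <- t_local[length(t_local)] - max(t_local[i0], 0)
  if (model_kind == "EMG") {
    above <- which(ydev >= 0.25 * peak)
    enh_dur <- if (length(above) >= 2) t_local[above[length(above)]] - t_local[above[1]] else dur
    post <- which(t_local > t_local[ip] & ydev <= 0.37 * peak)
    d0 <- if (length(post)) t_local[post[1]] - t_local[ip] else dur / 4
    c(a = peak, b = t_local[ip], c = max(enh_dur / 4, 1e-3), d = max(d0, 1e-3))
  } else {
    a0 <- 2
    b0 <- max(tp / a0, 1e-3)
    A0 <- peak / (tp^a0 * exp(-a0))
    c(A = A0, a = a0, b = b0)
  }
}

# Deterministic multiplicative jitters for restarts (no RNG involvement).
restart_jitter <- function(p, n_restarts) {
  base <- list(list(mult = rep(1, p)))
  facs <- c(0.5, 2, 0.25, 4, 0.8, 1.25)
  for (k in seq_len(n_restarts)) {
    f <- facs[((k - 1) %% length(facs)) + 1]
    base[[k + 1L]] <- list(mult = rep(f, p))
  }
  base
}

#' Build a model fit from known parameters
#'
#' Wraps known model parameters in a converged `ceus_fit` so that markers
#' and predictions can be computed for ground-truth kinetics (e.g. from the
#' synthetic generator) without fitting.
#'
#' @param model_kind `"EMG"` or `"GVF"`.
#' @param params numeric `(a,b,c,d)` or `(A,a,b)`.
#' @param baseline baseline intensity added to predictions (default 0).
#' @param t_onset model time origin in absolute seconds (default 0).
#' @return a converged `ceus_fit`.
#' @export
manual_fit <- function(model_kind = c("EMG", "GVF"), params, baseline = 0,
                       t_onset = 0) {
  model_kind <- match.arg(model_kind)
  params <- if (model_kind == "EMG") check_emg_params(params) else check_gvf_params(params)
  structure(list(model_kind = model_kind, params = unname(params),
                 baseline = baseline, t_onset = t_onset, converged = TRUE,
                 adj_r2 = NA_real_, residual_norm = NA_real_, n_obs = NA_integer_,
                 reason = "manual"),
            class = "ceus_fit")
}

#' Predict fitted intensities
#'
#' Returns `baseline + model(t - t_onset)` for a converged fit (the gamma
#' variate contribution is zero before onset).
#'
#' @param object a converged `ceus_fit`.
#' @param times numeric vector of absolute times (s).
#' @param ... unused.
#' @return numeric vector of intensities.
#' @export
predict.ceus_fit <- function(object, times, ...) {
  if (!object$converged) stop("cannot predict from a non-converged fit", call. = FALSE)
  object$baseline + model_component(object$model_kind, object$params,
                                    times - object$t_onset)
}

#' @export
print.ceus_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("<ceus_fit> %s converged, adj R^2 = %.4f, params = (%s)\n",
                x$model_kind, x$adj_r2, paste(signif(x$params, 5), collapse = ", ")))
  } else {
    cat(sprintf("<ceus_fit> %s FAILED (%s)\n", x$model_kind, x$reason))
  }
  invisible(x)
}

#' First derivative of a fitted model
#'
#' Analytic slope of the fitted enhancement model on the absolute time axis.
#'
#' @param fit a converged `ceus_fit`.
#' @param times numeric vector of absolute times (s).
#' @return numeric vector of slopes (intensity / s).
#' @export
model_derivative <- function(fit, times) {
  stopifnot(inherits(fit, "ceus_fit"))
  if (!fit$converged) {
    stop(errorCondition("model_derivative requires a converged fit",
                        class = c("ceus_invalid_state", "error", "condition")))
  }
  model_component_deriv(fit$model_kind, fit$params, times - fit$t_onset)
}
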