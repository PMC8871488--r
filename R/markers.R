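# Semi-quantitative perfusion markers derived from a fitted model and from
# the measured curve.

MARKER_NAMES <- c("wash_in", "wash_out", "ttp", "tmsp", "auc", "msi")

#' Compute semi-quantitative perfusion markers from a fitted model
#'
#' Markers are evaluated on a dense time grid over `window` (absolute time):
#' * `ttp` — time to peak: grid argmax of the fitted enhancement model;
#' * `wash_in` / `wash_out` — maximum / minimum of the analytic first
#'   derivative;
#' * `tmsp` — time of maximal slope (grid argmax of the derivative);
#' * `auc` — trapezoidal integral of the fitted enhancement model (baseline
#'   excluded) over the window.
#'
#' A time-valued marker is flagged undefined when its extremum falls on the
#' window boundary (no interior stationary point); `msi` is computed
#' separately on the measured curve by [compute_msi()] and left `NA` here.
#'
#' @param fit a converged `ceus_fit`.
#' @param window numeric `(t_start, t_end)` in absolute seconds.
#' @param grid_dt grid resolution in seconds (default 0.01); time-valued
#'   markers are accurate to within one grid step.
#' @return an object of class `marker_set`: numeric fields
#'   `wash_in, wash_out, ttp, tmsp, auc, msi` plus a logical `defined` flag
#'   vector of the same names.
#' @export
compute_markers <- function(fit, window, grid_dt = 0.01) {
  stopifnot(inherits(fit, "ceus_fit"))
  if (!fit$converged) {
    stop(errorCondition("compute_markers requires a converged fit",
                        class = c("ceus_invalid_state", "error", "condition")))
  }
  if (length(window) != 2L || window[2] <= window[1]) {
    stop("window must be (t_start, t_end) with t_end > t_start", call. = FALSE)
  }
  grid <- seq(window[1], window[2], by = grid_dt)
  if (grid[length(grid)] < window[2]) grid <- c(grid, window[2])
  vals <- model_component(fit$model_kind, fit$params, grid - fit$t_onset)
  dvals <- model_component_deriv(fit$model_kind, fit$params, grid - fit$t_onset)
  dvals[!is.finite(dvals)] <- NA_real_

  ng <- length(grid)
  interior <- function(i) i > 1L && i < ng

  i_peak <- which.max(vals)
  i_up <- which.max(dvals)
  i_dn <- which.min(dvals)

  defined <- c(wash_in = interior(i_up), wash_out = interior(i_dn),
               ttp = interior(i_peak), tmsp = interior(i_up),
               auc = TRUE, msi = FALSE)
  m <- list(
    wash_in = if (defined[["wash_in"]]) dvals[i_up] else NA_real_,
    wash_out = if (defined[["wash_out"]]) dvals[i_dn] else NA_real_,
    ttp = if (defined[["ttp"]]) grid[i_peak] else NA_real_,
    tmsp = if (defined[["tmsp"]]) grid[i_up] else NA_real_,
    auc = sum(diff(grid) * (vals[-1] + vals[-ng]) / 2),
    msi = NA_real_)
  structure(c(m, list(defined = defined)), class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  v <- vapply(MARKER_NAMES, function(nm) x[[nm]], numeric(1))
  cat("<marker_set>\n")
  for (nm in MARKER_NAMES) {
    cat(sprintf("  %-8s %s%s\n", nm, signif(v[[nm]], 6),
                if (x$defined[[nm]]) "" else " (undefined)"))
  }
  invisible(x)
}

#' Mean slope of increase on the measured curve
#'
#' MSI averages the consecutive intensity increments of the *measured* curve
#' from the end of the baseline to the acquisition sample nearest the time
#' to peak: `MSI = (1/N) * sum_i [Ct(t_{i+1}) - Ct(t_i)]`, `N` the number of
#' increments. By telescoping, `MSI * N = Ct(t_TTP) - Ct(t0)` exactly.
#'
#' @param curve a [perfusion_curve()] with `t0_index` set.
#' @param ttp time to peak in absolute seconds (must exceed the baseline-end
#'   time, with at least one acquisition sample in between).
#' @return the MSI (intensity per sample interval).
#' @export
compute_msi <- function(curve, ttp) {
  stopifnot(inherits(curve, "perfusion_curve"))
  if (is.null(curve$t0_index)) stop("curve has no t0_index; run detect_baseline_end first",
                                    call. = FALSE)
  i0 <- curve$t0_index
  tt <- curve$times
  if (ttp <= tt[i0]) stop("ttp must exceed the baseline-end time", call. = FALSE)
  d <- abs(tt - ttp)
  j <- which(d == min(d))[1] # ties -> earlier sample
  if (j <= i0) stop("no acquisition sample between baseline end and ttp", call. = FALSE)
  (curve$intensities[j] - curve$intensities[i0]) / (j - i0)
}
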