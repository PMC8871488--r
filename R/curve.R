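# Core containers: perfusion curves, cine loops, ROI masks.

#' Construct a perfusion curve
#'
#' A perfusion curve is one voxel's contrast-enhancement time series:
#' strictly increasing acquisition times and the matching intensities
#' (arbitrary units), optionally annotated with the index of the last
#' baseline sample (`t0_index`, 1-based), as set by [detect_baseline_end()].
#'
#' @param times numeric vector of acquisition times (s), strictly increasing.
#' @param intensities numeric vector of intensities, same length, all finite.
#' @param t0_index optional 1-based index of the final baseline sample.
#' @return an object of class `perfusion_curve`.
#' @export
perfusion_curve <- function(times, intensities, t0_index = NULL) {
  times <- as.numeric(times)
  intensities <- as.numeric(intensities)
  if (length(times) != length(intensities)) {
    stop("times and intensities must have equal length", call. = FALSE)
  }
  if (length(times) < 2L || any(diff(times) <= 0)) {
    stop("times must be strictly increasing (length >= 2)", call. = FALSE)
  }
  if (anyNA(intensities) || any(!is.finite(intensities))) {
    stop("intensities must be finite", call. = FALSE)
  }
  if (!is.null(t0_index)) {
    t0_index <- as.integer(t0_index)
    if (t0_index < 1L || t0_index >= length(times)) {
      stop("t0_index out of range", call. = FALSE)
    }
  }
  structure(list(times = times, intensities = intensities, t0_index = t0_index),
            class = "perfusion_curve")
}

#' @export
print.perfusion_curve <- function(x, ...) {
  cat(sprintf("<perfusion_curve> %d samples, t = [%g, %g] s, t0_index = %s\n",
              length(x$times), x$times[1], x$times[length(x$times)],
              if (is.null(x$t0_index)) "unset" else x$t0_index))
  invisible(x)
}

#' Construct a cine loop
#'
#' A cine loop is a time-ordered stack of grayscale frames: a `T x H x W`
#' array of non-negative intensities with one timestamp per frame.
#'
#' @param frames numeric array `T x H x W` (time, row, column).
#' @param times numeric vector of frame timestamps (s), strictly increasing.
#' @param region_tag one of `"RAW"`, `"BMODE"`, `"CEUS"` describing which
#'   screen region the frames come from.
#' @return an object of class `cine_loop`.
#' @export
cine_loop <- function(frames, times, region_tag = c("RAW", "BMODE", "CEUS")) {
  region_tag <- match.arg(region_tag)
  if (length(dim(frames)) != 3L) stop("frames must be a T x H x W array", call. = FALSE)
  times <- as.numeric(times)
  if (dim(frames)[1] != length(times)) {
    stop("number of frames must match length of times", call. = FALSE)
  }
  if (length(times) >= 2L && any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  structure(list(frames = frames, times = times, region_tag = region_tag),
            class = "cine_loop")
}

#' @export
print.cine_loop <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<cine_loop> %d frames of %d x %d [%s], t = [%g, %g] s\n",
              d[1], d[2], d[3], x$region_tag, x$times[1], x$times[d[1]]))
  invisible(x)
}

#' Construct a region-of-interest mask
#'
#' @param mask logical `H x W` matrix; `TRUE` marks lesion voxels.
#' @param patient_id character scalar.
#' @param class_label `"benign"` or `"malignant"`.
#' @return an object of class `roi_mask`.
#' @export
roi_mask <- function(mask, patient_id, class_label = c("benign", "malignant")) {
  class_label <- match.arg(class_label)
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop("mask must be a logical matrix", call. = FALSE)
  }
  if (!any(mask)) stop("mask must contain at least one TRUE voxel", call. = FALSE)
  structure(list(mask = mask, patient_id = as.character(patient_id),
                 class_label = class_label),
            class = "roi_mask")
}

#' Adjusted coefficient of determination
#'
#' Goodness-of-fit criterion penalized for model size:
#' \deqn{\bar R^2 = 1 - (1 - R^2)\frac{N-1}{N-p-1}, \qquad
#'       R^2 = 1 - SS_{res}/SS_{tot}.}
#' Values can be negative for fits worse than the mean predictor; they are
#' returned as computed.
#'
#' @param observed numeric vector of measured values.
#' @param fitted numeric vector of model predictions, same length.
#' @param p number of model parameters (4 for EMG, 3 for GVF).
#' @return the adjusted R-squared (scalar).
#' @export
adjusted_r2 <- function(observed, fitted, p) {
  n <- length(observed)
  if (length(fitted) != n) stop("observed and fitted must have equal length", call. = FALSE)
  if (n - p - 1 <= 0) stop("adjusted R^2 undefined: need N - p - 1 > 0", call. = FALSE)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("observed values have zero variance", call. = FALSE)
  r2 <- 1 - sum((observed - fitted)^2) / ss_tot
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Detect the end of the pre-contrast baseline
#'
#' The baseline end `t0` is the last sample before the first intensity that
#' exceeds `mean + k_sigma * SD` of the first `m` samples. A single-sample
#' reference window (`m = 1`) uses SD = 0.
#'
#' @param curve a [perfusion_curve()].
#' @param k_sigma threshold multiplier (default 3).
#' @param m number of leading samples defining the baseline statistics
#'   (default 5).
#' @return the input curve with `t0_index` set (1-based index of the last
#'   baseline sample).
#' @export
detect_baseline_end <- function(curve, k_sigma = 3, m = 5) {
  stopifnot(inherits(curve, "perfusion_curve"))
  y <- curve$intensities
  n <- length(y)
  m <- min(as.integer(m), n)
  if (m < 1L) stop("m must be >= 1", call. = FALSE)
  mu <- mean(y[seq_len(m)])
  sdv <- if (m >= 2L) stats::sd(y[seq_len(m)]) else 0
  thr <- mu + k_sigma * sdv
  exceed <- which(y > thr)
  exceed <- exceed[exceed >= 2L] # t0 must leave at least one baseline sample
  if (length(exceed) == 0L) {
    stop(errorCondition("no sample exceeds the baseline threshold (no enhancement)",
                        class = c("ceus_no_enhancement", "error", "condition")))
  }
  curve$t0_index <- exceed[1] - 1L
  curve
}
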