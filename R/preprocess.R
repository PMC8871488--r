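# Cine-loop pre-processing: luminance conversion, cropping, temporal
# subsampling, rigid translation registration, curve extraction.
#
# Coordinates are 1-based (row, col), row-major; rectangles are
# (row0, col0, height, width) with row0/col0 the 1-based top-left corner.

#' Convert an RGB frame to luminance
#'
#' Rec. 601 luma weights: `Y = 0.299 R + 0.587 G + 0.114 B`. The result is
#' kept as real values; quantization is deferred to file export.
#'
#' @param rgb_frame numeric array `H x W x 3` with values in `[0, 255]`.
#' @return `H x W` numeric matrix.
#' @export
to_luminance <- function(rgb_frame) {
  d <- dim(rgb_frame)
  if (length(d) != 3L || d[3] != 3L) {
    stop("rgb_frame must be an H x W x 3 array", call. = FALSE)
  }
  y <- 0.299 * rgb_frame[, , 1, drop = FALSE] +
    0.587 * rgb_frame[, , 2, drop = FALSE] +
    0.114 * rgb_frame[, , 3, drop = FALSE]
  matrix(y, d[1], d[2])
}

#' Crop a rectangular region from every frame
#'
#' @param loop a [cine_loop()].
#' @param rect `(row0, col0, height, width)`; `row0`, `col0` are the 1-based
#'   top-left corner of the region.
#' @param region_tag tag for the cropped loop (default keeps the input tag).
#' @return a [cine_loop()] of shape `T x height x width`; times unchanged.
#' @export
crop_region <- function(loop, rect, region_tag = loop$region_tag) {
  stopifnot(inherits(loop, "cine_loop"))
  rect <- as.integer(rect)
  if (length(rect) != 4L) stop("rect must be (row0, col0, height, width)", call. = FALSE)
  d <- dim(loop$frames)
  r0 <- rect[1]; c0 <- rect[2]; hh <- rect[3]; ww <- rect[4]
  if (r0 < 1L || c0 < 1L || hh < 1L || ww < 1L ||
      r0 + hh - 1L > d[2] || c0 + ww - 1L > d[3]) {
    stop("rect exceeds frame bounds", call. = FALSE)
  }
  cine_loop(loop$frames[, r0:(r0 + hh - 1L), c0:(c0 + ww - 1L), drop = FALSE],
            loop$times, region_tag)
}

#' Temporally subsample a cine loop
#'
#' For each target time `t_k = t_0 + k * dt` up to the last frame time, the
#' frame with the nearest timestamp is selected (ties resolved toward the
#' earlier frame). No interpolation: output frames are a subsequence of the
#' input frames and keep their original timestamps; targets mapping to an
#' already-selected frame are collapsed.
#'
#' @param loop a [cine_loop()].
#' @param dt target sampling interval (s), default 1.
#' @return a [cine_loop()].
#' @export
temporal_subsample <- function(loop, dt = 1.0) {
  stopifnot(inherits(loop, "cine_loop"))
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  tt <- loop$times
  targets <- seq(tt[1], tt[length(tt)], by = dt)
  idx <- vapply(targets, function(tk) {
    d <- abs(tt - tk)
    which(d == min(d))[1] # tie -> earlier frame
  }, integer(1))
  idx <- unique(idx)
  cine_loop(loop$frames[idx, , , drop = FALSE], tt[idx], loop$region_tag)
}

# integer-pixel translation (dy, dx) maximizing the circular
# cross-correlation of frame with ref, computed via FFT; returned as the
# correction to apply to frame. Ties broken toward the smallest shift.
estimate_shift <- function(ref, frame) {
  h <- nrow(ref); w <- ncol(ref)
  r <- ref - mean(ref); f <- frame - mean(frame)
  cc <- Re(stats::fft(stats::fft(r) * Conj(stats::fft(f)), inverse = TRUE))
  wrap <- function(k, n) ifelse(k > n / 2, k - n, k)
  best <- which(cc == max(cc), arr.ind = TRUE)
  dy <- wrap(best[, 1] - 1L, h)
  dx <- wrap(best[, 2] - 1L, w)
  pick <- which.min(abs(dy) + abs(dx))
  c(dy[pick], dx[pick])
}

shift_frame <- function(frame, dy, dx) {
  h <- nrow(frame); w <- ncol(frame)
  out <- matrix(0, h, w)
  src_r <- seq_len(h) - dy
  src_c <- seq_len(w) - dx
  ok_r <- src_r >= 1 & src_r <= h
  ok_c <- src_c >= 1 & src_c <= w
  out[which(ok_r), which(ok_c)] <- frame[src_r[ok_r], src_c[ok_c]]
  out
}

#' Register a cine loop by rigid integer translation
#'
#' Each frame is shifted by the integer-pixel translation that maximizes its
#' cross-correlation with the reference frame (mean-removed, FFT-based).
#' Pixels shifted in from outside the frame are filled with 0. The model is
#' rigid translation only; `engine` accepts a custom estimator
#' `function(ref, frame) -> c(dy, dx)` for richer transforms.
#'
#' @param loop a [cine_loop()] with at least two frames.
#' @param reference_index 1-based index of the reference frame.
#' @param engine shift estimator (default FFT cross-correlation).
#' @return a list: `loop` (registered [cine_loop()]) and `shifts`
#'   (`T x 2` matrix of applied `(dy, dx)` corrections; the reference row is
#'   `(0, 0)`).
#' @export
register_translation <- function(loop, reference_index = 1L,
                                 engine = estimate_shift) {
  stopifnot(inherits(loop, "cine_loop"))
  nt <- dim(loop$frames)[1]
  if (nt < 2L) stop("registration requires at least two frames", call. = FALSE)
  if (reference_index < 1L || reference_index > nt) {
    stop("reference_index out of range", call. = FALSE)
  }
  ref <- loop$frames[reference_index, , ]
  shifts <- matrix(0L, nt, 2, dimnames = list(NULL, c("dy", "dx")))
  frames <- loop$frames
  for (i in seq_len(nt)) {
    if (i == reference_index) next
    s <- engine(ref, loop$frames[i, , ])
    shifts[i, ] <- as.integer(s)
    if (any(s != 0)) frames[i, , ] <- shift_frame(loop$frames[i, , ], s[1], s[2])
  }
  list(loop = cine_loop(frames, loop$times, loop$region_tag), shifts = shifts)
}

#' Extract per-voxel perfusion curves
#'
#' @param loop a [cine_loop()].
#' @param mask an [roi_mask()] whose shape matches the loop frames.
#' @return a named list of [perfusion_curve()] objects keyed `"row,col"`,
#'   with attributes `coords` (matrix of row/col) and `patient_id`.
#' @export
extract_curves <- function(loop, mask) {
  stopifnot(inherits(loop, "cine_loop"), inherits(mask, "roi_mask"))
  d <- dim(loop$frames)
  if (!all(dim(mask$mask) == d[2:3])) {
    stop("mask shape does not match loop frames", call. = FALSE)
  }
  idx <- which(mask$mask, arr.ind = TRUE)
  curves <- vector("list", nrow(idx))
  for (k in seq_len(nrow(idx))) {
    curves[[k]] <- perfusion_curve(loop$times, loop$frames[, idx[k, 1], idx[k, 2]])
  }
  names(curves) <- paste(idx[, 1], idx[, 2], sep = ",")
  attr(curves, "coords") <- idx
  attr(curves, "patient_id") <- mask$patient_id
  curves
}
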