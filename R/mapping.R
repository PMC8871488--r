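# Voxel-wise fitting over an ROI and assembly of parametric maps.

#' Fit a model to every voxel of an ROI
#'
#' Runs [fit_curve()] on each masked voxel's curve and derives markers from
#' converged fits ([compute_markers()] over the window from the fitted onset
#' to the last frame; [compute_msi()] on the measured curve). Failed fits
#' are retained with `converged = FALSE` and `NA` markers. The result is a
#' pure function of the loop and mask: row order follows mask column-major
#' order and is independent of execution order.
#'
#' @param loop a [cine_loop()].
#' @param mask an [roi_mask()].
#' @param model_kind `"EMG"` or `"GVF"`.
#' @param options a [fit_options()] list.
#' @param grid_dt marker grid resolution (s).
#' @return a `voxel_fit_table`: data frame with one row per masked voxel
#'   (`patient_id, row, col, model_kind, converged, reason, adj_r2`, the six
#'   markers and their `*_defined` flags) and attributes `fits` (list of
#'   `ceus_fit`) and `shape`.
#' @export
fit_roi <- function(loop, mask, model_kind = c("EMG", "GVF"),
                    options = fit_options(), grid_dt = 0.01) {
  model_kind <- match.arg(model_kind)
  curves <- extract_curves(loop, mask)
  coords <- attr(curves, "coords")
  nt <- length(loop$times)
  t_end <- loop$times[nt]

  fits <- vector("list", length(curves))
  rows <- vector("list", length(curves))
  for (k in seq_along(curves)) {
    cur <- curves[[k]]
    fit <- fit_curve(cur, model_kind, options)
    fits[[k]] <- fit
    mk <- rep(NA_real_, 6); names(mk) <- MARKER_NAMES
    df <- rep(FALSE, 6); names(df) <- MARKER_NAMES
    if (fit$converged) {
      win_start <- if (model_kind == "GVF") fit$t_onset else loop$times[1]
      ms <- compute_markers(fit, c(win_start, t_end), grid_dt = grid_dt)
      for (nm in setdiff(MARKER_NAMES, "msi")) {
        mk[nm] <- ms[[nm]]; df[nm] <- ms$defined[[nm]]
      }
      if (df[["ttp"]]) {
        cur2 <- detect_baseline_end(cur, options$k_sigma, options$m_baseline)
        msi <- tryCatch(compute_msi(cur2, mk[["ttp"]]), error = function(e) NA_real_)
        if (is.finite(msi)) { mk["msi"] <- msi; df["msi"] <- TRUE }
      }
    }
    rows[[k]] <- data.frame(
      patient_id = mask$patient_id, row = coords[k, 1], col = coords[k, 2],
      model_kind = model_kind, converged = fit$converged, reason = fit$reason,
      adj_r2 = fit$adj_r2,
      t(mk), wash_in_defined = df[["wash_in"]], wash_out_defined = df[["wash_out"]],
      ttp_defined = df[["ttp"]], tmsp_defined = df[["tmsp"]],
      auc_defined = df[["auc"]], msi_defined = df[["msi"]],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  attr(out, "shape") <- dim(loop$frames)[2:3]
  class(out) <- c("voxel_fit_table", "data.frame")
  out
}

#' Assemble a parametric map from a voxel fit table
#'
#' Produces an `H x W` map of one marker. Pixels are valid only where the
#' fit converged and the marker is defined; failed or undefined voxels (and
#' everything outside the mask) are left invalid — never imputed.
#'
#' @param table a `voxel_fit_table` from [fit_roi()].
#' @param marker_name one of `"wash_in", "wash_out", "ttp", "tmsp", "auc",
#'   "msi"`.
#' @param shape `(H, W)`; defaults to the shape recorded in the table.
#' @return an object of class `parametric_map`: `marker_name`, `values`
#'   (`H x W`, `NA` where invalid) and `valid` (`H x W` logical).
#' @export
assemble_map <- function(table, marker_name, shape = attr(table, "shape")) {
  if (!marker_name %in% MARKER_NAMES) {
    stop(sprintf("unknown marker '%s'", marker_name), call. = FALSE)
  }
  if (is.null(shape)) stop("shape must be supplied", call. = FALSE)
  values <- matrix(NA_real_, shape[1], shape[2])
  valid <- matrix(FALSE, shape[1], shape[2])
  flag <- table[[paste0(marker_name, "_defined")]]
  # negative adjusted R^2 marks a fit worse than the mean predictor: such
  # voxels are colorless on maps, like outright fit failures
  ok <- table$converged & flag & is.finite(table[[marker_name]]) &
    is.finite(table$adj_r2) & table$adj_r2 >= 0
  if (any(ok)) {
    ij <- cbind(table$row[ok], table$col[ok])
    values[ij] <- table[[marker_name]][ok]
    valid[ij] <- TRUE
  }
  structure(list(marker_name = marker_name, values = values, valid = valid),
            class = "parametric_map")
}

#' @export
print.parametric_map <- function(x, ...) {
  cat(sprintf("<parametric_map> %s: %d x %d, %d valid pixels\n",
              x$marker_name, nrow(x$values), ncol(x$values), sum(x$valid)))
  invisible(x)
}

#' Summarize goodness of fit over converged voxels
#'
#' Mean and sample standard deviation (denominator `n - 1`) of the adjusted
#' R-squared over converged voxels, reported per model kind. Voxels with
#' `adj_r2 < 0` count as converged here but are flagged failed for mapping.
#'
#' @param table a `voxel_fit_table` (rows from several patients may be
#'   concatenated with `rbind` first).
#' @return data frame with columns `model_kind, n_converged, n_failed,
#'   mean_adj_r2, sd_adj_r2`.
#' @export
summarize_fit_quality <- function(table) {
  conv <- table$converged & is.finite(table$adj_r2)
  if (!any(conv)) {
    stop(errorCondition("no converged voxels to summarize",
                        class = c("ceus_empty_result", "error", "condition")))
  }
  out <- do.call(rbind, lapply(split(seq_len(nrow(table)), table$model_kind), function(i) {
    ci <- i[conv[i]]
    data.frame(model_kind = table$model_kind[i[1]],
               n_converged = length(ci), n_failed = length(i) - length(ci),
               mean_adj_r2 = mean(table$adj_r2[ci]),
               sd_adj_r2 = if (length(ci) >= 2) stats::sd(table$adj_r2[ci]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
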