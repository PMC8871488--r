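# Per-voxel feature vectors and minimum-redundancy maximum-relevance
# (mRMR) selection.

FEATURE_NAMES <- c("wash_in", "wash_out", "ttp", "tmsp", "auc", "msi",
                   "mean", "median", "max", "sd")

#' Extract the 10-dimensional feature vector for one voxel
#'
#' Six kinetic markers from the fitted model plus four statistics of the
#' measured curve (mean, median, max, sample SD over the full acquisition).
#' Voxels with a failed fit or any undefined marker raise a skip condition
#' of class `ceus_voxel_skip` rather than producing silent `NA`s.
#'
#' @param curve the measured [perfusion_curve()].
#' @param fit the voxel's `ceus_fit`.
#' @param markers the voxel's [compute_markers()] result with `msi` filled
#'   in (a `marker_set`, or a named list/vector of the six markers plus a
#'   `defined` logical vector).
#' @return named numeric vector of the 10 features.
#' @export
extract_features <- function(curve, fit, markers) {
  skip <- function(msg) stop(errorCondition(msg,
    class = c("ceus_voxel_skip", "error", "condition")))
  if (!fit$converged) skip("fit did not converge")
  mv <- vapply(MARKER_NAMES, function(nm) as.numeric(markers[[nm]]), numeric(1))
  if (!all(markers$defined) || any(!is.finite(mv))) skip("undefined marker")
  y <- curve$intensities
  c(mv, mean = mean(y), median = stats::median(y), max = max(y), sd = stats::sd(y))
}

#' Build a feature table for a whole cohort
#'
#' Fits every lesion voxel of every patient ([fit_roi()]), extracts feature
#' vectors and drops voxels whose fit failed or whose markers are undefined
#' (count recorded in attribute `n_dropped`).
#'
#' @param cohort a [generate_cohort()] result (or any list with the same
#'   `patients` structure).
#' @param model_kind `"EMG"` or `"GVF"` — which feature set to build.
#' @param options a [fit_options()] list.
#' @param grid_dt marker grid resolution (s). The default 0.05 s keeps
#'   cohort-scale runs fast; marker accuracy is one grid step.
#' @return a `feature_table`: data frame of the 10 features plus
#'   `patient_id`, `class_label`, `row`, `col`; attributes `feature_set_tag`
#'   and `n_dropped`.
#' @export
cohort_features <- function(cohort, model_kind = c("EMG", "GVF"),
                            options = fit_options(), grid_dt = 0.05) {
  model_kind <- match.arg(model_kind)
  all_rows <- list()
  n_dropped <- 0L
  for (p in cohort$patients) {
    tab <- fit_roi(p$loop, p$mask, model_kind, options, grid_dt = grid_dt)
    curves <- extract_curves(p$loop, p$mask)
    for (k in seq_len(nrow(tab))) {
      fit <- attr(tab, "fits")[[k]]
      mk <- as.list(tab[k, MARKER_NAMES])
      mk$defined <- unlist(tab[k, paste0(MARKER_NAMES, "_defined")])
      fv <- tryCatch(extract_features(curves[[k]], fit, mk),
                     ceus_voxel_skip = function(e) NULL)
      if (is.null(fv)) { n_dropped <- n_dropped + 1L; next }
      all_rows[[length(all_rows) + 1L]] <- data.frame(
        t(fv), patient_id = p$patient_id, class_label = p$class_label,
        row = tab$row[k], col = tab$col[k], stringsAsFactors = FALSE)
    }
  }
  if (!length(all_rows)) stop("no usable voxels in cohort", call. = FALSE)
  out <- do.call(rbind, all_rows)
  rownames(out) <- NULL
  attr(out, "feature_set_tag") <- model_kind
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Discretize features into three z-score bins
#'
#' Each feature column is z-scored and coded `0` below -1, `1` in [-1, 1],
#' `2` above +1 — the standard coarse discretization feeding the
#' mutual-information computations of [mrmr_select()].
#'
#' @param table a data frame whose feature columns (any column named in the
#'   10-feature set, or all numeric columns if none match) are discretized;
#'   other columns pass through.
#' @param bins number of bins; only 3 is supported.
#' @return the table with feature columns replaced by integer codes 0/1/2.
#' @export
discretize_features <- function(table, bins = 3) {
  if (bins != 3) stop("only 3-bin z-score discretization is supported", call. = FALSE)
  cols <- intersect(FEATURE_NAMES, names(table))
  if (!length(cols)) cols <- names(table)[vapply(table, is.numeric, TRUE)]
  for (cn in cols) {
    x <- table[[cn]]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      stop(sprintf("feature '%s' has zero variance", cn), call. = FALSE)
    }
    z <- (x - mean(x)) / s
    table[[cn]] <- ifelse(z < -1, 0L, ifelse(z > 1, 2L, 1L))
  }
  table
}

# Mutual information (nats) between two discrete vectors.
discrete_mi <- function(x, y) {
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  e <- outer(px, py)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / e[nz]))
}

#' Greedy mRMR feature selection (mutual-information difference scheme)
#'
#' Ranks features by the MID criterion on discretized inputs: the first
#' feature maximizes relevance `I(f; y)`; each subsequent feature maximizes
#' `I(f; y) - mean_{s in S} I(f; s)` over the already-selected set `S`.
#' Ties are broken by column order, making the ranking deterministic.
#'
#' @param discrete_table data frame / matrix of integer-coded features (see
#'   [discretize_features()]).
#' @param labels class labels, one per row; both classes must be present.
#' @param k number of features to select, `1 <= k <=` feature count
#'   (default 6, the size of the reported marker panels).
#' @return character vector of `k` feature names in selection order, with
#'   attributes `relevance` (named `I(f; y)` for all features) and `scores`
#'   (the greedy objective value at each pick).
#' @export
mrmr_select <- function(discrete_table, labels, k = 6) {
  feats <- as.data.frame(discrete_table)
  feats <- feats[, setdiff(names(feats), c("patient_id", "class_label", "row", "col")),
                 drop = FALSE]
  feats <- feats[, vapply(feats, is.numeric, TRUE), drop = FALSE]
  nf <- ncol(feats)
  if (k < 1 || k > nf) stop("k must be between 1 and the feature count", call. = FALSE)
  if (length(unique(labels)) < 2) stop("labels must contain both classes", call. = FALSE)
  rel <- vapply(feats, function(f) discrete_mi(f, labels), numeric(1))
  selected <- character(0)
  scores <- numeric(0)
  remaining <- names(feats)
  red <- matrix(0, nf, nf, dimnames = list(names(feats), names(feats)))
  while (length(selected) < k) {
    if (!length(selected)) {
      obj <- rel[remaining]
    } else {
      obj <- vapply(remaining, function(f) {
        rel[[f]] - mean(red[f, selected])
      }, numeric(1))
    }
    pick <- remaining[which.max(obj)] # which.max: first max -> column-order tie-break
    # cache pairwise redundancies against the new pick
    for (f in setdiff(remaining, pick)) {
      red[f, pick] <- discrete_mi(feats[[f]], feats[[pick]])
    }
    scores <- c(scores, obj[[pick]])
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  attr(selected, "relevance") <- rel
  attr(selected, "scores") <- scores
  selected
}
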