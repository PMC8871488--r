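# Patient-grouped cross-validated voxel classification and its metrics.

CLASSIFIER_NAMES <- c("QDA", "GaussianNB", "AdaBoost", "RandomForest",
                      "kNN", "LogisticRegression", "SVM-RBF")

#' Patient-grouped, class-stratified fold assignment
#'
#' Patients (never voxels) are assigned to folds so that all voxels of a
#' patient stay together. Within each class, patients are shuffled
#' deterministically by `seed` and dealt round-robin across folds, giving
#' approximate class stratification at the patient level. `n_folds` is
#' capped at the patient count (with a warning) so no fold is empty.
#'
#' @param patient_labels named character vector mapping patient id to
#'   `"benign"`/`"malignant"`.
#' @param n_folds number of folds (default 10).
#' @param seed integer seed for the shuffle.
#' @return a `fold_assignment`: data frame `(patient_id, class_label, fold)`
#'   with attributes `n_folds` and `seed`.
#' @export
make_patient_folds <- function(patient_labels, n_folds = 10, seed = 1) {
  if (length(patient_labels) < 2L) stop("need at least 2 patients", call. = FALSE)
  if (is.null(names(patient_labels))) stop("patient_labels must be named", call. = FALSE)
  n_folds <- as.integer(n_folds)
  if (n_folds < 2L) stop("n_folds must be >= 2", call. = FALSE)
  if (n_folds > length(patient_labels)) {
    warning(sprintf("n_folds capped at patient count (%d)", length(patient_labels)))
    n_folds <- length(patient_labels)
  }
  classes <- unique(patient_labels)
  if (n_folds >= 2L) {
    per_class <- table(patient_labels)
    if (length(classes) >= 2L && any(per_class < 2L)) {
      stop("need at least 2 patients per class", call. = FALSE)
    }
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  out <- list()
  offset <- 0L # dealing continues across classes so no fold stays empty
  for (cl in sort(classes)) {
    ids <- names(patient_labels)[patient_labels == cl]
    ids <- sample(ids)
    out[[cl]] <- data.frame(patient_id = ids, class_label = cl,
                            fold = ((offset + seq_along(ids) - 1L) %% n_folds) + 1L,
                            stringsAsFactors = FALSE)
    offset <- offset + length(ids)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_folds") <- n_folds
  attr(res, "seed") <- seed
  class(res) <- c("fold_assignment", "data.frame")
  res
}

#' Classification metrics for one evaluation set
#'
#' Malignant is the positive class. Sensitivity `= TP/(TP+FN)` and
#' specificity `= TN/(FP+TN)` are reported in percent; the geometric mean
#' is `sqrt(sensitivity * specificity)`. AUROC uses the rank (Mann-Whitney)
#' formulation, crediting ties one half, also in percent.
#'
#' @param true_labels character vector of `"benign"`/`"malignant"`.
#' @param predicted_labels character vector of hard predictions.
#' @param scores numeric vector; larger means more malignant.
#' @return named numeric vector `(sensitivity, specificity, g_mean, auroc)`
#'   in percent.
#' @export
compute_metrics <- function(true_labels, predicted_labels, scores) {
  if (length(unique(true_labels)) < 2L) {
    stop(errorCondition("metrics undefined: only one class in true labels",
                        class = c("ceus_undefined_metric", "error", "condition")))
  }
  pos <- true_labels == "malignant"
  tp <- sum(pos & predicted_labels == "malignant")
  fn <- sum(pos & predicted_labels != "malignant")
  tn <- sum(!pos & predicted_labels != "malignant")
  fp <- sum(!pos & predicted_labels == "malignant")
  sens <- 100 * tp / (tp + fn)
  spec <- 100 * tn / (fp + tn)
  r <- rank(scores) # average ranks give half credit to ties
  auroc <- (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
  c(sensitivity = sens, specificity = spec, g_mean = sqrt(sens * spec),
    auroc = 100 * auroc)
}

# z-score both partitions using statistics of the training rows only; the
# held-out voxels never influence the standardization.
fold_standardize <- function(x_all, test_idx) {
  xtr_raw <- x_all[!test_idx, , drop = FALSE]
  mu <- colMeans(xtr_raw)
  sg <- apply(xtr_raw, 2, stats::sd)
  sg[!is.finite(sg) | sg == 0] <- 1
  list(train = sweep(sweep(xtr_raw, 2, mu), 2, sg, "/"),
       test = sweep(sweep(x_all[test_idx, , drop = FALSE], 2, mu), 2, sg, "/"),
       mu = mu, sd = sg)
}

# --- classifier registry ----------------------------------------------------
# Each trainer takes standardized train x / factor y (levels benign,
# malignant) and returns function(newx) -> list(labels, scores), scores
# increasing with malignancy. Hard labels use the 0.5 probability threshold
# where a probability is available.

prob_to_pred <- function(p) ifelse(p > 0.5, "malignant", "benign")

train_classifier <- function(name, x, y, seed) {
  switch(name,
    "QDA" = {
      fit <- MASS::qda(x, grouping = y)
      function(newx) {
        p <- stats::predict(fit, newx)$posterior[, "malignant"]
        list(labels = prob_to_pred(p), scores = p)
      }
    },
    "GaussianNB" = {
      fit <- e1071::naiveBayes(x, y)
      function(newx) {
        p <- stats::predict(fit, newx, type = "raw")[, "malignant"]
        list(labels = prob_to_pred(p), scores = p)
      }
    },
    "AdaBoost" = {
      fit <- adaboost_train(x, y, n_rounds = 50)
      function(newx) adaboost_predict(fit, newx)
    },
    "RandomForest" = {
      set.seed(seed)
      fit <- randomForest::randomForest(x, y, ntree = 200)
      function(newx) {
        p <- stats::predict(fit, newx, type = "prob")[, "malignant"]
        list(labels = prob_to_pred(p), scores = p)
      }
    },
    "kNN" = {
      function(newx) {
        pr <- class::knn(x, newx, cl = y, k = 3, prob = TRUE)
        win <- attr(pr, "prob")
        p <- ifelse(pr == "malignant", win, 1 - win)
        list(labels = as.character(pr), scores = p)
      }
    },
    "LogisticRegression" = {
      df <- as.data.frame(x)
      df$.y <- as.integer(y == "malignant")
      fit <- suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
      function(newx) {
        p <- suppressWarnings(
          stats::predict(fit, newdata = as.data.frame(newx), type = "response"))
        list(labels = prob_to_pred(p), scores = p)
      }
    },
    "SVM-RBF" = {
      set.seed(seed)
      fit <- e1071::svm(x, y, kernel = "radial", scale = FALSE)
      function(newx) {
        pr <- stats::predict(fit, newx, decision.values = TRUE)
        dv <- attr(pr, "decision.values")
        # orient the margin so larger = malignant
        s <- if (grepl("^malignant", colnames(dv)[1])) dv[, 1] else -dv[, 1]
        list(labels = as.character(pr), scores = s)
      }
    },
    stop(sprintf("unknown classifier '%s'", name), call. = FALSE))
}

# Discrete AdaBoost.M1 over depth-1 rpart stumps; deterministic.
adaboost_train <- function(x, y, n_rounds = 50) {
  df <- as.data.frame(x)
  yy <- ifelse(y == "malignant", 1, -1)
  n <- length(yy)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  for (m in seq_len(n_rounds)) {
    df$.y <- factor(yy, levels = c(-1, 1))
    st <- rpart::rpart(.y ~ ., data = df, weights = w,
                       method = "class",
                       control = rpart::rpart.control(maxdepth = 1, cp = -1,
                                                      minsplit = 2, xval = 0))
    pred <- ifelse(stats::predict(st, df, type = "class") == "1", 1, -1)
    err <- sum(w * (pred != yy))
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- st
    alphas <- c(alphas, alpha)
    w <- w * exp(-alpha * yy * pred)
    w <- w / sum(w)
    if (err < 1e-9) break # perfect stump: voting is decided
  }
  list(stumps = stumps, alphas = alphas)
}

adaboost_predict <- function(fit, newx) {
  df <- as.data.frame(newx)
  f <- rep(0, nrow(df))
  for (m in seq_along(fit$stumps)) {
    pred <- ifelse(stats::predict(fit$stumps[[m]], df, type = "class") == "1", 1, -1)
    f <- f + fit$alphas[m] * pred
  }
  p <- 1 / (1 + exp(-2 * f)) # logistic transform of the additive margin
  list(labels = prob_to_pred(p), scores = p)
}

#' Evaluate classifiers under patient-grouped cross-validation
#'
#' For each fold: voxels of the fold's patients are held out, features are
#' z-scored with training-fold statistics only, each classifier is trained
#' on the training voxels and evaluated on the held-out voxels with
#' [compute_metrics()]. Folds whose test set contains a single class are
#' skipped with a message. Stochastic learners get a fixed per-fold seed
#' derived from `seed`.
#'
#' @param table a `feature_table` (see [cohort_features()]) or data frame
#'   with feature columns plus `patient_id` and `class_label`.
#' @param folds a [make_patient_folds()] assignment covering the table's
#'   patients.
#' @param classifiers character vector of classifier names from
#'   `QDA, GaussianNB, AdaBoost, RandomForest, kNN, LogisticRegression,
#'   SVM-RBF`, or `"all"`.
#' @param features which feature columns to use (default: the 10-feature
#'   panel intersected with the table's columns).
#' @param seed base seed for stochastic learners.
#' @return a `cv_result`: list with `per_fold` (data frame of classifier,
#'   fold, metrics) and `summary` (mean and over-fold sample SD per
#'   classifier and metric).
#' @export
evaluate_classifiers <- function(table, folds, classifiers = "all",
                                 features = NULL, seed = 1) {
  if (identical(classifiers, "all")) classifiers <- CLASSIFIER_NAMES
  unknown <- setdiff(classifiers, CLASSIFIER_NAMES)
  if (length(unknown)) {
    stop(sprintf("unknown classifier(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  if (is.null(features)) features <- intersect(FEATURE_NAMES, names(table))
  stopifnot(length(features) >= 1, all(features %in% names(table)))
  fold_of <- stats::setNames(folds$fold, folds$patient_id)
  if (anyNA(fold_of[table$patient_id])) stop("folds do not cover all patients", call. = FALSE)
  x_all <- as.matrix(table[, features, drop = FALSE])
  y_all <- factor(table$class_label, levels = c("benign", "malignant"))
  voxel_fold <- unname(fold_of[table$patient_id])

  per_fold <- list()
  for (f in sort(unique(folds$fold))) {
    test <- voxel_fold == f
    if (length(unique(y_all[test])) < 2L) {
      message(sprintf("fold %d skipped: single-class test set", f))
      next
    }
    std <- fold_standardize(x_all, test)
    xtr <- std$train
    xte <- std$test
    for (cl in classifiers) {
      predictor <- train_classifier(cl, xtr, y_all[!test], seed = seed + 1000L * f)
      pred <- predictor(xte)
      m <- compute_metrics(as.character(y_all[test]), pred$labels, pred$scores)
      per_fold[[length(per_fold) + 1L]] <- data.frame(
        classifier = cl, fold = f, t(m), stringsAsFactors = FALSE)
    }
  }
  if (!length(per_fold)) stop("all folds skipped", call. = FALSE)
  pf <- do.call(rbind, per_fold)
  rownames(pf) <- NULL
  metrics <- c("sensitivity", "specificity", "g_mean", "auroc")
  summ <- do.call(rbind, lapply(split(pf, pf$classifier), function(d) {
    row <- data.frame(classifier = d$classifier[1], n_folds = nrow(d))
    for (m in metrics) {
      row[[paste0(m, "_mean")]] <- mean(d[[m]])
      row[[paste0(m, "_sd")]] <- if (nrow(d) >= 2) stats::sd(d[[m]]) else NA_real_
    }
    row
  }))
  summ <- summ[match(classifiers, summ$classifier), ]
  rownames(summ) <- NULL
  structure(list(per_fold = pf, summary = summ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> mean ± SD over folds (%):\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-20s sens %5.1f ± %4.1f  spec %5.1f ± %4.1f  G %5.1f ± %4.1f  AUROC %5.1f ± %4.1f\n",
                s$classifier[i], s$sensitivity_mean[i], s$sensitivity_sd[i],
                s$specificity_mean[i], s$specificity_sd[i],
                s$g_mean_mean[i], s$g_mean_sd[i],
                s$auroc_mean[i], s$auroc_sd[i]))
  }
  invisible(x)
}

#' Export cross-validation metrics as a results table
#'
#' Writes one row per classifier with `mean ± sd` strings for sensitivity,
#' specificity, G_mean and AUROC.
#'
#' @param cvres a `cv_result`.
#' @param path output CSV path.
#' @return the formatted data frame, invisibly.
#' @export
export_metrics_csv <- function(cvres, path) {
  s <- cvres$summary
  fmt <- function(m, sdv) sprintf("%.1f ± %.1f", m, sdv)
  out <- data.frame(
    Classifier = s$classifier,
    Sensitivity = fmt(s$sensitivity_mean, s$sensitivity_sd),
    Specificity = fmt(s$specificity_mean, s$specificity_sd),
    G_mean = fmt(s$g_mean_mean, s$g_mean_sd),
    AUROC = fmt(s$auroc_mean, s$auroc_sd),
    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
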