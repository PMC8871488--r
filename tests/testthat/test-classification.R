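# Fold construction, metrics, and cross-validated classification.

test_that("patient folds partition patients with round-robin stratification", {
  labs <- stats::setNames(rep(c("benign", "malignant"), each = 5),
                          sprintf("P%02d", 1:10))
  f <- make_patient_folds(labs, 10, seed = 2)
  expect_identical(sort(table(f$fold)), sort(table(1:10))) # one patient per fold
  expect_identical(anyDuplicated(f$patient_id), 0L)
  expect_setequal(f$patient_id, names(labs))

  # 25 patients split 14/11 into 10 folds: per-class fold sizes differ by <= 1
  labs25 <- stats::setNames(c(rep("benign", 14), rep("malignant", 11)),
                            sprintf("Q%02d", 1:25))
  f25 <- make_patient_folds(labs25, 10, seed = 7)
  per <- table(f25$class_label, f25$fold)
  expect_lte(diff(range(per["benign", ])), 1)
  expect_lte(diff(range(per["malignant", ])), 1)
  expect_identical(sum(per), 25L)
})

test_that("fold count is capped at the patient count with a warning", {
  labs <- stats::setNames(rep(c("benign", "malignant"), 2), paste0("P", 1:4))
  expect_warning(f <- make_patient_folds(labs, 10, seed = 1), "capped")
  expect_lte(max(f$fold), 4)
})

test_that("fold construction rejects degenerate cohorts", {
  expect_error(make_patient_folds(c(P1 = "benign"), 2), "at least 2 patients")
  expect_error(make_patient_folds(c(P1 = "benign", P2 = "benign", P3 = "malignant"), 3),
               "per class")
})

test_that("classification metrics match the confusion-matrix arithmetic", {
  truth <- c(rep("malignant", 10), rep("benign", 10))
  pred <- c(rep("malignant", 9), "benign", rep("malignant", 3), rep("benign", 7))
  scores <- c(seq(0.9, 0.6, length.out = 10), seq(0.55, 0.1, length.out = 10))
  m <- compute_metrics(truth, pred, scores)
  expect_equal(m[["sensitivity"]], 90)
  expect_equal(m[["specificity"]], 70)
  expect_equal(m[["g_mean"]], 79.3725, tolerance = 1e-4)
  expect_equal(m[["g_mean"]]^2, m[["sensitivity"]] * m[["specificity"]])
  expect_equal(m[["auroc"]], 100) # scores perfectly ordered
})

test_that("AUROC follows the rank formulation with half-credit ties", {
  truth <- c(rep("malignant", 4), rep("benign", 4))
  pred <- rep("benign", 8)
  expect_equal(compute_metrics(truth, pred, rep(0.3, 8))[["auroc"]], 50)
  # hand-computed tie case: scores (1,1,0,0) for (mal, ben, mal, ben)
  m <- compute_metrics(c("malignant", "benign", "malignant", "benign"),
                       rep("benign", 4), c(1, 1, 0, 0))
  expect_equal(m[["auroc"]], 50)
  expect_error(compute_metrics(rep("malignant", 5), rep("malignant", 5), 1:5),
               class = "ceus_undefined_metric")
})

test_that("rank AUROC agrees with pROC on random scores", {
  skip_if_not_installed("pROC")
  set.seed(13)
  truth <- sample(c("benign", "malignant"), 60, TRUE)
  scores <- rnorm(60) + (truth == "malignant")
  m <- compute_metrics(truth, ifelse(scores > 0.5, "malignant", "benign"), scores)
  ref <- 100 * as.numeric(pROC::auc(pROC::roc(
    response = truth, predictor = scores, levels = c("benign", "malignant"),
    direction = "<", quiet = TRUE)))
  expect_equal(m[["auroc"]], ref)
})

test_that("every classifier runs and no patient leaks across a fold boundary", {
  coh <- generate_cohort(6, 0.5, "well_separated", seed = 3,
                         voxels_benign = 15, voxels_malignant = 25,
                         frame_shape = c(10, 10))
  ft <- cohort_features(coh, "EMG", grid_dt = 0.1)
  folds <- make_patient_folds(patient_label_map(coh), 3, seed = 4)
  cv <- evaluate_classifiers(ft, folds, "all", seed = 9)
  expect_setequal(cv$summary$classifier, ceusperf:::CLASSIFIER_NAMES)
  expect_true(all(cv$per_fold$sensitivity >= 0 & cv$per_fold$sensitivity <= 100))
  expect_true(all(cv$per_fold$auroc >= 0 & cv$per_fold$auroc <= 100))
  # per-fold g_mean identity to machine precision
  expect_equal(cv$per_fold$g_mean^2,
               cv$per_fold$sensitivity * cv$per_fold$specificity,
               tolerance = 1e-12)
  # leakage guard
  for (f in unique(folds$fold)) {
    train_pat <- folds$patient_id[folds$fold != f]
    test_pat <- folds$patient_id[folds$fold == f]
    expect_identical(length(intersect(train_pat, test_pat)), 0L)
  }
  # separable scenario: strong performance across the battery
  expect_true(all(cv$summary$auroc_mean >= 90))
})

test_that("unknown classifiers and uncovered patients are rejected", {
  coh <- tiny_cohort()
  ft <- cohort_features(coh, "EMG", grid_dt = 0.1)
  folds <- make_patient_folds(patient_label_map(coh), 2, seed = 1)
  expect_error(evaluate_classifiers(ft, folds, "DeepNet"), "unknown classifier")
  ft2 <- ft
  ft2$patient_id <- paste0("X", ft2$patient_id)
  expect_error(evaluate_classifiers(ft2, folds, "LogisticRegression"),
               "do not cover")
})

test_that("training standardization never uses held-out voxels", {
  set.seed(10)
  x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("wash_in", "auc")))
  test_idx <- rep(c(FALSE, TRUE), each = 10)
  x_shifted <- x
  x_shifted[test_idx, ] <- x_shifted[test_idx, ] + 1000 # move held-out voxels
  s1 <- ceusperf:::fold_standardize(x, test_idx)
  s2 <- ceusperf:::fold_standardize(x_shifted, test_idx)
  # statistics equal the train-only moments and ignore the test shift
  expect_equal(s1$mu, colMeans(x[!test_idx, ]))
  expect_equal(s1$sd, apply(x[!test_idx, ], 2, sd))
  expect_identical(s1$mu, s2$mu)
  expect_identical(s1$train, s2$train)
})

test_that("duplicating every voxel leaves deterministic predictions unchanged", {
  coh <- tiny_cohort(seed = 12)
  ft <- cohort_features(coh, "EMG", grid_dt = 0.1)
  folds <- make_patient_folds(patient_label_map(coh), 2, seed = 1)
  ft2 <- rbind(ft, ft)
  r1 <- evaluate_classifiers(ft, folds, "LogisticRegression", seed = 3)
  r2 <- evaluate_classifiers(ft2, folds, "LogisticRegression", seed = 3)
  expect_equal(r1$per_fold[, c("sensitivity", "specificity", "auroc")],
               r2$per_fold[, c("sensitivity", "specificity", "auroc")],
               tolerance = 1e-6)
})

test_that("metrics CSV export is shaped classifier x metric", {
  coh <- tiny_cohort(seed = 2)
  ft <- cohort_features(coh, "EMG", grid_dt = 0.1)
  folds <- make_patient_folds(patient_label_map(coh), 2, seed = 1)
  cv <- evaluate_classifiers(ft, folds, "LogisticRegression", seed = 2)
  path <- tempfile(fileext = ".csv")
  out <- export_metrics_csv(cv, path)
  expect_true(file.exists(path))
  re <- utils::read.csv(path, check.names = FALSE)
  expect_identical(names(re), c("Classifier", "Sensitivity", "Specificity",
                                "G_mean", "AUROC"))
  expect_match(re$Sensitivity[1], "±")
})
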