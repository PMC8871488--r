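# Feature extraction, discretization, and mRMR selection.

stub_markers <- function(values = c(wash_in = 5, wash_out = -2, ttp = 20,
                                    tmsp = 10, auc = 900, msi = 8)) {
  defined <- rep(TRUE, 6); names(defined) <- names(values)
  c(as.list(values), list(defined = defined))
}

test_that("feature vectors combine markers with curve statistics", {
  cur <- perfusion_curve(0:3, c(1, 2, 3, 4))
  fit <- manual_fit("EMG", c(1, 1, 1, 1))
  fv <- extract_features(cur, fit, stub_markers())
  expect_identical(length(fv), 10L)
  expect_equal(fv[["mean"]], 2.5)
  expect_equal(fv[["median"]], 2.5)
  expect_equal(fv[["max"]], 4)
  expect_equal(fv[["sd"]], 1.290994, tolerance = 1e-6)
  expect_equal(fv[["wash_in"]], 5)
  # constant curve
  cc <- perfusion_curve(0:5, rep(7, 6))
  fvc <- extract_features(cc, fit, stub_markers())
  expect_equal(unname(fvc[c("mean", "median", "max", "sd")]), c(7, 7, 7, 0))
})

test_that("failed fits and undefined markers raise a skip condition", {
  cur <- perfusion_curve(0:3, c(1, 2, 3, 4))
  bad <- ceusperf:::new_failed_fit("EMG", "no_convergence", 4L)
  expect_error(extract_features(cur, bad, stub_markers()),
               class = "ceus_voxel_skip")
  mk <- stub_markers()
  mk$defined[["msi"]] <- FALSE
  mk$msi <- NA_real_
  expect_error(extract_features(cur, manual_fit("EMG", c(1, 1, 1, 1)), mk),
               class = "ceus_voxel_skip")
})

test_that("three-bin discretization codes z-scores at the 1-sigma boundaries", {
  # entries sitting beyond +-1 SD of their column land in the outer bins
  tab <- data.frame(auc = c(-3, 0, 3, 0, 0) * 10 + 100)
  z <- scale(tab$auc)[, 1]
  dd <- discretize_features(tab)
  expect_identical(dd$auc, ifelse(z < -1, 0L, ifelse(z > 1, 2L, 1L)))
  expect_identical(dd$auc, c(0L, 1L, 2L, 1L, 1L))
  # z-scores of exactly +-1 stay in the middle bin (closed interval):
  # c(0, 1, 2) has mean 1 and sample SD 1, so z = (-1, 0, 1)
  tab2 <- data.frame(ttp = c(0, 1, 2))
  expect_identical(discretize_features(tab2)$ttp, rep(1L, 3))
})

test_that("middle-bin occupancy matches the normal distribution", {
  set.seed(12)
  tab <- data.frame(ttp = rnorm(1e4))
  d <- discretize_features(tab)
  expect_equal(mean(d$ttp == 1L), 2 * pnorm(1) - 1, tolerance = 0.02)
})

test_that("zero-variance columns are rejected by name", {
  expect_error(discretize_features(data.frame(msi = rep(3, 5))), "'msi'")
  expect_error(discretize_features(data.frame(x = 1:5), bins = 5), "only 3")
})

test_that("a label-copy feature is ranked first by mRMR", {
  set.seed(6)
  n <- 400
  y <- rep(c("benign", "malignant"), each = n / 2)
  tab <- data.frame(
    noise1 = sample(0:2, n, TRUE),
    copy = as.integer(y == "malignant"),
    noise2 = sample(0:2, n, TRUE),
    noise3 = sample(0:2, n, TRUE))
  sel <- mrmr_select(tab, y, k = 2)
  expect_identical(sel[1], "copy")
})

test_that("selecting all features returns a permutation", {
  set.seed(16)
  n <- 200
  y <- sample(c("benign", "malignant"), n, TRUE)
  tab <- data.frame(a = sample(0:2, n, TRUE), b = sample(0:2, n, TRUE),
                    c = sample(0:2, n, TRUE))
  sel <- mrmr_select(tab, y, k = 3)
  expect_setequal(sel, c("a", "b", "c"))
})

test_that("a duplicated top feature is demoted below an informative independent one", {
  # f1 is a noisy copy of the label, f1_dup its exact duplicate, f2 an
  # independent noisy channel of the label. After f1 is picked, the
  # duplicate's redundancy I(f1_dup; f1) = H(f1) >= I(f1_dup; y) drives its
  # objective below zero, while f2 retains positive conditional information
  # (its noise is independent of f1's).
  set.seed(23)
  n <- 2000
  y <- rep(c("benign", "malignant"), each = n / 2)
  yb <- as.integer(y == "malignant")
  f1 <- ifelse(runif(n) < 0.9, yb, 1L - yb)
  f2 <- ifelse(runif(n) < 0.8, yb, 1L - yb)
  tab <- data.frame(f1 = f1, f1_dup = f1, f2 = f2)
  sel <- mrmr_select(tab, y, k = 2)
  expect_identical(as.character(sel), c("f1", "f2"))
  # exact MI arithmetic oracle for the second greedy step
  mi <- ceusperf:::discrete_mi
  obj_dup <- mi(tab$f1_dup, y) - mi(tab$f1_dup, tab$f1)
  obj_f2 <- mi(tab$f2, y) - mi(tab$f2, tab$f1)
  expect_lte(obj_dup, 0)
  expect_gt(obj_f2, obj_dup)
})

test_that("discrete mutual information matches hand-computed values", {
  # joint: P(0,0)=P(1,1)=0.5 -> MI = log 2
  x <- c(0, 0, 1, 1); y <- c("a", "a", "b", "b")
  expect_equal(ceusperf:::discrete_mi(x, y), log(2))
  # independence -> 0
  x2 <- c(0, 1, 0, 1); y2 <- c("a", "a", "b", "b")
  expect_equal(ceusperf:::discrete_mi(x2, y2), 0)
})

test_that("mRMR validates k and label variety", {
  tab <- data.frame(a = c(0, 1, 2, 0), b = c(1, 1, 0, 2))
  y <- c("benign", "malignant", "benign", "malignant")
  expect_error(mrmr_select(tab, y, k = 0), "between 1")
  expect_error(mrmr_select(tab, y, k = 3), "between 1")
  expect_error(mrmr_select(tab, rep("benign", 4), k = 1), "both classes")
})

test_that("selection on the default cohort retains wash-in and the class effect", {
  coh <- generate_cohort(8, 0.5, "well_separated", seed = 31,
                         voxels_benign = 20, voxels_malignant = 40,
                         frame_shape = c(12, 12))
  ft <- cohort_features(coh, "EMG", grid_dt = 0.1)
  expect_identical(attr(ft, "feature_set_tag"), "EMG")
  disc <- discretize_features(ft)
  sel <- mrmr_select(disc, ft$class_label, k = 6)
  expect_identical(length(sel), 6L)
  expect_true("wash_in" %in% sel)
  expect_identical(sel[1], "wash_in") # top relevance, first pick
  rel <- attr(sel, "relevance")
  expect_gt(rel[["wash_in"]], 0)
  expect_gt(rel[["auc"]], 0)
  # the generated class effect: malignant voxels have larger wash-in and auc
  mal <- ft$class_label == "malignant"
  expect_gt(mean(ft$wash_in[mal]), mean(ft$wash_in[!mal]))
  expect_gt(mean(ft$auc[mal]), mean(ft$auc[!mal]))
})
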