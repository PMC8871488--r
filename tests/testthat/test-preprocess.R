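# Pre-processing: luminance, cropping, subsampling, registration, curves.

test_that("luminance conversion uses Rec. 601 weights on real values", {
  white <- array(255, dim = c(4, 5, 3))
  expect_identical(to_luminance(white), matrix(255, 4, 5))
  gray <- array(rep(matrix(1:20, 4, 5), 3), dim = c(4, 5, 3))
  expect_equal(to_luminance(gray), matrix(1:20, 4, 5))
  red <- array(0, dim = c(1, 1, 3)); red[1, 1, 1] <- 255
  expect_equal(to_luminance(red)[1, 1], 76.245)
  expect_error(to_luminance(array(0, dim = c(2, 2, 4))), "H x W x 3")
})

test_that("luminance is linear in the channels", {
  set.seed(2)
  a <- array(runif(60, 0, 255), dim = c(4, 5, 3))
  b <- array(runif(60, 0, 255), dim = c(4, 5, 3))
  expect_equal(to_luminance(0.3 * a + 0.7 * b),
               0.3 * to_luminance(a) + 0.7 * to_luminance(b))
})

test_that("cropping returns the requested sub-loop and validates bounds", {
  loop <- cine_loop(array(seq_len(3 * 6 * 7), dim = c(3, 6, 7)), 0:2)
  full <- crop_region(loop, c(1, 1, 6, 7))
  expect_identical(full$frames, loop$frames)
  one <- crop_region(loop, c(2, 3, 1, 1))
  expect_identical(dim(one$frames), c(3L, 1L, 1L))
  expect_identical(one$frames[, 1, 1], loop$frames[, 2, 3])
  expect_identical(one$times, loop$times)
  expect_error(crop_region(loop, c(1, 1, 6, 8)), "exceeds frame bounds")
  expect_error(crop_region(loop, c(0, 1, 2, 2)), "exceeds frame bounds")
})

test_that("temporal subsampling picks nearest frames without inventing any", {
  # already at 1 s: identity
  l1 <- cine_loop(array(rnorm(10 * 2 * 2), dim = c(10, 2, 2)), 0:9)
  s1 <- temporal_subsample(l1, 1)
  expect_identical(s1$frames, l1$frames)
  expect_identical(s1$times, l1$times)
  # 10 Hz over 0-10 s -> 11 frames at the integer-second nearest frames
  tt <- seq(0, 10, by = 0.1)
  l2 <- cine_loop(array(seq_along(tt), dim = c(length(tt), 1, 1)), tt)
  s2 <- temporal_subsample(l2, 1)
  expect_identical(length(s2$times), 11L)
  expect_equal(s2$times, 0:10)
  # output times are a subsequence of input times
  l3 <- cine_loop(array(rnorm(40), dim = c(10, 2, 2)), sort(runif(10, 0, 30)))
  s3 <- temporal_subsample(l3, 2.5)
  expect_true(all(s3$times %in% l3$times))
  expect_false(is.unsorted(match(s3$times, l3$times), strictly = TRUE))
  expect_error(temporal_subsample(l1, 0), "dt must be > 0")
})

test_that("subsampling ties resolve to the earlier frame", {
  # targets at 0,1,2: t=1 is equidistant between 0.5 and 1.5 -> earlier (0.5)
  tt <- c(0, 0.5, 1.5, 2)
  l <- cine_loop(array(1:4, dim = c(4, 1, 1)), tt)
  s <- temporal_subsample(l, 1)
  expect_equal(s$times, c(0, 0.5, 2))
})

test_that("translation registration recovers known shifts", {
  set.seed(7)
  base <- matrix(0, 32, 32)
  base[10:20, 8:18] <- matrix(runif(121, 50, 100), 11, 11)
  shifted <- ceusperf:::shift_frame(base, 3, -2) # displaced by (+3, -2)
  frames <- array(0, dim = c(2, 32, 32))
  frames[1, , ] <- base; frames[2, , ] <- shifted
  reg <- register_translation(cine_loop(frames, 0:1), reference_index = 1)
  expect_identical(reg$shifts[1, ], c(dy = 0L, dx = 0L))
  expect_identical(reg$shifts[2, ], c(dy = -3L, dx = 2L))
  # registered frame matches the reference where both are in-frame
  expect_equal(reg$loop$frames[2, 4:29, 3:30], base[4:29, 3:30])
})

test_that("FFT shift estimate agrees with exhaustive cross-correlation search", {
  set.seed(19)
  ref <- matrix(rnorm(15 * 13), 15, 13)
  exhaustive <- function(ref, frame, max_s = 4) {
    best <- c(0, 0); bv <- -Inf
    for (dy in -max_s:max_s) for (dx in -max_s:max_s) {
      sh <- ceusperf:::shift_frame(frame, dy, dx)
      v <- sum(sh * ref)
      if (v > bv) { bv <- v; best <- c(dy, dx) }
    }
    best
  }
  for (s in list(c(2, 1), c(-3, 2), c(0, -4))) {
    frame <- ceusperf:::shift_frame(ref, s[1], s[2])
    expect_identical(as.integer(ceusperf:::estimate_shift(ref, frame)),
                     as.integer(exhaustive(ref, frame)))
  }
})

test_that("registration of an already-registered loop changes nothing", {
  set.seed(4)
  fr <- matrix(runif(100, 10, 60), 10, 10)
  frames <- array(rep(fr, each = 3), dim = c(3, 10, 10))
  for (i in 1:3) frames[i, , ] <- fr
  reg <- register_translation(cine_loop(frames, 0:2), 2)
  expect_true(all(reg$shifts == 0))
  expect_identical(reg$loop$frames, frames)
})

test_that("registration validates the reference index and frame count", {
  l <- cine_loop(array(rnorm(8), dim = c(2, 2, 2)), 0:1)
  expect_error(register_translation(l, 3), "out of range")
  l1 <- cine_loop(array(rnorm(4), dim = c(1, 2, 2)), 0)
  expect_error(register_translation(l1, 1), "at least two frames")
})

test_that("curve extraction yields one curve per masked voxel", {
  frames <- array(0, dim = c(10, 4, 4))
  for (i in 1:10) frames[i, , ] <- i
  loop <- cine_loop(frames, 0:9)
  m <- matrix(FALSE, 4, 4); m[c(1, 6, 11)] <- TRUE
  curves <- extract_curves(loop, roi_mask(m, "P1", "benign"))
  expect_identical(length(curves), 3L)
  expect_identical(curves[[1]]$times, loop$times)
  # constant-in-space loop gives identical curves
  expect_identical(curves[[1]]$intensities, curves[[3]]$intensities)
  expect_identical(curves[[2]]$intensities, as.numeric(1:10))
  # shape mismatch
  m2 <- matrix(TRUE, 5, 5)
  expect_error(extract_curves(loop, roi_mask(m2, "P1", "benign")),
               "does not match")
  # masks cannot be empty by construction
  expect_error(roi_mask(matrix(FALSE, 4, 4), "P1", "benign"), "at least one TRUE")
})
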