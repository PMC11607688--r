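# Rigid registration, pyramidal Lucas-Kanade flow, temporal averaging.

textured_frame <- function(seed) {
  s <- make_benchmark_sample(seed)
  s$image$channels$T
}

test_that("registration recovers known shifts and rotations", {
  f1 <- textured_frame(21)
  f2 <- gastroquant:::shift_image(f1, 4, -2)
  reg <- register_timelapse(list(f1, f2))
  # the returned transform is the correction applied to re-align the frame
  expect_lt(abs(reg$transforms$shift_row[2] + 4), 0.5)
  expect_lt(abs(reg$transforms$shift_col[2] - 2), 0.5)

  reg_id <- register_timelapse(list(f1, f1))
  expect_equal(reg_id$transforms$angle_deg, c(0, 0))
  expect_lt(max(abs(reg_id$transforms$shift_row)), 1e-6)

  f3 <- gastroquant:::rotate_about_center(f1, 3)
  reg_rot <- register_timelapse(list(f1, f3), max_rotation_deg = 5)
  expect_lt(abs(reg_rot$transforms$angle_deg[2] + 3), 0.5)

  blank <- matrix(0, nrow(f1), ncol(f1))
  expect_warning(register_timelapse(list(f1, blank)), "blank")
})

test_that("KLT recovers uniform motion and returns zero on identical frames", {
  s <- make_benchmark_sample(22)
  fl <- flow_spec(function(r, c) cbind(rep(3, length(r)), rep(0, length(r))),
                  n_frames = 2)
  tl <- make_timelapse(s, fl, seed = 1)
  f <- klt_flow(tl$frames[[1]], tl$frames[[2]])
  v <- dplyr::filter(f, valid)
  expect_lt(abs(median(v$v_row) - 3), 0.5)
  expect_lt(abs(median(v$v_col)), 0.5)

  f0 <- klt_flow(tl$frames[[1]], tl$frames[[1]])
  v0 <- dplyr::filter(f0, valid)
  expect_lt(max(sqrt(v0$v_row^2 + v0$v_col^2)), 0.05)

  # textureless input yields invalid points, not an exception
  flat <- matrix(100, 128, 128)
  ff <- klt_flow(flat, flat)
  expect_false(any(ff$valid))
})

test_that("opposing flow domains are recovered with the correct sign map", {
  s <- make_benchmark_sample(23)
  fl <- flow_spec(function(r, c) cbind(rep(0, length(r)), ifelse(c <= 128, 2, -2)),
                  n_frames = 2,
                  domain_fn = function(r, c) ifelse(c <= 128, 1L, 2L))
  tl <- make_timelapse(s, fl, seed = 2)
  f <- klt_flow(tl$frames[[1]], tl$frames[[2]])
  j <- dplyr::inner_join(dplyr::filter(f, valid), tl$truth,
                         by = c("row", "col"))
  j <- dplyr::filter(j, abs(v_col.x) > 0.5)
  expect_gte(mean(sign(j$v_col.x) == sign(j$v_col.y)), 0.9)
})

test_that("the pyramid is required for large displacements", {
  s <- make_benchmark_sample(24)
  fl <- flow_spec(function(r, c) cbind(rep(15, length(r)), rep(0, length(r))),
                  n_frames = 2)
  tl <- suppressWarnings(make_timelapse(s, fl, seed = 3))
  f3 <- klt_flow(tl$frames[[1]], tl$frames[[2]], pyramid_levels = 3)
  f1 <- klt_flow(tl$frames[[1]], tl$frames[[2]], pyramid_levels = 1)
  err3 <- median(abs(dplyr::filter(f3, valid)$v_row - 15))
  err1 <- median(abs(dplyr::filter(f1, valid)$v_row - 15))
  expect_lte(err3, 1)
  expect_gt(err1, 1)
})

test_that("temporal averaging windows, strides and validity rules are exact", {
  base <- klt_flow(textured_frame(25), textured_frame(25))   # all-valid grid
  mk <- function(vr) { f <- base; f$v_row <- vr; f$v_col <- 0; f }
  fields <- lapply(1:32, function(i) mk(1))
  avg <- time_average_flow(fields, 16, 4)
  expect_length(avg, 5)   # floor((32 - 16) / 4) + 1
  expect_true(all(avg[[1]]$v_row[avg[[1]]$valid] == 1))

  # alternating +1/-1 averages to zero
  alt <- lapply(1:16, function(i) mk(ifelse(i %% 2 == 0, 1, -1)))
  a <- time_average_flow(alt, 16, 4)
  expect_length(a, 1)
  expect_true(all(abs(a[[1]]$v_row[a[[1]]$valid]) < 1e-12))

  # linearity: averaging a constant-plus-field equals average plus constant
  shifted <- lapply(fields[1:16], function(f) { f$v_row <- f$v_row + 2.5; f })
  a1 <- time_average_flow(fields[1:16], 16, 4)[[1]]
  a2 <- time_average_flow(shifted, 16, 4)[[1]]
  expect_equal(a2$v_row, a1$v_row + 2.5)

  # a point invalid in more than half the window is invalid in the average
  half_bad <- lapply(1:16, function(i) {
    f <- mk(1)
    if (i <= 9) { f$v_row[1] <- NA; f$valid[1] <- FALSE }
    f
  })
  ah <- time_average_flow(half_bad, 16, 4)[[1]]
  expect_false(ah$valid[1])
  expect_true(is.na(ah$v_row[1]))

  expect_warning(time_average_flow(fields[1:5], 16, 4), "truncated")
})
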