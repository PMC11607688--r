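# AP profiles: sampling, orientation, normalization, averaging, kymographs.

make_profiled_sample <- function(seed, fn = function(s) 10000 * s, curv = 1 / 200) {
  sp <- shape_spec(180, 50, bend_curvature = curv, orientation_deg = 15)
  ch <- list(polarization_spec("T", fn, noise_sd = 0, background_level = 100))
  make_gastruloid_image(sp, ch, seed = seed)
}

test_that("uniform intensity gives a flat profile; polar intensity stays in its half", {
  s <- make_profiled_sample(1, fn = function(s) rep(3000, length(s)))
  ml <- extract_midline(s$true_mask)
  pr <- suppressWarnings(ap_profile(s$image, s$true_mask, ml))
  expect_lt(diff(range(pr$intensity)), 0.02 * mean(pr$intensity))

  s2 <- make_profiled_sample(2, fn = function(s) ifelse(s > 0.8, 8000, 0))
  ml2 <- extract_midline(s2$true_mask)
  pr2 <- suppressWarnings(ap_profile(s2$image, s2$true_mask, ml2))
  L <- max(pr2$position_px)
  lo <- sum(pr2$intensity[pr2$position_px < L / 2])
  hi <- sum(pr2$intensity[pr2$position_px > L / 2])
  expect_gt(max(lo, hi) / (lo + hi), 0.9)
})

test_that("orientation flips decreasing reference profiles and is idempotent", {
  s <- make_profiled_sample(3)
  ml <- extract_midline(s$true_mask)
  pr <- suppressWarnings(ap_profile(s$image, s$true_mask, ml, sample_id = "a"))
  on <- orient_and_normalize(pr, "T", intensity_norm = "none")
  # posterior (position 1) half must hold the reference maximum
  expect_gt(on$position[which.max(on$intensity)], 0.5)

  # reversing the raw arc direction flips the decision but not the result
  pr_rev <- pr
  pr_rev$position_px <- max(pr$position_px) - pr$position_px
  on_rev <- orient_and_normalize(pr_rev, "T", intensity_norm = "none")
  expect_false(on_rev$flipped[1] == on$flipped[1])
  expect_equal(on_rev$intensity, on$intensity, tolerance = 1e-8)

  # idempotence: re-orienting an oriented profile changes nothing
  again <- on
  again$position_px <- again$position
  again2 <- orient_and_normalize(again[, c("sample_id", "channel", "position_px", "intensity")],
                                 "T", intensity_norm = "none")
  expect_false(again2$flipped[1])
  expect_equal(again2$intensity, on$intensity, tolerance = 1e-8)
})

test_that("a symmetric reference profile is an orientation tie and is flagged", {
  pr <- tibble::tibble(sample_id = "s", channel = "T",
                       position_px = 0:100,
                       intensity = c(0:50, 49:0))
  on <- orient_and_normalize(pr, "T", intensity_norm = "none")
  expect_true(all(on$orientation_tie))
  expect_false(any(on$flipped))
})

test_that("intensity normalization modes divide by the documented maxima", {
  pr <- dplyr::bind_rows(
    tibble::tibble(sample_id = "a", channel = "T", position_px = 0:10,
                   intensity = seq(0, 10, length.out = 11)),
    tibble::tibble(sample_id = "b", channel = "T", position_px = 0:10,
                   intensity = seq(0, 20, length.out = 11)))
  g <- orient_and_normalize(pr, "T", intensity_norm = "global")
  expect_equal(max(g$intensity[g$sample_id == "a"]), 0.5)
  expect_equal(max(g$intensity[g$sample_id == "b"]), 1.0)

  pg <- orient_and_normalize(pr, "T", intensity_norm = "per_group",
                             groups = c(a = "g1", b = "g2"))
  expect_equal(max(pg$intensity[pg$sample_id == "a"]), 1.0)
  expect_equal(max(pg$intensity[pg$sample_id == "b"]), 1.0)

  pm <- orient_and_normalize(pr, "T", intensity_norm = "per_channel_max")
  expect_true(all(abs(tapply(pm$intensity, pm$sample_id, max) - 1) < 1e-12))
})

test_that("profile averaging uses the sample s.d. convention", {
  pr <- dplyr::bind_rows(
    tibble::tibble(sample_id = "a", channel = "T", position_px = 0:10, intensity = 0),
    tibble::tibble(sample_id = "b", channel = "T", position_px = 0:10, intensity = 1))
  on <- orient_and_normalize(pr, "T", intensity_norm = "none")
  avg <- average_profiles(on)
  expect_true(all(abs(avg$mean - 0.5) < 1e-12))
  expect_true(all(abs(avg$sd - sqrt(0.5)) < 1e-12))   # sample s.d. of {0, 1}

  single <- average_profiles(on[on$sample_id == "a", ])
  expect_true(all(single$sd == 0))
})

test_that("kymographs lock orientation on the final frame and mark missing rows", {
  # pole intensifying linearly in time, anterior-heavy early frames
  frames <- dplyr::bind_rows(lapply(1:5, function(f) {
    tibble::tibble(frame = f, channel = "T", position_px = 0:99,
                   intensity = 100 + f * (0:99))
  }))
  ky <- kymograph(frames, "T", length_grid_n = 50)
  expect_equal(dim(ky$matrix), c(5, 50))
  post <- rowMeans(ky$matrix[, 26:50])
  expect_true(all(diff(post) > 0))

  # time-constant movie: all rows equal
  const <- dplyr::bind_rows(lapply(1:4, function(f) {
    tibble::tibble(frame = f, channel = "T", position_px = 0:99, intensity = 0:99)
  }))
  kc <- kymograph(const, "T", length_grid_n = 20)
  expect_true(all(apply(kc$matrix, 2, function(col) max(col) - min(col)) < 1e-9))

  # missing frame stays missing
  km <- kymograph(const, "T", length_grid_n = 20, missing_frames = 2)
  expect_true(all(is.na(km$matrix["2", ])))
  expect_false(anyNA(km$matrix["1", ]))

  # replicate average of identical movies equals the single-movie kymograph
  expect_equal(average_kymographs(list(kc, kc))$matrix, kc$matrix)
})

test_that("multichannel profiles share the reference axis and peak at exactly 1", {
  sp <- shape_spec(180, 50, bend_curvature = 1 / 250, orientation_deg = -10)
  ch <- list(
    polarization_spec("T", function(s) 9000 * s, noise_sd = 0),
    polarization_spec("Sox2", function(s) 7000 * (1 - s), noise_sd = 0),
    polarization_spec("Foxa2", function(s) 4000 * exp(-((s - 0.5) / 0.15)^2),
                      noise_sd = 0))
  s <- make_gastruloid_image(sp, ch, seed = 6)
  mp <- multichannel_profile(s$image, s$true_mask, reference_channel = "T")
  peaks <- tapply(mp$intensity, mp$channel, max)
  expect_true(all(abs(peaks - 1) < 1e-12))

  # anterior and posterior markers peak on opposite halves
  pos_T <- mp$position[mp$channel == "T"][which.max(mp$intensity[mp$channel == "T"])]
  pos_S <- mp$position[mp$channel == "Sox2"][which.max(mp$intensity[mp$channel == "Sox2"])]
  expect_gt(pos_T, 0.5)
  expect_lt(pos_S, 0.5)

  expect_error(multichannel_profile(s$image, s$true_mask, reference_channel = "nope"),
               "missing")
})
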