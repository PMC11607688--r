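#' Multichannel image sample
#'
#' Lightweight container for a single multichannel 2D microscopy image: named
#' intensity matrices sharing one shape, an optional physical pixel size and an
#' identifier. This is the unit all segmentation and profiling functions
#' operate on.
#'
#' @param channels named list of numeric matrices (same dimensions, finite,
#'   non-negative).
#' @param pixel_size_um microns per pixel, or `NULL` for pixel units.
#' @param id sample identifier.
#' @return An object of class `image_sample`.
#' @export
image_sample <- function(channels, pixel_size_um = NULL, id = "sample") {
  if (!is.list(channels) || is.null(names(channels)) || any(names(channels) == "")) {
    abort("`channels` must be a named list of matrices.")
  }
  dims <- unique(lapply(channels, dim))
  if (length(dims) != 1) abort("All channels must share one shape.")
  for (nm in names(channels)) {
    assert_matrix(channels[[nm]], nm)
    if (any(channels[[nm]] < 0)) abort(sprintf("Channel '%s' has negative intensities.", nm))
  }
  structure(list(channels = channels, pixel_size_um = pixel_size_um, id = id),
            class = "image_sample")
}

#' @export
print.image_sample <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<image_sample '%s'> %d x %d px, channels: %s\n",
              x$id, d[1], d[2], paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Silhouette geometry for a synthetic gastruloid
#'
#' Describes a capsule swept along a circular-arc midline: `length_px` is the
#' tip-to-tip arc length of the axis, `width_px` the silhouette width, and
#' `bend_curvature` the (constant) curvature of the axis in 1/px. The rendered
#' silhouette is the set of pixels within `width_px / 2` of the axis trimmed by
#' half a width at each end, so the recorded true midline spans the full
#' silhouette and has arc length `length_px`.
#'
#' @param length_px tip-to-tip axis length in pixels.
#' @param width_px silhouette width in pixels (must not exceed `length_px`).
#' @param bend_curvature curvature of the axis in 1/px; 0 gives a straight shape.
#' @param orientation_deg in-plane rotation of the axis midpoint tangent.
#' @param center (row, col) of the axis midpoint.
#' @return An object of class `shape_spec`.
#' @export
shape_spec <- function(length_px, width_px, bend_curvature = 0,
                       orientation_deg = 0, center = c(128, 128)) {
  if (length_px <= 0 || width_px <= 0) abort("Lengths must be positive.")
  if (width_px > length_px) abort("`width_px` must not exceed `length_px`.")
  structure(list(length_px = length_px, width_px = width_px,
                 bend_curvature = bend_curvature,
                 orientation_deg = orientation_deg, center = center),
            class = "shape_spec")
}

#' AP polarization of a synthetic fluorescence channel
#'
#' @param channel_name channel label, e.g. `"T"`.
#' @param profile_fn function mapping normalized arc position `s` in \[0, 1\]
#'   (0 = anterior, 1 = posterior) to mean intensity above background.
#' @param noise_sd per-pixel additive Gaussian noise s.d. (intensity units).
#' @param background_level intensity outside (and under) the aggregate.
#' @return An object of class `polarization_spec`.
#' @export
polarization_spec <- function(channel_name, profile_fn, noise_sd = 0,
                              background_level = 200) {
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  probe <- profile_fn(seq(0, 1, length.out = 11))
  if (!all(is.finite(probe))) abort("`profile_fn` must be finite on [0, 1].")
  structure(list(channel_name = channel_name, profile_fn = profile_fn,
                 noise_sd = noise_sd, background_level = background_level),
            class = "polarization_spec")
}

# Points along the full axis (tip to tip) at ~1 px arc steps, in (row, col).
axis_points <- function(shape, step = 1) {
  L <- shape$length_px
  k <- shape$bend_curvature
  t <- seq(-L / 2, L / 2, by = step)
  if (abs(t[length(t)] - L / 2) > 1e-9) t <- c(t, L / 2)
  if (abs(k) < 1e-12) {
    x <- t; y <- rep(0, length(t))
  } else {
    R <- 1 / k
    x <- R * sin(k * t)
    y <- R * (1 - cos(k * t))
  }
  th <- shape$orientation_deg * pi / 180
  # local x = along axis, y = normal; map to (row, col)
  row <- shape$center[1] + y * cos(th) + x * sin(th)
  col <- shape$center[2] + x * cos(th) - y * sin(th)
  cbind(row = row, col = col)
}

# Smooth multi-octave value-noise texture in [-1, 1]-ish range.
perlin_texture <- function(nr, nc, scale = 24, octaves = 3) {
  out <- matrix(0, nr, nc)
  amp <- 1
  sc <- scale
  for (o in seq_len(octaves)) {
    gn <- max(2, ceiling(nr / sc)); gc <- max(2, ceiling(nc / sc))
    coarse <- matrix(rnorm(gn * gc), gn, gc)
    up <- as.matrix(EBImage::resize(coarse, w = nr, h = nc))
    out <- out + amp * up
    amp <- amp / 2
    sc <- max(2, sc / 2)
  }
  out / max(abs(out))
}

#' Generate a synthetic gastruloid image with ground truth
#'
#' Renders a single aggregate silhouette (capsule swept along a circular-arc
#' axis) into a multichannel frame: a textured brightfield channel with a dark
#' rim at the aggregate boundary, plus one fluorescence channel per
#' [polarization_spec()], whose mean intensity at a pixel is the polarization
#' profile evaluated at the normalized arc position of the nearest axis point.
#' The returned object carries the exact mask, midline and profiles used for
#' rendering, so downstream stages can be scored against known truth.
#'
#' @param shape a [shape_spec()].
#' @param channels list of [polarization_spec()] objects (may be empty).
#' @param seed integer seed; identical seed and specs give bit-identical output.
#' @param frame_dim frame size (rows, cols).
#' @param id sample identifier.
#' @return A `synthetic_sample`: list with `image` ([image_sample()] including
#'   the `"BF"` brightfield channel), `true_mask` (binary matrix), `true_midline`
#'   (list with `vertices`, `arclength_px`, `local_width_px`), `true_profiles`
#'   (tibble: channel, position, intensity) and `seed`.
#' @export
make_gastruloid_image <- function(shape, channels = list(), seed = 1,
                                  frame_dim = c(256, 256), id = "synthetic") {
  stopifnot(inherits(shape, "shape_spec"))
  nr <- frame_dim[1]; nc <- frame_dim[2]
  ax <- axis_points(shape, step = 1)
  L <- shape$length_px
  w <- shape$width_px
  s_axis <- seq(0, 1, length.out = nrow(ax))
  # spine: axis trimmed by w/2 at each end
  spine_keep <- s_axis * L >= w / 2 - 1e-9 & (1 - s_axis) * L >= w / 2 - 1e-9
  if (!any(spine_keep)) abort("Shape too short for its width.")
  spine <- ax[spine_keep, , drop = FALSE]

  pad <- w / 2 + 2
  if (min(ax[, 1]) < pad || min(ax[, 2]) < pad ||
      max(ax[, 1]) > nr - pad + 1 || max(ax[, 2]) > nc - pad + 1) {
    abort("Silhouette would touch the frame border; enlarge the frame or shrink the shape.")
  }

  r0 <- max(1L, floor(min(ax[, 1]) - pad)); r1 <- min(nr, ceiling(max(ax[, 1]) + pad))
  c0 <- max(1L, floor(min(ax[, 2]) - pad)); c1 <- min(nc, ceiling(max(ax[, 2]) + pad))
  grid <- expand.grid(row = r0:r1, col = c0:c1)
  gr <- as.numeric(grid$row); gc <- as.numeric(grid$col)

  # distance to spine and arc position of nearest full-axis point, chunked
  np <- length(gr)
  d_spine <- numeric(np); s_near <- numeric(np)
  chunk <- 20000L
  for (i0 in seq(1L, np, by = chunk)) {
    i1 <- min(np, i0 + chunk - 1L)
    dr <- outer(gr[i0:i1], spine[, 1], "-")
    dc <- outer(gc[i0:i1], spine[, 2], "-")
    d_spine[i0:i1] <- sqrt(apply(dr * dr + dc * dc, 1, min))
    dr <- outer(gr[i0:i1], ax[, 1], "-")
    dc <- outer(gc[i0:i1], ax[, 2], "-")
    s_near[i0:i1] <- s_axis[max.col(-(dr * dr + dc * dc), ties.method = "first")]
  }

  inside <- d_spine <= w / 2
  mask <- matrix(0, nr, nc)
  mask[cbind(grid$row[inside], grid$col[inside])] <- 1

  out_channels <- with_seed(seed, {
    res <- list()
    # brightfield: bright background, brighter textured interior, dark rim
    bf <- matrix(25000, nr, nc) + 600 * perlin_texture(nr, nc, scale = 32)
    tex <- perlin_texture(nr, nc, scale = 12)
    idx <- cbind(grid$row[inside], grid$col[inside])
    bf[idx] <- 33000 + 2000 * tex[idx]
    rim <- inside & d_spine > w / 2 - 3
    bf[cbind(grid$row[rim], grid$col[rim])] <-
      bf[cbind(grid$row[rim], grid$col[rim])] * 0.55
    bf <- bf + matrix(rnorm(nr * nc, sd = 300), nr, nc)
    res$BF <- pmin(pmax(bf, 0), 65535)
    for (ch in channels) {
      fl <- matrix(ch$background_level, nr, nc)
      fl[idx] <- ch$background_level + ch$profile_fn(s_near[inside])
      if (ch$noise_sd > 0) fl <- fl + matrix(rnorm(nr * nc, sd = ch$noise_sd), nr, nc)
      res[[ch$channel_name]] <- pmin(pmax(fl, 0), 65535)
    }
    res
  })

  # local width of the true midline: w along the spine, chord width in the caps
  d_end <- pmin(s_axis, 1 - s_axis) * L
  lw <- ifelse(d_end >= w / 2, w, 2 * sqrt(pmax((w / 2)^2 - (w / 2 - d_end)^2, 0)))
  prof_grid <- seq(0, 1, length.out = 100)
  true_profiles <- purrr::map_dfr(channels, function(ch) {
    tibble(channel = ch$channel_name, position = prof_grid,
           intensity = ch$profile_fn(prof_grid))
  })

  structure(list(
    image = image_sample(out_channels, id = id),
    true_mask = mask,
    true_midline = list(vertices = ax,
                        arclength_px = c(0, cumsum(sqrt(rowSums(diff(ax)^2)))),
                        local_width_px = lw),
    true_profiles = true_profiles,
    shape = shape,
    seed = seed
  ), class = "synthetic_sample")
}

#' @export
print.synthetic_sample <- function(x, ...) {
  cat(sprintf("<synthetic_sample> axis %.0f px, width %.0f px, curvature %.4g 1/px, seed %d\n",
              x$shape$length_px, x$shape$width_px, x$shape$bend_curvature,
              as.integer(x$seed)))
  print(x$image)
  invisible(x)
}

#' Draw a random benchmark sample
#'
#' Standard conditions used throughout the package's benchmarks: axis length
#' 100-180 px, width 40-65 px, curvature 0 to 1/150 1/px (straight to clearly
#' bent), arbitrary orientation, and a linearly posterior-increasing T
#' reporter over background with additive Gaussian noise. All randomness
#' derives from `seed`.
#'
#' @param seed integer seed.
#' @param noise_sd fluorescence noise s.d. (default 300, ~5% of the reporter
#'   dynamic range).
#' @param frame_dim frame size.
#' @return A `synthetic_sample` (see [make_gastruloid_image()]).
#' @export
make_benchmark_sample <- function(seed, noise_sd = 300, frame_dim = c(256, 256)) {
  pars <- with_seed(seed, {
    list(L = runif(1, 100, 180), W = runif(1, 40, 65),
         k = sample(c(0, 1 / 300, 1 / 200, 1 / 150), 1),
         th = runif(1, 0, 180))
  })
  sp <- shape_spec(pars$L, pars$W, bend_curvature = pars$k,
                   orientation_deg = pars$th,
                   center = round(frame_dim / 2))
  ch <- list(polarization_spec("T", function(s) 6000 * s, noise_sd = noise_sd,
                               background_level = 200))
  make_gastruloid_image(sp, ch, seed = child_seed(seed, 1), frame_dim = frame_dim,
                        id = sprintf("bench_%d", seed))
}
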