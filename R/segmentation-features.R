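# Brightfield pixel-feature bank and image downsampling.

block_reduce <- function(m, f) {
  nr2 <- floor(nrow(m) / f); nc2 <- floor(ncol(m) / f)
  if (nr2 < 1 || nc2 < 1) abort("Downsampling factor larger than the image.")
  m <- m[seq_len(nr2 * f), seq_len(nc2 * f), drop = FALSE]
  m <- matrix(colMeans(matrix(m, nrow = f)), nr2, nc2 * f)
  t(matrix(colMeans(matrix(t(m), nrow = f)), nc2, nr2))
}

#' Downsample an image by local averaging
#'
#' Reduces each channel by an integer factor using non-overlapping block
#' means (trailing rows/columns that do not fill a block are dropped). The
#' factor is recorded so masks computed at the reduced scale can be upsampled
#' back to full resolution.
#'
#' @param image an [image_sample()] or a numeric matrix.
#' @param factor integer reduction factor (default 2).
#' @return Same type as the input, reduced; for an `image_sample` the factor
#'   is stored as attribute `downsample_factor`.
#' @export
downsample <- function(image, factor = 2) {
  factor <- as.integer(factor)
  if (factor < 1) abort("`factor` must be >= 1.")
  if (is.matrix(image)) {
    if (factor == 1) return(image)
    return(block_reduce(image, factor))
  }
  stopifnot(inherits(image, "image_sample"))
  if (factor == 1) {
    attr(image, "downsample_factor") <- 1L
    return(image)
  }
  image$channels <- lapply(image$channels, block_reduce, f = factor)
  if (!is.null(image$pixel_size_um)) image$pixel_size_um <- image$pixel_size_um * factor
  attr(image, "downsample_factor") <- factor
  image
}

#' Default feature-bank configuration
#'
#' The bank combines four multi-scale filter families on the brightfield
#' channel — Gaussian smoothing, difference of Gaussians between consecutive
#' scales, Gaussian gradient magnitude and Laplacian of Gaussian — with
#' DAISY-style local gradient-orientation descriptors (orientation maps
#' smoothed at ring-specific scales and sampled on concentric rings). The
#' default ladder gives 339 features per pixel.
#'
#' @param sigmas scale ladder (px) for the filter families.
#' @param daisy_orientations number of gradient orientation bins.
#' @param daisy_radii ring radii (px); the center point is always included.
#' @param daisy_points sample points per ring.
#' @param daisy_sigmas smoothing scale for the center and for each ring.
#' @return A `bank_config` list.
#' @export
bank_config <- function(sigmas = c(0.7, 1.5, 3, 5, 8),
                        daisy_orientations = 8,
                        daisy_radii = c(3, 6, 9),
                        daisy_points = 13,
                        daisy_sigmas = c(1.5, 2, 3, 4.5)) {
  if (length(daisy_sigmas) != length(daisy_radii) + 1) {
    abort("`daisy_sigmas` must have one value for the center plus one per ring.")
  }
  structure(list(sigmas = sigmas, daisy_orientations = daisy_orientations,
                 daisy_radii = daisy_radii, daisy_points = daisy_points,
                 daisy_sigmas = daisy_sigmas),
            class = "bank_config")
}

gblur_mat <- function(m, sigma) {
  # EBImage wants odd filter sizes comfortably inside the image
  as.matrix(EBImage::gblur(m, sigma = sigma,
                           radius = min(2 * ceiling(3 * sigma) + 1,
                                        2 * floor((min(dim(m)) - 1) / 2) - 1)))
}

shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dr, 1), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1), nc)
  m[ri, ci, drop = FALSE]
}

#' Extract the per-pixel feature stack of a brightfield image
#'
#' @param image single-channel numeric matrix (typically the downsampled
#'   brightfield channel).
#' @param config a [bank_config()].
#' @return A `feature_stack`: list with `features` (pixels x n_features matrix,
#'   pixels in column-major order), `feature_names`, and `dim`.
#' @export
extract_features <- function(image, config = bank_config()) {
  assert_matrix(image, "image")
  nr <- nrow(image); nc <- ncol(image)
  feats <- list()

  smoothed <- lapply(config$sigmas, function(s) gblur_mat(image, s))
  for (i in seq_along(config$sigmas)) {
    feats[[sprintf("gauss_s%g", config$sigmas[i])]] <- smoothed[[i]]
  }
  for (i in seq_len(length(config$sigmas) - 1)) {
    feats[[sprintf("dog_s%g_s%g", config$sigmas[i], config$sigmas[i + 1])]] <-
      smoothed[[i]] - smoothed[[i + 1]]
  }
  lap_kern <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  grad_rc <- function(m) {
    gr <- (shift_mat(m, -1, 0) - shift_mat(m, 1, 0)) / 2
    gc <- (shift_mat(m, 0, -1) - shift_mat(m, 0, 1)) / 2
    list(gr = gr, gc = gc)
  }
  for (i in seq_along(config$sigmas)) {
    g <- grad_rc(smoothed[[i]])
    feats[[sprintf("gradmag_s%g", config$sigmas[i])]] <- sqrt(g$gr^2 + g$gc^2)
    feats[[sprintf("log_s%g", config$sigmas[i])]] <-
      as.matrix(EBImage::filter2(smoothed[[i]], lap_kern))
  }

  # DAISY-style descriptors: rectified orientation maps of the gradient,
  # smoothed per ring and sampled at ring offsets around each pixel.
  g <- grad_rc(gblur_mat(image, 1))
  nth <- config$daisy_orientations
  thetas <- (seq_len(nth) - 1) * 2 * pi / nth
  omaps <- lapply(thetas, function(th) pmax(g$gr * sin(th) + g$gc * cos(th), 0))
  osm <- lapply(config$daisy_sigmas, function(s) lapply(omaps, gblur_mat, sigma = s))
  for (k in seq_len(nth)) {
    feats[[sprintf("daisy_c_o%d", k)]] <- osm[[1]][[k]]
  }
  for (ri in seq_along(config$daisy_radii)) {
    rad <- config$daisy_radii[ri]
    for (p in seq_len(config$daisy_points)) {
      ang <- (p - 1) * 2 * pi / config$daisy_points
      dr <- round(rad * sin(ang)); dc <- round(rad * cos(ang))
      for (k in seq_len(nth)) {
        feats[[sprintf("daisy_r%g_p%d_o%d", rad, p, k)]] <-
          shift_mat(osm[[ri + 1]][[k]], dr, dc)
      }
    }
  }

  fmat <- vapply(feats, as.numeric, numeric(nr * nc))
  structure(list(features = fmat, feature_names = names(feats), dim = c(nr, nc)),
            class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  cat(sprintf("<feature_stack> %d x %d px, %d features\n",
              x$dim[1], x$dim[2], length(x$feature_names)))
  invisible(x)
}
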