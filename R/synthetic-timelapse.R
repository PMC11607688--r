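#' Velocity-field specification for synthetic time-lapses
#'
#' @param field_fn function taking numeric vectors `row`, `col` (pixel
#'   coordinates) and returning a 2-column matrix of velocities
#'   `(v_row, v_col)` in px/frame.
#' @param n_frames number of frames to synthesize (>= 2).
#' @param domain_fn optional function of `row`, `col` returning an integer
#'   domain id per point (e.g. the two opposing flow domains of a polarizing
#'   aggregate).
#' @return An object of class `flow_spec`.
#' @export
flow_spec <- function(field_fn, n_frames = 2, domain_fn = NULL) {
  if (n_frames < 2) abort("`n_frames` must be >= 2.")
  structure(list(field_fn = field_fn, n_frames = n_frames, domain_fn = domain_fn),
            class = "flow_spec")
}

#' Synthesize a time-lapse advected by a known velocity field
#'
#' Starting from the reporter-fluorescence channel of a synthetic sample (or
#' any single matrix), each subsequent frame is the previous frame warped
#' backward by the specified velocity field (bilinear interpolation) plus
#' optional Gaussian noise. Ground-truth velocities are recorded on the same
#' coarse grid on which the optical-flow stage reports (one measurement every
#' `step_px` pixels), so flow estimates can be scored directly.
#'
#' @param base a `synthetic_sample`, an [image_sample()] or a numeric matrix.
#' @param flow a [flow_spec()].
#' @param seed integer seed for frame noise.
#' @param channel channel used as the moving signal (default the first
#'   non-brightfield channel, falling back to `"BF"`).
#' @param noise_sd additive Gaussian noise per frame (intensity units).
#' @param step_px grid spacing of the recorded ground-truth field.
#' @param window_px reference window size used only to warn when the per-frame
#'   displacement exceeds half a window (tracking validity).
#' @return A `synthetic_timelapse`: list with `frames` (list of matrices),
#'   `truth` (tibble: frame, row, col, v_row, v_col, domain) and `step_px`.
#' @export
make_timelapse <- function(base, flow, seed = 1, channel = NULL,
                           noise_sd = 0, step_px = 10, window_px = 20) {
  stopifnot(inherits(flow, "flow_spec"))
  img <- if (inherits(base, "synthetic_sample")) base$image else base
  frame0 <- if (inherits(img, "image_sample")) {
    if (is.null(channel)) {
      nms <- setdiff(names(img$channels), "BF")
      channel <- if (length(nms)) nms[1] else "BF"
    }
    img$channels[[channel]]
  } else {
    assert_matrix(img, "base")
  }
  nr <- nrow(frame0); nc <- ncol(frame0)

  rows <- seq(1, nr); cols <- seq(1, nc)
  grid_all <- expand.grid(row = rows, col = cols)
  v_all <- flow$field_fn(grid_all$row, grid_all$col)
  vmax <- max(sqrt(rowSums(v_all^2)))
  if (vmax > window_px / 2) {
    warn(sprintf("Per-frame displacement %.1f px exceeds half the tracking window (%d px).",
                 vmax, window_px))
  }
  vr <- matrix(v_all[, 1], nr, nc); vc <- matrix(v_all[, 2], nr, nc)

  gtr <- seq(step_px, nr - step_px + 1, by = step_px)
  gtc <- seq(step_px, nc - step_px + 1, by = step_px)
  gt_grid <- expand.grid(row = gtr, col = gtc)
  gt_v <- flow$field_fn(gt_grid$row, gt_grid$col)
  gt_dom <- if (is.null(flow$domain_fn)) NA_integer_ else
    flow$domain_fn(gt_grid$row, gt_grid$col)

  frames <- with_seed(seed, {
    fs <- vector("list", flow$n_frames)
    fs[[1]] <- frame0
    for (t in 2:flow$n_frames) {
      src_r <- grid_all$row - vr
      src_c <- grid_all$col - vc
      warped <- matrix(bilinear(fs[[t - 1]], src_r, src_c, fill = 0), nr, nc)
      if (noise_sd > 0) warped <- warped + matrix(rnorm(nr * nc, sd = noise_sd), nr, nc)
      fs[[t]] <- pmax(warped, 0)
    }
    fs
  })

  truth <- purrr::map_dfr(seq_len(flow$n_frames - 1), function(t) {
    tibble(frame = t, row = gt_grid$row, col = gt_grid$col,
           v_row = gt_v[, 1], v_col = gt_v[, 2], domain = gt_dom)
  })
  structure(list(frames = frames, truth = truth, step_px = step_px, seed = seed),
            class = "synthetic_timelapse")
}

#' @export
print.synthetic_timelapse <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<synthetic_timelapse> %d frames of %d x %d px, truth grid every %d px\n",
              length(x$frames), d[1], d[2], x$step_px))
  invisible(x)
}
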