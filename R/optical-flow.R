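# Coarse-grained tissue flow: rigid pre-registration, pyramidal Lucas-Kanade
# optical flow on a regular grid, and sliding-window temporal averaging.

# Translation between two equally sized frames by phase correlation, refined
# to sub-pixel precision with a parabolic fit around the correlation peak.
phase_correlate <- function(a, b) {
  fa <- fft(a); fb <- fft(b)
  cp <- fa * Conj(fb)
  denom <- Mod(cp); denom[denom < 1e-12] <- 1e-12
  r <- Re(fft(cp / denom, inverse = TRUE))
  nr <- nrow(r); nc <- ncol(r)
  pk <- which(r == max(r), arr.ind = TRUE)[1, ]
  wrap <- function(i, n) ((i - 1) %% n) + 1
  para <- function(ym, y0, yp) {
    d <- ym - 2 * y0 + yp
    if (abs(d) < 1e-12) 0 else 0.5 * (ym - yp) / d
  }
  fr <- para(r[wrap(pk[1] - 1, nr), pk[2]], r[pk[1], pk[2]], r[wrap(pk[1] + 1, nr), pk[2]])
  fc <- para(r[pk[1], wrap(pk[2] - 1, nc)], r[pk[1], pk[2]], r[pk[1], wrap(pk[2] + 1, nc)])
  sh <- c(pk[1] - 1 + fr, pk[2] - 1 + fc)
  sh[1] <- if (sh[1] > nr / 2) sh[1] - nr else sh[1]
  sh[2] <- if (sh[2] > nc / 2) sh[2] - nc else sh[2]
  list(shift = sh, score = max(r))
}

rotate_about_center <- function(m, angle_deg) {
  if (abs(angle_deg) < 1e-12) return(m)
  nr <- nrow(m); nc <- ncol(m)
  ctr <- c((nr + 1) / 2, (nc + 1) / 2)
  th <- angle_deg * pi / 180
  g <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  dr <- g$row - ctr[1]; dc <- g$col - ctr[2]
  src_r <- ctr[1] + cos(th) * dr - sin(th) * dc
  src_c <- ctr[2] + sin(th) * dr + cos(th) * dc
  matrix(bilinear(m, src_r, src_c, fill = mean(m)), nr, nc)
}

shift_image <- function(m, dr, dc) {
  g <- expand.grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  matrix(bilinear(m, g$row - dr, g$col - dc, fill = 0), nrow(m), ncol(m))
}

#' Rigid registration of a time-lapse
#'
#' Aligns every frame to the first by a rotation + translation estimated from
#' the image content: the rotation angle is found by a coarse-to-fine search
#' maximizing the phase-correlation peak, the translation by sub-pixel phase
#' correlation at the best angle. This removes drift and slow tumbling of the
#' aggregate before flow measurement.
#'
#' @param frames list of numeric matrices (>= 2, one shape).
#' @param max_rotation_deg half-width of the rotation search range.
#' @param rotation_step_deg coarse search step; refined to a tenth of it.
#' @return List with `frames` (registered) and `transforms` (tibble: frame,
#'   angle_deg, shift_row, shift_col).
#' @export
register_timelapse <- function(frames, max_rotation_deg = 10,
                               rotation_step_deg = 1) {
  if (length(frames) < 2) abort("Need at least 2 frames.")
  dims <- unique(lapply(frames, dim))
  if (length(dims) != 1) abort("Frames must share one shape.")
  ref <- frames[[1]]
  reg <- vector("list", length(frames))
  reg[[1]] <- ref
  tf <- tibble(frame = seq_along(frames), angle_deg = 0,
               shift_row = 0, shift_col = 0)
  for (i in seq_along(frames)[-1]) {
    fr <- frames[[i]]
    if (sd(fr) < 1e-9) {
      warn(sprintf("Frame %d is blank; identity transform used.", i))
      reg[[i]] <- fr
      next
    }
    best <- list(angle = 0, score = -Inf, shift = c(0, 0))
    search <- function(angles) {
      for (ang in angles) {
        rot <- rotate_about_center(fr, ang)
        pc <- phase_correlate(ref, rot)
        if (pc$score > best$score) {
          best <<- list(angle = ang, score = pc$score, shift = pc$shift)
        }
      }
    }
    search(seq(-max_rotation_deg, max_rotation_deg, by = rotation_step_deg))
    search(setdiff(seq(best$angle - rotation_step_deg,
                       best$angle + rotation_step_deg,
                       by = rotation_step_deg / 10), best$angle))
    rot <- rotate_about_center(fr, best$angle)
    reg[[i]] <- shift_image(rot, best$shift[1], best$shift[2])
    tf$angle_deg[i] <- best$angle
    tf$shift_row[i] <- best$shift[1]
    tf$shift_col[i] <- best$shift[2]
  }
  list(frames = reg, transforms = tf)
}

gauss_pyramid <- function(m, levels) {
  pyr <- vector("list", levels)
  pyr[[1]] <- m
  for (l in seq_len(levels - 1)) {
    sm <- gblur_mat(pyr[[l]], 1)
    pyr[[l + 1]] <- block_reduce(sm, 2)
  }
  pyr
}

# Iterative Lucas-Kanade refinement of flow at given points on one level.
lk_refine <- function(a, b, pts, init, half_win, max_iter = 10, tol = 0.01,
                      min_eig_frac = 1e-3) {
  gr_a <- (shift_mat(a, -1, 0) - shift_mat(a, 1, 0)) / 2
  gc_a <- (shift_mat(a, 0, -1) - shift_mat(a, 0, 1)) / 2
  offs <- expand.grid(dr = -half_win:half_win, dc = -half_win:half_win)
  n <- nrow(pts)
  v <- init
  valid <- rep(TRUE, n)
  for (i in seq_len(n)) {
    pr <- pts[i, 1] + offs$dr; pc <- pts[i, 2] + offs$dc
    Ix <- bilinear(gr_a, pr, pc); Iy <- bilinear(gc_a, pr, pc)
    A <- bilinear(a, pr, pc)
    G <- matrix(c(sum(Ix * Ix), sum(Ix * Iy), sum(Ix * Iy), sum(Iy * Iy)), 2, 2)
    msg <- mean(Ix^2 + Iy^2)
    ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
    if (msg < 1e-12 || min(ev) < min_eig_frac * msg * length(Ix)) {
      valid[i] <- FALSE
      next
    }
    Ginv <- solve(G)
    vi <- v[i, ]
    for (it in seq_len(max_iter)) {
      Bv <- bilinear(b, pr + vi[1], pc + vi[2])
      err <- A - Bv
      dv <- as.numeric(Ginv %*% c(sum(err * Ix), sum(err * Iy)))
      vi <- vi + dv
      if (sqrt(sum(dv^2)) < tol) break
    }
    if (!all(is.finite(vi)) || sqrt(sum(vi^2)) > 2 * (2 * half_win + 1)) {
      valid[i] <- FALSE
      vi <- c(NA_real_, NA_real_)
    }
    v[i, ] <- vi
  }
  list(v = v, valid = valid)
}

#' Pyramidal Lucas-Kanade optical flow on a regular grid
#'
#' Estimates the displacement from `frame_a` to `frame_b` at every grid point
#' (one measurement every `step_px` pixels) by windowed least squares,
#' coarse-to-fine over a Gaussian pyramid. Grid points whose window lacks
#' texture (rank-deficient structure tensor) are flagged invalid rather than
#' zero-filled.
#'
#' @param frame_a,frame_b numeric matrices of one shape.
#' @param pyramid_levels number of pyramid levels (default 3).
#' @param window_px side of the integration window at the finest level
#'   (default 20).
#' @param step_px grid spacing (default 10).
#' @return A `flow_field` tibble: `row`, `col`, `v_row`, `v_col`, `valid`,
#'   with attributes `step_px` and `dim`.
#' @export
klt_flow <- function(frame_a, frame_b, pyramid_levels = 3, window_px = 20,
                     step_px = 10) {
  assert_matrix(frame_a); assert_matrix(frame_b)
  if (!all(dim(frame_a) == dim(frame_b))) abort("Frames must share one shape.")
  if (window_px < 3) abort("`window_px` must be >= 3.")
  nr <- nrow(frame_a); nc <- ncol(frame_a)
  gr <- seq(step_px, nr - step_px + 1, by = step_px)
  gc <- seq(step_px, nc - step_px + 1, by = step_px)
  grid <- as.matrix(expand.grid(row = gr, col = gc))
  half_win <- max(1L, floor(window_px / 2))

  pyr_a <- gauss_pyramid(frame_a, pyramid_levels)
  pyr_b <- gauss_pyramid(frame_b, pyramid_levels)
  v <- matrix(0, nrow(grid), 2)
  valid <- rep(TRUE, nrow(grid))
  for (lev in rev(seq_len(pyramid_levels))) {
    sc <- 2^(lev - 1)
    pts <- (grid - 1) / sc + 1
    res <- lk_refine(pyr_a[[lev]], pyr_b[[lev]], pts, v / sc, half_win)
    ok <- res$valid & is.finite(res$v[, 1])
    v[ok, ] <- res$v[ok, , drop = FALSE] * sc
    if (lev == 1) valid <- ok
  }
  out <- tibble(row = grid[, 1], col = grid[, 2],
                v_row = ifelse(valid, v[, 1], NA_real_),
                v_col = ifelse(valid, v[, 2], NA_real_),
                valid = valid)
  attr(out, "step_px") <- step_px
  attr(out, "frame_dim") <- c(nr, nc)
  class(out) <- c("flow_field", class(out))
  out
}

#' Flow fields for every consecutive frame pair of a time-lapse
#'
#' @param frames list of matrices (e.g. registered frames).
#' @inheritParams klt_flow
#' @return List of `flow_field` tibbles (one per frame pair).
#' @export
timelapse_flow <- function(frames, pyramid_levels = 3, window_px = 20,
                           step_px = 10) {
  if (length(frames) < 2) abort("Need at least 2 frames.")
  purrr::map(seq_len(length(frames) - 1), function(t) {
    f <- klt_flow(frames[[t]], frames[[t + 1]], pyramid_levels, window_px, step_px)
    f$frame <- t
    f
  })
}

#' Sliding-window temporal average of flow fields
#'
#' Averages the per-grid-point velocity over windows of `window_frames`
#' consecutive fields, emitting one averaged field every `stride_frames`. A
#' grid point is valid in a window when it was valid in at least half the
#' member fields; its average uses the valid members only.
#'
#' @param fields list of `flow_field` tibbles on one grid.
#' @param window_frames frames per averaging window (default 16).
#' @param stride_frames stride between emitted windows (default 4).
#' @return List of averaged `flow_field` tibbles with a `window_id` column and
#'   attribute `frames` giving the member frame indices.
#' @export
time_average_flow <- function(fields, window_frames = 16, stride_frames = 4) {
  nf <- length(fields)
  if (nf == 0) abort("No fields supplied.")
  if (nf < window_frames) {
    warn(sprintf("Only %d field(s) for a window of %d; averaging the truncated window.",
                 nf, window_frames))
    starts <- 1L
    window_frames <- nf
  } else {
    starts <- seq(1L, nf - window_frames + 1L, by = stride_frames)
  }
  purrr::imap(starts, function(s, wid) {
    members <- fields[s:(s + window_frames - 1L)]
    vr <- vapply(members, function(f) f$v_row, numeric(nrow(members[[1]])))
    vc <- vapply(members, function(f) f$v_col, numeric(nrow(members[[1]])))
    nvalid <- rowSums(!is.na(vr))
    ok <- nvalid >= window_frames / 2
    out <- members[[1]]
    out$v_row <- ifelse(ok, rowMeans(vr, na.rm = TRUE), NA_real_)
    out$v_col <- ifelse(ok, rowMeans(vc, na.rm = TRUE), NA_real_)
    out$valid <- ok
    out$frame <- NULL
    out$window_id <- wid
    attr(out, "frames") <- s:(s + window_frames - 1L)
    out
  })
}
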