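# Shape measures: area/perimeter, distance-transform midline, straightening,
# second-moment eccentricity.

#' Area and perimeter of a segmentation mask
#'
#' Area is the pixel count times the pixel area. The perimeter is measured as
#' the length of the sub-pixel boundary contour traced at the 0.5 level
#' (marching squares), a low-bias estimator for smooth outlines.
#'
#' @param mask binary matrix, a single connected component.
#' @param pixel_size physical pixel edge length; results are in
#'   `pixel_size` units (squared for area). Default 1 (pixel units).
#' @return A tibble with columns `area` and `perimeter`.
#' @export
measure_area_perimeter <- function(mask, pixel_size = 1) {
  if (sum(mask) == 0) abort("Empty mask.")
  padded <- matrix(0, nrow(mask) + 8, ncol(mask) + 8)
  padded[5:(nrow(mask) + 4), 5:(ncol(mask) + 4)] <- (mask > 0) * 1
  padded <- gblur_mat(padded, 1)   # sub-pixel boundary, removes stair-step bias
  cl <- grDevices::contourLines(x = seq_len(nrow(padded)),
                                y = seq_len(ncol(padded)),
                                z = padded, levels = 0.5)
  per <- sum(vapply(cl, function(ct) {
    polyline_length(cbind(c(ct$x, ct$x[1]), c(ct$y, ct$y[1])))
  }, numeric(1)))
  tibble(area = sum(mask > 0) * pixel_size^2, perimeter = per * pixel_size)
}

# Kasa algebraic circle fit; NULL when the points are numerically collinear.
fit_circle <- function(pts) {
  A <- cbind(2 * pts[, 1], 2 * pts[, 2], 1)
  b <- pts[, 1]^2 + pts[, 2]^2
  sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(sol)) return(NULL)
  r2 <- sol[3] + sol[1]^2 + sol[2]^2
  if (!is.finite(r2) || r2 <= 0) return(NULL)
  list(center = sol[1:2], radius = sqrt(r2))
}

# Mean signed curvature of a polyline: total turning angle of the tangent
# divided by arc length. Robust to local lattice jitter because only the
# accumulated turn enters.
path_curvature <- function(pts) {
  if (nrow(pts) < 5) return(0)
  d <- diff(pts)
  len <- sum(sqrt(rowSums(d^2)))
  th <- atan2(d[, 1], d[, 2])
  dth <- diff(th)
  dth <- ((dth + pi) %% (2 * pi)) - pi
  sum(dth) / len
}

# March from `end` along `tangent`, turning by the signed curvature `kappa`
# per pixel, until leaving the mask. A curvature radius tighter than three
# local tube widths (distance transform `dist` at the end point) indicates an
# unreliable estimate on a blob-like mask; the tangent is used instead.
extend_march <- function(end, tangent, kappa, mask, dist, step = 1,
                         max_ext = Inf) {
  tl <- sqrt(sum(tangent^2)); if (tl < 1e-9) return(NULL)
  tangent <- tangent / tl
  d_end <- bilinear(dist, end[1], end[2])
  if (abs(kappa) > 1e-12 && 1 / abs(kappa) < 3 * d_end) kappa <- 0
  if (abs(kappa) < 5e-4) kappa <- 0
  inside <- function(p) {
    p[1] >= 1 && p[1] <= nrow(mask) && p[2] >= 1 && p[2] <= ncol(mask) &&
      bilinear(mask, p[1], p[2]) >= 0.5
  }
  max_steps <- min(ceiling(1.5 * max(dim(mask))), ceiling(max_ext))
  out <- matrix(NA_real_, max_steps, 2)
  ca <- cos(kappa * step); sa <- sin(kappa * step)
  p <- end; d <- tangent; k <- 0
  repeat {
    # rotate the (row, col) direction by kappa * step; theta = atan2(row, col)
    d <- c(d[1] * ca + d[2] * sa, d[2] * ca - d[1] * sa)
    p <- p + step * d
    if (k + 1 > max_steps || !inside(p)) break
    k <- k + 1
    out[k, ] <- p
  }
  if (k == 0) NULL else out[seq_len(k), , drop = FALSE]
}

#' Extract the midline (AP axis) of a mask via the distance transform
#'
#' The interior Euclidean distance transform defines a ridge; pixels within
#' `band_frac` of its maximum form the ridge band, through which the longest
#' geodesic path is traced (8-connected, weighted to stay central). The path
#' is smoothed with cubic smoothing splines, resampled at ~1 px arc steps and
#' extended to the mask boundary following the local curvature at each end.
#' The local width at each vertex is twice the distance-transform value.
#'
#' Near-spherical masks have no meaningful axis: when the extended midline is
#' shorter than `degenerate_ratio` times the mean width, the sample is flagged
#' `degenerate` and the short unextended ridge path is returned instead, so a
#' profile can still be computed (with the caveat that its placement is
#' arbitrary).
#'
#' @param mask binary matrix, single connected component.
#' @param band_frac fraction of the distance-transform maximum defining the
#'   ridge band.
#' @param degenerate_ratio length/width ratio below which the axis is flagged
#'   degenerate.
#' @return A `midline`: list with `vertices` (n x 2, row/col), `arclength_px`,
#'   `local_width_px`, `mean_width_px`, `length_px`, `degenerate`.
#' @export
extract_midline <- function(mask, band_frac = 0.9, degenerate_ratio = 1.5) {
  mask <- (mask > 0) * 1
  if (sum(mask) == 0) abort("Empty mask.")
  if (n_components(mask) != 1) abort("Mask must be a single connected component.")
  D <- as.matrix(EBImage::distmap(mask))
  Dmax <- max(D)
  if (Dmax < 1.5) abort("Mask is thinner than 3 px everywhere; no midline.")

  band <- (D >= band_frac * Dmax) * 1
  peak <- which(D == Dmax, arr.ind = TRUE)[1, , drop = FALSE]
  lab <- as.matrix(EBImage::bwlabel(band))
  band <- (lab == lab[peak]) * 1
  idx <- which(band > 0)
  pts <- which(band > 0, arr.ind = TRUE)
  np <- nrow(pts)

  path_rc <- if (np == 1) {
    pts
  } else {
    id <- matrix(0L, nrow(mask), ncol(mask)); id[idx] <- seq_len(np)
    edges <- NULL; weights <- NULL
    for (off in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
      r2 <- pts[, 1] + off[1]; c2 <- pts[, 2] + off[2]
      ok <- r2 >= 1 & r2 <= nrow(mask) & c2 >= 1 & c2 <= ncol(mask)
      ok[ok] <- id[cbind(r2[ok], c2[ok])] > 0
      if (!any(ok)) next
      a <- id[pts[ok, , drop = FALSE]]
      b <- id[cbind(r2[ok], c2[ok])]
      len <- sqrt(sum(off^2))
      # pull toward the ridge crest
      w <- len * (1 + 4 * (Dmax - (D[idx[a]] + D[idx[b]]) / 2) / Dmax)
      edges <- rbind(edges, cbind(a, b))
      weights <- c(weights, w)
    }
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    igraph::E(g)$weight <- weights
    start <- id[peak]
    d1 <- igraph::distances(g, v = start)[1, ]
    e1 <- which.max(ifelse(is.finite(d1), d1, -1))
    d2 <- igraph::distances(g, v = e1)[1, ]
    e2 <- which.max(ifelse(is.finite(d2), d2, -1))
    vp <- igraph::shortest_paths(g, from = e1, to = e2, output = "vpath")$vpath[[1]]
    pts[as.integer(vp), , drop = FALSE]
  }

  # drop the cap-influenced path ends (the distance-transform ridge forks
  # toward corners there) while keeping at least two tube widths of path,
  # then smooth and resample at ~1 px arc steps
  trim_used <- 0
  if (nrow(path_rc) > 2) {
    tc <- c(0, cumsum(sqrt(rowSums(diff(path_rc)^2))))
    trim <- min(ceiling(Dmax), max(0, (max(tc) - 2 * Dmax) / 2))
    if (trim > 0 && max(tc) > 2 * trim + 10) {
      keep <- tc >= trim & tc <= max(tc) - trim
      path_rc <- path_rc[keep, , drop = FALSE]
      trim_used <- trim
    }
  }
  smoothed <- if (nrow(path_rc) >= 8) {
    t0 <- c(0, cumsum(sqrt(rowSums(diff(path_rc)^2))))
    sr <- smooth.spline(t0, path_rc[, 1])
    sc <- smooth.spline(t0, path_rc[, 2])
    tt <- seq(0, max(t0), by = 1)
    cbind(predict(sr, tt)$y, predict(sc, tt)$y)
  } else {
    path_rc
  }

  # Crest reprojection: the geodesic tends to cut the chord inside the ridge
  # band, under-stating gentle bends; snap each vertex to the interpolated
  # distance-transform maximum along its normal (parabolic refinement).
  if (nrow(smoothed) >= 8) {
    n0 <- nrow(smoothed)
    tang <- rbind(smoothed[2, ] - smoothed[1, ],
                  (smoothed[3:n0, , drop = FALSE] - smoothed[1:(n0 - 2), , drop = FALSE]) / 2,
                  smoothed[n0, ] - smoothed[n0 - 1, ])
    tl <- sqrt(rowSums(tang^2)); tl[tl < 1e-9] <- 1
    nor <- cbind(-tang[, 2], tang[, 1]) / tl
    offs <- seq(-3, 3, by = 0.5)
    Dv <- vapply(offs, function(o) {
      bilinear(D, smoothed[, 1] + o * nor[, 1], smoothed[, 2] + o * nor[, 2])
    }, numeric(n0))
    # infinitesimal centring penalty so plateaus (flat ridges) resolve to the
    # smallest offset instead of the first candidate
    pen <- matrix(1e-6 * abs(offs), n0, length(offs), byrow = TRUE)
    best <- max.col(Dv - pen, ties.method = "first")
    ib <- pmin(pmax(best, 2), length(offs) - 1)
    y0 <- Dv[cbind(seq_len(n0), ib - 1)]
    y1 <- Dv[cbind(seq_len(n0), ib)]
    y2 <- Dv[cbind(seq_len(n0), ib + 1)]
    den <- y0 - 2 * y1 + y2
    frac <- ifelse(abs(den) > 1e-9, 0.5 * (y0 - y2) / den, 0)
    shift <- offs[ib] + pmin(pmax(frac, -1), 1) * 0.5
    refined <- smoothed + shift * nor
    # light re-smoothing keeps the reprojected crest but removes jitter
    t1 <- c(0, cumsum(sqrt(rowSums(diff(refined)^2))))
    sr2 <- smooth.spline(t1, refined[, 1])
    sc2 <- smooth.spline(t1, refined[, 2])
    tt2 <- seq(0, max(t1), by = 1)
    smoothed <- cbind(predict(sr2, tt2)$y, predict(sc2, tt2)$y)
  }

  # Curvature from a circle fit of the crest path; trusted only when the
  # path's empirical bow exceeds a pixel — below that, lattice jitter
  # dominates and the path is treated as straight.
  circ <- if (nrow(smoothed) >= 8) fit_circle(smoothed) else NULL
  n_s <- nrow(smoothed)
  chord <- smoothed[n_s, ] - smoothed[1, ]
  sag_emp <- 0
  if (n_s >= 3) {
    cl2 <- sum(chord^2)
    if (cl2 > 0) {
      sag_emp <- max(abs((smoothed[, 1] - smoothed[1, 1]) * chord[2] -
                           (smoothed[, 2] - smoothed[1, 2]) * chord[1]) / sqrt(cl2))
    }
  }
  kappa <- 0
  sag_fit <- if (is.null(circ)) 0 else sum(chord^2) / (8 * circ$radius)
  if (!is.null(circ) && circ$radius < 3000 && sag_emp >= 1.5 &&
      sag_fit >= 0.5 * sag_emp && sag_fit <= 2 * sag_emp) {
    m <- max(1, floor(n_s / 2))
    tg <- smoothed[min(n_s, m + 3), ] - smoothed[max(1, m - 3), ]
    u <- circ$center - smoothed[m, ]
    side <- tg[2] * u[1] - tg[1] * u[2]   # +1: centre left of travel, theta increasing
    kappa <- (if (side >= 0) 1 else -1) / circ$radius
  }
  # extension tangents: from the circle geometry when curved, else the chord
  end_tangent <- function(p, along) {
    if (kappa != 0) {
      u <- (p - circ$center)
      u <- u / sqrt(sum(u^2))
      tg <- c(u[2], -u[1])              # rotate radius by 90 degrees
    } else {
      tg <- chord / sqrt(sum(chord^2))
    }
    if (sum(tg * along) < 0) tg <- -tg  # align with the local travel direction
    tg
  }
  # each extension bridges the trimmed arc plus one cap depth; bounding it
  # stops wrongly-curved extensions from sliding along the boundary
  max_ext <- trim_used + 1.2 * Dmax + 3
  ext_tail <- if (n_s >= 2) {
    extend_march(smoothed[n_s, ],
                 end_tangent(smoothed[n_s, ], smoothed[n_s, ] - smoothed[max(1, n_s - 5), ]),
                 kappa, mask, D, max_ext = max_ext)
  }
  ext_head <- if (n_s >= 2) {
    extend_march(smoothed[1, ],
                 end_tangent(smoothed[1, ], smoothed[1, ] - smoothed[min(n_s, 6), ]),
                 -kappa, mask, D, max_ext = max_ext)
  }
  full <- rbind(if (!is.null(ext_head)) ext_head[rev(seq_len(nrow(ext_head))), , drop = FALSE],
                smoothed, ext_tail)
  core_range <- c(nrow(if (is.null(ext_head)) matrix(0, 0, 2) else ext_head) + 1,
                  nrow(full) - nrow(if (is.null(ext_tail)) matrix(0, 0, 2) else ext_tail))

  arce <- c(0, cumsum(sqrt(rowSums(diff(full)^2))))
  lw_full <- 2 * bilinear(D, full[, 1], full[, 2])
  mean_width <- mean(2 * bilinear(D, smoothed[, 1], smoothed[, 2]))
  degenerate <- max(arce) < degenerate_ratio * mean_width

  if (degenerate) {
    v <- smoothed
    arc <- c(0, cumsum(sqrt(rowSums(diff(v)^2))))
    lw <- 2 * bilinear(D, v[, 1], v[, 2])
  } else {
    v <- full; arc <- arce; lw <- lw_full
  }
  structure(list(vertices = unname(v), arclength_px = arc,
                 local_width_px = pmax(lw, 0),
                 mean_width_px = mean_width,
                 length_px = max(arc),
                 degenerate = degenerate),
            class = "midline")
}

#' @export
print.midline <- function(x, ...) {
  cat(sprintf("<midline> length %.1f px, mean width %.1f px%s\n",
              x$length_px, x$mean_width_px,
              if (x$degenerate) " [degenerate axis]" else ""))
  invisible(x)
}

midline_normals <- function(midline) {
  v <- midline$vertices
  n <- nrow(v)
  tang <- rbind(v[2, ] - v[1, ],
                (v[3:n, , drop = FALSE] - v[1:(n - 2), , drop = FALSE]) / 2,
                v[n, ] - v[n - 1, ])
  tl <- sqrt(rowSums(tang^2)); tl[tl < 1e-9] <- 1
  tang <- tang / tl
  cbind(-tang[, 2], tang[, 1])
}

#' Computationally straighten a mask or image along its midline
#'
#' Resamples the input on an (arc position x normal offset) grid: one row per
#' midline vertex (~1 px arc steps), one column per signed offset along the
#' local normal. For a binary input the second-moment equivalent-ellipse axis
#' lengths `a` and `b` of the straightened mask are recorded, from which the
#' eccentricity is computed.
#'
#' @param x binary mask or intensity matrix.
#' @param midline an [extract_midline()] result (or compatible list).
#' @param half_width_px maximum normal offset; default half the largest local
#'   width plus 2 px.
#' @return A `straightened_shape`: list with `grid` (arc x offset matrix),
#'   `is_mask`, `a`, `b` (binary input only), `arclength_px`.
#' @export
straighten <- function(x, midline, half_width_px = NULL) {
  assert_matrix(x, "x")
  is_mask <- all(x %in% c(0, 1))
  if (is.null(half_width_px)) {
    half_width_px <- max(midline$local_width_px) / 2 + 2
  }
  v <- midline$vertices
  nor <- midline_normals(midline)
  offs <- seq(-half_width_px, half_width_px, by = 1)
  n <- nrow(v); m <- length(offs)
  rr <- matrix(v[, 1], n, m) + outer(nor[, 1], offs)
  cc <- matrix(v[, 2], n, m) + outer(nor[, 2], offs)
  clipped <- any(rr < 1 | rr > nrow(x) | cc < 1 | cc > ncol(x))
  if (clipped) warn("Normals extend past the frame; samples clipped to 0.")
  grid <- matrix(bilinear(x, as.numeric(rr), as.numeric(cc), fill = 0), n, m)
  if (is_mask) grid <- (grid >= 0.5) * 1
  ab <- c(NA_real_, NA_real_)
  if (is_mask) ab <- moment_axes(grid)
  structure(list(grid = grid, is_mask = is_mask, a = ab[1], b = ab[2],
                 arclength_px = midline$arclength_px,
                 offsets_px = offs),
            class = "straightened_shape")
}

# Major/minor axis lengths of the ellipse with the same second moments.
moment_axes <- function(mask) {
  pts <- which(mask > 0.5, arr.ind = TRUE)
  if (nrow(pts) < 2) return(c(0, 0))
  cv <- stats::cov(pts) * (nrow(pts) - 1) / nrow(pts)
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev[ev < 0] <- 0
  c(4 * sqrt(ev[1]), 4 * sqrt(ev[2]))
}

#' Second-moment eccentricity
#'
#' `sqrt(1 - (b/a)^2)` where `a` and `b` are the major and minor axis lengths
#' of the ellipse with the same second moments as the (straightened) mask:
#' 0 for a circle, approaching 1 for a line. Accepts a
#' [straighten()] result or a binary mask directly (near-spherical shapes need
#' no straightening).
#'
#' @param shape a `straightened_shape` or a binary matrix.
#' @return Eccentricity in \[0, 1); attribute `degenerate` is `TRUE` when the
#'   minor axis collapses to zero after rasterization.
#' @export
eccentricity <- function(shape) {
  if (is.matrix(shape)) {
    ab <- moment_axes(shape)
  } else if (inherits(shape, "straightened_shape")) {
    if (!shape$is_mask) abort("Eccentricity requires a straightened mask, not an image.")
    ab <- c(shape$a, shape$b)
  } else {
    abort("`shape` must be a straightened_shape or a binary matrix.")
  }
  a <- ab[1]; b <- ab[2]
  if (a <= 0) abort("Degenerate mask: no extent.")
  if (b <= 0) {
    return(structure(1, degenerate = TRUE))
  }
  structure(sqrt(max(1 - (b / a)^2, 0)), degenerate = FALSE)
}

#' One-row shape summary of a mask
#'
#' Convenience wrapper producing the per-sample morphometrics record: area,
#' perimeter, midline length, mean width, straightened eccentricity and the
#' degenerate-axis flag.
#'
#' @param mask binary matrix (single connected component).
#' @param pixel_size physical pixel edge length (default 1 = pixel units).
#' @param sample_id identifier.
#' @return One-row tibble.
#' @export
measure_shape <- function(mask, pixel_size = 1, sample_id = "sample") {
  ap <- measure_area_perimeter(mask, pixel_size)
  ml <- extract_midline(mask)
  ecc <- if (ml$degenerate) {
    eccentricity((mask > 0) * 1)
  } else {
    eccentricity(straighten((mask > 0) * 1, ml))
  }
  tibble(sample_id = sample_id,
         area = ap$area, perimeter = ap$perimeter,
         midline_length = ml$length_px * pixel_size,
         mean_width = ml$mean_width_px * pixel_size,
         eccentricity = as.numeric(ecc),
         degenerate_axis = ml$degenerate)
}
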