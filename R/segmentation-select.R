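# Mask selection policy, smoothing and the end-to-end segmentation wrapper.

mask_solidity <- function(mask) {
  pts <- which(mask > 0, arr.ind = TRUE)
  if (nrow(pts) < 3) return(0)
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  x <- hp[, 2]; y <- hp[, 1]
  hull_area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
  if (hull_area <= 0) return(0)
  sum(mask > 0) / hull_area
}

check_mask <- function(mask, median_area, policy) {
  fails <- character(0)
  if (sum(mask) == 0) return("empty mask")
  if (n_components(mask) != 1) {
    fails <- c(fails, sprintf("connected components = %d (expected 1)", n_components(mask)))
  }
  sol <- mask_solidity(largest_component(mask))
  if (sol < policy$solidity_min) {
    fails <- c(fails, sprintf("solidity %.2f < %.2f", sol, policy$solidity_min))
  }
  a <- sum(mask)
  if (a < policy$area_range[1] * median_area || a > policy$area_range[2] * median_area) {
    fails <- c(fails, sprintf("area %d outside [%g, %g] x median candidate area",
                              a, policy$area_range[1], policy$area_range[2]))
  }
  fails
}

smooth_mask <- function(mask, radius = 2) {
  brush <- EBImage::makeBrush(2 * radius + 1, shape = "disc")
  m <- EBImage::closing(mask, brush)
  m <- EBImage::opening(m, brush)
  m <- EBImage::fillHull(m)
  largest_component(as.matrix(m) * 1)
}

upsample_mask <- function(mask, factor, full_dim = NULL) {
  if (factor == 1 && is.null(full_dim)) return(mask)
  if (is.null(full_dim)) full_dim <- dim(mask) * factor
  up <- as.matrix(EBImage::resize(mask, w = full_dim[1], h = full_dim[2],
                                  filter = "bilinear"))
  (up > 0.5) * 1
}

#' Select, smooth and upsample the final segmentation mask
#'
#' Implements the selection policy between the watershed and classifier masks:
#' the watershed mask is preferred; it falls back to the classifier mask when
#' automated plausibility checks fail (connected-component count, solidity,
#' area relative to the median candidate); a manually drawn mask, when given,
#' always wins. The selected mask is smoothed by binary closing then opening
#' with a small disc, hole-filled, reduced to a single connected component,
#' and upsampled to full resolution.
#'
#' @param watershed,classifier binary matrices at the working scale.
#' @param manual optional full-resolution binary matrix overriding both.
#' @param policy list with `solidity_min`, `area_range` (multiples of the
#'   median candidate area) and `smooth_radius`.
#' @param upsample_factor working-scale factor to undo (default 2).
#' @param full_dim optional exact full-resolution dimensions.
#' @return A `mask_result`: list with `mask` (full resolution), `provenance`
#'   (`"watershed"`, `"classifier"` or `"manual"`) and `qc_flags`.
#' @export
select_mask <- function(watershed, classifier, manual = NULL,
                        policy = list(solidity_min = 0.7,
                                      area_range = c(0.25, 4),
                                      smooth_radius = 2),
                        upsample_factor = 2, full_dim = NULL) {
  qc_flags <- character(0)
  if (!is.null(manual)) {
    m <- smooth_mask((manual > 0) * 1, policy$smooth_radius)
    return(structure(list(mask = m, provenance = "manual", qc_flags = qc_flags),
                     class = "mask_result"))
  }
  if (!all(dim(watershed) == dim(classifier))) abort("Masks must share one shape.")
  areas <- c(sum(watershed), sum(classifier))
  med <- median(areas)
  fails_w <- check_mask(watershed, med, policy)
  fails_c <- check_mask(classifier, med, policy)
  if (length(fails_w) == 0) {
    chosen <- watershed; prov <- "watershed"
  } else if (length(fails_c) == 0) {
    chosen <- classifier; prov <- "classifier"
    qc_flags <- paste("watershed rejected:", fails_w)
  } else {
    abort(paste0("All candidate masks fail plausibility checks and no manual mask given.\n",
                 "watershed: ", paste(fails_w, collapse = "; "), "\n",
                 "classifier: ", paste(fails_c, collapse = "; ")))
  }
  m <- smooth_mask(chosen, policy$smooth_radius)
  m <- upsample_mask(m, upsample_factor, full_dim)
  structure(list(mask = m, provenance = prov, qc_flags = qc_flags),
            class = "mask_result")
}

#' @export
print.mask_result <- function(x, ...) {
  cat(sprintf("<mask_result> %d x %d px, area %d px, provenance '%s'%s\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), x$provenance,
              if (length(x$qc_flags)) paste0("; flags: ", paste(x$qc_flags, collapse = " | ")) else ""))
  invisible(x)
}

#' Segment one image end to end
#'
#' Runs the full brightfield segmentation stage: pixel classification,
#' watershed on the edge-probability landscape, mask selection with automated
#' fallback, smoothing and upsampling.
#'
#' @param classifier a [train_pixel_classifier()] fit.
#' @param image an [image_sample()] (needs a `"BF"` channel) or matrix.
#' @param manual optional manual full-resolution mask (always wins).
#' @return A `mask_result` carrying the class-probability maps in `prob_maps`.
#' @export
segment_sample <- function(classifier, image, manual = NULL) {
  cls <- classify(classifier, image)
  cmask <- largest_component((cls$labels == "inside") * 1)
  cmask <- as.matrix(EBImage::fillHull(cmask)) * 1
  wmask <- tryCatch(
    watershed_mask(cls$prob_maps$edge, cls$prob_maps$inside, cls$prob_maps$background),
    error = function(e) matrix(0, nrow(cmask), ncol(cmask))
  )
  bf <- if (inherits(image, "image_sample")) image$channels[["BF"]] else image
  res <- select_mask(wmask, cmask, manual = manual,
                     upsample_factor = classifier$downsample_factor,
                     full_dim = dim(bf))
  res$prob_maps <- cls$prob_maps
  res
}

# Intersection over union of two binary masks.
#' @export
mask_iou <- function(a, b) {
  inter <- sum(a > 0 & b > 0)
  uni <- sum(a > 0 | b > 0)
  if (uni == 0) return(NA_real_)
  inter / uni
}
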