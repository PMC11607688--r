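#' Watershed segmentation from the edge-probability landscape
#'
#' Builds the alternative mask: the edge-class probability map is treated as a
#' topographic surface and flooded from high-confidence inside and background
#' seeds (priority-flood, deterministic). The union of basins grown from
#' inside seeds, reduced to its largest connected component, is returned as
#' the mask.
#'
#' @param edge_prob,inside_prob,background_prob per-class probability maps
#'   (same shape, values in \[0, 1\]).
#' @param inside_threshold probability above which pixels seed the inside.
#' @param background_threshold probability above which border-touching pixels
#'   seed the background.
#' @return Binary matrix (working scale) — the inside basin.
#' @export
watershed_mask <- function(edge_prob, inside_prob, background_prob,
                           inside_threshold = 0.8, background_threshold = 0.8) {
  assert_matrix(edge_prob); assert_matrix(inside_prob); assert_matrix(background_prob)
  if (!all(dim(edge_prob) == dim(inside_prob)) ||
      !all(dim(edge_prob) == dim(background_prob))) {
    abort("Probability maps must share one shape.")
  }
  nr <- nrow(edge_prob); nc <- ncol(edge_prob)
  inside_seed <- inside_prob > inside_threshold
  if (!any(inside_seed)) {
    abort("No inside seed found: image appears unsegmentable.")
  }
  in_lab <- as.matrix(EBImage::bwlabel(inside_seed * 1))
  n_in <- max(in_lab)

  bg <- background_prob > background_threshold
  border <- matrix(FALSE, nr, nc)
  border[1, ] <- TRUE; border[nr, ] <- TRUE; border[, 1] <- TRUE; border[, nc] <- TRUE
  bg_lab <- as.matrix(EBImage::bwlabel(bg * 1))
  touching <- unique(bg_lab[border & bg_lab > 0])
  bg_seed <- if (length(touching)) bg & matrix(bg_lab %in% touching, nr, nc) else bg
  if (!any(bg_seed)) {
    warn("No confident background seed; using the frame border.")
    bg_seed <- border
  }

  seeds <- matrix(0L, nr, nc)
  seeds[in_lab > 0] <- as.integer(in_lab[in_lab > 0])
  seeds[bg_seed & seeds == 0L] <- n_in + 1L
  # the edge-probability ridge is a plateau as wide as the trained edge band;
  # tilting it by the inside/background probability margin makes the floods
  # meet on the equiprobability line, i.e. at the band's centre
  altitude <- edge_prob - abs(inside_prob - background_prob)
  labels <- .priority_flood(altitude, seeds)
  largest_component((labels >= 1 & labels <= n_in) * 1)
}
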