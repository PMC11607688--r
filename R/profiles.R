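# Oriented, normalized anteroposterior fluorescence-intensity profiles.

#' Raw AP intensity profile along a midline
#'
#' For every position along the midline, averages the channel intensity over
#' the segment orthogonal to the midline, clipped to the mask. Positions whose
#' normal does not intersect the mask are dropped with a warning.
#'
#' @param image an [image_sample()] or a single-channel matrix.
#' @param mask binary mask delimiting the aggregate.
#' @param midline an [extract_midline()] result.
#' @param channels channels to profile (default: all non-brightfield channels
#'   of an `image_sample`, or the single matrix).
#' @param sample_id identifier stored on every row.
#' @return Tibble with columns `sample_id`, `channel`, `position_px`
#'   (arc length), `intensity`.
#' @export
ap_profile <- function(image, mask, midline, channels = NULL,
                       sample_id = "sample") {
  chan_list <- if (inherits(image, "image_sample")) {
    if (is.null(channels)) channels <- setdiff(names(image$channels), "BF")
    if (!length(channels)) channels <- names(image$channels)
    image$channels[channels]
  } else {
    assert_matrix(image, "image")
    list(intensity = image)
  }
  v <- midline$vertices
  nor <- midline_normals(midline)
  hw <- max(midline$local_width_px) / 2 + 2
  offs <- seq(-hw, hw, by = 1)
  n <- nrow(v); m <- length(offs)
  rr <- matrix(v[, 1], n, m) + outer(nor[, 1], offs)
  cc <- matrix(v[, 2], n, m) + outer(nor[, 2], offs)
  # strictly interior samples only: at the boundary the interpolated channel
  # mixes in background signal and dilutes the profile
  in_mask <- matrix(bilinear((mask > 0) * 1, as.numeric(rr), as.numeric(cc),
                             fill = 0), n, m) >= 0.999
  keep <- rowSums(in_mask) > 0
  if (!all(keep)) {
    warn(sprintf("%d midline position(s) had no in-mask samples and were dropped.",
                 sum(!keep)))
  }
  purrr::imap_dfr(chan_list, function(ch, nm) {
    vals <- matrix(bilinear(ch, as.numeric(rr), as.numeric(cc), fill = NA_real_), n, m)
    vals[!in_mask] <- NA
    tibble(sample_id = sample_id, channel = nm,
           position_px = midline$arclength_px[keep],
           intensity = rowMeans(vals[keep, , drop = FALSE], na.rm = TRUE))
  })
}

# Decide whether a single reference profile needs flipping: TRUE when the
# anterior (low-position) half carries more mass than the posterior half.
needs_flip <- function(position_px, intensity) {
  mid <- max(position_px) / 2
  lo <- sum(intensity[position_px < mid])
  hi <- sum(intensity[position_px > mid])
  if (isTRUE(all.equal(lo, hi))) return(NA)   # exact tie
  lo > hi
}

#' Orient and normalize a set of AP profiles
#'
#' Each sample is flipped, if needed, so that the half with the greater
#' reference-channel mass lies toward normalized position 1 — the posterior is
#' the highest-expressing pole of the reference (T) channel. Arc positions are
#' rescaled to \[0, 1\] on a common grid; intensities are divided per channel
#' by the maximum over all samples (`"global"`), over each sample's group
#' (`"per_group"`), by each sample x channel's own maximum
#' (`"per_channel_max"`), or left as-is (`"none"`). An exactly symmetric
#' reference profile is an orientation tie: the original direction is kept and
#' the sample flagged.
#'
#' @param profiles tibble from [ap_profile()] (rows from several samples may
#'   be bound together).
#' @param reference_channel channel defining the orientation (default `"T"`).
#' @param length_grid_n number of points of the common position grid.
#' @param intensity_norm one of `"global"`, `"per_group"`,
#'   `"per_channel_max"`, `"none"`.
#' @param groups optional named character vector mapping `sample_id` to group;
#'   required for `"per_group"`.
#' @return An `ap_profiles` tibble: `sample_id`, `group`, `channel`,
#'   `position` (in \[0, 1\]), `intensity`, `flipped`, `orientation_tie`,
#'   `norm`.
#' @export
orient_and_normalize <- function(profiles, reference_channel = "T",
                                 length_grid_n = 100,
                                 intensity_norm = c("global", "per_group",
                                                    "per_channel_max", "none"),
                                 groups = NULL) {
  intensity_norm <- match.arg(intensity_norm)
  profiles <- as_tibble(profiles)
  ids <- unique(profiles$sample_id)
  if (!all(vapply(ids, function(id)
    reference_channel %in% profiles$channel[profiles$sample_id == id], logical(1)))) {
    abort(sprintf("Reference channel '%s' missing from some samples.", reference_channel))
  }
  grid <- seq(0, 1, length.out = length_grid_n)

  out <- purrr::map_dfr(ids, function(id) {
    p <- profiles[profiles$sample_id == id, ]
    ref <- p[p$channel == reference_channel, ]
    fl <- needs_flip(ref$position_px, ref$intensity)
    tie <- is.na(fl); if (tie) fl <- FALSE
    L <- max(p$position_px)
    purrr::map_dfr(unique(p$channel), function(ch) {
      pc <- p[p$channel == ch, ]
      pos <- pc$position_px / L
      if (fl) pos <- 1 - pos
      o <- order(pos)
      tibble(sample_id = id,
             channel = ch,
             position = grid,
             intensity = approx(pos[o], pc$intensity[o], xout = grid, rule = 2)$y,
             flipped = fl, orientation_tie = tie)
    })
  })
  out$group <- if (is.null(groups)) "all" else unname(groups[out$sample_id])
  if (intensity_norm == "global") {
    out <- out %>% group_by(.data$channel) %>%
      mutate(intensity = .data$intensity / max(.data$intensity)) %>% ungroup()
  } else if (intensity_norm == "per_group") {
    out <- out %>% group_by(.data$channel, .data$group) %>%
      mutate(intensity = .data$intensity / max(.data$intensity)) %>% ungroup()
  } else if (intensity_norm == "per_channel_max") {
    out <- out %>% group_by(.data$channel, .data$sample_id) %>%
      mutate(intensity = .data$intensity / max(.data$intensity)) %>% ungroup()
  }
  out$norm <- intensity_norm
  class(out) <- c("ap_profiles", class(out))
  out
}

#' Mean and standard-deviation bands over replicate profiles
#'
#' Per channel and position, the mean and sample (n-1) standard deviation over
#' samples; a single profile gets an s.d. band of zero.
#'
#' @param profiles an `ap_profiles` tibble ([orient_and_normalize()]).
#' @param by extra grouping columns (e.g. `"group"`).
#' @return Tibble with `channel`, `position`, `mean`, `sd`, `n`.
#' @export
average_profiles <- function(profiles, by = character(0)) {
  profiles %>%
    group_by(across(dplyr::all_of(c("channel", "position", by)))) %>%
    summarise(mean = mean(.data$intensity),
              sd = ifelse(dplyr::n() > 1, sd(.data$intensity), 0),
              n = dplyr::n(), .groups = "drop")
}

#' Kymograph of an AP profile over time
#'
#' Stacks the oriented, normalized profile of one channel over the frames of a
#' time-lapse. The orientation (flip) is decided once, on the final frame —
#' where polarization is strongest — and applied to every frame, preventing
#' artifactual frame-to-frame axis reversals. Frames listed in
#' `missing_frames` (e.g. failed segmentations) become rows of `NA`, never
#' silently interpolated.
#'
#' @param frame_profiles tibble with columns `frame`, `channel`,
#'   `position_px`, `intensity` (e.g. [ap_profile()] run per frame with
#'   `sample_id` = frame).
#' @param reference_channel channel defining orientation and the one stacked.
#' @param length_grid_n points of the common position grid.
#' @param missing_frames integer frames to mark missing.
#' @return A `kymograph`: list with `matrix` (time x position), `frames`,
#'   `positions`, `channel`.
#' @export
kymograph <- function(frame_profiles, reference_channel = "T",
                      length_grid_n = 100, missing_frames = integer(0)) {
  fp <- as_tibble(frame_profiles)
  stopifnot(all(c("frame", "channel", "position_px", "intensity") %in% names(fp)))
  frames <- sort(unique(c(fp$frame, missing_frames)))
  last <- max(fp$frame)
  ref_last <- fp[fp$frame == last & fp$channel == reference_channel, ]
  fl <- needs_flip(ref_last$position_px, ref_last$intensity)
  if (is.na(fl)) fl <- FALSE
  grid <- seq(0, 1, length.out = length_grid_n)
  mat <- matrix(NA_real_, length(frames), length_grid_n,
                dimnames = list(frames, NULL))
  for (f in setdiff(frames, missing_frames)) {
    p <- fp[fp$frame == f & fp$channel == reference_channel, ]
    if (!nrow(p)) next
    pos <- p$position_px / max(p$position_px)
    if (fl) pos <- 1 - pos
    o <- order(pos)
    mat[as.character(f), ] <- approx(pos[o], p$intensity[o], xout = grid, rule = 2)$y
  }
  structure(list(matrix = mat, frames = frames, positions = grid,
                 channel = reference_channel, flipped = fl),
            class = "kymograph")
}

#' Average kymographs over replicate time-lapses
#'
#' @param kymos list of [kymograph()] objects on identical grids.
#' @return A `kymograph` whose matrix is the per-entry mean (NA-aware).
#' @export
average_kymographs <- function(kymos) {
  stopifnot(length(kymos) >= 1)
  dims <- unique(lapply(kymos, function(k) dim(k$matrix)))
  if (length(dims) != 1) abort("Kymographs must share time and position grids.")
  arr <- simplify2array(lapply(kymos, function(k) k$matrix))
  out <- kymos[[1]]
  out$matrix <- apply(arr, c(1, 2), function(v)
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  out
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> channel '%s', %d frames x %d positions\n",
              x$channel, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Multichannel AP profiles along a reference-defined axis
#'
#' For multiplexed (HCR-style) stainings: the axis — mask, midline and
#' orientation — is computed once from the reference (T) channel, every other
#' channel is sampled along that same axis, and each channel is normalized to
#' its own maximum, so every profile peaks at exactly 1.
#'
#' @param image an [image_sample()] (e.g. a sum-intensity projection).
#' @param mask binary mask of the reference channel (from segmentation of the
#'   reference signal); used to delimit sampling for all channels.
#' @param reference_channel channel defining the axis (default `"T"`).
#' @param length_grid_n points of the common position grid.
#' @param sample_id identifier.
#' @return An `ap_profiles` tibble (norm `"per_channel_max"`).
#' @export
multichannel_profile <- function(image, mask, reference_channel = "T",
                                 length_grid_n = 100, sample_id = "sample") {
  stopifnot(inherits(image, "image_sample"))
  if (!reference_channel %in% names(image$channels)) {
    abort(sprintf("Reference channel '%s' missing from the image.", reference_channel))
  }
  ml <- extract_midline(mask)
  raw <- ap_profile(image, mask, ml, sample_id = sample_id)
  orient_and_normalize(raw, reference_channel = reference_channel,
                       length_grid_n = length_grid_n,
                       intensity_norm = "per_channel_max")
}
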