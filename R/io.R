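# Reading/writing of images, masks, ground-truth sidecars and result tables.

#' Write an image sample as a multichannel TIFF
#'
#' Channels are written as 16-bit pages (intensities assumed in
#' \[0, 65535\]); channel names go to a JSON sidecar next to the file.
#'
#' @param image an [image_sample()].
#' @param path output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(image, path) {
  stopifnot(inherits(image, "image_sample"))
  pages <- lapply(image$channels, function(m) pmin(pmax(m / 65535, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  jsonlite::write_json(
    list(id = image$id, channels = names(image$channels),
         pixel_size_um = image$pixel_size_um),
    sub("\\.tiff?$", ".json", path), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read a multichannel TIFF written by [write_image_tiff()]
#'
#' @param path `.tif` path; channel names are taken from the JSON sidecar or
#'   `channel_names`.
#' @param channel_names optional channel names overriding the sidecar.
#' @return An [image_sample()].
#' @export
read_image_tiff <- function(path, channel_names = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  side <- sub("\\.tiff?$", ".json", path)
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else NULL
  nms <- channel_names %||% meta$channels %||% paste0("ch", seq_along(pages))
  chans <- setNames(lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    p * 65535
  }), nms[seq_along(pages)])
  image_sample(chans, pixel_size_um = meta$pixel_size_um,
               id = meta$id %||% basename(path))
}

#' Write a binary mask as an 8-bit TIFF
#' @param mask binary matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF((mask > 0) * 1, path, bits.per.sample = 8, compression = "none")
  invisible(path)
}

#' Read a binary mask TIFF
#' @param path mask path.
#' @return Binary matrix.
#' @export
read_mask_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  (m > 0.5) * 1
}

#' Write a synthetic sample: TIFF + ground-truth JSON sidecar
#'
#' @param sample a [make_gastruloid_image()] result.
#' @param dir output directory (created if needed).
#' @param name file stem (default the sample id).
#' @return The image path, invisibly.
#' @export
write_synthetic_sample <- function(sample, dir, name = NULL) {
  stopifnot(inherits(sample, "synthetic_sample"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  name <- name %||% sample$image$id
  img_path <- file.path(dir, paste0(name, ".tif"))
  write_image_tiff(sample$image, img_path)
  write_mask_tiff(sample$true_mask, file.path(dir, paste0(name, "_mask.tif")))
  jsonlite::write_json(
    list(seed = sample$seed,
         shape = unclass(sample$shape),
         midline_vertices = unname(sample$true_midline$vertices),
         midline_width = sample$true_midline$local_width_px,
         profiles = sample$true_profiles),
    file.path(dir, paste0(name, "_truth.json")),
    auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(img_path)
}

#' Write a time-lapse as a multipage TIFF plus truth CSV
#'
#' @param tl a [make_timelapse()] result.
#' @param dir output directory.
#' @param name file stem.
#' @return The stack path, invisibly.
#' @export
write_timelapse <- function(tl, dir, name = "timelapse") {
  stopifnot(inherits(tl, "synthetic_timelapse"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, paste0(name, ".tif"))
  pages <- lapply(tl$frames, function(m) pmin(pmax(m / 65535, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  write.csv(tl$truth, file.path(dir, paste0(name, "_truth.csv")), row.names = FALSE)
  invisible(path)
}

#' Read a multipage TIFF stack as a list of frames
#' @param path stack path.
#' @return List of matrices (intensities rescaled to \[0, 65535\]).
#' @export
read_timelapse <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    p * 65535
  })
}

# Deterministic CSV writer used by every CLI stage.
write_result_csv <- function(df, path) {
  write.csv(as.data.frame(df), path, row.names = FALSE)
  invisible(path)
}
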