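# Three-class logistic-regression pixel classifier.

CLASSES <- c("background", "inside", "edge")

# Convert a binary ground-truth mask into {background, inside, edge} labels.
# The edge class is a band of `edge_band_px` on both sides of the mask
# boundary; inside = mask minus the band; background = the rest.
three_class_gt <- function(mask, edge_band_px = 3) {
  d_in <- as.matrix(EBImage::distmap(mask))
  d_out <- as.matrix(EBImage::distmap(1 - mask))
  lab <- matrix(CLASSES[1], nrow(mask), ncol(mask))
  lab[mask > 0] <- CLASSES[2]
  edge <- (mask > 0 & d_in <= edge_band_px) | (mask == 0 & d_out <= edge_band_px)
  lab[edge] <- CLASSES[3]
  lab
}

#' Train the brightfield pixel classifier
#'
#' Converts binary ground-truth masks into three classes (background, inside,
#' edge — the edge being a morphological band of `edge_band_px` around the
#' mask boundary at the working scale), extracts the multi-scale feature bank
#' from each downsampled brightfield image, subsamples a balanced set of
#' pixels per class, and fits a ridge-regularized multinomial logistic
#' regression. Training is deterministic given `seed`.
#'
#' @param samples list of training samples; each a list with `image` (an
#'   [image_sample()] with a `"BF"` channel, or a matrix) and `mask` (binary
#'   matrix at full resolution).
#' @param config a [bank_config()].
#' @param edge_band_px edge-band half-width in pixels at the downsampled scale
#'   (default 2).
#' @param downsample_factor working-scale reduction applied before feature
#'   extraction (default 2).
#' @param n_per_class pixels sampled per class per image.
#' @param lambda ridge penalty of the multinomial fit.
#' @param seed integer seed controlling pixel subsampling.
#' @return A `pixel_classifier` with coefficient matrix, intercepts, feature
#'   names, bank configuration and training metadata.
#' @export
train_pixel_classifier <- function(samples, config = bank_config(),
                                   edge_band_px = 2, downsample_factor = 2,
                                   n_per_class = 2000, lambda = 1e-4, seed = 1) {
  if (length(samples) < 1) abort("Need at least one training sample.")
  xs <- list(); ys <- list(); ds <- list()
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    bf <- if (inherits(s$image, "image_sample")) s$image$channels[["BF"]] else s$image
    if (is.null(bf)) abort("Training image lacks a 'BF' channel.")
    bf_ds <- downsample(bf, downsample_factor)
    mask_ds <- (block_reduce(s$mask, downsample_factor) > 0.5) * 1
    if (downsample_factor == 1) mask_ds <- (s$mask > 0.5) * 1
    gt <- three_class_gt(mask_ds, edge_band_px)
    fs <- extract_features(bf_ds, config)
    xs[[i]] <- fs$features
    ys[[i]] <- as.character(gt)
    d_in <- as.matrix(EBImage::distmap(mask_ds))
    d_out <- as.matrix(EBImage::distmap(1 - mask_ds))
    ds[[i]] <- as.numeric(pmax(d_in, d_out))   # distance to the mask boundary
  }
  feature_names <- extract_features(matrix(0, 32, 32), config)$feature_names
  y_all <- unlist(ys)
  missing <- setdiff(CLASSES, unique(y_all))
  if (length(missing)) {
    abort(sprintf("Class '%s' absent from all training images.", missing[1]))
  }

  # balanced subsample per class; half of each quota comes from within 8 px of
  # the mask boundary, where the decision actually happens — uniform sampling
  # under-represents boundary-adjacent pixels and blurs the fitted boundary
  sel <- with_seed(seed, {
    purrr::pmap(list(xs, ys, ds), function(x, y, d) {
      idx <- unlist(lapply(CLASSES, function(cl) {
        w <- which(y == cl)
        if (length(w) <= n_per_class) return(w)
        near <- w[d[w] <= 8]
        n_near <- min(length(near), floor(n_per_class / 2))
        pick <- if (n_near > 0) sample(near, n_near) else integer(0)
        rest <- setdiff(w, pick)
        sort(c(pick, sample(rest, n_per_class - n_near)))
      }))
      list(x = x[idx, , drop = FALSE], y = y[idx])
    })
  })
  X <- do.call(rbind, lapply(sel, `[[`, "x"))
  Y <- factor(unlist(lapply(sel, `[[`, "y")), levels = CLASSES)

  fit <- glmnet::glmnet(X, Y, family = "multinomial", alpha = 0,
                        lambda = lambda, standardize = TRUE)
  cf <- glmnet::coef.glmnet(fit, s = lambda)
  weights <- vapply(CLASSES, function(cl) as.numeric(cf[[cl]])[-1],
                    numeric(ncol(X)))
  intercepts <- vapply(CLASSES, function(cl) as.numeric(cf[[cl]])[1], numeric(1))
  rownames(weights) <- colnames(X)

  structure(list(weights = weights, intercepts = intercepts,
                 feature_names = colnames(X), config = config,
                 edge_band_px = edge_band_px,
                 downsample_factor = downsample_factor,
                 classes = CLASSES,
                 training = list(n_samples = length(samples),
                                 n_pixels = nrow(X), seed = seed,
                                 lambda = lambda)),
            class = "pixel_classifier")
}

#' @export
print.pixel_classifier <- function(x, ...) {
  cat(sprintf("<pixel_classifier> %d features, classes %s; trained on %d image(s), %d pixels\n",
              length(x$feature_names), paste(x$classes, collapse = "/"),
              x$training$n_samples, x$training$n_pixels))
  invisible(x)
}

#' Tidiers for the pixel classifier
#'
#' `tidy()` returns one row per feature/class coefficient; `glance()` a
#' one-row summary of the fit.
#'
#' @param x a `pixel_classifier`.
#' @param ... unused.
#' @name pixel_classifier_tidiers
NULL

#' @rdname pixel_classifier_tidiers
#' @exportS3Method generics::tidy
tidy.pixel_classifier <- function(x, ...) {
  as_tibble(x$weights, rownames = "term") %>%
    tidyr::pivot_longer(-"term", names_to = "class", values_to = "estimate")
}

#' @rdname pixel_classifier_tidiers
#' @exportS3Method generics::glance
glance.pixel_classifier <- function(x, ...) {
  tibble(n_features = length(x$feature_names),
         n_classes = length(x$classes),
         n_training_pixels = x$training$n_pixels,
         n_training_images = x$training$n_samples,
         lambda = x$training$lambda,
         edge_band_px = x$edge_band_px,
         downsample_factor = x$downsample_factor)
}

#' Classify every pixel of a brightfield image
#'
#' Applies the trained classifier at its working scale and returns the argmax
#' label image together with all three class-probability maps (which sum to 1
#' per pixel). Exact probability ties resolve to the first class in the fixed
#' order background < inside < edge.
#'
#' @param classifier a [train_pixel_classifier()] fit.
#' @param image an [image_sample()] with a `"BF"` channel, or a matrix.
#' @return List with `labels` (character matrix at the working scale) and
#'   `prob_maps` (named list of matrices `background`, `inside`, `edge`).
#' @export
classify <- function(classifier, image) {
  stopifnot(inherits(classifier, "pixel_classifier"))
  bf <- if (inherits(image, "image_sample")) image$channels[["BF"]] else image
  if (is.null(bf)) abort("Image lacks a 'BF' channel.")
  bf_ds <- downsample(bf, classifier$downsample_factor)
  fs <- extract_features(bf_ds, classifier$config)
  if (!identical(fs$feature_names, classifier$feature_names)) {
    abort("Feature names do not match the classifier's training bank.")
  }
  scores <- sweep(fs$features %*% classifier$weights, 2,
                  classifier$intercepts, "+")
  scores <- scores - apply(scores, 1, max)
  es <- exp(scores)
  probs <- es / rowSums(es)
  lab_idx <- max.col(probs, ties.method = "first")
  nr <- fs$dim[1]; nc <- fs$dim[2]
  list(labels = matrix(classifier$classes[lab_idx], nr, nc),
       prob_maps = setNames(lapply(seq_along(classifier$classes),
                                   function(j) matrix(probs[, j], nr, nc)),
                            classifier$classes))
}
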