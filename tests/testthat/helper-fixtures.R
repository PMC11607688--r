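# Shared fixtures, all built in code.

disk_mask <- function(r, dim = 2 * r + 41) {
  ctr <- (dim + 1) / 2
  xx <- outer(seq_len(dim) - ctr, rep(1, dim))
  (xx^2 + t(xx)^2 <= r^2) * 1
}

rect_mask <- function(h, w, dim = c(h + 80, w + 60)) {
  m <- matrix(0, dim[1], dim[2])
  r0 <- floor((dim[1] - h) / 2) + 1
  c0 <- floor((dim[2] - w) / 2) + 1
  m[r0:(r0 + h - 1), c0:(c0 + w - 1)] <- 1
  m
}

ellipse_mask <- function(a, b, dim = 2 * a + 61) {
  ctr <- (dim + 1) / 2
  xx <- outer(seq_len(dim) - ctr, rep(1, dim))
  yy <- t(xx)
  ((yy / a)^2 + (xx / b)^2 <= 1) * 1   # major axis along columns
}

# memoised 3-image classifier shared by the segmentation tests
.shared <- new.env(parent = emptyenv())

bench_classifier <- function() {
  if (is.null(.shared$clf)) {
    train <- lapply(1:3, function(i) {
      s <- make_benchmark_sample(100 + i)
      list(image = s$image, mask = s$true_mask)
    })
    .shared$clf <- train_pixel_classifier(train, seed = 1)
  }
  .shared$clf
}

# brute-force second moments of a binary mask: independent oracle for the
# equivalent-ellipse axis lengths
oracle_moment_axes <- function(mask) {
  pts <- which(mask > 0, arr.ind = TRUE)
  mr <- mean(pts[, 1]); mc <- mean(pts[, 2])
  u20 <- mean((pts[, 1] - mr)^2)
  u02 <- mean((pts[, 2] - mc)^2)
  u11 <- mean((pts[, 1] - mr) * (pts[, 2] - mc))
  common <- sqrt((u20 - u02)^2 + 4 * u11^2)
  l1 <- (u20 + u02 + common) / 2
  l2 <- (u20 + u02 - common) / 2
  c(a = 4 * sqrt(l1), b = 4 * sqrt(max(l2, 0)))
}

# exhaustive O(n^2) nearest-neighbour oracle
oracle_knn <- function(query, reference, k) {
  idx <- matrix(0L, nrow(query), k)
  dst <- matrix(0, nrow(query), k)
  for (i in seq_len(nrow(query))) {
    d <- numeric(nrow(reference))
    for (j in seq_len(nrow(reference))) {
      d[j] <- sqrt(sum((query[i, ] - reference[j, ])^2))
    }
    o <- order(d)[seq_len(k)]
    idx[i, ] <- o
    dst[i, ] <- d[o]
  }
  list(index = idx, distance = dst)
}

cli_script <- function() {
  system.file("cli", "gastroquant.R", package = "gastroquant")
}

run_cli <- function(...) {
  out <- system2("Rscript", c(cli_script(), ...), stdout = TRUE, stderr = TRUE)
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("CLI failed: ", paste(out, collapse = "\n"))
  }
  invisible(out)
}
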