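# Internal helpers shared across modules.

# Run code with a local RNG state seeded from `seed`; restores the caller's
# RNG so generators never perturb user-level randomness.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed deterministically (kept below 2^31; double arithmetic
# avoids 32-bit overflow for large parent seeds).
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 69069 + as.numeric(offset)) %% 2147483647)
}

assert_matrix <- function(x, arg = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix.", arg))
  }
  if (!all(is.finite(x))) abort(sprintf("`%s` contains non-finite values.", arg))
  invisible(x)
}

# Bilinear interpolation of matrix `img` at (row, col) positions (1-based,
# fractional). Out-of-frame positions return `fill`.
bilinear <- function(img, r, c, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  ok <- r0 >= 1 & c0 >= 1 & r0 <= nr - 1 & c0 <= nc - 1
  # clamp exact-boundary hits
  edge <- r >= 1 & c >= 1 & r <= nr & c <= nc & !ok
  out <- rep(fill, length(r))
  if (any(ok)) {
    i00 <- cbind(r0[ok], c0[ok]); i10 <- cbind(r0[ok] + 1, c0[ok])
    i01 <- cbind(r0[ok], c0[ok] + 1); i11 <- cbind(r0[ok] + 1, c0[ok] + 1)
    out[ok] <- img[i00] * (1 - fr[ok]) * (1 - fc[ok]) +
      img[i10] * fr[ok] * (1 - fc[ok]) +
      img[i01] * (1 - fr[ok]) * fc[ok] +
      img[i11] * fr[ok] * fc[ok]
  }
  if (any(edge)) {
    out[edge] <- img[cbind(pmin(pmax(round(r[edge]), 1), nr),
                           pmin(pmax(round(c[edge]), 1), nc))]
  }
  out
}

# Largest connected component of a binary matrix (8-connectivity).
largest_component <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  if (max(lab) <= 1) return(mask)
  sizes <- tabulate(lab[lab > 0])
  (lab == which.max(sizes)) * 1
}

n_components <- function(mask) {
  max(EBImage::bwlabel(mask))
}

# Polyline length of an n x 2 matrix of vertices.
polyline_length <- function(v) {
  if (nrow(v) < 2) return(0)
  sum(sqrt(rowSums(diff(v)^2)))
}

# Directed + symmetric Hausdorff distance between two polylines (vertex sets).
hausdorff <- function(a, b) {
  d2 <- function(p, q) {
    dr <- outer(p[, 1], q[, 1], "-"); dc <- outer(p[, 2], q[, 2], "-")
    sqrt(dr^2 + dc^2)
  }
  d <- d2(a, b)
  max(max(apply(d, 1, min)), max(apply(d, 2, min)))
}
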