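# Nearest-neighbour label transfer in PC space, transfer-quality statistics,
# cluster correlation and cluster-average differential expression.

embedding_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  x <- as.data.frame(x)
  dims <- grep("^dim_", names(x), value = TRUE)
  if (!length(dims)) abort("Embedding must have dim_* columns or be a matrix.")
  as.matrix(x[, dims[order(as.integer(sub("dim_", "", dims)))]])
}

# k nearest reference rows per query row (Euclidean), deterministic ties by
# lowest reference index. Returns indices (n_query x k) and distances.
knn_index <- function(query, reference, k, chunk = 256L) {
  nq <- nrow(query); nr <- nrow(reference)
  if (k > nr) abort(sprintf("k = %d exceeds the reference size (%d).", k, nr))
  ref2 <- rowSums(reference^2)
  idx <- matrix(0L, nq, k); dst <- matrix(0, nq, k)
  for (s in seq(1L, nq, by = chunk)) {
    e <- min(nq, s + chunk - 1L)
    q <- query[s:e, , drop = FALSE]
    d2 <- outer(rowSums(q^2), ref2, "+") - 2 * tcrossprod(q, reference)
    d2[d2 < 0] <- 0
    for (i in seq_len(nrow(d2))) {
      o <- order(d2[i, ])[seq_len(k)]       # order() breaks ties by index
      idx[s + i - 1L, ] <- o
      dst[s + i - 1L, ] <- sqrt(d2[i, o])
    }
  }
  list(index = idx, distance = dst)
}

#' Transfer reference labels to query cells by nearest neighbour
#'
#' Assigns every query cell the label of its closest reference cell by
#' Euclidean distance in the shared embedding (e.g. 50-dimensional PC space).
#' Exact distance ties resolve to the lowest reference index.
#'
#' @param query tibble with `dim_*` columns (or a matrix).
#' @param reference tibble with `dim_*` columns and a `label` column (or a
#'   matrix plus `labels`).
#' @param labels reference labels when `reference` is a matrix.
#' @return Tibble with `cell_id`, `assigned_label`, `assigned_index`,
#'   `assigned_distance`.
#' @export
transfer_labels <- function(query, reference, labels = NULL) {
  qm <- embedding_matrix(query)
  rm_ <- embedding_matrix(reference)
  if (nrow(rm_) == 0) abort("Reference is empty.")
  if (ncol(qm) != ncol(rm_)) abort("Query and reference dimensionality differ.")
  if (is.null(labels)) {
    if (is.data.frame(reference) && "label" %in% names(reference)) {
      labels <- reference$label
    } else {
      abort("Reference labels required.")
    }
  }
  nn <- knn_index(qm, rm_, k = 1L)
  ids <- if (is.data.frame(query) && "cell_id" %in% names(query)) {
    query$cell_id
  } else {
    as.character(seq_len(nrow(qm)))
  }
  tibble(cell_id = ids,
         assigned_label = labels[nn$index[, 1]],
         assigned_index = nn$index[, 1],
         assigned_distance = nn$distance[, 1])
}

#' Transfer-quality statistics per query cluster
#'
#' The three label-transfer QC parameters: (1) `mean_knn_distance` — the mean
#' over member cells of each cell's mean Euclidean distance to its `k` nearest
#' reference cells; (2) `agreement_score` — the mean over member cells of the
#' fraction of those `k` neighbours whose label equals the cell's assigned
#' label; (3) `unique_fraction` — the number of distinct reference cells the
#' cluster's cells map to, divided by the cluster size (close to 1 for
#' well-mixed integrations).
#'
#' @param query tibble with `dim_*` and `cluster` columns.
#' @param reference tibble with `dim_*` and `label` columns.
#' @param assignments result of [transfer_labels()]; recomputed when omitted.
#' @param k neighbour count (default 30).
#' @return A `transfer_qc` tibble: `cluster`, `n_cells`, `mean_knn_distance`,
#'   `agreement_score`, `unique_fraction`; per-cell values are kept in
#'   attribute `per_cell`.
#' @export
transfer_qc <- function(query, reference, assignments = NULL, k = 30) {
  qm <- embedding_matrix(query)
  rm_ <- embedding_matrix(reference)
  if (k > nrow(rm_)) abort(sprintf("k = %d exceeds the reference size (%d).", k, nrow(rm_)))
  if (!is.data.frame(query) || !"cluster" %in% names(query)) {
    abort("`query` needs a `cluster` column.")
  }
  if (is.null(assignments)) assignments <- transfer_labels(query, reference)
  nn <- knn_index(qm, rm_, k = k)
  labs <- matrix(reference$label[nn$index], nrow(qm), k)
  per_cell <- tibble(
    cell_id = assignments$cell_id,
    cluster = query$cluster,
    assigned_label = assignments$assigned_label,
    assigned_index = assignments$assigned_index,
    mean_knn_distance = rowMeans(nn$distance),
    agreement = rowMeans(labs == assignments$assigned_label)
  )
  out <- per_cell %>%
    group_by(.data$cluster) %>%
    summarise(n_cells = dplyr::n(),
              mean_knn_distance = mean(.data$mean_knn_distance),
              agreement_score = mean(.data$agreement),
              unique_fraction = dplyr::n_distinct(.data$assigned_index) / dplyr::n(),
              .groups = "drop")
  attr(out, "per_cell") <- per_cell
  attr(out, "k") <- k
  class(out) <- c("transfer_qc", class(out))
  out
}

#' Tidiers for transfer-QC results
#'
#' @param x a `transfer_qc` tibble.
#' @param ... unused.
#' @name transfer_qc_tidiers
NULL

#' @rdname transfer_qc_tidiers
#' @exportS3Method generics::tidy
tidy.transfer_qc <- function(x, ...) {
  as_tibble(x) %>%
    tidyr::pivot_longer(c("mean_knn_distance", "agreement_score", "unique_fraction"),
                        names_to = "metric", values_to = "value")
}

#' @rdname transfer_qc_tidiers
#' @exportS3Method generics::glance
glance.transfer_qc <- function(x, ...) {
  tibble(n_clusters = nrow(x),
         n_cells = sum(x$n_cells),
         k = attr(x, "k"),
         min_agreement = min(x$agreement_score),
         min_unique_fraction = min(x$unique_fraction))
}

#' Pearson correlation between cluster-averaged embedding components
#'
#' Averages the embedding components over the member cells of every cluster in
#' each embedding, then computes the Pearson correlation between the two
#' average vectors for every cluster pair. A cluster whose average vector has
#' zero variance across components gets `NA` with a flag rather than silent
#' NaN propagation.
#'
#' @param emb_a,emb_b tibbles with `dim_*` columns and a cluster column
#'   (`cluster` or `label`).
#' @return A `cluster_cor` matrix (clusters of `emb_a` x clusters of `emb_b`)
#'   with attribute `flagged` listing degenerate clusters.
#' @export
cluster_correlation <- function(emb_a, emb_b) {
  get_cl <- function(x) {
    if ("cluster" %in% names(x)) x$cluster
    else if ("label" %in% names(x)) x$label
    else abort("Embeddings need a `cluster` or `label` column.")
  }
  ma <- embedding_matrix(emb_a); mb <- embedding_matrix(emb_b)
  if (ncol(ma) != ncol(mb)) abort("Embeddings must share dimensionality.")
  ca <- get_cl(emb_a); cb <- get_cl(emb_b)
  avg <- function(m, cl) {
    t(vapply(sort(unique(cl)), function(g) colMeans(m[cl == g, , drop = FALSE]),
             numeric(ncol(m))))
  }
  aa <- avg(ma, ca); bb <- avg(mb, cb)
  flagged <- c(rownames(aa)[apply(aa, 1, sd) == 0],
               rownames(bb)[apply(bb, 1, sd) == 0])
  r <- suppressWarnings(stats::cor(t(aa), t(bb)))
  if (length(flagged)) {
    warn(sprintf("Cluster(s) with zero component variance: %s; correlations set NA.",
                 paste(flagged, collapse = ", ")))
  }
  structure(r, flagged = flagged, class = c("cluster_cor", class(r)))
}

#' Cluster-average differential expression
#'
#' For a pair of clusters, the per-gene difference of cluster-averaged
#' normalized expression. Genes whose absolute difference reaches `cutoff`
#' (inclusive) are reported, ranked by absolute difference and truncated to
#' `top_n` per direction.
#'
#' @param expr cells x genes matrix of normalized expression.
#' @param clusters cluster label per cell (length `nrow(expr)`).
#' @param pair length-2 character vector of cluster ids to contrast.
#' @param cutoff minimum absolute difference (default 1).
#' @param top_n genes kept per direction (default 10).
#' @return Tibble with `gene`, `mean_a`, `mean_b`, `difference`, `direction`
#'   (`"up_in_a"` / `"up_in_b"`), ranked by `abs(difference)`.
#' @export
cluster_de <- function(expr, clusters, pair, cutoff = 1, top_n = 10) {
  assert_matrix(expr, "expr")
  if (length(clusters) != nrow(expr)) abort("`clusters` must match rows of `expr`.")
  if (length(pair) != 2) abort("`pair` must name two clusters.")
  for (p in pair) {
    if (!p %in% clusters) abort(sprintf("Unknown cluster id '%s'.", p))
  }
  ma <- colMeans(expr[clusters == pair[1], , drop = FALSE])
  mb <- colMeans(expr[clusters == pair[2], , drop = FALSE])
  res <- tibble(gene = colnames(expr) %||% as.character(seq_along(ma)),
                mean_a = unname(ma), mean_b = unname(mb),
                difference = unname(ma - mb)) %>%
    filter(abs(.data$difference) >= cutoff) %>%
    mutate(direction = ifelse(.data$difference > 0, "up_in_a", "up_in_b")) %>%
    arrange(desc(abs(.data$difference)))
  res %>%
    group_by(.data$direction) %>%
    slice(seq_len(min(dplyr::n(), top_n))) %>%
    ungroup() %>%
    arrange(desc(abs(.data$difference)))
}
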