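#' Simulate a per-cell QC table with expression and known cluster labels
#'
#' Draws per-cell QC covariates (unique feature count, mitochondrial
#' percentage, total RNA count) from truncated-normal distributions and, when a
#' `gene_spec` is given, a matrix of normalized expression values per gene and
#' cluster. Because every drawn value is returned, the exact set of cells
#' passing any QC threshold combination and the gating label of every cell are
#' known by construction.
#'
#' @param n_cells number of cells (>= 1).
#' @param qc_spec list with elements `ufc`, `mc`, `trc`, each `c(mean, sd)`.
#'   Defaults emulate a typical droplet scRNA-seq run of an early aggregate
#'   time course.
#' @param gene_spec optional data frame with columns `gene`, `cluster`, `mean`,
#'   `sd`: normalized expression distribution of each gene within each cluster.
#' @param seed integer seed.
#' @param dataset_id dataset label stored on every row.
#' @return A `cell_table_sim`: list with `cells` (tibble: cell_id,
#'   unique_feature_count, mito_percent, total_rna_count, dataset_id, cluster)
#'   and `expr` (cells x genes matrix of normalized values, or `NULL`).
#' @export
make_cell_table <- function(n_cells,
                            qc_spec = list(ufc = c(4000, 1200),
                                           mc = c(8, 5),
                                           trc = c(80000, 40000)),
                            gene_spec = NULL, seed = 1, dataset_id = "sim") {
  if (!is.numeric(n_cells) || n_cells < 1) abort("`n_cells` must be >= 1.")
  n_cells <- as.integer(n_cells)
  for (nm in c("ufc", "mc", "trc")) {
    p <- qc_spec[[nm]]
    if (is.null(p) || length(p) != 2 || !all(is.finite(p)) || p[2] < 0) {
      abort(sprintf("`qc_spec$%s` must be c(mean, sd) with sd >= 0.", nm))
    }
  }
  with_seed(seed, {
    draw <- function(p, lo = 0, hi = Inf) {
      pmin(pmax(rnorm(n_cells, p[1], p[2]), lo), hi)
    }
    cells <- tibble(
      cell_id = sprintf("cell_%05d", seq_len(n_cells)),
      unique_feature_count = round(draw(qc_spec$ufc)),
      mito_percent = draw(qc_spec$mc, 0, 100),
      total_rna_count = round(draw(qc_spec$trc)),
      dataset_id = dataset_id
    )
    expr <- NULL
    if (!is.null(gene_spec)) {
      gene_spec <- as_tibble(gene_spec)
      clusters <- sort(unique(gene_spec$cluster))
      cells$cluster <- rep_len(clusters, n_cells)
      genes <- unique(gene_spec$gene)
      expr <- matrix(0, n_cells, length(genes),
                     dimnames = list(cells$cell_id, genes))
      for (i in seq_len(nrow(gene_spec))) {
        rows <- which(cells$cluster == gene_spec$cluster[i])
        expr[rows, gene_spec$gene[i]] <-
          pmax(rnorm(length(rows), gene_spec$mean[i], gene_spec$sd[i]), 0)
      }
    } else {
      cells$cluster <- NA_character_
    }
    structure(list(cells = cells, expr = expr, seed = seed),
              class = "cell_table_sim")
  })
}

#' Simulate paired query/reference embeddings with controllable mixing
#'
#' Builds a reference embedding of Gaussian clusters in `d` dimensions and a
#' query embedding drawn around the same centroids. The per-cluster `mixing`
#' parameter in \[0, 1\] controls integration quality: at `mixing = 1` query
#' and reference share centroids ("well-mixed"); as `mixing` decreases, each
#' query centroid moves along a fixed path into sparse space — half-way toward
#' the nearest other reference centroid plus an equal off-manifold orthogonal
#' lift — degrading both the label agreement of nearby reference neighbours
#' and the fraction of unique reference cells hit, monotonically.
#'
#' @param n_clusters number of clusters.
#' @param n_query,n_reference cells per cluster in the query and the reference.
#' @param d embedding dimensionality (default 50, matching a 50-component PC
#'   space).
#' @param spread within-cluster s.d. per dimension.
#' @param centroid_scale s.d. of cluster centroid coordinates.
#' @param mixing scalar or per-cluster vector in \[0, 1\].
#' @param seed integer seed.
#' @param k_check neighbour count the downstream QC uses; clusters with fewer
#'   reference cells are flagged (not truncated).
#' @return An `embedding_pair`: list with `query` (tibble: cell_id, cluster,
#'   dim_1..dim_d), `reference` (tibble: cell_id, label, dim_1..dim_d) and
#'   `truth` (centroids, per-cluster mixing, expected nearest reference
#'   cluster, flags).
#' @export
make_embedding_pair <- function(n_clusters = 4, n_query = 60, n_reference = 200,
                                d = 50, spread = 1.5, centroid_scale = 2.5,
                                mixing = 1, seed = 1, k_check = 30) {
  if (d < 2) abort("`d` must be >= 2.")
  if (n_clusters < 2) abort("Need at least 2 clusters.")
  mixing <- rep_len(mixing, n_clusters)
  if (any(mixing < 0 | mixing > 1)) abort("`mixing` must lie in [0, 1].")
  cl_names <- paste0("C", seq_len(n_clusters))

  with_seed(seed, {
    cent_ref <- matrix(rnorm(n_clusters * d, sd = centroid_scale), n_clusters, d)
    # nearest other reference centroid per cluster
    dc <- as.matrix(stats::dist(cent_ref)); diag(dc) <- Inf
    nearest <- apply(dc, 1, which.min)
    # Poor mixing displaces the query centroid along a path that leaves the
    # reference manifold: half-way toward the nearest other cluster plus an
    # equal off-manifold (orthogonal) lift. The displaced cluster then sits in
    # sparse space between clusters, degrading both neighbour-label agreement
    # and the number of distinct reference cells hit, monotonically in mixing.
    cent_query <- cent_ref
    for (j in seq_len(n_clusters)) {
      gap <- cent_ref[nearest[j], ] - cent_ref[j, ]
      u <- rnorm(d)
      u <- u - sum(u * gap) / sum(gap^2) * gap
      u <- u / sqrt(sum(u^2)) * 0.5 * sqrt(sum(gap^2))
      cent_query[j, ] <- cent_ref[j, ] + (1 - mixing[j]) * (0.5 * gap + u)
    }

    draw_cells <- function(cent, n_per, prefix) {
      purrr::map_dfr(seq_len(n_clusters), function(j) {
        pts <- matrix(rnorm(n_per * d, sd = spread), n_per, d) +
          matrix(cent[j, ], n_per, d, byrow = TRUE)
        colnames(pts) <- paste0("dim_", seq_len(d))
        bind_cols(tibble(cell_id = sprintf("%s_%s_%03d", prefix, cl_names[j],
                                           seq_len(n_per)),
                         group = cl_names[j]),
                  as_tibble(pts))
      })
    }
    query <- draw_cells(cent_query, n_query, "q") %>% rename(cluster = "group")
    reference <- draw_cells(cent_ref, n_reference, "r") %>% rename(label = "group")

    flags <- character(0)
    if (n_reference < k_check) {
      flags <- sprintf("reference clusters have %d cells, fewer than k = %d",
                       n_reference, k_check)
      warn(flags)
    }
    structure(list(
      query = query, reference = reference,
      truth = list(centroids_reference = cent_ref,
                   centroids_query = cent_query,
                   mixing = setNames(mixing, cl_names),
                   nearest_reference_cluster = setNames(cl_names[nearest], cl_names),
                   flags = flags),
      d = d, seed = seed
    ), class = "embedding_pair")
  })
}

#' @export
print.embedding_pair <- function(x, ...) {
  cat(sprintf("<embedding_pair> %d query + %d reference cells in %d dims, %d clusters\n",
              nrow(x$query), nrow(x$reference), x$d,
              length(x$truth$mixing)))
  invisible(x)
}
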