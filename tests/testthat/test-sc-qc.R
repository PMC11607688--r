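# QC filtering, normalization, gating, label transfer, transfer QC,
# cluster correlation and differential expression.

test_that("QC filtering applies the printed strict inequalities per preset", {
  cells <- tibble::tibble(
    cell_id = c("boundary", "pass", "high_mito", "high_trc"),
    unique_feature_count = c(2500, 3000, 3000, 3000),
    mito_percent = c(5, 5, 12, 5),
    total_rna_count = c(100000, 100000, 100000, 150000))
  kept <- filter_cells(cells, "0h")
  expect_equal(kept$cell_id, "pass")   # UFC = 2500 fails the strict >
  rep <- attr(kept, "report")
  expect_equal(rep$kept[rep$condition == "all"], 1)
  expect_equal(rep$removed[rep$condition == "all"], 3)

  # lower mitochondrial bound where printed
  cells24 <- tibble::tibble(unique_feature_count = 3000,
                            mito_percent = c(0.5, 5),
                            total_rna_count = 50000)
  kept24 <- filter_cells(cells24, "24h_r1")
  expect_equal(nrow(kept24), 1)
  expect_equal(kept24$mito_percent, 5)

  # idempotence and conservation
  again <- filter_cells(kept, "0h")
  expect_equal(nrow(again), nrow(kept))
  expect_error(filter_cells(cells, "nonsense"), "preset")

  empty <- filter_cells(cells[0, ], "0h")
  expect_equal(nrow(empty), 0)

  presets <- qc_preset()
  expect_equal(nrow(presets), 6)
  expect_true(is.na(presets$mc_min[presets$preset == "0h"]))
})

test_that("log-normalization matches the closed form and is depth-invariant", {
  m <- matrix(c(5, 5), 1, 2, dimnames = list("c1", c("g1", "g2")))
  ln <- lognormalize(m, scale = 1e4)
  expect_equal(as.numeric(ln), rep(log(1 + 5000), 2), tolerance = 1e-12)

  expect_equal(unname(lognormalize(matrix(0:1, 1, 2,
                                          dimnames = list("c", c("a", "b"))))[1, 1]),
               0)

  m2 <- rbind(c1 = c(10, 30), c2 = c(20, 60))
  colnames(m2) <- c("a", "b")
  ln2 <- lognormalize(m2)
  expect_equal(ln2[1, ], ln2[2, ], tolerance = 1e-12)   # doubled depth, same values

  expect_warning(lognormalize(matrix(0, 1, 2, dimnames = list("c", c("a", "b")))),
                 "zero total")
})

test_that("marker gating partitions cells with inclusive negative boundary", {
  expr <- matrix(c(2.0, 0.05, 1.0, 1.5, 0.051), ncol = 1,
                 dimnames = list(paste0("c", 1:5), "T"))
  g <- gate_by_expression(expr, "T", 1.5, 0.05)
  expect_equal(as.character(g$gate),
               c("positive", "negative", "excluded", "excluded", "excluded"))
  expect_equal(sum(table(g$gate)), 5)   # partition into three disjoint sets

  gs <- gate_by_expression(expr, "T", pos_cutoff = 1.0, neg_cutoff = 0.05)
  expect_equal(as.character(gs$gate)[3], "excluded")   # 1.0 not > 1.0
  expect_equal(as.character(gs$gate)[4], "positive")

  expect_error(gate_by_expression(expr, "Sox2"), "absent")
  expect_error(gate_by_expression(expr, "T", 0.05, 1.5), "exceed")
})

test_that("label transfer matches the exhaustive nearest-neighbour oracle", {
  set.seed(99)
  qm <- matrix(rnorm(200 * 8), 200, 8)
  rm_ <- matrix(rnorm(150 * 8), 150, 8)
  labs <- sample(letters[1:4], 150, replace = TRUE)
  asn <- transfer_labels(qm, rm_, labels = labs)
  ora <- oracle_knn(qm, rm_, 1)
  expect_equal(asn$assigned_index, ora$index[, 1])
  expect_equal(asn$assigned_distance, ora$distance[, 1], tolerance = 1e-9)
  expect_equal(asn$assigned_label, labs[ora$index[, 1]])

  # coincident query takes that reference cell's label; ties take lowest index
  rm2 <- rbind(c(0, 0), c(1, 0), c(-1, 0))
  expect_equal(transfer_labels(rbind(c(1, 0)), rm2,
                               labels = c("x", "y", "z"))$assigned_label, "y")
  tie <- transfer_labels(rbind(c(0, 0)), rbind(c(1, 0), c(-1, 0), c(0, 1)),
                         labels = c("p", "q", "r"))
  expect_equal(tie$assigned_index, 1L)
  expect_error(transfer_labels(matrix(0, 1, 3), matrix(0, 2, 2),
                               labels = c("a", "b")), "dimensionality")
})

test_that("transfer QC reproduces brute-force statistics and hand cases", {
  ep <- make_embedding_pair(n_clusters = 3, n_query = 40, n_reference = 60,
                            d = 10, seed = 5)
  qc <- transfer_qc(ep$query, ep$reference, k = 30)
  qm <- as.matrix(ep$query[, paste0("dim_", 1:10)])
  rm_ <- as.matrix(ep$reference[, paste0("dim_", 1:10)])
  ora <- oracle_knn(qm, rm_, 30)
  labs <- matrix(ep$reference$label[ora$index], nrow(qm), 30)
  assigned <- ep$reference$label[ora$index[, 1]]
  for (cl in unique(ep$query$cluster)) {
    mem <- ep$query$cluster == cl
    expect_equal(qc$mean_knn_distance[qc$cluster == cl],
                 mean(rowMeans(ora$distance[mem, ])), tolerance = 1e-9)
    expect_equal(qc$agreement_score[qc$cluster == cl],
                 mean(rowMeans(labs[mem, , drop = FALSE] == assigned[mem])),
                 tolerance = 1e-12)
    expect_equal(qc$unique_fraction[qc$cluster == cl],
                 length(unique(ora$index[mem, 1])) / sum(mem))
  }

  # hand-checkable unique fractions
  q4 <- tibble::tibble(cell_id = paste0("q", 1:4), cluster = "A",
                       dim_1 = c(0, 0.1, 5, 9), dim_2 = 0)
  r4 <- tibble::tibble(cell_id = paste0("r", 1:3), label = "A",
                       dim_1 = c(0, 5, 9), dim_2 = 0)
  qc4 <- transfer_qc(q4, r4, k = 1)
  expect_equal(qc4$unique_fraction, 0.75)   # {r1, r1, r2, r3} / 4
  expect_equal(qc4$agreement_score, 1)
  expect_error(transfer_qc(q4, r4, k = 10), "exceeds")

  # collapse onto a single reference cell
  q1 <- tibble::tibble(cell_id = paste0("q", 1:4), cluster = "A",
                       dim_1 = 0, dim_2 = 0)
  r1 <- tibble::tibble(cell_id = c("r1", "r2"), label = "A",
                       dim_1 = c(0, 50), dim_2 = 0)
  qc1 <- transfer_qc(q1, r1, k = 1)
  expect_equal(qc1$unique_fraction, 1 / 4)
  expect_equal(qc1$mean_knn_distance, 0)
})

test_that("cluster correlation equals the direct formula and ignores cell order", {
  ep <- make_embedding_pair(n_clusters = 5, n_query = 30, n_reference = 40,
                            d = 50, seed = 8)
  cc <- cluster_correlation(ep$query, ep$reference)
  qm <- as.matrix(ep$query[, paste0("dim_", 1:50)])
  rm_ <- as.matrix(ep$reference[, paste0("dim_", 1:50)])
  for (a in rownames(cc)) for (b in colnames(cc)) {
    va <- colMeans(qm[ep$query$cluster == a, ])
    vb <- colMeans(rm_[ep$reference$label == b, ])
    r_direct <- sum((va - mean(va)) * (vb - mean(vb))) /
      sqrt(sum((va - mean(va))^2) * sum((vb - mean(vb))^2))
    expect_equal(cc[a, b], r_direct, tolerance = 1e-12)
  }
  # permutation invariance within clusters
  perm <- ep$query[sample(nrow(ep$query)), ]
  cc2 <- cluster_correlation(perm, ep$reference)
  expect_equal(cc, cc2, tolerance = 1e-12)

  # identical/negated average vectors
  e1 <- tibble::tibble(cell_id = "a", cluster = "X", dim_1 = 1, dim_2 = 2, dim_3 = 4)
  e2 <- tibble::tibble(cell_id = c("b", "c"), label = c("Y", "Z"),
                       dim_1 = c(1, -1), dim_2 = c(2, -2), dim_3 = c(4, -4))
  cc3 <- cluster_correlation(e1, e2)
  expect_equal(as.numeric(cc3["X", c("Y", "Z")]), c(1, -1))

  # zero-variance cluster is flagged, not propagated silently
  ez <- tibble::tibble(cell_id = "d", cluster = "W", dim_1 = 3, dim_2 = 3, dim_3 = 3)
  expect_warning(ccz <- cluster_correlation(ez, e2), "zero component variance")
  expect_true(all(is.na(ccz)))
})

test_that("cluster DE applies the inclusive +-1 cutoff and top-n truncation", {
  set.seed(42)
  n_genes <- 40
  base <- runif(n_genes, 0, 0.5)
  shift <- c(1.2, -1.5, 0.9, rep(0, n_genes - 3))   # 2 passing, 1 just below
  expr <- rbind(matrix(rep(base, 10), 10, byrow = TRUE),
                matrix(rep(base + shift, 10), 10, byrow = TRUE))
  colnames(expr) <- paste0("g", seq_len(n_genes))
  cl <- rep(c("A", "B"), each = 10)
  de <- cluster_de(expr, cl, c("B", "A"), cutoff = 1, top_n = 10)
  expect_setequal(de$gene, c("g1", "g2"))
  expect_equal(de$difference[de$gene == "g1"], 1.2, tolerance = 1e-12)
  expect_false("g3" %in% de$gene)   # 0.9 < 1

  # exact boundary difference of 1 is included
  expr2 <- rbind(A = c(g1 = 2.2, g2 = 1), B = c(g1 = 1.2, g2 = 0))
  de2 <- cluster_de(expr2, c("A", "B"), c("A", "B"))
  expect_setequal(de2$gene, c("g1", "g2"))

  # 25 genes passing in one direction truncate to the 10 largest
  big <- rbind(matrix(0, 5, 25), matrix(rep(seq(1, 3, length.out = 25), 5),
                                        5, byrow = TRUE))
  colnames(big) <- paste0("u", 1:25)
  de3 <- cluster_de(big, rep(c("lo", "hi"), each = 5), c("hi", "lo"), top_n = 10)
  expect_equal(nrow(de3), 10)
  expect_setequal(de3$gene, paste0("u", 16:25))

  expect_error(cluster_de(expr, cl, c("A", "C")), "Unknown cluster")
})
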