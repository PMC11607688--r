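# Single-cell QC filtering, normalization and marker-gene gating.

#' Per-dataset QC threshold presets
#'
#' The exact per-dataset thresholds used for the gastruloid time course:
#' cells are kept when unique feature count (UFC), mitochondrial percentage
#' (MC) and total RNA count (TRC) satisfy all of the strict inequalities.
#'
#' @param name preset name; one of `"0h"`, `"24h_r1"`, `"24h_r2"`, `"48h_r1"`,
#'   `"48h_r2"`, `"72h"`. Omit to list all presets.
#' @return A named list with `ufc_min`, `mc_max`, `mc_min` (or `NA`),
#'   `trc_max`; or a tibble of all presets when `name` is missing.
#' @export
qc_preset <- function(name) {
  presets <- list(
    "0h"     = list(ufc_min = 2500, mc_max = 10, mc_min = NA,  trc_max = 150000),
    "24h_r1" = list(ufc_min = 2750, mc_max = 15, mc_min = 1,   trc_max = 100000),
    "24h_r2" = list(ufc_min = 3750, mc_max = 15, mc_min = 1,   trc_max = 150000),
    "48h_r1" = list(ufc_min = 2750, mc_max = 15, mc_min = 1,   trc_max = 100000),
    "48h_r2" = list(ufc_min = 3500, mc_max = 15, mc_min = 1,   trc_max = 120000),
    "72h"    = list(ufc_min = 2500, mc_max = 20, mc_min = 1,   trc_max = 135000)
  )
  if (missing(name)) {
    return(purrr::imap_dfr(presets, function(p, nm)
      tibble(preset = nm, ufc_min = p$ufc_min, mc_max = p$mc_max,
             mc_min = p$mc_min, trc_max = p$trc_max)))
  }
  if (!name %in% names(presets)) {
    abort(sprintf("Unknown preset '%s'. Available: %s.", name,
                  paste(names(presets), collapse = ", ")))
  }
  presets[[name]]
}

#' Filter low-quality cells by QC thresholds
#'
#' Keeps rows satisfying all conditions, with the strict inequalities as
#' printed: `unique_feature_count > ufc_min`, `mito_percent < mc_max`,
#' `mito_percent > mc_min` (when given) and `total_rna_count < trc_max`.
#'
#' @param cells data frame with columns `unique_feature_count`,
#'   `mito_percent`, `total_rna_count`.
#' @param thresholds a [qc_preset()] name or a list with `ufc_min`, `mc_max`,
#'   optional `mc_min`, `trc_max`.
#' @return The filtered tibble, with attribute `report`: a tibble giving, per
#'   condition and overall, the kept/removed counts.
#' @export
filter_cells <- function(cells, thresholds) {
  cells <- as_tibble(cells)
  if (is.character(thresholds)) thresholds <- qc_preset(thresholds)
  need <- c("unique_feature_count", "mito_percent", "total_rna_count")
  if (!all(need %in% names(cells))) {
    abort(sprintf("`cells` must have columns %s.", paste(need, collapse = ", ")))
  }
  conds <- list(
    ufc_min = cells$unique_feature_count > thresholds$ufc_min,
    mc_max = cells$mito_percent < thresholds$mc_max,
    trc_max = cells$total_rna_count < thresholds$trc_max
  )
  if (!is.null(thresholds$mc_min) && !is.na(thresholds$mc_min)) {
    conds$mc_min <- cells$mito_percent > thresholds$mc_min
  }
  keep <- Reduce(`&`, conds)
  if (length(keep) == 0) keep <- logical(0)
  report <- bind_rows(
    purrr::imap_dfr(conds, function(ok, nm)
      tibble(condition = nm, kept = sum(ok), removed = sum(!ok))),
    tibble(condition = "all", kept = sum(keep), removed = sum(!keep))
  )
  out <- cells[keep, , drop = FALSE]
  attr(out, "report") <- report
  out
}

#' Log-normalize a count matrix
#'
#' Per cell: `log(1 + scale * count / cell_total)`, the standard library-size
#' normalization behind normalized-expression gating cutoffs. Cells with zero
#' total counts become all-zero rows with a warning.
#'
#' @param counts cells x genes matrix of raw counts.
#' @param scale size factor (default 1e4).
#' @return Matrix of the same shape with attribute
#'   `normalization = "lognorm"`.
#' @export
lognormalize <- function(counts, scale = 1e4) {
  assert_matrix(counts, "counts")
  tot <- rowSums(counts)
  zero <- tot == 0
  if (any(zero)) {
    warn(sprintf("%d cell(s) with zero total counts; their rows are all zero.", sum(zero)))
    tot[zero] <- 1
  }
  out <- log1p(scale * counts / tot)
  attr(out, "normalization") <- "lognorm"
  attr(out, "scale") <- scale
  out
}

#' Gate cells by a marker gene's normalized expression
#'
#' Classifies every cell as `positive` (value strictly above `pos_cutoff`),
#' `negative` (value at or below `neg_cutoff`; the boundary is inclusive) or
#' `excluded` (in between). Defaults match the T gate (> 1.5 / <= 0.05); use
#' `pos_cutoff = 1.0` for the Sox2 gate.
#'
#' @param expr cells x genes matrix of normalized expression.
#' @param gene gene (column) name.
#' @param pos_cutoff,neg_cutoff gate boundaries, `pos_cutoff > neg_cutoff`.
#' @return Tibble with `cell_id` (rownames or index), `value`, `gate`
#'   (factor: positive/negative/excluded).
#' @export
gate_by_expression <- function(expr, gene, pos_cutoff = 1.5, neg_cutoff = 0.05) {
  assert_matrix(expr, "expr")
  if (pos_cutoff <= neg_cutoff) abort("`pos_cutoff` must exceed `neg_cutoff`.")
  if (!gene %in% colnames(expr)) abort(sprintf("Gene '%s' absent from the matrix.", gene))
  v <- expr[, gene]
  gate <- ifelse(v > pos_cutoff, "positive",
                 ifelse(v <= neg_cutoff, "negative", "excluded"))
  tibble(cell_id = rownames(expr) %||% as.character(seq_along(v)),
         value = unname(v),
         gate = factor(gate, levels = c("positive", "negative", "excluded")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
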