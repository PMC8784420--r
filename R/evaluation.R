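# Validation statistics: immune-infiltration correlation rates and
# immune vs non-immune cell expression comparison.

#' Infiltration-correlation rates for an irlncRNA call set
#'
#' A lncRNA is infiltration-related (infrlncRNA) when, for at least one
#' immune cell type, the absolute correlation between its expression and
#' the infiltration level exceeds `corr_threshold` with BH-adjusted p below
#' `p_threshold` (adjustment across all lncRNA x cell-type tests). Four
#' rates are reported:
#' * `ir`    — irlncRNAs among all lncRNAs,
#' * `irinf` — irlncRNAs among infrlncRNAs,
#' * `infr`  — infrlncRNAs among all lncRNAs,
#' * `infri` — infrlncRNAs among irlncRNAs.
#' Rates with a zero denominator are `NA` (undefined).
#'
#' @param lnc_expr lncRNA expression matrix (genes x samples).
#' @param infiltration Tibble with `sample_id` plus one numeric column per
#'   immune cell type (see [read_infiltration()]).
#' @param irlnc Character vector of irlncRNA ids.
#' @param corr_threshold Strict lower bound on |correlation| (default 0.2).
#' @param p_threshold Strict upper bound on adjusted p (default 0.05).
#' @param method Correlation type, `"spearman"` (default) or `"pearson"`.
#' @return A one-row tibble: `n_lnc`, `n_ir`, `n_infr`, `n_overlap`, `ir`,
#'   `irinf`, `infr`, `infri`.
#' @export
infiltration_rates <- function(lnc_expr, infiltration, irlnc,
                               corr_threshold = 0.2, p_threshold = 0.05,
                               method = c("spearman", "pearson")) {
  method <- match.arg(method)
  shared <- intersect(colnames(lnc_expr), infiltration$sample_id)
  if (length(shared) < 3L) {
    stop("insufficient samples: need >= 3 samples shared with the ",
         "infiltration table", call. = FALSE)
  }
  infil <- infiltration[match(shared, infiltration$sample_id), , drop = FALSE]
  cells <- setdiff(names(infil), "sample_id")
  m <- lnc_expr[, shared, drop = FALSE]

  tests <- purrr::map(rownames(m), function(g) {
    purrr::map(cells, function(cell) {
      x <- m[g, ]
      y <- infil[[cell]]
      if (var_zero(x) || var_zero(y)) {
        return(tibble::tibble(lncrna_id = g, cell = cell,
                              cor = NA_real_, p = NA_real_))
      }
      ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                             exact = FALSE))
      tibble::tibble(lncrna_id = g, cell = cell,
                     cor = unname(ct$estimate), p = ct$p.value)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  tests$adj_p <- stats::p.adjust(tests$p, method = "BH")

  infr <- tests |>
    dplyr::filter(!is.na(.data$cor),
                  abs(.data$cor) > corr_threshold,
                  .data$adj_p < p_threshold) |>
    dplyr::pull(.data$lncrna_id) |>
    unique()

  all_lnc <- rownames(m)
  ir <- intersect(irlnc, all_lnc)
  overlap <- intersect(ir, infr)
  n_lnc <- length(all_lnc)
  n_ir <- length(ir)
  n_infr <- length(infr)
  n_overlap <- length(overlap)
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  tibble::tibble(
    n_lnc = n_lnc, n_ir = n_ir, n_infr = n_infr, n_overlap = n_overlap,
    ir = rate(n_ir, n_lnc),
    irinf = rate(n_overlap, n_infr),
    infr = rate(n_infr, n_lnc),
    infri = rate(n_overlap, n_ir))
}

#' Compare irlncRNA vs non-irlncRNA expression across cell groups
#'
#' For a cell x gene expression matrix with immune/non-immune cell labels,
#' computes the per-cell mean expression of irlncRNAs and of the remaining
#' lncRNAs, summarises the four group means, and tests
#' irlncRNA vs non-irlncRNA per-cell means within each cell group with a
#' two-sided Wilcoxon rank-sum test. Groups with fewer than two cells get
#' `p = NA` (flagged undefined).
#'
#' @param cell_expr Expression matrix, genes (lncRNAs) x cells.
#' @param cell_labels Named character vector cell id -> `"immune"` /
#'   `"non-immune"`.
#' @param irlnc Character vector of irlncRNA ids.
#' @return A tibble with one row per cell group: `group`, `n_cells`,
#'   `mean_ir`, `mean_non_ir`, `p`.
#' @export
group_expression_compare <- function(cell_expr, cell_labels, irlnc) {
  cells <- intersect(colnames(cell_expr), names(cell_labels))
  if (length(cells) == 0L) stop("no labelled cells in the matrix",
                                call. = FALSE)
  ir_genes <- intersect(rownames(cell_expr), irlnc)
  non_genes <- setdiff(rownames(cell_expr), irlnc)
  if (length(ir_genes) == 0L || length(non_genes) == 0L) {
    stop("need at least one irlncRNA and one non-irlncRNA in the matrix",
         call. = FALSE)
  }
  per_cell <- tibble::tibble(
    cell = cells,
    group = unname(cell_labels[cells]),
    mean_ir = colMeans(cell_expr[ir_genes, cells, drop = FALSE]),
    mean_non_ir = colMeans(cell_expr[non_genes, cells, drop = FALSE]))

  per_cell |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      p = if (dplyr::n() < 2L) NA_real_ else suppressWarnings(
        stats::wilcox.test(.data$mean_ir, .data$mean_non_ir,
                           exact = FALSE)$p.value),
      mean_ir = mean(.data$mean_ir),
      mean_non_ir = mean(.data$mean_non_ir),
      .groups = "drop") |>
    dplyr::select("group", "n_cells", "mean_ir", "mean_non_ir", "p")
}
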