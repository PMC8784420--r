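# Differential-expression summarisation and the Pscore pathogenicity
# statistic, plus ranking/binning against disease-reference lists.
#
# Pscore(l) = (sum over the 17 immune pathways of the per-pathway
# max-normalised cancer count NC(l, w) + R_DE + R_FC) / 19, where R_DE is
# the max-normalised number of cancers in which lncRNA l is differentially
# expressed and R_FC the max-normalised mean |log2 FC| over those cancers.

#' Differential expression of lncRNAs between tumour and normal samples
#'
#' Library-size (counts-per-million) normalisation using the supplied
#' matrix's column sums, log2(CPM + 1), per-gene log fold change
#' mean(tumor) - mean(normal), Wilcoxon rank-sum p, and Benjamini-Hochberg
#' adjustment across the tested lncRNAs. A gene is differentially expressed
#' when adj_p < `adj_p_threshold` and |logFC| > `logfc_threshold`, both
#' strict.
#'
#' @param expr Expression matrix (genes x samples) containing the labelled
#'   samples.
#' @param labels Named character vector sample id -> `"tumor"`/`"normal"`.
#' @param lnc_ids Genes to test; defaults to all rows of `expr`.
#' @param adj_p_threshold Strict upper bound on BH-adjusted p (default
#'   0.01).
#' @param logfc_threshold Strict lower bound on |logFC| (default 1.5).
#' @param cancer Cancer label recorded on every row.
#' @return A tibble with columns `lncrna_id`, `cancer`, `logfc`, `p`,
#'   `adj_p`, `is_de`.
#' @export
differential_expression <- function(expr, labels,
                                    lnc_ids = rownames(expr),
                                    adj_p_threshold = 0.01,
                                    logfc_threshold = 1.5,
                                    cancer = cancer_label(expr)) {
  labels <- labels[names(labels) %in% colnames(expr)]
  tumor <- names(labels)[labels == "tumor"]
  normal <- names(labels)[labels == "normal"]
  if (length(tumor) < 3L || length(normal) < 3L) {
    stop("insufficient group: need >= 3 tumor and >= 3 normal samples, got ",
         length(tumor), "/", length(normal), call. = FALSE)
  }
  samples <- c(tumor, normal)
  m <- expr[, samples, drop = FALSE]
  lib <- colSums(m)
  if (any(lib == 0)) {
    stop("sample(s) with zero library size: ",
         paste(samples[lib == 0], collapse = ", "), call. = FALSE)
  }
  logcpm <- log2(sweep(m, 2L, lib / 1e6, "/") + 1)

  lnc_ids <- intersect(lnc_ids, rownames(expr))
  res <- purrr::map(lnc_ids, function(g) {
    xt <- logcpm[g, tumor]
    xn <- logcpm[g, normal]
    p <- if (var_zero(c(xt, xn))) 1 else {
      suppressWarnings(stats::wilcox.test(xt, xn, exact = FALSE)$p.value)
    }
    tibble::tibble(lncrna_id = g, logfc = mean(xt) - mean(xn), p = p)
  }) |> purrr::list_rbind()
  res$adj_p <- stats::p.adjust(res$p, method = "BH")
  res$is_de <- res$adj_p < adj_p_threshold &
    abs(res$logfc) > logfc_threshold
  res$cancer <- cancer
  res[, c("lncrna_id", "cancer", "logfc", "p", "adj_p", "is_de")]
}

#' Divide-by-maximum normalisation
#'
#' Maps non-negative values onto \[0, 1\] by dividing by the maximum;
#' preserves zeros (an all-zero input stays all zero), so a count of zero
#' keeps meaning "absent" rather than being rescaled.
#'
#' @param x Named (or unnamed) non-negative numeric vector.
#' @return Vector of the same shape in \[0, 1\].
#' @export
normalize_max <- function(x) {
  stopifnot(all(x >= 0))
  m <- max(x)
  if (m == 0) return(x * 0)
  x / m
}

#' Breadth of differential expression (R_DE)
#'
#' NC(l), the number of cancers in which each irlncRNA is differentially
#' expressed, max-normalised across lncRNAs.
#'
#' @param nc_total Named integer vector lncrna_id -> NC(l).
#' @return Named numeric vector in \[0, 1\].
#' @export
r_de <- function(nc_total) {
  normalize_max(nc_total)
}

#' Intensity of differential expression (R_FC)
#'
#' Per lncRNA, the mean |logFC| over the cancers where it is differentially
#' expressed (0 when it is DE nowhere), max-normalised across lncRNAs.
#'
#' @param de_results DE tibble from [differential_expression()] rows for
#'   all cancers (columns `lncrna_id`, `logfc`, `is_de`).
#' @param lnc_ids The lncRNAs to score (others' DE rows are ignored);
#'   defaults to those present in `de_results`.
#' @return Named numeric vector in \[0, 1\] over `lnc_ids`.
#' @export
r_fc <- function(de_results, lnc_ids = unique(de_results$lncrna_id)) {
  mean_fc <- de_results |>
    dplyr::filter(.data$is_de, .data$lncrna_id %in% lnc_ids) |>
    dplyr::group_by(.data$lncrna_id) |>
    dplyr::summarise(mfc = mean(abs(.data$logfc)), .groups = "drop")
  out <- stats::setNames(rep(0, length(lnc_ids)), lnc_ids)
  out[mean_fc$lncrna_id] <- mean_fc$mfc
  normalize_max(out)
}

#' Pathogenicity score (Pscore) of each irlncRNA
#'
#' Pscore(l) = (sum_w N(NC(l, w)) + R_DE(l) + R_FC(l)) / (n_pathways + 2),
#' where NC(l, w) counts the cancers in which lncRNA l was called on
#' pathway w, N is divide-by-maximum per pathway, and `n_pathways`
#' (default 17, the immune pathway count) fixes the denominator; pathways
#' with no calls contribute 0.
#'
#' @param union_tbl Pan-cancer irlncRNA triples from [union_irlncrnas()].
#' @param de_results Combined DE tibble over all cancers with paired
#'   normals (may be `NULL`, in which case R_DE = R_FC = 0).
#' @param n_pathways Number of pathway terms in the numerator (default 17).
#' @return A tibble with one row per irlncRNA: `lncrna_id`, `nc_total`,
#'   `r_de`, `r_fc`, `pscore`, plus one `nc_<pathway>` count column per
#'   observed pathway; classed `irlnc_pscore`, sorted by descending
#'   `pscore` (ties lexicographic).
#' @export
compute_pscores <- function(union_tbl, de_results = NULL, n_pathways = 17) {
  counts <- pathway_cancer_counts(union_tbl)
  n_obs <- length(unique(counts$pathway))
  if (n_obs > n_pathways) {
    stop("more observed pathways (", n_obs, ") than `n_pathways` (",
         n_pathways, ")", call. = FALSE)
  }
  lnc_ids <- sort(unique(union_tbl$lncrna_id))

  norm <- counts |>
    dplyr::group_by(.data$pathway) |>
    dplyr::mutate(nc_norm = normalize_max(.data$nc)) |>
    dplyr::ungroup()
  pathway_sum <- norm |>
    dplyr::group_by(.data$lncrna_id) |>
    dplyr::summarise(path_term = sum(.data$nc_norm), .groups = "drop")

  nc_total <- stats::setNames(rep(0L, length(lnc_ids)), lnc_ids)
  rde <- rfc <- stats::setNames(rep(0, length(lnc_ids)), lnc_ids)
  if (!is.null(de_results) && nrow(de_results) > 0L) {
    de_results <- dplyr::filter(de_results, .data$lncrna_id %in% lnc_ids)
    nc_de <- de_results |>
      dplyr::filter(.data$is_de) |>
      dplyr::count(.data$lncrna_id, name = "nc")
    nc_total[nc_de$lncrna_id] <- nc_de$nc
    rde <- r_de(nc_total)
    rfc <- r_fc(de_results, lnc_ids)
  }

  wide <- counts |>
    dplyr::mutate(pathway = paste0("nc_", .data$pathway)) |>
    tidyr::pivot_wider(names_from = "pathway", values_from = "nc",
                       values_fill = 0L)

  out <- tibble::tibble(lncrna_id = lnc_ids) |>
    dplyr::left_join(pathway_sum, by = "lncrna_id") |>
    dplyr::mutate(
      nc_total = as.integer(nc_total[.data$lncrna_id]),
      r_de = unname(rde[.data$lncrna_id]),
      r_fc = unname(rfc[.data$lncrna_id]),
      pscore = (.data$path_term + .data$r_de + .data$r_fc) /
        (n_pathways + 2)) |>
    dplyr::select(-"path_term") |>
    dplyr::left_join(wide, by = "lncrna_id") |>
    dplyr::arrange(dplyr::desc(.data$pscore), .data$lncrna_id)
  class(out) <- c("irlnc_pscore", class(out))
  out
}

#' Pscore from its normalised components
#'
#' The pure arithmetic of the pathogenicity score: the mean of the
#' `n_pathways` per-pathway normalised cancer counts plus the normalised DE
#' breadth and intensity, all in \[0, 1\], divided by `n_pathways + 2`.
#'
#' @param pathway_terms Numeric vector of length `n_pathways`, each in
#'   \[0, 1\].
#' @param r_de,r_fc Normalised DE breadth and intensity in \[0, 1\].
#' @param n_pathways Number of pathway terms (default 17).
#' @return A number in \[0, 1\].
#' @export
pscore_components <- function(pathway_terms, r_de, r_fc, n_pathways = 17) {
  stopifnot(length(pathway_terms) == n_pathways,
            all(pathway_terms >= 0 & pathway_terms <= 1),
            r_de >= 0, r_de <= 1, r_fc >= 0, r_fc <= 1)
  (sum(pathway_terms) + r_de + r_fc) / (n_pathways + 2)
}

#' Rank irlncRNAs by Pscore and split into bins
#'
#' Sorts descending by Pscore (ties lexicographic by id) and bins either by
#' count (`equal_count`: near-equal bin sizes, the first bins take the
#' remainder) or by score range (`equal_range`: k equal-width intervals of
#' the observed Pscore range, descending; bins may be empty, and identical
#' scores all land in bin 1).
#'
#' @param pscores Tibble with `lncrna_id` and `pscore` columns (e.g. from
#'   [compute_pscores()]).
#' @param mode `"equal_count"` or `"equal_range"`.
#' @param k Number of bins.
#' @return The input rows sorted, with an integer `bin` column (1 = highest
#'   Pscore bin).
#' @export
rank_and_bin <- function(pscores, mode = c("equal_count", "equal_range"),
                         k = 5) {
  mode <- match.arg(mode)
  stopifnot(k >= 1, nrow(pscores) >= 1)
  df <- dplyr::arrange(tibble::as_tibble(pscores),
                       dplyr::desc(.data$pscore), .data$lncrna_id)
  n <- nrow(df)
  if (mode == "equal_count") {
    base <- n %/% k
    extra <- n %% k
    sizes <- rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
    df$bin <- rep(seq_len(k), times = sizes)
  } else {
    rng <- range(df$pscore)
    if (rng[1] == rng[2]) {
      df$bin <- 1L
    } else {
      # interval 1 holds the top of the range; lower edges half-open
      width <- (rng[2] - rng[1]) / k
      idx <- floor((rng[2] - df$pscore) / width) + 1
      df$bin <- as.integer(pmin(idx, k))
    }
  }
  df
}

#' Per-bin overlap with a disease-reference lncRNA list
#'
#' @param bins Output of [rank_and_bin()].
#' @param reference Character vector of reference lncRNA ids (e.g. a
#'   curated disease-lncRNA database).
#' @return A tibble with one row per bin plus a `total` row: `bin`,
#'   `count`, `count_in_reference`, `ratio`, `pscore_min`, `pscore_max`,
#'   `pscore_mean`.
#' @export
overlap_with_reference <- function(bins, reference) {
  per_bin <- bins |>
    dplyr::group_by(bin = as.character(.data$bin)) |>
    dplyr::summarise(
      count = dplyr::n(),
      count_in_reference = sum(.data$lncrna_id %in% reference),
      pscore_min = min(.data$pscore),
      pscore_max = max(.data$pscore),
      pscore_mean = mean(.data$pscore),
      .groups = "drop")
  total <- tibble::tibble(
    bin = "total",
    count = nrow(bins),
    count_in_reference = sum(bins$lncrna_id %in% reference),
    pscore_min = min(bins$pscore),
    pscore_max = max(bins$pscore),
    pscore_mean = mean(bins$pscore))
  out <- dplyr::bind_rows(total, per_bin)
  out$ratio <- ifelse(out$count > 0, out$count_in_reference / out$count, 0)
  out[, c("bin", "count", "count_in_reference", "ratio",
          "pscore_min", "pscore_max", "pscore_mean")]
}
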