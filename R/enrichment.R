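# Per-lncRNA ranked mRNA lists, preranked permutation enrichment against
# immune pathways, the lncRES transform, and irlncRNA extraction.
#
# The enrichment statistic is the standard preranked weighted running sum:
# walking down the ranked list, gene-set hits step up by |score|^w / N_R
# (N_R = sum of hit weights), misses step down by 1/(N - k); ES is the
# running-sum value of maximum magnitude. The null permutes gene-set
# membership over list positions (scores fixed); p is one-sided on the side
# of the observed ES with an add-one correction, so p > 0 always.

#' Build per-lncRNA ranked mRNA lists
#'
#' Keeps, for each lncRNA, the mRNAs whose heuristic coefficient H strictly
#' exceeds `threshold`, sorted descending by H with ties broken
#' lexicographically by mRNA id. lncRNAs with no qualifying mRNA are
#' omitted.
#'
#' @param triples Correlation tibble from [heuristic_matrix()] (needs
#'   columns `lncrna_id`, `mrna_id`, `H`).
#' @param threshold Strict lower bound on H (default 0.5).
#' @return A tibble with columns `lncrna_id`, `mrna_id`, `H`, `rank`.
#' @export
build_ranked_lists <- function(triples, threshold = 0.5) {
  stopifnot(all(c("lncrna_id", "mrna_id", "H") %in% names(triples)))
  triples |>
    dplyr::filter(.data$H > threshold) |>
    dplyr::arrange(.data$lncrna_id, dplyr::desc(.data$H), .data$mrna_id) |>
    dplyr::group_by(.data$lncrna_id) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("lncrna_id", "mrna_id", "H", "rank")
}

#' Preranked enrichment score of a gene set in a ranked list
#'
#' @param scores Numeric scores in rank (descending) order.
#' @param hits Logical vector marking gene-set members, same length.
#' @param weight Weight exponent on |score| (0 or 1; default 1).
#' @return The enrichment score in \[-1, 1\]; 1 when every list gene is a
#'   hit.
#' @export
enrichment_score <- function(scores, hits, weight = 1) {
  stopifnot(length(scores) == length(hits), weight %in% c(0, 1))
  if (!any(hits)) stop("no overlap between gene set and ranked list",
                       call. = FALSE)
  .gsea_es(abs(scores)^weight, as.logical(hits))
}

#' Permutation p-value for a preranked enrichment score
#'
#' The null shuffles the hit labels over list positions, keeping scores
#' fixed. The p-value is one-sided on the side of the observed ES sign with
#' an add-one correction:
#' p = (1 + #same-sign null ES at least as extreme) / (1 + #same-sign null
#' ES). Deterministic given the R random seed.
#'
#' @inheritParams enrichment_score
#' @param n_perm Number of permutations (>= 100; default 10000).
#' @return A list with `es`, `p` and `n_hits`.
#' @export
permutation_pvalue <- function(scores, hits, n_perm = 10000, weight = 1) {
  stopifnot(length(scores) == length(hits))
  if (n_perm < 100) {
    stop("configuration error: n_perm must be >= 100", call. = FALSE)
  }
  hits <- as.logical(hits)
  k <- sum(hits)
  if (k == 0L) stop("no overlap between gene set and ranked list",
                    call. = FALSE)
  if (k == length(hits)) {
    # all-hit list: ES = 1 and every permutation reproduces it
    return(list(es = 1, p = 1, n_hits = k))
  }
  res <- .gsea_perm(abs(scores)^weight, hits, as.integer(n_perm))
  es <- res$es
  same_sign <- if (es >= 0) res$es_null >= 0 else res$es_null < 0
  extreme <- same_sign & abs(res$es_null) >= abs(es)
  list(es = es,
       p = (1 + sum(extreme)) / (1 + sum(same_sign)),
       n_hits = k)
}

#' lncRNA enrichment score transform (lncRES)
#'
#' lncRES = 1 - 2p when ES >= 0 and 2p - 1 when ES < 0, mapping the
#' enrichment p-value onto \[-1, 1\] with the sign of the enrichment score.
#'
#' @param es Enrichment score(s).
#' @param p Nominal p-value(s) in (0, 1].
#' @return Numeric vector in \[-1, 1\].
#' @export
lncres <- function(es, p) {
  stopifnot(all(p > 0 & p <= 1))
  ifelse(es >= 0, 1 - 2 * p, 2 * p - 1)
}

#' Run preranked enrichment of every lncRNA against every pathway
#'
#' For each lncRNA's ranked list and each pathway (raw size at most
#' `max_size`) with at least `min_size` gene(s) in the list, computes the
#' permutation enrichment, the BH-adjusted FDR, and the lncRES statistic.
#' Pathway membership is intersected with each list's own gene universe.
#' FDR is Benjamini-Hochberg within each lncRNA's pathway tests by default
#' (one enrichment call per lncRNA); `global_fdr = TRUE` adjusts across all
#' tests instead.
#'
#' The permutation stream for each (lncRNA, pathway) pair is seeded from
#' `seed` and the pair's identifiers, so results do not depend on iteration
#' order.
#'
#' @param ranked Ranked lists from [build_ranked_lists()].
#' @param pathways Named list of character vectors (pathway -> mRNA ids).
#' @param min_size Minimum number of pathway genes present in the ranked
#'   list (default 1).
#' @param max_size Maximum raw pathway size (default 5000).
#' @param n_perm Permutations per test (default 10000).
#' @param seed Master integer seed.
#' @param weight Weight exponent on |H| (default 1).
#' @param global_fdr Adjust across all tests instead of within lncRNA.
#' @param cancer Cancer label recorded on every record.
#' @return A tibble with columns `lncrna_id`, `pathway`, `es`, `nominal_p`,
#'   `fdr`, `lncres`, `n_hits`, `list_length`, `cancer`, classed
#'   `irlnc_enrichment`.
#' @export
run_enrichment <- function(ranked, pathways, min_size = 1, max_size = 5000,
                           n_perm = 10000, seed = 1, weight = 1,
                           global_fdr = FALSE, cancer = "cancer") {
  stopifnot(is.list(pathways), !is.null(names(pathways)))
  pathways <- pathways[lengths(pathways) <= max_size]
  # re-sort so results do not depend on the input row order
  ranked <- dplyr::arrange(ranked, .data$lncrna_id, dplyr::desc(.data$H),
                           .data$mrna_id)
  lists <- split(ranked[c("mrna_id", "H")], ranked$lncrna_id)

  rows <- purrr::imap(lists, function(lst, lnc) {
    purrr::imap(pathways, function(genes, pw) {
      hits <- lst$mrna_id %in% genes
      if (sum(hits) < min_size) return(NULL)
      res <- withr::with_seed(
        pair_seed(seed, lnc, pw),
        permutation_pvalue(lst$H, hits, n_perm = n_perm, weight = weight))
      tibble::tibble(lncrna_id = lnc, pathway = pw, es = res$es,
                     nominal_p = res$p, n_hits = res$n_hits,
                     list_length = nrow(lst))
    }) |> purrr::compact() |> purrr::list_rbind()
  }) |> purrr::list_rbind()

  if (is.null(rows) || nrow(rows) == 0L) {
    rows <- tibble::tibble(lncrna_id = character(), pathway = character(),
                           es = numeric(), nominal_p = numeric(),
                           n_hits = integer(), list_length = integer())
  }
  if (nrow(rows) > 0L) {
    if (global_fdr) {
      rows$fdr <- stats::p.adjust(rows$nominal_p, method = "BH")
    } else {
      rows <- rows |>
        dplyr::group_by(.data$lncrna_id) |>
        dplyr::mutate(fdr = stats::p.adjust(.data$nominal_p, method = "BH")) |>
        dplyr::ungroup()
    }
    rows$lncres <- lncres(rows$es, rows$nominal_p)
  } else {
    rows$fdr <- numeric()
    rows$lncres <- numeric()
  }
  rows <- rows[, c("lncrna_id", "pathway", "es", "nominal_p", "fdr",
                   "lncres", "n_hits", "list_length")]
  rows$cancer <- cancer
  rows <- dplyr::arrange(rows, .data$lncrna_id, .data$pathway)
  class(rows) <- c("irlnc_enrichment", class(rows))
  rows
}

#' Extract immune-related lncRNA-pathway pairs
#'
#' Keeps pairs with |lncRES| strictly greater than `lncres_threshold` and
#' FDR strictly below `fdr_threshold`.
#'
#' @param records Enrichment tibble from [run_enrichment()].
#' @param lncres_threshold Strict lower bound on |lncRES| (default 0.995).
#' @param fdr_threshold Strict upper bound on FDR (default 0.05).
#' @return The qualifying rows, with a logical `kept` column dropped in
#'   favour of filtering; columns as in the input.
#' @export
extract_irlncrnas <- function(records, lncres_threshold = 0.995,
                              fdr_threshold = 0.05) {
  dplyr::filter(tibble::as_tibble(records),
                abs(.data$lncres) > lncres_threshold,
                .data$fdr < fdr_threshold)
}

#' Union of per-cancer irlncRNA sets
#'
#' Combines per-cancer extractions into the pan-cancer irlncRNA set,
#' retaining for each lncRNA the cancers and pathways it was called in so
#' that the pathway-cancer counts NC(l, w) and the cancer count NC(l) can
#' be recovered.
#'
#' @param sets A list of tibbles from [extract_irlncrnas()] (each carrying
#'   a `cancer` column), or a single combined tibble.
#' @return A tibble with one row per (lncrna_id, pathway, cancer) triple.
#' @export
union_irlncrnas <- function(sets) {
  if (is.data.frame(sets)) sets <- list(sets)
  empty <- tibble::tibble(lncrna_id = character(), pathway = character(),
                          cancer = character())
  combined <- purrr::list_rbind(c(list(empty), purrr::map(sets, function(s)
    tibble::as_tibble(s)[, c("lncrna_id", "pathway", "cancer")])))
  dplyr::distinct(combined) |>
    dplyr::arrange(.data$lncrna_id, .data$pathway, .data$cancer)
}

#' Pathway-cancer counts for the pan-cancer irlncRNA set
#'
#' @param union_tbl Output of [union_irlncrnas()].
#' @return A tibble with columns `lncrna_id`, `pathway`, `nc` (the number
#'   of cancers in which the pair was called).
#' @export
pathway_cancer_counts <- function(union_tbl) {
  union_tbl |>
    dplyr::count(.data$lncrna_id, .data$pathway, name = "nc")
}

# -- internal -----------------------------------------------------------

# order-independent per-pair seed derived from a master seed
pair_seed <- function(seed, lnc, pathway) {
  h <- string_hash(paste(lnc, pathway, sep = "\r"))
  as.integer((as.double(seed) * 2654435.0 + h) %% 2147483647)
}

string_hash <- function(s) {
  v <- utf8ToInt(s)
  h <- 5381
  for (ch in v) h <- (h * 33 + ch) %% 2147483647
  h
}
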