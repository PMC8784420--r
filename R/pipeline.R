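# End-to-end orchestration: correlation -> ranked lists -> enrichment ->
# irlncRNA extraction per cancer, then pan-cancer union, differential
# expression and Pscore. Stage boundaries log counts in/out of every filter
# so the cascade is auditable.

#' Pipeline configuration
#'
#' All thresholds default to the method's canonical values: rank threshold
#' 0.5 on H, |lncRES| > 0.995, FDR < 0.05, DE adjusted p < 0.01 and
#' |logFC| > 1.5, 10000 permutations, logistic c = -15 and d = ln(1999).
#'
#' @param rank_threshold Strict lower bound on H for ranked lists.
#' @param lncres_threshold Strict lower bound on |lncRES|.
#' @param fdr_threshold Strict upper bound on enrichment FDR.
#' @param de_adj_p,de_logfc DE thresholds (strict).
#' @param n_perm Permutations per enrichment test.
#' @param logistic A [logistic_params()] object.
#' @param weight Enrichment weight exponent (0 or 1).
#' @param global_fdr BH across all tests instead of within lncRNA.
#' @param n_pathways Pathway terms in the Pscore denominator.
#' @param seed Master seed for the permutation streams.
#' @return A named list, classed `irlnc_config`.
#' @export
pipeline_config <- function(rank_threshold = 0.5, lncres_threshold = 0.995,
                            fdr_threshold = 0.05, de_adj_p = 0.01,
                            de_logfc = 1.5, n_perm = 10000,
                            logistic = logistic_params(), weight = 1,
                            global_fdr = FALSE, n_pathways = 17,
                            seed = 1) {
  stopifnot(rank_threshold >= 0, rank_threshold < 1,
            lncres_threshold >= 0, lncres_threshold <= 1,
            fdr_threshold > 0, fdr_threshold <= 1,
            de_adj_p > 0, de_adj_p <= 1, de_logfc >= 0,
            n_perm >= 100, weight %in% c(0, 1), n_pathways >= 1)
  structure(list(rank_threshold = rank_threshold,
                 lncres_threshold = lncres_threshold,
                 fdr_threshold = fdr_threshold, de_adj_p = de_adj_p,
                 de_logfc = de_logfc, n_perm = n_perm, logistic = logistic,
                 weight = weight, global_fdr = global_fdr,
                 n_pathways = n_pathways, seed = seed),
            class = "irlnc_config")
}

#' Run the per-cancer stages on one cohort
#'
#' Correlation, ranked lists, enrichment and irlncRNA extraction for a
#' single cancer.
#'
#' @param mrna,lncrna Expression matrices sharing sample ids.
#' @param purity Named purity vector (see [read_purity()]).
#' @param pathways Named list of pathway gene sets.
#' @param config A [pipeline_config()].
#' @param verbose Log filter counts at stage boundaries.
#' @return A list with `correlations`, `ranked`, `enrichment`, `irlnc`
#'   tibbles and the `cancer` label.
#' @export
run_cancer <- function(mrna, lncrna, purity, pathways,
                       config = pipeline_config(), verbose = FALSE) {
  cancer <- cancer_label(mrna)
  log_stage <- function(...) if (verbose) message("[", cancer, "] ", ...)

  triples <- heuristic_matrix(mrna, lncrna, purity,
                              params = config$logistic)
  log_stage(nrow(triples), " correlation pairs from ",
            nrow(mrna), " mRNAs x ", nrow(lncrna), " lncRNAs")

  ranked <- build_ranked_lists(triples, threshold = config$rank_threshold)
  log_stage(dplyr::n_distinct(ranked$lncrna_id), " lncRNAs with H > ",
            config$rank_threshold, " (", nrow(ranked), " entries)")

  records <- run_enrichment(ranked, pathways, n_perm = config$n_perm,
                            seed = config$seed, weight = config$weight,
                            global_fdr = config$global_fdr, cancer = cancer)
  log_stage(nrow(records), " enrichment tests")

  irlnc <- extract_irlncrnas(records,
                             lncres_threshold = config$lncres_threshold,
                             fdr_threshold = config$fdr_threshold)
  log_stage(nrow(irlnc), " irlncRNA-pathway pairs kept")

  list(cancer = cancer, correlations = triples, ranked = ranked,
       enrichment = records, irlnc = irlnc)
}

#' Run the full pan-cancer analysis
#'
#' Runs [run_cancer()] on every cohort, unions the per-cancer irlncRNA
#' calls, performs differential expression in every cohort with both tumour
#' and normal samples, and computes Pscores.
#'
#' @param bundles A list of cohorts; each element needs `mrna`, `lncrna`,
#'   `purity`, `pathways` and optionally `labels` (as produced by
#'   [simulate_cancer()] or assembled from the readers).
#' @param config A [pipeline_config()].
#' @param verbose Log stage boundaries.
#' @return An object of class `irlnc_analysis`: a list with `per_cancer`,
#'   `irlnc_union`, `de`, `pscores`, `config`.
#' @export
run_pan_cancer <- function(bundles, config = pipeline_config(),
                           verbose = FALSE) {
  per_cancer <- purrr::map(bundles, function(b) {
    run_cancer(b$mrna, b$lncrna, b$purity, b$pathways,
               config = config, verbose = verbose)
  })
  irlnc_union <- union_irlncrnas(purrr::map(per_cancer, "irlnc"))
  ir_ids <- unique(irlnc_union$lncrna_id)

  de <- purrr::map(bundles, function(b) {
    if (is.null(b$labels) || length(ir_ids) == 0L) return(NULL)
    if (sum(b$labels == "tumor") < 3L || sum(b$labels == "normal") < 3L) {
      return(NULL)
    }
    combined <- rbind(unclass(b$mrna), unclass(b$lncrna))
    differential_expression(
      expression_matrix(combined, cancer_label(b$mrna)), b$labels,
      lnc_ids = ir_ids, adj_p_threshold = config$de_adj_p,
      logfc_threshold = config$de_logfc)
  }) |> purrr::compact() |> purrr::list_rbind()

  pscores <- if (nrow(irlnc_union) > 0L) {
    compute_pscores(irlnc_union, de, n_pathways = config$n_pathways)
  } else {
    empty <- tibble::tibble(lncrna_id = character(), nc_total = integer(),
                            r_de = numeric(), r_fc = numeric(),
                            pscore = numeric())
    class(empty) <- c("irlnc_pscore", class(empty))
    empty
  }

  structure(list(per_cancer = per_cancer, irlnc_union = irlnc_union,
                 de = de, pscores = pscores, config = config),
            class = "irlnc_analysis")
}

#' @export
print.irlnc_analysis <- function(x, ...) {
  cat("Pan-cancer immune-lncRNA analysis\n")
  cat("  cancers analysed:   ", length(x$per_cancer), "\n")
  cat("  irlncRNA-pathway-cancer triples:", nrow(x$irlnc_union), "\n")
  cat("  distinct irlncRNAs: ", dplyr::n_distinct(x$irlnc_union$lncrna_id),
      "\n")
  if (nrow(x$pscores) > 0L) {
    top <- x$pscores$lncrna_id[1]
    cat("  top Pscore:         ", format(x$pscores$pscore[1], digits = 4),
        " (", top, ")\n", sep = "")
  }
  invisible(x)
}

#' Tidy the per-pair results of a pan-cancer analysis
#'
#' @param x An `irlnc_analysis` object.
#' @param ... Unused.
#' @return The combined enrichment tibble over all cancers, with a logical
#'   `kept` column marking extracted irlncRNA-pathway pairs.
#' @export
tidy.irlnc_analysis <- function(x, ...) {
  rec <- purrr::list_rbind(purrr::map(x$per_cancer, function(pc)
    tibble::as_tibble(pc$enrichment)))
  kept <- purrr::list_rbind(purrr::map(x$per_cancer, function(pc)
    tibble::as_tibble(pc$irlnc)[, c("lncrna_id", "pathway", "cancer")]))
  kept$kept <- TRUE
  dplyr::left_join(rec, kept,
                   by = c("lncrna_id", "pathway", "cancer")) |>
    dplyr::mutate(kept = !is.na(.data$kept))
}

#' One-row summary of a pan-cancer analysis
#'
#' @inheritParams tidy.irlnc_analysis
#' @return A one-row tibble: `n_cancers`, `n_tests`, `n_pairs`,
#'   `n_irlncrna`, `n_de`, `max_pscore`.
#' @export
glance.irlnc_analysis <- function(x, ...) {
  tibble::tibble(
    n_cancers = length(x$per_cancer),
    n_tests = sum(purrr::map_int(x$per_cancer,
                                 function(pc) nrow(pc$enrichment))),
    n_pairs = nrow(x$irlnc_union),
    n_irlncrna = dplyr::n_distinct(x$irlnc_union$lncrna_id),
    n_de = if (is.null(x$de) || nrow(x$de) == 0L) 0L else
      sum(x$de$is_de),
    max_pscore = if (nrow(x$pscores) > 0L) max(x$pscores$pscore) else
      NA_real_)
}

#' Generic tidiers
#'
#' `tidy()` and `glance()` generics in the broom style, so analysis objects
#' summarise into tibbles.
#'
#' @param x An object.
#' @param ... Method-specific arguments.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Write every stage table of an analysis to a directory
#'
#' Emits `correlations_<cancer>.tsv`, `enrichment_<cancer>.tsv`,
#' `irlnc_union.tsv`, `de.tsv`, `pscores.tsv` and a plain-text
#' `manifest.tsv` echoing the configuration, all with deterministic row
#' order.
#'
#' @param analysis An `irlnc_analysis` object.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_analysis <- function(analysis, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  num <- function(df) {
    df[] <- lapply(df, function(col)
      if (is.numeric(col)) round(col, 6) else col)
    df
  }
  for (pc in analysis$per_cancer) {
    write_records(num(tibble::as_tibble(pc$correlations)),
                  file.path(dir, paste0("correlations_", pc$cancer, ".tsv")))
    write_records(num(tibble::as_tibble(pc$enrichment)),
                  file.path(dir, paste0("enrichment_", pc$cancer, ".tsv")))
  }
  write_records(analysis$irlnc_union, file.path(dir, "irlnc_union.tsv"))
  if (!is.null(analysis$de) && nrow(analysis$de) > 0L) {
    write_records(num(analysis$de), file.path(dir, "de.tsv"))
  }
  write_records(num(tibble::as_tibble(analysis$pscores)),
                file.path(dir, "pscores.tsv"))
  cfg <- analysis$config
  manifest <- tibble::tibble(
    key = c("rank_threshold", "lncres_threshold", "fdr_threshold",
            "de_adj_p", "de_logfc", "n_perm", "logistic_c", "logistic_d",
            "weight", "global_fdr", "n_pathways", "seed"),
    value = as.character(c(cfg$rank_threshold, cfg$lncres_threshold,
                           cfg$fdr_threshold, cfg$de_adj_p, cfg$de_logfc,
                           cfg$n_perm, cfg$logistic$c, cfg$logistic$d,
                           cfg$weight, cfg$global_fdr, cfg$n_pathways,
                           cfg$seed)))
  write_records(manifest, file.path(dir, "manifest.tsv"))
  invisible(dir)
}
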