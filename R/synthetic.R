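# Synthetic pan-cancer fixtures with planted ground truth.
#
# Expression is log-normal: per-sample log2 signals are built from latent
# pathway factors and exponentiated to non-negative units (every downstream
# statistic is rank- or correlation-based, so the marginal family matters
# little). One immune pathway is purity-coupled: its mRNAs follow
# (1 - purity), emulating infiltration-driven expression in bulk tumours;
# the remaining pathways follow independent latent factors. Planted
# "direct" lncRNAs track a pathway factor; planted "purity-mediated"
# lncRNAs track (1 - purity) itself, so their mRNA correlation exists only
# through purity and vanishes under the purity-conditioned partial
# correlation. Each pathway also gets a few "adjacent" background mRNAs
# with a weaker loading: they enter ranked lists below the pathway genes,
# so lists contain misses and permutation p-values are informative (an
# all-hit list has a permutation-invariant enrichment score).

#' Synthetic generator configuration
#'
#' The `"strong"` preset is the documented study condition for recovery
#' tests: 60 tumour + 30 normal samples, 60 mRNAs (3 pathways of 15 genes,
#' 4 purity/factor-adjacent background genes per pathway, 3 pure noise
#' genes), 20 lncRNAs, unit-variance pathway factors, noise SD 0.3 on
#' planted genes, planted DE log2 fold changes up to 3.
#'
#' @param preset Currently `"strong"`.
#' @param ... Overrides for individual fields.
#' @return A named list of generator parameters.
#' @export
synthetic_config <- function(preset = "strong", ...) {
  preset <- match.arg(preset)
  cfg <- list(
    n_tumor = 60L, n_normal = 30L,
    n_mrna = 60L, n_lnc = 20L,
    n_pathways = 3L, pathway_size = 15L, n_adjacent = 4L,
    noise_sd = 0.3, adjacent_loading = 0.7, adjacent_noise_sd = 0.5,
    background_sd = 1, baseline_log2 = 8,
    purity_min = 0.3, purity_max = 0.9,
    de_logfc = 3)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config field(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  cfg[names(dots)] <- dots
  if (cfg$n_tumor + 0 < 10L) {
    stop("config error: need n_tumor >= 10", call. = FALSE)
  }
  if (cfg$n_pathways * (cfg$pathway_size + cfg$n_adjacent) > cfg$n_mrna) {
    stop("config error: pathways + adjacent genes exceed n_mrna",
         call. = FALSE)
  }
  cfg
}

#' Default pan-cancer planting plan
#'
#' Describes which lncRNAs are planted, in which mode, on which pathway,
#' in which cancers, and with what tumour/normal log2 fold change:
#' * `lnc01` — high-pathogenicity: direct on pathway 2 in every cancer,
#'   strong DE everywhere (logFC = `de_logfc`);
#' * `lnc02` — low-pathogenicity: direct on pathway 2 in cancer 1 only,
#'   no DE;
#' * `lnc03`/`lnc04` — direct on pathway 3 (all cancers with DE logFC 2 /
#'   two cancers without DE);
#' * `lnc05`/`lnc06` — purity-mediated on pathway 1 (all / three cancers);
#' * remaining lncRNAs — null.
#'
#' @param k_cancers Number of cancers.
#' @param config A [synthetic_config()].
#' @return A tibble with columns `lncrna_id`, `mode`, `pathway`,
#'   `cancers` (list of integer vectors), `logfc`.
#' @export
default_plan <- function(k_cancers, config = synthetic_config()) {
  if (config$n_lnc < 6L) {
    stop("config error: the default plan plants 6 lncRNAs; n_lnc >= 6",
         call. = FALSE)
  }
  if (config$n_pathways < 3L) {
    stop("config error: the default plan needs >= 3 pathways", call. = FALSE)
  }
  ids <- lnc_ids(config$n_lnc)
  all_c <- seq_len(k_cancers)
  tibble::tibble(
    lncrna_id = ids,
    mode = c("direct", "direct", "direct", "direct", "purity", "purity",
             rep("null", config$n_lnc - 6L)),
    pathway = c("pathway2", "pathway2", "pathway3", "pathway3",
                "pathway1", "pathway1", rep(NA_character_,
                                            config$n_lnc - 6L)),
    cancers = c(list(all_c), list(1L), list(all_c),
                list(head(all_c, 2L)), list(all_c), list(head(all_c, 3L)),
                rep(list(integer()), config$n_lnc - 6L)),
    logfc = c(config$de_logfc, 0, 2, 0, 0, 0,
              rep(0, config$n_lnc - 6L)))
}

#' Simulate one cancer cohort
#'
#' Generates paired mRNA/lncRNA expression matrices (tumour + normal
#' samples), a tumour-purity table (tumour samples only; purity ~
#' U(purity_min, purity_max)), tumour/normal labels, immune pathway gene
#' sets, a six-cell-type infiltration table driven by (1 - purity), and the
#' planted truth. Deterministic given `seed`.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @param cancer_index Which cancer of the pan-cancer plan this cohort is.
#' @param plan Planting plan (see [default_plan()]); defaults to
#'   `default_plan(cancer_index, config)` so that a single cohort is the
#'   `k = 1` degenerate case of the pan-cancer design.
#' @return A list with elements `mrna`, `lncrna`, `purity`, `labels`,
#'   `pathways`, `infiltration`, `truth`, `cancer`.
#' @export
simulate_cancer <- function(config = synthetic_config(), seed = 1,
                            cancer_index = 1L, plan = NULL) {
  if (is.null(plan)) plan <- default_plan(max(cancer_index, 1L), config)
  if (nrow(plan) > config$n_lnc) {
    stop("config error: plan plants more lncRNAs than n_lnc", call. = FALSE)
  }
  withr::with_seed(seed, simulate_cancer_impl(config, cancer_index, plan))
}

simulate_cancer_impl <- function(config, cancer_index, plan) {
  cancer <- sprintf("cancer%02d", cancer_index)
  nt <- config$n_tumor
  nn <- config$n_normal
  tumor_ids <- sprintf("%s_T%03d", cancer, seq_len(nt))
  normal_ids <- if (nn > 0) sprintf("%s_N%03d", cancer, seq_len(nn)) else
    character()
  samples <- c(tumor_ids, normal_ids)
  n <- length(samples)

  purity <- stats::runif(nt, config$purity_min, config$purity_max)
  names(purity) <- tumor_ids
  # standardised infiltration signal: high when purity is low
  z_t <- (1 - purity - (1 - (config$purity_min + config$purity_max) / 2)) /
    ((config$purity_max - config$purity_min) / sqrt(12))
  z <- c(z_t, stats::rnorm(nn))           # normals: latent, no purity
  names(z) <- samples

  # latent factors: pathway 1 is the purity-coupled one
  np <- config$n_pathways
  factors <- matrix(stats::rnorm(n * np), nrow = np,
                    dimnames = list(paste0("pathway", seq_len(np)), samples))
  factors[1, ] <- z

  mids <- sprintf("mrna%03d", seq_len(config$n_mrna))
  gene_sets <- list()
  mrna_log <- matrix(stats::rnorm(config$n_mrna * n,
                                  sd = config$background_sd),
                     nrow = config$n_mrna, dimnames = list(mids, samples))
  idx <- 1L
  for (p in seq_len(np)) {
    pw <- paste0("pathway", p)
    members <- mids[idx:(idx + config$pathway_size - 1L)]
    idx <- idx + config$pathway_size
    mrna_log[members, ] <-
      matrix(rep(factors[p, ], each = length(members)),
             nrow = length(members)) +
      matrix(stats::rnorm(length(members) * n, sd = config$noise_sd),
             nrow = length(members))
    gene_sets[[pw]] <- members
    if (config$n_adjacent > 0L) {
      adj <- mids[idx:(idx + config$n_adjacent - 1L)]
      idx <- idx + config$n_adjacent
      mrna_log[adj, ] <-
        config$adjacent_loading *
        matrix(rep(factors[p, ], each = length(adj)), nrow = length(adj)) +
        matrix(stats::rnorm(length(adj) * n, sd = config$adjacent_noise_sd),
               nrow = length(adj))
    }
  }

  lids <- lnc_ids(config$n_lnc)
  lnc_log <- matrix(stats::rnorm(config$n_lnc * n,
                                 sd = config$background_sd),
                    nrow = config$n_lnc, dimnames = list(lids, samples))
  active <- plan[vapply(plan$cancers,
                        function(cs) cancer_index %in% cs, logical(1)), ]
  for (i in seq_len(nrow(active))) {
    row <- active[i, ]
    signal <- switch(row$mode,
      direct = factors[row$pathway, ],
      purity = z,
      NULL)
    if (is.null(signal)) next
    lnc_log[row$lncrna_id, ] <- signal +
      stats::rnorm(n, sd = config$noise_sd)
  }

  # planted tumour/normal fold change, applied on the log2 scale
  de_rows <- active[active$logfc != 0, ]
  for (i in seq_len(nrow(de_rows))) {
    lnc_log[de_rows$lncrna_id[i], tumor_ids] <-
      lnc_log[de_rows$lncrna_id[i], tumor_ids] + de_rows$logfc[i]
  }

  labels <- stats::setNames(c(rep("tumor", nt), rep("normal", nn)), samples)
  infiltration <- simulate_infiltration(z_t, tumor_ids)

  truth <- list(
    planted = active[, c("lncrna_id", "mode", "pathway", "logfc")] |>
      dplyr::mutate(cancer = cancer),
    plan = plan, seed_used = TRUE, config = config)

  list(
    mrna = expression_matrix(2^(config$baseline_log2 + mrna_log), cancer),
    lncrna = expression_matrix(2^(config$baseline_log2 + lnc_log), cancer),
    purity = purity,
    labels = labels,
    pathways = gene_sets,
    infiltration = infiltration,
    truth = truth,
    cancer = cancer)
}

simulate_infiltration <- function(z_t, tumor_ids) {
  cells <- c("B_cell", "T_cell_CD4", "T_cell_CD8", "Neutrophil",
             "Macrophage", "Dendritic")
  out <- tibble::tibble(sample_id = tumor_ids)
  for (cell in cells) {
    out[[cell]] <- 0.2 + 0.05 * (z_t + stats::rnorm(length(z_t), sd = 0.3))
  }
  out
}

#' Simulate a pan-cancer bundle with shared ground truth
#'
#' All cancers share the gene/lncRNA namespace and the planting plan
#' ([default_plan()]): a designated high-pathogenicity lncRNA is planted in
#' every cancer with strong differential expression, a low-pathogenicity
#' one in a single cancer without DE. `k_cancers = 1` degenerates to a
#' single [simulate_cancer()] cohort.
#'
#' @param k_cancers Number of cancer cohorts.
#' @param config A [synthetic_config()].
#' @param seed Integer master seed; cohort c uses `seed + c`.
#' @return A list with `cancers` (list of per-cancer bundles), `plan`, and
#'   `truth_pairs` (tibble of planted (lncrna_id, pathway, cancer) triples).
#' @export
simulate_pan_cancer <- function(k_cancers = 5L, config = synthetic_config(),
                                seed = 1) {
  stopifnot(k_cancers >= 1L)
  plan <- default_plan(k_cancers, config)
  bundles <- purrr::map(seq_len(k_cancers), function(ci) {
    simulate_cancer(config, seed = seed + ci, cancer_index = ci, plan = plan)
  })
  names(bundles) <- purrr::map_chr(bundles, "cancer")
  truth_pairs <- purrr::list_rbind(purrr::map(bundles, function(b) {
    dplyr::filter(b$truth$planted, !is.na(.data$pathway))[,
      c("lncrna_id", "pathway", "cancer")]
  }))
  list(cancers = bundles, plan = plan, truth_pairs = truth_pairs,
       config = config, seed = seed)
}

#' Simulate a single-cell style expression matrix for irlncRNA validation
#'
#' Immune cells express the designated irlncRNAs `effect` log2 units above
#' baseline; non-immune cells express all lncRNAs at baseline. Used to
#' exercise [group_expression_compare()].
#'
#' @param ir_ids irlncRNA identifiers (subset of `lnc_ids`).
#' @param lnc_ids All lncRNA identifiers.
#' @param n_immune,n_other Number of immune / non-immune cells.
#' @param effect log2 expression shift of irlncRNAs in immune cells.
#' @param seed Integer seed.
#' @return A list with `cell_expr` (genes x cells matrix) and
#'   `cell_labels` (named vector cell -> group).
#' @export
simulate_cell_matrix <- function(ir_ids, lnc_ids, n_immune = 40L,
                                 n_other = 40L, effect = 1, seed = 1) {
  stopifnot(all(ir_ids %in% lnc_ids))
  withr::with_seed(seed, {
    cells <- c(sprintf("imm%03d", seq_len(n_immune)),
               sprintf("oth%03d", seq_len(n_other)))
    groups <- stats::setNames(
      c(rep("immune", n_immune), rep("non-immune", n_other)), cells)
    base <- matrix(stats::rnorm(length(lnc_ids) * length(cells), sd = 1),
                   nrow = length(lnc_ids),
                   dimnames = list(lnc_ids, cells))
    base[ir_ids, groups == "immune"] <-
      base[ir_ids, groups == "immune"] + effect
    list(cell_expr = 2^(6 + base), cell_labels = groups)
  })
}

#' Write a simulated cohort to disk in the pipeline's input formats
#'
#' Emits `<prefix>_mrna.tsv`, `<prefix>_lncrna.tsv`, `<prefix>_purity.tsv`,
#' `<prefix>_labels.tsv`, `<prefix>_pathways.gmt` and
#' `<prefix>_infiltration.tsv`.
#'
#' @param bundle Output of [simulate_cancer()].
#' @param prefix Path prefix for the files.
#' @return Named character vector of the paths written, invisibly.
#' @export
write_bundle <- function(bundle, prefix) {
  expr_tsv <- function(m, path) {
    df <- tibble::as_tibble(unclass(m), rownames = "gene_id")
    readr::write_tsv(df, path, progress = FALSE)
  }
  paths <- c(
    mrna = paste0(prefix, "_mrna.tsv"),
    lncrna = paste0(prefix, "_lncrna.tsv"),
    purity = paste0(prefix, "_purity.tsv"),
    labels = paste0(prefix, "_labels.tsv"),
    pathways = paste0(prefix, "_pathways.gmt"),
    infiltration = paste0(prefix, "_infiltration.tsv"))
  expr_tsv(bundle$mrna, paths["mrna"])
  expr_tsv(bundle$lncrna, paths["lncrna"])
  readr::write_tsv(tibble::tibble(sample_id = names(bundle$purity),
                                  purity = unname(bundle$purity)),
                   paths["purity"], progress = FALSE)
  readr::write_tsv(tibble::tibble(sample_id = names(bundle$labels),
                                  group = unname(bundle$labels)),
                   paths["labels"], progress = FALSE)
  writeLines(vapply(names(bundle$pathways), function(pw) {
    paste(c(pw, "synthetic immune pathway", bundle$pathways[[pw]]),
          collapse = "\t")
  }, character(1)), paths["pathways"])
  readr::write_tsv(bundle$infiltration, paths["infiltration"],
                   progress = FALSE)
  invisible(paths)
}

lnc_ids <- function(n) sprintf("lnc%02d", seq_len(n))
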