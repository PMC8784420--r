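# ggplot2 visualisations of the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the heuristic-correlation landscape
#'
#' Histogram of H over all (lncRNA, mRNA) pairs with the rank threshold
#' marked; steeply bimodal by construction of the logistic transform.
#'
#' @param object A correlation tibble from [heuristic_matrix()].
#' @param threshold Rank threshold to mark (default 0.5).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.irlnc_cor <- function(object, threshold = 0.5, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$H)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey35") +
    ggplot2::geom_vline(xintercept = threshold, linetype = 2,
                        colour = "red") +
    ggplot2::labs(x = "heuristic correlation H",
                  y = "lncRNA-mRNA pairs") +
    ggplot2::theme_minimal()
}

#' Plot enrichment results as a lncRNA x pathway map
#'
#' Tiles coloured by lncRES; extracted pairs (|lncRES| above the threshold
#' and FDR below it) are outlined.
#'
#' @param object An enrichment tibble from [run_enrichment()].
#' @param lncres_threshold,fdr_threshold Extraction thresholds to mark.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.irlnc_enrichment <- function(object, lncres_threshold = 0.995,
                                      fdr_threshold = 0.05, ...) {
  df <- tibble::as_tibble(object)
  df$kept <- abs(df$lncres) > lncres_threshold & df$fdr < fdr_threshold
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pathway, y = .data$lncrna_id,
                                   fill = .data$lncres)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = df[df$kept, , drop = FALSE], fill = NA,
                       colour = "black", linewidth = 0.6) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "lncRES") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot the Pscore ranking
#'
#' Lollipop chart of Pscores in descending order, with the DE breadth and
#' intensity components shown as stacked context.
#'
#' @param object A pathogenicity tibble from [compute_pscores()].
#' @param top Show at most this many lncRNAs (default 30).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.irlnc_pscore <- function(object, top = 30, ...) {
  df <- utils::head(tibble::as_tibble(object), top)
  df$lncrna_id <- factor(df$lncrna_id, levels = rev(df$lncrna_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pscore, y = .data$lncrna_id)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$pscore,
                                       yend = .data$lncrna_id),
                          colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Pscore", y = NULL) +
    ggplot2::theme_minimal()
}
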