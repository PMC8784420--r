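# Direct, partial and heuristic correlation between every lncRNA and mRNA.
#
# Direct correlation D is the mean of Pearson and Spearman coefficients.
# Partial correlation P conditions D on tumour purity with the standard
# first-order recursion. The heuristic coefficient H passes the beta-optimal
# convex combination of D and P -- analytically max(|D|, |P|) -- through a
# steep logistic, accentuating strong and suppressing weak correlation.

#' Logistic transform parameters
#'
#' Defaults `c = -15`, `d = ln(1999)` make the transform L(x) =
#' 1 / (exp(c x + d) + 1) approximately 0 on \[0, 0.3\] and approximately 1 on
#' \[0.7, 1\], with L(0) = 1/2000.
#'
#' @param c Slope parameter; must be negative so L is increasing.
#' @param d Offset parameter.
#' @return A list with elements `c` and `d`, classed `logistic_params`.
#' @export
logistic_params <- function(c = -15, d = log(1999)) {
  stopifnot(is.numeric(c), is.numeric(d), length(c) == 1L, length(d) == 1L)
  if (c >= 0) stop("`c` must be negative so the transform is increasing",
                   call. = FALSE)
  structure(list(c = c, d = d), class = "logistic_params")
}

#' Steep logistic transform of an absolute correlation
#'
#' L(x) = 1 / (exp(c x + d) + 1), applied to `x` = |correlation| in \[0, 1\].
#' Strictly increasing for `c < 0`; at the defaults L(0) = 1/2000.
#'
#' @param x Numeric vector in \[0, 1\].
#' @param params A [logistic_params()] object.
#' @return Numeric vector in (0, 1).
#' @export
logistic_transform <- function(x, params = logistic_params()) {
  stopifnot(inherits(params, "logistic_params"))
  if (any(x < 0 | x > 1, na.rm = TRUE)) {
    stop("`x` must lie in [0, 1] (take the absolute correlation first)",
         call. = FALSE)
  }
  1 / (exp(params$c * x + params$d) + 1)
}

#' Pearson correlation with a zero-variance guard
#'
#' Plain product-moment correlation; returns `NA` (the "not computable"
#' signal, so the pair is skipped) when either vector is constant or the
#' vectors are shorter than 3.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A number in \[-1, 1\], or `NA`.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) return(NA_real_)
  if (var_zero(x) || var_zero(y)) return(NA_real_)
  clamp_unit(stats::cor(x, y, method = "pearson"))
}

#' Spearman correlation (Pearson of mid-ranks)
#'
#' Computed as the Pearson correlation of average ranks, which handles ties;
#' on tie-free input this equals the classical 1 - 6 sum(d_i^2) / (r(r^2-1)).
#' Returns `NA` when either rank vector is constant (all ties).
#'
#' @inheritParams pearson_cor
#' @return A number in \[-1, 1\], or `NA`.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) return(NA_real_)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (var_zero(rx) || var_zero(ry)) return(NA_real_)
  clamp_unit(stats::cor(rx, ry, method = "pearson"))
}

#' Direct correlation: mean of Pearson and Spearman
#'
#' @param r Pearson coefficient in \[-1, 1\].
#' @param s Spearman coefficient in \[-1, 1\].
#' @return (r + s) / 2.
#' @export
direct_correlation <- function(r, s) {
  (r + s) / 2
}

#' First-order partial correlation given the purity correlations
#'
#' Removes the linear effect of tumour purity t from the direct correlation
#' between an mRNA m and a lncRNA l:
#' P = (D_ml - D_mt D_tl) / sqrt((1 - D_mt^2)(1 - D_tl^2)).
#' Returns `NA` (undefined-partial signal) when |D_mt| or |D_tl| equals 1.
#' Because D averages Pearson and Spearman, the three coefficients need not
#' form a positive semi-definite system, so the raw ratio can stray beyond
#' \[-1, 1\]; results are truncated back into the interval.
#'
#' @param d_ml Direct correlation between mRNA and lncRNA.
#' @param d_mt Direct correlation between mRNA and purity.
#' @param d_tl Direct correlation between purity and lncRNA.
#' @return A number in \[-1, 1\], or `NA`.
#' @export
partial_correlation <- function(d_ml, d_mt, d_tl) {
  out <- (d_ml - d_mt * d_tl) / sqrt((1 - d_mt^2) * (1 - d_tl^2))
  out[abs(d_mt) >= 1 | abs(d_tl) >= 1] <- NA_real_
  pmin(pmax(out, -1), 1)
}

#' Optimal convex weight between direct and partial correlation
#'
#' Chooses beta in \[0, 1\] maximising |beta D + (1 - beta) P|. The objective
#' is linear in beta, so the optimum is an endpoint: beta = 1 (direct) when
#' |D| >= |P|, else beta = 0 (partial); ties prefer the direct coefficient.
#' The returned `combined` coefficient carries the sign of the selected
#' coefficient.
#'
#' @param d Direct correlation in \[-1, 1\].
#' @param p Partial correlation in \[-1, 1\].
#' @return A list with numeric vectors `beta` and `combined`.
#' @export
optimal_beta <- function(d, p) {
  take_direct <- abs(d) >= abs(p)
  list(beta = as.numeric(take_direct),
       combined = ifelse(take_direct, d, p))
}

#' Heuristic correlation coefficient
#'
#' H = L(|beta D + (1 - beta) P|) = L(max(|D|, |P|)): the logistic transform
#' of the magnitude of the beta-optimal combination of direct and partial
#' correlation. Always in (0, 1) and unsigned; the sign of the selected
#' coefficient is kept separately for diagnostics.
#'
#' @inheritParams optimal_beta
#' @param params A [logistic_params()] object.
#' @return Numeric vector in (0, 1).
#' @export
heuristic_correlation <- function(d, p, params = logistic_params()) {
  logistic_transform(pmax(abs(d), abs(p)), params)
}

#' All-pairs heuristic correlation between mRNAs and lncRNAs
#'
#' For every (mRNA, lncRNA) pair over the samples shared by both matrices
#' and the purity table, computes Pearson R, Spearman S, direct D =
#' (R + S)/2, purity-conditioned partial P, the optimal beta, and the
#' heuristic coefficient H. The purity correlations D(m, t) and D(t, l) use
#' the same combined Pearson-Spearman form as D(m, l). Pairs involving a
#' constant gene (or a degenerate purity correlation) are skipped with a
#' message.
#'
#' @param mrna,lncrna Expression matrices (genes x samples) sharing sample
#'   ids.
#' @param purity Named numeric vector sample id -> tumour purity in \[0, 1\].
#'   Samples without purity are excluded with a warning.
#' @param params A [logistic_params()] object.
#' @return A tibble with columns `lncrna_id`, `mrna_id`, `R`, `S`, `D`,
#'   `P`, `beta`, `H`, classed `irlnc_cor`.
#' @export
heuristic_matrix <- function(mrna, lncrna, purity,
                             params = logistic_params()) {
  shared <- intersect(colnames(mrna), colnames(lncrna))
  missing_purity <- setdiff(shared, names(purity))
  if (length(missing_purity)) {
    warning(length(missing_purity),
            " shared sample(s) lack tumour purity and were excluded",
            call. = FALSE)
  }
  shared <- intersect(shared, names(purity))
  if (length(shared) < 3L) {
    stop("insufficient samples: need >= 3 shared samples with purity, got ",
         length(shared), call. = FALSE)
  }
  mm <- mrna[, shared, drop = FALSE]
  ll <- lncrna[, shared, drop = FALSE]
  t <- purity[shared]

  # rank once per gene; Spearman = Pearson of mid-ranks
  rank_rows <- function(m) t(apply(m, 1L, rank, ties.method = "average"))
  keep_m <- apply(mm, 1L, function(v) !var_zero(v))
  keep_l <- apply(ll, 1L, function(v) !var_zero(v))
  n_drop <- sum(!keep_m) + sum(!keep_l)
  if (n_drop > 0L) {
    message(n_drop, " constant gene(s) skipped (undefined correlation)")
  }
  mm <- mm[keep_m, , drop = FALSE]
  ll <- ll[keep_l, , drop = FALSE]
  if (nrow(mm) == 0L || nrow(ll) == 0L) {
    return(new_cor_tbl(tibble::tibble(
      lncrna_id = character(), mrna_id = character(), R = numeric(),
      S = numeric(), D = numeric(), P = numeric(), beta = numeric(),
      H = numeric())))
  }

  R <- clamp_unit(stats::cor(t(mm), t(ll), method = "pearson"))
  S <- clamp_unit(stats::cor(t(rank_rows(mm)), t(rank_rows(ll)),
                             method = "pearson"))
  D <- (R + S) / 2

  if (var_zero(t) || var_zero(rank(t))) {
    warning("tumour purity is constant across samples; ",
            "partial correlations undefined, using direct only",
            call. = FALSE)
    D_mt <- rep(NA_real_, nrow(mm))
    D_tl <- rep(NA_real_, nrow(ll))
  } else {
    tm <- matrix(t, ncol = 1, dimnames = list(names(t), "t"))
    D_mt <- (clamp_unit(stats::cor(t(mm), tm)) +
             clamp_unit(stats::cor(t(rank_rows(mm)), rank(tm)))) / 2
    D_tl <- (clamp_unit(stats::cor(t(ll), tm)) +
             clamp_unit(stats::cor(t(rank_rows(ll)), rank(tm)))) / 2
    D_mt <- drop(D_mt)
    D_tl <- drop(D_tl)
  }

  P <- outer(seq_len(nrow(mm)), seq_len(nrow(ll)),
             function(i, j) partial_correlation(D[cbind(i, j)],
                                                D_mt[i], D_tl[j]))

  tbl <- tibble::tibble(
    lncrna_id = rep(rownames(ll), each = nrow(mm)),
    mrna_id = rep(rownames(mm), times = nrow(ll)),
    R = as.vector(R), S = as.vector(S), D = as.vector(D),
    P = as.vector(P))
  # a pair is kept only when all of R, S, P are computable
  n_bad <- sum(!stats::complete.cases(tbl))
  if (n_bad > 0L) {
    message(n_bad, " pair(s) skipped (partial correlation undefined)")
    tbl <- tbl[stats::complete.cases(tbl), , drop = FALSE]
  }
  ob <- optimal_beta(tbl$D, tbl$P)
  tbl$beta <- ob$beta
  tbl$H <- logistic_transform(abs(ob$combined), params)
  new_cor_tbl(dplyr::arrange(tbl, .data$lncrna_id, .data$mrna_id))
}

new_cor_tbl <- function(tbl) {
  class(tbl) <- c("irlnc_cor", class(tbl))
  tbl
}

var_zero <- function(x) {
  length(unique(x)) < 2L
}

clamp_unit <- function(x, tol = 1e-12) {
  x[x > 1 & x <= 1 + tol] <- 1
  x[x < -1 & x >= -1 - tol] <- -1
  x
}
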