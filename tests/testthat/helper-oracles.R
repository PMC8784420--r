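# Independent oracles and tiny fixture builders shared across tests.

# Tie-free Spearman closed form: 1 - 6 sum(d_i^2) / (r (r^2 - 1)).
# Valid only when neither vector has ties.
spearman_closed_form <- function(x, y) {
  stopifnot(!anyDuplicated(x), !anyDuplicated(y))
  d <- rank(x) - rank(y)
  r <- length(x)
  1 - 6 * sum(d^2) / (r * (r^2 - 1))
}

# Pearson written out from first principles (expectation form).
pearson_expectation_form <- function(x, y) {
  exy <- mean(x * y)
  (exy - mean(x) * mean(y)) /
    sqrt((mean(x^2) - mean(x)^2) * (mean(y^2) - mean(y)^2))
}

# Brute-force beta grid for the convex combination |b*D + (1-b)*P|.
beta_grid_max <- function(d, p, step = 1e-3) {
  betas <- seq(0, 1, by = step)
  max(abs(betas * d + (1 - betas) * p))
}

# Running-sum enrichment score recomputed independently with cumsum.
es_oracle <- function(scores, hits, weight = 1) {
  w <- abs(scores)^weight
  n <- length(scores)
  k <- sum(hits)
  steps <- ifelse(hits, w / sum(w[hits]), -1 / (n - k))
  runsum <- cumsum(steps)
  m <- max(abs(runsum))
  # magnitude tie between the positive and negative extreme -> positive
  if (any(runsum == m)) m else -m
}

# Exact enumeration of every hit placement for small ranked lists; returns
# the one-sided (by observed sign) exceedance proportion.
exact_enumeration_p <- function(scores, hits, weight = 1) {
  n <- length(scores)
  k <- sum(hits)
  obs <- es_oracle(scores, hits, weight)
  placements <- utils::combn(n, k)
  es_all <- apply(placements, 2L, function(idx) {
    h <- rep(FALSE, n)
    h[idx] <- TRUE
    es_oracle(scores, h, weight)
  })
  same_sign <- if (obs >= 0) es_all >= 0 else es_all < 0
  sum(same_sign & abs(es_all) >= abs(obs)) / sum(same_sign)
}

# A tiny deterministic expression matrix.
tiny_expr <- function(values, genes, samples, cancer = "toy") {
  expression_matrix(matrix(values, nrow = length(genes), byrow = TRUE,
                           dimnames = list(genes, samples)), cancer)
}

# Write a character vector as a temporary TSV file and return its path.
write_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
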