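test_that("Pearson and Spearman match hand-derived and degenerate cases", {
  expect_equal(pearson_cor(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_cor(c(1, 2, 3), c(6, 4, 2)), -1)
  expect_equal(pearson_cor(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_equal(spearman_cor(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_equal(spearman_cor(c(1, 5, 9, 11), c(2, 7, 20, 400)), 1)
  expect_true(is.na(pearson_cor(c(1, 1, 1), c(1, 2, 3))))
  expect_true(is.na(spearman_cor(c(2, 2, 2), c(1, 2, 3))))
  expect_true(is.na(pearson_cor(1:2, 2:3)))  # too short
})

test_that("correlations agree with independent re-implementations", {
  withr::with_seed(42, {
    for (i in 1:25) {
      n <- sample(10:50, 1)
      x <- rnorm(n)
      y <- rnorm(n) + 0.5 * x
      expect_equal(pearson_cor(x, y), pearson_expectation_form(x, y),
                   tolerance = 1e-12)
      expect_equal(spearman_cor(x, y), spearman_closed_form(x, y),
                   tolerance = 1e-12)
    }
  })
})

test_that("direct correlation is the arithmetic mean", {
  expect_equal(direct_correlation(1, 1), 1)
  expect_equal(direct_correlation(0.8, 0.8), 0.8)
  expect_equal(direct_correlation(0.9, 0.7), 0.8)
})

test_that("partial correlation matches the first-order recursion", {
  expect_equal(partial_correlation(0.8, 0.5, 0.5), 0.55 / 0.75)
  expect_equal(partial_correlation(0.25, 0.5, 0.5), 0)
  # purity uncorrelated => P = D, on a grid of D values
  d_grid <- seq(-1, 1, by = 0.05)
  expect_equal(partial_correlation(d_grid, 0, 0), d_grid)
  expect_true(is.na(partial_correlation(0.5, 1, 0.2)))
  expect_true(is.na(partial_correlation(0.5, 0.2, -1)))
})

test_that("logistic transform has the stated fixed points and is increasing", {
  p <- logistic_params()
  expect_equal(logistic_transform(0, p), 1 / 2000)
  expect_equal(logistic_transform(log(1999) / 15, p), 0.5)
  expect_equal(logistic_transform(0.3, p), 0.0430906620878123,
               tolerance = 1e-12)
  expect_equal(logistic_transform(0.7, p), 0.947826544507293,
               tolerance = 1e-12)
  # independent check against the standard logistic CDF
  x <- seq(0, 1, length.out = 101)
  expect_equal(logistic_transform(x, p), stats::plogis(-(p$c * x + p$d)),
               tolerance = 1e-14)
  grid <- logistic_transform(seq(0, 1, length.out = 1000), p)
  expect_true(all(diff(grid) > 0))
  expect_error(logistic_params(c = 2), "negative")
  expect_error(logistic_transform(1.5, p), "0, 1")
})

test_that("beta optimisation picks the stronger coefficient", {
  expect_equal(optimal_beta(0.8, 0.3), list(beta = 1, combined = 0.8))
  expect_equal(optimal_beta(0.3, -0.9), list(beta = 0, combined = -0.9))
  expect_equal(optimal_beta(0.6, 0.6), list(beta = 1, combined = 0.6))
  expect_equal(heuristic_correlation(0, 0), 0.0005)
  expect_equal(heuristic_correlation(0.8, 0.3), 0.987866743564547,
               tolerance = 1e-12)
  expect_equal(heuristic_correlation(0.3, -0.9), 0.997266942858452,
               tolerance = 1e-12)
})

test_that("heuristic matrix enumerates computable pairs", {
  samples <- paste0("s", 1:6)
  mrna <- tiny_expr(c(1, 2, 3, 4, 5, 6,
                      2, 4, 8, 16, 32, 64), c("m1", "m2"), samples)
  lncrna <- tiny_expr(c(6, 5, 4, 3, 2, 1,
                        1, 3, 2, 5, 4, 6,
                        1, 2, 3, 4, 5, 6), c("l1", "l2", "l3"), samples)
  purity <- setNames(c(0.4, 0.5, 0.6, 0.45, 0.55, 0.65), samples)
  triples <- heuristic_matrix(mrna, lncrna, purity)
  expect_equal(nrow(triples), 6L)
  expect_equal(sort(unique(triples$lncrna_id)), c("l1", "l2", "l3"))

  # planted copy: lncRNA identical to an mRNA gives R = S = D = 1, H = L(1)
  planted <- triples[triples$lncrna_id == "l3" & triples$mrna_id == "m1", ]
  expect_equal(planted$R, 1)
  expect_equal(planted$S, 1)
  expect_equal(planted$D, 1)
  expect_equal(planted$H, logistic_transform(1))

  # a constant mRNA's pairs are absent
  mrna2 <- tiny_expr(c(1, 2, 3, 4, 5, 6,
                       7, 7, 7, 7, 7, 7), c("m1", "mconst"), samples)
  suppressMessages(t2 <- heuristic_matrix(mrna2, lncrna, purity))
  expect_false("mconst" %in% t2$mrna_id)
  expect_equal(nrow(t2), 3L)

  # < 3 shared samples with purity is an error
  expect_error(
    suppressWarnings(heuristic_matrix(mrna, lncrna, purity[1:2])),
    "insufficient samples")
})

test_that("samples without purity are excluded with a warning", {
  samples <- paste0("s", 1:6)
  set.seed(1)
  mrna <- tiny_expr(rnorm(6, 10), "m1", samples)
  lncrna <- tiny_expr(rnorm(6, 10), "l1", samples)
  purity <- setNames(runif(4, 0.3, 0.9), samples[1:4])
  expect_warning(tr <- heuristic_matrix(mrna, lncrna, purity),
                 "lack tumour purity")
  # correlations must be computed on the 4 purity-covered samples only
  r4 <- pearson_cor(unclass(mrna)[1, 1:4], unclass(lncrna)[1, 1:4])
  expect_equal(tr$R, r4)
})

test_that("planted linear lncRNA outranks all unplanted pairs", {
  for (rep in 1:20) {
    withr::with_seed(100 + rep, {
      n <- 40
      samples <- paste0("s", seq_len(n))
      purity <- setNames(runif(n, 0.3, 0.9), samples)
      m <- matrix(2^rnorm(5 * n, 8), nrow = 5,
                  dimnames = list(paste0("m", 1:5), samples))
      planted <- 2 * m[3, ] + 2^rnorm(n, 4)  # a > 0, purity-independent
      l <- rbind(planted, matrix(2^rnorm(2 * n, 8), nrow = 2))
      dimnames(l) <- list(c("lp", "l1", "l2"), samples)
      tr <- heuristic_matrix(expression_matrix(m), expression_matrix(l),
                             purity)
      target <- tr$H[tr$lncrna_id == "lp" & tr$mrna_id == "m3"]
      expect_gt(target, max(tr$H[!(tr$lncrna_id == "lp" &
                                     tr$mrna_id == "m3")]))
    })
  }
})
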