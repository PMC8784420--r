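# Helper: an expression matrix where every sample has library size 1e6, so
# CPM of the tested gene equals its raw count and log fold changes can be
# controlled exactly.
fixed_library_expr <- function(tumor_counts, normal_counts, gene = "l1") {
  counts <- c(tumor_counts, normal_counts)
  samples <- c(sprintf("t%02d", seq_along(tumor_counts)),
               sprintf("n%02d", seq_along(normal_counts)))
  m <- rbind(counts, 1e6 - counts)
  dimnames(m) <- list(c(gene, "filler"), samples)
  labels <- setNames(c(rep("tumor", length(tumor_counts)),
                       rep("normal", length(normal_counts))), samples)
  list(expr = expression_matrix(m, "toy"), labels = labels)
}

test_that("differential expression recovers a planted multiplicative shift", {
  withr::with_seed(21, {
    base <- 2^rnorm(40, 8)
    fx <- fixed_library_expr(base[1:20] * 4, base[21:40])
  })
  de <- differential_expression(fx$expr, fx$labels, lnc_ids = "l1")
  expect_equal(de$logfc, 2, tolerance = 0.15)
  expect_true(de$is_de)

  # identical group distributions: logFC ~ 0, not DE
  withr::with_seed(22, {
    same <- 2^rnorm(40, 8)
    fx0 <- fixed_library_expr(same[1:20], same[21:40])
  })
  de0 <- differential_expression(fx0$expr, fx0$labels, lnc_ids = "l1")
  # null logFC: |mean difference| within 3 SE of zero (SE ~ sqrt(2/20))
  expect_lt(abs(de0$logfc), 3 * sqrt(2 / 20))
  expect_false(de0$is_de)

  expect_error(
    differential_expression(fx$expr, fx$labels[c(1:2, 21:40)]),
    "insufficient group")
})

test_that("a log fold change of exactly 1.5 is not differentially expressed", {
  # tumor log2(CPM+1) alternates 3 and 4 (mean 3.5, exact in floating
  # point); normal is constant 2, so logFC == 1.5 exactly
  fx <- fixed_library_expr(rep(c(7, 15), 10), rep(3, 20))
  de <- differential_expression(fx$expr, fx$labels, lnc_ids = "l1")
  expect_identical(de$logfc, 1.5)
  expect_lt(de$adj_p, 0.01)
  expect_false(de$is_de)   # strict ">"
  # nudging one tumour sample above the boundary flips the call
  fx2 <- fixed_library_expr(c(rep(c(7, 15), 9), 15, 15), rep(3, 20))
  de2 <- differential_expression(fx2$expr, fx2$labels, lnc_ids = "l1")
  expect_gt(de2$logfc, 1.5)
  expect_true(de2$is_de)
})

test_that("divide-by-max normalisation keeps zeros and the unit maximum", {
  expect_equal(normalize_max(c(a = 4, b = 2, c = 0)),
               c(a = 1, b = 0.5, c = 0))
  expect_equal(normalize_max(c(a = 0, b = 0)), c(a = 0, b = 0))
  expect_equal(normalize_max(c(a = 5)), c(a = 1))
  expect_equal(r_de(c(l1 = 24, l2 = 12)), c(l1 = 1, l2 = 0.5))
})

test_that("R_FC averages |logFC| over DE cancers and guards NC = 0", {
  de <- tibble::tibble(
    lncrna_id = c("l1", "l1", "l2", "l3"),
    cancer = c("c1", "c2", "c1", "c1"),
    logfc = c(4, -2, 1.5, 3), p = 0.001, adj_p = 0.001,
    is_de = c(TRUE, TRUE, TRUE, FALSE))
  out <- r_fc(de, lnc_ids = c("l1", "l2", "l3"))
  expect_equal(out, c(l1 = 1, l2 = 0.5, l3 = 0))  # mean(4,2)=3 -> max
})

test_that("Pscore arithmetic is bounded, exact and monotone", {
  expect_equal(pscore_components(rep(1, 17), 1, 1), 1)
  expect_equal(pscore_components(rep(0, 17), 0, 0), 0)
  expect_equal(pscore_components(c(1, rep(0, 16)), 0, 0), 1 / 19)
  withr::with_seed(31, {
    for (i in 1:50) {
      comp <- runif(19)
      base <- pscore_components(comp[1:17], comp[18], comp[19])
      expect_gte(base, 0); expect_lte(base, 1)
      # increasing any one component never decreases the score
      j <- sample(19, 1)
      bumped <- comp
      bumped[j] <- min(1, bumped[j] + runif(1, 0, 1 - bumped[j]))
      expect_gte(pscore_components(bumped[1:17], bumped[18], bumped[19]),
                 base - 1e-12)
    }
  })
})

test_that("compute_pscores combines pathway counts and DE components", {
  union_tbl <- tibble::tibble(
    lncrna_id = c(rep("lA", 3), "lB"),
    pathway = c("w1", "w1", "w2", "w1"),
    cancer = c("c1", "c2", "c1", "c1"))
  de <- tibble::tibble(
    lncrna_id = c("lA", "lA", "lB"), cancer = c("c1", "c2", "c1"),
    logfc = c(3, 2, 0.1), p = 0.001, adj_p = c(0.001, 0.001, 0.9),
    is_de = c(TRUE, TRUE, FALSE))
  ps <- compute_pscores(union_tbl, de, n_pathways = 17)
  psA <- ps[ps$lncrna_id == "lA", ]
  psB <- ps[ps$lncrna_id == "lB", ]
  # lA: both pathway terms at max (1 + 1), r_de = 1, r_fc = 1 -> 4/19
  expect_equal(psA$pscore, 4 / 19)
  # lB: w1 term 1/2, no DE -> 0.5/19
  expect_equal(psB$pscore, 0.5 / 19)
  expect_equal(psA$nc_total, 2L)
  expect_equal(psB$nc_w1, 1L)
  expect_true(all(ps$pscore >= 0 & ps$pscore <= 1))
  # without DE input both DE components are zero
  ps0 <- compute_pscores(union_tbl, NULL, n_pathways = 17)
  expect_equal(ps0$r_de, c(0, 0))
  expect_equal(ps0$r_fc, c(0, 0))
})

test_that("binning splits preserve sizes in both modes", {
  ps <- tibble::tibble(lncrna_id = sprintf("l%03d", 1:500),
                       pscore = seq(1, 0.002, length.out = 500))
  bins <- rank_and_bin(ps, "equal_count", k = 5)
  expect_equal(as.vector(table(bins$bin)), rep(100L, 5))
  # descending order within the binned frame
  expect_true(all(diff(bins$pscore) <= 0))

  ps7 <- tibble::tibble(lncrna_id = paste0("l", 1:7), pscore = 7:1 / 10)
  b7 <- rank_and_bin(ps7, "equal_count", k = 3)
  expect_equal(as.vector(table(b7$bin)), c(3L, 2L, 2L))

  br <- rank_and_bin(ps7, "equal_range", k = 3)
  expect_equal(sum(table(br$bin)), 7L)
  # equal-range with identical scores: everything in bin 1
  flat <- tibble::tibble(lncrna_id = paste0("l", 1:4), pscore = rep(0.3, 4))
  expect_equal(unique(rank_and_bin(flat, "equal_range", k = 4)$bin), 1L)

  # ties broken lexicographically by id in the descending sort
  tied <- tibble::tibble(lncrna_id = c("z", "a"), pscore = c(0.5, 0.5))
  expect_equal(rank_and_bin(tied, "equal_count", k = 1)$lncrna_id,
               c("a", "z"))
})

test_that("reference overlap counts conserve totals", {
  bins <- rank_and_bin(
    tibble::tibble(lncrna_id = c("l1", "l2", "l3", "l4"),
                   pscore = c(0.9, 0.8, 0.2, 0.1)),
    "equal_count", k = 2)
  ov <- overlap_with_reference(bins, reference = c("l2", "l4"))
  total <- ov[ov$bin == "total", ]
  per_bin <- ov[ov$bin != "total", ]
  expect_equal(total$count, sum(per_bin$count))
  expect_equal(total$count_in_reference, sum(per_bin$count_in_reference))
  expect_equal(per_bin$ratio, c(0.5, 0.5))
  ov0 <- overlap_with_reference(bins, reference = character())
  expect_true(all(ov0$count_in_reference == 0))
})
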