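test_that("ranked lists apply the strict threshold and tie rules", {
  triples <- tibble::tibble(
    lncrna_id = c("l1", "l1", "l1", "l2", "l2", "l3"),
    mrna_id = c("m1", "m2", "m3", "m2", "m1", "m1"),
    H = c(0.9, 0.4, 0.6, 0.7, 0.7, 0.5))
  ranked <- build_ranked_lists(triples, threshold = 0.5)
  expect_equal(ranked$mrna_id[ranked$lncrna_id == "l1"], c("m1", "m3"))
  # tie at 0.7 broken lexicographically by mRNA id
  expect_equal(ranked$mrna_id[ranked$lncrna_id == "l2"], c("m1", "m2"))
  # l3 sits exactly at the threshold: strict, so omitted entirely
  expect_false("l3" %in% ranked$lncrna_id)
  expect_equal(ranked$rank[ranked$lncrna_id == "l1"], 1:2)
})

test_that("enrichment score matches hand-walked running sums", {
  # top gene in the set: +3/3 then misses -1/2 each -> max 1
  expect_equal(enrichment_score(c(3, 2, 1), c(TRUE, FALSE, FALSE)), 1)
  # bottom gene: -1/2, -1, then +1 -> signed max magnitude -1
  expect_equal(enrichment_score(c(3, 2, 1), c(FALSE, FALSE, TRUE)), -1)
  expect_error(enrichment_score(c(3, 2, 1), c(FALSE, FALSE, FALSE)),
               "no overlap")
  # agreement with the independent cumsum oracle on random cases
  withr::with_seed(7, {
    for (i in 1:20) {
      n <- sample(5:40, 1)
      scores <- sort(runif(n, 0.5, 1), decreasing = TRUE)
      hits <- runif(n) < 0.3
      if (!any(hits) || all(hits)) next
      for (w in c(0, 1)) {
        expect_equal(enrichment_score(scores, hits, weight = w),
                     es_oracle(scores, hits, weight = w),
                     tolerance = 1e-12)
      }
    }
  })
})

test_that("reversing a tie-free list negates ES at weight 0", {
  withr::with_seed(11, {
    for (i in 1:10) {
      n <- 12
      scores <- sort(runif(n, 0.5, 1), decreasing = TRUE)
      hits <- rep(FALSE, n)
      hits[sample(n, 4)] <- TRUE
      # skip arrangements where the positive and negative extremes tie in
      # magnitude: there the sign convention, not the statistic, decides
      steps <- ifelse(hits, 1 / 4, -1 / (n - 4))
      runsum <- cumsum(steps)
      if (abs(max(runsum) + min(runsum)) < 1e-9) next
      es_fwd <- enrichment_score(scores, hits, weight = 0)
      es_rev <- enrichment_score(rev(scores), rev(hits), weight = 0)
      expect_equal(es_rev, -es_fwd, tolerance = 1e-12)
    }
  })
})

test_that("permutation p-values are deterministic and enumeration-consistent", {
  scores <- c(0.95, 0.9, 0.8, 0.7, 0.65, 0.6)
  hits <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  r1 <- withr::with_seed(5, permutation_pvalue(scores, hits, n_perm = 5000))
  r2 <- withr::with_seed(5, permutation_pvalue(scores, hits, n_perm = 5000))
  expect_identical(r1, r2)
  expect_error(permutation_pvalue(scores, hits, n_perm = 50),
               "configuration error")

  # exact enumeration over all C(6,2) = 15 hit placements
  p_exact <- exact_enumeration_p(scores, hits)
  mc_se <- sqrt(p_exact * (1 - p_exact) / 5000)
  expect_lt(abs(r1$p - p_exact), 3 * mc_se + 2 / 5001)
  expect_equal(r1$es, es_oracle(scores, hits), tolerance = 1e-12)
})

test_that("the enrichment statistic matches fgsea's preranked score", {
  withr::with_seed(13, {
    for (i in 1:10) {
      n <- sample(8:30, 1)
      scores <- sort(runif(n, 0.5, 1), decreasing = TRUE)
      hits <- rep(FALSE, n)
      hits[sample(n, sample(2:4, 1))] <- TRUE
      ours <- enrichment_score(scores, hits, weight = 1)
      theirs <- fgsea::calcGseaStat(scores, selectedStats = which(hits),
                                    gseaParam = 1)
      expect_equal(ours, theirs, tolerance = 1e-10)
    }
  })
})

test_that("lncRES follows the signed p transform", {
  expect_equal(lncres(0.5, 0.05), 0.9)
  expect_equal(lncres(-0.5, 0.5), 0)
  expect_equal(lncres(0, 0.2), 0.6)  # ES = 0 takes the non-negative branch
  p_grid <- seq(0.001, 1, by = 0.001)
  expect_true(all(abs(lncres(0.7, p_grid)) <= 1))
  expect_true(all(abs(lncres(-0.7, p_grid)) <= 1))
  expect_error(lncres(0.5, 0), "p > 0")
})

test_that("run_enrichment assembles records with per-lncRNA BH", {
  ranked <- tibble::tibble(
    lncrna_id = rep(c("l1", "l2", "l3"), each = 4),
    mrna_id = rep(c("m1", "m2", "m3", "m4"), 3),
    H = rep(c(0.9, 0.8, 0.7, 0.6), 3),
    rank = rep(1:4, 3))
  pathways <- list(p1 = c("m1", "m2"), p2 = c("m4"), p_absent = "zzz")
  rec <- run_enrichment(ranked, pathways, n_perm = 200, seed = 3)
  # cardinality bound: <= lncRNAs x overlapping pathways
  expect_lte(nrow(rec), 6L)
  expect_false("p_absent" %in% rec$pathway)
  expect_true(all(rec$n_hits >= 1))
  expect_equal(unique(rec$list_length), 4L)
  # lncres consistency with its definition
  expect_equal(rec$lncres,
               ifelse(rec$es >= 0, 1 - 2 * rec$nominal_p,
                      2 * rec$nominal_p - 1))
  # iteration-order invariance: same pair seeds regardless of input order
  rec_shuffled <- run_enrichment(ranked[sample(nrow(ranked)), ],
                                 pathways, n_perm = 200, seed = 3)
  expect_equal(as.data.frame(rec), as.data.frame(rec_shuffled))

  # BH hand check within one lncRNA: p = (.01, .02, .03) -> all 0.03
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))

  # max_size excludes oversized pathways
  rec2 <- run_enrichment(ranked, list(pbig = paste0("m", 1:3)),
                         max_size = 2, n_perm = 200, seed = 3)
  expect_equal(nrow(rec2), 0L)
})

test_that("irlncRNA extraction applies strict thresholds", {
  rec <- tibble::tibble(
    lncrna_id = c("a", "b", "c", "d"), pathway = "p",
    es = c(0.9, 0.9, -0.9, 0.9),
    nominal_p = c(0.002, 0.0025, 0.0005, 0.001),
    fdr = c(0.01, 0.01, 0.2, 0.05),
    lncres = c(0.996, 0.995, -0.999, 0.998),
    n_hits = 2L, list_length = 10L, cancer = "c1")
  kept <- extract_irlncrnas(rec)
  expect_equal(kept$lncrna_id, "a")          # b: |lncres| = 0.995 exactly
  # d: fdr = 0.05 exactly -> excluded      # c: fdr above threshold
  # every extracted pair necessarily has nominal p < 0.0025
  expect_true(all(kept$nominal_p < 0.0025))
})

test_that("union bookkeeping preserves pathway-cancer counts", {
  s1 <- tibble::tibble(lncrna_id = c("A"), pathway = "w", cancer = "c1")
  s2 <- tibble::tibble(lncrna_id = c("A", "B"), pathway = "w",
                       cancer = c("c2", "c2"))
  s3 <- tibble::tibble(lncrna_id = "A", pathway = "w", cancer = "c3")
  u <- union_irlncrnas(list(s1, s2, s3))
  expect_equal(sort(unique(u$lncrna_id)), c("A", "B"))
  nc <- pathway_cancer_counts(u)
  expect_equal(nc$nc[nc$lncrna_id == "A" & nc$pathway == "w"], 3L)
  expect_equal(nrow(union_irlncrnas(list())), 0L)
})
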