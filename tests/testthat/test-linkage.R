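test_that("r2 matches hand-computed two-locus cases", {
  # perfect association
  m <- toy_matrix(cbind(c(0, 0, 1, 1), c(0, 0, 1, 1)))
  expect_equal(pairwise_r2(m)[1, 2], 1)
  # independence
  m <- toy_matrix(cbind(c(0, 0, 1, 1), c(0, 1, 0, 1)))
  expect_equal(pairwise_r2(m)[1, 2], 0)
  # D = 0.25 - 0.25*0.5 = 0.125; denom = 0.1875 * 0.25
  m <- toy_matrix(cbind(c(0, 0, 0, 1), c(0, 0, 1, 1)))
  expect_equal(pairwise_r2(m)[1, 2], 1 / 3)
})

test_that("r2 matrix equals the gamete-counting oracle on random matrices", {
  set.seed(91)
  for (i in 1:60) {
    n <- sample(2:6, 1)
    L <- sample(2:4, 1)
    g <- matrix(rbinom(n * L, 1, runif(1, 0.2, 0.8)), n, L)
    m <- toy_matrix(g)
    r2 <- pairwise_r2(m)
    for (a in seq_len(L - 1)) {
      for (b in (a + 1):L) {
        expect_equal(r2[a, b], r2_oracle(g[, a], g[, b]))
      }
    }
    # symmetry and diagonal
    expect_true(isSymmetric(unname(r2)))
    p <- colMeans(g)
    expect_equal(unname(diag(r2)), ifelse(p > 0 & p < 1, 1, NA_real_))
  }
})

test_that("monomorphic pairs are reported missing", {
  m <- toy_matrix(cbind(c(1, 1, 1), c(0, 1, 0)))
  r2 <- pairwise_r2(m)
  expect_true(is.na(r2[1, 2]))
  expect_true(is.na(r2[1, 1]))
  expect_equal(r2[2, 2], 1)
})

test_that("four-gamete flag follows the gamete count", {
  m <- toy_matrix(cbind(c(0, 0, 1, 1), c(0, 1, 0, 1)))
  sc <- four_gamete_scan(m)
  expect_true(sc$pairs$recombination_signal[1])
  expect_equal(sc$pairs$n_distinct_gametes[1], 4L)
  m <- toy_matrix(cbind(c(0, 0, 1), c(0, 1, 1)))
  sc <- four_gamete_scan(m)
  expect_false(sc$pairs$recombination_signal[1])
  expect_equal(sc$n_flagged_pairs, 0L)
  expect_equal(sc$n_events, 0L)
})

test_that("flagged-pair count equals brute-force enumeration", {
  set.seed(17)
  for (i in 1:20) {
    g <- matrix(rbinom(8 * 5, 1, 0.5), 8, 5)
    m <- toy_matrix(g)
    sc <- four_gamete_scan(m)
    brute <- 0L
    for (a in 1:4) {
      for (b in (a + 1):5) {
        gam <- unique(paste(g[, a], g[, b]))
        brute <- brute + (length(gam) == 4L)
      }
    }
    expect_equal(sc$n_flagged_pairs, brute)
    expect_lte(sc$n_events, sc$n_flagged_pairs)
  }
})

test_that("no four-gamete signal on recombination-free tree histories", {
  set.seed(23)
  for (i in 1:100) {
    g <- tree_matrix(n_samples = 10, n_loci = 8)
    sc <- four_gamete_scan(toy_matrix(g))
    expect_equal(sc$n_flagged_pairs, 0L)
  }
})

test_that("interval collapsing merges overlapping flagged pairs", {
  # three samples of loci at 1k,2k,3k: pairs (1,2) and (2,3) flagged
  g <- rbind(c(0, 0, 0), c(0, 1, 1), c(1, 0, 0), c(1, 1, 0),
             c(0, 1, 0), c(1, 1, 1))
  sc <- four_gamete_scan(toy_matrix(g))
  expect_gte(sc$n_flagged_pairs, 2L)
  expect_lt(sc$n_events, sc$n_flagged_pairs)
})

test_that("haplotype classification counts focal derived alleles", {
  K <- 11
  freq <- rbind(rep(1, K), rep(0, K), c(rep(1, 4), rep(0, K - 4)))
  m <- toy_matrix(freq, focal = rep(TRUE, K))
  calls <- classify_haplotype(m)
  expect_equal(as.character(calls$class), c("High", "Low", "intermediate"))
  expect_equal(calls$n_high_alleles, c(11L, 0L, 4L))
  # invariant to locus order
  perm <- sample(K)
  m2 <- toy_matrix(freq[, perm], focal = rep(TRUE, K))
  calls2 <- classify_haplotype(m2)
  expect_equal(calls2$n_high_alleles, calls$n_high_alleles)
  expect_error(classify_haplotype(m, focal_loci = "nope"), "nope")
})

test_that("segregating focal loci are counted inside the band", {
  freq <- rbind(c(1, 1, 0.5), c(0.04, 0.96, 1))
  m <- toy_matrix(freq, focal = rep(TRUE, 3))
  calls <- classify_haplotype(m)
  expect_equal(calls$segregating_focal_count, c(1L, 0L))
})

test_that("coinfection screen flags mixed samples", {
  K <- 11
  pure <- rep(1, K)
  three_seg <- c(rep(0.5, 3), rep(1, K - 3))
  m <- toy_matrix(rbind(pure, three_seg), focal = rep(TRUE, K))
  sc <- coinfection_screen(m)
  expect_equal(sc$status, c("pure", "mixed"))
  # artificial 50:50 merge of a full High and a full Low profile
  merged <- merge_profiles(rep(1, K), rep(0, K), w = 0.5)
  expect_equal(merged, rep(0.5, K))
  m2 <- toy_matrix(rbind(merged, pure), focal = rep(TRUE, K))
  expect_equal(coinfection_screen(m2)$status, c("mixed", "pure"))
})

test_that("profile merging is a weighted average", {
  expect_equal(merge_profiles(c(a = 0.8), c(a = 0.2), w = 0.3), c(a = 0.38))
  expect_equal(merge_profiles(c(1, 0), c(0, 1), w = 1), c(1, 0))
  expect_error(merge_profiles(c(a = 1), c(b = 1), w = 0.5), "locus sets")
  expect_error(merge_profiles(c(1), c(0), w = 1.5), "w")
})

test_that("background partition matches brute-force set logic", {
  pops <- rep(c("A", "B"), each = 4)
  # 8 samples: A High, A Low x3, B High, B Low x3 (2 focal loci define type)
  focal <- rbind(c(1, 1), c(0, 0), c(0, 0), c(0, 0),
                 c(1, 1), c(0, 0), c(0, 0), c(0, 0))
  bg <- cbind(
    c(1, 1, 0, 0, 0, 0, 0, 0),  # private to A, both types -> class a
    c(1, 0, 0, 0, 1, 0, 0, 0),  # High-only, both pops -> class b
    c(0, 1, 0, 0, 0, 1, 0, 0),  # Low-only, both pops -> other
    c(1, 1, 0, 0, 0, 1, 0, 0),  # both pops, both types -> other
    c(0, 0, 0, 0, 0, 0, 0, 0)   # absent -> other
  )
  m <- toy_matrix(cbind(focal, bg), focal = c(TRUE, TRUE, rep(FALSE, 5)))
  part <- partition_background_snps(m, pops)
  expect_equal(unname(part$counts), c(1L, 1L, 3L))
  expect_equal(part$loci$population_private_shared_types,
               m$loci$locus_id[3])
  expect_equal(part$loci$shared_across_pops_high_exclusive,
               m$loci$locus_id[4])
  expect_error(partition_background_snps(m, rep("A", 8)), "2 populations")
})
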