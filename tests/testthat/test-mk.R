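test_that("site polarization follows the outgroup rules", {
  sites <- data.frame(
    gene = "g1",
    functional_class = c("nonsynonymous", "synonymous", "nonsynonymous",
                         "nonsynonymous", "synonymous", "nonsynonymous"),
    focal_alleles = c("TTTTT",   # fixed difference       -> Dn
                      "CCCCC",   # fixed difference       -> Ds
                      "TTTTC",   # polymorphic, minor 1   -> singleton
                      "TTTCC",   # polymorphic, minor 2   -> Pn
                      "AAGGG",   # polymorphic            -> Ps
                      "TTTTT"),  # matches outgroups      -> uninformative
    outgroup1 = c("C", "T", "T", "T", "A", "T"),
    outgroup2 = c("C", "T", "T", "T", "A", "T"),
    stringsAsFactors = FALSE
  )
  counts <- polarize_and_count(sites)
  expect_equal(counts$Dn, 1L)
  expect_equal(counts$Ds, 1L)
  expect_equal(counts$Pn, 1L)
  expect_equal(counts$Ps, 1L)
  # keeping singletons promotes the third site to Pn
  counts2 <- polarize_and_count(sites, drop_singletons = FALSE)
  expect_equal(counts2$Pn, 2L)
  # discordant outgroups are uninformative
  sites$outgroup2[1] <- "G"
  expect_equal(polarize_and_count(sites)$Dn, 0L)
})

test_that("polarized counts match a site-by-site oracle on a 12-site gene", {
  set.seed(4)
  bases <- c("A", "C", "G", "T")
  sites <- data.frame(
    gene = "g1",
    functional_class = sample(c("synonymous", "nonsynonymous"), 12, TRUE),
    focal_alleles = replicate(12, paste(sample(bases[1:2], 8, TRUE,
                                               prob = c(0.7, 0.3)),
                                        collapse = "")),
    outgroup1 = sample(bases[1:2], 12, TRUE),
    outgroup2 = sample(bases[1:2], 12, TRUE),
    stringsAsFactors = FALSE
  )
  counts <- polarize_and_count(sites)
  oracle <- c(Dn = 0, Ds = 0, Pn = 0, Ps = 0)
  for (i in 1:12) {
    al <- strsplit(sites$focal_alleles[i], "")[[1]]
    if (sites$outgroup1[i] != sites$outgroup2[i]) next
    anc <- sites$outgroup1[i]
    nd <- sum(al != anc)
    cls <- if (sites$functional_class[i] == "nonsynonymous") "n" else "s"
    if (nd == length(al)) {
      oracle[paste0("D", cls)] <- oracle[paste0("D", cls)] + 1
    } else if (nd > 1) {
      oracle[paste0("P", cls)] <- oracle[paste0("P", cls)] + 1
    }
  }
  expect_equal(c(Dn = counts$Dn, Ds = counts$Ds, Pn = counts$Pn,
                 Ps = counts$Ps), oracle)
  # invariant to site order
  counts_rev <- polarize_and_count(sites[rev(seq_len(12)), ])
  expect_equal(counts_rev[, -1], counts[, -1])
})

test_that("DoS arithmetic and guards", {
  expect_equal(dos(10, 5, 2, 8), 10 / 15 - 2 / 10, ignore_attr = TRUE)
  expect_equal(dos(4, 4, 7, 7), 0, ignore_attr = TRUE)
  d <- dos(0, 0, 2, 3)
  expect_true(is.na(d))
  expect_equal(attr(d, "reason"), "no substitutions")
  expect_error(dos(-1, 1, 1, 1), ">= 0")
})

test_that("DoS is antisymmetric under swapping divergence and polymorphism", {
  set.seed(9)
  for (i in 1:50) {
    x <- rpois(4, 5) + 1
    expect_equal(dos(x[1], x[2], x[3], x[4]),
                 -dos(x[3], x[4], x[1], x[2]), ignore_attr = TRUE)
  }
})

test_that("background contrast subtracts the median of other genes", {
  tab <- data.frame(gene = c("a", "b", "c"), statistic = c(0.1, 0.2, 0.6),
                    chromosome = "chr2", midpoint = c(1, 2, 3) * 1e4)
  out <- background_contrast(tab, scope = "genome_wide", min_background = 2)
  expect_equal(out$delta, c(0.1 - 0.4, 0.2 - 0.35, 0.6 - 0.15))
  # all equal -> all deltas zero
  tab$statistic <- 0.3
  expect_equal(background_contrast(tab, min_background = 2)$delta,
               rep(0, 3))
})

test_that("local background respects window and chromosome", {
  tab <- data.frame(
    gene = sprintf("g%d", 1:6),
    statistic = c(0.5, 0.1, 0.2, 0.3, 0.9, 0.4),
    chromosome = c(rep("chr2", 5), "chr3"),
    midpoint = c(0, 2e4, 4e4, 6e4, 1e6, 3e4)
  )
  out <- background_contrast(tab, scope = "local", local_window = 1e5,
                             min_background = 3)
  # gene 1 compares to genes 2-4 only (gene 5 too far, gene 6 other chrom)
  expect_equal(out$delta[1], 0.5 - median(c(0.1, 0.2, 0.3)))
  # gene 5 is isolated -> missing
  expect_true(is.na(out$delta[5]))
  # gene 6 alone on chr3 -> missing
  expect_true(is.na(out$delta[6]))
})

test_that("synthetic MK tables recover planted inflation", {
  counts <- generate_mk_counts(
    c(envelope = 120, background = 400),
    category_dn_inflation = c(envelope = 3),
    seed = 21
  )
  expect_equal(nrow(counts), 520L)
  d <- dos(counts)
  expect_gt(mean(d[counts$category == "envelope"], na.rm = TRUE),
            mean(d[counts$category == "background"], na.rm = TRUE))
  # neutral inflation: mean DoS near the DoS of the base expectations
  base <- c(Dn = 8, Ds = 6, Pn = 10, Ps = 12)
  neutral <- generate_mk_counts(c(all = 2000), base_rates = base, seed = 5)
  expect_equal(mean(dos(neutral), na.rm = TRUE),
               dos(base[1], base[2], base[3], base[4]),
               tolerance = 0.05, ignore_attr = TRUE)
  # zero polymorphism expectations give all-zero polymorphism cells
  zp <- generate_mk_counts(c(a = 50), base_rates = c(5, 5, 0, 0), seed = 2)
  expect_true(all(zp$Pn == 0) && all(zp$Ps == 0))
  expect_error(generate_mk_counts(c(a = 10), base_rates = c(-1, 1, 1, 1)),
               "base_rates")
  expect_error(generate_mk_counts(c(a = 10),
                                  category_dn_inflation = c(a = 0)),
               "category_dn_inflation")
})

test_that("category bootstrap flags planted enrichment and spares nulls", {
  counts <- generate_mk_counts(
    c(envelope = 60, background = 300),
    category_dn_inflation = c(envelope = 3),
    seed = 31
  )
  counts$statistic <- dos(counts)
  deltas <- background_contrast(counts, scope = "genome_wide")$delta
  enr <- category_enrichment(deltas, counts$category, n_boot = 2000,
                             seed = 7)
  env <- enr[enr$category == "envelope", ]
  expect_gt(env$mean_delta, 0)
  expect_true(env$excludes_zero && env$lower > 0)
  # single usable category: reported, no contrast implied
  one <- category_enrichment(rnorm(20, 0, 0.05), rep("only", 20),
                             n_boot = 500, seed = 3)
  expect_equal(nrow(one), 1L)
  expect_warning(
    category_enrichment(c(0.1, 0.2, 0.3), c("a", "a", "b"), n_boot = 100,
                        seed = 1),
    "fewer than 2|< 2"
  )
})

test_that("null inflation keeps false enrichment near the nominal rate", {
  hits <- 0L
  n_rep <- 60
  for (i in seq_len(n_rep)) {
    counts <- generate_mk_counts(c(a = 25, b = 25), seed = 1000 + i)
    counts$statistic <- dos(counts)
    deltas <- background_contrast(counts, scope = "genome_wide")$delta
    enr <- suppressWarnings(
      category_enrichment(deltas, counts$category, n_boot = 400,
                          seed = 1000 + i)
    )
    hits <- hits + sum(enr$excludes_zero)
  }
  # ~5% of 120 category intervals should exclude zero; allow generous slack
  expect_lt(hits / (2 * n_rep), 0.15)
})
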