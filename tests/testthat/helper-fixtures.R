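# Shared builders for small, fully-specified test objects.

# A compact cohort configuration that keeps test runtimes low.
small_config <- function(seed = 1L, ...) {
  defaults <- list(
    samples_per_population = c(30L, 30L, 30L, 30L),
    infection_rate_per_population = rep(0.7, 4),
    high_type_freq_per_population = rep(0.5, 4),
    n_background_private = c(5L, 5L, 5L, 5L),
    n_background_shared = 4L,
    n_noise_loci = 30L,
    seed = seed
  )
  do.call(cohort_config, utils::modifyList(defaults, list(...)))
}

# Genotype matrix straight from a 0/1 (or frequency) matrix, with evenly
# spaced positions unless given.
toy_matrix <- function(freq, positions = NULL, focal = NULL) {
  freq <- as.matrix(freq)
  if (is.null(rownames(freq))) {
    rownames(freq) <- sprintf("s%02d", seq_len(nrow(freq)))
  }
  L <- ncol(freq)
  if (is.null(positions)) positions <- seq_len(L) * 1000L
  if (is.null(focal)) focal <- rep(FALSE, L)
  loci <- data.frame(
    locus_id = sprintf("L%06d", positions),
    position = as.integer(positions),
    annotation = rep("intergenic", L),
    gene = sprintf("g%d", seq_len(L)),
    focal = focal,
    focal_order = ifelse(focal, cumsum(focal), NA_integer_)
  )
  genotype_matrix(freq, loci)
}

# Sample table matching a toy matrix: titers supplied per row.
toy_samples <- function(matrix, log10_titer,
                        population = rep("CH", nrow(matrix$freq)),
                        sex = rep(c("M", "F"), length.out = nrow(matrix$freq))) {
  data.frame(
    sample_id = rownames(matrix$freq),
    species = "innubila",
    population = population,
    sex = sex,
    wolbachia = FALSE,
    collection_date = as.Date("2017-08-01"),
    infected = TRUE,
    log10_titer = log10_titer,
    stringsAsFactors = FALSE
  )
}

# Independent step-up oracle for Benjamini-Hochberg q values.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    val <- min(prev, m * p[ord[i]] / i)
    q[ord[i]] <- val
    prev <- val
  }
  q
}

# Independent two-locus r2 oracle by explicit gamete counting.
r2_oracle <- function(a, b) {
  n <- length(a)
  n11 <- sum(a == 1 & b == 1)
  pa <- sum(a) / n
  pb <- sum(b) / n
  if (pa %in% c(0, 1) || pb %in% c(0, 1)) return(NA_real_)
  D <- n11 / n - pa * pb
  D^2 / (pa * (1 - pa) * pb * (1 - pb))
}

# Random laminar clade family on n tips (clades of a random binary tree),
# used to build recombination-free haplotype matrices.
random_clades <- function(tips) {
  if (length(tips) <= 1L) return(list())
  k <- sample.int(length(tips) - 1L, 1L)
  left <- tips[seq_len(k)]
  right <- tips[-seq_len(k)]
  c(list(left, right), random_clades(left), random_clades(right))
}

tree_matrix <- function(n_samples, n_loci) {
  clades <- random_clades(sample(n_samples))
  g <- matrix(0L, n_samples, n_loci)
  for (j in seq_len(n_loci)) {
    cl <- clades[[sample.int(length(clades), 1L)]]
    g[cl, j] <- 1L
  }
  g
}
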