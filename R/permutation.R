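#' Empirical quantile threshold of a permutation null
#'
#' The alpha-quantile of a null distribution, taken as the k-th smallest
#' value with `k = max(1, floor(alpha * n))` — so 1000 null minimum p values
#' at alpha 0.01 give the 10th smallest as the genome-wide significance
#' threshold.
#'
#' @param null_values numeric null draws.
#' @param alpha quantile level.
#' @return The threshold value.
#' @export
empirical_threshold <- function(null_values, alpha) {
  check_probability(alpha, "alpha")
  n <- length(null_values)
  if (n < 1L) stop("empty null", call. = FALSE)
  sort(null_values)[max(1L, floor(alpha * n))]
}

new_perm_null <- function(statistic, null, observed, empirical_p,
                          extra = list()) {
  structure(c(list(statistic = statistic, n_permutations = length(null),
                   null = null, observed = observed,
                   empirical_p = empirical_p), extra),
            class = "perm_null")
}

#' @export
print.perm_null <- function(x, ...) {
  cat(sprintf("permutation null (%s): %d permutations\n", x$statistic,
              x$n_permutations))
  cat(sprintf("  observed = %.6g, empirical p = %.6g\n", x$observed,
              x$empirical_p))
  if (!is.null(x$threshold)) {
    cat(sprintf("  threshold (alpha = %g) = %.6g\n", x$alpha, x$threshold))
  }
  invisible(x)
}

#' Permutation-based genome-wide significance threshold
#'
#' Permutes log10 titer across the analysed samples, refits the association
#' model at every locus per permutation, and records the genome-wide minimum
#' p value. The alpha-quantile of this null minimum-p distribution is the
#' genome-wide significance threshold (family-wise control without assuming
#' independent tests). The observed minimum p is compared to the null by
#' the plus-one rule: `p = (#\{null <= observed\} + 1) / (n + 1)`.
#'
#' @inheritParams fit_titer_gwas
#' @param n_perm number of permutations (values below 100 trigger a
#'   warning).
#' @param alpha threshold level.
#' @param seed integer seed for the permutation stream.
#' @return A `perm_null` object with elements `threshold`, `alpha`, the null
#'   minimum-p draws, the observed minimum p and its empirical p value.
#' @export
minp_permutation_threshold <- function(matrix, samples, n_perm = 1000L,
                                       alpha = 0.01, seed = 1L,
                                       covariates = c("sex", "population"),
                                       n_relationship_components = 5L,
                                       snp_interactions = "sex") {
  if (n_perm < 100L) warning("n_perm < 100: threshold will be unstable")
  prep <- prepare_gwas(matrix, samples, covariates,
                       n_relationship_components, snp_interactions)
  lqs <- lapply(seq_len(ncol(prep$freq)), function(j) locus_qr(prep, j))
  usable <- which(vapply(lqs, function(l) is.null(l$skip), logical(1)))
  if (!length(usable)) stop("no testable loci", call. = FALSE)
  min_p <- function(y) {
    min(vapply(usable, function(j) locus_test(lqs[[j]], y)[["p"]],
               numeric(1)))
  }
  observed <- min_p(prep$y)
  null <- with_seed(derive_seed(seed, "minp_perm"), {
    vapply(seq_len(n_perm), function(i) min_p(sample(prep$y)), numeric(1))
  })
  new_perm_null(
    "min_p", null, observed,
    empirical_p = (sum(null <= observed) + 1) / (n_perm + 1),
    extra = list(threshold = empirical_threshold(null, alpha), alpha = alpha)
  )
}

#' Haplotype permutation test for the High/Low titer difference
#'
#' Tests whether the titer difference between samples carrying a complete
#' High multilocus genotype and samples carrying none of its alleles could
#' arise by chance. Titers are permuted within population; per permutation,
#' a "permuted High haplotype" is assembled from the top-associated SNP
#' (mode `per_perm_top_snp`, refit each permutation) or a fixed focal SNP
#' (mode `fixed_focal`) together with the `n_linked` loci of highest r2 to
#' it; samples carrying all of its derived alleles are compared to samples
#' carrying none, and the mean log10-titer difference forms the null. The
#' empirical p value is `(#\{null >= observed\} + 1) / (n + 1)`.
#'
#' @inheritParams fit_titer_gwas
#' @param n_perm number of permutations.
#' @param mode haplotype anchor per permutation: the permutation's own top
#'   SNP, or a fixed supplied locus.
#' @param focal_locus locus id (required for mode `fixed_focal`).
#' @param n_linked number of loci most strongly linked to the anchor added
#'   to the haplotype.
#' @param min_bin smallest carrier/non-carrier group size for which the
#'   difference is computed (smaller bins give `NA`); matches the
#'   five-carrier minimum of the marker filter, so single-sample flukes do
#'   not masquerade as haplotype effects.
#' @param seed integer seed.
#' @return A `perm_null` object (statistic `high_low_difference`) with the
#'   observed difference, null draws and empirical p value.
#' @export
haplotype_permutation_test <- function(matrix, samples, n_perm = 1000L,
                                       mode = c("per_perm_top_snp",
                                                "fixed_focal"),
                                       focal_locus = NULL, n_linked = 10L,
                                       min_bin = 5L, seed = 1L,
                                       covariates = c("sex", "population"),
                                       n_relationship_components = 5L,
                                       snp_interactions = "sex") {
  mode <- match.arg(mode)
  if (mode == "fixed_focal" && is.null(focal_locus)) {
    stop("mode 'fixed_focal' requires `focal_locus`", call. = FALSE)
  }
  if (ncol(matrix$freq) < n_linked + 1L) {
    stop(sprintf("need >= %d loci", n_linked + 1L), call. = FALSE)
  }
  prep <- prepare_gwas(matrix, samples, covariates,
                       n_relationship_components, snp_interactions)
  g <- (prep$freq >= 0.5) + 0L
  r2 <- pairwise_r2(genotype_matrix(prep$freq, prep$loci))
  lqs <- lapply(seq_len(ncol(prep$freq)), function(j) locus_qr(prep, j))
  usable <- which(vapply(lqs, function(l) is.null(l$skip), logical(1)))
  if (!length(usable)) stop("no testable loci", call. = FALSE)

  top_snp <- function(y) {
    ps <- vapply(usable, function(j) locus_test(lqs[[j]], y)[["p"]],
                 numeric(1))
    usable[which.min(ps)]
  }
  hap_diff <- function(anchor, y) {
    link <- r2[anchor, ]
    link[anchor] <- -Inf
    link[is.na(link)] <- -Inf
    members <- c(anchor, order(link, decreasing = TRUE)[seq_len(n_linked)])
    carried <- rowSums(g[, members, drop = FALSE])
    hi <- carried == length(members)
    lo <- carried == 0L
    if (sum(hi) < min_bin || sum(lo) < min_bin) return(NA_real_)
    mean(y[hi]) - mean(y[lo])
  }
  anchor_obs <- if (mode == "fixed_focal") {
    match_loci(genotype_matrix(prep$freq, prep$loci), focal_locus)
  } else {
    top_snp(prep$y)
  }
  observed <- hap_diff(anchor_obs, prep$y)
  if (is.na(observed)) {
    stop("no samples carry the full haplotype (or its absence); cannot test",
         call. = FALSE)
  }

  pop <- prep$samples$population
  null <- with_seed(derive_seed(seed, "haplotype_perm"), {
    vapply(seq_len(n_perm), function(i) {
      y <- prep$y
      for (pp in unique(pop)) {
        idx <- which(pop == pp)
        y[idx] <- y[sample(idx)]
      }
      anchor <- if (mode == "fixed_focal") anchor_obs else top_snp(y)
      hap_diff(anchor, y)
    }, numeric(1))
  })
  new_perm_null(
    "high_low_difference", null, observed,
    empirical_p = (sum(null >= observed, na.rm = TRUE) + 1) / (n_perm + 1)
  )
}
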