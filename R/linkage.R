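#' Pairwise linkage disequilibrium (r-squared)
#'
#' Computes the standard r2 measure of linkage disequilibrium between all
#' pairs of loci from haploid consensus genotypes:
#' `r2 = (p_AB - p_A p_B)^2 / (p_A (1 - p_A) p_B (1 - p_B))`.
#' Pairs involving a monomorphic locus are undefined and reported as `NA`.
#'
#' @param matrix a [genotype_matrix].
#' @param loci optional locus ids or indices restricting the computation.
#' @return Symmetric matrix of r2 values with locus ids as dimnames; the
#'   diagonal is 1 for polymorphic loci.
#' @export
pairwise_r2 <- function(matrix, loci = NULL) {
  g <- consensus_calls(matrix)
  ids <- matrix$loci$locus_id
  if (!is.null(loci)) {
    idx <- match_loci(matrix, loci)
    g <- g[, idx, drop = FALSE]
    ids <- ids[idx]
  }
  if (nrow(g) < 2L) stop("need >= 2 samples with consensus calls",
                         call. = FALSE)
  n <- nrow(g)
  p <- colMeans(g)
  pab <- crossprod(g) / n           # two-locus derived-derived frequencies
  d <- pab - outer(p, p)
  v <- p * (1 - p)
  out <- d^2 / outer(v, v)
  poly <- v > 0
  out[!poly, ] <- NA_real_
  out[, !poly] <- NA_real_
  out[cbind(which(poly), which(poly))] <- 1
  dimnames(out) <- list(ids, ids)
  out
}

#' Four-gamete screen for recombination
#'
#' For every pair of polymorphic loci, counts the distinct two-locus
#' consensus gametes across samples. Observing all four combinations is
#' incompatible with a single mutation origin per allele on a tree without
#' recombination, so such pairs are flagged as recombination signals. Two
#' genome-wide tallies are returned: the raw number of flagged pairs, and a
#' collapsed event count in which each flagged pair is reduced to its
#' genomic interval and overlapping intervals are merged (a conservative
#' minimum number of distinct recombination events).
#'
#' @param matrix a [genotype_matrix].
#' @param loci optional locus ids or indices restricting the scan.
#' @return List of class `four_gamete_scan`: `pairs` (data.frame: locus_a,
#'   locus_b, pos_a, pos_b, n_distinct_gametes, recombination_signal),
#'   `n_flagged_pairs`, and `n_events` (collapsed intervals).
#' @export
four_gamete_scan <- function(matrix, loci = NULL) {
  idx <- if (is.null(loci)) seq_len(ncol(matrix$freq)) else match_loci(matrix, loci)
  g <- consensus_calls(matrix)[, idx, drop = FALSE]
  info <- matrix$loci[idx, , drop = FALSE]
  L <- ncol(g)
  res <- list()
  k <- 0L
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (j <= i) next
      gam <- unique(g[, i] * 2L + g[, j])
      n <- length(gam)
      k <- k + 1L
      res[[k]] <- c(i, j, n)
    }
  }
  if (k == 0L) {
    pairs <- data.frame(locus_a = character(0), locus_b = character(0),
                        pos_a = integer(0), pos_b = integer(0),
                        n_distinct_gametes = integer(0),
                        recombination_signal = logical(0))
  } else {
    m <- do.call(rbind, res)
    pairs <- data.frame(
      locus_a = info$locus_id[m[, 1]],
      locus_b = info$locus_id[m[, 2]],
      pos_a = info$position[m[, 1]],
      pos_b = info$position[m[, 2]],
      n_distinct_gametes = m[, 3],
      recombination_signal = m[, 3] == 4L,
      stringsAsFactors = FALSE
    )
  }
  flagged <- pairs[pairs$recombination_signal, , drop = FALSE]
  structure(list(
    pairs = pairs,
    n_flagged_pairs = nrow(flagged),
    n_events = count_merged_intervals(flagged$pos_a, flagged$pos_b)
  ), class = "four_gamete_scan")
}

# Merge overlapping [start, end] intervals and count the merged runs.
count_merged_intervals <- function(start, end) {
  if (length(start) == 0L) return(0L)
  ord <- order(start, end)
  start <- start[ord]; end <- end[ord]
  n <- 1L
  cur_end <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] > cur_end) {
      n <- n + 1L
      cur_end <- end[i]
    } else {
      cur_end <- max(cur_end, end[i])
    }
  }
  n
}

#' @export
print.four_gamete_scan <- function(x, ...) {
  cat(sprintf("four-gamete scan: %d pairs tested, %d flagged, %d merged events\n",
              nrow(x$pairs), x$n_flagged_pairs, x$n_events))
  invisible(x)
}

#' Classify samples as High, Low, or intermediate multilocus genotypes
#'
#' Counts the focal derived consensus alleles per sample: carrying all K is
#' the High type, carrying none the Low type, anything else intermediate.
#' Also counts focal loci segregating within the host (within-host frequency
#' strictly inside the segregation band).
#'
#' @param matrix a [genotype_matrix].
#' @param focal_loci locus ids/indices of the focal loci; defaults to the
#'   loci flagged focal in the matrix metadata.
#' @param segregation_band within-host frequency band counted as segregating.
#' @return data.frame: sample_id, n_high_alleles, class (factor High/Low/
#'   intermediate), segregating_focal_count.
#' @export
classify_haplotype <- function(matrix, focal_loci = NULL,
                               segregation_band = c(0.05, 0.95)) {
  if (is.null(focal_loci)) {
    idx <- which(matrix$loci$focal)
    if (!length(idx)) stop("no focal loci flagged in matrix", call. = FALSE)
  } else {
    idx <- match_loci(matrix, focal_loci)
  }
  f <- matrix$freq[, idx, drop = FALSE]
  K <- length(idx)
  n_high <- rowSums(f >= 0.5)
  seg <- rowSums(f > segregation_band[1] & f < segregation_band[2])
  cls <- ifelse(n_high == K, "High", ifelse(n_high == 0, "Low",
                                            "intermediate"))
  data.frame(
    sample_id = rownames(matrix$freq),
    n_high_alleles = as.integer(n_high),
    class = factor(cls, levels = c("High", "intermediate", "Low")),
    segregating_focal_count = as.integer(seg),
    stringsAsFactors = FALSE
  )
}

#' Screen samples for coinfection by both viral types
#'
#' A host coinfected by High- and Low-type virions shows many focal loci at
#' intermediate within-host frequencies. A sample is called mixed when more
#' than `max_segregating` focal loci have frequencies strictly inside the
#' segregation band, pure otherwise.
#'
#' @inheritParams classify_haplotype
#' @param max_segregating largest number of segregating focal loci still
#'   compatible with a pure infection.
#' @return data.frame: sample_id, n_segregating, status ("pure"/"mixed").
#' @export
coinfection_screen <- function(matrix, focal_loci = NULL,
                               segregation_band = c(0.05, 0.95),
                               max_segregating = 2L) {
  calls <- classify_haplotype(matrix, focal_loci, segregation_band)
  data.frame(
    sample_id = calls$sample_id,
    n_segregating = calls$segregating_focal_count,
    status = ifelse(calls$segregating_focal_count > max_segregating,
                    "mixed", "pure"),
    stringsAsFactors = FALSE
  )
}

#' Merge two within-host frequency profiles
#'
#' Weighted mixture of two samples' within-host allele-frequency profiles,
#' emulating an artificial coinfection: `w * f_a + (1 - w) * f_b` per locus.
#'
#' @param freq_a,freq_b named numeric frequency vectors over identical locus
#'   sets.
#' @param w mixture weight of `freq_a` in \[0, 1\].
#' @return Merged frequency vector.
#' @export
merge_profiles <- function(freq_a, freq_b, w = 0.5) {
  check_probability(w, "w")
  if (length(freq_a) != length(freq_b) ||
      (!is.null(names(freq_a)) && !is.null(names(freq_b)) &&
       !identical(names(freq_a), names(freq_b)))) {
    stop("locus sets of the two profiles differ", call. = FALSE)
  }
  w * freq_a + (1 - w) * freq_b
}

#' Partition background SNPs by population and type sharing
#'
#' Classifies every non-focal locus by where its derived consensus allele
#' occurs: (a) `population_private_shared_types` — present in exactly one
#' population, and there in at least one High and one Low sample (the
#' signature of a type that evolved recurrently on a local background);
#' (b) `shared_across_pops_high_exclusive` — present in two or more
#' populations but only ever in High samples; (c) `other`. Samples typed
#' intermediate count toward presence in a population but toward neither
#' type.
#'
#' @param matrix a [genotype_matrix].
#' @param populations character vector: population of each sample (matrix
#'   row order).
#' @param calls haplotype calls from [classify_haplotype]; computed from the
#'   flagged focal loci when omitted.
#' @return List of class `background_partition`: `counts` (named integer
#'   vector over the three classes) and `loci` (list of locus-id vectors per
#'   class).
#' @export
partition_background_snps <- function(matrix, populations, calls = NULL) {
  if (length(unique(populations)) < 2L) {
    stop("need >= 2 populations", call. = FALSE)
  }
  if (length(populations) != nrow(matrix$freq)) {
    stop("`populations` must match the matrix rows", call. = FALSE)
  }
  if (is.null(calls)) calls <- classify_haplotype(matrix)
  g <- consensus_calls(matrix)
  bg <- which(!matrix$loci$focal)
  is_high <- calls$class == "High"
  is_low <- calls$class == "Low"
  cls <- vapply(bg, function(l) {
    carriers <- g[, l] == 1L
    if (!any(carriers)) return("other")
    pops <- unique(populations[carriers])
    if (length(pops) == 1L) {
      if (any(carriers & is_high) && any(carriers & is_low)) {
        return("population_private_shared_types")
      }
      return("other")
    }
    if (all(is_high[carriers])) return("shared_across_pops_high_exclusive")
    "other"
  }, character(1))
  classes <- c("population_private_shared_types",
               "shared_across_pops_high_exclusive", "other")
  counts <- vapply(classes, function(cc) sum(cls == cc), integer(1))
  loci <- lapply(classes, function(cc) matrix$loci$locus_id[bg][cls == cc])
  names(loci) <- classes
  structure(list(counts = counts, loci = loci),
            class = "background_partition")
}

#' @export
print.background_partition <- function(x, ...) {
  cat("background SNP partition:\n")
  for (nm in names(x$counts)) {
    cat(sprintf("  %-38s %d\n", nm, x$counts[[nm]]))
  }
  invisible(x)
}
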