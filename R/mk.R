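#' Polarize per-site calls and accumulate McDonald-Kreitman counts
#'
#' Classifies each site of each gene against two outgroups and accumulates
#' the classic 2x2 McDonald-Kreitman table per gene. A site is a fixed
#' substitution on the focal branch when the focal samples are monomorphic
#' for an allele that differs from the state shared by both outgroups; it is
#' a derived polymorphism when the focal samples vary (optionally requiring
#' the derived allele to be seen more than once, i.e. singletons removed);
#' sites where the two outgroups disagree are uninformative.
#'
#' @param sites data.frame with columns `gene`, `functional_class`
#'   ("synonymous" or "nonsynonymous"), `focal_alleles` (character string,
#'   one letter per focal sample), `outgroup1`, `outgroup2` (single
#'   letters).
#' @param drop_singletons drop polymorphic sites whose derived allele is
#'   carried by exactly one focal sample.
#' @return data.frame of class `mk_counts`: one row per gene with columns
#'   `gene`, `Dn`, `Ds`, `Pn`, `Ps`.
#' @export
polarize_and_count <- function(sites, drop_singletons = TRUE) {
  needed <- c("gene", "functional_class", "focal_alleles", "outgroup1",
              "outgroup2")
  missing_cols <- setdiff(needed, names(sites))
  if (length(missing_cols)) {
    stop(sprintf("`sites` missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (!all(sites$functional_class %in% c("synonymous", "nonsynonymous"))) {
    stop("every site needs functional_class synonymous or nonsynonymous",
         call. = FALSE)
  }
  status <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    status[i] <- polarize_site(sites$focal_alleles[i], sites$outgroup1[i],
                               sites$outgroup2[i], drop_singletons)
  }
  genes <- unique(sites$gene)
  out <- data.frame(gene = genes, Dn = 0L, Ds = 0L, Pn = 0L, Ps = 0L,
                    stringsAsFactors = FALSE)
  nonsyn <- sites$functional_class == "nonsynonymous"
  for (j in seq_along(genes)) {
    g <- sites$gene == genes[j]
    out$Dn[j] <- sum(g & nonsyn & status == "fixed_focal_branch")
    out$Ds[j] <- sum(g & !nonsyn & status == "fixed_focal_branch")
    out$Pn[j] <- sum(g & nonsyn & status == "derived_polymorphic")
    out$Ps[j] <- sum(g & !nonsyn & status == "derived_polymorphic")
  }
  class(out) <- c("mk_counts", "data.frame")
  out
}

# Status of a single site: ancestral state is the allele shared by both
# outgroups; discordant outgroups are uninformative.
polarize_site <- function(focal, out1, out2, drop_singletons) {
  if (is.na(out1) || is.na(out2) || out1 != out2) return("uninformative")
  anc <- out1
  alleles <- strsplit(focal, "")[[1]]
  tab <- table(alleles)
  if (length(tab) == 1L) {
    if (names(tab) != anc) return("fixed_focal_branch")
    return("uninformative")
  }
  derived_n <- sum(alleles != anc)
  if (drop_singletons && derived_n == 1L) return("uninformative")
  "derived_polymorphic"
}

#' Direction of Selection statistic
#'
#' `DoS = Dn / (Dn + Ds) - Pn / (Pn + Ps)`. Positive values indicate an
#' excess of fixed amino-acid substitutions relative to segregating ones
#' (adaptive evolution); zero is the neutral expectation. Undefined when a
#' gene has no substitutions or no polymorphisms.
#'
#' @param Dn,Ds,Pn,Ps nonnegative counts (vectors recycle), or `Dn` may be a
#'   data.frame holding all four columns (e.g. the output of
#'   [polarize_and_count]).
#' @return Numeric vector of DoS values in \[-1, 1\], `NA` where undefined,
#'   with attribute `reason` (character: why each `NA` arose).
#' @export
dos <- function(Dn, Ds = NULL, Pn = NULL, Ps = NULL) {
  if (is.data.frame(Dn)) {
    d <- Dn
    Dn <- d$Dn; Ds <- d$Ds; Pn <- d$Pn; Ps <- d$Ps
  }
  if (any(c(Dn, Ds, Pn, Ps) < 0)) stop("counts must be >= 0", call. = FALSE)
  div <- Dn + Ds
  poly <- Pn + Ps
  out <- ifelse(div > 0 & poly > 0, Dn / div - Pn / poly, NA_real_)
  reason <- rep(NA_character_, length(out))
  reason[div == 0] <- "no substitutions"
  reason[poly == 0] <- "no polymorphisms"
  reason[div == 0 & poly == 0] <- "no substitutions or polymorphisms"
  attr(out, "reason") <- reason
  out
}

#' Contrast a per-gene statistic against the genomic background
#'
#' For each gene, the difference between its statistic and the median of
#' other genes: either all other genes (`scope = "genome_wide"`) or only
#' genes whose midpoints lie within `local_window` bp on the same chromosome
#' (`scope = "local"`). Genes whose comparison set has fewer than
#' `min_background` members get `NA`.
#'
#' @param stats_table data.frame with columns `gene`, `statistic`, and (for
#'   local scope) `chromosome` and `midpoint`.
#' @param scope "genome_wide" or "local".
#' @param local_window bp window for the local background.
#' @param min_background minimum number of background genes required.
#' @return Input data.frame with a `delta` column appended.
#' @export
background_contrast <- function(stats_table, scope = c("genome_wide", "local"),
                                local_window = 100000, min_background = 3L) {
  scope <- match.arg(scope)
  s <- stats_table$statistic
  n <- length(s)
  delta <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (scope == "genome_wide") {
      bg <- s[-i]
    } else {
      same <- stats_table$chromosome == stats_table$chromosome[i]
      near <- abs(stats_table$midpoint - stats_table$midpoint[i]) <= local_window
      bg <- s[same & near & seq_len(n) != i]
    }
    bg <- bg[!is.na(bg)]
    if (length(bg) >= min_background && !is.na(s[i])) {
      delta[i] <- s[i] - stats::median(bg)
    }
  }
  stats_table$delta <- delta
  stats_table
}

#' Bootstrap contrast of per-gene deltas by gene category
#'
#' Resamples genes with replacement within each category and reports the
#' mean background-contrast delta with a percentile bootstrap interval, as a
#' closed-form alternative to model-based category contrasts.
#'
#' @param deltas numeric vector of per-gene deltas (NA dropped).
#' @param categories character vector of gene categories, same length.
#' @param n_boot bootstrap replicates.
#' @param conf interval coverage.
#' @param seed integer seed.
#' @return data.frame: category, n genes, mean delta, lower, upper,
#'   `excludes_zero` flag. Categories with fewer than 2 usable genes are
#'   skipped with a warning.
#' @export
category_enrichment <- function(deltas, categories, n_boot = 10000,
                                conf = 0.95, seed = 1L) {
  if (length(deltas) != length(categories)) {
    stop("`deltas` and `categories` lengths differ", call. = FALSE)
  }
  keep <- !is.na(deltas)
  deltas <- deltas[keep]
  categories <- as.character(categories[keep])
  cats <- unique(categories)
  if (length(cats) < 1L) stop("no usable genes", call. = FALSE)
  with_seed(derive_seed(seed, "category_enrichment"), {
    rows <- lapply(cats, function(cc) {
      x <- deltas[categories == cc]
      if (length(x) < 2L) {
        warning(sprintf("category '%s' has < 2 genes; skipped", cc),
                call. = FALSE)
        return(NULL)
      }
      boots <- vapply(seq_len(n_boot), function(i) {
        mean(sample(x, length(x), replace = TRUE))
      }, numeric(1))
      qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                            names = FALSE)
      data.frame(category = cc, n = length(x), mean_delta = mean(x),
                 lower = qs[1], upper = qs[2],
                 excludes_zero = qs[1] > 0 | qs[2] < 0,
                 stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate synthetic per-gene McDonald-Kreitman count tables
#'
#' Poisson draws around shared base expectations, with the nonsynonymous
#' substitution mean multiplied by a per-category inflation factor (emulating
#' gene classes with an excess of adaptive fixation, e.g. envelope genes).
#' Genes are laid out on two chromosomes with evenly spaced midpoints so the
#' local background contrast is exercisable. Deterministic given `seed`.
#'
#' @param n_genes_per_category named integer vector (names are categories).
#' @param category_dn_inflation named positive multipliers of the Dn mean;
#'   categories not named get 1.
#' @param base_rates numeric length-4 vector of expectations (Dn, Ds, Pn,
#'   Ps).
#' @param seed integer seed.
#' @return data.frame of class `mk_counts`: gene, category, chromosome,
#'   midpoint, Dn, Ds, Pn, Ps.
#' @export
generate_mk_counts <- function(n_genes_per_category,
                               category_dn_inflation = NULL,
                               base_rates = c(Dn = 8, Ds = 6, Pn = 10, Ps = 12),
                               seed = 1L) {
  check_count(n_genes_per_category, "n_genes_per_category")
  if (is.null(names(n_genes_per_category))) {
    stop_field("n_genes_per_category", "must be named by category")
  }
  if (any(base_rates < 0)) stop_field("base_rates", "must be >= 0")
  if (!is.null(category_dn_inflation) && any(category_dn_inflation <= 0)) {
    stop_field("category_dn_inflation", "multipliers must be > 0")
  }
  cats <- rep(names(n_genes_per_category), n_genes_per_category)
  infl <- rep(1, length(cats))
  if (!is.null(category_dn_inflation)) {
    hit <- match(cats, names(category_dn_inflation))
    infl[!is.na(hit)] <- category_dn_inflation[hit[!is.na(hit)]]
  }
  n <- length(cats)
  with_seed(derive_seed(seed, "mk_counts"), {
    out <- data.frame(
      gene = sprintf("g%04d", seq_len(n)),
      category = cats,
      chromosome = rep(c("chr2", "chr3"), length.out = n),
      midpoint = as.integer(20000 * (((seq_len(n) - 1L) %/% 2L) + 1L)),
      Dn = stats::rpois(n, base_rates[1] * infl),
      Ds = stats::rpois(n, base_rates[2]),
      Pn = stats::rpois(n, base_rates[3]),
      Ps = stats::rpois(n, base_rates[4]),
      stringsAsFactors = FALSE
    )
    class(out) <- c("mk_counts", "data.frame")
    out
  })
}
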