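#' Configuration for the synthetic cohort generator
#'
#' Describes a multi-population field survey of flies screened for a DNA
#' virus segregating for two multilocus genotypes ("High" and "Low" types).
#' Defaults emulate the study design the generator targets: four host
#' populations of 57/92/92/92 sampled individuals with infection rates of
#' 26/44/71/79 percent, eleven linked focal SNPs whose full complement raises
#' titer ~100-fold with diminishing returns, population-private background
#' SNPs shared between the two types, a smaller set of High-exclusive SNPs
#' shared across populations, and unlinked noise loci.
#'
#' @param n_populations number of host populations.
#' @param samples_per_population integer vector of per-population sample
#'   sizes.
#' @param infection_rate_per_population per-population probability that a
#'   sampled fly is infected.
#' @param high_type_freq_per_population per-population probability that an
#'   infection is latently High type.
#' @param n_focal_loci number of focal (titer-associated) loci.
#' @param linkage_flip_rate per-focal-locus probability that a sample's
#'   allele is flipped away from its latent type's template, producing
#'   intermediate multilocus genotypes.
#' @param n_background_private integer vector: per-population count of
#'   population-private background loci (carried by all called-High samples
#'   of that population and a random fraction of the others there).
#' @param n_background_shared count of background loci fixed in called-High
#'   samples across all populations and absent elsewhere.
#' @param n_noise_loci count of unlinked loci with population frequency drawn
#'   uniformly on (0.05, 0.5), independent of titer.
#' @param low_carrier_range two-element range for the per-locus fraction of
#'   non-High samples carrying a population-private background locus.
#' @param mu_low_log10_titer mean log10 titer (viral genome copies per host
#'   genome) of a full Low-type infection.
#' @param titer_sd_log10 residual standard deviation of log10 titer.
#' @param full_fold_difference fold difference in titer between full High and
#'   full Low infections.
#' @param diminishing_lambda geometric-saturation rate in (0, 1) of the
#'   per-allele titer gain; smaller values saturate faster.
#' @param genome_length genome length in bp (circular genome, coordinates
#'   treated linearly).
#' @param focal_positions optional integer vector of focal-locus positions;
#'   defaults to `n_focal_loci` positions evenly spread across the genome.
#' @param segregating_locus add a within-host segregating helicase-like locus
#'   whose frequency has a non-monotone (bell-shaped) relation to titer rank.
#' @param segregating_beta_conc concentration of the Beta draw for that
#'   locus' within-host frequency.
#' @param wolbachia_rate probability of endosymbiont carriage (nuisance
#'   covariate).
#' @param seed integer seed; every draw of the generator flows from it.
#'
#' @return A validated object of class `cohort_config`.
#' @export
cohort_config <- function(n_populations = 4L,
                          samples_per_population = c(57L, 92L, 92L, 92L),
                          infection_rate_per_population = c(0.26, 0.44, 0.71, 0.79),
                          high_type_freq_per_population = c(0.30, 0.45, 0.70, 0.75),
                          n_focal_loci = 11L,
                          linkage_flip_rate = 0.01,
                          n_background_private = c(64L, 63L, 161L, 53L),
                          n_background_shared = 12L,
                          n_noise_loci = 1038L,
                          low_carrier_range = c(0.19, 0.94),
                          mu_low_log10_titer = 3.0,
                          titer_sd_log10 = 0.4,
                          full_fold_difference = 100,
                          diminishing_lambda = 0.7,
                          genome_length = 155000L,
                          focal_positions = NULL,
                          segregating_locus = TRUE,
                          segregating_beta_conc = 8,
                          wolbachia_rate = 0.4,
                          seed = 1L) {
  check_count(n_populations, "n_populations", min = 1L)
  check_count(samples_per_population, "samples_per_population", min = 0L)
  if (length(samples_per_population) != n_populations) {
    stop_field("samples_per_population",
               sprintf("must have length %d", n_populations))
  }
  check_probability(infection_rate_per_population,
                    "infection_rate_per_population", n = n_populations)
  check_probability(high_type_freq_per_population,
                    "high_type_freq_per_population", n = n_populations)
  check_count(n_focal_loci, "n_focal_loci", min = 1L)
  check_probability(linkage_flip_rate, "linkage_flip_rate")
  check_count(n_background_private, "n_background_private")
  if (length(n_background_private) == 1L) {
    n_background_private <- rep(n_background_private, n_populations)
  }
  if (length(n_background_private) != n_populations) {
    stop_field("n_background_private",
               sprintf("must have length %d", n_populations))
  }
  check_count(n_background_shared, "n_background_shared")
  check_count(n_noise_loci, "n_noise_loci")
  check_probability(low_carrier_range, "low_carrier_range", n = 2L)
  if (diff(low_carrier_range) < 0) {
    stop_field("low_carrier_range", "must be nondecreasing")
  }
  if (!is.numeric(full_fold_difference) || full_fold_difference <= 1) {
    stop_field("full_fold_difference", "must be > 1")
  }
  if (!is.numeric(diminishing_lambda) || diminishing_lambda <= 0 ||
      diminishing_lambda >= 1) {
    stop_field("diminishing_lambda", "must lie in (0, 1)")
  }
  if (!is.numeric(titer_sd_log10) || titer_sd_log10 < 0) {
    stop_field("titer_sd_log10", "must be >= 0")
  }
  check_count(genome_length, "genome_length", min = 1L)
  if (is.null(focal_positions)) {
    focal_positions <- round(seq(10000, genome_length - 5000,
                                 length.out = n_focal_loci))
  }
  check_count(focal_positions, "focal_positions", min = 1L)
  if (length(focal_positions) != n_focal_loci ||
      any(diff(focal_positions) <= 0)) {
    stop_field("focal_positions",
               "must be strictly increasing with length n_focal_loci")
  }
  check_probability(wolbachia_rate, "wolbachia_rate")
  check_count(seed, "seed")
  structure(list(
    n_populations = as.integer(n_populations),
    samples_per_population = as.integer(samples_per_population),
    infection_rate_per_population = infection_rate_per_population,
    high_type_freq_per_population = high_type_freq_per_population,
    n_focal_loci = as.integer(n_focal_loci),
    linkage_flip_rate = linkage_flip_rate,
    n_background_private = as.integer(n_background_private),
    n_background_shared = as.integer(n_background_shared),
    n_noise_loci = as.integer(n_noise_loci),
    low_carrier_range = low_carrier_range,
    mu_low_log10_titer = mu_low_log10_titer,
    titer_sd_log10 = titer_sd_log10,
    full_fold_difference = full_fold_difference,
    diminishing_lambda = diminishing_lambda,
    genome_length = as.integer(genome_length),
    focal_positions = as.integer(focal_positions),
    segregating_locus = isTRUE(segregating_locus),
    segregating_beta_conc = segregating_beta_conc,
    wolbachia_rate = wolbachia_rate,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Expected log10 titer for a given count of High-type alleles
#'
#' Geometric-saturation curve: carrying k of the K focal derived alleles
#' shifts mean log10 titer by
#' `log10(full_fold_difference) * (1 - lambda^k) / (1 - lambda^K)`,
#' so the gain per extra allele shrinks geometrically (diminishing returns)
#' and the full complement hits the configured fold difference exactly.
#'
#' @param n_high_alleles count of focal derived alleles, 0..K.
#' @param config a [cohort_config].
#' @return Mean log10 titer.
#' @export
titer_mean_log10 <- function(n_high_alleles, config) {
  k <- n_high_alleles
  K <- config$n_focal_loci
  if (any(k < 0) || any(k > K)) {
    stop(sprintf("n_high_alleles must lie in 0..%d", K), call. = FALSE)
  }
  lam <- config$diminishing_lambda
  config$mu_low_log10_titer +
    log10(config$full_fold_difference) * (1 - lam^k) / (1 - lam^K)
}

#' Draw a log10 titer for a sample
#'
#' Normal draw around [titer_mean_log10] with standard deviation
#' `config$titer_sd_log10`. Vectorized over `n_high_alleles`.
#'
#' @inheritParams titer_mean_log10
#' @param config a [cohort_config].
#' @return Numeric vector of log10 titers.
#' @export
sample_titer <- function(n_high_alleles, config) {
  mu <- titer_mean_log10(n_high_alleles, config)
  stats::rnorm(length(mu), mean = mu, sd = config$titer_sd_log10)
}

# Default population labels: the study's four mountain-range sites first.
population_labels <- function(n) {
  base <- c("HU", "SR", "CH", "PR")
  if (n <= length(base)) base[seq_len(n)] else c(base, sprintf("P%02d", seq_len(n - 4L) + 4L))
}

#' Generate a synthetic cohort
#'
#' Draws a seeded multi-population cohort: infection status per sampled fly,
#' a latent viral type (High/Low) per infection with rare per-locus linkage
#' flips producing intermediates, log10 titers from the diminishing-returns
#' curve, and a genotype matrix over focal, background (population-private
#' and shared High-exclusive), noise, and optionally one within-host
#' segregating locus. Deterministic given `config$seed`.
#'
#' @param config a [cohort_config].
#' @return List with `samples` (data.frame: sample_id, species, population,
#'   sex, wolbachia, collection_date, infected, log10_titer) and `genotypes`
#'   (a [genotype_matrix] over the infected samples; zero-row when nothing is
#'   infected).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(derive_seed(config$seed, "cohort"), generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  pops <- population_labels(config$n_populations)
  n_tot <- sum(config$samples_per_population)
  population <- rep(pops, config$samples_per_population)
  samples <- data.frame(
    sample_id = sprintf("%s_%03d", population,
                        unlist(lapply(config$samples_per_population, seq_len))),
    species = "innubila",
    population = population,
    sex = sample(c("M", "F"), n_tot, replace = TRUE),
    wolbachia = stats::runif(n_tot) < config$wolbachia_rate,
    collection_date = as.Date("2017-07-15") +
      sample.int(56L, n_tot, replace = TRUE) - 1L,
    stringsAsFactors = FALSE
  )
  rate <- rep(config$infection_rate_per_population,
              config$samples_per_population)
  samples$infected <- stats::runif(n_tot) < rate
  samples$log10_titer <- NA_real_

  inf <- which(samples$infected)
  loci <- build_locus_table(config)
  if (length(inf) == 0L) {
    freq <- matrix(numeric(0), nrow = 0, ncol = nrow(loci),
                   dimnames = list(NULL, loci$locus_id))
    return(list(samples = samples,
                genotypes = genotype_matrix(freq, loci)))
  }

  hi_freq <- rep(config$high_type_freq_per_population,
                 config$samples_per_population)[inf]
  latent_high <- stats::runif(length(inf)) < hi_freq

  K <- config$n_focal_loci
  template <- matrix(rep(as.integer(latent_high), each = K),
                     nrow = length(inf), ncol = K, byrow = TRUE)
  flips <- matrix(stats::runif(length(inf) * K) < config$linkage_flip_rate,
                  nrow = length(inf))
  focal_geno <- abs(template - flips)  # toggled away from the type template
  n_high <- rowSums(focal_geno)
  samples$log10_titer[inf] <- sample_titer(n_high, config)

  called_high <- n_high == K
  called_low <- n_high == 0L
  pop_inf <- samples$population[inf]

  n_loci <- nrow(loci)
  freq <- matrix(0, nrow = length(inf), ncol = n_loci,
                 dimnames = list(samples$sample_id[inf], loci$locus_id))
  # focal positions are strictly increasing, so mutational order equals
  # position order in the locus table
  freq[, loci$focal] <- focal_geno

  # population-private background: all called-High of the population carry
  # it; each remaining sample of the population carries it with a per-locus
  # fraction drawn uniformly from low_carrier_range.
  lc <- config$low_carrier_range
  for (j in seq_len(config$n_populations)) {
    idx <- which(loci$annotation_class == "background_private" &
                   loci$private_population == pops[j])
    in_pop <- pop_inf == pops[j]
    others <- which(in_pop & !called_high)
    lows <- others[called_low[others]]
    for (l in idx) {
      f <- stats::runif(1, lc[1], lc[2])
      pick <- integer(0)
      if (length(others)) {
        n_carry <- min(length(others), max(1L, round(f * length(others))))
        pick <- others[sample.int(length(others), n_carry)]
        # construction guarantee: shared between the two types whenever the
        # population has a called-Low sample at all
        if (length(lows) && !any(pick %in% lows)) {
          pick[1] <- lows[sample.int(length(lows), 1L)]
        }
      }
      freq[c(which(in_pop & called_high), pick), l] <- 1
    }
  }

  # shared High-exclusive background: carried by a random subset of
  # called-High samples spanning at least two populations (only the focal
  # loci themselves are in every High sample)
  shared_idx <- which(loci$annotation_class == "background_shared")
  highs <- which(called_high)
  if (length(shared_idx) && length(highs)) {
    high_pops <- pop_inf[highs]
    for (l in shared_idx) {
      f <- stats::runif(1, 0.3, 0.8)
      n_carry <- min(length(highs), max(2L, round(f * length(highs))))
      pick <- highs[sample.int(length(highs), n_carry)]
      if (length(unique(high_pops)) >= 2L &&
          length(unique(pop_inf[pick])) < 2L) {
        other <- highs[high_pops != pop_inf[pick[1]]]
        pick[2] <- other[sample.int(length(other), 1L)]
      }
      freq[pick, l] <- 1
    }
  }

  noise_idx <- which(loci$annotation_class == "noise")
  for (l in noise_idx) {
    f <- stats::runif(1, 0.05, 0.5)
    freq[stats::runif(length(inf)) < f, l] <- 1
  }

  seg_idx <- which(loci$annotation_class == "segregating")
  if (length(seg_idx)) {
    # bell-shaped relation between titer rank and within-host frequency
    r <- (rank(samples$log10_titer[inf]) - 0.5) / length(inf)
    mode <- 0.9 * 4 * r * (1 - r)
    cc <- config$segregating_beta_conc
    freq[, seg_idx] <- stats::rbeta(length(inf), 1 + cc * mode,
                                    1 + cc * (1 - mode))
  }

  list(samples = samples, genotypes = genotype_matrix(freq, loci))
}

# Assemble per-locus metadata: positions, annotations, and the generator's
# locus classes (focal / background_private / background_shared / noise /
# segregating, the latter carried in `annotation_class`).
build_locus_table <- function(config) {
  pops <- population_labels(config$n_populations)
  ann_cycle <- c("nonsynonymous", "upstream", "intergenic", "upstream",
                 "synonymous", "downstream")
  classes <- c(
    rep("focal", config$n_focal_loci),
    rep("background_private", sum(config$n_background_private)),
    rep("background_shared", config$n_background_shared),
    rep("noise", config$n_noise_loci),
    if (config$segregating_locus) "segregating"
  )
  priv_pop <- c(
    rep(NA_character_, config$n_focal_loci),
    rep(pops, config$n_background_private),
    rep(NA_character_, length(classes) - config$n_focal_loci -
          sum(config$n_background_private))
  )
  n_other <- length(classes) - config$n_focal_loci
  # non-focal positions: deterministic low-discrepancy fill of the genome,
  # shifted off the focal positions
  other_pos <- round(seq(501, config$genome_length - 250,
                         length.out = max(n_other, 1)))
  if (n_other > 0) {
    taken <- config$focal_positions
    for (i in seq_along(other_pos)) {
      while (other_pos[i] %in% taken) other_pos[i] <- other_pos[i] + 1L
      taken <- c(taken, other_pos[i])
    }
  } else {
    other_pos <- integer(0)
  }
  pos <- c(config$focal_positions, other_pos)
  ord <- order(pos)
  classes <- classes[ord]
  priv_pop <- priv_pop[ord]
  pos <- pos[ord]
  focal <- classes == "focal"
  focal_order <- rep(NA_integer_, length(pos))
  focal_order[focal] <- seq_len(sum(focal))
  annotation <- ann_cycle[(seq_along(pos) - 1L) %% length(ann_cycle) + 1L]
  annotation[classes == "segregating"] <- "nonsynonymous"
  loci <- data.frame(
    locus_id = sprintf("L%06d", pos),
    position = as.integer(pos),
    annotation = annotation,
    gene = sprintf("gene%03d", ((pos - 1L) %/% 2000L) + 1L),
    focal = focal,
    focal_order = focal_order,
    annotation_class = classes,
    private_population = priv_pop,
    stringsAsFactors = FALSE
  )
  rownames(loci) <- NULL
  loci
}
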