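#' Parameters of the titer-scaled susceptible-infected simulator
#'
#' Discrete-generation SI dynamics of a DNA virus in a host population of
#' fixed size `N`, tracking for every infected host which of `K` ordered
#' titer-raising mutations its virus carries. Viral titer multiplies both
#' the transmission probability (`beta0 * titer`) and, through the
#' virulence exponent `a`, the host removal probability
#' (`gamma0 * titer^a`), and scales the per-variant mutation supply
#' (`mu_variant * titer`, the rate being per viral particle). Mutations
#' confer their multiplicative titer gain only in order: a mutation arriving
#' before its predecessors adds nothing until they arrive. Recombination
#' swaps genotype suffixes between randomly paired viral genomes at
#' `recomb_rate` per adjacent-locus interval per generation, and is not
#' scaled by titer.
#'
#' @param N host population size.
#' @param beta0 transmission coefficient per generation at titer 1.
#' @param gamma0 removal coefficient per generation at titer 1.
#' @param virulence_exponent exponent `a` of titer in the removal
#'   probability. At `a = 1` (the literal reading: both infection and
#'   virulence multiplied by titer) the reproductive value of a genotype is
#'   titer-independent and no mutation is favoured; the default 0.5 makes
#'   higher titer a net transmission advantage, consistent with the higher
#'   basic reproduction number of the high-titer type.
#' @param mu_variant per-variant per-generation mutation probability at
#'   titer 1 (default 3.3e-7 = 1e-6 per base times 1/3 for the correct
#'   change).
#' @param K number of focal mutations simulated.
#' @param gains multiplicative titer gain of each mutation in order;
#'   strictly decreasing and > 1 (diminishing epistatic returns; the default
#'   product 112.5 is about the observed ~100-fold full-type difference).
#' @param T0 baseline titer of the unmutated (Low) virus.
#' @param recomb_rate probability per adjacent-locus interval per sampled
#'   pair per generation of a suffix swap.
#' @param init_infected_freq initial fraction of hosts infected with the
#'   unmutated virus (`init = "frequency"`).
#' @param init `"frequency"` (default) or `"single"` for one initial
#'   infected host (1/N).
#' @param max_generations hard cap per replicate.
#' @param n_replicates number of replicates for [run_replicates].
#' @param fixation_threshold carrier frequency among infected hosts at
#'   which a mutation is recorded fixed.
#' @param establishment_rule `"drift_barrier"`: a mutation is established
#'   when its carrier count first reaches `1/(2 s_k)`, with
#'   `s_k = (T_k/T_{k-1})^(1-a) - 1` the selective advantage implied by the
#'   consecutive-prefix titers (the standard scale at which a beneficial
#'   mutation escapes stochastic loss); `"absolute"`: a fixed carrier count.
#' @param establishment_count carrier count for the absolute rule.
#' @param seed integer master seed; replicate r uses a sub-seed derived
#'   from it.
#'
#' @return A validated object of class `sim_params` with precomputed
#'   genotype-class tables (titer per class, establishment thresholds,
#'   recombination swap masks).
#' @export
sim_params <- function(N = 1e6, beta0 = 0.1, gamma0 = 0.1,
                       virulence_exponent = 0.5, mu_variant = 3.3e-7,
                       K = 5L, gains = c(10, 3, 2, 1.5, 1.25), T0 = 1,
                       recomb_rate = 0.02, init_infected_freq = 0.10,
                       init = c("frequency", "single"),
                       max_generations = 100000L, n_replicates = 1000L,
                       fixation_threshold = 0.99,
                       establishment_rule = c("drift_barrier", "absolute"),
                       establishment_count = 100L, seed = 1L) {
  init <- match.arg(init)
  establishment_rule <- match.arg(establishment_rule)
  check_count(N, "N", min = 1L)
  check_count(K, "K", min = 1L)
  if (K > 12L) stop_field("K", "genotype-class implementation supports K <= 12")
  if (length(gains) != K) stop_field("gains", sprintf("must have length %d", K))
  if (any(gains <= 1) || (K > 1 && any(diff(gains) >= 0))) {
    stop_field("gains", "must be strictly decreasing and > 1")
  }
  if (beta0 < 0 || gamma0 < 0) stop_field("beta0/gamma0", "must be >= 0")
  check_probability(mu_variant, "mu_variant")
  check_probability(recomb_rate, "recomb_rate")
  check_probability(init_infected_freq, "init_infected_freq")
  check_probability(fixation_threshold, "fixation_threshold")
  check_count(max_generations, "max_generations", min = 1L)
  check_count(n_replicates, "n_replicates", min = 1L)
  check_count(seed, "seed")

  n_classes <- 2L^K
  cls <- 0:(n_classes - 1L)
  bit <- 2L^(0:(K - 1L))
  has <- outer(cls, bit, function(c, b) bitwAnd(c, b) > 0)  # class x locus
  prefix_len <- apply(has, 1, function(h) {
    m <- 0L
    for (k in seq_len(K)) {
      if (!h[k]) break
      m <- k
    }
    m
  })
  prefix_titer <- T0 * cumprod(c(1, gains))     # titer with prefix 0..K
  titer <- prefix_titer[prefix_len + 1L]
  a <- virulence_exponent
  s_k <- (prefix_titer[-1] / prefix_titer[-(K + 1L)])^(1 - a) - 1
  establish_thr <- switch(establishment_rule,
    drift_barrier = ifelse(s_k > 0, pmax(1, ceiling(1 / (2 * s_k))), Inf),
    absolute = rep(establishment_count, K)
  )
  # suffix-swap masks: crossing over at interval j exchanges loci j+1..K;
  # locus i is exchanged iff an odd number of chosen intervals lie before it
  n_masks <- 2L^(K - 1L)
  ex_mask <- integer(n_masks)
  if (K > 1L) {
    for (m in 0:(n_masks - 1L)) {
      ex <- 0L
      for (i in seq_len(K)) {
        before <- bitwAnd(m, 2L^(i - 1L) - 1L)
        if (sum(bitwAnd(before, 2L^(0:(K - 2L))) > 0) %% 2L == 1L) {
          ex <- ex + bit[i]
        }
      }
      ex_mask[m + 1L] <- ex
    }
    n_cross <- vapply(0:(n_masks - 1L), function(m) {
      sum(bitwAnd(m, 2L^(0:(K - 2L))) > 0)
    }, numeric(1))
    mask_prob <- recomb_rate^n_cross * (1 - recomb_rate)^(K - 1 - n_cross)
  } else {
    ex_mask <- 0L
    mask_prob <- 1
  }

  structure(list(
    N = N, beta0 = beta0, gamma0 = gamma0, virulence_exponent = a,
    mu_variant = mu_variant, K = as.integer(K), gains = gains, T0 = T0,
    recomb_rate = recomb_rate, init_infected_freq = init_infected_freq,
    init = init, max_generations = as.integer(max_generations),
    n_replicates = as.integer(n_replicates),
    fixation_threshold = fixation_threshold,
    establishment_rule = establishment_rule,
    establishment_count = establishment_count, seed = as.integer(seed),
    # precomputed tables
    n_classes = n_classes, bit = bit, has = has,
    prefix_ge = outer(prefix_len, seq_len(K), ">="), titer = titer,
    prefix_titer = prefix_titer, s_k = s_k, establish_thr = establish_thr,
    ex_mask = ex_mask, mask_prob = mask_prob,
    p_any_swap = if (K > 1L) 1 - mask_prob[1] else 0,
    mask_prob_swap = if (K > 1L && sum(mask_prob[-1]) > 0)
      mask_prob[-1] / sum(mask_prob[-1]) else mask_prob[-1],
    pair_idx = lapply(seq_len(n_classes), function(np)
      if (np >= 2L) utils::combn(np, 2L) else matrix(integer(0), 2, 0)),
    p_death = pmin(1, gamma0 * titer^a),
    p_mut = pmin(1, mu_variant * titer)
  ), class = "sim_params")
}

#' Titer of a multilocus viral genotype
#'
#' Multiplicative gains apply only along the maximal prefix of consecutive
#' derived mutations starting at the first locus; out-of-order mutations
#' contribute nothing until their predecessors arrive.
#'
#' @param g binary vector of length `K` (1 = mutation present).
#' @param params a [sim_params].
#' @return The titer.
#' @export
titer_of_genotype <- function(g, params) {
  if (length(g) != params$K || !all(g %in% c(0, 1))) {
    stop(sprintf("g must be binary of length %d", params$K), call. = FALSE)
  }
  m <- 0L
  for (k in seq_along(g)) {
    if (g[k] != 1) break
    m <- k
  }
  params$prefix_titer[m + 1L]
}

#' Deterministic discrete susceptible-infected trajectory
#'
#' Iterates `I' = I + S * I * beta - I * gamma` with `S = 1 - I` on
#' proportions, clipped to \[0, 1\]. Converges to the endemic equilibrium
#' `I* = max(0, 1 - gamma / beta)`.
#'
#' @param beta transmission coefficient per generation.
#' @param gamma removal coefficient per generation.
#' @param i0 initial infected proportion in (0, 1).
#' @param n_steps generations to iterate.
#' @return data.frame with columns `step`, `S`, `I`.
#' @export
si_deterministic <- function(beta, gamma, i0, n_steps) {
  stopifnot(beta >= 0, gamma >= 0, i0 > 0, i0 < 1, n_steps >= 1)
  I <- numeric(n_steps + 1L)
  I[1] <- i0
  for (t in seq_len(n_steps)) {
    s <- 1 - I[t]
    I[t + 1L] <- min(1, max(0, I[t] + s * I[t] * beta - I[t] * gamma))
  }
  data.frame(step = 0:n_steps, S = 1 - I, I = I)
}

#' Initial simulator state
#'
#' All infected hosts start with the unmutated (Low) genotype: a fraction
#' `init_infected_freq` of the population, or a single host when
#' `params$init == "single"`.
#'
#' @param params a [sim_params].
#' @return An object of class `sim_state`.
#' @export
sim_state_init <- function(params) {
  I <- numeric(params$n_classes)
  I[1] <- if (params$init == "single") 1 else round(params$N * params$init_infected_freq)
  structure(list(
    gen = 0L,
    S = params$N - I[1],
    I = I,
    t_first = rep(NA_real_, params$K),
    t_establish = rep(NA_real_, params$K),
    t_fix = rep(NA_real_, params$K),
    full_first_via = NA_character_,
    n_clipped = 0L
  ), class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("sim_state: generation %d, S = %g, infected = %g (%d classes occupied)\n",
              x$gen, x$S, sum(x$I), sum(x$I > 0)))
  invisible(x)
}

#' Advance the simulator by one generation
#'
#' Applies, in order: titer-scaled transmission (binomial draws per genotype
#' class), titer-scaled removal (dead hosts return to the susceptible pool),
#' titer-scaled mutation of each absent variant, and suffix-swap
#' recombination between randomly paired viral genomes; then records
#' per-mutation first-appearance, establishment and fixation generations.
#' Draws come from the current RNG state; seed beforehand for
#' reproducibility.
#'
#' @param state a `sim_state`.
#' @param params the matching [sim_params].
#' @return The updated `sim_state`.
#' @export
step_generation <- function(state, params) {
  p <- params
  I <- state$I
  S <- state$S
  N <- p$N
  active <- which(I > 0)

  # (i) transmission as competing risks: each susceptible is infected with
  # probability given by the total force of infection and assigned a source
  # class in proportion to its per-class force beta0 * T_g * I_g / N.
  # Equal in law to independent per-class binomials while the total force
  # is small; unlike capped per-class draws it preserves the between-class
  # fitness ordering when the force saturates.
  # (ii) removal is drawn from the same generation-start counts (parallel
  # update, matching I' = I + S*I*beta - I*gamma), so the discrete growth
  # factor of a class is 1 + beta*T*S/N - gamma*T^a; dead hosts are
  # replaced by susceptibles.
  if (length(active)) {
    force_g <- p$beta0 * p$titer[active] * I[active] / N
    force <- sum(force_g)
    new_tot <- 0
    new_inf <- numeric(length(active))
    if (force > 0 && S > 0) {
      if (force > 1) state$n_clipped <- state$n_clipped + 1L
      new_tot <- stats::rbinom(1, S, min(1, force))
      if (new_tot > 0) {
        new_inf <- if (length(active) == 1L) new_tot else
          as.vector(stats::rmultinom(1, new_tot, force_g / force))
      }
    }
    deaths <- stats::rbinom(length(active), I[active], p$p_death[active])
    I[active] <- I[active] + new_inf - deaths
    S <- S - new_tot + sum(deaths)
  }

  # (iii) mutation: each absent variant flips independently, rate scaled by
  # the class titer (out-of-order mutations allowed)
  active <- which(I > 0)
  full <- p$n_classes
  full_was_empty <- I[full] == 0
  if (any(p$p_mut[active] > 0)) {
    src <- rep(active, p$K - rowSums(p$has[active, , drop = FALSE]))
    loc <- unlist(lapply(active, function(g) which(!p$has[g, ])),
                  use.names = FALSE)
    if (length(src)) {
      m <- stats::rbinom(length(src), I[src], p$p_mut[src])
      for (q in which(m > 0)) {
        mm <- min(m[q], I[src[q]])
        I[src[q]] <- I[src[q]] - mm
        I[src[q] + p$bit[loc[q]]] <- I[src[q] + p$bit[loc[q]]] + mm
      }
    }
  }
  if (full_was_empty && I[full] > 0) state$full_first_via <- "mutation"
  full_was_empty <- I[full] == 0

  # (iv) recombination: random pairing of viral genomes; only cross-class
  # pairs with at least one interval swap can change counts
  if (p$recomb_rate > 0 && p$K > 1) {
    active <- which(I > 0)
    itot <- sum(I)
    if (length(active) >= 2 && itot >= 2 && itot <= 2000) {
      # small infected pool: draw the random perfect matching explicitly
      labels <- rep.int(active, I[active])
      labels <- labels[sample.int(length(labels))]
      M2 <- (length(labels) %/% 2L) * 2L
      g1 <- labels[seq.int(1L, M2, by = 2L)]
      g2 <- labels[seq.int(2L, M2, by = 2L)]
      cross <- which(g1 != g2)
      if (length(cross)) {
        rec <- cross[stats::runif(length(cross)) < p$p_any_swap]
        for (q in rec) {
          mi <- sample.int(length(p$mask_prob_swap), 1L,
                           prob = p$mask_prob_swap)
          ex <- p$ex_mask[mi + 1L]
          g <- g1[q]; h <- g2[q]
          g0 <- g - 1L; h0 <- h - 1L
          g2n <- bitwOr(bitwAnd(g0, bitwNot(ex)), bitwAnd(h0, ex)) + 1L
          h2n <- bitwOr(bitwAnd(h0, bitwNot(ex)), bitwAnd(g0, ex)) + 1L
          if (g2n == g && h2n == h) next
          I[g] <- I[g] - 1
          I[h] <- I[h] - 1
          I[g2n] <- I[g2n] + 1
          I[h2n] <- I[h2n] + 1
        }
      }
    } else if (length(active) >= 2 && itot > 2000) {
      M <- itot %/% 2
      pr <- I[active] / itot
      np <- length(active)
      pairs <- p$pair_idx[[np]]
      p_pair <- 2 * pr[pairs[1, ]] * pr[pairs[2, ]]
      counts <- as.vector(stats::rmultinom(1, M, c(p_pair, 1 - sum(p_pair))))
      n_pairs <- ncol(pairs)
      # two-stage: first how many pairs recombine at all, then which masks
      n_rec <- stats::rbinom(n_pairs, counts[seq_len(n_pairs)], p$p_any_swap)
      for (q in which(n_rec > 0)) {
        g <- active[pairs[1, q]]
        h <- active[pairs[2, q]]
        by_mask <- as.vector(stats::rmultinom(1, n_rec[q], p$mask_prob_swap))
        for (mi in which(by_mask > 0)) {
          ex <- p$ex_mask[mi + 1L]
          if (ex == 0L) next
          n <- min(by_mask[mi], I[g], I[h])
          if (n <= 0) next
          g0 <- g - 1L; h0 <- h - 1L
          g2 <- bitwOr(bitwAnd(g0, bitwNot(ex)), bitwAnd(h0, ex)) + 1L
          h2 <- bitwOr(bitwAnd(h0, bitwNot(ex)), bitwAnd(g0, ex)) + 1L
          if (g2 == g && h2 == h) next
          I[g] <- I[g] - n
          I[h] <- I[h] - n
          I[g2] <- I[g2] + n
          I[h2] <- I[h2] + n
        }
      }
    }
  }
  if (full_was_empty && I[full] > 0) state$full_first_via <- "recombination"

  # (v) event recording: first appearance counts any background;
  # establishment and fixation count in-order carriers (mutation k together
  # with all its predecessors), since only those enjoy the titer gain whose
  # selective advantage defines the establishment threshold
  gen <- state$gen + 1L
  itot <- sum(I)
  carriers_any <- as.vector(crossprod(I, p$has))
  carriers <- as.vector(crossprod(I, p$prefix_ge))
  newly <- is.na(state$t_first) & carriers_any > 0
  state$t_first[newly] <- gen
  newly <- is.na(state$t_establish) & carriers >= p$establish_thr
  state$t_establish[newly] <- gen
  if (itot > 0) {
    newly <- is.na(state$t_fix) & carriers / itot >= p$fixation_threshold
    state$t_fix[newly] <- gen
  }
  state$gen <- gen
  state$S <- S
  state$I <- I
  state
}

#' Run replicate simulations
#'
#' Runs `params$n_replicates` independent replicates, each from a sub-seed
#' derived from `params$seed`, stopping a replicate once every mutation has
#' fixed (or at extinction / `max_generations`). Summaries report the
#' per-mutation establishment waits, the fraction of replicates whose first
#' mutation establishes within 1000 generations, the latest full fixation,
#' and how often the full genotype was first assembled by recombination.
#'
#' @param params a [sim_params].
#' @param progress print a dot every 100 replicates.
#' @return Object of class `si_sim`: matrices `t_first`, `t_establish`,
#'   `t_fix` (replicates x mutations, NA = censored), logical
#'   `recombination_assembled`, numeric `final_full_freq`, integer
#'   `final_generation`, the `params`, and a `summary` list.
#' @export
run_replicates <- function(params, progress = FALSE) {
  R <- params$n_replicates
  K <- params$K
  t_first <- t_establish <- t_fix <- matrix(NA_real_, R, K)
  rec_asm <- logical(R)
  final_freq <- numeric(R)
  final_gen <- integer(R)
  for (r in seq_len(R)) {
    st <- with_seed(derive_seed(params$seed, paste0("replicate", r)),
                    run_one_replicate(params))
    t_first[r, ] <- st$t_first
    t_establish[r, ] <- st$t_establish
    t_fix[r, ] <- st$t_fix
    rec_asm[r] <- identical(st$full_first_via, "recombination")
    itot <- sum(st$I)
    final_freq[r] <- if (itot > 0) st$I[params$n_classes] / itot else 0
    final_gen[r] <- st$gen
    if (progress && r %% 100L == 0L) cat(".")
  }
  if (progress) cat("\n")
  out <- structure(list(
    t_first = t_first, t_establish = t_establish, t_fix = t_fix,
    recombination_assembled = rec_asm, final_full_freq = final_freq,
    final_generation = final_gen, params = params
  ), class = "si_sim")
  out$summary <- summarize_si_sim(out)
  out
}

run_one_replicate <- function(params) {
  st <- sim_state_init(params)
  while (st$gen < params$max_generations) {
    st <- step_generation(st, params)
    if (!anyNA(st$t_fix)) break
    if (sum(st$I) == 0) break
  }
  st
}

summarize_si_sim <- function(x) {
  waits <- summarize_wait_times(x)
  full_fix <- apply(x$t_fix, 1, max)   # NA when any mutation censored
  list(
    wait_times = waits,
    frac_establish_first_1000 =
      mean(!is.na(x$t_establish[, 1]) & x$t_establish[, 1] <= 1000),
    max_full_fixation = if (all(is.na(full_fix))) NA_real_ else
      max(full_fix, na.rm = TRUE),
    n_censored_full_fixation = sum(is.na(full_fix)),
    n_recombination_assembled = sum(x$recombination_assembled)
  )
}

#' @export
print.si_sim <- function(x, ...) {
  s <- x$summary
  cat(sprintf("si_sim: %d replicates, K = %d, N = %g\n",
              nrow(x$t_fix), x$params$K, x$params$N))
  cat(sprintf("  first establishment <= 1000 generations: %.2f%% of replicates\n",
              100 * s$frac_establish_first_1000))
  cat(sprintf("  latest full fixation: generation %s (%d censored)\n",
              format(s$max_full_fixation), s$n_censored_full_fixation))
  cat(sprintf("  full genotype first assembled by recombination in %d replicates\n",
              s$n_recombination_assembled))
  cat("  mean establishment waits by mutation index:\n    ")
  cat(format(round(s$wait_times$mean_wait, 1)), sep = "  ")
  cat("\n")
  invisible(x)
}

#' Per-mutation establishment wait times
#'
#' Wait `k` is `t_establish(k) - t_establish(k - 1)` (with
#' `t_establish(0) = 0`), over replicates where both are uncensored.
#' Reports the mean and standard deviation per mutation index and whether
#' each sequence decreases monotonically.
#'
#' @param results an `si_sim` object (or a list with a `t_establish`
#'   matrix).
#' @param min_uncensored minimum uncensored replicates required per index.
#' @return List: data.frame `per_index` (index, n_uncensored, mean_wait,
#'   sd_wait, insufficient flag), `mean_wait`, `sd_wait`,
#'   `mean_monotone_decreasing`, `sd_monotone_decreasing`.
#' @export
summarize_wait_times <- function(results, min_uncensored = 30L) {
  te <- results$t_establish
  K <- ncol(te)
  prev <- cbind(0, te[, -K, drop = FALSE])
  w <- te - prev
  n_unc <- colSums(!is.na(w))
  mean_wait <- colMeans(w, na.rm = TRUE)
  sd_wait <- apply(w, 2, stats::sd, na.rm = TRUE)
  insufficient <- n_unc < min_uncensored
  mean_wait[n_unc == 0] <- NA_real_
  usable <- !insufficient
  mono <- function(v) {
    v <- v[usable]
    length(v) >= 2 && !anyNA(v) && all(diff(v) < 0)
  }
  list(
    per_index = data.frame(index = seq_len(K), n_uncensored = n_unc,
                           mean_wait = mean_wait, sd_wait = sd_wait,
                           insufficient = insufficient),
    mean_wait = mean_wait,
    sd_wait = sd_wait,
    mean_monotone_decreasing = mono(mean_wait),
    sd_monotone_decreasing = mono(sd_wait)
  )
}
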