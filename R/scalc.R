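#' Selection coefficient from two allele frequencies
#'
#' Under discrete exponential growth `p_t = p_0 (1 + s)^t`, the selection
#' coefficient implied by observing frequencies `p0` and `p1` a known number
#' of generations apart is `s = (p1/p0)^(1/t) - 1`.
#'
#' @param p0,p1 frequencies in (0, 1\].
#' @param t generations elapsed (> 0).
#' @return The selection coefficient `s`.
#' @export
estimate_selection_coefficient <- function(p0, p1, t) {
  if (any(p0 <= 0) || any(p0 > 1) || any(p1 <= 0) || any(p1 > 1)) {
    stop("p0 and p1 must lie in (0, 1]", call. = FALSE)
  }
  if (any(t <= 0)) stop("t must be > 0", call. = FALSE)
  (p1 / p0)^(1 / t) - 1
}

#' Generations (and years) to reach a frequency under selection
#'
#' Inverts `p1 = p0 (1 + s)^t`: `t = ln(p1/p0) / ln(1 + s)`, converted to
#' years at a fixed number of viral generations per year. Used to ask how
#' long a sweep from the drift barrier (1/(2 N_e s)) to fixation would take.
#'
#' @param p0,p1 frequencies in (0, 1\].
#' @param s selection coefficient (> -1, nonzero unless `p1 == p0`).
#' @param generations_per_year viral generations per year (conservative
#'   default 5, the host generations per year).
#' @return List with `generations` and `years`.
#' @export
time_to_frequency <- function(p0, p1, s, generations_per_year = 5) {
  if (any(p0 <= 0) || any(p0 > 1) || any(p1 <= 0) || any(p1 > 1)) {
    stop("p0 and p1 must lie in (0, 1]", call. = FALSE)
  }
  if (s <= -1) stop("s must be > -1", call. = FALSE)
  if (p1 == p0) return(list(generations = 0, years = 0))
  if (s == 0) stop("s = 0 cannot move the frequency", call. = FALSE)
  t <- log(p1 / p0) / log(1 + s)
  list(generations = t, years = t / generations_per_year)
}

#' Probability that all K variants arise jointly in one generation
#'
#' `mu_variant^K` with the per-variant rate defaulting to the per-base rate
#' 1e-6 times 1/3 for the correct change.
#'
#' @param mu_variant per-variant per-generation mutation probability.
#' @param K number of variants.
#' @return The joint probability.
#' @export
joint_mutation_probability <- function(mu_variant = 1e-6 / 3, K = 5L) {
  if (mu_variant <= 0 || mu_variant >= 1) {
    stop("mu_variant must lie in (0, 1)", call. = FALSE)
  }
  check_count(K, "K", min = 1L)
  mu_variant^K
}
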