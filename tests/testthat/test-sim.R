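test_that("parameter validation enforces the gain structure", {
  expect_error(sim_params(gains = c(10, 3, 3, 1.5, 1.25)), "gains")
  expect_error(sim_params(gains = c(10, 3, 2, 1.5, 0.9)), "gains")
  expect_error(sim_params(gains = c(10, 3)), "gains")
  expect_error(sim_params(mu_variant = 2), "mu_variant")
  expect_silent(p <- sim_params())
  expect_equal(p$establish_thr, c(1, 1, 2, 3, 5))
})

test_that("genotype titer multiplies gains along the consecutive prefix", {
  p <- sim_params()
  expect_equal(titer_of_genotype(c(1, 1, 0, 0, 0), p), 30)
  expect_equal(titer_of_genotype(c(0, 1, 0, 0, 0), p), 1)
  expect_equal(titer_of_genotype(c(1, 1, 1, 1, 1), p), 112.5)
  expect_equal(titer_of_genotype(c(1, 0, 1, 1, 1), p), 10)
  expect_error(titer_of_genotype(c(1, 1), p), "length 5")
})

test_that("deterministic SI trajectory reaches the endemic equilibrium", {
  tr <- si_deterministic(0.5, 0.1, 0.01, 5000)
  expect_equal(tail(tr$I, 1), 0.8, tolerance = 1e-6)
  # subcritical: infection dies out
  tr2 <- si_deterministic(0.1, 0.2, 0.2, 5000)
  expect_lt(tail(tr2$I, 1), 1e-6)
  # no removal: infection saturates
  tr3 <- si_deterministic(0.3, 0, 0.05, 5000)
  expect_equal(tail(tr3$I, 1), 1, tolerance = 1e-6)
})

test_that("host counts are conserved every generation", {
  p <- sim_params(N = 50000, n_replicates = 1)
  st <- sim_state_init(p)
  set.seed(15)
  for (g in 1:1000) {
    st <- step_generation(st, p)
    expect_equal(st$S + sum(st$I), p$N)
    if (sum(st$I) == 0) break
  }
})

test_that("no variation enters without mutation or recombination", {
  p <- sim_params(N = 20000, mu_variant = 0, recomb_rate = 0,
                  n_replicates = 1)
  st <- sim_state_init(p)
  set.seed(7)
  for (g in 1:200) st <- step_generation(st, p)
  expect_equal(sum(st$I[-1]), 0)
  expect_true(all(is.na(st$t_first)))
  sim <- run_replicates(sim_params(N = 20000, mu_variant = 0,
                                   max_generations = 200,
                                   n_replicates = 3))
  expect_true(all(is.na(sim$t_establish)))
})

test_that("mutation influx matches its expectation", {
  # static population (no transmission or removal): carriers of the first
  # variant accumulate at rate I * mu * T0 per generation
  p <- sim_params(N = 1e5, beta0 = 0, gamma0 = 0, mu_variant = 1e-5,
                  recomb_rate = 0, n_replicates = 1)
  st <- sim_state_init(p)   # 10,000 infected
  set.seed(31)
  for (g in 1:500) st <- step_generation(st, p)
  carriers <- sum(st$I[bitwAnd(seq_along(st$I) - 1L, 1L) > 0])
  expected <- 10000 * (1 - (1 - 1e-5)^500)
  expect_equal(carriers, expected, tolerance = 4 / sqrt(expected))
})

test_that("a full-interval swap produces complementary offspring", {
  p <- sim_params(N = 1000, beta0 = 0, gamma0 = 0, mu_variant = 0,
                  recomb_rate = 1, n_replicates = 1)
  st <- sim_state_init(p)
  st$I[] <- 0
  st$I[1 + 1 + 2] <- 1           # loci 1,2      -> code 3
  st$I[1 + 4 + 8 + 16] <- 1      # loci 3,4,5    -> code 28
  st$S <- p$N - 2
  set.seed(2)
  st2 <- step_generation(st, p)
  expect_equal(sum(st2$I), 2)
  expect_equal(st2$I[1 + 1 + 8], 1)        # loci 1,4    -> code 9
  expect_equal(st2$I[1 + 2 + 4 + 16], 1)   # loci 2,3,5  -> code 22
})

test_that("recombination alone conserves marginal allele counts", {
  p <- sim_params(N = 5000, beta0 = 0, gamma0 = 0, mu_variant = 0,
                  recomb_rate = 0.3, n_replicates = 1)
  carriers_of <- function(I, k) {
    sum(I[bitwAnd(seq_along(I) - 1L, 2L^(k - 1L)) > 0])
  }
  set.seed(44)
  st <- sim_state_init(p)
  st$I <- as.numeric(rmultinom(1, 500, rep(1, 32)))
  st$S <- p$N - sum(st$I)
  before <- vapply(1:5, function(k) carriers_of(st$I, k), numeric(1))
  for (g in 1:50) {
    st <- step_generation(st, p)
    after <- vapply(1:5, function(k) carriers_of(st$I, k), numeric(1))
    expect_equal(after, before)
  }
})

test_that("with virulence exponent 1 no genotype class is favoured", {
  # two classes, no mutation/recombination: R0 = beta*T*S / (gamma*T*N) is
  # titer-free, so mean per-generation log growth should not differ
  p <- sim_params(N = 1e5, beta0 = 0.2, gamma0 = 0.05,
                  virulence_exponent = 1, mu_variant = 0, recomb_rate = 0,
                  gains = c(4, 2, 1.8, 1.5, 1.2), n_replicates = 1)
  diffs <- numeric(40)
  for (r in seq_len(40)) {
    set.seed(500 + r)
    st <- sim_state_init(p)
    st$I[] <- 0
    st$I[1] <- 30000          # Low: titer 1
    st$I[2] <- 30000          # first mutation: titer 4
    st$S <- p$N - sum(st$I)
    # burn in to the stationary susceptible fraction S*/N = gamma0/beta0,
    # at which every class is neutrally stationary when a = 1
    for (g in 1:150) st <- step_generation(st, p)
    st0 <- st
    for (g in 1:100) st <- step_generation(st, p)
    diffs[r] <- log(st$I[2] / st0$I[2]) - log(st$I[1] / st0$I[1])
  }
  expect_lt(abs(mean(diffs)), 4 * sd(diffs) / sqrt(length(diffs)) + 0.02)
  # contrast: the default exponent favours the mutant decisively
  p2 <- sim_params(N = 1e5, beta0 = 0.2, gamma0 = 0.05,
                   virulence_exponent = 0.5, mu_variant = 0,
                   recomb_rate = 0, gains = c(4, 2, 1.8, 1.5, 1.2),
                   n_replicates = 1)
  set.seed(600)
  st <- sim_state_init(p2)
  st$I[] <- 0
  st$I[1] <- 30000
  st$I[2] <- 30000
  st$S <- p2$N - sum(st$I)
  for (g in 1:150) st <- step_generation(st, p2)
  st0 <- st
  for (g in 1:100) st <- step_generation(st, p2)
  expect_gt(log(st$I[2] / st0$I[2]) - log(st$I[1] / st0$I[1]), 0.5)
})

test_that("replicates are reproducible and event times are ordered", {
  p <- sim_params(N = 50000, n_replicates = 4, max_generations = 3000,
                  mu_variant = 2e-5, seed = 77)
  a <- run_replicates(p)
  b <- run_replicates(p)
  expect_identical(a$t_fix, b$t_fix)
  expect_identical(a$recombination_assembled, b$recombination_assembled)
  ok <- !is.na(a$t_establish)
  expect_true(all(a$t_first[ok] <= a$t_establish[ok]))
  ok2 <- !is.na(a$t_fix)
  expect_true(all(a$t_establish[ok2] <= a$t_fix[ok2]))
})

test_that("wait-time summaries flag insufficient data and flat sequences", {
  fake <- list(t_establish = matrix(rep(c(10, 20, 30, 40, 50), each = 50),
                                    nrow = 50))
  s <- summarize_wait_times(fake)
  expect_equal(s$mean_wait, rep(10, 5))
  expect_false(s$mean_monotone_decreasing)
  one <- list(t_establish = matrix(1:5, nrow = 1))
  s1 <- summarize_wait_times(one)
  expect_true(all(s1$per_index$insufficient))
  dec <- list(t_establish = matrix(rep(c(40, 60, 75, 85, 90), each = 50),
                                   nrow = 50))
  expect_true(summarize_wait_times(dec)$mean_monotone_decreasing)
})

test_that("selection coefficient arithmetic matches closed forms", {
  expect_equal(estimate_selection_coefficient(0.3, 0.3, 50), 0)
  expect_equal(estimate_selection_coefficient(0.1, 0.2, 10), 2^0.1 - 1)
  expect_equal(estimate_selection_coefficient(0.52, 0.71, 80), 0.0039,
               tolerance = 0.01)
  expect_error(estimate_selection_coefficient(0, 0.5, 10), "\\(0, 1\\]")
  tt <- time_to_frequency(0.0000714, 0.99, 0.0055)
  expect_equal(tt$generations, 1739, tolerance = 0.001)
  expect_equal(tt$years, 348, tolerance = 0.002)
  expect_equal(time_to_frequency(0.4, 0.4, 0.01)$generations, 0)
  # inverse consistency
  s <- 0.02
  p1 <- 0.001 * (1 + s)^250
  expect_equal(time_to_frequency(0.001, p1, s)$generations, 250)
  expect_error(time_to_frequency(0.1, 0.5, 0), "s = 0")
  expect_error(time_to_frequency(0.1, 0.5, -1.5), "-1")
})

test_that("joint mutation probability matches the printed rate", {
  expect_equal(signif(joint_mutation_probability(), 3), 4.12e-33)
  expect_equal(joint_mutation_probability(0.1, 2), 0.01)
  expect_equal(joint_mutation_probability(0.3, 1), 0.3)
  expect_error(joint_mutation_probability(0, 5), "mu_variant")
})
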