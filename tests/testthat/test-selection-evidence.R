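test_that("the site likelihood is the folded binomial", {
  expect_equal(site_log_likelihood(0, 0, 0.9, 0.1), 0)
  expect_equal(site_log_likelihood(1, 1, 0.5, 0.5), log(0.5))
  ## maximal at the empirical frequency
  ll <- sapply(seq(0.05, 0.95, by = 0.05), function(p)
    site_log_likelihood(70, 30, 1 - p, p))
  expect_equal(seq(0.05, 0.95, by = 0.05)[which.max(ll)], 0.30)
})

test_that("EoS is zero for empty data and identical hypotheses", {
  expect_equal(eos_score(0, 0, runif(1000))$R, 0)
  ## alt posterior == null posterior: R = 0 within MC error
  set.seed(1)
  n <- 50; n_ns <- 5
  p_same <- rbeta(20000, n_ns + 0.5, n - n_ns + 0.5)
  sc <- eos_score(n_ns, n, p_same, seed = 2)
  expect_lt(abs(sc$R), 3 * sc$mc_se)
})

test_that("EoS matches a quadrature oracle for a near-point-mass null", {
  ## n = 87 clones, 0 nonsynonymous observed, null p_ns ~ 0.05:
  ## R = E_beta[87 log(1 - pA)] - 87 log(0.95), HA ~ Beta(0.5, 87.5)
  n <- 87; a <- 0.5; b <- 87.5
  integrand <- function(p) dbeta(p, a, b) * n * log1p(-p)
  EA <- integrate(integrand, 0, 1, rel.tol = 1e-10)$value
  oracle <- (EA - n * log(0.95)) / log(2)
  sc <- eos_score(0, n, rep(0.05, 2e4), seed = 3)
  expect_equal(sc$R, oracle, tolerance = 3 * sc$mc_se / abs(oracle))
  ## closed form for the beta expectation: psi(b) - psi(a+b)
  expect_equal(EA, n * (digamma(b) - digamma(a + b)), tolerance = 1e-8)
})

test_that("combined EoS is additive and rejects duplicate sites", {
  expect_equal(combined_eos(5.2), 5.2)
  expect_equal(combined_eos(c(3, -3)), 0)
  expect_error(combined_eos(c(1, 2), sites = c(4, 4)), "duplicate")
  ## additivity on simulated selected sites
  sim <- simulate_clones(simulation_config(
    wild_type = paste(rep("TAT", 30), collapse = ""),
    n_clones = 87, selected_sites = 1:3, seed = 31))
  C <- tabulate_nucleotide_counts(sim$us)
  Pd <- sample_mutation_matrices(C, 3000, seed = 5)
  e <- eos_scan(tabulate_codon_counts(sim$mx), Pd, n_mc = 3000, seed = 6,
                reliability_n_mc = 0, population = "mx")
  expect_equal(combined_eos(e$R[1:3], 1:3), sum(e$R[1:3]))
  expect_gt(combined_eos(e$R[1:3], 1:3), 3)
})

test_that("reliability reduces to the exact binomial Kullback-Leibler divergence", {
  ## point-mass hypotheses: exhaustive 88-term sum oracle
  n <- 87; pA <- 0.2; p0 <- 0.01
  x <- 0:n
  klA <- sum(dbinom(x, n, pA) * (dbinom(x, n, pA, log = TRUE) -
                                   dbinom(x, n, p0, log = TRUE)))
  kl0 <- sum(dbinom(x, n, p0) * (dbinom(x, n, p0, log = TRUE) -
                                   dbinom(x, n, pA, log = TRUE)))
  r <- reliability(rep(pA, 10), rep(p0, 10), n)
  expect_equal(r$D_HA, klA / log(2), tolerance = 1e-10)
  expect_equal(r$D_H0, kl0 / log(2), tolerance = 1e-10)
  ## identical hypotheses: zero divergence
  r0 <- reliability(rep(0.07, 10), rep(0.07, 10), n)
  expect_equal(r0$D_HA, 0)
  expect_equal(r0$D_H0, 0)
  ## Gibbs inequality holds for every paired draw
  set.seed(4)
  r1 <- reliability(rbeta(300, 2, 30), rbeta(300, 5, 80), 40)
  expect_gte(r1$D_HA, 0)
  expect_gte(r1$D_H0, 0)
})

test_that("the homogeneity Bayes factor separates concordant from discordant sites", {
  expect_equal(homogeneity_test(0, 0, 0, 0), 0)
  ## identical large counts: homogeneous
  expect_gt(homogeneity_test(5, 87, 5, 87), 0)
  ## 40 vs 2 nonsynonymous out of 87: strongly heterogeneous
  expect_lt(homogeneity_test(40, 87, 2, 87), 0)
  ## oracle: direct marginal-likelihood computation via beta functions
  a <- 0.5
  marg <- function(ns, n) beta(n - ns + a, ns + a) / beta(a, a)
  direct <- log2(marg(5 + 7, 40 + 40) / (marg(5, 40) * marg(7, 40)))
  expect_equal(homogeneity_test(5, 40, 7, 40), direct, tolerance = 1e-10)
})

test_that("the chi-squared statistic matches the two-cell formula", {
  expect_equal(chi2_site_statistic(5, 100, 0.05), 0)
  expect_equal(chi2_site_statistic(0, 100, 0.05), 25 / 5 + 25 / 95)
  expect_error(chi2_site_statistic(0, 10, 0), "zero expected")
})

test_that("chi-squared and EoS rank-correlate on simulated sites", {
  ## mix of conserved and free sites gives both statistics dynamic range
  set.seed(41)
  wt <- paste(c("ATG", sample(rep(c("TAT", "CGT", "AAA", "GCA"), 20))),
              collapse = "")
  sim <- simulate_clones(simulation_config(
    wild_type = wt, n_clones = 87, selected_sites = seq(2, 80, by = 4),
    seed = 41))
  C <- tabulate_nucleotide_counts(sim$us)
  Pd <- sample_mutation_matrices(C, 2000, seed = 7)
  e <- eos_scan(tabulate_codon_counts(sim$mx), Pd, n_mc = 2000, seed = 8,
                reliability_n_mc = 0)
  ## both statistics are monotone in the size of the mutation deficit, so
  ## compare ranks on deficit sites (hyper-mutability is not detectable by
  ## design, and excess sites scatter both statistics around zero)
  deficit <- e$n_ns_obs <= e$n_ns_exp
  expect_gt(sum(deficit), 30)
  expect_gt(cor(e$R[deficit], e$chi2[deficit], method = "spearman"), 0.6)
})

test_that("an eos scan returns coherent flags and expectations", {
  sim <- simulate_clones(simulation_config(
    wild_type = paste(c("ATG", rep("TAT", 3), rep("GCA", 16)), collapse = ""),
    n_clones = 87, selected_sites = 2:4, seed = 51))
  C <- tabulate_nucleotide_counts(sim$us)
  Pd <- sample_mutation_matrices(C, 3000, seed = 9)
  e <- eos_scan(tabulate_codon_counts(sim$mx), Pd, n_mc = 3000, seed = 10,
                population = "mx", reliability_n_mc = 400)
  expect_s3_class(e, "eos_result")
  expect_equal(nrow(e), 20L)
  expect_true(all(e$selected == (e$R >= log2(20))))
  expect_true(all(e$D_HA >= -1e-9))
  expect_true(all(e$D_H0 >= -1e-9))
  ## conserved high-rate sites flagged, most alanine sites not
  expect_true(all(e$selected[2:4]))
  expect_lt(mean(e$selected[5:20]), 0.5)
  ## observed vs expected accounting
  expect_equal(e$n_ns_obs[2:4], c(0L, 0L, 0L))
  expect_true(all(e$n_ns_exp[2:4] > 3))
})
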