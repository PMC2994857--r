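test_that("a PCR cycle conserves probability and fixes perfect fidelity", {
  K <- complement_fidelity()
  sp <- list(s = c(1, 0, 0, 0), n = c(0, 0, 0, 1))
  out <- pcr_cycle(sp, K)
  expect_equal(out$s, sp$s)
  expect_equal(out$n, sp$n)
  ## Markov conservation for arbitrary input
  T <- random_T(3)
  sp2 <- list(s = c(0.1, 0.2, 0.3, 0.4), n = c(0.25, 0.25, 0.25, 0.25))
  out2 <- pcr_cycle(sp2, T)
  expect_equal(sum(out2$s), 1)
  expect_equal(sum(out2$n), 1)
})

test_that("iterated cycles equal the binomial-coefficient expansion (k <= 7)", {
  for (seed in 1:3) {
    T <- unclass(random_T(seed, eps = 0.08))
    Tp <- function(m) Reduce(`%*%`, replicate(m, T, simplify = FALSE), diag(4))
    I4 <- diag(4)
    comp <- c(4, 3, 2, 1)
    for (l in 1:4) {
      s0 <- I4[, l]; n0 <- I4[, comp[l]]
      ## 2^7 s_7 = T^7 n0 + 7 T^6 s0 + 21 T^5 n0 + 35 T^4 s0
      ##         + 35 T^3 n0 + 21 T^2 s0 + 7 T n0 + s0
      poly7 <- (Tp(7) %*% n0 + 7 * Tp(6) %*% s0 + 21 * Tp(5) %*% n0 +
                  35 * Tp(4) %*% s0 + 35 * Tp(3) %*% n0 +
                  21 * Tp(2) %*% s0 + 7 * T %*% n0 + s0) / 2^7
      ## 2^2 s_2 = T^2 s0 + 2 T n0 + s0
      poly2 <- (Tp(2) %*% s0 + 2 * T %*% n0 + s0) / 4
      sp <- list(s = s0, n = n0)
      for (i in 1:2) sp <- pcr_cycle(sp, T)
      expect_equal(sp$s, as.vector(poly2), tolerance = 1e-12)
      for (i in 3:7) sp <- pcr_cycle(sp, T)
      expect_equal(sp$s, as.vector(poly7), tolerance = 1e-12)
    }
  }
})

test_that("the PCR mutation matrix is column-stochastic with exact identities", {
  T <- random_T(11)
  expect_equal(unclass(pcr_mutation_matrix(T, 0))[1:4, 1:4], diag(4),
               ignore_attr = TRUE)
  expect_equal(unclass(pcr_mutation_matrix(complement_fidelity(), 25))[1:4, 1:4],
               diag(4), ignore_attr = TRUE)
  P <- pcr_mutation_matrix(T, 30)
  expect_equal(colSums(unclass(P)[1:4, 1:4]), rep(1, 4), ignore_attr = TRUE)
})

test_that("the counts likelihood matches direct multinomial evaluation", {
  K <- complement_fidelity()
  Cd <- misincorporation_counts(diag(10, 4))
  expect_equal(counts_log_likelihood(Cd, K, 12), 0)   # probability one
  ## direct evaluation over the four columns
  T <- random_T(2)
  k <- 6
  P <- unclass(pcr_mutation_matrix(T, k))[1:4, 1:4]
  set.seed(8)
  C <- misincorporation_counts(sapply(1:4, function(j) rmultinom(1, 50, P[, j])))
  direct <- sum(sapply(1:4, function(j)
    dmultinom(unclass(C)[1:4, j], prob = P[, j], log = TRUE)))
  expect_equal(counts_log_likelihood(C, T, k), direct, tolerance = 1e-10)
  ## zero model probability with positive count
  Cz <- misincorporation_counts(matrix(5, 4, 4))
  expect_warning(ll <- counts_log_likelihood(Cz, K, 3), "zero model probability")
  expect_identical(ll, -Inf)
})

test_that("Fisher information matches finite differences and has the constraint nulls", {
  T <- random_T(7, eps = 0.06)
  ct <- c(24273, 18096, 11223, 15834)
  k <- 5
  fi <- fisher_information(T, ct, k)
  expect_equal(fi$F, t(fi$F), tolerance = 1e-10)
  ## four null directions = per-column constant log-shifts
  E <- matrix(0, 16, 4)
  for (j in 1:4) E[(j - 1) * 4 + (1:4), j] <- 1
  expect_lt(max(abs(fi$F %*% E)), 1e-6 * max(abs(fi$F)))
  ## eigen-spectrum on the quotient is strictly positive
  B <- qr.Q(qr(cbind(E, diag(16))))[, 5:16]
  ev <- eigen(crossprod(B, fi$F %*% B), symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))

  ## central finite differences of the expected-information identity:
  ## F_ab = sum_e w_e d_a p_e d_b p_e / p_e with derivatives in log-params.
  ## Differentiate P numerically in log space via column renormalisation.
  theta <- log(as.vector(unclass(T)))
  p_of_theta <- function(th) {
    M <- exp(matrix(th, 4, 4)); M <- sweep(M, 2, colSums(M), "/")
    as.vector(unclass(pcr_mutation_matrix(polymerase_matrix(M), k))[1:4, 1:4])
  }
  h <- 1e-5
  Gfd <- sapply(1:16, function(a) {
    tp <- theta; tp[a] <- tp[a] + h
    tm <- theta; tm[a] <- tm[a] - h
    (p_of_theta(tp) - p_of_theta(tm)) / (2 * h)
  })
  p <- as.vector(unclass(pcr_mutation_matrix(T, k))[1:4, 1:4])
  w <- rep(ct, each = 4) / p
  Ffd <- crossprod(Gfd * sqrt(w))
  expect_equal(fi$F, Ffd, tolerance = 1e-6)
})

test_that("the Jeffreys prior is gauge-invariant and scales with the totals", {
  T <- random_T(4, eps = 0.04)
  ct <- c(20000, 15000, 10000, 12000)
  lp <- jeffreys_log_prior(T, ct, 8)
  expect_true(is.finite(lp))
  ## invariance: the prior depends on T only through the quotient, and the
  ## softmax parameterisation is itself shift-invariant per column
  theta <- log(as.vector(unclass(T)))
  theta2 <- theta; theta2[1:4] <- theta2[1:4] + 5
  M <- exp(matrix(theta2, 4, 4)); M <- sweep(M, 2, colSums(M), "/")
  expect_equal(unclass(polymerase_matrix(M))[1:4, 1:4], unclass(T)[1:4, 1:4],
               tolerance = 1e-12)
  ## scaling all totals by c adds 6 log c (12 dims x 1/2, F linear in totals)
  lp2 <- jeffreys_log_prior(T, 10 * ct, 8)
  expect_equal(lp2 - lp, 6 * log(10), tolerance = 1e-8)
})

test_that("MAP recovers a known polymerase matrix from simulated counts", {
  T_true <- random_T(15, eps = 0.004)
  k <- 10
  P_true <- unclass(pcr_mutation_matrix(T_true, k))[1:4, 1:4]
  set.seed(77)
  n_col <- c(30000, 25000, 20000, 28000)
  C <- misincorporation_counts(
    sapply(1:4, function(j) rmultinom(1, n_col[j], P_true[, j])))
  fit <- map_estimate(C, k)
  expect_equal(fit$convergence, 0L)
  sd_P <- unigenicEoS:::map_posterior_sd_P(fit, n_col)
  expect_true(all(abs(unclass(fit$P)[1:4, 1:4] - P_true) <= 3 * sd_P + 1e-12))
})

test_that("Metropolis sampling is seeded, concentrated and complement-symmetric", {
  ## moderate-size counts keep the chain cheap; the posterior is still tight
  T_true <- random_T(15, eps = 0.004)
  k <- 10
  P_true <- unclass(pcr_mutation_matrix(T_true, k))[1:4, 1:4]
  set.seed(78)
  C <- misincorporation_counts(
    sapply(1:4, function(j) rmultinom(1, 20000, P_true[, j])))
  ch <- list(length = 1400, burn_in = 200, thin = 10, seed = 5, adapt = 400)
  samp <- sample_posterior_T(C, k, chain = ch)
  samp2 <- sample_posterior_T(C, k, chain = ch, map = samp$map)
  expect_identical(samp$P_draws, samp2$P_draws)   # same seed, same draws
  expect_gt(samp$acceptance_rate, 0.005)
  pm <- apply(samp$P_draws, c(1, 2), mean)
  ps <- apply(samp$P_draws, c(1, 2), sd)
  ## posterior concentration: mean within a few posterior sd of the MAP
  ## (the log-space posterior is mildly skewed, so exact equality is not
  ## expected; the chain mean must still sit inside the posterior bulk)
  expect_true(all(abs(pm - unclass(samp$map$P)[1:4, 1:4]) <= 3 * ps + 1e-5))
  ## complementary-entry similarity predicted by the strand-pair model
  comp <- c(4, 3, 2, 1)
  off <- which(row(pm) != col(pm))
  for (e in off) {
    i <- row(pm)[e]; j <- col(pm)[e]
    expect_lt(abs(pm[i, j] - pm[comp[i], comp[j]]),
              0.35 * max(pm[i, j], pm[comp[i], comp[j]]) + 1e-4)
  }
})
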