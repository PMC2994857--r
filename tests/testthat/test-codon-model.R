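test_that("the codon operator is the triple Kronecker product", {
  expect_true(all(unclass(codon_operator(mutation_matrix(diag(4)))) == diag(64)))
  P <- relative_frequencies(tab1_us())
  M <- codon_operator(P)
  Pm <- unclass(P)[1:4, 1:4]
  expect_equal(M["ACG", "AAA"], Pm["A", "A"] * Pm["C", "A"] * Pm["G", "A"],
               ignore_attr = TRUE)
  expect_equal(colSums(unclass(M)[1:64, 1:64]), rep(1, 64), ignore_attr = TRUE,
               tolerance = 1e-12)
  ## marginalising positions 2 and 3 recovers P exactly
  first <- substr(rownames(M), 1, 1)
  for (j in c("AAA", "CGT", "TTT")) {
    marg <- tapply(unclass(M)[, j], first, sum)[nuc_alphabet()]
    expect_equal(as.numeric(marg), unname(Pm[, substr(j, 1, 1)]),
                 tolerance = 1e-12)
  }
})

test_that("the synonymous partition sums the correct codon set", {
  code <- genetic_code("1")
  ## arginine example: AGA's synonymous set is exactly these six codons
  expect_setequal(unigenicEoS:::synonymous_set("AGA", code),
                  c("AGA", "CGT", "AGG", "CGA", "CGG", "CGC"))
  P <- relative_frequencies(tab1_us())
  M <- codon_operator(P)
  sp <- synonymous_partition(M, "AGA", code)
  expect_equal(sp$p_sn + sp$p_ns, 1)
  expect_equal(sp$p_sn,
               sum(unclass(M)[c("AGA", "CGT", "AGG", "CGA", "CGG", "CGC"), "AGA"]))
  ## identity mutation matrix: no nonsynonymous probability
  spI <- synonymous_partition(codon_operator(mutation_matrix(diag(4))), "CTT", code)
  expect_equal(spI$p_sn, 1)
  ## uniform mutation matrix: Met has a single codon, p_sn = 1/64
  spU <- synonymous_partition(codon_operator(mutation_matrix(matrix(0.25, 4, 4))),
                              "ATG", code)
  expect_equal(spU$p_sn, 1 / 64)
  expect_error(synonymous_partition(M, "TAA", code), "stop codon")
  ## direct-product path (mutation matrix without the 64x64 operator) agrees
  sp2 <- synonymous_partition(P, "AGA", code)
  expect_equal(sp2$p_sn, sp$p_sn, tolerance = 1e-12)
})

test_that("per-site partitions are site-independent and order-equivariant", {
  P <- relative_frequencies(tab1_us())
  parts <- site_partitions_for_sequence("ATGATGATG", P)
  expect_equal(length(unique(round(parts$p_ns, 15))), 1L)
  wt <- "ATGAAACTTTGGCGT"
  a <- site_partitions_for_sequence(wt, P)
  ## permuting codons permutes outputs
  wt2 <- "ATGCTTAAACGTTGG"
  b <- site_partitions_for_sequence(wt2, P)
  expect_equal(sort(a$p_ns), sort(b$p_ns), tolerance = 1e-12)
  ## internal stop rejected; terminal stop dropped with a message
  expect_error(site_partitions_for_sequence("ATGTAAAAA", P), "internal stop")
  expect_message(d <- site_partitions_for_sequence("ATGAAATAA", P),
                 "terminal stop")
  expect_equal(nrow(d), 2L)
  ## published-frequency partitions span roughly an order of magnitude
  codons61 <- setdiff(rownames(codon_operator(P)),
                      c("TAA", "TAG", "TGA"))
  pns61 <- vapply(codons61, function(cd)
    synonymous_partition(P, cd)$p_ns, numeric(1))
  expect_gt(max(pns61) / min(pns61), 5)
})

test_that("increasing an error rate weakly increases p_ns where it must", {
  P0 <- unclass(relative_frequencies(tab1_us()))[1:4, 1:4]
  ## bump A->C errors (column A) and renormalise
  P1 <- P0; P1["C", "A"] <- P1["C", "A"] + 0.01
  P1 <- sweep(P1, 2, colSums(P1), "/")
  code <- genetic_code("1")
  for (cd in c("ATG", "AAA", "TAT")) {
    a <- synonymous_partition(mutation_matrix(P0), cd, code)$p_ns
    b <- synonymous_partition(mutation_matrix(P1), cd, code)$p_ns
    expect_gte(b, a - 1e-12)
  }
})

test_that("kappa Monte Carlo matches the exact Poisson-binomial", {
  ## degenerate case
  parts0 <- data.frame(p_ns = rep(0, 5))
  kd0 <- mutation_count_distribution(parts0, n_sim = 100, seed = 1)
  expect_equal(unname(kd0$pmf[1]), 1)
  ## single Bernoulli site
  kd1 <- mutation_count_distribution(data.frame(p_ns = 0.3), n_sim = 2e4, seed = 2)
  expect_equal(unname(kd1$pmf[2]), 0.3, tolerance = 3 * sqrt(0.3 * 0.7 / 2e4))
  ## five stated sites: exact convolution oracle
  p <- c(0.05, 0.2, 0.01, 0.5, 0.1)
  kd <- mutation_count_distribution(data.frame(p_ns = p), n_sim = 5e4, seed = 3)
  ## independent oracle: enumerate all 2^5 outcomes
  grid <- expand.grid(rep(list(0:1), 5))
  pr <- apply(grid, 1, function(g) prod(ifelse(g == 1, p, 1 - p)))
  oracle <- tapply(pr, rowSums(grid), sum)
  expect_equal(as.numeric(kd$exact), as.numeric(oracle), tolerance = 1e-12)
  mc_se <- sqrt(kd$exact * (1 - kd$exact) / 5e4)
  expect_true(all(abs(kd$pmf - kd$exact) <= 3 * mc_se + 1e-9))
})

test_that("expected nonsynonymous table carries binomial percentiles", {
  P <- relative_frequencies(tab1_us())
  parts <- site_partitions_for_sequence("ATGTATAAA", P)
  tab <- expected_ns_table(parts, 87)
  expect_equal(tab$n_ns_expected, 87 * parts$p_ns)
  expect_true(all(tab$Q02 <= tab$Q50 & tab$Q50 <= tab$Q98))
})
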