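## codon_model: lift the per-nucleotide mutation matrix to codons.
##
## Site-independence of nucleotide mutation means the codon process is the
## triple Kronecker product M = P (x) P (x) P, a 64x64 column-stochastic
## operator in the package's lexicographic A,C,G,T codon order (first codon
## position most significant). Outcomes are partitioned per wild-type codon
## into "synonymous" (identity or same translation) and "nonsynonymous"
## (different translation; stop codons fall in the nonsynonymous class).

#' Codon mutation operator
#'
#' The 64x64 column-stochastic operator \eqn{M = P \otimes P \otimes P}
#' describing independent mutation of the three codon positions. Entry
#' `M[ikm, jln]` equals `p_ij * p_kl * p_mn`. Rows and columns are named by
#' codon in lexicographic A, C, G, T order.
#'
#' @param P a [mutation_matrix()].
#' @return 64x64 matrix of class `codon_operator`.
#' @examples
#' M <- codon_operator(mutation_matrix(diag(4)))
#' all(M == diag(64))
#' @export
codon_operator <- function(P) {
  P <- unclass(P)[1:4, 1:4]
  M <- kronecker(P, kronecker(P, P))
  dimnames(M) <- list(CODONS, CODONS)
  structure(M, class = c("codon_operator", "matrix"))
}

#' Synonymous/nonsynonymous outcome partition for one codon
#'
#' Probability that a wild-type codon, after mutagenic PCR, is read as a
#' codon with the same translation (including the unchanged codon itself) —
#' `p_sn` — versus any codon with a different translation (stop codons
#' included) — `p_ns = 1 - p_sn`.
#'
#' @param M a [codon_operator()] (or a [mutation_matrix()], from which the
#'   needed column products are computed directly).
#' @param wt_codon wild-type codon string; must be a sense codon.
#' @param code a [genetic_code()].
#' @return list with `wt_codon`, `p_sn`, `p_ns`.
#' @examples
#' P <- mutation_matrix(matrix(0.25, 4, 4))
#' M <- codon_operator(P)
#' synonymous_partition(M, "ATG", genetic_code("1"))$p_sn  # 1/64: Met is lone
#' @export
synonymous_partition <- function(M, wt_codon, code = genetic_code("1")) {
  if (code$map[[wt_codon]] == "*")
    stop("wild-type codon ", wt_codon, " is a stop codon")
  syn <- synonymous_set(wt_codon, code)
  if (inherits(M, "codon_operator")) {
    p_sn <- sum(unclass(M)[syn, wt_codon])
  } else {
    p_sn <- sum(codon_column_probs(M, wt_codon, syn))
  }
  list(wt_codon = wt_codon, p_sn = p_sn, p_ns = 1 - p_sn)
}

## probabilities of a set of target codons given wt codon, straight from P
## (avoids forming the 64x64 operator)
codon_column_probs <- function(P, wt_codon, targets) {
  P <- unclass(P)[1:4, 1:4]
  wt <- strsplit(wt_codon, "")[[1]]
  vapply(strsplit(targets, ""), function(tg)
    P[tg[1], wt[1]] * P[tg[2], wt[2]] * P[tg[3], wt[3]], numeric(1))
}

#' Per-site synonymous/nonsynonymous probabilities for a coding sequence
#'
#' Applies [synonymous_partition()] to every codon of a frame-valid coding
#' sequence (internal stop codons are rejected; a terminal stop codon is
#' dropped with a message).
#'
#' @param wt wild-type coding nucleotide sequence (length divisible by 3).
#' @param P a [mutation_matrix()].
#' @param code a [genetic_code()].
#' @return data.frame with columns `site`, `wt_codon`, `aa`, `p_sn`,
#'   `p_ns`.
#' @export
site_partitions_for_sequence <- function(wt, P, code = genetic_code("1")) {
  wt <- normalize_seq(wt)
  L <- nchar(wt)
  if (L %% 3L != 0L) stop("sequence length not divisible by 3")
  codons <- substring(wt, seq(1L, L, 3L), seq(3L, L, 3L))
  aa <- code$map[codons]
  n <- length(codons)
  if (n > 1L && aa[n] == "*") {
    message("dropping terminal stop codon at site ", n)
    codons <- codons[-n]; aa <- aa[-n]; n <- n - 1L
  }
  if (any(aa == "*"))
    stop("internal stop codon(s) at site(s) ",
         paste(which(aa == "*"), collapse = ", "))
  p_sn <- vapply(codons, function(cd)
    synonymous_partition(P, cd, code)$p_sn, numeric(1))
  data.frame(site = seq_len(n), wt_codon = codons, aa = unname(aa),
             p_sn = unname(p_sn), p_ns = 1 - unname(p_sn),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Whole-protein nonsynonymous mutation count distribution
#'
#' Distribution of \eqn{\kappa}, the total number of nonsynonymous
#' mutations per clone across all codon sites, under site-independent
#' mutation: Monte-Carlo in-silico mutagenesis (per-site Bernoulli draws on
#' `p_ns`) plus the exact Poisson-binomial probability mass function by
#' convolution for validation.
#'
#' @param partitions data.frame from [site_partitions_for_sequence()] (or
#'   any data.frame with a `p_ns` column).
#' @param n_sim Monte-Carlo replicates.
#' @param seed integer seed.
#' @return object of class `kappa_distribution`: list with `pmf`
#'   (Monte-Carlo estimate over 0..n_sites), `exact` (Poisson-binomial
#'   pmf), `n_sim`, `seed`, `mean_kappa`.
#' @export
mutation_count_distribution <- function(partitions, n_sim = 1e5, seed = 1L) {
  stopifnot(n_sim >= 1)
  p <- partitions$p_ns
  stopifnot(all(p >= 0 & p <= 1))
  set.seed(seed)
  n_sites <- length(p)
  kappa <- integer(n_sim)
  for (j in seq_len(n_sites))          # incremental to bound memory
    kappa <- kappa + rbinom(n_sim, 1L, p[j])
  pmf <- tabulate(kappa + 1L, nbins = n_sites + 1L) / n_sim
  ## exact Poisson-binomial by sequential convolution
  exact <- 1
  for (j in seq_len(n_sites))
    exact <- c(exact * (1 - p[j]), 0) + c(0, exact * p[j])
  names(pmf) <- names(exact) <- 0:n_sites
  structure(list(pmf = pmf, exact = exact, n_sim = as.integer(n_sim),
                 seed = as.integer(seed), mean_kappa = sum(p)),
            class = "kappa_distribution")
}

#' @export
print.kappa_distribution <- function(x, ...) {
  cat("kappa (nonsynonymous mutations per clone): mean ",
      round(x$mean_kappa, 2), ", ", x$n_sim, " MC replicates\n", sep = "")
  supp <- which(x$exact > 1e-6) - 1L
  cat("effective support:", min(supp), "-", max(supp), "\n")
  invisible(x)
}

#' Expected nonsynonymous counts with binomial percentiles
#'
#' Per-site expected nonsynonymous mutation count for a clone population of
#' size `n` with the 2%, 50% and 98% binomial percentiles — the table used
#' to judge attainable selection signal per codon and to choose sample
#' sizes.
#'
#' @param partitions data.frame from [site_partitions_for_sequence()].
#' @param n clone population size.
#' @return data.frame with columns `site`, `wt_codon`, `aa`, `p_sn`,
#'   `p_ns`, `n_ns_expected`, `Q02`, `Q50`, `Q98`.
#' @export
expected_ns_table <- function(partitions, n) {
  data.frame(partitions,
             n_ns_expected = n * partitions$p_ns,
             Q02 = qbinom(0.02, n, partitions$p_ns),
             Q50 = qbinom(0.50, n, partitions$p_ns),
             Q98 = qbinom(0.98, n, partitions$p_ns),
             row.names = NULL)
}
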