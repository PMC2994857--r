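## selection_evidence: per-site Evidence-of-Selection scores and
## Kullback-Leibler reliability.
##
## At each codon site the observed (synonymous-or-identity, nonsynonymous)
## clone counts are scored by the expected log-odds-ratio R of the
## alternate hypothesis HA (site-specific mutation frequencies, Dirichlet
## posterior from the site's own counts) against a null H (selection-free
## PCR mutation frequencies, pushed from the nucleotide-level null
## posterior through the codon operator). R > 0 favours selection; R near
## zero is indeterminate; small negative values are sampling variance.
## Internally natural logs are used; reported scores are log base 2.

#' Site log-likelihood of synonymous/nonsynonymous counts
#'
#' Log multinomial (binomial) probability of observing `n_sn` synonymous
#' and `n_ns` nonsynonymous outcomes in `n_sn + n_ns` clones, with the
#' identity (no-mutation) outcome folded into the synonymous class. `n_sn`
#' here is therefore the folded count: clones without a nonsynonymous
#' change at the site.
#'
#' @param n_sn folded synonymous-class count (identical + synonymous).
#' @param n_ns nonsynonymous count.
#' @param p_sn,p_ns class probabilities (must sum to 1).
#' @return scalar log-probability; `-Inf` if a zero-probability class has a
#'   positive count.
#' @examples
#' site_log_likelihood(1, 1, 0.5, 0.5)  # log(2 * 0.5 * 0.5)
#' @export
site_log_likelihood <- function(n_sn, n_ns, p_sn, p_ns) {
  stopifnot(abs(p_sn + p_ns - 1) < 1e-9, n_sn >= 0, n_ns >= 0)
  dbinom(n_ns, n_sn + n_ns, p_ns, log = TRUE)
}

## log-likelihood of n_ns out of n for a vector of p_ns draws; the binomial
## coefficient is included but cancels wherever differences are taken
loglik_terms <- function(n_ns, n, p_ns) {
  dbinom(n_ns, n, p_ns, log = TRUE)
}

#' Evidence-of-Selection score for one site
#'
#' Monte-Carlo evaluation of the expected log-odds-ratio
#' \deqn{R = E[\log \Pr(data \mid HA)\Pr(HA) - \log \Pr(data \mid H_0)\Pr(H_0)]}
#' where the expectation pairs independent draws from the HA posterior
#' (Beta from the site's own counts, Jeffreys prior) and from the null
#' posterior on the site's nonsynonymous probability.
#'
#' @param n_ns observed nonsynonymous count at the site.
#' @param n_total clones counted at the site.
#' @param pns_null draws of the null nonsynonymous probability at this site
#'   (vector; its length sets the Monte-Carlo size).
#' @param alpha Dirichlet hyperparameter for the HA posterior.
#' @param prior_odds prior odds Pr(HA)/Pr(H0), default 1.
#' @param seed optional seed for the HA draws.
#' @return list with `R` (log2), `mc_se` (log2), `n_mc`.
#' @export
eos_score <- function(n_ns, n_total, pns_null, alpha = 0.5, prior_odds = 1,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_mc <- length(pns_null)
  stopifnot(n_mc >= 1, n_ns <= n_total)
  if (n_total == 0L)
    return(list(R = 0, mc_se = 0, n_mc = n_mc))
  pA <- stats::rbeta(n_mc, n_ns + alpha, n_total - n_ns + alpha)
  d <- loglik_terms(n_ns, n_total, pA) - loglik_terms(n_ns, n_total, pns_null) +
    log(prior_odds)
  list(R = mean(d) / log(2), mc_se = sd(d) / sqrt(n_mc) / log(2), n_mc = n_mc)
}

#' Combined Evidence of Selection over a set of sites
#'
#' Sums per-site scores over a set of disjoint sites of one population —
#' the log relative probability that all sites in the set were observed
#' under selection. The sum self-corrects for the number of sites
#' considered, but systematically understates the posterior odds when the
#' set mixes true and false positives (a single false positive drags the
#' whole set down).
#'
#' @param R numeric vector of per-site scores (any fixed log base).
#' @param sites site indices, used to reject duplicates.
#' @return scalar combined score in the same base.
#' @export
combined_eos <- function(R, sites = seq_along(R)) {
  if (anyDuplicated(sites)) stop("duplicate sites in combined EoS set")
  sum(R)
}

## exact-outcome-sum KL between two binomials (n trials), natural log
binom_kl_terms <- function(n, p_from, p_to) {
  x <- 0:n
  lf <- matrix(dbinom(rep(x, length(p_from)), n, rep(p_from, each = n + 1L),
                      log = TRUE), n + 1L)
  lt <- matrix(dbinom(rep(x, length(p_to)), n, rep(p_to, each = n + 1L),
                      log = TRUE), n + 1L)
  w <- exp(lf)
  colSums(w * (lf - lt))
}

#' Kullback-Leibler reliability (power) of a site's hypothesis test
#'
#' For paired posterior draws of the nonsynonymous probability under HA and
#' under the null, computes the expected true-positive/false-negative
#' log-odds `D_HA` (KL of the HA outcome distribution from the null one)
#' and the true-negative/false-positive log-odds `D_H0` (roles swapped).
#' The sum over the `n_clones + 1` possible outcomes is exact; only the
#' posterior integration is Monte Carlo. Gibbs' inequality makes every
#' per-draw term non-negative.
#'
#' @param pns_alt,pns_null equal-length vectors of paired posterior draws.
#' @param n_clones number of clones scored at the site.
#' @return list with `D_HA`, `D_H0` (log2), their Monte-Carlo standard
#'   errors, and `n_mc`.
#' @examples
#' reliability(rep(0.2, 100), rep(0.01, 100), 87)
#' @export
reliability <- function(pns_alt, pns_null, n_clones) {
  stopifnot(length(pns_alt) == length(pns_null), n_clones >= 0)
  n_mc <- length(pns_alt)
  if (n_clones == 0L)
    return(list(D_HA = 0, D_H0 = 0, mc_se_HA = 0, mc_se_H0 = 0, n_mc = n_mc))
  dA <- binom_kl_terms(n_clones, pns_alt, pns_null)
  d0 <- binom_kl_terms(n_clones, pns_null, pns_alt)
  list(D_HA = mean(dA) / log(2), D_H0 = mean(d0) / log(2),
       mc_se_HA = sd(dA) / sqrt(n_mc) / log(2),
       mc_se_H0 = sd(d0) / sqrt(n_mc) / log(2), n_mc = n_mc)
}

#' Bayes-factor test of multinomial homogeneity between populations
#'
#' Compares, at one codon site, the hypothesis that the unselected and
#' selected populations share a single (synonymous, nonsynonymous)
#' frequency pair (pooled Dirichlet-multinomial marginal likelihood)
#' against independent pairs. Positive values favour homogeneity. This
#' pooled-versus-independent construction is this package's realisation of
#' a multinomial homogeneity test; it integrates over all frequencies
#' compatible with the data rather than comparing point estimates.
#'
#' @param n_ns_us,n_total_us nonsynonymous count and clone total at the
#'   site in the unselected population.
#' @param n_ns_mx,n_total_mx the same for the selected population.
#' @param alpha Dirichlet hyperparameter.
#' @return log2 Bayes factor (pooled over independent).
#' @export
homogeneity_test <- function(n_ns_us, n_total_us, n_ns_mx, n_total_mx,
                             alpha = 0.5) {
  s_us <- n_total_us - n_ns_us
  s_mx <- n_total_mx - n_ns_mx
  stopifnot(s_us >= 0, s_mx >= 0)
  lm_pool <- lbeta(s_us + s_mx + alpha, n_ns_us + n_ns_mx + alpha) -
    lbeta(alpha, alpha)
  lm_ind <- (lbeta(s_us + alpha, n_ns_us + alpha) - lbeta(alpha, alpha)) +
    (lbeta(s_mx + alpha, n_ns_mx + alpha) - lbeta(alpha, alpha))
  (lm_pool - lm_ind) / log(2)
}

#' Per-site one-degree-of-freedom chi-squared statistic
#'
#' The classical non-binned chi-squared comparing observed against expected
#' nonsynonymous counts at one site, provided for comparison plots against
#' the Evidence-of-Selection score; it is not used for inference.
#'
#' @param n_ns observed nonsynonymous count.
#' @param n_total clones at the site.
#' @param null_p_ns null nonsynonymous probability (point value).
#' @return chi-squared value with 1 degree of freedom.
#' @examples
#' chi2_site_statistic(0, 100, 0.05)  # 25/5 + 25/95
#' @export
chi2_site_statistic <- function(n_ns, n_total, null_p_ns) {
  e_ns <- n_total * null_p_ns
  e_sn <- n_total - e_ns
  if (e_ns <= 0 || e_sn <= 0) stop("zero expected count in chi-squared")
  (n_ns - e_ns)^2 / e_ns + ((n_total - n_ns) - e_sn)^2 / e_sn
}

## null p_ns draws per site from an array of mutation-matrix draws --------

## P_draws: 4 x 4 x n_mc; returns n_sites x n_mc matrix of p_ns draws
null_pns_draws <- function(wt_codons, P_draws, code = genetic_code("1")) {
  n_mc <- dim(P_draws)[3]
  Pf <- matrix(P_draws, 16L, n_mc)       # row (j-1)*4 + i
  idx <- function(i, j) (j - 1L) * 4L + i
  n_sites <- length(wt_codons)
  out <- matrix(0, n_sites, n_mc)
  base_idx <- function(cd) match(strsplit(cd, "")[[1]], NUC)
  for (s in seq_len(n_sites)) {
    wt <- base_idx(wt_codons[s])
    syn <- synonymous_set(wt_codons[s], code)
    p_sn <- 0
    for (d in syn) {
      di <- base_idx(d)
      p_sn <- p_sn + Pf[idx(di[1], wt[1]), ] * Pf[idx(di[2], wt[2]), ] *
        Pf[idx(di[3], wt[3]), ]
    }
    out[s, ] <- 1 - p_sn
  }
  out
}

#' Evidence-of-Selection scan over all codon sites
#'
#' Scores every site of one population's codon count table against a null
#' model given as draws of the nucleotide mutation matrix (from the
#' Dirichlet null via [sample_mutation_matrices()] or the polymerase null
#' via [sample_posterior_T()]), computing the EoS score, its Monte-Carlo
#' standard error, the reliability pair, and observed/expected
#' nonsynonymous counts.
#'
#' @param counts `site_counts` data.frame from [tabulate_codon_counts()].
#' @param P_draws 4 x 4 x n_mc array of null mutation-matrix draws (draws
#'   are recycled if fewer than `n_mc`).
#' @param code a [genetic_code()].
#' @param n_mc Monte-Carlo size per site.
#' @param seed integer seed for the HA draws.
#' @param alpha Dirichlet hyperparameter for HA.
#' @param prior_odds prior odds Pr(HA)/Pr(H0).
#' @param threshold_odds posterior odds at which a site is flagged as
#'   selected (default 20, i.e. R >= log2 20 ~ 4.32); the conventional 4:1
#'   "negligible" cut is also reported.
#' @param reliability_n_mc Monte-Carlo size for the reliability pair (the
#'   exact outcome sum makes it the expensive part; 0 skips it).
#' @param population label copied into the output.
#' @return data.frame of class `eos_result` with columns `site`,
#'   `wt_codon`, `population`, `R`, `mc_se`, `D_HA`, `D_H0`, `n_ns_obs`,
#'   `n_ns_exp`, `chi2`, `selected` (R at or above the threshold),
#'   `negligible` (posterior odds under 4:1).
#' @export
eos_scan <- function(counts, P_draws, code = genetic_code("1"),
                     n_mc = 10000L, seed = 1L, alpha = 0.5, prior_odds = 1,
                     threshold_odds = 20, reliability_n_mc = 2000L,
                     population = "us") {
  stopifnot(inherits(counts, "data.frame"), n_mc >= 1)
  set.seed(seed)
  n_draws <- dim(P_draws)[3]
  sel <- if (n_draws >= n_mc) seq_len(n_mc) else
    rep_len(seq_len(n_draws), n_mc)     # recycle short chains
  pns0 <- null_pns_draws(counts$wt_codon, P_draws[, , sel, drop = FALSE], code)
  n_sites <- nrow(counts)
  R <- mc_se <- D_HA <- D_H0 <- n_ns_exp <- chi2 <- numeric(n_sites)
  rel_sel <- if (reliability_n_mc > 0L)
    seq_len(min(reliability_n_mc, n_mc)) else integer(0)
  for (s in seq_len(n_sites)) {
    n <- counts$n_total[s]; k_ns <- counts$n_ns[s]
    p0 <- pns0[s, ]
    n_ns_exp[s] <- n * mean(p0)
    if (n == 0L) next
    pA <- stats::rbeta(n_mc, k_ns + alpha, n - k_ns + alpha)
    d <- loglik_terms(k_ns, n, pA) - loglik_terms(k_ns, n, p0) +
      log(prior_odds)
    R[s] <- mean(d) / log(2)
    mc_se[s] <- sd(d) / sqrt(n_mc) / log(2)
    chi2[s] <- chi2_site_statistic(k_ns, n, mean(p0))
    if (length(rel_sel)) {
      rel <- reliability(pA[rel_sel], p0[rel_sel], n)
      D_HA[s] <- rel$D_HA; D_H0[s] <- rel$D_H0
    }
  }
  out <- data.frame(site = counts$site, wt_codon = counts$wt_codon,
                    population = population, R = R, mc_se = mc_se,
                    D_HA = D_HA, D_H0 = D_H0,
                    n_ns_obs = counts$n_ns, n_ns_exp = n_ns_exp, chi2 = chi2,
                    selected = R >= log2(threshold_odds),
                    negligible = R < log2(4),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("eos_result", "data.frame")
  attr(out, "threshold_odds") <- threshold_odds
  out
}

#' @rdname eos_scan
#' @param results an `eos_result` data.frame.
#' @param path output TSV file.
#' @export
write_eos_table <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
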