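---
title: "Scoring unigenic evolution experiments: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring unigenic evolution experiments: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unigenicEoS)
```

## The experiment and the statistical problem

Unigenic evolution saturates a single gene with random point mutations
(error-prone PCR with a non-proofreading polymerase), clones the products,
and applies a functional selection. Sequencing two pools — clones that
never saw selection ("unselected", `us`) and clones that survived it
("selected", `mx`) — turns protein function into count data: at every
codon site, how many clones carry a synonymous versus a nonsynonymous
change. Sites essential for function tolerate fewer nonsynonymous changes
than the mutagenesis process would produce on its own, so a per-site
*deficit* of nonsynonymous mutations is evidence of purifying selection.

Two features make naive tests unreliable here. Per-site mutation
probabilities are small (roughly 0.005–0.07 per codon) while clone counts
are modest (tens to a hundred), so normal approximations behind
chi-squared statistics are shaky; and functionally-critical residues need
not be adjacent in sequence, so window-based smoothing answers the wrong
question. This package instead scores each site with a fully Bayesian
expected log-odds-ratio — the Evidence of Selection (EoS) — and pairs
every score with an explicit power estimate.

## Null models for the mutation process

Everything starts from the 4×4 misincorporation count matrix $C$ of the
unselected pool: $c_{ij}$ counts wild-type base $j$ read as clone base
$i$. Two null models turn $C$ into a column-stochastic per-site mutation
matrix $P$:

* **Black-box Dirichlet null.** Each column of $P$ is an independent
  multinomial with the objective (Jeffreys/Berger–Bernardo) reference
  prior, giving the conjugate posterior
  $P_{\cdot j} \mid C \sim \mathrm{Dirichlet}(C_{\cdot j} + \tfrac12)$.
  Point summaries are the relative counts $c_{ij}/c_{+j}$ and the
  natural-parameter (posterior mean log-frequency) estimate
  $E[\log p_i] = \psi(n_i + \tfrac12) - \psi(\sum_i (n_i + \tfrac12))$.
  The difference of digamma functions is the standard Dirichlet result and
  is what reproduces the published estimate table; we use it throughout.

* **Mechanistic polymerase null.** Mutagenic PCR is modelled as $k$
  cycles of error-prone synthesis by a polymerase operator $T$
  ($\tau_{ij}$ = probability adduct $i$ pairs against template $j$). One
  cycle maps the sense/nonsense strand pair to
  $\left(\tfrac12(s + Tn),\, \tfrac12(n + Ts)\right)$: half the molecules
  keep the old strand, half get a fresh error-prone copy. Iterating from
  each pure base gives $P(T, k)$. $T$ has 16 entries but 12 degrees of
  freedom; internally it is the column-softmax of 16 log-parameters, and
  all inference lives on the 12-dimensional quotient of that log-space by
  the four per-column shift directions. The prior is Jeffreys' rule — half
  the log pseudo-determinant of the Fisher information projected onto the
  quotient — which keeps the inference invariant to reparameterisation of
  the error rates. The Fisher information uses the expected-count
  approximation $E[c_{ij}] \approx c_{+j}\, p_{ij}$, i.e. the wild-type
  base composition is taken as observed. The MAP estimate maximises
  likelihood × prior by quasi-Newton iteration in the 12 gauge-fixed
  coordinates, and a random-walk Metropolis chain with the inverse
  projected Fisher information as proposal covariance samples the exact
  posterior (the asymptotic proposal only affects efficiency, never
  correctness).

The mechanistic model exists because complementary error rates
($p_{ij}$ versus $p_{\tilde i \tilde j}$) are empirically near-equal, a
pattern that per-column multinomials cannot explain but that falls out of
strand-pair copying automatically.

### Second derivatives and the Fisher information

Derivatives of $P(T,k)$ with respect to the entries of $T$ are propagated
forward through the cycle recursion together with the values — the same
idea as forward-mode differentiation arithmetic — and chain-ruled into
the softmax log-parameter coordinates. Because each column of $P$ sums to
one identically, the second-derivative term of the expected information
cancels after summation, leaving the outer-product form
$F = \sum_{ij} (c_{+j}/p_{ij}) \nabla p_{ij} \nabla p_{ij}^{\mathsf T}$,
which is what the MAP optimiser evaluates; `fisher_information()` computes
the full two-term expression and the test suite asserts both the
equality of the two forms and agreement with central finite differences.

## From nucleotides to codons

Site-independent nucleotide mutation lifts to codons by the Kronecker
product $M = P \otimes P \otimes P$ (codon order is lexicographic over
A, C, G, T; position one most significant — the ordering is fixed because
the Kronecker construction ties it to index arithmetic). For wild-type
codon $w$, the synonymous-class probability $p_{sn}$ sums $M_{\cdot w}$
over all codons translating identically to $w$, *including $w$ itself*
(the identity outcome is part of the synonymous class);
$p_{ns} = 1 - p_{sn}$. Genetic codes come from the NCBI translation
tables shipped with Biostrings, so non-standard codes are one argument
away. Stop codons always fall in the nonsynonymous class; a clone
acquiring a premature stop is counted as one nonsynonymous event at that
site by default (policy `drop-clone` removes the clone instead), because
stop production was rare enough in the reference system not to move
results. Multi-nucleotide codon changes count as one event, which matches
the per-clone multinomial likelihood.

## The EoS score and its reliability

At site $j$ with $n$ clones and $x$ nonsynonymous events, two hypotheses
compete. The null pushes the nucleotide-level posterior (either model)
through the codon operator to a posterior on $p_{ns,j}$; the alternate
infers $p_{ns,j}$ from the site's own counts, with posterior
$\mathrm{Beta}(x + \tfrac12,\, n - x + \tfrac12)$, accommodating any
selection mechanism. The score is the expected log-odds-ratio

$$R_j = E\!\left[\log_2 \frac{\Pr(x \mid p^{HA})\,\Pr(H_A)}
{\Pr(x \mid p^{H_0})\,\Pr(H_0)}\right],$$

evaluated by pairing independent Monte-Carlo draws from the two
posteriors (default 10 000 pairs, with the standard error of the mean
reported alongside; prior odds default to 1). $R_j > 0$ favours
selection; values near zero are indeterminate; small negative values are
expected from sampling variance and read as zero. Scores add over
disjoint site sets, which self-corrects for multiplicity at the cost of
understating the odds when a set mixes true and false positives. By
convention a site is reported as selected at posterior odds 20:1
($R \ge \log_2 20 \approx 4.32$); odds under 4:1 are flagged negligible.

Reliability is the Kullback–Leibler confusion pair: $D_{HA}$ averages the
log-likelihood-ratio over all $n + 1$ possible outcomes weighted by the
alternate hypothesis (expected true-positive : false-negative log-odds),
$D_{H_0}$ swaps the roles. The outcome sum is exact; only the posterior
integration is Monte Carlo, and Gibbs' inequality makes every per-draw
term non-negative. A companion per-site homogeneity Bayes factor (pooled
versus independent Dirichlet-multinomial marginals — this package's
construction, chosen for its closed form) shows why codon counts alone
cannot separate the pools, and a one-degree-of-freedom chi-squared is
provided purely for comparison plots.

## The synthetic-data generator

`simulate_clones()` emulates the reference experiment: 87 clones per
pool, 30 PCR cycles, and per-site mutation frequencies defaulting to the
column-normalised published unselected counts. Clones are drawn per site
i.i.d. from the columns of $P$ — exactly the process the inference model
assumes — rather than by simulating PCR strand lineages; jackpot effects,
stutter and chromatogram noise are deliberately out of scope, so passing
tests validate the inferential machinery, not robustness to those
artefacts. Selection is hard rejection: at each configured site the codon
is redrawn until it satisfies the mode (`reject-nonsynonymous` for
functional conservation, `reject-any-change` for the start-codon ligation
artefact), which by site independence equals rejection-sampling whole
clones. Positive-control sites in the shipped tests use tyrosine codons
because their nonsynonymous exposure under the published frequencies is
the largest of any amino acid (about 0.06 per clone), mirroring the fact
that in the reference system only the motif tyrosines cleared the 20:1
threshold.

## Numerical choices

* Cycle count defaults to $k = 30$ (the reference protocol); thermal
  cycles are treated as exactly $k$ applications of the cycle operator.
* The iterative cycle recursion is always used; the closed-form binomial
  expansion (tested against it to $10^{-12}$ up to $k = 7$) underflows at
  realistic $k$.
* MAP optimisation: BFGS with numerical gradients in the 12 gauge-fixed
  coordinates, restarted once at the optimum; degenerate points
  (numerically singular projected information) receive a large penalty so
  line searches retreat. Convergence failures are errors, never silent.
* Metropolis proposals use the inverse projected Fisher information at
  the MAP scaled by an adapted scalar (target band 10–40% acceptance,
  standard 2.38/\sqrt{12} starting scale); proposals that step outside
  the feasible region are rejected. Seeds are mandatory; a rerun with the
  same settings reproduces every draw.
* All randomness in the pipeline derives from one master seed through
  fixed named offsets, so reruns are byte-identical.
* N bases mask a position (and its codon, for that clone) from all
  counts; clones of deviating length are rejected rather than aligned,
  since indels break the codon frame and the experimental design
  sequences full-length clones.
* Wild-type sequences must be stop-free after removal of a terminal stop
  codon; internal stops are errors.

## Problem sizes used in the shipped tests

The acceptance checks run the published count matrix through all three
estimators (the MAP fit takes seconds), and exercise the synthetic
pipeline at the study scale: 266 codons, 87 + 87 clones, six
hard-conserved tyrosine sites, 10 000 Monte-Carlo pairs per site for
scoring, 500 for reliability, a Metropolis chain of 12 000 recorded steps
thinned to a few hundred draws, and $10^5$ replicates for the
whole-protein mutation-count distribution against its exact
Poisson-binomial oracle.

## Known limitations

* **Null-site scores are not pinned to zero.** At realistic clone counts
  the alternate hypothesis's posterior is much more diffuse than the
  null's, so an unselected site's score sits in a band of roughly
  $-0.7$ to $+3$ log2-odds driven by binomial sampling of the clones —
  *not* by Monte-Carlo error, which is two orders of magnitude smaller.
  The negative control is therefore "no site clears the reporting
  threshold beyond the nominal false-positive rate", not "every score is
  numerically zero". Occasional large null-site scores are expected
  (about one site in a few hundred at 20:1) and match the false-positive
  accounting.
* **The two null models agree closely but not to within Monte-Carlo
  error.** Posterior means of rare error rates under the Dirichlet and
  polymerase nulls differ by up to ~10% relative (visible in the
  published estimate table itself: e.g. 0.27 versus 0.24 for one entry),
  which propagates to per-site score differences of up to a few tenths of
  a log2-odds unit at mutation-bearing sites. This is far below any
  decision threshold — no site classification changes between nulls — but
  it is a systematic model difference, and with large Monte-Carlo sizes
  it is resolvable above the sampling error. The shipped regression test
  records it.
* Second-site interactions (epistasis, premature-stop truncation of
  downstream codons) are not modelled; hyper-mutability is undetectable
  by design, since selection can only remove variants.
* The sample-size ("divided by sample size") convention in the
  asymptotic posterior is interpreted as: the information matrix already
  carries the observed per-column event counts, so its inverse *is* the
  asymptotic covariance — no second division — with the Metropolis
  accept/reject step guaranteeing correctness regardless.

## A worked example

```{r example, eval = FALSE}
library(unigenicEoS)

## published unselected counts -> three estimates of P
C <- ibmoi_counts()$us
relative_frequencies(C)
fit <- map_estimate(C, k = 30)       # mechanistic null, Jeffreys prior
round(100 * fit$P, 2)

## synthetic experiment at study scale
cfg <- simulation_config(n_codons = 100, n_clones = 87,
                         selected_sites = c(10, 40),
                         selection_mode = "reject-nonsynonymous", seed = 1)
sim <- simulate_clones(cfg)
Cs <- tabulate_nucleotide_counts(sim$us)
draws <- sample_mutation_matrices(Cs, 10000, seed = 2)
scores <- eos_scan(tabulate_codon_counts(sim$mx), draws,
                   n_mc = 10000, seed = 3, population = "mx")
subset(scores, selected)
```
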