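## shared fixtures, built in code

## a random column-stochastic polymerase matrix near the perfect-fidelity
## complement operator
random_T <- function(seed = 1, eps = 0.05) {
  set.seed(seed)
  T <- complement_fidelity() + matrix(runif(16, 0, eps), 4)
  polymerase_matrix(sweep(T, 2, colSums(T), "/"))
}

## published unselected counts and their column totals
tab1_us <- function() ibmoi_counts()$us

## Table-layout percentages of the published frequency estimates
## (relative-count and natural-parameter blocks are identical at 2 d.p.)
tab2_relative <- function() {
  matrix(c(97.46, 0.10, 0.24, 1.15,
           0.27, 99.72, 0.01, 1.16,
           1.16, 0.02, 99.58, 0.18,
           1.11, 0.16, 0.17, 97.51),
         4, 4, byrow = TRUE, dimnames = list(nuc_alphabet(), nuc_alphabet()))
}

tab2_map <- function() {
  matrix(c(97.47, 0.13, 0.20, 1.14,
           0.24, 99.66, 0.02, 1.17,
           1.16, 0.02, 99.65, 0.23,
           1.12, 0.19, 0.13, 97.46),
         4, 4, byrow = TRUE, dimnames = list(nuc_alphabet(), nuc_alphabet()))
}

## small deterministic clone population with known differences
tiny_population <- function() {
  wt <- "ATGCTTAAA"               # M  L  K
  clones <- c("ATGCTTAAA",        # identical
              "ATGCTGAAA",        # CTT->CTG  Leu->Leu  synonymous
              "ATACTTAAA",        # ATG->ATA  Met->Ile  nonsynonymous
              "ATGCTTTAA",        # AAA->TAA  Lys->stop nonsynonymous
              "ATGNTTAAA")        # N masks codon 2 for this clone
  clone_population(wt, clones, "us")
}
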