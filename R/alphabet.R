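#' @importFrom stats optim rgamma rbinom runif rnorm setNames dbinom quantile
#'   qbinom sd median cor
#' @importFrom utils write.table read.table modifyList
NULL

## Fixed nucleotide alphabet.  Row/column order of every 4x4 matrix in the
## package is A, C, G, T; Watson-Crick complement is the involution A<->T,
## C<->G.  All index arithmetic (including the 64-codon Kronecker ordering)
## hangs off this ordering, so it is defined once here.

NUC <- c("A", "C", "G", "T")
NUC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Nucleotide alphabet and complement
#'
#' The package uses the fixed alphabet ordering A, C, G, T for all
#' misincorporation matrices. `nuc_alphabet()` returns that ordering;
#' `nuc_complement()` maps each base to its Watson-Crick complement.
#'
#' @param x character vector of single bases (subset of A, C, G, T).
#' @return `nuc_alphabet()`: the character vector `c("A","C","G","T")`.
#'   `nuc_complement(x)`: the complemented bases, same length as `x`.
#' @examples
#' nuc_complement(nuc_alphabet())   # "T" "G" "C" "A"
#' @export
nuc_alphabet <- function() NUC

#' @rdname nuc_alphabet
#' @export
nuc_complement <- function(x) {
  out <- NUC_COMPLEMENT[x]
  if (anyNA(out)) stop("non-ACGT base passed to nuc_complement()")
  unname(out)
}

## 4x4 permutation matrix K with K e_j = e_{complement(j)}; the
## perfect-fidelity polymerase is exactly K.
complement_operator <- function() {
  K <- matrix(0, 4, 4, dimnames = list(NUC, NUC))
  K[cbind(unname(NUC_COMPLEMENT[NUC]), NUC)] <- 1
  K
}

## All 64 codons in lexicographic A,C,G,T order: AAA, AAC, ..., TTT.
## This order is consistent with kronecker(P, kronecker(P, P)): position 1
## is the most significant index.
CODONS <- as.vector(t(outer(
  as.vector(t(outer(NUC, NUC, paste0))), NUC, paste0)))

codon_index <- function(codon) {
  i <- match(codon, CODONS)
  if (anyNA(i)) stop("unknown codon(s): ", paste(codon[is.na(i)], collapse = ", "))
  i
}

#' Genetic code tables
#'
#' Wraps the NCBI translation tables shipped with Biostrings into the codon
#' ordering used by this package (lexicographic over A, C, G, T). Any NCBI
#' table id accepted by [Biostrings::getGeneticCode()] can be used, so
#' mitochondrial or plastid codes need no extra code.
#'
#' @param table_id NCBI translation-table identifier as a string
#'   (e.g. `"1"` standard, `"2"` vertebrate mitochondrial).
#' @return An object of class `genetic_code`: a list with `table_id` and
#'   `map`, a named character vector of length 64 mapping each codon (in
#'   package order) to its one-letter amino acid, with `"*"` for stops.
#' @examples
#' code <- genetic_code("1")
#' code$map[["ATG"]]  # "M"
#' sum(code$map == "*")  # 3 stops in the standard code
#' @export
genetic_code <- function(table_id = "1") {
  tab <- Biostrings::getGeneticCode(as.character(table_id))
  map <- setNames(unname(tab[CODONS]), CODONS)
  stopifnot(length(map) == 64L, !anyNA(map))
  structure(list(table_id = as.character(table_id), map = map),
            class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code (NCBI table ", x$table_id, "): ",
      sum(x$map != "*"), " sense codons, ",
      sum(x$map == "*"), " stops\n", sep = "")
  invisible(x)
}

## Codons synonymous with `codon` (same translation, codon itself included).
synonymous_set <- function(codon, code) {
  aa <- code$map[[codon]]
  names(code$map)[code$map == aa]
}
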