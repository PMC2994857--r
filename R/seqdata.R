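## seqdata: clone populations, misincorporation counts, codon mutation counts.
##
## Clones are assumed pre-aligned to the wild type and indel-free (full-length
## sequencing); a clone of different length is rejected rather than aligned.
## The ambiguity code N masks a nucleotide position (and its codon, for that
## clone only) from all counts.

#' Construct a clone population
#'
#' Bundles a wild-type coding sequence with a set of equal-length clone
#' sequences from one pool of a unigenic-evolution experiment. The two pools
#' are conventionally labelled `"us"` (unselected, no functional selection)
#' and `"mx"` (selected for function).
#'
#' @param wild_type single nucleotide string, length divisible by 3.
#' @param clones character vector of clone sequences, each the same length
#'   as the wild type. Characters must be A, C, G, T or N; lower case and U
#'   are normalised.
#' @param label population label, `"us"` or `"mx"`.
#' @return An object of class `clone_population` with elements `label`,
#'   `wild_type`, `clones`, `n_clones`, `length`.
#' @examples
#' pop <- clone_population("ATGAAA", c("ATGAAA", "ATGAAG"), "us")
#' pop$n_clones
#' @export
clone_population <- function(wild_type, clones, label = c("us", "mx")) {
  label <- match.arg(label)
  wild_type <- normalize_seq(wild_type)
  clones <- vapply(clones, normalize_seq, character(1), USE.NAMES = FALSE)
  L <- nchar(wild_type)
  if (L == 0L) stop("empty wild-type sequence")
  if (L %% 3L != 0L)
    stop("wild-type length ", L, " is not divisible by 3 (frame violation)")
  bad <- which(nchar(clones) != L)
  if (length(bad))
    stop("alignment error: clone(s) ", paste(bad, collapse = ", "),
         " differ in length from the wild type (", L, " nt); ",
         "indel-bearing clones are not supported")
  if (grepl("N", wild_type, fixed = TRUE))
    stop("wild-type sequence may not contain N")
  structure(list(label = label, wild_type = wild_type, clones = clones,
                 n_clones = length(clones), length = L),
            class = "clone_population")
}

normalize_seq <- function(x) {
  x <- chartr("u", "t", tolower(x))
  x <- toupper(x)
  if (grepl("[^ACGTN]", x))
    stop("parse error: sequence contains non-IUPAC characters ",
         "(only A, C, G, T, U, N are accepted)")
  x
}

#' @export
print.clone_population <- function(x, ...) {
  cat("clone_population '", x$label, "': ", x$n_clones, " clones x ",
      x$length, " nt (", x$length / 3L, " codons)\n", sep = "")
  invisible(x)
}

## character matrix clones x positions, NA where base is N
clone_char_matrix <- function(pop) {
  m <- matrix(unlist(strsplit(pop$clones, "", fixed = TRUE), use.names = FALSE),
              nrow = pop$n_clones, byrow = TRUE)
  m[m == "N"] <- NA_character_
  m
}

#' Tabulate nucleotide misincorporation counts
#'
#' Counts, over all clones and positions, how often wild-type nucleotide
#' \eqn{j} was read as clone nucleotide \eqn{i}, giving the 4x4 matrix
#' \eqn{C} with entry \eqn{c_{ij}}. Columns correspond to the wild-type
#' base, rows to the clone base; each non-N clone position contributes
#' exactly one count to the column of its wild-type base.
#'
#' @param pop a [clone_population()].
#' @return An object of class `misincorporation_counts`: a 4x4 integer
#'   matrix (rows/cols A, C, G, T) with attribute `column_totals`.
#' @examples
#' pop <- clone_population("AAA", c("AAA", "ACA"), "us")
#' tabulate_nucleotide_counts(pop)  # c_AA = 5, c_CA = 1
#' @export
tabulate_nucleotide_counts <- function(pop) {
  stopifnot(inherits(pop, "clone_population"))
  wt <- strsplit(pop$wild_type, "", fixed = TRUE)[[1]]
  m <- clone_char_matrix(pop)
  wt_mat <- matrix(wt, nrow = pop$n_clones, ncol = pop$length, byrow = TRUE)
  keep <- !is.na(m)
  C <- table(factor(m[keep], levels = NUC), factor(wt_mat[keep], levels = NUC))
  C <- matrix(as.integer(C), 4, 4, dimnames = list(NUC, NUC))
  misincorporation_counts(C)
}

#' Misincorporation count matrix
#'
#' Validates and classes a 4x4 wild-type-to-clone nucleotide count matrix
#' in the fixed A, C, G, T ordering.
#'
#' @param C 4x4 non-negative integer matrix, `C[i, j]` = count of wild-type
#'   base j read as clone base i.
#' @return object of class `misincorporation_counts`.
#' @export
misincorporation_counts <- function(C) {
  C <- as.matrix(C)
  stopifnot(identical(dim(C), c(4L, 4L)), all(C >= 0), all(C == round(C)))
  dimnames(C) <- list(NUC, NUC)
  structure(C, column_totals = colSums(C), class = c("misincorporation_counts", "matrix"))
}

#' @export
print.misincorporation_counts <- function(x, ...) {
  cat("Misincorporation counts (clone row <- wild-type column):\n")
  print(unclass(x)[seq_len(4), seq_len(4)])
  cat("Total:", attr(x, "column_totals"), "\n")
  invisible(x)
}

## split wild type into codons
wt_codons <- function(pop) {
  substring(pop$wild_type,
            seq(1L, pop$length, by = 3L),
            seq(3L, pop$length, by = 3L))
}

#' Tabulate per-codon synonymous/nonsynonymous mutation counts
#'
#' For each codon site (1-based, reading frame fixed at position 1) counts
#' the clones whose codon differs from the wild-type codon, split into
#' synonymous (same translation) and nonsynonymous (different translation).
#' A whole-codon change counts as one event regardless of how many of its
#' three nucleotides differ. A clone codon containing N is skipped at that
#' site for that clone. Premature stop codons are counted as nonsynonymous
#' by default (`stop_policy = "nonsynonymous"`); with
#' `stop_policy = "drop-clone"` a clone acquiring a premature stop is
#' excluded from codon counts entirely.
#'
#' @param pop a [clone_population()].
#' @param code a [genetic_code()].
#' @param stop_policy how clone codons translating to stop are treated.
#' @return data.frame of class `site_counts` with columns `site`,
#'   `wt_codon`, `aa`, `n_sn`, `n_ns`, `n_total` (clones counted at that
#'   site; `n_sn + n_ns <= n_total`, the remainder being identical codons).
#' @examples
#' pop <- clone_population("CTT", c("CTG", "CTT"), "us")
#' tabulate_codon_counts(pop, genetic_code("1"))  # CTG is still Leu: n_sn = 1
#' @export
tabulate_codon_counts <- function(pop, code = genetic_code("1"),
                                  stop_policy = c("nonsynonymous", "drop-clone")) {
  stopifnot(inherits(pop, "clone_population"), inherits(code, "genetic_code"))
  stop_policy <- match.arg(stop_policy)
  wt <- wt_codons(pop)
  n_sites <- length(wt)
  wt_aa <- code$map[wt]
  if (any(wt_aa == "*"))
    stop("wild-type sequence contains stop codon(s) at site(s) ",
         paste(which(wt_aa == "*"), collapse = ", "),
         "; trim the terminal stop before analysis")

  starts <- seq(1L, pop$length, by = 3L)
  cl <- matrix("", nrow = pop$n_clones, ncol = n_sites)
  for (j in seq_len(n_sites))
    cl[, j] <- substr(pop$clones, starts[j], starts[j] + 2L)
  masked <- matrix(grepl("N", cl, fixed = TRUE), nrow = pop$n_clones)
  aa <- matrix(NA_character_, nrow = pop$n_clones, ncol = n_sites)
  aa[!masked] <- code$map[cl[!masked]]

  if (stop_policy == "drop-clone") {
    has_stop <- apply(aa == "*", 1L, any, na.rm = TRUE)
    keep <- !has_stop
    cl <- cl[keep, , drop = FALSE]
    aa <- aa[keep, , drop = FALSE]
    masked <- masked[keep, , drop = FALSE]
  }

  n_total <- colSums(!masked)
  differs <- sweep(cl, 2L, wt, FUN = "!=") & !masked
  same_aa <- sweep(aa, 2L, wt_aa, FUN = "==")
  same_aa[is.na(same_aa)] <- FALSE
  n_sn <- colSums(differs & same_aa)
  n_ns <- colSums(differs & !same_aa)

  out <- data.frame(site = seq_len(n_sites), wt_codon = wt,
                    aa = unname(wt_aa), n_sn = as.integer(n_sn),
                    n_ns = as.integer(n_ns), n_total = as.integer(n_total),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("site_counts", "data.frame")
  out
}

#' Read a clone population from FASTA files
#'
#' Reads the wild-type sequence (first record of `wild_type_path`) and one
#' multi-record FASTA of clone sequences. Sequences are upper-cased and U
#' is mapped to T; record order is preserved.
#'
#' @param path FASTA of clone sequences, one record per clone.
#' @param wild_type_path FASTA containing the wild-type sequence.
#' @param label population label, `"us"` or `"mx"`.
#' @return a [clone_population()].
#' @export
read_fasta_population <- function(path, wild_type_path, label = c("us", "mx")) {
  label <- match.arg(label)
  wt_set <- Biostrings::readBStringSet(wild_type_path)
  if (length(wt_set) == 0L) stop("empty wild-type FASTA: ", wild_type_path)
  clones <- Biostrings::readBStringSet(path)
  if (length(clones) == 0L) stop("empty clone FASTA: ", path)
  clone_population(as.character(wt_set[[1L]]),
                   as.character(clones), label = label)
}

#' Write count tables as TSV
#'
#' `write_nucleotide_counts` writes the 4x4 misincorporation matrix with a
#' Total row (the layout of the experiment's published count table);
#' `write_codon_counts` writes the per-site synonymous/nonsynonymous table.
#'
#' @param C a `misincorporation_counts` matrix.
#' @param counts a `site_counts` data.frame.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_nucleotide_counts <- function(C, path) {
  df <- as.data.frame(rbind(unclass(C)[1:4, 1:4], Total = attr(C, "column_totals")))
  df <- cbind(base = rownames(df), df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_nucleotide_counts
#' @export
write_codon_counts <- function(counts, path) {
  write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a misincorporation count matrix from TSV
#'
#' Accepts the layout written by [write_nucleotide_counts()] (a `base`
#' column, four count columns A, C, G, T, and an optional Total row).
#'
#' @param path TSV file.
#' @return a `misincorporation_counts` matrix.
#' @export
read_nucleotide_counts <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  rownames(df) <- df[[1L]]
  df <- df[, -1L, drop = FALSE]
  df <- df[rownames(df) %in% NUC, , drop = FALSE]
  C <- as.matrix(df[NUC, NUC])
  misincorporation_counts(C)
}
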