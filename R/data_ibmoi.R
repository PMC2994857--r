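#' Published I-BmoI misincorporation counts
#'
#' The 4x4 wild-type-to-clone nucleotide misincorporation count matrices
#' tabulated from 87 unselected and 87 functionally selected clones of the
#' GIY-YIG homing endonuclease I-BmoI after 30 cycles of mutagenic PCR.
#' Columns are the wild-type base, rows the clone base; both populations
#' share the same column totals because the same 266-codon coding sequence
#' was sequenced in every clone.
#'
#' These counts are the packaged reference fixture: the unselected matrix
#' drives the null mutation models and the worked examples.
#'
#' @return list with elements `us` and `mx`, each a
#'   [misincorporation_counts()] matrix.
#' @examples
#' attr(ibmoi_counts()$us, "column_totals")  # 24273 18096 11223 15834
#' @export
ibmoi_counts <- function() {
  us <- matrix(c(
    23656,    18,    27,   182,
       65, 18045,     1,   184,
      282,     4, 11176,    29,
      270,    29,    19, 15439), nrow = 4, byrow = TRUE,
    dimnames = list(NUC, NUC))
  mx <- matrix(c(
    24024,    11,    12,    80,
       24, 18058,     1,    72,
      154,     0, 11203,     9,
       71,    27,     7, 15673), nrow = 4, byrow = TRUE,
    dimnames = list(NUC, NUC))
  list(us = misincorporation_counts(us), mx = misincorporation_counts(mx))
}
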