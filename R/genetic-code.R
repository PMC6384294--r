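#' Plastid genetic code (NCBI translation table 11)
#'
#' Builds the codon table used for all conceptual translation: NCBI
#' translation table 11 (bacterial, archaeal and plant plastid), in which
#' TAA, TAG and TGA are the stop codons. The set of codons accepted as a
#' valid translation initiation site is configurable; the default is ATG
#' only, so that alternative initiators such as GTG are *not* silently
#' accepted and an ACG start still triggers an editing annotation.
#'
#' @param valid_start_codons character vector of codons (DNA alphabet)
#'   accepted as valid starts without editing. Default `"ATG"`.
#' @return An object of class `genetic_code`: a list with elements
#'   `table` (named character vector mapping all 64 codons to one-letter
#'   amino acids, stops to `"*"`), `valid_start_codons` and `stop_codons`.
#' @examples
#' code <- genetic_code()
#' code$table[["TGG"]]   # "W"
#' code$stop_codons      # TAA, TAG, TGA
#' @export
genetic_code <- function(valid_start_codons = "ATG") {
  valid_start_codons <- toupper(valid_start_codons)
  if (!all(grepl("^[ACGT]{3}$", valid_start_codons))) {
    stop("valid_start_codons must be 3-letter codons over {A,C,G,T}")
  }
  tab <- Biostrings::getGeneticCode("11")
  tab <- tab[order(names(tab))]
  structure(
    list(
      table = tab,
      valid_start_codons = unique(valid_start_codons),
      stop_codons = sort(names(tab)[tab == "*"])
    ),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code: translation table 11 (plastid)\n")
  cat("  valid start codons:", paste(x$valid_start_codons, collapse = ", "), "\n")
  cat("  stop codons:       ", paste(x$stop_codons, collapse = ", "), "\n")
  invisible(x)
}

#' Split a nucleotide string into codons
#'
#' @param seq single nucleotide string, length divisible by 3.
#' @return character vector of 3-letter codons, 5' to 3'.
#' @keywords internal
split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3")
  if (n == 0L) return(character(0))
  starts <- seq.int(1L, n, by = 3L)
  substring(seq, starts, starts + 2L)
}

#' Translate a codon vector
#'
#' Codons absent from the table (e.g. containing N) translate to `"X"`.
#'
#' @param codons character vector of codons.
#' @param code a [genetic_code()] object.
#' @return character vector of one-letter amino acids (`"*"` for stops).
#' @keywords internal
translate_codons <- function(codons, code) {
  aa <- unname(code$table[codons])
  aa[is.na(aa)] <- "X"
  aa
}

revcomp <- function(seq) {
  # IUPAC-complete complement; fixtures only use ACGTN
  chartr("ACGTNRYSWKMBDHVacgtnryswkmbdhv",
         "TGCANYRSWMKVHDBtgcanyrswmkvhdb",
         vapply(seq, function(s) {
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
         }, character(1), USE.NAMES = FALSE))
}
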