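# Small in-code fixtures shared across test files.

# a handcrafted minimal flat file: gene + CDS over a 300-bp sequence
minimal_gb_sequence <- paste(rep("ATGGCTGCAGCT", 25L), collapse = "")

minimal_gb_lines <- function(seq = minimal_gb_sequence) {
  lc <- tolower(seq)
  starts <- seq.int(1L, nchar(lc), by = 60L)
  origin <- vapply(starts, function(s) {
    cs <- seq.int(s, min(s + 59L, nchar(lc)), by = 10L)
    sprintf("%9d %s", s,
            paste(substring(lc, cs, pmin(cs + 9L, nchar(lc))),
                  collapse = " "))
  }, character(1))
  c(sprintf("LOCUS       TESTACC %d bp    DNA     linear PLN 01-JAN-2019",
            nchar(seq)),
    "DEFINITION  minimal two-feature record.",
    "ACCESSION   TESTACC",
    "FEATURES             Location/Qualifiers",
    "     gene            1..300",
    "                     /gene=\"tst\"",
    "     CDS             1..300",
    "                     /gene=\"tst\"",
    "                     /product=\"test protein\"",
    "ORIGIN      ",
    origin,
    "//")
}

write_minimal_gb <- function(path = tempfile(fileext = ".gb"), ...) {
  writeLines(minimal_gb_lines(...), path)
  path
}

gff3_text <- function(lines, path = tempfile(fileext = ".gff3"),
                      pragma = "##gff-version 3") {
  writeLines(c(pragma, lines), path)
  path
}

# deterministic defective fixture used by several files
defective_fixture <- function(seed = 2024L, n_genes = 12L) {
  make_plastome(n_genes = n_genes, fraction_edited = 0.6,
                strand_mix = 0.4, introns = 0.25, seed = seed,
                dir = tempfile("fx"))
}

sorted_edit_cols <- c("gene", "genomic_position", "strand", "direction",
                      "role", "codon_before", "codon_after")

normalize_edits <- function(df) {
  df <- df[order(df$gene, df$genomic_position, df$role), sorted_edit_cols]
  rownames(df) <- NULL
  df
}
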