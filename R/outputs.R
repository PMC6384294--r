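#' Write an NCBI five-column feature table
#'
#' Emits the tab-delimited `.tbl` submission format consumed by
#' table2asn: a `>Feature <accession>` header, then per feature a
#' `start<TAB>end<TAB>key` line (minus-strand features written
#' `end>start`, compound locations as continuation coordinate lines) and
#' `<TAB><TAB><TAB>qualifier<TAB>value` lines. The `/translation`
#' qualifier is omitted (table2asn recomputes it); the `source` feature
#' is not part of the table format and is skipped.
#'
#' @param record a [genome_record()].
#' @param path output path.
#' @return `invisible(path)`.
#' @export
write_feature_table <- function(record, path) {
  validate_record(record)
  out <- sprintf(">Feature %s", record$accession)
  for (f in record$features) {
    if (f$kind == "source") next
    iv <- f$intervals          # already in coding 5'->3' order
    for (r in seq_len(nrow(iv))) {
      a <- iv[r, 1L]; b <- iv[r, 2L]
      if (f$strand == "-") { tmp <- a; a <- b; b <- tmp }
      out <- c(out, if (r == 1L) sprintf("%d\t%d\t%s", a, b, f$kind)
                    else sprintf("%d\t%d", a, b))
    }
    for (q in f$qualifiers) {
      if (q$name == "translation") next
      out <- c(out, if (is.na(q$value)) sprintf("\t\t\t%s", q$name)
                    else sprintf("\t\t\t%s\t%s", q$name, q$value))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Write conceptual translations of edited genes as protein FASTA
#'
#' One record per gene with at least one inferred editing event (genes
#' without edits are excluded); headers are
#' `><accession>_<gene_id>` and sequences are the conceptual
#' translations without the terminal stop, wrapped at 60 columns. A run
#' with no edits yields an empty file.
#'
#' @param reports list of `gene_report` from [process_gene()].
#' @param path output path.
#' @param accession accession used in headers.
#' @return `invisible(path)`.
#' @export
write_protein_fasta <- function(reports, path, accession) {
  keep <- Filter(function(r) length(r$edits) > 0L && !is.na(r$translation),
                 reports)
  seqs <- vapply(keep, `[[`, character(1), "translation")
  names(seqs) <- sprintf("%s_%s", accession,
                         vapply(keep, `[[`, character(1), "gene_id"))
  aa <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

#' Write the per-gene run report as TSV
#'
#' Columns: `gene`, `status`, `n_edits`, `five_prime_shift`,
#' `three_prime_shift`, `messages` (semicolon-joined).
#'
#' @param reports list of `gene_report`.
#' @param path output path.
#' @return `invisible(path)`.
#' @export
write_run_report <- function(reports, path) {
  df <- data.frame(
    gene = vapply(reports, `[[`, character(1), "gene_id"),
    status = vapply(reports, `[[`, character(1), "status"),
    n_edits = vapply(reports, function(r) length(r$edits), integer(1)),
    five_prime_shift = vapply(reports, function(r) r$boundary_shift[1L],
                              integer(1)),
    three_prime_shift = vapply(reports, function(r) r$boundary_shift[2L],
                               integer(1)),
    messages = vapply(reports, function(r) {
      paste(r$messages, collapse = "; ")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
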