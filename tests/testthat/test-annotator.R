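# builds a one-gene plus-strand genome around a codon vector, with
# all-G spacers so the boundary window never finds spurious candidates
one_gene_genome <- function(codons, flank = strrep("G", 60L)) {
  spliced <- paste(codons, collapse = "")
  seq <- paste0(flank, spliced, flank)
  start <- nchar(flank) + 1L
  model <- gene_model("g1", cbind(start, start + nchar(spliced) - 1L), "+")
  genome <- genome_record("ONE1", seq, list(
    gb_feature("gene", cbind(start, start + nchar(spliced) - 1L), "+",
               list(plastedit:::qualifier("gene", "g1"))),
    gb_feature("CDS", cbind(start, start + nchar(spliced) - 1L), "+",
               list(plastedit:::qualifier("gene", "g1")))))
  model$source_feature_index <- 2L
  list(genome = genome, model = model)
}

test_that("a defect-free gene is reported clean with zero edits", {
  x <- one_gene_genome(c("ATG", rep("GGA", 10L), "TAA"))
  rep <- process_gene(x$model, x$genome)
  expect_identical(rep$status, "clean")
  expect_length(rep$edits, 0L)
  expect_identical(rep$boundary_shift, c(0L, 0L))
  expect_identical(rep$translation, paste0("M", strrep("G", 10L)))
})

test_that("a gene with bad start, bad stop and one internal stop yields exactly three edits", {
  codons <- c("ACG", rep("GGA", 12L), "CAA")
  codons[8L] <- "TGA"
  x <- one_gene_genome(codons)
  rep <- process_gene(x$model, x$genome)
  expect_identical(rep$status, "edited")
  expect_length(rep$edits, 3L)
  roles <- vapply(rep$edits, `[[`, character(1), "role")
  expect_setequal(roles, c("start_rescue", "stop_rescue",
                           "internal_stop_rescue"))
  expect_false(grepl("*", rep$translation, fixed = TRUE))
  # each edit's genomic base matches its direction (C for C-to-U, T for U-to-C)
  for (ev in rep$edits) {
    base <- substr(x$genome$sequence, ev$genomic_position,
                   ev$genomic_position)
    expect_identical(base, if (ev$direction == "C-to-U") "C" else "T")
  }
})

test_that("more internal stops than the limit flags the gene and applies nothing", {
  codons <- c("ATG", rep("GGA", 20L), "TAA")
  codons[2L + 2L * (1:6)] <- "TAG"
  x <- one_gene_genome(codons)
  rep <- process_gene(x$model, x$genome)
  expect_identical(rep$status, "manual_check")
  expect_length(rep$edits, 0L)
  expect_match(rep$messages[1L], "6 internal stop")
  expect_true(is.na(rep$translation))

  # at the limit, the gene is fully rescued
  codons[2L + 2L * 6L] <- "GGA"
  x <- one_gene_genome(codons)
  rep <- process_gene(x$model, x$genome)
  expect_identical(rep$status, "edited")
  expect_length(rep$edits, 5L)

  # and the limit is a configuration knob
  rep <- process_gene(x$model, x$genome,
                      plastedit_config(internal_stop_limit = 4L))
  expect_identical(rep$status, "manual_check")
})

test_that("boundary adjustment rescues a start five codons upstream but not six", {
  build <- function(offset) {
    # ACG planted `offset` codons upstream of the annotated CTG start
    up <- rep("GGG", 10L)
    up[10L - offset + 1L] <- "ACG"
    codons <- c("CTG", rep("GGA", 10L), "TAA")
    flank <- strrep("G", 30L)
    seq <- paste0(flank, paste(up, collapse = ""),
                  paste(codons, collapse = ""), flank)
    start <- nchar(flank) + 31L
    genome <- genome_record("BW1", seq, list(
      gb_feature("CDS", cbind(start, start + 35L), "+",
                 list(plastedit:::qualifier("gene", "gb")))))
    model <- gene_model("gb", cbind(start, start + 35L), "+")
    model$source_feature_index <- 1L
    process_gene(model, genome)
  }
  rep <- build(5L)
  expect_identical(rep$status, "boundary_adjusted")
  expect_identical(rep$boundary_shift[1L], -5L)
  expect_length(rep$edits, 1L)
  expect_identical(rep$edits[[1L]]$role, "start_rescue")
  expect_identical(rep$edits[[1L]]$codon_index, 0L)

  rep <- build(6L)
  expect_identical(rep$status, "manual_check")
  expect_length(rep$edits, 0L)
})

test_that("apply_annotations adds one misc_feature per edit site and is idempotent", {
  codons <- c("ATG", rep("GGA", 12L), "TAA")
  codons[6L] <- "TGA"
  x <- one_gene_genome(codons)
  rep <- process_gene(x$model, x$genome)
  out <- apply_annotations(x$genome, list(rep))
  misc <- Filter(function(f) f$kind == "misc_feature", out$features)
  expect_length(misc, 1L)
  expect_identical(unname(misc[[1L]]$intervals),
                   cbind(rep$edits[[1L]]$genomic_position,
                         rep$edits[[1L]]$genomic_position))
  cds <- Filter(function(f) f$kind == "CDS", out$features)[[1L]]
  expect_identical(plastedit:::qual_values(cds, "exception"), "RNA editing")
  expect_identical(plastedit:::qual_values(cds, "translation"),
                   rep$translation)

  # second application adds nothing
  out2 <- apply_annotations(out, list(rep))
  expect_length(out2$features, length(out$features))
  expect_true(record_equal(out, out2))
})

test_that("a report with zero edits only adds the /translation qualifier", {
  x <- one_gene_genome(c("ATG", rep("GGA", 10L), "TAA"))
  rep <- process_gene(x$model, x$genome)
  out <- apply_annotations(x$genome, list(rep))
  expect_length(out$features, length(x$genome$features))
  stripped <- out
  i <- x$model$source_feature_index
  stripped$features[[i]]$qualifiers <-
    Filter(function(q) q$name != "translation",
           stripped$features[[i]]$qualifiers)
  expect_true(record_equal(stripped, x$genome))
})

test_that("pseudo-flagged genes are skipped untouched even when defective", {
  codons <- c("ACG", rep("GGA", 8L), "TGA", rep("GGA", 3L), "TAA")
  x <- one_gene_genome(codons)
  x$model$pseudo <- TRUE
  rep <- process_gene(x$model, x$genome)
  expect_identical(rep$status, "skipped")
  expect_length(rep$edits, 0L)
  out <- apply_annotations(x$genome, list(rep))
  expect_true(record_equal(out, x$genome))
})

test_that("the full pipeline writes four outputs and reports the planted edits exactly", {
  fx <- defective_fixture(seed = 777L)
  out_dir <- tempfile("run")
  res <- annotate_plastome(fx$genbank, fx$gff3, out_dir)
  expect_true(all(file.exists(res$files)))
  expect_identical(res$totals$genes, fx$manifest$n_genes)
  expect_identical(normalize_edits(edit_table(res)),
                   normalize_edits(fx$truth_table))
  # totals aggregate the per-gene reports
  expect_identical(res$totals$edits,
                   sum(vapply(res$reports, function(r) length(r$edits),
                              integer(1))))
  # no input feature is lost (same kind at the same location and strand)
  input <- read_genbank(fx$genbank)
  out <- res$record
  key <- function(f) paste(f$kind, f$strand, paste(t(f$intervals), collapse = ","))
  out_keys <- vapply(out$features, key, character(1))
  for (f in input$features) expect_true(key(f) %in% out_keys)
})

test_that("missing inputs fail before any output is written", {
  out_dir <- tempfile("none")
  expect_error(annotate_plastome(tempfile(), tempfile(), out_dir))
  expect_false(dir.exists(out_dir))
})

test_that("run reports print a human-readable summary", {
  fx <- defective_fixture(seed = 31L, n_genes = 4L)
  res <- annotate_plastome(fx$genbank, fx$gff3)
  expect_output(print(res), "gene\\(s\\)")
  expect_output(print(res$reports[[1L]]), "gene_report")
})
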