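#' @title Synthetic plastome fixtures with planted RNA-editing defects
#' @description
#' Real validation of an editing annotator needs cDNA-confirmed
#' plastomes; for automated testing this module instead generates toy
#' plastomes in which every editing-required defect is planted by
#' *reverse-applying* a legal edit (write ACG where ATG belongs, write a
#' genomic stop where a sense codon belongs, write CAA/CAG/CGA where the
#' stop belongs). Every planted defect is therefore rescuable by
#' construction and a correct annotator must recover the planted truth
#' set exactly.
#' @name synthetic_fixtures
NULL

sense_codons <- function(code = genetic_code()) {
  setdiff(names(code$table), code$stop_codons)
}

# one random ORF as a codon vector: ATG start, sense body, stop end
random_orf <- function(n_codons, code) {
  body <- sample(sense_codons(code), n_codons - 2L, replace = TRUE)
  c("ATG", body, sample(code$stop_codons, 1L))
}

# reverse-apply edits; returns list(codons, defects) with codon-space truth
plant_defects <- function(codons, n_defects, code) {
  n <- length(codons)
  roles <- character(0)
  pool <- c("start", "stop")
  n_internal_max <- min(5L, n - 3L)
  for (i in seq_len(n_defects)) {
    choices <- c(pool, if (sum(roles == "internal") < n_internal_max) "internal")
    if (length(choices) == 0L) break
    pick <- sample(choices, 1L)
    if (pick != "internal") pool <- setdiff(pool, pick)
    roles <- c(roles, pick)
  }
  defects <- list()
  internal_at <- sample(seq.int(2L, n - 1L),
                        sum(roles == "internal"))  # 1-based codon slots
  ii <- 0L
  for (role in roles) {
    if (role == "start") {
      codons[1L] <- "ACG"
      defects[[length(defects) + 1L]] <- list(
        codon_index = 0L, pos_in_codon = 2L, role = "start_rescue",
        direction = "C-to-U", codon_before = "ACG", codon_after = "ATG",
        amino_acid_after = "M")
    } else if (role == "stop") {
      after <- codons[n]
      before <- sub("^T", "C", after)     # CAA / CAG / CGA
      codons[n] <- before
      defects[[length(defects) + 1L]] <- list(
        codon_index = n - 1L, pos_in_codon = 1L, role = "stop_rescue",
        direction = "C-to-U", codon_before = before, codon_after = after,
        amino_acid_after = "*")
    } else {
      ii <- ii + 1L
      at <- internal_at[ii]
      planted <- sample(code$stop_codons, 1L)
      rescued <- sub("^T", "C", planted)  # unique single-T rescue
      codons[at] <- planted
      defects[[length(defects) + 1L]] <- list(
        codon_index = at - 1L, pos_in_codon = 1L,
        role = "internal_stop_rescue", direction = "U-to-C",
        codon_before = planted, codon_after = rescued,
        amino_acid_after = unname(code$table[rescued]))
    }
  }
  list(codons = codons, defects = defects)
}

random_spacer <- function() {
  paste(sample(c("A", "C", "G", "T"), sample(30:150, 1L), replace = TRUE),
        collapse = "")
}

# gene spec: list(id, product, codons, strand, intron_split (spliced bases
# before the intron, or NULL), intron_seq, defects, pseudo, declare_trim)
assemble_plastome <- function(genes, accession, dir, spacer_fun = random_spacer) {
  seq_parts <- character(0)
  pos <- 0L
  add <- function(s) {
    seq_parts[[length(seq_parts) + 1L]] <<- s
    pos <<- pos + nchar(s)
  }
  features <- list()
  gff <- c("##gff-version 3")
  truth <- list()

  add(spacer_fun())
  for (g in genes) {
    spliced <- paste(g$codons, collapse = "")
    len <- nchar(spliced)
    if (!is.null(g$intron_split)) {
      p <- g$intron_split
      il <- nchar(g$intron_seq)
      segment <- paste0(substr(spliced, 1L, p), g$intron_seq,
                        substring(spliced, p + 1L))
      g0 <- pos + 1L
      if (g$strand == "+") {
        iv <- rbind(c(g0, g0 + p - 1L),
                    c(g0 + p + il, g0 + p + il + (len - p) - 1L))
      } else {
        segment <- revcomp(segment)
        L <- len + il
        iv <- rbind(c(g0 + L - p, g0 + L - 1L),
                    c(g0, g0 + (len - p) - 1L))
      }
      add(segment)
    } else {
      g0 <- pos + 1L
      segment <- if (g$strand == "-") revcomp(spliced) else spliced
      add(segment)
      iv <- rbind(c(g0, g0 + len - 1L))
    }

    trim <- if (!is.null(g$declare_trim)) g$declare_trim else 0L
    div <- iv
    if (trim > 0L) {       # mis-declared frame: declared CDS is short
      if (g$strand == "+") div[nrow(div), 2L] <- div[nrow(div), 2L] - trim
      else div[nrow(div), 1L] <- div[nrow(div), 1L] + trim
    }

    quals <- list(qualifier("gene", g$id))
    gene_f <- gb_feature("gene", cbind(min(div), max(div)), g$strand, quals)
    cds_quals <- c(quals, list(qualifier("product", g$product),
                               qualifier("transl_table", "11", quoted = FALSE)))
    if (isTRUE(g$pseudo)) {
      cds_quals <- c(cds_quals, list(qualifier("pseudo")))
      gene_f$qualifiers <- c(gene_f$qualifiers, list(qualifier("pseudo")))
    }
    features[[length(features) + 1L]] <- gene_f
    features[[length(features) + 1L]] <- gb_feature("CDS", div, g$strand,
                                                    cds_quals)

    gff <- c(gff, gff_lines_for_gene(accession, g, div))

    model <- gene_model(g$id, div, g$strand)
    for (d in g$defects) {
      gp <- spliced_index_to_genomic(model, d$codon_index, d$pos_in_codon)
      truth[[length(truth) + 1L]] <- data.frame(
        gene = g$id, genomic_position = gp, strand = g$strand,
        direction = d$direction, role = d$role,
        codon_before = d$codon_before, codon_after = d$codon_after,
        amino_acid_after = d$amino_acid_after, stringsAsFactors = FALSE)
    }
    add(spacer_fun())
  }

  sequence <- paste(seq_parts, collapse = "")
  features <- c(list(gb_feature("source", cbind(1L, nchar(sequence)), "+",
                                list(qualifier("organism", "synthetic construct"),
                                     qualifier("mol_type", "genomic DNA")))),
                features)
  rec <- genome_record(accession, sequence, features, topology = "circular")

  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gb_path <- file.path(dir, paste0(accession, ".gb"))
  gff_path <- file.path(dir, paste0(accession, ".gff3"))
  truth_path <- file.path(dir, paste0(accession, "_truth.tsv"))
  write_genbank(rec, gb_path)
  writeLines(gff, gff_path)
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(gene = character(0), genomic_position = integer(0),
               strand = character(0), direction = character(0),
               role = character(0), codon_before = character(0),
               codon_after = character(0), amino_acid_after = character(0),
               stringsAsFactors = FALSE)
  utils::write.table(truth_df, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  list(genbank = gb_path, gff3 = gff_path, truth = truth_path,
       truth_table = truth_df, record = rec, accession = accession,
       manifest = list(
         n_genes = length(genes),
         n_features = length(features),
         genes = data.frame(
           gene = vapply(genes, `[[`, character(1), "id"),
           strand = vapply(genes, `[[`, character(1), "strand"),
           n_codons = vapply(genes, function(g) length(g$codons), integer(1)),
           n_defects = vapply(genes, function(g) length(g$defects), integer(1)),
           multi_exon = vapply(genes, function(g) !is.null(g$intron_split),
                               logical(1)),
           pseudo = vapply(genes, function(g) isTRUE(g$pseudo), logical(1)),
           stringsAsFactors = FALSE)))
}

gff_lines_for_gene <- function(accession, g, div) {
  gid <- paste0("gene-", g$id)
  cid <- paste0("cds-", g$id)
  attr_extra <- if (isTRUE(g$pseudo)) ";pseudo=true" else ""
  lines <- sprintf("%s\t.\tgene\t%d\t%d\t.\t%s\t.\tID=%s;gene=%s%s",
                   accession, min(div), max(div), g$strand, gid, g$id,
                   attr_extra)
  # phase per coding-order part; emit rows in ascending coordinate order
  widths <- div[, 2L] - div[, 1L] + 1L
  phase <- (3L - c(0L, cumsum(widths)[-length(widths)]) %% 3L) %% 3L
  o <- order(div[, 1L])
  for (r in o) {
    lines <- c(lines, sprintf(
      "%s\t.\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s;Parent=%s;gene=%s;product=%s%s",
      accession, div[r, 1L], div[r, 2L], g$strand, phase[r], cid, gid,
      g$id, g$product, attr_extra))
  }
  lines
}

#' Generate a toy plastome with planted RNA-editing defects
#'
#' Genes are random open reading frames (ATG start, stop end, sense-only
#' body, lengths 150-1500 bp) separated by random intergenic spacers;
#' a chosen fraction carry planted defects obtained by reverse-applying
#' legal single-base edits, so each defect is rescuable and the truth
#' set records exactly the events a correct annotator must emit.
#' Minus-strand genes are reverse-complemented into the genome; a
#' fraction of genes carry one intron (two CDS intervals).
#'
#' @param n_genes number of protein-coding genes (>= 1).
#' @param fraction_edited fraction of genes carrying planted defects.
#' @param defects_per_gene integer vector sampled from for the number of
#'   defects per edited gene (default 1:3; at most one bad start, one
#'   bad stop, five internal stops).
#' @param strand_mix fraction of genes on the minus strand.
#' @param introns fraction of genes with a single intron.
#' @param seed integer seed; identical parameters and seed give
#'   byte-identical files.
#' @param dir output directory.
#' @param accession accession for the fixture (default derived from
#'   seed).
#' @return list with paths `genbank`, `gff3`, `truth`, plus
#'   `truth_table` (data.frame of planted events), the in-memory
#'   `record`, and a generator `manifest`.
#' @export
make_plastome <- function(n_genes = 20L, fraction_edited = 0.5,
                          defects_per_gene = 1:3, strand_mix = 0.3,
                          introns = 0.2, seed = 1L,
                          dir = tempfile("plastome"),
                          accession = sprintf("SYNPL%05d", seed %% 100000L)) {
  stopifnot(n_genes >= 1L, fraction_edited >= 0, fraction_edited <= 1,
            strand_mix >= 0, strand_mix <= 1, introns >= 0, introns <= 1)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  code <- genetic_code()

  n_edited <- round(n_genes * fraction_edited)
  edited <- rep(FALSE, n_genes)
  if (n_edited > 0L) edited[sample.int(n_genes, n_edited)] <- TRUE

  genes <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    n_codons <- sample(50:500, 1L)
    codons <- random_orf(n_codons, code)
    defects <- list()
    if (edited[i]) {
      k <- sample(rep(defects_per_gene, 2L), 1L)
      planted <- plant_defects(codons, k, code)
      codons <- planted$codons
      defects <- planted$defects
    }
    strand <- if (stats::runif(1) < strand_mix) "-" else "+"
    has_intron <- stats::runif(1) < introns
    intron_split <- NULL
    intron_seq <- NULL
    if (has_intron) {
      intron_split <- sample(seq.int(6L, 3L * n_codons - 6L), 1L)
      intron_seq <- paste(sample(c("A", "C", "G", "T"), sample(50:200, 1L),
                                 replace = TRUE), collapse = "")
    }
    genes[[i]] <- list(id = sprintf("g%03d", i),
                       product = sprintf("hypothetical plastid protein %d", i),
                       codons = codons, strand = strand,
                       intron_split = intron_split, intron_seq = intron_seq,
                       defects = defects, pseudo = FALSE)
  }
  assemble_plastome(genes, accession, dir)
}

#' Generate the pathological edge-case fixture
#'
#' A deterministic toy plastome exercising the manual-check and skip
#' paths: a gene with six internal stops (over the default limit of
#' five), a gene whose CTG start has no valid or rescuable codon within
#' five codons, a CDS whose declared length is not divisible by 3, a
#' gene with N in its start codon, a minus-strand two-exon gene with one
#' planted internal stop in each exon, and a pseudo-flagged gene with a
#' planted start defect.
#'
#' @param dir output directory.
#' @return as [make_plastome()]; `manifest$expected_status` gives the
#'   expected per-gene annotator status.
#' @export
make_edge_cases <- function(dir = tempfile("edgecases")) {
  code <- genetic_code()
  gga <- function(n) rep("GGA", n)

  genes <- list()
  # 1. six internal stops: over the default limit -> manual_check
  codons <- c("ATG", gga(20), "TAA")
  codons[3L + 3L * (0:5)] <- "TGA"
  genes$g_sixstops <- list(id = "g_sixstops", product = "six internal stops",
                           codons = codons, strand = "+",
                           intron_split = NULL, intron_seq = NULL,
                           defects = list(), pseudo = FALSE)
  # 2. five internal stops: exactly at the limit -> fully rescued
  codons <- c("ATG", gga(20), "TAA")
  idx5 <- 3L + 3L * (0:4)
  codons[idx5] <- "TGA"
  genes$g_fivestops <- list(
    id = "g_fivestops", product = "five internal stops", codons = codons,
    strand = "+", intron_split = NULL, intron_seq = NULL,
    defects = lapply(idx5, function(i) list(
      codon_index = i - 1L, pos_in_codon = 1L,
      role = "internal_stop_rescue", direction = "U-to-C",
      codon_before = "TGA", codon_after = "CGA", amino_acid_after = "R")),
    pseudo = FALSE)
  # 3. unrescuable start, nothing in the window -> manual_check
  genes$g_badstart <- list(id = "g_badstart", product = "unrescuable start",
                           codons = c("CTG", gga(15), "TAA"), strand = "+",
                           intron_split = NULL, intron_seq = NULL,
                           defects = list(), pseudo = FALSE)
  # 4. declared CDS length not divisible by 3 -> manual_check
  genes$g_frame <- list(id = "g_frame", product = "frame suspect",
                        codons = c("ATG", gga(12), "TAA"), strand = "+",
                        intron_split = NULL, intron_seq = NULL,
                        defects = list(), pseudo = FALSE, declare_trim = 1L)
  # 5. N in the start codon -> manual_check
  genes$g_ncodon <- list(id = "g_ncodon", product = "ambiguous start",
                         codons = c("ANG", gga(10), "TAA"), strand = "+",
                         intron_split = NULL, intron_seq = NULL,
                         defects = list(), pseudo = FALSE)
  # 6. minus-strand, two exons, one planted internal stop in each
  codons <- c("ATG", rep("GCT", 18), "TAG")
  codons[5L] <- "TAA"; codons[15L] <- "TGA"
  genes$g_twoexon <- list(
    id = "g_twoexon", product = "two-exon minus-strand gene",
    codons = codons, strand = "-", intron_split = 30L,
    intron_seq = strrep("AT", 30L),
    defects = list(
      list(codon_index = 4L, pos_in_codon = 1L,
           role = "internal_stop_rescue", direction = "U-to-C",
           codon_before = "TAA", codon_after = "CAA",
           amino_acid_after = "Q"),
      list(codon_index = 14L, pos_in_codon = 1L,
           role = "internal_stop_rescue", direction = "U-to-C",
           codon_before = "TGA", codon_after = "CGA",
           amino_acid_after = "R")),
    pseudo = FALSE)
  # 7. pseudo-flagged gene with defects -> skipped, zero edits
  genes$g_pseudo <- list(id = "g_pseudo", product = "pseudogene",
                         codons = c("ACG", gga(8), "TGA", gga(3), "TAA"),
                         strand = "+", intron_split = NULL,
                         intron_seq = NULL, defects = list(), pseudo = TRUE)

  out <- assemble_plastome(unname(genes), "SYNEDGE01", dir,
                           spacer_fun = function() strrep("G", 60L))
  out$manifest$expected_status <- c(
    g_sixstops = "manual_check", g_fivestops = "edited",
    g_badstart = "manual_check", g_frame = "manual_check",
    g_ncodon = "manual_check", g_twoexon = "edited",
    g_pseudo = "skipped")
  out
}
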