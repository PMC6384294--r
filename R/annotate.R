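#' Annotation run configuration
#'
#' @param internal_stop_limit maximum number of internal stop codons the
#'   annotator will rescue in one gene; above this the gene is flagged
#'   for manual checking (default 5). Genes with more than five edited
#'   internal stops exist but are rare, so exceeding the limit is
#'   treated as a sign of a frameshift, pseudogene or assembly error.
#' @param boundary_window_codons how far (in codons) to search for a
#'   valid or rescuable codon when the annotated boundary codon cannot
#'   itself be rescued (default 5).
#' @param valid_start_codons codons accepted as valid starts without
#'   editing; default `"ATG"` (add `"GTG"` etc. to accept table-11
#'   alternative initiators, at the cost of fewer editing annotations).
#' @param seqid_alias optional named character vector mapping GFF3
#'   seqids to the GenBank accession.
#' @return object of class `plastedit_config`.
#' @export
plastedit_config <- function(internal_stop_limit = 5L,
                             boundary_window_codons = 5L,
                             valid_start_codons = "ATG",
                             seqid_alias = NULL) {
  stopifnot(internal_stop_limit >= 0L, boundary_window_codons >= 0L)
  structure(list(internal_stop_limit = as.integer(internal_stop_limit),
                 boundary_window_codons = as.integer(boundary_window_codons),
                 valid_start_codons = toupper(valid_start_codons),
                 seqid_alias = seqid_alias,
                 code = genetic_code(valid_start_codons)),
            class = "plastedit_config")
}

new_gene_report <- function(gene_id, status, edits = list(),
                            boundary_shift = c(0L, 0L),
                            translation = NA_character_,
                            messages = character(0), model = NULL) {
  structure(list(gene_id = gene_id, status = status, edits = edits,
                 boundary_shift = as.integer(boundary_shift),
                 translation = translation, messages = messages,
                 model = model),
            class = "gene_report")
}

#' @export
print.gene_report <- function(x, ...) {
  cat(sprintf("<gene_report> %s: %s, %d edit(s), shift (%+d, %+d)\n",
              x$gene_id, x$status, length(x$edits),
              x$boundary_shift[1L], x$boundary_shift[2L]))
  for (m in x$messages) cat("  -", m, "\n")
  invisible(x)
}

# genomic flank on the coding strand, truncated at the sequence ends;
# returns list(seq, codons = number of whole codons obtained)
coding_flank <- function(genome, model, side, n_codons) {
  len <- nchar(genome$sequence)
  need <- 3L * n_codons
  outward_5p <- (side == "five_prime")
  if (model$strand == "+") {
    if (outward_5p) {
      to <- model$intervals[1L, 1L] - 1L
      from <- max(1L, to - need + 1L)
      s <- if (to >= from) substr(genome$sequence, from, to) else ""
      # keep frame: trim from the far (upstream) end
      extra <- nchar(s) %% 3L
      if (extra) s <- substring(s, extra + 1L)
    } else {
      from <- model$intervals[nrow(model$intervals), 2L] + 1L
      to <- min(len, from + need - 1L)
      s <- if (to >= from) substr(genome$sequence, from, to) else ""
      s <- substr(s, 1L, nchar(s) - nchar(s) %% 3L)
    }
  } else {
    if (outward_5p) {
      from <- model$intervals[1L, 2L] + 1L
      to <- min(len, from + need - 1L)
      s <- if (to >= from) revcomp(substr(genome$sequence, from, to)) else ""
      extra <- nchar(s) %% 3L
      if (extra) s <- substring(s, extra + 1L)
    } else {
      to <- model$intervals[nrow(model$intervals), 1L] - 1L
      from <- max(1L, to - need + 1L)
      s <- if (to >= from) revcomp(substr(genome$sequence, from, to)) else ""
      s <- substr(s, 1L, nchar(s) - nchar(s) %% 3L)
    }
  }
  list(seq = s, codons = nchar(s) %/% 3L)
}

# shift gene boundaries by whole codons; negative five_off extends 5',
# positive three_off extends 3'
shift_model <- function(model, five_off = 0L, three_off = 0L) {
  iv <- model$intervals
  b5 <- 3L * five_off
  b3 <- 3L * three_off
  n <- nrow(iv)
  if (model$strand == "+") {
    if (b5 < 0L) iv[1L, 1L] <- iv[1L, 1L] + b5
    if (b3 > 0L) iv[n, 2L] <- iv[n, 2L] + b3
  } else {
    if (b5 < 0L) iv[1L, 2L] <- iv[1L, 2L] - b5
    if (b3 > 0L) iv[n, 1L] <- iv[n, 1L] - b3
  }
  # inward shifts consume spliced bases across exon boundaries
  if (b5 > 0L) iv <- consume_front(iv, model$strand, b5)
  if (b3 < 0L) iv <- consume_back(iv, model$strand, -b3)
  out <- model
  out$intervals <- iv
  out
}

consume_front <- function(iv, strand, nbases) {
  while (nbases > 0L && nrow(iv) > 0L) {
    w <- iv[1L, 2L] - iv[1L, 1L] + 1L
    if (nbases >= w) {
      iv <- iv[-1L, , drop = FALSE]
      nbases <- nbases - w
    } else {
      if (strand == "+") iv[1L, 1L] <- iv[1L, 1L] + nbases
      else iv[1L, 2L] <- iv[1L, 2L] - nbases
      nbases <- 0L
    }
  }
  iv
}

consume_back <- function(iv, strand, nbases) {
  while (nbases > 0L && nrow(iv) > 0L) {
    n <- nrow(iv)
    w <- iv[n, 2L] - iv[n, 1L] + 1L
    if (nbases >= w) {
      iv <- iv[-n, , drop = FALSE]
      nbases <- nbases - w
    } else {
      if (strand == "+") iv[n, 2L] <- iv[n, 2L] - nbases
      else iv[n, 1L] <- iv[n, 1L] + nbases
      nbases <- 0L
    }
  }
  iv
}

# anchor a codon-space edit to the genome
place_edit <- function(ev, model, codon_index) {
  ev$codon_index <- as.integer(codon_index)
  ev$genomic_position <- spliced_index_to_genomic(model, codon_index,
                                                  ev$pos_in_codon)
  ev$strand <- model$strand
  ev$gene_id <- model$gene_id
  ev
}

#' Process one gene model for RNA-editing rescue
#'
#' Runs the full per-gene procedure: (1) the annotated start codon is
#' checked for validity, then for single-edit rescue, then the boundary
#' window is scanned; (2) likewise for the final (stop) codon; (3)
#' internal stops of the (possibly re-bounded) CDS are counted — more
#' than `internal_stop_limit` flags the gene for manual checking with no
#' edits applied — and each is rescued by a U-to-C edit; (4) the
#' conceptual translation of the edited transcript is computed. A gene
#' either resolves completely or is reported `manual_check` with none of
#' its annotations changed; no error is raised.
#'
#' @param model a reconciled [gene_model()].
#' @param genome the [genome_record()].
#' @param config a [plastedit_config()].
#' @return a `gene_report` with fields `gene_id`, `status` (`clean`,
#'   `edited`, `boundary_adjusted`, `manual_check` or `skipped`),
#'   `edits`, `boundary_shift` (5' and 3' offsets in codons),
#'   `translation`, `messages`, and the final `model`.
#' @export
process_gene <- function(model, genome, config = plastedit_config()) {
  code <- config$code
  manual <- function(msg, extra = character(0)) {
    new_gene_report(model$gene_id, "manual_check",
                    messages = c(msg, extra), model = model)
  }
  if (model$pseudo) {
    return(new_gene_report(model$gene_id, "skipped",
                           messages = "pseudogene annotation: skipped",
                           model = model))
  }
  if (!is.null(model$flag)) return(manual(model$flag))

  edits <- list()          # codon-space; anchored after boundaries settle
  shift <- c(0L, 0L)
  cur <- model
  spliced <- extract_spliced(genome, cur)

  ## --- 5' boundary -------------------------------------------------
  start_codon <- substr(spliced, 1L, 3L)
  start_edit <- NULL
  if (codon_has_n(start_codon)) {
    return(manual(sprintf("start codon %s contains N; not rescued",
                          start_codon)))
  }
  if (!is_valid_start(start_codon, code)) {
    start_edit <- rescue_start(start_codon, code)
    if (is.null(start_edit)) {
      fl <- coding_flank(genome, cur, "five_prime",
                         config$boundary_window_codons)
      hit <- scan_for_boundary(paste0(fl$seq, spliced), "five_prime",
                               config$boundary_window_codons, code,
                               flank_codons = fl$codons)
      if (is.null(hit)) {
        return(manual(sprintf(
          "start codon %s invalid, not editing-rescuable, and no valid or rescuable codon within %d codons",
          start_codon, config$boundary_window_codons)))
      }
      shift[1L] <- hit$offset_codons
      cur <- shift_model(cur, five_off = hit$offset_codons)
      spliced <- extract_spliced(genome, cur)
      start_edit <- hit$edit
    }
  }
  if (!is.null(start_edit)) edits <- c(edits, list(list(ev = start_edit, at = 0L)))

  ## --- 3' boundary -------------------------------------------------
  n_codons <- nchar(spliced) %/% 3L
  stop_codon <- substr(spliced, nchar(spliced) - 2L, nchar(spliced))
  if (codon_has_n(stop_codon)) {
    return(manual(sprintf("final codon %s contains N; not rescued",
                          stop_codon)))
  }
  if (!is_stop(stop_codon, code)) {
    stop_edit <- rescue_stop(stop_codon, code)
    if (is.null(stop_edit)) {
      fl <- coding_flank(genome, cur, "three_prime",
                         config$boundary_window_codons)
      hit <- scan_for_boundary(paste0(spliced, fl$seq), "three_prime",
                               config$boundary_window_codons, code,
                               flank_codons = fl$codons)
      if (is.null(hit)) {
        return(manual(sprintf(
          "final codon %s is not a stop, not editing-rescuable, and no stop or rescuable codon within %d codons",
          stop_codon, config$boundary_window_codons)))
      }
      shift[2L] <- hit$offset_codons
      cur <- shift_model(cur, three_off = hit$offset_codons)
      spliced <- extract_spliced(genome, cur)
      n_codons <- nchar(spliced) %/% 3L
      stop_edit <- hit$edit
    }
    if (!is.null(stop_edit)) {
      edits <- c(edits, list(list(ev = stop_edit, at = n_codons - 1L)))
    }
  }

  ## --- internal stops ----------------------------------------------
  internal <- find_internal_stops(spliced, code)
  if (nrow(internal) > config$internal_stop_limit) {
    return(manual(sprintf(
      "%d internal stop codons exceed the limit of %d; check for frameshift, pseudogene or assembly error",
      nrow(internal), config$internal_stop_limit)))
  }
  if (nrow(internal) > 0L) {
    for (r in seq_len(nrow(internal))) {
      ev <- rescue_internal_stop(internal$codon[r], code)
      if (is.null(ev)) {
        return(manual(sprintf(
          "internal stop %s at codon %d cannot be rescued by a single U-to-C edit",
          internal$codon[r], internal$codon_index[r])))
      }
      edits <- c(edits, list(list(ev = ev, at = internal$codon_index[r])))
    }
  }

  ## --- translate and commit ----------------------------------------
  placed <- lapply(edits, function(e) place_edit(e$ev, cur, e$at))
  translation <- conceptual_translation(spliced, placed, code)
  status <- if (any(shift != 0L)) "boundary_adjusted"
            else if (length(placed) > 0L) "edited"
            else "clean"
  msgs <- character(0)
  if (any(shift != 0L)) {
    msgs <- sprintf("gene boundaries shifted by (%+d, %+d) codons",
                    shift[1L], shift[2L])
  }
  new_gene_report(model$gene_id, status, edits = placed,
                  boundary_shift = shift, translation = translation,
                  messages = msgs, model = cur)
}

#' Apply gene reports to a genome record
#'
#' Adds one `misc_feature` per editing site (single genomic base, with a
#' note giving the edit direction and gene), an
#' `exception="RNA editing"` qualifier and the conceptual
#' `/translation` on every edited CDS, and updated coordinates for
#' boundary-adjusted genes (the parent `gene` feature is resized with
#' its CDS). Identical pre-existing misc_features are not duplicated, so
#' re-annotating an already-annotated record adds nothing.
#'
#' @param genome a [genome_record()].
#' @param reports list of `gene_report` from [process_gene()].
#' @return the modified [genome_record()].
#' @export
apply_annotations <- function(genome, reports) {
  for (rep in reports) {
    if (rep$status %in% c("manual_check", "skipped")) next
    model <- rep$model
    idx <- model$source_feature_index
    if (is.na(idx)) {
      f <- gb_feature("CDS", model$intervals, model$strand,
                      list(qualifier("gene", model$gene_id)))
      if (nzchar(model$product)) f <- set_qualifier(f, "product", model$product)
      genome$features[[length(genome$features) + 1L]] <- f
      idx <- length(genome$features)
    }
    f <- genome$features[[idx]]
    if (any(rep$boundary_shift != 0L)) {
      old_range <- range(f$intervals)
      f$intervals <- model$intervals
      genome <- resize_parent_gene(genome, model, old_range)
    }
    if (length(rep$edits) > 0L) {
      if (!("RNA editing" %in% qual_values(f, "exception"))) {
        f <- set_qualifier(f, "exception", "RNA editing")
      }
    }
    f <- set_qualifier(f, "translation", rep$translation)
    genome$features[[idx]] <- f
    for (ev in rep$edits) {
      genome <- add_edit_misc_feature(genome, ev)
    }
  }
  genome$features <- sort_features(genome$features)
  validate_record(genome)
  genome
}

resize_parent_gene <- function(genome, model, old_range) {
  for (i in seq_along(genome$features)) {
    f <- genome$features[[i]]
    if (f$kind != "gene") next
    g <- qual_values(f, "gene")
    if (length(g) && g[1L] == model$gene_id &&
        identical(range(f$intervals), as.integer(old_range))) {
      f$intervals[1L, 1L] <- min(model$intervals)
      f$intervals[nrow(f$intervals), 2L] <- max(model$intervals)
      f$intervals <- matrix(range(model$intervals), ncol = 2L,
                            dimnames = list(NULL, c("start", "end")))
      genome$features[[i]] <- f
      break
    }
  }
  genome
}

edit_note <- function(ev) {
  sprintf("RNA editing (%s) in %s: %s becomes %s",
          sub("-to-", " to ", ev$direction), ev$gene_id,
          ev$codon_before, ev$codon_after)
}

add_edit_misc_feature <- function(genome, ev) {
  note <- edit_note(ev)
  pos <- ev$genomic_position
  for (f in genome$features) {
    if (f$kind == "misc_feature" &&
        f$intervals[1L, 1L] == pos && f$intervals[1L, 2L] == pos &&
        note %in% qual_values(f, "note")) {
      return(genome)        # already annotated: idempotence
    }
  }
  f <- gb_feature("misc_feature", cbind(pos, pos), ev$strand,
                  list(qualifier("gene", ev$gene_id),
                       qualifier("note", note)))
  genome$features[[length(genome$features) + 1L]] <- f
  genome
}

sort_features <- function(features) {
  if (length(features) <= 1L) return(features)
  start <- vapply(features, function(f) min(f$intervals), integer(1))
  kind_rank <- vapply(features, function(f) {
    match(f$kind, c("source", "gene", "CDS", "tRNA", "rRNA"),
          nomatch = 9L)
  }, integer(1))
  features[order(start, kind_rank)]
}

#' Annotate a plastid genome for RNA editing
#'
#' The full pipeline: read the GenBank flat file and GFF3, reconcile the
#' gene models, process every CDS for editing rescue, apply annotations,
#' and write four outputs into `out_dir`:
#' `<accession>_edited.gb` (annotated flat file),
#' `<accession>.tbl` (NCBI five-column feature table),
#' `<accession>_proteins.fasta` (conceptual translations of edited
#' genes), and `<accession>_report.tsv` (one row per gene).
#' Genes flagged `manual_check` are warnings, not errors.
#'
#' @param gb_path path to the GenBank flat file.
#' @param gff_path path to the matching GFF3 file.
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing and returns the report and annotated record only.
#' @param config a [plastedit_config()].
#' @return a `run_report`: list with `reports` (per-gene), `totals`,
#'   `notes` (reconciliation messages), `record` (annotated
#'   [genome_record()]) and `files` (paths written).
#' @export
annotate_plastome <- function(gb_path, gff_path, out_dir = NULL,
                              config = plastedit_config()) {
  genome <- read_genbank(gb_path)
  models <- read_gff3(gff_path, genome, seqid_alias = config$seqid_alias)
  models <- reconcile(models, genome)
  reports <- lapply(models, process_gene, genome = genome, config = config)
  annotated <- apply_annotations(genome, reports)

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    acc <- genome$accession
    files <- c(
      genbank = file.path(out_dir, paste0(acc, "_edited.gb")),
      tbl = file.path(out_dir, paste0(acc, ".tbl")),
      proteins = file.path(out_dir, paste0(acc, "_proteins.fasta")),
      report = file.path(out_dir, paste0(acc, "_report.tsv"))
    )
    write_genbank(annotated, files[["genbank"]])
    write_feature_table(annotated, files[["tbl"]])
    write_protein_fasta(reports, files[["proteins"]], accession = acc)
    write_run_report(reports, files[["report"]])
  }
  new_run_report(reports, attr(models, "notes"), annotated, files)
}

new_run_report <- function(reports, notes, record, files) {
  statuses <- vapply(reports, `[[`, character(1), "status")
  all_edits <- unlist(lapply(reports, `[[`, "edits"), recursive = FALSE)
  roles <- vapply(all_edits, `[[`, character(1), "role")
  totals <- list(
    genes = length(reports),
    edits = length(all_edits),
    edits_by_role = c(
      start_rescue = sum(roles == "start_rescue"),
      stop_rescue = sum(roles == "stop_rescue"),
      internal_stop_rescue = sum(roles == "internal_stop_rescue")),
    by_status = table(factor(statuses, levels = c(
      "clean", "edited", "boundary_adjusted", "manual_check", "skipped")))
  )
  structure(list(reports = reports, totals = totals,
                 notes = if (is.null(notes)) character(0) else notes,
                 record = record, files = files),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  t <- x$totals
  cat(sprintf("<run_report> %d gene(s), %d RNA-editing event(s)\n",
              t$genes, t$edits))
  cat(sprintf("  start rescues: %d, stop rescues: %d, internal-stop rescues: %d\n",
              t$edits_by_role[["start_rescue"]],
              t$edits_by_role[["stop_rescue"]],
              t$edits_by_role[["internal_stop_rescue"]]))
  st <- t$by_status
  cat("  status:", paste(sprintf("%s %d", names(st), st), collapse = ", "),
      "\n")
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Collect all editing events from a run report
#'
#' @param x a `run_report` or list of `gene_report`s.
#' @return data.frame with one row per editing event (gene,
#'   genomic_position, strand, direction, role, codon_before,
#'   codon_after, amino_acid_after).
#' @export
edit_table <- function(x) {
  reports <- if (inherits(x, "run_report")) x$reports else x
  evs <- unlist(lapply(reports, `[[`, "edits"), recursive = FALSE)
  if (length(evs) == 0L) {
    return(data.frame(gene = character(0), genomic_position = integer(0),
                      strand = character(0), direction = character(0),
                      role = character(0), codon_before = character(0),
                      codon_after = character(0),
                      amino_acid_after = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    gene = vapply(evs, `[[`, character(1), "gene_id"),
    genomic_position = vapply(evs, `[[`, integer(1), "genomic_position"),
    strand = vapply(evs, `[[`, character(1), "strand"),
    direction = vapply(evs, `[[`, character(1), "direction"),
    role = vapply(evs, `[[`, character(1), "role"),
    codon_before = vapply(evs, `[[`, character(1), "codon_before"),
    codon_after = vapply(evs, `[[`, character(1), "codon_after"),
    amino_acid_after = vapply(evs, `[[`, character(1), "amino_acid_after"),
    stringsAsFactors = FALSE
  )
}
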