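#' Construct a gene model
#'
#' One protein-coding gene as the annotator processes it: the spliced
#' coordinate intervals of its CDS, the strand, and identifiers. Models
#' flagged at construction (trans-splicing, frame problems, too short)
#' are carried through to [process_gene()], which reports them for
#' manual checking instead of inferring edits.
#'
#' @param gene_id gene identifier.
#' @param intervals two-column integer matrix of 1-based inclusive
#'   intervals in coding-strand 5'->3' order.
#' @param strand `"+"` or `"-"`.
#' @param product product description (may be `""`).
#' @param source_feature_index index of the matching CDS feature in the
#'   GenBank record, or `NA` (set by [reconcile()]).
#' @param flag `NULL`, or a character reason why the model must be
#'   manually checked.
#' @param pseudo logical; pseudogene-annotated models are skipped.
#' @return object of class `gene_model`.
#' @export
gene_model <- function(gene_id, intervals, strand, product = "",
                       source_feature_index = NA_integer_,
                       flag = NULL, pseudo = FALSE) {
  intervals <- matrix(as.integer(intervals), ncol = 2L,
                      dimnames = list(NULL, c("start", "end")))
  stopifnot(strand %in% c("+", "-"))
  len <- sum(intervals[, 2L] - intervals[, 1L] + 1L)
  if (is.null(flag)) {
    if (len < 6L) {
      flag <- sprintf("spliced length %d < 6 (no room for start + one codon)", len)
    } else if (len %% 3L != 0L) {
      flag <- sprintf("spliced length %d not divisible by 3 (frame suspect)", len)
    }
  }
  structure(list(gene_id = gene_id, product = product,
                 intervals = intervals, strand = strand,
                 source_feature_index = as.integer(source_feature_index),
                 flag = flag, pseudo = isTRUE(pseudo)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  ivs <- paste(sprintf("%d..%d", x$intervals[, 1L], x$intervals[, 2L]),
               collapse = ",")
  cat(sprintf("<gene_model> %s (%s) %s%s%s\n", x$gene_id, x$strand, ivs,
              if (x$pseudo) " [pseudo]" else "",
              if (!is.null(x$flag)) paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

spliced_length <- function(model) {
  sum(model$intervals[, 2L] - model$intervals[, 1L] + 1L)
}

# spliced CDS on the coding strand
extract_spliced <- function(genome, model) {
  parts <- apply(model$intervals, 1L, function(iv) {
    s <- substr(genome$sequence, iv[1L], iv[2L])
    if (model$strand == "-") revcomp(s) else s
  })
  paste(parts, collapse = "")
}

#' Read gene models from a GFF3 file
#'
#' CDS lines are grouped by their `Parent` attribute (falling back to
#' `ID`) into one [gene_model()] per coding sequence, with multi-exon
#' models ordered 5' to 3' along the coding strand. GFF3 coordinates
#' (1-based inclusive) are kept as-is. A CDS group with parts on both
#' strands (trans-splicing, e.g. rps12) is flagged for manual checking
#' rather than rejected.
#'
#' @param path path to a GFF3 file; the `##gff-version 3` pragma is
#'   required.
#' @param genome the matching [genome_record()]; every CDS `seqid` must
#'   equal its accession (after aliasing).
#' @param seqid_alias optional named character vector mapping GFF3
#'   seqids to the GenBank accession.
#' @return list of [gene_model()] objects.
#' @export
read_gff3 <- function(path, genome, seqid_alias = NULL) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !grepl("^##gff-version[ \t]+3", first)) {
    stop("not a GFF3 file (missing '##gff-version 3' pragma): ", path)
  }
  g <- as.data.frame(rtracklayer::readGFF(path))
  cds <- g[g$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0L) return(list())

  seqids <- as.character(cds$seqid)
  if (!is.null(seqid_alias)) {
    hit <- seqids %in% names(seqid_alias)
    seqids[hit] <- seqid_alias[seqids[hit]]
  }
  bad <- setdiff(unique(seqids), genome$accession)
  if (length(bad)) {
    stop(sprintf("GFF3 seqid '%s' does not match GenBank accession '%s'",
                 bad[1L], genome$accession))
  }

  parent <- vapply(seq_len(nrow(cds)), function(i) {
    p <- cds$Parent[[i]]
    if (length(p) >= 1L && nzchar(p[1L])) p[1L]
    else if (!is.null(cds$ID) && !is.na(cds$ID[i])) cds$ID[i]
    else sprintf("cds%d", i)
  }, character(1))

  models <- list()
  for (grp in unique(parent)) {
    rows <- cds[parent == grp, , drop = FALSE]
    gene_id <- gff_gene_name(rows, grp)
    product <- if (!is.null(rows$product) && !is.na(rows$product[1L])) {
      rows$product[1L]
    } else ""
    pseudo <- gff_is_pseudo(rows)
    strands <- unique(as.character(rows$strand))
    if (length(strands) > 1L) {
      models[[length(models) + 1L]] <- gene_model(
        gene_id, cbind(min(rows$start), max(rows$end)), "+",
        product = product,
        flag = "CDS parts on both strands (trans-splicing unsupported)",
        pseudo = pseudo)
      next
    }
    strand <- strands
    if (!strand %in% c("+", "-")) {
      models[[length(models) + 1L]] <- gene_model(
        gene_id, cbind(min(rows$start), max(rows$end)), "+",
        product = product, flag = "CDS without strand", pseudo = pseudo)
      next
    }
    o <- order(rows$start)
    if (strand == "-") o <- rev(o)
    iv <- cbind(rows$start[o], rows$end[o])
    models[[length(models) + 1L]] <- gene_model(
      gene_id, iv, strand, product = product, pseudo = pseudo)
  }
  models
}

gff_gene_name <- function(rows, fallback) {
  for (col in c("gene", "Name", "locus_tag")) {
    if (!is.null(rows[[col]]) && !is.na(rows[[col]][1L]) &&
        nzchar(rows[[col]][1L])) {
      return(as.character(rows[[col]][1L]))
    }
  }
  sub("^(gene[-:])?", "", fallback)
}

gff_is_pseudo <- function(rows) {
  for (col in c("pseudo", "pseudogene")) {
    v <- rows[[col]]
    if (!is.null(v) && !all(is.na(v)) &&
        any(tolower(as.character(v)) %in% c("true", "1", "yes", ""))) {
      return(TRUE)
    }
  }
  FALSE
}

#' Link GFF3 gene models to GenBank CDS features
#'
#' GFF3 is authoritative for gene coordinates; the GenBank record is
#' authoritative for the sequence and pre-existing qualifiers. Each
#' model is linked to a CDS feature first by exact coordinate identity,
#' then by gene name; a model with no match is still processed (a new
#' CDS feature is created on output) and the mismatch is recorded.
#' Features spanning the sequence end of a circular record are flagged
#' rather than resolved by modular arithmetic. A `/pseudo` qualifier on
#' the linked feature marks the model as a pseudogene.
#'
#' @param gff_models list of [gene_model()] from [read_gff3()].
#' @param genome a [genome_record()].
#' @return the model list with `source_feature_index` and `pseudo`
#'   filled in; attribute `"notes"` carries reconciliation messages.
#' @export
reconcile <- function(gff_models, genome) {
  cds_idx <- which(vapply(genome$features, function(f) f$kind == "CDS",
                          logical(1)))
  notes <- character(0)
  sig <- function(iv, strand) {
    paste(strand, paste(t(iv), collapse = ","))
  }
  feat_sigs <- vapply(cds_idx, function(i) {
    f <- genome$features[[i]]
    sig(f$intervals, f$strand)
  }, character(1))
  feat_genes <- vapply(cds_idx, function(i) {
    g <- qual_values(genome$features[[i]], "gene")
    if (length(g)) g[1L] else NA_character_
  }, character(1))

  matched_cds <- integer(0)
  out <- lapply(gff_models, function(m) {
    hit <- which(feat_sigs == sig(m$intervals, m$strand))
    if (length(hit) == 0L) hit <- which(feat_genes == m$gene_id)
    if (length(hit) >= 1L) {
      i <- cds_idx[hit[1L]]
      m$source_feature_index <- i
      matched_cds <<- c(matched_cds, i)
      if (has_qualifier(genome$features[[i]], "pseudo")) m$pseudo <- TRUE
      if (!nzchar(m$product)) {
        p <- qual_values(genome$features[[i]], "product")
        if (length(p)) m$product <- p[1L]
      }
    } else {
      notes <<- c(notes, sprintf(
        "gene %s: no matching CDS feature in GenBank record; a new CDS feature will be created",
        m$gene_id))
    }
    if (is.null(m$flag) && any(m$intervals[, 1L] > m$intervals[, 2L])) {
      m$flag <- "interval with start > end (origin-spanning feature unsupported)"
    }
    m
  })
  orphan <- setdiff(cds_idx, matched_cds)
  for (i in orphan) {
    g <- feat_genes[match(i, cds_idx)]
    notes <- c(notes, sprintf(
      "GenBank CDS %s not present in GFF3; passed through untouched",
      ifelse(is.na(g), sprintf("#%d", i), g)))
  }
  attr(out, "notes") <- notes
  out
}
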