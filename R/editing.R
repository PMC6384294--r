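#' @title Codon-level RNA-editing rescue logic
#' @description
#' In fern and hornwort plastomes, C-to-U and U-to-C RNA editing routinely
#' creates start codons, creates stop codons, and removes premature stop
#' codons at the transcript level, so the genomic CDS appears defective.
#' These functions decide, for a single codon, whether exactly one C<->U
#' substitution explains the defect, and construct the corresponding
#' editing event. Directionality follows from the codon alphabet: creating
#' a U (start/stop restoration) needs genomic C read as U (C-to-U);
#' removing a U from a genomic stop needs T read as C (U-to-C).
#' @name editing
NULL

#' Construct an RNA-editing event
#'
#' Low-level constructor for one inferred editing site. The rescue
#' functions return events with codon-space information filled in;
#' [process_gene()] later anchors them to genomic coordinates via
#' [spliced_index_to_genomic()].
#'
#' @param role one of `"start_rescue"`, `"stop_rescue"`,
#'   `"internal_stop_rescue"`.
#' @param direction `"C-to-U"` or `"U-to-C"`, in coding-strand sense.
#' @param codon_before,codon_after genomic codon and post-editing mRNA
#'   codon (written in the DNA alphabet).
#' @param pos_in_codon 1, 2 or 3: the edited position within the codon.
#' @param amino_acid_after one-letter amino acid after editing (`"*"` for
#'   a restored stop).
#' @param codon_index 0-based codon index within the spliced CDS.
#' @param genomic_position 1-based forward-strand genomic coordinate of
#'   the edited base.
#' @param strand `"+"` or `"-"` (coding strand of the gene).
#' @param gene_id gene identifier, if known.
#' @return object of class `edit_event`.
#' @export
edit_event <- function(role, direction, codon_before, codon_after,
                       pos_in_codon, amino_acid_after,
                       codon_index = NA_integer_,
                       genomic_position = NA_integer_,
                       strand = NA_character_,
                       gene_id = NA_character_) {
  stopifnot(role %in% c("start_rescue", "stop_rescue", "internal_stop_rescue"),
            direction %in% c("C-to-U", "U-to-C"),
            pos_in_codon %in% 1:3)
  bb <- substr(codon_before, pos_in_codon, pos_in_codon)
  ab <- substr(codon_after, pos_in_codon, pos_in_codon)
  if (!((direction == "C-to-U" && bb == "C" && ab == "T") ||
        (direction == "U-to-C" && bb == "T" && ab == "C"))) {
    stop("edit_event: codon change inconsistent with direction")
  }
  structure(
    list(role = role, direction = direction,
         codon_before = codon_before, codon_after = codon_after,
         pos_in_codon = as.integer(pos_in_codon),
         amino_acid_after = amino_acid_after,
         codon_index = as.integer(codon_index),
         genomic_position = as.integer(genomic_position),
         strand = strand, gene_id = gene_id),
    class = "edit_event"
  )
}

#' @export
print.edit_event <- function(x, ...) {
  cat(sprintf("<edit_event> %s %s %s->%s pos %d (codon %s, genomic %s%s)\n",
              x$role, x$direction, x$codon_before, x$codon_after,
              x$pos_in_codon,
              ifelse(is.na(x$codon_index), "?", x$codon_index),
              ifelse(is.na(x$genomic_position), "?", x$genomic_position),
              ifelse(is.na(x$strand), "", paste0(" ", x$strand))))
  invisible(x)
}

check_codon <- function(c) {
  if (!is.character(c) || length(c) != 1L || nchar(c) != 3L)
    stop("codon must be a single 3-letter string")
  toupper(c)
}

codon_has_n <- function(c) grepl("[^ACGT]", c)

#' Is a codon a valid start codon?
#'
#' @param c a 3-letter codon (DNA alphabet).
#' @param code a [genetic_code()] object.
#' @return `TRUE` iff `c` is in the configured valid start set (default
#'   ATG only).
#' @examples
#' is_valid_start("ATG", genetic_code())  # TRUE
#' is_valid_start("ACG", genetic_code())  # FALSE: needs editing
#' @export
is_valid_start <- function(c, code = genetic_code()) {
  check_codon(c) %in% code$valid_start_codons
}

#' Is a codon a stop codon?
#'
#' @inheritParams is_valid_start
#' @return `TRUE` iff `c` is TAA, TAG or TGA.
#' @export
is_stop <- function(c, code = genetic_code()) {
  check_codon(c) %in% code$stop_codons
}

single_sub_edit <- function(codon, target, from, to) {
  # one `from`->`to` substitution turning codon into target, or NULL
  cb <- strsplit(codon, "", fixed = TRUE)[[1]]
  tb <- strsplit(target, "", fixed = TRUE)[[1]]
  d <- which(cb != tb)
  if (length(d) == 1L && cb[d] == from && tb[d] == to) d else NULL
}

#' Rescue an invalid start codon by one C-to-U edit
#'
#' A genomic codon is start-rescuable when a single C-to-U editing event
#' (genomic C read as U) converts it to AUG; in the DNA alphabet the only
#' such codon is ACG (position 2). Codons containing N are never
#' candidates.
#'
#' @inheritParams is_valid_start
#' @return an [edit_event()] with `role = "start_rescue"`, or `NULL`.
#' @examples
#' rescue_start("ACG")  # C-to-U at codon position 2 -> ATG
#' rescue_start("GTG")  # NULL: G->A is not C<->U editing
#' @export
rescue_start <- function(c, code = genetic_code()) {
  c <- check_codon(c)
  if (codon_has_n(c)) return(NULL)
  d <- single_sub_edit(c, "ATG", from = "C", to = "T")
  if (is.null(d)) return(NULL)
  edit_event("start_rescue", "C-to-U", c, "ATG", d, "M")
}

#' Rescue a missing stop codon by one C-to-U edit
#'
#' A genomic codon is stop-rescuable when a single C-to-U edit yields one
#' of the stops TAA, TAG, TGA; exhaustive enumeration over all 64 codons
#' shows the rescuable set is exactly CAA->TAA, CAG->TAG and CGA->TGA
#' (each at codon position 1).
#'
#' @inheritParams is_valid_start
#' @return an [edit_event()] with `role = "stop_rescue"`, or `NULL`.
#' @export
rescue_stop <- function(c, code = genetic_code()) {
  c <- check_codon(c)
  if (codon_has_n(c) || is_stop(c, code)) return(NULL)
  for (stop_codon in code$stop_codons) {
    d <- single_sub_edit(c, stop_codon, from = "C", to = "T")
    if (!is.null(d)) {
      return(edit_event("stop_rescue", "C-to-U", c, stop_codon, d, "*"))
    }
  }
  NULL
}

#' Rescue an internal (premature) stop codon by one U-to-C edit
#'
#' A genomic in-frame stop is removed at the transcript level when a
#' single U-to-C edit (genomic T read as C) yields a sense codon. For all
#' three stops the rescue is unique: TAA->CAA (Q), TAG->CAG (Q),
#' TGA->CGA (R), always at codon position 1. If several T positions
#' yielded sense codons the lowest position would be chosen; enumeration
#' shows the choice never arises.
#'
#' @inheritParams is_valid_start
#' @return an [edit_event()] with `role = "internal_stop_rescue"`, or
#'   `NULL` if `c` is not a stop codon or no single T->C edit gives a
#'   sense codon.
#' @export
rescue_internal_stop <- function(c, code = genetic_code()) {
  c <- check_codon(c)
  if (!is_stop(c, code)) return(NULL)
  cb <- strsplit(c, "", fixed = TRUE)[[1]]
  for (p in 1:3) {           # lowest position wins (deterministic)
    if (cb[p] != "T") next
    alt <- cb
    alt[p] <- "C"
    alt <- paste(alt, collapse = "")
    aa <- unname(code$table[alt])
    if (!is.na(aa) && aa != "*") {
      return(edit_event("internal_stop_rescue", "U-to-C", c, alt, p, aa))
    }
  }
  NULL
}

#' Find in-frame internal stop codons
#'
#' @param spliced_cds spliced CDS nucleotide string (coding strand),
#'   length divisible by 3.
#' @param code a [genetic_code()] object.
#' @return data.frame with columns `codon_index` (0-based, strictly before
#'   the final codon) and `codon`, in ascending order.
#' @export
find_internal_stops <- function(spliced_cds, code = genetic_code()) {
  codons <- split_codons(toupper(spliced_cds))
  n <- length(codons)
  idx <- which(codons %in% code$stop_codons)
  idx <- idx[idx < n]        # final codon is not "internal"
  data.frame(codon_index = idx - 1L, codon = codons[idx],
             stringsAsFactors = FALSE)
}

#' Conceptual translation of an edited CDS
#'
#' Applies each editing event's post-editing codon, translates under
#' table 11, and drops the terminal stop. The result must contain no `*`;
#' a remaining internal stop indicates the caller failed to rescue the
#' gene and is an error.
#'
#' @param spliced_cds spliced CDS nucleotide string, length divisible
#'   by 3.
#' @param edits list of [edit_event()] objects with `codon_index` set.
#' @param code a [genetic_code()] object.
#' @return single amino-acid string without the terminal stop.
#' @examples
#' conceptual_translation("ATGAAATAA", list())  # "MK"
#' @export
conceptual_translation <- function(spliced_cds, edits = list(),
                                   code = genetic_code()) {
  codons <- split_codons(toupper(spliced_cds))
  for (e in edits) {
    i <- e$codon_index + 1L
    if (is.na(i) || i < 1L || i > length(codons)) {
      stop("edit codon_index out of range")
    }
    if (codons[i] != e$codon_before) {
      stop(sprintf("edit at codon %d expected %s, found %s",
                   e$codon_index, e$codon_before, codons[i]))
    }
    codons[i] <- e$codon_after
  }
  aa <- translate_codons(codons, code)
  n <- length(aa)
  if (n > 0L && aa[n] == "*") aa <- aa[-n]
  if (any(aa == "*")) {
    stop("internal stop remains after applying edits; gene should have been flagged for manual check")
  }
  paste(aa, collapse = "")
}

#' Scan near an annotated gene boundary for a valid or rescuable codon
#'
#' When the annotated terminal codon is neither valid nor rescuable by a
#' single edit, nearby in-frame codons (within `window_codons`, default
#' five) are examined; if one is a valid start/stop, or becomes one
#' through a single C-to-U edit, the gene boundary is moved there.
#' Candidates are ranked by smallest absolute offset; at equal offset a
#' directly valid codon beats an edit-rescuable one, and the direction
#' that extends the gene (upstream for starts, downstream for stops) is
#' preferred.
#'
#' @param spliced_seq in-frame nucleotide string consisting of the CDS
#'   plus up to `window_codons` codons of genomic flank on the relevant
#'   side (upstream flank prepended for `end = "five_prime"`, downstream
#'   flank appended for `end = "three_prime"`).
#' @param end `"five_prime"` (start codon) or `"three_prime"` (stop).
#' @param window_codons maximum absolute offset, in codons (default 5).
#' @param code a [genetic_code()] object.
#' @param flank_codons number of flank codons actually present in
#'   `spliced_seq` (may be fewer than `window_codons` near a sequence
#'   end, in which case the window is truncated).
#' @return `NULL` if no candidate, else a list with `offset_codons`
#'   (signed; negative = upstream of the annotated boundary), `codon`,
#'   and `edit` (an [edit_event()] or `NULL` for a directly valid codon).
#' @export
scan_for_boundary <- function(spliced_seq,
                              end = c("five_prime", "three_prime"),
                              window_codons = 5L,
                              code = genetic_code(),
                              flank_codons = window_codons) {
  end <- match.arg(end)
  codons <- split_codons(toupper(spliced_seq))
  n <- length(codons)
  flank_codons <- min(flank_codons, window_codons)
  if (end == "five_prime") {
    # annotated start codon sits at index flank_codons + 1
    anchor <- flank_codons + 1L
    n_cds <- n - flank_codons
    # keep at least 2 CDS codons when shrinking from the 5' side
    offsets <- setdiff(seq.int(-flank_codons,
                               min(window_codons, n_cds - 2L)), 0L)
  } else {
    # annotated stop codon is the last CDS codon
    anchor <- n - flank_codons
    offsets <- setdiff(seq.int(max(-window_codons, -(anchor - 2L)),
                               flank_codons), 0L)
  }
  if (length(offsets) == 0L) return(NULL)

  test_direct <- if (end == "five_prime") {
    function(cd) is_valid_start(cd, code)
  } else {
    function(cd) is_stop(cd, code)
  }
  test_rescue <- if (end == "five_prime") {
    function(cd) rescue_start(cd, code)
  } else {
    function(cd) rescue_stop(cd, code)
  }
  preferred_sign <- if (end == "five_prime") -1L else 1L

  cand <- list()
  for (k in offsets) {
    cd <- codons[anchor + k]
    if (test_direct(cd)) {
      cand[[length(cand) + 1L]] <- list(offset_codons = k, codon = cd,
                                        edit = NULL, direct = TRUE)
    } else {
      ev <- test_rescue(cd)
      if (!is.null(ev)) {
        cand[[length(cand) + 1L]] <- list(offset_codons = k, codon = cd,
                                          edit = ev, direct = FALSE)
      }
    }
  }
  if (length(cand) == 0L) return(NULL)
  key <- vapply(cand, function(x) {
    abs(x$offset_codons) * 4 +
      (!x$direct) * 2 +
      (sign(x$offset_codons) != preferred_sign) * 1
  }, numeric(1))
  best <- cand[[which.min(key)]]
  best$direct <- NULL
  best
}

#' Map a spliced codon position to a genomic coordinate
#'
#' Walks the gene model's intervals (stored 5' to 3' along the coding
#' strand) to convert a codon-space position into a 1-based forward-strand
#' genomic coordinate; minus-strand models walk their intervals from high
#' to low genomic coordinates.
#'
#' @param model a `gene_model` (see [read_gff3()]).
#' @param codon_index 0-based codon index within the spliced CDS.
#' @param pos_in_codon 1, 2 or 3.
#' @return single 1-based genomic position.
#' @export
spliced_index_to_genomic <- function(model, codon_index, pos_in_codon) {
  stopifnot(pos_in_codon %in% 1:3)
  spos <- 3L * as.integer(codon_index) + as.integer(pos_in_codon)
  spliced_pos_to_genomic(model, spos)
}

# spliced 1-based position -> genomic 1-based forward-strand position
spliced_pos_to_genomic <- function(model, spos) {
  iv <- model$intervals
  widths <- iv[, 2L] - iv[, 1L] + 1L
  if (spos < 1L || spos > sum(widths)) stop("spliced position out of range")
  cum <- cumsum(widths)
  i <- which(spos <= cum)[1L]
  off <- spos - c(0L, cum)[i] - 1L        # 0-based offset within interval i
  unname(if (model$strand == "+") iv[i, 1L] + off else iv[i, 2L] - off)
}
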