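test_that("start/stop/internal-stop rescue agrees with the brute-force oracle on all 64 codons", {
  code <- genetic_code()
  for (cd in ALL_CODONS) {
    ora <- oracle_start_rescues(cd)
    got <- rescue_start(cd, code)
    if (cd == "ATG" || length(ora) == 0L) {
      expect_null(got, info = cd)
    } else {
      expect_s3_class(got, "edit_event")
      expect_identical(got$pos_in_codon, ora[[1L]]$pos)
      expect_identical(got$codon_after, "ATG")
      expect_identical(got$direction, "C-to-U")
    }

    ora <- oracle_stop_rescues(cd)
    got <- rescue_stop(cd, code)
    if (cd %in% STOPS || length(ora) == 0L) {
      expect_null(got, info = cd)
    } else {
      expect_s3_class(got, "edit_event")
      expect_identical(got$pos_in_codon, ora[[1L]]$pos)
      expect_true(got$codon_after %in% STOPS)
      expect_identical(got$direction, "C-to-U")
      expect_identical(got$amino_acid_after, "*")
    }

    ora <- oracle_internal_rescues(cd)
    got <- rescue_internal_stop(cd, code)
    if (length(ora) == 0L) {
      expect_null(got, info = cd)
    } else {
      expect_s3_class(got, "edit_event")
      # lowest-position tie-break (provably unique for the three stops)
      expect_length(ora, 1L)
      expect_identical(got$pos_in_codon, ora[[1L]]$pos)
      expect_identical(got$codon_after, ora[[1L]]$codon)
      expect_identical(got$direction, "U-to-C")
      expect_identical(got$amino_acid_after, CODE11[[ora[[1L]]$codon]])
    }
  }
})

test_that("the rescuable codon sets are exactly those enumeration predicts", {
  start_set <- Filter(function(cd) length(oracle_start_rescues(cd)) > 0L,
                      setdiff(ALL_CODONS, "ATG"))
  expect_identical(start_set, "ACG")

  stop_set <- Filter(function(cd) length(oracle_stop_rescues(cd)) > 0L,
                     setdiff(ALL_CODONS, STOPS))
  expect_setequal(stop_set, c("CAA", "CAG", "CGA"))

  expect_identical(rescue_internal_stop("TAA")$codon_after, "CAA")
  expect_identical(rescue_internal_stop("TAA")$amino_acid_after, "Q")
  expect_identical(rescue_internal_stop("TGA")$codon_after, "CGA")
  expect_identical(rescue_internal_stop("TGA")$amino_acid_after, "R")
  expect_identical(rescue_internal_stop("TAG")$codon_after, "CAG")
  expect_identical(rescue_internal_stop("TAG")$amino_acid_after, "Q")
})

test_that("start validity honours the configured start-codon set", {
  expect_true(is_valid_start("ATG", genetic_code()))
  expect_false(is_valid_start("ACG", genetic_code()))
  expect_false(is_valid_start("GTG", genetic_code()))
  expect_true(is_valid_start("GTG", genetic_code(c("ATG", "GTG"))))
})

test_that("codons containing N are never rescue candidates", {
  expect_null(rescue_start("ANG"))
  expect_null(rescue_stop("CNA"))
})

test_that("find_internal_stops reports in-frame stops strictly before the final codon", {
  code <- genetic_code()
  expect_identical(nrow(find_internal_stops("ATGAAATAA", code)), 0L)
  hits <- find_internal_stops("ATGTGAAAATAA", code)
  expect_identical(hits$codon_index, 1L)
  expect_identical(hits$codon, "TGA")

  # planted stops recovered at exactly the planted indices
  codons <- rep("GCT", 40L)
  codons[c(5L, 18L, 31L)] <- c("TAA", "TGA", "TAG")
  codons[1L] <- "ATG"; codons[40L] <- "TAA"
  hits <- find_internal_stops(paste(codons, collapse = ""), code)
  expect_identical(hits$codon_index, c(4L, 17L, 30L))
})

test_that("conceptual translation applies edits, drops the terminal stop and matches an independent translation", {
  code <- genetic_code()
  expect_identical(conceptual_translation("ATGAAATAA", list(), code), "MK")

  ev <- rescue_internal_stop("TAA", code)
  ev$codon_index <- 1L
  expect_identical(conceptual_translation("ATGTAAAAATAA", list(ev), code),
                   "MQK")
  expect_identical(oracle_translate("ATGCAAAAA"), "MQK")

  ev <- rescue_start("ACG", code)
  ev$codon_index <- 0L
  expect_identical(conceptual_translation("ACGAAATAA", list(ev), code), "MK")

  # unresolved internal stop is an internal error, never silent output
  expect_error(conceptual_translation("ATGTAAAAATAA", list(), code),
               "internal stop")
})

test_that("conceptual translation equals Biostrings translation of the edit-applied mRNA on random ORFs", {
  code <- genetic_code()
  set.seed(11)
  for (i in 1:25) {
    n <- sample(10:60, 1L)
    codons <- c("ATG", sample(setdiff(names(code$table), code$stop_codons),
                              n, replace = TRUE), "TGA")
    edited <- codons
    at <- sample(2:(n + 1L), 1L)
    codons[at] <- sample(code$stop_codons, 1L)
    ev <- rescue_internal_stop(codons[at], code)
    ev$codon_index <- at - 1L
    edited[at] <- ev$codon_after
    got <- conceptual_translation(paste(codons, collapse = ""), list(ev), code)
    ref <- oracle_translate(paste(edited, collapse = ""))
    expect_identical(paste0(got, "*"), ref)
    expect_false(grepl("*", got, fixed = TRUE))
  }
})

test_that("boundary scan finds the nearest valid or rescuable codon with the documented tie-breaks", {
  code <- genetic_code()
  flank <- function(...) paste(c(...), collapse = "")

  # direct hit upstream at -1 beats nothing closer
  s <- flank("GGG", "GGG", "GGG", "GGG", "ATG", "CTGGGAGGATAA")
  hit <- scan_for_boundary(s, "five_prime", 5L, code)
  expect_identical(hit$offset_codons, -1L)
  expect_identical(hit$codon, "ATG")
  expect_null(hit$edit)

  # rescuable at +2, nothing closer
  s <- flank("GGG", "GGG", "GGG", "GGG", "GGG", "CTGGGGACGGGAGGATAA")
  hit <- scan_for_boundary(s, "five_prime", 5L, code)
  expect_identical(hit$offset_codons, 2L)
  expect_identical(hit$codon, "ACG")
  expect_identical(hit$edit$role, "start_rescue")

  # equal |offset|: directly valid beats edit-rescuable
  s <- flank("GGG", "GGG", "GGG", "GGG", "ACG", "CTGATGGGAGGATAA")
  hit <- scan_for_boundary(s, "five_prime", 5L, code)
  expect_identical(hit$offset_codons, 1L)
  expect_identical(hit$codon, "ATG")

  # equal |offset| and both rescuable: upstream (extending) preferred
  s <- flank("GGG", "GGG", "GGG", "GGG", "ACG", "CTGACGGGAGGATAA")
  hit <- scan_for_boundary(s, "five_prime", 5L, code)
  expect_identical(hit$offset_codons, -1L)

  # three-prime: stop at +1 downstream
  s <- flank("ATGGGAGGACAC", "TAA", "GGG", "GGG", "GGG", "GGG")
  hit <- scan_for_boundary(s, "three_prime", 5L, code)
  expect_identical(hit$offset_codons, 1L)
  expect_identical(hit$codon, "TAA")
  expect_null(hit$edit)

  # nothing in the window
  s <- flank("GGG", "GGG", "GGG", "GGG", "GGG", "CTGGGAGGAGAC",
             "GGG", "GGG", "GGG", "GGG", "GGG")
  expect_null(scan_for_boundary(substr(s, 1, 27), "five_prime", 5L, code))
})

test_that("boundary scan offsets are within the window and |offset|-minimal (exhaustive re-scan)", {
  code <- genetic_code()
  set.seed(99)
  is_cand <- function(cd, end) {
    if (end == "five_prime") {
      is_valid_start(cd, code) || !is.null(rescue_start(cd, code))
    } else {
      is_stop(cd, code) || !is.null(rescue_stop(cd, code))
    }
  }
  for (i in 1:60) {
    end <- sample(c("five_prime", "three_prime"), 1L)
    n_cds <- sample(6:20, 1L)
    cds <- paste(sample(ALL_CODONS, n_cds, replace = TRUE), collapse = "")
    fl <- paste(sample(ALL_CODONS, 5L, replace = TRUE), collapse = "")
    s <- if (end == "five_prime") paste0(fl, cds) else paste0(cds, fl)
    hit <- scan_for_boundary(s, end, 5L, code)
    codons <- substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3))
    anchor <- if (end == "five_prime") 6L else length(codons) - 5L
    # the scan never shrinks the CDS below two codons
    offs <- if (end == "five_prime") {
      setdiff(seq.int(-5L, min(5L, n_cds - 2L)), 0L)
    } else {
      setdiff(seq.int(max(-5L, -(n_cds - 2L)), 5L), 0L)
    }
    cand_offs <- offs[vapply(offs, function(k) {
      is_cand(codons[anchor + k], end)
    }, logical(1))]
    if (is.null(hit)) {
      expect_length(cand_offs, 0L)
    } else {
      expect_lte(abs(hit$offset_codons), 5L)
      expect_identical(abs(hit$offset_codons), min(abs(cand_offs)))
      expect_true(is_cand(hit$codon, end))
    }
  }
})

test_that("spliced-to-genomic mapping matches explicit position enumeration", {
  # single interval, both strands
  m <- gene_model("g", cbind(101L, 400L), "+")
  expect_identical(spliced_index_to_genomic(m, 0L, 1L), 101L)
  m <- gene_model("g", cbind(101L, 400L), "-")
  expect_identical(spliced_index_to_genomic(m, 0L, 1L), 400L)

  # two intervals crossing an exon boundary
  m <- gene_model("g", rbind(c(101L, 103L), c(201L, 206L)), "+")
  expect_identical(spliced_index_to_genomic(m, 1L, 1L), 201L)

  set.seed(5)
  for (i in 1:25) {
    strand <- sample(c("+", "-"), 1L)
    n_iv <- sample(1:3, 1L)
    starts <- cumsum(sample(50:100, n_iv))
    iv <- cbind(starts, starts + sample(10:40, n_iv))
    if (strand == "-") iv <- iv[rev(seq_len(n_iv)), , drop = FALSE]
    m <- gene_model("g", iv, strand, flag = "unchecked")
    positions <- oracle_spliced_positions(iv, strand)
    for (spos in sample(seq_along(positions), 5L)) {
      expect_identical(
        spliced_index_to_genomic(m, (spos - 1L) %/% 3L,
                                 (spos - 1L) %% 3L + 1L),
        positions[spos])
    }
  }
  expect_error(spliced_index_to_genomic(
    gene_model("g", cbind(1L, 9L), "+"), 3L, 1L), "out of range")
})

test_that("edit events are internally consistent by construction", {
  expect_error(edit_event("start_rescue", "U-to-C", "ACG", "ATG", 2L, "M"),
               "inconsistent")
  ev <- rescue_stop("CGA")
  expect_identical(substr(ev$codon_before, ev$pos_in_codon, ev$pos_in_codon), "C")
  expect_identical(substr(ev$codon_after, ev$pos_in_codon, ev$pos_in_codon), "T")
})
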