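# Independent brute-force oracles for the codon-rescue logic and an
# independent translation path (Biostrings). These enumerate rather than
# reason: every single-position T<->C substitution of a codon is listed
# and filtered, so the fast-path rescue functions can be checked
# exhaustively over all 64 codons.

ALL_CODONS <- apply(expand.grid(c("A", "C", "G", "T"),
                                c("A", "C", "G", "T"),
                                c("A", "C", "G", "T"),
                                stringsAsFactors = FALSE),
                    1L, paste, collapse = "")

STOPS <- c("TAA", "TAG", "TGA")

CODE11 <- Biostrings::getGeneticCode("11")

# all single-position substitutions `from` -> `to` of a codon
oracle_subs <- function(codon, from, to) {
  b <- strsplit(codon, "")[[1]]
  out <- list()
  for (p in 1:3) {
    if (b[p] == from) {
      v <- b
      v[p] <- to
      out[[length(out) + 1L]] <- list(pos = p,
                                      codon = paste(v, collapse = ""))
    }
  }
  out
}

# codons turned into ATG by exactly one C->T (genomic C read as U)
oracle_start_rescues <- function(codon) {
  Filter(function(s) s$codon == "ATG", oracle_subs(codon, "C", "T"))
}

# codons turned into a stop by exactly one C->T
oracle_stop_rescues <- function(codon) {
  Filter(function(s) s$codon %in% STOPS, oracle_subs(codon, "C", "T"))
}

# stop codons turned into a sense codon by exactly one T->C
oracle_internal_rescues <- function(codon) {
  if (!codon %in% STOPS) return(list())
  Filter(function(s) CODE11[[s$codon]] != "*", oracle_subs(codon, "T", "C"))
}

# independent translation of a DNA string under table 11
oracle_translate <- function(dna) {
  as.character(Biostrings::translate(Biostrings::DNAString(dna),
                                     genetic.code = CODE11,
                                     no.init.codon = TRUE))
}

# spliced -> genomic mapping by explicit enumeration of every position
oracle_spliced_positions <- function(intervals, strand) {
  unlist(apply(intervals, 1L, function(iv) {
    if (strand == "+") seq.int(iv[1L], iv[2L]) else seq.int(iv[2L], iv[1L])
  }, simplify = FALSE))
}
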