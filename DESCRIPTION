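Package: plastedit
Title: Annotate C-to-U and U-to-C RNA Editing in Plastid Genome Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Refines existing plastid genome (plastome) annotations by
    recognising apparent nonsense defects in protein-coding genes --
    invalid start codons, missing stop codons, and in-frame premature stop
    codons -- that are explained by single-base C-to-U or U-to-C RNA
    editing of the transcript, as is common in ferns and hornworts. Reads
    a GenBank flat file together with a GFF3 file describing the same gene
    models, infers the minimal editing events that rescue each defect,
    optionally shifts gene boundaries to a nearby valid codon, and writes
    a corrected GenBank flat file with misc_feature editing-site
    annotations and conceptual translations, an NCBI five-column feature
    table for submission, a protein FASTA of edited conceptual
    translations, and a per-gene report. A seeded simulator generates toy
    plastomes with planted, machine-readable editing defects for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    optparse,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
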