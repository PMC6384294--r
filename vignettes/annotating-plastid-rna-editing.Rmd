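---
title: "Annotating RNA editing in plastid genomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating RNA editing in plastid genomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastedit)
```

## The model

Plastid transcripts in ferns, hornworts and scattered other lineages
undergo extensive C-to-U and U-to-C RNA editing. `plastedit` models the
consequence relevant to annotation: a protein-coding gene whose genomic
sequence shows a *nonsense defect* — an invalid start codon, a missing
stop codon, or an in-frame premature stop — that a **single** C&harr;U
substitution at one codon position repairs at the mRNA level.

Two assumptions frame everything the annotator does:

* **Only C&harr;U editing occurs.** This is the dominant editing
  chemistry in plastomes, and it fixes the direction of every rescue
  arithmetically: *creating* a U (restoring `AUG` or a stop) requires a
  genomic C read as U (C-to-U); *removing* a U from a genomic stop
  requires a genomic T read as C (U-to-C).
* **Every nonsense defect is caused by editing.** Plastid genes are
  overwhelmingly essential, so a gene that looks broken is usually a
  gene that is edited. The assumption fails for true pseudogenes,
  frameshifted annotations and assembly errors; the manual-check policy
  below is the guard rail, not a fix.

Under the single-edit rule the rescuable codon sets are tiny and
provable by enumeration (the test suite performs the enumeration
independently of the implementation):

| defect | rescuable codons | direction |
|---|---|---|
| invalid start | `ACG` → `ATG` (position 2) | C-to-U |
| missing stop | `CAA`→`TAA`, `CAG`→`TAG`, `CGA`→`TGA` (position 1) | C-to-U |
| internal stop | `TAA`→`CAA` (Q), `TAG`→`CAG` (Q), `TGA`→`CGA` (R) (position 1) | U-to-C |

For each of the three stops the sense-restoring T→C substitution is
unique, so the documented lowest-position tie-break never actually has
to discriminate; it exists to make the behaviour deterministic by
specification rather than by accident.

## The per-gene procedure

`process_gene()` runs, in order: start-codon validity → single-edit
start rescue → boundary scan; then the same for the final codon against
the stops; then internal-stop detection on the (possibly re-bounded)
CDS; then conceptual translation (NCBI table 11). The ordering follows
the principle of minimal intervention: a direct interpretation of the
annotated codon is preferred to an edit, and an edit at the annotated
position is preferred to moving the annotation.

**Boundary scan.** If the annotated terminal codon is neither valid nor
rescuable, in-frame codons within `boundary_window_codons` (default 5)
of the boundary are examined. Candidates are ranked by: smallest
absolute offset; at equal offset a directly valid codon beats an
edit-rescuable one; at equal offset and class, the direction that
*extends* the gene (upstream for starts, downstream for stops) is
preferred. These tie-breaks are this package's design decisions — the
window idea constrains only the distance, not the preference order —
and were chosen so that the least perturbing, most conservative
re-annotation wins. The scan never shrinks a CDS below two codons, and
the window is truncated (and logged) at the sequence ends.

**Manual-check policy.** A gene either resolves completely or is
reported with status `manual_check` and *none* of its annotations
changed; partially rescued genes would emit misleading translations.
Triggers: more internal stops than `internal_stop_limit` (default 5 —
genes with more than five edited internal stops exist but are rare
enough that exceeding the limit more often indicates a frameshift,
pseudogene or assembly error; the limit is a configuration knob for
users who know better); an unrescuable boundary with an empty scan
window; a spliced length not divisible by three or shorter than six
bases; an N in a codon the annotator would need to interpret (edits are
never inferred through ambiguity); and trans-spliced CDS groups with
parts on both strands (e.g. plastid *rps12*), which the coordinate
model does not represent. Features that span the origin of a circular
sequence are likewise refused loudly rather than resolved by modular
arithmetic. Pseudogene-flagged CDS (`/pseudo` in GenBank, or
`pseudo=true` in GFF3) get the distinct status `skipped`: they are
deliberately not processed, which is neither "clean" nor "check me".

## Parameters

| parameter | default | meaning |
|---|---|---|
| `internal_stop_limit` | 5 | max internal stops rescued per gene (count) |
| `boundary_window_codons` | 5 | boundary scan radius (codons) |
| `valid_start_codons` | `ATG` | codons accepted as starts without editing |
| `seqid_alias` | none | GFF3 seqid → GenBank accession map |

`ATG`-only is deliberate: table 11 lists alternative initiators such as
`GTG`, but silently accepting them would suppress exactly the editing
annotations this tool exists to make. Users working on lineages where
`GTG` starts are established can widen the set.

## Input handling and coordinate conventions

Both input files describe the same genome: the GFF3 is authoritative
for gene coordinates (upstream annotation pipelines emit GFF3 natively)
and the GenBank flat file is authoritative for the nucleotide sequence
and pre-existing qualifiers. `reconcile()` links each GFF3 CDS group to
a GenBank CDS feature by exact coordinate identity, then by gene name;
unmatched models are still processed (a new CDS feature is created on
output) and every mismatch is reported in the run notes.

All coordinates are 1-based inclusive throughout, the native convention
of GenBank, GFF3 and R's sequence containers; intervals are stored in
5'→3' order along the coding strand, so minus-strand codon arithmetic
is a single walk from high to low genomic coordinates. The annotated
flat file is regenerated on write (fixed 79-column qualifier wrapping,
60-base ORIGIN lines) rather than patched byte-wise; round-trips are
therefore feature- and sequence-equal, not byte-identical. Unknown
feature keys and qualifiers pass through verbatim — the tool refines an
annotation and must not lose information. On edited CDS the flat file
gains `exception="RNA editing"` (the standard GenBank vocabulary for a
translation that deviates from the genomic sequence due to editing),
one single-base `misc_feature` per editing site, and the conceptual
`/translation`. The five-column feature table omits `/translation`
because table2asn recomputes it downstream.

## What the simulator emulates — and what it does not

`make_plastome()` generates genes as random open reading frames (ATG
start, sense-codon body, stop end; lengths uniform over 150–1500 bp in
multiples of 3, the plastid ballpark) separated by random intergenic
spacers, with a configurable fraction of minus-strand genes (default
0.3) and single-intron genes (default 0.2, intron placed at an
arbitrary spliced offset precisely so that codon↔genome mapping across
exon boundaries is exercised). Defects are planted by
*reverse-applying* a legal edit — writing `ACG` where `ATG` belongs,
a genomic stop where a sense codon belongs, `CAA`/`CAG`/`CGA` where the
stop belongs — so every planted defect is rescuable by construction and
exact recall of the recorded truth set is a legitimate expectation, not
an optimistic one. Defaults (half the genes edited, 1–3 defects each)
reflect heavily edited fern/hornwort plastomes, where editing can touch
most protein-coding genes.

The simulator does **not** emulate codon-usage bias, sequencing error,
indels, real intron boundaries, operons or IR structure. Passing tests
therefore demonstrate the annotator's logic — codon arithmetic, strand
and splice handling, format fidelity, the decision policy — on
annotations whose defects really are editing. They cannot demonstrate
robustness to mis-annotated inputs; on real data the manual-check
report is part of the result, not noise. `make_edge_cases()`
complements the random generator with a deterministic fixture driving
every refusal path (six internal stops, an unrescuable start with an
empty window, a broken reading frame, an N-containing start codon, a
two-exon minus-strand gene, a defective pseudogene).

## Verification

The rescue tables above are asserted against a brute-force enumerator
of all single T&harr;C substitutions of all 64 codons, written in the
test suite independently of the implementation; conceptual translations
are compared against Biostrings' table-11 translator on edit-applied
sequences. Two end-to-end properties anchor the suite: on 100 seeded
defect-free plastomes (10–50 genes each, mixed strands, 20% spliced)
the annotator emits zero editing events, and on 100 seeded defective
plastomes the emitted event set equals the planted truth set exactly.
These sizes keep the full suite under a minute on one core while still
covering hundreds of genes per property; `scripts/acceptance.R`
recomputes the same quantities at 20 genomes per suite from any seed.
Re-annotating the annotator's own output is verified to add no features
(misc_features are deduplicated by position and note, qualifiers are
replaced rather than appended).

## Known limitations

* Only single-substitution rescues are considered; a codon needing two
  edits (not observed in the motivating lineages' nonsense repairs) is
  reported for manual checking rather than speculatively double-edited.
* Silent and missense editing sites are invisible to this approach by
  design; tools that predict editing from protein conservation answer a
  different question.
* Boundary adjustment trusts the ±5-codon heuristic; a true start
  further away is reported as unrescuable.
* The GenBank parser covers the flat-file subset plastome annotation
  uses (`join`/`complement` locations, wrapped qualifiers); exotic
  location operators (`order`, external references, fuzzy `<`/`>`
  bounds — the latter are stripped) are not round-trip targets.
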