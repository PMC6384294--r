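# plastedit

Automatic annotation of C-to-U and U-to-C RNA editing in plastid genome
(plastome) annotations.

## The problem

In ferns, hornworts and some other plant lineages, plastid mRNAs are
heavily edited after transcription: specific cytidines are read as
uridines (C-to-U) and vice versa (U-to-C). Many of these edits fall on
codons that matter for gene structure, so the *genomic* sequence of a
perfectly functional gene can show an apparent nonsense defect:

* an invalid start codon — genomic `ACG` edited to `AUG` in the mRNA;
* a missing stop codon — genomic `CAA`/`CAG`/`CGA` edited to
  `UAA`/`UAG`/`UGA`;
* an in-frame premature stop — genomic `TAA`/`TAG`/`TGA` edited to the
  sense codons `CAA` (Gln), `CAG` (Gln) or `CGA` (Arg).

Standard plastome annotation pipelines do not account for this, which
leaves annotations that look broken and blocks GenBank submission.
Curating these sites by hand takes hours per genome. `plastedit`
automates the final step: it takes an existing annotation (GenBank flat
file + GFF3), finds every CDS whose defect is explained by a **single
C&harr;U edit**, annotates the editing sites, and emits
submission-ready files.

For each CDS the annotator, in order:

1. checks the annotated start codon: valid (`ATG` by default)? else
   rescuable by one C-to-U edit (`ACG` is the only such codon)? else
   scans in-frame codons within &plusmn;5 codons of the boundary for a
   valid or rescuable start and moves the boundary there;
2. does the same for the final codon against the table-11 stops
   (`TAA`, `TAG`, `TGA`; single-edit rescues are exactly
   `CAA→TAA`, `CAG→TAG`, `CGA→TGA`);
3. finds in-frame internal stops and removes each with the unique
   U-to-C rescue (`TAA→CAA`, `TAG→CAG`, `TGA→CGA`); more than five
   internal stops flags the gene for manual checking instead (a likely
   frameshift, pseudogene or assembly error);
4. computes the conceptual translation of the edited transcript
   (NCBI translation table 11).

A gene either resolves completely or is reported `manual_check` with
none of its annotations changed. Pseudogene-flagged CDS are skipped.

## Outputs

`annotate_plastome(gb, gff3, out_dir)` writes, per accession:

| file | content |
|---|---|
| `<acc>_edited.gb` | flat file with `misc_feature` per editing site, `exception="RNA editing"` and `/translation` on edited CDS |
| `<acc>.tbl` | NCBI five-column feature table for table2asn |
| `<acc>_proteins.fasta` | conceptual translations of edited genes |
| `<acc>_report.tsv` | one row per gene: status, edit count, boundary shifts, messages |

## Worked example

The package ships a seeded simulator that generates toy plastomes with
*planted* editing defects (each defect is created by reverse-applying a
legal edit) plus a truth table of the planted events:

```r
library(plastedit)
fx  <- make_plastome(n_genes = 8, fraction_edited = 0.5, seed = 42, dir = tempfile())
res <- annotate_plastome(fx$genbank, fx$gff3, out_dir = "out")
res
#> <run_report> 8 gene(s), 5 RNA-editing event(s)
#>   start rescues: 2, stop rescues: 1, internal-stop rescues: 2
#>   status: clean 4, edited 4, boundary_adjusted 0, manual_check 0, skipped 0
edit_table(res)
#>   gene genomic_position strand direction                 role codon_before codon_after amino_acid_after
#> 1 g001               35      +    C-to-U         start_rescue          ACG         ATG                M
#> 2 g005             3379      +    C-to-U         start_rescue          ACG         ATG                M
#> 3 g005             3819      +    C-to-U          stop_rescue          CGA         TGA                *
#> 4 g006             4456      +    U-to-C internal_stop_rescue          TGA         CGA                R
#> 5 g008             6952      +    U-to-C internal_stop_rescue          TAA         CAA                Q
```

The five reported events are exactly the five planted in
`fx$truth_table`: gene `g001` starts with genomic `ACG` (read as `AUG`
after editing at position 35), `g005` additionally lacks a genomic stop
(`CGA` edited to `UGA`), and `g006`/`g008` each carry one premature
genomic stop removed by U-to-C editing. In the emitted feature table the
editing site of `g001` appears as

```
35	35	misc_feature
			gene	g001
			note	RNA editing (C to U) in g001: ACG becomes ATG
```

## Scope

`plastedit` refines existing annotations; it does not predict
synonymous or otherwise silent editing sites, confirm edits against
cDNA, perform de novo gene annotation, repair frameshifts, or handle
trans-spliced multi-strand genes (those are flagged for manual
checking). Its output is only as good as the annotation it is given —
it is not a substitute for inspecting flagged genes.
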