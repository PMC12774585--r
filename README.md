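# crisprDonor

Offline design of CRISPR/Cas9 **gene-deletion** and **endogenous-tagging**
experiments for annotated genomes, in R.

Tagging a gene at its native locus with a fluorescent protein (or deleting
it outright) by homology-directed repair (HDR) takes a surprising amount of
bookkeeping: find SpCas9 cut sites near the start or stop codon, check
their genome-wide off-targets, design PCR primers to amplify and sequence
the region, extract homology arms, disrupt the PAM in the donor so the
repaired allele is not re-cut, assemble the donor plasmid, and verify that
the fusion stays in frame after the screening marker is floxed out.
crisprDonor automates that pipeline end to end and emits the three
annotated GenBank maps a cloning project needs: the guide-RNA vector, the
unaltered locus, and the edited locus with the circular donor plasmid.

It is aimed at fly-style knock-in workflows (pHD-type donors carrying an
SspB/fluorophore fusion cassette for iLID optogenetics plus a floxable
3xP3-DsRed eye marker, guides delivered from a U6/BbsI golden-gate
vector), but any genome supplied as FASTA + GFF3 and any vector supplied
as an annotated GenBank file will do.

## The method in brief

* **Guides.** All 20-nt protospacers adjacent to an NGG PAM on either
  strand whose blunt cut (3 bp 5′ of the PAM) falls within a window
  (default ±20 bp) of the start codon (N-terminal tag) or stop codon
  (C-terminal tag / deletion ends). Off-targets are counted exactly: for
  each mismatch count *m* ∈ {0..3}, the number of NGG-adjacent 20-mers in
  the whole genome at Hamming distance *m*. Guides are ranked by a
  position-weight efficiency score Σᵢ w(i, bᵢ) (the default 20×4 matrix is
  a labeled synthetic stand-in; plug in your own), with exact-off-target
  sites flagged and demoted.
* **Primers.** Amplification primers are sought with their 5′ ends
  1000–1200 bp from the cut on both sides, sequencing primers 400–600 bp,
  filtered on nearest-neighbor Tm (SantaLucia 1998, 57–63 °C), GC 30–70 %,
  homopolymer runs ≤ 4 and 3′ self-complementarity ≤ 3 bp, then paired by
  Tm difference and product size.
* **Donor.** 1000-bp homology arms flank the insertion point (just after
  the ATG, or just before the stop codon). A silent mutation disrupts the
  PAM in the donor — synonymous codon change if the PAM is coding, direct
  substitution if not, synonymous seed mutations as fallback — and the
  edited junction is re-checked so no exact target site survives anywhere
  in the donor.
* **Cre/LoxP.** Marker excision between the two LoxP sites is simulated
  (one 34-bp LoxP "scar" remains and serves as a peptide linker) and the
  resulting fusion is translated through the junction; designs that would
  go out of frame are rejected.

Coordinates are 0-based half-open on the plus strand everywhere inside the
package; GFF3's 1-based inclusive coordinates are converted at the parser.

## Worked example

Everything below runs offline: the `fixtures` subcommand generates a
seeded synthetic mini-genome (50 kb, 5 intron-containing genes on
alternating strands) with its GFF3 annotation.

```sh
Rscript inst/scripts/crispr-design.R fixtures --out fx --seed 42
Rscript inst/scripts/crispr-design.R guides --genome fx/genome.fa \
    --annotation fx/genes.gff3 --gene g1 --out g1_guides.tsv
```

`g1_guides.tsv` ranks the candidate guides around g1's start codon:

```
rank  protospacer           pam  strand  contig  pam_start  cut_pos  anchor_distance  efficiency  ot0  ot1  ot2  ot3
1     GCGACTTGTCATATCTACAG  GGG  +       chr1    3477       3474     -16              5.13        0    0    0    0
2     GTGCGACTTGTCATATCTAC  AGG  +       chr1    3475       3472     -18              4.91        0    0    0    0
3     CTATATCGTTTTCCATATTC  TGG  -       chr1    3485       3488     -2               4.79        0    0    0    0
```

The top guide cuts 16 bp upstream of the ATG (`anchor_distance = -16`),
scores 5.13 with the default matrix, and has no genomic off-target within
3 mismatches (`ot0..ot3` all zero). A full N-terminal EGFP tagging design:

```sh
Rscript inst/scripts/crispr-design.R tag --genome fx/genome.fa \
    --annotation fx/genes.gff3 --gene g1 --terminus N \
    --fluorophore EGFP --out design
```

writes `g1_guides.gb` (guide plasmid after simulated BbsI golden gate),
`g1_locus.gb` (unaltered locus), `g1_edited.gb` (edited locus + circular
donor, two records) and `g1_report.txt`, which ends:

```
## selected guide(s)
guide	GCGACTTGTCATATCTACAG	GGG	+	cut=3474	efficiency=5.1300	ot=0/0/0/0

## silent mutations
mutation	3478	G>T	PAM	non-coding	-

## post-flox frame check
frame	PASS	insert=1146 bp	offset=0

## guide cloning oligos
oligo	forward	CTTCGCGACTTGTCATATCTACAG
oligo	reverse	AAACCTGTAGATATGACAAGTCGC
WARN	guide cut site is 19 bp from the insertion point (threshold 10)
```

Reading this: the PAM lies upstream of the CDS, so its G at genomic
position 3478 was mutated directly (`non-coding`); after floxing out the
DsRed marker the residual insert is 1146 bp ≡ 0 (mod 3) and the fusion
translates without a premature stop (`frame PASS`); the two oligos are
ready for annealing into the U6/BbsI guide vector; and the tool warns that
the cut is 19 bp from the insertion point (re-cutting risk rises with
distance, threshold 10 bp). The maps open in Ape or any GenBank-aware
viewer. `delete --gene g2` works the same way with two cut sites and a
DsRed (or attP-DsRed) replacement cassette.

The same pipeline is available programmatically:
`parseFasta()` / `parseGff3()` → `scanGuides()` → `annotateGuides()` →
`rankGuides()` → `buildTaggingMaps()` / `buildDeletionMaps()` →
`writeGenbank()`.

### Custom vectors

Any circular GenBank record can serve as a donor template if it carries
features labeled `HA_left_slot` and `HA_right_slot` (1-bp anchors with a
`slot_at=<pos>` note marking the insertion boundary), plus optionally
`cassette` and a `loxP` pair; a `source` feature note `kind=tagN|tagC|
deletion|guide` overrides the inferred type. Pass its path via
`--vector`.

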