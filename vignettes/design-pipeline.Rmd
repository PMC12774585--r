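---
title: "Designing CRISPR deletion and tagging constructs with crisprDonor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing CRISPR deletion and tagging constructs with crisprDonor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprDonor)
```

## What the pipeline models

crisprDonor designs homology-directed-repair (HDR) experiments for SpCas9:
either replacing a gene body with a screening cassette (deletion) or
inserting a fluorophore/SspB fusion cassette at the N- or C-terminus of an
isoform (endogenous tagging). The design problem decomposes into guide
selection, primer proposal, donor construction, and post-edit validation;
each stage is deterministic given its inputs, so a whole design is
reproducible byte for byte.

The package assumes: SpCas9 with a strict NGG PAM (NAG optionally counted
as an off-target PAM, off by default); a blunt double-strand break between
protospacer bases 17 and 18 (3 bp 5′ of the PAM); HDR from a circular
double-stranded donor with two homology arms; and Cre-mediated excision of
the marker between two identical, same-orientation LoxP sites that leaves
a single 34-bp site behind.

### Coordinates

All internal coordinates are 0-based, half-open, on the plus strand;
strand is applied only when sequence is extracted. GFF3 (1-based,
inclusive) is converted exactly once, in the parser, and
`gffToInternal()`/`internalToGff()` are exact inverses (property-tested).
A guide's `pam_start` is the genomic coordinate of the PAM base that comes
first in the PAM's own 5′→3′ reading order, so the cut coordinate is
`pam_start − 3` on the plus strand and `pam_start + 3` on the minus
strand, and always falls inside the protospacer interval.

## Guide selection

`scanGuides()` enumerates every 20-nt protospacer adjacent to an NGG on
both strands whose cut position lies within a window of the anchor codon.
The default window is **±20 bp**: the cassette is inserted at the
start/stop codon, so a cut close to the insertion point maximizes the
chance that the integrated payload itself destroys the target site and
suppresses re-cutting. The window is configurable (`guide_window`); loci
with sparse PAMs may need 50–100 bp.

Off-targets are counted exactly (`countOfftargets()`): for each mismatch
count m in 0..3, the number of NGG-adjacent 20-mers genome-wide at
Hamming distance exactly m from the protospacer, excluding the site's own
locus. No bulges and no cleavage-likelihood model (CFD/MIT) are used: an
exact mismatch count is auditable and is verified in the test suite
against a brute-force scan of every genomic offset. Windows containing N
never match a PAM; N inside a candidate protospacer counts as a mismatch.

Efficiency is a position-weight sum: score = Σᵢ w(i, baseᵢ) over the 20
protospacer positions. The shipped matrix is a synthetic stand-in with
generic, hand-set preferences (mild GC preference toward the PAM-proximal
seed, a penalty for a PAM-proximal T, a small bonus for a 5′ G); its
provenance header says so explicitly. The matrix is a plug-in
(`readEfficiencyMatrix()`): tests exercise only the scoring contract,
never the default values, and no claim is made that the default
reproduces any trained efficiency model.

`rankGuides()` orders by: exact-off-target sites last (flagged, not
removed — the user, not the tool, should make the final call), then
efficiency descending, total off-targets (ot1+ot2+ot3) ascending,
|distance to anchor| ascending, then cut position, PAM position and
strand. The trailing keys make the order total, so ranked output is
byte-reproducible and re-ranking is the identity.

## Primer proposal

Primer search windows are anchored on the **cut position**: amplification
primers have their 5′ ends 1000–1200 bp away on both sides, sequencing
primers 400–600 bp. Windows are stored as half-open intervals using those
numbers literally (`[cut−1200, cut−1000)` and so on) and are clipped to
the locus, warning when a window is lost entirely. Measuring from the cut
to the primer 5′ end is this package's documented convention; measuring
from the insertion point or the arm edges would shift windows by at most
the cut-to-insertion distance, which is warned above 10 bp anyway.

Candidates of length 18–27 nt are filtered, in a fixed order with
per-filter failure counts reported: alphabet (no N), GC 30–70 %,
homopolymer run ≤ 4, melting temperature 57–63 °C, 3′ self-complementarity
≤ 3 bp. Tm uses nearest-neighbor thermodynamics (SantaLucia 1998 unified
parameters; entropy salt correction 0.368·(N−1)·ln[Na⁺]; Tm =
1000·ΔH/(ΔS + R·ln(Cₜ/4)) − 273.15, with defaults Cₜ = 50 nM and [Na⁺] =
50 mM), verified in tests against an independently coded summation to
0.01 °C; the 2·(A+T)+4·(G+C) Wallace rule is available as a cheap
alternative. 3′ self-complementarity is scored as the longest suffix that
is its own reverse complement — the simplest model of two 3′ ends
annealing — and hairpin ΔG is deliberately out of scope. Amplification
pairs are ranked by |ΔTm| then by distance of the product size from its
optimum (default 2200 bp, the midpoint of what the far windows allow);
sequencing primers are single oligos ranked by closeness to the Tm-range
midpoint. All constraints live in `designConfig()`.

## Donor construction

Homology arms default to **1000 bp**, anchored at the insertion point
(N-terminal: immediately after the ATG, keeping the genomic start codon;
C-terminal: immediately before the stop codon) or at the two cut positions
for deletions. Arms are exact plus-strand genomic substrings except for
the silent mutations below; arms that would run off the contig are
shortened with a warning.

### Silent PAM disruption

An HDR donor that still matches the guide perfectly will be re-cut. The
mutation strategy is a deterministic priority list:

1. a **synonymous** single-base change at a PAM GG base lying in
   annotated CDS (codon translation unchanged, PAM no longer NGG);
2. a direct substitution at a PAM GG base lying outside CDS (flagged
   `non-coding`);
3. substitutions in the PAM-proximal 10-nt seed — synonymous where
   coding, free where non-coding — up to two at distinct codons;
4. a hard error telling the user to pick another guide.

After assembly the edited sequence is re-scanned for the exact
protospacer+PAM in both orientations: an intact protospacer in one arm
can be completed by a coincidental NGG at the cassette edge, in which
case seed mutations are forced and the design is rejected if the site
still survives. Every emitted donor therefore satisfies two invariants
that the test suite checks directly: the translated arm CDS equals the
unmutated translation, and the guide matches the donor nowhere at zero
mismatches.

### Templates, LoxP register and floxing

Four tagging templates (SspB(R73Q)–linker–EGFP/mCherry and the
C-terminal mirror images), two deletion templates (floxable DsRed, with
or without an attP landing site) and a U6/BbsI guide vector are shipped
as GenBank files. Their backbone and ORF sequences are **synthetic
stand-ins** — deterministic sequences with the correct topology,
lengths, reading frames and restriction-site placement — because the
real plasmid sequences are not bundled; every record carries a
`synthetic stand-in` note and users can substitute real GenBank files.

The canonical 34-bp LoxP reads without a stop codon only when codons
start at its first base, and 34 ≡ 1 (mod 3). Each tagging template
therefore carries a fixed 2-nt `CC` spacer on the payload side of the
LoxP pair, so that the residual insert after floxing (cassette + LoxP +
spacer = 1146 bp for EGFP, 1137 for mCherry) is a codon multiple and the
junction codon reads TCC (Ser). This register is a property of the
template; `validateFrame()` enforces it rather than assuming it: it
translates from the isoform ATG through the residual insert into the
downstream CDS and fails on any premature stop or non-multiple-of-3
insert. `simulateFlox()` requires exactly two identical same-orientation
LoxP features, excises between their start positions, and errors on
zero, one, more than two, or inverted sites (Cre inversion is out of
scope).

Guide cloning follows BbsI golden gate: two outward-facing BbsI sites are
released with the stuffer, exposing GAAG/GTTT overhangs; the annealed
oligo pair (`CTTC(G)+protospacer` / `AAAC+revcomp`) is ligated in silico
and the product is checked to contain the spacer exactly once downstream
of the U6 promoter with no residual BbsI site. A 5′ G is prepended to
protospacers that lack one (the U6 polymerase-III start preference).

## The synthetic mini-genome

`makeMiniGenome()` is a first-class, tested module, not a test shortcut.
It emulates a compact annotated genome: uniform-random intergenic
background, 5 genes of 160–320 codons on alternating strands, optional
GT..AG introns of 60–200 bp, a written GFF3 with gene/mRNA/exon/CDS rows
and correct phases, and a truth table of codon anchors and spliced CDS
strings. Identical specs give byte-identical files. It can also plant
exact duplicates of a guide locus to give known nonzero off-target
counts. What it does **not** emulate: real base composition and repeats,
UTRs and alternative isoforms, chromatin or expression context, and any
relationship between the efficiency score and real cutting. Passing
tests on this genome therefore demonstrate the pipeline's bookkeeping
(coordinates, frames, identities, determinism), not wet-lab performance.

Default generator conditions (50 kb contig, 5 genes, 2 exons, seed-driven)
were chosen once to be large enough that every gene supports 1000-bp arms
and 1200-bp primer windows; the test suite additionally runs the scanner
oracle on ~200 random sequences of 300–800 bp and off-target oracles on
10 kb genomes — sizes at which exhaustive brute-force verification stays
fast on one CPU.

## Degenerate inputs and failure modes

Empty guide windows return empty tables (the CLI turns them into a design
error naming the window); `arm_length = 0` produces empty arms with a
warning; windows off the contig are clipped with warnings; inverted or
equal deletion cuts, unknown genes/isoforms, non-ACGTN genomes and
frame-breaking designs are hard errors with distinct condition classes
(and distinct CLI exit codes). Warnings raised during a design are
collected and echoed as machine-readable `WARN` lines in the report.

## Known limitations

* Off-target counting is exact-match Hamming only: no bulges, no
  cleavage-probability score, no genome index persisted to disk.
* The efficiency matrix is a stand-in; rankings are reproducible but not
  predictive until a user supplies a trained matrix.
* Primer filtering has no secondary-structure thermodynamics.
* Cre inversion (inverted LoxP), PBac/marker-excision scarless designs,
  prime editing and non-SpCas9 nucleases are out of scope.
* Circular coordinates never wrap: templates are stored rotated so no
  feature spans the origin.
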