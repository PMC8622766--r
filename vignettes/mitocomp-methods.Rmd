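---
title: "Comparative mitogenomics with mitocomp: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative mitogenomics with mitocomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

## The problem

Insect mitochondrial genomes are compact circular molecules of roughly
14–20 kb carrying a fixed gene complement: 13 protein-coding genes
(PCGs), 22 tRNAs, two rRNAs, and one long A+T-rich control region (CR).
Most species retain the ancestral pancrustacean arrangement of those 37
genes, so departures from it — translocations, inversions, and the
non-coding regions (NCRs) they leave behind — are rare, effectively
neutral characters that can diagnose whole lineages. A well-studied
example is the rhinoceros-beetle subfamily Dynastinae, where the two
tRNAs that follow the control region have swapped positions and acquired
an intervening NCR, turning the ancestral trnI-trnQ-trnM cluster into
trnQ-NCR-trnI-trnM, while the related flower chafers (Cetoniinae) keep
the ancestral order.

`mitocomp` implements the comparative analyses this kind of study rests
on: composition and strand-skew statistics, codon usage and start/stop
codon calling under the invertebrate mitochondrial code, scanning for
overlaps, spacers, motifs, homopolymers and tandem repeats,
control-region characterization, gene-order comparison against the
ancestral arrangement, and exhaustive enumeration of single
tandem-duplication–random-loss (TDRL) events that could explain an
observed rearrangement. A synthetic-mitogenome generator with complete
ground truth makes every stage testable without downloading data.

## Composition and strand asymmetry

Base composition is summarized by the AT fraction and the two skews

$$\mathrm{AT\ skew} = \frac{A - T}{A + T}, \qquad
  \mathrm{GC\ skew} = \frac{G - C}{G + C},$$

computed on the forward (majority, "J") strand. Ambiguity codes are
excluded from every denominator, and a zero denominator yields `NA`
rather than an error. Skews are antisymmetric under reverse
complementation, which the test suite asserts as a property.

`region_composition()` concatenates a selected feature set. The default
is genome **forward-strand** orientation even for minority-strand (N)
genes, because the characteristic contrast between J-strand and N-strand
PCG skews only exists on a fixed strand; `orientation = "reading"`
switches to reading orientation when the codon-level view is wanted.
AT percentages are reported to one decimal at genome scale and two for
the control region, matching the conventional reporting precision of
mitogenome papers; raw fractions are always retained.

## Codon usage and RSCU

Codon counting uses NCBI translation table 5 (invertebrate
mitochondrial). Each CDS, read in its own orientation, is cut into
triplets; a terminal complete TAA/TAG and any incomplete remainder are
excluded from the usable total, so "total codons" means codons that
encode amino acids. Because it is genuinely ambiguous whether an
incomplete terminal codon should count as one codon, the table carries
both conventions (`total_codons` and `total_codons_incl_incomplete`),
defaulting to exclusion.

Relative synonymous codon usage is

$$\mathrm{RSCU}(c) = \frac{n_c \, k}{\sum_{c' \in \mathrm{fam}(c)} n_{c'}},$$

with $k$ the synonymous family size. Families follow the mitochondrial
convention of splitting leucine into Leu1 (CUN) and Leu2 (UUR) and
serine into Ser1 (AGN, which under table 5 includes AGA/AGG) and Ser2
(UCN); this matches how the field reports "Leu2 (UUA)" among the most
used codons and keeps every family mean at exactly 1 whenever the family
is observed.

## Start- and stop-codon calling

Mitochondrial PCGs often lack a canonical ATN start at the annotated
position; COX1 in particular frequently begins with an atypical codon.
The rule implemented by `identify_start_codon()` is the
minimize-intergenic-space principle: scan offsets $0..W$ (default
$W = 60$ bp) downstream of the upstream gene's 3' end, accept the first
codon that belongs to a candidate set, and therefore never overlap the
upstream gene. Candidate sets, in rank order at equal offset, are the
canonical ATN starts (ATA/ATT/ATC/ATG), the AAN pair (AAC/AAT), and a
rarer atypical set (GTC, GTG, TTG, CAA, CGA, AAA, CTA) drawn from codons
reported as starts in beetle mitogenomes. Because the sets are disjoint,
one offset holds exactly one candidate and the rank only matters as a
formal tie-break; the consequential behaviour is that an AAC one base
after the upstream tRNA beats a canonical ATN 34 bp away. The window of
60 bp was chosen once to cover that observed 34 bp case with a margin;
no gene in the test fixtures comes close to the bound.

Stops use the annotated reading frame: a complete in-frame TAA/TAG at
the 3' end, otherwise a trailing in-frame `T` or `TA` is called as an
incomplete stop completed by post-transcriptional polyadenylation.
`TA` is supported and flagged distinctly even though single-`T` stops
dominate published tables. An in-frame stop strictly before the
annotated end raises a premature-stop flag rather than silently
re-annotating.

## Gene orders, breakpoints, and moved genes

A gene order is a signed circular permutation of canonical labels
(`-trnQ` = minority strand). Two orders are compared as rotations but
**not** reflections: the circular chromosome is read on a fixed strand,
and identifying reflections would conflate a whole-genome inversion with
identity.

The breakpoint distance counts unsigned circular adjacencies of the
reference absent from the observation. NCR elements are excluded —
they are products of rearrangement, not markers. Sign changes do not
enter the distance; they surface through `moved_genes()` and the event
classification, so an in-place strand flip reports distance 0 with
event class `inversion` (the one place where distance 0 is not "no
event").

`moved_genes()` returns *all* minimal sets of genes whose removal makes
the two orders rotation-equal, searching removal sets exhaustively up to
size 3 and falling back to a single optimum recovered from a maximum
circular common subsequence (computed exactly over all rotation pairs)
for larger events. Reporting every optimum matters: for the dynastine
arrangement, removing either trnI or trnQ alone restores the ancestral
order, and the two singletons are different biological hypotheses.

Event classes: `none` (no distance, no flips), `inversion` (every moved
gene changed strand only), `translocation` (strands preserved),
`complex` (mixed). A separate `tdrl_compatible` flag records whether a
single TDRL can produce the observation, because a translocation can be
simultaneously TDRL-compatible and the two statements are answers to
different questions.

## Single-TDRL enumeration

A tandem duplication–random loss event duplicates one contiguous block
in tandem and then loses exactly one of the two copies of each
duplicated gene; degenerate remnants of lost copies can persist as
NCRs. `enumerate_single_tdrl()` searches exhaustively: every contiguous
block of the source window, every assignment of each duplicated gene to
its first or second copy, keeping scenarios whose surviving sequence
equals the target. Windows are capped at 12 elements — the observed
rearrangement hotspot (CR-trnI-trnQ-trnM) has four — which bounds the
search at $78 \times 2^{12}$ cases and keeps enumeration exact and fast.
A TDRL never changes a gene's strand, so scenarios are only sought when
moved genes preserve sign.

Each scenario records which lost copies sit, after the loss, exactly
between the surviving genes that flank an NCR in the target. These are
the candidate physical origins of the NCR. The enumeration deliberately
does not pick one: for the dynastine cluster both the lost control
region copy and a lost tRNA copy sit in the right slot, and the data do
not distinguish them.

The analysis window for `classify_rearrangement()` is built from the
moved genes plus their neighbours in both orders, expanded to a minimal
circular interval until both orders cover the same gene set; NCRs
inside the observed window are retained so remnant slots can be
assigned.

NCR lengths are classed by the published dichotomy: below 100 bp NCR1,
above 400 bp NCR2; 100–400 bp is reported as `intermediate` and flagged
as outside that dichotomy rather than forced into a class.

## Region scanning

`adjacent_spacers()` walks circularly adjacent feature pairs, including
the origin-spanning pair; negative lengths are overlaps. Features nested
inside another feature are excluded from the chain (and listed
separately) so that the conservation identity — feature lengths plus
signed spacer lengths equal the genome length — holds exactly; the test
suite asserts it for every fixture. Every positive spacer counts as an
intergenic spacer at the default threshold of 1 bp; because published
"IGS counts" often use an unstated minimum, the genome summary also
reports the count at a 5 bp threshold.

Motif search supports IUPAC degeneracy and reports overlapping hits
(TACTA twice in TACTACTA). The tandem-repeat finder is exact-match by
design (mismatch-tolerant detection in the style of Tandem Repeats
Finder is out of scope): it scans each period length with an
$O(n \cdot u_{max})$ self-comparison, reports maximal arrays with at
least the requested copy number (fractionally, when a partial copy
trails), and reports each array once under its smallest period by
keeping only primitive units — by the Fine–Wilf periodicity argument a
primitive-unit array of two or more copies cannot hide a smaller
period.

`locate_control_region()` derives the CR span from gene boundaries —
from the 3' end of rrnS to the start of the next annotated gene,
circularly — rather than trusting a CR annotation. In the ancestral
order that next gene is trnI; in the rearranged order it is trnQ, which
is itself a diagnostic observable. Whether flanking micro-spacers
belong to the CR is convention; the boundary used here is documented
and the computed span is returned alongside length and AT fraction.

## The synthetic-mitogenome generator

The generator emulates the observables of scarab-beetle mitogenomes at
study scale, with every planted feature returned as ground truth:

* **Templates.** `"cetoniinae"`: ancestral order, COX1 starting AAC one
  base downstream of trnY (the canonical-ATN-at-34-bp geometry is
  exercised separately in fixtures), TACTAA motif in the trnS2–ND1
  spacer. `"dynastinae"`: rearranged trnQ-NCR-trnI-trnM order, NCR of
  56 bp by default or 412 bp for the long class, TACTA motif, and an
  11 bp C homopolymer in a 20 bp trnK–trnD spacer. Both: an 8 bp
  trnW/trnC overlap and an incomplete T stop on COX2.
* **Lengths.** PCG lengths follow a realistic beetle profile (ATP8
  156 bp, ND5 1716 bp, total ≈ 11.1 kb; the profile yields 3703 coding
  codons, inside the published 3696–3703 range), tRNAs 65 bp, rrnS
  780 bp, rrnL 1280 bp, CR 1776 bp — together ≈ 16.4 kb, at the small
  end of the observed 16.4–19.5 kb span, chosen to keep tests fast
  without leaving the realistic range.
* **Composition.** Non-coding background is sampled per base at
  AT = 0.75 with AT skew +0.05 and GC skew −0.20 on the forward strand
  (mid-range of published whole-genome values); the CR and NCR use a
  richer AT = 0.80. PCG bodies are drawn codon-wise from an
  independent-base codon pool *recalibrated* so that the conditional
  composition after excluding stop codons hits the same targets —
  without the recalibration, removing the AT-rich stops TAA/TAG biases
  coding AT down by almost a percent. N-strand genes use sign-flipped
  skew targets in reading orientation so their forward-strand
  contribution stays coherent. The whole-genome AT expectation is
  therefore a mixture of the background and CR targets; the ground
  truth reports that mixture (`expected_genome_at`), and measured AT at
  16 kb falls within ±0.01 of it (≈ 3 sampling standard deviations).
* **Exactness by rejection.** Spacers that sit upstream of a PCG start
  are resampled until no spurious start-codon candidate precedes the
  planted one; motif spacers are resampled until the motif occurs
  exactly once; homopolymer spacers pin non-matching flanking bases so
  genomic context cannot extend the run; the CR repeat array uses a
  primitive unit with both boundaries pinned so the detected array has
  exactly the planted start, unit, and copy number. This is what makes
  "every stage recovers ground truth exactly" a testable statement
  rather than a statistical one.
* **Determinism.** One integer seed drives all draws through a
  local-RNG helper that never touches global random state; the same
  spec and seed give byte-identical output, and changing only the seed
  changes sequence content but not annotation geometry.

What the generator does **not** emulate: tRNA cloverleaf structure or
any RNA secondary structure, codon usage shaped by selection (codons
are drawn independently), mismatch-containing repeat arrays,
length/composition covariation across lineages, and sequencing error.
Passing the round-trip tests therefore demonstrates correctness of the
measurement code on annotated sequence, not robustness to annotation
error in real GenBank records — unmappable names, missing genes and
duplicates are instead exercised by dedicated messy-input tests.

## Numerical and interface choices

* Internal coordinates are 0-based half-open; user-facing tables are
  1-based inclusive (GenBank convention). Origin-spanning features are
  a single feature with `end > length`, interpreted modulo the genome
  length.
* Unknown gene names never abort a run; they become flagged
  `unknown:<raw>` features excluded from 37-gene logic.
* The Leu/Ser tRNA paralogs are resolved by codon-family tags or
  anticodons (GCU → Ser1/AGN, UGA → Ser2/UCN, UAG → Leu1/CUN,
  UAA → Leu2/UUR).
* RSCU of an unobserved family is 0 (not NA); stop codons carry no
  RSCU.
* All report tables are plain tibbles; TSV/JSON writers are
  deterministic so repeated runs are byte-stable.

## Problem sizes used by the test suite

The property tests run at sizes chosen to finish in well under a minute
each while exercising the full combinatorics: TDRL enumeration is
cross-checked against an independent brute-force oracle on 200 random
signed windows of 3–6 elements; RSCU normalization on 100 random codon
tables; composition properties on 100 random sequences up to 2 kb; the
generator round trip on 20 random specs across both templates at full
16.4 kb scale. The exhaustive `moved_genes()` search is capped at
removal sets of size 3 (beyond which the exact circular-LCS fallback
returns one optimum instead of all).

## Known limitations

* Only single-TDRL scenarios are enumerated; multi-event histories and
  rearrangement distances (DCJ, sorting by reversals) are out of scope.
* The breakpoint distance is the simplest adequate statistic; it is not
  a phylogenetic distance.
* The GenBank writer emits the minimal dialect the reader parses; it is
  intended for round-tripping and fixtures, not for submission-grade
  records.
* Start-codon calling trusts the annotated upstream gene; if the
  upstream annotation is wrong the offset is wrong with it.
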