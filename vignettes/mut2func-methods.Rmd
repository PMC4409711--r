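---
title: "Methods: from candidate mutations to functional consequences"
author: "mut2func"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from candidate mutations to functional consequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mut2func)
```

This vignette explains the models and procedures behind each stage of the
package, the parameters that matter, the choices made where the design was
genuinely open, and what the synthetic-data tests do and do not demonstrate
about real data.

## The problem

A classical mutant of a filamentous fungus loses a phenotype (here the
motivating case is loss of cellulase production); resequencing produces a
list of candidate variants. The package implements the desk half of the
analysis: trustworthy-context filtering, placement of variants into gene
elements, exact consequence prediction on spliced coding sequence, and
physicochemical characterization of truncated protein products — plus the
two quantitative assays (live-cell nucleo-cytoplasmic imaging and RT-qPCR)
used to confirm a candidate, implemented against simulated data with known
ground truth.

## Coordinate model

All coordinates are 1-based with inclusive intervals. A `TranscriptModel`
stores exons in ascending genomic order and the genomic CDS span; the
*spliced CDS* is the concatenation of coding bases in transcript
orientation, with offset 1 at the first base of the start codon. Offset
`o` lies in codon `((o - 1) %/% 3) + 1` at codon position
`((o - 1) %% 3) + 1`. This start-anchored convention is the only one
consistent with the worked codon mappings in the test suite (offset 38 in
codon 13, 71 in 24, 2294 in 765). One deliberately preserved tension: a
printed source table pairs offset +1189 with residue 389, while the
arithmetic gives codon 397; the pipeline reports the arithmetic result and
the packaged fixture carries a conflict note rather than silently adopting
either reading.

Minus-strand genes are fully supported: variant alleles are expected on the
forward genomic strand (VCF convention) and complemented during CDS
application; the mapping functions are validated against an exhaustive
per-base oracle over randomized multi-exon models on both strands.

## Context filters

The published analysis filtered homozygous calls on genomic context:
"complexity = 1, uniqueness > 15.8, GC between 0.31 and 0.74", without
defining the scorers (they came from an in-house short-read-era pipeline).
The package makes each scorer explicit, pluggable and documented:

* **Window**: 100 bp centered on the variant, clipped at scaffold ends.
* **GC**: (G+C)/(non-N window length). Bounds 0.31–0.74 inclusive.
* **Linguistic complexity**: distinct k-mers / min(4^k, L−k+1). The default
  is k = 2: any non-degenerate 100-bp window contains all 16 dinucleotides
  and scores exactly 1, matching a threshold that every accepted real
  variant met, while homopolymer and dinucleotide tracts score far below 1.
  With k = 4 a 100-bp window (97 positions, 256 possible words) cannot
  reach 1 even for perfectly unique sequence, which would make the
  published threshold reject everything — that is why k = 4 is available
  but not the default.
* **Uniqueness**: each window k-mer is counted genome-wide,
  strand-symmetrically (a k-mer and its reverse complement are one key),
  and scored 16/occurrences; the site score is the mean. Unique context
  scores 16, an exact two-copy repeat 8, so the published threshold 15.8
  reads as "essentially unique". The default k-mer length is 31,
  the scale of the short reads whose mappability the score emulates; at
  this length chance duplications in a multi-megabase genome are
  negligible (expected rate ≈ 2N/4^31), so the score separates planted
  repeats cleanly from background.

Degenerate (all-N) contexts are flagged `no-context`, never dropped
silently. Filters are monotone by construction: relaxing any one threshold
can only grow the surviving set (property-tested).

## Element assignment

Scan windows are asymmetric and anchored on the coding region: promoter =
up to 800 bp 5' of the translation start, terminator = up to 200 bp 3' of
the stop, both strand-aware; positions inside the transcript are exon
(with a UTR sub-flag where exonic but non-coding), or intron. Where the
source material says both "800 bp window flanking" and "800 bp upstream",
the asymmetric 800/200 reading is implemented, since the worked gene list
is only consistent with coding-region-anchored windows. Ties between
overlapping genes go to the nearest CDS boundary; exact ties are all
reported with the first-by-coordinate marked primary, so the choice is
visible rather than silent.

## Consequence prediction

SNVs are compared codon-by-codon (synonymous/missense/stop gained/stop
lost). Indels anchored VCF-style are mapped onto the spliced CDS; events
whose bases are not spliced-contiguous coding positions are called
`splice_disrupting` and not translated (the spliced product is undefined).
Net length ≡ 0 (mod 3) gives an in-frame indel; anything else is a
frameshift. The mutated CDS is then translated from the start codon with
the standard code; the **novel peptide starts at the codon containing the
first altered base** — not the first fully downstream codon — because a
frameshift inside codon position 2 already changes that codon's residue
(this is exactly what makes the 16-residue peptide of the flagship fixture
start at codon 765 although the deleted base is offset 2294, codon position
2). Stop types are reported by name (amber TAG, ochre TAA, opal TGA);
absence of a downstream stop is reported as `none_found` with a flag, and
genomic 3' read-through is out of scope. N bases translate to X and
degrade calls to `uncertain` rather than fabricating residues.

## Protein features

* **Instability index**: the published 400-entry dipeptide weight table
  (Guruprasad et al. 1990), II = (10/L)·Σ DIWV; ≥ 40 classifies a protein
  unstable. Non-standard residues are skipped with a warning and L
  renormalized. The implementation is checked against formula identities
  and frozen values from an independent implementation of the same table.
* **Isoelectric point**: Henderson–Hasselbalch net charge with the classic
  Bjellqvist pKa set, including residue-specific N/C-terminal overrides,
  solved by monotone root search to 1e-4 pH. Because the C-terminal pKa
  depends on the terminal residue, pI is monotone in acid content only for
  interior insertions; the tests encode exactly that.
* **Coiled coils**: Lupas-style window scan (window 14/21/28, default 28)
  over per-position heptad propensities (the MTIDK residue table), best of
  the 7 registers per window via geometric mean, per-residue maximum over
  covering windows, converted to probability by a two-Gaussian
  (coiled-coil vs globular) likelihood ratio with a 1:30 prior. The
  Gaussian calibration constants per window are this package's own,
  chosen so that globular-composition scores map below 0.5 and canonical
  heptad repeats above 0.9; the upstream web tool's exact constants are
  unpublished at this granularity, so region boundaries should be read
  with a tolerance of one window. Zero propensities (e.g. proline at most
  positions) are floored at 1e-6 for log-space scoring, which keeps
  poly-proline at probability ~0.
* **Truncation report**: a domain is intact iff it ends at or before the
  mutant length, lost iff it starts beyond it, else partial.

## Imaging simulation and quantification

Single-plane scenes stand in for confocal sections: nuclei are disks
(default radius 5 px) on a jittered grid that guarantees non-overlap and a
clear cytoplasmic patch at a fixed offset for each paired cytoplasm ROI.
Pixel intensities model photon-limited detection: Poisson shot noise on the
signal plus additive Gaussian read noise (default SD 2) and an optional
flat background (default 0 — raw relative intensities, no background
subtraction). The quantifier reproduces the fixed-size circular ROI
protocol: per-ROI means, condition means over ≥ 120 nuclei (a warning is
emitted below that), the n/c ratio, and fold-change of the nuclear mean
versus the first time point; the SD across nuclei is reported as
biological dispersion, not a standard error. The normalization baseline
for "relative intensity" is the t = 0 nuclear mean, documented here
because the source figures leave it implicit.

Default study conditions in the tests mirror the confirmed biology: a
full-length construct rising eight-fold in nuclear signal within 60 min of
induction, a truncated construct rising only three-fold and reaching 13%
of the full-length nuclear concentration; recovery is asserted within 10%
(fold-changes) and ±0.02 (the 13% ratio) at 120 nuclei. ROI placement uses
ground-truth centers: nucleus segmentation is deliberately out of scope,
so the tests validate the quantification arithmetic and noise behavior,
not detection on real images.

## qPCR

Amplification efficiency comes from a least-squares fit of mean Cq on
log10(dilution) over the standard four-level series (1, 0.1, 0.01, 0.001,
triplicates); E = 10^(−1/slope), fractional efficiency E − 1, R² reported.
Expression ratios are efficiency-corrected (Pfaffl):
E_t^ΔCq_t / E_r^ΔCq_r with ΔCq = control − sample, so upregulation gives a
ratio > 1; at E = 2 this reduces exactly to 2^(−ΔΔCq) (property-tested).
Significance uses a REST-style randomization test: whole replicates
(target and reference Cq kept paired) are permuted between groups, the
statistic is the absolute log ratio displacement, and the p-value uses the
add-one correction; permutation is on Cq values, the published default of
the cited tool. Defaults: 10,000 iterations, explicit seed. Type-I error
at nominal 0.05 is verified ≤ 0.07 over 1000 null simulations at n = 6 per
group.

## Synthetic data: what it emulates and what it does not

The generator produces seeded, byte-reproducible scenarios: multi-scaffold
genomes at a target GC (default 0.5, two 50-kb scaffolds), intron-containing
genes on both strands with valid ORFs, planted adverse-context tracts (an
exact cross-scaffold two-copy repeat, a dinucleotide low-complexity tract,
GC-rich and GC-poor windows), and twenty planted variants: fourteen in
clean context with the element mix of the motivating study (six exonic —
three missense SNVs, three 1-nt frameshift deletions — two promoter
deletions, six intergenic; i.e. eight indels and six SNVs expected to
survive) and six in adverse context expected to fail with the matching
reason. Each planted coding intent is verified against the package's own
consequence caller at planting time, and the pipeline's output is compared
against the truth table in the tests.

One construction detail is worth making explicit: every planted variant
window receives a fresh random 17-nt sequence containing all 16
dinucleotides (a random Eulerian circuit of the dinucleotide graph; inside
CDS, an 18-nt six-codon non-stop variant of it). This guarantees
complexity exactly 1 at the variant — as it was for every accepted real
variant — without ever repeating a k-mer between sites, so the uniqueness
score is untouched.

The frameshift fixture solves the overlapping-frame constraint exactly:
reference codons 765–781 are chosen (by synonymous codon choice under a
no-reference-stop constraint) so that deleting the A at offset 2294 yields,
from codon 765, the prescribed 16-residue peptide followed by an amber
stop, inside an otherwise seeded, stop-free 920-codon CDS; unconstrained
codons come from a fixed seeded stream so the fixture is stable across
releases. The packaged 14-variant discovery table is reconstructed on a
synthetic multi-scaffold genome whose gene coordinates are invented
(minimal scaffolds accommodating the printed positions, generated in code
at run time); two of its SNVs are only consistent with minus-strand genes,
which the fixture places accordingly — a deliberate exercise of the strand
paths.

What passing these tests shows: the arithmetic, filtering logic,
consequence accounting, and assay quantifiers are correct against
exhaustive oracles and known ground truth. What it does not show: read
mapping and variant calling quality, nucleus segmentation, or the behavior
of the context scorers on real repeat families — real genomes have
structured repeats, GC heterogeneity and N-runs that the uniform-background
generator only caricatures.

## Numerical choices and degenerate inputs

Problem sizes used by the default test run were chosen to keep the suite
comfortably inside a routine desk run: ~120 randomized models per oracle
property, 1000 null simulations for the type-I check, 120-nucleus scenes,
and one full pipeline pass over the ~5.5-Mb reconstructed discovery
genome. Tolerances: pI root at 1e-4 pH; imaging recovery at the
Poisson-noise scale of 120 nuclei; identity checks exact. Ties and edge
cases: empty variant lists produce valid empty reports; identical
ref/alt alleles, off-scaffold positions, all-N windows, sub-codon CDS and
out-of-bound domains raise informative errors; reports are
deterministically ordered (numeric scaffold order, then position) and
byte-identical across reruns.

## Known limitations

Single transcript per gene (no isoform selection); no nonsense-mediated
decay or codon-usage modelling; no enhancer/motif discovery; genomic 3'
read-through after stop loss unreported; coiled-coil boundaries are
calibration-dependent as discussed; the imaging module quantifies but does
not detect nuclei; qPCR fold-change values from the motivating study are
not reproducible without its unpublished raw Cq tables, so the qPCR tests
validate the estimator, not historical numbers.
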