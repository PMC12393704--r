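---
title: "Methods: how pinvade measures a P-element invasion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how pinvade measures a P-element invasion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pinvade)
```

`pinvade` quantifies the state of a transposable-element invasion from
alignments against the element consensus. This vignette describes the
estimators, their assumptions, the tunable parameters, what the
synthetic-data generator does and does not emulate, and the numerical
and design choices that were genuinely open.

## Coordinates and inputs

All coordinates are 1-based closed intervals on the consensus forward
strand; conversion to and from 0-based or half-open conventions happens
only at the SAM/GFF boundaries. Inputs are text SAM (read through
`Rsamtools`/`GenomicAlignments`), a consensus FASTA, a GFF3 feature
annotation (ORF0–ORF3, IVS1–IVS3, TIRs, transposase-binding sites and
the DNA-binding domain inside ORF0), and RepeatMasker `.out` tables for
assembly censuses. The bundled consensus is a synthetic stand-in with
the correct anatomy; every function accepts a user-supplied consensus
and annotation, so a run against the real published sequence only needs
those two files.

## Copy number

Copies per haploid genome are estimated as mean element coverage divided
by mean single-copy-gene coverage. A single-copy gene is present exactly
once per haploid genome, so its depth calibrates sequencing effort; the
three genes are weighted equally rather than by length, which keeps one
short gene from dominating the normaliser. The mean is taken over *all*
consensus positions, deleted regions included: the estimate is therefore
a sequence-dosage measure that under-counts insertions when internal
deletions segregate. This is intentional — the per-variant accounting
lives in the deletion-frequency estimator — and it reproduces the
textbook example exactly (element 50×, single-copy genes 5× → 10
copies). No trimming is applied before averaging, and no GC or
mappability correction is attempted.

## Internal deletions

Split reads — alignments whose CIGAR skips a reference interval of at
least `min_gap` bp (default 20, separating genuine internal deletions
from small indel polymorphisms; no published floor exists), or
primary/supplementary pairs on one strand leaving such a gap — are
clustered into deletions. Clustering merges evidence whose start and end
each differ by at most `tolerance` bp (default 3) and takes the
support-weighted modal coordinates, breaking ties towards the smallest
start and largest end.

The frequency of a deletion is its split-read count divided by a
baseline: the mean depth over positions outside every deletion,
excluding `end_trim = 50` bp at either element end where coverage is
systematically lower. Frequencies are clamped to [0, 1] because the
ratio estimator can exceed 1 by sampling noise, and deletions supported
by fewer than 2 reads are dropped as singleton artefacts (both choices
ours; the ratio itself follows the published recipe). Deletions below
`min_frequency = 0.05` are filtered before reporting.

Two full-length measures complement this. The *zero-coverage test* is
one-sided: any uncovered position proves the sample holds no full-length
copy, but full coverage does not prove one exists, because
non-overlapping deletions in different insertions can tile the element.
The *full-length frequency* of a replicate is the minimum (over
positions, after the same end trim) of the cross-individual mean depth,
divided by the same baseline; we compute it on raw depth with a shared
baseline, since whether the original recipe used normalised or raw
minima is ambiguous, and record that choice here. Finally the *deletion
landscape* assigns each position the mean frequency of deletions
spanning it — a per-site picture of how favourable losing that site is
for reaching high frequency.

## Repressor classification

The repressor model is the KP-element configuration: a protein that
cannot transpose but still occupies transposase-binding sites requires
(i) interrupted transposase translation and (ii) an intact DNA-binding
domain in ORF0.

For each variant we reconstruct the germline message: ORF0–ORF3
concatenated with IVS1–3 spliced out, mapped through the deletions. The
germline frame is used for defect calling because repressor biology
concerns the germline transposase message (IVS3 is somatically
retained); the somatic frame is not needed for classification. An
intron whose donor or acceptor (first or last two bases) is destroyed by
a deletion is treated as unspliceable and its remaining sequence stays
in the message; a fully deleted intron contributes nothing.

The defect scan translates from frame 0 with the standard nuclear stop
set {TAA, TAG, TGA}. Status is `frameshift` when a junction offsets the
downstream frame by a non-multiple of 3, `premature_stop` when a stop
codon appears before the final codon, `deleted` when coding sequence is
missing without either defect (an in-frame deletion still interrupts
the transposase — it removes part of the protein), and `intact` only
when no deletion touches any ORF. When several defects occur the first
one 5′→3′ is reported; how combined defects should be labelled is not
specified anywhere, so first-defect reporting is our convention. The
DNA-binding domain is `intact` only if untouched by deletions and in
frame up to its end, `truncated` on any partial deletion or upstream
frameshift (severity is deliberately not graded — any damage lands in
the single ambiguous class), `absent` when fully deleted.

Classes follow mechanically: intact transposase → autonomous; defective
transposase with intact domain → putative repressor; with truncated
domain → ambiguous non-autonomous; otherwise other non-autonomous.
Summaries report each class as its summed variant frequency × 100 and
the repressor percentage as a [definite, definite + ambiguous] range.

## Small-RNA signatures

Reads of 18–35 nt are ingested with their 5′-end position (for
minus-strand reads, the highest consensus coordinate), length and
5′-most base; piRNAs are 23–29 nt, siRNAs 20–22 nt. The ping-pong
signature counts, for each distance d in 1..25, sense/antisense pairs
whose 5′ ends overlap by d (a sense 5′ at p pairs with an antisense 5′
at p + d − 1); counting is done at the level of unique 5′-position pairs
weighted by read multiplicity, which bounds the quadratic blow-up of
read-by-read enumeration. The strength of the d = 10 peak is summarised
both as a frequency and as a z-score against the other distances, since
published figures are ambiguous about which is plotted. Multimapping
reads contribute their reported alignment only.

The phasing signature tabulates 3′-to-5′ distances between same-strand
piRNAs in transcript orientation, d in 0..25, again as position-level
products. We deliberately use this cross-correlation form rather than
"distance to the single next read sorted by 3′ end": at realistic read
densities an unrelated read almost always sits between two phased
neighbours, and the sorted-neighbour statistic degenerates to d ≤ 0
while the cross-correlation keeps the 1 nt adjacency peak intact.
Upstream (overlapping) pairs are excluded rather than pooled into the
d = 0 bin.

## Splicing and expression

A read supports splicing of an intron only if it carries an `N` gap
exactly matching the annotated intron — no fuzz, since no tolerance is
published. Levels are spliced reads per million mapped library reads
(srpm); the "per million" phrasing is read as total library reads, not
element-mapped reads. The companion rate estimator divides spliced by
spliced-plus-retained junction reads, where a retained read aligns
continuously through the donor site. Expression is reported as rpkm
split by strand; the published y-axis unit is unstated, so rpkm is our
recorded convention, not a reproduced one.

## Census rules

Short reads: a sample is credited with a full-length insertion when its
normalised coverage exceeds 1 at the minimum over all positions — the
strictest reading of "coverage > 1 over the whole sequence" — with an
optional interval restriction for analyses that only trust central
regions. Assemblies: RepeatMasker hits of the element are merged when
they lie on the same contig and strand within `merge_gap = 100` bp
(fragment merging is undescribed in the original; 100 bp covers typical
assembly gaps) and advance through the consensus in the strand's
direction. A merged insertion's aligned length is the union length of
its fragments' consensus intervals — not the span, so an internally
deleted copy whose flanking fragments are contiguous in the contig is
not mistaken for full length. Insertions longer than
`floor(0.8 × consensus length)` (2325 bp for 2907) are full length,
strictly.

## The synthetic-data generator

The generator is the package's study design, with defaults fixed to the
experimental setting it emulates: pools of 60 diploid flies, 125 bp
single-end reads, error-free by default (a uniform substitution mode
exists, but estimator properties are assessed without aligner
artefacts), piRNA lengths 23–29 nt with mode 26, ping-pong offset 10 nt,
initiator 5′-U probability 0.85, phased-trail gaps peaked at 1 nt (half
of all gaps), and 21 nt-centred siRNAs with a weaker (0.5) U bias.
Single-end simulation is used even though the emulated design was
paired-end, as read pairing adds nothing to any estimator here.

DNA-seq pools fix the total copy count at `round(copy number × 2N)`,
split it multinomially across variants and uniformly across genomes, and
draw reads at per-genome depth `coverage / 2N`. Each insertion is
treated as embedded in flanking genomic DNA: read starts run over the
flanks and alignments are clipped to the element, so expected depth is
uniform to the element's edges, as for a real insertion (the 50 bp end
trim in the frequency baseline then guards against alignment-edge
artefacts of real aligners, which the simulator does not reproduce).
Junction-spanning reads are emitted as gapped (`D`) single alignments
rather than split alignment pairs, so the detector's CIGAR path is
exercised; soft-clip re-alignment, mismatches, multimapping ambiguity
and insert-size information are *not* modelled, and passing recovery
tests therefore demonstrates estimator correctness, not robustness to
alignment noise.

Every simulation takes a seed, is byte-reproducible given it, and writes
ground truth (realised copy counts and variant frequencies) alongside
the SAM, which is what the tests compare against.

## Numerical choices and test scale

Degenerate inputs fail loudly: zero single-copy coverage, empty
baselines and non-positive library sizes are errors, not NaNs. Empty
read sets yield empty signatures with zero counts. Signature distance
ranges are capped at 25 nt (display convention).

The test suite exercises recovery at desk scale: copy numbers 1/7/20 at
40× (10% relative tolerance), deletion frequencies around 0.1–0.3 at 50×
(±0.05), splicing rates at 10⁴ junction reads (±0.02), and small-RNA
pools of 10⁴ pairs, sizes at which the whole suite runs in a few minutes
on one CPU. These tolerances are the binomial/Poisson sampling scales of
the corresponding estimators at those depths.

## Limitations

The pipeline operates per consensus; multi-family analyses are separate
runs. It does not detect tandem duplications, inversions or foreign-DNA
insertions within the element, does not model repressor strength at the
protein level, and does not assign small RNAs to genomic source loci
(piRNA clusters). The copy-number estimate is dosage-based and is
expected to sit below the insertion count whenever internal deletions
are common — compare it with the deletion frequencies before
interpreting a plateau.
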