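---
title: "Discovering cryptic poison exons from conservation and split reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering cryptic poison exons from conservation and split reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Introns of protein-coding genes contain far more evolutionarily conserved
sequence than can be explained by known regulatory elements, and part of it
consists of unannotated ("cryptic") cassette exons that are spliced in only
in specific tissues or conditions. Many of these are *poison exons*: their
inclusion introduces a premature termination codon (PTC), so the resulting
transcript is degraded by nonsense-mediated decay (NMD) and is
systematically depleted from RNA-seq libraries — which is precisely why
such exons are missing from annotation catalogs built from expression
evidence alone. `nexon` turns this around: it uses conservation as the
primary signal and split reads and read coverage as corroboration.

## The discovery model

A candidate arises from per-sample assembled transcript models. An internal
exon $[x, y]$ of a model is a **cassette exon** when its flanking introns
$[a, x-1]$ and $[y+1, b]$ together skip-join an *annotated* intron
$[a, b]$: the exon sits inside a known intron and splices to the annotated
flanking exons on both sides. Multi-exon skips and alternative splice sites
are excluded by construction. Each candidate receives three metrics:

* **conservation** — the conserved-element score (0–1000) weighted by the
  length of the exon–element intersection,
  $\sum_i s_i |o_i| / \sum_i |o_i|$;
* **coverage** — the assembler-reported mean reads per nucleotide of the
  exon (falling back to a per-base track when absent);
* **split support** — the minimum split-read count over the two flanking
  junctions.

Rather than fixing absolute cutoffs, each sample learns its own thresholds:
the 10th percentile (nearest-rank lower quantile) of each metric over the
*annotated* cassette exons expressed in that sample. This adapts to
library depth and quality per sample and lets rarely expressed exons
surface in the samples where they are expressed. Candidates passing all
three thresholds, not annotated and not overlapping any annotated exon
(same strand, ≥ 1 bp) are aggregated across samples; an exon observed with
several flanking pairs keeps the pair with the highest pooled split-read
support (ties: shorter skip intron, then leftmost — determinism matters for
reproducible catalogs).

Split reads themselves are filtered the way splice-junction pipelines do:
the Shannon entropy of the distribution of read offsets at a junction must
reach 1.5 bits (a stack of reads all at one offset is a PCR/alignment
artifact signature), and the intron must have canonical GT/AG
dinucleotides, which also assigns its strand. GC/AG is deliberately not
accepted.

## Inclusion quantification

Percent-spliced-in uses the standard two-junction estimator on counts
pooled within a group *before* the ratio:

$$\Psi = \frac{inc_{up} + inc_{down}}{inc_{up} + inc_{down} + 2\,exc},$$

the factor 2 compensating the inclusion isoform's two read opportunities.
Estimates with denominator below 40 reads are reported missing rather than
noisy. Condition responses are plain differences
$\Delta\Psi = \Psi_a - \Psi_b$ with missingness propagated. Downstream
filters follow the same inclusive-threshold convention throughout (≥),
with one deliberate exception: a regulator must affect *strictly more
than* ten exons.

## Poison classification: the 50-nt rule

Each catalog exon is inserted in silico into every transcript of its host
gene; the mRNA is rebuilt from genomic sequence (reverse-complemented for
minus-strand genes) and translated from the annotated CDS start. The first
in-frame stop codon is a PTC when its 3' end lies **at least 50 nt**
upstream of the last exon–exon junction — the distance at which a
terminating ribosome fails to displace downstream exon-junction complexes,
triggering NMD. Two measurement choices are fixed here because the rule's
verbal form underdetermines them: the distance runs from the stop codon's
last nucleotide to the junction, and "at least 50" is inclusive. The
annotated stop codon is never a PTC, even when a frameshifted reading
lands on it at qualifying distance. Insertions upstream of the CDS or
downstream of the stop yield `utr_5prime`/`utr_3prime`; transcripts
without a CDS yield `noncoding`.

Across the host gene's transcripts, an exon is **APE** (a PTC in every
evaluable transcript), **APC** (in none) or **MIX**. UTR insertions do not
induce a PTC and therefore count on the non-poison side — this mirrors the
observation that most mixed cases are exons falling into 5'-UTRs of short
isoforms — while no-CDS transcripts are recorded but excluded.

## Conservation periodicity and frame inference

Protein-coding sequence is conserved with codon periodicity: third
(wobble) positions tolerate substitutions, so their per-base conservation
dips. For an exon with a known phase the package averages per-base scores
at codon positions 1–3 (phase follows the GFF convention); for unannotated
exons it evaluates all three phases and picks the one with the *lowest*
third-position mean (ties to phase 0). Poison exons, which are conserved
for regulatory rather than coding reasons, show no such dip — this
contrast is built into the synthetic generator and is what the
phase-recovery tests measure. An exon's phase can also be derived from an
insertion: the annotated exon following the insertion keeps its annotated
frame, so a length-$L$ exon inserted $I'$ coding nucleotides into the ORF
starts at codon offset $(I' - L) \bmod 3$. Per-base scores are genuinely
missing in real tracks, so positions without scores are excluded from the
means and a profile with under 50% coverage is reported as undefined
rather than imputed.

## Cross-species support

Coordinate mappings to another assembly are consumed as a table (liftover
itself is out of scope). A mapping is usable when gap-free with canonical
GT/AG on both mapped flanking introns. "Expressed in the other species"
requires at least one split read at *both* boundaries **within one
sample** — the strict reading of an ambiguous criterion; the laxer
each-boundary-in-some-sample reading is available as `mode = "lax"`.

## The synthetic generator: what it emulates, and what not

All tests run against `generate_locus_set()` + `generate_conservation()` +
`simulate_sample()`, which build a complete miniature study: one gene per
chromosome with a valid ORF spanning 5–8 exons, a second annotated isoform
skipping one internal exon (these annotated cassette exons drive threshold
learning), and cryptic exons planted strictly inside introns with known
class — poison plants carry a codon-aligned in-frame stop placed so the
50-nt rule holds after insertion; coding plants are frame-preserving and
drawn from a T-free alphabet so no stop can arise in any frame (with a CC
dinucleotide guarding the entry codon); UTR plants sit in 5'-UTR introns.
The generator *self-verifies*: every plant is run through the classifier
at build time and any mismatch is an error. Junction counts are binomial
at the design depth (optionally beta-overdispersed); NMD inhibition
multiplies the inclusion odds of poison exons by 3, giving ΔΨ of
the magnitude reported for experimentally validated poison exons;
single-end 150-nt split reads are emitted as SAM with uniform offsets.
Per-sample seeds derive deterministically from the cohort seed, and all
outputs are byte-reproducible.

Default study conditions: 20 genes, 15 planted exons split 73% poison /
20% coding / 7% UTR, four tissues × two samples at depth 100, three
false-positive assembled exons with moderate inclusion but no conservation
element (exercising specifically the conservation filter), element scores
U(300, 900) for annotated and U(600, 950) for planted exons, per-base
scores 3.0 with a third-position dip of 1.5 and Gaussian noise (sd 0.5)
for coding sequence only. Plants get a home tissue at ψ ∈ (0.3, 0.7) and
near-zero inclusion elsewhere; annotated cassettes span ψ ∈ (0.05, 0.95).
Larger problem sizes are used where a property needs them (≥ 100 poison
plants for the NMD-inhibition sign test; 200 coding plants for
phase-recovery rates); sizes were chosen as the smallest that make these
rates statistically meaningful.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: alignment and assembly errors, multi-mapping,
non-uniform read sampling, overlapping genes and antisense transcription,
alternative splice sites and multi-exon skips, incomplete or wrong
reference annotation, and conservation tracks with region-scale biases.
Recall/precision figures on synthetic cohorts are upper bounds, not
field performance estimates.

## Numerical and design choices

* Coordinates are 1-based closed throughout (the GRanges/GTF convention),
  so annotation I/O involves no shifting; CDS spans include the stop
  codon.
* Quantiles are nearest-rank lower quantiles: deterministic and exact on
  integer-valued count metrics.
* The weighted conservation score divides by intersected length by
  default (a true weighted mean over elements); dividing by exon length —
  uncovered bases scoring 0 — is available via
  `denominator = "exon"` since both readings of "weighted by the length
  of the intersection" are defensible. An exon touching no element scores
  0, the conservative choice for a lower-bound filter.
* Junction strand is assigned from the dinucleotides, not alignment
  flags; junctions matching neither strand are dropped and counted.
* The read offset at a junction counts all query-consuming CIGAR
  operations (including soft clips) before the junction.
* Degenerate inputs error early and name the offender: a chromosome
  missing from the FASTA, an intron under 4 nt, fewer than 10 annotated
  cassette exons for threshold learning, an exon with no coverage source.
  Incompatible insertions are a *status*, not an exception, because they
  are an expected outcome (7% of exons in the motivating analysis).

## Limitations

The pipeline only detects simple cassette events whose skip junction is
already annotated; a cryptic exon inside a never-annotated intron
configuration is invisible. Threshold learning needs enough expressed
annotated cassette exons per sample. PSI pooling assumes samples within a
group are exchangeable. The 50-nt rule is a useful approximation to NMD
targeting, not a mechanistic model — long 3' UTRs and EJC-independent NMD
are not represented.

## Running the pieces

```r
library(nexon)

truth <- generate_locus_set(locus_config(), seed = 1)
cons <- generate_conservation(truth, seed = 1)
design <- cohort_design()
sim <- simulate_cohort(truth, design, seed = 1)

samples <- data.frame(
  sample = design$sample, tissue = design$tissue,
  condition = design$condition,
  sam = vapply(sim$samples, `[[`, character(1), "sam"),
  models = vapply(sim$samples, `[[`, character(1), "gtf"))

res <- run_pipeline(nexon_config(
  annotation = truth$paths$gtf, genome = truth$paths$genome,
  elements = cons$paths$elements, track = cons$paths$track,
  samples = samples))
res$catalog
res$verdicts
```
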