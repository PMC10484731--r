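---
title: "quadtag: methods and design notes"
author: "quadtag authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{quadtag: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadtag)
```

# Scope

`quadtag` implements the downstream computational analysis of an
antibody-directed tagmentation (CUT&Tag) experiment that maps i-motif (iM)
and G-quadruplex (G4) DNA secondary structures: normalized coverage
tracks and QC, signal-block peak calling with replicate consensus,
quadruplex motif prediction with a shuffle-based enrichment null, genomic
feature annotation and TSS metaprofiles, and integration of structure
calls with gene-expression categories.  Everything upstream of aligned
fragments (base calling, alignment) and everything wet-lab is out of
scope; inputs are fragment BED files, bedGraph tracks, a genome FASTA, a
gene table and a TPM table.

Because the real assays require deposited sequencing data, the package
ships a first-class synthetic-data generator whose outputs have the
statistical structure the analysis assumes.  Every stage is exercised and
tested end to end on these synthetic studies.

# The synthetic study

`simConfig()` bundles the generator's study conditions.  The defaults
describe the package's standard toy study:

* a 1 Mb two-chromosome genome with i.i.d. bases at 45% GC —
  GC in the human-genome neighbourhood, split evenly between G and C;
* ten 1 kb designated "peak" regions (about 1% of the genome);
* three replicates of 4000 fragments with normal lengths
  (mean 150 bp, sd 30, minimum 50), matching the ~150 bp fragment scale
  of tagmentation libraries.  Fragment midpoints follow a two-rate
  mixture: the rate inside peak regions is `enrichmentRatio = 10` times
  the background rate.  The depth is chosen so that enriched regions are
  covered contiguously (roughly 10x inside, 0.6x outside): the
  block-based peak caller assumes an enriched region forms one signal
  block, which is exactly what a practitioner tunes sequencing depth to
  achieve;
* a planting plan of canonical motif instances (below);
* optionally, PCR-style duplicates: with `duplicateRate = d`, fragments
  are resampled with replacement from a pool of `n(1-d)` templates, which
  gives the complexity-curve machinery something to measure.

No public enrichment ratio exists for this assay class, so the ratio is
an explicit free parameter, not an estimate of any particular
experiment; 10 is a deliberately strong but not degenerate choice that
leaves visible background.

All randomness flows from one root seed through named sub-streams
(`deriveSeed(seed, label)`), so a configuration reproduces every
artifact byte-identically; replicate-to-replicate variation is realized
purely through independent sub-seeded sampling (no batch effects — the
consensus logic only needs independence).

What the generator does **not** emulate: sequence-composition biases
(real genomes are not i.i.d.; CpG islands make real promoters both
GC-rich and quadruplex-rich), mappability artifacts, chromatin
accessibility confounding, fragment-length/position coupling, and
antibody efficiency differences.  Tests passing on synthetic data
therefore demonstrate the correctness of the computations, not the
biological robustness of the assay.

## Motif planting

Each pattern class is planted as its canonical instance — minimal
tracts, single-base loops (e.g. `CCACCACCACC` for the low-stringency
iM class) — so class membership is unambiguous; note a canonical
instance satisfies both the short- and long-loop variant of its class.
Each plant is written with a 13 bp neutral spacer (one base longer than
the longest loop) of the loop base on both sides.  The spacer guarantees
that no pattern match can bridge a plant and its background, so the
greedy scanner recovers every plant at exactly its recorded coordinates
— this makes the truth set an exact oracle, with recall 1 by
construction, which the tests assert.  Plants never overlap one another.

# Coverage tracks and QC

`coverageTrack()` computes mean per-base fragment coverage in fixed bins
(default 5 bp) and scales by genome length divided by summed fragment
length ("reads per genomic content", 1x normalization).  Defining the
scale factor from summed fragment lengths — rather than read count times
an assumed read length — makes the 1x contract exact: the genome-wide
mean per-base value is 1 to floating-point accuracy for any non-empty
fragment set, and the tests hold it to 1e-9.

`frip()` offers two estimators.  The *exact* fraction of fragments
overlapping at least one peak is the default in reports because it is
directly testable.  The *sampled* estimator mirrors common practice —
sample 10000 1 bp genome positions and ratio the fragment coverage at
in-peak positions over all sampled positions.  Position sampling weights
fragments by the bases they cover, so the two estimators agree exactly
only when fragment lengths are exchangeable between peak and background;
both are reported.  An empty peak set yields FRiP 0 by definition, not
an error.

`trackPearson()` re-bins both tracks to a caller-chosen common bin size
and correlates **all** genome bins, zeros included.  No masking is
applied: including empty bins is the simplest contract to state and
test, at the cost of inflating correlations on sparse tracks (both
tracks share their zeros).  Zero variance raises an error rather than
returning a silent `NA`.  No consensus bin size exists for this metric
in the field, so the bin size is a required argument.

`saturationCurve()` subsamples each replicate without replacement at
each requested fraction, rebuilds the track, re-calls peaks, counts
subsampled fragments in the re-called peaks, and averages over
replicates.  At fraction 1 the subsample *is* the full set, so the curve
equals the full analysis there exactly.

`complexityCurve()` treats the exact (chrom, start, end, strand) tuple
as duplicate identity — the only identity available without alignment
metadata.  The expected number of distinct fragments among `n` drawn
without replacement has the closed hypergeometric form
$\sum_u [1 - \binom{N-c_u}{n}/\binom{N}{n}]$ over unique fragments $u$
with copy counts $c_u$; an empirical subsampling route is also provided
and the tests require the two to agree within Monte-Carlo error.

# Peak calling and consensus

`callPeaks()` emulates the numeric-threshold stringent mode of
block-based CUT&Tag peak callers: maximal runs of strictly positive
signal are blocks; each block is scored by its total signal (area under
the curve); the top `ceiling(threshold * B)` blocks are kept (default
threshold 0.01), with ties at the cutoff all included so the result is
well-defined on degenerate inputs.  Control-track (IgG) calibration,
summit refinement and exact parity with any external caller are
non-goals.

`consensusPeaks()` returns the chained coordinate-wise intersection of
all replicates — the maximal regions present in every replicate.  The
intersection convention (rather than keeping first-replicate peaks that
overlap the others) was chosen because it is symmetric in the replicates
and therefore reproducible regardless of replicate order.

`sharedUnique()` counts, for each set separately, the intervals
overlapping (>= 1 bp) the other set.  The A-anchored and B-anchored
counts differ whenever intervals split or merge across sets, which is
why both are always reported; percentages round half-up.

`classifySignalQuartiles()` labels peaks bottom/middle/top by the
interpolated (type 7) quartiles of total signal, checking `top` first so
an all-equal distribution is all-top; the same quantile rule and
precedence order are used for expression categories, keeping the two
quartile semantics identical and exactly testable.

# Motif prediction and enrichment

The six pattern classes per base are three stringency levels — low
(four tracts of >= 2), medium (four tracts of >= 3), high (five tracts
of >= 3, the "spare-tyre" arrangement) — each with loops 0–7 (short) or
0–12 (long).  The pattern for base `b`, tract length `m`, `k` tracts and
loop limit `L` is the greedy regular expression
`(b{m,}[ACGT]{0,L}){k-1}b{m,}`; `N` matches nowhere.  Scanning is
leftmost, non-overlapping and greedy within one class; different classes
are scanned independently and may overlap.  A minus-strand structure is
found by scanning the plus strand for the complementary-base pattern and
reported in plus-strand coordinates with strand `-`; consequently
plus-strand iM matches coincide with minus-strand G4 matches of the same
class, which the tests assert.  The test suite also contains an
independent brute-force matcher (a longest-first backtracking search
written directly from the tract/loop definition) and requires exact
agreement with the production scanner across hundreds of random
sequences.

`foldEnrichment()` counts matches on the sequences extracted from the
region set (regions are joined with an `N` spacer longer than any loop,
so no match bridges regions), then repeats the count on `n = 10`
independent reshuffles of the regions and reports observed over mean
null.  Counting on extracted sequences mirrors scanning a per-peak FASTA
and makes the boundary question moot: a motif counts exactly when it
lies within a region.  Counts are of matches, not of motif-containing
regions (the phrase "counts within regions" reads most naturally as
match counts; region-level counting can be recovered by intersecting the
scan output with the regions).  When the null mean is zero with a
positive observed count the row is flagged `infinite` and the fold
carries the observed count — never a silent division error; a zero
observed count gives fold 0 with flag `zero_observed`.

`shuffleRegions()` relocates each region independently: a chromosome is
drawn proportional to length among those long enough to hold it, then a
uniform start.  Widths are preserved exactly; shuffled regions may
overlap each other; no gap/exclusion lists are honoured (synthetic
genomes have no gaps, and no exclusion set is canonical for this
analysis).  Same-chromosome placement would be a one-line restriction
but genome-wide placement is the default.

`gcEnrichment()` is a one-sided permutation test reusing the same
shuffle null: `p = (1 + #{null >= observed}) / (n + 1)`.  A permutation
test needs no distributional assumption, which is why no parametric test
was hard-wired.

## Calibration choices in the tests

The null-calibration suite checks that fold enrichment on uniformly
random regions stays within [0.8, 1.25] for classes with at least 50
genome-wide matches.  That harness runs on a deliberately GC-rich (70%)
0.8 Mb genome with regions covering half of it: GC-richness populates
even the rarest class with hundreds of matches and the large region
share keeps the observed count's coefficient of variation at a few
percent, so the band tests estimator bias rather than raw Poisson noise.
This is a property of the harness design, not a tuned constant.

# Annotation and profiles

`annotatePeaks()` anchors each peak at its midpoint — the single-anchor
rule is what guarantees exactly one category per peak — and assigns the
first matching category in the priority order Promoter > Exon > Intron >
Downstream > Distal intergenic.  The promoter window is strand-aware
around the TSS and is a **mandatory** argument: annotators in common use
default to anything from ±1 kb to ±3 kb and the choice materially
changes the result, so it is never defaulted silently.  The
structure-by-expression integration uses its own 3 kb TSS window, which
is deliberately independent of the annotation window.  UTR categories
are not modelled because the simple gene table carries no UTR structure;
UTR bases fold into Exon.  Distances to the nearest TSS are signed in
the gene's transcriptional orientation (negative = upstream), with exact
ties broken by gene id for determinism.

`normalizedFeatureDistribution()` divides each category's peak fraction
by its genomic base fraction (base-level membership resolved with the
same priority order) and rescales the ratios to sum to 100.  A category
with annotated peaks but zero genomic footprint is excluded from the
normalization with a warning rather than producing an infinity.

`tssMatrix()` averages the track in 25 bp bins across TSS ± 1 kb by
default, flips minus-strand rows so columns always run upstream to
downstream, and treats bins clipped at chromosome edges as missing (they
are excluded from the column-mean profile, not zero-filled).  The
z-score variant standardizes with the matrix-global mean and SD (per-row
scaling would erase between-gene differences, which is the thing these
heatmaps display); an all-constant matrix z-scores to zero by
convention.

# Expression integration

TPM 0 means "not expressed" ("at least one transcript" is interpreted
as TPM > 0).  Expressed genes split at the interpolated quartiles of
their TPM distribution into low (<= Q1), medium, high (>= Q3, checked
first).  Because the rule is rank-based it is invariant under monotone
rescaling of TPMs, which the tests exploit.

`structureByExpression()` labels each gene both / iM-only / G4-only /
none by the presence of a peak within 3 kb of its TSS, and emits the
joint table in **both** orientations (expression categories within each
structure label, and structure labels within each expression category),
since either conditional reading of such percentages is legitimate and
the caller should not have to re-derive the other.  Per-label TPM
summaries exclude two-sided 1.5 x IQR outliers — the exclusion applies
only to the summaries, never to category assignment.

# Pipeline, determinism, numerics

`runPipeline()` chains the stages on a synthetic study, validates its
configuration against a closed key schema (unknown keys are errors; the
promoter window is mandatory), writes all declared outputs, and records
a manifest with the configuration snapshot, every derived sub-seed, the
key parameters and MD5 digests of all outputs.  Re-running the same
configuration reproduces the output tree byte-identically, which the
test suite asserts.

Numerical conventions, stated once: coordinates are 1-based closed in
memory (`GRanges`) and 0-based half-open in every file; quantiles are
interpolated type 7 throughout; report percentages round half-up;
all-equal distributions classify as top/high by the stated precedence;
zero-valued runs are dropped when writing bedGraphs (the value function
is unchanged); empty peak sets give FRiP 0 and empty consensus, while
empty fragment sets and empty peak lists where a statistic is undefined
raise errors.

## Problem sizes

The shipped tests and the acceptance script run on genomes between 0.2
and 9 Mb, libraries of 500–4000 fragments per replicate, and 3–50
shuffle randomizations.  These sizes give every stochastic check a
comfortable statistical margin (binomial/Poisson coefficients of
variation of a few percent at the asserted tolerances) while the whole
suite completes in a few minutes on a laptop; all algorithms are linear
or near-linear in genome size, so nothing changes structurally at
chromosome scale.

# Known limitations

* Peak calling emulates numeric-threshold block selection only; IgG
  control calibration and exact parity with external callers are out of
  scope.
* The annotation category set omits UTRs (not representable in the
  simple gene table) and assumes one TSS per gene record.
* The shuffle null ignores gap/exclusion lists and GC-matched
  backgrounds; on real genomes, GC-matched nulls would be the natural
  next step (quadruplex motifs are GC-correlated by construction).
* The synthetic genome is i.i.d.; conclusions about real-genome
  performance require real data.
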