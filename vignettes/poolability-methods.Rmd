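---
title: "Methods: read loss, read separation and copy-number analysis for pooled samples"
author: "poolability authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: read loss, read separation and copy-number analysis for pooled samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolability)
```

## The problem

Sequencing costs are dominated by per-sample preparation (extraction, rRNA
depletion, library construction), not by the reads themselves. If samples of
*different* organisms are pooled before preparation and sequenced together,
those costs are shared — provided the reads can be assigned back to their
organisms afterwards. Whether that works depends on sequence: a read is
separable only if no other organism in the pool carries the same (or a
nearly identical) stretch of DNA, and it is quantifiable only if it is not
already ambiguous within its own genome.

`poolability` quantifies exactly this, for bacterial replicon sets, at three
levels:

1. **Organism-level read loss** (`readLoss()`): which fraction of all
   possible reads is lost to intra-genomic repeats (lost in ordinary
   single-sample sequencing too) and which *additional* fraction is lost to
   inter-organism homology when pooling.
2. **Gene-level read loss** (`perGeneLoss()`): the same partition resolved
   per gene, since a small genome-wide loss can still concentrate on a few
   genes.
3. **Error-driven misassignment** (`misassignmentRate()`): how often a
   sequencing error converts a read of one organism into a unique best match
   on another.

A fourth component, `fitReplichores()`, performs marker-frequency analysis
on DNA-seq coverage — the standard downstream check that pooled data
preserve replication-dynamics signal.

## Read model and uniqueness criterion

All possible reads of length $k$ (default **150 bp**) are enumerated by
sliding a window with a shift of one over the forward strand of each
replicon. Circular replicons (the bacterial default) contribute exactly $L$
reads each, windows crossing the junction wrapping around; linear ones
contribute $L - k + 1$.

Separation uses the **unique best match** criterion: a read is kept only if
no second locus aligns it with the same or a smaller number of mismatches
(the *best stratum*), with a mismatch allowance of **1** by default.
`resolveBestStratum()` implements this directly; an optional `"any-valid"`
mode discards a read as soon as *any* second locus lies within the
allowance, as a sensitivity check on aligner suppression behaviour.

Two consequences shape the implementation:

* For **error-free** enumerated reads, a read's best stratum contains its
  own locus at 0 mismatches, so ambiguity reduces to *exact* duplication.
  Classification therefore only needs canonical k-mer multiplicities: each
  window is mapped to the lexicographic minimum of itself and its reverse
  complement (`canonicalKmers()`), and a locus is ambiguous iff its
  canonical form occurs at $\ge 2$ loci. Loci are strand-collapsed: a
  palindromic window at one position is one locus, matching how an aligner
  reports one alignment per position.
* For **mutated** reads, the Hamming-distance-1 neighbourhood must be
  searched. `minMismatchHits()` uses exact half-seed lookup — any alignment
  with $\le 1$ mismatch matches at least one read half exactly — with
  mismatch-count verification of the candidates, so the minimum over
  returned loci is exact within the allowance.

Reads containing non-ACGT characters are excluded from classification but
kept in `total_reads` and reported in their own column: real RefSeq genomes
contain rare ambiguity codes, and explicit accounting beats silent drops.

The loss partition per organism is

$$\text{intra\_loss} = \frac{\#\{\text{reads ambiguous within own
genome}\}}{\#\text{reads}},\qquad
\text{inter\_loss} = \frac{\#\{\text{reads unique within own genome but
duplicated in the pool}\}}{\#\text{reads}},$$

with intra taking precedence, so `inter_loss` is exactly the *additional*
loss caused by pooling: uniquely mappable reads in single mapping minus
uniquely mappable reads in pooled mapping.

### Gene attribution

A read counts toward every gene it overlaps by $\ge 1$ bp (a read near a
boundary counts toward both neighbours), the same convention coverage-based
quantifiers use for boundary reads. Percent denominators are per-gene
overlapping-read totals, not gene lengths. GFF3 input is 1-based inclusive;
features default to type `gene` with a `CDS` fallback, and gene identity is
taken from `locus_tag` > `ID` > `Name`, which is stable across bacterial
annotations.

## Error-driven misassignment

A sequencing error can relocate a read only if it turns the read into a
sequence lying within the mismatch allowance of a *foreign* locus while
beating the read's own locus — with one error and allowance 1 this requires
a foreign homolog differing in exactly the errored position with exactly the
right base flip. `misassignmentRate()` samples reads uniformly from the
source organism's loci, injects substitution errors (fixed count per read or
i.i.d. per base; no indels, consistent with the mismatch-only mapping
model), and resolves each read against the pool. Under best-stratum
semantics an error-free read can never be misassigned — its own perfect
locus cannot be beaten — and the implementation preserves this exactly, which
the tests assert. The module reproduces the *mechanism* of error-driven
misassignment; it makes no attempt to reproduce any particular real-data
rate, which depends on platform error profiles outside this model.

## Marker-frequency analysis

Replicating bacteria hold more copies of origin-proximal than
terminus-proximal loci, so DNA-seq coverage decays approximately
exponentially from *oriC* to *ter* along each replichore. `fitReplichores()`

1. averages depth in consecutive **5000 bp** windows (a trailing partial
   window is kept iff $\ge$ half a window; zero-coverage windows are
   excluded from regression),
2. unrolls the circle at the terminus (default: diametrically opposite the
   annotated origin) so the origin is interior,
3. fits ordinary least squares to $\log_2(\text{window mean})$ versus
   position separately per replichore, and
4. evaluates the two lines at their intersections near the origin and near
   the terminus (the left line re-entering across the cut for the terminus
   intersection), back-transforms to linear scale, and reports
   `ratio = oriValue / terValue`, normalised so the terminus has copy
   number 1.

The intersection is read as the regression-line *value* at the crossing
point; evaluating the crossing's coordinate alone has no copy-number
meaning, so the value reading is the only self-consistent interpretation.
If the two lines are parallel — flat coverage being the practical case —
there is no crossing; each line is then evaluated at the origin/terminus
positions and the two values averaged in log space, with a warning. This
makes a perfectly flat track return a ratio of exactly 1. No outlier or
origin-proximal window exclusion is applied by default; all usable windows
enter the regressions.

The estimator is invariant to positive rescaling of the track (intercepts
shift equally, the ratio cancels) and, up to window re-binning (~1%), to
circular rotation. On simulated gradients with Poisson noise at 100× depth,
ratios of 1–8 are recovered with median relative error well under 5% (the
acceptance suite runs 20 seeds per ratio at 100 kb / 5 kb windows).

## Comparison statistics

For replicate- and pooled-vs-single comparisons the package reports a
symmetric percent difference of 5 kb window means,
$100\,(a-b)/\frac{a+b}{2}$, and the squared Pearson correlation of the
window means, after total-count scaling of the two tracks; gene-expression
comparisons use log2 ratios of total-count-scaled gene counts with a
minimum-count filter (default 10, applied after scaling) against ratio
blow-ups at near-zero counts. These formula choices are stated openly —
deviation and $R^2$ can be defined in several reasonable ways, so printed
$R^2$ values from other tools are not directly comparable — and both are
deliberately simple: no TMM or median-of-ratios normalisation is applied,
as nothing in the intended use (checking that pooling preserves signal)
requires variance-stabilised estimates.

## The synthetic-data generator

`simulateGenome()`, `simulateHomologPair()`, `simulateCoverage()` and
`writeFixtureSet()` produce the exact structures the analysis assumes:

* i.i.d. background sequence at a requested GC content, with **planted exact
  repeats** (intra-organism loss), **shared segments** between organism
  pairs at a controlled identity (inter-organism loss), and evenly spaced
  ~1 kb gene features;
* homolog pairs derived by i.i.d. substitutions (no indels — consistent with
  the mismatch-only mapping model);
* coverage tracks that are exactly log-linear per replichore,
  $\mathbb{E}[\text{depth}] = \text{meanDepth}\cdot
  \text{ratio}^{\,1-d/D}$ at circular distance $d$ from the origin, with
  optional Poisson noise.

Every generator is a pure function of its seed and recipe, and truth records
list every planted interval, so expected loss counts are computable by brute
force on small genomes. A post-generation collision check asserts that no
accidental exact duplicate windows exist outside the planted intervals; at
$k \ge 20$ on i.i.d. backgrounds chance duplicates are vanishingly rare, so
any hit indicates an infeasible recipe. One behaviour worth knowing: the
base *adjacent* to a planted repeat matches the other copy's context with
probability 1/4, extending the effective repeat by a window or two. Tests
that need exact expected counts therefore pin the flanking bases; tests that
do not simply compare against the brute-force oracle.

What the generator does **not** emulate: real genomes' repeat families
(rRNA operons, IS elements) with their internal divergence, k-mer
composition bias, indel variation between strains, and library artefacts
(GC bias, coverage dips). Passing tests on these fixtures therefore
demonstrate correctness of the bookkeeping and estimators under the model's
assumptions, not the magnitude of loss on any particular pair of real
genomes — for real organisms, run the tool on their actual FASTA/GFF files.

## Numerical and design choices

* **Coordinates.** GFF3 is 1-based inclusive on disk; internally the package
  uses the Bioconductor convention (1-based closed intervals, `GRanges`),
  eliminating conversion layers around every `IRanges` operation.
* **Window enumeration from the forward strand only**, with strand handling
  via canonicalization; reverse-complementing a whole organism provably
  changes no counts (tested).
* **Index scale.** Canonical windows are held as R character vectors —
  simple and exactly verifiable. At 150 bp windows this costs roughly
  200 bytes per genomic position, comfortable for the multi-hundred-kb
  synthetic studies in the test and acceptance suites and for single
  bacterial genome pairs; pooling many full-size genomes at once is
  memory-bound before it is CPU-bound.
* **Problem sizes** used by the shipped analyses: the acceptance script
  builds a three-organism pool of 150 kb total at 150 bp reads, a 2×50 kb
  strain-control pair, 20-seed copy-number recovery at 100 kb per track, and
  8000-read misassignment simulations — sizes chosen so the whole study runs
  in minutes while keeping every per-window statistic well-populated.
* **Ties and degenerate inputs.** Two loci at the same minimum mismatch
  count ⇒ ambiguous (never broken by position); all-zero coverage ⇒ hard
  error; fewer than 3 usable windows per replichore ⇒ hard error; duplicate
  replicon ids across organisms are rewritten `organism|id`; duplicate gene
  ids get numeric suffixes.
* **Seeds.** Every stochastic function takes an explicit seed and restores
  the caller's RNG state; results are bit-for-bit reproducible.

## Known limitations

* Substitution-only error and divergence model: indels are out of scope, as
  is quality-aware error simulation.
* The mismatch allowance is capped at 1 (the half-seed search guarantee);
  the enumeration-based loss analysis itself is allowance-free since
  error-free ambiguity is exact duplication.
* No paired-end fragment model; reads are single windows.
* Gene-level percentages use overlapping-window denominators; tools that
  attribute reads by start position or full containment will differ
  slightly near gene boundaries.
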