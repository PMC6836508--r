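---
title: "Post-processing and filtering short-read CNV calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Post-processing and filtering short-read CNV calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvpost)
```

## The problem

Short-read structural-variant callers (Delly, GRIDSS, LUMPY, Manta)
disagree in how they represent copy-number variants and in which variants
they find. Worse, several of them systematically misreport **dispersed
duplications** — duplications whose copy lands at a locus away from the
template, the signature of copy-and-paste transposition that is rampant in
plant genomes — as an overlapping pair of a large deletion and a tandem
duplication. `cnvpost` implements the post-processing and filtering half of
an ensemble CNV workflow: it converts each caller's VCF into a common
adjacency representation, reclassifies adjacencies into four CNV types
(DEL, INS, TDUP, DDUP, all at least 50 bp), merges concordant calls across
callers, and filters the merged set with a random-forest classifier. A
spike-in simulator and evaluator make the whole pipeline testable without
any sequencing data.

## The adjacency model

Every CNV is represented by **novel adjacencies**: pairs of bases adjacent
in the sample genome but not in the reference. The two ends of an
adjacency are **breakends**; the two breakends of one adjacency are mates
and are always stored together.

Internally a breakend is a junction coordinate in 0-based half-open space
with an orientation: `R` (right-anchored; retained reference sequence ends
just before the junction) or `L` (left-anchored; retained sequence starts
at the junction). Conversion from the 1-based VCF convention happens
exactly once, at I/O, and the package documents fixed bijections to VCF
bracket notation (`t[p[`, `t]p]`, `]p]t`, `[p[t`) and to BEDPE strands
(`R` = `+`, `L` = `-`). Under this convention:

* deletion of `[s, e)` — one adjacency `(s R, e L)`;
* tandem duplication of `[s, e)` — one adjacency `(s L, e R)`;
* insertion at `p` — one point adjacency `(p R, p L)` carrying the
  inserted sequence, or an explicit *unknown* sentinel when the sequence
  is unresolved (`unknown_seq()`; never 0 or −1, so unknown sizes cannot
  leak into arithmetic);
* dispersed duplication of template `[s, e)` landing at `p` — **two**
  adjacencies. For a downstream intrachromosomal copy these are the
  TDUP-like junction `(s L, p R)` and the DEL-like junction `(e R, p L)`.

The last line is the crux: a caller that interprets those two junctions in
isolation emits a tandem duplication spanning `[s, p)` *and* a deletion
spanning `[e, p)` — two large, mutually overlapping false positives — and
misses the dispersed duplication entirely.

## Reclassification

`reclassify()` proceeds per source tool:

1. **Cluster** (`cluster_adjacencies()`): same-tool adjacencies whose
   breakpoints co-locate within 10 bp on either end join one
   single-linkage cluster. The sweep over sorted breakend positions is
   provably identical to the naive pairwise union-find and is tested
   against that oracle.
2. **Classify** (`classify_cluster()`): each cluster is searched for
   dispersed-duplication signatures first — the downstream pattern above,
   its upstream mirror (`(p R, s L)` + `(p L, e R)`), and the
   interchromosomal variant in which the two adjacencies' breakends on the
   acceptor chromosome co-locate within the window while the donor-side
   breakends delimit the template. Each adjacency participates in at most
   one DDUP; in multi-member clusters candidate pairs are taken greedily
   by smallest shared-breakpoint distance with leftmost tie-breaking,
   which is deterministic and reduces to the pairwise logic on two-member
   clusters. Remaining members fall through to `classify_singleton()`.
3. **Exclude with a reason**: inversion-like (same-orientation) pairs,
   interchromosomal singletons and events below the 50 bp floor are kept
   in a side-channel with reason codes (`inversion_like`,
   `interchromosomal_singleton`, `below_min_size`) rather than silently
   dropped. Every input adjacency ends up backing exactly one call or one
   exclusion record — a tested invariant.

Three design points were genuinely open and are decided here:

* **DDUP support counts** are the per-signal minimum over the two member
  adjacencies: both junctions must be supported for the event to be real.
  (Medians are defined for cross-caller merging, not for intra-call
  aggregation.)
* **Interchromosomal orientation matching** requires opposite orientations
  within each chromosome side but not a particular cross-pairing. The
  strict cross-pairing that a direct (non-inverted) insertion implies is
  what the simulator emits and what the closure property tests; the
  relaxed check additionally tolerates callers that encode the mate
  orientations inconsistently, at no observed cost on synthetic data.
* **Inverted-copy signatures** (the copy inserted in reverse complement
  yields same-orientation adjacency pairs) are recognized only behind
  `allow_inverted_ddup = TRUE`, default off: the signature enumeration for
  inverted events is less settled, and by default such pairs are excluded
  as inversion-like rather than guessed at.

If only one of a dispersed duplication's two adjacencies survives calling,
the cluster contains a lone DEL-like or TDUP-like member and is classified
as exactly that false-positive deletion or tandem duplication — the
documented fallback, reproduced by the singleton-fallback test.

## Merging

Calls from different tools describing the same event are collapsed by
`merge_calls()` when **all** of the following hold: same type; breakpoints
within 1000 bp on both the 5′ and 3′ end; at least 50 % reciprocal overlap
(not applied to insertions); insertion sites within 10 bp (applied to
insertions and dispersed duplications; for a DDUP the first two tests
apply to the template region, the third to the landing site — the only
reading under which all conditions are applicable). Components are the
single-linkage closure of the pairwise relation: the union-region
semantics ("calls covering 12–30 and 14–32 merge into one covering
12–32") extends naturally to chains, and the implementation is tested
against a brute-force transitive closure. Merged calls take the union
(minimal covering) region, the median of donor PE and SR supports (even
counts: mean of the central pair, stored unrounded), and the union of the
donor tool sets. Within-tool survivors of reclassification are also
eligible — the donor provenance map keeps counting honest.

## Random-forest filtering

`extract_features()` turns each merged call into 14 numbers: type one-hot,
`log10` size with an explicit `size_known` flag (unknown-size insertions
contribute 0/0, not a fake magnitude), caller-concordance count and
per-tool flags, and the merged median PE/SR/total supports. The classifier
is a bagged ensemble of CART trees (Gini impurity, `mtry` feature
subsampling), implemented in C++ inside this package because the
deployment environment provides no tree-ensemble library; its score is the
mean over trees of the leaf positive-class fraction, a posterior estimate
in [0, 1] of the call being a true positive.

`train_rf()` grid-searches `n_trees` × `max_depth` × `mtry` with
stratified 10-fold cross-validation on mean validation accuracy, breaking
ties towards the smaller, shallower model, then refits on the full
training set. Stratification is used because dispersed duplications are
rare and plain folds would starve classes; plain (unweighted) accuracy is
the criterion and is recorded as such in the CV report. Evaluation splits
by **hold-out chromosome** (`split_by_chromosome()`), not at random, so
locus-level structure cannot leak. The cutoff applied by
`filter_by_score()` defaults to 0.5 — the Bayes threshold under equal
costs for a calibrated posterior — and remains user-set; recall is
monotone non-increasing in the cutoff by construction.

One seed fixes fold assignment and all tree randomness: identical data and
seed give byte-identical CV reports and predictions, and a model persisted
to JSON (17 significant digits, enough to reconstruct IEEE doubles
exactly) reloads to identical scores.

## Auxiliary filters

Two optional subset filters, **disabled by default** — they are meant for
samples distantly related to the reference or for gap-ridden assemblies:

* `depth_filter()` keeps deletions whose region median depth, normalized
  by the chromosome median, is at most 0.75, and duplications at least
  1.25; any call whose raw median depth exceeds 1000× is removed as a
  collapsed-repeat artifact. Insertions are not ratio-tested.
* `gap_filter()` removes calls whose 400 bp flanking windows (clipped at
  chromosome ends; flanks only, not the call interior) contain more than
  50 % N bases.

The ratio and fraction thresholds are this package's own defaults — the
source evidence is a pair of density plots without printed cutoffs — so
they sit between the expected modes for heterozygous and homozygous events
and are prominently exposed in `aux_filter_config()`. Removal uses strict
inequalities so boundary values survive, and both filters are idempotent
and never modify calls. Depth is consumed through a provider contract
(`depth_track()`); computing depth from alignments is left to standard
external tooling.

## The simulator's stated world

`simulate_truth()` places non-overlapping events uniformly at random on a
synthetic genome, sizes log-uniform over [50 bp, 100 kb] (the floor is the
CNV definition; the ceiling and shape are package defaults, exposed as
configuration). Allele dosage defaults to the ploidy — homozygous
spike-ins, matching simulations that rearrange a reference genome and
sequence it — with lower dosages available to reproduce the
dosage-sensitivity experiment: caller profiles with `dosage_scaling` scale
detection probabilities and support means by `dosage / ploidy`, so
dispersed-duplication recovery (which needs *both* adjacencies) falls
roughly quadratically at low dosage, and recovered-DDUP recall is
monotone non-decreasing in dosage — a tested property.

`emulate_caller()` models callers at the *signal* level: per-adjacency
Bernoulli detection, integer Gaussian breakpoint jitter, Poisson support
counts, uniform false positives per Mb, and — the key behaviour —
`split_ddup = TRUE` profiles emit the two adjacencies of a dispersed
duplication independently and unlinked. Read simulation, alignment and
the callers themselves are deliberately out of scope, so a green test
establishes that the post-processing logic is correct *given* adjacency
level signals; it says nothing about alignment artifacts, coverage
waviness, or caller-specific biases that real data would add. The
evaluator (`evaluate_calls()`) uses greedy one-to-one best-overlap-first
matching (50 % reciprocal overlap; insertion points within 100 bp for
insertions and dispersed duplications) with deterministic leftmost
tie-breaking.

## Numerical and degenerate-input choices

* Coordinates are numeric doubles (exact for genome-scale integers);
  positions are validated non-negative and regions non-empty.
* Canonical adjacency order is chromosome-major then position; ties at
  identical positions put the right-anchored breakend first, making
  canonicalization idempotent and order-insensitive.
* Empty inputs flow through: empty VCFs give empty adjacency tables,
  empty call sets give header-only BEDPE files that read back empty, and
  a pipeline run with nothing classifiable warns and succeeds.
* Unmatched VCF breakend mates are skipped with a warning and counted;
  missing support fields default to 0 with a warning; truncated BEDPE
  lines fail with the line number.
* The placement sampler rejects overlapping events and fails with a
  clear "lower the density" error after bounded retries.

## Known limitations

* The four caller dialect field maps are editable defaults documented
  against specific caller versions; other versions may need remapping.
* Multi-sample VCFs and caller-auxiliary evidence files are not parsed.
* Inversions, balanced translocations and nested complex events are
  recognized only to be excluded.
* The classifier is only as good as its labels; the package ships no
  pretrained model, and labels derived from synthetic data (as in the
  acceptance pipeline) are easier to separate than long-read-validated
  labels from real samples.
* Genotyping (copy-number estimation) and breakpoint refinement are
  non-goals.
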