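---
title: "mavekit: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mavekit: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mavekit)
```

This vignette documents the models, algorithmic choices and numerical
conventions behind `mavekit`, a workflow for multiplexed assays of
variant effect (MAVE) and deep mutational scanning. It is written for
users who need to know precisely what the package computes, and for
maintainers who need to know why it computes it that way.

## The read-layout grammar

Amplicon designs in MAVE experiments differ widely, but nearly all can
be described by five element types along the read: the **variable**
region carrying the variant (V), fixed-sequence **constant** regions (C)
whose only purposes are quality control and error-rate estimation,
**skipped** bases (S), a **primer** (P) located by exact search rather
than a fixed coordinate, and a unique molecular identifier (**U**). A
layout is an element string plus an integer length vector, with `-1` as
a "remainder" sentinel for the one element whose length is inferred from
the read length. A primer splits the read into two parts that are
resolved independently, so a sentinel is allowed on each side.

Conventions frozen here:

* **Leftmost primer match.** If the primer occurs more than once, the
  first exact occurrence anchors the read. This is a deterministic
  choice; the alternative (best downstream fit) would make anchoring
  depend on later filters.
* **Coordinates.** 0-based half-open arithmetic internally (including
  the value returned by `locate_primer()`); all user-facing mutation
  positions are 1-based, in base or codon units.
* **Region concatenation.** Multiple regions of one element type are
  concatenated in read order into a single logical component, so
  downstream matching always sees one variable (and one constant) string
  per read.
* **Qualities** are Phred+33 throughout, valid range 0–93.

## The digestion cascade

Reads pass the following filters in a fixed order; the first failing
step claims the read in the accounting table (`filterTally`), so the
counters plus the retained reads always sum exactly to the input reads.

1. adapter detection (`fAdapter`) — exact substring containment of the
   configured adapter in the forward or reverse read. Exact matching is
   deliberate: no mismatch model for adapters is defined here, and
   detection-and-drop (not trimming) is the contract.
2. layout segmentation (`fNoPrimer`, `fReadLengthMismatch`),
3. optional reverse-complementing of variable/constant components,
4. pair merging (`fMergeFailed`) — overlap widths are scanned from the
   longest allowed to the shortest; the first width whose mismatch
   fraction is within `max_mismatch_fraction` and whose merged length is
   admissible wins. Within the overlap, a discordant base is resolved
   towards the higher quality (tie: forward base); the kept quality is
   the maximum of the two. Longest-first scanning maximizes the use of
   sequence evidence and is deterministic.
5. average variable-region quality (`fAvgQualTooLow`) — the arithmetic
   mean of Phred scores, the simplest reading of "average base quality"
   (not the error-probability mean). When merging is enabled the filter
   applies to the merged sequence, since that is the sequence that will
   be matched.
6. N content in the variable region and UMI (`fTooManyNinVar`,
   `fTooManyNinUmi`),
7. wild-type matching (`fNoValidWildtype`, `fTooManyMutations`,
   `fMutQualTooLow`, `fForbiddenCodon`) — see below,
8. constant-region check (`fConstantMismatch`) — nearest reference by
   Hamming distance; ties and distances above the threshold fail.
   Match/mismatch tallies per base quality accumulate for every read
   that reaches this step, pass or fail, and only for those reads: the
   error-rate estimate deliberately mirrors the cascade, since reads
   dropped earlier were never inspected at this stage.

Digestion output is independent of read order: all per-read decisions
are made independently, and the count table is aggregated and sorted by
variant name.

### Wild-type matching and variant naming

The variable region is compared to every wild-type sequence of equal
length by Hamming distance (unequal lengths are non-candidates; amplicon
designs handled here are fixed-length, which is why a
Levenshtein/alignment mode is out of scope). The unique nearest
wild-type wins; if two or more tie at the minimum, the read is dropped
as ambiguous rather than assigned arbitrarily.

The mutation budget depends on the analysis unit. With `unit = "base"`,
a nearest distance above `max_mutations` means no valid wild-type
(`fNoValidWildtype`). With `unit = "codon"` the nearest wild-type is
accepted at any base distance and the number of distinct mutated codons
is then checked against the budget (`fTooManyMutations`). After the
budget: every mutated base must reach `min_mutation_quality`
(`fMutQualTooLow`), and no observed mutated codon may match a forbidden
IUPAC pattern such as `NNW` (`fForbiddenCodon`). The forbidden-codon
test applies to the *observed* codon — the designed mutagenesis alphabet
constrains what the library can contain, so an observed codon outside it
is evidence of a sequencing artifact.

Variant names are `WT.pos.ALT` per mutated base, or `WT.codon.ALTCODON`
per mutated codon, joined with `_` in position order; a read identical
to a wild-type gets the bare wild-type name. The `_` separator and the
bare-name convention are package conventions (only the single-mutation
form is fixed by precedent). In paired, unmerged designs with separate
forward and reverse wild-type sets, each mate is matched against its own
set and the two names are joined with `_` as well.

### Collapsing and UMI deduplication

In reference-free mode (no wild-types), distinct variable sequences that
plausibly arise from sequencing or PCR errors can be collapsed: sweeping
sequences in decreasing count order (ties broken lexicographically for
determinism), each sequence is absorbed into the earliest seed within
`max_distance` whose count is at least `min_abundance` and at least
`min_ratio` times its own. Absorption is single-pass and non-transitive
— an absorbed sequence never absorbs others — which is the literal
reading of greedy most-abundant-first collapsing. Thresholds are tested
against the original (pre-sweep) counts, so the outcome does not depend
on the order in which counts were accumulated during the sweep. Total
read counts are conserved and all constituents are recorded.

UMI deduplication within one variant is the same sweep without
thresholds; the UMI count is the number of surviving seeds, which is
non-increasing in the radius.

## The joint experiment

Per-sample results merge into a `SummarizedExperiment`: the variant
universe is the union over samples, with zeros where a variant was not
observed; read counts and UMI counts are separate assays. Rows are keyed
internally by (wild-type, variant name) so equally named variants
matched to different wild-types can never collide silently. Mutation
annotations use the standard genetic code only (codon table 1): a
mutated codon translating identically is *silent*, to a different
residue *nonsynonymous*, to a termination signal *stop*. Codons
containing ambiguous bases (N) count as mutated but contribute no
amino-acid call. Amino-acid-level collapsing sums rows with identical
translations under the same wild-type and conserves every column sum by
construction.

Sample concordance is summarized as Pearson correlation of
`log10(count + 1)`; a zero-variance sample yields `NA` rather than an
arbitrary value.

## Statistical inference

The per-variant testing problem — thousands of count features, a
handful of samples — is precisely the digital gene-expression setting,
so model fitting is delegated to the established frameworks rather than
re-derived: negative-binomial generalized linear models with
quasi-likelihood F-tests (edgeR), or precision-weighted linear models on
log-CPM with moderated t-statistics (limma-voom). Dispersion estimation
and empirical-Bayes shrinkage use those frameworks' own defaults
(trended dispersion, empirically estimated prior degrees of freedom); we
considered freezing a fixed prior df for the quasi-dispersion shrinkage
but decided the frameworks' data-driven estimate is better justified and
better tested. Both paths accept any full-column-rank fixed-effect
design and either a coefficient name or a numeric contrast.

Two normalization modes define the two score types:

* **Absolute** enrichment: TMM normalization factors (log-ratio trim
  0.30, abundance trim 0.05, precision-weighted, factors normalized to
  geometric mean 1) converted to effective library sizes. TMM assumes
  most variants do not change; with strong global selection, prefer the
  relative mode.
* **Relative** (wild-type-referenced) enrichment: per-sample offsets
  `log(aggregate of wild-type counts)`, with sum or geometric-mean
  aggregation across multiple wild-type rows. Under these offsets, the
  wild-type row's fitted logFC is exactly 0 in the NB path (the fit is
  exact, and coefficient shrinkage preserves exact proportionality); in
  the voom path the 0.5 pseudocount leaves a residual of order 1e-5 at
  typical depths.

For growth-based protein-interaction assays, per-replicate PPI scores
are computed as
`log2((out_v + p)/(in_v + p)) - log2((out_wt + p)/(in_wt + p))`, so the
wild-type scores identically zero; an optional multiplicative constant
accommodates rescaling to generations of growth (the exact historical
scaling lives in the assay-specific literature, so it is exposed as a
plain constant rather than hard-coded). Multiple-testing correction is
Benjamini–Hochberg throughout (the conventional FDR procedure for this
setting).

Before testing, variants are typically filtered to a minimum count in
all input samples (`filter_by_input_count()`, default threshold 50):
variants too rare in the input carry almost no information about
selection and only dilute the FDR control.

## The synthetic-data engine

`simulate_library()` emulates an amplicon library with known
composition: variants drawn by frequency from a table of codon-level
edits to the wild-types, reads assembled per layout (random skipped
bases, per-variant UMI pools, fixed constant content, primer anchors),
uniform per-base substitution errors, N injection, and adapter
contamination that overwrites the interior of the forward read. The
ground-truth table records the exact counts a noise-free digestion must
recover — the master end-to-end invariant of the test suite. All
randomness derives from a single seed, and quality strings are constant
per configured tier, which makes error-rate estimates analytically
checkable (a Q20 tier with 1% injected errors must estimate 0.01 within
binomial sampling error).

What the generator does *not* emulate: realistic instrument error
profiles (cycle- or homopolymer-dependent errors, indels), PCR jackpot
effects beyond what UMI pools capture, variable read lengths, or
quality-score miscalibration. Passing tests therefore demonstrate
correctness of the bookkeeping, matching, and inference machinery under
the stated error model — not robustness to every real-world artifact.
Layouts used for simulation must have fixed element lengths (the
generator has to place every element at a known coordinate); sentinel
layouts remain fully supported on the digestion side.

`simulate_counts()` draws negative-binomial counts
(`variance = mu + dispersion * mu^2`; `dispersion = 0` degenerates to
Poisson) with lognormal per-variant baselines around a target depth and
a log2 fold change applied to the second condition level.

## Problem sizes and numerical conventions

The test suite exercises a 50,000-read paired library end-to-end
(retained and recovered exactly), 20 randomized noisy configurations for
read-accounting conservation, 1,000 random matching instances against an
exhaustive Hamming-scan oracle, 200 random collapsing instances against
a brute-force greedy oracle, and null/spiked count simulations of 1,000
variants across 6–12 samples for calibration (empirical type-I error at
nominal 0.05, pooled Kolmogorov–Smirnov uniformity) and recovery (mean
estimated logFC for variants simulated at logFC 2, with the spiked
variants embedded among nulls so that TMM normalization is anchored by
the unchanged majority — a design in which *every* variant changes
would, by construction, be re-centered by any global normalization).
These sizes give stable verdicts in seconds on a single CPU while being
large enough for the binomial/KS bands used.

Numerical notes worth knowing:

* TMM factor invariance under a pure depth change of one sample is exact
  for the M-statistics but only approximate (relative error below ~2%)
  for the final factors, because the precision weights and the abundance
  trim see the changed depth.
* The greedy collapse tie-break (lexicographic at equal counts) and the
  sorted variant table make every digestion output bit-reproducible and
  independent of input order.
* Merging scans overlaps longest-first; with highly repetitive variable
  sequences (period-3 repeats, for instance) a longer spurious overlap
  can satisfy a zero-mismatch criterion, so constrain
  `min_merged_length`/`max_merged_length` to the construct length in
  such designs.
* Degenerate inputs fail loudly: all-zero samples in normalization,
  zero wild-type aggregates in offsets, rank-deficient designs,
  non-estimable contrasts, unequal paired FASTQ record counts, and
  untranslatable rows in amino-acid collapsing are all hard errors, not
  silent repairs.

## Known limitations

* Hamming matching only; variants with indels relative to the wild-type
  are filtered, not called.
* Adapter handling is detection-and-drop; no trimming.
* No mixed/random-effect models; designs are fixed-effect only.
* The genetic code is the standard table; non-standard codes are not
  supported.
* Thread-level parallelism is not implemented; the contract that results
  are independent of read-processing order is what matters for
  correctness and is tested directly.
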