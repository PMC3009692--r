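---
title: "Methods: triple colligation of small-RNA evidence"
author: "colligator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: triple colligation of small-RNA evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colligator)
```

## The problem

Deep sequencing of small-RNA libraries routinely turns up abundant short
sequences that are fragments of well-known noncoding RNAs (snRNAs,
snoRNAs, tRNAs, vault RNAs).  Whether such a fragment is degradation
debris or a candidate regulator is not decidable from abundance alone.
This package operationalises a three-way test, a *triple colligation*:

1. the fragment is an abundant, exactly repeated **core sequence** in the
   reads;
2. the core lies in a **stable stem-loop hairpin** of its source ncRNA,
   the geometry from which miRNA-like processing is plausible; and
3. the core contains long, exact **reverse complements of 3'UTR
   segments** of a gene whose protein is complexed with that same ncRNA,
   so that regulation would close a feedback loop on the ncRNA's own
   machinery.

The motivating instance is the 16-nt core `UUCGCGCUUUCCCCUG` carried by
the 3'-terminal hairpin of the 164-nt spliceosomal snRNA RNU1, with
candidate sites in the 3'UTR of the splicing factor gene SFRS1; the
package's defaults and examples are built around this geometry, but every
stage is generic.

## Read cleanup and core discovery

Reads (35 nt by default) are processed in a fixed order:

* **Adapter removal.** The leftmost position where at least
  `min_adapter_prefix = 6` bases of the 3' adapter
  `TCTCGTATGCCGTCTTCTGCTTGAAA` match exactly, and where the match runs to
  the read's 3' end or covers the whole adapter, anchors the insert's 3'
  boundary.  Requiring the match to be 3'-anchored (or complete) prevents
  chance internal 6-mers from truncating inserts.  Reads with no such hit
  are discarded by default: without the adapter the insert boundary is
  unknown.  This is configurable (`keep_unanchored`) because the
  alternative convention is defensible for libraries with long inserts.
* **Poly-A trimming.** At most `max_polyA = 4` trailing A's are removed
  after adapter removal.  The cap reflects the library protocol's
  templated tailing of zero to four A's; an uncapped trim would eat
  genuine A-rich insert ends.
* **Length filter.** Inserts of 16–29 nt are retained — below 16 nt exact
  matching loses specificity, above 29 nt the insert cannot be complete
  in a 35-nt read with a 6-nt adapter anchor.

Retained inserts are collapsed to exact-copy counts and filtered at
`min_copies = 3`: a sequence seen fewer than three times in a library of
millions is indistinguishable from error.  Counts are conserved at every
step (`reads_in = retained + discarded_no_adapter + discarded_length`),
and the suite asserts this identity on simulated libraries.

**Core clustering.** Abundant inserts that share a long exact subsequence
(ragged-ended fragments of one underlying RNA) are merged.  Multiple
sequence alignment would do this, but alignment heuristics are not
reproducible across tools and versions, so the package uses a
deterministic greedy procedure on exact substrings: repeatedly find the
longest common substring (at least `min_core_len = 16` nt) over all
remaining pairs, absorb every sequence containing it, and report the
longest substring common to all absorbed members as the cluster's core.
Ties are broken by total instance count, then lexicographically.  The
procedure is order-insensitive and is checked against an exhaustive
substring-enumeration oracle on small instances.

## The permutation null

A biological core should be present because of its specific sequence, so
shuffles of its bases should be absent.  `p_none(K, M, L, k)` gives the
probability, under a uniform-random base model, that none of `K` random
k-mers occurs at any of the `L - k + 1` positions of any of `M` random
L-mers:

$$P_0 = \left(1 - 4^{-k}\right)^{K \cdot M \cdot (L - k + 1)}.$$

Position overlaps make occurrences weakly dependent; the product form
ignores this deliberately, and `p_none_monte_carlo()` validates the
approximation by simulation (the suite checks agreement within three
binomial standard errors at parameters where expected occurrence counts
are of order one).  At `K = 1000`, `M = 10^6`, `L = 30`, `k = 16` the
value is `r round(p_none(1000, 1e6, 30, 16), 4)`: finding *no* shuffle is
itself mildly unexpected under randomness, which sharpens the contrast
with an abundant original.  `generate_distinct_permutations()` draws the
shuffles by rejection against a seen-set, excluding the identity, and
fails with the attainable maximum when the base multiset admits too few
distinct orderings.

## Hairpin model and scores

The structural stage looks for *perfect* stem-loops: contiguous
Watson-Crick or G:U-wobble pairs closed by a loop of 3–30 nt.  This is a
deliberate restriction — the hairpins of interest in this setting are
perfect or near-perfect stems, and a full dynamic-programming folder
(bulges, internal loops, multiloops, ensembles) would add unverifiable
machinery.  Consequences of the restriction:

* Free energies are a nearest-neighbour sum: stacking terms over adjacent
  stem pairs, a hairpin-loop initiation term by loop size (logarithmic
  extrapolation beyond 30), and tabulated replacement energies for known
  stable tetraloops.  The constants are the published Turner 2004
  parameters, shipped as versioned plain-text tables under
  `inst/extdata/` and hand-summable in tests.
* Absolute dG values will differ from full folding engines, which also
  score terminal mismatches and dangles.  Stability comparisons are
  therefore treated as *rankings* (hairpin A outranks hairpin B), never
  as point targets, and `load_external_energies()` lets users substitute
  energies computed by any engine for exact spans.

Two scores are computed per hairpin of span `L`:
the **stability ratio** $-\Delta G / L$ (kcal/mol per nt; threshold
`min_ratio = 0.30` for a "stable" hairpin) and the **MFEI**
$-\Delta G / n_{GC}$ with $n_{GC}$ the number of G and C *nucleotides* in
the span — a score used to screen miRNA-precursor-like hairpins.  The two
satisfy the identity $\text{ratio} \cdot L = \text{MFEI} \cdot n_{GC}$
(both equal $-\Delta G$), asserted for every scored hairpin in every
test run.  Note the distinct bookkeeping: `gc_pair_count` counts C-G
*pairs* in the stem (used for geometry claims), `gc_nt_count` counts
nucleotides (used by MFEI).

`scan_ncrna()` slides 50-nt windows at a 5-nt step (the window matches
common practice for pre-miRNA-sized structures; the step is a
resolution/cost compromise), deduplicates hairpins found in overlapping
windows by span, and drops window-truncated stems that are still
extendable in the full molecule.  Hairpins must span at least
`min_span = 25` nt, the size regime of processed regulatory precursors.

`reconstruct_hairpin()` inverts the observation "core = loop + 3' side":
the first `loop_len = 4` core bases become the loop, the rest the 3'
side, and the strict Watson-Crick reverse complement is prepended as the
5' side.  Strict complementarity (no wobble) is used for the built side
because the reconstruction models a stem described by its C-G bond
count.  For the default core this yields a 28-nt hairpin with 12 stem
pairs, 8 of them C-G — and its loop + 3' side is exactly the 16-nt core,
since $4 + 12 = 16$.

## Target scanning

`find_target_sites()` reports every *maximal* block (default at least
`min_site_len = 7` nt, the miRNA seed length) where a core segment is the
exact reverse complement of a UTR segment.  No wobble and no mismatches
are allowed: the evidence sought is exact complementarity, with the
biologically notable site lengths (9, 11) arising as outputs, not
thresholds.  Implementation is by maximal runs along diagonals of the
match matrix; the suite checks equality with a brute-force
all-substring-pairs oracle on hundreds of random instances.

`seed_overlap()` compares all 7-mer windows of a core against the seeds
(mature positions 2–8) of a user-supplied miRNA table; an empty overlap
means targeting by the core would not be redundant with known miRNA
action.

## The join

`colligate()` is a deterministic three-way inner join with explicit
thresholds: core in hairpin (overlap fraction at least
`overlap_min = 0.8` of core bases inside the hairpin span — strict but
tolerant of ragged core ends), hairpin stability ratio at least 0.30, and
a site of at least 7 nt in the 3'UTR of an RNP-linked protein.  Each
emitted record re-verifies its three predicates independently from the
raw sequences (`verify_colligation()`), and record counts are monotone
non-increasing in every threshold.  No significance is attached to a
join: the package provides no null model for triple co-occurrence, and
the thresholds are exposed rather than asserted.

## The synthetic-data generator

Real libraries of this kind (millions of 35-base reads from post-mortem
brain tissue) are not redistributable, so the generator produces inputs
with the statistical structure the analysis assumes:

* **Reads** (default 2000, of which 300 carry the planted core): planted
  reads are insert + 0–4 trailing A's (uniform over 0–4) + adapter,
  truncated to 35 nt; background reads are uniform-random and
  rejection-sampled so that none contains a planted core and none
  survives trimming.  Planted inserts default to the bare core
  (`flank_max = 0`), so the recovered core's instance count equals the
  planted abundance exactly.  Library size is kept in the thousands so
  the full suite runs in seconds per replicate; abundance 300 keeps the
  planted core far above the `min_copies = 3` floor, mimicking the
  orders-of-magnitude gap observed in real libraries.
* **ncRNA** (164 nt, the length of RNU1): the reconstructed 28-nt hairpin
  is embedded at a random offset in a uniform-random background,
  rejection-sampled until a full scan reports exactly the planted span —
  so recovery tests are exact, not probabilistic.
* **3'UTR** (150 nt): reverse complements of core positions 3–13 (11 nt)
  and 8–16 (9 nt) are embedded at non-overlapping offsets, the background
  rejection-sampled until the target scan reports exactly the planted
  sites.  The two interval choices reproduce the 11/9-nt site-length
  geometry of the motivating example; their positions within the core are
  a design choice, as the real site coordinates are not available in
  machine-readable form.

Uniform base composition matches the permutation-null model and is
configurable.  All generators are pure functions of (config, seed).

**What passing tests do and do not show.**  The generator plants one
unambiguous signal in clean backgrounds; recovery demonstrates that the
pipeline's logic is correct, not that it is robust to sequencing error,
composition bias, paralogous sources, or near-identical competing
hairpins — none of which the generator emulates.  Conclusions about real
data still require the invariance-under-retuning checks that any
multi-parameter pipeline demands.

## Numerical choices and degenerate inputs

* All coordinates, everywhere, are 1-based inclusive (the R convention).
* The internal alphabet is RNA (`U`); DNA input spelling is normalized on
  read, and writers can emit either spelling.
* Reads containing `N` are dropped at parse time with a count, since
  every stage relies on exact identity.
* Loops shorter than 3 nt are rejected as sterically impossible; a loop
  placement whose end bases could pair into a *legal* smaller loop is not
  reported separately, so each physical hairpin appears once.
* Ties in core clustering: higher total count, then lexicographic order;
  in side annotation: 3' side, then loop, then 5' side.
* MFEI is reported as `NA` for a G/C-free span; the hairpin is retained
  by its stability ratio.
* Empty inputs (no reads, no hairpins, empty RNP table) propagate as
  empty data frames, never as errors.

## Known limitations

* The energy model scores only perfect stems; a real hairpin with a
  one-base bulge is invisible to the enumerator, and its window-scan
  would report the shorter perfect sub-stem instead.
* Exact-substring core clustering does not merge variants with
  sequencing errors (by design; abundance filtering removes most).
* The permutation null models reads as uniform random; real read sets
  are composition-biased, so `p_none` is a calibration reference, not a
  test of real libraries.
* Target scanning is pure complementarity: no accessibility, context or
  conservation scoring.

## Problem sizes used by the test suite

Oracle-equivalence checks run on 500 random sequences (length ≤ 20 nt)
for hairpin enumeration and 200 random core/UTR instances for target
scanning; planted-hairpin recovery uses 100 replicate 164-nt ncRNAs; the
Monte-Carlo validation of the closed form uses 2000 trials at
`K = 10, M = 1000, L = 30, k = 8`.  These sizes were chosen so that the
complete suite exercises every claim in well under two minutes on one
CPU while keeping every expected count in the informative regime.
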