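---
title: "Methods: distance-based lineage delimitation, strict-clock dating, and the optimized-comparison screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distance-based lineage delimitation, strict-clock dating, and the optimized-comparison screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shrimpdelim)
```

This vignette is the package's own account of the science it implements:
the models, the tunable parameters and their defaults, the numerical
choices, and what the synthetic-data tests do and do not demonstrate
about real data.

## The problem

Single-locus barcoding data for freshwater shrimps (here a ~550 bp
fragment of mitochondrial 16S rDNA, reduced to 435 unambiguous columns
after filtering) often reveal deep, geographically structured lineages
inside what is nominally one species. Three questions follow, and the
package answers each with a deliberately simple, fully auditable tool:

1. **Are there distinct lineages?** Summarize the pairwise divergence
   surface — if intralineage variation (here, low single-digit percent)
   is cleanly separated from interlineage divergence (here, >10%), the
   "barcoding gap" supports distinct lineages.
2. **How old is the split?** Convert corrected divergence to time under
   a strict clock calibrated from an independently dated sister pair.
3. **Can the lineages be diagnosed morphologically?** Screen categorical
   characters for between-clade constancy with a staged, block-wise
   validation design that mimics how a taxonomist actually works through
   museum lots.

## Sequence statistics

**Column filtering.** All multi-sequence statistics operate after
complete-deletion filtering: a column is dropped if *any* sequence
carries `-` (gap), `?` (missing) or a non-ACGT IUPAC letter (ambiguous;
`N` included). The three classes are distinguished in the filter report
with a fixed priority (gap > missing > ambiguous) so each excluded
column has exactly one recorded reason. Complete deletion is the default
because it gives a single shared column count for every downstream
statistic; pairwise deletion remains available in `p_distance()` because
distance software commonly defaults to it and the two can differ on
gappy matrices. Which convention an upstream matrix used for terminal
overhangs (`-` vs `?`) changes nothing here, since both classes are
excluded by default.

**Site classification.** A column is *variable* iff ≥2 states occur and
*parsimony-informative* iff ≥2 states each occur in ≥2 sequences;
variable non-informative columns are singletons. These definitions are
checked in the test suite against an independent brute-force per-column
tally on randomized alignments.

**Distances.** `p_distance()` is the proportion of differing compared
sites. Corrections: Jukes–Cantor
\(d = -\tfrac34 \ln(1 - \tfrac{4p}{3})\) and Kimura two-parameter
\(d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q)\) with transition
proportion \(P\) and transversion proportion \(Q\). Both are monotone
and never below \(p\); both error at their saturation bounds
(\(p \ge 3/4\) for JC; non-positive log arguments for K2P) rather than
returning `NaN`. Matrices are stored as *proportions* throughout;
percent is applied only when rendering reports, to keep units
single-sourced. K2P is the package default correction for dating and JC
is always reported alongside, because the source data's correction model
is not pinned down and a robust conclusion should not depend on the
choice; the two agree closely at 16S-like divergences.

## Lineage partitioning

The primary path takes **predefined group labels** from the specimen
metadata (the lineages as delimited by proper phylogenetic analysis,
which this package intentionally does not re-implement — Bayesian/ML/
parsimony tree inference is out of scope). An unsupervised fallback is
provided: UPGMA agglomeration (size-weighted average linkage; node
height = half the joining distance, so heights live on the divergence
scale) with a threshold cut. Ties in the agglomeration are broken by the
lexicographically smallest pair of cluster representatives, making the
tree fully deterministic. The cut groups leaves joined strictly below
the threshold, so a cut at 0 yields singletons and a cut above the root
one group. UPGMA is clock-consistent, which is exactly the regime the
simulator generates; it is *not* a substitute for model-based
phylogenetics on real data, and the documentation of `cut_tree()` says
so.

`summarize_distances()` reports min/mean/max per intra- and inter-group
cell with unweighted arithmetic means over pairs (a defined, simple
statistic; ranges are what gets reported descriptively). Singleton
groups get an *undefined* intra cell (`NA`, `n_pairs = 0`), never a fake
zero. Both the per-cell values and the conservation of all \(\binom n2\)
pairs across cells are tested against brute-force enumeration.

## Strict-clock dating

Under a strict clock, divergence accumulates at \(d = 2rt\), so a sister
pair with corrected divergence \(d_{cal}\) isolated \(t_{cal}\) Ma ago
calibrates \(r = d_{cal}/(2\,t_{cal})\), and any corrected divergence
maps to \(\hat t = d/(2r)\). The default rate, 0.0083
substitutions/site/Myr, corresponds to a transisthmian palaemonid pair
separated ~3 Ma and sits inside the 0.006–0.009 range reported for
decapod 16S. Group-level divergence is the **mean of corrected
cross-pair distances** (not the midpoint of the range): a point estimate
needs a defined statistic, and ranges stay available in the summary.

Uncertainty comes from a **site bootstrap**: columns are resampled with
replacement, the mean corrected cross-group distance and \(\hat t\) are
recomputed per replicate, and the 2.5/97.5 percentiles form the
interval. This is a site-resampling construct, *not* a Bayesian credible
interval, and the dating report labels it as such. Replicates that hit
the correction's saturation bound are dropped and counted; more than 10%
dropped is an error, because the interval would no longer describe the
intended statistic. Clock-likeness can be checked with Tajima's
one-degree-of-freedom relative-rate test on an ingroup pair plus
outgroup: the counts of sites unique to each ingroup sequence have equal
expectation under a clock, and \((n_A-n_B)^2/(n_A+n_B)\) is compared to
\(\chi^2_1\). With few informative sites the statistic is undefined and
reported as such rather than as \(p = 1\).

## The optimized-comparison morphology screen

The screen formalizes a staged workflow over museum material:

1. **Initial screen** — only sequenced voucher specimens (the specimens
   actually placed in the molecular tree), adults by default. For each
   character: modal state per clade among known (non-`"unknown"`)
   states; a candidate needs *different* modal states and constancy
   strictly above the threshold (default 0.80) **in both clades**.
2. **Block validation** — the remaining specimens from the voucher lots,
   shuffled per clade with a recorded seed and processed in blocks of 10
   per clade. After each block the *cumulative* constancy (initial
   specimens plus all blocks so far) is recomputed against the fixed
   modal states; a character is discarded at the first block where
   either clade falls strictly below the threshold, and discarded
   characters skip later blocks. Every decision is recorded in a trace.
3. **Final check** — specimens from lots containing no voucher, same
   block rule, but the tally starts **fresh**: the hold-out stage is an
   independent confirmation, and a fresh tally is the only reading under
   which a survivor can, e.g., fall to 0.7 on a single hold-out block
   and be removed.

Design choices that were genuinely open, and how they were resolved:

* *Per-clade vs pooled constancy*: per-clade, required in **both**
  clades — a diagnostic character must be reliable on each side, and a
  pooled criterion can hide one-sided failure.
* *Strict vs inclusive threshold*: strict (`> 0.80`), exposed as a
  parameter; 4/5 = 0.80 is therefore *not* retained, and the boundary
  case is a unit test.
* *Cumulative vs per-block constancy*: cumulative. Per-block constancy
  on blocks of 10 has a granularity of 10 percentage points and would
  discard characters on single-specimen noise; the cumulative tally uses
  all evidence seen so far, and the trace still shows each block.
* *Modal-state ties*: a clade without a unique modal state cannot define
  a diagnostic state; the character is skipped for that comparison and
  the skip recorded.
* *Juveniles*: excluded by default (`adults_only = TRUE`) because
  ontogenetic variation mimics between-clade differences;
  `adults_only = FALSE` exists for sensitivity analysis, and the
  simulator generates exactly this failure mode.
* *Block composition*: randomized with a recorded seed — the historical
  order in which lots were examined is not recoverable, and a recorded
  shuffle makes the whole trace reproducible.

One statistical property worth knowing: with a fresh hold-out tally, the
first hold-out block of 10 passes a character of true constancy 0.95 in
a clade with probability \(P(\mathrm{Bin}(10, 0.95) \ge 8) \approx
0.99\); characters near the threshold can legitimately fail a short,
strict confirmation. The property tests therefore measure
retention-vs-constancy behaviour at the *block-validation* stage, where
the cumulative tally makes retention of a 0.95-constancy character
essentially certain and retention of a 0.60-constancy character
essentially impossible; the hold-out stage is covered by deterministic
hand-built cases.

## The synthetic-data generator

`simulate_alignment()` evolves a uniform-random root sequence down a
fixed topology `((lineage1, (lineage2, lineage3) @ 2.6 Ma) @ 10 Ma,
outgroup @ 25 Ma)`, default rate 0.0083 subs/site/Myr, 435 sites.
Substitutions are placed as per-site Poisson counts with expected value
rate × branch duration, applied sequentially so multiple hits overwrite
— observed divergence then saturates exactly as the JC expectation
\(E[p] = \tfrac34(1 - e^{-4rT/3})\) (total path time \(T\)) assumes,
which is what the simulation-vs-closed-form tests exploit. The sister
split default of 2.6 Ma is back-computed from the low-4-percent
divergence such sister species show at the default rate
(\(t = d/2r\)); the outgroup age of 25 Ma is arbitrary but safely older
than all ingroup splits while staying below the saturation regime; the
within-lineage star age of 1.1 Ma puts expected intralineage divergence
in the low single-digit percent range typical of such data. Per-lineage
sample sizes default to 4 + 4 + 1 sequences plus one outgroup, matching
the sampling structure of the motivating dataset.

What the simulator deliberately does **not** model: indels (the
column-filter path is tested on handcrafted gapped fixtures instead),
rate heterogeneity across sites or lineages (no gamma, no relaxed
clock), and within-lineage coalescent genealogy (within-lineage
variation is a star of short terminal branches). Passing tests on this
generator therefore demonstrate correctness of the *estimators and
procedures under their own assumptions* — an unbiased clock estimate on
relaxed-clock data, or distance behaviour under strong rate
heterogeneity, is explicitly not claimed.

`simulate_morphology()` emulates the museum sampling design: per clade
60 specimens over 12 lots (round-robin), 8 voucher lots with 3 sequenced
adults each (so 24 initial-screen specimens per clade), 4 hold-out lots,
15% juveniles among non-vouchers, 2% unscored cells. Characters are
`diagnostic` (clade-specific modal state with probability =
constancy), `overlapping` (one shared, mildly skewed distribution —
never legitimately diagnostic), or `ontogenetic` (diagnostic in adults;
juveniles flip toward the other clade's state with probability 0.5).
These defaults were fixed from design-stage binomial arithmetic (the
initial screen needs enough vouchers that a truly 0.95-constant
character passes `> 0.80` with high probability; 24 gives
\(P(\mathrm{Bin}(24, 0.95) \ge 20) \approx 0.997\)) and from what a
revision of a widespread Amazonian species can realistically assemble.

## Numerical and degenerate-input choices

* Distances are proportions end-to-end; percent only at rendering.
* Corrections error (never `NaN`) at saturation; the bootstrap drops and
  counts saturated replicates, failing beyond 10%.
* UPGMA ties: lexicographic smallest representative pair; heights are
  checked monotone by construction of average linkage.
* Zero-length tree cut and cuts above the root are defined (singletons /
  one group), not errors.
* Empty validation or hold-out pools pass candidates through with an
  explicit trace note or warning — silence would misrepresent a screen
  that never ran.
* All stochastic steps (simulators, block shuffles, bootstrap) take
  explicit integer seeds, restore the caller's RNG state, and record the
  seed in their outputs.

## Problem sizes used by the test suite

The suite checks oracle equality on 100 randomized alignments, clock
recovery as the mean over 200 simulated 435-site datasets (within 0.5 Ma
of the 10 Ma truth), bootstrap coverage over 100 datasets × 1000
replicates (≥90% coverage required), screen behaviour over 200 simulated
matrices (≥95% correct retention/rejection required) and 500-replicate
retention curves at constancy 0.95 vs 0.60. These sizes give binomial
standard errors comfortably inside the asserted margins while keeping
the default test run around half a minute.

## Known limitations

* Single locus, strict clock, point calibration: honest uncertainty in
  the calibration itself (the 3 Ma isolation, the calibration pair's
  divergence) is not propagated; the site bootstrap only captures
  site-sampling noise.
* The UPGMA fallback will mis-partition data whose true tree is far from
  clock-like; use predefined labels from a proper phylogeny there.
* The screen's constancy statistic treats specimens as exchangeable
  within clades; lot-level correlation (shared locality effects) is
  represented in the simulator's design but not modelled in the
  statistic itself.
* Distance corrections stop at K2P; strongly saturated or
  composition-biased data need model-based estimates outside this
  package's scope.
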