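# shrimpdelim

Integrative lineage delimitation for DNA-barcoding-style data, built
around the analysis of two sister lineages of Amazonian freshwater
shrimps (*Palaemon carteri* and the *P. ivonicus* / *P. yuna* group)
delimited from mitochondrial 16S rDNA and then diagnosed morphologically.
The package is for taxonomists and molecular ecologists who have an
aligned single-locus matrix, a specimen table, and a categorical
morphology matrix, and want the complete chain from raw alignment to
dated, morphologically diagnosed lineages — reproducibly and with every
intermediate step auditable.

## What it computes

**Sequence side.** After complete-deletion column filtering (columns with
a gap `-`, missing `?`, or any non-ACGT IUPAC symbol are dropped), the
package classifies sites (constant / variable / singleton /
parsimony-informative), computes uncorrected pairwise divergence

&nbsp;&nbsp;&nbsp;&nbsp;*p* = mismatches / compared sites,

with complete- or pairwise-deletion semantics, and corrects it for
multiple hits under Jukes–Cantor, *d* = −(3/4) ln(1 − 4*p*/3), or Kimura
two-parameter, *d* = −(1/2) ln(1 − 2*P* − *Q*) − (1/4) ln(1 − 2*Q*),
where *P* and *Q* are the transition and transversion proportions.
Sequences are partitioned into lineages either from predefined metadata
labels or by cutting a UPGMA tree at a divergence threshold, and the
intra-/inter-lineage divergence surface is summarized cell by cell.

**Dating.** Under a strict molecular clock, two lineages that split *t*
Ma ago are separated by *d* = 2 *r* *t* substitutions per site. A rate
calibrated from a dated sister pair (*r* = *d*/2*t*; the default
0.0083 substitutions/site/Myr comes from a transisthmian palaemonid pair
isolated ~3 Ma) converts mean corrected cross-lineage divergence into a
divergence time, with a site-bootstrap percentile interval and a Tajima
relative-rate test as a clock sanity check.

**Morphology side.** The block-wise "optimized comparison" screen:
candidate diagnostic characters are those whose modal states differ
between the clades with per-clade constancy strictly above 80% among the
sequenced voucher specimens; candidates are then validated in shuffled
blocks of 10 specimens per clade drawn from the voucher lots (cumulative
constancy; a character is discarded at the first block where either
clade drops below the threshold) and finally confirmed on hold-out lots
that contributed no sequences.

**Synthetic data.** A clock-like sequence simulator (Poisson
substitutions per branch, multiple-hit overwriting, JC or K2P) on the
three-lineage-plus-outgroup study topology, and a morphology simulator
with controlled per-character constancy, ontogenetic noise and a
lot/voucher sampling design, so the entire pipeline runs and is tested
without any external data.

## Worked example

```r
library(shrimpdelim)

sim  <- simulate_alignment(scenario_config(seed = 42))
fc   <- filter_columns(sim$aln)
classify_sites(fc$aln)
#> 435 aligned positions: 252 constant, 183 variable (115 singleton,
#> 68 parsimony-informative)

part <- partition_from_metadata(sim$aln)
summarize_distances(p_distance(sim$aln), part)
#>    kind        group1        group2 n_pairs    min   mean    max
#> 1 intra       carteri       carteri       6 0.0069 0.0126 0.0184
#> 2 intra ivonicus_yuna ivonicus_yuna      10 0.0092 0.0255 0.0437
#> 4 inter       carteri ivonicus_yuna      20 0.1563 0.1663 0.1770
#> ...

est <- bootstrap_time(fc$aln, part, c("carteri", "ivonicus_yuna"),
                      rate_constant(0.0083), model = "K2P",
                      n_reps = 1000, seed = 42)
est
#> divergence time 11.340 Ma (site-bootstrap 95%: 8.941-14.056, 1000 reps, K2P)

m   <- simulate_morphology(morph_scenario(seed = 42))
res <- screen_characters(m, c("carteri", "ivonicus_yuna"), seed = 42)
as.data.frame(res$confirmed)[, 1:5]
#>                       character state_a state_b screen_const_a screen_const_b
#> 1 branchiostegal_tooth_position      s1      s2          1.000          1.000
#> 2           rostral_tooth_count      s1      s2          0.971          0.895
#> 3       appendix_masculina_size      s1      s2          0.946          0.923
#> 4               telson_spinules      s1      s2          1.000          0.974
```

Reading: the simulated matrix shows the barcoding-gap structure the
method relies on (intralineage divergence ≤ ~4%, interlineage 15.6–17.7%
uncorrected); the clock converts the corrected cross-lineage divergence
into ≈10 Ma (the generating truth) with a site-resampling interval; and
the screen confirms the characters simulated as genuinely diagnostic
while the distribution-identical ones never reach the candidate list.

Each stage is also exposed as a `run_*()` function writing
JSON/TSV/Newick outputs plus a run manifest, and as a subcommand of the
thin CLI at `inst/cli/shrimpdelim.R`
(`simulate | align-stats | distances | lineages | date | screen |
run-all`), configured by YAML with flag overrides.

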