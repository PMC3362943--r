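---
title: "Methods: pseudo-testcross mapping and EST-SSR analysis in an allotetraploid"
author: "clovermap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pseudo-testcross mapping and EST-SSR analysis in an allotetraploid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clovermap)
```

# The mapping problem

White clover (*Trifolium repens*) is an outcrossing allotetraploid
(2n = 4X = 32) carrying two diploid subgenomes.  Its mapping populations
are full-sib F1 families between two heterozygous parents.  Because each
parent is highly heterozygous, every locus that is heterozygous in one
parent and absent (or monomorphic) in the other segregates 1:1 among the
F1 progeny — a testcross.  The *two-way pseudo-testcross* strategy
exploits this: the segregation data are split into two parental-specific
haploid ("HAP1") data sets, one per parental meiosis, each mapped
independently, and the two maps are merged afterwards through loci that
are heterozygous in *both* parents (bi-parental "bridge" loci).  In an
allotetraploid the expected outcome is `2 * 8 = 16` linkage groups per
parent, arranged in homeologous pairs (LG1a/LG1b, ...), and a single
marker frequently amplifies loci on both homeologs.

`clovermap` implements this workflow end to end, together with the two
analyses that sit on top of the maps: a grid-sampled gametic r² scan
that can detect linkage disequilibrium (LD) *across* linkage groups, and
synteny-block detection against reference genome coordinates.

# Two-point analysis and grouping

For loci `i, j` with `n` jointly informative progeny and `R`
phase-minimized recombinant gametes (`R <= n - R`; the a/b labelling of
each locus is arbitrary, so the phase minimizing mismatches is used):

* `r_hat = R / n`, the standard haploid testcross estimator;
* `LOD = R log10(2 r) + (n - R) log10(2 (1 - r))`, with the `r = 0`
  limit `n log10 2`;
* map distance by Kosambi's function `d = 25 ln((1 + 2r) / (1 - 2r))`
  cM, inverse `r = 0.5 tanh(d / 50)`.

Pairs with fewer than `pair_n_min = 20` jointly informative progeny are
ignored (about 10% of a 188-progeny family; the study design this
package addresses used 188 F1 individuals).  Loci scored in fewer than
20% of progeny are excluded from mapping entirely — they cannot support
stable two-point estimates and would otherwise seed spurious linkage.
Both thresholds are configurable in `pipeline_config()`.

Grouping is single linkage: loci are connected when `LOD >= 10` and
`r_hat <= 0.4` (the published thresholds), and linkage groups are the
connected components.  Single linkage mirrors how threshold-based
grouping modules in standard mapping software behave, including their
known failure mode — a single spurious strong pair merges two
chromosomes — which is exactly the failure the disassembly procedure
(below) repairs.

# Marker ordering

Ordering is regression-style and greedy:

1. the highest-LOD pair seeds the order;
2. remaining loci are added in decreasing informativeness (summed LOD to
   placed loci); each addition tries every insertion slot and keeps the
   one minimizing the LOD-weighted least-squares misfit between map
   distances and pairwise Kosambi distances (pairs with `LOD >= 1` and
   `r_hat <= 0.4` contribute, the published ordering parameters);
3. after each addition, every sliding window of three loci is
   exhaustively permuted (a "ripple") and improvements kept;
4. a locus whose best insertion raises the normalized misfit by more
   than `jump = 5.0` is set aside and retried once after all other loci
   are placed (the "third round");
5. orientation puts the lexicographically smaller terminal locus at
   0 cM.

Two numerical choices deserve explanation:

**Slot search.**  Candidate insertions are ranked with a cheap misfit
whose positions chain adjacent-pair Kosambi distances; only the three
best-ranked slots are re-evaluated under the least-squares objective.
On clean simulated groups this reproduces the exhaustive-permutation
optimum (tested for groups up to 7 loci).

**Position fit and the span limit.**  Final cM positions come from a
weighted least-squares fit of interval lengths, anchored at 0 — but only
pairs spanning at most **two** intervals in the final order enter the
fit.  The reason is a property of any meiosis model without full
interference (including this package's simulator, and real meioses): the
recombination fraction between distant loci composes multiplicatively
along the chromosome, so the pairwise Kosambi distance of a
distant pair systematically *understates* the true map separation.
Fitting all pairs compresses a simulated 100-cM chromosome to about
72 cM; fitting only short-range pairs recovers 94–99 cM (median over 20
simulations, reproduced in the test suite).  The goodness-of-fit jump
statistic is evaluated on the same short-range residuals, so its
baseline does not drift upwards as loci are added; insertion ranking
still uses all informative pairs, because the long-range distances are
what identify the global order.

# Reference-guided disassembly of an over-merged group

When one linkage group of a parental data set holds more than
`suspect_flag_fraction = 25%` of that parent's loci (the pathological
group in the motivating study held 32.4%), the group is treated as an
artifact of grouping — several chromosomes whose segregation patterns
are coupled — and `disassemble()` reassigns its loci by precedence:

1. **Partner map, locus level**: a bi-parental bridge locus is looked up
   directly on the other parent's map via its shared `base_id`.
2. **Partner map, marker level**: other loci of the same marker (the
   multi-band homeolog copies) vote for a partner-map group.
3. **Reference chromosome**: the best homolog hit's chromosome,
   translated into partner-map groups by majority vote over loci that
   carry both kinds of evidence.
4. **Linkage rescue**: remaining loci join the labelled subgroup with
   the highest mean LOD; loci with no evidence at all are reported
   unresolved.

Each subgroup is then re-validated by LOD-threshold grouping.  Partner
evidence wins over reference evidence on conflict (the conflict is
recorded in the evidence table).  A mosaicism score
(`mosaicism_score()`, the mean adjacent-locus switch rate) is available
as the numeric analogue of inspecting graphical genotypes.

# Map integration

Group correspondence between the parental maps is established greedily
from shared bi-parental locus counts.  When a pair of corresponding
groups shares at least `min_anchors = 3` bridge loci, each parental
scale is rescaled by monotone piecewise-linear interpolation through the
mean anchor positions (the second map is flipped first if anchor
positions correlate negatively), non-anchor loci ride along, anchors
appear once at the mean of their transformed positions, and the combined
group is re-anchored at 0.  `min_anchors = 3` because integration
through two anchors determines only a line, not a monotone warp — with
exactly two shared loci the group is left un-integrated and reported
with the documented fallback statistics
`n = n1 + n2 - n_shared` and `length = mean(length1, length2)`.

Mean-anchor interpolation is an approximation chosen over joint
re-estimation of all distances from the pooled data; it is transparent,
order-preserving where the parental anchor orders agree, and resolves
anchor-order conflicts by the (equal-weight) mean position.

Map statistics follow the conventional arithmetic: per-group density is
`length / n_loci` (mean spacing), totals sum lengths and counts, and the
total density and distortion are count-weighted.  Segregation distortion
is tested per locus by `chi2 = (n_a - n_b)^2 / (n_a + n_b)` on 1 df
against 1:1 at `alpha = 0.05`, without continuity correction (n = 188 is
large, and on selection-free simulations the distorted fraction tracks
alpha).

# LD scan

Loci are grid-sampled about every `5` cM (for each grid point, the
nearest not-yet-chosen locus — deterministic and auditable), and gametic
r² is computed for every sampled pair over jointly informative progeny:
with haplotype counts `f11, f10, f01, f00` and margins `p1 p0 q1 q0`,

```
r2 = (f11 f00 - f10 f01)^2 / (p1 p0 q1 q0)
```

which equals the squared Pearson correlation of the 0/1 codes and is
invariant to relabelling.  Haplotype (not genotype) r² is appropriate
because HAP1 coding makes each parental channel phase-known gametic
data.  Pairs with fewer than `ld_n_min = 30` shared informative progeny
are skipped.  Cross-group pairs with `r2 > 0.5` are reported, and 5-cM
bins are ranked by their number of high-LD cross-group partners.  The
scan reports; it does not attribute mechanism.

# Synteny blocks

Markers are anchored to reference coordinates by their best homolog hit
(highest bitscore; ties by smaller E-value, then lexicographic reference
id) after an E-value filter (defaults 1e-20 for nucleotide-level, 1e-10
for translated comparisons).  Within each (linkage group, chromosome)
cell, anchors sorted by cM are chained into maximal runs in which every
consecutive pair lies within 10 cM on the map AND 500 kb on the
chromosome; runs of three or more anchors are blocks.  The "within a
10-cM region and a 500-kb stretch" definition is interpreted as
consecutive-anchor gap bounds: deterministic, order-free, and equivalent
to a window rule when anchors are dense.  Blocks are not stitched across
intervening foreign-chromosome anchors.  Orientation is the sign of the
Spearman correlation of cM vs bp inside the block (`mixed` below
|rho| = 0.5); colinearity (monotonicity) is recorded, not enforced.

# SSR mining

`find_ssrs()` reports every maximal tract of length ≥ 15 nt whose
Hamming distance to some phase of a primitive di-, tri- or
tetra-nucleotide repeat is at most `max_mismatch` (0, 1 or 2; no
indels).  Details that matter:

* **Canonical motif class** = lexicographic minimum over rotations of
  the unit and of its reverse complement (so GA/TC/CT/AG are all "AG"),
  the strand/phase-collapsed labelling used in published SSR frequency
  tables.
* **Primitivity** excludes units that are repetitions of shorter units
  (ATAT is (AT)2, poly-A is not a di repeat); GC remains a legal di
  class even though it is rare in practice.
* Tracts must start and end on a matching base, preventing unbounded
  mismatch extension; `N` never matches.
* Candidate windows are collected as maximal windows at *every*
  mismatch budget up to the cap, so a perfect core nested inside a
  mismatch-extended window is still reported when the larger window
  loses the overlap resolution.
* **Overlap resolution** is greedy: longest tract wins, ties go to
  fewer mismatches, then to the leftmost start; each reported hit
  carries the minimal mismatch count achieving its interval.

The scanner prunes its unit search by first locating short perfect
periodicity runs (any valid tract contains a perfect segment of length
`>= ceil((min_len - k)/(k + 1))`); the test suite proves it equivalent
to a brute-force oracle that scores every interval against every
unit/phase by direct template comparison.

A tract is *designable* (marker-design-feasible) when at least 20
non-SSR bases flank it on each side and an amplicon of 90–300 bp
containing tract plus both minimal flanks fits in the sequence — a
feasibility flag standing in for actual primer design, which is outside
this package's scope.  `summarize_motifs()` produces the per-motif
frequency table (counts, percentages, bp-per-SSR density, designable
counts by mismatch class); all printed percentages round half-up at the
published precision.

# The synthetic-data generator

The generator exists so that every inference can be scored against known
truth.  What it emulates, and how:

* **Genome**: `n_pairs = 8` homeologous pairs → 16 linkage groups,
  default length 140 cM with 120 marker positions each (about the
  density of a saturated clover map); positions may be given explicitly.
* **Design**: `n_progeny = 188`; 424 / 789 / 584 loci segregating
  bi-parentally, female-only and male-only — the study layout.
* **Meiosis**: each parental gamete is a Markov chain over the ordered
  markers of each group; the allele switches between adjacent markers
  with probability `kosambi_inverse(delta_cm)`.  This makes
  adjacent-interval estimates self-consistent with the mapping function
  used downstream.  Crossover interference beyond the map function is
  not modelled, with the long-range consequence discussed under
  *Position fit* above.
* **Cross-group LD** is planted at anchor loci: anchor alleles are drawn
  jointly with a requested gametic `D'` (pairs may chain, A–B then B–C,
  via sequential conditional sampling) and the rest of each chromosome
  is walked conditionally outward from its anchor.  This reproduces the
  observed phenomenon — coupled haplotypes across chromosomes — without
  committing to a biological mechanism, which the motivating study could
  not identify either.
* **Segregation distortion** is gametic viability selection: progeny are
  resampled with weights `1` vs `1 - s` by the allele carried at each
  selected locus.  No distortion loci are planted by default, because
  the study reports distortion frequencies but no selection
  coefficients; tests that need distortion plant it explicitly.
* **Multi-locus (multi-band) markers**: a configurable fraction of loci
  (default 0.5) is merged with a same-class locus on the homeolog
  partner group under one marker id, locus ids suffixed a/b — Type I
  markers.  A small fraction (default 0.02) of bi-parental loci have
  their male channel rewired to the partner group — Type II placements.
* **Noise**: symmetric call error (default 0.005) and
  missing-at-random masking (default 0.05), plus random a/b label
  polarity per channel so that phase alignment is always exercised.
* **Transcripts**: uniform-random background with SSR tracts planted at
  one per 4.7 kb (unit-length mix 19 / 69.8 / 11.2% di/tri/tetra); the
  repeat phase is broken at both flanks so planted coordinates are exact
  truth.  Mismatch-free planting is used for density-recovery checks
  because mismatch-tolerant scanning of random background yields chance
  tracts at a rate comparable to this planting density — background is
  a property of the mismatch definition, not a scanner artifact.
* **Reference genomes**: every marker gets a gene at
  `bp = pos_cm * 40000` on the chromosome of its homeologous pair, with
  optional translocations/inversions, wrong-chromosome decoy hits at
  lower bitscore, and missing hits.

What it does **not** emulate: sequence-level homeologous gene copies,
realistic base composition, partially informative (ab × ab) band
patterns (only fully informative testcross configurations are
generated), linked viability selection acting on whole chromosomes, or
genotyping error that correlates across progeny.  Passing tests
therefore demonstrate correctness of the algorithms under the stated
model, not robustness to every artifact of real gel scoring.

# Problem sizes used in the tests

The test-suite and acceptance-script simulations use a full-size family
(n = 188) with scaled-down genomes chosen so each check isolates one
property: 16 groups × 44 marker positions for grouping purity,
10-locus groups over 45 cM (5-cM spacing, giving ~9 expected
recombinants per interval) for order recovery, 20 markers on 100 cM for
map-length calibration, 2–4 pair genomes for the LD and disassembly
scenarios, and 400 transcripts (~0.3 Mbp) for SSR density recovery.
Full-scale designs (1797 loci) run through the same code paths and are
exercised by the generator defaults.

# Known limitations

* Equivalence with JoinMap output is not claimed anywhere: JoinMap's
  regression-mapping objective and goodness-of-fit "jump" are
  unpublished, so this package states its own objective precisely and
  tests against that.
* Ordering is two-point greedy with ripple, not multipoint
  hidden-Markov likelihood; for very tight marker clusters
  (< ~1 cM at n = 188) adjacent orders are statistically
  unidentifiable and the reported order within such clusters is
  arbitrary.
* Integration is anchor interpolation, not joint re-estimation; its
  accuracy degrades when anchor orders disagree strongly between
  parents.
* The LD scan reports association among gametes of one parent; it is
  family-based LD, not population LD.
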