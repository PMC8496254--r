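---
title: "Linkage mapping from capture genotyping: models and methods"
author: "mirrormap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linkage mapping from capture genotyping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirrormap)
```

This vignette is the package's account of the statistical machinery it
implements: the genetic model, the estimators, the numerical choices, and
what the simulation-based tests do and do not demonstrate about real
data.

## The genetic setting

The target experiment is an S1 population: a single heterozygous,
self-fertile diploid parent is selfed, and several hundred progeny are
genotyped at a few thousand SNPs that are heterozygous in the parent.
Genetically this is an F2 intercross: each progeny receives two
independent parental gametes, and at every marker the genotype classes
AA, AB, BB segregate 1:2:1. Meiosis is modelled without crossover
interference (the Haldane model): the number of crossovers on a
chromosome of genetic length $L$ cM is Poisson with mean $L/100$ and
crossover positions are uniform. Under this model the recombination
fraction $r$ between loci $d$ cM apart is $r = (1 - e^{-2d/100})/2$, and
conversely $d = -50 \ln(1 - 2r)$. All map estimation in the package uses
this function; interference models (e.g. Kosambi) are deliberately out of
scope because the pipeline's reference workflow maps with Haldane
distances.

## Genotype calling

Calls are made per (marker, individual) cell from the counts of the two
parental alleles plus other bases. The rules, with their default
thresholds:

* depth outside $[20, 1000]$ reads → `NA` (too little evidence, or a
  suspicious pile-up);
* minor parental fraction $< 5\%$ → homozygous for the major allele;
* both parental fractions $\ge 30\%$ → heterozygous;
* anything in between → `NA`.

Fractions are computed over parental reads only (`count_a + count_b`) by
default: error bases then cannot push a clean homozygote into the
intermediate zone. A `fraction_denominator = "total"` switch restores
total-depth denominators. Boundary semantics are strict for the 5% rule
and inclusive for the 30% and depth rules. A marker is kept only when at
least 80% of individuals have in-range depth; the source workflow states
this rule in two conflicting forms (a 20% floor in one place, an 80%
floor in the other), and the 80% reading is adopted because it matches
the high completeness of the retained marker set; it is configurable
(`marker_cov_fraction`).

## Quality filtering

The cascade runs individuals → markers → duplicate individuals → excess
heterozygosity → redundancy collapse, logging counts at each stage.
Noteworthy choices:

* *Duplicate individuals.* Pairs with $\ge 90\%$ genotype similarity
  (matching calls over markers typed in both) are flagged; the member
  with more missing data is removed, ties broken by removing the larger
  id. Greedy processing in order of decreasing similarity also resolves
  transitive clusters deterministically.
* *Redundant markers.* Two markers "match" when they agree at every
  individual typed in both — a deliberately weak relation (missingness
  can hide differences) that is not transitive, so matches are closed
  into groups by union-find. One marker per group is kept: fewest `NA`s,
  ties broken by the smallest id. The weak relation mirrors the
  `exact.only = FALSE` behaviour of the established tooling for this
  step.
* *Excess heterozygosity.* Markers with strictly more than 90%
  heterozygous calls are removed; such markers are overwhelmingly
  paralogous pile-ups rather than real loci. Distorted markers are
  otherwise retained — distortion is a finding, not an artifact, when it
  affects consecutive markers.
* The fixed 3500 typed-marker threshold for individuals can be replaced
  by a Tukey lower-fence scan (`typed_marker_outlier_threshold()`), since
  the original outlier procedure is not fully specified.

## Two-point analysis

For a marker pair with recombination fraction $r$, each gamete is
independently recombinant with probability $r$, which gives the joint
genotype table (coupling phase): corner cells $(1-r)^2/4$ (same
homozygote) and $r^2/4$ (opposite homozygotes), single-het cells
$r(1-r)/2$, and the double-het cell $((1-r)^2 + r^2)/2$. The MLE of $r$
is computed by EM with the number of recombinant gametes per individual
as missing data: same-corner pairs contribute 0 recombinant gametes,
single-het pairs exactly 1, opposite corners 2, and the double-het cell
the posterior mixture $2r^2/((1-r)^2+r^2)$; the M-step divides the
expected total by $2n$. The LOD score is
$\log_{10} L(\hat r) - \log_{10} L(0.5)$.

Estimates are clamped to $[0, 0.5]$. A pair that is really linked in
*repulsion* (phase-reversed) has its likelihood maximized above 0.5 and
is reported as 0.5 — by design: the mirror strategy (below) guarantees
that the complementary copy of one of the markers carries that linkage
instead. Pairs with fewer than 20 co-typed individuals are reported `NA`
(the threshold is configurable; the underlying workflow is silent on it,
and two-point estimates below that depth are too unstable to threshold
on). The all-pairs computation is exact and vectorized: the nine cell
counts for all pairs come from indicator-matrix cross-products, and the
EM fixed-point iteration runs element-wise on full matrices.

## Mirror-marker phasing

Capture genotypes of an S1 population are unphased: which homozygote is
labelled "A" at a marker is arbitrary. Two adjacent markers labelled in
opposite phase appear unlinked (their $\hat r$ clamps at 0.5), so naive
grouping shreds chromosomes. The fix: for every marker add an artificial
*mirror* marker with the complementary genotype (A↔B, H and `NA`
unchanged — e.g. observed calls `AAHB` give mirror `BBHA`), exactly
doubling the marker set. For any two markers on one chromosome, exactly
one of the four original/mirror combinations is phase-consistent, so
linkage groups formed on the augmented set at `max.rf = 0.05` **and**
`min.lod = 10` (the AND of the two conditions is the conservative reading
of the two named thresholds) appear in complementary pairs, one pair per
chromosome. `pair_mirror_groups()` verifies the pairing exactly — a group
whose mirror image is not itself a group is an orphan, and a group
containing a marker together with its own mirror is a hard
phase-inconsistency error.

One member of each pair is redundant. The reference procedure discards
one "arbitrarily"; for reproducibility `resolve_phase()` makes the choice
deterministic: the kept group is the one containing the un-mirrored copy
of the lexicographically smallest underlying marker id. Pairs with fewer
than 8 markers are dropped (the unlinked debris groups observed in
practice have at most 7), as are orphans; retained markers get their
original ids back, with the possibly-complemented calls now in one
consistent phase per linkage group. Phase is therefore recovered *up to
one global flip per chromosome* — an intrinsic ambiguity: nothing in the
data distinguishes a chromosome's two haplotypes.

## Marker ordering

Within a linkage group, ordering minimizes the total *obligate crossover*
count: per individual, the minimum number of recombination events
consistent with its ordered calls, computed by dynamic programming over
the four phased genotype states (ordered gamete-allele pairs), with
missing calls skipped — adjacent A↔B implies 2 events, A↔H or H↔B
implies 1.

The search has three layers:

1. `initial_order()` — greedy nearest-neighbour chain growth on the mean
   pairwise dose-difference distance, from a seeded random start.
2. `ripple_window()` — a window of 7 markers slides across the order and
   all $7! = 5040$ arrangements are scored; a minimal one is adopted,
   ties broken uniformly at random with the run's seeded RNG; passes
   repeat until no improvement. Window scoring is exact but incremental:
   only the window segment and each individual's nearest non-missing
   flanking calls can change, and individuals without missing data inside
   the window are scored in aggregate through precomputed pairwise
   dose-difference sums (the compiled kernel walks only the
   missing-data individuals per permutation). The window factorial is
   enumerated, so the window is capped at 8.
3. `order_markers()` — 9 independent seeded runs of (1)+(2); candidate
   orders, deduplicated up to reversal, are compared by the multipoint
   log10 likelihood and the best is kept. The reference workflow chose
   among repeated runs partly by visual heat-map inspection; that step is
   replaced by the likelihood criterion, with the pairwise rf/LOD table
   exported (`cmd_map()`) for optional human review.

Orientation of a finished order is arbitrary; it is normalized so the
majority scaffold's physical coordinates increase along the map when
metadata is available, otherwise so the lexicographically smaller marker
id comes first.

## Multipoint map estimation

`estimate_map()` fits interval recombination fractions by EM in a hidden
Markov model per individual: states are the true genotypes
$\{AA, AB, BB\}$ with the S1 prior $(\tfrac14, \tfrac12, \tfrac14)$;
the transition matrix across an interval with fraction $r$ comes from
independent recombination of the two gametes (e.g.
$AA \to AA: (1-r)^2$, $AA \to AB: 2r(1-r)$, $AA \to BB: r^2$,
$AB \to AB: (1-r)^2 + r^2$); the observed call equals the true genotype
with probability $1-\varepsilon$ and each other class with
$\varepsilon/2$ (default $\varepsilon = 10^{-4}$), and missing calls are
uninformative (emission 1, the standard treatment). Forward–backward
recursions with per-step scaling give expected recombinant-gamete counts
per interval (the double-het ambiguity reappears as the transition
$AB \to AB$, weighted $2r^2/((1-r)^2+r^2)$); the M-step divides by $2n$.
Convergence is $\max_k |\Delta r_k| < 10^{-9}$ or 500 iterations, with
intervals initialized from adjacent two-point estimates floored at
$10^{-4}$ (a hard zero cannot escape the M-step). Converged fractions map
to cM by the Haldane function and accumulate from 0. The per-individual
log10 likelihood sum is the order-comparison score; it is invariant under
order reversal, as is the map length.

## Diagnostics

* *Segregation distortion*: per-marker chi-square goodness of fit of the
  non-missing genotype counts against 1:2:1 (df = 2, no continuity
  correction — the standard three-class test). Flags use a Bonferroni
  threshold $\alpha / n_{\text{tests}}$ with $n_{\text{tests}}$ the
  mapped marker count. Distorted markers are flagged, never removed.
* *Crossover screen*: obligate crossovers summed over linkage groups per
  individual; under the meiosis model the expectation is $2L/100$ for a
  genome of total length $L$ cM. Individuals outside a configurable
  range are reported, not removed.
* *Marey comparison*: per linkage group, the majority scaffold, counts
  of markers from other scaffolds and unintegrated contigs, the absolute
  Spearman correlation between cM and bp among majority-scaffold markers,
  and the longest contiguous run of physical steps against the dominant
  direction (a candidate inversion). The reference workflow assessed
  inversions visually; the longest-discordant-run statistic is the
  package's mechanical stand-in.

## The simulator

`sim_config()` defaults define the emulated study: 12 chromosomes with
the published linkage-group genetic lengths (87.65 … 86.14 cM, 942.2 cM
in total), $n = 415$ selfed individuals, mean coverage 96 reads per cell,
3% missing data, sequencing error $10^{-3}$.

Choices worth knowing:

* *Coverage* is negative-binomial with size $\mu/2$, i.e. variance
  $\approx 3\mu$ — a long right tail like real capture data; the exact
  tail shape of real experiments is not modelled.
* *Read emission*: per cell, error ("other") bases are
  $\mathrm{Bin}(\text{depth}, e)$ and the remaining parental reads split
  with A-read probability $1-e$, $\tfrac12$, $e$ for true genotypes AA,
  AB, BB. This keeps `count_a + count_b + count_other = depth` exact and
  equals the simpler "allele-1 $\sim$ Bin(depth, p)" description to
  first order in $e$.
* *Phase* is randomized per marker, so downstream phasing is a genuine
  inference problem; `truth_phased_geno()` returns the haplotype-
  coordinate matrix that a perfect phasing step would recover, for
  truth-based evaluation of ordering and map estimation.
* *Physical coordinates* come from a monotone cM→bp map mixing a linear
  term with a steep central logistic component, giving each chromosome a
  recombination coldspot (large physical span per cM) like a real
  Marey sigmoid; slope parameters are configurable.
* *Selection* is rejection sampling at a chosen locus: zygotic (reject
  zygotes of a disfavored homozygous genotype), gametic in one gamete
  draw (one-sex), or in both. Strength is the survival probability of
  the disfavored class; rejection loops are capped at 10,000 attempts.
  Zygotic selection against AA leaves AB:BB near 2:1; one-sex gametic
  selection against A leaves AB:BB near 1:1 — the two signatures that
  motivate the distortion diagnostics. The simulator supports both and
  does not adjudicate between them for any observed pattern.
* *Seeding*: one master seed; per-individual streams are drawn as a
  prefix-stable sequence, so growing the population leaves earlier
  individuals identical, and read-count streams use a fixed offset of
  the master seed so they are unrelated to the meiosis streams.

What passing simulation tests shows — and what it does not: the
simulator emulates Mendelian segregation, Haldane meiosis, overdispersed
coverage, random missingness and simple selection. It does not emulate
alignment artifacts, paralogy, copy-number variation, batch effects in
coverage, or genotyping errors correlated across individuals, so the
pipeline's recovery rates on simulation are an upper bound on real-data
performance; the diagnostics (distortion, crossover counts, Marey
collinearity) are exactly the tools for noticing those real-data
pathologies.

## Problem sizes and numerical notes

The test suite and the acceptance script size their simulations as: 12
chromosomes × 50 markers at $n = 415$ for the grouping recovery; 20
replicates of one 100 cM, 50-marker chromosome at $n = 415$ for length
and order recovery; exhaustive crossover-oracle checks to sequence
length 6 over all four call symbols (plus length 7 over complete calls
and random spot checks at 7–8). Two-point EM iterates the scalar fixed
point to $|\Delta r| < 10^{-12}$; the vectorized all-pairs version uses
the same tolerance on the max over pairs. LOD terms treat
$0 \cdot \log 0$ as 0. Writers emit numbers at 6 significant digits with
stable ordering, so identical inputs give byte-identical files.

## Known limitations

* Diploid, selfed/intercross populations only; no outbred or polyploid
  configurations.
* Haldane map function only; no interference.
* The redundancy "match" relation is closed by union-find, which can, in
  principle, chain non-identical markers through a poorly-typed
  intermediate; the established tooling for this step has the same
  property.
* The sliding-window search is local; a chromosome fragmented by severe
  distortion or missingness may need the grouping thresholds relaxed
  before ordering can see it as one group.
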