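---
title: "Microsatellite diversity, F-statistics, and UPGMA clustering with ssrpop"
author: "ssrpop authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microsatellite diversity, F-statistics, and UPGMA clustering with ssrpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrpop)
```

## The problem

Microsatellites (SSRs) are short tandem repeats whose length-polymorphic
alleles, scored as fragment sizes, remain the workhorse codominant marker for
surveying genetic diversity in wild plant populations. A typical conservation
survey genotypes a few dozen individuals from several small populations at
10–20 SSR loci, and asks three questions: how much diversity does each
population hold, how strongly are populations differentiated (and how much
migration does that imply), and how do populations group genetically.
`ssrpop` implements that full workflow — diversity indices, hierarchical
F-statistics with gene-flow estimates, Nei's unbiased genetic distance, and
UPGMA dendrograms — on a single validated genotype container, together with a
population-genetic simulator that makes every stage testable against known
truth.

The motivating use case is a survey of wild apricot (*Prunus armeniaca*)
stands in mountain gorges: 54 trees in 11 populations of 1–18 individuals
each, genotyped at 13 SSR loci, with populations nested in three gorges. The
package's defaults and report layouts follow that design, but nothing in the
methods is specific to it.

## Data model

A `genotype_matrix` stores, for every individual and locus, an unordered pair
of integer allele labels, with `NA` (or `0` on disk) marking a missing call.
Two invariants are enforced at construction: every individual belongs to
exactly one population, and a call is either complete or wholly missing.
Half-calls are rejected rather than silently coerced, because a one-allele
call is a genotyping error that should surface, not vanish. Alleles are
compared as opaque integer labels; fragment-size binning belongs upstream of
this package. Population order is first appearance in the input and locus
order is column order; every report preserves these orders.

Input formats are the GenAlEx-dialect CSV (three header rows: counts and
population sizes, titles, column names; two allele columns per locus) and a
long TSV with one row per (sample, locus) call. Both have writers, and
read–write round trips are identity maps (tested property).

## Diversity indices

All within-population indices are functions of the within-population allele
frequencies $p_i$ at a locus, estimated from the $2N_l$ gene copies of the
$N_l$ individuals with non-missing calls there:

* $N_a$ — observed allele count; $N_e = 1/\sum_i p_i^2$ — effective allele
  count (the count of an equally-frequent locus with the same homozygosity).
* $I = -\sum_i p_i \ln p_i$ — Shannon information index, natural log.
* $H_o$ — observed heterozygote fraction; $H_e = 1 - \sum_i p_i^2$ —
  expected heterozygosity under random mating;
  $uH_e = \frac{2N_l}{2N_l - 1} H_e$ — its small-sample-unbiased version.
* $F = (H_e - H_o)/H_e$ — fixation index; positive for heterozygote
  deficit, negative for excess, undefined (0/0) at a fixed locus.

These always satisfy the Hill-number ordering $N_e \le e^I \le N_a$, which
the test suite asserts over hundreds of random datasets.

Per-population summaries are unweighted means across loci, plus the percent
of polymorphic loci $\%P = 100 \cdot \#\{N_a \ge 2\}/L$ over all $L$ loci.
Mean $F$ averages only loci where $F$ is defined; treating fixed loci as
$F = 0$ would bias the mean toward zero, and exclusion also matches how the
widely used GenAlEx reports behave. The same exclusion rule applies when
grand means are taken over populations. Realized per-locus sample sizes
($N_l$, not the nominal population size) enter $H_o$ and $uH_e$, since the
unbiased estimator needs the sample size actually observed.

A worked consequence of these formulas, used throughout the tests: a single
individual heterozygous at 11 of 13 loci has
$N_a = N_e = 24/13 \approx 1.846$, $I = 11\ln 2/13 \approx 0.587$,
$H_o = 11/13 \approx 0.846$, $H_e = 5.5/13 \approx 0.423$,
$uH_e = 11/13$, and $\%P = 1100/13 \approx 84.62$.

```{r fixture}
population_summary(make_single_individual_fixture(13, 11), "Pop1")
```

Note that at every heterozygous locus of such an individual $F = -1$
(observed heterozygosity 1 against expected 0.5); the sign is occasionally
flipped in published tables, but it follows directly from the definition.

## F-statistics and gene flow

Among-population structure uses the gene-diversity (heterozygosity-based)
formulation with *unweighted* population means, the convention of
GenAlEx-style SSR reports. Per locus, over the populations with data:

$$H_i = \overline{H_o}, \qquad H_s = \overline{H_e}, \qquad
  H_t = 1 - \sum_i \bar p_i^2,$$

with $\bar p_i$ the unweighted mean of per-population frequencies, and

$$F_{is} = \frac{H_s - H_i}{H_s}, \quad
  F_{it} = \frac{H_t - H_i}{H_t}, \quad
  F_{st} = \frac{H_t - H_s}{H_t}, \quad
  N_m = \frac{1 - F_{st}}{4 F_{st}}.$$

No small-sample correction is applied to $H_s$ or $H_t$: the uncorrected
estimator keeps the partition identity
$(1 - F_{it}) = (1 - F_{is})(1 - F_{st})$ exact (asserted to $10^{-9}$ in the
tests) and matches the convention of the report format this package mirrors.
$N_m$ is the classical island-model migrant estimate; $N_m > 1$ is the usual
threshold above which migration overcomes drift. The table-level summary
reports per-locus rows plus unweighted column means and standard errors
(sample SD / $\sqrt{L}$), excluding undefined cells with a warning.

## Nei's unbiased genetic distance

Between populations $X$ and $Y$, per locus with frequencies $x_i$, $y_i$ and
sample sizes $N_x$, $N_y$:

$$J_{xy} = \sum_i x_i y_i, \qquad
  \hat J_x = \frac{2N_x \sum_i x_i^2 - 1}{2N_x - 1},$$

and after arithmetic averaging over the loci genotyped in both populations,

$$D = -\ln \frac{\bar J_{xy}}{\sqrt{\bar J_x \, \bar J_y}}.$$

Three numerical edge cases are handled explicitly:

* the unbiased correction can make $D$ slightly negative for very similar
  populations — such values are clamped to 0 with a warning, since the
  downstream clustering needs a dissimilarity;
* zero shared identity gives $D = \infty$; the written matrix preserves the
  `Inf`, while clustering replaces it by ten times the largest finite entry
  so the agglomeration stays defined without hiding the singularity;
* a single fully heterozygous individual has unbiased identity 0 — if a
  population's mean identity is non-positive the distance is undefined and
  an error names the populations involved.

Loci are excluded pairwise (a locus missing in one pair of populations is
still used for other pairs), maximizing data use.

## UPGMA and tree outputs

The distance matrix is clustered by true average linkage: merge the closest
pair at height $d_{\min}/2$, then update distances by the cluster-size
weighted mean. Ties on $d_{\min}$ are broken by the lexicographically
smallest pair of contained leaf labels, making the merge order (and thus all
outputs) platform-independent. Merge heights are provably non-decreasing and
the output cophenetic matrix is ultrametric; both are asserted in tests, and
the whole implementation is checked against an independent average-linkage
agglomeration (`stats::hclust`) on 100 random matrices plus exactness on
ultrametric inputs.

Trees serialize to Newick with branch lengths equal to height differences
(leaf-to-root depth = root height), subtrees ordered by smallest contained
label, and single-quoting of labels with unsafe characters. `cluster_membership(tree, k)`
cuts the tree by undoing the last $k-1$ merges; equal-height ties at the cut
are resolved by the deterministic merge order, with a warning.

## The simulator: what it emulates and what it does not

`simulate_genotypes()` implements the Balding–Nichols model: ancestral
frequencies per locus from a symmetric Dirichlet(1), population frequencies
from a Dirichlet with mean equal to the ancestral vector and concentration
$(1-\theta)/\theta$, so $\theta$ is directly the expected $F_{st}$.
Genotypes are drawn with an inbreeding parameter $f$:
$P(A_iA_i) = p_i^2 + f p_i(1-p_i)$ and $P(A_iA_j) = 2p_ip_j(1-f)$. These sum
to one for any $f$; for negative $f$ (heterozygote excess) rare-homozygote
probabilities can go negative and are clipped and renormalized, with a
warning. Missing calls are masked independently. The generator is
bit-reproducible from its seed and restores the caller's RNG state.

Defaults are fixed to the motivating survey's design: 11 populations of
sizes 3, 18, 1, 6, 5, 1, 3, 6, 3, 4, 4 (54 individuals), 13 loci,
$\theta = 0.22$. The two parameters that design does not pin down — the
ancestral allele count and $f$ — were calibrated once, before the test
expectations were frozen, so that a default run reproduces the surveyed
regime: 16 ancestral alleles and $f = -0.05$ give a realized allele count of
about 5.9 in the largest (N = 18) population, a grand mean of ~3.6 alleles
per locus, mean $H_o \approx 0.75 > H_e \approx 0.58$, and a mean fixation
index near $-0.33$ — the magnitudes reported for the real stands. Note the
population-level $F$ estimate is substantially more negative than the
genotype-level $f$ because small samples underestimate $H_e$; the
calibration accounts for that.

`make_gorge_scenario()` nests the 11 populations in three gorges
(populations 1–4, 5–7 with 11, and 8–10) by a two-level Balding–Nichols
cascade: gorges diverge from a common ancestor at $\theta = 0.25$ and
populations from their gorge at $\theta = 0.05$. Between-gorge divergence
then dominates, and cutting the UPGMA tree at $k = 3$ recovers the gorges in
at least 9 of 10 seeds (tested).

The simulator emulates drift-driven differentiation, inbreeding/outbreeding,
and missingness. It does **not** emulate stepwise mutation (allele identities
are abstract), linkage between loci, spatial continua, null alleles, or
scoring error — so passing tests demonstrate correctness of the estimators
under the stated model, not robustness to those artifacts in real data.

## Problem sizes and runtime choices

The test suite runs its statistical checks at deliberately modest sizes —
10-seed recovery runs at 11 populations × 20 individuals × 13 loci for
$F_{st}$, the 54-individual gorge scenario for cluster recovery, 100–200
random instances for the property suites — sizes at which the Monte-Carlo
tolerances quoted above (±0.05 on $F_{st}$ and $F$) are comfortably met and
the whole suite completes in well under a minute. All simulation-based
checks use fixed seeds.

## Known limitations

* Rarefied allelic richness, private alleles, HWE exact tests, AMOVA
  variance components, pairwise-population $F_{st}$, and bootstrap support
  on the dendrogram are out of scope.
* The gene-diversity $F_{st}$ with unweighted means is not the
  Weir–Cockerham $\theta$ estimator; with very unequal sample sizes the two
  can differ noticeably.
* Nei's unbiased distance is unstable for $N = 1$ populations (see the
  degenerate-identity error above); singleton populations are usable but
  their distances carry large sampling noise.
* The NDVI helper is band arithmetic only: `(NIR - RED) / (NIR + RED)` on
  co-registered arrays with masking of zero-signal pixels. Georeferencing,
  multispectral file I/O, and orthophoto workflows are not provided.
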