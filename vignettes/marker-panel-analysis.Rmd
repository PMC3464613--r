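---
title: "Population structure, diversity and LD in dominant marker panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population structure, diversity and LD in dominant marker panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dartpop)
```

## The data model

`dartpop` analyses panels of biallelic **dominant** markers — hybridisation
presence/absence assays such as DArT — scored 0/1 on **fully inbred lines**.
Two modelling commitments follow and run through every statistic:

1. *Lines are haplotypes.* An inbred line is homozygous, and a dominant
   assay cannot distinguish heterozygotes anyway, so a line contributes a
   single allele per locus. LD statistics are therefore computed directly
   on the 0/1 calls without a genotype-phase model, and the allele
   frequency of a marker is simply the mean of its non-missing calls.
2. *Missingness is handled by pairwise deletion.* Every pairwise statistic
   (similarity, distance, r², Fisher table) uses the loci — or lines —
   where both members of the pair are observed, so denominators vary per
   pair. This is the standard choice for marker panels; its cost is that
   distance matrices can become slightly non-Euclidean (see PCoA below).

A `genetic_map` assigns each marker a linkage group and a cM position.
Split linkage groups (`2R-1`, `2R-2`) are treated as *distinct* groups for
every distance computation: no cM distance is defined across the split,
and pairs across it count as unlinked. Genome labels (A/B/R for a
wheat–rye amphiploid) are derived from the trailing letter of the linkage
group name after stripping a `-<number>` suffix.

## Structure statistics

For lines $i,j$ with $m_{ij}$ pairwise-complete loci and $H_{ij}$
disagreements, the simple-matching similarity is
$S_{ij} = 1 - H_{ij}/m_{ij}$ and the modified Rogers' distance reduces to
$\mathrm{MRD}_{ij} = \sqrt{H_{ij}/m_{ij}}$, so $\mathrm{MRD}^2 = 1 - S$
exactly on complete data — an identity the test suite checks exhaustively,
with both sides computed by independent code paths.

Principal coordinate analysis is classical metric scaling: eigendecompose
the double-centred $-\tfrac12 D^2$, scale eigenvector $j$ by
$\sqrt{\lambda_j}$. Numerical conventions:

* per-axis % variance uses the sum of **positive** eigenvalues as the
  denominator (Gower's convention); negative eigenvalues — possible for
  MRD under pairwise deletion — are returned separately, never silently
  folded in;
* each axis is oriented so its largest-magnitude coordinate is positive,
  making output reproducible across BLAS/eigensolver sign choices;
* missing distances are an error, not an imputation: the fix belongs
  upstream (pairwise-deletion policy), not inside the eigensolver.

Axis density summaries use a Gaussian kernel with Silverman's
rule-of-thumb bandwidth (the `bw` argument is a knob; the summary is
descriptive, any standard choice is acceptable). An axis is flagged
bimodal when its KDE has at least two local maxima above 5% of the global
maximum — a cheap, deterministic surrogate for "distribution indicative
of population structure".

## Diversity

PIC for a biallelic locus is $1-(p^2+q^2)$: 0 at fixation, 0.5 at equal
frequencies. Group-wise summaries **recompute allele frequencies within
the group's own lines**; without this, subpopulation rows could never
differ from the pooled row. Markers monomorphic *within the evaluated
line set* are excluded from means by default (they would deflate them,
and whether to count them is a reporting policy, not a fact about the
data); `include_monomorphic = TRUE` keeps them at PIC 0. One visible
consequence: a narrow subpopulation has more within-group-monomorphic
markers, so under the default policy its mean over *polymorphic* markers
can exceed the pooled mean even though its overall diversity is lower —
compare both policies when reading group tables.

Sliding-window profiles evaluate a mean or median at `n_positions = 500`
equally spaced grid points spanning the observed marker positions of each
linkage group, with a window of **total width** `window_cm = 5` (markers
within ±2.5 cM). "Window = 5 cM" is read as total width, the conventional
reading; it is configurable. Empty windows yield `NA` rather than an
interpolated value. Note the endpoint geometry: a window equal to the
chromosome span does *not* reproduce the chromosome mean at the ends —
that requires width ≥ twice the span.

## Divergence scan

The per-locus distance between two subpopulations defaults to the
single-locus modified Rogers' distance
$\sqrt{((p_1-p_2)^2+(q_1-q_2)^2)/2} = |p_1-p_2|$, chosen because it is
the per-locus analogue of the line-level distance already in use; an
FST-like $(p_1-p_2)^2/(2\bar p\bar q)$ alternative is available and the
metric is pluggable, since per-locus "genetic distance" has no single
field-wide definition.

Regions are flagged where the windowed mean exceeds a cutoff. The default
cutoff is the 95th percentile of the **scan maximum** under label
permutations (200 permutations, seeded). The maximum — rather than the
pooled distribution of all windowed values — is deliberate: with ~500
grid points per linkage group, a pointwise 95% cutoff is exceeded
somewhere in essentially every null dataset, while the max-based cutoff
gives family-wise control: a null scan stays entirely below it with
probability ≈ 0.95. The pointwise variant remains available
(`null = "pointwise"`) for exploratory use. Runs separated by a single
below-cutoff grid point are merged; separations of two or more points
split regions.

The permutation null accounts for sampling noise, **not** for founder
drift: if two subpopulations were founded from independently drawn
founder pools, genuine genome-wide frequency differences exist and will
be flagged. That is a property of the populations, not an error of the
scan — but it is why the simulator shares founder pools by default (below).

## Linkage disequilibrium

$r^2 = D^2/(p_Aq_Ap_Bq_B)$ with $D = p_{AB} - p_Ap_B$, computed on
pairwise-complete lines; it equals the squared Pearson correlation of the
two binary vectors, which is how the vectorised all-pairs path computes
it (cross-products of the call and observation-mask matrices). Pairs
monomorphic on their shared lines have undefined r² and are excluded
downstream. No MAF filter is applied by default; a minimum of 2 shared
lines guards the degenerate cases.

Fisher's exact test is implemented by hypergeometric enumeration
(two-sided: sum of outcome probabilities ≤ the observed, with a 1e-7
relative tie tolerance, matching `stats::fisher.test`); degenerate tables
return p = 1. Because the ~10⁶ *unlinked* pairs feed only the threshold
quantile, exact p-values are attached to linked pairs by default
(`fisher = "all"` computes every pair). A Bonferroni column over all
pairs is emitted for convenience; no correction is otherwise applied.

The population-specific threshold $t^*$ is the 95% quantile
(type-7, linear interpolation — fixed for reproducibility) of unlinked-pair
r². The decay curve is `stats::loess` (tricube weights, degree 1 — local
linear regression) of r² on cM distance, span 0.33 by default; the span
is a top-level knob and **every reported extent states its span**, since
the literature rarely fixes one. Fits use `surface = "direct"` up to
1,000 pairs (exactness matters in tests) and the interpolation surface
beyond (speed matters at panel scale); fitted values are clipped to
[0, 1] and evaluated on a 0-to-max-distance grid. The LD extent is the
first grid crossing of the curve below $t^*$, linearly interpolated;
curves starting below $t^*$ have extent 0 and curves never crossing are
censored at the maximum observed distance, with an explicit flag.
"Close-range LD" is reported two ways: the curve value at the smallest
observed linked distance, and the plain mean of r² in the 0–1 cM bin.
Genome-level curves pool linked pairs by the genome of their linkage
group; cross-genome pairs are by construction unlinked.

## The synthetic world

`simulate_panel()` generates two subpopulations over a configurable map.
Founder allele frequencies are Uniform(0.1, 0.9) (avoids near-fixed
markers dominating); each subpopulation has $F$ founder haplotypes, and a
line is a founder mosaic: crossover breakpoints follow a Poisson process
with rate $G$ per Morgan, with the founder re-drawn uniformly at each
breakpoint. This generates LD *mechanistically*: markers within a founder
segment are correlated through founder identity (same-segment r² scales
like $1/(F-1)$), and segments shorten as $G$ grows, producing the
cM-dependent decay the loess stage must detect. Planted divergence
regions redraw the second subpopulation's founder alleles from
frequencies shifted by `delta_p` (direction chosen to stay in [0, 1];
infeasible shifts are an error). Missing calls are masked uniformly at
2% by default, typical of DArT panels.

Defaults, chosen once as a realistic stated world: 50 + 50 lines, three
100 cM linkage groups (one per genome) of 120 markers, founders 8
(winter-like) vs 4 (spring-like) — giving adjacent-marker r² near 0.15
vs 0.35 and the higher within-group similarity in the narrower pool, the
published growth-habit contrast — and $G = 8$ generations. The
`paper_preset()` configuration scales this to 22 linkage groups, 2,079
markers split 306/502/1,271 over A/B/R and 74 + 81 lines for
realistic-scale smoke tests.

`share_founders = TRUE` (default) draws one founder pool and nests the
smaller subpopulation's founders inside it, as when both breeding groups
trace to common primary founders; only then is a label-permutation null
for the divergence scan well calibrated. `share_founders = FALSE` draws
independent pools from the same frequencies, adding genome-wide founder
drift — that is the "two well-separated clusters" world (PCo1 then
separates the groups nearly perfectly) but any divergence scan on it
flags drift everywhere, correctly.

What the generator does **not** emulate: ascertainment bias of array
markers, non-uniform marker spacing beyond uniform placement, linkage-map
error, family pedigree structure within subpopulations, and
habit-correlated missingness. A green recovery test therefore establishes
that the statistics recover the generative truth of *this* world, not
that field data meet the model's assumptions.

## What the tests establish

* Analytic identities (MRD² + S = 1; r² against a brute-force
  D²/(pq·pq) oracle; Fisher p against full margin enumeration) hold
  exhaustively at small size and to 1e-12.
* PCoA agrees with `stats::cmdscale` as an independent oracle and
  recovers Euclidean configurations to machine precision.
* On seeded synthetic panels: per-marker allele frequencies and PIC match
  the founder-pool truth within binomial error; planted divergence
  regions are recovered (interval Jaccard > 0.5 against the union of
  flagged intervals, which may split across marker-sparse dips) in 10/10
  seeds; LD extent decreases monotonically in $G$ over {1, 2, 4, 8, 16}
  (mean Spearman ρ < −0.8 over 10 seeds); and the fewer-founder
  subpopulation shows the higher similarity and adjacent LD in 10/10
  seeds.
* The realistic-scale preset runs all stages end-to-end in well under its
  budget, with the linked/unlinked partition checked against an
  enumeration oracle.

## Known limitations

* No VCF/PLINK import: dominant presence/absence calls on inbreds do not
  map cleanly onto diploid genotype formats. TSV/CSV only.
* The LD extent depends visibly on the loess span; comparisons across
  panels are only meaningful at a common, stated span.
* Fisher p-values on ~10⁶ unlinked pairs are opt-in for runtime reasons.
* The divergence cutoff assumes exchangeable lines under the null;
  pedigree structure within groups makes it anti-conservative.
* `pcoa()` requires a complete distance matrix; pairs with no shared loci
  must be resolved upstream.
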