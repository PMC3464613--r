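# dartpop

Population structure, genetic diversity and linkage disequilibrium (LD)
analysis for panels of **biallelic dominant markers** (presence/absence
scores, e.g. DArT) genotyped on fully inbred lines with a genetic map.

The package targets the standard pre-association-mapping workup of a crop
breeding panel: how is the panel structured, where along the genome is
diversity depleted, which regions differ between subpopulations under
divergent selection, and over what map distance does marker–marker LD
persist. It was built around the worked case of a triticale
(× *Triticosecale* Wittmack) collection of winter- and spring-habit lines,
but applies to any 0/1 inbred-line marker panel with linkage-group/cM
positions.

## What it computes

With lines treated as haplotypes (dominant markers on homozygous lines
admit no heterozygous call):

- **Relatedness / structure** — simple-matching similarity
  S<sub>ij</sub> = (# agreeing loci)/(# pairwise-complete loci), the
  modified Rogers' distance, which for this data reduces to
  MRD<sub>ij</sub> = √(1 − S<sub>ij</sub>), and principal coordinate
  analysis (classical scaling of MRD) with per-axis % variance, axis
  density summaries (violin-plot view) and within-group similarity means.
- **Diversity** — allele frequency p per marker and the polymorphic
  information content PIC = 1 − (p² + q²) ∈ [0, 0.5], summarised per
  chromosome / genome / subpopulation and profiled along chromosomes with
  a sliding window (default 5 cM window at 500 positions per linkage
  group).
- **Divergence scan** — per-locus genetic distance between two
  subpopulations (default single-locus modified Rogers' distance, |p₁ −
  p₂| for biallelic loci), its windowed mean along chromosomes, and
  contiguous regions above a label-permutation cutoff.
- **LD** — pairwise r² = D²/(p<sub>A</sub>q<sub>A</sub>p<sub>B</sub>q<sub>B</sub>)
  with D = p<sub>AB</sub> − p<sub>A</sub>p<sub>B</sub> (the squared
  allele-frequency correlation), Fisher's exact tests of association, the
  population-specific significance threshold t* = 95% quantile of r² over
  **unlinked** marker pairs (different linkage groups), a loess decay
  curve of r² against cM distance (tricube, degree 1), and the **LD
  extent**: the distance where the curve first crosses t*. Plus
  adjacent-marker LD and its windowed median along chromosomes.
- **Synthetic panels** — a founder-mosaic simulator (Poisson crossovers at
  rate G per Morgan over F founder haplotypes per subpopulation, planted
  divergence regions, missingness) with machine-readable ground truth, so
  the whole pipeline is testable without external data.

## Worked example

```r
library(dartpop)

sim <- simulate_panel(sim_config(seed = 42))     # two subpopulations
ds  <- align_markers(sim$genotypes, sim$map)
ds
#> aligned_dataset: 100 lines x 360 mapped markers, 3 linkage groups
#> genomes: A=120 B=120 R=120

gs <- group_similarity_summary(simple_matching(ds), ds$habit)
gs$means
#>    group n_lines n_pairs mean_similarity
#> 1    all     100    4950           0.660
#> 2 winter      50    1225           0.654
#> 3 spring      50    1225           0.692

la <- ld_analysis(ds, fisher = "none", n_positions = 100)
la
#> ld_analysis: threshold (level 0.95) = 0.0452 over 43200 unlinked pairs
#>   A: close-range r2 0.128, extent 11.3 cM (span 0.33, 5565 pairs)
#>   B: close-range r2 0.136, extent 11.2 cM (span 0.33, 5356 pairs)
#>   R: close-range r2 0.135, extent 11.5 cM (span 0.33, 5995 pairs)
#>   ABR: close-range r2 0.133, extent 11.3 cM (span 0.33, 16916 pairs)
#>   adjacent-marker mean r2: 0.146
```

Reading the output: 95% of unlinked marker pairs have r² below 0.045, so
r² above that threshold is attributed to linkage; the fitted decay curve
starts near 0.13 for closely linked markers and falls below the threshold
about 11 cM out — the range over which association signals can be tagged
by a marker in this panel. The spring-like subpopulation (simulated from
the narrower founder pool) shows the higher within-group similarity
(0.692 vs 0.654), the contrast typical of growth-habit subpopulations.

## Command line

```sh
exec/dartpop simulate  --out-dir data --seed 1
exec/dartpop all --genotypes data/simulate.genotypes.tsv \
    --map data/simulate.map.tsv --groups data/simulate.groups.tsv \
    --out-dir results
```

Subcommands `simulate`, `structure`, `diversity`, `divergence`, `ld`,
`all`; every output is a TSV named `<stage>.<name>.tsv` whose commented
header records the resolved parameters.

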