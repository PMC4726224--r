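# stexpat

Recurrent spatial-temporal expression patterns on the developing-brain
grid.

`stexpat` is for researchers mining in situ hybridization (ISH) energy
data of the developing mouse brain — per-gene expression energies averaged
over anatomical substructures that flatten onto a rectangular grid of 20
anterior–posterior segments × 4 dorsal–ventral layers (80 blocks), across
the seven stages E11.5, E13.5, E15.5, E18.5, P4, P14 and P28. The usual
gene-centric or region-centric views miss that such a field `E_g(x, y, t)`
is a superposition of patterns; `stexpat` decomposes it while keeping the
spatial dependency explicit:

1. **Demarcation.** For each gene and stage, the binarization threshold θ
   is swept over the sorted distinct energies; each maximal run of values
   with a constant connected-component count is a *component structure*
   with a *valid interval*. The structure with the longest interval
   (length counted in distinct values, lower bound held at or above the
   floor 0.2) is selected, and the slice is binarized at its lower bound
   — or its upper bound for the smallest high-expression cores. Being
   rank-based, the procedure is invariant under any increasing transform
   of the energies.
2. **Global states.** A gene is globally expressed at a stage when the
   largest expressed component covers more than half of the substructures
   with valid data — a rule backed by a random-matrix null in which
   independently activated cells essentially never produce such a
   component. The seven calls form a 7-bit state vector `G(g)`, and
   states are ranked by gene count.
3. **Local patterns.** Components from non-global slices are pooled,
   filtered (≥ 2 cells, ≤ half the valid cells), connected into a Jaccard
   overlap graph (edge iff overlap ≥ 0.5), and its connected components
   become recurrent patterns, summarized by occurrence/gene counts and
   per-cell frequency maps.

Downstream: hypergeometric gene-set enrichment with Benjamini–Hochberg
correction, temporal occurrence distributions of regional pattern groups,
co-expression group selection against a reference profile with a
two-sample Kolmogorov–Smirnov comparison, and a seeded synthetic-field
generator with planted ground truth for end-to-end validation.

## Worked example

Simulate a field with planted structure, run the pipeline, and score the
recovery:

```r
library(stexpat)

spec <- grid_spec()
spec
#> grid_spec: 20 AP segments x 4 DV layers = 80 blocks
#>   connectivity: 4-neighbor; severed interfaces: 2

sim <- generate_field(synthetic_config(seed = 11), spec)
sim$field
#> expression_field: 45 genes x 7 time points on a 20x4 grid
#>   observed entries: 23572 of 25200

qf       <- demarcate_field(sim$field)       # threshold sweep per slice
states   <- global_state_table(qf)           # 7-bit vectors per gene
patterns <- find_patterns(qf, min_members = 5)

head(rank_states(states), 4)
#>     state gene_count
#> 1 0000000         40
#> 2 0001101          1
#> 3 0010100          1
#> 4 0011011          1

patterns[[1]]
#> pattern_cluster 1: 22 occurrences in 12 genes; support cells: 12

evaluate_recovery(sim$truth, states, patterns)[
  c("state_recovery", "global_gene_recovery", "mean_pattern_jaccard")]
#> $state_recovery        [1] 1
#> $global_gene_recovery  [1] 1
#> $mean_pattern_jaccard  [1] 0.969697
```

The ranking shows the 40 non-global genes (pattern carriers and
background) at the all-zeros state and the five planted global genes on
their own vectors; the top recovered pattern collects 22 occurrences —
one planted 10-carrier × 2-stage pattern plus two spurious overlapping
members — on a 12-cell support. All five global vectors and (here) 97%
of pattern memberships are recovered despite 2% energy jitter, 5% bright
flips and the missing-data model.

Published global-state rankings can be interrogated directly. With the
shipped 29-row ranking of the 1826-gene atlas analysis:

```r
r <- aba_state_ranking()
count_rank_window(r, 3, 12, "E11.5", 0L)
#> [1] 10
```

i.e. all ten states ranked 3–12 are silent brain-wide at E11.5.

Real data enter through a flat TSV (`gene, timepoint, ap, dv, energy`)
via `read_energy_table()` / `filter_genes()`; `inst/cli/stexpat.R` wraps
the pipeline as a command line (`simulate`, `quantize`, `states`,
`states-null`, `patterns`, `coupling`, `enrich`).

## Scope

The package models the grid topologically: no 3-D geometry, no voxel
processing, no image registration, and no comparison of continuous
energies across stages (only the quantized expressed/unexpressed calls
are tracked over development). See the methods vignette
(`vignettes/stexpat-methods.Rmd`) for the model, parameter defaults, the
synthetic generator's assumptions, and known limitations.
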