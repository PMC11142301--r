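# modpres

Co-expression module detection and preservation analysis for single-cell
RNA-seq.

## What it is for

When a single-cell cohort spans two biological conditions — early versus
late tumor stages, right versus left colon, treated versus control — a
natural question is structural: which gene co-expression modules of the
reference condition survive in the test condition, and how does the
wiring of the ones that do not survive change? modpres implements that
analysis end to end for cell-by-gene count matrices with per-cell group
labels:

1. **QC and normalization** — cells dropped for >15% mitochondrial
   reads, <300 UMIs, <500 genes, or complexity
   `log10(genes)/log10(UMIs)` < 0.70; genes seen in <10 cells dropped;
   `ln(1 + 1e4 * x / total)` normalization.
2. **Dimension reduction** — top-fraction variable genes
   (trend-standardized variance on counts), scaling, PCA, and a
   two-criterion rule for the number of informative components; SNN +
   Louvain clustering and marker-based assignment of seven major cell
   types when labels are not supplied.
3. **Down-sampling** — every group reduced to the base group's total by
   largest-remainder quotas that preserve each group's cell-type ratios,
   with a deterministic farthest-point (space-filling) sampler on PCA
   coordinates.
4. **Reference network** — soft-thresholded adjacency `|cor|^beta`
   (beta by scale-free fit or the conventional 6), topological overlap,
   and module detection by an average-linkage tree cut with kME
   membership refinement and eigengene merging; labels in ascending size
   order, unassigned genes grey.
5. **Preservation** — four density and three connectivity statistics of
   each reference module in the test network, permutation Z-scores
   (`Zsummary`), and observed-statistic median ranks; a module is
   flagged non-preserved when its median rank is at least 10 and its
   size at most 100 genes.
6. **Sub-network comparison** — for flagged modules (plus the most
   preserved one): module-dominated cell selection per condition,
   per-condition adjacency, top-10% unique edges, node connectivities
   and their Spearman rho (`1 - 6*sum(d^2)/(n(n^2-1))` when tie-free),
   per-gene two-sample z-scores
   `(mean_test - mean_ref)/sqrt(s2_t/n_t + s2_r/n_r)` colored
   blue-white-red clamped at ±2, circle plots, and a local
   hypergeometric over-representation test against GMT gene sets.

A synthetic-data generator (`synth_config()`, `generate_dataset()`)
plants cell types, markers, mitochondrial genes, and co-expression
modules whose preservation between the two conditions is controlled,
giving every stage a ground truth to be tested against. See the methods
vignette (`vignettes/module-preservation.Rmd`) for the model, the
parameter choices, and known limitations.

## Worked example

Simulate the default staged cohort (one small early-stage group, three
larger late-stage groups, twelve planted modules of which two are
non-preserved) and run the full comparison:

```r
library(modpres)

sim <- generate_dataset(synth_config(seed = 7))
sim$ref
#> sc_dataset: 500 cells x 1500 genes
#>   groups: pT1 = 500
#>   cell types: 7
#>   mitochondrial genes: 75

all <- bind_datasets(sim$ref, sim$test)
cfg <- comparison_config(
  ref_groups = "pT1", test_groups = c("pT2", "pT3", "pT4"),
  base_group = "pT1", var_mode = "reference_only",
  fraction = 0.6, n_perm = 0, seed = 7)
res <- run_pipeline(all, cfg)
res
#> pipeline result
#>   cells: 2600 in, 2591 after QC; genes kept: 1500
#>   variable genes: 900; PCA dims: 11; power: 6
#>   modules: 12 (sizes 31, 39, 41, 46, 49, 61, 63, 70, 72, 75, 86, 90)
#>   flagged non-preserved: M2, M5, M9
#>   rho[M2] = -0.317
#>   rho[M5] = 0.121
#>   rho[M9] = 0.866
#>   rho[M1] = 0.667

head(res$flags)
#>   module median_rank size flagged
#> 1     M1         2.5   31   FALSE
#> 2     M2        11.5   39    TRUE
#> 3     M3         5.5   41   FALSE
#> 4     M4         7.0   46   FALSE
#> 5     M5        11.5   49    TRUE
#> 6     M6         3.0   61   FALSE

res$comparisons[["M2"]]
#> subnetwork comparison, module M2: 39 genes, rho = -0.317
#>   cells: 240 (ref) / 807 (test); unique top edges: 65 / 65
```

Reading the output: twelve modules were detected in the reference
network; the two planted non-preserved modules land at the worst median
ranks (11.5 of 12) and are flagged, and their sub-network connectivity
barely correlates between conditions (rho -0.32 and 0.12) while a
preserved module stays high (0.87 for M9, a borderline third flag whose
rho reveals it as intact; the most preserved module M1 sits at 0.67).
The ground truth in `sim$truth` marks M2 and M5 as non-preserved —
exactly the two with collapsed rho. Writing products to disk
(`run_pipeline(..., out_dir = "out/")`) emits the partition,
preservation report, flags, quota table, QC table, node/edge TSVs and a
run manifest; `plot_circle()` draws the flagged modules' unique-edge
circle plots.

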