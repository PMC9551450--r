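# rareassembly

Community-assembly inference for abundant and rare microbial taxa.

Soil microbial surveys are dominated by a handful of abundant OTUs while
most taxa form a sparse "rare biosphere", and the two fractions need not
be assembled by the same ecological processes. `rareassembly` implements
the standard desk-scale toolkit for asking which processes — dispersal
limitation, environmental selection, or abundance-driven stochasticity —
structure each fraction of an OTU table:

* **Partition** OTUs into abundant (> 0.1% of total reads), rare
  (< 0.01%) and intermediate classes; occupancy and abundance–occupancy
  statistics.
* **Biogeography**: Bray–Curtis β-diversity, great-circle distances,
  distance-decay regression (permutation-tested), Levins niche breadth
  *B* and abundance-weighted community breadth *Bcom*.
* **Abundance-based null model**: 999 null communities preserving each
  sample's richness and depth, and the standardized effect size
  β-deviation = (β_obs − mean β_null) / sd β_null, with the usual
  interpretation rules (≫ 0: dispersal limitation or heterogeneous
  selection; ≪ 0: homogenizing processes; ≈ 0: stochasticity).
* **Sloan neutral community model**: occurrence frequency vs mean
  relative abundance, migration rate *m*, R², bootstrap CI.
* **Distance-matrix statistics**: Mantel tests, MRM with permutation
  forward selection, variation partitioning of β-deviations into pure
  environmental / pure spatial / shared / residual fractions, and the
  environment-to-space effect ratio **ESDR** (pure env ÷ pure space;
  ESDR < 1 means dispersal limitation outweighs selection).
* **Synthetic data** with known assembly regimes (neutral,
  dispersal-limited, environment-filtered, mixed), so the whole pipeline
  is testable end-to-end without sequencing data.

Input formats are QIIME-classic OTU tables (`#OTU ID` TSV, optional
taxonomy column) and tab-separated sample metadata (coordinates, climate,
soil chemistry).

## Worked example

Simulate a mixed-regime survey (24 sites in a ~600 km box, 300 OTUs,
2,000 reads/sample, dispersal kernel + pH/TSP selection) and run the full
analysis. At this reduced depth the survey-scale defaults
(`min_reads = 20`, rare < 0.01%) would empty the rare class, so the demo
uses demo-scale cuts:

```r
library(rareassembly)
cfg <- scenario_config(regime = "mixed", seed = 42)
paths <- write_scenario(cfg, "scenario")
report <- run_pipeline(paths[["otu"]], paths[["meta"]],
  config = list(seed = 1, n_null = 199, n_perm = 199, min_reads = 2,
                abundant_frac = 0.005, rare_frac = 0.001, ncm_boot = 0))
print(report)
```

```
== abundance partition (depth 1998) ==
         class n_otus pct_otus reads pct_reads
1     abundant     30    10.99 37645    78.506
2 intermediate     67    24.54  7745    16.152
3         rare    176    64.47  2562     5.343

== whole (273 OTUs) ==
distance-decay: slope -0.06571 per 100 km (-0.000657 per km), R^2 0.213, p 0.005 (276 pairs)
mean Bcom 6.18
beta_deviation over 276 pairs (n_null = 199): mean 51.198, median 54.249, sd 16.657
interpretation: dispersal-limitation-or-heterogeneous-selection
Sloan NCM fit: m = 0.0836 (95% CI NA-NA), R^2 = 0.404, NT = 1998, 273 OTUs
VPA: env 28.78% | shared -3.02% | space 17.67% | residual 56.57% | ESDR 1.628

== abundant (30 OTUs) ==
distance-decay: slope -0.06876 per 100 km (-0.000688 per km), R^2 0.199, p 0.005 (276 pairs)
mean Bcom 6.47
beta_deviation over 276 pairs (n_null = 199): mean 29.535, median 28.605, sd 13.861
interpretation: dispersal-limitation-or-heterogeneous-selection
Sloan NCM fit: m = 0.0156 (95% CI NA-NA), R^2 = -0.110, NT = 1569, 30 OTUs
VPA: env 3.82% | shared 1.43% | space 11.88% | residual 82.87% | ESDR 0.321

== rare (176 OTUs) ==
distance-decay: slope -0.03802 per 100 km (-0.00038 per km), R^2 0.182, p 0.005 (276 pairs)
mean Bcom 4.70
beta_deviation over 276 pairs (n_null = 199): mean 2.084, median 2.378, sd 2.240
interpretation: dispersal-limitation-or-heterogeneous-selection
Sloan NCM fit: m = 0.2636 (95% CI NA-NA), R^2 = 0.495, NT = 107, 176 OTUs
VPA: env 46.98% | shared -3.23% | space 13.52% | residual 42.73% | ESDR 3.475
```

Reading it: community similarity decays with distance (negative DDR
slope, permutation p 0.005); β-deviations far above zero flag turnover in
excess of abundance-constrained resampling; for the abundant
sub-community space explains 11.9% of β-deviation variance against 3.8%
for environment (ESDR 0.32 < 1 — dispersal limitation dominates), while
the generator's pH/TSP filter pushes the rare fraction the other way
(ESDR 3.5). The NCM fit on the rare sub-table (NT = 107, and NT = 4 at
survey thresholds) is ill-posed at demo depth — see the methods vignette.

A command-line interface wraps the same pipeline:

```sh
Rscript -e 'quit(status = rareassembly::cli())' -- \
    simulate --regime mixed --seed 42 --out-dir scenario
Rscript -e 'quit(status = rareassembly::cli())' -- \
    all --otu scenario/otu_table.tsv --meta scenario/metadata.tsv \
        --seed 1 --out-dir results_dir
```

Artifacts (partition table, distance matrices, β-deviation matrices, NCM
fits, Mantel/MRM/VPA summaries, `report.md`, provenance with all seeds)
are written to `--out-dir`.

## Documentation

The methods vignette (`vignettes/assembly-methods.Rmd`) documents the
models, parameter defaults, numerical choices, the synthetic world and
its limits, and the calibration caveats of the β-deviation statistic.
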