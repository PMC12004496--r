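# cptradeoff

Grassland ecosystems route fresh carbon inputs into two competing sinks:
the plant community's own carbon pools and the soil microbial biomass.
`cptradeoff` is for ecologists analysing factorial grazing × litter-input
field experiments who want to go from plot-level measurements to a
quantitative statement of which sink a treatment favors, with the
supporting treatment statistics.

The package computes, per replicate plot:

- **APCP / RCP** — aboveground / root plant carbon pools (g C/m²),
  `biomass (g/m²) × carbon content (mg/g) / 1000`;
- **TPCP** — the total plant community pool, the exact sum APCP + RCP;
- **MBC** — soil microbial biomass carbon from chloroform
  fumigation–extraction, `(C_fumigated − C_unfumigated) / kEC` with
  kEC = 0.45;
- **MBCP** — the areal microbial pool, summed over soil layers from MBC,
  bulk density and layer thickness (both the verbatim field formula and a
  dimensionally consistent SI mode are provided).

At its core is the two-service trade-off statistic. Within a
standardization scope each pool is min–max rescaled to a relative benefit
A_std = (A − A_min) / (A_max − A_min) ∈ [0, 1]; for a treatment cell with
benefits (a, b) the trade-off index is the RMSD of the two benefits from
their mean,

    RMSD = sqrt( ((a − ā)² + (b − ā)²) / (n − 1) ),  n = 2,  ā = (a+b)/2
         = |a − b| / √2,

geometrically the perpendicular distance of the point to the 1:1 line
(0 = balanced, 1/√2 = maximal imbalance). The side of the line gives the
**propensity**: TPCP-favoring above, MBCP-favoring below. Per-grassland
one-way ANOVA with Tukey HSD and compact letter displays covers the
treatment comparisons, and a synthetic-data generator with known ground
truth makes the whole pipeline testable without the (undeposited) field
data.

## Worked example

The pool formulas applied to published peak treatment means of a fenced
alpine meadow (aboveground biomass 213.35 g/m² at carbon content
368.43 mg/g; root biomass 118.52 g/m² at 300.05 mg/g):

```r
library(cptradeoff)
apcp <- compute_pool(213.35, 368.43)  # 78.60 g C/m2
rcp  <- compute_pool(118.52, 300.05)  # 35.56 g C/m2
total_plant_pool(apcp, rcp)           # 114.17 g C/m2
```

The aboveground pool of 78.60 g C/m² sits within 0.05% of the published
78.57 (the inputs are printed rounded), and the total of ≈114.2 g C/m²
matches the published 114.23 g/m² obtained as the sum of the printed
component pools.

An end-to-end synthetic run and its trade-off table:

```r
cfg   <- synthetic_config(seed = 1)          # 3 grasslands x 4 litter x 4 reps
pools <- derive_pools(generate_plots(cfg))
tt    <- tradeoff_table(pools)
subset(tt, grassland == "fenced")
#>   litter tpcp_std mbcp_std  index propensity
#> 1     T0    0.109    0.170 0.0435       MBCP
#> 2     T1    0.379    0.513 0.0949       MBCP
#> 3     T2    0.679    0.785 0.0753       MBCP
#> 4     T3    0.880    0.403 0.3369       TPCP
```

Read: under this generator configuration the fenced meadow's microbial
pool gains relatively more than the plant pool at T0–T2 (points below the
1:1 line), while the full litter dose T3 tips the balance toward plant
carbon with the largest imbalance (index 0.34 of a possible 0.71).
`autoplot(tt)` draws these cells against the 1:1 line;
`treatment_summary(pools, "tpcp_g_m2")` gives means, SDs and Tukey
letters; `run_pipeline(run_config(synthetic = cfg))` writes the four
result CSVs plus a settings-echoing log.

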