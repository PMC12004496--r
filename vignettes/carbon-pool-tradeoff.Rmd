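---
title: "Quantifying the plant-microbe carbon-pool trade-off"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the plant-microbe carbon-pool trade-off}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cptradeoff)
library(dplyr)
```

## The question

In grazed and fenced alpine meadows, fresh litter (carbon) inputs feed two
competing sinks: carbon accumulating in the plant community itself and
carbon immobilized in the soil microbial biomass. `cptradeoff` implements
the full chain from plot-level field measurements to a quantitative answer
to "which sink does a treatment favor, and by how much?": carbon-pool
bookkeeping, a standardized-benefit trade-off index, a propensity
classification, and the treatment statistics that go with them.

## Carbon pools

Each replicate plot contributes five derived quantities.

* **APCP** (aboveground plant community carbon pool, g C/m²) =
  aboveground biomass (g/m²) × tissue carbon content (mg/g) / 1000.
* **RCP** (root carbon pool) — same formula on root biomass and root
  carbon content.
* **TPCP** = APCP + RCP, computed as the exact sum so the identity
  `tpcp == apcp + rcp` holds to machine precision.
* **MBC** (mg/kg soil) comes from chloroform fumigation-extraction:
  (fumigated − unfumigated extractable C) / kEC with kEC = 0.45. A
  negative flush is measurement error; it is clamped to zero with a
  warning rather than propagated as negative biomass.
* **MBCP**, the areal microbial pool, sums per-layer contributions over
  the sampled profile (three 10-cm layers by default).

### The MBCP unit question

The field formula for the layer pool, MBC × BD × H × 10, is not
dimensionally consistent under any single standard reading of the bulk
density unit, and published per-area microbial pools from it cannot be
regenerated by unit algebra alone. We therefore treat the scale as
configuration, not hard-coded truth:

* `unit_mode = "literal"` (default) applies the formula verbatim to the
  numbers supplied, reproducing the scale of any source that used it.
* `unit_mode = "si"` returns a physically meaningful g C/m² with BD in
  g/cm³: a 1 m² column of thickness H cm at BD g/cm³ holds 10·BD·H kg of
  soil, so the stock is MBC × BD × H / 100.

The two modes differ by a constant factor (1000 when BD is supplied in
g/cm³), so every scale-free downstream quantity — standardized benefits,
trade-off indices, propensities, ANOVA F statistics — is identical under
either mode. Nothing in the analysis hinges on the choice.

## The trade-off statistic

Within a standardization scope, each pool's observations are rescaled to
relative benefits in [0, 1]:

$$A_{std} = \frac{A - A_{min}}{A_{max} - A_{min}}$$

For one treatment cell with standardized benefits $(a, b)$ for TPCP and
MBCP, the trade-off index is the root-mean-square deviation of the two
benefits from their own mean $\bar A = (a+b)/2$ with $n = 2$ services:

$$\mathrm{RMSD} = \sqrt{\frac{(a-\bar A)^2 + (b-\bar A)^2}{n-1}}
  = \frac{|a-b|}{\sqrt 2}$$

which is exactly the perpendicular distance from the point $(b, a)$ to
the 1:1 line: 0 means the two sinks benefit equally, $1/\sqrt 2$ is the
maximal possible imbalance. The **propensity** is the side of the line:
TPCP if $a - b$ exceeds the neutrality tolerance, MBCP if $b - a$ does,
neutral otherwise. The default tolerance of `1e-12` treats only exact
ties as neutral — with continuous data a genuine tie has probability
zero, and a wider neutral band is a presentation choice the caller can
make explicitly.

Two choices are genuinely open and are exposed as arguments rather than
fixed silently:

* **Scope** (`per_grassland`, default, vs `global`): whether min-max
  bounds are taken within each grassland or across all of them. Treatment
  rankings within a grassland are invariant to this, but index magnitudes
  are not comparable across scopes.
* **Aggregation** (`mean_then_index`, default, vs `index_then_mean`):
  whether replicate benefits are averaged before the index is taken, or a
  per-replicate index is averaged. By convexity the second is never
  smaller; with treatment means as the object of interest we default to
  the first.

```{r tradeoff-example}
cfg <- synthetic_config(seed = 1)
pools <- derive_pools(generate_plots(cfg))
tradeoff_table(pools)
```

`autoplot()` on the result draws the standardized-benefit plane with the
1:1 line; the default orientation puts the microbial benefit on x so
"upper left" favors the plant pool, and can be flipped via
`axis_orientation` without touching any computation.

### Properties worth knowing

The index computed by the RMSD formula agrees with an independently coded
point-to-line distance to 1e-12 over random pairs (this is a test, not a
promise), is symmetric, and is invariant to any common affine rescaling
of the raw pool values within a scope — so unit conventions cannot leak
into it.

One subtlety of the estimator deserves emphasis. Because the min-max
bounds are computed from *replicate observations*, the sample range
widens as replicates accumulate, compressing standardized treatment means
toward the interior by roughly a factor $1/(1 + c \cdot cv)$ (with $c
\approx 2$ at 30 replicates). The estimated index is therefore slightly
conservative, the estimator converges to the noise-free ground truth as
measurement noise shrinks — not as the replicate count grows — and
treatment *orderings* are unaffected (the compression is common to all
cells). The test suite pins both facts: error decreasing in the noise cv
at fixed n, and exact ordering recovery at cv = 0.05, n = 30.

## Group statistics

Per grassland, each pool response is compared across litter levels with a
classical one-way ANOVA and Tukey HSD multiple comparisons
(Tukey-Kramer under unequal replication), summarized as a compact letter
display in which treatments sharing a letter do not differ at `alpha`.
Letters are assigned in descending order of the group means (`"a"` =
largest), the convention of grazing-experiment figures. The letter
algorithm is the standard insert-absorb construction and is
cross-checked in the tests against `multcomp`'s display, pair by pair.
Shapiro-Wilk and Levene diagnostics are computed and reported alongside
but never gate the analysis: with 4-6 replicates per cell such gates are
noise, and no remediation path is defined for this design anyway.

```{r stats-example}
gs <- group_statistics(pools, "tpcp_g_m2")
glance(gs)
treatment_summary(pools, "tpcp_g_m2")
```

## The synthetic generator

No replicate-level field data are deposited for this design, so the
generator is the package's test bed: a 3 grassland × 4 litter × 4
replicate factorial whose cell means anchor on published peak treatment
values (for example fenced aboveground biomass 213.35 g/m² at T3, fenced
profile MBC 1005.14 mg/kg at its T2 peak), with the non-peak levels
ramping linearly from 70% of the anchor — an illustrative monotone dose
response, not a reconstruction of the data. Remaining choices a field
scientist would recognise: profile MBC split 50/30/20% over the three
layers (microbial biomass declines with depth), bulk density 1.1/1.2/1.3
g/cm³ increasing with depth, and a replicate coefficient of variation of
0.1 (no variance statistics were published; 10% is typical plot-scale
scatter for biomass and MBC in alpine meadows).

Noise is truncated-at-zero normal per variable, so configured cell means
remain interpretable as the targets (truncation bias is negligible below
cv ≈ 0.1, where zero sits 10 standard deviations from the mean);
`shared_plot_cv` optionally multiplies both biomass draws by a common
plot factor to induce realistic aboveground-root correlation.
`ground_truth()` pushes the noise-free cell means through the same pool
and trade-off code and is the recovery target of the calibration tests.

What the generator does **not** emulate — and what passing tests
therefore cannot certify about real data: correlated measurement error
between MBC layers, spatial autocorrelation between plots,
non-normal (skewed) biomass distributions, and any mechanistic link
between litter dose and microbial response. Treatment effects enter only
through the configured means.

## Pipeline and problem sizes

`run_pipeline(run_config(...))` chains ingest (or synthesis) → pools →
group statistics → trade-offs and writes `pools.csv`, `anova.csv`,
`tukey.csv`, `tradeoffs.csv` and a `run.log` echoing every setting, so
the under-determined choices (scope, aggregation, unit mode) are always
visible next to the numbers. Tables are written with 6 significant
digits; two runs with the same config and seed are byte-identical.

The calibration experiments in the tests and the acceptance script use 30
replicates per cell at cv = 0.05 for recovery checks, 2000 null
simulations for the ANOVA type-I rate (binomial 95% band around 0.05),
and 200 random instances for the letter-display invariant — sizes at
which each check resolves its question in seconds on a laptop.

## Limitations

* The trade-off index inherits min-max standardization's sensitivity to
  extremes; with replicate-level bounds it is mildly conservative (see
  above) and magnitudes are only comparable within a scope.
* Published index values for this design cannot be recomputed without the
  undeposited raw data; the package carries them only as a feasibility
  fixture (`reported_tradeoff_indices()`).
* The fumigation arithmetic assumes extract concentrations have already
  been converted to a soil-mass basis; extract-volume bookkeeping is out
  of scope.
* Exactly two services are supported; the RMSD formula generalizes, but
  two pools are what the design measures.
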