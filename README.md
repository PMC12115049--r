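# metalsource

Heavy-metal pollution assessment and source apportionment for paired
soil–plant surveys, in R.

Surveys of this kind sample topsoil (0–20 cm) and the aboveground
tissue of wild plants at the same locations and assay both for a panel
of trace metals (Cr, Cu, Zn, Cd, Pb, Hg, As by default). Two questions
follow: *how polluted is the soil–plant system*, and *which candidate
sources — factories, roads, railways, geogenic background,
atmospheric deposition — are responsible*. `metalsource` implements
the standard toolchain for both, for environmental scientists and
ecotoxicologists working on contamination surveys:

- **Pollution indices** — single-factor index `Pi = Ci/Bi` against a
  regional background; Nemerow composite
  `NIPI = sqrt((Pave² + Pmax²)/2)` with the standard five-class
  labelling; Hakanson potential ecological risk `Er = Tr·Pi` with
  canonical toxicity coefficients (Cd 30, Hg 40, As 10, Pb 5, Cu 5,
  Cr 2, Zn 1) and composite `RI = Σ Er`.
- **Soil–plant transfer** — bioconcentration factors `BCF = Cp/Cs` on
  matched pairs (species means, then an unweighted cross-species
  mean), exceedance folds against plant standard limits, per-species
  soil–plant Pearson correlation matrices, and rank-based
  group-difference tests (Kruskal–Wallis + pairwise Mann–Whitney with
  Bonferroni adjustment).
- **APCS-MLR receptor model** — standardization, correlation-matrix
  PCA with Kaiser retention, absolute principal component scores
  (scores minus the artificial zero-concentration sample's score),
  per-metal multiple linear regression, and percent source
  contributions including an *unidentified* term from the intercept.
- **Random-forest apportionment** — per-metal regression forests on
  distance-decay source-proximity features `exp(−d/λ)`, evaluated by
  train/test R², RMSE, MAE and RPD (= sd(obs)/RMSE), with
  impurity importances normalized to percent shares per source.
- **Synthetic surveys** — a generator producing paired soil–plant
  tables from known source structure (geogenic log-normal background
  + distance-decaying point/polyline sources, species-specific
  transfer, atmospheric deposition, log-normal noise), with
  closed-form ground-truth shares for validating every stage.

## Worked example

Simulate a 36-sample survey on the bundled arid-reserve preset (four
shrub species; two factories, a railway and two highways as sources),
then run the full toolchain:

```r
library(metalsource)

sv <- simulate_survey(make_scenario(seed = 7))

pollution_indices(sv$soil)
#> Pollution indices over 36 samples
#>  metal  p_ave  p_max   nipi      nipi_level        ri     risk_level
#>     Cr 0.9250 1.6837 1.3584 Light Pollution   66.6020       Low Risk
#>     Cu 0.7463 1.3549 1.0938 Light Pollution  134.3301       Low Risk
#>     Zn 0.8697 1.4822 1.2152 Light Pollution   31.3100       Low Risk
#>     Cd 1.2027 2.5063 1.9657 Light Pollution 1298.9256 Very High Risk
#>     Pb 0.7947 1.8897 1.4496 Light Pollution  143.0449       Low Risk
#>     Hg 0.4601 1.0700 0.8236           Alert  662.5700 Very High Risk
#>     As 0.6165 1.0166 0.8407           Alert  221.9396  Moderate Risk
```

Cd and Hg carry extreme composite ecological risk despite moderate
NIPI — their high toxicity coefficients (30 and 40) dominate `RI` —
while Cr's high concentrations carry little toxicity weight.

```r
species_bcf_summary(sv$plants, sv$soil)
#> Bioconcentration factors: 4 species, 7 metals
#> Cross-species means (unweighted over species):
#>  metal mean_bcf
#>     Cr    3.191
#>     Cu    0.233
#>     Zn    0.142
#>     Cd    0.931
#>     Pb    0.098
#>     Hg    1.254
#>     As    0.109
```

Cr and Hg accumulate actively in tissue (BCF > 1); Cu, Zn, Pb and As
do not.

```r
fit <- apcs_mlr(sv$plants)
round(fit$contribution_percent, 1)
#>     PC1  PC2 unidentified
#> Cr 72.3  0.8         26.9
#> Cd 81.9  7.8         10.4
#> Pb 64.2 20.4         15.3
#> Hg 51.2  3.9         44.9
#> ...
```

The first retained component (factory-correlated in this simulation)
carries most of Cd/Zn/Cr; Hg keeps the largest *unidentified* share —
its plant burden is partly atmospheric, invisible to the retained
components.

```r
rf <- rf_apportion(sv$plants, sources = sv$sources, seed = 42)
round(rf$importance["Pb", ], 1)
#> factory_1 factory_2   railway      G216       S11
#>       9.8      15.5      10.7      48.6      15.4

subset(sv$truth$shares, metal == "Pb" & source == "G216")
#>    metal source share_percent
#> 26    Pb   G216      48.89349
```

The forest ranks highway G216 first for Pb, matching the generator's
ground truth (48.9% of mean soil Pb).

A command-line wrapper over the same functions ships in
`inst/exec/metalsource` (subcommands `run`, `indices`, `bcf`, `apcs`,
`rf`, `simulate`).

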