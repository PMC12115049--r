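---
title: "Assessing and apportioning heavy-metal pollution in soil-plant surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing and apportioning heavy-metal pollution in soil-plant surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metalsource)
```

`metalsource` analyses paired soil-plant heavy-metal surveys: the kind
of study where topsoil (0-20 cm) and the aboveground tissue of wild
plants are sampled at the same locations, assayed for a panel of trace
metals (here Cr, Cu, Zn, Cd, Pb, Hg, As), and the questions are *how
polluted is the system* and *where is the pollution coming from*. The
package covers four method families -- pollution indices,
soil-to-plant transfer, APCS-MLR receptor modelling, and random-forest
source apportionment -- plus a synthetic survey generator with known
source structure for validating all of them.

## Pollution indices

The single-factor index compares a concentration with the regional
geochemical background, $P_i = C_i / B_i$. The Nemerow composite index
aggregates a metal's survey-average and survey-maximum single-factor
indices,

$$\mathrm{NIPI} = \sqrt{\tfrac{1}{2}\left(P_{ave}^2 + P_{max}^2\right)},$$

deliberately over-weighting the most polluted observation. We label
NIPI on the standard scheme with right-closed intervals: $\le 0.7$
Safe, $(0.7, 1]$ Alert, $(1, 2]$ Light, $(2, 3]$ Moderate, $> 3$
Heavy Pollution. The Hakanson potential ecological risk weights each
single-factor index by a toxicity coefficient, $E_r = T_r \cdot P_i$,
and `aggregate_ri()` sums $E_r$ along whichever axis the caller
chooses: across metals for a sample's composite risk, or across
samples for a per-metal survey total. Default coefficients are the
canonical Hakanson values (Cd 30, Hg 40, As 10, Pb 5, Cu 5, Cr 2,
Zn 1); because published lists occasionally permute these, the
`reference_set` makes them configurable, along with the background
values, plant limits, screening values and class thresholds. Er/RI
labels use the left-closed Hakanson scheme (Er: 40/80/160/320; RI:
150/300/600).

All reference values default to the bundled arid-region set (Xinjiang
soil backgrounds, plant standard limits, GB 15618-2018 screening
values); any or all can be replaced through `reference_set()` or a
CSV/YAML file. The Hg background in particular is worth checking
against local data -- published regional tables disagree at the
0.016-0.02 mg/kg level, which moves the Hg NIPI appreciably, so it is
configuration, never a constant.

## Soil-plant transfer and association

The bioconcentration factor $\mathrm{BCF} = C_p / C_s$ is computed per
matched sample pair, then averaged within species, then across species
*unweighted*. The last convention matters: a pooled per-sample mean
weights species by their sample counts and gives a different (and for
heterogeneous uptake, misleading) survey-level number; the unweighted
mean of species means is what survey reports conventionally quote.
Exceedance folds divide species-mean tissue concentrations by plant
standard limits. Per-species Pearson correlation matrices between
plant and soil metal columns (`soil_plant_correlations()`) describe
which tissue burdens track the local soil and which are decoupled
(e.g. atmospherically deposited Hg).

Group differences across species use a Kruskal-Wallis omnibus test
per metal, followed (when the omnibus $p < 0.05$) by pairwise
Mann-Whitney comparisons with Bonferroni adjustment; comparisons
against fixed reference values use the one-sample Wilcoxon signed-rank
test. Rank-based tests are the defensible default at the n = 6-14 per
species typical of such surveys; with all observations tied the
omnibus p-value is reported as 1 rather than NaN. Both raw and
adjusted pairwise p-values are returned, since adjustment conventions
vary between reports.

## The APCS-MLR receptor model

Receptor models work backwards from concentrations measured at
receptors (samples) to source contributions. The Thurston-style
APCS-MLR chain implemented by `apcs_mlr()` is:

1. standardize each metal, $Z = (C - \bar{C}) / \sigma$ (sample sd);
2. eigendecompose the metal correlation matrix; retain components with
   eigenvalue $> 1$ (Kaiser). Loadings are eigenvectors scaled by
   $\sqrt{\lambda}$; score coefficients $V \Lambda^{-1/2}$ give
   unit-variance component scores;
3. convert scores to *absolute* principal component scores by
   subtracting the score of an artificial sample with all
   concentrations zero: $\mathrm{APCS}_{jk} = (A_Z)_{jk} - (A_0)_j$
   with $(Z_0)_i = (0 - \bar{C}_i)/\sigma_i$. By construction the
   zero-concentration sample scores exactly zero, which anchors the
   score origin at "no pollution";
4. regress each metal on the APCS columns by OLS,
   $C_i = b_{0i} + \sum_j b_{ij}\,\mathrm{APCS}_j$;
5. convert to contributions: component $j$'s mean contribution to
   metal $i$ is $b_{ij}\cdot\overline{\mathrm{APCS}_j}$ and the
   intercept $b_{0i}$ is the *unidentified* contribution. Percent
   shares are absolute mean contributions normalized to sum to 100.

Design choices where the literature is genuinely open: we take
absolute values in the share normalization (negative mean
contributions arise under sign indeterminacy and would otherwise
produce shares outside [0, 100]); we apply no rotation by default,
presenting loadings as raw PCs, with varimax available as an option;
each component's sign is flipped so its largest-magnitude loading is
positive, making output reproducible across eigen-solvers; and the
retained-component count follows the data through the Kaiser rule
rather than being forced to a fixed dimension, with `ncomp` available
as an override. Collinear APCS designs abort with a condition-number
diagnostic rather than returning unstable coefficients.

## Random-forest apportionment

`rf_apportion()` regresses each metal on one proximity feature per
candidate source, $\exp(-d/\lambda)$, where $d$ is the planar
Euclidean distance (km) to a point source or to the nearest point of a
polyline source (roads, railways) and $\lambda$ defaults to 10 km.
Proximity rather than raw distance makes impurity importances read
directly as source influence. Forests use 500 trees and
$\lfloor\sqrt{p}\rfloor$ candidate features per split; the 70/30
train/test split is stratified by species and fully seeded, so
identical seeds give bitwise-identical metrics. Performance is
reported as train/test $R^2$, RMSE, MAE, and the chemometrics residual
prediction deviation $\mathrm{RPD} = \mathrm{sd(obs)}/\mathrm{RMSE}$
on the test split (above 2 conventionally indicates a reliable model),
plus the OOB estimate from the bagged trees. Importances are
impurity-based, normalized to percent shares per source.

For plant tables the response is, by default, normalized within
species (each metal divided by its species mean) before fitting.
Species-specific uptake spans an order of magnitude for some metals
(Cr and Pb in particular), and that variance component carries no
information about *where* pollution comes from; left in place it
swamps the spatial signal that the proximity features can explain.
The normalized response is the dimensionless within-species relative
enrichment, and evaluation metrics are then on that scale; setting
`normalize_species = FALSE` recovers metrics in mg/kg.

## The synthetic survey generator

`make_scenario()` / `simulate_survey()` generate paired surveys with
known ground truth, so that every stage above can be validated by
parameter recovery rather than by comparison with unreleased field
data. Soil at sample $i$ is

$$C_i(m) = \Big(B_i(m) + \sum_s E_s(m)\, e^{-d_{is}/\lambda_s}\Big)
  \cdot \varepsilon_i(m),$$

a log-normal geogenic background draw plus distance-decaying source
terms, times mean-one log-normal noise; plant tissue is
$T(\mathrm{species}_i, m)\cdot C_i(m) + a(m)$, times its own noise.
Ground-truth shares are defined on the noise-free mixture -- the
estimand the apportionment methods target -- and are recomputed in
tests by brute-force summation.

The `"kalamaili-like"` preset emulates an arid nature-reserve survey:
36 samples over a 40 x 40 km domain; four shrub species with counts
(9, 7, 6, 14); five sources (two factories as points, a railway and
two highways as polylines); factory-loaded Cd/Zn/Cr, road-loaded Pb
with one clearly dominant highway (road family about 73% of mean soil
Pb), Hg split between a factory and an additive atmospheric deposition
term that decouples plant Hg from soil; and log-normal noise with sd
0.2 on the log scale, reflecting the strictly positive, right-skewed
distributions typical of trace metals. Background means and transfer
factors are chosen so that noise-free survey means land near
regionally typical soil and plant concentrations; emission strengths
were derived once from the intended per-source shares and the mean
source proximity over the domain. All source decay lengths equal the
feature-transform default (10 km) so that recovery by the RF stage is
well-posed rather than confounded by scale mismatch.

What the generator does *not* emulate: geochemical speciation, pH and
organic-matter covariates, spatially correlated background fields,
measurement censoring at detection limits, and temporal dynamics.
Passing recovery tests therefore demonstrates that the estimators are
correct and identifiable under the stated generative model, not that
any particular field dataset satisfies that model.

## Numerical conventions and degenerate inputs

Sample standard deviations use the n - 1 denominator throughout;
kurtosis and skewness are the adjusted (SPSS/Excel-style, type 2)
estimators. Classification intervals are right-closed for NIPI and
left-closed for Er/RI, matching each scheme's convention. Zero soil
concentrations exclude a pair from BCFs with a warning;
zero-variance columns make correlations NA (warning) and abort
standardization (error, naming the metal); constant responses abort
forest fits and metric evaluation (R-squared undefined); a perfect
fit reports RPD = Inf rather than an arbitrary cap. Species groups
with fewer than two observations are excluded from group tests with a
warning.

## Problem sizes used in the validation suite

The test suite validates oracle equivalences on 100 random tables,
PCA limiting behaviour at n = 10,000, regression null behaviour at
n = 1,000, forest behaviour at n = 200-300, and preset recovery over
20 simulated surveys of 36 samples each -- sizes at which the checked
properties are stable while the whole suite stays fast.

## Worked example

```{r, eval = FALSE}
library(metalsource)

sv <- simulate_survey(make_scenario(seed = 7))

pollution_indices(sv$soil)           # NIPI and RI per metal
species_bcf_summary(sv$plants, sv$soil)

fit <- apcs_mlr(sv$plants)
summary(fit)                         # loadings + contribution shares
source_contributions(fit)

rf <- rf_apportion(sv$plants, sources = sv$sources, seed = 42)
summary(rf)                          # metrics + importance shares

sv$truth$shares                      # generator ground truth
```
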