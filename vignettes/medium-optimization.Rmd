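---
title: "Scoring and optimizing fermentation media with AHP and response surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and optimizing fermentation media with AHP and response surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ahprsm)
```

## The problem

Optimizing a fermentation medium for biosurfactant production is a
multi-criteria problem: a candidate condition is judged simultaneously on
culture biomass (OD600), the protein concentration of the crude extract
(g/L), the surface tension it achieves (mN/m, lower is better) and the
clear-zone diameter of the oil-displacement assay (cm). `ahprsm` implements
the two-stage workflow used in flask-scale medium studies of marine
*Vibrio* strains:

1. **Screening.** Each single-factor experiment (temperature, liquid volume,
   inoculum size, carbon source, nitrogen source, NaCl level, trace ion) is
   scored by the analytic hierarchy process (AHP): the four indices become
   criteria, the tested levels become alternatives, and every pairwise
   comparison matrix is checked for consistency before the overall weights
   are trusted.
2. **Response-surface optimization.** The factors surviving the screen enter
   a rotatable central composite design (CCD); the composite "overall
   weight" response is fitted with a full second-order polynomial, the fit
   is dissected with a lack-of-fit ANOVA, and the fitted surface is searched
   for its constrained optimum.

## The AHP model

A judgment matrix $A = (a_{ij})_{n \times n}$ holds Saaty-scale comparisons:
$a_{ij} \in \{1, \dots, 9\}$ (or a reciprocal) states how strongly item $i$
beats item $j$, with $a_{ji} = 1/a_{ij}$ and $a_{ii} = 1$. Priorities are
derived by the geometric-mean method,

$$W_i = \frac{\left(\prod_j a_{ij}\right)^{1/n}}
             {\sum_i \left(\prod_j a_{ij}\right)^{1/n}},$$

computed in log space. Consistency is diagnosed through the maximal
eigenvalue: $CI = (\lambda_{\max} - n)/(n - 1)$ and $CR = CI/RI(n)$, with
the tabulated random index $RI$ and the conventional acceptance rule
$CR < 0.1$. Two estimators of $\lambda_{\max}$ are provided:

* `"row_ratio"` (default): the mean of $(Aw)_i / w_i$ over the
  geometric-mean weights — the worksheet arithmetic whose results match the
  diagnostics tables this package's fixtures were transcribed from;
* `"power"`: power iteration to the exact principal eigenvalue (relative
  tolerance $10^{-10}$), cross-checked in the tests against `base::eigen`.

Orders 1–2 are consistent by construction ($RI = 0$); the package
short-circuits $CI = CR = 0$ there instead of dividing by zero. Ties in the
final selection break to the earliest alternative and are flagged with a
warning.

```{r criteria}
A <- rank_to_matrix(c(1, 2, 3, 4),
                    labels = c("biomass", "protein", "surface_tension",
                               "clear_zone"))
round(priority_weights(A), 3)
consistency(A)
```

## From measurements to matrices

The screening tables record continuous measurements, not verbal judgments,
so a quantization rule must map performance ratios onto the discrete Saaty
scale. Two distinct mappings are used:

* **Criteria level.** The four indices carry importance scores 1 (biomass)
  through 4 (clear zone), with surface tension the only cost criterion
  (direction $-1$). `rank_to_matrix()` uses the ceiling-of-ratio rule
  $a_{ij} = \lceil s_i/s_j \rceil$ clipped to $[1, 9]$; with scores
  $(1,2,3,4)$ this is the unique construction consistent with the reference
  criteria weights $(0.10, 0.18, 0.29, 0.43)$ and $CR = 0.017$.
* **Alternative level.** For measured values the default quantizer is
  logarithmic, $q(r) = \mathrm{round}(1 + 8 \ln r / \ln 9)$ clipped to
  $[1, 9]$: equal values map to 1, a nine-fold advantage to 9, and
  intermediate ratios are graded geometrically, which is the natural scale
  for ratio judgments. The ceiling and nearest-integer rules remain
  selectable (`quantizer =` in `run_screen()`), and a custom function can be
  plugged in. The logarithmic default was adopted because, across the seven
  packaged screening experiments, it is the rule whose selections agree with
  all seven reference optima (28 °C, 100 mL, 4 % inoculum, lactose, yeast
  extract, 20 g/L NaCl, Na₂HPO₄), whereas the coarser ceiling rule — which
  saturates small ratios upward — flips two of the closer calls.

Cost criteria are inverted before quantization, which makes the benefit/cost
treatment exactly symmetric, and zero measurements (designed dropouts such
as a carbon source producing no clear zone) compare at the maximal
disparity 9 (zero-vs-zero compares as 1), keeping every matrix on the Saaty
scale rather than producing infinite ratios.

```{r screen}
tab <- read_screen_csv(ahprsm_example("temperature_screen.csv"),
                       experiment = "temperature")
res <- run_screen(tab)
res$best_label
res$footer
```

A result is flagged (`consistent = FALSE`, non-fatally) whenever any matrix
has $CR \ge 0.1$. One packaged case trips this flag by construction: the
nitrogen-source protein column spans a 160-fold range, which saturates any
bounded 9-point quantizer and leaves its matrix marginally inconsistent; the
selected optimum is unaffected.

## Composite response for the designed experiment

For CCD runs the four indices are collapsed into one response with the
criteria weights $w_c$ and directions $s_c$:

$$Y_k = \sum_c w_c \, s_c \, \frac{x_{ck}}{\sum_k x_{ck}},$$

i.e. signed column-sum normalization (`"max"` and `"minmax"` normalizations
are selectable). This construction is documented as an *approximation*: the
packaged run sheet ships with its own response column, and whenever a
response column is present it is used verbatim for fitting — the
reconstruction differs from the shipped responses by < 0.01 on every run
but is not bit-identical, because the exact normalization behind the shipped
column is not recoverable.

## The response-surface model

With $k = 3$ coded factors $x_1$ (lactose), $x_2$ (yeast extract), $x_3$
(NaCl), the full second-order model

$$Y = \beta_0 + \sum_i \beta_i x_i + \sum_{i<j} \beta_{ij} x_i x_j
      + \sum_i \beta_{ii} x_i^2$$

is fitted by ordinary least squares (QR, via `stats::lm`). All ten terms are
always kept: the reference variance decomposition reports every term, so no
stepwise selection is performed. The ANOVA uses partial (drop-one) sums of
squares $SS_j = \hat\beta_j^2 / [(X'X)^{-1}]_{jj}$ in coded units — the
convention of standard DOE software; linear terms are orthogonal in a CCD,
so partial and sequential SS coincide for them. Pure error comes from
replicate groups identified by exact coded-row equality (the six center
points), lack-of-fit rows are emitted only when replicates exist, and the
fit statistics are

$$R^2 = 1 - \frac{SS_{res}}{SS_{tot}},\qquad
R^2_{adj} = 1 - \frac{MS_{res}}{MS_{tot}},\qquad
R^2_{pred} = 1 - \frac{PRESS}{SS_{tot}},$$

with $PRESS = \sum_i (e_i/(1 - h_{ii}))^2$ from the leave-one-out
hat-matrix closed form (verified in the tests against explicit refits).
P-values are reported from the upper tail of the F distribution and are
never used for control flow.

```{r rsm}
runs <- read_ccd_csv(ahprsm_example("ccd_runs.csv"))
fit <- fit_quadratic(runs, runs$response)
rsm_anova(fit)
```

The surface is explored with `stationary_point()` (gradient solve plus
Hessian eigen-classification, with optional frozen factors) and
`constrained_optimum()` (analytic interior maximum when it exists, else a
deterministic 101-per-axis grid over the coded box followed by a bounded
quasi-Newton polish).

### Units

Coded and actual units are linked by `factor_mapping()`,
$x = (X - \mathrm{center})/\mathrm{step}$. The packaged configuration uses
centers 5, 6 and 20 g/L for lactose, yeast extract and NaCl. The step sizes
are protocol metadata that the fixture tables do not determine; the packaged
defaults (2, 3, 5 g/L per coded unit) were chosen once as a plausible
flask-scale spacing consistent with the tested single-factor ranges, and
`estimate_steps()` can recover steps from a published actual-units equation
via $\beta^{coded}_{ii} = \beta^{actual}_{ii}\,\mathrm{step}_i^2$ when one
is available. The full quadratic model space is closed under affine
recoding, so $R^2$, F statistics and predictions are invariant to this
choice (tested); only the reporting of the optimum in g/L depends on it.

## Synthetic data and what it shows

`simulate_screen()` draws screen tables from a latent-utility model: each
index is a linear (surface tension: decreasing) transform of the true
utility into a plausible range — OD600 in [0, 1.2], protein in [0, 7] g/L,
surface tension falling from 55 toward 30 mN/m, clear zone in [0, 7.5] cm —
plus independent Gaussian noise scaled to the index range and truncated at
zero. Defaults: five alternatives with geometrically decaying utilities
$0.8^{0:4}$ and noise at 5 % of each range, a separation comparable to the
packaged screens. Designed dropouts (zero clear zone) are injectable. Each
index column uses a substream seed derived from the global seed, so adding
an index never perturbs the others. `simulate_ccd()` evaluates a known
coefficient vector on the coded design and adds i.i.d. Gaussian noise.

These generators exercise identifiability (noiseless tables must be ranked
exactly; noiseless responses must return the generating coefficients to
$10^{-10}$), determinism, truncation safety, ranking robustness under noise
and coefficient recovery. They deliberately do **not** model growth
kinetics, index correlations induced by shared biology, heteroscedastic
measurement error or time-course dynamics — a passing suite shows the
arithmetic and the decision logic are right, not that real fermentations
are this well behaved.

## Numerical choices and edge cases

* Geometric means in log space; priority vectors normalized to sum 1 within
  $10^{-9}$.
* Reciprocity and positivity are enforced at construction with relative
  tolerance $10^{-9}$; violations name the offending cell.
* $\lambda_{\max}$ estimates marginally below $n$ are clamped to $n$ (CI is
  never negative).
* Rank-deficient designs are rejected naming the collinear columns (QR with
  pivoting) rather than silently dropping terms.
* Replicate groups use exact coded-row equality after rounding to 10
  decimals.
* Displayed tables round to 4 decimals; machine-readable JSON keeps full
  precision (`digits = NA` round trip).

## Known limitations

* A bounded 9-point scale cannot faithfully encode measurement columns
  spanning two orders of magnitude; such matrices saturate and may exceed
  $CR = 0.1$ (flagged, not fatal).
* The composite-response construction is one of several defensible
  normalizations; supplied response columns always take precedence.
* With a 20-run CCD the residual degrees of freedom are 10, so
  standardized coefficient errors follow a $t_{10}$ distribution: about
  1.3 % of individual coefficients exceed 3 estimated standard errors by
  chance, and roughly one replicate in nine exceeds it on at least one of
  the ten coefficients. Fit statistics recomputed from responses rounded to
  4 decimals can differ from those computed on unrounded data by more than
  one unit in the last printed digit for the largest F statistics (the
  residual sum of squares is itself only ~$1.4\times10^{-4}$).
* Only full second-order models on CCDs are supported — no Box–Behnken or
  mixture designs, no stepwise selection, no multi-response desirability.
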