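---
title: "Modelling cool-induced inflorescence formation with accumulated cooling temperature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cool-induced inflorescence formation with accumulated cooling temperature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coolact)
```

## The problem

Commercial *Phalaenopsis* production separates a warm vegetative stage from a
cooling room in which mature plants are induced to spike (form an
inflorescence). Growers need to answer two questions quantitatively: *what
fraction of a cohort will have spiked after a given cooling treatment*, and
*how many cooling days does a target fraction require*. Both day and night
temperatures matter, and different varieties arrive from vegetative regimes
with different set-points, so raw "days in the cooling room" is not a
comparable axis across varieties.

The package's answer is a thermal-time index, the **accumulated cooling
temperature** (ACT, °C·h): per day in the cooling room,

$$\mathrm{ACT/day} = (T_{vd} - T_{cd})\,H_d + (T_{vn} - T_{cn})\,H_n,$$

where $T_{vd}/T_{vn}$ are the vegetative day/night set-points,
$T_{cd}/T_{cn}$ the cooling-room set-points, and $H_d + H_n = 24$ h the
photoperiod split. The induction response is modelled as a three-parameter
sigmoid in ACT:

$$Y(\mathrm{ACT}) = \frac{Y_{max}}{1 + B\,e^{-\mathrm{ACT}/K}},$$

with $Y$ the cohort spiking percentage, $Y_{max}$ the plateau, $K$ the ACT
scale of induction, and $B$ fixing the starting level
$Y(0) = Y_{max}/(1+B)$. The curve reaches half its plateau at
$\mathrm{ACT} = K\log B$.

### A note on the model's published form

Fitted versions of this curve are sometimes typeset flat, as
`Y = Ymax + B Exp(−ACT/K)`, with the fraction bar lost. The package reads
all such triplets as the logistic ratio above: the additive reading would
put $Y(0) = Y_{max} + B$ well above 100 % (about 138 % for the
four-variety parameter set), which is impossible for a percentage, while
the ratio reading gives a plausible near-zero origin. Every fit JSON and
pipeline run log records this convention so downstream comparisons are
unambiguous.

## The ACT index and its conventions

`daily_act()` clamps each of the day and night differentials at zero
*independently*: a cooling room warmer than the vegetative reference
supplies no induction signal, and a warm night never cancels a cool day.
Clamping is what makes cumulative ACT monotone nondecreasing. The
unclamped algebraic sum remains available (`clamp = FALSE`) for
sensitivity checks only.

```{r}
daily_act(phal_regime("KHM1220"))   # (27-22)*14 + (23-19)*10
daily_act(temperature_regime(20, 18))  # warmer cooling room: clamped to 0
```

Three further conventions, each genuinely open when the index is written
down only as a sum over days:

* **Photoperiod split.** Defaults are $H_d = 14$ h and $H_n = 10$ h, the
  standard commercial induction photoperiod; both are configurable at
  regime construction.
* **High-temperature inhibition.** Day temperatures around 28–29 °C are
  reported to delay or block spike initiation. The base index expresses
  this only through clamping (no accumulation), so an explicit cutoff
  that zeroes a whole day's accumulation is provided as an opt-in
  `inhibition_threshold` argument and is **off by default**: it is a
  documented phenomenon, but not part of the base index definition.
* **Hourly logs.** `accumulate_log()` generalizes the index to recorded
  temperatures: each sample contributes
  $\max(0, T_{ref} - T_{sample}) \times \Delta t$, with the day/night
  reference chosen by a configured lights-on clock window (not solar
  position — induction rooms run on artificial light). Clamping is
  per-sample, so a transient warm excursion pauses accumulation for its
  own samples rather than voiding the day. On a square-wave log matching
  a set-point regime the result equals `accumulate_regime()` exactly,
  which is how the two paths check each other. Gaps larger than twice
  the sampling interval are an error naming the first missing interval:
  silently bridging holes would fabricate degree-hours.

The day-only variant (`daily_day_act()`, `index = "day_only"`) keeps just
the $H_d$ term. It exists to ask a scientific question — does daytime
cooling alone explain induction? — not as a recommended index; see the
index comparison below.

## Fitting the sigmoid

`fit_sigmoid()` minimizes the unweighted residual sum of squares of the
observed percentages by Levenberg–Marquardt (through \pkg{minpack.lm})
with an analytic Jacobian and box constraints $Y_{max} \in (0, 200]$,
$B, K > 0$. Percentages are kept on the 0–100 scale throughout the
package; the only 0–1 conversion lives inside the simulator.

Numerical choices worth knowing about:

* **Default start.** $Y_{max,0} = \min(100, 1.05 \max Y)$,
  $K_0 = (\max \mathrm{ACT} - \min \mathrm{ACT})/4$, and $B_0$ solved
  from the lowest-ACT observation and clamped to $[1, 500]$ — a
  moment-style start in the model's own geometry that converges for
  every data shape the simulator produces.
* **The $Y_{max}$ bound is 200, not 100.** Constraining the plateau to
  100 during optimization would let boundary attraction masquerade as a
  physical fit. Instead the bound sits far above the physical range, a
  warning fires whenever the fitted plateau exceeds 100 %, and a fit
  that lands at the 200 bound (possible from starts with jointly large
  $B_0$ and $K_0$, which create a boundary-constrained local optimum) is
  restarted once from the default start, keeping the lower-SSE solution.
* **Convergence tolerances** are `ftol = ptol = 1e-12` with a 200
  iteration cap — tight enough that noise-free data reproduce their
  generating parameters to better than $10^{-4}$ relative, the
  resolution at which published triplets are compared.
* **Failure is explicit.** An optimizer error returns a `sigmoid_fit`
  with `converged = FALSE`, `params = NULL` and the error message, never
  a silent bad answer. Duplicate ACT rows are allowed (independent
  observations); fewer than 4 rows or constant ACT are errors.

Fit quality is reported the way nonlinear-regression software prints it:
$R^2 = 1 - SS_{res}/SS_{tot}$ with $SS_{tot}$ about the mean of the
observed percentages, and the residual standard error
$s = \sqrt{SS_{res}/(n-3)}$ with $n-3$ degrees of freedom (3 fitted
parameters). Both definitions are embedded in every fit JSON. When the
response is constant, $SS_{tot} = 0$ and $R^2$ is reported as `NA`
rather than a fabricated number; $s$ is still computed. A
binomial-likelihood (GLM) alternative would weight the percentages by
cohort size; it is deliberately out of scope because the estimator being
characterized here is least squares on percentages.

```{r}
pooled <- phal_params("pooled")
obs <- data.frame(act_c_h = seq(0, 4000, 100),
                  pct_spiked = predict(pooled, seq(0, 4000, 100)))
fit_sigmoid(obs, init = c(Ymax = 100, B = 10, K = 500))
```

## Scheduling

`required_act()` inverts the fitted curve in closed form,
$\mathrm{ACT} = -K \log[(Y_{max}/Y - 1)/B]$, clamped at zero when the
target is already met at move-in; a target at or above $Y_{max}$ is
rejected with the attainable plateau in the message.
`days_to_target()` divides by the regime's daily increment and rounds
**up** to whole days: plants are moved and scored daily, and a grower
who needs 36.2 days of cooling schedules 37. The returned plan carries
the day-by-day predicted trajectory so the ceiling can always be checked
against the forward curve.

```{r}
days_to_target(pooled, phal_regime("KHM1220"), target = 90)
```

## What the simulator emulates — and what it does not

Raw per-plant induction records for this system are not publicly
deposited, so the package ships a cohort simulator that reproduces the
*statistical structure* the analysis assumes, and the whole fitting and
comparison chain is validated against it.

`generate_cohort()` draws, under the default `plant_threshold` noise
model, one latent uniform threshold per plant; a plant is scored as
spiked on every day where the true curve has reached its threshold.
This makes spiking irreversible (counts are monotone nondecreasing, as
visual scoring of floral buds is), gives each day's count a marginal
Binomial($n$, $p_d$) distribution, and makes the fraction of plants
that ever spike converge to $Y_{max}/100$. An independent-binomial
model (fresh draw each day) is retained for variance calibration, and
`noise = "none"` returns exact curve values. Tables are pure functions
of (spec, seed), and the caller's RNG stream is left untouched.

Defaults mirror the reference experiment: cohorts of 1000 plants, the
22/19 °C cooling room with a 14 h photoperiod, one shared true curve
across the four variety presets (their observed induction curves
coincide in the full ACT index), and the pooled reference parameter
set. Scoring cadence is not stated anywhere authoritative; every 2 days
to day 40 was chosen once as a realistic nursery schedule and is a
package convention, not a claim about any particular study. The
`generate_study_fixtures()` bundle adds a "literature-like" cohort
generated from the previously-reported-data parameter set under a
nominal 110 °C·h/day regime — synthetic stand-ins, clearly so, since
the original regimes behind pooled literature data are unknowable.

What passing tests on these fixtures do **not** show: real cohorts may
violate the shared-curve assumption across varieties, thresholds are
unlikely to be exactly uniform, scoring may miss or double-count buds,
and greenhouse temperatures wander around set-points. The hourly-log
path addresses the last point; the others are why parameter recovery on
simulated data is a consistency check on the machinery, not evidence
about any real cohort.

## Why the full index beats the day-only index

The four variety presets accumulate 190, 110, 96 and 96 °C·h/day under
the shared cooling room. When one true curve in full ACT governs all
four cohorts, rewriting the data on the day-only abscissa rescales each
group by its own factor (140/190 for the 32/24 °C variety, 70/110 for
27/23 °C, 56/96 for 26/23 °C) — the groups land on *different* sigmoid
curves and no single pooled fit can track them all. `compare_indices()`
operationalizes this: one pooled fit per index, per-group residual
spread about each pooled curve, and the index with the smaller pooled
$s$ flagged. The degenerate case is informative too: with a single
group (or identical day/night differential ratios across groups) the
two abscissas are proportional, the sigmoid family absorbs the
rescaling into $K$, and the indices tie — the comparison only separates
them when vegetative histories genuinely differ.

```{r}
fx <- generate_study_fixtures(seed = 1)
compare_indices(do.call(rbind, fx[1:4]))
```

## Problem sizes and reproducibility

The validation suite uses 41-point noise-free grids (ACT 0–4000 by 100)
for parameter recovery, 25–50-case property loops under fixed seeds for
clamping, monotonicity, inversion round-trips (tolerance $10^{-9}$) and
schedule-ceiling checks, and 200 seeded 1000-plant cohort simulations
for stochastic recovery of the plateau — sizes at which every result in
this vignette recomputes in seconds. `run_pipeline()` ties the stages
together (simulate → accumulate → fit → schedule) and writes artifacts
that are byte-identical under a repeated seed, with every configuration
value recorded in the run log.

## Known limitations

* ACT is linear in the temperature differential; any saturation of the
  cold signal at large differentials is outside the model.
* No photoperiod covariate, light-intensity, humidity or fertilizer
  terms: those are held constant in the system the model describes.
* The scheduler does whole-day arithmetic only — no calendar dates,
  holidays or room-capacity optimization.
* Percentages are modelled directly by least squares; cohort-size
  weighting (a GLM) is a possible extension, not an implemented one.
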