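---
title: "Methods: climate-driven population viability analysis for forest bats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: climate-driven population viability analysis for forest bats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(batpva)
```

## The problem

Temperate-zone insectivorous bats in arid western North America are
long-lived, reproduce at most once a year, and usually raise a single pup.
Field series from the Colorado Front Range show that the proportion of adult
female fringed myotis (*Myotis thysanodes*) that are reproductively active
drops in hot, dry years, when maternity roosts heat up and surface water is
scarce. `batpva` asks what such climate-driven fertility variation does to a
population over decades: it couples a four-class female-only Leslie-type
matrix model to a logistic climate-fertility link and projects populations
through 2086 with Monte Carlo simulation under four families of fertility
drivers.

## The matrix model

Four census classes: pups (0–1 yr), yearlings (1 yr), two-year-olds (2 yr),
and a terminal 3+ class. The census falls on day 1 of each year; births on
the last day. A female counted in class $j$ therefore contributes newborn
females

$$a_{1j} = S_j \, F_j \, \tfrac{1}{2},$$

her survival for the year times her class's probability of producing a
viable pup times the female fraction at birth (parity, single pups).
Survivors advance along the subdiagonal and the 3+ class retains itself:

```{r}
A <- projection_matrix(vital_rates())
A
```

Defaults are first-approximation literature rates for western forest bats:
adult survival $S_A = 0.79$, pup survival $S_P = 0.64$, adult fertility
$F_A = 0.85$, yearling fertility $0.9\,F_A$, and no pup-class reproduction
($a_{11} = 0$). With this composition the dominant eigenvalue is

```{r}
eigen_analysis(A)$lambda
```

so the baseline population is essentially stationary, which is the premise
of the stable scenario (we do not know whether real populations are growing
or declining; the model is anchored at $\lambda \approx 1$ on purpose). The
worked expected-offspring products deliberately *exclude* maternal
survival — $E[O_A] = 0.5 \times 0.85 = 0.425$ and
$E[O_Y] = 0.5 \times 0.85 \times 0.9 = 0.3825$ — while the matrix entries
include it, because the expectation describes a female who reproduces while
the matrix entry describes a census cohort that must first survive to the
birth pulse.

### Sensitivity and elasticity

`perturbation_analysis()` varies one vital rate by −10 % (rate × 0.90),
recomputes $\lambda$, and reports the finite-difference sensitivity
$\Delta\lambda / \Delta a_{ij}$ and elasticity
$e_{ij} = (a_{ij}/\lambda)\,\Delta\lambda/\Delta a_{ij}$. Two conventions
matter and were genuinely open:

* **One element per rate.** Each survival rate perturbs only its transition
  element (e.g. $S_{3+} \to a_{44}$, not also the $S$ factor inside
  $a_{14}$), and each fertility rate only its first-row element. Joint
  perturbation of every element containing the rate gives visibly different
  numbers; the single-element convention is the one whose $S_1$, $S_2$ and
  fertility rows agree with the reference elasticities, so it is the
  package's contract.
* **Fertility labels index census classes.** $F_i$ is the fertility of
  class $i$'s column: $F_0$ maps to the pup column whose entry is
  structurally zero (hence zero sensitivity and elasticity — a proportional
  perturbation of 0 is 0), $F_1$ to the yearling column carrying
  $0.9\,F_A$, and $F_2$, $F_{3+}$ to the adult columns. Under this reading
  the anchored reference rows are reproduced within a few percent;
  no composition we tried reproduces the reference $F_0$, $S_0$ and
  $S_{3+}$ *sensitivity* values, which is why only the $S_1$, $S_2$ and
  fertility rows serve as numerical anchors.

`analytic_elasticity()` provides the classical eigenvector elasticities
($e_{ij} = \frac{a_{ij}}{\lambda}\frac{v_i w_j}{\langle v, w\rangle}$),
which sum to exactly 1 and cross-check the finite-difference table (whose
−10 % steps sum to ≈ 0.986 — finite differences of a concave function
undershoot slightly).

### Numerical choices

Eigen-analysis uses a dense `eigen()` decomposition, ordering roots by
modulus then real part; the default matrix is primitive so the dominant
root is unique and real. If a materially complex dominant root appears
(possible only for imprimitive inputs), a power-iteration fallback on
$A + I$ — which shifts every eigenvalue by +1 and breaks rotational
ties — takes over. The stable distribution is clipped at 0 and normalised
to sum 1.

## The climate-fertility link

The probability that an adult female is reproductively active in a year
with mean annual temperature $T$ (°C) and annual precipitation $P$ (mm) is

$$\Pr\{Y = 1\} = \operatorname{logit}^{-1}(\beta_0 + \beta_T T + \beta_P P),$$

with packaged defaults $(\beta_0, \beta_T, \beta_P) =
(2.6419, -0.2534, 0.0040)$: hotter years depress reproduction, wetter years
support it. Covariates enter untransformed — no centring on the 1986–2005
reference means (10.85 °C, 541 mm), which serve only as a documentation
anchor:

```{r}
predict_fertility(logistic_coefficients(), T = 10.85, P = 541)
```

`fit_fertility_model()` refits the model to reproductive-status records by
IRLS (binomial `glm`, logit link, deviance tolerance 1e-8), accepting
per-individual 0/1 records or year-level success/trial counts (these are
likelihood-equivalent and tested as such). Complete or quasi-complete
separation and rank-deficient designs raise explicit errors instead of
returning divergent estimates. The original ~190-record capture dataset
behind the packaged coefficients is not distributed anywhere we can read
it from, so all fitting exercises run on synthetic records generated under
the packaged truth; at that historical sample size the climate slopes are
recoverable only with wide standard errors, which is worth remembering
when interpreting downstream projections.

## Scenario drivers

Every scenario is a per-year triple (central fertility, min, max) for
2009–2086. The table carries 78 calendar rows; a simulation replicate
starting from the 2009 census performs 77 annual transitions and so
consumes the fertilities of 2009–2085 (a year-$y$ birth is censused on day
1 of $y+1$).

* **Stable** — central $F_A$ every year, envelope $(0.9, 1.1) \times$
  central. The 0.9/1.1 multipliers are the environmental-stochasticity rule
  and are config-overridable.
* **Yearly series** — central from `predict_fertility()` at each year's
  $(T, P)$; envelope from the extremes over the four corners of
  $(T_{\min}|T_{\max}) \times (P_{\min}|P_{\max})$. Corner evaluation is
  exact for a monotone link; corners are evaluated explicitly so either
  coefficient sign works.
* **Step ramp** — "equivalent change each year including 2070" is read as
  a linear ramp anchored at the 2008 baseline that hits the 2070 endpoint
  exactly and continues at the same slope through 2086; that is the only
  reading under which every year carries the same increment. Central values
  are floored at 0.
* **Ensemble endpoint** — year-2070 fertility predicted per
  (location, climate model), averaged over models within location, then
  over locations. With complete tables this equals the flat grand mean
  (asserted in tests); missing model entries are excluded and counted.
  `fertility_change_table()` reports the per-location change
  $\Delta_i$ = mean-over-models 2070 prediction − baseline prediction and
  the grand mean $\bar\Delta$.

The Boulder-ensemble style endpoint can be supplied either as an extracted
climate pair or directly as a fertility value, so real reproductions are
possible when a user supplies extracted climate while the packaged tests
stay self-contained.

## Monte Carlo engine

Each replicate draws, per year, one triangular deviate per vital rate and
age class: four survivals on $((1-h)S,\, S,\, \min((1+h)S, 1))$ with
demographic half-width $h = 0.10$ by default, and three fertilities on the
year's envelope scaled per class (yearlings ×0.9, pups 0). The triangular
inverse CDF is implemented directly (no installed package provides it; it
is also the model's stochasticity primitive): linear-density triangle,
peak at the mode, draws bounded by construction. Survival draws are capped
at 1; fertility draws are not — in a good year the expected offspring of a
class may exceed the central rate.

Design choices that were genuinely open:

* **Rates, not fates.** States stay real-valued: the model randomises
  rates, not individual survival outcomes, so there is no binomial
  sampling; totals are rounded only at reporting.
* **Survival noise bounds.** The ±10 % demographic half-width for survival
  is not dictated by the fertility rule but mirrors it; it reproduces the
  reference stable-run spread (SD ≈ 430 vs the reference 415) and is
  exposed in `simulation_config()`.
* **No double-counting.** When a scenario supplies an environmental
  envelope, the fertility draw uses that envelope alone; demographic ±h
  fertility noise applies only when environmental noise is switched off.
  Toggles allow either source alone; with both off the engine reproduces
  the deterministic matrix product exactly (degenerate triangles sample
  their mode).
* **Reproducible parallel streams.** One root seed yields per-replicate
  child seeds by counter; each replicate consumes its own `runif` stream,
  so results are bit-reproducible and independent of replicate ordering.
  This is asserted by stepping single replicates by hand in the tests.

The default initial vector (600, 290, 230, 880) — 2,000 females — is the
conventional starting state of the reference analysis. It is close to, but
not exactly, the stable distribution of the default matrix (which would be
≈ 495/316/250/939); both are supported, the conventional vector is the
default, and the ≈ 2 % gap between the two 77-year deterministic finals
(2003 vs 2047) is part of the stochastic-run tolerance budget.

## What the synthetic generators emulate — and what they do not

`gen_climate_series()` (linear trend + Gaussian jitter, fixed-half-width
envelopes), `gen_repro_records()` (Bernoulli statuses under a known
logistic truth), and `gen_occurrence_table()` (baseline climates with
across-location spread; per-model 2070 offsets + jitter) emulate the three
external inputs of the original pipeline: agency climate tables, capture
records, and occurrence-climate extractions. Defaults mirror the reference
system: 13 years × ~15 records (~190 records), Boulder-like baseline
(10.85 °C, 541 mm), eleven model labels whose offsets straddle a mid-range
2070 warming, and a 2,038-location scale for range-wide tables. Where the
sources state no value we chose once what is realistic for the region
(interannual jitter 0.6 °C / 60 mm; envelope half-widths 1 °C / 80 mm;
across-location spread 2.5 °C / 120 mm) and did not revisit it.

Deliberately absent: spatial autocorrelation (no downstream computation
uses it), within-year climate structure, observation error in reproductive
classification, and any survival-climate link (the model assumes survival
unaffected by climate). Passing tests therefore demonstrate the machinery
and its internal consistency under the stated conditions — not that real
fringed myotis populations will follow these trajectories. The projections
are first-approximation models.

## Problem sizes

The packaged analyses and tests run the full reference design where it is
cheap — 10,000 replicates × 77 years for the stable-scenario checks
(about two seconds) — and smaller designs elsewhere: 500–2,000 replicates
for distributional properties, ~5,000 synthetic records for
parameter-recovery checks, 50–2,038 locations for pooling checks. Each
size is stated where it is used.

## Known limitations

* Table rows for the reference Boulder/General climate scenarios require
  extracted NCAR/WorldClim/GBIF climate, which the package does not ship;
  those runs are demonstrated on synthetic endpoints instead.
* The printed dataset-wide reproductive proportion (0.887) is not the
  arithmetic mean of the printed yearly proportions (0.8795); the yearly
  sample sizes needed to reconcile them are not public, and the package
  reports the honest mean.
* Fertility labels/elasticity conventions are reconstructed (see above);
  the reference $F_0$, $S_0$, $S_{3+}$ sensitivity rows are not reproduced
  by any single-element convention we tried.
* No density dependence, two-sex structure, stage-duration distributions,
  twinning, or extinction-time analysis beyond final-year summaries.

## Interfaces

The analysis scripts under `analysis/` are the workflow surface
(demography → fertility model → scenarios → simulations); every
computation they narrate lives in package functions, and
`scripts/acceptance.R` recomputes the headline quantities from scratch.
Readers/writers cover the CSV dialects (climate series, occurrence tables,
reproductive records, result tables), vital-rate JSON/YAML configs, and
JSON run manifests pairing each emitted result with its provenance.
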