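---
title: "Methods: groundwater quality and nitrate risk assessment with aquachem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: groundwater quality and nitrate risk assessment with aquachem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquachem)
```

aquachem implements the standard analysis battery for a major-ion
groundwater survey — the kind of campaign where a few dozen wells and
springs are sampled once, the laboratory reports mg/L concentrations of
the eight major ions plus nitrate, and the analyst must answer three
questions: *what controls the water's chemistry, is it fit to drink and
irrigate with, and how dangerous is its nitrate to people who drink it?*
This vignette documents the models, the default parameters and the design
decisions, in enough detail to audit or override any of them.

## 1. Units and quality control

All chemistry is computed on milliequivalents per liter:
meq/L = mg/L × |z| / M, with fixed IUPAC molar masses (`ion_meta()`):
K 39.098, Na 22.990, Ca 40.078, Mg 24.305, Cl 35.453, SO₄ 96.06,
HCO₃ 61.016, CO₃ 60.008, NO₃ 62.004 g/mol. A missing CO₃ column is
treated as 0 mg/L, appropriate for the near-neutral, HCO₃-dominated
waters the package targets.

Analytical QC uses the charge-balance error

$$\mathrm{CBE} = 100\%\times\frac{\sum \mathrm{cations}-\sum \mathrm{anions}}
{\sum \mathrm{cations}+\sum \mathrm{anions}},$$

with cations {K, Na, Ca, Mg} and anions {Cl, SO₄, HCO₃, CO₃, NO₃} in
meq/L and the conventional acceptance |CBE| ≤ 5%. Total hardness uses the
CaCO₃-equivalent convention TH = 2.497 Ca + 4.118 Mg (each ion's meq
times 50.04 mg CaCO₃ per meq); a `th` column supplied in the input takes
precedence over the derived value.

Threshold classifiers are lower-bound inclusive on the *named* range:
TDS < 1000 mg/L is fresh (1000 itself brackish), TH < 150 mg/L soft,
and well depths 0–20 m / 20–50 m / > 50 m are shallow / middle / deep
with the upper bound belonging to the shallower class (20 m is shallow).
Exceedance screens (e.g. nitrate against the 20 mg/L class III limit)
are strict (>): a sample exactly at the limit does not exceed it.
Summary tables report the sample (n−1) standard deviation and
CV = SD/mean, the convention of survey statistics.

## 2. Facies and source attribution

* **Piper coordinates.** Cation fractions (Ca, Mg, Na+K) and anion
  fractions (HCO₃+CO₃, SO₄, Cl) as percent of each class's meq total;
  the diamond point is the intersection of the +60° line through the
  cation-triangle point and the −60° line through the anion-triangle
  point, the classical geometric construction.
* **Shchukarev types.** Every ion contributing ≥ 25% of its class's meq
  total, anions first then cations, each group in decreasing order —
  the classical inclusion threshold, configurable.
* **Gibbs regions.** The mechanism regions (rock, precipitation,
  evaporation dominance) are advisory boxes on the TDS-versus-ratio
  plane — rock: TDS 70–1000 mg/L and ratio ≤ 0.7; precipitation:
  TDS < 70 and ratio ≥ 0.5; evaporation: TDS > 1000 and ratio ≥ 0.5;
  otherwise "outside". The published envelope is drawn by eye, so the
  continuous ratios Na/(Na+Ca) and Cl/(Cl+HCO₃) are the primary output
  and the boxes are fully configurable.
* **Ratios.** Endmember ratios (Mg/Na, Ca/Na, HCO₃/Na), the carbonate
  index (Ca+Mg)/HCO₃ (> 1 carbonate weathering dominant), the evaporite
  index (Cl+SO₄)/HCO₃ and the anthropogenic ratios Cl/Na, NO₃/Na are
  computed on meq/L by default (`basis = "mg"` available); ratios with
  zero denominators are flagged `NA` rather than failing.
* **Cation exchange.** CAI-I = (Cl − (Na+K))/Cl and
  CAI-II = (Cl − (Na+K))/(SO₄+HCO₃+CO₃+NO₃) (Schoeller's definitions,
  on meq/L): both negative means aquifer Na/K is being released in
  exchange for Ca/Mg. The exchange regression fits
  Mg+Ca−SO₄−HCO₃ against Na+K−Cl by OLS; a slope near −1 is the
  equivalence-for-equivalence signature of alternate cation adsorption.
* **Correlation screen.** Pairwise Pearson r with two-sided p from the
  t-transform on n−2 degrees of freedom, starred at p < 0.10 / 0.05 /
  0.01, on pairwise-complete observations. No multiple-testing
  correction is applied — the screen is exploratory, and that choice is
  deliberately visible here.

## 3. Drinking-water quality index

With per-parameter weights $w_i$ and permissible standards $S_i$,

$$W_i = \frac{w_i}{\sum w_i},\qquad
\mathrm{WQI} = \sum_i W_i \frac{C_i}{S_i}\times 100,\qquad
EW_i = \frac{W_i\, C_i/S_i}{\mathrm{WQI}}\times 100,$$

classed excellent (< 50), good (50–100), poor (100–200), very poor
(200–300), non-drinkable (≥ 300), lower bounds inclusive. The default
table (`wqi_weights()`) covers {pH, TDS, TH, Ca, Mg, Na, K, Cl, SO₄,
HCO₃, NO₃} with weights {4, 4, 3, 3, 3, 3, 2, 4, 4, 2, 5}; standards are
the Chinese GB/T 14848-2017 class III limits where that standard
regulates the parameter (TDS 1000, TH 450, Na 200, Cl 250, SO₄ 250,
NO₃ 20 mg/L, pH envelope 6.5–8.5) and common guideline values otherwise
(Ca 75, Mg 50, K 12, HCO₃ 300 mg/L). Nitrate and pH carry the largest
weights, reflecting their dominance of drinking-water concern in
nitrate-impacted aquifers; on default synthetic cohorts they are indeed
the top effective weights. Everything is overridable by passing any
`parameter`/`weight`/`standard` tibble.

pH needs a rating rule because a raw C/S ratio would score strongly
acidic water as *better*: the package rates pH as |pH − 7| / (S_pH − 7)
with S_pH = 8.5, so neutral water contributes nothing and water at the
envelope edge rates 1.0, exactly like a parameter at its standard. This
is a documented design choice, replaceable by supplying a pre-computed
rating column.

Parameters in the weight table but absent from the data are dropped with
the remaining weights renormalised (warned, never silent).

## 4. Irrigation suitability

On meq/L:

$$\mathrm{SAR} = \frac{\mathrm{Na}}{\sqrt{(\mathrm{Ca}+\mathrm{Mg})/2}},\quad
\%\mathrm{Na} = 100\,\frac{\mathrm{Na}+\mathrm{K}}
{\mathrm{Na}+\mathrm{K}+\mathrm{Ca}+\mathrm{Mg}},\quad
\mathrm{RSC} = (\mathrm{CO}_3+\mathrm{HCO}_3)-(\mathrm{Ca}+\mathrm{Mg}).$$

%Na includes K in both numerator and denominator, as is standard for the
soluble-sodium percentage. Hazard bands are lower-bound inclusive:
SAR < 10 / 10–18 / 18–26 / > 26 and %Na < 20 / 20–40 / 40–60 / 60–80 /
> 80.

The USSL grid crosses salinity classes C1–C4 (EC < 250 / 250–750 /
750–2250 / ≥ 2250 µS/cm) with sodium classes S1–S4. By default the
S-classes use the fixed SAR bands above (matching how survey tables are
usually reported); `sloped = TRUE` switches to the classical
downward-sloping boundaries, declining linearly in log₁₀(EC) from
10/18/26 at EC = 100 to 2.5/6.5/11 at EC = 5000 µS/cm.

The five Wilcox regions are approximated by slanted boundary lines of
constant u = EC/3000 + %Na/90 at u = 0.5, 1, 1.5, 2 — both hazards push a
sample toward "unsuitable", boundary points take the safer (less
suitable) class, and anything beyond the chart envelope (EC > 3500) is
unsuitable with a warning. The published region boundaries are drawn,
not defined, so these lines are a configurable approximation
(`ec_scale`, `pna_scale`, `breaks`); the underlying EC and %Na values
are always returned alongside the class.

When EC was not measured it is estimated as TDS/0.64 µS/cm and flagged
(`ec_estimated`), the usual conductivity-to-TDS factor for fresh
groundwater.

## 5. Nitrate health risk

The oral-ingestion model:

$$E = \frac{C \times IR \times EF \times ED}{BW \times AT},\qquad
HQ = \frac{E}{RfD},$$

with HQ > 1 (strictly) deemed unacceptable. Default exposure parameters
(`exposure_params()`, editable tibble):

| group    | IR (L/d) | EF (d/a) | ED (a) | BW (kg) | AT (d)   | RfD |
|----------|----------|----------|--------|---------|----------|-----|
| infant   | 0.6      | 365      | 1      | 9       | ED × 365 | 1.6 |
| child    | 1.0      | 365      | 10     | 20      | ED × 365 | 1.6 |
| teenager | 1.4      | 365      | 8      | 50      | ED × 365 | 1.6 |
| adult    | 1.5      | 365      | 30     | 60      | ED × 365 | 1.6 |

These are Chinese exposure-factor handbook values for non-carcinogenic
drinking-water risk; with EF = 365 and AT = ED × 365 the model reduces to
HQ = C·IR/(BW·RfD), so group ordering is fixed by the intake-to-weight
ratio — infants highest, adults lowest, for any concentration
distribution. Nitrate is used exactly as reported; set
`nitrate_basis = "as_n"` to convert nitrate-N input to the NO₃ ion basis
(× 4.427).

Monte Carlo propagation treats C, BW and IR as independent random inputs
(point-mass, moment-matched lognormal, truncated-normal or triangular
families), holding EF, ED, AT, RfD fixed, with 10,000 iterations by
default and every draw tied to a seed. Negative draws are rejected and
resampled (bounded attempts). With point masses everywhere the simulated
HQ equals the deterministic value bit for bit — the degenerate case is
the correctness anchor, and a moment-matched lognormal concentration has
a closed-form mean against which the simulated mean is checked. The
pipeline's default input distributions are: C lognormal moment-matched to
the cohort's positive nitrate values; BW truncated-normal (mean = group
BW, sd = 15% of it, left-truncated at 0); IR triangular
(0.5·IR, IR, 1.5·IR) — modest, symmetric uncertainty around the
deterministic intake values.

## 6. The synthetic survey generator

The raw data of real campaigns are rarely published, so the package
ships a generator (`synthesize_samples()`) that emulates a
tropical-island survey well enough to exercise and statistically
validate every stage.

* **Marginals.** Each ion and TDS is lognormal, moment-matched exactly
  (σ² = log(1+CV²), μ = log(mean) − σ²/2) to the target mean/SD in
  `hainan_marginals()` — the defaults reproduce a published campaign's
  summary statistics, with CVs of 0.75–1.61 motivating the right-skewed
  family. pH is a truncated normal on [5.11, 9.37] whose *parent* mean
  and SD are solved numerically (Nelder–Mead on the truncated-moment
  equations) so that the truncated distribution hits the target moments;
  a target SD above the (upper−lower)/√12 uniform limit is reported as
  infeasible, naming the analyte.
* **Dependence.** A Gaussian copula. For target Pearson correlations
  between lognormal margins the latent correlation is recovered by exact
  inversion of the attenuation identity
  r = (e^{ρσ₁σ₂} − 1)/√((e^{σ₁²}−1)(e^{σ₂²}−1)) — no iteration needed.
  Default targets: Na–Cl 0.92, Ca–HCO₃ 0.78, Mg–HCO₃ 0.70, NO₃–K 0.71,
  the marine/evaporite, carbonate-weathering and agricultural-input
  signatures of the emulated system. Unspecified concentration pairs
  share a background latent correlation of 0.45 — a common
  ionic-strength factor; fully independent residuals would make total
  hardness and charge balance far more dispersed than any real
  campaign — and pH is left uncorrelated. If the assembled matrix is not
  positive definite it is projected to the nearest correlation matrix
  (reported via a message).
* **Ancillary columns.** Depth classes are drawn with proportions
  shallow 0.45 / middle 0.35 / deep 0.20 (a plausible mix for a
  civilian-well campaign spanning 3.5–340 m; uniform within class,
  log-uniform for deep wells). EC = TDS/0.64 with 5% multiplicative
  noise; CO₃ is 0.
* **Charge balance.** Independent heavy-tailed marginals cannot satisfy
  electroneutrality: with the calibrated copula the raw CBE has an SD
  near 11%, and the four strong cross-class correlation targets leave
  the latent matrix near-singular, so no admissible correlation
  structure tightens it much further. The generator therefore repairs
  samples outside the QC band. Two methods are provided. The
  single-ion method rescales the one candidate ion (Na or Cl by
  default) needing the smallest meq change, leaving everything else
  untouched — transparent, but it concentrates the correction and
  measurably biases the Na and Cl marginals when many samples need
  repair. The default proportional method multiplies the cation vector
  by f and the anion vector by 1/f with f chosen to land the sample
  just inside the tolerance boundary — the minimal log-scale L2
  perturbation across all ions. Proportional repair preserves every
  marginal mean (within 3% at n = 10,000) and every cation SD; its known
  residual cost is a compression of the two heaviest anion tails
  (Cl SD ≈ −6%, NO₃ SD ≈ −9% relative to target) and a slight
  strengthening of cross-ion correlations, because rebalancing is, by
  construction, a dependence between the two sides of the charge
  ledger. Analyses that need the untouched copula marginals should
  generate with `cbe_repair = FALSE`; `validate_synthetic()` reports
  achieved-versus-target moments, correlations and the QC pass rate for
  whichever dataset it is given.
* **Reproducibility.** One seed drives every draw; the same seed and
  configuration give a byte-identical dataset.

Validation problem sizes: the statistical recovery checks in the test
suite run the generator at n = 10,000 (moments and correlations of the
copula stage; QC pass rate of the repaired stage) and n = 20,000 for the
pH truncation check — sizes at which sampling error is comfortably
inside the 3%/5%/±0.05 recovery tolerances while the whole suite stays
fast. Cohort-level demonstrations use the survey-sized n = 63.

What passing these checks does *not* show about real data: the generator
has no spatial structure, no seawater-intrusion mixing endmember, no
geology-conditioned stratification with depth, no detection-limit
censoring and no analytical error model. It demonstrates that the
*methods* are computed correctly and behave sensibly on realistic
magnitudes, not that any particular aquifer looks like its output.

## 7. Numerical conventions and degenerate inputs

* Zero denominators in ratios produce per-quantity `NA` flags, never
  errors; all-zero ionic content makes CBE undefined and fails QC
  explicitly.
* All classifier bands are lower-bound inclusive; exceedance tests are
  strict.
* Charge-balance repair targets the nearest tolerance boundary scaled by
  (1 − 10⁻⁹) so floating-point round-off cannot leave a repaired sample
  infinitesimally outside the band; unrepairable samples (non-negativity
  binding) are flagged, not dropped.
* The exchange regression refuses degenerate designs (zero x-variance,
  fewer than 3 complete pairs) with explicit errors.
* `run_pipeline()` embeds the seed, a configuration hash and the package
  version in every report bundle; a rerun from the same configuration is
  bit-identical.

## 8. Known limitations

* The WQI weight/standard table and the exposure-parameter table are
  literature defaults, not the (unpublished) tables of any specific
  study; absolute WQI and HQ levels shift with those choices, while
  the structural results (identity WQI = 100 at standards, EW summing to
  100%, group orderings) do not.
* The Wilcox and Gibbs region boundaries are documented approximations
  of charts that were originally drawn, not defined.
* The correlation screen applies no multiple-testing correction.
* Monte Carlo inputs are sampled independently (no copula between C, BW,
  IR), consistent with treating them as three separate uncertainty
  sources.
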