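---
title: "Yield-scaled environmental impacts of reactive nitrogen losses: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Yield-scaled environmental impacts of reactive nitrogen losses: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nrimpact)
```

`nrimpact` estimates the environmental burden of reactive nitrogen (Nr)
losses from wheat, maize and rice production — per megagram of grain and as
national totals — and couples mitigation-strategy effects with yield
responses. This vignette is the package's account of its statistical
methods: the model and its assumptions, the parameters that matter, the
synthetic data the tests rest on, and the places where the design was
genuinely open.

## 1. Data model

The unit of analysis is a pairwise field comparison: a fertilized treatment
and its control, observed over one growing season, with

* seasonal Nr loss means for one pathway (NH₃ volatilization, N₂O emission
  or NO₃⁻ leaching), in kg N ha⁻¹;
* grain yields in Mg ha⁻¹ and replicate counts per arm;
* a dispersion record per arm: an SD, or one of SE / CV / CI / t / p, or
  nothing;
* management descriptors — N source (urea, other synthetic fertilizers
  `OCF`, improved slow-release urea `IU`, organic sources `OA`), N rate,
  placement (surface / subsurface), amendment (none / mulch / biochar /
  inhibitor);
* six environmental moderators: seasonal mean temperature (°C), water load
  (precipitation + irrigation, mm), soil pH, SOM, STN and clay (g kg⁻¹).

N rates partition into three classes: `R1` below 150 kg N ha⁻¹ (reduced
rate), `R2` in [150, 250) (conventional) and `R3` at 250 and above
(excessive). The class bounds are quoted with strict inequalities in the
source literature, which leaves 150 and 250 unassigned; we use half-open
intervals so the partition is total — round-number rates are common in
field trials and silently dropping them would bias group membership. The
crop-specific conventional ranges (150–250, 200–260, 170–260 for
wheat/maize/rice) are retained as schema metadata but grouping uses the
generic cutoffs.

The **baseline practice** — the reference for every strategy comparison —
is urea at R2, surface-applied, with no amendment. Each mitigation strategy
varies exactly one lever away from it.

## 2. Dispersion imputation

Meta-analytic weighting needs an SD per arm; field papers frequently report
something else. The completion hierarchy is:

1. a reported SD is never touched;
2. exact closed forms: `SD = SE·√n`; `SD = CV/100 · mean`;
   `SD = √n (U − L) / (2 t_{1−α/2, n−1})` for a CI (t quantile by default —
   agronomy CIs are overwhelmingly t-based; a normal-quantile flag exists);
   t statistics are inverted through `SE_D = |MD/t|` and the pooled-SD
   identity; two-sided p values are first converted to `|t|` with
   `n₁+n₂−2` df. t and p describe the comparison, not an arm, so they yield
   one pooled SD assigned to both arms;
3. records reporting nothing receive `SD = ratio × mean`, where `ratio` is
   the bootstrap mean of the SD/mean ratio over complete cases in the
   record's crop × pathway stratum (default 2,000 resamples, seed
   mandatory). Stratification by crop × pathway was our choice — the source
   method does not say over which set its ratio was computed — because
   dispersion scales differ by an order of magnitude between pathways.
   Strata with fewer than 5 complete cases refuse to impute and flag their
   records instead of guessing.

Imputed SDs are treated as known downstream; no multiple-imputation
uncertainty is propagated. Shapiro–Wilk screening (`normality_screen()`,
p < 0.05) is available for QC of raw and derived vectors.

## 3. Random-effects pooling

Effect sizes are raw mean differences with the pooled-SD variance
`V_D = (n₁+n₂)/(n₁n₂) · s²_pooled`. Groups are pooled with inverse-variance
weights `1/(V_i + τ²)`, where τ² is the DerSimonian–Laird method-of-moments
estimate. DL is the tested default because it is closed-form and verifiable
by hand; a REML option sits behind a flag (`method = "REML"`) and is
cross-checked against `metafor` in the test suite. The 95% CI uses the
normal multiplier 1.96; Knapp–Hartung adjustment is deliberately not
applied. Heterogeneity is reported as Cochran's Q (with its p), I², and
per-group between-study variance; publication bias as Rosenthal's fail-safe
N (two-sided α = 0.05, `⌊(Σz)²/z²_{0.975} − k⌋`) and the Egger regression
of `es/se` on `1/se` with funnel coordinates for plotting.

For the *absolute* per-Mg potentials the pairwise language defines no
control, so two modes exist: `single_group` (default) pools the
treatment-arm value with per-record variance `s²/n`; `difference` pools
treatment-minus-control contrasts. The default is a config switch, not a
claim about which the source analysis used.

## 4. Impact conversion and upscaling

Yield-scaled losses (`loss/GY`, kg N Mg⁻¹) convert to potentials with fixed
equivalency factors — 58.75 acid equiv. per kg NH₃-N, 298 kg CO₂ equiv. per
kg N₂O-N (100-year horizon), 0.1 kg PO₄ equiv. per kg NO₃-N. The defaults
are pinned by tests; overrides exist for sensitivity analyses (e.g.
alternative GWP₁₀₀ values). N₂O inputs are interpreted as N₂O-N; a flag
applies the 28/44 molecular conversion for datasets reporting the molecule.
Indirect N₂O from volatilized or leached N, CH₄, and N₂O's contribution to
acidification are out of scope.

National totals multiply a per-Mg potential by provincial grain production
and divide by 10⁹ (kg → Tg, AP and GWP) or 10⁶ (kg → Gg, AEP). The sums are
linear in production, so totals are invariant to how national production is
partitioned over provinces; a single pseudo-province row carrying national
production is mathematically identical and accepted. Grain production
itself converts Mg → Tg via 10⁶.

Strategy coupling applies the identity chain
`effect% = 100·(D_b − D_s)/D_b` and `T_s = T_b·(1 − effect%/100)` — exactly
equivalent to `T_s = T_b · D_s / D_b`, which the tests assert to 1e-12
relative. Positive percentages mean the strategy decreases the quantity
below baseline. Groups with fewer than `min_k = 3` comparisons are emitted
as explicit rejected rows; the source analysis rejected sparse groups via
heterogeneity p-values but states no count, and a count threshold is more
transparent (the heterogeneity p is logged alongside). Yield outcomes run
through the same machinery with `D` = pooled yield; the observation schema
carries no yield dispersion, so yield records are weighted with an assumed
CV (`cv_yield = 0.10`, configurable) — a pragmatic choice documented here
rather than hidden.

## 5. Driver meta-regression and importance

For each crop × impact group, effect sizes are regressed on subsets of the
six moderators with weights `1/(v_i + τ²_resid)`. Residual τ² uses the
DL-type method of moments on the weighted residuals
(`τ² = max(0, (Q_E − (k−p))/tr(P))`); REML is available behind a flag.
Moderators are z-standardized before fitting so slopes are comparable
across drivers with different units; raw-scale slopes are reported
alongside, and model ranking is invariant to affine rescaling of any
moderator. Perfectly collinear or constant drivers raise a named error,
never a silent fit.

All 2^p subsets (p ≤ 12) are ranked by
`AICc = −2ℓ + 2q + 2q(q+1)/(k−q−1)` with `q` = coefficients + 1 for the
residual variance. Akaike weights `exp(−Δ/2)/Σexp(−Δ/2)` sum the evidence;
a driver's importance is the total weight of models containing it, with
0.8 as the cutoff between unimportant and important. Both the best-model
and model-averaged slopes are emitted, since the source figures do not say
which they show. Missing moderators are handled complete-case per candidate
model with per-model row counts logged, so AICc-comparability caveats stay
visible. Pseudo-R² is the clamped proportional τ² reduction
`max(0, (τ²_null − τ²_model)/τ²_null)` — the source prints R² without a
formula, and proportional heterogeneity reduction is the standard
meta-regression analogue.

A calibration caveat the tests quantify rather than hide: with six
independent pure-noise moderators at k = 300, at least one spurious
importance exceeds 0.8 in roughly 14% of replicates (measured 14/100; the
AICc penalty of 2 per parameter corresponds to flagging a null driver at
|z| ≈ 2.2, i.e. ~3% per driver family-wise over six). Summed Akaike-weight
importance at a fixed 0.8 cutoff is therefore mildly anti-conservative as a
family-wise test; single-driver conclusions should be read together with
the slope's p-value.

## 6. The synthetic-data generator

`sim_config()` / `simulate_observations()` generate observation databases
whose statistical structure matches what the analysis assumes, with ground
truth serialized for every downstream estimate. Defaults are the study
conditions: 1,893 pairwise datasets split 60/21/19% over NH₃/N₂O/NO₃,
equal crop shares (no crop split is published; a neutral third each),
40% of each crop × pathway cell under the baseline practice and the rest
spread evenly over the nine strategies, true baseline per-Mg potentials
equal to the published pooled values (AP 131/109/153 acid equiv., GWP
74/33/35 kg CO₂ equiv., AEP 0.37/0.34/0.03 kg PO₄ equiv. for
wheat/maize/rice), between-study SD at 15% of the group mean,
within-replicate CV 20%, 3–4 replicates, conventional rates centred on
200/230/215 kg N ha⁻¹, a 30% missing-dispersion rate, and moderators drawn
uniformly from realistic seasonal ranges (temperature 7–24 °C, water load
20–2,000 mm, pH 5–8.5, SOM 5–40, STN 0.5–2.5, clay 100–500 g kg⁻¹).
Moderator slopes default to zero — no published magnitudes exist to copy —
and tests plant known slopes when power is the question. Strategy effects
default to plausible signed percent shifts per lever (e.g. rate reduction
cuts losses 25% and yield 15%; inhibitors cut losses 35% and raise yield);
recovery tests override them with configured truths.

Generation is hierarchical: study-level true yield-scaled losses are
`Normal(μ_group, τ²)`; reported arm means add replicate-level sampling
noise `Normal(0, s²/n)`. The replicate-noise scale is set by the *group*
mean rather than each study's own draw — otherwise inverse-variance weights
correlate with the effect sizes and the weighted mean is biased low by
construction, an artifact of the generator rather than the estimator.
Dispersion masking uses exact inverse transforms (SE = SD/√n, CV =
100·SD/mean, CI from the t quantile, t/p from the comparison), so
imputation recovery is testable to numerical precision where closed forms
apply. Identical seeds give byte-identical output.

What the generator does *not* emulate: geographic structure beyond
range-matched moderators, correlation between moderators and management,
non-normal study-effect distributions, yield dispersions, multi-season
dependence, or the real observation database's values. Passing recovery
tests therefore demonstrates the estimators' correctness under the assumed
model, not the field accuracy of any published estimate.

`simulate_province_yields()` allocates each crop's national production
(defaults 131.4 / 257.2 / 212.1 Tg for wheat/maize/rice) over 31 provinces
with random weights, rounded to whole Mg by largest remainder so provincial
productions sum exactly to the target.

## 7. Numerical choices and degenerate inputs

* τ² estimates are floored at zero; k = 1 groups pool trivially with
  τ² = 0 and report no heterogeneity statistics.
* Both arm SDs zero is a hard error (`zero-variance`), not an infinite
  weight; empty groups are errors, not NaNs.
* Zero-N rates are never classified into a rate class (domain error).
* The REML profile is optimized on [0, 10·max(var, DL)] with a boundary
  check at zero.
* The bootstrap preserves and restores the caller's RNG state.
* Grid-search cross-checks in the tests refine to 1e-6; algebraic
  identities (coupling round-trip, upscaling linearity) are asserted to
  1e-12 relative.

## 8. Problem sizes used by the tests

Unit tests run on hand-sized fixtures (k ≤ 20). Recovery tests use a
database of 6,250 records (k = 500 in the NH₃ baseline groups, matching a
k = 200–500 recovery regime), 100-replicate calibration runs at k = 300 for
driver importance and Egger/Shapiro screening, and 2,400–2,500-record
databases for strategy recovery. The acceptance script pools the default
1,893-record database. These sizes were chosen to keep Monte-Carlo error
well inside the asserted bounds.

## 9. Known limitations

* DL τ² and the normal-multiplier CI understate uncertainty for very small
  k; REML plus Knapp–Hartung would be the conservative alternative.
* Imputed SDs enter as known; dispersion-imputation uncertainty is not
  propagated into pooled variances.
* Single-group pooling of absolute per-Mg means treats the treatment arm as
  an absolute level; if the intended estimand is the increment over a
  zero-N control, use `mode = "difference"`.
* Importance at a fixed 0.8 cutoff is anti-conservative family-wise
  (Section 5).
* National upscaling assumes the pooled per-Mg burden applies uniformly
  across provinces; no spatial disaggregation below province is attempted.
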