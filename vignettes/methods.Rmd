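---
title: "Methods: normative APM scoring and six-month outcome prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: normative APM scoring and six-month outcome prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proprioscore)
```

This vignette documents the models implemented in `proprioscore`, the
assumptions behind them, the choices made where the design was genuinely
open, and what the synthetic cohorts do and do not emulate.

## 1. The arm position matching task and its parameters

One APM session is 54 trials: 9 targets on a 20 cm × 20 cm square (8 outer
targets around a centre target), each presented once per block in
pseudorandom order, 6 blocks. The robot moves the affected arm; the
participant mirror-matches with the other arm, so matched positions are
reflected about the body midline (x-axis reflection, `mirror_match()`)
before any comparison. Coordinates are metres throughout.

Four parameters, each per axis, summarise a session
(`apm_parameters()`):

* **Absolute Error** (m) — mean |mirrored match − robot|. Overall accuracy.
* **Variability** (m) — the sample SD (n − 1) of the mirrored matched
  positions across a target's 6 repetitions, averaged over the 9 targets.
* **Contraction/Expansion** (ratio) — range of per-target mean mirrored
  matches across the 8 outer targets ÷ range of the robot targets; < 1
  means the perceived workspace is shrunken.
* **Shift** (m, signed) — mean (mirrored match − robot); a systematic
  displacement of the perceived workspace.

The exact formulas used by the proprietary analysis software that
accompanies the robot are not public; the definitions above are this
package's normative definitions, chosen to match the parameters' published
qualitative descriptions (per-axis scoring, "lower contraction/expansion =
more contraction", best score = 0 after folding). They may deviate in
detail from the vendor implementation, and the package documents them as
its own contract. The centre target is identified geometrically (the
target closest to the centroid of the per-target robot means) rather than
by a fixed index, so sessions from any target-numbering convention score
identically.

## 2. Normative model

The scoring chain converts a raw parameter value into a z-score relative
to a healthy control population of the same age, sex and handedness:

1. **Box-Cox** (`fit_boxcox()`): a location shift `1 − min(x)` (when
   `min(x) ≤ 0`) makes values positive; the exponent is chosen by profile
   maximum likelihood on the fixed grid −5…5, step 0.01. A grid keeps the
   fit deterministic and makes refits bit-identical.
2. **Trimming** (`trim_outliers()`): transformed values beyond ±3.29 SD
   (two-sided normal tail ≈ 0.1%) are removed once, before the regression.
   The source description is ambiguous about whether trimming precedes the
   covariate regression; we trim first, and the held-out calibration tests
   confirm the chain is well calibrated under that order.
3. **Weighted regression**: transformed values on age + sex + handedness,
   per-observation weight 1/(sessions contributed by that subject), so
   subjects assessed repeatedly do not dominate the norms. The weighting
   scheme is unspecified in the source; inverse session count is this
   package's choice. The weighted residual SD completes the z-score.
4. **Folding** (`one_sided_transform()`): absolute error and variability
   are one-sided (only high values are bad; negative z clamps to 0); shift
   and contraction/expansion are two-sided (|z|). The assignment is a
   package decision — the source only states that 0 is best.
5. **Composite**: RSS = √Σ folded z², Box-Cox transformed and standardised
   by the control RSS mean/SD (no covariate regression on the RSS, and the
   same 3.29 SD trim), then mapped to the zeta scale:
   ζ = Φ⁻¹((Φ(z)+1)/2). This is the half-normal quantile map: if z is
   standard normal in controls, ζ is distributed as |N(0,1)|, so exactly
   95% of controls fall below 1.96 — the property the published threshold
   relies on — and ζ ≥ 0 with 0 the best attainable score. Impairment is
   ζ > 1.96.

Numerical edges: a raw value whose shifted counterpart is ≤ 0 lies outside
the Box-Cox domain (possible for, say, a perfect error of 0 m when the
training shift is 0); it is scored at the domain edge — the smallest
shifted value seen at fit time — and flagged with a warning, rather than
propagating −∞. The zeta map is evaluated through upper-tail quantiles so
it stays finite and monotone far beyond |z| = 8.

Assumptions: parameter noise is approximately Gaussian after Box-Cox;
covariate effects are linear in age and additive in sex/handedness; the
residual scale is shared across demographics. The generator's age effect
is multiplicative on noise SD, which the log-like Box-Cox transform turns
into an additive mean shift with stable residual variance — the held-out
tests (per-parameter mean z within ±0.1, SD within 0.9–1.1, ≈95% of Task
Scores below 1.96) verify that the chain absorbs it.

## 3. Synthetic cohorts

`synthetic_config()` fixes the study conditions; all randomness descends
from its single seed, and generation is bit-reproducible.

**Controls** (`generate_control_cohort()`): 799 subjects by default, each
contributing `1 + Poisson(1.79)` sessions (≈2.79 on average, ≈2229 total).
Age ~ U(20, 85); sex and handedness balanced (the control population's
composition is not published; uniform/balanced is the neutral default).
A subject's matched positions are the mirrored robot positions plus a
systematic per-subject workspace bias (SD 8 mm), a workspace scale jitter
(SD 0.05 about 1), and per-trial Gaussian noise whose SD (base 15 mm)
increases 0.4%/year with age and by 10% for males and left-handers. These
effect sizes are artifact choices at the scale of ordinary kinematic
variability; they exist so the covariate regression has something real to
remove.

**Stroke** (`generate_stroke_cohort()`): 133 participants by default, 42
female, 78 left-affected. Each carries a latent severity *s* ≥ 0 from a
two-component mixture: a near-zero component (|N(0, 0.05)|) and an
impaired log-normal tail (meanlog 0, sdlog 0.5), with left-affected
participants shifted toward the tail by 0.8 log-odds (the lateralisation
of proprioception to the right hemisphere). Severity multiplies the trial
noise SD (gain 1.2 per unit *s*) and contracts the workspace
(scale × e^(−0.12 s)); the per-subject bias — the Shift parameter — and
age are independent of *s* by construction, so Shift and age carry no
outcome signal (the null features of the univariate battery). Six-month
severity is the mixture draw; at two weeks a recovering half of the cohort
is worse by 1/(1 − recovery_factor), default 2×, so mean Task Scores
improve over time.

**Prevalence calibration.** The Task Score is a nonlinear composite, so
the severity scale that yields a 36.1% six-month impairment rate cannot be
set analytically. A global scale factor is calibrated by bisection against
the supplied fitted normative model: all random draws are made once, the
scale is the only moving part, and bisection stops when the realized
fraction is within 1 percentage point of the target (or errors after a
bounded number of iterations if it cannot come within 5 points — e.g. when
severity is decoupled from every APM channel).

**Clinical scores** are driven by the *unit-scale* two-week severity (the
calibrated scale only adapts severity to APM noise units): TLT = ordinal
cut of s + N(0, 0.3) at (0.4, 1.0, 1.8); BIT = 144 − 14 s + N(0, 3)
clamped to [0, 146]; FIM = 112 − 20 s + N(0, 8) clamped to [18, 126] —
discretised Gaussians clamped to each instrument's legal range, with
slopes set so a typical impaired participant (s ≈ 2 at two weeks) loses
≈2 TLT points, ≈28 BIT points and ≈40 FIM points.

**Lesions** are random ellipsoids on a 40 × 48 × 40 grid of 4 mm isotropic
voxels (a coarse MNI-like box; geometry is metadata — no registration is
performed or implied). Volume is log-normal around 120 voxels (≈7.7 cc)
growing 0.45 log-units per unit severity; impaired-component lesions are
centred inside the implanted critical region with probability 0.75 (else
anywhere in the brain box) and unimpaired lesions land there with
probability 0.15, so lesion location is informative but overlapping —
without that overlap the imaging features become unrealistically
discriminative relative to the clinical and robotic modalities.

**What the generator does not emulate**: brain anatomy and registration,
neglect recovery dynamics (BIT < 130 is only a flag), non-linear age
effects, correlated measurement error across parameters, session-to-session
learning, or missing data. Passing tests therefore show that the
*analysis machinery* is correct and well calibrated under its stated
assumptions — not that the pipeline will achieve any particular accuracy
on real clinical data.

## 4. Lesion-symptom mapping

`vlsm_zmap()` tests each voxel lesioned in at least ⌈5% of the cohort⌉
participants (7 of 133), requiring ≥2 participants per group: the default
statistic is the pooled-variance two-sample t on the behavioural score,
mapped to z via Φ⁻¹(F_t(t)) and clamped to ±8.21 (the point where the t
CDF saturates in double precision); a rank-sum alternative (normal
approximation with tie correction) is available via `test = "ranksum"`
because the voxel-wise test used by the published toolbox run is not
stated. Signs are positive where the lesioned group scores worse.
`vlsm_mean_z()` averages the map over a lesion's *tested* voxels; lesions
with no tested voxels return 0 with an explicit flag. The map for the
prediction feature uses the two-week Task Score as behaviour and — like
the source analysis — is computed on the same cohort it feeds; a
leave-one-out mode (`build_feature_table(leave_one_out = TRUE)`) is
provided as an extension for users who want to avoid that reuse, and is
off by default.

## 5. Statistics and classifiers

The univariate battery follows the published analysis plan: OLS for
continuous features (both plain and adjusted R² are reported, since the
source prints a negative "R²" that implies the adjusted form), Spearman
with midrank ties and a t-approximation p for the ordinal TLT, Student
(pooled) two-sample t-tests for sex and affected arm ("two sample t-test"
is read as the classical pooled form), and Mann–Whitney U with the normal
approximation, tie and continuity corrections for the 14
impaired-vs-unimpaired comparisons at Bonferroni α = 0.05/14 = 0.00357.
The continuity correction matters: without it the approximation misses the
exact permutation p of small complete-separation samples by ~0.05; with it
the gap in the decision-relevant tail is under 0.02 (the approximation is
intrinsically ~0.03–0.04 off at mid-distribution U for n = 3–4, which no
implementation choice can remove).

The five classifier configurations take the published feature sets
(demographics in every model; clinical, imaging, robotic blocks added per
configuration). Evaluation uses stratified k-fold cross-validation (fold
labels dealt round-robin within class, so per-fold class counts differ by
at most 1); feature standardisation is learned on each training fold only.
Out-of-fold probabilities are pooled before computing metrics (the source
reports single values with no fold dispersion, which pooling matches;
fold-averaging is the other convention and is *not* used). Classification
uses threshold 0.5 — no threshold is published. F1 is reported both for
the positive (impaired) class and class-weighted: a majority-class
classifier with near-zero sensitivity has positive-class F1 ≈ 0 but
weighted F1 ≈ 0.5, and the published Basic-model value is only consistent
with the weighted form. AUC is the trapezoidal area of the pooled ROC with
tied scores grouped, which equals pairwise concordance with half-credit
ties. AIC = 2(p + 1) − 2 logLik comes from one unpenalized full-data fit
(AIC is undefined per fold and incompatible with penalisation; the
optional ridge mode — penalized Newton, intercept unpenalized — exists to
stabilise coefficient importances under separation and is excluded from
AIC reporting). Sex is encoded male = 1 and affected arm left = 1;
coefficient signs flip with the encoding, which is recorded in the feature
table's attributes.

## 6. Problem sizes used by the test suite

The suite fits one shared normative model on the full default control
population (799 subjects, ≈2229 assessments), checks held-out calibration
on ≈1100 and on 10,000 single-session controls, uses stroke cohorts of
133 (default), 200 (20-seed sweeps for the recovery, VLSM-localisation and
ordering properties) and 500 (association structure), and exercises the
full pipeline end-to-end at 60 controls / 40 stroke on a reduced lesion
grid. These sizes were chosen so each property is tested at the scale at
which it is stated while keeping every run deterministic under fixed
seeds.

## 7. Known limitations

* The APM parameter formulas are reconstructions from qualitative
  descriptions; absolute parameter values need not match vendor software.
* The zeta transform is likewise a reconstruction pinned to its published
  defining property (95% of controls < 1.96), not to vendor code.
* The normative model assumes a shared residual scale across demographics;
  strong heteroscedasticity that Box-Cox cannot absorb would distort the
  tails of the z distribution.
* VLSM maps carry no family-wise error correction — by design, they are a
  feature source here, not an inferential map.
* With 16 features and n ≈ 133, the unpenalized augmented fit can separate;
  its AIC remains defined via the converged deviance, but coefficient
  magnitudes are then only interpretable through the ridge mode.
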