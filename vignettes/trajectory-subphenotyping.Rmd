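---
title: "Dynamic vital-sign subphenotyping: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic vital-sign subphenotyping: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Patients arriving at an emergency department (ED) with suspected infection are
clinically heterogeneous, and single "snapshot" vital signs discriminate
outcomes poorly. `vstraj` implements a *dynamic* subphenotyping pipeline: the
joint trajectories of five vital-sign channels — temperature (TEMP, °C), heart
rate (HR, bpm), respiratory rate (RR, breaths/min), systolic and diastolic
blood pressure (SBP/DBP, mmHg) — over the first 24 h of ED care are clustered
with a group-based trajectory model (GBTM), and the resulting subphenotypes
are tested for association with 30-day mortality.

## The model

GBTM is a finite mixture model. Patient $i$ belongs to one of $G$ latent
groups with prior probabilities $\pi_1,\dots,\pi_G$. Within group $g$, channel
$v$ follows a polynomial mean trajectory in time $t$ (hours since ED
admission, uncentred):

$$\mu_{gv}(t) = \beta_{gv0} + \beta_{gv1}\,t \;(+\; \beta_{gv2}\,t^2),$$

and each observation is $x = \mu_{gv}(t) + \varepsilon$, with
$\varepsilon \sim N(0, \sigma_{gv}^2)$ independent across observed
(channel, time) cells given the group. A patient's component likelihood is
the product over their *observed* cells only, so missing measurements simply
contribute nothing to the likelihood — nothing is ever imputed. The mixture
log-likelihood is maximised with an EM algorithm; mixture densities are
combined by log-sum-exp so that patients whose component densities differ by
hundreds of orders of magnitude are handled without underflow.

Patients are then given their *modal* assignment (the group with the highest
posterior probability), and adequacy is checked with the average posterior
probability (APP): the mean of the maximal posterior among patients assigned
to each group, required to be strictly above 0.70.

### Model selection

The selection procedure mirrors the study design it implements:

1. **Polynomial order.** Before mixture fitting, each channel's order
   (linear vs quadratic) is chosen by a likelihood-ratio test on the
   one-group fit: $2\Delta\ell \sim \chi^2(1)$, quadratic iff $p < 0.05$.
2. **Group sweep.** Models with $G = 1,\dots,4$ groups are fitted and
   compared by BIC, $-2\ell + k\ln n$.
3. **Screens.** A candidate is "not amenable to selection" if any modal
   group holds less than 5% of the cohort, or if any populated group's APP
   is not above 0.70. The lowest-BIC survivor is selected; if nothing
   survives, the report says so (failure is a reportable outcome, not an
   exception).
4. **Labels.** Fitted groups are mapped to the clinical labels A–D from
   their fitted 24-h mean profiles using fixed cut-offs (fever TEMP ≥ 38 °C,
   tachycardia HR ≥ 100, tachypnea RR ≥ 22, hypertension SBP ≥ 140,
   hypotension SBP < 100): A = most channels deranged, B = hypertensive
   pattern, C = fewest derangements, D = hypotension-only. The best
   injective map is found by exact enumeration (≤ 24 permutations); ties
   break deterministically with larger groups taking earlier labels.

### The mortality stage

Given assignments, the outcome stage computes the deaths/survivors
contingency table; Pearson $X^2$ and likelihood-ratio $G^2$ statistics with
the expected-count rule (flag when any expected cell < 5) and an optional
seeded Monte-Carlo conditional test (fixed-margin table sampling, $10^5$
draws); odds ratios against the control group C with Woolf standard errors
$\sqrt{1/a+1/b+1/c+1/d}$ and $\exp(b \pm 1.96\,\mathrm{se})$ intervals;
an unconditional logistic regression fitted by Newton–Raphson (convergence:
max |score| < 1e-8, SEs from the inverse observed information) whose
dummy-only coefficients reproduce the contingency log-ORs exactly; the
tie-corrected Mann–Whitney ROC AUC with the Hanley–McNeil SE; and one-way
ANOVA with Bonferroni-corrected pairwise Welch comparisons for continuous
covariates. The 1.96 multiplier (not a $t$ quantile) is deliberate: it
reproduces the published intervals exactly from the printed counts.

ROC scores are the logistic predicted probabilities, which for a categorical
predictor equal the group mortality rates; any monotone transform of the
scores gives the same AUC (asserted in the tests).

## The synthetic world

No patient-level data are distributed with the study, so the package carries
a fully synthetic ED cohort generator whose defaults *are* the published
cohort structure: $n = 675$; four archetypes with shares 2.66 / 9.2 / 19 /
69.2 % and mortality probabilities 3/18, 4/62, 3/128, 48/467; vital signs
every 4 h over 0–24 h. The archetype patterns are qualitative in the source
(A: fever + tachycardia + tachypnea + hypotension; B: hypertension only;
C: normal; D: hypotension only), so magnitudes are fixed here once at
clinically plausible values: deranged means TEMP 38.8, HR 118, RR 26,
SBP 88, DBP 52, drifting linearly about halfway back to normal over 24 h;
normal means TEMP 36.8, HR 84, RR 17, SBP 122 (B: 162), DBP 74. Residual
SDs are typical clinical measurement noise (TEMP 0.4, HR 9, RR 3, SBP 11,
DBP 8). Observations are dropped completely at random at rate 0.10 and
duplicated at the same recorded time (with an independent noise draw) at
rate 0.03 — both rates are unstated in the source and chosen once as
realistic; the duplicate mechanism exists so the duplicate-averaging rule in
preprocessing is genuinely exercised. The latent archetype is emitted only
in a separate truth table.

What a green recovery test establishes: that the EM machinery can recover
well-separated Gaussian linear-trajectory groups and their labels at the
published sample size. What it does not establish: performance under
informative missingness, non-Gaussian noise, within-patient autocorrelation,
or archetypes less separated than these templates — all of which real ED
data will have.

### The 5%-share contradiction

The published selection rule ("any subphenotype under 5% makes the model not
amenable to selection") and the published selected model (group A holds
2.66% of the cohort) contradict each other. `vstraj` implements the rule as
stated, so on the default synthetic cohort the 3- and 4-group candidates are
screened out (the small archetype-A group is recovered at ≈ 2.7%) and the
sweep selects a smaller model. The corresponding acceptance expectations are
deliberately left failing rather than weakening the screen; the 4-group
candidate itself is still fitted, reported, passes the APP screen, and
recovers the latent archetypes for > 99% of patients. Users who want the
published behaviour can pass `min_share = 0` (or any value ≤ 0.0266) to
`sweep_groups()` or `pipeline_config()`.

## Numerical choices

* **Standardization.** Channels are z-scored with pooled cohort mean/SD by
  default before fitting (the scaling record is kept and inverted for
  reporting in natural units). The source is silent on this; standardized
  fitting puts the five channels on comparable footing in the joint
  likelihood, which otherwise would be dominated by the large-variance
  channels. Raw fitting is supported (`standardize = FALSE`).
* **Variance structure.** Group-specific residual SD per channel by default
  (`variance = "shared"` pools over groups), matching the general GBTM
  formulation.
* **σ floor.** Residual SDs are clipped at 1e-3 (standardized units): the
  mixture likelihood is unbounded as any σ → 0.
* **Initialisation.** Start 1 is a k-means split on per-patient channel
  means; remaining starts (default 10 total) draw random Dirichlet(1)
  posteriors. All draws derive from the single fit seed, so fits are
  bit-reproducible.
* **Convergence.** |Δ log-likelihood| < 1e-6, at most 500 iterations per
  start; the best converged, non-degenerate start wins. A start whose
  mixing weight collapses below $1/(2n)$ is discarded as degenerate, which
  keeps the 5% screening meaningful at selection time rather than inside EM.
* **Duplicate averaging.** "Same time" means equal recorded `time_hours`
  after rounding to 2 decimals (no tolerance is stated in the source).
* **Zero-noise templates.** `residual_sd = 0` is admitted in templates so
  the noiseless sanity world (observations equal template means exactly,
  OLS refit recovers coefficients to 1e-8) can be generated.

## Limitations

* Gaussian measurement error and independence across cells within patient
  and group are assumed; no censored-normal or autocorrelated alternatives.
* At most 4 groups and quadratic trajectories, per the procedure modelled.
* The cohort-specific descriptive comparisons of the source (laboratory
  ANOVAs, comorbidity tables) require the unavailable patient-level data;
  the *procedures* (ANOVA + Bonferroni, chi-square with the expected-count
  rule) are implemented and property-tested instead.
* The mortality stage treats the modal assignment as known, ignoring
  classification uncertainty — as does the analysis it reproduces.
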