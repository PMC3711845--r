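---
title: "Model structure, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`brcascreen` is a Markov cohort model of breast-cancer screening in
BRCA1/2 mutation carriers: annual MRI alternating with annual
mammography versus annual mammography alone. This vignette documents the
model's structure, the calibration of its inputs, and the design choices
made where the published evidence leaves the implementation open. It is
the package's reference for *why* the code does what it does; the README
shows *how* to run it.

## Cohort structure and timing

The cohort enters well at age 25 and is followed in 6-month cycles to
age 100 (150 cycles). Within each cycle the order of events is fixed:

1. background (non-breast-cancer) mortality removes a fraction of every
   alive compartment;
2. a fraction of well women develop a first breast cancer (onset);
3. the cycle's screening event, if any, is applied — detection for women
   harbouring cancer, false positives for cancer-free women;
4. costs and utilities accrue to everyone still alive.

Deaths accrue nothing in their death cycle and no half-cycle correction
is applied; state membership is evaluated at cycle end. This convention
is symmetric across arms, so incremental results are insensitive to it
to first order. Discounting uses $(1.035)^{-t}$ with $t$ the time in
years from cohort entry at the end of the accruing cycle.

**Screening calendars.** In the combined arm MRI is given at whole ages
25–64 and mammography at half ages 30.5–79.5, so the two alternate every
6 months wherever both are offered; women 25–29 receive only annual MRI
and women 65–79 only annual mammography. The comparator arm screens with
mammography at whole ages 30–79. Within the combined arm, ages 25–64 use
the meta-analytic MRI/mammography sensitivities and specificities, while
ages 65–79 (mammography only) fall back to the age-specific mammography
performance table — the same table the comparator arm uses throughout,
reflecting the different evidence sources behind each programme.

**Detection window.** A cancer can be detected at its onset cycle's
screening event and at the next cycle's event; if the first screen
produced a false negative, the second uses the conditional sensitivity
$P(A \mid \bar B) = (se_A - se_{A \cap B}) / (1 - se_B)$, where the joint
detection probability is solved from the published marginal and
either-test sensitivities. Cancers still undetected at the end of that
second cycle surface clinically and receive the historical
(pre-screening) stage distribution. This caps preclinical latency at one
year, which operationalises the model's assumption that screening
benefit acts through stage at detection rather than through lead time.
Women with diagnosed cancer exit screening permanently.

**Diagnosis bookkeeping.** A diagnosed woman accrues the well utility in
her diagnosis cycle minus a two-week diagnostic-work-up decrement
$(1-u_{workup}) \times 14/365.25$, plus the work-up cost; treatment
begins the following cycle. The work-up cost and decrement are charged
to *all* diagnoses — true positives and clinically surfacing cancers —
as well as to false positives, since every diagnosis passes through the
same work-up pathway. False positives return to the well state within
the cycle.

## Post-diagnosis pathways

Stage at diagnosis depends only on the detecting modality (MRI-detected,
mammography-detected, or non-screen rows). Each stage carries:

* a total treatment cost spread in equal thirds over the three 6-month
  treatment cycles (the published totals do not reveal the true split;
  an equal split is the neutral choice and only affects discounting at
  the margin);
* a treatment utility for those cycles, then a remission utility until
  10 years from diagnosis, then full health (cure);
* a Weibull survival model fitted through the published 5- and 10-year
  survival anchors, $k = \log(\log s_2/\log s_1)/\log(t_2/t_1)$,
  $\lambda = t_1/(-\log s_1)^{1/k}$ — two anchors identify the two
  parameters exactly, so the printed survival figures are reproduced to
  numerical precision. In-situ disease does not progress: its survival
  is identically 1.

Cancer deaths within 18 months of diagnosis go directly to the dead
state; later deaths spend their final three cycles in progressive
disease, where the progression utility and the end-of-life cost (in
equal thirds) override treatment/remission bookkeeping. Survivors at 20
cycles are cured and face background mortality only. Cancer and
background death compete independently within a cycle, with cancer death
taking precedence in the bookkeeping.

The two-point calibration is a documented approximation: a registry fit
would use full follow-up, not two anchors. The synthetic-data module
exists to show the consequences are small (see below).

## Background mortality

Competing mortality uses a Gompertz hazard $h(a) = \alpha e^{\beta a}$
with the slope fixed at $\beta = 0.09$/yr — a typical adult-female
log-hazard slope — and the level $\alpha$ calibrated by bisection so the
comparator arm's all-cause death by age 65 equals 20.9%, the published
validation figure for this population. A one-parameter calibration
anchored to an in-model quantity keeps the package self-contained where
the original mortality schedule is not published. Consequence: the
comparator arm's survival to 65 is an anchor, not an independent
prediction; the combined arm's survival is a genuine model output. The
calibrated level is recorded in every run manifest. Background mortality
is held fixed across PSA draws because no uncertainty interval exists
for it.

## Input uncertainty

Distribution families are not part of the published record, so the
package uses standard two-parameter choices, each calibrated so its mean
equals the published mean *exactly* and its 2.5%/97.5% quantiles match
the published CI in least squares (one-dimensional search):

* **Beta** for probabilities, utilities and the 10-year incidence risks;
* **Gamma** for costs (the published analysis fitted costs to gamma
  distributions);
* **Dirichlet** for the three stage-at-diagnosis rows, with the
  effective sample size chosen to match the component with the widest
  printed CI. Rows printed as 101% (rounding) are renormalised.

Calibration quality is recorded per leaf (`spec_validation_report()`):
all leaves reproduce their mean within 1%; the in-situ treatment cost is
the one input whose nearly symmetric CI no gamma of that mean can match
exactly (flagged, fit retained). Utility CIs with an upper bound of 1.00
are matched as closely as a Beta allows.

In the PSA all leaves are drawn independently (no correlation structure
is published) in a fixed documented order from a single seeded
generator, so adding parameters cannot silently reorder streams. Two
structural invariants are enforced by joint redraw: the sensitivity
triple must admit a joint detection probability, and 10-year survival
must lie below 5-year survival. The conditional sensitivities are
*derived* from each draw's triple, not sampled separately. Both arms are
evaluated on the same draw (paired design), which is what makes the
incremental distributions meaningful.

The ICER point estimate from a PSA is the ratio of mean ΔC to mean ΔE;
per-draw ICERs are summarised by 2.5/97.5 percentiles with dominance
labels when ΔE ≤ 0. Net-monetary-benefit ties count as cost-effective (a
measure-zero convention).

## Sensitivity analyses

One-way analysis replaces a single named leaf at the mean parameter set
and re-evaluates both arms deterministically. The tornado covers the MRI
unit cost, MRI sensitivity and specificity, the MRI-detected stage row
(varied through the 95% interval of its local-stage component, other
components scaled proportionally), and the discount rate. The discount
rate has no CI, so its range is a convention, set to 0–5%; with that
range its bar rivals the MRI-cost bar, consistent with screening models
generally — costs are paid from age 25 while benefits arrive decades
later. Among the CI-based parameters the MRI unit cost dominates.

## Synthetic data and what it shows

The original calibration inputs — patient-level treatment-cost records
(n = 68) and registry survival records — are not available. The
`generate_cost_records()` / `generate_survival_records()` generators
emulate their *statistical shape*: gamma-distributed 18-month totals
split over three 6-month intervals by a front-loaded Dirichlet share
(the true interval split is unpublished; this split is a stand-in and is
independent of the engine's equal-thirds convention), and Weibull event
times with administrative right-censoring mirroring a registry window.
The companion MLE fitters (`fitdistrplus` for gamma,
`survival::survreg` for censored Weibull) close the loop: parameter
recovery at n = 10,000 is verified to within 2% (cost means) and 5%
(Weibull shape/scale, censoring below 50%), and at the study's own
n = 68 the tests document the wide sampling spread — a faithful picture
of the input uncertainty the PSA propagates.

What passing these tests does *not* show: that real treatment-cost or
registry data follow gamma/Weibull laws, that costs are front-loaded in
the assumed proportion, or that survival in mutation carriers matches
the general breast-cancer population. The generators validate the
calibration *machinery*, not the epidemiology.

## Verification strategy and problem sizes

* The cohort engine's primary oracle is an individual-level
  microsimulation (1,000,000 women per arm, in the test suite) that
  re-implements onset, screening, staging, death and accrual at the
  event level and must agree with the expected-value engine within 3
  Monte-Carlo standard errors on per-arm costs and QALYs.
* Compartment occupancies are conserved to 10⁻¹⁰ every cycle (achieved:
  ~10⁻¹⁵), with cancer and background deaths accounted independently.
* Closed-form streams (in-situ value with and without discounting,
  distant-stage end-of-life cost by direct enumeration) pin the
  post-diagnosis accounting.
* The PSA uses 10,000 draws (a few minutes on one CPU); a PSA over a
  spec with every distribution collapsed to its mean must reproduce the
  deterministic base case exactly; equal seeds must give bit-identical
  results.
* Results are insensitive to the horizon choice (age 95 vs 100 moves the
  ICER by <0.2%).

## Known limitations

* The comparator arm's survival-to-65 is a calibration anchor (see
  above).
* The model reproduces the published central estimates well, but the
  spread of *incremental* QALYs across PSA draws is narrower than the
  published one (≈0.04 vs ≈0.055 standard deviations), even though every
  per-arm and screening-effectiveness output reproduces its published
  interval closely. With paired arms and the printed inputs, the
  published share of draws in which MRI screening is less effective
  (~4%) is not reachable — this package obtains well under 1% — and the
  acceptability at high willingness-to-pay sits a few points above the
  published value. The discrepancy traces to implementation details of
  the original analysis that are not recoverable from the printed
  record (distribution families and concentrations, the competing-
  mortality schedule, software internals); the package reports its own
  computed values rather than adjusting inputs to match.
* Overdiagnosis, second primary cancers, prophylactic surgery and
  dynamic programme entry/exit are out of scope, as in the original
  analysis design.
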