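---
title: "A semi-mechanistic model of erythropoiesis and hemoglobin synthesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A semi-mechanistic model of erythropoiesis and hemoglobin synthesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erythrosim)
```

## The system being modelled

Red blood cells are produced in the bone marrow from precursor cells that
mature over roughly five days into reticulocytes. Reticulocytes reside
briefly in the marrow and then in the blood, where they mature into
erythrocytes that circulate for about four months before removal.
Hemoglobin is synthesized almost entirely in the immature reticulocyte
stage, so a drug that inhibits hemoglobin synthesis (such as a glycine
transporter inhibitor) produces cells of normal number but reduced
hemoglobin content, a microcytic-hypochromic pattern. The body counters a
falling blood hemoglobin concentration through erythropoietin-mediated
stimulation of precursor recruitment and accelerated marrow release,
visible clinically as reticulocytosis and a rising immature reticulocyte
fraction (IRF).

`erythrosim` implements this system as a transit-compartment lifespan
model with 15 states:

* `PRE` — bone-marrow precursors (lifespan `LS_PRE = 5` days, fixed),
* `TOL1`, `TOL2` — two tolerance compartments tracking `PRE` with rate
  `k_TOL`,
* a four-compartment reticulocyte block: immature/mature crossed with
  marrow/blood, all sharing the maturation rate constant `k_RET`,
* `RBC1..RBC4` — an Erlang transit chain for circulating erythrocytes,
  `k_RBC = 4 / LS_RBC`,
* `Hb1..Hb4` — the hemoglobin *amount* carried by each erythrocyte
  compartment (g/L).

The observables are blood reticulocytes `RET`, erythrocytes `RBC`, mean
corpuscular hemoglobin `MCH = Hb_tot / RBC`, `IRF`, and total hemoglobin
`Hb_tot = sum(Hb_n)`, which equals the sum over compartments of
cell count times per-cell content.

## Baseline homeostasis

All rate constants are derived from observable baselines, so the drug-free
system starts — and provably stays — at steady state:

* `k_RBC = n_CTR / LS_RBC` with `n_CTR = 4`,
* the baseline marrow output `F0 = k_RBC RBC_0 / n_CTR` (converted to
  1e9 cells/L/day),
* `k_RET = F0 / (RET_0 (1 - IRF_0))`,
* premature-release odds `p_release = IRF_0 / (1 - IRF_0)`, which makes
  the steady-state blood IRF exactly `p/(1+p) = IRF_0`,
* `Hb_0 = RBC_0 MCH_0`.

```{r baseline}
p <- model_parameters()     # typical male subject
derive_rates(p)[c("k_RBC", "k_RET", "p_release")]
observe(steady_state(p))
```

## Feedback, tolerance, and drug effect

**Feedback.** A hemoglobin deficit stimulates erythropoiesis through
`S = exp(gamma_FB (Hb_0 - Hb_tot) / Hb_0)`, with `gamma_FB = 2.42` by
default. `S` multiplies precursor recruitment (`R_in = F0 S M`) and the
two marrow-to-blood release transitions (immature release
`p_release k_RET S`, mature release `k_RET S`), i.e. the deficit drives
both more production and *earlier, faster release* of reticulocytes into
blood. We deliberately do not scale the maturation transitions: if every
reticulocyte rate constant is multiplied by `S`, the factor cancels out of
the blood pools at quasi-steady state, leaving blood reticulocytes flat
(in fact slightly falling, through tolerance) and IRF exactly constant —
the opposite of the reticulocytosis and rising IRF that characterize the
compensatory response this term exists to describe. Restricting `S` to
the release arrows reduces to the same equations at `S = 1`, preserves
the baseline steady state, and produces the correct compensation. The
orientation of the exponent (deficit stimulates) is itself held in a
`feedback_sign` flag, since the suppressive orientation is a plausible
transcription variant; the default is the physiologically meaningful one.

**Tolerance.** Sustained stimulation depletes the stem-cell reservoir.
Two first-order compartments track `PRE` with rate `k_TOL = 0.022`/day;
recruitment is multiplied by `M = PRE_0 / TOL2`, equal to 1 at baseline
and below 1 when the delayed precursor signal exceeds baseline. The state
is clamped at a configurable floor (`1e-9 PRE_0`) with a warning, since a
fully depleted tracker would otherwise make the modulation singular. With
`k_TOL = 0` the tolerance states freeze and `M` stays at 1.

**Drug effect.** Exposure enters as a steady-state AUC held constant over
a treatment window (`[0, 120)` days by default; the compound's own
concentration kinetics are out of scope). The inhibited fraction is
`I = Imax AUC_ss / (AUC50 + AUC_ss)` with `Imax = 0.6` fixed and
`AUC50 = 16.5` mg/L·h; exposures of half and twice `AUC50` give 20% and
40% pathway inhibition. Four mechanisms place `1 - I` on different arrows:

| Mechanism | Inhibited pathway |
|---|---|
| A | hemoglobin synthesis (content of newly released cells) |
| B | precursor recruitment `R_in` |
| C | precursor-to-reticulocyte differentiation `k_PRE` |
| D | hemoglobin synthesis, with the feedback silenced (`S = 1`) during treatment |

Mechanism D silences the *whole* stimulation term (both the recruitment
and the release arms): the two arms share one feedback parameter, and only
silencing both keeps reticulocytes and erythrocytes steady during
treatment, the behaviour that distinguishes D.

```{r mechanisms}
out <- simulate_individual(p, mechanism_spec("A", AUC_ss = 2 * p$AUC50),
                           times = c(0, 30, 120, 240))
round(out, 3)
```

## Hemoglobin: mass chain, not content chain

The model is often described as two parallel transit chains — cell counts
and per-cell content. A literal content chain does not conserve
hemoglobin mass when cell counts change, so the default state carries
hemoglobin *amounts* `Hb_n = RBC_n × MCH_n` with plain transit; the two
formulations are identical at baseline and the literal content chain is
available for sensitivity analysis via
`simulate_individual(..., hb_chain = "content")`. Inhibited synthesis
scales the content of cells *entering* `RBC1`/`Hb1` with no additional
maturation delay, which matches the immediate onset of the observed MCH
response. Under sustained inhibition `I`, the transit algebra gives the
closed-form limit `MCH -> MCH_0 (1 - I)`, which the tests verify at a
horizon of ten erythrocyte lifespans.

## Statistical model

Inter-individual variability is log-normal: each varying parameter is
`typical × exp(eta)` with `omega^2 = log(1 + CV^2)`, so the stated
percent CV is the CV on the natural scale and the median equals the
typical value. Default CVs: `LS_RBC` 28.02, `RET_0` 26.02, `RBC_0` 5.34,
`MCH_0` 4.82, `IRF_0` 32.09, `AUC50` 49.50 (no published correlations, so
the default correlation is identity, overridable). Residual error is
endpoint-specific: proportional 0.22 for RET, additive 0.18×10¹²/L for
RBC, additive 0.35 pg for MCH, and combined for IRF — additive 0.96
*percentage points* (0.0096 on the fraction scale used in datasets) plus
proportional 0.38. Negative simulated observations are retained by
default (truncation at zero is a flag), keeping the error model honest.

## The synthetic trial

No subject-level data from the underlying Phase-1 study are public, so
the package generates trials with the same structure: 62 healthy subjects
in four once-daily arms (placebo/10/30/60 mg, n = 15/17/16/14), 120 days
of treatment plus 120 days of follow-up, hematology at baseline, weeks 1
and 2, every 2 weeks to week 16, week 17, week 18, then every 2 weeks to
week 34 (20 visits, day 238 last). Two quantities the source never
published are synthetic by construction and chosen once:

* the dose-to-exposure coefficient `c_exp = 1.1` mg/L·h per mg, which
  places the arms at roughly 0.67/2/4 × `AUC50` (the 30 mg arm therefore
  sits at ~40% inhibition, a plausible mid-range potency layout);
* between-subject exposure variability of 30% CV
  (`AUC_ss = dose · c_exp · e^eta`), a typical magnitude for
  pharmacokinetic variability in healthy adults;
* an additive 5.6 g/L residual SD for the held-out `Hb_tot` endpoint,
  the delta-method combination of the RBC and MCH additive errors at
  baseline.

Simulations default to male subjects. The published female baseline
offset is carried (`rbc_diff_female = 1.59`), but its unit/scale is
internally implausible, so mixed-sex sampling is opt-in.

What passing tests on these trials show — and what they do not: the
generator reproduces the *assumed* statistical structure exactly
(log-normal IIV, the stated error models, the design), so recovery tests
demonstrate that the estimation machinery is consistent with the model,
not that the model describes any real cohort. Real hematology data add
assay drift, circadian effects, dropout and model misspecification, none
of which are emulated.

## Estimation

The estimation surface is deliberately simpler than a full nonlinear
mixed-effects analysis (stochastic EM machinery is a non-goal):

* **Naive-pooled** (`fit_pooled`): one parameter set for everyone,
  Gaussian likelihood with the endpoint error variances
  `sd_add² + pred² sd_prop²`. Residual SDs are estimated by *profiling*
  inside the objective — the conditional MLE is analytic for pure
  additive/proportional errors and a cheap two-parameter search for the
  combined model — which removes five dimensions from the outer search at
  no cost. Free by default: `LS_RBC`, the four baselines, `gamma_FB`,
  `AUC50`; fixed: `LS_PRE = 5` d, `Imax = 0.6`, `k_TOL`. Transforms: log
  for positive parameters, logit for fractions; finite natural-scale
  bounds are enforced by penalty. The optimizer is Nelder-Mead followed
  by a BFGS polish, multi-started from jittered copies of a data-driven
  start (`start_from_data`: day-0 medians for baselines, 120 d lifespan,
  neutral feedback, median active exposure for potency).
* **Two-stage** (`fit_two_stage`): per-subject fits (placebo subjects
  contribute baselines only; the feedback exponent is held fixed, as one
  subject's data barely informs it), then geometric means as typicals and
  log-scale SDs as IIV CVs.

The two estimators are complementary. Naive pooling is the only one of
the two that estimates the feedback exponent, but for a parameter with
large skewed variability — potency has ~50% CV — its estimate drifts
toward a population-average value (of order `exp(omega²/2)` above the
median). The two-stage geometric mean targets the typical (median) value
directly and also yields the variability estimates, so it is the
preferred reporter of typical potency in the packaged analyses.

With a proportional error component the Gaussian MLE carries a known
O(sd_prop²) bias even on noise-free data (the log-variance term rewards
under-prediction); the self-recovery test therefore fixes small SDs, and
the estimator-consistency property (bias shrinking with the SDs) is the
honest statement of what pooled fitting guarantees. `Hb_tot` records are
excluded from every fit by default and reserved for external validation
through the VPC machinery.

## Simulation outputs and predictive checks

`mechanism_panel` simulates mechanisms A–D at 0.5× and 2× the typical
`AUC50` and reports the median with a 90% prediction interval across
subjects. These bands reflect inter-individual variability only — no
residual error — because they describe the plausible range of *true*
individual trajectories. `vpc` simulates replicate datasets (IIV *and*
residual error), bins by nominal visit, and wraps 90% confidence bands
around the 5th/50th/95th simulated percentiles; the interval choices are
configurable, with the 5/50/95 + 90% CI convention as default.

## Numerical choices

* `lsoda` with relative tolerance 1e-8 and per-state absolute tolerances
  scaled to the baseline state; the exposure step at the window edges is
  handled by segmenting the integration and restarting the solver, so no
  discontinuity is smoothed over.
* The compiled C right-hand side is used for speed (the reference R
  implementation is property-tested to agree to solver tolerance and
  backs the literal content chain).
* Degenerate states (non-positive reticulocytes or erythrocytes in the
  observation map, NaN or materially negative solver output) raise
  explicit errors rather than propagating silently.
* Desk-scale problem sizes used throughout the packaged analyses: 500
  subjects per mechanism panel (2000 reproduces the published layout),
  200 VPC replicates, and two optimizer starts for the 62-subject
  recovery experiment; all are arguments, not constants.

## Known limitations

* Exposure is a step function of time; real washout kinetics would
  smooth the post-cessation transients.
* The tolerance term is empirical; its functional form (delayed
  inverse-proportional modulation, trackers initialized at `PRE_0`) is a
  modelling choice among several consistent with a depletable-reservoir
  description.
* Naive-pooled estimation absorbs inter-individual variability into the
  residual error; its typical-value estimates are adequate at the
  tolerances used here but are not a substitute for mixed-effects
  estimation.
* Iron metabolism, erythropoietin as an explicit state, reticulocyte
  hemoglobin content, transfusion/blood-loss terms and covariate models
  are out of scope.
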