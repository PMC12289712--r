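# erythrosim

Semi-mechanistic population modelling of erythropoiesis and hemoglobin
synthesis in R, for pharmacometricians and clinical pharmacologists who
need to ask: *if a compound inhibits one step of red-blood-cell
production, what happens to the hematology panel over months?*

The core is a transit-compartment lifespan model. Bone-marrow precursors
(`PRE`, transit time `LS_PRE = 5` d) mature into reticulocytes — a
four-pool block crossing immature/mature with marrow/blood, sharing one
rate constant `k_RET` — which feed a four-compartment Erlang chain of
circulating erythrocytes (`k_RBC = n_CTR / LS_RBC`, `LS_RBC = 125` d). A
parallel chain carries the hemoglobin mass of each cohort, so that

```
Hb_tot = Σₙ RBCₙ · MCHₙ ,   MCH = Hb_tot / RBC ,   IRF = RET_imm,blood / RET
```

Premature marrow release is governed by the odds `p_release =
IRF₀/(1−IRF₀)`; all rates derive from observable baselines so the
drug-free system is exactly at steady state. A hemoglobin deficit drives
the erythropoietin-like feedback `S = exp(γ (Hb₀ − Hb_tot)/Hb₀)`
(γ = 2.42) on precursor recruitment and on marrow→blood release, damped
by a two-compartment tolerance term (`k_TOL = 0.022`/d) representing
stem-cell reservoir depletion. Drug effect is an Imax model on
steady-state exposure, `I = Imax·AUC_ss/(AUC₅₀ + AUC_ss)` (`Imax = 0.6`,
`AUC₅₀ = 16.5` mg/L·h), applied over a 120-day treatment window to one of
four pathways: hemoglobin synthesis (A), precursor recruitment (B),
precursor differentiation (C), or hemoglobin synthesis with the feedback
silenced (D).

On top of the structural model sit log-normal inter-individual
variability and endpoint-specific residual errors, a synthetic Phase-1
trial generator (62 subjects, placebo/10/30/60 mg, 120-day treatment +
120-day follow-up, 20 visits), naive-pooled and two-stage maximum
likelihood estimation, mechanism simulation panels with 90% prediction
intervals, and visual predictive checks.

## Worked example

```r
library(erythrosim)

p <- model_parameters()          # typical male subject
derive_rates(p)[c("k_RBC", "k_RET", "p_release")]
#> $k_RBC      0.032       /day
#> $k_RET      1.035717    /day
#> $p_release  0.04942806

# 40% inhibition of hemoglobin synthesis for 120 days, then follow-up
out <- simulate_individual(p, mechanism_spec("A", AUC_ss = 2 * p$AUC50),
                           times = c(0, 30, 120, 240))
round(out, 3)
#>   time    RET   RBC    MCH   IRF  Hb_tot
#> 1    0 39.800 4.910 29.800 0.047 146.318
#> 2   30 47.182 4.996 26.794 0.056 133.866
#> 3  120 53.893 5.955 19.977 0.070 118.968
#> 4  240 39.419 5.260 26.988 0.050 141.958
```

Reading the rows: hemoglobin synthesis is inhibited, so the per-cell
content (MCH) slides from 29.8 pg toward its long-run limit
`MCH₀(1−I) = 17.9` pg while total hemoglobin falls; the deficit triggers
reticulocytosis (RET 39.8 → 53.9 ×10⁹/L, IRF 4.7 → 7.0%) and a
compensatory rise in erythrocyte count (4.91 → 5.96 ×10¹²/L), which is
why Hb_tot falls much less than MCH. After cessation (day 240) everything
relaxes back toward baseline.

The numbered scripts under `analysis/` run the packaged analyses:
baseline homeostasis (`01`), mechanism panels A–D (`02`), the synthetic
trial (`03`), simulation-estimation (`04`) and the VPC (`05`), writing
tidy CSVs under `results/`.

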