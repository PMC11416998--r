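---
title: "Methods: a partitioned-survival cost-effectiveness model for first-line EV plus pembrolizumab in metastatic urothelial carcinoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partitioned-survival cost-effectiveness model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evpcea)
```

## The decision problem

Enfortumab vedotin (EV), an anti-nectin-4 antibody-drug conjugate, combined
with pembrolizumab roughly halves the hazards of death and of progression
relative to platinum-based chemotherapy in previously untreated metastatic
urothelial carcinoma (mUC), at a very large drug-acquisition cost. `evpcea`
implements the full economic-evaluation pipeline a US-payer appraisal of
this comparison requires: reconstruction of patient-level data from
published Kaplan-Meier (KM) figures, parametric survival extrapolation with
information-criterion model selection, a lifetime three-state cohort model
with oncology dosing rules, and deterministic plus probabilistic
sensitivity analysis.

Because the underlying trial deposits no patient-level data, the package
also ships a synthetic trial *emulator* that generates two-arm survival
data with the published summary behaviour (chemotherapy-arm median OS 16.9
months and median PFS 6.3 months; proportional-hazards treatment effects
HR 0.47 for OS and 0.45 for PFS). Every downstream stage is exercised and
tested against this emulator.

## Model structure

The cohort model is a partitioned-survival model with three states:
progression-free (PFS), progressed disease (PD), and dead. State occupancy
at each cycle boundary is read directly off the two survival curves:

* progression-free: $S_{\mathrm{PFS}}(t)$
* progressed: $S_{\mathrm{OS}}(t) - S_{\mathrm{PFS}}(t)$
* dead: $1 - S_{\mathrm{OS}}(t)$

Cycles are 21 days (0.690 months, using 30.4375 days/month); the horizon is
40 years (effectively lifetime from a starting age of 69); costs and
health outcomes are discounted at 3% per year; all accruals use half-cycle
correction (trapezoidal averaging of adjacent occupancies). Each cycle's
conditional death probability on both curves is floored at the
background-mortality rate for the cohort's current age, so extrapolated
disease-specific survival can never outlive the general population.

The combination arm's curves are obtained from the fitted
chemotherapy-arm curves by hazard-ratio scaling,
$S'(t) = S(t)^{\mathrm{HR}}$, i.e. proportional hazards over the whole
horizon — the central structural assumption of the analysis.

### Costs and utilities

Treatment rules follow the trial protocol and US practice:

* **Combination arm, first line**: pembrolizumab 200 mg flat on day 1 of
  each cycle for at most 35 cycles; EV 1.25 mg/kg on days 1 and 8 with no
  cap. After progression, platinum-based chemotherapy.
* **Chemotherapy arm, first line**: gemcitabine 1000 mg/m² on days 1 and 8
  plus cisplatin 70 mg/m² or carboplatin AUC 4.5 (Calvert formula,
  dose = AUC × (CrCl + 25)) on day 1, for at most 6 cycles (a 50/50
  cisplatin/carboplatin cohort split — the two prices differ by
  < $0.35/mg, so this split is immaterial). Afterwards 30.2% of
  progression-free patients receive avelumab maintenance (800 mg every two
  weeks, i.e. 1.5 administrations per 3-week cycle). After progression,
  pembrolizumab for at most 35 cycles.

Doses use a reference patient (70 kg, 1.86 m², CrCl 70 mL/min).
Administration is costed per infusion visit at the Medicare first-hour
rate, plus the additional-hour rate for each further drug given the same
day. Best supportive care ($1,213 per cycle) accrues on PD occupancy.
Utilities are 0.80 (PFS) and 0.75 (PD). Grade ≥ 3 adverse events enter
once, at cycle 1, as incidence-weighted cost and QALY decrements — the
incidence-times-disutility construction implies a one-off decrement; a
per-cycle alternative would require duration data that are not available.

Some treatment-rule details are not published and are package defaults,
exposed in configuration: the first-line chemotherapy cap (6 cycles, the
protocol convention), the second-line pembrolizumab cap (35 cycles,
mirroring first line; implemented by carrying entrant cohorts of
progressors forward at most 35 cycles, decayed by the overall-survival
ratio), second-line chemotherapy until death, and best supportive care
attached to the PD state.

## Reconstructing patient-level data from published curves

Published KM figures provide curve coordinates and a number-at-risk table.
`reconstruct()` inverts the product-limit construction: within each
interval between risk-table times, it iterates on the number of censorings
(spread uniformly over the interval, with events placed at the digitized
step times) until the implied number at risk matches the printed table,
walking the curve steps and rounding event counts against the running KM
estimate so totals self-correct. Subjects still at risk at the end are
censored there; a known total event count can optionally rescale the final
interval. Digitization noise is handled by a running-minimum repair.
Reconstruction *refuses to run without a risk table*: guessing the
censoring pattern silently is the main failure mode of naive digitization.

On curves generated by `km_with_risk_table()` the round trip (curve →
pseudo-IPD → KM) agrees with the input to a sup-distance below 0.02 at
n = 500, and the implied numbers at risk match the table exactly.

## Survival modelling

Eight families are fitted by maximum likelihood with right censoring:
exponential, Weibull, log-logistic, log-normal, Gompertz, generalized
gamma, a Royston-Parmar spline on the log cumulative hazard (1 internal
knot by default, at log-time quantiles of the event times), and a
mixture-cure model (cured fraction plus Weibull latency, fitted by direct
likelihood maximization from three starts, since the generalized-gamma and
cure likelihoods are multi-modal; generalized-gamma fits are also
restarted from perturbed initial values). Selection is by minimum AIC;
ties prefer fewer parameters; non-converged fits are excluded with a
warning and the full ranking is retained for the run manifest.

## The synthetic trial emulator and its calibration

The emulator draws, per subject, an OS time and a latent progression time,
and sets PFS = min(OS, progression), which guarantees the ordering the
three-state model needs. Both chemotherapy-arm *marginals* are log-normal:
OS with median 16.9 months and σ = 0.85, PFS with median 6.3 months and
σ = 1.00. The latent progression distribution is defined by the survival
ratio $S_{\mathrm{PFS}}/S_{\mathrm{OS}}$, which is a valid (non-increasing)
distribution wherever the PFS hazard dominates the OS hazard — true
throughout the modelled range for the defaults (the hazards only cross
some 70 years out; the generator enforces monotonicity numerically, so
the far-extreme tail is imperceptibly distorted). The combination arm
transforms the *same* per-subject uniforms through the HR-scaled
inversions (common random numbers): marginals are untouched while the
Monte-Carlo variance of between-arm contrasts such as the estimated
hazard ratios shrinks substantially, and with both HRs equal to 1 the two
arms are identical by construction. Uniform accrual over 20 months with a
data cut at 24 months yields trial-like administrative censoring.

Two design points deserve emphasis:

* **Why log-normal marginals for both endpoints.** An earlier design used
  a log-logistic latent progression process. Its PFS marginal (a
  log-normal × log-logistic product) lies *outside* the candidate family
  set, and a 24-month observation window cannot identify such a tail: AIC
  selection then flips between families whose 40-year extrapolations
  differ by more than two-fold in the resulting ICER, purely by simulation
  seed. With log-normal marginals the truth is inside the candidate set,
  selection is consistent, and the occasional selection of a nesting
  family (generalized gamma, spline) extrapolates nearly identically.
  This mirrors the real appraisal problem: when the window cannot
  discriminate tails, the extrapolation — not the fit — drives the
  decision.
* **Calibration.** The two σ values are the only free shape parameters and
  were fixed once against the published base case using the *true*
  generating curves through the cohort model (no fitting): σ_OS = 0.85
  reproduces the published incremental life-years (2.10) almost exactly,
  and σ_PFS = 1.00 places the incremental QALYs (≈ 1.75 vs 1.72) and the
  ICER within a few percent of the published values. They are not
  re-tuned thereafter.

The emulator reproduces summary behaviour, not patient-level reality: no
subgroup structure, no treatment discontinuation separate from
progression, no loss to follow-up beyond administrative censoring, and
exact proportional hazards. Tests passing against it therefore validate
the *pipeline machinery*, not the clinical generalizability of any
particular extrapolation.

## Sensitivity analysis

* **One-way**: every parameter moved to its low/high value (±20% or the
  95% CI) with the rest at baseline; entries sorted by ICER spread. The
  influential set (patient weight, EV unit price, both HRs, discount
  rate) has strictly positive spread on the calibrated base case.
* **Two-way**: the two arms' PFS utilities varied jointly from 50% of
  baseline up to 1.
* **Probabilistic**: 1,000 draws with all distributions varied jointly.
  Beta and gamma parameters are moment-matched with
  sd = (high − low)/3.92; normal uses that sd directly; hazard ratios are
  log-normal with log-sd = (log high − log low)/3.92. The patient-weight
  range (60-140 kg) is strongly asymmetric around its baseline of 70 kg;
  the moment rule is applied as stated, which makes the sampled mean sit
  above the baseline — a property of the published range, not of the
  sampler. Survival-curve shape parameters stay fixed in PSA (only the
  HRs are sampled), matching the parameter table's distribution
  assignments.
* **Price threshold**: bisection on a drug's unit price (distribution
  ranges scaled along) until the probability of cost-effectiveness at a
  given willingness-to-pay crosses a target, using common random numbers
  across candidate prices; with degenerate (fixed) distributions this
  reduces to solving ICER = WTP.
* **Subgroups**: the identical pipeline re-run on per-subgroup curves and
  hazard ratios.

## Numerical choices

* Cycle conversion fixed at 21/30.4375 months; time is months everywhere.
* AIC ties (within 1e-9) break toward fewer parameters.
* `S(0) = 1` is enforced and survival values clipped to [0, 1];
  occupancy conservation (PFS + PD + dead = 1) holds to 1e-9 per cycle.
* If a fitted PFS curve exceeds the OS curve (possible under independent
  fitting), occupancy is clipped, with a warning beyond a 0.02 violation.
* The background-mortality floor converts annual probabilities to
  per-cycle probabilities via `1 - (1 - q)^(cycle/12)` at the cohort's
  attained age.
* All randomness fans out from one integer seed; identical configuration
  and seed reproduce every artifact byte-for-byte.

Test and example problem sizes are deliberately moderate — 500 subjects
per arm for round-trip and property checks, 2,000 per arm for statistical
recovery, 1,000 PSA draws — sizes at which the checked tolerances are
comfortably identifiable while the whole suite runs in well under a
minute per stage.

## Known limitations

* Proportional hazards over a lifetime horizon is an extrapolation far
  beyond the observed window; no waning or time-varying effect is
  modelled.
* The AIC-selected extrapolation remains the dominant uncertainty; the
  probabilistic analysis varies parameters, not curve shapes (an
  extension hook exists but is off by default, matching the published
  distribution table).
* Partitioned survival cannot track time-in-state individually; the
  second-line duration cap therefore uses a cohort-level entrant
  approximation.
* Costs are US-payer 2023 dollars; no societal perspective, no vial
  wastage, no dose modifications.
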