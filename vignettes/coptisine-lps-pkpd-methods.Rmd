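---
title: "Methods: the coptisine/LPS inflammation PK-PD model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the coptisine/LPS inflammation PK-PD model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coptipkpd)
```

## The model

`coptipkpd` implements a mechanism-based PK-PD model of acute inflammation in
rats challenged intravenously with lipopolysaccharide (LPS, 100 µg/kg) and
treated with IV bolus coptisine. Ten states are integrated jointly
(canonical order `pkpd_states()`):

**Coptisine kinetics.** A linear two-compartment model with central
elimination,

$$\frac{d\,cop}{dt} = -(k_{10}+k_{12})\,cop + k_{21}\,cop_2, \qquad
\frac{d\,cop_2}{dt} = k_{12}\,cop - k_{21}\,cop_2,$$

plus a first-order lung distribution compartment
$d\,cop_{lung}/dt = k_{13}\,cop - k_{31}\,cop_{lung}$. The lung compartment
receives drug without depleting plasma (a sampling compartment), so plasma
kinetics remain exactly biexponential — `closed_form_2cpt()` is the
independent oracle the solver is tested against.

**Plasma TNF-α.** LPS triggers a zero-order TNF-α burst with two production
phases, `k0_phase1` on $[t_{LPS}, t_{LPS}+w_1)$ and `k0_phase2` on
$[t_{LPS}+w_1, t_{LPS}+w_2)$ (defaults $w_1 = 0.333$, $w_2 = 0.667$ h), and
saturable Michaelis–Menten elimination:

$$\frac{d\,TNF\alpha}{dt} = k_0(t)\,\bigl(1 - f(cop)\bigr)
 - \frac{V_m\,TNF\alpha}{k_m + TNF\alpha},
\qquad f(cop) = InhibitCon \times cop.$$

Coptisine inhibits production linearly. The linear model is unbounded; above
$1/InhibitCon \approx 1133$ ng/mL it would drive production negative, so
`f` is clamped at 1 by default (`clamp = FALSE` restores the strict linear
form below that threshold).

**Downstream cascade.** Lung TNF-α is a diffusion delay of plasma TNF-α;
iNOS mRNA, lung iNOS and plasma iNOS form a linear turnover chain; NO is
produced from a precursor pool driven by plasma iNOS raised to an
amplification exponent $\Delta$:

$$\frac{d\,NO_{pre}}{dt} = k_{iNOSNO}\,(iNOS_p)^{\Delta} - k_{inNO}\,NO_{pre},
\qquad
\frac{d\,NO_{plasma}}{dt} = k_{inNO}\,NO_{pre} - k_{outNO}\,NO_{plasma}.$$

All cross-scale unit bridging (pg/mL → relative iNOS units → µmol/L) is
absorbed into the rate constants, so downstream states live on the scales
implied by the packaged estimates rather than literal assay scales.

## Parameters and key conventions

`model_parameters()` ships the published population estimates; the same set
is available as the flat YAML config `extdata/params_table1.yaml`.

Decisions taken where the source material was ambiguous:

* **V1 units.** The central volume is carried as **2630 mL per animal**, and
  per-kg doses are converted through the regimen body weight
  (default 0.20 kg), giving a bolus jump $dose \cdot BW \cdot 10^6 / V_1$
  (588.6 ng/mL for 7.74 mg/kg). A literal per-kg reading of the printed
  value is inconsistent with the reported peak concentrations.
* **Production window end.** The second production phase ends at
  $w_2 = 0.667$ h (configurable); this matches both the parameter definition
  and the observed sub-1 h plasma TNF-α peak.
* **Initial conditions.** All states start at 0 at the LPS injection: the
  production model has no baseline-maintenance term, so pre-challenge
  baselines are treated as zero in the mechanistic states.
* **LPS is not a state.** Its effect is fully encoded in the $k_0$ schedule;
  the dose value on the regimen is informational.
* **Vm units.** $V_m$ is used as a rate in pg/(mL·h) — the only reading
  under which the elimination term is dimensionally consistent.

## Simulation

`simulate_pkpd()` integrates with `deSolve::lsoda` driving a compiled C
right-hand side (the production-rate spans and the Michaelis–Menten and
precursor terms make the system moderately stiff; an adaptive
implicit-capable integrator is required). Integration restarts at the
production breakpoints and at every bolus so discontinuities are resolved
exactly; boluses are instantaneous state jumps, and values reported at a
dose time are post-dose. Default tolerances are `rtol = 1e-8`,
`atol = 1e-10`; tiny negative solver excursions (within `max(1e-9, 100 *
atol)`) are floored to zero and larger ones raise an error. Halving grid
step and tolerances changes reported AUCs by well under 0.01%.

Under the default parameters the cascade peaks in causal order — plasma
TNF-α at the end of the production window (0.667 h), lung TNF-α ≈ 2.4 h,
iNOS mRNA ≈ 2.9 h, lung iNOS ≈ 3.2 h, plasma iNOS ≈ 3.8 h, plasma NO
≈ 4.2 h — each driven stage strictly after its driver.

## Exposure metrics

AUCs use the **linear** trapezoidal rule (the reported analysis states no
log-linear variant), with linear interpolation at window edges and no
extrapolation; observed-data AUCs use only scheduled sample times, model
AUCs a dense grid. `percent_reduction()` and `auc_ratio()` reproduce the
reported derived arithmetic from `reference_exposures()`, the table of
printed observed AUC values shipped with the package (the raw animal data
are not deposited). `relative_inos_ratio()` is the western-blot double
normalization (iNOS/GAPDH over the t = 0 control lane).

## Synthetic studies

`study_design(1:4)` packages the four experimental designs (9, 12, 74 and
57 animals; serial tail-vein vs destructive terminal sampling; the six
observables coded 1–6). `generate_study()` draws, per animal, log-normal
between-animal variability $\theta_i = \theta_{pop} e^{\eta_i}$,
$\eta_i \sim N(0, \omega^2)$, a body weight from Uniform(0.18, 0.22) kg
(200 ± 20 g rats), simulates the individual, and adds additive Gaussian
residual noise per observable, truncating negative draws at zero and
flagging them.

The published analysis states the *form* of both variability terms but not
their magnitudes, so the defaults are documented stand-ins chosen once:
$\omega = 0.2$ (≈20% CV) on the PK parameters and the two production
phases, 0 elsewhere; and residual SDs at roughly 4–5% of each observable's
peak under the default parameters (25 ng/mL plasma coptisine, 0.08 lung
coptisine, 80 pg/mL plasma TNF-α, 2.5e-5 lung TNF-α, 2.5e-9 iNOS ratio,
2.5e-7 µmol/L NO, all in model units). What the generator emulates is the
studies' sampling structure and statistical error model; it does not emulate
assay-specific artifacts (ELISA plate effects, blot saturation), dropout,
inter-occasion variability, or any model misspecification — so tests passing
on synthetic data demonstrate self-consistency of the pipeline, not model
correctness on real animals.

Datasets round-trip through an event-record CSV dialect
(`ID,GROUP,TIME,DVID,DV,AMT,CMT,BW`; dose rows carry `AMT` with `CMT` 1 =
coptisine mg/kg, 4 = LPS µg/kg).

## Estimation

`fit_pkpd()` is **pooled maximum likelihood**: each group's curve is
predicted once at the candidate population parameters and compared with all
observations under the additive Gaussian residual model. This is the major
deliberate simplification relative to the nonlinear mixed-effects estimation
used for the published fit — between-animal variability enters only through
simulation and the parametric bootstrap (`fit_rse()`), not the likelihood.
Consequences: with BAV in the data, pooled estimates of nonlinearly
propagated parameters can be mildly biased, and the packaged study designs
bound what is identifiable.

Technical choices: parameters are optimized on the log scale within ±3
orders of magnitude of the initial values; multi-start (default 5 starts,
log-normal jitter SD 0.3); residual SDs are either fixed or profiled at
their closed-form conditional MLE $\hat\sigma_j^2 = RSS_j/n_j$ per
observable — profiling is also this package's answer to how plasma and lung
observables are weighted in a simultaneous fit. Optimizers: `L-BFGS-B`
(default) and `Nelder-Mead`; the latter is preferred for simulation studies
because the objective carries solver-level noise at loosened fitting
tolerances, which finite-difference gradients amplify. Nelder-Mead's
simplex-degeneracy stop near an optimum is conservatively reported as
`converged = FALSE`. `k_TNFapl` and `delta` are weakly identified at these
designs; `delta` stays fixed at its packaged value unless explicitly freed.
AIC/BIC follow `objective + 2k` and `objective + k log n` on the −2LL
scale.

Recovery behaviour (recomputed by the test suite and acceptance script):
noise-free dense two-dose plasma PK data return the free PK parameters
(`V1`, `k10`, `k12`, `k21`) within 1%; twenty virtual repetitions of the
serial PD study plus the destructive PK-PD study at default ω/σ recover the
TNF-α production/inhibition subset (`k0_phase1`, `k0_phase2`, `InhibitCon`,
`k_outTNFa`) with median relative error within ±10% per parameter and no
sign bias.

## Model qualification

`vpc()`, `npc()` and `npde()` simulate replicate studies under the full
model (fresh body weights, BAV draws and residual noise per replicate,
truncation included) and compare observations against the resulting
distributions; bins are the scheduled nominal times stratified by group and
observable (designs are fixed-schedule, so no adaptive binning). The VPC
reports the envelope of each requested percentile across replicates and
records `n_sim` (2000 by default, matching the published qualification).

The NPDE is rank-based *without* the reference method's decorrelation step:
serial correlation within animals is ignored. For destructive designs each
animal contributes one observation per observable, so within an observable
the omission is exact; across observables the same animal's BAV draw is
shared, which is why null checks are evaluated per observable.

Two practical caveats, both verified numerically and reflected in the test
design:

* **Truncation point mass.** Observations truncated at zero (and bins whose
  simulated values pile up at zero) violate the continuity assumption behind
  rank and interval diagnostics — coverage of a 50% interval rises to
  ~0.6–0.75 in such bins even under the true model. Null-behaviour checks
  therefore restrict to high-signal bins (population prediction > 5σ).
* **Cross-observable correlation.** Pooled coverage over all observables is
  over-dispersed relative to binomial bounds because each animal's BAV draw
  shifts all its observables together; `npc(by_dvid = TRUE)` provides the
  per-observable strata on which binomial confidence bounds are valid.

Problem sizes used by the packaged checks: 500 simulation replicates for
NPDE/NPC null behaviour on the 74-animal destructive design (the VPC
default stays at 2000, the published qualification size), and 20 seeds for
the recovery study — sizes chosen to make the suite comfortably
reproducible on a laptop-class single core.

## Known limitations

* Pooled ML is not NLME; the published AIC/BIC and parameter uncertainties
  are not reproducible without the raw animal data, and are not targets.
* The printed terminal half-life (1.51 h) is an NCA value from raw data; the
  packaged micro-constants imply a β-phase half-life of ≈7 h, so half-life
  is deliberately not reproduced.
* Model lung-coptisine scale: the packaged `k13`/`k31` put simulated lung
  coptisine at ~0.3% of plasma, while the observed lung/plasma AUC ratios
  (4.33, 6.34) come from the printed observed AUCs. The ratio arithmetic is
  therefore computed from the shipped observed values, with unit bridging
  absorbed in the constants.
* No mechanistic receptor signalling, no IFN-γ contribution, no lung NO
  modelling, no covariates — all outside the model's scope.
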