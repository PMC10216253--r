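---
title: "Models and methods behind nicodose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nicodose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nicodose)
```

This vignette is the package's own account of the models it implements,
the defaults it ships, and the reasoning behind choices that were
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The two-compartment nicotine model

Intravenous nicotine in the rat is described by a linear mammillary
two-compartment model: a central pool representing blood, plasma, CSF and
other well-perfused spaces, exchanging with a peripheral pool of poorly
perfused tissue (fat, muscle), with first-order elimination from the
central pool. In amounts (µg):

$$\frac{dA_c}{dt} = u(t) - (k_{el} + k_{cp})A_c + k_{pc}A_p, \qquad
  \frac{dA_p}{dt} = k_{cp}A_c - k_{pc}A_p, \qquad
  C(t) = A_c / V_c .$$

The default parameter set is $V_c = 5$ l/kg, $k_{el} = 0.8$ h$^{-1}$,
$k_{cp} = 1.5$ h$^{-1}$, $k_{pc} = 1.2$ h$^{-1}$, body mass 0.35 kg.
Because `V_c` is in litres and amounts in micrograms, µg/l and ng/ml are
the same unit and no conversion factor appears anywhere.

Three interpretation decisions deserve comment:

* **Units of the rate constants.** The constants are dimensionless in
  their original listing; we interpret them as h$^{-1}$. This is the only
  reading under which the derived clearance $k_{el} V_c = 0.8 \times
  1.75$ l $= 1.4$ l/h coincides exactly with the listed clearance value
  of 1.4, and it yields a terminal half-life of
  $\ln 2 / 0.3 \approx 2.3$ h (the slow hybrid rate at these constants is
  0.3 h$^{-1}$), physiologically plausible for nicotine in the rat.
* **Clearance is derived, not a second loss term.** `clearance` in
  `pk_parameters()` is a consistency reference checked by
  `derive_clearance()`; applying it as an additional elimination pathway
  would double-count drug loss and roughly halve predicted maintenance
  concentrations. For sensitivity analyses the alternative reading is
  available through the `extra_loss_rate` parameter.
* **"Plasma" and "CSF" are synonyms here.** The model has a single
  central compartment; we report one central concentration and make no
  distinction between plasma and CSF predictions.

Infusion records enter as event times (pump onset; at these time scales
the distinction from pump completion, 2 s later, is immaterial). The
default dosing mode treats each 2-s infusion as an instantaneous bolus —
justified because 2 s is four orders of magnitude below the slowest system
time constant; the test suite checks that the explicit 2-s zero-order mode
changes the peak by less than 0.5%. Integration uses `deSolve::lsoda`
(rtol $10^{-8}$, atol $10^{-10}$) restarted at each dosing event so that
state jumps are never smeared across a discontinuity; the default output
grid is 1 s.

The closed-form biexponential bolus solution (`analytic_bolus()`), with
hybrid rates the roots of
$\lambda^2 - (k_{el}+k_{cp}+k_{pc})\lambda + k_{el}k_{pc} = 0$
(3.2 and 0.3 h$^{-1}$ at the defaults), serves as an independent oracle:
the suite requires pointwise agreement within $10^{-6}$ relative error,
plus superposition and mass-balance invariants on random schedules.

### Reconstructed reference sessions

`reference_session_schedule()` encodes two stylised 2-h intake patterns
used for the headline exposure predictions:

* `"standard"` (30 µg/kg/inf): 10 loading infusions evenly spaced over
  minutes 0–18, then 12 maintenance infusions every 8 min from minute 26
  to 114 — the loading-then-maintenance shape of standard-dose sessions,
  with 22 infusions in total (a typical stable-responder day).
* `"lowdose"` (1.5 µg/kg/inf): 10 infusions over the first hour and 30
  over minutes 60–118 — the weaker loading and late boosting seen in
  low-dose sessions (40 infusions, a high-responder day).

`scripts/acceptance.R` simulates both and reports the time-averaged
maintenance concentration and trough (minutes 40–120) of the standard
session and the end-of-session concentration of the low-dose session.
The 40-min window start excludes the loading transient; it is where the
profile has visibly stabilised at a 2-s output resolution.

## Session logs and acquisition rules

The log dialect is deliberately minimal (one header row, then
`t_sec,kind` events) rather than a binary Med-PC format; a validator
replays each log against the FR-$n$/TO-20 s semantics: pokes during the
20 s after an infusion are recorded but never count toward the next
ratio, and every infusion must be preceded by exactly $n$ counting pokes
since the previous timeout expired.

Boundary conventions follow the printed inequalities exactly: rule 1 uses
strictly fewer than 10 infusions, rule 2 strictly below a 2.0 ratio, the
75%-or-greater drop is inclusive, and the low-dose 11.1 cutoff fails on
strictly-less-than (a subject exactly maintaining the reference level has,
literally, maintained it). Two conventions were open and are decided
here:

* **Baseline for the 75%-drop rule.** The drop is referenced to the mean
  active-poke count over sessions 1–5 — the only well-defined pre-window
  for a rule evaluated in sessions 6–10. A running-max or
  previous-session baseline would make the rule fire on single noisy
  sessions.
* **Ratio degeneracies.** A session with active pokes but zero inactive
  pokes has ratio $+\infty$ (perfect discrimination, passes); a session
  with no pokes at all has an undefined ratio and counts against the
  ratio criterion, since a non-responding animal is not discriminating.
* **Consecutiveness** is by session order; weekend calendar gaps are
  ignored.
* The control-referenced cutoff uses the sample (n−1) SD across
  per-subject window means, the natural small-cohort estimate.

## Hill fitting

Activation fits estimate $(EC_{50}, n, top)$ in
$r = top \cdot c^n/(c^n + EC_{50}^n)$ with the bottom fixed at 0;
inhibition fits fix the baseline at 1 and the floor at 0 (responses are
baseline-normalised) and estimate $(IC_{50}, n)$. The midpoint is
parameterised as $\log EC_{50}$ and the Hill slope as $\log n$, and the
Levenberg–Marquardt search (`minpack.lm`, ftol/ptol $10^{-12}$) is
restarted from every tested concentration; the best converged start by
residual sum of squares wins. This multi-start makes the fit invariant to
replicate ordering and robust to the local minima that plague single-start
Hill fits on noisy 12-dose designs.

Confidence intervals use a case-resampling bootstrap over replicates
(percentile interval, refits initialised at the point estimate),
deterministic under a fixed seed. A bootstrap was chosen because no CI
procedure is canonical for small oocyte/slice designs; asymptotic
Wald intervals on $\log EC_{50}$ are easily obtained from the returned
`nls` model if preferred. With zero residual noise the interval collapses
onto the point estimate. The suite checks midpoint recovery over 200
synthetic 12-dose datasets (3-fold spacing, Gaussian noise SD 0.05;
median $|\log_{10}$ error$|$ below 0.05) and ≥90% empirical coverage at a
6-replicate design — a typical oocyte batch size.

## Dopamine release and uptake kinetics

Evoked transients follow Michaelis–Menten clearance,
$d[\mathrm{DA}]/dt = -V_{max}[\mathrm{DA}]/(K_m + [\mathrm{DA}])$, with an
instantaneous concentration increment $[\mathrm{DA}]_p$ per stimulus
pulse (4-ms pulses are far below trace resolution). $K_m$ is fixed at
0.16 µM — the conventional striatal dopamine uptake affinity — because
$V_{max}$ and $K_m$ are poorly jointly identifiable from single
transients; it is a configurable argument throughout. Fitting estimates
$(V_{max}, [\mathrm{DA}]_p)$ by Nelder–Mead least squares on
log-parameters, simulating candidate traces on the recording's own grid.
An independent fixed-step explicit-Euler integrator in the test helpers
bounds the simulator's error below $10^{-3}$ µM on multi-pulse traces.

Protocol helpers mirror the standard slice experiment: a single-pulse
intensity series over 0.5–10 V (with, in the generator, per-pulse release
a saturating Hill-shaped function of input voltage), four-pulse trains at
3, 10, 30 and 100 Hz normalised to single-pulse release, electrode
calibration by OLS regression of sensitivity on background-current
features (a single peak-background regressor by default, arbitrary
feature columns accepted), and nicotine modulation curves (release at
1–100 nM bath nicotine, half-log steps, normalised to the drug-free
baseline and fit with the inhibition Hill model to give per-slice
IC$_{50}$s).

## What the synthetic generators do and do not emulate

`generate_session()` constructs logs that satisfy the schedule semantics
*by construction*: infusion times come from a loading burst plus
log-normal maintenance inter-infusion intervals (heavy right tail, as
with post-infusion pausing), each infusion is preceded by exactly $fr$
counting pokes, extra pokes fall inside timeouts, and inactive pokes are
homogeneous Poisson. Scenario defaults place the acquiring low-dose
groups at ~18–20 infusions/session (well above the 11.1 cutoff),
non-acquirers at ~4–8 declining, standard-dose responders at ~20–22 with
a 10-infusion loading burst, the transgenic scenario at ~15–20 rising to
~40 by day 17 with low-responding controls, and saline substitution
decaying geometrically after the switch. Per-subject variability is a
log-normal rate multiplier (CV 0.12).

These are structural emulations: the true inter-infusion distributions,
day-to-day correlations and within-session satiation dynamics of real
animals are unknown and not modelled, and no pharmacodynamic link runs
from simulated exposure back to poke rates. Passing recovery and
classification tests on these cohorts therefore demonstrates that the
analysis layer is correct and well-calibrated under its stated
assumptions — not that real cohorts would classify with the same margins.
Inter-animal variability in nicotine metabolism is likewise not modelled
on the PK side.

## Numerical choices and degenerate inputs

* PK solver tolerances rtol $10^{-8}$/atol $10^{-10}$; tiny negative
  solver undershoots are clipped to zero.
* Simulation grids are held in integer-friendly seconds and event
  breakpoints are snapped onto the output grid within $10^{-6}$ s, so
  profiles of different schedules share identical grids.
* Repeated disposition eigenvalues (impossible at the default constants)
  raise an explicit degenerate-eigenvalue error.
* Hill fits refuse designs with fewer than 4 distinct concentrations;
  all-zero replicates cannot be normalised and error out.
* MM fits require a positive transient (`no signal` otherwise); trains
  must be sampled at no coarser than half the inter-pulse interval.
* Flat nicotine modulation curves (all doses within 2% of baseline) are
  flagged rather than fitted.
* Group bands use the sample-SD SEM and flag single-subject bands as
  undefined rather than reporting 0.

## Problem sizes used by the test suite

The suite's simulation studies use sizes chosen to make the statistical
assertions stable: 100 random schedules for the PK invariants, 200
datasets for Hill midpoint recovery, 100 rounds × 99 bootstrap resamples
for CI coverage, and 100 noisy transients for MM recovery (~2 min total).
The acceptance script itself is deterministic and runs in seconds.

## Known limitations

* No physiologically based PK, no brain-compartment kinetics, no
  metabolite (cotinine) modelling, linear elimination only.
* Acquisition rules assume complete day coverage inside their windows;
  missing days raise coverage errors rather than being imputed.
* The Hill CI is a percentile bootstrap over replicates; with very few
  replicates (2–3) it can undercover.
* Voltammogram-level processing (background subtraction, drift and pH
  artifacts) is out of scope: the kinetic layer starts from
  concentration traces, with electrode calibration as the only
  current-to-concentration step.
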