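---
title: "Multistable action potentials as fixed points of the stroboscopic map"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multistable action potentials as fixed points of the stroboscopic map}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the reduction

A ventricular myocyte paced with periodic current pulses is a periodically
forced, dissipative dynamical system. Its observable steady behaviours —
normal action potentials, action potentials carrying early
afterdepolarisations (EADs), and outright repolarisation failure — are
periodic (or quasi-periodic) responses of that system. `eadmap` analyses
them through the standard reduction: sampling the full state at every
stimulus onset turns the forced flow into a diffeomorphism, the
stroboscopic Poincaré map \(P\). A period-1 AP is a fixed point of \(P\); a
period-\(k\) response (e.g. alternans after a period doubling) is a fixed
point of \(P^k\). Stability is read off the characteristic multipliers —
the eigenvalues of the monodromy matrix \(DP^k\) — with the response stable
iff all multipliers lie strictly inside the unit circle. Because the system
is non-autonomous, no trivial multiplier is pinned at +1.

On top of this reduction the package implements the full working cycle of a
bifurcation study:

1. **Settling** (`run_to_steady_state`): iterate the stroboscopic sample
   until consecutive samples one period apart differ by less than 1e-8 in
   every component (raw mixed units — mV, mM, dimensionless — without
   rescaling).
2. **Shooting** (`newton_shoot`): refine the sampled state by damped Newton
   on \(P^k(x) - x = 0\), which converges equally to stable and to unstable
   responses — the only route to the saddle orbits that organise basins of
   attraction.
3. **Continuation** (`continue_branch`): trace the fixed point in a
   conductance parameter by pseudo-arclength predictor–corrector steps, so
   saddle-node folds are rounded and unstable segments are part of the
   branch.
4. **Classification** (`detect_crossings`, `localize_bifurcation`): flag
   multiplier exits through +1 (saddle-node, SN), −1 (period doubling, PD)
   or a complex pair (Neimark–Sacker, NS), and refine them — by bracketed
   root finding on the multiplier test function for PD/NS, and by a damped
   Newton solve of the Moore–Spence extended system
   \(\{P(x;p)=x,\ (DP-I)v=0,\ c^\top v=1\}\) for SN.
5. **Protocols** (`hysteresis_sweep`, `multistability_census`,
   `perturb_and_settle`, `nai_fixed_analysis`): the experiment designs that
   reveal hysteresis and coexisting attractors in simulation, cross-checked
   against the continuation picture.

## The paced system and its parameters

The myocyte-side contract is a forced ODE with membrane equation
\[
dV_m/dt = I_{stim} - I_{net}, \qquad
I_{net} = \textstyle\sum_j I_j \quad (\text{outward positive, pA/pF}),
\]
driven by square pulses of 80 pA/pF lasting 1 ms at a pacing cycle length
of 2000 ms (0.5 Hz) — `pacing_protocol()`'s defaults. The two
delayed-rectifier conductances enter as percentages of control
(`pctGKr`, `pctGKs`), so a scaled current is exactly linear in its
percentage at fixed state; this is the repolarisation-reserve dial the
whole analysis is organised around. `model_params()` also carries the fixed
external concentrations (Ca 2, Na 140, K 5.4 mM; internal K 140 mM) used by
full human-myocyte formulations, and an optional sodium clamp `nai_clamp`
that freezes the intracellular-Na equation and reduces the effective
dimension by one.

The model itself is pluggable: any `dynsys` object providing a right-hand
side (interpreted R, compiled C, or both) joins the same machinery.

## The bundled surrogate and what it stands for

Full human ventricular ionic models have dozens of state variables and are
not required to validate Poincaré-map machinery. The package ships a
three-variable paced surrogate (`make_paced_surrogate_ap`) engineered to
have, verifiably, the *topological* structure the analysis targets:

* `Vm` — a fast excitable voltage with inward (`ICaL`-like, gated by a slow
  inactivation variable `h`), rectifier (`IKr`/`IKs`-like, percentage
  scaled), inward-rectifier (`IK1`-like, rest only) and pump currents;
* an ungated *window* inward current, active between −45 and −22 mV, which
  can capture repolarisation into a sustained depolarised plateau — a
  repolarisation-failure (LAVO-like) response;
* `Nai` — a slow sodium-like variable (time constant 20 s) that accumulates
  during diastole and powers an outward pump current `kp·Nai`; high `Nai`
  protects repolarisation, low `Nai` permits capture.

The feedback loop is positive: a failing response abolishes diastole, so
`Nai` collapses, the pump weakens, and failure is reinforced; a short AP
restores diastole, `Nai` accumulates, and short APs are reinforced. Over an
intermediate band of `pctGKr` the two responses coexist as period-1
attractors separated by a saddle, with saddle-node folds at both edges of
the band — the minimal bistability-plus-hysteresis structure. Clamping
`Nai` severs the loop and the band collapses to a single response, exactly
the qualitative signature the sodium-clamped analyses probe. All surrogate
constants are frozen in code (`surrogate_constants()` internally), so every
surrogate result is reproducible without seeds; `bistable = FALSE` removes
the window current and yields a monostable control with the same interface.

What the surrogate does *not* emulate: calcium cycling (no SR
compartments, no CICR), a sodium current inventory (Na enters as a lumped
diastolic influx), EAD voltage oscillations on the plateau (its failure
response is a static plateau), and any quantitative electrophysiology —
conductances and gates are tuned for structure, not for fitting. Passing
tests on the surrogate therefore demonstrate that the *machinery* —
settling, shooting, multipliers, continuation, localization, sweeps,
censuses — is correct on a system with known answers; they do not certify
physiological numbers, which belong to a full transcribed ionic model
dropped into the same contract.

The analytic testbed plays the same role one level down:
`make_logistic_map` (PD at \(r = 3\), multiplier \(2-r\)),
`make_delayed_logistic_map` (NS at \(r = 2\), modulus \(\sqrt{r-1}\)),
`make_sn_normal_form` (fold at \(\mu = 0\), multipliers
\(1 \pm 2\sqrt{-\mu}\)) and `make_forced_linear` (affine stroboscopic map
with multiplier \(e^{-T/\tau}\)). Maps bypass the integrator — a map is its
own Poincaré map — isolating the continuation and classification logic from
integration error; the acceptance suite re-derives each closed form through
the full pipeline.

## Numerical choices

**Integrator.** `lsoda` with segmented pulses: each cycle is integrated as
[0, pulse-off] and [pulse-off, cycle end], so the square-pulse
discontinuity never falls inside an adaptive step. Default tolerances are
rtol 1e-10 / atol 1e-12. We initially ran at rtol 1e-8, but the integrator's
beat-to-beat jitter on the stroboscopic sample then sits near 5e-8 — at or
above the 1e-8 steady-state criterion — and settling fails spuriously next
to a genuine fixed point. Two orders of headroom below the criterion make
it meaningful; the criterion itself (1e-8, absolute, raw mixed units) is a
deliberate convention and unchanged.

**Steady-state periods.** Convergence is tested at lags 1..4. A period-p
claim with p > 1 additionally requires every shorter lag to sit clearly
above the criterion (10×), because near a period-1 point integrator jitter
could otherwise tip an arbitrary lag below 1e-8 first and report a spurious
period. Non-convergence is a *result* (quasi-periodic and irregular
responses are flagged for period-k analysis), never an exception.

**Monodromy.** Two independent routes that must agree: central finite
differences of the map with per-variable steps of 1e-5 × the variable's
typical scale (chosen to balance truncation against integrator noise; at
1e-6 the noise term dominates), and the variational equations integrated
alongside the flow with a finite-differenced right-hand-side Jacobian. The
FD route is the fast default inside Newton; the variational route backs
the Moore–Spence fold solve, where Jacobian noise directly limits how
precisely the fold is pinned.

**Shooting.** Damped Newton (step halving, up to 8 halvings) on the
sup-norm residual, tolerance 1e-9 in mixed units. A nearly singular
\(DP^k - I\) is reported as a diagnostic (smallest singular value), not
raised — it is precisely the bifurcation signal continuation is looking
for.

**Continuation.** Secant predictor and bordered-Newton corrector in scaled
(state, parameter) coordinates (scales: 100 mV, 1, 10 mM, parameter range).
Two safeguards proved necessary on the surrogate: a cap on the corrector's
per-iteration Newton step and a trust-region rejection of any "solution"
further than 3 step-lengths from the prediction — without them the
corrector occasionally converges onto a *different* branch across the
saddle. Steps halve on failure, grow 1.3× after three successes, and a
branch can be terminated once its leading multiplier exceeds `stop_mult`
(strongly unstable middle-branch orbits have exploding multipliers — the
saddle's expansion rate grows by orders of magnitude along the branch —
and are expensive to track beyond their existence). A branch that stalls
by step underflow while a real multiplier climbs toward +1 has run into a
fold whose turning radius is below the resolvable arclength; it is handed
to the Moore–Spence solve from its end point, which pins the fold without
needing to round it.

**Feature extraction.** APD90 uses the per-beat baseline (the potential at
stimulus onset) and the *last* downward crossing of
\(V_{90} = V_{peak} - 0.9\,(V_{peak} - V_{baseline})\), linearly
interpolated, so re-depolarisations above threshold lengthen APD — the
convention under which an emerging EAD abruptly prolongs APD. A beat whose
potential never falls below −60 mV is a repolarisation failure by an
absolute criterion as well: when the diastolic state is itself a
depolarised plateau the relative rule is meaningless. The
transient-depolarisation count (`count_tdmp`) uses a −40 mV floor and a
1 mV prominence filter after the primary peak; the numeric rule is a
declared convention — robust to integrator jitter and sub-millisecond
resampling — since no standard quantitative definition exists. Flat traces
return a no-AP flag rather than an error.

**Censuses and attractor identity.** Two converged stroboscopic states are
the same attractor when they differ by at most 1e-4 in any component (raw
units), orbit points matched up to cyclic shift for period-k responses;
the threshold sits far above integrator noise and far below the
inter-attractor distances observed on the surrogate (order 50 mV, 5 mM).
The default initial-condition bank crosses 11 sodium levels with a
polarised rest configuration and a depolarised plateau configuration (the
analogue of low/high load starting conditions). A census from finitely
many starts is a lower bound on the true multistability order — near the
upper fold the failure response's basin narrows below the bank's
resolution long before the branch actually ends.

**Sweeps.** `hysteresis_sweep` carries each step's converged state into
the next step (1% grid by default). The carry-over *is* the hysteresis
mechanism: within the bistable band the occupied branch depends on the
path. Sweep transitions agree with the continuation-localized folds to
within one grid step; strict bracketing by the transition cell is not
guaranteed by any sweep, because the vanishing attractor's basin narrows
like \(\sqrt{p^*-p}\) and the carried state can hop out one cell early.

## Problem sizes used by the shipped analyses

The test-suite and the acceptance script run: continuation branches of
tens of points (up to ~120 on the surrogate, with `stop_mult` cutting the
explosive middle branch); settling runs capped at 1500–3000 beats (the
slow sodium mode contracts by ≈ 0.905/beat, so 1e-8 convergence needs
≈ 200 beats, more near folds); a 50-start census at 20 parameter values
for the continuation/brute-force cross-check; and 1%-step sweeps spanning
both folds. These sizes resolve every structural feature of the surrogate
with comfortable margins while keeping a complete run in minutes on one
core.

## Known limitations

* Post-PD period-doubled branches are found by simulation (period-2
  settling and shooting on \(P^2\)), not by automatic branch switching at
  the PD point; the surrogate's window is fold-bounded, so its PD-side
  machinery is validated on the logistic testbed.
* The census lower-bound caveat above: basins thinner than the bank's
  spacing are missed (quantified by the gap between the census-visible
  band edge and the continuation fold).
* Two-parameter bifurcation curves are out of scope; `pctGKs` is varied
  only as a fixed level at which one-parameter scans in `pctGKr` are run.
* The surrogate's repolarisation-failure attractor is static; analyses of
  oscillatory plateau behaviour (EAD morphology, LAVO oscillations) need a
  full ionic model behind the same `dynsys` contract.
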