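# eadmap

Bifurcation and multistability analysis of paced cardiac action potentials
via the stroboscopic Poincaré map.

## The problem

When the repolarisation reserve of a ventricular myocyte is attenuated —
reduced rapid (IKr) or slow (IKs) delayed-rectifier conductance — the
paced cell does not simply prolong its action potential. It can hold
several *coexisting* stable responses at one and the same parameter set:
a normal AP, APs carrying early afterdepolarisations (EADs), and
repolarisation failure. Which one you observe depends on history
(hysteresis), and abrupt transitions between them happen at bifurcation
points of the underlying dynamical system.

`eadmap` is for modellers who want to map that structure rather than stare
at simulated traces. A paced myocyte model is a periodically forced ODE;
sampling the state at every stimulus onset reduces it to a diffeomorphism
(the stroboscopic Poincaré map *P*), whose fixed points are the periodic
AP responses. The package provides:

* beat-by-beat stiff integration with the strict steady-state criterion
  (componentwise change < 1e-8 between stroboscopic samples) and
  period-aware convergence (alternans is flagged as period 2, never
  mistaken for a converged period-1 AP);
* Newton **shooting** for stable *and unstable* periodic responses, with
  characteristic multipliers from the monodromy matrix *DP* (two
  independent Jacobian routes: map finite differences and variational
  equations);
* **pseudo-arclength continuation** of response branches in a conductance
  percentage (%GKr), rounding saddle-node folds onto unstable segments,
  with detection and precise localization of saddle-node (multiplier
  through +1, solved by the Moore–Spence extended system), period-doubling
  (through −1) and Neimark–Sacker (complex pair through the unit circle)
  bifurcations;
* the experiment **protocols** that expose multistability in simulation:
  1%-step hysteresis sweeps with state carry-over, multi-start attractor
  censuses, instantaneous sodium perturbations, and sodium-clamped
  (reduced-system) analyses;
* per-beat **AP features**: APD90 (last-crossing convention, so EADs
  extend APD), transient-depolarisation counts, diastolic ion levels,
  response classification (noEAD / EADn / LAVO / irregular);
* an analytically solvable **testbed** (logistic map, delayed logistic
  map, saddle-node normal form, pulsed linear relaxation) plus a bundled
  three-variable bistable paced surrogate, so every stage of the pipeline
  is validated against closed forms and brute force.

The model layer is pluggable: any system exposing the `dynsys` contract
(an R or compiled right-hand side plus a pacing protocol) plugs into the
same machinery.

## Worked example

Two different initial conditions at the same parameters (half the control
IKr conductance) settle onto two different stable period-1 responses of
the same paced cell:

```r
library(eadmap)
sys <- make_paced_surrogate_ap()          # bundled bistable paced surrogate
p50 <- sys$params; p50$pctGKr <- 50       # half the control IKr conductance

## two different initial conditions, same parameters
short <- run_to_steady_state(sys, c(-86, 1, 9),      p50, max_beats = 1500)
fail  <- run_to_steady_state(sys, c(-35, 0.05, 0.2), p50, max_beats = 1500)

fp_short <- newton_shoot(sys, short$state, params = p50)
fp_fail  <- newton_shoot(sys, fail$state,  params = p50)
print(fp_short)
#> <fixed_point k=1 converged residual=2.46e-10 iter=1>
#>   x: Vm=-86.0543, h=0.98716, Nai=6.09118
#>   multipliers (|.|): 0.9291, 0.0000, 0.0000  [stable]
print(fp_fail)
#> <fixed_point k=1 converged residual=2.06e-12 iter=1>
#>   x: Vm=-31.4938, h=0.00856872, Nai=4.97783e-06
#>   multipliers (|.|): 0.9048, 0.0000, 0.0000  [stable]

tr <- simulate_beats(sys, fp_short$x, 1, params = p50, dt_sample = 0.5)[[1]]
cat("APD90 of the short response:", round(apd90(tr), 1), "ms\n")
#> APD90 of the short response: 774.7 ms

ce <- multistability_census(sys, 50)
print(ce)
#> <census at 50: order 2 (LAVO + noEAD); 22/22 starts settled>
```

The first response is a normal short AP (diastolic potential −86 mV,
diastolic Na ≈ 6.1 mM, APD90 ≈ 775 ms, leading multiplier 0.93 — the slow
sodium mode). The second is repolarisation failure: the membrane is
arrested near −31 mV, diastolic sodium has collapsed, and the beat
classifies as LAVO. Both are genuine attractors (all multipliers inside
the unit circle); the census confirms the cell is bistable at this
conductance. Continuing either fixed point in `pctGKr`
(`continue_branch`, `detect_crossings`, `localize_bifurcation`) locates
the saddle-node folds bounding the bistable window, and 1%-step
`hysteresis_sweep`s transition at different parameters in the two
directions — the hysteresis loop those folds imply.

A thin command-line wrapper over the same functions is installed at
`inst/cli/eadmap.R`
(`Rscript eadmap.R <simulate|sweep|continue|census|clamp-scan|selftest>`).

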