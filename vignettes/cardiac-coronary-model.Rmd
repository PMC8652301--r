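---
title: "The cardiac-coronary closed loop: model, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cardiac-coronary closed loop: model, numerics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coroperf)
```

# What the model is

`coroperf` simulates the interaction between left-ventricular (LV)
mechanics, the systemic circulation, and passive coronary microvascular
perfusion in a closed loop, to predict how myocardial *demand* (myofiber
work density $W_f$) and *supply* (cycle-integrated network flow $Q$) are
distributed across the ventricular wall, and how their ratio — the work
density–perfusion mismatch index $W_f/Q$ — responds to contractility,
preload, afterload, wall thickness and cavity volume.

Three coupled components exchange state once per global time step:

1. **Systemic circulation (0D).** Five compartments — left atrium (LA),
   LV, proximal and distal peripheral arteries, veins — connected by
   linear resistances with ideal-diode mitral and aortic valves.  Storage
   compartments have linear pressure–volume laws
   $P = (V - V_0)/C$; the LA is a time-varying-elastance chamber that
   blends an end-systolic line $E_{es}(V - V_0)$ with an end-diastolic
   exponential $A\{\exp[B(V-V_0)]-1\}$ through a sine-rise /
   exponential-decay activation $e_{LA}(t)$.

2. **Transmural LV backend (reduced).** The LV is an incompressible
   thick-walled spherical shell with tangential fibers, discretized into
   `n_shells` shells of equal reference volume.  The backend contract is
   $(V_{LV}, t) \mapsto (P_{LV},\, p(\hat R),\, S_{ff}, E_{ff}
   \text{ per shell})$: given the cavity volume, incompressibility fixes
   every material radius, fiber stretch $\lambda = r/R$, and
   Green–Lagrange fiber strain $E_{ff} = (\lambda^2 - 1)/2$.  Total fiber
   stress is passive (Fung-type, tension-only;
   $S_{pas} = C_f b_f E\, e^{b_f E^2}$ for $E>0$) plus active
   (Guccione-type, $S_{act} = T_{max}\,
   \mathrm{Ca}_0^2/(\mathrm{Ca}_0^2 + \mathrm{ECa}_{50}^2)\, C(t)$ with
   length-dependent calcium sensitivity
   $\mathrm{ECa}_{50} = (\mathrm{Ca}_0)_{max}/\sqrt{e^{B(l - l_0)} - 1}$
   and a sine-rise / exponential-decay activation $C(t)$).  Radial
   equilibrium of the shell yields the cavity pressure
   $P_{LV} = \int_{r_i}^{r_o} 2\,T_t(r)/r\, dr$ with
   $T_t = \lambda^2 S_{ff}$, and the **intramyocardial pressure** (IMP)
   at radius $r$ is the same integral truncated at $r$:
   $p(r) = \int_r^{r_o} 2\,T_t/s\, ds$.  By construction
   $p(\text{endo}) = P_{LV}$ and $p(\text{epi}) = 0$ exactly — the radial
   compressive stress plays the role of the incompressibility Lagrange
   multiplier of a full 3D formulation.

3. **Coronary microvascular networks.** Four identical 400-vessel trees
   (195 bifurcations, 3 trifurcations) sit at normalized depths
   $\hat R \in \{0, 1/3, 2/3, 1\}$.  Each vessel is a nonlinear
   three-element Windkessel: two equal Poiseuille half-resistances
   $R_1 = R_2 = 64 \mu L / (\pi D^4)$ and a capacitor at the mid node
   whose charge is the vessel blood volume.  The diameter follows the
   arctangent law
   $D = 2B_p + \tfrac{2(A_p - B_p)}{\pi}\left[\tfrac{\pi}{2} +
   \arctan\tfrac{P_{trans} - \phi_p}{C_p}\right]$ of the transvascular
   pressure (mid-node pressure minus the IMP of the network's depth), so
   both resistance and capacitance are state-dependent.  Inlet and outlet
   pressures are the proximal arterial and venous compartment pressures;
   mass conservation holds at every junction.

The coupling per 1-ms step is explicit and ordered: LV backend first
($V_{LV} \to P_{LV}$, IMP profile), then circulation pressures and diode
flows, then each network advances over the step with frozen boundaries;
the networks' interval-averaged inlet/outlet flows are withdrawn from the
proximal arterial compartment and returned to the veins in the same Euler
update, so total blood volume is conserved to machine precision.

# Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| `cycle_length` | ms | 800 | 75 bpm; makes the calibrated stroke volume (~67 ml) a normal cardiac output.  Not printed by the study this reproduces. |
| `T_max` | kPa | 130 | Baseline contractility; the sweep spans 65–205. |
| `t0`, `tau`, `T_trans` | ms | 275, 25, 275 | Time to peak tension (late systole), relaxation constant (sweepable 25–105), transition time. |
| `Ca0`, `Ca0_max`, `B`, `l0`, `l_ref` | µM, µM, 1/µm, µm, µm | 4.35, 4.35, 4.75, 1.58, 1.85 | Standard published active-law constants; `l = l_ref * lambda`. |
| `C_f`, `b_f` | kPa, – | calibrated, 9.5 | One-dimensional passive fiber law; `C_f` is the stiffness knob that places the end-diastolic point (110 ml at 8 mmHg). |
| `V_cav0`, `V_wall` | ml | calibrated (~72, ~68) | Unloaded geometry.  Calibrated under the constraint that endocardial sarcomeres stay within their physiological operating range (`l >= l0` down to end-systole); see below. |
| `R_*`, `C_*`, `V_*0` | mmHg·ms/ml, ml/mmHg, ml | calibrated | Circulation impedances and resting volumes; `R_ad` is the dominant (distal) resistance and the afterload lever, `V_ven0` the preload lever. |
| `root_D`, `terminal_D`, `k_LD` | µm, µm, – | 160, 12, 20 | Surrogate morphometry: root-to-terminal taper anchors and length-to-diameter ratio. |
| `Ap_scale`, `Bp_scale`, `phi_p`, `Cp` | –, –, mmHg, mmHg | 0.60, 0.35, 70, 30 | Passive vessel law scaled from each reference diameter, then pinned so `D(P_trans = 100 mmHg) = D_ref`. |
| `mu` | MPa·s | 2.7e-9 | Constant blood viscosity; no diameter dependence. |
| `dt`, `n_sub` | ms, – | 1, 5 | Global coupling step and network sub-steps. |
| `convergence_tol` | – | 1e-3 | Cycle-to-cycle relative change of {EDV, ESV, peak LV pressure, per-network flow}. |

The packaged defaults *are* the calibrated baseline: end-diastolic volume
110 ml at 8 mmHg, ejection fraction ≈61 %, arterial pressure ≈130/73
mmHg, peak LV pressure ≈131 mmHg.  `calibrate_baseline()` re-derives such
an operating point from scratch if parameters are perturbed.

# The synthetic coronary tree

The measured 400-vessel network behind the original study is not public,
so `build_tree()` grows a seeded surrogate: branching events split a
uniformly chosen terminal into two (or, for 3 of the 198 events, three)
children whose diameters shrink by the ratio implied by a total
cross-sectional area expansion of 1.2, with lognormal jitter; lengths are
`k_LD` times the diameter.  Two stated morphometric anchors — root
diameter 160 µm and typical terminal diameter 12 µm — cannot both be met
by the fixed area-expansion ratio at the depth a 400-vessel tree actually
reaches, so after growth the taper is exponent-corrected (root fixed) to
land the geometric-mean terminal diameter on `terminal_D`.  The tree is
then treated as a **fixed study input**, like the printed parameter
values: one canonical tree (default seed) is implanted at all four
transmural depths, exactly as the study reused one measured network.
Across generator seeds the transmural flow and work-density ratios move
by about a percent; the sharpest feature — briefly retrograde
endocardial inflow during early systole — sits close to its threshold in
this reduction and is only robustly reproduced on the corrected
morphometry.

What the surrogate does *not* emulate: measured per-order passive-law
parameters (a single $\phi_p$, $C_p$ pair scaled by diameter stands in),
transmural differences in bed morphology, collaterals between depths, and
any flow regulation — perfusion is passive throughout, comparable to
maximal pharmacological vasodilation.  Passing tests therefore validate
the solver and the qualitative transmural mechanics, not the absolute
flow magnitudes of any particular coronary bed.

# Numerics

* **Circulation:** explicit forward Euler at `dt = 1` ms, the same grid
  the coupling exchanges on.  Valves are hysteresis-free diodes evaluated
  on the grid; no sub-ms event detection.  A non-positive compartment
  volume raises a diverged-simulation error naming the compartment.
* **Networks:** the stiff per-vessel system is written in *volume-state*
  form — the vessel volume is the ODE state, the mid-node pressure follows
  algebraically from the pressure–diameter law plus IMP, junction
  pressures from Kirchhoff conservation — which makes volume bookkeeping
  exact regardless of step size and avoids the ambiguity of
  differentiating a state-dependent capacitance.  Two integrators share
  this formulation: a BDF route (deSolve, tolerances 1e-8/1e-10 on scaled
  volumes) used as the reference, and the production stepper, a
  linearized-implicit (semi-implicit backward-Euler) scheme whose linear
  tree system is solved exactly in $O(n)$ per sub-step by leaf-to-root
  elimination.  Five sub-steps per global step keep the two routes within
  a fraction of a percent of each other; both are unconditionally stable.
  Vessel diameters are intrinsically confined to $(2B_p, 2A_p)$.
* **LV shell:** per-shell midpoint quadrature of the equilibrium
  integral; at 24 shells the cavity pressure is within ~0.1 % of a
  512-shell reference and matches the constant-tension closed form
  $P = 2 T_t \ln(r_o/r_i)$.
* **Periodicity:** cycles repeat until the composite residual falls below
  `convergence_tol` (or `max_cycles`); the first cycle is always
  discarded.  All summary quantities come from the final cycle only.
* **Load holding:** the afterload sweep holds preload by a secant on
  `V_ven0` (|EDP − target| ≤ 0.2 mmHg); the geometry sweeps hold preload
  and afterload with alternating bounded log-secants on `R_ad` (peak
  pressure) and `R_ap` (EDP), every iterate a full converged run.  When a
  target combination is unreachable the closest achieved operating point
  is returned and the row is flagged infeasible rather than silently
  accepted.
* **Problem sizes:** all shipped analyses run the full 400-vessel
  networks on the 1-ms grid; the test suite uses a reduced 63-vessel tree
  for iteration-heavy checks and the full size for the end-to-end
  battery.

# Design choices made where the design was open

* **Tension-only passive fiber law.**  An odd (tension–compression
  symmetric) fiber law was considered and rejected: at end-systole the
  spherical reduction compresses endocardial fibers to stretches near
  0.76, and an odd law then produces large negative tangential stress,
  a non-monotone transmural IMP and an inverted endo/mid-endo flow
  ordering — contradicting the physiology the model exists to capture.
  Treating fibers as unable to bear compression (they buckle) is the
  standard convention of fiber-reinforced myocardial models and
  guarantees $T_t \ge 0$, hence a monotone IMP profile.  The price is an
  end-diastolic pressure–volume relation that is flat below the unloaded
  cavity volume.
* **Sarcomere-range calibration constraint.**  The baseline geometry is
  calibrated under the requirement that endocardial sarcomere lengths
  stay at or above the zero-tension length through end-systole.  Without
  it the endocardium goes slack mid-ejection, which suppresses
  endocardial work and flattens the transmural $W_f$ gradient.  The
  resulting unloaded wall is thinner (~0.64 cm) than a textbook LV; the
  thickness sweep (0.53–1.73 cm) brackets it.
* **Work-density sign.** $W_f$ is reported as the net work done by the
  fiber over the closed loop (positive when tension is high during
  shortening), in kPa per cycle (≡ kJ/m³); only fiber-direction work is
  counted.
* **Euler–Almansi strains.** Referenced to end-diastole
  (mitral-closure step).  The spherical reduction cannot distinguish
  circumferential from longitudinal directions, so `e_cc = e_ll`, and the
  tangential stretch overstates fiber-direction strain relative to a 3D
  fiber architecture: peak strain magnitudes run above measured values
  and are not validated outputs.
* **Exchange ordering** within a step is fixed (LV → circulation →
  networks); the couplings themselves define no intra-step order.
* **Cycle length** 800 ms, chosen once so the calibrated stroke volume
  yields a normal cardiac output.

# Known limitations

* IMP at the endocardial face equals $P_{LV}$ *identically*.  A 3D
  incompressible formulation lets the Lagrange multiplier exceed cavity
  pressure (measured endo IMP/LVP ratios reach 1.1–1.3, rising with
  contractility); this reduction cannot.  Consequently the mechanisms
  that depend on IMP amplification — endocardial flow suppression
  *growing* with contractility or wall thickness at held loads, and with
  it the increase of the endocardial mismatch ratio — are muted or
  absent: those sweep endpoints are reported with that caveat.
* The closed-loop end-systolic elastance is steep (the active law
  operates on the sensitive part of its force–length relation), so
  pressure responses to afterload and preload changes overshoot the
  study's printed endpoint pressures.
* At the largest unloaded cavity volume (205 ml) the tension-only wall
  cannot hold an 8-mmHg EDP below the unloaded volume: the ventricle
  fills past it and the level is flagged infeasible by the load-holding
  machinery.  (The study's own printed combination — EDV ≈ 114 ml at an
  unloaded volume of 205 ml under positive filling pressure — has no
  consistent realization in this reduction.)
* No pulmonary circulation or right heart, no valve inertance or
  regurgitation, no baroreflex, no flow regulation, no fiber-angle
  distribution, no poroelastic wall, no collaterals.

# A minimal run

```{r example, eval = FALSE}
params <- default_params()
res <- run_closed_loop(params, simulation_config())
cycle_summary(res)
transmural_profile(res, "W_f")

## one sweep with its holding constraint
sw <- run_sweep(sweep_spec("afterload", c(33, 318),
                           constraints = list(EDP = 8)),
                params)

## the whole study battery
study <- run_study(params)
study_headlines(study)
```
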