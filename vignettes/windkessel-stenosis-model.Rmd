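---
title: "A lumped-parameter model of branch stenosis in the internal carotid tree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lumped-parameter model of branch stenosis in the internal carotid tree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icaflow)
```

## The model

`icaflow` simulates pulsatile blood flow through a truncated model of the
internal carotid artery (ICA) and its intracranial branches: the
ophthalmic artery (OA), the anterior cerebral artery (ACA), and the
middle cerebral artery (MCA) with its proximal segments M1 and M2
treated as separate outlets,

```
ICA ─┬─ OA   (outlet)
     ├─ ACA  (outlet)
     └─ MCA ─┬─ M1 (outlet)
             └─ M2 (outlet)
```

Each vessel is a rigid Hagen–Poiseuille conduit with resistance
$R = 8\mu L/(\pi r^4)$ and pressure drop $\Delta P = RQ$. The vasculature
beyond each truncated outlet is lumped into a two-element Windkessel: a
distal resistance $R_d$ to a reference pressure $P_d$ (0 Pa gauge by
default) with a compliance $C$ in parallel at the outlet node, giving
the pressure state

$$C\,\frac{dP_c}{dt} = Q_{\mathrm{outlet}} - \frac{P_c - P_d}{R_d}.$$

Blood is shear-thinning; the apparent viscosity follows the Carreau law

$$\mu(\gamma) = \mu_\infty + (\mu_0-\mu_\infty)\,
  \bigl[1+(\lambda\gamma)^2\bigr]^{(n-1)/2}$$

with $\mu_0 = 0.056$, $\mu_\infty = 0.0035$ kg m⁻¹ s⁻¹,
$\lambda = 3.313$ s, $n = 0.3568$ and density 1060 kg m⁻³. A
zero-dimensional model does not resolve the shear field, so each
segment's representative shear rate is the Poiseuille wall shear rate
$\gamma = 4|Q|/(\pi r^3)$ — exact for a parabolic profile and the
standard lumped-model closure. Because $\gamma$ depends only on the
flow, the coupled viscosity–resistance fixed point closes in a single
evaluation (`effective_segment_resistance()` asserts this).

A stenosis is a fractional diameter reduction $s$ of the (circular)
distal lumen, so at fixed length and viscosity the distal resistance
scales as

$$R(s) = \frac{R_0}{(1-s)^4},$$

independent of the rheology (the viscosity cancels in $R(s)/R_0$).
`build_resistance_table()` regenerates the branch-by-severity resistance
table from the three healthy resistances; residuals against the
published table are below 0.4%, the headroom of its 3-significant-figure
printing, which is why table comparisons use a 1% tolerance.

## Default geometry and boundary conditions

Healthy distal resistances are $1.04\times10^8$ (M1),
$2.43\times10^8$ (M2), $3.34\times10^8$ (ACA) and
$1.33\times10^{12}$ (OA) kg m⁻⁴ s⁻¹. The subject's geometry is not
public, so the default tree is synthetic but anchored to measured
quantities: the MCA radius 1.568 mm inverts the healthy MCA flow
(3.206 ml s⁻¹) at its plane-averaged velocity (0.415 m s⁻¹), and the
ACA radius 1.166 mm likewise inverts 0.964 ml s⁻¹ at 0.226 m s⁻¹. The
ICA trunk is 2.0 mm × 30 mm and the M1/M2/OA stubs are 5 mm long with
radii 1.4/1.1/0.6 mm; segment resistances ($\sim10^7$) are an order
below the outlet resistances, so the stub dimensions are second-order.
All of this is configurable (`generate_default_geometry()`, YAML
configs via `load_config()`).

Only resistances are published for the outlets; compliances are not.
Each outlet therefore receives $C = \tau/R_d$ with a shared time
constant $\tau = 1$ s, which yields a physiological diastolic decay
without inventing per-branch values. An optional $\tau = 0$ degrades
every outlet to a pure resistance.

The inlet is a prescribed periodic **flow**. The synthetic waveform
(`generate_inlet_waveform()`) is a Gaussian systolic pulse over an
exponential diastolic decay with cardiac period 0.876 s, renormalised
so the cycle mean is exactly $4.17\times10^{-6}$ m³ s⁻¹ — the sum of
the healthy ACA and MCA flows — with a single systolic maximum at 1.8×
the mean and strictly positive flow. `peak_to_mean = 1` degenerates to
constant flow. The measured waveform is available only graphically, so
only its period and derived mean are used; the shape parameters exist
to let calibration tests probe waveform sensitivity. What the generator
does **not** emulate: beat-to-beat variability, measured waveform
harmonics, velocity-encoding artifacts of phase-contrast MRI, or image
noise — passing tests demonstrate correctness of the pipeline on this
idealised forcing, not fidelity to any subject's waveform.

## Numerical scheme

The tree is solved by Thevenin reduction — every subtree collapses leaf
to root into an equivalent (resistance, source pressure) pair, then a
forward pass distributes pressures and flows. This is exact for trees
and $O(n)$ per solve. Its correctness is cross-checked in the tests
against an independent dense nodal-analysis oracle (conductance-matrix
stamping and a linear solve) on 100+ random trees to $10^{-9}$
relative.

Pulsatile integration is implicit (backward) Euler: each compliance is
replaced by its companion Thevenin branch (resistance $dt/C$, source
$P_c^{(n)}$), so every step is one linear tree solve and the scheme is
unconditionally stable across the four-decade spread of outlet
resistances ($10^8$–$10^{12}$). The default step is $dt = 1$ ms
(≈876 steps per cycle; the effective step divides the period exactly),
and runs span 5 cardiac cycles with only the final cycle analysed.
Flow conservation — inflow equals distal outflow plus compliance
storage rate — holds to machine precision by construction of the
companion model and is monitored at every step (reported residuals
$\sim10^{-13}$, asserted $\le 10^{-8}$).

A cold start from the steady solution leaves a slow transient: the
coupled outlet RC modes relax with time constants near $\tau = 1$ s,
comparable to the 4.38 s of a 5-cycle run, leaving a cycle-to-cycle
periodicity residual of $1.6\times10^{-3}$. The stepper therefore
settles the Windkessel states first with a short coarse-step run
(6 cycles at 128 steps per cycle) before the reported cycles; the
periodicity residual then falls to $\sim3\times10^{-5}$, and the
postcondition $\max_t|P(t)-P(t-T)|/\max|P| \le 10^{-3}$ holds at the
5-cycle convention. Agreement between $dt$ and $dt/2$ runs is
$\sim1.2\times10^{-4}$ on final-cycle pressures.

Within each step the Carreau segment resistances are refreshed from the
current flows (a lagged solve plus one refresh); the residual viscosity
lag is second order in the per-step flow change and shows up only below
$10^{-6}$ relative in quasi-static comparisons.

## Calibration and identifiability

`calibrate_outlet_resistances()` mirrors the validation procedure that
produced the healthy resistances: iterate a forward solution and update
every tunable outlet multiplicatively,
$R \leftarrow R\,(v_{\mathrm{computed}}/v_{\mathrm{target}})^{d}$,
using the cycle-mean plane-averaged velocity at the target site
upstream of it. The update exploits the monotone resistance–velocity
relationship (raising an outlet's resistance lowers the velocity at
every site feeding it, asserted as a property test); the damping
exponent $d \le 1$ (default 1) guards oscillation. Convergence is
declared when all relative site residuals fall within a tolerance
(default 1%, the scale of the reported validation errors, 1.7–7%).
Sites feeding several tunable outlets (the MCA plane feeds both M1 and
M2) apply a common factor, preserving the downstream resistance ratio —
the same role the prior-study initial values play in the original
procedure. OA is excluded from tuning by default; its $10^{12}$
resistance makes its flow negligible.

An important structural property, established empirically during
development and asserted in the test suite: with a **flow-prescribed
inlet, velocity targets determine the outlet resistances only up to a
common-scale mode.** The targets fix the flow split; conservation then
fixes the untuned OA flow; the absolute pressure level — and hence the
resistance scale — is pinned only through the near-closed OA branch,
a $\sim5\times10^{-5}$ relative sensitivity. Starting all three
tunable outlets at twice their true values converges to velocity
congruence with the resistances still near 2× truth. Claims that such
a resistance set is unique are therefore correct only formally; in
practice the scale must come from elsewhere. The package's
parameter-recovery experiments consequently use the identifiable
design: tune ACA and M1 from a 2× start with M2 anchored at its known
value. That design recovers the resistances to 0.4% in ~20 iterations
(noiseless) and to within 5% under 1% multiplicative target noise.

Synthetic calibration targets (`generate_velocity_targets()`) apply
seeded multiplicative lognormal noise to the model's own cycle-mean
velocities, emulating plane-averaged measurement scatter; the default
5% stress level brackets the reported validation errors. Generators
are pure functions of their parameters (seed included) and restore the
global RNG state.

## The three analyses

**Branch sensitivity.** Each sweep (`stenosis_sweep()`) replaces one
outlet's distal resistance with $R(s)$, severity 0–60% in 2% steps,
keeping the healthy compliance (the stenosis adds series resistance; the
distal bed volume is unchanged). `sensitivity_report()` compares, at a
chosen site, the **magnitude** of the change in final-cycle cycle-mean
pressure between baseline and top severity, and expresses each branch
against a reference branch as $100\,(1-\Delta P_b/\Delta P_{\rm ref})$.
Magnitude, not signed change, is the deliberate choice: with a
prescribed inlet flow every distal resistance increase *raises* the
upstream pressures (a passive network driven by a flow source cannot
lower them), whereas a pressure-like inlet would lower them — the sign
is a property of the inlet constraint, while the branch-influence
comparison concerns the size of the disturbance. A systolic-peak
variant is available via `statistic = "systolic"`. On the calibrated
default network the influence ordering is M1 > ACA > M2 at all three
sites — and calibration matters: with the printed resistances applied
to the synthetic geometry uncalibrated, the small ACA–M2 gap inverts.

**Reverse flow.** `reverse_flow_threshold()` computes, per severity,
the cycle-minimum gradient $G(s) = \min_t [P_{\rm up}(t) -
P_{\rm down}(t)]$ between two sites and locates the smallest severity
with $G < 0$ by linear interpolation between grid points ("none within
sweep" otherwise). On the default model no onset occurs anywhere on the
0–60% sweeps: the prescribed inlet flow keeps the resistive part of the
ICA–MCA gradient at a positive floor (~40–60 Pa) that the compliance
ripple (~30 Pa) cannot overcome. Thresholds reported from
three-dimensional simulations depend on the full pressure field and an
absolute reference this surrogate does not possess; the operation is
therefore exercised end to end, its interpolation verified on synthetic
gradient curves, and its model conclusion checked for grid independence.

**Fractional flow reserve.** FFR is the post- over pre-stenotic
pressure ratio. $P_{\rm pre}$ is the cycle-mean pressure at the node
feeding the stenosed outlet (plus a configurable absolute-pressure
offset, default 0 = gauge); $P_{\rm post}$ subtracts the drop across
the **added** stenotic resistance, $(R(s)-R_0)\,\bar Q$. Using the
incremental rather than total resistance makes $FFR(0) = 1$ exactly, as
the definition requires. With a gauge reference the model's FFR is
steeper than catheter-style values (approximately $(1-s)^4$, since the
outlet pressure itself is $\approx R(s)\bar Q$ above the distal
reference); absolute FFR magnitudes require the unavailable 3D pressure
field and are treated as out of reach, while the defining properties —
$FFR \in (0,1]$, equality to 1 at zero severity, strict decrease with
severity — are asserted per branch.

## Problem sizes and costs

The default study is three 31-point sweeps at $dt = 1$ ms over 5 cycles
plus warm start — 93 pulsatile simulations, about 15–25 s total on one
core — with calibration (quasi-steady forward model, a few iterations),
the 100-tree oracle comparison, and a $dt/2$ refinement run alongside.
These sizes keep the full workflow and test suite in the tens of
seconds while leaving the numerical margins (conservation $10^{-13}$,
periodicity $3\times10^{-5}$, refinement $10^{-4}$) far from their
asserted bounds.

## Limitations

* Zero-dimensional: no wave propagation, no spatial pressure field, no
  wall shear stress, no post-stenotic recirculation.
* Rigid conduits; no fluid–structure interaction.
* No collateral circulation (no Circle of Willis compensation) — the
  tree ends at four Windkessel outlets.
* The stenosis acts through the outlet resistance only; in-lumen
  geometric stenosis is out of scope.
* Absolute pressures are gauge values relative to the Windkessel distal
  reference; quantities that need an absolute reference (clinical FFR
  magnitudes, reverse-flow thresholds against a 3D field) are reported
  as model-relative properties only.
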