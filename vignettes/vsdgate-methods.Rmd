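---
title: "vsdgate: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{vsdgate: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vsdgate)
```

# Scope

`vsdgate` studies how the S4 "sliding helix" of a sodium-channel
voltage-sensing domain (VSD) deactivates, and how a charge-reversing
substitution of its uppermost arginine (R1) changes whole-cell gating. It has
two arms that share nothing but the biology:

* a **structural arm** — a coarse-grained toy VSD, a steered S4 downshift
  trajectory with Monte-Carlo (MC) energy minimization under the published
  restraint scheme, and salt-bridge / rotation analytics; and
* an **electrophysiology arm** — a synthetic whole-cell Nav current generator
  with a known gating truth, plus the complete patch-clamp analysis chain
  (peaks, current density, chord conductance, Boltzmann and bi-exponential
  fits, group statistics).

The synthetic generator exists so that every analysis stage can be validated
end-to-end without recordings: simulate from a known truth, analyze, and
check that the truth is recovered.

# The structural arm

## Toy voltage sensor

`build_toy_vsd()` places four ideal alpha-helices (rise 1.5 A/residue,
100 degrees/residue, CA radius 2.3 A) on a ~12 A square, axes parallel to
the membrane normal z, extracellular side +z. S4 descends from the
extracellular side and carries the voltage-sensing basic residues R1, R2,
R3, K4 at the canonical i, i+3, i+6, i+9 spacing. Each ionizable residue
carries one side-chain interaction site (Arg 4.1, Lys 3.9, Glu 3.1,
Asp 2.5 A from the CA along the outward radial), named by the residue's
representative atom (CZ/NZ/CD/CG) so that toy and full-atom structures are
analyzed by one code path.

The countercharge ladder mirrors a real VSD: S2 carries the uppermost
glutamate E1 and a deeper E2, S3 an aspartate D1. E1 is placed two helical
turns (10.5 A) below R1's starting CA level: after the full default
downshift, R1 arrives at E1's level while E2 and D1 take over R2 and R3.
With a single glutamate (a configuration the test suite also builds), the
minimizer instead parks E1 between R2 and R3 permanently — a useful negative
control showing why real voltage sensors need a ladder of acceptors for
sequential state-dependent bridging.

The builder is a *stated world*, not a reconstruction: no coordinates of any
deposited structure enter the package. Distances along the toy trajectory
are qualitative surrogates; published inter-carboxylate distances depend on
cryoEM coordinates and a proprietary force-field implementation and are out
of numeric scope.

## Surrogate energy

The energy is a declared surrogate that preserves the *sign structure* of
the interactions the conclusions rest on:

* Coulomb between charged sites, `332.06 q_i q_j / (eps(r) r)` kcal/mol with
  the distance-proportional dielectric `eps(r) = r` (configurable constant
  dielectric as an alternative; arbitrary closures are accepted by
  `total_energy()` but not inside the C++ MC hot loop);
* 12-6 Lennard-Jones (sigma 4.0 A, epsilon 0.1 kcal/mol) on nonbonded
  site/CA pairs (different helices, or >= 3 residues apart);
* harmonic virtual bonds on the CA trace (i,i+1 at 3.8 A; i,i+4 at 6.2 A;
  k = 10 kcal mol^-1 A^-2) and a harmonic tether holding each interaction
  site near its ideal CA offset. The tether constrains the *length* only, so
  sites swing freely about their CA — a one-parameter stand-in for
  side-chain dihedral freedom that lets salt-bridge partners swap.

The exact dielectric of the original workflow is unpublished; `eps(r) = r`
is the classic screened-electrostatics surrogate and is exposed in
`energy_model()`.

## Steered deactivation and MC minimization

`deactivate_s4()` translates S4 down in 0.5 A steps (default 21 steps = two
helical turns, 10.5 A). At each step the four basic-residue CA atoms are
constrained to their downshifted plane — free in x/y, fixed z (the
constraint is enforced *by construction*: constrained z is never a degree of
freedom, so the residual is exactly zero). S1-S3 CA atoms carry flat-bottom
restraints to their step-0 positions: free up to 4 A, then
`10 (d - 4)^2` kcal/mol.

`mc_minimize()` concretizes "MC energy minimization" as: random move (rigid
S4 in-plane shift/rotation, rigid S1-S3 shifts, per-site jitter with an
occasional 5x "shake" that lets sites cross steric barriers), local
step-halving coordinate descent over the moved degrees of freedom, and
Metropolis acceptance at 300 K. A run terminates when 100 consecutive
candidate minimizations fail to improve the best energy (improvements below
1e-9 kcal/mol count as non-improving), or at a hard move cap. Everything is
driven by one seeded RNG stream, so a trajectory is byte-reproducible
through the multi-model PDB writer.

Step 0 of a trajectory is the minimized starting state; the canonical "21
structures" are the downshifted, minimized states at offsets -0.5 .. -10.5 A
(`n_downshifted()`). Whether the undisplaced state is part of the published
count cannot be decided from the text; the convention here reproduces the
printed count under 0.5 A steps and is recorded, not asserted as intent.

What a green structural test establishes: constraint bookkeeping, the
restraint formula, seeded determinism, and the electrostatic signatures —
the wild-type trajectory ends with the R1-E1 site distance under the 4.5 A
bridge criterion, and the charge-reversed variant (R1 -> Glu) shows positive
(repulsive) R1E-E1 Coulomb energy at every step. It does *not* establish
force-field realism, absolute distances, or the direction of S4 rotation
(the toy's emergent rotation is not constrained to the anticlockwise sense
seen in real structures; `s4_rotation_series()` measures it with an explicit
sign convention instead).

# The electrophysiology arm

## Generative model

Currents follow a two-gate scheme with closed-form kinetics at fixed
voltage:

$$I(t) = g_{max}\,(V - V_{rev})\, m(t)\, h(t) + \varepsilon,\qquad
\varepsilon \sim N(0, \sigma^2)$$

with exponential relaxation of each gate toward its steady state:
activation $m_\infty(V) = 1/(1+e^{(V_{1/2}-V)/k})$ and availability
$h_\infty(V) = 1/(1+e^{(V-V_{1/2})/k})$, both with $k > 0$ (the printed
table of the source study mixes slope signs; the decreasing availability
form with positive k removes the ambiguity without changing magnitudes).

Deliberate design choices:

* **Activation gate exponent 1** (not Hodgkin-Huxley m^3): the analysis fits
  a single Boltzmann to the G-V curve, and an exponent-3 generator would
  make the generating and fitted half-points differ by construction.
* **tau_m(V) = 0.15 + 2 exp(-((V+45)/15)^2) ms** (bell-shaped, peak
  2.15 ms near threshold).
* **tau_h(V) = 10 tau_m(V) + 40 exp(-((V+95)/12)^2) ms.** The proportional
  part makes the peak of $m(t)h(t)$ attenuate by a *voltage-independent*
  factor at IV test potentials, so the extracted peak-conductance curve
  equals the generating Boltzmann (the factor cancels in normalization);
  any non-proportional tau_h in the activation range biases the fitted
  half-point — the bell-shaped default inherited from common simulators
  produced a ~9 mV artifact. The slow hyperpolarized lobe (centered at
  -95 mV, below both presets' activation ranges) restores slow inactivation
  kinetics so that a 20 ms prepulse availability curve lies depolarized of
  the 500 ms curve, as in the experiments.
* **Bi-exponential recovery from an explicit two-population mixture**
  (`1 - A_f e^{-t/\tau_f} - (1-A_f) e^{-t/\tau_s}`): a single h gate cannot
  produce two time constants. The fast amplitude A_f = 0.8 is a one-time
  realism choice (the source study reports only the taus).
* **Noise**: additive Gaussian per 20 kHz sample, default 2% of the
  protocol's maximal noiseless peak current.
* **Presets** `nav_preset("WT")` / `nav_preset("R219E")` carry the published
  activation, availability, fast-inactivation and recovery values; g_max
  (95 / 70 nS) reproduces the published peak current densities at the
  published capacitances (8.6 / 9.2 pF) given V_rev = +40 mV. V_rev is
  placed inside the -80..+60 mV IV span so the reversal-potential
  interpolation has a bracketing sign change (the Nernst value for the
  stated solutions, ~+68 mV, would fall outside the protocol).

Protocols (`protocol_spec()`): IV -80..+60 mV in 5 mV / 40 ms steps from a
-100 mV holding; steady-state inactivation (SSI) 500 ms prepulse
-120..+10 mV with a -15 mV / 20 ms test pulse; fast inactivation the same
with a 20 ms prepulse; two-pulse recovery with 500 ms / -15 mV conditioning
and 12 log-spaced intervals 1..3000 ms (the source does not state its
interval ladder; these are declared package defaults). Sampling 20 kHz.

`fast_inactivation_params()` deserves a note. The published fast-inactivation
half-point *is the 20 ms prepulse curve*, so the generator is parameterized
with that Boltzmann as h_inf and a voltage-flat tau_h = 2.5 ms: 20 ms is
then 8 time constants (equilibrated at every prepulse voltage) while the
test-pulse current still rises an order of magnitude faster than it decays.
A tau_h proportional to tau_m cannot do both (tau_m peaks at 2.15 ms near
-45 mV), and inverting the 20 ms relaxation onto the target Boltzmann under
the default tau_h has no solution with h_inf in [0,1].

## Estimators

The analysis chain is deliberately engineered to be *unbiased*, because its
validation criterion is calibration (replicate mean within 2 SEM of truth),
not mean-squared error:

* **Peak current** (`robust_peak()`): the raw signed extremum of a noisy
  sweep overestimates the peak by roughly $\sigma\sqrt{2\ln n}$ on
  signal-free sweeps and by a sharpness-dependent amount elsewhere, which
  lifts the tails of normalized curves and biased the fitted activation
  half-point by +0.15 to +0.9 mV in our measurements (smoothing first
  over-corrects to about -0.4 mV via voltage-dependent peak flattening).
  The split-sample estimator locates the peak on the even-indexed samples
  and reads the value from a local quadratic over the odd-indexed samples
  at the selected index; selection and read-out noise are independent, so
  the estimate is first-order unbiased for any signal shape. Residual bias
  measured over three disjoint 30-seed replicate sets is below 0.05 mV for
  every fitted half-point.
* **Chord conductance** `G = I/(V - V_rev)` with points within 5 mV of
  V_rev excluded, and the activation Boltzmann fitted by generalized least
  squares with weights $(V - V_{rev})^2$ — the transform divides by the
  driving force, so conductance noise scales as its inverse.
* **Free amplitudes**: Boltzmann fits carry a free amplitude and the
  recovery fit a free plateau. Normalizing by a noisy maximum (or a noisy
  conditioning peak) otherwise couples one point's noise into every other
  point; the free plateau alone removed a 15-40 ms upward skew in the
  fitted slow recovery time constant. Availability points are normalized by
  *signed* ratio — rectifying near-zero peaks would lift the depolarized
  tail by the mean of a folded Gaussian.
* **Initialization** is deterministic everywhere: half-amplitude voltage
  for V1/2, multi-start k in {2, 5, 10} mV (ties to the smallest k);
  recovery fits multi-start over tau_f in {10, 30, 100} ms and A_f in
  {0.5, 0.8}, Nelder-Mead then BFGS polish, with tau_f < tau_s enforced by
  parameterization.
* **decay50** replaces exponential decay fitting (the source's own choice):
  time from the peak to the first return to 50% of peak, flagged undefined
  if never reached; undefined values are excluded, not imputed.
* **Group statistics**: pooled-variance two-sample t for raw data;
  Welch-style statistic from mean/SEM/n summaries; two-sided p, no
  multiplicity correction (none is applied in the source).

## What a green ephys test does and does not establish

The closed loop (simulate with noise -> analyze -> compare to truth, 30
replicates, seeds 1-30) establishes that the analysis chain is calibrated —
unbiased at the 0.1 mV / few-ms level — under the generator's assumptions:
additive white Gaussian noise, no leak or capacitive transients, no series
resistance, no rundown, a single Boltzmann truth. It does not establish
robustness to those real-data artifacts (leak subtraction and transient
removal are explicit non-goals), and the noiseless generator/analysis
identity is limited by real physics: the charge-reversed preset keeps a ~4%
non-inactivating fraction at -75 mV, which bounds the identity there at
about 1.3e-3 instead of 1e-3.

The qualitative signature of the charge reversal — hyperpolarized activation
and availability, slowed recovery — emerges from the presets by
construction of their published values; the package's contribution is that
the *fitted* values preserve the ordering through the full noisy pipeline.

# Numerical conventions

* Membrane normal is z, extracellular +z; "downshift" is translation toward
  -z; anticlockwise rotation viewed from +z is positive.
* Salt-bridge criterion: charged-site distance <= 4.5 A (configurable); the
  carboxylate-carbon / guanidinium-carbon convention follows the source's
  distance reporting.
* Helix axis for rotation analytics: first principal component of the S4 CA
  cloud, oriented toward +z.
* MC improvements below 1e-9 kcal/mol are treated as non-improving
  (tie-break for the 100-candidate termination window).
* PDB I/O is fixed-column; altloc/insertion codes are ignored with a
  warning; multi-model files are the trajectory interchange format. Files
  are written in binary mode so seeded runs are byte-identical across
  platforms.

# Known limitations

* The structural arm is a sign-structure surrogate: no solvent, membrane,
  or all-atom force field; no activation (upshift) modelling beyond
  sign-flipped reuse of the driver.
* The rotation direction of the toy S4 is emergent, not calibrated.
* The ephys generator omits late/persistent current, temperature effects,
  series-resistance artifacts and vendor formats (CSV import only).
* Published shift magnitudes quoted in running text of the source (9.6,
  5.6, 15.1 mV) disagree with the differences of its tabulated half-points
  (7.7, 5.4, 11.1 mV); the package reports differences computed from its
  own fits and takes the tabulated values as generating truths.
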