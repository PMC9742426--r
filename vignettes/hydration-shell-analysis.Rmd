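---
title: "Hydration-shell analysis: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydration-shell analysis: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`hydrashell` quantifies the structure and dynamics of water around a
protein in an MD trajectory: where water is ordered (a bulk-normalized
3D density grid and discrete hydration sites), how the layering looks as
a function of distance from the protein surface (a cylinder-scanned
G(r)), how long individual waters stay bound (occupancy autocorrelation
and single-exponential residence times), how long protein-water hydrogen
bonds live, and the protein-side metrics (RMSF, S², Rg, Cα-RMSD, SASA)
used to argue that two systems are in corresponding dynamical states. A
separate evaluator implements the flat-bottom chemical-shift restraint
energy used to bias such simulations toward experimental NMR shifts. The
package runs no MD and predicts no chemical shifts.

# The models and their conventions

## Surface distance

Every shell-resolved quantity needs a notion of "distance from the
protein surface". The package operationalizes the surface as the set of
protein heavy-atom centers: the surface distance of a point is its
distance to the nearest heavy-atom center (`surface_distance()`,
`metric = "center"`). This is monotone, parameter-free, and exact; the
price is that absolute peak positions include an atom-radius offset. A
`metric = "vdw"` switch subtracts Bondi radii for users who prefer a
van-der-Waals surface. All shipped thresholds (8–10 Å bulk shell,
fallback shell boundaries) are interpreted in the center convention.

## Density grid and bulk normalization

Water oxygens are re-imaged (minimum image, orthorhombic boxes only)
around the protein center after Cα superposition, then binned on a
0.5 Å grid fixed in the reference frame. Raw node densities
(counts / frames / step³) are divided by the bulk density, the mean raw
density over nodes whose surface distance (to the reference frame) lies
in 8.0–10.0 Å. Normalized density is therefore 1.0 in bulk by
construction, and a value of 2.0 means twice bulk order.

## Hydration sites (MDHS)

A hydration site is a grid node that (a) is a strict local maximum over
all nodes within 1.4 Å (0.14 nm) and (b) has normalized density ≥ 2.0.
Exact ties are broken toward the lower node index, and candidates are
accepted greedily in descending density with mutual exclusion at the
same 1.4 Å radius — this makes the under-determined case of closely
spaced equal maxima deterministic. No sub-grid interpolation is done;
detected positions are node centers, so recovery accuracy is half a
grid diagonal (≈ 0.43 Å) by construction. The same 2.0× threshold is
applied in all shells.

## Surface G(r)

An infinite, double-sided cylinder of diameter 4 Å passes through the
protein center of mass; its axis is scanned over Euler angles α ∈
{0°, 20°, …, 340°} and β ∈ {0°, 20°, …, 160°} (the third Euler angle is
degenerate for a cylinder, and β beyond 180° repeats axes). Waters
inside a cylinder contribute their surface distance to a histogram once
per containing orientation; the curve is normalized so its 8–10 Å mean
is 1, matching the grid convention so grid and G(r) read on the same
scale. Peaks and the two shell-boundary minima are located on a
3-bin moving average (bin width 0.1 Å) to suppress Poisson noise.

Two geometric facts matter when interpreting G(r):

* **Finite cylinder width bias.** For a uniform gas, the cylinder
  geometry itself produces G(r) ≈ 1 + (d/2)²/(4r²) where r is distance
  from the *center*: at protein scale (first shell at sphere radius
  ≈ 8 Å) this is ~1%, but for a degenerate point-like scaffold it
  reaches +10% at 3 Å. Flatness checks therefore use a protein-sized
  test scaffold.
* **Box truncation.** Beyond roughly half the box minus the scaffold
  radius, spherical shells leave the periodic box and the raw histogram
  decays; the meaningful window ends at the bulk shell (10 Å).

## Shell classification

Distances at or below the first G(r) minimum are *first* shell, at or
below the second minimum *second*, else *outer* (closed boundaries).
When the minima cannot be located (noisy or featureless curves) the
classifier falls back to fixed boundaries of 2.25 Å and 3.5 Å —
bracketing the ~1.9 Å and ~2.6 Å shell peaks — and warns; the warning is
collected into the pipeline report.

## Occupancy autocorrelation and residence times

Per site, the occupant at each frame is the nearest water oxygen within
the capture radius (default 1.4 Å, the only length scale attached to a
site; ties go to the lower atom index). The survival function P(τ) is
the fraction of occupied time origins whose occupant is unchanged after
lag τ. The underlying autocorrelation definition is ambiguous between
two readings, and both are implemented:

* **continuous** (default): the same water must hold the site for every
  intermediate frame — memoryless exit gives a clean single-exponential
  decay, matching the "residence" semantics of the fitted model;
* **intermittent**: only the endpoints are compared, so a water that
  leaves and returns still counts. Continuous ≤ intermittent pointwise,
  with equality only when re-entry never happens.

P(0) = 1 because the estimator averages over origins (the raw sum in
the defining formula is normalized so the exponential fit is
dimensionless). The residence time is the single parameter of a
least-squares fit of exp(−τ/τ_res) with amplitude fixed at 1, using
lags with P ≥ 0.01 and at least 10 origins; a Brent bracket from a
log-linear seed is polished by a derivative root so noiseless curves are
recovered to ~1e-9 relative. Sites with τ > 1 ns are flagged
*superstructured* and excluded from shell averages (the exclusion count
is reported). Curves that have not decayed below 0.9 at the last usable
lag are flagged unreliable and the value reported as a lower bound.

On discrete frames the continuous-mode survival of a memoryless site is
geometric, (1 − dt/τ_dwell)^(τ/dt), so fitted values carry a small
O(dt/τ) discretization bias (≈ −5% at τ = 20 ps with dt = 2 ps) — well
inside the 15% recovery tolerance used in the tests.

## Hydrogen-bond lifetimes

An H-bond exists in a frame when the protein N/O to water-oxygen
distance is ≤ 3.5 Å and, when hydrogens are present on the donor, the
D–H···A angle is ≥ 150° (the community-default criteria, configurable).
Without hydrogens
the distance criterion alone is applied and the output is flagged
`geometric_only`. A continuous bonded run of L ≥ 2 frames is one event
of duration (L−1)·dt; single-frame contacts are discarded as unresolved
at the sampling interval. For a memoryless partner this conditional
mean is exactly the dwell time, so no debiasing is needed.

## Protein metrics

RMSF is computed per atom about time-average positions on the superposed
trajectory and averaged per residue. S² uses the time-averaged
second-rank tensor formula on N–H unit vectors, S² = 3/2 Σ⟨μ_aμ_b⟩² −
1/2, clamped to [0,1] with clamping logged; the tensor formula is the
standard full-trajectory limit of the autocorrelation plateau, and a
sliding-window mode exists for comparison with ns-timescale NMR S². SASA
is Shrake–Rupley with Bondi radii, probe 1.4 Å and 960 golden-spiral
points per atom; note a fixed quadrature set makes SASA
rotation-invariant only to quadrature error (~0.5%). Rg and Cα-RMSD
(Kabsch fit, then RMSD) are standard.

## Chemical-shift restraints

The restraint energy is K·ΣᵢΣⱼ Δᵢⱼ² over residues i and the six backbone
shifts j ∈ {Cα, Cβ, C′, N, HN, Hα}, with Δ = max(0, |δ_exp − δ_calc| −
ε). Demanding only that the force vanish inside the experimental
uncertainty leaves the outside branch under-determined; the deviation-
shrinkage form used here is the branch that also keeps the force
continuous (C¹) at the boundary, which an MD integrator needs. The gradient in δ_calc is −2KΔ·sign(δ_exp −
δ_calc). The weight schedule is a linear ramp from 0 to K_max =
300 kJ·mol⁻¹·ppm⁻² over 10 ns, constant thereafter; linear is the
simplest monotone shape, and alternatives can be configured. Per-atom-type ε defaults to 0 (pure
harmonic) and should be set from the measurement errors when known.

# The synthetic-data generator

The generator (`synthetic_spec()` / `generate_system()`) builds the
*stated world* every analysis is tested against:

* a rigid (optionally jittered) protein-like scaffold — dummy heavy
  atoms on a 6 Å sphere by default (128 atoms, so the nearest-atom
  surface metric is smooth to ≲ 0.1 Å), or a 20-bead, 3.8 Å-spaced
  chain for non-spherical surfaces;
* bulk waters uniform outside an exclusion zone, resampled i.i.d. per
  frame by default (exactly uniform, exactly Poisson counts) or
  diffusing with Gaussian steps;
* planted sites: two-state Markov occupancy per frame with exit
  probability dt/dwell and entry rate giving the requested stationary
  occupancy — the discrete-time analogue of exponential dwell, making
  the true residence time analytic ((1−dt/τ)^k survival). Occupant
  identity persists within a run and is re-drawn (from a per-site pool)
  on re-entry, so the continuous and intermittent survival definitions
  provably differ;
* optional shell-enrichment waters placed at exact planted surface
  distances along outward scaffold normals, used to recover G(r) peak
  positions and shell boundaries.

What the generator does **not** emulate: water-water structure,
orientational/H-bond networks, drift or conformational change of the
protein, and realistic water self-diffusion. A green recovery test
therefore establishes that the estimators are correct for their defining
models, not that the physics of any particular force field is
reproduced.

**Calibration-gas densities.** Counting statistics, not physics, set the
water density in the test worlds. A grid node of (0.5 Å)³ at real-water
density accumulates ~0.03 counts per frame, so site detection at a 2×
bulk threshold needs ~46 expected counts per node before Poisson noise
cannot fake a site anywhere in a ~3·10⁵-node grid
(P(Poisson(λ) ≥ 2λ) ≲ 10⁻⁹ at λ ≈ 46). The test systems reach that
with density × frames ≈ 370 Å⁻³ (e.g. ~0.37 Å⁻³ for 1000 frames) —
a deliberately dense uniform gas standing in for the ~10⁵ frames of a
production trajectory, chosen once from this calculation and not tuned
against outcomes. Normalization divides the absolute density out.

**Statistical tolerances in tests.** Time origins within one occupancy
run are maximally correlated, so "binomial" error bars for survival
curves use the number of independent occupancy runs, not the number of
origins, as n. Recovery tolerances (15% on residence times, 0.5 Å on
site positions) follow from run-count and grid-resolution arithmetic at
the stated world sizes.

# Numerical choices and degenerate inputs

* Orthorhombic boxes only; triclinic input is rejected loudly.
* Kabsch superposition rejects < 3 or collinear fit atoms; the SVD sign
  correction guarantees proper rotations.
* Waters are wrapped per frame after superposition using the original
  box lengths — exact for a rigid scaffold, an approximation for weak
  rotations, harmless after bulk normalization.
* Empty cases are defined: zero waters give an all-zero, flagged G(r);
  an unoccupied site is an error in `survival_function` and a recorded
  per-site warning in the pipeline; an empty shell yields an n = 0
  summary row.
* Reports are serialized with fixed numeric formatting, and every stage
  is deterministic given the input and config, so identical runs are
  byte-identical (the basis of the determinism test).

# Known limitations

* Binary trajectory formats (XTC/DCD/TRR) are not read; convert to a
  GRO series or multi-model PDB first.
* G(r) carries the finite-cylinder-width bias described above; compare
  curves, not absolute values, below ~3 Å from the surface.
* The residence-time estimator truncates runs at the trajectory ends;
  for sites with τ within an order of magnitude of the trajectory
  length the fit is a lower bound (and is flagged).
* SASA is quadrature-based; 960 points give ~0.5% accuracy, raise
  `n_points` for tighter work.
* The per-residue hydration table counts water oxygens only; no
  orientation or donor/acceptor resolution at the contact level.
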