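---
title: "Methods: spin-label distance restraints, restrained docking, and binding energetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spin-label distance restraints, restrained docking, and binding energetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinpose)
```

This vignette is the package's account of its science: the models it
implements, the assumptions behind them, the tunable parameters and their
defaults, the numerical choices, and the limits of what the synthetic-data
tests establish.

## 1. From linewidths to distances

### The fast-exchange linewidth model

A ligand in fast exchange between solution and a protein site shows
population-averaged NMR linewidths: `LW_obs = LW_free + FB · (R2_bound / π)`,
where `FB` is the fraction of ligand bound and `R2_bound` collects the
bound-state transverse relaxation beyond the free-state linewidth. Fast
exchange means the exchange rate exceeds the bound/free Larmor-frequency
difference; the package assumes it throughout and models no exchange-rate
correction. The slope of an observed-linewidth versus fraction-bound line
therefore measures `R2_bound / π`. Two constructs are measured: a
paramagnetic one carrying a nitroxide spin label, and a diamagnetic
control in which the nitroxide is replaced by an inert ring. The
difference of the two slopes, times π, is the purely paramagnetic rate
`R2` (`paramagnetic_r2()`); the linewidth–rate conversion is fixed as
`R2 = π · FWHM`, and subtracting slopes in Hz before converting is
algebraically identical to subtracting rates.

`FB` is computed exactly from the single-site mass-action quadratic
(`fraction_bound()`, `free_ligand()`), not from the free ≈ total
approximation, because the enzyme-site concentrations (up to 25 µM) are
far above the ligand's dissociation constant.

### The Solomon–Bloembergen inversion

`sb_r2()` / `sb_distance()` implement

$$R_2 = \frac{1}{15}\left(\frac{\mu_0}{4\pi}\right)^2
\gamma^2 g^2 \mu_B^2\, S(S+1)\, r^{-6}
\left(4\tau_c + \frac{3\tau_c}{1 + (\omega\tau_c)^2}\right)$$

with CODATA constants. Two parameters matter:

* **`proton_frequency`** (Hz; default 600 MHz). Enters only through the
  dispersive term, which is negligible for `ωτc ≫ 1`.
* **`tau_c`** (s; default 35 ns). The rotational correlation time of the
  protein is rarely measured directly; the default is a Stokes–Einstein
  estimate for a ~70 kDa dimer in water at 25 °C
  (`τc ≈ ηV/kT`, hydrated radius ~3.3 nm). Because `r ∝ τc^{1/6}`, even a
  two-fold error in `τc` shifts distances by only 12%; the tests assert
  this scaling numerically.

Published versions of this equation are sometimes typeset with a garbled
prefactor; `prefactor_mode = "as_printed"` reproduces the literal
`(μ0/60π)²` reading, which differs from the standard form by a constant
factor of 15 in rate (15^(1/6) ≈ 1.57 in distance). The standard form is
the default because it reproduces the well-established ~25 Å practical
detection radius of nitroxide–proton broadening: at 600 MHz and 35 ns,
`sb_r2(25) ≈ 7 s⁻¹`, about 2 Hz of slope — near the resolution limit of a
linewidth measurement.

**Beyond-detection handling.** A paramagnetic slope at or below the
diamagnetic slope means the proton is too far to broaden measurably; the
rate is clipped to zero with a flag, and `sb_distance()` returns `NA` (a
sentinel, not an error) for non-positive rates and for distances computed
beyond `max_detect` (default 30 Å), where the inversion is dominated by
noise.

**Uncertainties.** `distance_ci()` propagates the rate standard error to
first order: `σ_r = r σ_{R2} / (6 R2)`. A Monte-Carlo oracle (resample the
rate, invert) agrees with this to better than 8% for relative rate errors
up to 0.2; beyond ~0.3 the inverse-sixth-root map is skewed enough that
first-order propagation undershoots by ~20%, a known limitation recorded
in the tests.

## 2. Triangulation and constraint ellipsoids

With distances from three (or more) spin-label sites, `trilaterate()`
places each proton group: a closed-form three-sphere intersection for
exactly three sites (two mirror-image candidates when the discriminant is
positive), Gauss–Newton least squares for more. Collinear sites are
rejected; non-intersecting spheres return an empty candidate set with the
best-achievable residual attached.

The mirror ambiguity is intrinsic to three-site trilateration. The
original workflow never faced it explicitly because the restrained-MD
force field kept the ligand out of the protein interior; here
`disambiguate()` makes the same choice explicitly, keeping the candidate
with the smaller steric overlap count against scaffold heavy atoms (ties
broken toward the scaffold centroid, both candidates retained in the
report).

`build_ellipsoid()` converts a triangulated point plus per-distance
uncertainties into the docking restraint region: axes directed along the
site-to-centre unit vectors, semi-axis *i* equal to σ of distance *i*.
Printed distance tables usually report 95% CIs, so σ = CI95/1.96. On
noise-free synthetic data the CIs collapse; a floor of 0.25 Å
(`min_sigma` in `triangulate_groups()`) keeps the ellipsoids
non-degenerate.

## 3. The restrained docking surrogate

The original structures were determined by distance-restrained MD in
explicit solvent. At desk scale the restraint geometry, not the force
field, determines the pose, so the package replaces MD with multistart
rigid-body optimization: 6 rigid degrees of freedom plus the single
rotatable inter-ring dihedral of the biphenyl ligand, an objective of
`restraint_energy + steric_energy`, a seeded greedy random walk with
shrinking steps alternating with Nelder–Mead polish (deterministic per
seed), and `n_starts` independent random starts in a 10 Å half-width box
around the restraint centroid. There is no solvent, no electrostatics and
no trajectory — only the restrained optimum.

* **Restraint energy.** Flat-bottom: zero inside the ellipsoid; outside,
  the excess distance to the surface is penalized as `½k·excess²` with
  `k = 50 kJ mol⁻¹` per Å. A force constant printed in kJ mol⁻¹ Å⁻¹
  literally implies a linear force; the harmonic form is the conventional
  MD-package interpretation and the default, with
  `force_form = "linear"` selectable.
* **Steric energy.** Soft spheres: `c·overlap²` over ligand/scaffold
  heavy-atom pairs inside the sum of van der Waals radii, `c = 10 kJ mol⁻¹ Å⁻²`.
  This is a clash penalty, not an interaction model.
* **Pair handling.** Proton pairs that are NMR-indistinguishable give one
  peak and one distance per site. `pair_mode = "chord_midpoint"` restrains
  the midpoint of the chord connecting the pair — the convention of the
  original workflow. `pair_mode = "r6_average"` instead restrains, per
  site, the effective distance `((r1⁻⁶ + r2⁻⁶)/2)^(−1/6)` to the measured
  value with a flat bottom of half-width σ, which is what the
  exchange-averaged peak actually reports. Singleton groups always use
  their ellipsoid.

**Why the pipeline defaults to `r6_average`.** For this ligand all four
chord-midpoint targets are collinear on the biphenyl long axis (the
midpoints of both primed pairs, the H3/H5 midpoint, and H4 all lie on the
para axis). Midpoint restraints therefore leave rotation about that axis —
and the dihedral — undetermined; in the original MD the force field
resolved this silently. The r6-effective distances of a pair *do* depend
on the rotation, so the distance-based mode restores the information the
averaged peak carries, and the singleton's point restraint pins the
global mirror solution. End-to-end pose recovery is tested in this mode.

`cluster_poses()` reimplements greedy centroid clustering: the
best-objective pose seeds a cluster and absorbs everything within the
RMSD cutoff (default 2.0 Å); a well-determined restraint set yields a
single cluster. `pose_rmsd()` is computed over heavy atoms in the fixed
scaffold frame (the scaffold never moves, so no re-superposition) and
minimized over the symmetry-equivalent atom mappings generated by flipping
either phenyl ring 180° about its para axis.

## 4. Binding and kinetics models

All fits are nonlinear least squares (Levenberg–Marquardt) with
covariance-based standard errors, returned as broom-style `tidy()`
tables.

* **Quadratic (tight-binding) isotherm** (`quadratic_isotherm()`,
  `fit_isotherm()`): the exact closed form
  `I = I₀ − ΔI·[(L+E+Kd) − √((L+E+Kd)² − 4LE)]/(2E)`, valid when enzyme
  sites are comparable to Kd so free ≈ total would fail. A titration with
  no signal change is flagged as unidentifiable rather than fitted.
* **Noncompetitive inhibition** (`fit_inhibition()`): at saturating
  substrate (the 100 × Km design), `v/Vmax = 1/(1 + I/Ki)`. Whether the
  underlying mechanism carries a mixed-inhibition α cannot be resolved at
  saturating substrate; α is exposed as a fixed option and defaults to 1.
* **Michaelis–Menten, weighted double-reciprocal**
  (`fit_michaelis_menten()`): a linear fit of 1/v on 1/[S] with weights
  v⁴ on the reciprocal residuals. The algebra:
  `(1/v − 1/v̂)² ≈ (v − v̂)²/v⁴`, so v⁴ weights make the reciprocal-space
  fit first-order equivalent to unweighted least squares on the raw
  velocities — the classical correction ("(1/v⁴) weighting") for the
  small-velocity bias of a naive double-reciprocal fit. On noise-free data
  it is exactly equivalent to a direct nonlinear fit, which the tests use
  as an oracle. Non-positive velocities are excluded with a warning.
* **Single-site activation** (`fit_ec50()`):
  `OD = OD_initial + ΔOD·[X]/(EC50 + [X])`; a fitted EC50 outside the
  titrated range triggers a bracketing warning.

### Ratio analyses

`fold_effect()` reports Ki(variant)/Ki(reference) rounded half away from
zero (the convention of printed tables; banker's rounding would turn 10.5
into 10). Units are metadata: mismatched labels raise an error, and the
package never rescales a constant silently — relevant because published
tables sometimes print the same constant in different units in different
places. `coupling_ratio()` converts a Kd ratio into an interaction free
energy `RT·ln(ratio)`; by thermodynamic-cycle closure the ratio must be
the same whichever ligand is called the partner, which the tests assert
with propagated errors. `order_of_binding()` encodes the classic
saturating-partner test: if binding were obligatorily ordered, an n-fold
increase in saturating partner would appear to tighten the ligand's
affinity n-fold; a ±2-fold tolerance band (the default) separates
"random" (ratio ≈ 1) from "ordered" (ratio ≈ n) from "indeterminate".

## 5. The synthetic-data generator

`paper_like_scenario()` fixes the study conditions; its defaults are the
published designs, not tuning knobs:

* NMR series: enzyme ladder 0/2.5/5/10/25 µM active sites, 50 µM ligand,
  ligand Kd 60 nM, 600 MHz, τc 35 ns; free linewidth 2 Hz and a
  diamagnetic bound-state rate of 40 s⁻¹ (typical for a small ligand
  rigidly bound to a slowly tumbling ~70 kDa protein). Each emitted
  linewidth is the mean of three independent Gaussian draws — the
  triplicate-and-average design of the underlying experiments — with
  per-series homoscedastic noise, sd = CV × the series' largest
  linewidth (default CV 2%). Pair peaks broaden with the (1/r⁶)-mean of
  the two member protons' rates, the correct population average for one
  exchange-averaged resonance.
* Scaffold: a packed random cloud at protein heavy-atom density
  (2300 atoms, 21 Å radius, 1.8 Å minimum separation) standing in for a
  sulfotransferase-sized monomer. Five spin-label oxygens sit 2 Å above
  the surface in a near-trigonal-bipyramidal layout (pairwise ≥ 20 Å);
  five sites, not three, because surface coverage ≥ 95% at the 25 Å
  detection radius is geometrically unattainable with three labels on a
  monomer-scale scaffold, exactly why the original screening strategy
  used five. Distance measurements use the first three (the trio
  surrounding the ligand pocket), as the structural study did.
* Planted pose: the idealized dichloro-biphenylol (`build_ligand()`:
  hexagonal rings, 1.39 Å C–C, 1.48 Å inter-ring bond, one rotatable
  dihedral) sits in a carved surface pocket with all twelve true
  effective distances in 16.6–24.2 Å — inside the published 14–28 Å range
  and the reliable detection band — and with mirror trilateration
  solutions buried in the scaffold core, so steric disambiguation works
  as it does on the real system. This geometry was fixed once, from
  forward geometry only.
* Titration generators evaluate their models exactly and add seeded
  Gaussian noise (sd = CV × maximal model value); CV 0 reproduces the
  curve to machine precision, and generating parameters ride along as
  `attr(, "truth")`.

**What the synthetic tests do and do not show.** They establish that the
estimators invert their own forward models correctly at realistic noise,
that trilateration and docking recover a known pose from realistic
distance errors, and that the fitted standard errors have honest
frequentist coverage. They do not validate the physical model against
real spectra: real data add baseline distortion, peak overlap, exchange
broadening beyond the fast limit, spin-label flexibility (the nitroxide
oxygen moves several Å about its attachment point), and anisotropic
tumbling — none of which the generator emulates. Published distance
tables are therefore treated as pipeline *inputs* whose geometric
feasibility can be checked (`embed_distance_table()` embeds a printed
proton-by-site table by gauge-fixed least squares and reports per-proton
trilateration residuals), not as quantities the package re-derives.

## 6. Numerical choices and problem sizes

* Nonlinear fits: `minpack.lm::nlsLM` with `ftol = ptol = 1e-15`, so
  noise-free recoveries are exact to ≤ 1e-6 relative.
* Trilateration accepts a discriminant-clamped (site-plane) solution only
  within `tolerance`; the Gauss–Newton branch starts from the closed-form
  solution of the first non-degenerate triple.
* Pose optimization: two cycles of 150 greedy random steps (step sizes
  1.5 Å / 0.3 rad, shrinking) plus Nelder–Mead (≤ 400 iterations),
  deterministic per seed; scaffold atoms farther than 28 Å from the
  restraint centroid are excluded from the steric term since the ligand
  cannot reach them. A zero-objective start returns unchanged — which also
  realizes the published control that releasing the restraints after
  convergence leaves the pose in place.
* Default problem sizes keep the full suite fast: the end-to-end docking
  check uses the 2300-atom scaffold, 10 starts and completes in ~12 s;
  the replicate-statistics suite uses 200 seeded replicates per model.
  These sizes were chosen as representative desk-scale analyses.
* Confidence-interval coverage is assessed with t-quantile intervals
  (df = n − p), the appropriate small-sample interval for least-squares
  fits.

## 7. Known limitations

* The fast-exchange assumption is untested within the package; slowly
  exchanging ligands would need an exchange-rate correction term that is
  deliberately out of scope.
* The steric term is a clash penalty only; poses are restraint-determined,
  and nothing in the objective rewards favourable contacts.
* The r6-average pair mode restrains per-site effective distances but
  still reports the ellipsoid geometry of the chord midpoint; for pairs
  whose two protons sit at very different distances from a site the
  midpoint is a biased summary (the effective distance is dominated by
  the closer proton).
* `order_of_binding()`'s ±2-fold band is a conventional, not inferential,
  threshold; with partner ratios near 4 the "random" and "ordered" bands
  touch and most outcomes will be "indeterminate".
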