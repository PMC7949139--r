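# spinpose

Spin-label NMR distance restraints, restrained ligand-pose determination,
and binding energetics — in R.

## The problem

When a small ligand exchanges rapidly between solution and a protein
binding site, an unpaired electron on a protein-attached nitroxide spin
label broadens the ligand's solution NMR peaks in a distance-dependent way.
The slope of the observed linewidth against the fraction of ligand bound
isolates the bound-state broadening; subtracting the slope measured with a
diamagnetic control construct leaves the purely paramagnetic transverse
relaxation rate R2. The Solomon–Bloembergen relation then converts R2 into
an electron–proton distance:

    R2 = (1/15) (μ0/4π)² γ² g² μB² S(S+1) · r⁻⁶ · [ 4τc + 3τc / (1 + (ωτc)²) ]

where γ is the proton gyromagnetic ratio, g and μB the electron g-factor
and Bohr magneton, S the electron spin, ω the proton Larmor frequency and
τc the protein's rotational correlation time. Because r depends on R2 only
to the −1/6 power, distances are robust to moderate rate errors; nitroxide
broadening is practically detectable out to ~25 Å.

With distances from three well-separated spin-label sites, each ligand
proton (or NMR-indistinguishable proton pair) is trilaterated onto the
protein scaffold. The triangulated points, with their measurement
uncertainties, become flat-bottom ellipsoid restraints, and a restrained
multistart optimization over the ligand's rigid-body degrees of freedom
plus its one rotatable inter-ring dihedral determines the bound pose; RMSD
clustering of the ensemble reports whether the restraints determine a
single structure. The package was built around the hydroxylated-PCB /
estrogen-sulfotransferase system — a chlorinated biphenylol inhibitor
bound to a ~70 kDa dimeric enzyme — and ships the accompanying solution
energetics: tight-binding (quadratic) fluorescence isotherms,
noncompetitive inhibition, (1/v⁴)-weighted double-reciprocal
Michaelis–Menten kinetics, single-site receptor-activation curves, and the
fold-effect / thermodynamic-coupling / order-of-binding analyses built on
the fitted constants.

Every input stream has a seeded synthetic generator with ground truth
attached, so the full pipeline runs and is tested without any external
data. A PDB scaffold of your own can be substituted for the generated one.

## Worked example

```r
library(spinpose)

scenario <- paper_like_scenario(seed = 17)   # scaffold + planted ligand + designs
peaks    <- simulate_linewidths(scenario)    # para/dia peak lists, 2% noise
distances <- estimate_distances(peaks, scenario$ctx, kd = scenario$kd_nmr)
head(distances[, c("proton_group", "site_id", "r", "ci95")], 4)
#>   proton_group site_id     r  ci95
#> 1 H2' 6'       150      20.6 0.336
#> 2 H3 5         150      22.6 0.537
#> 3 H3' 5'       150      19.5 0.355
#> 4 H4           150      24.2 1.37

result <- run_pipeline(scenario, n_starts = 10)
result
#> <sp_pipeline_result> seed 17
#>   12 distance estimates (12 usable), 4 ellipsoids
#>   10 poses -> 1 cluster(s); best objective 0.000 kJ/mol
```

Each distance `r` (Å, with its 95% CI) is the Solomon–Bloembergen
inversion of one proton group's paramagnetic broadening at one spin-label
site. All ten optimization starts converge to a single cluster at the
2.0 Å RMSD cutoff — the restraints determine one pose, and
`pose_rmsd(result$representative, scenario$planted_pose)` confirms it is
the planted one (1.2 Å here).

The binding side follows broom conventions:

```r
fit <- fit_isotherm(simulate_titration(
  ligand_total = 10^seq(log10(12.5), log10(1000), length.out = 12),
  enzyme_sites = 15, kd = 62, cv = 0.03, seed = 1))
tidy(fit)
#>   term  estimate std.error
#> 1 Kd      64.2     13.5
#> 2 I0       0.987    0.0281
#> 3 dI       0.570    0.0252

coupling_ratio(750, 62)     # partner tightens binding ~12-fold
#>   ratio ddG_kJ_mol
#> 1  12.1       6.18
```

A Kd of 62 nM generated with 3% noise comes back as 64 ± 14 nM; the
coupling ratio of the two dissociation constants (without / with the
partner ligand bound) corresponds to ~6.2 kJ/mol of interaction energy.
`autoplot()` on any fit overlays data and fitted curve;
`plot_broadening()` shows the linewidth-versus-fraction-bound lines whose
slopes carry the distances.

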