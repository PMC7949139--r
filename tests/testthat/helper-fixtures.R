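# Shared fixtures, all generated in code. The scenario is deterministic, so
# building it once per test run is safe.

sp_test_scenario <- paper_like_scenario()

# titrant grids at the two standard fluorescence-titration designs:
# low-enzyme (15 nM sites, 12.5-1000 nM titrant) and high-enzyme
# (50 nM sites, 0.25-20 uM titrant), 12 log-spaced points each
sp_grid_low <- 10^seq(log10(12.5), log10(1000), length.out = 12)
sp_grid_high <- 10^seq(log10(250), log10(20000), length.out = 12)

# the published proton-by-site distance table (rows: the four proton
# groups; columns: attachment sites 16/150/233) and its 95% CIs, Angstrom
sp_published_distances <- rbind(
  c(19, 22, 24),
  c(20, 25, 22),
  c(22, 24, 16),
  c(28, 25, 14)
)
sp_published_ci <- rbind(
  c(3, 4, 3),
  c(3, 4, 3),
  c(3, 3, 3),
  c(4, 4, 2)
)

# noise-free peak list for a single proton group at a chosen true distance,
# mirroring the linewidth forward model
sp_make_peaks <- function(r_true, ctx, ladder = c(0, 2.5, 5, 10, 25),
                          lt = 50, kd = 0.060, lw_free = 2, r2_dia = 40) {
  fb <- fraction_bound(lt, ladder, kd)
  r2p <- sb_r2(r_true, ctx)
  dplyr::bind_rows(
    tibble::tibble(construct = "paramagnetic", site_id = "s1", proton_group = "g",
                   enzyme_sites = ladder, ligand_total = lt,
                   fwhm = lw_free + fb * (r2_dia + r2p) / pi),
    tibble::tibble(construct = "diamagnetic", site_id = "s1", proton_group = "g",
                   enzyme_sites = ladder, ligand_total = lt,
                   fwhm = lw_free + fb * r2_dia / pi)
  )
}
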