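# Seeded generators for every input stream the pipeline consumes, with
# ground truth attached, so all stages are testable without external data.

#' Generate a synthetic protein scaffold with spin-label sites
#'
#' A deterministic packed random cloud at protein heavy-atom density
#' (~2300 atoms in a ~21 A sphere, minimum separation 1.8 A) standing in
#' for a sulfotransferase-sized monomer, plus spin-label oxygen positions
#' just above the surface. The default five-site layout mirrors the
#' screening strategy of coating the whole surface in detectable
#' paramagnetic field (a near-trigonal-bipyramidal arrangement, pairwise
#' separations >= 20 A); distance measurements conventionally use the first
#' three sites, which surround the ligand-bearing pole.
#'
#' @param seed Integer seed; the same seed reproduces the scaffold exactly.
#' @param n_atoms Number of heavy atoms (default 2300).
#' @param radius Scaffold radius, Angstrom (default 21).
#' @param n_sites Number of spin-label sites, 3-5 (default 5).
#' @param min_site_sep Minimum pairwise site separation, Angstrom
#'   (default 20).
#' @param site_offset Height of the nitroxyl oxygen above the surface,
#'   Angstrom (default 2).
#' @return List with `atoms` (tibble `x`, `y`, `z`, `element`) and `sites`
#'   (tibble `site_id`, `residue`, `x`, `y`, `z`).
#' @export
make_scaffold <- function(seed = 17, n_atoms = 2300, radius = 21,
                          n_sites = 5, min_site_sep = 20, site_offset = 2) {
  stopifnot(n_sites >= 3, n_sites <= 5)
  min_sep <- 1.8
  atoms <- withr::with_seed(seed, {
    pts <- matrix(NA_real_, n_atoms, 3)
    n_ok <- 0L
    attempts <- 0L
    while (n_ok < n_atoms) {
      attempts <- attempts + 1L
      if (attempts > 60L * n_atoms) {
        abort("Could not pack the scaffold at the requested density.")
      }
      p <- runif(3, -radius, radius)
      if (sum(p^2) > radius^2) next
      if (n_ok > 0L) {
        d2 <- colSums((t(pts[seq_len(n_ok), , drop = FALSE]) - p)^2)
        if (min(d2) < min_sep^2) next
      }
      n_ok <- n_ok + 1L
      pts[n_ok, ] <- p
    }
    pts
  })

  # site directions: ligand-pole trio at 60 deg polar angle (120 deg apart
  # in azimuth), plus the antipole and one mid-latitude filler
  th <- 60 * pi / 180
  dirs <- rbind(
    c(sin(th), 0, cos(th)),
    c(sin(th) * cos(2 * pi / 3), sin(th) * sin(2 * pi / 3), cos(th)),
    c(sin(th) * cos(4 * pi / 3), sin(th) * sin(4 * pi / 3), cos(th)),
    c(0, 0, -1),
    c(sin(115 * pi / 180) * cos(pi / 3), sin(115 * pi / 180) * sin(pi / 3),
      cos(115 * pi / 180))
  )[seq_len(n_sites), , drop = FALSE]
  site_r <- radius + site_offset
  sites <- dirs * site_r
  seps <- as.matrix(dist(sites))
  diag(seps) <- Inf
  if (min(seps) < min_site_sep) {
    abort(sprintf("Site layout infeasible: minimum separation %.1f A < %.1f A.",
                  min(seps), min_site_sep))
  }
  residues <- c(16L, 150L, 233L, 25L, 163L)[seq_len(n_sites)]
  list(
    atoms = tibble::tibble(x = atoms[, 1], y = atoms[, 2], z = atoms[, 3],
                           element = "C"),
    sites = tibble::tibble(site_id = as.character(residues), residue = residues,
                           x = sites[, 1], y = sites[, 2], z = sites[, 3])
  )
}

#' Assemble the default end-to-end synthetic scenario
#'
#' The "paper-like" study conditions: a scaffold with five spin-label sites
#' (three used for distances), an idealized hydroxy-dichlorobiphenyl ligand
#' planted in a carved surface pocket near the site trio (true
#' proton-to-site distances in the 14-28 A range), a 600 MHz acquisition
#' context with tau_c 35 ns, the NMR enzyme ladder 0/2.5/5/10/25 uM sites
#' with 50 uM ligand, and the generating equilibrium/kinetic constants used
#' by the titration simulators.
#'
#' @param seed Master seed (default 17); every downstream random draw
#'   derives from it.
#' @param noise_cv Named list of noise levels (fraction of the maximal
#'   model value) per data stream. Defaults: linewidth 0.02, others 0.03.
#' @return An object of class `sp_scenario`.
#' @export
paper_like_scenario <- function(seed = 17,
                                noise_cv = list(linewidth = 0.02, binding = 0.03,
                                                inhibition = 0.03, kinetics = 0.03,
                                                activation = 0.03)) {
  scaf <- make_scaffold(seed = seed)
  ligand <- build_ligand()

  # plant the ligand at the pole the first three sites surround, long axis
  # tangent to the surface, then carve the pocket
  target <- c(0, 0, 18)
  rot <- c(0.30, 0.20, 1.05)
  R <- .rotmat_axis_angle(rot)
  base_centroid <- colMeans(.as_xyz(ligand$atoms))
  tr <- target - as.numeric(R %*% base_centroid)
  pose <- make_pose(ligand, c(tr, rot, 0))

  heavy <- pose$xyz[ligand$heavy, , drop = FALSE]
  l_rad <- .vdw_radius(ligand$atoms$element[ligand$heavy])
  keep <- rep(TRUE, nrow(scaf$atoms))
  sxyz <- .as_xyz(scaf$atoms)
  for (i in seq_len(nrow(heavy))) {
    keep <- keep & .dist_point_sites(heavy[i, ], sxyz) >= (l_rad[i] + 1.70 + 0.4)
  }
  scaf$atoms <- scaf$atoms[keep, , drop = FALSE]

  structure(
    list(
      seed = seed,
      scaffold = scaf$atoms,
      sites = scaf$sites,
      distance_sites = scaf$sites$site_id[1:3],
      ligand = ligand,
      planted_pose = pose,
      ctx = acquisition_context(),
      enzyme_ladder = c(0, 2.5, 5, 10, 25),   # uM active sites
      ligand_total = 50,                       # uM
      kd_nmr = 0.060,                          # uM, ternary-complex affinity
      lw_free = 2.0,                           # Hz, free-ligand linewidth
      r2_dia = 40,                             # s^-1, diamagnetic bound rate
      noise_cv = noise_cv,
      params = list(kd_binary_nM = 750, kd_ternary_nM = 62, ki_nM = 0.060,
                    km_nM = 4.0, kcat_min = 150, ec50_nM = 38)
    ),
    class = "sp_scenario"
  )
}

#' @export
print.sp_scenario <- function(x, ...) {
  cat(sprintf("<sp_scenario> seed %d: %d scaffold atoms, %d sites (%s for distances)\n",
              x$seed, nrow(x$scaffold), nrow(x$sites),
              paste(x$distance_sites, collapse = "/")))
  invisible(x)
}

# true per-(group, site) effective distance: proton pairs broaden their
# single exchange-averaged peak with the mean of the two r^-6 rates, i.e.
# an effective distance ((r1^-6 + r2^-6)/2)^(-1/6)
.true_distances <- function(scenario) {
  lig <- scenario$ligand
  pose <- scenario$planted_pose
  sites <- scenario$sites[scenario$sites$site_id %in% scenario$distance_sites, ]
  purrr::map_dfr(names(lig$groups), function(g) {
    idx <- .group_indices(lig, g)
    coords <- pose$xyz[idx, , drop = FALSE]
    purrr::map_dfr(seq_len(nrow(sites)), function(j) {
      sj <- as.numeric(sites[j, c("x", "y", "z")])
      ri <- .dist_point_sites(sj, coords)
      tibble::tibble(proton_group = g, site_id = sites$site_id[j],
                     r_true = (mean(ri^-6))^(-1 / 6))
    })
  })
}

.add_noise <- function(x, cv, seed) {
  if (cv <= 0) return(x)
  withr::with_seed(seed, x + rnorm(length(x), 0, cv * max(abs(x))))
}

#' Simulate linewidth peak lists for para- and diamagnetic constructs
#'
#' Fast-exchange mixing of free and bound linewidths across the enzyme
#' ladder: `LW = LW_free + FB * (R2_dia + R2_para) / pi` for the
#' paramagnetic construct (without `R2_para` for the diamagnetic control,
#' measured at the third distance site), with `R2_para` from the
#' Solomon-Bloembergen forward relation applied to the planted pose's true
#' distances and Gaussian noise at the scenario's linewidth CV. Zero-enzyme
#' rows carry the free linewidth exactly.
#'
#' @param scenario An [paper_like_scenario()] object.
#' @param noise_cv Override of the linewidth noise level.
#' @param seed Override of the noise seed.
#' @param n_reps Independent determinations averaged per point (default 3,
#'   the standard triplicate design; the emitted linewidth is their mean).
#' @return A peak-list tibble (`construct`, `site_id`, `proton_group`,
#'   `enzyme_sites`, `ligand_total`, `fwhm`) with the ground-truth distance
#'   table in `attr(, "truth")`.
#' @export
simulate_linewidths <- function(scenario,
                                noise_cv = scenario$noise_cv$linewidth,
                                seed = scenario$seed, n_reps = 3) {
  truth <- .true_distances(scenario)
  truth$r2_para_true <- sb_r2(truth$r_true, scenario$ctx)
  fb <- fraction_bound(scenario$ligand_total, scenario$enzyme_ladder,
                       scenario$kd_nmr)
  ladder <- tibble::tibble(enzyme_sites = scenario$enzyme_ladder, fb = fb)

  para <- truth |>
    tidyr::crossing(ladder) |>
    dplyr::mutate(
      construct = "paramagnetic",
      fwhm = scenario$lw_free + .data$fb * (scenario$r2_dia + .data$r2_para_true) / pi
    )
  dia_site <- scenario$distance_sites[3]
  dia <- tibble::tibble(proton_group = unique(truth$proton_group)) |>
    tidyr::crossing(ladder) |>
    dplyr::mutate(
      construct = "diamagnetic", site_id = dia_site,
      fwhm = scenario$lw_free + .data$fb * scenario$r2_dia / pi
    )
  peaks <- dplyr::bind_rows(
    dplyr::select(para, "construct", "site_id", "proton_group",
                  "enzyme_sites", "fwhm"),
    dplyr::select(dia, "construct", "site_id", "proton_group",
                  "enzyme_sites", "fwhm")
  )
  peaks$ligand_total <- scenario$ligand_total
  # homoscedastic within each peak series, scaled to that series' maximal
  # linewidth: broad peaks are measured less precisely than sharp ones
  if (noise_cv > 0) {
    sd_series <- peaks |>
      dplyr::group_by(.data$construct, .data$site_id, .data$proton_group) |>
      dplyr::mutate(.sd = noise_cv * max(.data$fwhm)) |>
      dplyr::pull(".sd")
    peaks$fwhm <- withr::with_seed(seed, {
      reps <- vapply(seq_len(n_reps), function(k) {
        peaks$fwhm + rnorm(nrow(peaks), 0, sd_series)
      }, numeric(nrow(peaks)))
      rowMeans(reps)
    })
  }
  peaks <- peaks[, c("construct", "site_id", "proton_group", "enzyme_sites",
                     "ligand_total", "fwhm")]
  attr(peaks, "truth") <- truth
  peaks
}

#' Render a peak as a digitized Lorentzian window
#'
#' Produces the frequency-domain curve a linewidth fit would consume, for
#' exercising [fit_lorentzian()] against known widths.
#'
#' @param fwhm Full width at half maximum, Hz.
#' @param center Peak centre, Hz (default 0).
#' @param amplitude Peak height (default 1).
#' @param window Half-width of the simulated window, Hz (default 10 x
#'   fwhm).
#' @param n Points across the window (default 257).
#' @param noise_sd Gaussian noise standard deviation on the intensities.
#' @param seed Seed for the noise.
#' @return Tibble with `frequency` and `intensity`.
#' @export
simulate_peak_window <- function(fwhm, center = 0, amplitude = 1,
                                 window = 10 * fwhm, n = 257,
                                 noise_sd = 0, seed = 1) {
  f <- seq(center - window, center + window, length.out = n)
  y <- amplitude / (1 + ((f - center) / (fwhm / 2))^2)
  y <- if (noise_sd > 0) withr::with_seed(seed, y + rnorm(n, 0, noise_sd)) else y
  tibble::tibble(frequency = f, intensity = y)
}

#' Simulate titration, inhibition, kinetic and activation datasets
#'
#' Exact model evaluation plus seeded Gaussian noise (standard deviation =
#' `cv` times the maximal model value); `cv = 0` reproduces the model curve
#' exactly. Generating parameters are attached as `attr(, "truth")`.
#'
#' @param kd,enzyme_sites Generating dissociation constant and site
#'   concentration (same unit as `ligand_total`).
#' @param ligand_total Titrant grid.
#' @param i0,di Fluorescence endpoints.
#' @param cv Noise level (fraction of maximal signal).
#' @param seed Integer seed.
#' @return A tibble matching the corresponding fit function's input.
#' @name simulate_titration
#' @export
simulate_titration <- function(ligand_total, enzyme_sites, kd,
                               i0 = 1, di = 0.6, cv = 0, seed = 1) {
  signal <- quadratic_isotherm(ligand_total, enzyme_sites, kd, i0, di)
  out <- tibble::tibble(ligand_total = ligand_total,
                        signal = .add_noise(signal, cv, seed),
                        enzyme_sites = enzyme_sites)
  attr(out, "truth") <- list(kd = kd, i0 = i0, di = di)
  out
}

#' @rdname simulate_titration
#' @param ki Generating inhibition constant.
#' @param inhibitor Inhibitor grid (default 0 plus 0.2-20 x Ki,
#'   log-spaced, the usual inhibition design).
#' @export
simulate_inhibition <- function(ki, inhibitor = c(0, ki * 10^seq(log10(0.2), log10(20), length.out = 9)),
                                cv = 0, seed = 1) {
  v <- noncompetitive_rate(inhibitor, ki)
  out <- tibble::tibble(inhibitor = inhibitor,
                        v_over_vmax = .add_noise(v, cv, seed))
  attr(out, "truth") <- list(ki = ki)
  out
}

#' @rdname simulate_titration
#' @param km,kcat Generating Michaelis constant and turnover number.
#' @param substrate Substrate grid (default 0.2-5 x Km, the initial-rate
#'   design).
#' @export
simulate_kinetics <- function(km, kcat,
                              substrate = km * c(0.2, 0.35, 0.6, 1, 1.75, 3, 5),
                              cv = 0, seed = 1) {
  v <- kcat * substrate / (km + substrate)
  out <- tibble::tibble(substrate = substrate,
                        velocity = .add_noise(v, cv, seed))
  attr(out, "truth") <- list(km = km, kcat = kcat)
  out
}

#' @rdname simulate_titration
#' @param ec50 Generating half-maximal effector concentration.
#' @param effector Effector grid (default 3 decades bracketing EC50 plus
#'   zero).
#' @param od0,dod Activation endpoints.
#' @export
simulate_activation <- function(ec50,
                                effector = c(0, ec50 * 10^seq(-1.5, 1.5, length.out = 11)),
                                od0 = 0.05, dod = 1.0, cv = 0, seed = 1) {
  od <- od0 + dod * effector / (ec50 + effector)
  out <- tibble::tibble(effector = effector, od = .add_noise(od, cv, seed))
  attr(out, "truth") <- list(ec50 = ec50, od0 = od0, dod = dod)
  out
}
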