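# Solomon-Bloembergen relaxometry: linewidths -> paramagnetic rates -> distances.

#' Acquisition context for Solomon-Bloembergen distance calculations
#'
#' Bundles the spectrometer and molecular-tumbling parameters that the
#' electron-proton dipolar relaxation model needs. The transverse relaxation
#' rate of a proton a distance \eqn{r} from an unpaired electron is
#' \deqn{R_2 = \frac{C}{r^6}\left(4\tau_c + \frac{3\tau_c}{1+(\omega\tau_c)^2}\right)}
#' with \eqn{C = (1/15)(\mu_0/4\pi)^2\gamma^2 g^2 \mu_B^2 S(S+1)} in the
#' standard form, \eqn{\omega} the proton Larmor frequency and \eqn{\tau_c}
#' the rotational correlation time of the protein.
#'
#' @param proton_frequency Spectrometer proton frequency in Hz (default
#'   600 MHz, a typical cryoprobe field for ligand work).
#' @param tau_c Rotational correlation time in seconds. The default, 35 ns,
#'   is a Stokes-Einstein estimate for a ~70 kDa dimeric enzyme in water at
#'   25 degC; because \eqn{r \propto \tau_c^{1/6}} the derived distances are
#'   insensitive to this choice.
#' @param spin_S Electron spin quantum number (1/2 for a nitroxide).
#' @param prefactor_mode `"standard_SB"` (default) uses the standard
#'   Solomon-Bloembergen prefactor \eqn{(1/15)(\mu_0/4\pi)^2};
#'   `"as_printed"` uses the literal \eqn{(\mu_0/(60\pi))^2} reading found
#'   in some typeset versions of the equation. Only the standard form
#'   reproduces the ~25 A practical detection radius of nitroxide labels.
#' @param constants Named list overriding the physical constants
#'   (`mu0`, `gamma_h`, `g_e`, `mu_b`), SI units.
#'
#' @return An object of class `sp_acquisition` (a list).
#' @examples
#' ctx <- acquisition_context(tau_c = 35e-9)
#' sb_r2(15, ctx)          # rate at 15 A
#' sb_distance(150, ctx)   # distance giving 150 s^-1
#' @export
acquisition_context <- function(proton_frequency = 600e6,
                                tau_c = 35e-9,
                                spin_S = 0.5,
                                prefactor_mode = c("standard_SB", "as_printed"),
                                constants = list()) {
  .assert_scalar_pos(proton_frequency, "proton_frequency")
  .assert_scalar_pos(tau_c, "tau_c")
  .assert_scalar_pos(spin_S, "spin_S")
  prefactor_mode <- match.arg(prefactor_mode)
  const <- modifyList(.sp_const[c("mu0", "gamma_h", "g_e", "mu_b")], constants)
  structure(
    list(proton_frequency = proton_frequency, tau_c = tau_c, spin_S = spin_S,
         prefactor_mode = prefactor_mode, constants = const),
    class = "sp_acquisition"
  )
}

#' @export
print.sp_acquisition <- function(x, ...) {
  cat(sprintf(
    "<sp_acquisition> %0.0f MHz, tau_c %.3g ns, S = %g, prefactor = %s\n",
    x$proton_frequency / 1e6, x$tau_c * 1e9, x$spin_S, x$prefactor_mode))
  invisible(x)
}

# C * J(tau_c, omega): the r^6-scaled dipolar rate (units m^6 s^-1), so that
# R2 = .sb_kernel(ctx) / r_m^6.
.sb_kernel <- function(ctx) {
  const <- ctx$constants
  pref <- switch(ctx$prefactor_mode,
    standard_SB = (1 / 15) * (const$mu0 / (4 * pi))^2,
    as_printed  = (const$mu0 / (60 * pi))^2
  )
  C <- pref * const$gamma_h^2 * const$g_e^2 * const$mu_b^2 *
    ctx$spin_S * (ctx$spin_S + 1)
  omega <- 2 * pi * ctx$proton_frequency
  tc <- ctx$tau_c
  C * (4 * tc + 3 * tc / (1 + (omega * tc)^2))
}

#' Solomon-Bloembergen forward and inverse relations
#'
#' `sb_r2()` gives the paramagnetic transverse relaxation rate of a proton a
#' distance `r` (Angstrom) from the unpaired electron; `sb_distance()`
#' inverts it. The two are exact inverses: for fixed context,
#' \eqn{R_2(r)\,r^6} is constant.
#'
#' @param r Electron-proton distance(s) in Angstrom; must be > 0.
#' @param r2_para Paramagnetic transverse relaxation rate(s) in s^-1.
#'   Non-positive values mean the proton is beyond the detection radius and
#'   yield `NA` (a sentinel, not an error).
#' @param ctx An [acquisition_context()].
#' @param max_detect Distances computed beyond this radius (Angstrom,
#'   default 30) are reported as `NA`: the corresponding broadening is below
#'   what linewidth measurements resolve. Set to `Inf` to disable.
#' @return Rates in s^-1 (`sb_r2`) or distances in Angstrom (`sb_distance`).
#' @examples
#' ctx <- acquisition_context()
#' sb_distance(sb_r2(18, ctx), ctx)  # 18
#' @export
sb_r2 <- function(r, ctx) {
  stopifnot(inherits(ctx, "sp_acquisition"))
  if (any(!is.finite(r) | r <= 0)) abort("`r` must be positive and finite (Angstrom).")
  .sb_kernel(ctx) / (r * 1e-10)^6
}

#' @rdname sb_r2
#' @export
sb_distance <- function(r2_para, ctx, max_detect = 30) {
  stopifnot(inherits(ctx, "sp_acquisition"))
  out <- rep(NA_real_, length(r2_para))
  ok <- is.finite(r2_para) & r2_para > 0
  out[ok] <- (.sb_kernel(ctx) / r2_para[ok])^(1 / 6) * 1e10
  out[ok & out > max_detect] <- NA_real_
  out
}

#' Fit a single Lorentzian peak
#'
#' Least-squares fit of \eqn{I(f) = A / (1 + ((f - f_0)/(w/2))^2)} to a
#' digitized peak window, as used to extract full-widths at half maximum
#' from 1D proton spectra.
#'
#' @param frequency_axis Numeric vector, Hz.
#' @param intensity Numeric vector, arbitrary units, same length.
#' @param peak_id Optional label used in error messages.
#' @return A tibble with columns `center`, `fwhm`, `amplitude` (one row).
#' @examples
#' f <- seq(-60, 60, length.out = 201)
#' y <- 5 / (1 + (f / 6)^2)           # fwhm 12 Hz
#' fit_lorentzian(f, y)
#' @export
fit_lorentzian <- function(frequency_axis, intensity, peak_id = "peak") {
  if (length(frequency_axis) != length(intensity)) {
    abort("`frequency_axis` and `intensity` must have the same length.")
  }
  if (length(intensity) < 5L) abort("Need at least 5 points to fit a Lorentzian.")
  if (max(intensity) <= 0 || stats::var(intensity) == 0) {
    abort(sprintf("Lorentzian fit failed for '%s': no peak in window.", peak_id),
          class = "sp_fit_failure")
  }
  i_max <- which.max(intensity)
  a0 <- intensity[i_max]
  c0 <- frequency_axis[i_max]
  # crude half-height width for starting value
  above <- frequency_axis[intensity >= a0 / 2]
  w0 <- max(diff(range(above)), diff(range(frequency_axis)) / 20)
  df <- data.frame(f = frequency_axis, y = intensity)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A / (1 + ((f - f0) / (w / 2))^2),
      data = df, start = list(A = a0, f0 = c0, w = w0),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14, ptol = 1e-14)
    ),
    error = function(e) {
      abort(sprintf("Lorentzian fit failed for '%s': %s", peak_id, conditionMessage(e)),
            class = "sp_fit_failure")
    }
  )
  est <- coef(fit)
  if (!is.finite(est[["w"]]) || est[["w"]] <= 0) {
    abort(sprintf("Lorentzian fit failed for '%s': non-positive width.", peak_id),
          class = "sp_fit_failure")
  }
  tibble::tibble(center = est[["f0"]], fwhm = abs(est[["w"]]),
                 amplitude = est[["A"]])
}

#' Fraction of ligand bound at equilibrium
#'
#' Single-site mass action: fraction of *ligand* molecules bound given total
#' ligand, total binding sites and the dissociation constant. Used to build
#' the x axis of linewidth-versus-fraction-bound plots.
#'
#' @param ligand_total,enzyme_sites,kd Concentrations, any single consistent
#'   unit.
#' @return Fraction in \[0, 1\].
#' @export
fraction_bound <- function(ligand_total, enzyme_sites, kd) {
  free <- free_ligand(ligand_total, enzyme_sites, kd)
  lt <- rep_len(ligand_total, length(free))
  fb <- numeric(length(free))
  pos <- lt > 0
  fb[pos] <- (lt[pos] - free[pos]) / lt[pos]
  pmin(pmax(fb, 0), 1)
}

#' Slope of a linewidth-versus-fraction-bound series
#'
#' Ordinary least-squares slope of observed FWHM (Hz) against fraction of
#' ligand bound. Under fast exchange the observed linewidth is the
#' population-weighted average of free and bound linewidths, so this slope
#' isolates the bound-state broadening.
#'
#' @param series Data frame with columns `fraction_bound` and `fwhm`
#'   (at least 3 rows spanning a nonzero fraction-bound range).
#' @return A tibble with `slope` (Hz per unit fraction bound), `slope_se`,
#'   `intercept`, `n`.
#' @export
broadening_slope <- function(series) {
  stopifnot(is.data.frame(series))
  if (!all(c("fraction_bound", "fwhm") %in% names(series))) {
    abort("`series` needs columns `fraction_bound` and `fwhm`.")
  }
  if (nrow(series) < 3L) abort("Need at least 3 points for a broadening slope.")
  if (diff(range(series$fraction_bound)) <= 0) {
    abort("All `fraction_bound` values identical: slope is undefined.",
          class = "sp_rank_deficient")
  }
  fit <- lm(fwhm ~ fraction_bound, data = series)
  sm <- suppressWarnings(summary(fit))$coefficients  # exact fits warn benignly
  se <- if (nrow(series) > 2L && is.finite(sm["fraction_bound", "Std. Error"])) {
    sm["fraction_bound", "Std. Error"]
  } else 0
  tibble::tibble(slope = unname(coef(fit)[["fraction_bound"]]),
                 slope_se = se,
                 intercept = unname(coef(fit)[["(Intercept)"]]),
                 n = nrow(series))
}

#' Paramagnetic relaxation rate from paired construct slopes
#'
#' Subtracts the diamagnetic (protein-only) broadening measured with the
#' control construct from the paramagnetic construct's broadening, then
#' converts the Hz slope difference to a rate: R2 = pi * FWHM. Subtracting
#' slopes in Hz and converting is algebraically identical to subtracting
#' rates.
#'
#' @param slope_para,slope_dia Broadening slopes (Hz per unit fraction
#'   bound) for the paramagnetic and diamagnetic constructs at the same
#'   attachment site.
#' @param slope_para_se,slope_dia_se Optional standard errors, propagated in
#'   quadrature.
#' @return A tibble with `r2_para` (s^-1, clipped at 0), `r2_se`, and
#'   `beyond_detection` (`TRUE` when the raw difference was <= 0).
#' @export
paramagnetic_r2 <- function(slope_para, slope_dia,
                            slope_para_se = 0, slope_dia_se = 0) {
  diff_hz <- slope_para - slope_dia
  beyond <- diff_hz <= 0
  if (any(beyond)) {
    warn("Paramagnetic slope <= diamagnetic slope: proton(s) beyond detection radius; rate clipped to 0.")
  }
  tibble::tibble(
    r2_para = pi * pmax(diff_hz, 0),
    r2_se = pi * sqrt(slope_para_se^2 + slope_dia_se^2),
    beyond_detection = beyond
  )
}

#' First-order confidence interval for a Solomon-Bloembergen distance
#'
#' Because \eqn{r \propto R_2^{-1/6}}, a relative rate error maps onto a
#' six-fold smaller relative distance error:
#' \eqn{\sigma_r = r\,\sigma_{R_2}/(6 R_2)}; the 95% CI is
#' \eqn{1.96\,\sigma_r}.
#'
#' @param r Distance (Angstrom).
#' @param r2_para Paramagnetic rate (s^-1).
#' @param r2_se Standard error of the rate (s^-1, >= 0).
#' @return 95% confidence half-width in Angstrom.
#' @export
distance_ci <- function(r, r2_para, r2_se) {
  if (any(r2_se < 0)) abort("`r2_se` must be >= 0.")
  1.96 * r * r2_se / (6 * r2_para)
}

#' Distances from a peak-list table
#'
#' The full relaxometry pipeline on a tidy peak list: compute fraction
#' bound, fit broadening slopes per (proton group, site, construct), pair
#' paramagnetic with diamagnetic slopes, subtract, and invert the
#' Solomon-Bloembergen relation.
#'
#' @param peaks Data frame with columns `construct`
#'   (`"paramagnetic"`/`"diamagnetic"`), `site_id`, `proton_group`,
#'   `enzyme_sites`, `ligand_total` (same molar unit), `fwhm` (Hz). The
#'   diamagnetic control (one site is sufficient) is recycled across sites
#'   if measured at a single site, mirroring the single-control design.
#' @param ctx An [acquisition_context()].
#' @param kd Ligand dissociation constant, same unit as the concentrations,
#'   used to compute fraction bound.
#' @param max_detect Passed to [sb_distance()].
#' @return A tibble, one row per (proton_group, site_id): slopes, `r2_para`,
#'   `r` and `ci95` in Angstrom, and `beyond_detection`.
#' @export
estimate_distances <- function(peaks, ctx, kd, max_detect = 30) {
  need <- c("construct", "site_id", "proton_group", "enzyme_sites",
            "ligand_total", "fwhm")
  if (!all(need %in% names(peaks))) {
    abort(paste("`peaks` must have columns:", paste(need, collapse = ", ")))
  }
  peaks <- dplyr::mutate(
    peaks,
    fraction_bound = fraction_bound(.data$ligand_total, .data$enzyme_sites, kd)
  )
  slopes <- peaks |>
    dplyr::group_by(.data$construct, .data$site_id, .data$proton_group) |>
    dplyr::group_modify(~ broadening_slope(.x)) |>
    dplyr::ungroup()

  para <- dplyr::filter(slopes, .data$construct == "paramagnetic")
  dia <- dplyr::filter(slopes, .data$construct == "diamagnetic")
  if (nrow(dia) == 0L) abort("No diamagnetic control rows in `peaks`.", class = "sp_pairing_error")
  # single-site diamagnetic control serves all sites
  if (length(unique(dia$site_id)) == 1L) {
    dia <- dplyr::select(dia, -"site_id", -"construct")
    joined <- dplyr::left_join(para, dia, by = "proton_group",
                               suffix = c("_para", "_dia"))
  } else {
    joined <- dplyr::left_join(
      para, dplyr::select(dia, -"construct"),
      by = c("site_id", "proton_group"), suffix = c("_para", "_dia"))
  }
  if (anyNA(joined$slope_dia)) {
    abort("Unmatched paramagnetic/diamagnetic series.", class = "sp_pairing_error")
  }
  rates <- paramagnetic_r2(joined$slope_para, joined$slope_dia,
                           joined$slope_se_para, joined$slope_se_dia)
  r <- sb_distance(rates$r2_para, ctx, max_detect = max_detect)
  tibble::tibble(
    proton_group = joined$proton_group,
    site_id = joined$site_id,
    slope_para = joined$slope_para,
    slope_dia = joined$slope_dia,
    r2_para = rates$r2_para,
    r2_se = rates$r2_se,
    r = r,
    ci95 = ifelse(is.na(r), NA_real_, distance_ci(r, rates$r2_para, rates$r2_se)),
    beyond_detection = rates$beyond_detection | is.na(r)
  )
}
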