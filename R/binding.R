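# Equilibrium binding, inhibition, initial-rate and activation models, and
# the ratio analyses built on them.

#' Free ligand at single-site equilibrium
#'
#' Positive root of the mass-action quadratic for E + L <-> EL:
#' free^2 + (E_tot - L_tot + Kd) free - Kd L_tot = 0. Exact (tight-binding)
#' treatment, valid when enzyme and ligand concentrations are comparable.
#'
#' @param L_total,E_total,Kd Concentrations in any one consistent unit
#'   (vectors recycle).
#' @return Free ligand concentration, same unit.
#' @examples
#' free_ligand(50, 25, 0.060)  # ~25: half the ligand is sequestered
#' @export
free_ligand <- function(L_total, E_total, Kd) {
  if (any(L_total < 0) || any(E_total < 0) || any(Kd < 0)) {
    abort("Concentrations and Kd must be >= 0.")
  }
  b <- E_total - L_total + Kd
  free <- (-b + sqrt(b^2 + 4 * Kd * L_total)) / 2
  # Kd = 0 limit: stoichiometric depletion
  n <- length(free)
  kd_v <- rep_len(Kd, n)
  stoich <- pmax(rep_len(L_total, n) - rep_len(E_total, n), 0)
  free[kd_v == 0] <- stoich[kd_v == 0]
  free
}

#' Quadratic (tight-binding) single-site isotherm
#'
#' The closed-form fluorescence model
#' \deqn{I = I_0 - \Delta I\,\frac{(L+E+K_d) - \sqrt{(L+E+K_d)^2 - 4LE}}{2E}}
#' where the quotient is the fraction of sites occupied, solved exactly from
#' mass action rather than assuming free ~ total ligand.
#'
#' @param L_total Total ligand (titrant) concentrations.
#' @param E_total Total binding sites (> 0).
#' @param Kd Dissociation constant (> 0).
#' @param I0 Signal at zero ligand.
#' @param dI Total signal change at saturation.
#' @return Signal values, bounded between `I0` and `I0 - dI`.
#' @export
quadratic_isotherm <- function(L_total, E_total, Kd, I0, dI) {
  if (any(L_total < 0)) abort("`L_total` must be >= 0.")
  .assert_scalar_pos(E_total, "E_total")
  .assert_scalar_pos(Kd, "Kd")
  s <- L_total + E_total + Kd
  disc <- s^2 - 4 * L_total * E_total
  if (any(disc < 0)) abort("Negative discriminant: inputs are inconsistent.")
  I0 - dI * (s - sqrt(disc)) / (2 * E_total)
}

## fit-object scaffolding ------------------------------------------------

.sp_new_fit <- function(subclass, params, model, data, fitted) {
  structure(
    list(params = params, model = model, data = data, fitted = fitted,
         residuals = (if (!is.null(data$.response)) data$.response - fitted else NULL)),
    class = c(subclass, "sp_fit")
  )
}

#' @export
print.sp_fit <- function(x, ...) {
  cat(sprintf("<%s> %s\n", class(x)[1], x$model))
  print(x$params)
  invisible(x)
}

#' @export
tidy.sp_fit <- function(x, ...) x$params

#' @export
glance.sp_fit <- function(x, ...) {
  r <- x$residuals %||% NA_real_
  tibble::tibble(
    sigma = if (all(is.na(r))) NA_real_ else sqrt(sum(r^2) / max(length(r) - nrow(x$params), 1)),
    rss = sum(r^2),
    nobs = length(x$fitted)
  )
}

.coef_tbl <- function(fit) {
  sm <- summary(fit)$coefficients
  tibble::tibble(term = rownames(sm), estimate = unname(sm[, 1]),
                 std.error = unname(sm[, 2]))
}

.nls_ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15, ptol = 1e-15)

#' Fit the quadratic single-site isotherm to a titration
#'
#' Nonlinear least squares for (Kd, I0, dI) with covariance-based standard
#' errors, as used for intrinsic-fluorescence binding titrations where the
#' enzyme concentration is comparable to Kd.
#'
#' @param data Data frame with columns `ligand_total` and `signal`
#'   (>= 5 rows), and optionally a constant `enzyme_sites` column.
#' @param enzyme_sites Total binding-site concentration (same unit as
#'   `ligand_total`); taken from the data column if omitted.
#' @return An object of classes `sp_binding_fit`/`sp_fit`; [tidy()] gives
#'   `Kd`, `I0`, `dI` with standard errors.
#' @export
fit_isotherm <- function(data, enzyme_sites = NULL) {
  stopifnot(is.data.frame(data), all(c("ligand_total", "signal") %in% names(data)))
  if (nrow(data) < 5L) abort("Need at least 5 titration points.")
  E <- enzyme_sites %||% unique(data$enzyme_sites)
  if (length(E) != 1L || !is.finite(E) || E <= 0) {
    abort("`enzyme_sites` must be a single positive concentration.")
  }
  if (sd(data$signal) < 1e-12 * max(abs(data$signal), 1)) {
    abort("Signal does not change over the titration: Kd is unidentifiable.",
          class = "sp_fit_failure")
  }
  df <- data.frame(L = data$ligand_total, y = data$signal)
  i0_0 <- df$y[which.min(df$L)]
  di_0 <- i0_0 - min(df$y)
  if (di_0 <= 0) di_0 <- max(df$y) - min(df$y)
  kd_0 <- stats::median(df$L)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ quadratic_isotherm(L, E, Kd, I0, dI),
      data = df, start = list(Kd = kd_0, I0 = i0_0, dI = di_0),
      lower = c(Kd = .Machine$double.xmin, I0 = -Inf, dI = -Inf),
      control = .nls_ctrl
    ),
    error = function(e) abort(paste("Isotherm fit failed:", conditionMessage(e)),
                              class = "sp_fit_failure")
  )
  params <- .coef_tbl(fit)
  if (abs(params$estimate[params$term == "dI"]) <
      1e-6 * max(abs(df$y), 1)) {
    abort("Fitted signal change is ~0: Kd is unidentifiable.", class = "sp_fit_failure")
  }
  .sp_new_fit("sp_binding_fit", params,
              "quadratic single-site isotherm",
              data.frame(df, .response = df$y), stats::fitted(fit))
}

#' Noncompetitive inhibition at saturating substrate
#'
#' With substrate held at ~100 x Km a noncompetitive inhibitor reduces the
#' rate as \eqn{v/V_{max} = 1/(1 + [I]/(\alpha K_i))}. `alpha = 1` is the
#' pure noncompetitive case.
#'
#' @param I Inhibitor concentration(s).
#' @param Ki Inhibition constant (> 0).
#' @param alpha Optional mixed-inhibition factor (default 1).
#' @return v/Vmax in (0, 1].
#' @export
noncompetitive_rate <- function(I, Ki, alpha = 1) {
  .assert_scalar_pos(Ki, "Ki")
  1 / (1 + I / (alpha * Ki))
}

#' Fit a noncompetitive inhibition curve
#'
#' Least-squares (Ki, scale) for normalized rates versus inhibitor
#' concentration, `scale` absorbing any small error in the Vmax
#' normalization.
#'
#' @param data Data frame with columns `inhibitor` and `v_over_vmax`.
#' @param alpha Fixed mixed-inhibition factor (default 1, pure
#'   noncompetitive).
#' @return `sp_inhibition_fit`/`sp_fit` with terms `Ki` and `scale`.
#' @export
fit_inhibition <- function(data, alpha = 1) {
  stopifnot(is.data.frame(data), all(c("inhibitor", "v_over_vmax") %in% names(data)))
  if (sd(data$v_over_vmax) < 1e-12) {
    abort("Rates do not vary with inhibitor: Ki is unidentifiable.",
          class = "sp_fit_failure")
  }
  df <- data.frame(I = data$inhibitor, y = data$v_over_vmax)
  ki_0 <- df$I[which.min(abs(df$y - 0.5))]
  if (ki_0 <= 0) ki_0 <- stats::median(df$I[df$I > 0])
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ scale / (1 + I / (alpha * Ki)),
      data = df, start = list(Ki = ki_0, scale = max(df$y)),
      lower = c(Ki = .Machine$double.xmin, scale = 0),
      control = .nls_ctrl
    ),
    error = function(e) abort(paste("Inhibition fit failed:", conditionMessage(e)),
                              class = "sp_fit_failure")
  )
  .sp_new_fit("sp_inhibition_fit", .coef_tbl(fit),
              "noncompetitive inhibition (saturating substrate)",
              data.frame(df, .response = df$y), stats::fitted(fit))
}

#' Weighted double-reciprocal Michaelis-Menten fit
#'
#' Fits 1/v versus 1/\[S\] by weighted linear least squares with weights
#' v^4 on the reciprocal residuals -- the classical "(1/v^4)" weighting of
#' double-reciprocal fits. Since
#' \eqn{(1/v - 1/\hat v)^2 \approx (v - \hat v)^2 / v^4}, these weights make
#' the reciprocal-space fit equivalent, to first order, to unweighted least
#' squares on the untransformed velocities, removing the small-velocity
#' bias of a naive Lineweaver-Burk fit.
#'
#' @param data Data frame with columns `substrate` and `velocity`
#'   (per-site rates, e.g. min^-1). Non-positive velocities are excluded
#'   with a warning.
#' @return `sp_mm_fit`/`sp_fit` with terms `Km` and `kcat` (delta-method
#'   standard errors).
#' @export
fit_michaelis_menten <- function(data) {
  stopifnot(is.data.frame(data), all(c("substrate", "velocity") %in% names(data)))
  bad <- data$velocity <= 0
  if (any(bad)) {
    warn(sprintf("Excluding %d non-positive velocity point(s).", sum(bad)))
    data <- data[!bad, , drop = FALSE]
  }
  if (nrow(data) < 3L) abort("Need at least 3 positive-velocity points.")
  df <- data.frame(x = 1 / data$substrate, y = 1 / data$velocity,
                   w = data$velocity^4)
  fit <- lm(y ~ x, data = df, weights = w)
  a <- coef(fit)[["(Intercept)"]]  # 1/kcat
  b <- coef(fit)[["x"]]            # Km/kcat
  V <- vcov(fit)
  kcat <- 1 / a
  km <- b / a
  se_kcat <- sqrt(V[1, 1]) / a^2
  se_km <- abs(km) * sqrt(V[1, 1] / a^2 + V[2, 2] / b^2 - 2 * V[1, 2] / (a * b))
  params <- tibble::tibble(term = c("Km", "kcat"),
                           estimate = c(km, kcat),
                           std.error = c(se_km, se_kcat))
  .sp_new_fit("sp_mm_fit", params,
              "Michaelis-Menten, (1/v^4)-weighted double-reciprocal",
              data.frame(substrate = data$substrate, .response = data$velocity),
              kcat * data$substrate / (km + data$substrate))
}

#' Fit a single-site activation curve
#'
#' Least-squares (OD_initial, dOD, EC50) for
#' \eqn{OD = OD_{initial} + \Delta OD \cdot [X]/(EC_{50} + [X])}, the
#' single-site model for reporter-based receptor-activation titrations.
#'
#' @param data Data frame with columns `effector` and `od` (>= 5 rows).
#' @param od_col Name of the response column (default `"od"`).
#' @return `sp_ec50_fit`/`sp_fit` with terms `EC50`, `OD_initial`, `dOD`.
#'   A warning is raised when the fitted EC50 is not bracketed by the data.
#' @export
fit_ec50 <- function(data, od_col = "od") {
  stopifnot(is.data.frame(data), all(c("effector", od_col) %in% names(data)))
  if (nrow(data) < 5L) abort("Need at least 5 titration points.")
  df <- data.frame(C = data$effector, y = data[[od_col]])
  od0 <- min(df$y)
  dod0 <- max(df$y) - od0
  pos <- df$C[df$C > 0]
  ec0 <- if (length(pos)) exp(mean(log(range(pos)))) else 1
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ OD_initial + dOD * C / (EC50 + C),
      data = df, start = list(EC50 = ec0, OD_initial = od0, dOD = dod0),
      lower = c(EC50 = .Machine$double.xmin, OD_initial = -Inf, dOD = -Inf),
      control = .nls_ctrl
    ),
    error = function(e) abort(paste("EC50 fit failed:", conditionMessage(e)),
                              class = "sp_fit_failure")
  )
  params <- .coef_tbl(fit)
  ec <- params$estimate[params$term == "EC50"]
  if (length(pos) && (ec < min(pos) || ec > max(pos))) {
    warn("Fitted EC50 lies outside the titrated range; expect a wide standard error.")
  }
  .sp_new_fit("sp_ec50_fit", params, "single-site activation",
              data.frame(df, .response = df$y), stats::fitted(fit))
}

## ratio analyses --------------------------------------------------------

#' Fold effect of a variant on an inhibition constant
#'
#' Ki(variant) / Ki(reference), rounded to significant figures. Units are
#' metadata: the ratio is unit-invariant, but mismatched unit labels raise
#' an error rather than being silently rescaled.
#'
#' @param ki_variant,ki_reference Positive inhibition constants.
#' @param sig_figs Significant figures for the reported ratio (default 2).
#' @param units_variant,units_reference Optional unit labels; if both are
#'   given they must agree.
#' @return The rounded ratio.
#' @examples
#' fold_effect(6.8, 0.060, sig_figs = 3)  # 113
#' @export
fold_effect <- function(ki_variant, ki_reference, sig_figs = 2,
                        units_variant = NULL, units_reference = NULL) {
  .assert_scalar_pos(ki_variant, "ki_variant")
  .assert_scalar_pos(ki_reference, "ki_reference")
  if (!is.null(units_variant) && !is.null(units_reference) &&
      units_variant != units_reference) {
    abort(sprintf("Unit mismatch: '%s' vs '%s'.", units_variant, units_reference),
          class = "sp_unit_mismatch")
  }
  ratio <- ki_variant / ki_reference
  # half-away-from-zero rounding, the convention of printed tables
  # (signif() rounds half to even: 10.5 would become 10, not 11)
  mag <- 10^(sig_figs - 1 - floor(log10(ratio)))
  floor(ratio * mag + 0.5) / mag
}

#' Thermodynamic coupling between two ligands
#'
#' How much a bound partner tightens a ligand's affinity:
#' ratio = Kd(without partner) / Kd(with partner), with coupling free energy
#' \eqn{\Delta\Delta G = RT \ln(\mathrm{ratio})}. By thermodynamic-cycle
#' closure the ratio is the same whichever ligand is called the partner.
#'
#' @param kd_without_partner,kd_with_partner Positive dissociation
#'   constants, same unit.
#' @param temperature Kelvin (default 298).
#' @return A tibble with `ratio` and `ddG_kJ_mol`.
#' @examples
#' coupling_ratio(750, 62)  # ~12-fold, ~6.2 kJ/mol
#' @export
coupling_ratio <- function(kd_without_partner, kd_with_partner, temperature = 298) {
  .assert_scalar_pos(kd_without_partner, "kd_without_partner")
  .assert_scalar_pos(kd_with_partner, "kd_with_partner")
  ratio <- kd_without_partner / kd_with_partner
  tibble::tibble(ratio = ratio,
                 ddG_kJ_mol = .sp_const$R_gas * temperature * log(ratio))
}

#' Order-of-binding verdict from apparent affinities
#'
#' If ligand binding were obligatorily ordered (partner first), raising a
#' saturating partner concentration n-fold would appear to tighten the
#' ligand's affinity n-fold; for random binding the apparent Kd is
#' unchanged. The verdict compares the apparent-Kd ratio to 1 and to the
#' partner ratio within a tolerance band.
#'
#' @param kd_app_low,kd_app_high Apparent Kd at the lower and higher
#'   partner concentration (both saturating).
#' @param partner_ratio Fold difference between the partner concentrations
#'   (> 1).
#' @param band Tolerance band, fold (default 2: ratios within 2-fold of a
#'   benchmark match it).
#' @return `"random"`, `"ordered"`, or `"indeterminate"`.
#' @examples
#' order_of_binding(62, 62, 10)   # "random"
#' order_of_binding(400, 40, 10)  # "ordered"
#' @export
order_of_binding <- function(kd_app_low, kd_app_high, partner_ratio, band = 2) {
  .assert_scalar_pos(kd_app_low, "kd_app_low")
  .assert_scalar_pos(kd_app_high, "kd_app_high")
  if (partner_ratio <= 1) abort("`partner_ratio` must exceed 1.")
  ratio <- kd_app_low / kd_app_high
  within <- function(x, target) x >= target / band && x <= target * band
  if (within(ratio, 1)) "random"
  else if (within(ratio, partner_ratio)) "ordered"
  else "indeterminate"
}
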