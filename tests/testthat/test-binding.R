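# Equilibrium binding, inhibition, kinetics, activation, and the ratio
# analyses.

test_that("the quadratic isotherm matches a numeric mass-action solver", {
  E <- 15; Kd <- 62; I0 <- 1; dI <- 0.6
  L <- c(0, 1, 5, 12.5, 40, 100, 400, 1000, 5000)
  got <- quadratic_isotherm(L, E, Kd, I0, dI)
  # oracle: root-find the free-ligand equation, then mass action
  oracle <- vapply(L, function(l) {
    if (l == 0) return(I0)
    f <- uniroot(function(free) free + E * free / (Kd + free) - l,
                 c(0, l), tol = 1e-14)$root
    I0 - dI * (f / (Kd + f))
  }, numeric(1))
  expect_equal(got, oracle, tolerance = 1e-9)

  expect_equal(quadratic_isotherm(0, E, Kd, I0, dI), I0)
  expect_equal(quadratic_isotherm(1e9, E, Kd, I0, dI), I0 - dI, tolerance = 1e-4)
  # stoichiometric limit: occupancy approaches L/E below saturation
  occ <- (I0 - quadratic_isotherm(5, E, 1e-9, I0, dI)) / dI
  expect_equal(occ, 5 / 15, tolerance = 1e-6)
})

test_that("free ligand solves mass action exactly", {
  expect_equal(free_ligand(50, 0, 0.06), 50)
  # conservation: free + bound = total
  free <- free_ligand(50, 25, 0.06)
  bound <- 25 * free / (0.06 + free)
  expect_equal(free + bound, 50, tolerance = 1e-12)
  # bisection oracle
  oracle <- uniroot(function(f) f + 25 * f / (0.06 + f) - 50,
                    c(0, 50), tol = 1e-14)$root
  expect_equal(free, oracle, tolerance = 1e-9)
  # the canonical NMR condition check: free ligand exceeds Ki ~420-fold
  expect_equal(signif(free / 0.06, 2), 420)
})

test_that("isotherm fits recover generating constants exactly on clean data", {
  d1 <- simulate_titration(sp_grid_low, 15, 62)
  f1 <- tidy(fit_isotherm(d1))
  expect_equal(f1$estimate[f1$term == "Kd"], 62, tolerance = 1e-8)

  d2 <- simulate_titration(sp_grid_high, 50, 750)
  f2 <- tidy(fit_isotherm(d2))
  expect_equal(f2$estimate[f2$term == "Kd"], 750, tolerance = 1e-8)

  # flat signal: unidentifiable
  flat <- simulate_titration(sp_grid_low, 15, 62, di = 0)
  expect_error(fit_isotherm(flat), class = "sp_fit_failure")
})

test_that("noncompetitive inhibition behaves and fits as 1/(1 + I/Ki)", {
  expect_equal(noncompetitive_rate(0, 0.06), 1)
  expect_equal(noncompetitive_rate(0.06, 0.06), 0.5)
  d <- simulate_inhibition(0.060)
  f <- tidy(fit_inhibition(d))
  expect_equal(f$estimate[f$term == "Ki"], 0.060, tolerance = 1e-8)
  flat <- tibble::tibble(inhibitor = 1:6, v_over_vmax = rep(0.8, 6))
  expect_error(fit_inhibition(flat), class = "sp_fit_failure")
})

test_that("weighted double-reciprocal MM fitting matches a nonlinear oracle", {
  d <- simulate_kinetics(4.0, 150)
  f <- tidy(fit_michaelis_menten(d))
  expect_equal(f$estimate[f$term == "Km"], 4.0, tolerance = 1e-8)
  expect_equal(f$estimate[f$term == "kcat"], 150, tolerance = 1e-8)

  # oracle: direct nonlinear MM fit agrees on noise-free data
  nls_fit <- nls(velocity ~ kcat * substrate / (km + substrate), data = d,
                 start = list(km = 2, kcat = 100),
                 control = nls.control(maxiter = 200, scaleOffset = 1))
  expect_equal(f$estimate, unname(coef(nls_fit)[c("km", "kcat")]),
               tolerance = 1e-6)

  # saturation: v -> kcat
  sat <- simulate_kinetics(4.0, 150, substrate = 4000)
  expect_equal(sat$velocity, 150, tolerance = 1e-2)

  # non-positive velocities are excluded with a warning
  bad <- rbind(d, tibble::tibble(substrate = 1, velocity = 0))
  expect_warning(fb <- fit_michaelis_menten(bad), "Excluding")
  expect_equal(tidy(fb)$estimate[1], 4.0, tolerance = 1e-8)
})

test_that("activation fits recover EC50 and flag non-bracketing designs", {
  d <- simulate_activation(38)
  f <- tidy(fit_ec50(d))
  expect_equal(f$estimate[f$term == "EC50"], 38, tolerance = 1e-8)
  # model endpoints
  expect_equal(simulate_activation(38, effector = 0)$od, 0.05)
  expect_equal(simulate_activation(38, effector = 38)$od, 0.05 + 0.5)
  # titration stopping far below EC50
  low <- simulate_activation(5000, effector = c(0.5, 1, 2, 4, 8, 16))
  expect_warning(fit_ec50(low), "outside the titrated range")
})

test_that("noisy replicate fits stay within their standard errors", {
  hits <- 0
  for (k in 1:30) {
    f <- tidy(fit_isotherm(simulate_titration(sp_grid_low, 15, 62,
                                              cv = 0.03, seed = k)))
    est <- f$estimate[f$term == "Kd"]; se <- f$std.error[f$term == "Kd"]
    if (abs(est - 62) <= 3 * se) hits <- hits + 1
  }
  expect_gte(hits, 28)  # within 3 SE nearly always
})

test_that("fold effects reproduce the published mutant ratios", {
  expect_equal(fold_effect(6.8, 0.060, sig_figs = 3), 113)
  expect_equal(fold_effect(0.73, 0.060), 12)
  expect_equal(fold_effect(0.63, 0.060), 11)
  expect_equal(fold_effect(0.34, 0.060), 5.7)
  expect_equal(fold_effect(5, 5), 1.0)
  expect_error(fold_effect(1, 1, units_variant = "nM", units_reference = "uM"),
               class = "sp_unit_mismatch")
})

test_that("coupling ratios close the thermodynamic cycle", {
  cpl <- coupling_ratio(750, 62)
  expect_equal(signif(cpl$ratio, 3), 12.1)
  expect_equal(cpl$ddG_kJ_mol, 8.314462618e-3 * 298 * log(750 / 62),
               tolerance = 1e-9)
  expect_equal(coupling_ratio(5, 5)$ratio, 1)
  expect_equal(coupling_ratio(5, 5)$ddG_kJ_mol, 0)

  # cycle closure: the partner's coupling (13 +- 1 over 0.98 +- 0.10) must
  # agree with this ligand's (750 +- 27 over 62 +- 2) within propagated error
  r_a <- 13 / 0.98
  se_a <- r_a * sqrt((1 / 13)^2 + (0.10 / 0.98)^2)
  r_b <- 750 / 62
  se_b <- r_b * sqrt((27 / 750)^2 + (2 / 62)^2)
  expect_lt(abs(r_a - r_b), 1.96 * sqrt(se_a^2 + se_b^2))
})

test_that("order-of-binding verdicts follow the tolerance band", {
  expect_equal(order_of_binding(62, 62, 10), "random")
  expect_equal(order_of_binding(400, 40, 10), "ordered")
  expect_equal(order_of_binding(350, 100, 10), "indeterminate")
  # boundary of the default 2-fold band
  expect_equal(order_of_binding(200, 100, 10), "random")
  expect_error(order_of_binding(1, 1, 0.5), "exceed 1")
})
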