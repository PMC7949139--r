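# Trilateration, ellipsoids, coverage, and feasibility of the published
# distance table.

test_that("three-sphere trilateration returns mirror candidates exactly", {
  s <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0))
  p <- c(3, 4, 5)
  d <- sqrt(colSums((t(s) - p)^2))
  cand <- trilaterate(s, d)
  expect_equal(nrow(cand), 2)
  got <- cand[order(cand$z), c("x", "y", "z")]
  expect_equal(as.numeric(got[2, ]), c(3, 4, 5), tolerance = 1e-9)
  expect_equal(as.numeric(got[1, ]), c(3, 4, -5), tolerance = 1e-9)
  expect_lt(max(cand$residual), 1e-9)
})

test_that("trilateration is exact on random noise-free instances", {
  set.seed(41)
  n_done <- 0
  while (n_done < 100) {
    s <- matrix(rnorm(9, 0, 15), 3, 3)
    e1 <- s[2, ] - s[1, ]; e2 <- s[3, ] - s[1, ]
    cr <- c(e1[2] * e2[3] - e1[3] * e2[2],
            e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    if (sqrt(sum(cr^2)) < 50) next  # skip near-degenerate site triples
    p <- rnorm(3, 0, 10)
    d <- sqrt(colSums((t(s) - p)^2))
    cand <- trilaterate(s, d)
    expect_gt(nrow(cand), 0)
    err <- min(sqrt((cand$x - p[1])^2 + (cand$y - p[2])^2 + (cand$z - p[3])^2))
    expect_lt(err, 1e-6)
    expect_lt(attr(cand, "residual"), 1e-6)
    n_done <- n_done + 1
  }
})

test_that("degenerate and infeasible trilateration inputs are reported", {
  collinear <- rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0))
  expect_error(trilaterate(collinear, c(5, 5, 5)), class = "sp_geometry_error")

  # spheres far too small to intersect
  s <- rbind(c(0, 0, 0), c(30, 0, 0), c(0, 30, 0))
  expect_warning(cand <- trilaterate(s, c(1, 1, 1), tolerance = 0.5))
  expect_equal(nrow(cand), 0)
  expect_gt(attr(cand, "residual"), 0.5)
})

test_that("more than three sites are resolved by least squares", {
  set.seed(7)
  s <- rbind(c(0, 0, 0), c(20, 0, 0), c(0, 20, 0), c(5, 5, 18))
  p <- c(6, 7, 4)
  d <- sqrt(colSums((t(s) - p)^2))
  cand <- trilaterate(s, d)
  expect_equal(nrow(cand), 1)
  expect_equal(as.numeric(cand[1, c("x", "y", "z")]), p, tolerance = 1e-6)
})

test_that("mirror disambiguation prefers the less buried candidate", {
  # dense blob centred at (0,0,-6): the z < 0 candidate is buried
  set.seed(2)
  blob <- data.frame(x = rnorm(300, 0, 3), y = rnorm(300, 0, 3),
                     z = rnorm(300, -6, 3))
  cand <- tibble::tibble(x = c(0, 0), y = c(0, 0), z = c(6, -6),
                         residual = c(0, 0))
  pick <- disambiguate(cand, blob)
  expect_equal(unname(pick["z"]), 6)
  rep_tbl <- attr(pick, "candidates")
  expect_true(rep_tbl$chosen[rep_tbl$z == 6])
  expect_equal(nrow(rep_tbl), 2)

  # single candidate passes through unchanged
  one <- cand[1, ]
  expect_equal(as.numeric(disambiguate(one, blob)), c(0, 0, 6))

  # symmetric scaffold: tie broken toward the centroid side
  sym <- expand.grid(x = seq(-4, 4, 2), y = seq(-4, 4, 2), z = 0)
  shifted <- tibble::tibble(x = c(10, 30), y = 0, z = 0, residual = 0)
  pick2 <- disambiguate(shifted, sym)
  expect_equal(unname(pick2["x"]), 10)
})

test_that("constraint ellipsoids have sigma semi-axes along site-to-centre lines", {
  s <- rbind(c(20, 0, 0), c(0, 20, 0), c(0, 0, 20))
  ctr <- c(0, 0, 0)
  sig <- c(1.5, 2, 1.5)
  e <- build_ellipsoid("H4", ctr, s, sig)
  expect_equal(e$semi_axes, sig)
  # axis i points from site i toward the centre
  expect_equal(e$axes[, 1], c(-1, 0, 0), tolerance = 1e-12)

  # centre norm 0; surface point along an axis has norm 1
  expect_equal(ellipsoid_norm(e, ctr), 0)
  expect_equal(ellipsoid_norm(e, ctr + c(-1.5, 0, 0)), 1, tolerance = 1e-12)
  # equal sigmas on orthogonal sites give a sphere
  e_s <- build_ellipsoid("g", ctr, s, c(2, 2, 2))
  dirs <- rbind(c(1, 1, 1) / sqrt(3), c(1, -1, 0) / sqrt(2))
  for (i in 1:2) {
    expect_equal(ellipsoid_norm(e_s, ctr + 2 * dirs[i, ]), 1, tolerance = 1e-9)
  }
  expect_error(build_ellipsoid("g", ctr, s, c(1, 0, 1)), "positive")
})

test_that("chord midpoint targets pairs and passes singletons through", {
  expect_equal(chord_midpoint_target(rbind(c(0, 0, 0), c(2, 0, 0))), c(1, 0, 0))
  expect_equal(chord_midpoint_target(rbind(c(2, 0, 0), c(0, 0, 0))), c(1, 0, 0))
  expect_equal(chord_midpoint_target(c(4, 5, 6)), c(4, 5, 6))
  expect_error(chord_midpoint_target(matrix(0, 3, 3)), "multiplicity")
})

test_that("coverage fraction matches a brute-force count", {
  set.seed(9)
  lobe1 <- matrix(rnorm(150 * 3, 0, 4), ncol = 3)
  lobe2 <- sweep(matrix(rnorm(150 * 3, 0, 4), ncol = 3), 2, c(60, 0, 0), `+`)
  scaffold <- as.data.frame(rbind(lobe1, lobe2))
  names(scaffold) <- c("x", "y", "z")
  site <- matrix(c(0, 0, 0), 1, 3)

  # with the exposure heuristic disabled, every atom counts as surface and
  # the oracle is an exhaustive distance check
  got <- coverage_fraction(scaffold, site, radius = 25, max_neighbors = Inf)
  brute <- mean(sqrt(scaffold$x^2 + scaffold$y^2 + scaffold$z^2) <= 25)
  expect_equal(got, brute)
  expect_equal(coverage_fraction(scaffold, site, radius = 1e4), 1.0)
  expect_equal(coverage_fraction(scaffold, site, radius = 0), 0.0)
  expect_error(coverage_fraction(scaffold[0, ], site), class = "sp_geometry_error")
})

test_that("perturbed distances move the centre within the conditioned bound", {
  # first-order: delta_centre = A^-T delta_r, so |delta_centre| is bounded
  # by ||A^-1|| times the ellipsoid diagonal (equality to half the diagonal
  # when the site directions are orthogonal)
  set.seed(12)
  n_done <- 0
  while (n_done < 25) {
    s <- t(vapply(1:3, function(i) { v <- rnorm(3); 23 * v / sqrt(sum(v^2)) },
                  numeric(3)))
    p <- rnorm(3, 0, 6)
    e1 <- s[2, ] - s[1, ]; e2 <- s[3, ] - s[1, ]
    cr <- c(e1[2] * e2[3] - e1[3] * e2[2],
            e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    if (sqrt(sum(cr^2)) < 400) next
    d <- sqrt(colSums((t(s) - p)^2))
    sig <- runif(3, 0.3, 1.0)
    dr <- runif(3, -1, 1) * sig
    cand <- trilaterate(s, d + dr, tolerance = 10)
    if (nrow(cand) == 0) next
    shift <- min(sqrt((cand$x - p[1])^2 + (cand$y - p[2])^2 + (cand$z - p[3])^2))
    ell <- build_ellipsoid("g", p, s, sig)
    cond <- norm(ell$Ainv, type = "2")
    expect_lt(shift, cond * 2 * sqrt(sum(sig^2)) + 1e-6)
    n_done <- n_done + 1
  }
})

test_that("the published distance table embeds with residuals inside its CIs", {
  emb <- embed_distance_table(sp_published_distances)
  expect_lt(emb$rms_residual, 1e-4)
  # per-proton trilateration residuals are far inside the printed 95% CIs
  expect_true(all(emb$per_proton$residual < apply(sp_published_ci, 1, min)))
  # the embedded sites are a genuine non-degenerate triangle
  seps <- dist(emb$sites)
  expect_true(all(seps > 5))
})
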