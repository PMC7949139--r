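# Ligand model, restraint/steric energies, pose optimization, clustering.

# ellipsoids built from a pose's own group targets, with measured per-site
# effective distances attached
sp_ellipsoids_from_pose <- function(pose, sites, sigma = 0.4) {
  lig <- pose$ligand
  lapply(names(lig$groups), function(g) {
    idx <- match(lig$groups[[g]], lig$atoms$name)
    coords <- pose$xyz[idx, , drop = FALSE]
    ctr <- colMeans(coords)
    dists <- vapply(seq_len(nrow(sites)), function(j) {
      ri <- sqrt(colSums((t(coords) - sites[j, ])^2))
      (mean(ri^-6))^(-1 / 6)
    }, numeric(1))
    build_ellipsoid(g, ctr, sites, sigmas = rep(sigma, 3), distances = dists)
  })
}

sp_sites <- rbind(c(25, 0, 8), c(-12, 21, 8), c(-12, -21, 8))
sp_no_scaffold <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0))

test_that("the ligand model has the expected topology and symmetry groups", {
  lig <- build_ligand()
  expect_equal(nrow(lig$atoms), 22)
  expect_equal(length(lig$heavy), 15)
  expect_equal(vapply(lig$groups, length, integer(1)),
               c("H4" = 1L, "H3 5" = 2L, "H2' 6'" = 2L, "H3' 5'" = 2L))
  # dihedral rotation moves only ring B atoms
  p0 <- make_pose(lig, rep(0, 7))
  p1 <- make_pose(lig, c(0, 0, 0, 0, 0, 0, 0.8))
  moved <- rowSums((p0$xyz - p1$xyz)^2) > 1e-16
  expect_true(all(which(moved) %in% lig$ring_b))
  # bond-length preservation under an arbitrary pose (rigid rings)
  ca <- which(lig$atoms$name %in% paste0("C", 1:6))
  d0 <- dist(p0$xyz[ca, ])
  p2 <- make_pose(lig, c(3, -2, 5, 0.7, -0.3, 0.2, 1.1))
  expect_equal(as.numeric(dist(p2$xyz[ca, ])), as.numeric(d0), tolerance = 1e-9)
})

test_that("pose RMSD respects translation and ring-flip equivalence", {
  lig <- build_ligand()
  a <- make_pose(lig, c(1, 2, 3, 0.2, 0.3, 0.1, 0.4))
  expect_equal(pose_rmsd(a, a), 0)
  b <- make_pose(lig, c(4, 2, 3, 0.2, 0.3, 0.1, 0.4))
  expect_equal(pose_rmsd(a, b), 3.0, tolerance = 1e-9)
  # flipping ring B by pi about the long axis is chemically invisible
  flip <- make_pose(lig, c(1, 2, 3, 0.2, 0.3, 0.1, 0.4 + pi))
  expect_lt(pose_rmsd(a, flip), 1e-9)
  # mismatched atom sets are an error
  lig2 <- build_ligand()
  lig2$atoms$name[1] <- "XX"
  expect_error(pose_rmsd(a, make_pose(lig2, a$par)), "atom sets")
})

test_that("restraint energy is flat-bottomed with the documented penalty", {
  lig <- build_ligand()
  pose <- make_pose(lig, rep(0, 7))
  ells <- sp_ellipsoids_from_pose(pose, sp_sites, sigma = 1)
  rs <- restraint_set(ells)
  expect_equal(restraint_energy(pose, rs), 0)  # targets at ellipsoid centres

  # single group 1 A beyond the surface along a principal axis: 0.5*k*1^2.
  # Constructed with orthogonal axis directions so the excess is exactly 1.
  p_h4 <- pose$xyz[match("H4", lig$atoms$name), ]
  ctr <- p_h4 - c(2, 0, 0)  # sigma 1 + 1 A excess along +x
  ortho_sites <- rbind(ctr - c(20, 0, 0), ctr - c(0, 20, 0), ctr - c(0, 0, 20))
  shifted <- build_ellipsoid("H4", ctr, ortho_sites, c(1, 1, 1))
  rs1 <- restraint_set(list(shifted), force_constant = 50)
  expect_equal(restraint_energy(pose, rs1), 25, tolerance = 1e-9)
  rs_lin <- restraint_set(list(shifted), force_constant = 50, force_form = "linear")
  expect_equal(restraint_energy(pose, rs_lin), 50, tolerance = 1e-9)

  # r6 mode: effective distances measured from the pose itself give zero
  rs_r6 <- restraint_set(ells, pair_mode = "r6_average")
  expect_equal(restraint_energy(pose, rs_r6), 0)
  # the r6-effective distance of an equal-distance pair is that distance:
  # offsetting one observation by sigma + 1 costs 0.5*k*1^2 per site term
  pair <- ells[[2]]
  stopifnot(pair$group_id == "H3 5")
  idx <- match(lig$groups[["H3 5"]], lig$atoms$name)
  coords <- pose$xyz[idx, , drop = FALSE]
  perturbed <- build_ellipsoid("H3 5", pair$center, pair$sites, pair$semi_axes,
                               distances = pair$distances + c(pair$semi_axes[1] + 1, 0, 0))
  rs_p <- restraint_set(list(perturbed), force_constant = 50, pair_mode = "r6_average")
  expect_equal(restraint_energy(pose, rs_p), 25, tolerance = 1e-6)

  # unmapped group
  bogus <- build_ellipsoid("H9", c(0, 0, 0), sp_sites, c(1, 1, 1))
  expect_error(restraint_energy(pose, restraint_set(list(bogus))),
               class = "sp_config_error")
  # r6 mode demands distances
  no_d <- build_ellipsoid("H3 5", pair$center, pair$sites, pair$semi_axes)
  expect_error(restraint_set(list(no_d), pair_mode = "r6_average"),
               class = "sp_config_error")
})

test_that("steric energy matches a naive pairwise loop", {
  lig <- build_ligand()
  pose <- make_pose(lig, c(0, 0, 30, 0.3, 0.1, 0.2, 0))
  set.seed(6)
  scaffold <- data.frame(x = rnorm(120, 0, 6), y = rnorm(120, 0, 6),
                         z = rnorm(120, 26, 6), element = "C")
  got <- steric_energy(pose, scaffold, c_const = 10)
  # independent brute-force double loop
  brute <- 0
  heavy <- pose$xyz[lig$heavy, ]
  lr <- c(C = 1.70, Cl = 1.75, O = 1.52)[lig$atoms$element[lig$heavy]]
  for (i in seq_len(nrow(heavy))) {
    for (j in seq_len(nrow(scaffold))) {
      dd <- sqrt(sum((heavy[i, ] - c(scaffold$x[j], scaffold$y[j], scaffold$z[j]))^2))
      ov <- unname(lr[i]) + 1.70 - dd
      if (ov > 0) brute <- brute + 10 * ov^2
    }
  }
  expect_gt(got, 0)
  expect_equal(got, brute, tolerance = 1e-9)

  # ligand in solvent: zero
  far <- make_pose(lig, c(0, 0, 500, 0, 0, 0, 0))
  expect_equal(steric_energy(far, scaffold), 0)

  # one atom overlapping by exactly 1 A contributes c
  o4 <- pose$xyz[match("O4'", lig$atoms$name), ]
  # direction pointing away from all other ligand atoms
  ctr <- colMeans(pose$xyz)
  dir <- (o4 - ctr) / sqrt(sum((o4 - ctr)^2))
  probe <- data.frame(x = o4[1] + dir[1] * (1.52 + 1.70 - 1),
                      y = o4[2] + dir[2] * (1.52 + 1.70 - 1),
                      z = o4[3] + dir[3] * (1.52 + 1.70 - 1), element = "C")
  expect_equal(steric_energy(pose, probe, c_const = 10), 10, tolerance = 1e-9)
})

test_that("pose optimization is deterministic and returns clean starts unchanged", {
  lig <- build_ligand()
  pose <- make_pose(lig, rep(0, 7))
  ells <- sp_ellipsoids_from_pose(pose, sp_sites, sigma = 2)
  rs <- restraint_set(ells)
  # already satisfied, no clashes: returned unchanged at objective 0
  out <- optimize_pose(pose, rs, sp_no_scaffold, seed = 3)
  expect_equal(out$objective, 0)
  expect_equal(out$xyz, pose$xyz)

  # determinism from a displaced start
  start <- make_pose(lig, c(5, -4, 3, 0.5, 0.2, -0.3, 0.6))
  o1 <- optimize_pose(start, rs, sp_no_scaffold, seed = 11)
  o2 <- optimize_pose(start, rs, sp_no_scaffold, seed = 11)
  expect_identical(o1$xyz, o2$xyz)

  # the reported objective decomposes exactly into its two terms
  expect_equal(o1$objective,
               restraint_energy(o1, rs) + steric_energy(o1, sp_no_scaffold),
               tolerance = 1e-12)
})

test_that("restrained optimization recovers a planted pose from a distant start", {
  lig <- build_ligand()
  true_pose <- make_pose(lig, c(2, -1, 14, 0.5, 0.2, 0.3, 0.3))
  ells <- sp_ellipsoids_from_pose(true_pose, sp_sites, sigma = 0.4)
  rs <- restraint_set(ells, pair_mode = "r6_average")
  start <- make_pose(lig, true_pose$par + c(4, -4, 5, 0.6, -0.5, 0.4, 0.5))
  expect_gt(pose_rmsd(start, true_pose), 8)
  opt <- optimize_pose(start, rs, sp_no_scaffold, seed = 11)
  expect_lte(pose_rmsd(opt, true_pose), 2.0)
})

test_that("multistart docking converges and clusters to a single solution", {
  lig <- build_ligand()
  true_pose <- make_pose(lig, c(2, -1, 14, 0.5, 0.2, 0.3, 0.3))
  ells <- sp_ellipsoids_from_pose(true_pose, sp_sites, sigma = 0.4)
  rs <- restraint_set(ells, pair_mode = "r6_average")
  ens <- dock_ensemble(lig, rs, sp_no_scaffold, n_starts = 6, seed = 17)
  expect_length(ens$poses, 6)
  expect_lt(max(ens$objectives) - min(ens$objectives), 1.0)
  rep1 <- cluster_poses(ens)
  expect_equal(rep1$n_clusters, 1)
  # different master seed, same cluster structure
  ens2 <- dock_ensemble(lig, rs, sp_no_scaffold, n_starts = 6, seed = 99)
  expect_equal(cluster_poses(ens2)$n_clusters, 1)
  # reproducibility of the whole ensemble
  ens3 <- dock_ensemble(lig, rs, sp_no_scaffold, n_starts = 6, seed = 17)
  expect_identical(ens$objectives, ens3$objectives)
})

test_that("greedy clustering separates distinct pose families", {
  lig <- build_ligand()
  a <- make_pose(lig, rep(0, 7)); a$objective <- 1
  b <- make_pose(lig, c(0.2, 0, 0, 0, 0, 0, 0)); b$objective <- 2
  c_ <- make_pose(lig, c(10, 0, 0, 0, 0, 0, 0)); c_$objective <- 3
  ens <- structure(list(poses = list(a, b, c_), objectives = c(1, 2, 3),
                        seeds = 1:3), class = "sp_pose_ensemble")
  rep_ <- cluster_poses(ens, cutoff = 2.0)
  expect_equal(rep_$n_clusters, 2)
  expect_equal(rep_$assignments$cluster, c(1, 1, 2))
  # intra-cluster RMSD to representative never exceeds the cutoff
  expect_true(all(rep_$assignments$rmsd_to_rep <= 2.0))
  expect_equal(representative_pose(ens, rep_, 1)$objective, 1)

  same <- structure(list(poses = list(a, a, a), objectives = c(1, 1, 1),
                         seeds = 1:3), class = "sp_pose_ensemble")
  expect_equal(cluster_poses(same)$n_clusters, 1)
})

test_that("converged poses stay put when the restraints are removed", {
  # mirrors the published control: no structural change on releasing the
  # distance constraints, because the pose sits in a zero-penalty basin
  lig <- build_ligand()
  true_pose <- make_pose(lig, c(2, -1, 14, 0.5, 0.2, 0.3, 0.3))
  ells <- sp_ellipsoids_from_pose(true_pose, sp_sites, sigma = 0.4)
  rs <- restraint_set(ells, pair_mode = "r6_average")
  start <- make_pose(lig, true_pose$par + c(3, 2, -3, 0.3, 0.3, -0.2, 0.3))
  opt <- optimize_pose(start, rs, sp_no_scaffold, seed = 4)
  # release: huge ellipsoids accept any pose, so re-optimization returns
  # the converged pose unchanged
  released <- restraint_set(sp_ellipsoids_from_pose(opt, sp_sites, sigma = 100))
  re <- optimize_pose(opt, released, sp_no_scaffold, seed = 5)
  expect_equal(re$xyz, opt$xyz)
})
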