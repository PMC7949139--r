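# Restrained rigid-body (+ one dihedral) pose optimization: a desk-scale
# surrogate for restrained MD docking. The restraint geometry, not a force
# field, determines the pose; sterics enter only as a soft-sphere penalty.

#' Bundle constraint ellipsoids into a restraint set
#'
#' @param ellipsoids List of [build_ellipsoid()] objects (one per proton
#'   group); names default to their `group_id`s.
#' @param force_constant Restoring force constant k, kJ mol^-1 per Angstrom
#'   of surface excess (default 50). With the default harmonic form the
#'   energy is 0.5 * k * excess^2 (the conventional reading of a
#'   "kJ mol^-1 A^-1" restraint constant); `force_form = "linear"` gives the
#'   literal linear-force energy k * excess.
#' @param pair_mode How multiplicity-2 proton groups are restrained:
#'   `"chord_midpoint"` (default) restrains the midpoint of the chord
#'   connecting the pair to the group's ellipsoid; `"r6_average"` restrains,
#'   per site, the (1/r^6)-weighted effective distance
#'   \eqn{((r_1^{-6}+r_2^{-6})/2)^{-1/6}} to the measured distance with a
#'   flat bottom of half-width sigma. Singleton groups always use their
#'   ellipsoid. The r6 mode requires ellipsoids built with `distances`.
#' @param force_form `"harmonic"` (default) or `"linear"` (see above).
#' @return An object of class `sp_restraints`.
#' @export
restraint_set <- function(ellipsoids, force_constant = 50,
                          pair_mode = c("chord_midpoint", "r6_average"),
                          force_form = c("harmonic", "linear")) {
  pair_mode <- match.arg(pair_mode)
  force_form <- match.arg(force_form)
  .assert_scalar_pos(force_constant, "force_constant")
  stopifnot(length(ellipsoids) >= 1L,
            all(vapply(ellipsoids, inherits, logical(1), "sp_ellipsoid")))
  if (is.null(names(ellipsoids))) {
    names(ellipsoids) <- vapply(ellipsoids, `[[`, character(1), "group_id")
  }
  if (pair_mode == "r6_average" &&
      any(vapply(ellipsoids, function(e) is.null(e$distances), logical(1)))) {
    abort("r6_average mode needs ellipsoids carrying measured `distances`.",
          class = "sp_config_error")
  }
  structure(list(ellipsoids = ellipsoids, force_constant = force_constant,
                 pair_mode = pair_mode, force_form = force_form),
            class = "sp_restraints")
}

.penalty <- function(excess, k, form) {
  if (form == "harmonic") 0.5 * k * excess^2 else k * excess
}

#' Restraint energy of a pose
#'
#' Flat-bottom penalty: zero while each proton group's target sits inside
#' its constraint ellipsoid (or, in r6 mode, while each effective distance
#' is within sigma of its measurement); outside, the excess (Angstrom) is
#' penalized harmonically (or linearly).
#'
#' @param pose An `sp_pose`.
#' @param restraints An [restraint_set()].
#' @return Energy in kJ mol^-1.
#' @export
restraint_energy <- function(pose, restraints) {
  stopifnot(inherits(pose, "sp_pose"), inherits(restraints, "sp_restraints"))
  k <- restraints$force_constant
  total <- 0
  for (e in restraints$ellipsoids) {
    idx <- .group_indices(pose$ligand, e$group_id)
    coords <- pose$xyz[idx, , drop = FALSE]
    use_r6 <- restraints$pair_mode == "r6_average" && length(idx) == 2L
    if (!use_r6) {
      p <- chord_midpoint_target(coords)
      nrm <- ellipsoid_norm(e, p)
      if (nrm > 1) {
        excess <- sqrt(sum((p - e$center)^2)) * (1 - 1 / nrm)
        total <- total + .penalty(excess, k, restraints$force_form)
      }
    } else {
      for (i in 1:3) {
        ri <- .dist_point_sites(e$sites[i, ], coords)  # both protons to site i
        d_eff <- (mean(ri^-6))^(-1 / 6)
        dev <- abs(d_eff - e$distances[i]) - e$semi_axes[i]
        if (dev > 0) total <- total + .penalty(dev, k, restraints$force_form)
      }
    }
  }
  total
}

#' Soft-sphere steric energy between ligand and scaffold
#'
#' \eqn{E = c \sum \mathrm{overlap}^2} over all ligand/scaffold heavy-atom
#' pairs closer than the sum of their van der Waals radii, with overlap in
#' Angstrom.
#'
#' @param pose An `sp_pose`.
#' @param scaffold Data frame of scaffold heavy atoms: `x`, `y`, `z` and
#'   optionally `element` (defaults to carbon radii).
#' @param c_const Penalty constant, kJ mol^-1 A^-2 (default 10).
#' @return Energy in kJ mol^-1.
#' @export
steric_energy <- function(pose, scaffold, c_const = 10) {
  stopifnot(inherits(pose, "sp_pose"))
  sxyz <- .as_xyz(scaffold)
  s_rad <- if ("element" %in% names(scaffold)) .vdw_radius(scaffold$element) else rep(1.70, nrow(sxyz))
  heavy <- pose$ligand$heavy
  lxyz <- pose$xyz[heavy, , drop = FALSE]
  l_rad <- .vdw_radius(pose$ligand$atoms$element[heavy])
  total <- 0
  for (i in seq_len(nrow(lxyz))) {
    d <- .dist_point_sites(lxyz[i, ], sxyz)
    ov <- (l_rad[i] + s_rad) - d
    ov <- ov[ov > 0]
    if (length(ov)) total <- total + c_const * sum(ov^2)
  }
  total
}

.pose_objective <- function(ligand, restraints, scaffold, c_const = 10) {
  function(par) {
    pose <- make_pose(ligand, par)
    restraint_energy(pose, restraints) + steric_energy(pose, scaffold, c_const)
  }
}

.restraint_centroid <- function(restraints) {
  ctrs <- t(vapply(restraints$ellipsoids, `[[`, numeric(3), "center"))
  colMeans(ctrs)
}

# scaffold atoms the moving ligand can plausibly touch: within `margin` of
# the restraint centroid (ligand excursions are bounded by the start box
# plus its own extent).
.local_scaffold <- function(scaffold, restraints, margin = 28) {
  ctr <- .restraint_centroid(restraints)
  sxyz <- .as_xyz(scaffold)
  keep <- .dist_point_sites(ctr, sxyz) <= margin
  scaffold[keep, , drop = FALSE]
}

#' Optimize a ligand pose against restraints and sterics
#'
#' Seeded greedy random search over the 7 pose parameters (translation,
#' rotation, dihedral) with geometrically shrinking step sizes, alternating
#' with Nelder-Mead polish. The objective is
#' `restraint_energy + steric_energy`; only strictly improving random steps
#' are accepted, so the objective is non-increasing across accepted steps,
#' and the whole procedure is deterministic for a fixed seed.
#'
#' @param start_pose An `sp_pose` to start from.
#' @param restraints An [restraint_set()].
#' @param scaffold Scaffold heavy-atom data frame.
#' @param seed Integer seed.
#' @param n_steps Random-search steps per cycle (default 150).
#' @param cycles Search/polish cycles (default 2).
#' @param c_const Steric constant passed to [steric_energy()].
#' @return An `sp_pose` with its `objective` (kJ mol^-1) filled in.
#' @export
optimize_pose <- function(start_pose, restraints, scaffold, seed = 17,
                          n_steps = 150, cycles = 2, c_const = 10) {
  stopifnot(inherits(start_pose, "sp_pose"))
  local_sc <- .local_scaffold(scaffold, restraints)
  obj <- .pose_objective(start_pose$ligand, restraints, local_sc, c_const)
  par <- start_pose$par
  f <- obj(par)
  if (!is.finite(f)) {
    abort("Non-finite objective at the starting pose.", class = "sp_config_error")
  }
  if (f == 0) {
    out <- make_pose(start_pose$ligand, par)
    out$objective <- 0
    return(out)
  }
  step0 <- c(1.5, 1.5, 1.5, 0.30, 0.30, 0.30, 0.30)
  withr::with_seed(seed, {
    for (cy in seq_len(cycles)) {
      shrink <- 0.5^(cy - 1)
      for (s in seq_len(n_steps)) {
        scale <- shrink * (0.15 + 0.85 * (1 - s / n_steps))
        cand <- par + rnorm(7, 0, step0 * scale)
        fc <- obj(cand)
        if (fc < f) { par <- cand; f <- fc }
        if (f == 0) break
      }
      nm <- optim(par, obj, method = "Nelder-Mead",
                  control = list(maxit = 400, reltol = 1e-10))
      if (nm$value < f) { par <- nm$par; f <- nm$value }
      if (f == 0) break
    }
  })
  out <- make_pose(start_pose$ligand, par)
  out$objective <- f
  out
}

#' Multistart restrained docking
#'
#' Runs `n_starts` independent [optimize_pose()] optimizations from random
#' placements: ligand centroid uniform in a cube of half-width `box` around
#' the restraint centroid, orientation from a uniform random axis-angle,
#' dihedral uniform. Start `k` uses seed `seed + k`, so the ensemble is
#' reproducible from `seed`.
#'
#' @param ligand An [build_ligand()] model.
#' @param restraints An [restraint_set()].
#' @param scaffold Scaffold heavy-atom data frame.
#' @param n_starts Number of independent starts (default 10).
#' @param seed Integer seed (default 17).
#' @param box Half-width of the start box, Angstrom (default 10).
#' @param ... Passed to [optimize_pose()].
#' @return An object of class `sp_pose_ensemble`: list with `poses`,
#'   `objectives`, `seeds`.
#' @export
dock_ensemble <- function(ligand, restraints, scaffold, n_starts = 10,
                          seed = 17, box = 10, ...) {
  stopifnot(n_starts >= 1)
  ctr <- .restraint_centroid(restraints)
  base_centroid <- colMeans(.as_xyz(ligand$atoms))
  poses <- vector("list", n_starts)
  seeds <- seed + seq_len(n_starts)
  for (k in seq_len(n_starts)) {
    par0 <- withr::with_seed(seeds[k], {
      target <- ctr + runif(3, -box, box)
      axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
      angle <- runif(1, 0, pi)
      rot <- axis * angle
      R <- .rotmat_axis_angle(rot)
      tr <- target - as.numeric(R %*% base_centroid)
      c(tr, rot, runif(1, -pi, pi))
    })
    poses[[k]] <- optimize_pose(make_pose(ligand, par0), restraints, scaffold,
                                seed = seeds[k], ...)
  }
  objectives <- vapply(poses, `[[`, numeric(1), "objective")
  if (all(!is.finite(objectives))) {
    abort("No start achieved a finite objective.", class = "sp_fit_failure")
  }
  structure(list(poses = poses, objectives = objectives, seeds = seeds),
            class = "sp_pose_ensemble")
}

#' @export
print.sp_pose_ensemble <- function(x, ...) {
  cat(sprintf("<sp_pose_ensemble> %d poses, objectives %.3f - %.3f kJ/mol\n",
              length(x$poses), min(x$objectives), max(x$objectives)))
  invisible(x)
}

#' Greedy RMSD clustering of a pose ensemble
#'
#' The best-objective pose seeds cluster 1 and absorbs every pose within
#' `cutoff` RMSD of it; the procedure repeats on the remainder. A
#' well-determined restraint set yields a single cluster.
#'
#' @param ensemble An [dock_ensemble()] result.
#' @param cutoff RMSD cutoff in Angstrom (default 2.0).
#' @return An object of class `sp_cluster_report`: tibble `assignments`
#'   (`pose`, `objective`, `cluster`, `rmsd_to_rep`, `representative`),
#'   plus `cutoff` and `n_clusters`.
#' @export
cluster_poses <- function(ensemble, cutoff = 2.0) {
  stopifnot(inherits(ensemble, "sp_pose_ensemble"))
  n <- length(ensemble$poses)
  cluster <- rep(NA_integer_, n)
  rmsd_to_rep <- rep(NA_real_, n)
  representative <- rep(FALSE, n)
  cl <- 0L
  while (anyNA(cluster)) {
    cl <- cl + 1L
    remaining <- which(is.na(cluster))
    rep_i <- remaining[which.min(ensemble$objectives[remaining])]
    representative[rep_i] <- TRUE
    for (i in remaining) {
      r <- pose_rmsd(ensemble$poses[[rep_i]], ensemble$poses[[i]])
      if (r <= cutoff) {
        cluster[i] <- cl
        rmsd_to_rep[i] <- r
      }
    }
  }
  structure(
    list(
      assignments = tibble::tibble(
        pose = seq_len(n), objective = ensemble$objectives,
        cluster = cluster, rmsd_to_rep = rmsd_to_rep,
        representative = representative),
      cutoff = cutoff,
      n_clusters = cl
    ),
    class = "sp_cluster_report"
  )
}

#' @export
print.sp_cluster_report <- function(x, ...) {
  cat(sprintf("<sp_cluster_report> %d cluster(s) at %.1f A cutoff\n",
              x$n_clusters, x$cutoff))
  print(x$assignments)
  invisible(x)
}

#' Representative pose of a cluster
#'
#' @param ensemble The docked ensemble.
#' @param report Its [cluster_poses()] report.
#' @param cluster Cluster index (default 1, the best-objective cluster).
#' @return The `sp_pose` representing that cluster.
#' @export
representative_pose <- function(ensemble, report, cluster = 1L) {
  a <- report$assignments
  i <- a$pose[a$representative & a$cluster == cluster]
  ensemble$poses[[i]]
}
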