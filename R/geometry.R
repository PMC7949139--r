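# Trilateration of ligand protons and constraint-ellipsoid construction.

.as_xyz <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("x", "y", "z") %in% names(x)))
    m <- as.matrix(x[, c("x", "y", "z")])
  } else {
    m <- as.matrix(x)
    stopifnot(ncol(m) == 3L)
  }
  storage.mode(m) <- "double"
  unname(m)
}

.dist_point_sites <- function(p, sites) sqrt(colSums((t(sites) - p)^2))

.trilat_residual <- function(p, sites, r) {
  sqrt(mean((.dist_point_sites(p, sites) - r)^2))
}

#' Locate a point from its distances to reference sites
#'
#' Three-sphere intersection in closed form for exactly three sites (two
#' mirror-image candidates when the discriminant is positive); a
#' Gauss-Newton least-squares point for more than three. This is how each
#' ligand proton (or proton-pair effective position) is placed on the
#' scaffold from its per-site spin-label distances.
#'
#' @param sites Data frame with columns `x`, `y`, `z` (plus optional
#'   `site_id`) or an n x 3 matrix of spin-label oxygen coordinates, Angstrom.
#' @param distances Numeric vector of measured distances (Angstrom), one per
#'   site, length >= 3.
#' @param tolerance When the three spheres fail to intersect, a projected
#'   (discriminant-clamped) solution is still returned provided its RMS
#'   distance mismatch is below `tolerance` (Angstrom); otherwise the
#'   candidate set is empty and the residual is reported as an attribute.
#' @return A tibble of candidate points with columns `x`, `y`, `z`,
#'   `residual` (RMS distance mismatch, Angstrom); 0-2 rows. The attribute
#'   `"residual"` always carries the best achievable residual.
#' @examples
#' s <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0))
#' d <- sqrt(colSums((t(s) - c(3, 4, 5))^2))
#' trilaterate(s, d)  # (3,4,5) and its mirror (3,4,-5)
#' @export
trilaterate <- function(sites, distances, tolerance = 1.0) {
  s <- .as_xyz(sites)
  r <- as.numeric(distances)
  if (nrow(s) < 3L) abort("Need at least 3 sites.", class = "sp_geometry_error")
  if (length(r) != nrow(s)) abort("One distance per site required.")
  if (any(r <= 0)) abort("Distances must be positive.", class = "sp_geometry_error")

  if (nrow(s) == 3L) {
    e1 <- s[2, ] - s[1, ]
    d12 <- sqrt(sum(e1^2))
    v3 <- s[3, ] - s[1, ]
    cr <- c(e1[2] * v3[3] - e1[3] * v3[2],
            e1[3] * v3[1] - e1[1] * v3[3],
            e1[1] * v3[2] - e1[2] * v3[1])
    if (d12 < 1e-9 || sqrt(sum(cr^2)) / max(d12, 1) < 1e-6) {
      abort("Sites are collinear (or coincident): trilateration is degenerate.",
            class = "sp_geometry_error")
    }
    ex <- e1 / d12
    i <- sum(ex * v3)
    eyv <- v3 - i * ex
    ey <- eyv / sqrt(sum(eyv^2))
    ez <- c(ex[2] * ey[3] - ex[3] * ey[2],
            ex[3] * ey[1] - ex[1] * ey[3],
            ex[1] * ey[2] - ex[2] * ey[1])
    j <- sum(ey * v3)
    x <- (r[1]^2 - r[2]^2 + d12^2) / (2 * d12)
    y <- (r[1]^2 - r[3]^2 + i^2 + j^2 - 2 * i * x) / (2 * j)
    z2 <- r[1]^2 - x^2 - y^2
    base <- s[1, ] + x * ex + y * ey
    if (z2 > 0) {
      z <- sqrt(z2)
      pts <- rbind(base + z * ez, base - z * ez)
    } else {
      pts <- rbind(base)  # projected onto the site plane
    }
  } else {
    # least squares: initialize from the first non-collinear triple
    init <- tryCatch(trilaterate(s[1:3, ], r[1:3], tolerance = Inf),
                     error = function(e) NULL)
    starts <- if (!is.null(init) && nrow(init) > 0) {
      lapply(seq_len(nrow(init)), function(k) as.numeric(init[k, c("x", "y", "z")]))
    } else list(colMeans(s))
    sols <- lapply(starts, function(p0) {
      fit <- minpack.lm::nls.lm(
        par = p0,
        fn = function(p) .dist_point_sites(p, s) - r,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
      fit$par
    })
    res <- vapply(sols, .trilat_residual, numeric(1), sites = s, r = r)
    pts <- rbind(sols[[which.min(res)]])
  }

  resid <- apply(pts, 1, .trilat_residual, sites = s, r = r)
  keep <- resid <= tolerance
  out <- tibble::tibble(x = pts[keep, 1], y = pts[keep, 2], z = pts[keep, 3],
                        residual = resid[keep])
  if (nrow(out) == 0L) {
    warn(sprintf("No trilateration solution within tolerance (best residual %.2f A).",
                 min(resid)))
  }
  attr(out, "residual") <- min(resid)
  out
}

#' Choose between mirror trilateration solutions
#'
#' Three-site trilateration yields two candidates, mirror images through the
#' site plane. The physically meaningful one sits in solvent or in the
#' binding cleft; its twin is usually buried in the protein core. The rule:
#' keep the candidate with the smaller steric overlap count against scaffold
#' heavy atoms (atoms within `clash_radius`); ties are broken toward the
#' candidate nearer the scaffold centroid.
#'
#' @param candidates Tibble from [trilaterate()] (1-2 rows).
#' @param scaffold Data frame of scaffold heavy atoms with `x`, `y`, `z`.
#' @param clash_radius Angstrom; scaffold atoms closer than this count as
#'   overlapping (default 2.5, roughly a heavy-atom contact distance).
#' @param buried_neighbors A candidate with at least this many scaffold
#'   atoms within 3.5 A is considered buried; if both candidates are buried
#'   a warning is raised (default 12, an interior packing density).
#' @return A named numeric vector `c(x, y, z)` with attribute
#'   `"candidates"`: the input augmented with `overlap` counts and a
#'   `chosen` flag.
#' @export
disambiguate <- function(candidates, scaffold, clash_radius = 2.5,
                         buried_neighbors = 12) {
  stopifnot(is.data.frame(candidates), nrow(candidates) >= 1L)
  sxyz <- .as_xyz(scaffold)
  pts <- .as_xyz(candidates[, c("x", "y", "z")])
  overlap <- apply(pts, 1, function(p) sum(.dist_point_sites(p, sxyz) < clash_radius))
  burial <- apply(pts, 1, function(p) sum(.dist_point_sites(p, sxyz) < 3.5))
  centroid <- colMeans(sxyz)
  d_centroid <- apply(pts, 1, function(p) sqrt(sum((p - centroid)^2)))
  ord <- order(overlap, d_centroid)  # fewer clashes, then nearer centroid
  pick <- ord[1]
  if (all(burial >= buried_neighbors)) {
    warn("Both trilateration candidates are buried in the scaffold.")
  }
  report <- dplyr::mutate(candidates, overlap = overlap,
                          chosen = seq_len(nrow(candidates)) == pick)
  structure(c(x = pts[pick, 1], y = pts[pick, 2], z = pts[pick, 3]),
            candidates = report)
}

#' Build the constraint ellipsoid for a proton group
#'
#' The restrained-docking target region: centred on the triangulated point,
#' with principal axes along the site-to-centre unit vectors and semi-axis
#' lengths equal to the +-1 sigma uncertainties of the corresponding
#' distance measurements (95% CIs divided by 1.96).
#'
#' @param group_id Proton-group label.
#' @param center Numeric length-3, the triangulated (and disambiguated)
#'   point, Angstrom.
#' @param sites Three spin-label site coordinates (data frame or 3 x 3
#'   matrix).
#' @param sigmas Three positive 1-sigma distance uncertainties, Angstrom.
#' @param distances Optional measured distances (Angstrom) to the three
#'   sites, carried along for distance-based (r6-average) restraints.
#' @param residual Optional trilateration residual to carry along.
#' @return An object of class `sp_ellipsoid`.
#' @export
build_ellipsoid <- function(group_id, center, sites, sigmas,
                            distances = NULL, residual = NA_real_) {
  s <- .as_xyz(sites)
  if (nrow(s) != 3L) abort("Ellipsoid axes require exactly 3 sites.")
  sigmas <- as.numeric(sigmas)
  if (length(sigmas) != 3L || any(!is.finite(sigmas)) || any(sigmas <= 0)) {
    abort("`sigmas` must be 3 positive numbers.")
  }
  center <- as.numeric(center)
  A <- vapply(1:3, function(i) {
    v <- center - s[i, ]
    v / sqrt(sum(v^2))
  }, numeric(3))                     # columns = axis directions
  if (abs(det(A)) < 1e-6) {
    abort("Axis directions are linearly dependent.", class = "sp_geometry_error")
  }
  structure(
    list(group_id = group_id, center = center, semi_axes = sigmas,
         axes = A, Ainv = solve(A), sites = s,
         distances = if (is.null(distances)) NULL else as.numeric(distances),
         residual = residual),
    class = "sp_ellipsoid"
  )
}

#' @export
print.sp_ellipsoid <- function(x, ...) {
  cat(sprintf("<sp_ellipsoid> %s  center (%.2f, %.2f, %.2f) A  semi-axes (%s) A\n",
              x$group_id, x$center[1], x$center[2], x$center[3],
              paste(sprintf("%.2f", x$semi_axes), collapse = ", ")))
  invisible(x)
}

#' Ellipsoidal norm of a point
#'
#' Expresses `point - center` in the (generally non-orthogonal) axis basis
#' and returns \eqn{\sqrt{\sum (t_i/\sigma_i)^2}}: 0 at the centre, 1 on the
#' surface, > 1 outside.
#'
#' @param ellipsoid An [build_ellipsoid()] object.
#' @param point Numeric length-3 or n x 3 matrix.
#' @return Numeric vector of norms.
#' @export
ellipsoid_norm <- function(ellipsoid, point) {
  p <- if (is.null(dim(point))) matrix(point, nrow = 1) else .as_xyz(point)
  t_coords <- ellipsoid$Ainv %*% (t(p) - ellipsoid$center)
  sqrt(colSums((t_coords / ellipsoid$semi_axes)^2))
}

#' Restraint target point for a proton group
#'
#' Proton pairs indistinguishable by NMR are restrained at the midpoint of
#' the chord connecting them; singleton groups at the proton itself.
#'
#' @param member_xyz Coordinates of the group's member protons (1 x 3 or
#'   2 x 3 matrix / data frame).
#' @return Numeric length-3 target point.
#' @examples
#' chord_midpoint_target(rbind(c(0, 0, 0), c(2, 0, 0)))  # (1, 0, 0)
#' @export
chord_midpoint_target <- function(member_xyz) {
  m <- if (is.null(dim(member_xyz))) matrix(member_xyz, nrow = 1) else .as_xyz(member_xyz)
  if (!nrow(m) %in% 1:2) abort("Proton groups have multiplicity 1 or 2.")
  colMeans(m)
}

#' Paramagnetic coverage of the scaffold surface
#'
#' Fraction of scaffold *surface* atoms lying within the detection radius of
#' at least one spin-label oxygen. Surface atoms are identified by a
#' neighbour-count exposure heuristic: an atom is a surface atom when it has
#' at most `max_neighbors` scaffold atoms within `neighbor_radius` (default:
#' 70% of the median neighbour count, which tracks the packing density of
#' the particular scaffold).
#'
#' @param scaffold Data frame of scaffold atoms (`x`, `y`, `z`).
#' @param sites Spin-label oxygen coordinates (data frame or matrix).
#' @param radius Detection radius, Angstrom (default 25, the practical limit
#'   for nitroxide-proton broadening).
#' @param neighbor_radius Angstrom, for the exposure heuristic.
#' @param max_neighbors Optional integer override of the exposure threshold.
#' @return Fraction in \[0, 1\].
#' @export
coverage_fraction <- function(scaffold, sites, radius = 25,
                              neighbor_radius = 5, max_neighbors = NULL) {
  sxyz <- .as_xyz(scaffold)
  if (nrow(sxyz) == 0L) abort("Empty scaffold.", class = "sp_geometry_error")
  stxyz <- .as_xyz(sites)
  if (nrow(stxyz) == 0L) abort("Need at least one site.")
  dmat <- as.matrix(dist(sxyz))
  counts <- rowSums(dmat <= neighbor_radius) - 1L
  thr <- max_neighbors %||% (0.7 * stats::median(counts))
  surface <- which(counts <= thr)
  if (length(surface) == 0L) surface <- seq_len(nrow(sxyz))
  covered <- vapply(surface, function(i) {
    any(.dist_point_sites(sxyz[i, ], stxyz) <= radius)
  }, logical(1))
  mean(covered)
}

#' Least-squares embedding of a proton-by-site distance table
#'
#' Given an n-proton by 3-site table of measured distances, finds site and
#' proton coordinates that realize the table as closely as possible
#' (Levenberg-Marquardt on all coordinates, gauge-fixed to remove the six
#' rigid-body degrees of freedom). With 4 protons and 3 sites there are 12
#' constraints and 15 free coordinates, so a consistent table embeds
#' essentially exactly. Used to check that a printed distance table is
#' geometrically feasible.
#'
#' @param d Numeric matrix (protons x 3 sites) of distances, Angstrom.
#' @param n_starts Random multistarts (default 8).
#' @param seed RNG seed for the starts.
#' @return List with `sites` (3 x 3 matrix), `protons` (n x 3 matrix),
#'   `rms_residual`, and `per_proton` tibble of trilateration residuals at
#'   the embedded site geometry.
#' @export
embed_distance_table <- function(d, n_starts = 8, seed = 1) {
  d <- as.matrix(d)
  if (ncol(d) != 3L) abort("Expected distances to exactly 3 sites.")
  n <- nrow(d)
  scale <- mean(d)

  unpack <- function(par) {
    sites <- rbind(c(0, 0, 0),
                   c(par[1], 0, 0),
                   c(par[2], par[3], 0))
    protons <- matrix(par[-(1:3)], ncol = 3, byrow = TRUE)
    list(sites = sites, protons = protons)
  }
  resid_fn <- function(par) {
    g <- unpack(par)
    dd <- vapply(1:3, function(j) {
      sqrt(rowSums((g$protons - matrix(g$sites[j, ], n, 3, byrow = TRUE))^2))
    }, numeric(n))
    as.numeric(dd - d)
  }

  ssq <- function(par) sum(resid_fn(par)^2)
  best <- NULL
  withr::with_seed(seed, {
    for (k in seq_len(n_starts)) {
      par0 <- c(scale, scale / 2, scale,
                as.numeric(t(matrix(rnorm(3 * n, 0, scale / 2), n, 3) +
                               matrix(c(scale / 3, scale / 3, scale / 3), n, 3, byrow = TRUE))))
      fit <- optim(par0, ssq, method = "BFGS",
                   control = list(maxit = 2000, reltol = 1e-15))
      rms <- sqrt(fit$value / length(d))
      if (is.null(best) || rms < best$rms) best <- list(par = fit$par, rms = rms)
    }
  })
  g <- unpack(best$par)
  per <- purrr::map_dfr(seq_len(n), function(i) {
    tibble::tibble(proton = i,
                   residual = .trilat_residual(g$protons[i, ], g$sites, d[i, ]))
  })
  list(sites = g$sites, protons = g$protons,
       rms_residual = best$rms, per_proton = per)
}
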