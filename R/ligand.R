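# Idealized hydroxy-dichlorobiphenyl ligand model and pose algebra.

.element_radius <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                     Cl = 1.75, H = 1.10)

.vdw_radius <- function(element) {
  r <- .element_radius[element]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Idealized 4'-hydroxy-2,6-dichlorobiphenyl model
#'
#' Builds an idealized-geometry model of the biphenyl ligand: two hexagonal
#' rings (C-C 1.39 A) joined by a 1.48 A inter-ring bond along the x axis,
#' chlorines at the 2 and 6 positions of ring A, a hydroxyl oxygen at the 4'
#' position of ring B, and ring protons at 1.08 A. The single rotatable
#' degree of freedom is the inter-ring dihedral (rotation of ring B about
#' the long axis). Ring protons fall into the four NMR-distinguishable
#' groups: H4 (singleton), H3/H5, H2'/H6', H3'/H5'.
#'
#' @param dihedral Initial inter-ring dihedral, radians (default 0.69 rad
#'   ~ 40 deg, a typical ortho-substituted biphenyl twist).
#' @return An object of class `sp_ligand`: a list with `atoms` (tibble:
#'   `name`, `element`, `ring`, `x`, `y`, `z`), `groups` (proton-group ->
#'   atom-name map with multiplicities), `heavy` (indices of heavy atoms),
#'   `ring_b` (indices rotated by the dihedral).
#' @export
build_ligand <- function(dihedral = 0.69) {
  rc <- 1.39; d_cc <- 1.48; d_ch <- 1.08; d_ccl <- 1.73; d_co <- 1.36
  ang <- function(k) (k - 1) * pi / 3
  ring_a_c <- t(vapply(1:6, function(k) rc * c(cos(ang(k)), sin(ang(k)), 0),
                       numeric(3)))
  out_a <- ring_a_c / rc
  cb <- c(rc + d_cc + rc, 0, 0)  # ring B centre
  ring_b_c <- t(vapply(1:6, function(k) {
    cb + rc * c(cos(pi + ang(k)), sin(pi + ang(k)), 0)
  }, numeric(3)))
  out_b <- sweep(ring_b_c, 2, cb) / rc

  atoms <- rbind(
    data.frame(name = paste0("C", 1:6), element = "C", ring = "A", ring_a_c),
    data.frame(name = c("Cl2", "Cl6"), element = "Cl", ring = "A",
               ring_a_c[c(2, 6), ] + d_ccl * out_a[c(2, 6), ]),
    data.frame(name = c("H3", "H4", "H5"), element = "H", ring = "A",
               ring_a_c[3:5, ] + d_ch * out_a[3:5, ]),
    data.frame(name = paste0("C", 1:6, "'"), element = "C", ring = "B", ring_b_c),
    data.frame(name = "O4'", element = "O", ring = "B",
               ring_b_c[4, , drop = FALSE] + d_co * out_b[4, , drop = FALSE]),
    data.frame(name = c("H2'", "H3'", "H5'", "H6'"), element = "H", ring = "B",
               ring_b_c[c(2, 3, 5, 6), ] + d_ch * out_b[c(2, 3, 5, 6), ])
  )
  names(atoms)[4:6] <- c("x", "y", "z")
  atoms <- tibble::as_tibble(atoms)

  lig <- structure(
    list(
      atoms = atoms,
      groups = list(
        "H4"     = "H4",
        "H3 5"   = c("H3", "H5"),
        "H2' 6'" = c("H2'", "H6'"),
        "H3' 5'" = c("H3'", "H5'")
      ),
      heavy = which(atoms$element != "H"),
      ring_b = which(atoms$ring == "B"),
      base_dihedral = dihedral
    ),
    class = "sp_ligand"
  )
  lig
}

#' @export
print.sp_ligand <- function(x, ...) {
  cat(sprintf("<sp_ligand> %d atoms (%d heavy), %d proton groups, 1 rotatable dihedral\n",
              nrow(x$atoms), length(x$heavy), length(x$groups)))
  invisible(x)
}

.group_indices <- function(ligand, group_id) {
  nm <- ligand$groups[[group_id]]
  if (is.null(nm)) abort(sprintf("Proton group '%s' is not mapped on the ligand.", group_id),
                         class = "sp_config_error")
  match(nm, ligand$atoms$name)
}

.rotmat_axis_angle <- function(v) {
  theta <- sqrt(sum(v^2))
  if (theta < 1e-12) return(diag(3))
  k <- v / theta
  K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Pose parameters to ligand coordinates
#'
#' A pose is 7 numbers: rigid translation (3), rotation as an axis-angle
#' vector (3), and the inter-ring dihedral increment (1, radians). The
#' dihedral rotates ring B about the ligand's long (x) axis in the body
#' frame, then the global rotation and translation are applied.
#'
#' @param ligand An [build_ligand()] model.
#' @param par Numeric length-7: `tx, ty, tz, rx, ry, rz, dihedral`.
#' @return An object of class `sp_pose`: list with `par`, `xyz`
#'   (atoms x 3), and the `ligand` template.
#' @export
make_pose <- function(ligand, par = rep(0, 7)) {
  stopifnot(inherits(ligand, "sp_ligand"), length(par) == 7L)
  xyz <- .as_xyz(ligand$atoms)
  phi <- ligand$base_dihedral + par[7]
  rot_x <- matrix(c(1, 0, 0,
                    0, cos(phi), -sin(phi),
                    0, sin(phi), cos(phi)), 3, 3, byrow = TRUE)
  xyz[ligand$ring_b, ] <- xyz[ligand$ring_b, ] %*% t(rot_x)
  R <- .rotmat_axis_angle(par[4:6])
  xyz <- xyz %*% t(R)
  xyz <- sweep(xyz, 2, par[1:3], `+`)
  structure(list(par = as.numeric(par), xyz = xyz, ligand = ligand,
                 objective = NA_real_),
            class = "sp_pose")
}

#' @export
print.sp_pose <- function(x, ...) {
  cat(sprintf("<sp_pose> centroid (%.2f, %.2f, %.2f) A, dihedral %+.2f rad, objective %s\n",
              mean(x$xyz[, 1]), mean(x$xyz[, 2]), mean(x$xyz[, 3]),
              x$ligand$base_dihedral + x$par[7],
              ifelse(is.na(x$objective), "NA", sprintf("%.3f kJ/mol", x$objective))))
  invisible(x)
}

# symmetry-equivalent atom mappings: each phenyl ring can flip 180 degrees
# about its para axis, swapping the chemically identical 2/6 and 3/5
# substituents.
.ring_flip_perms <- function(ligand) {
  nm <- ligand$atoms$name
  base <- seq_along(nm)
  swap <- function(perm, a, b) {
    ia <- match(a, nm); ib <- match(b, nm)
    perm[c(ia, ib)] <- perm[c(ib, ia)]
    perm
  }
  flip_a <- base
  for (p in list(c("C2", "C6"), c("C3", "C5"), c("Cl2", "Cl6"), c("H3", "H5"))) {
    flip_a <- swap(flip_a, p[1], p[2])
  }
  flip_b <- base
  for (p in list(c("C2'", "C6'"), c("C3'", "C5'"), c("H2'", "H6'"), c("H3'", "H5'"))) {
    flip_b <- swap(flip_b, p[1], p[2])
  }
  list(base, flip_a, flip_b, flip_b[flip_a])
}

#' RMSD between two poses of the same ligand
#'
#' Heavy-atom root-mean-square deviation in the fixed scaffold frame (no
#' re-superposition), minimized over the symmetry-equivalent atom mappings
#' generated by flipping either phenyl ring 180 degrees about its para
#' axis.
#'
#' @param a,b `sp_pose` objects sharing an atom set.
#' @return RMSD in Angstrom.
#' @export
pose_rmsd <- function(a, b) {
  stopifnot(inherits(a, "sp_pose"), inherits(b, "sp_pose"))
  if (!identical(a$ligand$atoms$name, b$ligand$atoms$name)) {
    abort("Poses have different atom sets.")
  }
  heavy <- a$ligand$heavy
  perms <- .ring_flip_perms(a$ligand)
  vals <- vapply(perms, function(perm) {
    diff <- a$xyz[heavy, , drop = FALSE] - b$xyz[perm[heavy], , drop = FALSE]
    sqrt(mean(rowSums(diff^2)))
  }, numeric(1))
  min(vals)
}
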