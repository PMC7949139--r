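# PDB / CSV / JSON interfaces. Structural I/O goes through bio3d.

#' Read a PDB file into an atom tibble
#'
#' Wraps `bio3d::read.pdb()`: ATOM/HETATM records become a tibble with
#' coordinates in Angstrom and elements per PDB v3.3 columns. Alternate
#' locations beyond 'A' are skipped with a warning.
#'
#' @param path Path to a PDB file.
#' @return Tibble with columns `name`, `element`, `resid`, `resno`,
#'   `chain`, `x`, `y`, `z`.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) abort(sprintf("PDB file not found: %s", path),
                                class = "sp_config_error")
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) abort(sprintf("Malformed PDB '%s': %s",
                                                    path, conditionMessage(e))))
  a <- pdb$atom
  drop <- !(is.na(a$alt) | a$alt %in% c("", "A"))
  if (any(drop)) {
    warn(sprintf("Skipping %d altloc record(s) beyond 'A'.", sum(drop)))
    a <- a[!drop, , drop = FALSE]
  }
  elem <- a$elesy
  missing_e <- is.na(elem) | elem == ""
  elem[missing_e] <- substr(trimws(a$elety[missing_e]), 1, 1)
  tibble::tibble(name = trimws(a$elety), element = trimws(elem),
                 resid = a$resid, resno = a$resno, chain = a$chain,
                 x = a$x, y = a$y, z = a$z)
}

.write_pdb_atoms <- function(atoms, path, resid = "SCF") {
  n <- nrow(atoms)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(.as_xyz(atoms))),
    type = rep("ATOM", n),
    resno = if ("resno" %in% names(atoms)) atoms$resno else seq_len(n),
    resid = if ("resid" %in% names(atoms)) atoms$resid else rep(resid, n),
    elety = if ("name" %in% names(atoms)) atoms$name else rep("C", n),
    elesy = if ("element" %in% names(atoms)) atoms$element else rep("C", n)
  )
  invisible(path)
}

#' Write a scaffold or single-model atom table as PDB
#'
#' @param atoms Tibble with `x`, `y`, `z` and optionally `name`, `element`,
#'   `resno`, `resid`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_pdb <- function(atoms, path) .write_pdb_atoms(atoms, path)

#' Write a pose ensemble as a multi-MODEL PDB
#'
#' Each pose becomes one MODEL/ENDMDL block (ligand atoms as HETATM-style
#' ATOM records), the conventional format for NMR-like ensembles.
#'
#' @param ensemble An [dock_ensemble()] result.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_pose_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "sp_pose_ensemble"))
  lines <- character(0)
  for (k in seq_along(ensemble$poses)) {
    pose <- ensemble$poses[[k]]
    tmp <- tempfile(fileext = ".pdb")
    atoms <- pose$ligand$atoms
    atoms$x <- pose$xyz[, 1]; atoms$y <- pose$xyz[, 2]; atoms$z <- pose$xyz[, 3]
    atoms$resno <- 1L
    atoms$resid <- "LIG"
    .write_pdb_atoms(atoms, tmp)
    body <- readLines(tmp)
    unlink(tmp)
    body <- body[grepl("^(ATOM|HETATM)", body)]
    lines <- c(lines, sprintf("MODEL     %4d", k), body, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read spin-label site coordinates from CSV
#'
#' Expected columns: `site_id`, `residue`, `x`, `y`, `z` (Angstrom).
#' @param path CSV path.
#' @return Tibble of sites.
#' @export
read_sites_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "x", "y", "z")
  if (!all(need %in% names(df))) {
    abort("Sites CSV needs columns site_id, x, y, z.", class = "sp_config_error")
  }
  df$site_id <- as.character(df$site_id)
  tibble::as_tibble(df)
}

#' Read a peak-list CSV
#'
#' Expected columns: `construct`, `site_id`, `proton_group`,
#' `enzyme_sites_uM`, `ligand_total_uM`, `fwhm_hz` (the on-disk layout);
#' concentrations are returned in uM under the internal column names.
#'
#' @param path CSV path.
#' @return Peak tibble suitable for [estimate_distances()].
#' @export
read_peaks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("construct", "site_id", "proton_group", "enzyme_sites_uM",
            "ligand_total_uM", "fwhm_hz")
  if (!all(need %in% names(df))) {
    abort(paste("Peaks CSV needs columns:", paste(need, collapse = ", ")),
          class = "sp_config_error")
  }
  tibble::tibble(construct = df$construct, site_id = as.character(df$site_id),
                 proton_group = df$proton_group,
                 enzyme_sites = df$enzyme_sites_uM,
                 ligand_total = df$ligand_total_uM, fwhm = df$fwhm_hz)
}

#' Write a distance table CSV
#'
#' One row per proton group, one distance (and CI) column pair per site --
#' the conventional proton-by-site layout of spin-label distance tables.
#'
#' @param distances Output of [estimate_distances()].
#' @param path CSV path.
#' @return The path, invisibly.
#' @export
write_distances_csv <- function(distances, path) {
  wide <- distances |>
    dplyr::select("proton_group", "site_id", "r", "ci95") |>
    tidyr::pivot_wider(names_from = "site_id", values_from = c("r", "ci95"))
  utils::write.csv(wide, path, row.names = FALSE)
  invisible(path)
}

#' Read and validate a JSON run configuration
#'
#' Known keys: `peaks`, `sites`, `scaffold`, `ligand`, `out_dir` (paths);
#' `proton_frequency`, `tau_c`, `spin_S`, `prefactor_mode` (acquisition);
#' `kd`, `max_detect`; `n_starts`, `seed`, `cutoff`, `pair_mode`,
#' `force_constant` (docking). Unknown keys are rejected; referenced files
#' must exist.
#'
#' @param path JSON path.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config not found: %s", path),
                                class = "sp_config_error")
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("peaks", "sites", "scaffold", "ligand", "out_dir",
             "proton_frequency", "tau_c", "spin_S", "prefactor_mode",
             "kd", "max_detect",
             "n_starts", "seed", "cutoff", "pair_mode", "force_constant")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    abort(paste("Unknown config key(s):", paste(unknown, collapse = ", ")),
          class = "sp_config_error")
  }
  for (key in intersect(c("peaks", "sites", "scaffold", "ligand"), names(cfg))) {
    if (!file.exists(cfg[[key]])) {
      abort(sprintf("Config key '%s' points to a missing file: %s", key, cfg[[key]]),
            class = "sp_config_error")
    }
  }
  cfg
}

#' Write constraint ellipsoids as JSON
#'
#' @param ellipsoids List of [build_ellipsoid()] objects.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_ellipsoids_json <- function(ellipsoids, path) {
  payload <- lapply(ellipsoids, function(e) {
    list(group_id = e$group_id, center = e$center, semi_axes = e$semi_axes,
         axes = apply(e$axes, 2, identity, simplify = FALSE),
         distances = e$distances, residual = e$residual)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
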