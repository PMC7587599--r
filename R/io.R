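#' Write configurations as extended XYZ
#'
#' One frame per snapshot; the comment line carries the orthorhombic box
#' (`Lattice`), the column layout (`Properties=species:S:1:pos:R:3:chain:I:1`)
#' and the reduced time. Coordinates are written at full double precision so
#' a write/read round trip is the identity.
#'
#' @param config an [configuration()] or an `llps_trajectory` (all frames).
#' @param path output file.
#' @param topo optional topology supplying species labels and chain ids.
#' @param append append frames instead of overwriting.
#' @export
write_xyz <- function(config, path, topo = NULL, append = FALSE) {
  if (inherits(config, "llps_trajectory")) {
    topo <- if (is.null(topo)) config$topology else topo
    con <- file(path, if (append) "a" else "w")
    on.exit(close(con))
    for (i in seq_len(n_frames(config)))
      write_xyz_frame(config$frames[, , i], config$box[i, ],
                      config$times[i], topo, con)
    return(invisible(path))
  }
  stopifnot(inherits(config, "llps_configuration"))
  con <- file(path, if (append) "a" else "w")
  on.exit(close(con))
  write_xyz_frame(config$positions, config$box, config$time, topo, con)
  invisible(path)
}

write_xyz_frame <- function(pos, box, time, topo, con) {
  n <- nrow(pos)
  species <- if (is.null(topo)) rep("A", n) else topo$species[topo$chain_id]
  chain <- if (is.null(topo)) rep(1L, n) else topo$chain_id
  writeLines(sprintf("%d", n), con)
  writeLines(sprintf(
    'Lattice="%.17g 0 0 0 %.17g 0 0 0 %.17g" Properties=species:S:1:pos:R:3:chain:I:1 Time=%.17g',
    box[1], box[2], box[3], time), con)
  writeLines(sprintf("%s %.17g %.17g %.17g %d",
                     species, pos[, 1], pos[, 2], pos[, 3], chain), con)
}

#' Read an extended-XYZ file
#'
#' Parses one or more frames written by [write_xyz()] (species, positions
#' and chain ids; box from the `Lattice` field). Malformed input raises a
#' parse error naming the offending line.
#'
#' @param path input file.
#' @return list of frames; each frame is a list with `positions`, `box`,
#'   `species`, `chain`, `time`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!grepl("^\\s*\\d+\\s*$", lines[i]))
      stop("parse error at line ", i, ": expected an atom count")
    n <- as.integer(lines[i])
    if (i + 1 > length(lines))
      stop("parse error at line ", i + 1, ": missing comment line (frame ",
           length(frames) + 1, " truncated)")
    hdr <- lines[i + 1]
    lat <- regmatches(hdr, regexec('Lattice="([^"]+)"', hdr))[[1]]
    if (length(lat) < 2)
      stop("parse error at line ", i + 1, ": no Lattice field")
    cell <- as.numeric(strsplit(trimws(lat[2]), "\\s+")[[1]])
    if (length(cell) != 9 || anyNA(cell))
      stop("parse error at line ", i + 1, ": Lattice must hold 9 numbers")
    box <- cell[c(1, 5, 9)]
    tm <- regmatches(hdr, regexec("Time=([-0-9.eE+]+)", hdr))[[1]]
    time <- if (length(tm) == 2) as.numeric(tm[2]) else 0
    if (i + 1 + n > length(lines))
      stop("parse error: frame ", length(frames) + 1,
           " truncated at line ", length(lines) + 1,
           " (expected ", n, " atom lines)")
    rows <- strsplit(lines[i + 1 + seq_len(n)], "\\s+")
    nf <- lengths(rows)
    if (any(nf < 4))
      stop("parse error at line ", i + 1 + which(nf < 4)[1],
           ": expected at least 4 columns")
    species <- vapply(rows, `[[`, character(1), 1)
    pos <- matrix(as.numeric(unlist(lapply(rows, `[`, 2:4))), n, 3,
                  byrow = TRUE)
    if (anyNA(pos))
      stop("parse error in frame ", length(frames) + 1,
           ": non-numeric coordinate")
    chain <- if (all(nf >= 5)) as.integer(vapply(rows, `[[`, character(1), 5))
             else rep(1L, n)
    frames[[length(frames) + 1]] <-
      list(positions = pos, box = box, species = species, chain = chain,
           time = time)
    i <- i + 2 + n
  }
  if (!length(frames)) stop("no frames found in ", path)
  frames
}

#' Write a LAMMPS-style data file
#'
#' Full-style atoms with bond and angle sections, for cross-validation of a
#' configuration against an external MD engine. Write-only.
#'
#' @param config an [configuration()].
#' @param topo an [chain_topology()].
#' @param ff an [force_field()].
#' @param path output file.
#' @export
write_lammps_data <- function(config, topo, ff, path) {
  pos <- config$positions
  box <- config$box
  sp <- species_index0(topo, ff) + 1L
  n_types <- nrow(ff$eps_matrix)
  ang_types <- sort(unique(topo$angle_k))
  lines <- c(
    "coarse-grained IDR model (reduced units)", "",
    sprintf("%d atoms", nrow(pos)),
    sprintf("%d bonds", nrow(topo$bonds)),
    sprintf("%d angles", nrow(topo$angles)), "",
    sprintf("%d atom types", n_types),
    if (nrow(topo$bonds)) "1 bond types",
    if (nrow(topo$angles)) sprintf("%d angle types", length(ang_types)), "",
    sprintf("0 %.10g xlo xhi", box[1]),
    sprintf("0 %.10g ylo yhi", box[2]),
    sprintf("0 %.10g zlo zhi", box[3]), "",
    "Masses", "",
    sprintf("%d %.10g", seq_len(n_types), rep(topo$mass[1], n_types)), "",
    "Atoms # molecular", "",
    sprintf("%d %d %d %.10g %.10g %.10g", seq_len(nrow(pos)),
            topo$chain_id, sp, pos[, 1], pos[, 2], pos[, 3]))
  if (nrow(topo$bonds))
    lines <- c(lines, "", "Bonds", "",
               sprintf("%d 1 %d %d", seq_len(nrow(topo$bonds)),
                       topo$bonds[, 1], topo$bonds[, 2]))
  if (nrow(topo$angles))
    lines <- c(lines, "", "Angles", "",
               sprintf("%d %d %d %d %d", seq_len(nrow(topo$angles)),
                       match(topo$angle_k, ang_types), topo$angles[, 1],
                       topo$angles[, 2], topo$angles[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Read/write coexistence-point tables
#'
#' Tab-separated tables of (T*, rho_l*, rho_h*, se_l, se_h), the exchange
#' format between the direct-coexistence stage and the critical-point fit.
#'
#' @param points data.frame with at least `T_star`, `rho_l`, `rho_h`.
#' @param path file path.
#' @export
write_binodal_table <- function(points, path) {
  cols <- intersect(c("T_star", "rho_l", "rho_h", "se_l", "se_h"),
                    names(points))
  write.table(as.data.frame(points)[, cols], path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_binodal_table
#' @export
read_binodal_table <- function(path) {
  out <- read.table(path, header = TRUE, sep = "\t")
  if (!all(c("T_star", "rho_l", "rho_h") %in% names(out)))
    stop("binodal table must have columns T_star, rho_l, rho_h")
  class(out) <- c("llps_binodal_points", "data.frame")
  out
}

# ---------------------------------------------------------------------------
# run configuration (YAML)
# ---------------------------------------------------------------------------

run_config_defaults <- function() {
  list(
    protocol = "single_chain", # single_chain | bulk | direct_coexistence | mixture
    seed = 1L,
    protein = list(n_beads = 20L, k_theta = 0, rigid = FALSE, species = "A"),
    protein_b = NULL,          # second component for mixtures
    n_replicas = 1L,
    rho_star = 0.7,
    elongation_factor = 3,
    temperatures = 2.0,
    force_field = list(epsilon = 1, sigma = 1, r_cut = 2.5, k_bond = 40,
                       r0 = 1, heterotypic_factor = 1),
    integrator = list(dt = 4e-4, ensemble = "nvt", thermostat = "nose-hoover",
                      T_target = 2.0, p_target = 0, thermostat_tau = 0.4,
                      barostat_tau = 0.401, n_steps = 100000L,
                      neighbor_skin = 0.4, thermo_every = 1000L,
                      snapshot_every = 10000L),
    box = NULL,                # explicit box for single-chain runs
    output = list(prefix = "llpsmd_run"))
}

merge_config <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(user[[nm]])))
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]])
    else defaults[[nm]] <- user[[nm]]
  }
  defaults
}

#' Read a run configuration
#'
#' YAML run configuration declaring the protocol (`single_chain`, `bulk`,
#' `direct_coexistence` or `mixture`), the protein variant(s), force-field
#' block, integrator block, temperatures, seed and output paths. Every
#' physical parameter defaults to the model's canonical value and may be
#' overridden; the structure round-trips losslessly through
#' [write_run_config()].
#'
#' @param path YAML file.
#' @return a named list of class `llps_run_config` with all defaults filled.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- merge_config(run_config_defaults(), user)
  structure(cfg, class = "llps_run_config")
}

#' @rdname read_run_config
#' @param config a run-configuration list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Write a thermodynamic log as tab-separated text
#' @param traj an `llps_trajectory`.
#' @param path output file.
#' @export
write_thermo <- function(traj, path) {
  write.table(traj$thermo, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
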