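#' Integrator settings
#'
#' Velocity-Verlet core at the model's timestep `dt = 0.0004` (reduced).
#' Ensembles: `"nve"`, `"nvt"` (Nose-Hoover chains, length 3, relaxation time
#' 0.4, or Langevin dynamics with friction `1/thermostat_tau`), and `"npt"`
#' for preparation runs (NVT plus an isotropic or z-only Berendsen-type
#' box rescale towards a target pressure; production coexistence runs are
#' NVT). Same seed and settings give a bit-identical trajectory.
#'
#' @param n_steps number of MD steps.
#' @param T_target reduced target temperature (NVT/NpT).
#' @param dt reduced timestep.
#' @param ensemble `"nve"`, `"nvt"` or `"npt"`.
#' @param thermostat `"nose-hoover"` or `"langevin"`.
#' @param p_target reduced target pressure (NpT only).
#' @param thermostat_tau thermostat relaxation time (reduced).
#' @param barostat_tau barostat relaxation time (reduced).
#' @param seed integer seed, recorded in all outputs.
#' @param neighbor_skin Verlet-list skin; the list is rebuilt when any bead
#'   has moved more than half the skin.
#' @param thermo_every,snapshot_every log/snapshot cadences (steps).
#' @param cap_lj cap the LJ core below `cap_r` (construction/annealing only).
#' @param cap_r cap radius in units of sigma.
#' @param npt_axis `"iso"` or `"z"` (z-only box scaling).
#' @param barostat_compressibility dimensionless rate constant of the
#'   pressure coupling.
#' @param abort_energy_per_bead abort threshold for numeric blow-up.
#' @return an object of class `llps_settings`.
#' @export
integrator_settings <- function(n_steps, T_target = 1, dt = 4e-4,
                                ensemble = c("nvt", "nve", "npt"),
                                thermostat = c("nose-hoover", "langevin"),
                                p_target = 0, thermostat_tau = 0.4,
                                barostat_tau = 0.401, seed = 1L,
                                neighbor_skin = 0.4, thermo_every = 1000L,
                                snapshot_every = 10000L, cap_lj = FALSE,
                                cap_r = 0.3, npt_axis = c("iso", "z"),
                                barostat_compressibility = 0.1,
                                abort_energy_per_bead = 1e8) {
  ensemble <- match.arg(ensemble)
  thermostat <- match.arg(thermostat)
  npt_axis <- match.arg(npt_axis)
  if (dt <= 0) stop("dt must be positive")
  if (thermostat_tau <= dt || barostat_tau <= dt)
    stop("relaxation times must exceed the timestep")
  if (ensemble != "nve" && (!is.numeric(T_target) || T_target <= 0))
    stop("T_target must be positive for thermostatted runs")
  structure(list(dt = dt, n_steps = as.integer(n_steps), ensemble = ensemble,
                 thermostat = if (thermostat == "nose-hoover") "nh" else "langevin",
                 T_target = T_target, p_target = p_target,
                 thermostat_tau = thermostat_tau, barostat_tau = barostat_tau,
                 seed = as.integer(seed), neighbor_skin = neighbor_skin,
                 thermo_every = as.integer(thermo_every),
                 snapshot_every = as.integer(snapshot_every),
                 cap_lj = isTRUE(cap_lj), cap_r = cap_r, npt_axis = npt_axis,
                 barostat_compressibility = barostat_compressibility,
                 abort_energy_per_bead = abort_energy_per_bead),
            class = "llps_settings")
}

#' Maxwell-Boltzmann velocities
#'
#' Draws bead velocities at the requested reduced temperature, removes the
#' net linear momentum, and rescales so the kinetic temperature equals the
#' target exactly after momentum removal (free-bead degrees of freedom
#' `3n - 3`). For systems containing rigid chains the draw is projected onto
#' rigid motion (per-body COM velocity and angular momentum) before the
#' rescale, with `6 n_bodies + 3 n_free - 3` degrees of freedom.
#'
#' @param topo an [chain_topology()].
#' @param temperature reduced target temperature (> 0).
#' @param seed integer seed; the same seed reproduces the same draw.
#' @param config required when the topology contains rigid chains (the body
#'   geometry enters the projection).
#' @return n x 3 velocity matrix.
#' @export
initialize_velocities <- function(topo, temperature, seed, config = NULL) {
  stopifnot(inherits(topo, "llps_topology"), temperature > 0)
  set.seed(seed)
  n <- topo$n_beads
  v <- matrix(rnorm(3 * n, sd = sqrt(temperature / topo$mass)), n, 3)
  if (topo$n_bodies > 0) {
    if (is.null(config))
      stop("config is required to initialise velocities of rigid chains")
    v <- project_rigid_velocities_cpp(config$positions, v, topo$mass,
                                      topo$body, topo$n_bodies)
  }
  p <- colSums(topo$mass * v)
  v <- sweep(v, 2, p / sum(topo$mass))
  n_free <- sum(topo$body < 0)
  dof <- 3 * n_free + 6 * topo$n_bodies - 3
  ke2 <- sum(topo$mass * v^2) # rigid beads: projected velocities are exact
  v * sqrt(dof * temperature / ke2)
}

#' Run molecular dynamics
#'
#' Propagates a configuration with the compiled velocity-Verlet engine and
#' returns the trajectory: periodic snapshots (unwrapped coordinates), a
#' thermodynamic log (kinetic temperature, virial pressure, energy
#' components, density) and the final state. If the configuration carries no
#' velocities they are drawn at `settings$T_target` with `settings$seed`.
#'
#' @param config an [configuration()].
#' @param topo an [chain_topology()].
#' @param ff an [force_field()].
#' @param settings an [integrator_settings()].
#' @return an object of class `llps_trajectory`: list with `frames`
#'   (n x 3 x n_frames array), `times`, `box` (n_frames x 3), `thermo`
#'   (data.frame), `final` configuration, and the `topology`/`settings` used.
#' @export
run_md <- function(config, topo, ff, settings) {
  stopifnot(inherits(config, "llps_configuration"),
            inherits(topo, "llps_topology"),
            inherits(ff, "llps_forcefield"),
            inherits(settings, "llps_settings"))
  if (nrow(config$positions) != topo$n_beads)
    stop("configuration/topology bead count mismatch")
  if (any(config$box <= 2 * ff$r_cut))
    stop("box edges must exceed twice the LJ cutoff")
  set.seed(settings$seed)
  v <- config$velocities
  if (is.null(v)) {
    Tinit <- if (settings$ensemble == "nve") 1 else settings$T_target
    v <- initialize_velocities(topo, Tinit, settings$seed, config)
    set.seed(settings$seed + 1L) # fresh stream for the dynamics
  }
  res <- run_md_cpp(config$positions, v, config$box, topo$mass,
                    topo$bonds - 1L, topo$angles - 1L, topo$angle_k,
                    species_index0(topo, ff), ff$eps_matrix, ff$sigma,
                    ff$r_cut, ff$k_bond, ff$r0, ff$theta0, topo$body,
                    topo$n_bodies,
                    c(unclass(settings), list(time0 = config$time)))
  thermo <- as.data.frame(res$thermo)
  structure(list(frames = res$frames, times = res$frame_times,
                 box = res$frame_box, thermo = thermo,
                 final = configuration(res$x, res$box, res$v,
                                       time = config$time +
                                         settings$n_steps * settings$dt),
                 topology = topo, settings = settings, seed = settings$seed),
            class = "llps_trajectory")
}

#' @export
print.llps_trajectory <- function(x, ...) {
  nf <- dim(x$frames)[3]
  cat(sprintf("Trajectory: %d frames of %d beads, t* = %g .. %g (seed %d)\n",
              nf, dim(x$frames)[1], x$times[1], x$times[nf], x$seed))
  cat(sprintf("  final T_kin = %.4g, e_total = %.6g\n",
              tail(x$thermo$T_kin, 1), tail(x$thermo$e_total, 1)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `llps_trajectory`.
#' @export
n_frames <- function(traj) dim(traj$frames)[3]

#' Extract one frame as a configuration
#' @param traj an `llps_trajectory`.
#' @param i frame index.
#' @export
get_frame <- function(traj, i) {
  configuration(traj$frames[, , i], traj$box[i, ], time = traj$times[i])
}

# frames kept after discarding an initial equilibration fraction
production_frames <- function(traj, equilibration_fraction) {
  nf <- n_frames(traj)
  first <- floor(equilibration_fraction * nf) + 1
  if (first > nf) stop("no frames left after discarding equilibration")
  seq.int(first, nf)
}

#' Candidate neighbour pairs within a cutoff
#'
#' Returns every unordered bead pair within `r_cut + skin` under minimum
#' image, with directly bonded pairs and same-rigid-body pairs removed --
#' the same candidate set the engine uses, exposed for verification.
#'
#' @param config an [configuration()].
#' @param r_cut interaction cutoff.
#' @param skin extra margin (the Verlet skin).
#' @param topo optional topology providing exclusions; omitting it returns
#'   all pairs.
#' @return two-column integer matrix of 1-based bead indices.
#' @export
build_neighbor_list <- function(config, r_cut, skin = 0, topo = NULL) {
  stopifnot(inherits(config, "llps_configuration"))
  if (any(config$box <= 2 * (r_cut + skin)))
    stop("box edges must exceed twice (r_cut + skin)")
  n <- nrow(config$positions)
  bonds <- if (is.null(topo)) matrix(integer(0), 0, 2) else topo$bonds - 1L
  body <- if (is.null(topo)) rep(-1L, n) else topo$body
  neighbor_pairs_cpp(config$positions, config$box, r_cut + skin, bonds, body)
}

#' Conserved energy of an NVE trajectory
#'
#' The model's LJ potential is truncated and unshifted, so the tallied
#' potential energy jumps by the (small) cutoff value whenever a pair
#' crosses `r_cut`; forces are unaffected. The quantity conserved by the
#' dynamics is therefore the total energy computed with the shifted LJ
#' tally, reconstructed here from the logged within-cutoff pair count:
#' `e_total - eps_in_cutoff * u_lj(r_cut)/eps`. Use this column to measure
#' integrator drift.
#'
#' @param traj an `llps_trajectory`.
#' @param ff the force field used for the run.
#' @return numeric vector, one value per thermo record.
#' @export
nve_conserved_energy <- function(traj, ff) {
  sr6 <- (ff$sigma / ff$r_cut)^6
  u_cut1 <- 4 * (sr6^2 - sr6) # LJ value at the cutoff for eps = 1
  traj$thermo$e_total - traj$thermo$eps_in_cutoff * u_cut1
}
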