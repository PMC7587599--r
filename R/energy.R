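#' Total potential energy and forces
#'
#' Sums the truncated LJ interactions over all non-excluded pairs under the
#' minimum-image convention, the harmonic bond terms and the bending terms,
#' and returns the exact negative gradient as per-bead forces. Only directly
#' bonded (1-2) pairs are excluded from the LJ sum; 1-3 and longer-range
#' intra-chain pairs interact. Rigid bodies contribute inter-body LJ only.
#'
#' Overlapping beads (any non-excluded pair closer than `0.3 sigma`) are
#' flagged; with `cap_overlaps = TRUE` the LJ core is replaced below
#' `0.3 sigma` by a linear continuation (finite energy and constant force) --
#' intended for construction and annealing only, never production.
#'
#' @param config an [configuration()].
#' @param topo an [chain_topology()].
#' @param ff an [force_field()].
#' @param cap_overlaps cap the LJ core (construction/annealing only).
#' @return list with `energy`, components `e_lj`, `e_bond`, `e_angle`,
#'   `forces` (n x 3), `virial`, `overlap` flag and `min_distance`.
#' @export
total_energy_forces <- function(config, topo, ff, cap_overlaps = FALSE) {
  stopifnot(inherits(config, "llps_configuration"),
            inherits(topo, "llps_topology"),
            inherits(ff, "llps_forcefield"))
  if (nrow(config$positions) != topo$n_beads)
    stop("configuration holds ", nrow(config$positions),
         " beads but topology declares ", topo$n_beads)
  if (any(config$box <= 2 * ff$r_cut))
    stop("box edges must exceed twice the LJ cutoff")
  res <- energy_forces_cpp(config$positions, config$box,
                           topo$bonds - 1L, topo$angles - 1L, topo$angle_k,
                           species_index0(topo, ff), ff$eps_matrix,
                           ff$sigma, ff$r_cut, ff$k_bond, ff$r0, ff$theta0,
                           topo$body, cap_overlaps, 0.3)
  list(energy = res$energy, e_lj = res$e_lj, e_bond = res$e_bond,
       e_angle = res$e_angle, forces = res$forces, virial = res$virial,
       overlap = res$n_overlap > 0, min_distance = res$min_distance)
}
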