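#' Protein variant specification
#'
#' Declares one protein type: chain length, bending stiffness (for flexible
#' IDR variants) or a frozen reference structure (for rigid globular
#' variants), and the species label used to wire interaction strengths.
#'
#' @param N beads per chain (>= 2).
#' @param k_theta bending constant Ktheta* (epsilon/rad^2); ignored for
#'   rigid chains.
#' @param rigid logical; rigid chains are propagated as one body and keep
#'   their reference geometry exactly.
#' @param reference_structure N x 3 coordinates; required when `rigid`.
#' @param species species label.
#' @return an object of class `llps_protein_spec`.
#' @export
protein_spec <- function(N, k_theta = 0, rigid = FALSE,
                         reference_structure = NULL, species = "A") {
  stopifnot(N >= 2)
  if (rigid) {
    if (is.null(reference_structure))
      stop("rigid chains need a reference_structure (see make_globule())")
    reference_structure <- as.matrix(reference_structure)
    if (nrow(reference_structure) != N)
      stop("reference_structure must have N rows")
  }
  structure(list(N = as.integer(N), k_theta = k_theta, rigid = rigid,
                 reference_structure = reference_structure,
                 species = as.character(species)),
            class = "llps_protein_spec")
}

#' Build a single chain conformation
#'
#' `"straight"` places beads on a line at exact spacing `r0`;
#' `"random_walk"` grows a freely jointed chain with fixed bond length `r0`,
#' rejecting any step that brings a non-bonded pair closer than `min_sep`.
#'
#' @param N beads (>= 2).
#' @param mode `"straight"` or `"random_walk"`.
#' @param seed integer seed (random_walk mode).
#' @param r0 bond length.
#' @param min_sep self-overlap rejection distance (random_walk mode).
#' @return N x 3 coordinate matrix.
#' @export
build_chain <- function(N, mode = c("straight", "random_walk"), seed = 1L,
                        r0 = 1, min_sep = 0.9) {
  if (N < 2) stop("a chain needs at least 2 beads")
  mode <- match.arg(mode)
  if (mode == "straight")
    return(cbind(0, 0, (seq_len(N) - 1) * r0))
  set.seed(seed)
  for (attempt in 1:100) {
    x <- matrix(0, N, 3)
    ok <- TRUE
    for (i in 2:N) {
      placed <- FALSE
      for (try in 1:200) {
        u <- rnorm(3)
        cand <- x[i - 1, ] + r0 * u / sqrt(sum(u^2))
        prev <- x[seq_len(max(i - 2, 1)), , drop = FALSE]
        if (i == 2 ||
            min(sqrt(rowSums(sweep(prev, 2, cand)^2))) >= min_sep) {
          x[i, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(x)
  }
  stop("failed to grow a self-avoiding random walk of length ", N)
}

# capped-LJ steepest descent with a per-bead displacement ceiling; used for
# push-off after packing and for quenching annealed globules
steepest_descent <- function(config, topo, ff, max_iter = 400,
                             max_disp = 0.05, f_tol = 1,
                             min_sep_stop = NULL) {
  x <- config$positions
  for (it in seq_len(max_iter)) {
    res <- energy_forcefield(x, config$box, topo, ff, cap = TRUE)
    fmax <- sqrt(max(rowSums(res$forces^2)))
    if (fmax < f_tol) break
    if (!is.null(min_sep_stop) && res$min_distance >= min_sep_stop &&
        fmax < 50) break
    x <- x + res$forces * (max_disp / max(fmax, 1e-12))
  }
  configuration(x, config$box, time = config$time)
}

# thin internal wrapper around the compiled single-point evaluation
energy_forcefield <- function(positions, box, topo, ff, cap = FALSE) {
  energy_forces_cpp(positions, box, topo$bonds - 1L, topo$angles - 1L,
                    topo$angle_k, species_index0(topo, ff), ff$eps_matrix,
                    ff$sigma, ff$r_cut, ff$k_bond, ff$r0, ff$theta0,
                    topo$body, cap, 0.3)
}

#' Anneal a chain into a rigid globular reference structure
#'
#' Collapses a single self-attracting chain by Langevin dynamics at low
#' temperature (LJ core capped during construction), tracking the radius of
#' gyration, and returns the snapshot whose Rg is closest to `target_rg`
#' after a brief near-zero-temperature quench that settles the bonds to
#' within a few percent of `r0`. The returned structure is meant to be
#' frozen as a rigid body (see [protein_spec()]).
#'
#' @param N beads.
#' @param target_rg target radius of gyration (reduced); must lie between
#'   the collapsed-globule minimum and the straight-rod value
#'   `sqrt(r0^2 (N^2 - 1) / 12)`.
#' @param seed integer seed.
#' @param tol acceptance window on Rg (default 0.05 sigma).
#' @param anneal_T annealing temperature (reduced).
#' @param max_steps annealing budget in MD steps.
#' @param ff force field (single species).
#' @return N x 3 coordinate matrix (centred), with attributes `rg` and
#'   `seed`. Fails with the closest Rg achieved if the target is not
#'   reachable within the budget.
#' @export
make_globule <- function(N, target_rg, seed = 1L, tol = 0.05,
                         anneal_T = 0.5, max_steps = 2e6,
                         ff = force_field()) {
  rod_rg <- sqrt(ff$r0^2 * (N^2 - 1) / 12)
  if (target_rg <= 0 || target_rg > rod_rg)
    stop("target_rg must lie in (0, rod value ", round(rod_rg, 3), "]")
  topo <- chain_topology(1, N)
  L <- max(4 * rod_rg, 2.5 * ff$r_cut + 1)
  x <- build_chain(N, "straight", r0 = ff$r0)
  config <- configuration(sweep(x, 2, colMeans(x)) + L / 2, rep(L, 3))

  chunk <- 2e4
  best <- NULL
  best_err <- Inf
  # brief, heavily damped low-T settle: relaxes bond lengths to within a few
  # percent of r0 while leaving the global fold essentially untouched
  quench <- function(coords) {
    cfg <- configuration(coords, rep(L, 3))
    s <- integrator_settings(n_steps = 1500, T_target = 0.01,
                             thermostat = "langevin", thermostat_tau = 0.05,
                             seed = seed + 7L, cap_lj = TRUE,
                             thermo_every = 1500, snapshot_every = 1500)
    tr <- run_md(cfg, topo, ff, s)
    tr$final$positions
  }
  steps_done <- 0
  k <- 0L
  # two running optima: the best fold with all bonds within 5% of r0, and
  # the best fold regardless (compact folds can strain a bond or two)
  best_ok <- NULL
  err_ok <- Inf
  best_any <- NULL
  err_any <- Inf
  shift <- 0 # running estimate of the quench-induced Rg shift
  while (steps_done < max_steps) {
    s <- integrator_settings(n_steps = chunk, T_target = anneal_T,
                             thermostat = "langevin", seed = seed + k,
                             cap_lj = TRUE, thermo_every = chunk,
                             snapshot_every = 100)
    traj <- run_md(config, topo, ff, s)
    config <- traj$final
    rgs <- apply(traj$frames, 3, radius_of_gyration)
    # quench up to three well-separated candidate snapshots per chunk
    # (compact folds often strain one bond; several tries per chunk make an
    # unstrained fold much more likely)
    ord <- order(abs(rgs - (target_rg - shift)))
    cand_idx <- ord[1]
    for (i in ord[-1]) {
      if (length(cand_idx) >= 3) break
      if (all(abs(i - cand_idx) >= 5)) cand_idx <- c(cand_idx, i)
    }
    for (i_cand in cand_idx) {
      cand <- quench(traj$frames[, , i_cand])
      rg_q <- radius_of_gyration(cand)
      shift <- max(min(0.5 * shift + 0.5 * (rg_q - rgs[i_cand]), 0.1), -0.1)
      score <- abs(rg_q - target_rg)
      if (score < err_any) {
        best_any <- cand
        err_any <- score
      }
      if (score < err_ok &&
          all(abs(bond_lengths(cand) - ff$r0) <= 0.05 * ff$r0)) {
        best_ok <- cand
        err_ok <- score
      }
      if (err_ok <= tol * 0.8) break
    }
    if (err_ok <= tol * 0.8) break
    steps_done <- steps_done + chunk
    k <- k + 1L
  }
  if (err_ok <= tol) {
    best <- best_ok
  } else if (err_any <= tol) {
    best <- best_any
    warning("some bonds deviate from r0 by more than 5%")
  } else {
    stop(sprintf(
      "annealing did not reach Rg = %.3f within %.2f (closest achieved: %.3f)",
      target_rg, tol, if (is.null(best_any)) NA_real_ else
        radius_of_gyration(best_any)))
  }
  out <- sweep(best, 2, colMeans(best))
  attr(out, "rg") <- radius_of_gyration(out)
  attr(out, "seed") <- seed
  out
}

#' Build a bulk box of protein replicas
#'
#' Places `n_replicas` copies of a protein on a cubic lattice of cells in a
#' box sized so that `rho* = n_replicas N sigma^3 / V` exactly, randomises
#' chain conformations/orientations, and removes construction overlaps with
#' a short capped-LJ steepest-descent relaxation (flexible chains) or
#' rejection packing (rigid chains).
#'
#' @param spec an [protein_spec()].
#' @param n_replicas number of chains.
#' @param rho_star target reduced density.
#' @param seed integer seed.
#' @param ff force field.
#' @param min_sep minimum allowed non-bonded pair distance after relaxation.
#' @return list with `config` and `topology`.
#' @export
build_bulk <- function(spec, n_replicas, rho_star, seed = 1L,
                       ff = force_field(), min_sep = 0.8) {
  stopifnot(inherits(spec, "llps_protein_spec"), rho_star > 0)
  build_multi(list(spec), rep(n_replicas, 1), rho_star, seed, ff, min_sep)
}

#' Build a binary mixture box
#'
#' A box of `n_A` chains of type A and `n_B` of type B at the requested
#' overall density. With a heterotypic force field
#' (`force_field(species = c("A","B"), heterotypic_factor = 2)`) unlike
#' pairs attract twice as strongly as like pairs.
#'
#' @param spec_A,spec_B [protein_spec()] objects with distinct species.
#' @param n_A,n_B replica counts.
#' @param rho_star overall reduced density.
#' @param seed integer seed.
#' @param ff force field; defaults to the heterotypic 2:1 rule.
#' @param min_sep minimum non-bonded pair distance after relaxation.
#' @return list with `config` and `topology`.
#' @export
build_mixture <- function(spec_A, spec_B, n_A, n_B, rho_star, seed = 1L,
                          ff = force_field(species = c("A", "B"),
                                           heterotypic_factor = 2),
                          min_sep = 0.8) {
  if (spec_A$species == spec_B$species)
    stop("mixture components must carry distinct species labels")
  build_multi(list(spec_A, spec_B), c(n_A, n_B), rho_star, seed, ff, min_sep)
}

build_multi <- function(specs, counts, rho_star, seed, ff, min_sep) {
  Ns <- vapply(specs, `[[`, integer(1), "N")
  if (length(unique(Ns)) != 1)
    stop("all components must share the same chain length")
  N <- Ns[1]
  n_chains <- sum(counts)
  n_beads <- n_chains * N
  V <- n_beads * ff$sigma^3 / rho_star
  L <- V^(1 / 3)
  if (L <= 2 * ff$r_cut)
    stop("box too small relative to the LJ cutoff at this density")
  set.seed(seed)
  m <- ceiling(n_chains^(1 / 3))
  cell <- L / m
  centers <- as.matrix(expand.grid(x = seq_len(m), y = seq_len(m),
                                   z = seq_len(m))) - 0.5
  centers <- centers[sample(nrow(centers), n_chains), , drop = FALSE] * cell

  chain_spec <- rep(seq_along(specs), counts)
  chain_spec <- sample(chain_spec) # randomise species over lattice sites
  rigid_any <- any(vapply(specs, `[[`, logical(1), "rigid"))

  pos <- matrix(0, n_beads, 3)
  placed <- 0L
  for (c in seq_len(n_chains)) {
    sp <- specs[[chain_spec[c]]]
    if (sp$rigid) {
      ok <- FALSE
      for (try in 1:500) {
        R <- random_rotation()
        cand <- sp$reference_structure %*% t(R)
        shift <- if (try == 1) centers[c, ] else runif(3, 0, L)
        cand <- sweep(cand, 2, -shift)
        if (placed == 0L ||
            min_image_min_dist(cand, pos[seq_len(placed), , drop = FALSE],
                               rep(L, 3)) >= min_sep) {
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("density too high to pack rigid replicas without overlap")
      coords <- cand
    } else {
      coords <- build_chain(N, "random_walk",
                            seed = seed + 1000L + c, r0 = ff$r0)
      coords <- coords %*% t(random_rotation())
      coords <- sweep(coords, 2, colMeans(coords) - centers[c, ])
    }
    pos[(c - 1) * N + seq_len(N), ] <- coords
    placed <- placed + N
  }

  topo <- chain_topology(
    n_chains, N,
    species = vapply(specs, `[[`, character(1), "species")[chain_spec],
    k_theta = vapply(specs, `[[`, numeric(1), "k_theta")[chain_spec],
    rigid = vapply(specs, `[[`, logical(1), "rigid")[chain_spec])
  config <- configuration(pos, rep(L, 3))
  if (!rigid_any) {
    config <- steepest_descent(config, topo, ff, max_iter = 600,
                               min_sep_stop = min_sep + 0.02)
    chk <- energy_forcefield(config$positions, config$box, topo, ff,
                             cap = TRUE)
    if (chk$min_distance < min_sep)
      stop(sprintf(
        "density too high to pack: closest pair %.3f sigma after relaxation",
        chk$min_distance))
  }
  list(config = config, topology = topo)
}

random_rotation <- function() {
  # uniform random rotation via QR of a Gaussian matrix
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

min_image_min_dist <- function(a, b, box) {
  best <- Inf
  for (i in seq_len(nrow(a))) {
    d <- sweep(b, 2, a[i, ])
    d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
    best <- min(best, sqrt(min(rowSums(d^2))))
  }
  best
}

#' Elongate a bulk box into a direct-coexistence slab
#'
#' Extends the box along one axis by `elongation_factor`, leaving all
#' particle coordinates untouched except for a rigid shift that centres the
#' condensed block in the new box. Molecules straddling the old periodic
#' boundary along that axis are re-imaged first so they stay whole.
#'
#' @param bulk a `configuration` (typically from [build_bulk()]).
#' @param topo the matching topology (used to keep molecules whole).
#' @param elongation_factor factor >= 2 applied to one box edge.
#' @param axis `"z"`, `"y"` or `"x"` (slab normal; default z).
#' @return a new `configuration` with the same particle count.
#' @export
carve_slab <- function(bulk, topo, elongation_factor = 3, axis = "z") {
  stopifnot(inherits(bulk, "llps_configuration"))
  if (elongation_factor < 2) stop("elongation_factor must be >= 2")
  ax <- match(match.arg(axis, c("x", "y", "z")), c("x", "y", "z"))
  box <- bulk$box
  pos <- bulk$positions
  # make every molecule whole, then wrap its centre of mass into the old box
  for (c in seq_len(topo$n_chains)) {
    idx <- which(topo$chain_id == c)
    w <- unwrap_chain(pos[idx, , drop = FALSE], box)
    com <- colMeans(w)
    shift <- floor(com / box) * box
    pos[idx, ] <- sweep(w, 2, shift)
  }
  newbox <- box
  newbox[ax] <- box[ax] * elongation_factor
  pos[, ax] <- pos[, ax] + (newbox[ax] - box[ax]) / 2
  configuration(pos, newbox, time = bulk$time)
}
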