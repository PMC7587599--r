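# Independent R-side oracles and small system builders shared by the tests.
# The brute-force energy oracle is a vectorised O(N^2) double loop written
# against the model definition only -- it never calls the engine.

brute_energy <- function(pos, box, topo, ff) {
  n <- nrow(pos)
  sp <- topo$species[topo$chain_id]
  e_lj <- 0
  bonded <- matrix(FALSE, n, n)
  if (nrow(topo$bonds)) {
    bonded[topo$bonds] <- TRUE
    bonded[topo$bonds[, c(2, 1)]] <- TRUE
  }
  same_body <- outer(topo$body, topo$body,
                     function(a, b) a >= 0 & a == b)
  dmin <- Inf
  for (d in 1:3) {
    dd <- outer(pos[, d], pos[, d], "-")
    dd <- dd - box[d] * round(dd / box[d])
    e_lj <- if (d == 1) dd^2 else e_lj + dd^2
  }
  r <- sqrt(e_lj)
  keep <- upper.tri(r) & !bonded & !same_body
  rv <- r[keep]
  dmin <- suppressWarnings(min(rv))
  eps <- matrix(pair_strength(rep(sp, n), rep(sp, each = n), ff), n, n)[keep]
  e_pair <- sum(lj_energy(rv, eps, ff$sigma, ff$r_cut))
  mi <- function(d) d - box * round(d / box) # minimum image, per row below
  e_bond <- if (nrow(topo$bonds)) {
    db <- pos[topo$bonds[, 1], , drop = FALSE] -
      pos[topo$bonds[, 2], , drop = FALSE]
    db <- t(apply(db, 1, mi))
    sum(bond_energy(sqrt(rowSums(db^2)), ff$k_bond, ff$r0))
  } else 0
  e_ang <- 0
  if (nrow(topo$angles)) {
    for (a in seq_len(nrow(topo$angles))) {
      v1 <- mi(pos[topo$angles[a, 1], ] - pos[topo$angles[a, 2], ])
      v2 <- mi(pos[topo$angles[a, 3], ] - pos[topo$angles[a, 2], ])
      cth <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      th <- acos(max(-1, min(1, cth)))
      e_ang <- e_ang + angle_energy(th, topo$angle_k[a], ff$theta0)
    }
  }
  list(e_lj = e_pair, e_bond = e_bond, e_angle = e_ang,
       energy = e_pair + e_bond + e_ang, min_distance = dmin)
}

# exact within-cutoff pair set by the O(N^2) double loop (minimum image)
brute_pairs <- function(pos, box, r_cut) {
  n <- nrow(pos)
  r2 <- 0
  for (d in 1:3) {
    dd <- outer(pos[, d], pos[, d], "-")
    dd <- dd - box[d] * round(dd / box[d])
    r2 <- r2 + dd^2
  }
  idx <- which(upper.tri(r2) & r2 < r_cut^2, arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

rod_rg <- function(N, r0 = 1) sqrt(r0^2 * (N^2 - 1) / 12)

# one chain, loosely packed in a large box, ready to run
single_chain_system <- function(N = 20, k_theta = 0, L = 60,
                                start = "straight", seed = 1) {
  ff <- force_field(k_theta = k_theta)
  topo <- chain_topology(1, N, k_theta = k_theta)
  x <- build_chain(N, start, seed = seed)
  config <- configuration(sweep(x, 2, colMeans(x) - L / 2), rep(L, 3))
  list(config = config, topo = topo, ff = ff)
}

single_chain_traj <- function(k_theta, T_star, n_steps, seed, N = 20,
                              thermostat = "langevin", start = "straight",
                              init = NULL) {
  sys <- single_chain_system(N, k_theta, L = max(60, 1.2 * N), start = start,
                             seed = seed)
  if (!is.null(init)) # continue from an earlier final configuration
    sys$config <- configuration(init$positions, sys$config$box)
  s <- integrator_settings(n_steps = n_steps, T_target = T_star,
                           thermostat = thermostat, seed = seed,
                           thermo_every = max(n_steps %/% 20, 1000),
                           snapshot_every = 1000)
  run_md(sys$config, sys$topo, sys$ff, s)
}

run_single_chain <- function(k_theta, T_star, n_steps, seed, N = 20,
                             thermostat = "langevin",
                             equilibration_fraction = 0.25,
                             start = "straight", init = NULL) {
  traj <- single_chain_traj(k_theta, T_star, n_steps, seed, N, thermostat,
                            start, init)
  chain_observables(traj, equilibration_fraction = equilibration_fraction)
}

# random, mildly separated bead cloud for pair-set tests
random_beads <- function(n, L, seed, min_sep = 0.85) {
  set.seed(seed)
  pos <- matrix(runif(3 * n, 0, L), n, 3)
  # push apart catastrophic overlaps deterministically (keeps the oracle honest
  # without simulating): jitter any pair closer than min_sep
  for (it in 1:20) {
    pr <- brute_pairs(pos, rep(L, 3), min_sep)
    if (!nrow(pr)) break
    pos[pr[, 2], ] <- pos[pr[, 2], ] + matrix(runif(3 * nrow(pr), -0.5, 0.5),
                                              nrow(pr), 3)
    pos <- pos %% L
  }
  pos
}

# synthetic slab density profile object (for analysis-stage tests)
make_profile <- function(rho, L, axis = 3) {
  nb <- length(rho)
  out <- data.frame(coord = (seq_len(nb) - 0.5) * L / nb, rho = rho)
  attr(out, "box") <- c(10, 10, 10)
  attr(out, "box")[axis] <- L
  attr(out, "axis") <- axis
  attr(out, "bin_width") <- L / nb
  attr(out, "n_frames") <- 1L
  class(out) <- c("llps_profile", "data.frame")
  out
}

tanh_profile <- function(nb = 120, L = 36, rho_lo = 0.05, rho_hi = 0.75,
                         z1 = 12, z2 = 24, width = 1) {
  z <- (seq_len(nb) - 0.5) * L / nb
  rho <- rho_lo + (rho_hi - rho_lo) *
    (tanh((z - z1) / width) - tanh((z - z2) / width)) / 2
  make_profile(rho, L)
}
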