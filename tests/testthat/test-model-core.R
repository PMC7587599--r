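test_that("LJ pair energy: minimum, zero crossing, truncation, domain", {
  expect_equal(lj_energy(2^(1 / 6)), -1)
  expect_equal(lj_energy(1), 0)
  expect_identical(lj_energy(2.6), 0)            # beyond the 2.5 sigma cutoff
  expect_identical(lj_energy(2.5), 0)            # truncated exactly at r_cut
  expect_lt(lj_energy(2.4999), 0)                # unshifted: nonzero inside
  expect_equal(lj_energy(c(1, 2^(1 / 6), 3)), c(0, -1, 0))
  expect_equal(lj_energy(2^(1 / 6) * 2, eps = 3, sigma = 2, r_cut = 5), -3)
  expect_error(lj_energy(0), "positive")
  expect_error(lj_energy(-1), "positive")
})

test_that("bond energy is the printed harmonic without 1/2 prefactor", {
  expect_equal(bond_energy(1.0), 0)
  expect_equal(bond_energy(1.1), 0.4)
  expect_equal(bond_energy(0.9), bond_energy(1.1)) # symmetric about r0
  expect_error(bond_energy(-0.1), ">= 0")
})

test_that("bending energy in radians about theta0 = pi", {
  expect_equal(angle_energy(pi, 20), 0)
  expect_equal(angle_energy(pi - 0.1, 20), 0.2)
  expect_equal(angle_energy(pi / 2, 0), 0)       # fully flexible limit
  expect_error(angle_energy(-0.1, 1), "\\[0, pi\\]")
  expect_error(angle_energy(3.2, 1), "\\[0, pi\\]")
})

test_that("pair strengths follow the homotypic/heterotypic rules", {
  ff1 <- force_field()
  expect_equal(pair_strength("A", "A", ff1), 1)
  ff2 <- force_field(species = c("A", "B"), heterotypic_factor = 2)
  expect_equal(pair_strength("A", "A", ff2), 1)
  expect_equal(pair_strength("B", "B", ff2), 1)
  expect_equal(pair_strength("A", "B", ff2), 2)
  expect_equal(pair_strength("B", "A", ff2), pair_strength("A", "B", ff2))
  expect_error(pair_strength("A", "C", ff2), "unknown species")
  expect_error(force_field(species = c("A", "B"),
                           eps_matrix = matrix(c(1, 2, 3, 1), 2)),
               "symmetric")
  expect_error(force_field(epsilon = -1), "positive")
  expect_error(force_field(r_cut = 0.5), "r_cut")
  expect_error(force_field(theta0 = 3), "pi")
})

test_that("total energy matches analytic two-bead cases and exclusions", {
  ff <- force_field()
  # bonded dimer at r0: bond at rest, LJ excluded between bonded beads
  topo <- chain_topology(1, 2)
  cfg <- configuration(rbind(c(10, 10, 10), c(10, 10, 11)), rep(22, 3))
  res <- total_energy_forces(cfg, topo, ff)
  expect_equal(res$energy, 0)
  expect_equal(max(abs(res$forces)), 0)
  # two non-bonded beads at the LJ minimum: energy -eps, zero force
  topo2 <- chain_topology(2, 1)
  cfg2 <- configuration(rbind(c(10, 10, 10), c(10, 10, 10 + 2^(1 / 6))),
                        rep(22, 3))
  res2 <- total_energy_forces(cfg2, topo2, ff)
  expect_equal(res2$energy, -1)
  expect_lt(max(abs(res2$forces)), 1e-12)
})

test_that("energy and forces match the brute-force oracle on random chains", {
  for (seed in 1:5) {
    set.seed(seed)
    k_theta <- sample(c(0, 1, 3, 20), 1)
    ff <- force_field(k_theta = k_theta)
    topo <- chain_topology(2, 10, k_theta = k_theta)
    pos <- rbind(build_chain(10, "random_walk", seed = seed),
                 sweep(build_chain(10, "random_walk", seed = seed + 50), 2,
                       runif(3, 1, 3)))
    cfg <- configuration(pos + 10, rep(20, 3))
    res <- total_energy_forces(cfg, topo, ff)
    orc <- brute_energy(cfg$positions, cfg$box, topo, ff)
    expect_equal(res$e_lj, orc$e_lj, tolerance = 1e-12)
    expect_equal(res$e_bond, orc$e_bond, tolerance = 1e-12)
    expect_equal(res$e_angle, orc$e_angle, tolerance = 1e-10)
  }
})

test_that("forces are the exact negative gradient of the energy", {
  h <- 1e-6
  for (seed in 1:3) {
    ff <- force_field(k_theta = 3)
    topo <- chain_topology(1, 8, k_theta = 3)
    pos <- build_chain(8, "random_walk", seed = seed) + 10
    cfg <- configuration(pos, rep(20, 3))
    f <- total_energy_forces(cfg, topo, ff)$forces
    set.seed(seed)
    for (k in 1:12) {
      i <- sample(8, 1)
      d <- sample(3, 1)
      xp <- pos; xp[i, d] <- xp[i, d] + h
      xm <- pos; xm[i, d] <- xm[i, d] - h
      fd <- -(total_energy_forces(configuration(xp, cfg$box), topo, ff)$energy -
              total_energy_forces(configuration(xm, cfg$box), topo, ff)$energy) /
        (2 * h)
      expect_lt(abs(fd - f[i, d]) / max(1, abs(fd)), 1e-6)
    }
  }
})

test_that("energy is invariant under translation, rotation and re-imaging", {
  ff <- force_field(k_theta = 1)
  topo <- chain_topology(2, 8, k_theta = 1)
  pos <- rbind(build_chain(8, "random_walk", seed = 1),
               sweep(build_chain(8, "random_walk", seed = 2), 2, c(2, 1, 0)))
  box <- rep(24, 3)
  e0 <- total_energy_forces(configuration(pos + 12, box), topo, ff)$energy
  for (seed in 1:4) {
    set.seed(seed)
    shift <- runif(3, -30, 30)
    e1 <- total_energy_forces(configuration(pos + 12 +
                                              rep(shift, each = 16), box),
                              topo, ff)$energy
    expect_equal(e1, e0, tolerance = 1e-9)
    # random rotation about the cloud centre
    qrR <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(qrR) < 0) qrR[, 1] <- -qrR[, 1]
    cen <- colMeans(pos)
    rot <- sweep(sweep(pos, 2, cen) %*% t(qrR), 2, -cen)
    e2 <- total_energy_forces(configuration(rot + 12, box), topo, ff)$energy
    expect_equal(e2, e0, tolerance = 1e-9)
    # shift one bead by whole box images
    img <- pos + 12
    i <- sample(16, 1)
    img[i, ] <- img[i, ] + box * sample(c(-2, -1, 1, 2), 3, replace = TRUE)
    e3 <- total_energy_forces(configuration(img, box), topo, ff)$energy
    expect_equal(e3, e0, tolerance = 1e-9)
  }
})

test_that("Newton's third law: isolated system feels zero net force", {
  ff <- force_field(k_theta = 3)
  topo <- chain_topology(3, 7, k_theta = 3)
  set.seed(9)
  pos <- do.call(rbind, lapply(1:3, function(i)
    sweep(build_chain(7, "random_walk", seed = i), 2, runif(3, 0, 4))))
  res <- total_energy_forces(configuration(pos + 15, rep(30, 3)), topo, ff)
  expect_lt(max(abs(colSums(res$forces))), 1e-10)
})

test_that("uniform eps matrix reproduces the single-species energy", {
  ff1 <- force_field()
  ff2 <- force_field(species = c("A", "B"), heterotypic_factor = 1)
  topo1 <- chain_topology(2, 10)
  topo2 <- chain_topology(2, 10, species = c("A", "B"))
  pos <- rbind(build_chain(10, "random_walk", seed = 3),
               sweep(build_chain(10, "random_walk", seed = 4), 2, c(2, 0, 0)))
  cfg <- configuration(pos + 10, rep(20, 3))
  expect_equal(total_energy_forces(cfg, topo2, ff2)$energy,
               total_energy_forces(cfg, topo1, ff1)$energy)
})

test_that("overlapping beads are flagged but finite; cap bounds the energy", {
  ff <- force_field()
  topo <- chain_topology(2, 1)
  cfg <- configuration(rbind(c(10, 10, 10), c(10, 10, 10.2)), rep(22, 3))
  res <- total_energy_forces(cfg, topo, ff)
  expect_true(res$overlap)
  expect_true(is.finite(res$energy))
  capped <- total_energy_forces(cfg, topo, ff, cap_overlaps = TRUE)
  expect_true(capped$overlap)
  expect_lt(capped$energy, res$energy)
  # mismatched topology is a structural error
  expect_error(total_energy_forces(cfg, chain_topology(1, 3), ff), "beads")
})

test_that("unit conversions hit the anchors and round-trip exactly", {
  expect_equal(convert_units(1, "temperature"), 119.81)
  expect_equal(convert_units(1, "length"), 3.405)
  expect_equal(convert_units(1, "density"), 1.6447, tolerance = 1e-4)
  expect_equal(convert_units(1, "time"), 2.133e-12, tolerance = 1e-3)
  for (kind in c("temperature", "length", "density", "time", "pressure")) {
    x <- c(0.5, 1, 2.34)
    expect_equal(convert_units(convert_units(x, kind, "real"), kind,
                               "reduced"), x,
                 info = kind)
  }
  expect_error(convert_units(1, "charge"), "unsupported")
  expect_error(unit_system(epsilon_K = -1), "positive")
})
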