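test_that("straight chains have exact geometry and rod Rg", {
  x <- build_chain(20, "straight")
  expect_equal(bond_lengths <- sqrt(rowSums(diff(x)^2)), rep(1, 19))
  expect_equal(end_to_end(x), 19)
  expect_equal(radius_of_gyration(x), sqrt(399 / 12))
  expect_equal(radius_of_gyration(build_chain(80, "straight")),
               sqrt((80^2 - 1) / 12))
  expect_error(build_chain(1), "at least 2")
})

test_that("random walks are reproducible, bonded at r0 and self-avoiding", {
  x1 <- build_chain(20, "random_walk", seed = 42)
  x2 <- build_chain(20, "random_walk", seed = 42)
  expect_identical(x1, x2)
  expect_false(identical(x1, build_chain(20, "random_walk", seed = 43)))
  expect_equal(sqrt(rowSums(diff(x1)^2)), rep(1, 19), tolerance = 1e-12)
  d <- as.matrix(dist(x1))
  nonbonded <- d[abs(row(d) - col(d)) >= 2 & upper.tri(d)]
  expect_true(all(nonbonded >= 0.9))
})

test_that("annealed globules hit their Rg targets and freeze cleanly", {
  g <- make_globule(20, 1.75, seed = 1)
  expect_equal(attr(g, "rg"), 1.75, tolerance = 0.05 / 1.75)
  expect_equal(radius_of_gyration(g), attr(g, "rg"))
  expect_lt(max(abs(sqrt(rowSums(diff(g)^2)) - 1)), 0.05 + 1e-9)
  g2 <- make_globule(20, 2.40, seed = 1)
  expect_equal(attr(g2, "rg"), 2.40, tolerance = 0.05 / 2.40)
  # near-rod target degenerates to an almost straight chain
  expect_error(make_globule(20, 7), "target_rg")
  expect_error(make_globule(20, 1.75, seed = 1, max_steps = 0), "did not reach")
})

test_that("bulk boxes satisfy the density identity and carry no overlaps", {
  ff <- force_field()
  spec <- protein_spec(20, k_theta = 0)
  sys <- build_bulk(spec, 64, 0.6, seed = 3, ff = ff)
  expect_equal(prod(sys$config$box), 64 * 20 / 0.6)
  expect_equal(sys$config$box, rep((64 * 20 / 0.6)^(1 / 3), 3))
  expect_equal(number_density(sys$config), 0.6, tolerance = 1e-12)
  res <- total_energy_forces(sys$config, sys$topology, ff)
  expect_false(res$overlap)
  expect_gte(res$min_distance, 0.8)
  # deterministic given the seed
  sys2 <- build_bulk(spec, 64, 0.6, seed = 3, ff = ff)
  expect_identical(sys$config$positions, sys2$config$positions)
})

test_that("rigid replicas pack at moderate density and refuse impossible ones", {
  g <- make_globule(10, 1.5, seed = 2)
  spec <- protein_spec(10, rigid = TRUE, reference_structure = g)
  sys <- build_bulk(spec, 8, 0.15, seed = 4)
  expect_equal(number_density(sys$config), 0.15, tolerance = 1e-12)
  expect_equal(sys$topology$n_bodies, 8)
  res <- total_energy_forces(sys$config, sys$topology, force_field())
  expect_false(res$overlap)
  expect_error(build_bulk(spec, 27, 0.9, seed = 4), "density too high")
})

test_that("carved slabs preserve particles and show the step profile exactly", {
  ff <- force_field()
  sys <- build_bulk(protein_spec(20, 0), 27, 0.7, seed = 5, ff = ff)
  slab <- carve_slab(sys$config, sys$topology, 3)
  L <- sys$config$box[1]
  expect_equal(slab$box, c(L, L, 3 * L))
  expect_equal(nrow(slab$positions), 27 * 20)
  # chains stay whole through the re-imaging: every chain keeps exactly the
  # bond lengths and Rg it had in the bulk box
  for (c in c(1, 13, 27)) {
    idx <- which(sys$topology$chain_id == c)
    before <- unwrap_chain(sys$config$positions[idx, ], sys$config$box)
    expect_equal(sqrt(rowSums(diff(slab$positions[idx, ])^2)),
                 sqrt(rowSums(diff(before)^2)), tolerance = 1e-9)
    expect_equal(radius_of_gyration(slab$positions[idx, ], check = FALSE),
                 radius_of_gyration(before, check = FALSE), tolerance = 1e-9)
  }
  expect_error(carve_slab(sys$config, sys$topology, 1.5), ">= 2")
  # density profile of the carved state: bulk density in the central third,
  # zero outside (cross-module consistency, before any dynamics; whole
  # molecules may poke slightly past the block edges, hence the edge bins
  # are left out of the zero check)
  prof <- density_profile(slab, n_bins = 12)
  expect_equal(mean(prof$rho[6:7]), 0.7, tolerance = 0.06)
  expect_equal(prof$rho[c(1:2, 11:12)], rep(0, 4))
  # matter conservation: sum(rho) * bin volume = bead count
  expect_equal(sum(prof$rho) * attr(prof, "bin_width") * L^2, 27 * 20,
               tolerance = 1e-9)
})

test_that("mixtures carry the requested composition and interaction rules", {
  ff <- force_field(species = c("A", "B"), heterotypic_factor = 2)
  sys <- build_mixture(protein_spec(20, 0, species = "A"),
                       protein_spec(20, 0, species = "B"),
                       32, 32, 0.5, seed = 6, ff = ff)
  expect_equal(as.vector(table(sys$topology$species)), c(32L, 32L))
  expect_equal(sys$topology$n_chains, 64)
  # one A-B pair at the LJ minimum scores -2 eps; A-A scores -eps
  tAB <- chain_topology(2, 1, species = c("A", "B"))
  cfg <- configuration(rbind(c(10, 10, 10), c(10, 10, 10 + 2^(1 / 6))),
                       rep(22, 3))
  expect_equal(total_energy_forces(cfg, tAB, ff)$energy, -2)
  tAA <- chain_topology(2, 1, species = c("A", "A"))
  expect_equal(total_energy_forces(cfg, tAA, ff)$energy, -1)
  expect_error(build_mixture(protein_spec(20, 0, species = "A"),
                             protein_spec(20, 0, species = "A"), 2, 2, 0.3),
               "distinct species")
})
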