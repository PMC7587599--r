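test_that("velocity initialisation: zero momentum, exact temperature, determinism", {
  topo <- chain_topology(50, 20)
  v <- initialize_velocities(topo, 2, seed = 7)
  expect_lt(max(abs(colSums(v))), 1e-10)
  dof <- 3 * topo$n_beads - 3
  expect_equal(sum(v^2) / dof, 2, tolerance = 1e-12)
  expect_identical(v, initialize_velocities(topo, 2, seed = 7))
  expect_false(identical(v, initialize_velocities(topo, 2, seed = 8)))
})

test_that("same seed and settings give a bit-identical trajectory", {
  sys <- single_chain_system(10, k_theta = 1, L = 30)
  s <- integrator_settings(n_steps = 5000, T_target = 2, seed = 3,
                           thermo_every = 1000, snapshot_every = 1000)
  t1 <- run_md(sys$config, sys$topo, sys$ff, s)
  t2 <- run_md(sys$config, sys$topo, sys$ff, s)
  expect_identical(t1$frames, t2$frames)
  expect_identical(t1$thermo, t2$thermo)
  s2 <- integrator_settings(n_steps = 5000, T_target = 2, seed = 4,
                            thermo_every = 1000, snapshot_every = 1000)
  expect_false(identical(run_md(sys$config, sys$topo, sys$ff, s2)$frames,
                         t1$frames))
})

test_that("NVE conserves the shifted-tally total energy", {
  sys <- single_chain_system(20, k_theta = 3, L = 30, start = "random_walk",
                             seed = 3)
  sys$config$velocities <- initialize_velocities(sys$topo, 2, 11)
  s <- integrator_settings(n_steps = 2e4, ensemble = "nve",
                           thermo_every = 500, snapshot_every = 2e4)
  tr <- run_md(sys$config, sys$topo, sys$ff, s)
  ec <- nve_conserved_energy(tr, sys$ff)
  expect_lt((max(ec) - min(ec)) / 20, 1e-4)
})

test_that("NVT reproduces the target kinetic temperature in the mean", {
  sys <- single_chain_system(20, k_theta = 0, L = 30, start = "random_walk",
                             seed = 5)
  for (th in c("nose-hoover", "langevin")) {
    s <- integrator_settings(n_steps = 2e5, T_target = 2, thermostat = th,
                             seed = 21, thermo_every = 1000,
                             snapshot_every = 2e5)
    tr <- run_md(sys$config, sys$topo, sys$ff, s)
    Tk <- tr$thermo$T_kin[-(1:20)]
    se <- sd(Tk) / sqrt(length(Tk) / 10) # ~10-sample decorrelation
    expect_lt(abs(mean(Tk) - 2), max(3 * se, 0.05), label = th)
  }
})

test_that("a very stiff chain approaches the rigid-rod limit", {
  # thermal bond stretching lengthens the effective rod: normalise the
  # measured Rg by the mean bond length before comparing to the closed form
  sys <- single_chain_system(20, k_theta = 2000, L = 60)
  s <- integrator_settings(n_steps = 4e5, T_target = 2,
                           thermostat = "langevin", seed = 13,
                           thermo_every = 1e5, snapshot_every = 1000)
  tr <- run_md(sys$config, sys$topo, sys$ff, s)
  keep <- seq(101, n_frames(tr))
  rg_over_b <- vapply(keep, function(i) {
    x <- tr$frames[, , i]
    radius_of_gyration(x, check = FALSE) /
      mean(sqrt(rowSums(diff(x)^2)))
  }, numeric(1))
  expect_equal(mean(rg_over_b), rod_rg(20), tolerance = 0.02)
})

test_that("pressure control drives the box towards the target pressure", {
  # chain fluid at rho* = 0.35, T* = 2.5 sits near zero pressure; compressing
  # to p* = 0.3 must shrink the box and settle the mean pressure at the target
  ff <- force_field()
  sys <- build_bulk(protein_spec(20, 0), 12, 0.35, seed = 2, ff = ff)
  s0 <- integrator_settings(n_steps = 2e4, T_target = 2.5, seed = 5,
                            thermo_every = 1000, snapshot_every = 2e4)
  nvt <- run_md(sys$config, sys$topology, ff, s0)
  s1 <- integrator_settings(n_steps = 9e4, T_target = 2.5,
                            ensemble = "npt", p_target = 0.3, seed = 6,
                            thermo_every = 1000, snapshot_every = 9e4)
  npt <- run_md(nvt$final, sys$topology, ff, s1)
  p_mean <- mean(tail(npt$thermo$p, 30))
  expect_lt(npt$final$box[1], nvt$final$box[1])
  expect_lt(abs(p_mean - 0.3), 0.1)
  expect_gt(tail(npt$thermo$rho, 1), 0.4)
})

test_that("numeric blow-up aborts with a diagnostic", {
  # a timestep far above the stable limit of the stiff bonds must abort,
  # not return garbage
  sys <- single_chain_system(20, k_theta = 0, L = 30, start = "random_walk",
                             seed = 2)
  sys$config$velocities <- initialize_velocities(sys$topo, 2, 3)
  s <- integrator_settings(n_steps = 5000, dt = 0.05, ensemble = "nve",
                           thermo_every = 10, snapshot_every = 5000)
  expect_error(run_md(sys$config, sys$topo, sys$ff, s), "blow-up")
})
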