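test_that("radius of gyration and end-to-end distance: closed forms", {
  expect_equal(radius_of_gyration(matrix(5, 7, 3), check = FALSE), 0)
  expect_equal(radius_of_gyration(build_chain(20, "straight")), sqrt(399 / 12))
  expect_equal(radius_of_gyration(build_chain(80, "straight")),
               sqrt(6399 / 12))
  expect_equal(end_to_end(build_chain(20, "straight")), 19)
  ring <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0), c(0, 0, 0))
  expect_equal(end_to_end(ring, check = FALSE), 0) # closed loop
  # mass weighting, by hand on a 3-bead rod with a heavy end bead:
  # com = 0.75, Rg^2 = (2 * 0.75^2 + 0.25^2 + 1.25^2) / 4
  x <- build_chain(3, "straight")
  expect_equal(radius_of_gyration(x, masses = c(2, 1, 1), check = FALSE),
               sqrt((2 * 0.75^2 + 0.25^2 + 1.25^2) / 4))
})

test_that("random chains respect the contour-length bound on Dee", {
  for (seed in 1:10) {
    x <- build_chain(30, "random_walk", seed = seed)
    expect_lte(end_to_end(x), 29 * (1 + 1e-9))
    expect_gte(end_to_end(x), 0)
  }
})

test_that("broken molecules are rejected; unwrapping restores invariance", {
  box <- c(12, 12, 12)
  x <- sweep(build_chain(10, "random_walk", seed = 3), 2, c(6, 6, 11))
  wrapped <- x %% rep(box, each = 10)
  expect_error(radius_of_gyration(wrapped), "broken molecule")
  fixed <- unwrap_chain(wrapped, box)
  expect_equal(radius_of_gyration(fixed), radius_of_gyration(x, check = FALSE),
               tolerance = 1e-12)
  expect_equal(end_to_end(fixed), end_to_end(x, check = FALSE),
               tolerance = 1e-12)
})

test_that("Rg and Dee are invariant under rigid motion and re-imaging", {
  x <- build_chain(15, "random_walk", seed = 5)
  box <- c(20, 20, 20)
  rg0 <- radius_of_gyration(x)
  dee0 <- end_to_end(x)
  for (seed in 1:5) {
    set.seed(seed)
    R <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    y <- sweep(x %*% t(R), 2, runif(3, -40, 40))
    expect_equal(radius_of_gyration(y, check = FALSE), rg0, tolerance = 1e-10)
    expect_equal(end_to_end(y, check = FALSE), dee0, tolerance = 1e-10)
    # wrap into the box, then unwrap again
    w <- unwrap_chain(y %% rep(box, each = 15), box)
    expect_equal(radius_of_gyration(w, check = FALSE), rg0, tolerance = 1e-10)
  }
})

test_that("intra-molecular contact counting and its exclusion rules", {
  expect_equal(count_intra_contacts(build_chain(20, "straight")), 0)
  expect_equal(count_intra_contacts(build_chain(80, "straight")), 0)
  expect_equal(count_intra_contacts(build_chain(20, "straight"), min_sep = 2),
               0) # |i-j| = 2 rod distances are 2 sigma, beyond 1.2
  # equilateral triangle of bonded beads at side 1.1: with only the directly
  # bonded pairs excluded the 1-3 pair is the single contact; the default
  # separation rule (>= 3) sees none
  tri <- rbind(c(0, 0, 0), c(1.1, 0, 0), c(0.55, 1.1 * sqrt(3) / 2, 0))
  expect_equal(count_intra_contacts(tri, min_sep = 2, check = FALSE), 1)
  expect_equal(count_intra_contacts(tri, check = FALSE), 0)
  # a hairpin: beads i and i+3 in register at 1.0 sigma
  hp <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(count_intra_contacts(hp, check = FALSE), 1)
})

test_that("two register-matched rods share exactly N inter contacts", {
  rods <- configuration(rbind(build_chain(20, "straight"),
                              sweep(build_chain(20, "straight"), 2,
                                    c(-1, 0, 0))) + 5,
                        rep(40, 3))
  topo <- chain_topology(2, 20)
  for (mode in c("pairs", "beads")) {
    cc <- count_inter_contacts(rods, topo, mode = mode)
    expect_equal(cc, c(20, 20), info = mode)
  }
  # an isolated chain has none
  lone <- configuration(build_chain(20, "straight") + 5, rep(40, 3))
  expect_equal(count_inter_contacts(lone, chain_topology(1, 20)), 0)
})

test_that("inter-contact bookkeeping: even total, enumeration invariance", {
  set.seed(8)
  n_chains <- 5
  pos <- do.call(rbind, lapply(1:n_chains, function(i)
    sweep(build_chain(10, "random_walk", seed = i), 2, runif(3, 0, 6))))
  box <- rep(14, 3)
  cfg <- configuration(pos %% rep(box, each = nrow(pos)), box)
  topo <- chain_topology(n_chains, 10)
  cc <- count_inter_contacts(cfg, topo)
  expect_gt(sum(cc), 0)
  expect_equal(sum(cc) %% 2, 0) # every pair feeds two chains
  # relabel chains (reverse block order): counts permute accordingly
  perm <- rev(seq_len(n_chains))
  idx <- unlist(lapply(perm, function(c) which(topo$chain_id == c)))
  cc2 <- count_inter_contacts(configuration(cfg$positions[idx, ], box), topo)
  expect_equal(cc2, cc[perm])
  # unique-bead counting never exceeds pair counting
  ccb <- count_inter_contacts(cfg, topo, mode = "beads")
  expect_true(all(ccb <= cc))
})

test_that("phase assignment against dividing surfaces", {
  surfaces <- c(10, 20)
  expect_equal(as.character(assign_phase(15, surfaces, 30)), "condensed")
  expect_equal(as.character(assign_phase(29, surfaces, 30)), "dilute")
  expect_equal(as.character(assign_phase(c(10.2, 19.9), surfaces, 30)),
               rep("unassigned", 2))
  # synthetic frame: 10 chains per region, all classified correctly
  com <- c(runif(10, 12, 18), (runif(10, 22.5, 37.5) %% 30))
  ph <- assign_phase(com, surfaces, 30, buffer = 1)
  expect_equal(as.character(ph), rep(c("condensed", "dilute"), each = 10))
  # wrapping dense region
  ph2 <- assign_phase(c(1, 27, 15), c(25, 5), 30, buffer = 1)
  expect_equal(as.character(ph2), c("condensed", "condensed", "dilute"))
  # homogeneous frame: everything unassigned
  expect_true(all(assign_phase(com, c(NA, NA), 30) == "unassigned"))
})

test_that("five-number summaries follow the linear-interpolation rule", {
  s <- summarize_distribution(1:5)
  expect_equal(unname(s$five_num), c(1, 2, 3, 4, 5))
  s2 <- summarize_distribution(rep(3.3, 9))
  expect_true(all(s2$five_num == 3.3))
  expect_error(summarize_distribution(1:4), "at least 5")
  set.seed(4)
  big <- rnorm(20000, mean = 7, sd = 2)
  s3 <- summarize_distribution(big)
  expect_equal(unname(s3$five_num["median"]), mean(big), tolerance = 0.01)
  expect_equal(sum(s3$histogram$count), 20000)
})

test_that("two-sample KS: identical, disjoint and calibrated null", {
  x <- c(1.2, 3.4, 2.2, 5.5)
  expect_equal(ks_two_sample(x, x)$D, 0)
  expect_equal(ks_two_sample(1:10, 101:110)$D, 1)
  expect_error(ks_two_sample(numeric(0), x), "non-empty")
  set.seed(12)
  p_ok <- vapply(1:50, function(i)
    ks_two_sample(rnorm(500), rnorm(500))$p_value > 0.01, logical(1))
  expect_gte(mean(p_ok), 0.9)
})

test_that("chain_observables table is consistent with the scalar functions", {
  sys <- single_chain_system(12, k_theta = 1, L = 30)
  s <- integrator_settings(n_steps = 2e4, T_target = 2, seed = 9,
                           thermo_every = 1e4, snapshot_every = 2000)
  tr <- run_md(sys$config, sys$topo, sys$ff, s)
  obs <- chain_observables(tr)
  expect_equal(nrow(obs), n_frames(tr))
  i <- nrow(obs)
  last <- tr$frames[, , n_frames(tr)]
  expect_equal(obs$rg[i], radius_of_gyration(last, check = FALSE))
  expect_equal(obs$dee[i], end_to_end(last, check = FALSE))
  expect_equal(obs$n_intra[i], count_intra_contacts(last, check = FALSE))
  expect_equal(obs$n_inter[i], 0)
})
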