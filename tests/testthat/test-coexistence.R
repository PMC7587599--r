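test_that("density profiles are flat for uniform systems and conserve matter", {
  set.seed(1)
  n <- 4000
  box <- c(10, 10, 30)
  pts <- cbind(runif(n, 0, 10), runif(n, 0, 10), runif(n, 0, 30))
  cfg <- configuration(pts, box)
  prof <- density_profile(cfg, n_bins = 15)
  rho_bar <- n / prod(box)
  expect_lt(max(abs(prof$rho - rho_bar)) / rho_bar, 0.25)
  expect_equal(sum(prof$rho) * attr(prof, "bin_width") * 100, n,
               tolerance = 1e-9)
  expect_error(density_profile(cfg, n_bins = 5), "10 bins")
})

test_that("a constructed two-phase step yields its plateau densities", {
  # dense central block at 0.8, empty elsewhere
  set.seed(2)
  box <- c(10, 10, 30)
  n_h <- round(0.8 * 1000)
  pts <- cbind(runif(n_h, 0, 10), runif(n_h, 0, 10), runif(n_h, 10, 20))
  prof <- density_profile(configuration(pts, box), n_bins = 30)
  pt <- coexisting_densities(prof, interface_margin = 2)
  expect_false(pt$homogeneous)
  expect_equal(pt$rho_h, 0.8, tolerance = 0.05)
  expect_lt(pt$rho_l, 0.02)
  # the dividing surfaces sit near the construction boundaries
  expect_equal(sort(pt$surfaces), c(10, 20), tolerance = 0.15)
})

test_that("tanh-shaped profiles give exact plateaus; flat profiles refuse", {
  pt <- coexisting_densities(tanh_profile(), interface_margin = 3)
  expect_false(pt$homogeneous)
  expect_equal(pt$rho_l, 0.05, tolerance = 1e-3 / 0.05)
  expect_equal(pt$rho_h, 0.75, tolerance = 1e-3 / 0.75)
  flat <- make_profile(rep(0.3, 60), 36)
  expect_true(coexisting_densities(flat)$homogeneous)
  # noisy flat profile is still homogeneous
  set.seed(3)
  noisy <- make_profile(0.3 + rnorm(60, 0, 0.01), 36)
  expect_true(coexisting_densities(noisy)$homogeneous)
  # hard step with any margin smaller than the plateau width: exact values
  step <- make_profile(c(rep(0.05, 40), rep(0.75, 40), rep(0.05, 40)), 36)
  pt2 <- coexisting_densities(step, interface_margin = 2)
  expect_equal(pt2$rho_h, 0.75, tolerance = 1e-12)
  expect_equal(pt2$rho_l, 0.05, tolerance = 1e-12)
})

test_that("the dense slab may wrap around the periodic boundary", {
  rho <- c(rep(0.7, 20), rep(0.05, 80), rep(0.7, 20))
  pt <- coexisting_densities(make_profile(rho, 36), interface_margin = 2)
  expect_false(pt$homogeneous)
  expect_equal(pt$rho_h, 0.7, tolerance = 1e-6)
  expect_equal(pt$rho_l, 0.05, tolerance = 1e-6)
})

test_that("critical-point fit recovers generating parameters exactly", {
  for (seed in 1:5) {
    set.seed(seed)
    Tc <- runif(1, 2.2, 3.2)
    rho_c <- runif(1, 0.25, 0.4)
    s1 <- runif(1, 0.8, 2)
    s2 <- runif(1, 0.02, 0.12)
    pts <- synthetic_binodal(seq(0.72, 0.94, length.out = 6) * Tc,
                             Tc, rho_c, s1, s2)
    fit <- fit_critical_point(pts)
    expect_equal(fit$Tc_star, Tc, tolerance = 1e-9)
    expect_equal(fit$rho_c, rho_c, tolerance = 1e-9)
    expect_equal(fit$s1, s1, tolerance = 1e-8)
    expect_equal(fit$s2, s2, tolerance = 1e-8)
    expect_lt(max(abs(unlist(fit$residuals))), 1e-10)
  }
})

test_that("degenerate or inconsistent point sets are flagged failures", {
  one <- synthetic_binodal(2.0)
  dup <- one[rep(1, 4), ]
  expect_error(fit_critical_point(dup), "fit failure|singular")
  expect_error(fit_critical_point(one), "at least 3")
  # order parameter growing with T implies Tc below the data: flagged
  bad <- data.frame(T_star = c(2.0, 2.1, 2.2),
                    rho_l = c(0.20, 0.15, 0.10),
                    rho_h = c(0.50, 0.56, 0.62))
  expect_error(fit_critical_point(bad), "fit failure")
  expect_error(fit_critical_point(data.frame(T_star = 1, rho_l = 0.5,
                                             rho_h = 0.2)),
               "rho_h|at least")
})

test_that("bootstrap intervals bracket the estimate and usually the truth", {
  set.seed(11)
  covered <- 0L
  for (i in 1:20) {
    pts <- synthetic_binodal(seq(1.8, 2.4, by = 0.1), Tc = 2.5, rho_c = 0.3,
                             noise_sd = 0.01)
    fit <- fit_critical_point(pts, n_boot = 40, seed = i)
    expect_false(is.null(fit$ci))
    expect_lt(fit$ci["Tc", 1], fit$Tc_star)
    expect_gt(fit$ci["Tc", 2], fit$Tc_star)
    if (fit$ci["Tc", 1] <= 2.5 && 2.5 <= fit$ci["Tc", 2])
      covered <- covered + 1L
  }
  expect_gte(covered, 12L) # nominal 95% intervals; small-sample slack
})

test_that("fitted binodal branches are monotone towards the critical point", {
  pts <- synthetic_binodal(seq(1.8, 2.4, by = 0.1), Tc = 2.5, rho_c = 0.3)
  fit <- fit_critical_point(pts)
  curve <- binodal_curve(fit, seq(1.8, 2.499, length.out = 50))
  expect_true(all(diff(curve$rho_h) < 0)) # dense branch falls towards Tc
  expect_true(all(diff(curve$rho_l) > 0)) # dilute branch rises towards Tc
  expect_lt(max(curve$rho_l), fit$rho_c)
  expect_gt(min(curve$rho_h), fit$rho_c)
})

test_that("a deep-quench direct-coexistence run phase separates", {
  pts <- run_direct_coexistence(protein_spec(20, 0), 1.5, n_replicas = 18,
                                n_equil = 3e4, n_prod = 3e4, seed = 7,
                                snapshot_every = 2000, verbose = FALSE)
  expect_false(pts$homogeneous[1])
  expect_gt(pts$rho_h[1], 0.4)
  expect_lt(pts$rho_l[1], 0.1)
  expect_gt(pts$rho_h[1], pts$rho_l[1])
})
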