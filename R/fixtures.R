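#' Exact synthetic binodal points
#'
#' Generates coexistence points that satisfy the laws of rectilinear
#' diameters and critical exponents exactly, for fit validation:
#' `(rho_h - rho_l)^alpha = s1 (1 - T/Tc)` and
#' `(rho_h + rho_l)/2 = rho_c + s2 (Tc - T)`.
#'
#' @param T_star temperatures (all below `Tc`).
#' @param Tc,rho_c critical temperature and density.
#' @param s1,s2 law coefficients.
#' @param alpha critical exponent.
#' @param noise_sd optional Gaussian noise added to both densities.
#' @return data.frame with `T_star`, `rho_l`, `rho_h`.
#' @export
synthetic_binodal <- function(T_star, Tc = 2.5, rho_c = 0.3, s1 = 1.5,
                              s2 = 0.08, alpha = 3.06, noise_sd = 0) {
  if (any(T_star >= Tc)) stop("all temperatures must lie below Tc")
  d <- (s1 * (1 - T_star / Tc))^(1 / alpha)
  m <- rho_c + s2 * (Tc - T_star)
  out <- data.frame(T_star = T_star, rho_l = m - d / 2, rho_h = m + d / 2)
  if (noise_sd > 0) {
    out$rho_l <- out$rho_l + rnorm(nrow(out), sd = noise_sd)
    out$rho_h <- out$rho_h + rnorm(nrow(out), sd = noise_sd)
  }
  out
}

# uniformly random points in a z-slab of the box (synthetic ideal gas)
random_points_slab <- function(n, box, z_lo, z_hi) {
  cbind(runif(n, 0, box[1]), runif(n, 0, box[2]), runif(n, z_lo, z_hi))
}

#' Generate the synthetic test-fixture bundle
#'
#' Writes every file-based fixture the test suite and CLI examples use:
#' straight rods (N = 20, 80), a random coil, a two-rod contact geometry, a
#' synthetic two-phase slab frame, and noise-free plus noisy synthetic
#' binodal tables, together with a JSON manifest holding each fixture's
#' expected values (the single source of truth for file-based tests). All
#' fixtures are constructed, not simulated.
#'
#' @param dir output directory (created if missing).
#' @param seed integer seed.
#' @return invisibly, the manifest as a list.
#' @export
generate_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  p <- function(...) file.path(dir, ...)
  manifest <- list(seed = seed, provenance = "constructed fixtures; no simulation")

  box20 <- rep(50, 3)
  for (N in c(20L, 80L)) {
    rod <- build_chain(N, "straight")
    topo <- chain_topology(1, N)
    nm <- sprintf("rod%d.xyz", N)
    write_xyz(configuration(sweep(rod, 2, c(-25, -25, -5)), rep(max(100, 3 * N), 3)),
              p(nm), topo)
    manifest[[sprintf("rod%d", N)]] <- list(
      file = nm, rg = sqrt((N^2 - 1) / 12), dee = N - 1, n_intra = 0)
  }

  coil <- build_chain(20, "random_walk", seed = seed)
  write_xyz(configuration(sweep(coil, 2, colMeans(coil) - 25), box20),
            p("coil20.xyz"), chain_topology(1, 20))
  manifest$coil20 <- list(file = "coil20.xyz",
                          rg = radius_of_gyration(coil),
                          dee = end_to_end(coil),
                          n_intra = count_intra_contacts(coil),
                          min_nonbonded_distance = 0.9)

  # two parallel 20-bead rods offset by 1.0 sigma: only register-matched
  # bead pairs sit within 1.2 sigma (off-register pairs are at sqrt(2))
  rods <- rbind(build_chain(20, "straight"),
                sweep(build_chain(20, "straight"), 2, c(-1, 0, 0)))
  write_xyz(configuration(sweep(rods, 2, c(-25, -25, -5)), box20),
            p("two_rods.xyz"), chain_topology(2, 20))
  manifest$two_rods <- list(file = "two_rods.xyz", offset = 1.0,
                            n_inter_per_chain = 20)

  # synthetic two-phase slab: ideal-gas beads at rho* 0.75 (central third)
  # and 0.05 elsewhere in a 10 x 10 x 30 box
  slab_box <- c(10, 10, 30)
  rho_h <- 0.75
  rho_l <- 0.05
  n_h <- round(rho_h * 10 * 10 * 10)
  n_l <- round(rho_l * 10 * 10 * 20)
  pts <- rbind(random_points_slab(n_h, slab_box, 10, 20),
               random_points_slab(n_l %/% 2, slab_box, 0, 10),
               random_points_slab(n_l - n_l %/% 2, slab_box, 20, 30))
  write_xyz(configuration(pts, slab_box), p("slab.xyz"),
            chain_topology(nrow(pts), 1))
  manifest$slab <- list(file = "slab.xyz", rho_h = rho_h, rho_l = rho_l,
                        dense_interval = c(10, 20))

  bino <- list(Tc = 2.5, rho_c = 0.3, s1 = 1.5, s2 = 0.08, alpha = 3.06)
  Tgrid <- seq(1.8, 2.4, by = 0.1)
  clean <- synthetic_binodal(Tgrid, bino$Tc, bino$rho_c, bino$s1, bino$s2,
                             bino$alpha)
  write_binodal_table(clean, p("binodal_exact.tsv"))
  noisy <- synthetic_binodal(Tgrid, bino$Tc, bino$rho_c, bino$s1, bino$s2,
                             bino$alpha, noise_sd = 0.01)
  write_binodal_table(noisy, p("binodal_noisy.tsv"))
  manifest$binodal <- c(bino, list(file_exact = "binodal_exact.tsv",
                                   file_noisy = "binodal_noisy.tsv",
                                   noise_sd = 0.01,
                                   temperatures = Tgrid))

  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
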