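#' Density profile along a box axis
#'
#' Mean reduced density per bin along the slab normal, averaged over the
#' frames that remain after discarding an initial equilibration fraction.
#' The profile conserves matter: `sum(rho) * bin_volume = N sigma^3`.
#'
#' @param traj an `llps_trajectory` (or a single `configuration`).
#' @param axis profile axis, `"x"`, `"y"` or `"z"`.
#' @param n_bins number of bins (>= 10).
#' @param equilibration_fraction fraction of initial frames to discard.
#' @param sigma bead diameter.
#' @return data.frame of class `llps_profile` with columns `coord` (bin
#'   centres) and `rho`; attributes carry the box, axis and bin width.
#' @export
density_profile <- function(traj, axis = "z", n_bins = 100,
                            equilibration_fraction = 0.2, sigma = 1) {
  if (n_bins < 10) stop("use at least 10 bins")
  ax <- match(match.arg(axis, c("x", "y", "z")), c("x", "y", "z"))
  if (inherits(traj, "llps_configuration")) {
    frames <- array(traj$positions, c(nrow(traj$positions), 3, 1))
    boxes <- matrix(traj$box, 1, 3)
  } else {
    keep <- production_frames(traj, equilibration_fraction)
    frames <- traj$frames[, , keep, drop = FALSE]
    boxes <- traj$box[keep, , drop = FALSE]
  }
  if (dim(frames)[3] == 0) stop("empty trajectory")
  rho <- density_profile_cpp(frames, boxes, ax - 1L, n_bins, sigma)
  L <- boxes[nrow(boxes), ax]
  out <- data.frame(coord = (seq_len(n_bins) - 0.5) * L / n_bins, rho = rho)
  attr(out, "box") <- boxes[nrow(boxes), ]
  attr(out, "axis") <- ax
  attr(out, "bin_width") <- L / n_bins
  attr(out, "n_frames") <- dim(frames)[3]
  class(out) <- c("llps_profile", "data.frame")
  out
}

#' Coexisting densities from a slab density profile
#'
#' Locates the two Gibbs dividing surfaces at the crossings of the midpoint
#' density and averages the bins farther than `interface_margin` from either
#' surface, separately for the condensed and dilute regions. If the profile
#' shows no resolvable two-plateau structure the result is an explicit
#' homogeneous classification rather than a density pair.
#'
#' @param profile an `llps_profile` from [density_profile()].
#' @param interface_margin distance from each dividing surface to exclude
#'   (reduced length; the fluctuating interfacial region).
#' @param min_contrast minimum relative plateau contrast
#'   `(rho_h - rho_l)/(rho_h + rho_l)` below which the profile is declared
#'   homogeneous.
#' @return list of class `llps_coex_point`: either
#'   `homogeneous = TRUE`, or densities `rho_l`, `rho_h` with standard
#'   errors and the dividing `surfaces`.
#' @export
coexisting_densities <- function(profile, interface_margin = 3,
                                 min_contrast = 0.25) {
  stopifnot(inherits(profile, "llps_profile"))
  rho <- profile$rho
  nb <- length(rho)
  L <- attr(profile, "box")[attr(profile, "axis")]
  bw <- attr(profile, "bin_width")
  s <- smooth3(rho)
  hi <- max(s)
  lo <- min(s)
  homogeneous <- list(homogeneous = TRUE, rho_mean = mean(rho))
  class(homogeneous) <- "llps_coex_point"
  if (hi - lo < 1e-3 || (hi - lo) / (hi + lo) < min_contrast)
    return(homogeneous)
  mid <- (hi + lo) / 2
  dense <- s >= mid
  if (all(dense) || !any(dense)) return(homogeneous)
  # largest circular run of dense bins is the condensed slab
  run <- largest_circular_run(dense)
  i1 <- run$start
  i2 <- run$end # inclusive, may wrap (i2 < i1)
  # dividing surfaces at the bin-edge crossings of the midpoint density
  z_lo <- crossing_position(s, i1, -1, mid, bw)
  z_hi <- crossing_position(s, i2, +1, mid, bw)
  margin_bins <- ceiling(interface_margin / bw)
  idx <- seq_len(nb)
  d_lo <- circ_dist(idx, i1, nb)
  d_hi <- circ_dist(idx, i2, nb)
  core <- in_run(idx, i1, i2, nb) & d_lo > margin_bins & d_hi > margin_bins
  far <- !in_run(idx, i1, i2, nb) & d_lo > margin_bins & d_hi > margin_bins
  if (!any(core) || !any(far)) return(homogeneous)
  rho_h <- mean(rho[core])
  rho_l <- mean(rho[far])
  se <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else 0
  if (rho_h - rho_l < min_contrast * (rho_h + rho_l)) return(homogeneous)
  structure(list(homogeneous = FALSE, rho_l = rho_l, rho_h = rho_h,
                 se_l = se(rho[far]), se_h = se(rho[core]),
                 surfaces = c(z_lo, z_hi) %% L),
            class = "llps_coex_point")
}

#' @export
print.llps_coex_point <- function(x, ...) {
  if (isTRUE(x$homogeneous)) {
    cat("homogeneous (no two-plateau structure)",
        if (!is.null(x$rho_mean)) sprintf("; mean rho* = %.4f", x$rho_mean),
        "\n", sep = "")
  } else {
    cat(sprintf("coexisting densities: rho_l* = %.4f (%.4f), rho_h* = %.4f (%.4f)\n",
                x$rho_l, x$se_l, x$rho_h, x$se_h))
  }
  invisible(x)
}

smooth3 <- function(x) {
  n <- length(x)
  (x + x[c(n, seq_len(n - 1))] + x[c(seq_len(n - 1) + 1, 1)]) / 3
}

largest_circular_run <- function(flag) {
  n <- length(flag)
  # unroll twice to capture wrapping runs
  f2 <- c(flag, flag)
  best <- c(len = 0, start = 1, end = 1)
  i <- 1
  while (i <= n) {
    if (f2[i]) {
      j <- i
      while (j < i + n && f2[j + 1]) j <- j + 1
      len <- j - i + 1
      if (len > best["len"])
        best <- c(len = len, start = i, end = ((j - 1) %% n) + 1)
      i <- j + 1
    } else i <- i + 1
  }
  list(start = unname(best["start"]), end = unname(best["end"]))
}

# linear interpolation of the mid-density crossing adjacent to run edge i,
# moving outward in direction dir (-1 for the lower edge, +1 for the upper)
crossing_position <- function(s, i, dir, mid, bw) {
  n <- length(s)
  j <- ((i - 1 + dir) %% n) + 1 # first bin outside the dense run
  si <- s[i]
  sj <- s[j]
  frac <- if (abs(si - sj) < 1e-12) 0.5 else (si - mid) / (si - sj)
  frac <- min(max(frac, 0), 1)
  (i - 0.5 + dir * frac) * bw
}

circ_dist <- function(i, j, n) pmin(abs(i - j), n - abs(i - j))

in_run <- function(idx, i1, i2, n) {
  if (i1 <= i2) idx >= i1 & idx <= i2 else idx >= i1 | idx <= i2
}

#' Direct-coexistence protocol over a temperature list
#'
#' For each temperature: start from a freshly carved slab (a bulk liquid at
#' `rho_slab`, relaxed, equilibrated briefly, elongated along z), run NVT
#' equilibration with a stationarity check on the two plateau means across
#' trajectory halves, then production, and extract the coexisting densities
#' from the z density profile. Temperatures where the slab dissolves are
#' reported as homogeneous.
#'
#' @param spec an [protein_spec()].
#' @param T_list reduced temperatures to probe.
#' @param n_replicas chain replicas in the slab.
#' @param rho_slab density of the condensed starting block.
#' @param elongation_factor slab elongation along z.
#' @param n_equil,n_prod equilibration / production steps per temperature
#'   (`n_equil` may be a vector, recycled over `T_list`).
#' @param seed integer seed.
#' @param ladder start each temperature after the first from the previous
#'   temperature's final state instead of a fresh slab (a heating ladder;
#'   cheaper equilibration along a temperature sweep).
#' @param ff force field.
#' @param n_bins,interface_margin,equilibration_fraction profile options.
#' @param thermostat thermostat for the NVT runs.
#' @param snapshot_every production snapshot cadence (steps).
#' @param verbose print progress.
#' @return data.frame of class `llps_binodal_points` with one row per
#'   temperature: `T_star`, `rho_l`, `rho_h`, `se_l`, `se_h`, `homogeneous`,
#'   `stationary`.
#' @export
run_direct_coexistence <- function(spec, T_list, n_replicas = 64,
                                   rho_slab = 0.7, elongation_factor = 3,
                                   n_equil = 4e5, n_prod = 4e5, seed = 1L,
                                   ff = force_field(species = spec$species,
                                                    k_theta = spec$k_theta),
                                   n_bins = 100, interface_margin = 3,
                                   equilibration_fraction = 0,
                                   thermostat = "nose-hoover",
                                   snapshot_every = 2000L, ladder = FALSE,
                                   verbose = interactive()) {
  n_equil <- rep_len(as.numeric(n_equil), length(T_list))
  bulk <- build_bulk(spec, n_replicas, rho_slab, seed = seed, ff = ff)
  # settle the dense block at the lowest probed temperature before carving
  pre <- integrator_settings(n_steps = 2e4, T_target = min(T_list),
                             thermostat = "langevin", seed = seed + 1L,
                             cap_lj = TRUE, thermo_every = 1e4,
                             snapshot_every = 2e4)
  bulk_run <- run_md(bulk$config, bulk$topology, ff, pre)
  rows <- vector("list", length(T_list))
  prev_final <- NULL
  for (k in seq_along(T_list)) {
    Tk <- T_list[k]
    if (ladder && !is.null(prev_final)) {
      slab <- prev_final
    } else {
      slab <- carve_slab(bulk_run$final, bulk$topology, elongation_factor, "z")
    }
    slab$velocities <- NULL # re-draw at the run temperature
    eq <- integrator_settings(n_steps = n_equil[k], T_target = Tk,
                              thermostat = thermostat,
                              seed = seed + 100L * k,
                              thermo_every = max(n_equil[k] %/% 20, 1000),
                              snapshot_every = snapshot_every)
    eq_run <- run_md(slab, bulk$topology, ff, eq)
    stationary <- plateau_stationary(eq_run, n_bins, interface_margin)
    pr <- integrator_settings(n_steps = n_prod, T_target = Tk,
                              thermostat = thermostat,
                              seed = seed + 100L * k + 1L,
                              thermo_every = max(n_prod %/% 20, 1000),
                              snapshot_every = snapshot_every)
    pr_run <- run_md(eq_run$final, bulk$topology, ff, pr)
    pr_run$topology <- bulk$topology
    prev_final <- pr_run$final
    prof <- density_profile(pr_run, "z", n_bins, equilibration_fraction)
    pt <- coexisting_densities(prof, interface_margin)
    rows[[k]] <- data.frame(
      T_star = Tk,
      rho_l = if (pt$homogeneous) NA_real_ else pt$rho_l,
      rho_h = if (pt$homogeneous) NA_real_ else pt$rho_h,
      se_l = if (pt$homogeneous) NA_real_ else pt$se_l,
      se_h = if (pt$homogeneous) NA_real_ else pt$se_h,
      homogeneous = pt$homogeneous, stationary = stationary)
    if (verbose)
      message(sprintf("T* = %.3f: %s", Tk,
                      if (pt$homogeneous) "homogeneous" else
                        sprintf("rho_l* = %.4f, rho_h* = %.4f",
                                pt$rho_l, pt$rho_h)))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("llps_binodal_points", "data.frame")
  out
}

# plateau means agree across the two halves of a run (slab has stopped drifting)
plateau_stationary <- function(traj, n_bins, interface_margin, rel_tol = 0.15) {
  nf <- n_frames(traj)
  if (nf < 6) return(NA)
  halves <- list(seq_len(nf %/% 2), (nf %/% 2 + 1):nf)
  vals <- lapply(halves, function(keep) {
    sub <- traj
    sub$frames <- traj$frames[, , keep, drop = FALSE]
    sub$box <- traj$box[keep, , drop = FALSE]
    sub$times <- traj$times[keep]
    pt <- coexisting_densities(density_profile(sub, "z", n_bins, 0),
                               interface_margin)
    if (pt$homogeneous) c(NA, NA) else c(pt$rho_l, pt$rho_h)
  })
  a <- vals[[1]]; b <- vals[[2]]
  if (anyNA(a) || anyNA(b)) return(anyNA(a) == anyNA(b))
  abs(a[2] - b[2]) / b[2] < rel_tol &&
    abs(a[1] - b[1]) < max(0.05, rel_tol * b[2])
}

#' Critical point from coexistence densities
#'
#' Joint least-squares fit of the law of critical exponents
#' `(rho_h - rho_l)^alpha = s1 (1 - T/Tc)` and the law of rectilinear
#' diameters `(rho_h + rho_l)/2 = rho_c + s2 (Tc - T)`, with `alpha = 3.06`
#' (the 3D Ising value on this parametrisation). Both laws are linear in T,
#' so the fit is two linear regressions: the first yields `Tc` and `s1`, the
#' second `rho_c` and `s2` given `Tc`.
#'
#' @param points data.frame with columns `T_star`, `rho_l`, `rho_h` (>= 3
#'   phase-separated rows; homogeneous rows are dropped with a message).
#' @param alpha critical exponent.
#' @param n_boot bootstrap resamples for uncertainty intervals (0 = none).
#' @param seed seed for the bootstrap.
#' @return object of class `llps_binodal_fit`: `Tc_star`, `rho_c`, `s1`,
#'   `s2`, `alpha`, per-law `residuals`, and bootstrap quantiles when
#'   requested.
#' @export
fit_critical_point <- function(points, alpha = 3.06, n_boot = 0, seed = 1L) {
  pts <- as.data.frame(points)
  if (!all(c("T_star", "rho_l", "rho_h") %in% names(pts)))
    stop("points must provide T_star, rho_l, rho_h")
  if ("homogeneous" %in% names(pts) && any(pts$homogeneous %in% TRUE)) {
    message("dropping ", sum(pts$homogeneous), " homogeneous point(s)")
    pts <- pts[!pts$homogeneous, ]
  }
  pts <- pts[stats::complete.cases(pts[, c("T_star", "rho_l", "rho_h")]), ]
  if (nrow(pts) < 3) stop("need at least 3 phase-separated points")
  if (any(pts$rho_h <= pts$rho_l)) stop("rho_h must exceed rho_l")
  core <- function(p) {
    y1 <- (p$rho_h - p$rho_l)^alpha
    f1 <- lm(y1 ~ p$T_star)
    a <- coef(f1)[[1]]; b <- coef(f1)[[2]]
    if (!is.finite(b) || b >= 0)
      stop("fit failure: order parameter does not shrink with temperature")
    Tc <- -a / b
    y2 <- (p$rho_h + p$rho_l) / 2
    f2 <- lm(y2 ~ p$T_star)
    c2 <- coef(f2)[[1]]; d2 <- coef(f2)[[2]]
    list(Tc = Tc, s1 = a, rho_c = c2 + d2 * Tc, s2 = -d2,
         res1 = stats::residuals(f1), res2 = stats::residuals(f2))
  }
  fit <- core(pts)
  if (!is.finite(fit$Tc) || fit$Tc <= max(pts$T_star))
    stop(sprintf("fit failure: Tc* = %.4f does not exceed the highest fitted temperature %.4f",
                 fit$Tc, max(pts$T_star)))
  boot <- NULL
  ci <- NULL
  if (n_boot > 0) {
    set.seed(seed)
    bs <- lapply(seq_len(n_boot), function(i) {
      idx <- sample(nrow(pts), replace = TRUE)
      out <- try(core(pts[idx, ]), silent = TRUE)
      if (inherits(out, "try-error") || !is.finite(out$Tc) ||
          out$Tc <= 0 || out$Tc > 10 * fit$Tc)
        return(NULL)
      c(Tc = out$Tc, rho_c = out$rho_c)
    })
    bs <- do.call(rbind, bs[!vapply(bs, is.null, logical(1))])
    if (!is.null(bs) && nrow(bs) >= max(10, n_boot / 2)) {
      boot <- as.data.frame(bs)
      # normal-theory interval with the bootstrap standard error: percentile
      # intervals undercover at the few-point sample sizes typical of
      # coexistence tables
      ci <- rbind(
        Tc = fit$Tc + c(-1.96, 1.96) * sd(bs[, "Tc"]),
        rho_c = fit$rho_c + c(-1.96, 1.96) * sd(bs[, "rho_c"]))
      colnames(ci) <- c("2.5%", "97.5%")
    }
  }
  structure(list(Tc_star = fit$Tc, rho_c = fit$rho_c, s1 = fit$s1,
                 s2 = fit$s2, alpha = alpha,
                 residuals = list(order_parameter = unname(fit$res1),
                                  diameter = unname(fit$res2)),
                 points = pts, boot = boot, ci = ci),
            class = "llps_binodal_fit")
}

#' @export
print.llps_binodal_fit <- function(x, ...) {
  cat(sprintf("Critical point (alpha = %.2f): Tc* = %.6g, rho_c* = %.6g\n",
              x$alpha, x$Tc_star, x$rho_c))
  cat(sprintf("  s1 = %.6g, s2 = %.6g; fitted on %d points up to T* = %.4g\n",
              x$s1, x$s2, nrow(x$points), max(x$points$T_star)))
  cat(sprintf("  rms residuals: order parameter %.3g, diameter %.3g\n",
              sqrt(mean(x$residuals$order_parameter^2)),
              sqrt(mean(x$residuals$diameter^2))))
  if (!is.null(x$ci)) {
    cat(sprintf("  bootstrap 95%% CI: Tc* in [%.4g, %.4g], rho_c* in [%.4g, %.4g]\n",
                x$ci["Tc", 1], x$ci["Tc", 2], x$ci["rho_c", 1],
                x$ci["rho_c", 2]))
  }
  invisible(x)
}

#' Fitted binodal branches
#'
#' Evaluates the fitted dense and dilute coexistence branches at the given
#' temperatures (must not exceed the fitted Tc).
#'
#' @param fit an `llps_binodal_fit`.
#' @param T_star temperatures (reduced).
#' @return data.frame with `T_star`, `rho_l`, `rho_h`.
#' @export
binodal_curve <- function(fit, T_star) {
  stopifnot(inherits(fit, "llps_binodal_fit"))
  T_star <- T_star[T_star <= fit$Tc_star]
  d <- (pmax(fit$s1 * (1 - T_star / fit$Tc_star), 0))^(1 / fit$alpha)
  m <- fit$rho_c + fit$s2 * (fit$Tc_star - T_star)
  data.frame(T_star = T_star, rho_l = m - d / 2, rho_h = m + d / 2)
}
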