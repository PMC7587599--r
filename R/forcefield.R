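#' Force field for the coarse-grained IDR model
#'
#' Bundles every interaction constant of the model: the species-pair
#' Lennard-Jones well depths (`eps_matrix`), the bead diameter `sigma` (the
#' unit of length), the LJ cutoff, the harmonic bond constants and the
#' bending stiffness. Defaults are the model's canonical parameters:
#' `k_bond = 40` epsilon/sigma^2, `r0 = 1` sigma, cutoff `2.5` sigma,
#' resting angle `theta0 = pi`. The LJ potential is truncated and unshifted
#' at the cutoff.
#'
#' The bending constant `k_theta` (in epsilon/rad^2) is declared per species
#' so that chain types of different flexibility can coexist in one system;
#' `k_theta = 0` is a fully flexible random coil, `k_theta = 20` a fully
#' extended chain.
#'
#' @param epsilon homotypic LJ well depth (energy, reduced); the unit of energy.
#' @param species character vector of species labels (e.g. `"A"` or `c("A","B")`).
#' @param k_theta bending constant(s), one per species (epsilon/rad^2, >= 0).
#' @param heterotypic_factor multiplier applied to unlike-pair well depths;
#'   `2` gives the heterotypic mixture rule eps_AB = 2 eps (and is only
#'   meaningful with two or more species).
#' @param eps_matrix optional full symmetric matrix of pair well depths with
#'   species dimnames; overrides `epsilon`/`heterotypic_factor`.
#' @param sigma bead diameter (length, reduced).
#' @param r_cut LJ cutoff (length; must exceed `sigma`).
#' @param k_bond harmonic bond stiffness (energy/length^2, no 1/2 prefactor).
#' @param r0 equilibrium bond length.
#' @param theta0 resting angle in radians (must be `pi` in this model).
#' @return an object of class `llps_forcefield`.
#' @export
force_field <- function(epsilon = 1, species = "A", k_theta = 0,
                        heterotypic_factor = 1, eps_matrix = NULL,
                        sigma = 1, r_cut = 2.5 * sigma, k_bond = 40,
                        r0 = 1 * sigma, theta0 = pi) {
  species <- as.character(species)
  ns <- length(species)
  if (ns < 1 || anyDuplicated(species))
    stop("species labels must be non-empty and unique")
  if (is.null(eps_matrix)) {
    eps_matrix <- matrix(epsilon * heterotypic_factor, ns, ns,
                         dimnames = list(species, species))
    diag(eps_matrix) <- epsilon
  } else {
    eps_matrix <- as.matrix(eps_matrix)
    if (is.null(rownames(eps_matrix))) dimnames(eps_matrix) <- list(species, species)
  }
  if (!isTRUE(all.equal(eps_matrix, t(eps_matrix))))
    stop("eps_matrix must be symmetric")
  if (any(eps_matrix <= 0)) stop("eps_matrix entries must be strictly positive")
  if (r_cut <= sigma) stop("r_cut must exceed sigma")
  k_theta <- rep_len(as.numeric(k_theta), ns)
  names(k_theta) <- species
  if (any(k_theta < 0)) stop("k_theta must be >= 0")
  if (!isTRUE(all.equal(theta0, pi)))
    stop("theta0 must be pi (fully extended resting angle) in this model")
  structure(list(eps_matrix = eps_matrix, sigma = sigma, r_cut = r_cut,
                 k_bond = k_bond, r0 = r0, k_theta = k_theta,
                 theta0 = theta0, species = species),
            class = "llps_forcefield")
}

#' @export
print.llps_forcefield <- function(x, ...) {
  cat("Coarse-grained IDR force field (reduced units)\n")
  cat(sprintf("  sigma = %g, r_cut = %g (LJ truncated, unshifted)\n",
              x$sigma, x$r_cut))
  cat(sprintf("  k_bond = %g, r0 = %g, theta0 = pi\n", x$k_bond, x$r0))
  cat("  k_theta:", paste(sprintf("%s=%g", names(x$k_theta), x$k_theta),
                          collapse = ", "), "\n")
  cat("  eps matrix:\n")
  print(x$eps_matrix)
  invisible(x)
}

#' Truncated Lennard-Jones pair energy
#'
#' `4 eps ((sigma/r)^12 - (sigma/r)^6)` for r below `r_cut` and exactly zero
#' at and beyond the cutoff (truncated, unshifted).
#'
#' @param r pair distance(s), strictly positive.
#' @param eps well depth.
#' @param sigma bead diameter.
#' @param r_cut cutoff distance.
#' @return energy (vectorised over `r`).
#' @export
lj_energy <- function(r, eps = 1, sigma = 1, r_cut = 2.5 * sigma) {
  if (any(r <= 0)) stop("pair distance must be strictly positive")
  sr6 <- (sigma / r)^6
  e <- 4 * eps * (sr6 * sr6 - sr6)
  e[r >= r_cut] <- 0
  e
}

#' Harmonic bond energy
#'
#' `k_bond (r - r0)^2`, with no 1/2 prefactor.
#'
#' @param r bond length(s), >= 0.
#' @param k_bond stiffness (energy/length^2).
#' @param r0 equilibrium bond length.
#' @export
bond_energy <- function(r, k_bond = 40, r0 = 1) {
  if (any(r < 0)) stop("bond length must be >= 0")
  k_bond * (r - r0)^2
}

#' Harmonic bending energy
#'
#' `k_theta (theta - theta0)^2` with `theta` in radians and resting angle
#' `theta0 = pi`; identically zero for `k_theta = 0` (fully flexible chain).
#'
#' @param theta angle(s) in radians, in `[0, pi]`.
#' @param k_theta bending constant (epsilon/rad^2).
#' @param theta0 resting angle (radians).
#' @export
angle_energy <- function(theta, k_theta, theta0 = pi) {
  if (any(theta < 0 | theta > pi)) stop("theta must lie in [0, pi]")
  k_theta * (theta - theta0)^2
}

#' Species-pair interaction strength
#'
#' Looks up the LJ well depth for a pair of species labels; symmetric in its
#' arguments. In a heterotypic binary mixture unlike pairs are twice as
#' attractive as like pairs.
#'
#' @param species_i,species_j species labels.
#' @param ff an [force_field()] object.
#' @export
pair_strength <- function(species_i, species_j, ff) {
  stopifnot(inherits(ff, "llps_forcefield"))
  lbl <- rownames(ff$eps_matrix)
  i <- match(species_i, lbl)
  j <- match(species_j, lbl)
  if (anyNA(i) || anyNA(j))
    stop("unknown species label: ",
         paste(setdiff(c(species_i, species_j), lbl), collapse = ", "))
  ff$eps_matrix[cbind(i, j)]
}
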