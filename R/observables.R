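#' Radius of gyration of one chain
#'
#' Mass-weighted root-mean-square bead distance from the chain's centre of
#' mass. Coordinates must describe a whole (unwrapped) molecule; a bond
#' longer than 1.5 r0 is treated as a wrapping artefact and raises an error.
#'
#' @param coords N x 3 matrix, beads in chain order.
#' @param masses per-bead masses (equal masses in this model).
#' @param check verify bond continuity (set `FALSE` for non-chain input).
#' @param r0 bond length used by the continuity check.
#' @export
radius_of_gyration <- function(coords, masses = NULL, check = TRUE, r0 = 1) {
  coords <- as.matrix(coords)
  if (is.null(masses)) masses <- rep(1, nrow(coords))
  if (check) check_whole_chain(coords, r0)
  com <- colSums(coords * masses) / sum(masses)
  sqrt(sum(masses * rowSums(sweep(coords, 2, com)^2)) / sum(masses))
}

#' End-to-end distance of one chain
#'
#' Distance between the first and last bead of a whole (unwrapped) chain.
#'
#' @inheritParams radius_of_gyration
#' @export
end_to_end <- function(coords, check = TRUE, r0 = 1) {
  coords <- as.matrix(coords)
  if (check) check_whole_chain(coords, r0)
  sqrt(sum((coords[nrow(coords), ] - coords[1, ])^2))
}

#' Intra-molecular contacts of one chain
#'
#' Number of bead pairs (i, j) within one chain with |i - j| >= `min_sep`
#' and distance below `r_contact` (default 1.2 sigma); an indirect measure
#' of chain compaction in the dilute phase. The default `min_sep = 3`
#' excludes directly bonded pairs and second neighbours (whose separation is
#' bounded by chain geometry rather than attraction); it is the convention
#' that reproduces the reference contact tallies for all flexible variants.
#' `min_sep = 2` excludes only directly bonded pairs.
#'
#' @param coords N x 3 matrix of one whole chain, beads in chain order.
#' @param r_contact contact cutoff (reduced length).
#' @param min_sep minimum index separation counted.
#' @param check verify bond continuity.
#' @param r0 bond length for the continuity check.
#' @export
count_intra_contacts <- function(coords, r_contact = 1.2, min_sep = 3,
                                 check = TRUE, r0 = 1) {
  coords <- as.matrix(coords)
  if (check) check_whole_chain(coords, r0)
  n <- nrow(coords)
  if (n <= min_sep) return(0L)
  d <- as.matrix(stats::dist(coords))
  sep <- abs(row(d) - col(d))
  sum(d < r_contact & sep >= min_sep & upper.tri(d))
}

#' Inter-molecular contacts per chain
#'
#' For each chain, the number of contacts with beads of other chains closer
#' than `r_contact` under minimum image. With `mode = "pairs"` (default)
#' every bead-bead pair below the cutoff counts once for each of the two
#' chains involved, so the system-wide sum is even; with `mode = "beads"`
#' each foreign bead is counted at most once per reference chain.
#'
#' @param config an [configuration()] (condensed-phase snapshot).
#' @param topo an [chain_topology()].
#' @param r_contact contact cutoff.
#' @param mode `"pairs"` or `"beads"`.
#' @return numeric vector of length `n_chains`.
#' @export
count_inter_contacts <- function(config, topo, r_contact = 1.2,
                                 mode = c("pairs", "beads")) {
  mode <- match.arg(mode)
  frames <- array(config$positions, c(topo$n_beads, 3, 1))
  res <- contact_counts_cpp(frames, matrix(config$box, 1, 3), topo$chain_id,
                            topo$n_chains, r_contact, mode, 3L)
  as.numeric(res$inter[1, ])
}

#' Per-chain observables over a trajectory
#'
#' Radius of gyration, end-to-end distance and intra-/inter-molecular
#' contact counts for every chain in every retained frame.
#'
#' @param traj an `llps_trajectory` from [run_md()].
#' @param equilibration_fraction fraction of initial frames to discard.
#' @param r_contact contact cutoff (reduced).
#' @param mode inter-contact convention, `"pairs"` or `"beads"`.
#' @param min_sep minimum index separation for intra-molecular contacts
#'   (see [count_intra_contacts()]).
#' @return data.frame with columns `frame`, `time`, `chain`, `species`,
#'   `rg`, `dee`, `n_intra`, `n_inter`.
#' @export
chain_observables <- function(traj, equilibration_fraction = 0,
                              r_contact = 1.2, mode = c("pairs", "beads"),
                              min_sep = 3) {
  mode <- match.arg(mode)
  topo <- traj$topology
  keep <- production_frames(traj, equilibration_fraction)
  frames <- traj$frames[, , keep, drop = FALSE]
  met <- chain_metrics_cpp(frames, topo$chain_id, topo$mass, topo$n_chains)
  cc <- contact_counts_cpp(frames, traj$box[keep, , drop = FALSE],
                           topo$chain_id, topo$n_chains, r_contact, mode,
                           as.integer(min_sep))
  nf <- length(keep)
  data.frame(
    frame = rep(keep, topo$n_chains),
    time = rep(traj$times[keep], topo$n_chains),
    chain = rep(seq_len(topo$n_chains), each = nf),
    species = rep(topo$species, each = nf),
    rg = as.vector(met$rg), dee = as.vector(met$dee),
    n_intra = as.vector(cc$intra), n_inter = as.vector(cc$inter))
}

# per-chain centres of mass for selected frames (n_frames x n_chains x 3)
chain_coms <- function(traj, keep = seq_len(n_frames(traj))) {
  topo <- traj$topology
  chain_metrics_cpp(traj$frames[, , keep, drop = FALSE], topo$chain_id,
                    topo$mass, topo$n_chains)$com
}

#' Assign chains to the condensed or dilute phase
#'
#' Classifies chain centres of mass against the two Gibbs dividing surfaces
#' located by [coexisting_densities()]: inside the condensed slab (minus a
#' buffer) is `"condensed"`, outside (plus the buffer) is `"dilute"`, and
#' anything within the buffer of an interface is `"unassigned"` and should
#' be excluded from per-phase histograms.
#'
#' @param com numeric vector of chain COM coordinates along the slab normal.
#' @param surfaces numeric(2): dividing-surface positions bounding the
#'   condensed region (from [coexisting_densities()]; may wrap around the
#'   periodic boundary).
#' @param box_length box edge along the slab normal.
#' @param buffer interface buffer width (reduced length).
#' @return factor with levels condensed/dilute/unassigned.
#' @export
assign_phase <- function(com, surfaces, box_length, buffer = 1) {
  if (length(surfaces) != 2 || anyNA(surfaces))
    return(factor(rep("unassigned", length(com)),
                  levels = c("condensed", "dilute", "unassigned")))
  z <- com %% box_length
  lo <- surfaces[1] %% box_length
  hi <- surfaces[2] %% box_length
  inside <- function(a, b, x) if (a <= b) x >= a & x <= b else x >= a | x <= b
  cond <- inside((lo + buffer) %% box_length, (hi - buffer) %% box_length, z)
  dil <- !inside((lo - buffer) %% box_length, (hi + buffer) %% box_length, z)
  out <- ifelse(cond, "condensed", ifelse(dil, "dilute", "unassigned"))
  factor(out, levels = c("condensed", "dilute", "unassigned"))
}

#' Five-number summary and histogram of a sample
#'
#' Quartiles use linear interpolation (type 7), the convention fixed for all
#' distribution summaries in this package.
#'
#' @param samples numeric vector (>= 5 values).
#' @param n_bins histogram bin count.
#' @return list with `five_num` (min, q1, median, q3, max), `histogram`
#'   (data.frame of bin mids and counts) and `n`.
#' @export
summarize_distribution <- function(samples, n_bins = 30) {
  samples <- as.numeric(samples)
  if (length(samples) < 5) stop("need at least 5 samples")
  q <- quantile(samples, c(0, 0.25, 0.5, 0.75, 1), names = FALSE, type = 7)
  h <- graphics::hist(samples, breaks = n_bins, plot = FALSE)
  list(five_num = c(min = q[1], q1 = q[2], median = q[3], q3 = q[4],
                    max = q[5]),
       histogram = data.frame(mid = h$mids, count = h$counts),
       n = length(samples))
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Classical two-sample KS statistic D = sup |ECDF_a - ECDF_b| with the
#' asymptotic p-value, as used to compare per-phase radius-of-gyration
#' distributions.
#'
#' @param sample_a,sample_b numeric vectors (non-empty).
#' @return list with `D` and `p_value`.
#' @export
ks_two_sample <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b)) stop("samples must be non-empty")
  k <- suppressWarnings(ks.test(sample_a, sample_b, exact = FALSE))
  list(D = unname(k$statistic), p_value = unname(k$p.value))
}
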