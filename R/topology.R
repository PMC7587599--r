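#' Chain topology
#'
#' Bead/chain bookkeeping for a system of `n_chains` homopolymer chains of
#' `chain_length` beads each: bond pairs between consecutive beads, angle
#' triplets centred on every non-terminal bead, per-chain species labels,
#' bending constants and rigid-body membership. Rigid chains carry no
#' internal bonded terms (their geometry is frozen and propagated as one
#' body), and their intra-chain LJ interactions are excluded by the engine.
#'
#' @param n_chains number of chains.
#' @param chain_length beads per chain (N >= 1; N >= 2 for bonded chains).
#' @param species per-chain species label, recycled.
#' @param k_theta per-chain bending constant (epsilon/rad^2), recycled.
#' @param rigid per-chain logical flag, recycled.
#' @param mass per-bead mass (reduced; the model uses 1).
#' @return an object of class `llps_topology`.
#' @export
chain_topology <- function(n_chains, chain_length, species = "A",
                           k_theta = 0, rigid = FALSE, mass = 1) {
  stopifnot(n_chains >= 1, chain_length >= 1)
  species <- rep_len(as.character(species), n_chains)
  k_theta <- rep_len(as.numeric(k_theta), n_chains)
  rigid <- rep_len(as.logical(rigid), n_chains)
  n_beads <- n_chains * chain_length
  chain_id <- rep(seq_len(n_chains), each = chain_length)

  bonds <- matrix(integer(0), 0, 2)
  angles <- matrix(integer(0), 0, 3)
  angle_k <- numeric(0)
  for (c in seq_len(n_chains)) {
    if (rigid[c] || chain_length < 2) next
    off <- (c - 1) * chain_length
    i <- off + seq_len(chain_length - 1)
    bonds <- rbind(bonds, cbind(i, i + 1))
    if (chain_length >= 3) {
      j <- off + seq_len(chain_length - 2)
      angles <- rbind(angles, cbind(j, j + 1, j + 2))
      angle_k <- c(angle_k, rep(k_theta[c], chain_length - 2))
    }
  }
  body <- rep(-1L, n_beads)
  nb <- 0L
  for (c in which(rigid)) {
    body[chain_id == c] <- nb
    nb <- nb + 1L
  }
  structure(list(n_chains = n_chains, chain_length = chain_length,
                 n_beads = n_beads, chain_id = chain_id, species = species,
                 k_theta = k_theta, rigid = rigid,
                 mass = rep_len(mass, n_beads),
                 bonds = bonds, angles = angles, angle_k = angle_k,
                 body = body, n_bodies = nb),
            class = "llps_topology")
}

#' @export
print.llps_topology <- function(x, ...) {
  cat(sprintf("Topology: %d chain(s) x %d beads (%d beads, %d bonds, %d angles)\n",
              x$n_chains, x$chain_length, x$n_beads, nrow(x$bonds),
              nrow(x$angles)))
  if (x$n_bodies > 0) cat(sprintf("  %d rigid bodies\n", x$n_bodies))
  cat("  species:", paste(unique(x$species), collapse = ", "),
      " k_theta:", paste(unique(x$k_theta), collapse = ", "), "\n")
  invisible(x)
}

# map per-bead species labels onto 0-based indices of the eps matrix
species_index0 <- function(topo, ff) {
  lbl <- rownames(ff$eps_matrix)
  if (length(lbl) == 1) return(rep(0L, topo$n_beads))
  sp_bead <- topo$species[topo$chain_id]
  idx <- match(sp_bead, lbl)
  if (anyNA(idx))
    stop("topology species not present in the force field: ",
         paste(unique(sp_bead[is.na(idx)]), collapse = ", "))
  as.integer(idx - 1L)
}
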