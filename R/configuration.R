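#' Particle configuration in a periodic orthorhombic box
#'
#' Positions (and optionally velocities) in reduced units. Coordinates may be
#' stored wrapped or unwrapped; the engine propagates unwrapped coordinates
#' so that molecules stay whole, and [unwrap_chain()] reconstructs whole
#' molecules from wrapped input via bond continuity.
#'
#' @param positions n x 3 numeric matrix (reduced length).
#' @param box numeric(3) edge lengths of the periodic box.
#' @param velocities optional n x 3 matrix.
#' @param time elapsed reduced time.
#' @return an object of class `llps_configuration`.
#' @export
configuration <- function(positions, box, velocities = NULL, time = 0) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must be an n x 3 matrix")
  if (!is.numeric(box) || length(box) != 3 || any(box <= 0))
    stop("box must be three positive edge lengths")
  if (!is.null(velocities)) {
    velocities <- as.matrix(velocities)
    if (!all(dim(velocities) == dim(positions)))
      stop("velocities must match positions in shape")
  }
  structure(list(positions = positions, box = as.numeric(box),
                 velocities = velocities, time = time),
            class = "llps_configuration")
}

#' @export
print.llps_configuration <- function(x, ...) {
  cat(sprintf("Configuration: %d beads, box %.4g x %.4g x %.4g (t* = %g)\n",
              nrow(x$positions), x$box[1], x$box[2], x$box[3], x$time))
  invisible(x)
}

#' Reduced number density of a configuration
#' @param config an [configuration()].
#' @param sigma bead diameter.
#' @export
number_density <- function(config, sigma = 1) {
  nrow(config$positions) * sigma^3 / prod(config$box)
}

#' Unwrap a chain across periodic boundaries
#'
#' Rebuilds a whole molecule from wrapped coordinates by walking the chain
#' and applying the minimum-image displacement bead to bead. Beads must be
#' given in chain order.
#'
#' @param coords n x 3 matrix of (possibly wrapped) positions of one chain.
#' @param box periodic box edges.
#' @return n x 3 matrix of unwrapped positions.
#' @export
unwrap_chain <- function(coords, box) {
  coords <- as.matrix(coords)
  out <- coords
  if (nrow(coords) < 2) return(out)
  for (i in 2:nrow(coords)) {
    d <- coords[i, ] - out[i - 1, ]
    d <- d - box * round(d / box)
    out[i, ] <- out[i - 1, ] + d
  }
  out
}

# consecutive-bead distances; used to detect molecules broken by wrapping
bond_lengths <- function(coords) {
  if (nrow(coords) < 2) return(numeric(0))
  sqrt(rowSums((coords[-1, , drop = FALSE] -
                coords[-nrow(coords), , drop = FALSE])^2))
}

check_whole_chain <- function(coords, r0 = 1, tol = 1.5) {
  bl <- bond_lengths(coords)
  if (length(bl) && any(bl > tol * r0))
    stop("broken molecule: a bond exceeds ", tol, " r0; unwrap the chain ",
         "across periodic boundaries first (see unwrap_chain())")
  invisible(TRUE)
}
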