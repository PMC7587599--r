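#' Reduced/real unit system
#'
#' The model's reduced units are anchored to argon-like constants chosen so
#' that phase separation happens at biologically sensible temperatures and
#' densities: `epsilon/kB = 119.81` K, `sigma = 3.405` angstrom, bead mass
#' `39.1` amu.
#'
#' @param epsilon_K LJ well depth over Boltzmann's constant, in kelvin.
#' @param sigma_A bead diameter in angstrom.
#' @param mass_amu bead mass in atomic mass units.
#' @return an object of class `llps_units`.
#' @export
unit_system <- function(epsilon_K = 119.81, sigma_A = 3.405, mass_amu = 39.1) {
  if (epsilon_K <= 0 || sigma_A <= 0 || mass_amu <= 0)
    stop("all unit constants must be strictly positive")
  structure(list(epsilon_K = epsilon_K, sigma_A = sigma_A,
                 mass_amu = mass_amu),
            class = "llps_units")
}

#' Convert between reduced and real units
#'
#' Supported kinds: `"temperature"` (T* <-> kelvin), `"length"`
#' (sigma <-> angstrom), `"density"` (rho* <-> g/cm^3), `"time"`
#' (t* <-> seconds, with the time unit sigma * sqrt(m/epsilon)), and
#' `"pressure"` (p* <-> pascal). Every conversion is multiplicative, so
#' converting there and back is the identity.
#'
#' @param value numeric value(s) to convert.
#' @param kind one of `"temperature"`, `"length"`, `"density"`, `"time"`,
#'   `"pressure"`.
#' @param to `"real"` (reduced input) or `"reduced"` (real input).
#' @param units an [unit_system()].
#' @export
convert_units <- function(value, kind, to = c("real", "reduced"),
                          units = unit_system()) {
  to <- match.arg(to)
  stopifnot(inherits(units, "llps_units"))
  kB <- 1.380649e-23          # J/K
  amu <- 1.66053906892e-24    # g
  factor <- switch(kind,
    temperature = units$epsilon_K,
    length = units$sigma_A,
    density = units$mass_amu * amu / (units$sigma_A * 1e-8)^3, # g/cm^3
    time = {
      m_kg <- units$mass_amu * amu * 1e-3
      eps_J <- kB * units$epsilon_K
      (units$sigma_A * 1e-10) * sqrt(m_kg / eps_J)            # seconds
    },
    pressure = kB * units$epsilon_K / (units$sigma_A * 1e-10)^3, # Pa
    stop("unsupported kind: ", kind)
  )
  if (to == "real") value * factor else value / factor
}
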