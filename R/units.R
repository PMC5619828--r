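#' Simulation unit system
#'
#' DPD is scale-free; a unit mapping is imposed a posteriori.  The length
#' unit is fixed at 1 um (the filament model is parameterised at that
#' scale).  The energy unit follows from the filament-block parameter
#' ratios (e.g. a filament spring constant of 0.092 N/m mapping to 8e4 sim
#' units gives ~1.15e-18 J), and the time unit from the membrane viscosity
#' parameter mapping (1.15e-9 N s/m <-> 30 sim units).  The membrane
#' bending rows imply a different energy unit; no consistency is forced --
#' both mappings are configurable and the filament-block one is the
#' default.
#'
#' @param energy physical energy per simulation energy unit (J).
#' @param length physical length per simulation length unit (m).
#' @param gamma_phys,gamma_sim a matched pair of friction coefficients
#'   (N s/m and sim units) fixing the time unit.
#' @return object of class `unit_system` with derived `time` (s), `force`
#'   (N), `pressure` (Pa), `velocity` (m/s) and `viscosity` (Pa s) units.
#' @examples
#' us <- unit_system()
#' us$time   # ~3.33e-5 s per simulation time unit
#' @export
unit_system <- function(energy = 1.15e-18, length = 1e-6,
                        gamma_phys = 1.15e-9, gamma_sim = 30) {
  stopifnot(energy > 0, length > 0, gamma_phys > 0, gamma_sim > 0)
  time <- (gamma_phys / gamma_sim) * length^2 / energy
  structure(list(
    energy = energy,
    length = length,
    time = time,
    force = energy / length,
    pressure = energy / length^3,
    velocity = length / time,
    viscosity = energy * time / length^3
  ), class = "unit_system")
}

#' @export
print.unit_system <- function(x, ...) {
  cat("<unit_system>\n")
  cat(sprintf("  energy:    %.4g J\n", x$energy))
  cat(sprintf("  length:    %.4g m\n", x$length))
  cat(sprintf("  time:      %.4g s\n", x$time))
  cat(sprintf("  pressure:  %.4g Pa\n", x$pressure))
  cat(sprintf("  viscosity: %.4g Pa s\n", x$viscosity))
  invisible(x)
}

#' Convert between physical and simulation units
#'
#' @param x numeric values.
#' @param quantity one of "energy", "length", "time", "force", "pressure",
#'   "velocity", "viscosity", "rate" (rate = 1/time).
#' @param units a [unit_system()].
#' @return converted numeric values.
#' @export
to_sim <- function(x, quantity, units = unit_system()) {
  if (quantity == "rate") return(x * units$time)
  x / units[[quantity]]
}

#' @rdname to_sim
#' @export
to_phys <- function(x, quantity, units = unit_system()) {
  if (quantity == "rate") return(x / units$time)
  x * units[[quantity]]
}
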