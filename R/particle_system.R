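#' Particle system container
#'
#' Positions, velocities, forces and type ids of all DPD particles in a
#' periodic or walled box.  Positions are kept unwrapped; the minimum-image
#' convention is applied inside all force routines.  Wall particles
#' (type 5) are frozen: zero velocity at all times.
#'
#' @param positions n x 3 numeric matrix (sim length units = um).
#' @param velocities n x 3 numeric matrix (default zero).
#' @param types integer vector of [particle_types] codes.
#' @param box lengths of the simulation box (3-vector).
#' @param periodic logical 3-vector of periodicity flags.
#' @param mass particle mass (uniform, default 1).
#' @return object of class `particle_system`.
#' @export
particle_system <- function(positions, velocities = NULL, types = NULL,
                            box, periodic = c(TRUE, TRUE, TRUE), mass = 1) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  n <- nrow(positions)
  if (ncol(positions) != 3) stop("positions must be an n x 3 matrix")
  if (is.null(velocities)) velocities <- matrix(0, n, 3)
  velocities <- as.matrix(velocities)
  storage.mode(velocities) <- "double"
  if (is.null(types)) types <- rep(1L, n)
  types <- as.integer(types)
  sys <- structure(list(positions = positions, velocities = velocities,
                        forces = matrix(0, n, 3), types = types,
                        box = as.numeric(box), periodic = as.logical(periodic),
                        mass = mass),
                   class = "particle_system")
  validate_particle_system(sys)
  sys
}

#' @rdname particle_system
#' @param sys a `particle_system`.
#' @export
validate_particle_system <- function(sys) {
  if (!all(is.finite(sys$positions))) stop("non-finite particle positions")
  if (length(sys$types) != nrow(sys$positions))
    stop("types length must match particle count")
  if (!all(sys$types %in% 1:5)) stop("unknown particle type id")
  wall <- sys$types == 5L
  if (any(wall) && any(sys$velocities[wall, ] != 0))
    stop("wall particles must have zero velocity")
  if (length(sys$box) != 3 || any(sys$box <= 0)) stop("invalid box")
  invisible(sys)
}

#' @export
print.particle_system <- function(x, ...) {
  tab <- table(factor(x$types, levels = 1:5,
                      labels = names(particle_types)))
  cat(sprintf("<particle_system> %d particles in box [%g x %g x %g]\n",
              nrow(x$positions), x$box[1], x$box[2], x$box[3]))
  print(tab)
  invisible(x)
}

#' Number of particles
#' @param sys a `particle_system`.
#' @export
n_particles <- function(sys) nrow(sys$positions)

#' Wrap positions into the primary periodic image
#' @param sys a `particle_system`.
#' @return matrix of wrapped positions (the system itself is unchanged;
#'   unwrapped coordinates are the canonical state).
#' @export
wrapped_positions <- function(sys) {
  p <- sys$positions
  for (k in 1:3) if (sys$periodic[k]) p[, k] <- p[, k] %% sys$box[k]
  p
}

#' Instantaneous kinetic temperature
#'
#' `kBT_kin = m <v^2> / 3` over mobile (non-wall) particles.
#' @param sys a `particle_system`.
#' @export
kinetic_temperature <- function(sys) {
  mob <- sys$types != 5L
  v <- sys$velocities[mob, , drop = FALSE]
  sys$mass * sum(v^2) / (3 * sum(mob))
}

#' Total momentum of mobile particles
#' @param sys a `particle_system`.
#' @export
total_momentum <- function(sys) {
  mob <- sys$types != 5L
  sys$mass * colSums(sys$velocities[mob, , drop = FALSE])
}

#' Thermostat / integration state
#'
#' @param kBT thermostat temperature (sim energy units, default 1).
#' @param dt time step (sim time units, default 1e-3).
#' @param seed RNG seed; identical seeds reproduce identical trajectories
#'   bit-for-bit on one thread.
#' @export
thermo_state <- function(kBT = 1, dt = 1e-3, seed = 1L) {
  if (dt <= 0) stop("dt must be > 0")
  structure(list(kBT = kBT, dt = dt, seed = as.integer(seed)),
            class = "thermo_state")
}
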