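#' Conservative DPD force
#'
#' Soft linear repulsion `a (1 - r/R_c) rhat` for `r < R_c`, zero beyond
#' the cutoff.  The force on particle i points away from particle j.
#'
#' @param r_ij displacement vector `r_i - r_j`.
#' @param a maximum repulsion strength.
#' @param R_c repulsion cutoff.
#' @return force vector on particle i.
#' @export
conservative_force <- function(r_ij, a, R_c) {
  r <- sqrt(sum(r_ij^2))
  if (r == 0) stop("degenerate pair: coincident particles (r = 0)")
  if (r >= R_c) return(c(0, 0, 0))
  a * (1 - r / R_c) * r_ij / r
}

#' Dissipative and random DPD pair forces
#'
#' The pair thermostat: `f_D = -gamma w_D(r) <rhat, v_ij> rhat` with
#' `w_D = w_R^2`, and `f_R = sigma w_R(r) theta rhat / sqrt(dt)` with
#' `sigma = sqrt(2 gamma kBT)` and `w_R(r) = (1 - r/R_c)^s`.  The noise
#' `theta` must be symmetric per pair (`theta_ij = theta_ji`), zero mean,
#' unit variance; the `1/sqrt(dt)` scaling makes the discrete dynamics
#' equilibrate at `kBT`.
#'
#' @param r_ij displacement `r_i - r_j`.
#' @param v_ij relative velocity `v_i - v_j`.
#' @param gamma dissipative strength (>= 0).
#' @param R_c thermostat cutoff.
#' @param kBT temperature; `sigma` is derived from it.
#' @param dt time step.
#' @param theta the pair noise variate (supply it to share between both
#'   pair members); default draws one standard normal.
#' @param s weight exponent (default 0.25).
#' @param sigma random strength; if supplied it must satisfy
#'   `sigma^2 = 2 gamma kBT`.
#' @return list with `dissipative`, `random`, and their sum `total`.
#' @export
dissipative_random_forces <- function(r_ij, v_ij, gamma, R_c, kBT = 1,
                                      dt = 1e-3, theta = stats::rnorm(1),
                                      s = 0.25, sigma = NULL) {
  if (gamma < 0) stop("configuration error: gamma < 0")
  if (is.null(sigma)) sigma <- sqrt(2 * gamma * kBT)
  if (abs(sigma^2 - 2 * gamma * kBT) > 1e-10 * max(1, sigma^2))
    stop("configuration error: sigma^2 != 2 gamma kBT")
  r <- sqrt(sum(r_ij^2))
  if (r == 0) stop("degenerate pair: coincident particles (r = 0)")
  if (r >= R_c) {
    z <- c(0, 0, 0)
    return(list(dissipative = z, random = z, total = z))
  }
  e <- r_ij / r
  wR <- (1 - r / R_c)^s
  fD <- -gamma * wR^2 * sum(e * v_ij) * e
  fR <- sigma * wR * theta / sqrt(dt) * e
  list(dissipative = fD, random = fR, total = fD + fR)
}

#' Build neighbor lists
#'
#' Cell-list search over all particle pairs within `max_cutoff`
#' (minimum-image in periodic dimensions).  Each pair appears exactly
#' once, with the smaller index first.
#'
#' @param sys a [particle_system()].
#' @param max_cutoff search radius; must not exceed a third of the box in
#'   any periodic dimension.
#' @return integer matrix of pairs (1-based).
#' @export
build_neighbor_lists <- function(sys, max_cutoff) {
  if (any(sys$periodic & sys$box < 3 * max_cutoff))
    stop("configuration error: periodic box smaller than 3x the cutoff")
  cpp_neighbor_pairs(sys$positions, sys$box, sys$periodic, max_cutoff)
}

#' Bonded force field container
#'
#' Collects the bonded terms registered with the integrator: harmonic
#' bonds/angles, cosine torsions, and triangulated-membrane blocks.
#'
#' @param bonds list(i, j, kappa, r0) or NULL.
#' @param angles list(i, j, k, kappa, theta0) or NULL.
#' @param torsions list(i, j, k, l, ktor, phi0) or NULL.
#' @param meshes list of engine mesh blocks (see [mesh_block()]).
#' @export
force_field <- function(bonds = NULL, angles = NULL, torsions = NULL,
                        meshes = list()) {
  structure(list(bonds = bonds, angles = angles, torsions = torsions,
                 meshes = meshes), class = "force_field")
}

# internal: assemble the list the C++ engine consumes
engine_model <- function(sys, table, thermo, bonded = force_field(),
                         sdf = NULL, body_force = NULL, frozen = NULL) {
  list(types = sys$types, box = sys$box, periodic = sys$periodic,
       kBT = thermo$kBT, dt = thermo$dt, mass = sys$mass,
       table = table_for_engine(table),
       frozen = frozen,
       bonds = bonded$bonds, angles = bonded$angles,
       torsions = bonded$torsions,
       meshes = if (length(bonded$meshes)) bonded$meshes else NULL,
       body_force = body_force,
       sdf = sdf)
}

#' Advance the system by DPD time steps
#'
#' Modified velocity-Verlet (lambda = 1/2) update of all non-wall
#' particles: pairwise DPD forces from the interaction table plus any
#' registered bonded terms, wall bounce-back on the signed distance
#' function, and optional body-force driving.  One symmetric noise variate
#' is drawn per interacting pair per step.
#'
#' @param sys a [particle_system()].
#' @param table an [interaction_table()].
#' @param thermo a [thermo_state()]; its seed makes the run reproducible.
#' @param nsteps number of steps.
#' @param bonded a [force_field()] of bonded terms.
#' @param sdf wall geometry (list of SDF primitives, see [sdf_union()]).
#' @param body_force list(g = force vector, types = type ids, region =
#'   optional cylinder region) or NULL.
#' @param sample_every diagnostics cadence in steps (0 = none).
#' @param track optional particle indices whose centroid and maximal
#'   coordinate along `track_axis` are recorded.
#' @param track_axis coordinate axis (1..3) for the `track_max` diagnostic.
#' @param skin Verlet-list skin distance.
#' @return the updated `particle_system`, with the diagnostics matrix in
#'   attribute `"diagnostics"`.
#' @export
run_dpd <- function(sys, table, thermo, nsteps, bonded = force_field(),
                    sdf = NULL, body_force = NULL, sample_every = 0L,
                    track = integer(0), track_axis = 1L, skin = 0.3) {
  model <- engine_model(sys, table, thermo, bonded, sdf, body_force)
  out <- cpp_run(sys$positions, sys$velocities, model, as.integer(nsteps),
                 as.double(thermo$seed), as.integer(sample_every),
                 as.integer(track), as.integer(track_axis), skin)
  sys$positions <- out$positions
  sys$velocities <- out$velocities
  sys$forces <- out$forces
  attr(sys, "diagnostics") <- out$diagnostics
  sys
}

#' @rdname run_dpd
#' @export
step <- function(sys, table, thermo, bonded = force_field(), sdf = NULL,
                 body_force = NULL) {
  run_dpd(sys, table, thermo, 1L, bonded = bonded, sdf = sdf,
          body_force = body_force)
}
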