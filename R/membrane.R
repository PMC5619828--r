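#' Membrane force components
#'
#' Each routine returns the per-vertex forces (n x 3) of one energy term
#' of the viscoelastic membrane model, evaluated at arbitrary vertex
#' positions with the mesh's reference state; the corresponding energy is
#' attached as attribute `"energy"`.  Forces are exact negative gradients
#' of their energies (verified against central differences in the test
#' suite).
#'
#' @param mesh a [tri_mesh] (carries topology and reference quantities).
#' @param positions vertex coordinates (defaults to the mesh reference).
#' @name membrane_forces
NULL

.nobox <- c(0, 0, 0)
.noper <- c(FALSE, FALSE, FALSE)

#' @describeIn membrane_forces in-plane elasticity: attractive WLC spring
#'   on every edge, `U = kBT lmax (3x^2 - 2x^3) / (4 p (1 - x))` with
#'   `x = l/lmax`, balanced by the per-triangle POW repulsion `C1 / A`.
#'   Errors if any edge reaches `x >= 1` (overstretch).
#' @export
wlc_pow_forces <- function(mesh, positions = mesh$positions) {
  out <- cpp_wlc_pow_forces(positions, mesh$edges, mesh$l0, mesh$lmax,
                            mesh$tris, mesh$C1, mesh$p, mesh$kBT,
                            .nobox, .noper)
  structure(out$forces, energy = out$energy)
}

#' @describeIn membrane_forces bending resistance
#'   `U = kb sum(1 - cos(theta - theta0))` over adjacent-triangle
#'   dihedrals, with stress-free equilibrium angles from the constructed
#'   mesh.
#' @export
bending_forces <- function(mesh, positions = mesh$positions) {
  out <- cpp_bending_forces(positions, mesh$dihedrals, mesh$phi0, mesh$kb,
                            .nobox, .noper)
  structure(out$forces, energy = out$energy)
}

#' @describeIn membrane_forces global area and volume constraints
#'   `U_a = ka kBT (A - A0)^2 / (2 l0^2 A0)`,
#'   `U_v = kv kBT (V - V0)^2 / (2 l0^3 V0)` with signed volume from the
#'   oriented triangles; errors on inconsistent (negative-volume)
#'   orientation.  Attributes `"area"` and `"volume"` carry the
#'   instantaneous values.
#' @export
area_volume_forces <- function(mesh, positions = mesh$positions) {
  out <- cpp_area_volume_forces(positions, mesh$tris, mesh$A0, mesh$V0,
                                mesh$ka, mesh$kv, mesh$kBT, mesh$l0bar)
  structure(out$forces, energy = out$energy, area = out$area,
            volume = out$volume)
}

#' @describeIn membrane_forces membrane viscosity: per-edge dissipative
#'   force `-gammaT v_ij - gammaC <v_ij, rhat> rhat` plus the matched
#'   random force built from the traceless-symmetric part of a Wiener
#'   increment matrix, so an isolated membrane equilibrates at `kBT`.
#'   Requires `gammaT = 3 gammaC` (the trace term then vanishes).
#' @param velocities vertex velocities.
#' @param dt time step (scales the random force).
#' @param seed RNG seed for the random part.
#' @param with_random include the random force (TRUE) or only the
#'   dissipative part (FALSE).
#' @export
membrane_viscous_forces <- function(mesh, positions = mesh$positions,
                                    velocities, dt = 1e-3, seed = 1,
                                    with_random = TRUE) {
  if (mesh$gammaC < 0) stop("configuration error: gammaC < 0")
  if (abs(mesh$gammaT - 3 * mesh$gammaC) > 1e-9)
    stop("configuration error: gammaT must equal 3 gammaC")
  cpp_mesh_viscous_forces(positions, velocities, mesh$edges, mesh$gammaT,
                          mesh$gammaC, mesh$kBT, dt, seed, with_random,
                          .nobox, .noper)
}

#' Instantaneous mesh area and volume
#' @param mesh a [tri_mesh].
#' @param positions vertex coordinates.
#' @export
mesh_area_volume <- function(mesh, positions = mesh$positions) {
  cpp_mesh_area_volume(positions, mesh$tris)
}
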