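#' Cytoskeleton filament network
#'
#' Chains of filament particles joined by harmonic bonds and angles,
#' direct filament-filament cross-link (CL) bonds produced by the
#' assembly pipeline, CL anchor angles, filament-CL-filament torsion
#' quadruples, and membrane-link bonds.  All indices refer to rows of
#' `positions`.
#'
#' @param positions n x 3 coordinates of filament particles.
#' @param chains list of integer vectors, one ordered chain per filament;
#'   every particle belongs to exactly one chain.
#' @param bonds data.frame(i, j, kappa, r0, class) where class is one of
#'   "filament", "crosslink", "cell_link", "nucleus_link".
#' @param angles data.frame(i, j, k, kappa, theta0, class).
#' @param torsions data.frame(i, j, k, l, ktor, phi0).
#' @param links data.frame(particle, vertex, mesh) of membrane links
#'   (vertex indexes the mesh's own vertex numbering).
#' @param box,periodic domain of the network (used during assembly).
#' @return object of class `filament_network`.
#' @export
filament_network <- function(positions, chains, bonds = NULL, angles = NULL,
                             torsions = NULL, links = NULL,
                             box = NULL, periodic = c(TRUE, TRUE, TRUE)) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  empty_bonds <- data.frame(i = integer(), j = integer(), kappa = numeric(),
                            r0 = numeric(), class = character())
  empty_angles <- data.frame(i = integer(), j = integer(), k = integer(),
                             kappa = numeric(), theta0 = numeric(),
                             class = character())
  empty_tor <- data.frame(i = integer(), j = integer(), k = integer(),
                          l = integer(), ktor = numeric(), phi0 = numeric())
  empty_links <- data.frame(particle = integer(), vertex = integer(),
                            mesh = character())
  net <- structure(list(
    positions = positions, chains = chains,
    bonds = if (is.null(bonds)) empty_bonds else bonds,
    angles = if (is.null(angles)) empty_angles else angles,
    torsions = if (is.null(torsions)) empty_tor else torsions,
    links = if (is.null(links)) empty_links else links,
    box = box, periodic = periodic
  ), class = "filament_network")
  validate_network(net)
  net
}

#' @rdname filament_network
#' @param net a `filament_network`.
#' @export
validate_network <- function(net) {
  n <- nrow(net$positions)
  idx <- unlist(net$chains)
  if (anyDuplicated(idx))
    stop("a filament particle belongs to more than one chain")
  if (length(idx) && (max(idx) > n || min(idx) < 1))
    stop("chain index out of range")
  cl <- net$bonds[net$bonds$class == "crosslink", , drop = FALSE]
  if (nrow(cl) && anyDuplicated(c(cl$i, cl$j)))
    stop("a filament particle holds more than one cross-link")
  if (nrow(net$links) && anyDuplicated(net$links$particle))
    stop("a filament particle carries more than one membrane link")
  invisible(net)
}

#' @export
print.filament_network <- function(x, ...) {
  ncl <- sum(x$bonds$class == "crosslink")
  cat(sprintf(
    "<filament_network> %d particles in %d chains | %d CL bonds | %d links | %d torsions\n",
    nrow(x$positions), length(x$chains), ncl, nrow(x$links),
    nrow(x$torsions)))
  invisible(x)
}

# chain id per particle
chain_id_of <- function(net) {
  id <- integer(nrow(net$positions))
  for (c in seq_along(net$chains)) id[net$chains[[c]]] <- c
  id
}

net_box <- function(net) {
  if (is.null(net$box)) list(box = c(0, 0, 0), periodic = rep(FALSE, 3))
  else list(box = net$box, periodic = net$periodic)
}

#' Bonded filament and cross-link forces
#'
#' Negative gradients of the harmonic terms
#' `E_bond = kappa (r - r0)^2` and `E_angle = kappa (theta - theta0)^2`
#' for filament and CL terms.  The energy is attached as attribute
#' `"energy"`, and per-bond force magnitudes (the `F` entering the Bell
#' unbinding law) as attribute `"bond_force"`.
#'
#' @param net a [filament_network()].
#' @param positions particle coordinates (defaults to the network state).
#' @return n x 3 force matrix.
#' @export
bond_angle_forces <- function(net, positions = net$positions) {
  bx <- net_box(net)
  F <- matrix(0, nrow(positions), 3)
  U <- 0
  bf <- numeric(0)
  if (nrow(net$bonds)) {
    out <- cpp_bond_forces(positions, net$bonds$i, net$bonds$j,
                           net$bonds$kappa, net$bonds$r0,
                           bx$box, bx$periodic)
    F <- F + out$forces
    U <- U + out$energy
    bf <- out$bond_force
  }
  if (nrow(net$angles)) {
    out <- cpp_angle_forces(positions, net$angles$i, net$angles$j,
                            net$angles$k, net$angles$kappa,
                            net$angles$theta0, bx$box, bx$periodic)
    F <- F + out$forces
    U <- U + out$energy
  }
  structure(F, energy = U, bond_force = bf)
}

#' Filament-CL-filament torsion forces
#'
#' Negative gradient of `k_tor (1 - cos(phi - phi0))` over the dihedral
#' of each torsion quadruple (chain neighbour of anchor A, anchor A,
#' anchor B, chain neighbour of anchor B).
#'
#' @inheritParams bond_angle_forces
#' @export
torsion_forces <- function(net, positions = net$positions) {
  if (!nrow(net$torsions))
    return(structure(matrix(0, nrow(positions), 3), energy = 0))
  bx <- net_box(net)
  out <- cpp_torsion_forces(positions,
                            as.matrix(net$torsions[, c("i", "j", "k", "l")]),
                            net$torsions$ktor, net$torsions$phi0,
                            bx$box, bx$periodic)
  structure(out$forces, energy = out$energy)
}

#' Bell-law bond kinetics parameters
#'
#' Force-dependent dissociation: `kappa(F) = kappa0 exp(lambda F / kBT)`
#' for separations `r >= r0`, and the zero-force rate `kappa0` for
#' `r < r0` (a slack tether does not feel load).
#'
#' @param kappa0 zero-force unbinding rate (1/s); must be > 0.
#' @param lambda mechanical sensitivity (um); must be >= 0.
#' @param r0 binding radius (um).
#' @return object of class `bell_params`.
#' @export
bell_params <- function(kappa0, lambda, r0) {
  if (kappa0 <= 0) stop("kappa0 must be > 0")
  if (lambda < 0) stop("lambda must be >= 0")
  structure(list(kappa0 = kappa0, lambda = lambda, r0 = r0),
            class = "bell_params")
}

#' @rdname bell_params
#' @export
bell_params_cl <- function() bell_params(78, 3.5e-5, 0.25)

#' @rdname bell_params
#' @export
bell_params_cell_link <- function() bell_params(30, 1e-4, 0.5)

#' @rdname bell_params
#' @export
bell_params_nucleus_link <- function() bell_params(78, 2e-4, 0.4)

#' Bell unbinding rate and per-step probability
#'
#' `bell_rate()` returns the physical dissociation rate (1/s);
#' `bell_unbind_probability()` converts it to the probability of
#' unbinding within `dt` simulation time units,
#' `1 - exp(-kappa(F) dt_phys)`, using the time-unit mapping.
#' Monotone nondecreasing in `F` for `r >= r0`; exponent overflow is
#' clamped to probability 1.
#'
#' @param F bond force magnitude (sim force units).
#' @param r bond separation (um).
#' @param params a [bell_params()].
#' @param kBT temperature (sim energy units).
#' @param dt elapsed simulation time (time units, e.g. `n_steps * dt`).
#' @param units a [unit_system()] fixing seconds per sim time unit.
#' @export
bell_rate <- function(F, r, params, kBT = 1) {
  stopifnot(all(F >= 0))
  arg <- ifelse(r < params$r0, 0, params$lambda * F / kBT)
  ifelse(arg > 700, Inf, params$kappa0 * exp(arg))
}

#' @rdname bell_rate
#' @export
bell_unbind_probability <- function(F, r, params, kBT = 1, dt,
                                    units = unit_system()) {
  if (dt <= 0) stop("dt must be > 0")
  rate <- bell_rate(F, r, params, kBT) # 1/s
  dt_phys <- dt * units$time
  p <- 1 - exp(-rate * dt_phys)
  pmin(p, 1)
}
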