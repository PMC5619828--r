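#' Particle type codes
#'
#' Integer type ids used throughout: fluid = 1, filament = 2, membrane = 3,
#' nucleus = 4, wall = 5.
#' @export
particle_types <- c(fluid = 1L, filament = 2L, membrane = 3L,
                    nucleus = 4L, wall = 5L)

#' Pairwise DPD interaction table
#'
#' Symmetric per-type-pair parameters of the soft conservative repulsion
#' and the pair thermostat: conservative strength `a`, dissipative strength
#' `gamma`, random strength `sigma = sqrt(2 gamma kBT)` (fixed by the
#' fluctuation-dissipation relation), a repulsion cutoff and a thermostat
#' cutoff, and the weight-function exponent `s` in
#' `w_R(r) = (1 - r/R_c)^s`.  Wall-wall interactions are excluded (wall
#' particles are frozen).
#'
#' @param a,gamma,rc_rep,rc_th 5x5 symmetric matrices (rows/cols indexed by
#'   [particle_types]).  Defaults reproduce the calibrated parameter set:
#'   fluid pairs 10/30, filament pairs strongly repulsive (a = 100) with a
#'   short repulsion cutoff 0.5 and thermostat cutoff 1.0, membranes
#'   strongly repulsive at short range.
#' @param kBT thermostat temperature (energy, sim units).
#' @param s weight exponent (default 0.25).
#' @param filament_gamma,filament_rc_th override the dissipative strength
#'   and thermostat cutoff of the filament rows (the knobs that set bulk
#'   cell viscosity).
#' @return object of class `interaction_table`.
#' @export
interaction_table <- function(a = NULL, gamma = NULL, rc_rep = NULL,
                              rc_th = NULL, kBT = 1, s = 0.25,
                              filament_gamma = NULL, filament_rc_th = NULL) {
  sym <- function(m) { m[lower.tri(m)] <- t(m)[lower.tri(m)]; m }
  if (is.null(a)) {
    a <- matrix(0, 5, 5)
    a[1, ] <- c(10, 10, 4, 4, 10)
    a[2, 2:5] <- c(100, 100, 4, 4)
    a[3, 3:5] <- c(100, 100, 10)
    a[4, 4:5] <- c(100, 10)
    a[5, 5] <- 0 # excluded
    a <- sym(a)
  }
  if (is.null(gamma)) {
    gamma <- matrix(0, 5, 5)
    gamma[1, ] <- c(30, 45, 45, 45, 30)
    gamma[2, 2:5] <- c(65, 65, 65, 65)
    gamma[3, 3:5] <- c(45, 45, 45)
    gamma[4, 4:5] <- c(45, 45)
    gamma[5, 5] <- 0
    gamma <- sym(gamma)
  }
  if (is.null(rc_rep)) {
    rc_rep <- matrix(1, 5, 5)
    # short repulsion cutoff: filament-filament/membrane, and the strongly
    # repulsive membrane pairs
    rc_rep[2, 2] <- rc_rep[2, 3] <- rc_rep[3, 2] <- 0.5
    rc_rep[3, 3] <- rc_rep[3, 4] <- rc_rep[4, 3] <- rc_rep[4, 4] <- 0.5
  }
  if (is.null(rc_th)) {
    rc_th <- matrix(1, 5, 5)
    rc_th[3, 3] <- rc_th[3, 4] <- rc_th[4, 3] <- rc_th[4, 4] <- 0.5
  }
  if (!is.null(filament_gamma)) {
    gamma[2, 1:4] <- filament_gamma
    gamma[1:4, 2] <- filament_gamma
  }
  if (!is.null(filament_rc_th)) {
    rc_th[2, 1:4] <- filament_rc_th
    rc_th[1:4, 2] <- filament_rc_th
  }
  dimnames(a) <- dimnames(gamma) <- dimnames(rc_rep) <- dimnames(rc_th) <-
    list(names(particle_types), names(particle_types))
  tb <- structure(list(a = a, gamma = gamma, sigma = sqrt(2 * gamma * kBT),
                       rc_rep = rc_rep, rc_th = rc_th, s = s, kBT = kBT),
                  class = "interaction_table")
  validate_interaction_table(tb)
  tb
}

#' @rdname interaction_table
#' @param table an `interaction_table`.
#' @export
validate_interaction_table <- function(table) {
  for (f in c("a", "gamma", "rc_rep", "rc_th")) {
    m <- table[[f]]
    if (!is.matrix(m) || any(dim(m) != 5))
      stop("interaction table field '", f, "' must be a 5x5 matrix")
    if (!isTRUE(all.equal(m, t(m))))
      stop("interaction table field '", f, "' must be symmetric")
  }
  if (any(table$gamma < 0)) stop("dissipative strength gamma must be >= 0")
  if (!isTRUE(all.equal(table$sigma^2, 2 * table$gamma * table$kBT)))
    stop("sigma inconsistent with fluctuation-dissipation: sigma^2 != 2 gamma kBT")
  invisible(table)
}

#' @export
print.interaction_table <- function(x, ...) {
  cat("<interaction_table> a/gamma (wall-wall excluded):\n")
  m <- matrix(sprintf("%g/%g", x$a, x$gamma), 5, 5,
              dimnames = dimnames(x$a))
  m[5, 5] <- "excl."
  print(m, quote = FALSE)
  invisible(x)
}

# internal: strip to the plain-list layout the C++ engine expects
table_for_engine <- function(table) {
  list(a = table$a, gamma = table$gamma, rc_rep = table$rc_rep,
       rc_th = table$rc_th, s = table$s)
}
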