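#' Effective opening size of a rectangular constriction
#'
#' The radius of the circle whose area equals the gap-by-depth opening
#' area: `sqrt(gap * depth / pi)`.
#'
#' @param gap constriction gap size (um).
#' @param depth device depth (um).
#' @return effective opening radius-like size (um).
#' @examples
#' effective_opening_size(12, 25.8) # 9.93 for the medium-cell device
#' @export
effective_opening_size <- function(gap, depth) {
  if (any(gap <= 0) || any(depth <= 0))
    stop("domain error: gap and depth must be > 0")
  sqrt(gap * depth / pi)
}

#' Signed distance function primitives
#'
#' Wall geometry is described by a list of primitives whose union is the
#' solid region; the SDF is positive inside solid, negative in fluid.
#' `sdf_slab()` makes everything outside `[lo, hi]` along one axis solid
#' (a pair of flat walls); `sdf_pipette()` is an annular tube of inner
#' radius `radius` opening at plane `x = x0` with its bore along +x;
#' `sdf_pillars()` is an equilateral triangular pillar (apex pointing
#' upstream, -x) replicated along y with the given period.
#'
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @param lo,hi fluid interval along the axis.
#' @export
sdf_slab <- function(axis, lo, hi) {
  list(kind = "slab", axis = axis, lo = lo, hi = hi)
}

#' @rdname sdf_slab
#' @param x0 mouth plane; the tube wall occupies `x >= x0`.
#' @param radius inner (bore) radius R_p (um).
#' @param thickness wall thickness (um).
#' @param cy,cz bore axis position in the y-z plane.
#' @export
sdf_pipette <- function(x0, radius, thickness = 1, cy = 0, cz = 0) {
  stopifnot(radius > 0, thickness > 0)
  list(kind = "pipette", x0 = x0, radius = radius, thickness = thickness,
       cy = cy, cz = cz)
}

#' @rdname sdf_slab
#' @param xc,yc pillar centroid.
#' @param side pillar side length (um).
#' @param period replication period along y (um); `side + gap`.
#' @export
sdf_pillars <- function(xc, yc, side, period) {
  stopifnot(side > 0, period > side)
  list(kind = "pillars", xc = xc, yc = yc, side = side, period = period)
}

#' @rdname sdf_slab
#' @param ... SDF primitives to combine (solid = union).
#' @export
sdf_union <- function(...) {
  prims <- list(...)
  # flatten nested unions / lists of primitives
  out <- list()
  for (p in prims) {
    if (!is.null(p$kind)) out[[length(out) + 1L]] <- p
    else out <- c(out, p)
  }
  out
}

#' Evaluate an SDF on points
#' @param sdf list of primitives ([sdf_union()]).
#' @param points n x 3 matrix.
#' @param box,periodic domain (periodic coordinates are wrapped before
#'   evaluation).
#' @export
sdf_eval <- function(sdf, points, box = c(0, 0, 0),
                     periodic = c(FALSE, FALSE, FALSE)) {
  cpp_sdf_eval(sdf, as.matrix(points), box, periodic)
}

#' Pipette geometry
#'
#' @param radius inner pipette radius R_p (um); the default 3 um suits a
#'   16 um cell (not printed in the source experiments; exposed as a
#'   configuration choice).
#' @param thickness wall thickness (um).
#' @param x0 mouth plane position.
#' @param cy,cz bore axis.
#' @return object of class `pipette_geometry` with the SDF in `$sdf`.
#' @export
pipette_geometry <- function(radius = 3, thickness = 1, x0 = 0, cy = 0,
                             cz = 0) {
  stopifnot(radius > 0)
  structure(list(radius = radius, thickness = thickness, x0 = x0,
                 cy = cy, cz = cz,
                 sdf = sdf_union(sdf_pipette(x0, radius, thickness, cy, cz))),
            class = "pipette_geometry")
}

#' Obstacle-array device geometry
#'
#' One constriction period of a microfluidic obstacle device: an
#' equilateral triangular pillar row (apex upstream), periodic along the
#' transverse y direction with period `side + gap`, bounded by flat walls
#' across the depth (z), periodic along the flow (x) over `row_spacing`.
#' The physical devices use gaps of 10/12/15 um at depth 25.8 um, row
#' spacing 60 um and a driving pressure drop of 0.67 Pa/um.
#'
#' @param gap gap between facing pillar edges (um).
#' @param depth device depth (um).
#' @param row_spacing spacing between obstacle rows (um) = flow period.
#' @param side pillar side length (um); defaults to `gap` (pillar scale
#'   is not printed for the physical devices and is configurable).
#' @param pressure_gradient driving pressure drop (Pa/um).
#' @return object of class `device_geometry`; `$box` is the one-period
#'   simulation box, `$sdf` the wall geometry, `$periodic` the
#'   periodicity flags (x, y periodic; z walled).
#' @export
device_geometry <- function(gap, depth = 25.8, row_spacing = 60,
                            side = gap, pressure_gradient = 0.67) {
  stopifnot(gap > 0, depth > 0, row_spacing > 0)
  period <- side + gap
  wall_pad <- 1.2
  box <- c(row_spacing, period, depth + 2 * wall_pad)
  sdf <- sdf_union(
    sdf_slab(3, wall_pad, wall_pad + depth),
    sdf_pillars(xc = row_spacing / 2, yc = period / 2, side = side,
                period = period))
  structure(list(gap = gap, depth = depth, row_spacing = row_spacing,
                 side = side, period = period,
                 pressure_gradient = pressure_gradient,
                 box = box, periodic = c(TRUE, TRUE, FALSE), sdf = sdf,
                 effective_opening = effective_opening_size(gap, depth)),
            class = "device_geometry")
}

#' Fill the solid region with frozen wall particles
#'
#' Places a jittered lattice of frozen DPD particles at the fluid number
#' density in the solid shell `0 < sdf <= depth` (one thermostat cutoff
#' deep), which together with bounce-back reflection at the SDF
#' zero-level enforces no-slip.
#'
#' @param sdf wall geometry.
#' @param box,periodic domain.
#' @param density number density of wall particles.
#' @param depth fill depth into the solid (um).
#' @param jitter lattice jitter amplitude as a fraction of spacing.
#' @param seed RNG seed.
#' @return matrix of wall particle positions.
#' @export
build_walls <- function(sdf, box, periodic, density = 3, depth = 1,
                        jitter = 0.25, seed = 1L) {
  set.seed(seed)
  h <- density^(-1 / 3)
  g <- lapply(1:3, function(k) seq(h / 2, box[k] - h / 2, by = h))
  pts <- as.matrix(expand.grid(g[[1]], g[[2]], g[[3]]))
  colnames(pts) <- NULL
  pts <- pts + matrix(stats::runif(length(pts), -jitter * h, jitter * h),
                      nrow(pts), 3)
  s <- sdf_eval(sdf, pts, box, periodic)
  pts[s > 0 & s <= depth, , drop = FALSE]
}

#' Fill the fluid region with particles
#'
#' @inheritParams build_walls
#' @param clearance keep-out distance from walls (um).
#' @param exclude optional function(points) -> logical of extra exclusion
#'   (e.g. inside a cell).
#' @export
fill_fluid <- function(sdf, box, periodic, density = 3, clearance = 0.3,
                       exclude = NULL, seed = 1L) {
  set.seed(seed)
  n <- as.integer(round(density * prod(box)))
  pts <- matrix(stats::runif(3 * n), n, 3) %*% diag(box)
  if (!is.null(sdf) && length(sdf)) {
    s <- sdf_eval(sdf, pts, box, periodic)
    pts <- pts[s < -clearance, , drop = FALSE]
  }
  if (!is.null(exclude)) pts <- pts[!exclude(pts), , drop = FALSE]
  pts
}

#' Body force equivalent to a pressure gradient
#'
#' In periodic DPD cells, pressure-boundary driving is replaced by a
#' uniform body force per particle: `g = grad_P / rho` where `rho` is the
#' fluid number density.  The gradient is given in Pa/um and converted to
#' simulation units through the unit system.
#'
#' @param pressure_gradient pressure drop per length (Pa/um).
#' @param density fluid number density.
#' @param units a [unit_system()].
#' @param direction unit vector of the drive (default +x).
#' @param types particle type ids that feel the force (fluid and all cell
#'   components by default; walls never).
#' @return a body-force spec for [run_dpd()].
#' @export
drive_flow <- function(pressure_gradient, density = 3,
                       units = unit_system(), direction = c(1, 0, 0),
                       types = 1:4) {
  # Pa/um -> sim pressure per sim length unit
  grad_sim <- pressure_gradient * (units$length / 1e-6) / units$pressure
  g <- grad_sim / density
  list(g = g * direction, types = as.integer(types), region = NULL)
}
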