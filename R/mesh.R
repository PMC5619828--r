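#' Triangulated membrane mesh
#'
#' A closed, outward-oriented, genus-0 triangulation carrying the
#' reference state of the viscoelastic membrane model: per-edge wormlike
#' chain (WLC) springs with equilibrium length `l0` (taken from the
#' constructed state) and maximum extension `lmax`, a per-triangle
#' power-law (POW) repulsion `C1 / A` whose constant is chosen so the net
#' in-plane force vanishes at the reference state, cosine bending terms
#' over all dihedrals with stress-free equilibrium angles, and global
#' area/volume constraints around the reference `A0`, `V0`.
#'
#' @name tri_mesh
NULL

# WLC tension dU/dl at extension x = l/lmax
wlc_tension <- function(l, lmax, p, kBT = 1) {
  x <- l / lmax
  kBT / (4 * p) * (6 * x - 9 * x^2 + 4 * x^3) / (1 - x)^2
}

# POW balance constant: for a regular triangulation with edge length l0,
# d/dl [3/2 U_wlc(l) + C1/A(l)] = 0 at l = l0 gives
# C1 = (3 sqrt(3) / 16) f_wlc(l0) l0^3.
pow_constant <- function(l0, lmax, p, kBT = 1) {
  3 * sqrt(3) / 16 * wlc_tension(l0, lmax, p, kBT) * l0^3
}

#' Construct a near-uniform sphere triangulation
#'
#' Fibonacci-lattice seed points are relaxed on the sphere by soft
#' point-repulsion and triangulated by their convex hull, which lets the
#' mesh hit an arbitrary vertex count exactly (icosphere subdivision
#' cannot).  All reference quantities (edge lengths, dihedral angles,
#' total area and volume) are taken from the constructed state, so the
#' mesh is stress-free as built.
#'
#' @param n_vertices number of vertices (>= 12).
#' @param diameter sphere diameter (um).
#' @param lmax maximum WLC spring extension (um); cell default 3.0,
#'   nucleus 1.2.
#' @param p WLC persistence length (um).
#' @param kb bending modulus (sim energy); cell 65, nucleus 250.
#' @param ka,kv area / volume constraint constants; cell 10000/15000,
#'   nucleus 5000/15000.
#' @param gammaC membrane viscosity parameter; `gammaT = 3 gammaC`.
#' @param kBT energy unit.
#' @param relax_iters point-repulsion iterations.
#' @return object of class `tri_mesh`.
#' @examples
#' m <- make_sphere_mesh(200, diameter = 6)
#' nrow(m$tris)  # 2 * 200 - 4
#' @export
make_sphere_mesh <- function(n_vertices, diameter, lmax = 3.0, p = 0.00141,
                             kb = 65, ka = 10000, kv = 15000, gammaC = 30,
                             kBT = 1, relax_iters = 200) {
  if (n_vertices < 12) stop("n_vertices must be >= 12")
  n <- as.integer(n_vertices)
  # Fibonacci lattice
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- 2 * pi * i * (2 / (1 + sqrt(5)))
  rho <- sqrt(pmax(0, 1 - z^2))
  pts <- cbind(rho * cos(phi), rho * sin(phi), z)
  pts <- cpp_sphere_relax(pts, as.integer(relax_iters), 0.2)
  # polish: Laplacian smoothing rounds with hull re-triangulation, which
  # equalises edge lengths far faster than pure repulsion
  for (round in 1:6) {
    tris <- cpp_convex_hull(pts)
    ed <- unique(rbind(tris[, 1:2], tris[, 2:3], tris[, c(3, 1)]))
    pts <- cpp_sphere_smooth(pts, ed, 30L, 0.6)
  }
  pts <- pts * diameter / 2
  tris <- cpp_convex_hull(pts)
  mesh_from_faces(pts, tris, lmax = lmax, p = p, kb = kb, ka = ka, kv = kv,
                  gammaC = gammaC, kBT = kBT)
}

#' Build a `tri_mesh` from vertices and faces
#'
#' Reference lengths, areas, volume and dihedral angles are taken from the
#' supplied configuration.
#'
#' @param positions n x 3 vertex coordinates.
#' @param tris m x 3 face matrix (1-based).
#' @inheritParams make_sphere_mesh
#' @export
mesh_from_faces <- function(positions, tris, lmax = 3.0, p = 0.00141,
                            kb = 65, ka = 10000, kv = 15000, gammaC = 30,
                            kBT = 1) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  tris <- as.matrix(tris)
  storage.mode(tris) <- "integer"
  av <- cpp_mesh_area_volume(positions, tris)
  if (av$volume < 0) { # flip to outward orientation
    tris <- tris[, c(1, 3, 2)]
    av <- cpp_mesh_area_volume(positions, tris)
  }
  # undirected edges + the two faces adjacent to each
  ed_all <- rbind(tris[, 1:2], tris[, 2:3], tris[, c(3, 1)])
  ekey <- paste(pmin(ed_all[, 1], ed_all[, 2]),
                pmax(ed_all[, 1], ed_all[, 2]))
  face_of <- rep(seq_len(nrow(tris)), 3)
  sp <- split(seq_along(ekey), ekey)
  if (any(lengths(sp) != 2))
    stop("mesh is not closed: every edge must border exactly two faces")
  edges <- t(vapply(sp, function(ix) {
    c(pmin(ed_all[ix[1], 1], ed_all[ix[1], 2]),
      pmax(ed_all[ix[1], 1], ed_all[ix[1], 2]))
  }, integer(2)))
  adj <- t(vapply(sp, function(ix) face_of[ix], integer(2)))
  edge_key <- rownames(edges)
  rownames(edges) <- NULL
  # dihedral quadruple (opp1, i, j, opp2) about shared edge i-j
  opp <- function(f, i, j) setdiff(tris[f, ], c(i, j))
  dih <- matrix(0L, nrow(edges), 4)
  for (q in seq_len(nrow(edges))) {
    i <- edges[q, 1]; j <- edges[q, 2]
    dih[q, ] <- c(opp(adj[q, 1], i, j), i, j, opp(adj[q, 2], i, j))
  }
  l0 <- sqrt(rowSums((positions[edges[, 1], ] - positions[edges[, 2], ])^2))
  if (any(l0 >= lmax))
    stop("constructed edge length >= lmax; increase lmax or mesh resolution")
  bigbox <- c(0, 0, 0) # sentinel: no periodic wrapping
  phi0 <- cpp_dihedral_angles(positions, dih, bigbox, rep(FALSE, 3))
  # per-triangle POW constant from its own mean reference edge length
  el <- structure(l0, names = edge_key)
  tri_l0 <- vapply(seq_len(nrow(tris)), function(f) {
    v <- tris[f, ]
    k <- paste(pmin(v, v[c(2, 3, 1)]), pmax(v, v[c(2, 3, 1)]))
    mean(el[k])
  }, numeric(1))
  names(el) <- NULL
  mesh <- structure(list(
    positions = positions, tris = tris, edges = edges, l0 = l0,
    lmax = rep(lmax, length(l0)), dihedrals = dih, phi0 = phi0,
    C1 = pow_constant(tri_l0, lmax, p, kBT),
    p = p, kb = kb, ka = ka, kv = kv,
    gammaT = 3 * gammaC, gammaC = gammaC,
    A0 = av$area, V0 = av$volume, l0bar = mean(l0), kBT = kBT
  ), class = "tri_mesh")
  validate_mesh(mesh)
  mesh
}

#' @rdname tri_mesh
#' @param mesh a `tri_mesh`.
#' @export
validate_mesh <- function(mesh) {
  nv <- nrow(mesh$positions)
  nf <- nrow(mesh$tris)
  ne <- nrow(mesh$edges)
  if (nf != 2 * nv - 4 || ne != 3 * nv - 6)
    stop("not a closed genus-0 triangulation (Euler counts violated)")
  if (nv - ne + nf != 2) stop("Euler characteristic != 2")
  # consistent orientation: every directed edge used exactly once
  de <- paste(c(mesh$tris[, 1], mesh$tris[, 2], mesh$tris[, 3]),
              c(mesh$tris[, 2], mesh$tris[, 3], mesh$tris[, 1]))
  if (anyDuplicated(de)) stop("inconsistent face orientation")
  if (any(mesh$l0 >= mesh$lmax)) stop("l0 must be < lmax on every edge")
  invisible(mesh)
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf(
    "<tri_mesh> %d vertices, %d edges, %d faces | mean edge %.3f | A0 %.2f V0 %.2f\n",
    nrow(x$positions), nrow(x$edges), nrow(x$tris), mean(x$l0), x$A0, x$V0))
  invisible(x)
}

#' Mesh summary statistics
#' @param mesh a `tri_mesh`.
#' @return list with vertex/edge/face counts, mean and sd edge length,
#'   area, volume.
#' @export
mesh_stats <- function(mesh) {
  list(n_vertices = nrow(mesh$positions), n_edges = nrow(mesh$edges),
       n_faces = nrow(mesh$tris), mean_edge = mean(mesh$l0),
       sd_edge = stats::sd(mesh$l0), area = mesh$A0, volume = mesh$V0)
}

#' Nucleus size from the nuclear-cytoplasmic ratio
#'
#' NC is the projected (visible) nucleus area over the projected cell
#' area, so the nucleus diameter is `D * sqrt(NC)`.
#' @param diameter cell diameter (um).
#' @param nc NC ratio in [0, 1].
#' @export
nucleus_diameter <- function(diameter, nc) {
  stopifnot(nc >= 0, nc <= 1)
  diameter * sqrt(nc)
}

#' Default nucleus mesh vertex count
#'
#' Chosen so the mean edge length is ~0.5 um at the nucleus diameter,
#' matching the surface resolution of the cell membrane mesh.
#' @param nucleus_d nucleus diameter (um).
#' @export
nucleus_vertex_count <- function(nucleus_d) {
  max(12L, as.integer(round(3500 * (nucleus_d / 16)^2 * (0.518 / 0.5)^2)))
}

#' Engine block for a membrane mesh
#'
#' Re-indexes a mesh into the global particle numbering of an assembled
#' system (its vertices occupy indices `offset + 1 ... offset + n`).
#' @param mesh a `tri_mesh`.
#' @param offset index of the particle preceding the first mesh vertex.
#' @export
mesh_block <- function(mesh, offset = 0L) {
  list(edges = mesh$edges + offset, l0 = mesh$l0, lmax = mesh$lmax,
       tris = mesh$tris + offset, C1 = mesh$C1,
       dihedrals = mesh$dihedrals + offset, phi0 = mesh$phi0,
       kb = mesh$kb, p = mesh$p, ka = mesh$ka, kv = mesh$kv,
       A0 = mesh$A0, V0 = mesh$V0, l0bar = mesh$l0bar,
       gammaT = mesh$gammaT, gammaC = mesh$gammaC)
}

#' Read / write meshes in OFF format
#'
#' Plain-text Object File Format; reference quantities are reconstructed
#' on read via [mesh_from_faces()].
#' @param mesh a `tri_mesh`.
#' @param path file path.
#' @param ... passed to [mesh_from_faces()] on read.
#' @export
write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$positions), nrow(mesh$tris)), con)
  writeLines(apply(mesh$positions, 1, function(r)
    sprintf("%.10g %.10g %.10g", r[1], r[2], r[3])), con)
  writeLines(apply(mesh$tris, 1, function(f)
    sprintf("3 %d %d %d", f[1] - 1, f[2] - 1, f[3] - 1)), con)
  invisible(path)
}

#' @rdname write_off
#' @export
read_off <- function(path, ...) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln)) & !startsWith(trimws(ln), "#")]
  if (toupper(trimws(ln[1])) != "OFF") stop("not an OFF file")
  hdr <- as.integer(strsplit(trimws(ln[2]), "\\s+")[[1]])
  nv <- hdr[1]; nf <- hdr[2]
  vt <- do.call(rbind, lapply(ln[3:(2 + nv)], function(s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1]][1:3])))
  fc <- do.call(rbind, lapply(ln[(3 + nv):(2 + nv + nf)], function(s) {
    v <- as.integer(strsplit(trimws(s), "\\s+")[[1]])
    if (v[1] != 3) stop("only triangular faces supported")
    v[2:4] + 1L
  }))
  mesh_from_faces(vt, fc, ...)
}
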