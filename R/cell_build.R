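#' Carve a network to the cell volume and link it to the membranes
#'
#' Cuts the periodic-box network to the part inside the cell membrane and
#' outside the nucleus interior (splitting chains as needed), generates
#' the chromatin network inside the nucleus with the same model, then
#' simulates spontaneous formation of filament-membrane connections: a
#' link bond forms when a filament particle comes within the link radius
#' of a membrane vertex (0.5 um for the cell membrane, 0.4 um for the
#' nucleus envelope; at most one link per filament particle and per
#' vertex), and unbinds following the Bell law with the per-membrane
#' parameter sets.  The phase runs until the linked-vertex count
#' converges.  Finally, filament-CL-filament torsion quadruples are
#' installed with their equilibrium angles set to the constructed values.
#'
#' @param net a cross-linked [filament_network()] in a periodic box.
#' @param cell_mesh cell-surface [tri_mesh] centred at the origin.
#' @param nucleus_mesh nucleus envelope mesh or NULL.
#' @param config an [assembly_config()].
#' @param seed RNG seed.
#' @return list with the carved+linked `network`, updated `cell_mesh` and
#'   `nucleus_mesh` vertex positions, and [topology_stats()] `stats`.
#' @export
carve_and_link <- function(net, cell_mesh, nucleus_mesh = NULL,
                           config = assembly_config(), seed = 1L) {
  set.seed(derive_seed(seed, 3))
  if (!is.null(nucleus_mesh)) {
    inside <- cpp_points_in_mesh(nucleus_mesh$positions,
                                 cell_mesh$positions, cell_mesh$tris)
    if (!all(inside))
      stop("geometry error: nucleus mesh not contained in cell mesh")
  }
  carved <- carve_network(net, cell_mesh, nucleus_mesh)
  if (!is.null(nucleus_mesh)) {
    nfn <- if (is.null(config$n_fil_nucleus)) config$n_fil else
      config$n_fil_nucleus
    if (nfn > 0) {
      chrom_cfg <- config
      chrom_cfg$n_fil <- nfn
      nd <- 2 * max(sqrt(rowSums(nucleus_mesh$positions^2)))
      chrom_box <- rep(max(nd * 1.25, config$filament_length + 0.5), 3)
      chrom <- assemble_network(chrom_box, chrom_cfg,
                                derive_seed(seed, 17))
      chrom <- carve_network(chrom, nucleus_mesh, NULL)
      carved <- merge_networks(carved, chrom, config)
    }
  }
  linked <- link_membranes(carved, cell_mesh, nucleus_mesh, config, seed)
  net2 <- add_torsions(linked$network, config)
  stats <- topology_stats(net2, cell_mesh, nucleus_mesh)
  list(network = net2, cell_mesh = linked$cell_mesh,
       nucleus_mesh = linked$nucleus_mesh, stats = stats)
}

# cut a periodic network to inside `outer` (and outside `inner`), with
# chains unwrapped and re-centred on the mesh origin
carve_network <- function(net, outer, inner = NULL) {
  box <- net$box
  pos <- net$positions
  newchains <- list()
  newpos <- list()
  cl_map <- rep(NA_integer_, nrow(pos)) # old index -> new index
  for (ch in net$chains) {
    p <- pos[ch, , drop = FALSE]
    # unwrap along the chain, anchor at the wrapped first particle
    p0 <- p[1, ] %% box - box / 2
    up <- matrix(0, nrow(p), 3)
    up[1, ] <- p0
    if (nrow(p) > 1)
      for (q in 2:nrow(p))
        up[q, ] <- up[q - 1, ] + minimg(p[q, ] - p[q - 1, ], box)
    keep <- cpp_points_in_mesh(up, outer$positions, outer$tris)
    if (!is.null(inner))
      keep <- keep & !cpp_points_in_mesh(up, inner$positions, inner$tris)
    # split into consecutive kept runs of length >= 2
    r <- rle(as.logical(keep))
    stops <- cumsum(r$lengths)
    starts <- stops - r$lengths + 1L
    for (s in which(r$values & r$lengths >= 2)) {
      ix <- starts[s]:stops[s]
      base <- sum(vapply(newpos, nrow, integer(1)))
      newpos[[length(newpos) + 1L]] <- up[ix, , drop = FALSE]
      newchains[[length(newchains) + 1L]] <- base + seq_along(ix)
      cl_map[ch[ix]] <- base + seq_along(ix)
    }
  }
  if (!length(newchains))
    stop("carving removed the whole network; box/mesh sizes inconsistent")
  pos2 <- do.call(rbind, newpos)
  cl <- net$bonds[net$bonds$class == "crosslink", , drop = FALSE]
  cl$i <- cl_map[cl$i]
  cl$j <- cl_map[cl$j]
  cl <- cl[!is.na(cl$i) & !is.na(cl$j), , drop = FALSE]
  an <- net$angles[net$angles$class == "crosslink", , drop = FALSE]
  an$i <- cl_map[an$i]; an$j <- cl_map[an$j]; an$k <- cl_map[an$k]
  an <- an[!is.na(an$i) & !is.na(an$j) & !is.na(an$k), , drop = FALSE]
  cfg_like <- list(kappa_fil = net$bonds$kappa[
    match("filament", net$bonds$class)], r0_fil = net$bonds$r0[
      match("filament", net$bonds$class)], kappa_bend = net$angles$kappa[
        match("filament", net$angles$class)])
  if (is.na(cfg_like$kappa_fil)) cfg_like <- assembly_config()
  out <- filament_network(pos2, newchains, bonds = cl, angles = an,
                          box = NULL, periodic = rep(FALSE, 3))
  rebuild_chain_topology(out, cfg_like)
}

merge_networks <- function(a, b, config) {
  off <- nrow(a$positions)
  bumped <- lapply(b$chains, function(ch) ch + off)
  bb <- b$bonds; bb$i <- bb$i + off; bb$j <- bb$j + off
  ba <- b$angles; ba$i <- ba$i + off; ba$j <- ba$j + off; ba$k <- ba$k + off
  out <- filament_network(rbind(a$positions, b$positions),
                          c(a$chains, bumped),
                          bonds = rbind(a$bonds[a$bonds$class != "filament", ],
                                        bb[bb$class != "filament", ]),
                          angles = rbind(
                            a$angles[a$angles$class != "filament", ],
                            ba[ba$class != "filament", ]),
                          box = NULL, periodic = rep(FALSE, 3))
  rebuild_chain_topology(out, config)
}

# chunked dynamics with membrane-link binding/unbinding until the linked
# vertex count converges
link_membranes <- function(net, cell_mesh, nucleus_mesh, config, seed) {
  nf <- nrow(net$positions)
  nv_c <- nrow(cell_mesh$positions)
  nv_n <- if (is.null(nucleus_mesh)) 0L else nrow(nucleus_mesh$positions)
  pos <- rbind(net$positions, cell_mesh$positions,
               if (nv_n) nucleus_mesh$positions)
  types <- c(rep(2L, nf), rep(3L, nv_c), rep(4L, nv_n))
  n <- nrow(pos)
  vel <- matrix(stats::rnorm(3 * n, sd = sqrt(config$kBT)), n, 3)
  span <- 2 * max(abs(pos)) + 6
  box <- rep(span, 3)
  pos_shift <- span / 2 # keep coordinates positive for binning
  thermo <- thermo_state(config$kBT, config$dt)
  tab <- interaction_table(kBT = config$kBT)
  meshes <- list(mesh_block(cell_mesh, nf))
  if (nv_n) meshes <- c(meshes, list(mesh_block(nucleus_mesh, nf + nv_c)))
  units <- unit_system()
  chunk_time <- config$chunk * config$dt
  links <- data.frame(particle = integer(), vertex = integer(),
                      mesh = character(), r0 = numeric())
  n_iter <- as.integer(ceiling(config$link_max_steps / config$chunk))
  win_iters <- max(1L, as.integer(round(config$window / config$chunk)))
  trace <- integer(0)
  last_win <- -Inf
  for (it in seq_len(n_iter)) {
    bonds <- net$bonds[, c("i", "j", "kappa", "r0")]
    if (nrow(links)) {
      voff <- ifelse(links$mesh == "cell", nf, nf + nv_c)
      bonds <- rbind(bonds, data.frame(i = links$particle,
                                       j = voff + links$vertex,
                                       kappa = config$kappa_cl,
                                       r0 = links$r0))
    }
    model <- list(types = types, box = box, periodic = rep(FALSE, 3),
                  kBT = config$kBT, dt = config$dt, mass = 1,
                  table = table_for_engine(tab), frozen = NULL,
                  bonds = bonds,
                  angles = net$angles[, c("i", "j", "k", "kappa", "theta0")],
                  torsions = NULL, meshes = meshes, body_force = NULL,
                  sdf = NULL)
    out <- cpp_run(pos + pos_shift, vel, model, as.integer(config$chunk),
                   derive_seed(seed, 5000 + it), 0L, integer(0), 1L, 0.3)
    pos <- out$positions - pos_shift
    vel <- out$velocities
    # Bell unbinding per membrane class
    if (nrow(links)) {
      voff <- ifelse(links$mesh == "cell", nf, nf + nv_c)
      d <- pos[links$particle, , drop = FALSE] -
        pos[voff + links$vertex, , drop = FALSE]
      len <- sqrt(rowSums(d^2))
      Fb <- 2 * config$kappa_cl * abs(len - links$r0)
      pu <- numeric(nrow(links))
      for (cls in c("cell", "nucleus")) {
        sel <- links$mesh == cls
        if (!any(sel)) next
        bp <- if (cls == "cell") config$bell_cell else config$bell_nucleus
        pu[sel] <- bell_unbind_probability(Fb[sel], len[sel], bp,
                                           config$kBT, chunk_time, units)
      }
      links <- links[stats::runif(nrow(links)) >= pu, , drop = FALSE]
    }
    # binding pass
    taken_p <- rep(FALSE, nf)
    taken_p[links$particle] <- TRUE
    for (cls in c("cell", "nucleus")) {
      if (cls == "nucleus" && !nv_n) next
      radius <- if (cls == "cell") config$link_radius_cell else
        config$link_radius_nucleus
      voff <- if (cls == "cell") nf else nf + nv_c
      nv <- if (cls == "cell") nv_c else nv_n
      taken_v <- rep(FALSE, nv)
      taken_v[links$vertex[links$mesh == cls]] <- TRUE
      cand <- cpp_pairs_between(pos[seq_len(nf), , drop = FALSE],
                                pos[voff + seq_len(nv), , drop = FALSE],
                                radius, c(0, 0, 0), rep(FALSE, 3))
      if (!length(cand$i)) next
      for (q in order(cand$dist)) {
        fp <- cand$i[q]
        vx <- cand$j[q]
        if (taken_p[fp] || taken_v[vx]) next
        links <- rbind(links, data.frame(particle = fp, vertex = vx,
                                         mesh = cls,
                                         r0 = max(cand$dist[q], 0.05)))
        taken_p[fp] <- TRUE
        taken_v[vx] <- TRUE
      }
    }
    trace <- c(trace, nrow(links))
    if (it %% win_iters == 0) {
      win <- mean(tail(trace, win_iters))
      if (is.finite(last_win) &&
          abs(win - last_win) / max(last_win, 1) < config$tol) break
      last_win <- win
    }
  }
  net$positions <- pos[seq_len(nf), , drop = FALSE]
  net$links <- links # particle, vertex, mesh, r0 (resolved at assembly)
  cm <- cell_mesh
  cm$positions <- pos[nf + seq_len(nv_c), , drop = FALSE]
  nm <- nucleus_mesh
  if (nv_n) nm$positions <- pos[nf + nv_c + seq_len(nv_n), , drop = FALSE]
  list(network = net, cell_mesh = cm, nucleus_mesh = nm)
}

# install torsion quadruples over merged CL bonds; equilibrium angle =
# constructed dihedral
add_torsions <- function(net, config) {
  cl <- net$bonds[net$bonds$class == "crosslink", , drop = FALSE]
  if (!nrow(cl)) return(net)
  chain_id <- chain_id_of(net)
  quads <- list()
  for (q in seq_len(nrow(cl))) {
    A <- cl$i[q]
    B <- cl$j[q]
    nbr <- function(p) {
      ch <- net$chains[[chain_id[p]]]
      k <- match(p, ch)
      if (k > 1) ch[k - 1] else ch[k + 1]
    }
    nA <- nbr(A)
    nB <- nbr(B)
    if (is.na(nA) || is.na(nB)) next
    phi <- tryCatch(
      cpp_dihedral_angles(net$positions,
                          matrix(c(nA, A, B, nB), 1, 4),
                          c(0, 0, 0), rep(FALSE, 3)),
      error = function(e) NA_real_)
    if (is.na(phi)) next # degenerate (collinear) construction
    quads[[length(quads) + 1L]] <- data.frame(
      i = nA, j = A, k = B, l = nB, ktor = config$k_tor, phi0 = phi)
  }
  if (length(quads)) net$torsions <- do.call(rbind, quads)
  net
}

#' Build a complete cell model
#'
#' Generates the cell-surface mesh, the nucleus envelope (diameter
#' `D sqrt(NC)`), a periodic-box cytoskeleton network at the configured
#' densities, carves it to the cell volume, generates chromatin inside
#' the nucleus, and links filaments to both membranes.
#'
#' @param diameter cell diameter (um).
#' @param nc nuclear-cytoplasmic (projected area) ratio; 0 = no nucleus.
#' @param n_vertices cell-surface mesh vertex count.
#' @param config an [assembly_config()].
#' @param seed RNG seed (the whole build is deterministic in it).
#' @param box network generation box; default fits the cell.
#' @param lmax_cell,lmax_nucleus WLC maximum extensions (um).
#' @return object of class `cell_bundle`: meshes, network, stats, and the
#'   build parameters.
#' @export
build_cell <- function(diameter = 16, nc = 0.29, n_vertices = 3500,
                       config = assembly_config(), seed = 1L, box = NULL,
                       lmax_cell = 3.0, lmax_nucleus = 1.2) {
  cell_mesh <- make_sphere_mesh(n_vertices, diameter, lmax = lmax_cell)
  nucleus_mesh <- NULL
  if (nc > 0) {
    nd <- nucleus_diameter(diameter, nc)
    nucleus_mesh <- make_sphere_mesh(nucleus_vertex_count(nd), nd,
                                     lmax = lmax_nucleus, kb = 250,
                                     ka = 5000, kv = 15000)
  }
  if (is.null(box)) box <- rep(diameter + 4, 3)
  net <- assemble_network(box, config, seed)
  res <- carve_and_link(net, cell_mesh, nucleus_mesh, config, seed)
  structure(list(cell_mesh = res$cell_mesh,
                 nucleus_mesh = res$nucleus_mesh,
                 network = res$network, stats = res$stats,
                 diameter = diameter, nc = nc, config = config,
                 seed = seed),
            class = "cell_bundle")
}

#' @export
print.cell_bundle <- function(x, ...) {
  cat(sprintf("<cell_bundle> D = %g um, NC = %g, seed %d\n", x$diameter,
              x$nc, x$seed))
  print(x$stats)
  invisible(x)
}

#' Rotate a cell bundle about an axis through the origin
#'
#' @param bundle a [build_cell()] result.
#' @param angle rotation angle (radians).
#' @param axis unit axis (default z, orthogonal to the x flow/pipette
#'   axis).
#' @export
rotate_bundle <- function(bundle, angle, axis = c(0, 0, 1)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  rot <- function(m) m %*% t(R)
  bundle$cell_mesh$positions <- rot(bundle$cell_mesh$positions)
  if (!is.null(bundle$nucleus_mesh))
    bundle$nucleus_mesh$positions <- rot(bundle$nucleus_mesh$positions)
  bundle$network$positions <- rot(bundle$network$positions)
  bundle
}
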