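#' Cytoskeleton assembly configuration
#'
#' Parameters of the stochastic network-generation pipeline: filaments are
#' seeded as straight chains in a periodic box, grown/shrunk by a
#' polymerization phase, cross-linked by diffusing auxiliary CL particles
#' with Bell-law unbinding, and finally carved to the cell volume and
#' linked to the membranes.
#'
#' @param n_fil filament particle number density (um^-3).
#' @param filament_length filament length (um).
#' @param n_cl cross-link particle number density (um^-3).
#' @param r0_fil spacing of particles along a filament (um); the filament
#'   bond equilibrium length.
#' @param growth_radius binding radius of the polymerization phase (um).
#' @param cl_radius CL binding radius r0 (um).
#' @param link_radius_cell,link_radius_nucleus membrane-link formation
#'   radii (um).
#' @param kappa_fil,kappa_bend,kappa_cl,kappa_clfil,k_tor stiffness
#'   constants (sim units): filament spring 8e4, filament bending 350, CL
#'   spring 8e3, CL-filament bending 550, torsion 470.
#' @param bell_cl,bell_cell,bell_nucleus [bell_params()] per bond class.
#' @param polymerize_steps steps of the polymerization phase.
#' @param cl_max_steps cap on the CL-formation phase (convergence usually
#'   stops it much earlier).
#' @param link_max_steps cap on the membrane-linking phase.
#' @param chunk dynamics steps between binding/unbinding passes.
#' @param window convergence window (steps); the phase stops when the
#'   windowed free-CL (or linked-vertex) count changes by < `tol`
#'   relative.
#' @param tol relative convergence tolerance.
#' @param n_fil_nucleus chromatin filament density inside the nucleus
#'   (defaults to `n_fil`).
#' @param dt,kBT integration parameters used during assembly.
#' @return object of class `assembly_config`.
#' @export
assembly_config <- function(n_fil = 3.5, filament_length = 4.0,
                            n_cl = 0.525, r0_fil = 0.5,
                            growth_radius = 0.5, cl_radius = 0.25,
                            link_radius_cell = 0.5,
                            link_radius_nucleus = 0.4,
                            kappa_fil = 8e4, kappa_bend = 350,
                            kappa_cl = 8e3, kappa_clfil = 550, k_tor = 470,
                            bell_cl = bell_params_cl(),
                            bell_cell = bell_params_cell_link(),
                            bell_nucleus = bell_params_nucleus_link(),
                            polymerize_steps = 1e4, cl_max_steps = 6e5,
                            link_max_steps = 1e5, chunk = 200,
                            window = 1e4, tol = 0.01,
                            n_fil_nucleus = NULL, dt = 1e-3, kBT = 1) {
  stopifnot(n_fil >= 0, n_cl >= 0, r0_fil > 0, growth_radius > 0,
            cl_radius > 0, link_radius_cell > 0, link_radius_nucleus > 0)
  structure(as.list(environment()), class = "assembly_config")
}

# deterministic sub-seed stream (kept < 2^31)
derive_seed <- function(seed, k) {
  (as.double(seed) * 1009 + 9973 * as.double(k)) %% 2147483629 + 1
}

# interaction table used during assembly: CL particles (stored as type 1)
# couple to filaments through the thermostat only, so that binding at
# r < 0.25 is not blocked by the soft repulsion barrier; their friction is
# kept low so CL exploration (a transport property of auxiliary particles
# the model does not otherwise constrain) is not rate-limiting
assembly_table <- function(kBT = 1, cl_gamma = 4.5) {
  tb <- interaction_table(kBT = kBT)
  a <- tb$a
  a[1, 1:5] <- 0
  a[1:5, 1] <- 0
  g <- tb$gamma
  g[1, 1:5] <- cl_gamma
  g[1:5, 1] <- cl_gamma
  interaction_table(a = a, gamma = g, rc_rep = tb$rc_rep,
                    rc_th = tb$rc_th, kBT = kBT)
}

#' Seed straight filaments in a periodic box
#'
#' Chains of `round(filament_length / r0_fil) + 1` particles at spacing
#' `r0_fil` are placed with uniform random origins and orientations until
#' the filament particle density reaches `n_fil`.  Harmonic bonds
#' (`kappa_fil`, r0 = `r0_fil`) and straight angles (`kappa_bend`,
#' theta0 = pi) are installed along every chain.
#'
#' @param box periodic box lengths (um).
#' @param config an [assembly_config()].
#' @param seed RNG seed.
#' @return a [filament_network()].
#' @export
seed_filaments <- function(box, config = assembly_config(), seed = 1L) {
  if (any(box < config$filament_length))
    stop("configuration error: box smaller than one filament")
  set.seed(seed)
  npc <- as.integer(round(config$filament_length / config$r0_fil)) + 1L
  n_chains <- as.integer(round(config$n_fil * prod(box) / npc))
  pos <- matrix(0, n_chains * npc, 3)
  chains <- vector("list", n_chains)
  for (c in seq_len(n_chains)) {
    o <- stats::runif(3) * box
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2))
    ix <- ((c - 1L) * npc + 1L):(c * npc)
    pos[ix, ] <- rep(o, each = npc) +
      (seq_len(npc) - 1L) * config$r0_fil * rep(u, each = npc)
    chains[[c]] <- ix
  }
  net <- filament_network(pos, chains, box = box)
  rebuild_chain_topology(net, config)
}

# regenerate filament bonds/angles from the chain lists, preserving
# cross-link bonds, anchor angles, torsions and membrane links
rebuild_chain_topology <- function(net, config) {
  bonds <- list()
  angles <- list()
  for (ch in net$chains) {
    m <- length(ch)
    if (m >= 2)
      bonds[[length(bonds) + 1L]] <- data.frame(
        i = ch[-m], j = ch[-1], kappa = config$kappa_fil,
        r0 = config$r0_fil, class = "filament")
    if (m >= 3)
      angles[[length(angles) + 1L]] <- data.frame(
        i = ch[1:(m - 2)], j = ch[2:(m - 1)], k = ch[3:m],
        kappa = config$kappa_bend, theta0 = pi, class = "filament")
  }
  keep_b <- net$bonds[net$bonds$class != "filament", , drop = FALSE]
  keep_a <- net$angles[net$angles$class != "filament", , drop = FALSE]
  net$bonds <- rbind(do.call(rbind, bonds), keep_b)
  net$angles <- rbind(do.call(rbind, angles), keep_a)
  if (is.null(net$bonds)) net$bonds <- filament_network(
    net$positions, net$chains)$bonds
  rownames(net$bonds) <- rownames(net$angles) <- NULL
  net
}

# run a chunk of DPD dynamics on a bare network (+ optional CL particles)
run_network_chunk <- function(pos, vel, types, bonds, box, thermo, steps,
                              seed, table, angles = NULL) {
  model <- list(types = types, box = box, periodic = rep(TRUE, 3),
                kBT = thermo$kBT, dt = thermo$dt, mass = 1,
                table = table_for_engine(table), frozen = NULL,
                bonds = bonds, angles = angles, torsions = NULL,
                meshes = NULL, body_force = NULL, sdf = NULL)
  cpp_run(pos, vel, model, as.integer(steps), as.double(seed), 0L,
          integer(0), 1L, 0.3)
}

#' Polymerization / depolymerization phase
#'
#' Alternates chunks of DPD dynamics with growth passes: the plus end of
#' each chain gains a particle (extending along the end direction) when
#' another filament's particle lies within `growth_radius`; the minus end
#' loses its particle with a probability proportional to the
#' added-minus-removed count of the previous iteration, with the
#' proportionality constant calibrated online so the expected net change
#' is zero and total filament length stays approximately constant.
#'
#' @param net a [filament_network()] from [seed_filaments()].
#' @param steps total DPD steps of the phase (0 = identity).
#' @param config an [assembly_config()].
#' @param seed RNG seed.
#' @return the updated network, with the per-iteration particle-count
#'   trace in attribute `"count_trace"`.
#' @export
polymerize <- function(net, steps = NULL, config = assembly_config(),
                       seed = 1L) {
  if (is.null(steps)) steps <- config$polymerize_steps
  if (steps <= 0) return(net)
  set.seed(derive_seed(seed, 1))
  thermo <- thermo_state(config$kBT, config$dt)
  tab <- assembly_table(config$kBT)
  n_iter <- max(1L, as.integer(ceiling(steps / config$chunk)))
  p_grow <- 0.3 # growth attempts per eligible end per iteration
  n0 <- nrow(net$positions)
  trace <- integer(n_iter)
  vel <- NULL
  for (it in seq_len(n_iter)) {
    n <- nrow(net$positions)
    if (is.null(vel) || nrow(vel) != n)
      vel <- matrix(stats::rnorm(3 * n, sd = sqrt(config$kBT)), n, 3)
    out <- run_network_chunk(
      net$positions, vel, rep(2L, n),
      net$bonds[, c("i", "j", "kappa", "r0")], net$box, thermo,
      config$chunk, derive_seed(seed, 100 + it), tab,
      net$angles[, c("i", "j", "k", "kappa", "theta0")])
    net$positions <- out$positions
    vel <- out$velocities
    chain_id <- chain_id_of(net)
    # growth pass
    ends <- vapply(net$chains, function(ch) ch[length(ch)], integer(1))
    endpos <- net$positions[ends, , drop = FALSE]
    nb <- cpp_pairs_between(endpos, net$positions, config$growth_radius,
                            net$box, rep(TRUE, 3))
    can_grow <- rep(FALSE, length(net$chains))
    if (length(nb$i)) {
      ok <- chain_id[nb$j] != seq_along(net$chains)[nb$i]
      can_grow[unique(nb$i[ok])] <- TRUE
    }
    can_grow <- can_grow & stats::runif(length(net$chains)) < p_grow
    added <- sum(can_grow)
    # depolymerisation probability proportional to the surplus of added
    # over removed particles, with the constant set so the expected net
    # change per iteration is zero (total filament length conserved)
    deficit <- nrow(net$positions) + added - n0
    p_rem <- min(1, max(0, deficit / max(1, length(net$chains))))
    rem_draw <- stats::runif(length(net$chains)) < p_rem
    removed <- 0
    newpos <- list()
    newchains <- net$chains
    for (c in seq_along(net$chains)) {
      ch <- newchains[[c]]
      if (can_grow[c]) {
        m <- length(ch)
        dirv <- net$positions[ch[m], ] - net$positions[ch[m - 1], ]
        dirv <- minimg(dirv, net$box)
        dirv <- dirv / sqrt(sum(dirv^2))
        newpos[[length(newpos) + 1L]] <-
          net$positions[ch[m], ] + config$r0_fil * dirv
        newchains[[c]] <- c(ch, nrow(net$positions) + length(newpos))
      }
      if (rem_draw[c] && length(newchains[[c]]) > 2) {
        newchains[[c]] <- newchains[[c]][-1]
        removed <- removed + 1
      }
    }
    if (length(newpos))
      net$positions <- rbind(net$positions, do.call(rbind, newpos))
    # drop orphaned particles and reindex
    keep <- sort(unique(unlist(newchains)))
    remap <- integer(nrow(net$positions))
    remap[keep] <- seq_along(keep)
    net$positions <- net$positions[keep, , drop = FALSE]
    net$chains <- lapply(newchains, function(ch) remap[ch])
    net <- rebuild_chain_topology(net, config)
    vel <- NULL # counts changed; rethermalize
    trace[it] <- nrow(net$positions)
  }
  attr(net, "count_trace") <- trace
  net
}

#' Cross-link formation phase
#'
#' Auxiliary CL particles at density `n_cl` diffuse through the filament
#' network (thermostat coupling only) and bind to filament particles
#' within `cl_radius`; one CL binds at most two distinct filaments, a
#' filament particle holds at most one CL, and no CL links a filament to
#' itself.  Bound CLs unbind in a force-dependent manner following the
#' Bell law.  The phase runs until the free-CL count converges (windowed
#' relative change below `tol`), then CLs bound to a single filament are
#' deleted and each doubly-bound CL is merged into one direct
#' filament-filament bond (`kappa_cl`, stress-free rest length), with
#' CL-filament anchor angles (theta0 = pi/2) installed at both anchors.
#'
#' @inheritParams polymerize
#' @return the network with merged CL bonds; the free-CL count trace is
#'   in attribute `"free_cl_trace"`.
#' @export
form_crosslinks <- function(net, config = assembly_config(), seed = 1L) {
  set.seed(derive_seed(seed, 2))
  nf <- nrow(net$positions)
  n_cl <- as.integer(round(config$n_cl * prod(net$box)))
  if (n_cl == 0) {
    attr(net, "free_cl_trace") <- integer(0)
    return(net)
  }
  clpos <- matrix(stats::runif(3 * n_cl), n_cl, 3) %*% diag(net$box)
  thermo <- thermo_state(config$kBT, config$dt)
  tab <- assembly_table(config$kBT)
  chain_id <- chain_id_of(net)
  # chain-neighbour maps for point-to-segment binding distances
  prv <- rep(NA_integer_, nf)
  nxt <- rep(NA_integer_, nf)
  for (ch in net$chains) {
    m <- length(ch)
    if (m >= 2) {
      prv[ch[-1]] <- ch[-m]
      nxt[ch[-m]] <- ch[-1]
    }
  }
  # cl_bonds: one row per CL-filament attachment
  clb <- data.frame(cl = integer(), fp = integer(), r0 = numeric())
  units <- unit_system()
  chunk_time <- config$chunk * config$dt
  n_iter <- as.integer(ceiling(config$cl_max_steps / config$chunk))
  win_iters <- max(1L, as.integer(round(config$window / config$chunk)))
  trace <- integer(0)
  vel <- matrix(stats::rnorm(3 * (nf + n_cl), sd = sqrt(config$kBT)),
                nf + n_cl, 3)
  pos <- rbind(net$positions, clpos)
  types <- c(rep(2L, nf), rep(1L, n_cl))
  last_win <- Inf
  for (it in seq_len(n_iter)) {
    bonds <- net$bonds[, c("i", "j", "kappa", "r0")]
    if (nrow(clb))
      bonds <- rbind(bonds, data.frame(i = nf + clb$cl, j = clb$fp,
                                       kappa = config$kappa_cl,
                                       r0 = clb$r0))
    out <- run_network_chunk(pos, vel, types, bonds, net$box, thermo,
                             config$chunk, derive_seed(seed, 1000 + it), tab,
                             net$angles[, c("i", "j", "k", "kappa", "theta0")])
    pos <- out$positions
    vel <- out$velocities
    # unbinding pass (Bell law on the instantaneous spring force)
    if (nrow(clb)) {
      d <- pos[nf + clb$cl, , drop = FALSE] - pos[clb$fp, , drop = FALSE]
      d <- minimg_rows(d, net$box)
      len <- sqrt(rowSums(d^2))
      Fb <- 2 * config$kappa_cl * abs(len - clb$r0)
      pu <- bell_unbind_probability(Fb, len, config$bell_cl, config$kBT,
                                    chunk_time, units)
      clb <- clb[stats::runif(nrow(clb)) >= pu, , drop = FALSE]
    }
    # binding pass: a CL binds when its distance to the *filament* (the
    # polyline, not just the discrete particles) falls below cl_radius;
    # the bond partner is the nearest filament particle
    n_bonds_of_cl <- tabulate(clb$cl, nbins = n_cl)
    open_cl <- which(n_bonds_of_cl < 2L)
    taken_fp <- rep(FALSE, nf)
    taken_fp[clb$fp] <- TRUE
    if (length(open_cl)) {
      cand <- cpp_pairs_between(pos[nf + open_cl, , drop = FALSE],
                                pos[seq_len(nf), , drop = FALSE],
                                config$cl_radius + config$r0_fil / 2,
                                net$box, rep(TRUE, 3))
      if (length(cand$i)) {
        segd <- segment_distances(pos[nf + open_cl[cand$i], , drop = FALSE],
                                  cand$j, pos[seq_len(nf), , drop = FALSE],
                                  prv, nxt, net$box)
        keep <- segd <= config$cl_radius
        ci <- cand$i[keep]; cj <- cand$j[keep]
        cd <- cand$dist[keep]; sd_ <- segd[keep]
        for (q in order(sd_)) {
          cl <- open_cl[ci[q]]
          fp <- cj[q]
          if (taken_fp[fp] || n_bonds_of_cl[cl] >= 2L) next
          bound_chains <- chain_id[clb$fp[clb$cl == cl]]
          if (chain_id[fp] %in% bound_chains) next # no self-link
          clb <- rbind(clb, data.frame(cl = cl, fp = fp,
                                       r0 = max(cd[q], 0.05)))
          taken_fp[fp] <- TRUE
          n_bonds_of_cl[cl] <- n_bonds_of_cl[cl] + 1L
        }
      }
    }
    trace <- c(trace, n_cl - sum(tabulate(clb$cl, nbins = n_cl) > 0))
    if (it %% win_iters == 0) {
      win <- mean(tail(trace, win_iters))
      if (win == 0) break # no free CLs left over a whole window
      if (is.finite(last_win) &&
          abs(win - last_win) / max(last_win, 1) < config$tol) break
      last_win <- win
    }
  }
  net$positions <- pos[seq_len(nf), , drop = FALSE]
  # prune single-bound CLs, merge double-bound into direct fil-fil bonds
  nb <- tabulate(clb$cl, nbins = n_cl)
  merged <- list()
  cl_angles <- list()
  for (cl in which(nb == 2L)) {
    fps <- clb$fp[clb$cl == cl]
    d <- minimg(net$positions[fps[1], ] - net$positions[fps[2], ], net$box)
    merged[[length(merged) + 1L]] <- data.frame(
      i = fps[1], j = fps[2], kappa = config$kappa_cl,
      r0 = max(sqrt(sum(d^2)), 0.05), class = "crosslink")
    for (k in 1:2) {
      anc <- fps[k]
      oth <- fps[3 - k]
      ch <- net$chains[[chain_id[anc]]]
      pos_in <- match(anc, ch)
      nbr <- if (pos_in > 1) ch[pos_in - 1] else ch[pos_in + 1]
      cl_angles[[length(cl_angles) + 1L]] <- data.frame(
        i = nbr, j = anc, k = oth, kappa = config$kappa_clfil,
        theta0 = pi / 2, class = "crosslink")
    }
  }
  if (length(merged)) {
    net$bonds <- rbind(net$bonds, do.call(rbind, merged))
    net$angles <- rbind(net$angles, do.call(rbind, cl_angles))
    rownames(net$bonds) <- rownames(net$angles) <- NULL
  }
  validate_network(net)
  attr(net, "free_cl_trace") <- trace
  net
}

#' Assemble a periodic-box cytoskeleton network
#'
#' Convenience pipeline: [seed_filaments()], [polymerize()],
#' [form_crosslinks()].
#' @inheritParams seed_filaments
#' @export
assemble_network <- function(box, config = assembly_config(), seed = 1L) {
  net <- seed_filaments(box, config, seed)
  net <- polymerize(net, config$polymerize_steps, config, seed)
  form_crosslinks(net, config, seed)
}

# distance from point p_q to the filament polyline near particle fp_q:
# the minimum over the segments joining fp to its chain neighbours
segment_distances <- function(p, fp, filpos, prv, nxt, box) {
  a <- filpos[fp, , drop = FALSE]
  ap <- minimg_rows(p - a, box)
  best <- sqrt(rowSums(ap^2)) # distance to the particle itself
  for (nb in list(prv[fp], nxt[fp])) {
    has <- !is.na(nb)
    if (!any(has)) next
    ab <- minimg_rows(filpos[nb[has], , drop = FALSE] -
                        a[has, , drop = FALSE], box)
    t <- rowSums(ap[has, , drop = FALSE] * ab) / rowSums(ab^2)
    t <- pmin(pmax(t, 0), 1)
    dd <- sqrt(rowSums((ap[has, , drop = FALSE] - ab * t)^2))
    best[has] <- pmin(best[has], dd)
  }
  best
}

# minimum image helpers (R side)
minimg <- function(d, box) {
  if (is.null(box)) return(d)
  d - box * round(d / box)
}
minimg_rows <- function(m, box) {
  if (is.null(box)) return(m)
  for (k in 1:3) m[, k] <- m[, k] - box[k] * round(m[, k] / box[k])
  m
}

#' Cross-links-per-filament benchmark
#'
#' Runs the full periodic-box network generation (seeding at the default
#' densities, polymerization, CL formation to convergence, prune/merge)
#' for several seeds and reports the mean cross-links per filament -- the
#' headline topology statistic of the assembly procedure.
#'
#' @param seeds integer vector of RNG seeds (>= 3 recommended).
#' @param box periodic box lengths (um).
#' @param config an [assembly_config()].
#' @return list with per-seed means/SDs and the pooled `mean`.
#' @export
cl_density_benchmark <- function(seeds = 1:3, box = rep(10, 3),
                                 config = assembly_config()) {
  per_seed <- lapply(seeds, function(s) {
    st <- topology_stats(assemble_network(box, config, seed = s))
    c(mean = st$cl_per_filament_mean, sd = st$cl_per_filament_sd)
  })
  m <- vapply(per_seed, `[[`, numeric(1), "mean")
  list(seed_means = m,
       seed_sds = vapply(per_seed, `[[`, numeric(1), "sd"),
       mean = mean(m))
}

#' Network topology statistics
#'
#' @param net a [filament_network()].
#' @param cell_mesh,nucleus_mesh optional meshes to report linked-vertex
#'   fractions against.
#' @return object of class `topology_stats`: mean and SD of cross-links
#'   per filament, linked membrane-vertex fractions, and the free-CL
#'   count trace if available.
#' @export
topology_stats <- function(net, cell_mesh = NULL, nucleus_mesh = NULL) {
  chain_id <- chain_id_of(net)
  cl <- net$bonds[net$bonds$class == "crosslink", , drop = FALSE]
  per_fil <- tabulate(c(chain_id[cl$i], chain_id[cl$j]),
                      nbins = length(net$chains))
  frac <- function(mesh, name) {
    if (is.null(mesh)) return(NA_real_)
    lk <- net$links[net$links$mesh == name, , drop = FALSE]
    length(unique(lk$vertex)) / nrow(mesh$positions)
  }
  structure(list(
    n_filaments = length(net$chains),
    n_crosslinks = nrow(cl),
    cl_per_filament_mean = mean(per_fil),
    cl_per_filament_sd = stats::sd(per_fil),
    cell_linked_fraction = frac(cell_mesh, "cell"),
    nucleus_linked_fraction = frac(nucleus_mesh, "nucleus"),
    free_cl_trace = attr(net, "free_cl_trace")
  ), class = "topology_stats")
}

#' @export
print.topology_stats <- function(x, ...) {
  cat(sprintf(
    "<topology_stats> %d filaments, %d CLs | CLs/filament %.2f +- %.2f\n",
    x$n_filaments, x$n_crosslinks, x$cl_per_filament_mean,
    x$cl_per_filament_sd))
  if (!is.na(x$cell_linked_fraction))
    cat(sprintf("  linked vertex fraction: cell %.3f nucleus %s\n",
                x$cell_linked_fraction,
                ifelse(is.na(x$nucleus_linked_fraction), "NA",
                       sprintf("%.3f", x$nucleus_linked_fraction))))
  invisible(x)
}
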