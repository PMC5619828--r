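#' Experiment record
#'
#' Time series of measured observables from a virtual experiment, with
#' ensemble metadata (cell id, rotation) and physics diagnostics.
#'
#' @param data data.frame of the time series.
#' @param kind "aspiration" or "transit".
#' @param meta named list of metadata.
#' @export
experiment_record <- function(data, kind, meta = list()) {
  stopifnot(is.data.frame(data))
  if (is.unsorted(data$time_s)) stop("time stamps must be monotone")
  structure(list(data = data, kind = kind, meta = meta),
            class = "experiment_record")
}

#' @export
print.experiment_record <- function(x, ...) {
  cat(sprintf("<experiment_record> %s, %d samples\n", x$kind, nrow(x$data)))
  if (!is.null(x$meta$velocity_mm_s))
    cat(sprintf("  transit velocity: %.3f mm/s (%s)\n",
                x$meta$velocity_mm_s, x$meta$outcome))
  invisible(x)
}

#' Micropipette aspiration protocol
#'
#' The physical protocol ramps the suction pressure from 0 to
#' `max_pressure` at `rate`; in simulation the ramp is applied as a
#' staircase of `n_levels` equal pressure increments held for
#' `steps_per_level` DPD steps each (a quasi-static acceleration of the
#' wall-clock ramp, which would be computationally unreachable at the
#' physical rate).  The first level doubles as the "tiny pressure"
#' baseline defining `L_p0`.
#'
#' @param rate physical pressure ramp rate (Pa/s), recorded as metadata.
#' @param max_pressure maximum suction pressure (Pa).
#' @param n_levels number of staircase levels.
#' @param steps_per_level DPD steps held at each level.
#' @param equil_steps equilibration steps before the ramp.
#' @param hold if TRUE the protocol holds `max_pressure` for
#'   `hold_steps` steps, sampling the creep response (viscosity runs).
#' @param hold_steps steps of the constant-pressure hold.
#' @export
aspiration_protocol <- function(rate = 3.27, max_pressure = 117.72,
                                n_levels = 12L, steps_per_level = 1500L,
                                equil_steps = 1000L, hold = FALSE,
                                hold_steps = 20000L) {
  stopifnot(rate > 0, max_pressure > 0, n_levels >= 2)
  structure(list(rate = rate, max_pressure = max_pressure,
                 n_levels = as.integer(n_levels),
                 steps_per_level = as.integer(steps_per_level),
                 equil_steps = as.integer(equil_steps), hold = hold,
                 hold_steps = as.integer(hold_steps)),
            class = "aspiration_protocol")
}

# assemble a cell bundle into a particle system at the given centre;
# returns the system pieces and index bookkeeping
bundle_system <- function(bundle, centre) {
  shift <- function(m) sweep(m, 2, centre, "+")
  net <- bundle$network
  nf <- nrow(net$positions)
  nv_c <- nrow(bundle$cell_mesh$positions)
  nv_n <- if (is.null(bundle$nucleus_mesh)) 0L else
    nrow(bundle$nucleus_mesh$positions)
  pos <- rbind(shift(net$positions), shift(bundle$cell_mesh$positions),
               if (nv_n) shift(bundle$nucleus_mesh$positions))
  types <- c(rep(2L, nf), rep(3L, nv_c), rep(4L, nv_n))
  bonds <- net$bonds[, c("i", "j", "kappa", "r0")]
  if (nrow(net$links)) {
    voff <- ifelse(net$links$mesh == "cell", nf, nf + nv_c)
    bonds <- rbind(bonds, data.frame(i = net$links$particle,
                                     j = voff + net$links$vertex,
                                     kappa = bundle$config$kappa_cl,
                                     r0 = net$links$r0))
  }
  meshes <- list(mesh_block(bundle$cell_mesh, nf))
  if (nv_n)
    meshes <- c(meshes, list(mesh_block(bundle$nucleus_mesh, nf + nv_c)))
  list(pos = pos, types = types, bonds = bonds,
       angles = net$angles[, c("i", "j", "k", "kappa", "theta0")],
       torsions = if (nrow(net$torsions)) net$torsions[
         , c("i", "j", "k", "l", "ktor", "phi0")] else NULL,
       meshes = meshes, nf = nf,
       membrane_idx = nf + seq_len(nv_c),
       cell_idx = seq_len(nf + nv_c + nv_n))
}

#' Run a micropipette aspiration experiment
#'
#' The cell is placed at the pipette mouth and the staircase pressure
#' ramp applied; the suction acts as a body force on cell particles
#' inside the pipette bore, rescaled each chunk so the total force equals
#' `dP * pi * R_p^2` (the pressure force on the aspirated tongue).  The
#' aspiration length `L_p` is the maximal penetration of any cell-surface
#' vertex past the mouth plane, `L_p0` its value at the first (baseline)
#' level, and `L_n = (L_p - L_p0) / R_p`.
#'
#' @param bundle a [build_cell()] result.
#' @param pipette a [pipette_geometry()].
#' @param protocol an [aspiration_protocol()].
#' @param thermo a [thermo_state()].
#' @param seed RNG seed (the full run is deterministic in it).
#' @param units a [unit_system()].
#' @param chunk steps between suction-force rescalings.
#' @param max_aspirated abort threshold: protocol aborts with a flag if
#'   `L_p` exceeds this multiple of the pipette radius.
#' @return an [experiment_record()] with columns `pressure_Pa`, `Lp`,
#'   `Ln`.
#' @export
run_aspiration <- function(bundle, pipette = pipette_geometry(),
                           protocol = aspiration_protocol(),
                           thermo = thermo_state(), seed = 1L,
                           units = unit_system(), chunk = 250L,
                           max_aspirated = 4) {
  R <- bundle$diameter / 2
  Rp <- pipette$radius
  span <- bundle$diameter + 6
  centre <- c(R + 2, span / 2, span / 2)
  x0 <- centre[1] + R * 0.98 # mouth plane just touching the cell front
  box <- c(x0 + max_aspirated * Rp + 4 * Rp, span, span)
  pip <- pipette_geometry(Rp, pipette$thickness, x0, centre[2], centre[3])
  sys <- bundle_system(bundle, centre)
  walls <- build_walls(pip$sdf, box, rep(FALSE, 3), seed = derive_seed(seed, 7))
  n_cell <- nrow(sys$pos)
  pos <- rbind(sys$pos, walls)
  types <- c(sys$types, rep(5L, nrow(walls)))
  set.seed(derive_seed(seed, 8))
  vel <- rbind(matrix(stats::rnorm(3 * n_cell, sd = sqrt(thermo$kBT)),
                      n_cell, 3), matrix(0, nrow(walls), 3))
  tab <- interaction_table(kBT = thermo$kBT)
  region <- list(x0 = x0 - 1, radius = Rp * 0.98, cy = centre[2],
                 cz = centre[3])
  pressures <- seq(protocol$max_pressure / protocol$n_levels,
                   protocol$max_pressure, length.out = protocol$n_levels)
  run_chunk <- function(pos, vel, g, steps, sd) {
    model <- list(types = types, box = box, periodic = rep(FALSE, 3),
                  kBT = thermo$kBT, dt = thermo$dt, mass = 1,
                  table = table_for_engine(tab), frozen = NULL,
                  bonds = sys$bonds, angles = sys$angles,
                  torsions = sys$torsions, meshes = sys$meshes,
                  body_force = if (g > 0) list(g = c(g, 0, 0),
                                               types = 2:4,
                                               region = region) else NULL,
                  sdf = pip$sdf)
    cpp_run(pos, vel, model, as.integer(steps), sd, 0L, integer(0), 1L, 0.3)
  }
  # equilibration
  out <- run_chunk(pos, vel, 0, protocol$equil_steps, derive_seed(seed, 9))
  pos <- out$positions
  vel <- out$velocities
  rows <- list()
  Lp0 <- NA_real_
  tsim <- protocol$equil_steps * thermo$dt
  aborted <- FALSE
  level_list <- c(pressures, if (protocol$hold) rep(
    protocol$max_pressure, ceiling(protocol$hold_steps /
                                     protocol$steps_per_level)))
  hold_from <- length(pressures) + 1L
  for (lev in seq_along(level_list)) {
    dP <- level_list[lev]
    dP_sim <- dP / units$pressure
    steps_left <- protocol$steps_per_level
    while (steps_left > 0) {
      nstep <- min(chunk, steps_left)
      # suction force: dP * pi Rp^2 shared by cell particles in the bore
      inb <- which(types %in% 2:4 &
                     pos[, 1] > region$x0 &
                     (pos[, 2] - region$cy)^2 + (pos[, 3] - region$cz)^2 <
                       region$radius^2)
      g <- if (length(inb)) dP_sim * pi * Rp^2 / length(inb) else 0
      out <- run_chunk(pos, vel, g, nstep,
                       derive_seed(seed, 20 + lev * 100 + steps_left))
      pos <- out$positions
      vel <- out$velocities
      steps_left <- steps_left - nstep
      tsim <- tsim + nstep * thermo$dt
    }
    Lp <- max(pos[sys$membrane_idx, 1]) - x0
    Lp <- max(Lp, 0)
    if (lev == 1) Lp0 <- Lp
    rows[[lev]] <- data.frame(
      time_sim = tsim, time_s = tsim * units$time, pressure_Pa = dP,
      Lp = Lp, Ln = max((Lp - Lp0) / Rp, 0),
      phase = if (lev >= hold_from) "hold" else "ramp")
    if (Lp > max_aspirated * Rp) { aborted <- TRUE; break }
  }
  experiment_record(do.call(rbind, rows), "aspiration",
                    meta = list(seed = seed, pipette = pip,
                                protocol = protocol, aborted = aborted,
                                Lp0 = Lp0, diameter = bundle$diameter))
}

#' Run a microfluidic transit experiment
#'
#' The cell is inserted upstream of the constriction in a one-period
#' obstacle-array domain filled with DPD fluid; a uniform body force
#' equivalent to the pressure gradient drives the flow.  The transit
#' velocity is the travelled centroid distance over elapsed time once the
#' cell has crossed `n_periods` constriction rows; a cell whose centroid
#' advances less than `stuck_tol` over `stuck_window` chunks is reported
#' "stuck".
#'
#' @param bundle a [build_cell()] result (NULL runs tracer-free fluid
#'   and reports the mean fluid speed instead).
#' @param device a [device_geometry()].
#' @param pressure_gradient driving pressure drop (Pa/um).
#' @param thermo a [thermo_state()].
#' @param seed RNG seed.
#' @param units a [unit_system()].
#' @param n_periods constriction rows to traverse.
#' @param chunk steps per measurement chunk.
#' @param max_steps step budget.
#' @param equil_steps flow pre-equilibration steps.
#' @param stuck_tol,stuck_window stuck-detection parameters (um, chunks).
#' @return an [experiment_record()] with the centroid trajectory and
#'   `meta$velocity_mm_s`.
#' @export
run_transit <- function(bundle, device,
                        pressure_gradient = device$pressure_gradient,
                        thermo = thermo_state(), seed = 1L,
                        units = unit_system(), n_periods = 2L,
                        chunk = 500L, max_steps = 2e5L,
                        equil_steps = 1000L, stuck_tol = 0.5,
                        stuck_window = 10L) {
  box <- device$box
  centre <- c(device$row_spacing * 0.15, 0, box[3] / 2)
  has_cell <- !is.null(bundle)
  if (has_cell) {
    sys <- bundle_system(bundle, centre)
    excl <- function(p) {
      # exclude fluid from the cell interior (all periodic y images)
      inside <- rep(FALSE, nrow(p))
      for (dy in c(-box[2], 0, box[2])) {
        q <- p
        q[, 2] <- q[, 2] + dy
        inside <- inside | cpp_points_in_mesh(
          q, sweep(bundle$cell_mesh$positions, 2, centre, "+"),
          bundle$cell_mesh$tris)
      }
      inside
    }
  } else {
    sys <- list(pos = matrix(0, 0, 3), types = integer(0), bonds = NULL,
                angles = NULL, torsions = NULL, meshes = NULL,
                cell_idx = integer(0))
    excl <- NULL
  }
  fl <- fill_fluid(device$sdf, box, device$periodic, exclude = excl,
                   seed = derive_seed(seed, 11))
  walls <- build_walls(device$sdf, box, device$periodic,
                       seed = derive_seed(seed, 12))
  pos <- rbind(sys$pos, fl, walls)
  types <- c(sys$types, rep(1L, nrow(fl)), rep(5L, nrow(walls)))
  n_mob <- nrow(sys$pos) + nrow(fl)
  set.seed(derive_seed(seed, 13))
  vel <- rbind(matrix(stats::rnorm(3 * n_mob, sd = sqrt(thermo$kBT)),
                      n_mob, 3), matrix(0, nrow(walls), 3))
  tab <- interaction_table(kBT = thermo$kBT)
  bf <- drive_flow(pressure_gradient, units = units)
  track <- if (has_cell) sys$cell_idx else seq_len(n_mob)
  model_of <- function(drive) list(
    types = types, box = box, periodic = device$periodic,
    kBT = thermo$kBT, dt = thermo$dt, mass = 1,
    table = table_for_engine(tab), frozen = NULL,
    bonds = sys$bonds, angles = sys$angles, torsions = sys$torsions,
    meshes = sys$meshes, body_force = if (drive) bf else NULL,
    sdf = device$sdf)
  out <- cpp_run(pos, vel, model_of(FALSE), as.integer(equil_steps),
                 derive_seed(seed, 14), 0L, integer(0), 1L, 0.3)
  pos <- out$positions
  vel <- out$velocities
  rows <- list()
  tsim <- 0
  x_start <- mean(pos[track, 1])
  goal <- x_start + n_periods * device$row_spacing
  outcome <- "running"
  it <- 0L
  recent <- numeric(0)
  repeat {
    it <- it + 1L
    out <- cpp_run(pos, vel, model_of(TRUE), as.integer(chunk),
                   derive_seed(seed, 1e4 + it), as.integer(chunk),
                   as.integer(track), 1L, 0.3)
    pos <- out$positions
    vel <- out$velocities
    tsim <- tsim + chunk * thermo$dt
    cx <- mean(pos[track, 1])
    rows[[it]] <- data.frame(time_sim = tsim, time_s = tsim * units$time,
                             cx = cx, cy = mean(pos[track, 2]),
                             cz = mean(pos[track, 3]),
                             temperature = out$diagnostics[1, "temperature"])
    recent <- c(recent, cx)
    if (cx >= goal) { outcome <- "transited"; break }
    if (it * chunk >= max_steps) { outcome <- "timeout"; break }
    if (length(recent) > stuck_window &&
        diff(range(tail(recent, stuck_window))) < stuck_tol) {
      outcome <- "stuck"
      break
    }
  }
  dat <- do.call(rbind, rows)
  rownames(dat) <- NULL
  v_sim <- (tail(dat$cx, 1) - x_start) / tsim
  experiment_record(dat, "transit", meta = list(
    seed = seed, device = device, outcome = outcome,
    velocity_sim = v_sim,
    velocity_mm_s = v_sim * units$velocity * 1e3,
    pressure_gradient = pressure_gradient,
    has_cell = has_cell))
}

#' Run an ensemble of experiments over cells and rotations
#'
#' Each cell is rotated by `rotations` equal angles about the z axis
#' (orthogonal to the pipette/flow x axis) and the experiment repeated;
#' per-run records are retained and a mean +- SD summary returned.
#'
#' @param cells list of [build_cell()] bundles (>= 1).
#' @param experiment "aspiration" or "transit".
#' @param rotations number of rotation angles.
#' @param seed RNG seed stream base.
#' @param ... passed to [run_aspiration()] / [run_transit()]
#'   (`device` is required for transit).
#' @return list with `records` and a `summary` data.frame: per-pressure
#'   mean/SD of `Ln` for aspiration, per-cell velocity table plus overall
#'   mean/SD for transit.
#' @export
run_ensemble <- function(cells, experiment = c("aspiration", "transit"),
                         rotations = 4L, seed = 1L, ...) {
  experiment <- match.arg(experiment)
  if (!length(cells)) stop("empty ensemble")
  records <- list()
  k <- 0L
  for (ci in seq_along(cells)) {
    for (ri in seq_len(rotations)) {
      k <- k + 1L
      b <- rotate_bundle(cells[[ci]], 2 * pi * (ri - 1) / rotations)
      rec <- if (experiment == "aspiration")
        run_aspiration(b, seed = derive_seed(seed, k), ...)
      else run_transit(b, seed = derive_seed(seed, k), ...)
      rec$meta$cell_id <- ci
      rec$meta$rotation <- ri
      records[[k]] <- rec
    }
  }
  if (experiment == "aspiration") {
    all <- do.call(rbind, lapply(seq_along(records), function(i)
      cbind(records[[i]]$data, run = i)))
    agg <- do.call(rbind, lapply(split(all, all$pressure_Pa), function(d)
      data.frame(pressure_Pa = d$pressure_Pa[1], Ln_mean = mean(d$Ln),
                 Ln_sd = if (nrow(d) > 1) stats::sd(d$Ln) else 0)))
    rownames(agg) <- NULL
    list(records = records, summary = agg)
  } else {
    v <- vapply(records, function(r) r$meta$velocity_mm_s, numeric(1))
    cellid <- vapply(records, function(r) r$meta$cell_id, numeric(1))
    list(records = records,
         summary = data.frame(cell = cellid,
                              velocity_mm_s = v),
         velocity_mean = mean(v),
         velocity_sd = if (length(v) > 1) stats::sd(v) else 0)
  }
}
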