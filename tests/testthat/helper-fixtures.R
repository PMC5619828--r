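# shared, lazily built fixtures (each built once per test run)

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

small_mesh <- function() cached("small_mesh", function() make_sphere_mesh(40, 3))

membrane_mesh <- function() cached("membrane_mesh",
                                   function() make_sphere_mesh(200, 6))

fluid_box <- function() cached("fluid_box", function() make_fixture("fluid-box", 3))

network_box <- function() cached("network_box", function() {
  assemble_network(rep(6, 3),
                   assembly_config(polymerize_steps = 2000,
                                   cl_max_steps = 3e4, window = 3000),
                   seed = 2)
})

mini_cell <- function() cached("mini_cell", function() make_fixture("mini-cell", 1))

icosahedron_mesh <- function(scale = 3, lmax = 8) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2) * scale
  mesh_from_faces(v, dpdcell:::cpp_convex_hull(v), lmax = lmax)
}

# max relative error between analytic forces and the central-difference
# gradient of the energy, probed at sampled coordinates
fd_max_rel_err <- function(force_fun, energy_fun, pos, n_probe = 30,
                           h = 1e-6) {
  F <- force_fun(pos)
  worst <- 0
  probes <- sample(length(pos), min(n_probe, length(pos)))
  for (q in probes) {
    p1 <- pos; p1[q] <- p1[q] + h
    p2 <- pos; p2[q] <- p2[q] - h
    g <- -(energy_fun(p1) - energy_fun(p2)) / (2 * h)
    worst <- max(worst, abs(g - F[q]) / max(abs(F[q]), 1e-4))
  }
  worst
}

# steady pressure-driven slab flow; the channel height is kept small so
# the momentum-diffusion time (rho H^2 / eta, the time to reach steady
# state) fits the step budget.  Results are memoised per (g, steps, seed).
poiseuille_run <- function(g, steps = 150000, seed = 4) {
  key <- sprintf("poiseuille_%g_%g_%g", g, steps, seed)
  if (exists(key, envir = .fixture_cache))
    return(get(key, envir = .fixture_cache))
  res <- poiseuille_run_impl(g, steps, seed)
  assign(key, res, envir = .fixture_cache)
  res
}

poiseuille_run_impl <- function(g, steps, seed) {
  box <- c(8, 6, 6)
  per <- c(TRUE, TRUE, FALSE)
  s <- sdf_union(sdf_slab(3, 1, 5))
  walls <- build_walls(s, box, per, seed = 1)
  fl <- fill_fluid(s, box, per, seed = 2)
  pos <- rbind(fl, walls)
  types <- c(rep(1L, nrow(fl)), rep(5L, nrow(walls)))
  set.seed(3)
  vel <- rbind(matrix(rnorm(3 * nrow(fl)), nrow(fl), 3),
               matrix(0, nrow(walls), 3))
  sys <- particle_system(pos, vel, types, box, per)
  bf <- list(g = c(g, 0, 0), types = 1L, region = NULL)
  th <- thermo_state(seed = seed)
  # accumulate a time-averaged velocity profile over chunks
  breaks <- seq(1, 5, by = 0.5)
  acc <- numeric(length(breaks) - 1)
  cnt <- numeric(length(breaks) - 1)
  warm <- steps / 2
  chunk <- 125
  done <- 0
  while (done < steps) {
    sys <- run_dpd(sys, interaction_table(), thermo_state(seed = seed + done),
                   chunk, sdf = s, body_force = bf)
    done <- done + chunk
    if (done > warm) {
      z <- sys$positions[types == 1L, 3]
      vx <- sys$velocities[types == 1L, 1]
      b <- findInterval(z, breaks, all.inside = TRUE)
      acc <- acc + tapply(vx, factor(b, levels = seq_along(acc)), sum,
                          default = 0)
      cnt <- cnt + tabulate(b, nbins = length(acc))
    }
  }
  list(z = (head(breaks, -1) + tail(breaks, -1)) / 2, v = acc / pmax(cnt, 1),
       sys = sys, types = types, sdf = s, box = box, per = per)
}
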