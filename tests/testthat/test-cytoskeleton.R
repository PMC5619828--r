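make_two_chain_net <- function(pos, cfg = assembly_config()) {
  filament_network(pos, list(1:3, 4:6),
                   bonds = data.frame(i = c(1, 2, 4, 5), j = c(2, 3, 5, 6),
                                      kappa = cfg$kappa_fil, r0 = 0.5,
                                      class = "filament"),
                   angles = data.frame(i = c(1, 4), j = c(2, 5),
                                       k = c(3, 6), kappa = cfg$kappa_bend,
                                       theta0 = pi, class = "filament"))
}

test_that("harmonic bond and angle forces behave at their minima", {
  cfg <- assembly_config()
  # straight chains at rest length: zero force
  pos <- rbind(cbind(seq(0, 1, by = 0.5), 0, 0),
               cbind(seq(0, 1, by = 0.5), 1, 0))
  net <- make_two_chain_net(pos, cfg)
  F <- bond_angle_forces(net)
  expect_lt(max(abs(F)), 1e-10)
  expect_equal(attr(F, "energy"), 0)
  # quadratic energy near the bond minimum
  d <- 1e-3
  pos2 <- pos
  pos2[3, 1] <- pos2[3, 1] + d
  F2 <- bond_angle_forces(net, pos2)
  expect_equal(attr(F2, "energy"), cfg$kappa_fil * d^2, tolerance = 1e-6)
  # gradient check on a distorted configuration
  set.seed(11)
  posr <- pos + matrix(rnorm(18, sd = 0.05), 6, 3)
  err <- fd_max_rel_err(function(p) bond_angle_forces(net, p),
                        function(p) attr(bond_angle_forces(net, p), "energy"),
                        posr, n_probe = 18)
  expect_lt(err, 1e-4)
})

test_that("torsion term is a cosine well over the CL dihedral", {
  cfg <- assembly_config()
  set.seed(12)
  pos <- matrix(rnorm(12), 4, 3)
  net <- filament_network(pos, list(1:2, 3:4),
                          torsions = data.frame(i = 1, j = 2, k = 3, l = 4,
                                                ktor = cfg$k_tor,
                                                phi0 = 0.4))
  phi <- dpdcell:::cpp_dihedral_angles(pos, matrix(1:4, 1, 4), c(0, 0, 0),
                                       rep(FALSE, 3))
  # zero force at phi = phi0
  net0 <- net
  net0$torsions$phi0 <- phi
  expect_lt(max(abs(torsion_forces(net0))), 1e-10)
  # energy at phi0 + pi is 2 k_tor
  netpi <- net
  netpi$torsions$phi0 <- phi + pi
  expect_equal(attr(torsion_forces(netpi), "energy"), 2 * cfg$k_tor,
               tolerance = 1e-9)
  err <- fd_max_rel_err(function(p) torsion_forces(net, p),
                        function(p) attr(torsion_forces(net, p), "energy"),
                        pos, n_probe = 12)
  expect_lt(err, 1e-4)
})

test_that("Bell kinetics follow the two-branch dissociation law", {
  bp <- bell_params_cl() # kappa0 = 78/s, lambda = 3.5e-5 um
  # slack branch: rate is kappa0 regardless of force
  expect_equal(bell_rate(c(0, 10, 1e4), rep(0.1, 3), bp), rep(78, 3))
  # loaded branch at lambda F = kBT: kappa0 * e
  expect_equal(bell_rate(1 / bp$lambda, 0.3, bp), 78 * exp(1))
  # continuity at zero force
  expect_equal(bell_rate(0, 0.1, bp), bell_rate(0, 0.3, bp))
  # monotone nondecreasing in F on the loaded branch
  Fs <- seq(0, 5e5, length.out = 50)
  expect_true(all(diff(bell_rate(Fs, 0.3, bp)) >= 0))
  # overflow guard clamps the probability at 1
  expect_equal(bell_unbind_probability(1e10, 0.3, bp, dt = 1e-3), 1)
  expect_error(bell_unbind_probability(1, 0.3, bp, dt = 0), "dt")
  expect_error(bell_params(-1, 0, 0.25), "kappa0")
})

test_that("unloaded bond survival is exponential with mean 1/kappa0", {
  bp <- bell_params_cl()
  us <- unit_system()
  dt_chunk <- 50 # sim time units between unbinding draws
  p <- bell_unbind_probability(0, 0.1, bp, dt = dt_chunk, units = us)
  set.seed(13)
  lifetimes <- (stats::rgeom(1e4, p) + 1) * dt_chunk * us$time
  expect_equal(mean(lifetimes), 1 / bp$kappa0, tolerance = 0.1)
  # geometric sampling of the exponential law: KS against pexp after
  # randomising within the sampling interval
  jitter <- stats::runif(1e4, 0, dt_chunk * us$time)
  ks <- suppressWarnings(stats::ks.test(lifetimes - jitter, stats::pexp,
                                        rate = bp$kappa0))
  expect_gt(ks$p.value, 0.01)
})

test_that("crossing filaments do not interpenetrate", {
  # two short filaments driven through each other: the a = 100, Rc = 0.5
  # repulsion keeps the chains > 0.2 apart in every trial
  cfg <- assembly_config()
  tab <- interaction_table()
  th <- thermo_state()
  npart <- 5
  mins <- numeric(100)
  for (trial in 1:100) {
    set.seed(trial)
    off <- runif(2, -0.2, 0.2)
    a <- cbind(seq(-1, 1, length.out = npart), off[1], -0.4)
    b <- cbind(off[2], seq(-1, 1, length.out = npart), 0.4)
    pos <- rbind(a, b) + 5
    vel <- rbind(matrix(rep(c(0, 0, 1), each = npart), npart, 3),
                 matrix(rep(c(0, 0, -1), each = npart), npart, 3))
    bonds <- data.frame(i = c(1:4, 6:9), j = c(2:5, 7:10),
                        kappa = cfg$kappa_fil, r0 = 0.5)
    model_net <- filament_network(pos, list(1:5, 6:10),
                                  bonds = cbind(bonds, class = "filament"),
                                  box = rep(10, 3))
    sys <- particle_system(pos, vel, rep(2L, 10), rep(10, 3))
    out <- run_dpd(sys, tab, thermo_state(seed = trial), 1500,
                   bonded = force_field(bonds = bonds))
    dmin <- min(dpdcell:::cpp_pairs_between(
      out$positions[1:5, ], out$positions[6:10, ], 5, rep(10, 3),
      rep(TRUE, 3))$dist)
    mins[trial] <- dmin
  }
  expect_gt(min(mins), 0.2)
})
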