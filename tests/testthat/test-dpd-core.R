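test_that("conservative force has the linear soft-repulsion form", {
  # at the cutoff and at half the cutoff
  expect_equal(conservative_force(c(1, 0, 0), a = 10, R_c = 1), c(0, 0, 0))
  f <- conservative_force(c(0.5, 0, 0), a = 10, R_c = 1)
  expect_equal(f, c(5, 0, 0)) # repulsive, pushes i away from j
  # short-cutoff filament row: a = 100, R_c = 0.5, r = 0.25
  f <- conservative_force(c(0, 0.25, 0), a = 100, R_c = 0.5)
  expect_equal(sqrt(sum(f^2)), 50)
  expect_error(conservative_force(c(0, 0, 0), 10, 1), "degenerate")
})

test_that("dissipative and random forces follow the pair thermostat", {
  # perpendicular relative velocity: no dissipative force
  out <- dissipative_random_forces(c(1, 0, 0) * 0.5, c(0, 1, 0),
                                   gamma = 45, R_c = 1, theta = 0)
  expect_equal(out$dissipative, c(0, 0, 0))
  # weight at half the cutoff
  expect_equal((1 - 0.5)^0.25, 0.8408964, tolerance = 1e-6)
  out <- dissipative_random_forces(c(0.5, 0, 0), c(0, 0, 0), gamma = 45,
                                   R_c = 1, kBT = 1, dt = 1e-3, theta = 1)
  expect_equal(out$random[1],
               sqrt(2 * 45) * 0.5^0.25 / sqrt(1e-3), tolerance = 1e-10)
  # zero-mean noise: mean of f_R over many samples within 4 SE
  set.seed(1)
  th <- rnorm(1e5)
  fr <- sqrt(2 * 45) * 0.5^0.25 * th / sqrt(1e-3)
  expect_lt(abs(mean(fr)), 4 * sd(fr) / sqrt(length(fr)))
  expect_error(dissipative_random_forces(c(0.5, 0, 0), c(0, 0, 0),
                                         gamma = -1, R_c = 1),
               "gamma")
  expect_error(dissipative_random_forces(c(0.5, 0, 0), c(0, 0, 0),
                                         gamma = 45, R_c = 1, sigma = 1),
               "sigma")
})

test_that("neighbor lists match the brute-force oracle", {
  box <- c(6, 6, 6)
  two <- function(d) particle_system(rbind(c(1, 1, 1), c(1 + d, 1, 1)),
                                     box = box)
  expect_equal(nrow(build_neighbor_lists(two(0.9), 1.0)), 1)
  expect_equal(nrow(build_neighbor_lists(two(1.1), 1.0)), 0)
  set.seed(5)
  p <- matrix(runif(300), 100, 3) * 6
  sys <- particle_system(p, box = box)
  key <- function(m) sort(paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2])))
  np <- build_neighbor_lists(sys, 1.0)
  bp <- dpdcell:::cpp_brute_pairs(p, box, rep(TRUE, 3), 1.0)
  expect_identical(key(np), key(bp))
  expect_error(build_neighbor_lists(two(0.9), 2.5), "configuration")
})

test_that("free streaming: zero forces advance r by v dt", {
  p <- rbind(c(1, 1, 1), c(3, 3, 3))
  v <- rbind(c(0.5, -0.2, 0.1), c(0, 1, 0))
  sys <- particle_system(p, v, box = c(6, 6, 6))
  tb <- interaction_table()
  tb$a[, ] <- 0
  tb$gamma[, ] <- 0
  tb$sigma[, ] <- 0
  out <- step(sys, tb, thermo_state(dt = 1e-3))
  expect_equal(out$positions, p + v * 1e-3)
})

test_that("momentum is conserved in a periodic fluid box", {
  out <- run_dpd(fluid_box(), interaction_table(), thermo_state(seed = 7),
                 2000, sample_every = 200)
  d <- attr(out, "diagnostics")
  drift <- max(abs(sweep(d[, 4:6], 2, d[1, 4:6])))
  expect_lt(drift / n_particles(out) / 2000, 1e-8)
})

test_that("thermostat holds kBT within 3% for gamma in {30, 45, 65}", {
  for (g in c(30, 45, 65)) {
    tb <- interaction_table(gamma = matrix(g, 5, 5))
    out <- run_dpd(fluid_box(), tb, thermo_state(seed = 11), 3000,
                   sample_every = 100)
    d <- attr(out, "diagnostics")
    Tk <- mean(d[d[, 1] > 1000, 3])
    expect_lt(abs(Tk - 1), 0.03)
  }
})

test_that("fixed seed reproduces the trajectory bit for bit", {
  a <- run_dpd(fluid_box(), interaction_table(), thermo_state(seed = 9), 500)
  b <- run_dpd(fluid_box(), interaction_table(), thermo_state(seed = 9), 500)
  expect_identical(a$positions, b$positions)
  expect_identical(a$velocities, b$velocities)
  # no particle loss
  expect_equal(n_particles(a), n_particles(fluid_box()))
})

test_that("pairwise forces are antisymmetric", {
  set.seed(2)
  p <- matrix(runif(60), 20, 3) * 4
  v <- matrix(rnorm(60), 20, 3)
  tb <- interaction_table()
  F <- dpdcell:::cpp_pair_forces(p, v, rep(1L, 20), rep(FALSE, 20),
                                 dpdcell:::table_for_engine(tb),
                                 c(4, 4, 4), rep(TRUE, 3), 1, 1e-3, 5, TRUE)
  # total force exactly zero in every component
  expect_equal(colSums(F), c(0, 0, 0), tolerance = 1e-12)
})
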