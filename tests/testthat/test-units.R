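test_that("unit system derives the expected scales", {
  us <- unit_system()
  expect_equal(us$time, 1 / 3e4, tolerance = 1e-6) # ~3.33e-5 s
  expect_equal(us$pressure, 1.15, tolerance = 1e-12) # 1.15e-18 J / um^3
  # round trips
  for (q in c("energy", "length", "time", "pressure", "velocity", "rate"))
    expect_equal(to_phys(to_sim(2.5, q, us), q, us), 2.5)
})

test_that("filament-block parameter ratios share one energy unit to 15%", {
  # phys/sim ratios (lengths in m, 1 sim length = 1e-6 m)
  unit_per_row <- c(
    kappa_fil = 0.092 * 1e-12 / 8e4, # N/m spring constants scale as E/L^2
    kappa_cl = 0.0092 * 1e-12 / 8e3,
    kappa_bend = 4.025e-16 / 350, # energies map directly
    kappa_clfil = 6.325e-16 / 550,
    k_tor = 4.7e-16 / 470
  )
  expect_true(all(abs(unit_per_row / 1.15e-18 - 1) < 0.15))
})

test_that("interaction table enforces fluctuation-dissipation and symmetry", {
  tb <- interaction_table()
  expect_equal(tb$sigma^2, 2 * tb$gamma * tb$kBT)
  expect_equal(tb$a, t(tb$a))
  expect_equal(tb$a[1, 1], 10)
  expect_equal(tb$gamma[2, 2], 65)
  expect_equal(tb$rc_rep[2, 2], 0.5)
  expect_equal(tb$rc_th[2, 2], 1.0)
  expect_equal(tb$a[5, 5], 0) # wall-wall excluded
  bad <- tb
  bad$a[1, 2] <- 99
  expect_error(validate_interaction_table(bad), "symmetric")
})
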