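tiny_protocol <- function(maxp = 117.72, nlev = 3)
  aspiration_protocol(max_pressure = maxp, n_levels = nlev,
                      steps_per_level = 150, equil_steps = 100)

test_that("aspiration at negligible suction leaves Ln at thermal noise", {
  b <- mini_cell()
  pip <- pipette_geometry(radius = 1.2)
  rec <- run_aspiration(b, pip, tiny_protocol(maxp = 1e-4), seed = 21)
  expect_true(all(rec$data$Ln < 0.05))
  expect_true(all(rec$data$Ln >= 0))
  expect_false(rec$meta$aborted)
})

test_that("aspiration records are deterministic in the seed", {
  b <- mini_cell()
  pip <- pipette_geometry(radius = 1.2)
  r1 <- run_aspiration(b, pip, tiny_protocol(), seed = 22)
  r2 <- run_aspiration(b, pip, tiny_protocol(), seed = 22)
  expect_identical(r1$data, r2$data)
  expect_true(all(diff(r1$data$time_s) > 0)) # monotone time stamps
})

test_that("transit records a centroid trajectory and an outcome", {
  b <- mini_cell()
  dev <- make_fixture("mini-device")
  rec <- run_transit(b, dev, seed = 23, chunk = 250, max_steps = 2000,
                     equil_steps = 200)
  expect_s3_class(rec, "experiment_record")
  expect_true(rec$meta$outcome %in% c("transited", "timeout", "stuck"))
  expect_true(is.finite(rec$meta$velocity_mm_s))
  expect_true(all(diff(rec$data$time_s) > 0))
  # flow pushes the cell downstream
  expect_gt(tail(rec$data$cx, 1), rec$data$cx[1] - 0.5)
})

test_that("ensembles aggregate per-pressure summaries with nonnegative SD", {
  b <- mini_cell()
  pip <- pipette_geometry(radius = 1.2)
  ens <- run_ensemble(list(b), "aspiration", rotations = 2, seed = 24,
                      pipette = pip, protocol = tiny_protocol())
  expect_length(ens$records, 2)
  expect_true(all(ens$summary$Ln_sd >= 0))
  expect_equal(nrow(ens$summary), 3) # one row per pressure level
  # one cell, one rotation: the summary equals the single record
  one <- run_ensemble(list(b), "aspiration", rotations = 1, seed = 24,
                      pipette = pip, protocol = tiny_protocol())
  expect_equal(one$summary$Ln_mean, one$records[[1]]$data$Ln)
  expect_error(run_ensemble(list(), "aspiration"), "empty")
})

test_that("rotating a membrane-only cell leaves aspiration invariant", {
  # a cytoskeleton-free bundle is statistically spherically symmetric:
  # rotation changes nothing but the (identical) initial state
  m <- membrane_mesh()
  empty_net <- filament_network(matrix(0, 0, 3), list())
  b <- structure(list(cell_mesh = m, nucleus_mesh = NULL,
                      network = empty_net, stats = NULL, diameter = 6,
                      nc = 0, config = assembly_config(), seed = 1L),
                 class = "cell_bundle")
  pip <- pipette_geometry(radius = 1.2)
  recs <- lapply(c(0, pi / 2), function(ang) {
    run_aspiration(rotate_bundle(b, ang), pip, tiny_protocol(), seed = 25)
  })
  ln <- vapply(recs, function(r) tail(r$data$Ln, 1), numeric(1))
  # rotation variance ~ 0 relative to the signal scale
  expect_lt(diff(range(ln)), 0.05)
})
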