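test_that("effective opening size is the equal-area-circle radius", {
  expect_equal(effective_opening_size(pi, 1), 1) # unit circle
  expect_equal(round(effective_opening_size(10, 25.8), 1), 9.1)
  expect_equal(round(effective_opening_size(12, 25.8), 2), 9.93)
  expect_equal(round(effective_opening_size(15, 25.8), 1), 11.1)
  expect_error(effective_opening_size(-1, 25.8), "domain")
  expect_error(effective_opening_size(10, 0), "domain")
})

test_that("SDF primitives partition fluid and solid as specified", {
  # slab: fluid inside [1, 5] along z
  s <- sdf_union(sdf_slab(3, 1, 5))
  v <- sdf_eval(s, rbind(c(0, 0, 3), c(0, 0, 0.5), c(0, 0, 6)))
  expect_true(v[1] < 0 && v[2] > 0 && v[3] > 0)
  # pipette: bore is fluid, annulus is solid, upstream of mouth is fluid
  p <- sdf_union(sdf_pipette(x0 = 0, radius = 2, thickness = 1))
  v <- sdf_eval(p, rbind(c(1, 0, 0), c(1, 2.5, 0), c(-1, 2.5, 0),
                         c(1, 3.5, 0)))
  expect_true(v[1] < 0 && v[2] > 0 && v[3] < 0 && v[4] < 0)
})

test_that("the obstacle-array SDF reproduces the printed gap", {
  dev <- device_geometry(gap = 12)
  expect_equal(dev$period, dev$side + 12)
  # scan across y at the pillar base: the fluid-passable width equals the
  # gap within sampling tolerance
  y <- seq(0, dev$box[2], length.out = 4001)
  h <- sqrt(3) / 2 * dev$side
  x <- dev$row_spacing / 2 + h / 3 - 1e-6
  pts <- cbind(x, y, dev$box[3] / 2)
  s <- sdf_eval(dev$sdf, pts, dev$box, dev$periodic)
  fluid_width <- mean(s < 0) * dev$box[2]
  expect_lt(abs(fluid_width - dev$gap), 0.05)
  expect_equal(dev$effective_opening, effective_opening_size(12, 25.8))
})

test_that("wall particles fill the solid shell and stay frozen", {
  box <- c(8, 6, 12)
  per <- c(TRUE, TRUE, FALSE)
  s <- sdf_union(sdf_slab(3, 1, 11))
  w <- build_walls(s, box, per, seed = 1)
  expect_gt(nrow(w), 0)
  sv <- sdf_eval(s, w, box, per)
  expect_true(all(sv > 0 & sv <= 1))
  f <- fill_fluid(s, box, per, seed = 2)
  expect_true(all(sdf_eval(s, f, box, per) < 0))
})


test_that("driven channel flow recovers the continuum Poiseuille profile", {
  pr <- poiseuille_run(0.2)
  # parabolic fit v(z) = vmax (1 - ((z - zc)/H)^2) in the bulk; the
  # near-wall layer (~ one cutoff) carries the usual DPD wall structure
  # and is excluded from the continuum comparison
  bulk <- pr$z > 1.6 & pr$z < 4.4
  fit <- lm(pr$v[bulk] ~ pr$z[bulk] + I(pr$z[bulk]^2))
  pred <- fitted(fit)
  r2 <- 1 - sum((pr$v[bulk] - pred)^2) /
    sum((pr$v[bulk] - mean(pr$v[bulk]))^2)
  expect_gt(r2, 0.95)
  expect_lt(coef(fit)[3], 0) # concave: maximum in the channel interior
  zmax <- -coef(fit)[2] / (2 * coef(fit)[3])
  expect_lt(abs(zmax - 3), 0.4) # centred
  # near-wall no-slip: edge bins move much slower than the centre
  expect_lt(mean(abs(pr$v[c(1, length(pr$v))])), 0.5 * max(pr$v))
  # containment: no fluid particle inside the solid
  wp <- wrapped_positions(pr$sys)[pr$types == 1L, ]
  expect_equal(sum(sdf_eval(pr$sdf, wp, pr$box, pr$per) > 0), 0)
})

test_that("mean flow responds linearly to the driving gradient", {
  v1 <- mean(poiseuille_run(0.06)$v)
  v2 <- mean(poiseuille_run(0.12)$v)
  expect_lt(abs(v2 / v1 - 2), 0.25) # low-Re linearity within noise
})

test_that("drive_flow converts the printed gradient to a body force", {
  us <- unit_system()
  bf <- drive_flow(0.67, density = 3, units = us)
  expect_equal(bf$g[1], 0.67 / us$pressure / 3, tolerance = 1e-12)
  expect_equal(drive_flow(0)$g, c(0, 0, 0))
})
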