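test_that("Theret modulus matches the half-space closed form", {
  # direct evaluation: dP = 100 Pa at Ln = 0.42 with Phi_p = 2.1
  rec <- experiment_record(
    data.frame(time_sim = 1:3, time_s = 1:3,
               pressure_Pa = c(50, 75, 100), Lp = NA,
               Ln = c(0.21, 0.315, 0.42), phase = "ramp"),
    "aspiration")
  fit <- theret_modulus(rec, fit_fraction = 1)
  expect_equal(fit$E, 3 * 2.1 * 100 / (2 * pi * 0.42), tolerance = 1e-10)
  # doubling all pressures at fixed Ln doubles E
  rec2 <- rec
  rec2$data$pressure_Pa <- rec$data$pressure_Pa * 2
  expect_equal(theret_modulus(rec2, fit_fraction = 1)$E, 2 * fit$E)
  # round trip through the synthetic generator
  for (E in c(75, 237.47, 300)) {
    syn <- synthetic_aspiration_record(E)
    expect_lt(abs(theret_modulus(syn)$E / E - 1), 0.01)
  }
  # nonpositive slope is a fit error
  bad <- rec
  bad$data$Ln <- -bad$data$Ln
  expect_error(theret_modulus(bad), "3 \\(pressure|slope")
})

test_that("creep fit recovers the time constant and scales viscosity", {
  base_fit <- theret_modulus(synthetic_aspiration_record(237.47))
  syn <- synthetic_creep_record(tau = 1.3)
  vf <- creep_viscosity(syn, base_fit)
  expect_lt(abs(vf$tau_s / 1.3 - 1), 0.05)
  # noisy round trip still within 5%
  syn_n <- synthetic_creep_record(tau = 0.8, noise_sd = 0.01, seed = 2)
  vfn <- creep_viscosity(syn_n, base_fit)
  expect_lt(abs(vfn$tau_s / 0.8 - 1), 0.05)
  # eta = E tau: strictly increasing in tau at fixed E, -> 0 as tau -> 0
  vf2 <- creep_viscosity(synthetic_creep_record(tau = 2.6), base_fit)
  expect_gt(vf2$eta_mPa_s, vf$eta_mPa_s)
  vf0 <- creep_viscosity(
    synthetic_creep_record(tau = 0.01, times = seq(0, 0.2, by = 0.002)),
    base_fit)
  expect_lt(vf0$eta_mPa_s, vf$eta_mPa_s / 50)
  # no plateau within the record is a fit-window error
  early <- synthetic_creep_record(tau = 5, times = seq(0, 1, by = 0.05))
  expect_error(creep_viscosity(early, base_fit), "plateau|fit-window")
})

test_that("sweep summaries aggregate one metric per level", {
  runs <- list(
    list(parameter = 1.25, metric = "E_Pa", value = 80, kind = "aspiration"),
    list(parameter = 1.25, metric = "E_Pa", value = 90, kind = "aspiration"),
    list(parameter = 4.0, metric = "E_Pa", value = 260, kind = "aspiration"))
  tab <- sweep_summary(runs, "n_fil")
  expect_equal(nrow(tab), 2)
  expect_equal(tab$mean, c(85, 260))
  expect_equal(tab$sd[2], 0) # single replicate
  expect_true(all(tab$parameter == "n_fil"))
  mixed <- c(runs, list(list(parameter = 2, metric = "velocity_mm_s",
                             value = 3, kind = "transit")))
  expect_error(sweep_summary(mixed, "n_fil"), "mixed")
})
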