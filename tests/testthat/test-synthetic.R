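test_that("noiseless current families obey the steady-state signal model", {
  proto <- voltage_protocol(seq(-80, 50, by = 10))
  tr <- ground_truth(control_v_half = -30, control_slope = 10,
                     control_gmax = 1, noise_sd = 0)
  fam <- gen_current_family(proto, tr, "control")
  ss <- steady_state_current(fam)

  # zero driving force at V = V_K -> exactly zero current
  expect_identical(ss$current_uA[ss$voltage_mV == -80], 0)

  # far above V1/2 the conductance saturates at GMAX (up to the settled
  # activation factor, which is < 1e-4 away from 1 in the window)
  i50 <- ss$current_uA[ss$voltage_mV == 50]
  expect_equal(i50, 1 * (50 - (-80)), tolerance = 1e-3)

  # generator noise must be per-sweep consistent
  expect_error(
    gen_current_family(proto, ground_truth(noise_sd = c(1, 2)), "control"),
    "scalar or one value per test voltage")
})

test_that("protocol construction rejects a window longer than the sweep", {
  expect_error(voltage_protocol(sweep_ms = 50, window_ms = 60),
               "exceeds sweep duration")
  expect_error(voltage_protocol(c(0, -10)), "strictly increasing")
})

test_that("generated families round-trip through the G(V) pipeline", {
  proto <- voltage_protocol(seq(-80, 50, by = 10))
  tr <- ground_truth(control_v_half = -30, control_slope = 10,
                     control_gmax = 1, noise_sd = 0)
  fam <- gen_current_family(proto, tr, "control", seed = 11)
  fit <- fit_boltzmann(suppressWarnings(
    compute_conductance(steady_state_current(fam), proto$v_rev_mV)))
  expect_true(fit$converged)
  expect_equal(fit$v_half, -30, tolerance = 0.1)
  expect_equal(fit$slope, 10, tolerance = 0.01)
  expect_equal(fit$gmax, 1, tolerance = 1e-3)

  # compound condition applies shift and gmax scaling
  tr2 <- ground_truth(shift = -40.7, gmax_ratio = 0.5, noise_sd = 0)
  fam2 <- gen_current_family(proto, tr2, "compound")
  fit2 <- fit_boltzmann(suppressWarnings(
    compute_conductance(steady_state_current(fam2), proto$v_rev_mV)))
  expect_equal(fit2$v_half, -30 - 40.7, tolerance = 0.1)
  expect_equal(fit2$gmax, 0.5, tolerance = 1e-3)
})

test_that("fixed seeds make generator output bit-identical", {
  proto <- voltage_protocol()
  tr <- ground_truth(noise_sd = 0.5)
  f1 <- gen_current_family(proto, tr, "control", seed = 42)
  f2 <- gen_current_family(proto, tr, "control", seed = 42)
  expect_identical(f1$currents, f2$currents)
  t1 <- gen_trajectory(c(`5` = 0.3), n_frames = 20, seed = 9)
  t2 <- gen_trajectory(c(`5` = 0.3), n_frames = 20, seed = 9)
  expect_identical(t1$xyz, t2$xyz)
})

test_that("dose-response generator follows the hyperbolic curve", {
  tr <- ground_truth(ec50 = 29.1, delta_v_max = -36.1, noise_sd = 0)
  # midpoint: shift at c = EC50 is half the saturating shift
  d <- gen_dose_response(tr, concentrations = 29.1, n_per_conc = 3)
  expect_equal(d$shift_mV, -36.1 / 2)
  # saturation
  d_inf <- gen_dose_response(tr, concentrations = 1e9, n_per_conc = 1)
  expect_equal(d_inf$shift_mV, -36.1, tolerance = 1e-6)
  # value at 100 uM from the published WT Wu50 curve parameters
  d100 <- gen_dose_response(tr, concentrations = 100, n_per_conc = 1)
  expect_equal(d100$shift_mV, -36.1 / (1 + 29.1 / 100))
  expect_error(gen_dose_response(tr, numeric(0)), "empty concentration")
})

test_that("replicate scatter converges to the requested noise SD", {
  tr <- ground_truth(ec50 = 30, delta_v_max = -50, noise_sd = 2)
  d <- gen_dose_response(tr, concentrations = 30, n_per_conc = 1e4, seed = 5)
  reps <- attr(d, "replicates")
  expect_equal(sd(reps), 2, tolerance = 0.05)
  expect_equal(mean(reps), -25, tolerance = 0.1)
})

test_that("synthetic shift panels obey the additive site structure", {
  configs <- list(
    mutant_config("WT"),
    mutant_config("2R", has_2R = TRUE),
    mutant_config("R362Q", R362Q = TRUE),
    mutant_config("2R/W454A", has_2R = TRUE, W454A = TRUE))
  pore <- c(WT_362_454 = -15, R362Q = -34, W454A = -6)

  # residual only: every mutant's shift equals the residual
  tab0 <- gen_shift_table(configs, s3s4_mV = 0,
                          pore_mV = c(WT_362_454 = 0, R362Q = 0, W454A = 0),
                          residual_mV = -10, noise_sd = 0)
  expect_true(all(tab0$shift_mV == -10))

  # without the 2R motif the S3/S4 term never contributes
  tab_a <- gen_shift_table(configs[c(1, 3)], s3s4_mV = -17, pore_mV = pore,
                           residual_mV = -10, noise_sd = 0)
  tab_b <- gen_shift_table(configs[c(1, 3)], s3s4_mV = 0, pore_mV = pore,
                           residual_mV = -10, noise_sd = 0)
  expect_identical(tab_a$shift_mV, tab_b$shift_mV)

  # noiseless table round-trips through the fitter exactly
  tab <- gen_shift_table(configs, s3s4_mV = -17, pore_mV = pore,
                         residual_mV = -10, noise_sd = 0)
  fit <- fit_site_model(tab, fixed = c(residual = -10))
  expect_equal(unname(fit$coefficients["s3s4"]), -17, tolerance = 1e-9)
  expect_equal(unname(fit$coefficients["pore_R362Q"]), -34, tolerance = 1e-9)
  expect_error(
    gen_shift_table(configs, s3s4_mV = 0, pore_mV = c(WT_362_454 = 0),
                    residual_mV = 0),
    "no pore contribution")
})

test_that("toy trajectories realise their contact schedules exactly", {
  # full-time and zero-time contacts
  t1 <- gen_trajectory(c(`10` = 1.0, `20` = 0.0), n_frames = 25, seed = 2)
  f1 <- contact_frequency(t1)$frequencies
  expect_identical(f1$frequency[f1$resno == 10], 1)
  expect_identical(f1$frequency[f1$resno == 20], 0)

  # 10 frames at fraction 0.4 -> exactly 4 contact frames
  t2 <- gen_trajectory(c(`7` = 0.4), n_frames = 10, seed = 3)
  f2 <- contact_frequency(t2)$frequencies
  expect_identical(f2$frequency, 0.4)

  expect_error(gen_trajectory(c(`1` = 0.5), 10, cutoff_nm = 0),
               "must be > 0")
  expect_error(gen_trajectory(c(`1` = 0.7, `2` = 0.7), 10),
               "sum to more than 1")
  expect_error(gen_trajectory(c(`1` = 1.2), 10), "in \\[0, 1\\]")
})
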