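test_that("noiseless WLC curves reproduce the Marko-Siggia force exactly", {
  cv <- gen_wlc_curve(1000, 50, n_points = 50, rel_noise = 0, seed = 1)
  expect_equal(cv$force_pN, wlc_force(cv$extension_nm, 1000, 50, 298))
  expect_error(gen_wlc_curve(-10, 50), "positive")
  expect_error(gen_wlc_curve(100, 200), "P < Lc")
})

test_that("generators are bit-identical under a fixed seed", {
  a <- gen_wlc_curve(5300, 52, seed = 7)
  b <- gen_wlc_curve(5300, 52, seed = 7)
  expect_identical(a$force_pN, b$force_pN)
  t1 <- gen_trapped_bead_trace(duration_s = 0.5, seed = 11)
  t2 <- gen_trapped_bead_trace(duration_s = 0.5, seed = 11)
  expect_identical(t1$signal, t2$signal)
  m1 <- gen_tether_movie(n_frames = 2, seed = 5)
  m2 <- gen_tether_movie(n_frames = 2, seed = 5)
  expect_identical(m1$stack, m2$stack)
})

test_that("trapped-bead generator encodes the physical corner frequency", {
  tr <- gen_trapped_bead_trace(k_trap_pN_per_um = 10, bead_radius_um = 1.5,
                               viscosity_Pa_s = 8.9e-4, duration_s = 0.4,
                               seed = 1)
  # fc = k / (2 pi 6 pi eta R) evaluated by hand: ~63 Hz
  expect_equal(tr$ground_truth$corner_frequency_Hz, 63.2, tolerance = 0.005)
  expect_error(gen_trapped_bead_trace(k_trap_pN_per_um = 1e6, fs_Hz = 5000,
                                      duration_s = 10),
               "aliasing")
})

test_that("trapped-bead variance approaches equipartition at high stiffness", {
  tr <- gen_trapped_bead_trace(k_trap_pN_per_um = 500, duration_s = 1, seed = 2)
  expect_equal(stats::var(tr$signal), tr$ground_truth$position_variance_nm2,
               tolerance = 0.05)
})

test_that("OU autocorrelation time matches gamma/k at a million samples", {
  tr <- gen_trapped_bead_trace(duration_s = 20, seed = 4)
  a1 <- stats::acf(tr$signal, lag.max = 1, plot = FALSE)$acf[2]
  tau_emp <- -1 / (tr$fs_Hz * log(a1))
  expect_equal(tau_emp, tr$ground_truth$relaxation_time_s, tolerance = 0.05)
})

test_that("driven-rotor phase lag follows the overdamped transfer function", {
  rot <- gen_driven_rotation_trace(drive_freqs_Hz = c(0.6, 2, 6), seed = 1)
  slopes <- vapply(rot, function(t) t$ground_truth$phase_slope_rad_per_Hz, 0)
  expect_true(all(abs(slopes - 0.431) < 0.01))  # 2 pi gamma_theta / k_theta
  # quasi-static limit: phase -> 0 as f -> 0
  phis <- vapply(rot, function(t) t$ground_truth$phase_rad, 0)
  expect_true(all(diff(phis) > 0))
  expect_lt(phis[1], 0.3)
  # doubling the rotational drag doubles the slope
  rot2 <- gen_driven_rotation_trace(viscosity_Pa_s = 2 * 8.9e-4,
                                    drive_freqs_Hz = c(1), seed = 1)
  expect_equal(rot2$f1$ground_truth$phase_slope_rad_per_Hz,
               unname(2 * slopes[1]), tolerance = 1e-12)
  expect_error(gen_driven_rotation_trace(drive_freqs_Hz = 0.2), "0.5")
})

test_that("synthetic hat curves are symmetric below Fc and asymmetric above", {
  lo <- gen_hat_curve(force_pN = 0.5, seed = 1)
  hi <- gen_hat_curve(force_pN = 1.1, seed = 1)
  s_lo <- classify_hat_symmetry(list(turns = lo$turns, extension_nm = lo$extension_nm))
  s_hi <- classify_hat_symmetry(list(turns = hi$turns, extension_nm = hi$extension_nm))
  expect_identical(s_lo$label, "symmetric")
  expect_identical(s_hi$label, "asymmetric")
  # zero slope: flat curve, no buckling detectable
  flat <- gen_hat_curve(force_pN = 0.5, slope_nm_per_turn = 0, seed = 2)
  pos <- flat$segment == 1
  b <- detect_buckling(flat$turns[pos], flat$extension_nm[pos])
  expect_true(is.na(b$buckling_turn))
})

test_that("planted bp-trajectory bubbles respect bounds and exclusivity", {
  expect_error(gen_bp_param_trajectory(
    n_bp = 10, planted_bubbles = data.frame(start_bp = 9, length_bp = 4,
                                            t_start_ns = 0, duration_ns = 1)),
    "within sequence")
  expect_error(gen_bp_param_trajectory(
    planted_bubbles = data.frame(start_bp = c(5, 7), length_bp = c(4, 4),
                                 t_start_ns = c(0, 1), duration_ns = c(5, 5))),
    "overlap")
  tj <- gen_bp_param_trajectory(seed = 6)
  expect_true(all(tj$hbond))
})

test_that("force clamp holds the setpoint and settles in about a second", {
  # no disturbance, started at the setpoint: constant traces
  quiet <- simulate_force_clamp(1.0, duration_s = 2)
  expect_true(all(abs(quiet$force_pN - 1.0) < 1e-12))
  # step disturbance: returns within +/-0.1 pN with ~1 s response
  step <- simulate_force_clamp(1.0, disturbance_pN = function(t) 0.5 * (t > 2),
                               duration_s = 10)
  settle <- attr(step, "settling_time_s") - 2
  expect_gt(settle, 0.2)
  expect_lt(settle, 3)
  expect_lt(abs(step$force_pN[nrow(step)] - 1.0), 0.1)
  # proportional-only unit gain corrects in one step
  db <- simulate_force_clamp(1.0, gains = list(kp = 1, ki = 0, kd = 0),
                             duration_s = 0.1, start_at_setpoint = FALSE)
  expect_equal(db$force_pN[1], 0)
  expect_true(all(abs(db$force_pN[-1] - 1.0) < 1e-12))
  expect_error(simulate_force_clamp(1.0, gains = list(kp = 3, ki = 0, kd = 0),
                                    start_at_setpoint = FALSE),
               "unstable")
})

test_that("tether movie validates punctum placement and intensity budget", {
  expect_error(gen_tether_movie(puncta = data.frame(bp_fraction = c(0.6, 0.5),
                                                    D_nm2_per_s = c(0, 0))),
               "sum below 1")
  expect_error(gen_tether_movie(puncta = data.frame(bp_fraction = 0.2,
                                                    D_nm2_per_s = 0,
                                                    start_fraction = 1.2)),
               "on the tether")
  expect_error(gen_tether_movie(tether_endpoints_nm = rbind(c(-100, 0), c(100, 0))),
               "field of view")
})

test_that("an immobile punctum's track scatter is localisation noise only", {
  mv <- gen_tether_movie(n_frames = 12,
                         puncta = data.frame(bp_fraction = 0.4, D_nm2_per_s = 0),
                         seed = 21)
  tr <- track_puncta(mv$stack)[[1]]
  expect_gte(nrow(tr), 10)
  expect_lt(stats::sd(tr$x_nm), 10)   # nm; pure localisation scatter
  expect_lt(stats::sd(tr$y_nm), 10)
})
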