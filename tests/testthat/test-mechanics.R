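test_that("Marko-Siggia force matches hand-evaluated values", {
  expect_equal(wlc_force(0, 1000, 50), 0)
  # x/Lc = 0.5, P = 50 nm, T = 298 K: 1.25 kBT/P
  expect_equal(wlc_force(500, 1000, 50, 298), 1.25 * kBT(298) / 50)
  expect_equal(round(wlc_force(500, 1000, 50, 298), 3), 0.103)
  x <- seq(0, 970, by = 10)
  expect_true(all(diff(wlc_force(x, 1000, 50)) > 0))
  expect_error(wlc_force(1000, 1000, 50), "\\[0, Lc\\)")
  expect_error(wlc_force(-1, 1000, 50), "\\[0, Lc\\)")
})

test_that("WLC fitting recovers generating parameters", {
  clean <- gen_wlc_curve(5300, 52, n_points = 200, rel_noise = 0, seed = 1)
  f0 <- fit_wlc(clean)
  expect_equal(signif(f0$Lc_nm, 4), 5300)
  expect_equal(signif(f0$P_nm, 4), 52)
  noisy <- gen_wlc_curve(5300, 52, n_points = 500, rel_noise = 0.05, seed = 7)
  f1 <- fit_wlc(noisy)
  expect_equal(f1$Lc_nm, 5300, tolerance = 0.02)
  expect_equal(f1$P_nm, 52, tolerance = 0.02)
  # stretch and release halves of a noiseless cycle fit identically
  rel <- clean[rev(seq_len(nrow(clean))), ]
  attr(rel, "temperature_K") <- 298
  class(rel) <- class(clean)
  f2 <- fit_wlc(rel)
  expect_equal(f2$Lc_nm, f0$Lc_nm, tolerance = 1e-8)
  expect_equal(f2$P_nm, f0$P_nm, tolerance = 1e-8)
})

test_that("WLC fit is scale-equivariant under nm <-> um rescaling", {
  cv <- gen_wlc_curve(5300, 52, n_points = 300, rel_noise = 0.02, seed = 3)
  f_nm <- fit_wlc(cv)
  # rescaling extensions to um rescales the contour length with them; the
  # persistence length is set by kBT/force and stays in nm
  cv_um <- fx_curve(cv$extension_nm / 1000, cv$force_pN, temperature_K = 298)
  f_um <- fit_wlc(cv_um, start = list(Lc_nm = 5.5, P_nm = 50))
  expect_equal(f_um$Lc_nm * 1000, f_nm$Lc_nm, tolerance = 1e-6)
  expect_equal(f_um$P_nm, f_nm$P_nm, tolerance = 1e-6)
})

test_that("bootstrap errors vanish without noise and grow with it", {
  clean <- gen_wlc_curve(5300, 52, n_points = 600, rel_noise = 0, seed = 1)
  b0 <- bootstrap_wlc(clean, n_boot = 50, frac = 0.01, seed = 4)
  expect_lt(b0$bootstrap_pct["P_nm"], 1e-6)
  sds <- vapply(c(0.01, 0.02, 0.05), function(nz) {
    cv <- gen_wlc_curve(5300, 52, n_points = 600, rel_noise = nz, seed = 9)
    bootstrap_wlc(cv, n_boot = 60, frac = 0.01, seed = 4)$bootstrap_sd["P_nm"]
  }, 0)
  expect_true(all(diff(sds) > 0))
  # reproducible under a fixed seed
  b1 <- bootstrap_wlc(clean, n_boot = 20, frac = 0.01, seed = 5)
  b2 <- bootstrap_wlc(clean, n_boot = 20, frac = 0.01, seed = 5)
  expect_identical(b1$bootstrap_sd, b2$bootstrap_sd)
  expect_error(bootstrap_wlc(clean, frac = 0.001), "at least 5")
})

test_that("supercoiling density arithmetic matches the 14.6 kbp construct", {
  expect_equal(round(supercoil_density(200, 14600), 2), 0.14)
  expect_equal(round(supercoil_density(150, 14600), 2), 0.11)
  expect_equal(supercoil_density(0, 14600), 0)
  turns <- seq(-300, 300, by = 50)
  expect_equal(supercoil_density(turns, 14600), -supercoil_density(-turns, 14600))
})

test_that("torque per turn is C/L and accumulates linearly", {
  expect_equal(round(torque_per_turn(410, 14600 * 0.34), 2), 0.08)
  expect_equal(torque_per_turn(410, 410), 1.0)
  expect_equal(cumulative_torque(10, 410, 4964), 10 * torque_per_turn(410, 4964))
})

test_that("drift correction removes linear drift and flags curvature", {
  set.seed(8)
  t <- seq(0, 100, by = 0.1)
  noise <- stats::rnorm(length(t), sd = 5)
  drifted <- 15 * t + noise
  dc <- drift_correct(t, drifted, anchor_times_s = c(0, 50, 100))
  expect_equal(mean(dc$drift_velocity_nm_per_s), 15, tolerance = 0.05)
  expect_lt(stats::sd(dc$corrected), 2 * stats::sd(noise))
  expect_false(dc$nonlinear)
  # zero drift: output equals input up to the anchor-mean offset
  dc0 <- drift_correct(t, noise, anchor_times_s = c(0, 50, 100))
  expect_lt(max(abs(dc0$corrected - noise)), 3 * stats::sd(noise))
  # quadratic drift leaves anchors off a straight line
  dcq <- drift_correct(t, 0.05 * t^2 + noise, anchor_times_s = c(0, 50, 100))
  expect_true(dcq$nonlinear)
  expect_error(drift_correct(t, noise, anchor_times_s = 50), "2 anchor")
})

test_that("hat-curve assembly labels symmetry and is idempotent", {
  lo <- gen_hat_curve(force_pN = 0.5, seed = 1)
  hc <- build_hat_curve(lo$turns, lo$extension_nm, lo$segment, lo$time_s,
                        clamp_force_pN = 0.5, Lc_nm = 5300)
  expect_identical(attr(hc, "symmetry")$label, "symmetric")
  expect_true(all(hc$fractional_extension <= 1.1))
  hi <- gen_hat_curve(force_pN = 1.1, seed = 2)
  hch <- build_hat_curve(hi$turns, hi$extension_nm, hi$segment, hi$time_s,
                         clamp_force_pN = 1.1, Lc_nm = 5300)
  expect_identical(attr(hch, "symmetry")$label, "asymmetric")
  # negative side sits at the plateau
  neg <- hch$turns < -100; pos <- hch$turns > 100
  expect_gt(mean(hch$extension_nm[neg]), mean(hch$extension_nm[pos]))
  # re-running on already-corrected data changes nothing material
  hc2 <- build_hat_curve(hc$turns, hc$extension_nm, hc$segment, hc$time_s,
                         clamp_force_pN = 0.5, Lc_nm = 5300)
  expect_equal(hc2$extension_nm, hc$extension_nm, tolerance = 0.02)
  expect_warning(build_hat_curve(1:10, rep(4500, 10), clamp_force_pN = 0.5,
                                 Lc_nm = 5300),
                 "partial")
})

test_that("hat symmetry score is 0 for mirrors, 1 for one-sided plateaus", {
  turns <- -100:100
  sym <- list(turns = turns, extension_nm = 4500 - 10 * abs(turns))
  expect_lt(classify_hat_symmetry(sym)$score, 1e-12)
  asym <- list(turns = turns,
               extension_nm = ifelse(turns < 0, 4500, 4500 - 10 * turns))
  expect_equal(classify_hat_symmetry(asym)$score, 1, tolerance = 1e-6)
  # score rises monotonically as the negative side flattens
  scores <- vapply(c(0, 0.3, 0.6, 1), function(flat) {
    ext <- ifelse(turns < 0, 4500 - 10 * (1 - flat) * abs(turns),
                  4500 - 10 * turns)
    classify_hat_symmetry(list(turns = turns, extension_nm = ext))$score
  }, 0)
  expect_true(all(diff(scores) > 0))
  # invariant to uniform extension offset and time order
  shuf <- sample(length(turns))
  s1 <- classify_hat_symmetry(list(turns = turns, extension_nm = asym$extension_nm + 500))
  s2 <- classify_hat_symmetry(list(turns = turns[shuf],
                                   extension_nm = asym$extension_nm[shuf]))
  expect_equal(s1$score, classify_hat_symmetry(asym)$score, tolerance = 1e-9)
  expect_equal(s2$score, classify_hat_symmetry(asym)$score, tolerance = 1e-9)
})

test_that("buckling detection finds the knee and the fluctuation jump", {
  set.seed(3)
  turns <- 0:300
  ext <- ifelse(turns < 120, 4500, 4500 - 12 * (turns - 120)) +
    stats::rnorm(301, sd = c(rep(10, 120), rep(20, 181)))
  b <- detect_buckling(turns, ext)
  expect_lte(abs(b$buckling_turn - 120), 5)
  expect_equal(b$fluctuation_ratio, 2, tolerance = 0.4)
  expect_true(b$buckled)
  flat <- 4500 - 2 * turns + stats::rnorm(301, sd = 10)
  expect_true(is.na(detect_buckling(turns, flat)$buckling_turn))
  expect_error(detect_buckling(1:10, 1:10, window = 15), "too short")
})
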