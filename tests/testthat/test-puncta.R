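# direct splat of a Gaussian punctum onto a pixel grid (no tether, no noise)
render_punctum <- function(x_nm, y_nm, ny = 32, nx = 48, pixel = 55,
                           sigma = 110, amp_total = 5e4, background = 100) {
  xs <- (seq_len(nx) - 1) * pixel
  ys <- (seq_len(ny) - 1) * pixel
  gx <- exp(-(xs - x_nm)^2 / (2 * sigma^2))
  gy <- exp(-(ys - y_nm)^2 / (2 * sigma^2))
  background + amp_total * pixel^2 / (2 * pi * sigma^2) * outer(gy, gx)
}

test_that("a noise-free punctum at a pixel centre localises sub-centipixel", {
  img <- render_punctum(22 * 55, 15 * 55)
  tr <- track_puncta(img, threshold_sd = 6)[[1]]
  expect_lt(abs(tr$x_nm - 22 * 55), 0.01 * 55)
  expect_lt(abs(tr$y_nm - 15 * 55), 0.01 * 55)
})

test_that("tracking on a rendered movie meets 20 nm localisation", {
  mv <- gen_tether_movie(n_frames = 10,
                         puncta = data.frame(bp_fraction = 0.4,
                                             D_nm2_per_s = 1500),
                         seed = 5)
  tr <- track_puncta(mv$stack)[[1]]
  expect_gte(nrow(tr), 9)
  gt <- mv$ground_truth
  gx <- gt$tether_endpoints_nm[1, 1] + gt$positions_along_tether_nm[, 1]
  expect_lt(max(abs(tr$x_nm - gx[tr$frame])), 20)
  expect_lt(max(abs(tr$y_nm - gt$tether_endpoints_nm[1, 2])), 20)
})

test_that("two well-separated puncta give two unbroken tracks", {
  mv <- gen_tether_movie(n_frames = 8,
                         puncta = data.frame(bp_fraction = c(0.3, 0.3),
                                             D_nm2_per_s = c(500, 500),
                                             start_fraction = c(0.25, 0.75)),
                         seed = 12)
  trks <- track_puncta(mv$stack)
  expect_gte(length(trks), 2)
  expect_equal(nrow(trks[[1]]), 8)
  expect_equal(nrow(trks[[2]]), 8)
})

test_that("tracking is translation-equivariant", {
  img <- render_punctum(20 * 55, 14 * 55)
  sh <- 3L
  img2 <- img * 0 + 100
  img2[, (sh + 1):ncol(img)] <- img[, 1:(ncol(img) - sh)]
  t1 <- track_puncta(img)[[1]]
  t2 <- track_puncta(img2)[[1]]
  expect_equal(t2$x_nm - t1$x_nm, sh * 55, tolerance = 1e-3)
  expect_equal(t2$y_nm, t1$y_nm, tolerance = 1e-3)
})

test_that("punctum bp fraction recovers planted intensity fractions", {
  for (cfg in list(list(frac = 0.5, seed = 6), list(frac = 0.4, seed = 5))) {
    mv <- gen_tether_movie(n_frames = 8,
                           puncta = data.frame(bp_fraction = cfg$frac,
                                               D_nm2_per_s = 1000),
                           seed = cfg$seed)
    tr <- track_puncta(mv$stack)[[1]]
    bf <- punctum_bp_fraction(tr, mv$stack, mv$ground_truth$tether_endpoints_nm,
                              construct_bp = 14600)
    expect_equal(bf$mean_fraction, cfg$frac, tolerance = 0.05)
    expect_equal(bf$mean_bp_content, cfg$frac * 14600,
                 tolerance = 0.05 / cfg$frac)
  }
  # a spot placed on bare background integrates to ~0
  mv0 <- gen_tether_movie(n_frames = 2,
                          puncta = data.frame(bp_fraction = numeric(0),
                                              D_nm2_per_s = numeric(0)),
                          seed = 4)
  fake <- data.frame(frame = 1:2, x_nm = c(3300, 3300), y_nm = c(1300, 1300),
                     sigma_nm = c(110, 110))
  bf0 <- punctum_bp_fraction(fake, mv0$stack,
                             mv0$ground_truth$tether_endpoints_nm)
  expect_lt(bf0$mean_fraction, 0.05)
})

test_that("rmsd components satisfy the quadrature identity", {
  tks <- gen_diffusion_tracks(n_tracks = 5, n_frames = 50, seed = 2)
  for (tr in tks) {
    s <- rmsd_components(tr)
    expect_equal(s$rmsd_tot_nm^2,
                 s$rmsd_parallel_nm^2 + s$rmsd_perp_nm^2,
                 tolerance = 1e-9)
  }
  # printed mobility-table pairs combine to the printed totals
  expect_equal(round(rmsd_total(108, 96)), 144)
  expect_equal(round(rmsd_total(76, 72)), 105)
  # pure parallel motion
  tr <- data.frame(frame = 1:10, x_nm = cumsum(rep(50, 10)), y_nm = rep(0, 10))
  attr(tr, "tether_axis") <- rbind(c(0, 0), c(1, 0))
  s <- rmsd_components(tr)
  expect_equal(s$rmsd_perp_nm, 0)
  expect_equal(s$rmsd_tot_nm, s$rmsd_parallel_nm)
  attr(tr, "tether_axis") <- rbind(c(0, 0), c(0, 0))
  expect_error(rmsd_components(tr), "degenerate")
})

test_that("MSD regression estimates D without bias and flags ballistic tracks", {
  tks <- gen_diffusion_tracks(n_tracks = 500, n_frames = 41,
                              D_nm2_per_s = 1900, frame_interval_s = 0.04,
                              seed = 9)
  Ds <- vapply(tks, function(t) estimate_D(t, 0.04)$D_nm2_per_s, 0)
  expect_equal(mean(Ds), 1900, tolerance = 0.1)
  still <- data.frame(frame = 1:20, x_nm = rep(0, 20), y_nm = rep(0, 20))
  expect_equal(estimate_D(still, 0.04)$D_nm2_per_s, 0)
  ball <- data.frame(frame = 1:30, x_nm = 200 * (1:30), y_nm = 0)
  expect_true(estimate_D(ball, 0.04)$nonlinear)
  expect_error(estimate_D(still[1:4, ], 0.04), "max_lag")
})

test_that("diffusion-coefficient ratios report the supercoiling asymmetry", {
  expect_equal(ratio_of_D(1900, 310, round_to_integer = TRUE), 6)
  expect_equal(ratio_of_D(5, 5), 1)
  expect_equal(ratio_of_D(1900, 310) * ratio_of_D(310, 1900), 1)
  expect_error(ratio_of_D(1, 0), "positive")
})

test_that("perpendicular FWHM profiles report the rendered PSF width", {
  for (sig in c(205 / 2.355, 110, 251 / 2.355)) {
    mv <- gen_tether_movie(n_frames = 1,
                           puncta = data.frame(bp_fraction = numeric(0),
                                               D_nm2_per_s = numeric(0)),
                           psf_sigma_nm = sig, read_noise_sd = 1, seed = 2)
    fw <- line_profile_fwhm(mv$stack[, , 1], mv$ground_truth$tether_endpoints_nm)
    expect_equal(attr(fw, "mean_fwhm_nm"), 2.355 * sig, tolerance = 0.02)
  }
  # ratio of two rendered widths reproduces the input ratio within 3%
  w <- vapply(c(251, 205), function(target) {
    mv <- gen_tether_movie(n_frames = 1,
                           puncta = data.frame(bp_fraction = numeric(0),
                                               D_nm2_per_s = numeric(0)),
                           psf_sigma_nm = target / 2.355, seed = 3)
    attr(line_profile_fwhm(mv$stack[, , 1],
                           mv$ground_truth$tether_endpoints_nm), "mean_fwhm_nm")
  }, 0)
  expect_equal(w[1] / w[2], 251 / 205, tolerance = 0.03)
})
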