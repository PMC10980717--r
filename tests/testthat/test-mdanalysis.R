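make_baseline <- function(seed = 11) {
  relaxed_baseline(gen_bp_param_trajectory(n_bp = 30, n_frames = 600, seed = seed))
}

test_that("bp-parameter tables round-trip and reject ragged grids", {
  tj <- gen_bp_param_trajectory(n_bp = 8, n_frames = 120, seed = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_bp_params(tj, f)
  back <- read_bp_params(f, dt_ns = tj$dt_ns)
  expect_equal(back$propeller, tj$propeller)
  expect_equal(back$opening, tj$opening)
  expect_equal(back$buckle, tj$buckle)
  expect_identical(back$hbond, tj$hbond)
  # drop one frame's worth of rows for a single bp: error names the frame
  tab <- utils::read.delim(f)
  utils::write.table(tab[-3, ], f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_bp_params(f), "frame 1")
})

test_that("nastruct-style whitespace tables parse", {
  f <- withr::local_tempfile(fileext = ".dat")
  writeLines(c(
    "#Frame BP Opening Propeller Buckle HBonds",
    "1 1  2.1 -11.5  0.3 2",
    "1 2  1.9 -12.0 -0.2 3",
    "1 3  2.4 -13.1  0.1 2",
    "2 1 35.0  20.5 25.3 0",
    "2 2  2.0 -11.8  0.4 2",
    "2 3  1.8 -12.2  0.0 3"), f)
  tj <- read_bp_params(f, dt_ns = 0.5)
  expect_equal(tj$n_frames, 2L)
  expect_equal(tj$n_bp, 3L)
  expect_equal(tj$opening[2, 1], 35.0)
  expect_false(tj$hbond[2, 1])
  expect_true(all(tj$hbond[1, ]))
})

test_that("relaxed baseline recovers generator moments, excluding termini", {
  tj <- gen_bp_param_trajectory(n_bp = 30, n_frames = 2000, dt_ns = 0.1,
                                seed = 7)
  bl <- relaxed_baseline(tj)
  expect_equal(unname(bl$mean[["propeller"]]), -12, tolerance = 0.02 * 12)
  expect_equal(unname(bl$sd[["propeller"]]), 8, tolerance = 0.02)
  expect_equal(unname(bl$sd[["opening"]]), 4, tolerance = 0.02)
  # constant trajectory: zero spread
  const <- bp_trajectory(matrix(-12, 200, 10), matrix(2, 200, 10),
                         matrix(0, 200, 10), matrix(TRUE, 200, 10), 0.1)
  blc <- relaxed_baseline(const)
  expect_equal(unname(blc$sd), c(0, 0, 0))
  # perturbing a terminal bp leaves the baseline unchanged
  pert <- tj
  pert$propeller[, 1] <- 500
  expect_equal(relaxed_baseline(pert)$mean, bl$mean)
  expect_error(relaxed_baseline(bp_trajectory(matrix(0, 50, 10),
                                              matrix(0, 50, 10),
                                              matrix(0, 50, 10),
                                              matrix(TRUE, 50, 10), 0.1)),
               "100 frames")
})

test_that("bubble calls honour the length, deviation and duration thresholds", {
  bl <- make_baseline()
  tj <- gen_bp_param_trajectory(n_bp = 30, n_frames = 600, dt_ns = 0.1,
                                planted_bubbles = data.frame(
                                  start_bp = 10, length_bp = 4,
                                  t_start_ns = 20, duration_ns = 2),
                                seed = 3)
  calls <- detect_bubbles(tj, bl)
  expect_equal(nrow(calls), 1)
  expect_lte(abs(calls$start_bp - 10), 1)
  expect_lte(abs(calls$length_bp - 4), 1)
  expect_lte(abs(calls$t_start_ns - 20), 0.1)
  expect_lte(abs(calls$duration_ns - 2), 0.1)
  # too short a run
  t2 <- gen_bp_param_trajectory(n_bp = 30, n_frames = 600, dt_ns = 0.1,
                                planted_bubbles = data.frame(
                                  start_bp = 10, length_bp = 2,
                                  t_start_ns = 20, duration_ns = 2),
                                seed = 4)
  expect_equal(nrow(detect_bubbles(t2, bl)), 0)
  # too brief a disruption
  t3 <- gen_bp_param_trajectory(n_bp = 30, n_frames = 600, dt_ns = 0.1,
                                planted_bubbles = data.frame(
                                  start_bp = 10, length_bp = 5,
                                  t_start_ns = 20, duration_ns = 0.5),
                                seed = 5)
  expect_equal(nrow(detect_bubbles(t3, bl)), 0)
  expect_error(detect_bubbles(tj, bl, z_thresh = 0), "positive")
})

test_that("bubble caller agrees exactly with the run-scan oracle", {
  bl <- make_baseline()
  for (seed in 1:4) {
    set.seed(seed)
    nb <- 3
    pb <- data.frame(start_bp = sample(3:12, nb),
                     length_bp = sample(3:6, nb, replace = TRUE),
                     t_start_ns = c(5, 20, 35),
                     duration_ns = sample(c(0.5, 1.5, 3), nb, replace = TRUE))
    tj <- try(gen_bp_param_trajectory(n_bp = 20, n_frames = 500, dt_ns = 0.1,
                                      planted_bubbles = pb, seed = seed),
              silent = TRUE)
    if (inherits(tj, "try-error")) next  # overlapping plant: skip this draw
    got <- detect_bubbles(tj, bl)
    want <- oracle_detect_bubbles(tj, bl)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      expect_equal(got$start_bp, want$start_bp)
      expect_equal(got$length_bp, want$length_bp)
      expect_equal(got$t_start_ns, want$t_start_ns)
      expect_equal(got$duration_ns, want$duration_ns)
    }
  }
})

test_that("prevalence is the covered fraction of the final window", {
  tj <- gen_bp_param_trajectory(n_bp = 20, n_frames = 1000, dt_ns = 0.5, seed = 2)
  full <- data.frame(start_bp = 5, length_bp = 4, t_start_ns = 0,
                     duration_ns = 500, first_frame = 1, last_frame = 1000)
  expect_equal(bubble_prevalence(tj, full, analysis_window_ns = 400), 100)
  none <- full[0, ]
  expect_equal(bubble_prevalence(tj, none, analysis_window_ns = 400), 0)
  half <- data.frame(start_bp = 5, length_bp = 4, t_start_ns = 300,
                     duration_ns = 200, first_frame = 601, last_frame = 1000)
  expect_equal(bubble_prevalence(tj, half, analysis_window_ns = 400), 50)
  expect_error(bubble_prevalence(tj, full, analysis_window_ns = 600), "longer")
  # prevalence depends only on the per-frame indicator, not frame order
  ind <- bubble_indicator(tj, half, 400)
  expect_equal(100 * mean(ind), 50)
  expect_equal(100 * mean(sample(ind)), 50)
})

test_that("prevalence bootstrap matches the binomial error and is seeded", {
  expect_equal(prevalence_bootstrap(rep(1, 5000), seed = 1), 0)
  set.seed(10)
  ind <- stats::rbinom(1e5, 1, 0.5)
  sd_boot <- prevalence_bootstrap(ind, n_boot = 200, frac = 0.01, seed = 2)
  expect_equal(sd_boot, 100 * sqrt(0.25 / 1000), tolerance = 0.2)
  expect_identical(prevalence_bootstrap(ind, seed = 3),
                   prevalence_bootstrap(ind, seed = 3))
  # sd shrinks as the replicate fraction grows
  expect_lt(prevalence_bootstrap(ind, frac = 0.5, seed = 4),
            prevalence_bootstrap(ind, frac = 0.01, seed = 4))
  expect_error(prevalence_bootstrap(rep(1, 100), frac = 0.01), "at least 10")
})

test_that("convergence flag tracks the cumulative end-to-end mean", {
  expect_true(convergence_curve(rep(7, 500))$converged)
  expect_false(convergence_curve(seq_len(500))$converged)
  # an OU series converges once many correlation times are averaged
  tau_samples <- 50
  a <- exp(-1 / tau_samples)
  set.seed(3)
  x <- as.numeric(stats::filter(stats::rnorm(5000, sd = sqrt(1 - a^2)), a,
                                method = "recursive")) + 10
  expect_true(convergence_curve(x)$converged)
  expect_error(convergence_curve(1:50), "100 samples")
})
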