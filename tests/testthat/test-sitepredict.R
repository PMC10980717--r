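test_that("intrinsic curvature is flat on homopolymers and mirrors on revcomp", {
  polyG <- strrep("G", 400)
  cv <- intrinsic_curvature(polyG, 120)$curvature_deg_per_turn
  expect_lt(diff(range(cv, na.rm = TRUE)), 1e-10)
  set.seed(4)
  sq <- sample(c("A", "C", "G", "T"), 1500, replace = TRUE)
  a <- intrinsic_curvature(paste(sq, collapse = ""))$curvature_deg_per_turn
  b <- intrinsic_curvature(paste(reverse_complement(sq), collapse = ""))$curvature_deg_per_turn
  expect_equal(a, rev(b), tolerance = 1e-9)
  expect_error(intrinsic_curvature("ACGTN"), "outside")
  expect_error(intrinsic_curvature(strrep("A", 200), window_bp = 5), "10 bp")
})

test_that("phased A-tracts produce a curvature maximum verified by the oracle", {
  set.seed(4)
  sq <- sample(c("G", "C", "A", "T"), 2000, replace = TRUE)
  for (k in 0:20) {
    p <- 800 + round(k * 10.5)
    sq[p:(p + 5)] <- "A"
  }
  prof <- intrinsic_curvature(paste(sq, collapse = ""), 120)
  pk <- which.max(prof$curvature_deg_per_turn)
  expect_gte(pk, 800)
  expect_lte(pk, 1010)
  # vectorised profile equals direct per-window vector summation
  for (centre in c(200, 861, 1500)) {
    start <- centre - 60
    expect_equal(prof$curvature_deg_per_turn[centre],
                 oracle_curvature_window(sq, start, 120), tolerance = 1e-9)
  }
})

test_that("plectoneme density is uniform without curvature contrast", {
  set.seed(1)
  prof <- plectoneme_probability(strrep("GC", 3000), sigma = 0.14)
  d <- prof$density[is.finite(prof$density)]
  expect_lt(max(d) / min(d), 1.01)
  expect_equal(sum(d), 1, tolerance = 1e-9)
})

test_that("plectoneme density peaks at planted curvature maxima", {
  set.seed(11)
  n <- 10000
  sq <- sample(c("G", "C", "A", "T"), n, replace = TRUE)
  at <- round(0.4 * n)
  for (k in 0:30) {
    p <- at + round(k * 10.5)
    sq[p:(p + 5)] <- "A"
  }
  prof <- plectoneme_probability(paste(sq, collapse = ""), sigma = 0.14)
  mode_bp <- prof$position[which.max(prof$density)]
  # the phased block spans ~320 bp from `at`; the mode must fall within
  # 200 bp of it
  expect_lt(abs(mode_bp - (at + 160)), 200 + 160)
  # a centrally curved tether puts the mode mid-tether
  sq2 <- sample(c("G", "C", "A", "T"), n, replace = TRUE)
  for (k in 0:30) {
    p <- round(n / 2) + round(k * 10.5)
    sq2[p:(p + 5)] <- "A"
  }
  prof2 <- plectoneme_probability(paste(sq2, collapse = ""), sigma = 0.14)
  mode2 <- prof2$position[which.max(prof2$density)]
  expect_lt(abs(mode2 - n / 2), 0.05 * n)
  expect_error(plectoneme_probability(strrep("GC", 400), sigma = 0.14,
                                      size_cutoff_bp = 2000),
               "below the sequence length")
})

test_that("plectoneme size cutoffs default per supercoiling regime", {
  p1 <- plectoneme_probability(strrep("GC", 5000), sigma = 0.14)
  p2 <- plectoneme_probability(strrep("GC", 5000), sigma = 0.11)
  p3 <- plectoneme_probability(strrep("GC", 5000), sigma = -0.14)
  expect_equal(attr(p1, "size_cutoff_bp"), 8300)
  expect_equal(attr(p2, "size_cutoff_bp"), 6700)
  expect_equal(attr(p3, "size_cutoff_bp"), 1900)
})

test_that("plectoneme density mirrors under sequence reversal", {
  set.seed(6)
  sq <- sample(c("G", "C", "A", "T"), 4000, replace = TRUE)
  a <- plectoneme_probability(paste(sq, collapse = ""), 0.14)$density
  b <- plectoneme_probability(paste(reverse_complement(sq), collapse = ""),
                              0.14)$density
  expect_equal(a, rev(b), tolerance = 1e-6)
})

test_that("single-run SIDD equals the exhaustive enumeration oracle", {
  set.seed(2)
  for (n in c(80, 120)) {
    sq <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    got <- sidd_profile(sq, sigma = -0.06, max_runs = 1)
    want <- oracle_sidd_single_run(sq, sigma = -0.06)
    expect_equal(got$p_open, want$p_open, tolerance = 1e-10)
    expect_equal(attr(got, "run_length_mean"), want$run_length_mean,
                 tolerance = 1e-10)
  }
})

test_that("opening vanishes without driving stress and grows with |sigma|", {
  sq <- md_core_sequence()
  p0 <- sidd_profile(sq, sigma = 0)
  expect_lt(max(p0$p_open), 1e-4)
  expect_match(attr(p0, "note"), "no driving stress")
  at <- strrep("AT", 60)
  pa <- sidd_profile(at, -0.05)
  pb <- sidd_profile(at, -0.08)
  pc <- sidd_profile(at, -0.11)
  expect_true(all(pb$p_open >= pa$p_open - 1e-12))
  expect_true(all(pc$p_open >= pb$p_open - 1e-12))
})

test_that("the 300 bp fixture opens preferentially in its A/T-rich tract", {
  p <- sidd_profile(md_core_sequence(), sigma = -0.1)
  top <- which.max(p$p_open)
  expect_gte(top, 51)
  expect_lte(top, 60)   # the ACTTTTTTTC tract
  expect_error(sidd_profile(strrep("A", 30), -0.1), ">= 50")
  expect_error(sidd_profile(strrep("AT", 11000), -0.1), "20 kbp")
})

test_that("expected bubble size is the weighted mean open-run length", {
  d <- opening_profile(rep(0.5, 100),
                       run_table = data.frame(length = 60, weight = 1))
  expect_equal(expected_bubble_size(d), 60)
  d2 <- opening_profile(rep(0.5, 100),
                        run_table = data.frame(length = c(40, 80),
                                               weight = c(1, 1)))
  expect_equal(expected_bubble_size(d2), 60)
  z <- opening_profile(rep(0, 100))
  expect_warning(expect_true(is.na(expected_bubble_size(z))), "undefined")
})

test_that("expected bubble size tracks a tunable AT block", {
  # stress high enough to open the whole block (its boundaries, not the
  # superhelicity, then set the favoured run length)
  for (block in c(30, 60)) {
    sq <- paste0(strrep("GC", 150), strrep("AT", block / 2), strrep("GC", 150))
    p <- sidd_profile(sq, sigma = -0.15)
    expect_equal(expected_bubble_size(p), block, tolerance = 0.1)
  }
})

test_that("peak matching reports fractional offsets", {
  x <- seq_len(1000)
  prof <- exp(-(x - 300)^2 / (2 * 30^2)) + 0.8 * exp(-(x - 700)^2 / (2 * 30^2))
  same <- compare_profiles(prof, prof)
  expect_true(all(same$offset_percent == 0))
  shift <- round(0.036 * 1000)
  prof_b <- c(rep(0, shift), prof)[seq_len(1000)]
  rep_ <- compare_profiles(prof, prof_b)
  expect_equal(rep_$offset_percent, rep(3.6, nrow(rep_)), tolerance = 0.01)
  # invariant to uniform intensity scaling
  sc <- compare_profiles(prof, 7.3 * prof)
  expect_true(all(sc$offset_percent == 0))
  none <- compare_profiles(rep(0, 100), rep(0, 100))
  expect_equal(nrow(none), 0)
})
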