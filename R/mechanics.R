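#' Worm-like chain force at a given extension
#'
#' Marko-Siggia interpolation for the entropic force of an inextensible
#' worm-like chain:
#' \deqn{F(x) = \frac{k_B T}{P}\left[\frac{1}{4(1 - x/L_c)^2} - \frac14 + \frac{x}{L_c}\right]}
#' valid for forces up to ~10 pN, which covers the whole working range of a
#' low-stiffness optical trap. No stretch-modulus term is included.
#'
#' @param x_nm extension in nm (vectorised); must satisfy `0 <= x < Lc_nm`
#' @param Lc_nm contour length in nm
#' @param P_nm persistence length in nm
#' @param temperature_K temperature in K
#' @return force in pN
#' @export
#' @examples
#' wlc_force(500, 1000, 50, 298)  # ~0.103 pN
wlc_force <- function(x_nm, Lc_nm, P_nm, temperature_K = 298) {
  .check_positive(Lc_nm, "Lc_nm"); .check_positive(P_nm, "P_nm")
  if (P_nm >= Lc_nm) stop("persistence length must be below contour length", call. = FALSE)
  if (any(x_nm < 0) || any(x_nm >= Lc_nm)) {
    stop("extension must lie in [0, Lc)", call. = FALSE)
  }
  r <- x_nm / Lc_nm
  (kBT(temperature_K) / P_nm) * (1 / (4 * (1 - r)^2) - 0.25 + r)
}

#' Fit the worm-like chain model to force-extension data
#'
#' Least-squares fit of the Marko-Siggia expression for (Lc, P). A list of
#' curves (e.g. consecutive stretch/release half cycles) is fitted per half
#' cycle and the parameter estimates averaged.
#'
#' @param curve an `fx_curve`, or a list of them
#' @param start optional named list with starting values `Lc_nm`, `P_nm`
#' @return an object of class `wlc_fit` with elements `Lc_nm`, `P_nm`,
#'   `n_half_cycles`, `per_cycle` (matrix of per-cycle estimates), `fit`
#'   (the last `nls` object) and `residual_sd`
#' @export
fit_wlc <- function(curve, start = NULL) {
  curves <- if (inherits(curve, "fx_curve")) list(curve) else curve
  stopifnot(length(curves) >= 1, all(vapply(curves, inherits, TRUE, "fx_curve")))
  fits <- lapply(curves, .fit_wlc_one, start = start)
  est <- t(vapply(fits, function(f) stats::coef(f), c(Lc_nm = 0, P_nm = 0)))
  out <- list(Lc_nm = mean(est[, "Lc_nm"]), P_nm = mean(est[, "P_nm"]),
              n_half_cycles = length(curves), per_cycle = est,
              fit = fits[[length(fits)]],
              residual_sd = stats::sd(stats::resid(fits[[length(fits)]])))
  class(out) <- "wlc_fit"
  out
}

.fit_wlc_one <- function(curve, start = NULL) {
  x <- curve$extension_nm; f <- curve$force_pN
  if (length(x) < 20) stop("need at least 20 points for a WLC fit", call. = FALSE)
  if (diff(range(x)) < 0.5 * max(x)) {
    stop("force-extension data must span at least half the extension range", call. = FALSE)
  }
  T_K <- attr(curve, "temperature_K") %||% 298
  .fit_wlc_core(x, f, T_K, start)
}

# unchecked Marko-Siggia evaluation for use inside the optimiser, where
# intermediate parameter iterates may be unphysical
.ms_force <- function(x, Lc, P, T_K) {
  r <- x / Lc
  (kBT(T_K) / P) * (1 / (4 * (1 - r)^2) - 0.25 + r)
}

.fit_wlc_core <- function(x, f, T_K, start = NULL) {
  if (is.null(start)) start <- list(Lc_nm = 1.05 * max(x), P_nm = 50)
  fit <- tryCatch(
    minpack.lm::nlsLM(f ~ .ms_force(x, Lc_nm, P_nm, T_K),
                      start = start,
                      lower = c(Lc_nm = max(x) * 1.0000001, P_nm = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("WLC fit did not converge: ", conditionMessage(e),
                             call. = FALSE))
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.wlc_fit <- function(x, ...) {
  cat(sprintf("WLC fit: Lc = %.1f nm, P = %.2f nm (%d half cycle%s)\n",
              x$Lc_nm, x$P_nm, x$n_half_cycles,
              if (x$n_half_cycles > 1) "s" else ""))
  if (!is.null(x$bootstrap_sd)) {
    cat(sprintf("  bootstrap s.d.: Lc %.3g nm (%.3g%%), P %.3g nm (%.3g%%)\n",
                x$bootstrap_sd["Lc_nm"], x$bootstrap_pct["Lc_nm"],
                x$bootstrap_sd["P_nm"], x$bootstrap_pct["P_nm"]))
  }
  invisible(x)
}

#' Bootstrap parameter errors for a WLC fit
#'
#' Refits random subsets of the data (`frac` of the points per replicate,
#' drawn without replacement) and reports the standard deviation of the
#' fitted parameters over replicates, both absolute and as a percentage of
#' the full-data point estimate.
#'
#' @param curve an `fx_curve`
#' @param n_boot number of bootstrap replicates (default 1000)
#' @param frac fraction of points per replicate (default 0.01)
#' @param seed integer seed
#' @return a `wlc_fit` augmented with `bootstrap_sd` and `bootstrap_pct`
#' @export
bootstrap_wlc <- function(curve, n_boot = 1000, frac = 0.01, seed = 1) {
  stopifnot(inherits(curve, "fx_curve"))
  n <- nrow(curve)
  m <- floor(frac * n)
  if (m < 5) stop("frac * n_points must be at least 5", call. = FALSE)
  full <- fit_wlc(curve)
  rng <- .seeded_rng(seed)
  est <- matrix(NA_real_, n_boot, 2, dimnames = list(NULL, c("Lc_nm", "P_nm")))
  T_K <- attr(curve, "temperature_K") %||% 298
  for (b in seq_len(n_boot)) {
    idx <- sort(sample.int(n, m))
    fit <- tryCatch(.fit_wlc_core(curve$extension_nm[idx], curve$force_pN[idx],
                                  T_K,
                                  start = list(Lc_nm = full$Lc_nm, P_nm = full$P_nm)),
                    error = function(e) NULL)
    if (!is.null(fit)) est[b, ] <- stats::coef(fit)
  }
  rng$restore()
  full$bootstrap_sd <- apply(est, 2, stats::sd, na.rm = TRUE)
  full$bootstrap_pct <- 100 * full$bootstrap_sd / c(full$Lc_nm, full$P_nm)
  full$n_boot <- n_boot
  full
}

# Scoped RNG: set a seed, and restore the caller's RNG state afterwards.
.seeded_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  list(restore = function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
}

#' Supercoiling density
#'
#' sigma = applied turns divided by the number of helical turns in the
#' relaxed, torsionally active region: `turns * helical_repeat / active_bp`.
#' For the 15.6 kbp construct the torsionally active region is the 14.6 kbp
#' centre (the 500 bp handles are multiply attached and do not twist).
#'
#' @param turns signed number of bead rotations
#' @param active_bp torsionally active length in bp
#' @param helical_repeat helical repeat of relaxed B-DNA in bp/turn
#' @return sigma (dimensionless, sign preserved)
#' @export
#' @examples
#' supercoil_density(200, 14600)  # 0.14
supercoil_density <- function(turns, active_bp, helical_repeat = 10.5) {
  .check_positive(active_bp, "active_bp"); .check_positive(helical_repeat, "helical_repeat")
  turns * helical_repeat / active_bp
}

#' Torque per turn and cumulative torque of an isotropic rod
#'
#' For an isotropic elastic rod the torque added per complete twist is
#' approximately C/L where C is the torsional modulus and L the rod length;
#' `cumulative_torque` is `turns * C/L`.
#'
#' @param C_pNnm torsional modulus in pN.nm (default 410)
#' @param L_nm rod (DNA) length in nm
#' @param turns number of applied turns
#' @return torque in pN.nm (per turn, or cumulative)
#' @export
#' @examples
#' torque_per_turn(410, 14600 * 0.34)  # ~0.08 pN.nm per turn
torque_per_turn <- function(C_pNnm = 410, L_nm) {
  .check_positive(L_nm, "L_nm")
  C_pNnm / L_nm
}

#' @rdname torque_per_turn
#' @export
cumulative_torque <- function(turns, C_pNnm = 410, L_nm) {
  turns * torque_per_turn(C_pNnm, L_nm)
}

#' Piecewise-linear drift correction from anchor epochs
#'
#' Long experiments accumulate slow stage drift (typically ~15 nm/s lateral,
#' ~7 nm/s axial). Anchor epochs are times at which the true position is
#' known to be identical (e.g. segment boundaries revisiting the same
#' supercoiling state); the drift is estimated as the piecewise-linear curve
#' through the observed positions at those epochs and subtracted.
#'
#' @param time_s sample times
#' @param position numeric vector, or a matrix with one column per axis
#' @param anchor_times_s times of the anchor epochs (>= 2)
#' @param anchor_window_s half-width of the window averaged around each
#'   anchor to beat down noise
#' @param nonlinearity_tol_nm with >= 3 anchors, flag the correction if the
#'   anchors deviate from a single straight line by more than this
#' @return list with `corrected` (same shape as `position`),
#'   `drift_velocity_nm_per_s` (per axis, per inter-anchor interval),
#'   `nonlinear` flag and `anchor_residual_nm`
#' @export
drift_correct <- function(time_s, position, anchor_times_s,
                          anchor_window_s = 0.5, nonlinearity_tol_nm = 25) {
  pos <- if (is.matrix(position)) position else matrix(position, ncol = 1)
  if (length(anchor_times_s) < 2) {
    stop("need at least 2 anchor epochs to estimate drift", call. = FALSE)
  }
  anchor_times_s <- sort(anchor_times_s)
  n_axes <- ncol(pos)
  corrected <- pos
  vel <- matrix(NA_real_, length(anchor_times_s) - 1, n_axes)
  resid_max <- numeric(n_axes)
  for (a in seq_len(n_axes)) {
    anchors <- vapply(anchor_times_s, function(t0) {
      sel <- abs(time_s - t0) <= anchor_window_s
      if (!any(sel)) sel <- which.min(abs(time_s - t0))
      mean(pos[sel, a])
    }, 0)
    drift_at_anchor <- anchors - anchors[1]
    drift <- stats::approx(anchor_times_s, drift_at_anchor, xout = time_s,
                           rule = 2)$y
    corrected[, a] <- pos[, a] - drift
    vel[, a] <- diff(drift_at_anchor) / diff(anchor_times_s)
    if (length(anchors) >= 3) {
      lf <- stats::lm(anchors ~ anchor_times_s)
      resid_max[a] <- max(abs(stats::resid(lf)))
    }
  }
  if (!is.matrix(position)) corrected <- corrected[, 1]
  list(corrected = corrected,
       drift_velocity_nm_per_s = vel,
       anchor_residual_nm = resid_max,
       nonlinear = any(resid_max > nonlinearity_tol_nm))
}

#' Assemble a hat curve from a turn-stamped extension series
#'
#' Produces the canonical extension-versus-turns ("hat") representation of a
#' twist experiment at clamped force: drift correction between segments
#' (consecutive rotation sections are aligned on their overlapping turn
#' ranges), fractional extension relative to the contour length, and a
#' symmetry classification via [classify_hat_symmetry()].
#'
#' @param turns per-sample applied turn count (signed)
#' @param extension_nm per-sample extension
#' @param segment integer/factor segment label per sample (time-ordered
#'   rotation sections); a single segment disables inter-segment alignment
#' @param time_s optional per-sample timestamps
#' @param clamp_force_pN the clamped force
#' @param Lc_nm contour length for fractional extension
#' @param active_bp,helical_repeat used to attach sigma per sample
#' @param drift_correct align segment offsets (default TRUE)
#' @return a data.frame of class `hat_curve` with columns `turns`, `sigma`,
#'   `extension_nm`, `fractional_extension`, `segment`, `time_s`; attributes
#'   `clamp_force_pN`, `Lc_nm`, `symmetry` (see [classify_hat_symmetry()])
#'   and `segment_offsets_nm`
#' @export
build_hat_curve <- function(turns, extension_nm, segment = 1L, time_s = NULL,
                            clamp_force_pN, Lc_nm, active_bp = 14600,
                            helical_repeat = 10.5, drift_correct = TRUE) {
  stopifnot(length(turns) == length(extension_nm))
  if (length(segment) == 1L) segment <- rep(segment, length(turns))
  if (is.null(time_s)) time_s <- seq_along(turns)
  if (min(turns) >= 0 || max(turns) <= 0) {
    warning("hat curve does not cover both rotation signs; partial curve",
            call. = FALSE)
  }
  segs <- unique(segment)
  offsets <- stats::setNames(numeric(length(segs)), segs)
  ext <- extension_nm
  if (drift_correct && length(segs) > 1) {
    # align each segment to the previous ones on overlapping turn ranges
    for (k in seq_along(segs)[-1]) {
      cur <- segment == segs[k]
      prev <- segment %in% segs[seq_len(k - 1)]
      lo <- max(min(turns[cur]), min(turns[prev]))
      hi <- min(max(turns[cur]), max(turns[prev]))
      if (lo > hi) next  # no overlap: leave as is
      in_cur <- cur & turns >= lo & turns <= hi
      in_prev <- prev & turns >= lo & turns <= hi
      if (sum(in_cur) < 2 || sum(in_prev) < 2) next
      grid <- seq(lo, hi, length.out = 25)
      f_cur <- stats::approx(turns[in_cur], ext[in_cur], grid, rule = 2, ties = mean)$y
      f_prev <- stats::approx(turns[in_prev], ext[in_prev], grid, rule = 2, ties = mean)$y
      off <- mean(f_cur - f_prev)
      ext[cur] <- ext[cur] - off
      offsets[k] <- off
    }
  }
  out <- data.frame(turns = turns,
                    sigma = supercoil_density(turns, active_bp, helical_repeat),
                    extension_nm = ext,
                    fractional_extension = ext / Lc_nm,
                    segment = segment, time_s = time_s)
  attr(out, "clamp_force_pN") <- clamp_force_pN
  attr(out, "Lc_nm") <- Lc_nm
  attr(out, "segment_offsets_nm") <- offsets
  class(out) <- c("hat_curve", "data.frame")
  attr(out, "symmetry") <- classify_hat_symmetry(out)
  out
}

#' Classify hat-curve symmetry about sigma = 0
#'
#' Below the critical force supercoiling shortens DNA symmetrically in both
#' twist directions; above it the undertwisted side stays extended (melting
#' instead of plectoneme formation) and the curve is asymmetric. The score
#' compares extension at matched +/-|turns|:
#' \deqn{s = \sum_n |x(+n) - x(-n)| \big/ \sum_n \max_\pm\,[x(0) - x(\pm n)]}
#' so a mirror-symmetric curve scores 0 and a flat negative side with a
#' linear positive drop scores 1.
#'
#' @param hat a `hat_curve`, or anything with `turns` and `extension_nm`
#' @param threshold label the curve asymmetric when the score exceeds this
#' @param n_grid number of |turns| grid points used for matching
#' @return list with `score` in [0,1], `label` ("symmetric"/"asymmetric")
#'   and `threshold`
#' @export
classify_hat_symmetry <- function(hat, threshold = 0.25, n_grid = 50) {
  turns <- hat$turns; ext <- hat$extension_nm
  nmax <- min(max(turns), -min(turns))
  if (!is.finite(nmax) || nmax <= 0) {
    return(list(score = NA_real_, label = "partial", threshold = threshold))
  }
  grid <- seq(nmax / n_grid, nmax, length.out = n_grid)
  ep <- stats::approx(turns, ext, xout = grid, rule = 2, ties = mean)$y
  em <- stats::approx(turns, ext, xout = -grid, rule = 2, ties = mean)$y
  e0 <- stats::approx(turns, ext, xout = 0, rule = 2, ties = mean)$y
  drop_ref <- pmax(e0 - ep, e0 - em)
  denom <- sum(pmax(drop_ref, 0))
  score <- if (denom <= 0) 0 else min(1, sum(abs(ep - em)) / denom)
  list(score = score,
       label = if (score > threshold) "asymmetric" else "symmetric",
       threshold = threshold)
}

#' Detect the buckling transition in an extension-versus-turns record
#'
#' Twist is first absorbed as elastic torsion with little extension change;
#' at the buckling transition further twist converts to writhe and extension
#' drops linearly, with a marked increase in fluctuation amplitude. The
#' change point is found as the two-segment piecewise-linear fit minimising
#' the residual sum of squares, and the fluctuation ratio is the ratio of
#' detrended residual s.d. after versus before the change point.
#'
#' @param turns monotone turn counts
#' @param extension_nm extension at each turn count
#' @param window number of samples per rolling window used for the residual
#'   s.d. estimate (also the minimum segment length); >= 3 windows must fit
#'   before a candidate change point
#' @param min_slope_change_nm_per_turn minimum steepening of the post-knee
#'   slope, relative to the pre-knee slope, to accept a change point
#' @param fluct_ratio_threshold label the molecule buckled when the
#'   post/pre fluctuation ratio reaches this (default 1.5)
#' @return list with `buckling_turn` (NA if no change point),
#'   `buckling_index`, `fluctuation_ratio`, `buckled`, `slope_pre`,
#'   `slope_post`
#' @export
detect_buckling <- function(turns, extension_nm, window = 15,
                            min_slope_change_nm_per_turn = 1,
                            fluct_ratio_threshold = 1.5) {
  n <- length(turns)
  stopifnot(n == length(extension_nm))
  if (n < 3 * window + 2) stop("series too short for the chosen window", call. = FALSE)
  none <- list(buckling_turn = NA_real_, buckling_index = NA_integer_,
               fluctuation_ratio = NA_real_, buckled = FALSE,
               slope_pre = NA_real_, slope_post = NA_real_)
  # two-segment piecewise-linear scan
  cand <- seq(window + 1, n - window)
  sse <- vapply(cand, function(c0) {
    f1 <- stats::lm.fit(cbind(1, turns[1:c0]), extension_nm[1:c0])
    f2 <- stats::lm.fit(cbind(1, turns[c0:n]), extension_nm[c0:n])
    sum(f1$residuals^2) + sum(f2$residuals^2)
  }, 0)
  c0 <- cand[which.min(sse)]
  f1 <- stats::lm.fit(cbind(1, turns[1:c0]), extension_nm[1:c0])
  f2 <- stats::lm.fit(cbind(1, turns[c0:n]), extension_nm[c0:n])
  s1 <- f1$coefficients[2]; s2 <- f2$coefficients[2]
  if (!is.finite(s1) || !is.finite(s2) ||
      (s1 - s2) < min_slope_change_nm_per_turn) {
    return(none)  # no steepening: constant-slope record
  }
  sd_pre <- stats::sd(f1$residuals)
  sd_post <- stats::sd(f2$residuals)
  ratio <- sd_post / sd_pre
  list(buckling_turn = turns[c0], buckling_index = c0,
       fluctuation_ratio = ratio,
       buckled = is.finite(ratio) && ratio >= fluct_ratio_threshold,
       slope_pre = unname(s1), slope_post = unname(s2))
}
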