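#' One-sided power spectral density of a trace
#'
#' Two estimators are provided. `"welch"` averages modified periodograms of
#' Hann-windowed segments (default 2^13 samples, 50% overlap), the standard
#' choice for trap calibration where variance reduction matters. `"periodogram"`
#' is the plain unwindowed periodogram of the whole trace, which satisfies
#' Parseval exactly (the PSD sums to the signal power) and is used for
#' spectral-fraction diagnostics.
#'
#' @param trace a [qpd_trace()], or a numeric vector (then `fs_Hz` must be given)
#' @param method "welch" or "periodogram"
#' @param seg_len Welch segment length (samples)
#' @param overlap Welch fractional overlap
#' @param fs_Hz sampling rate, required when `trace` is a bare vector
#' @return data.frame with `freq_Hz` and `psd` (signal units^2 per Hz),
#'   excluding the DC bin
#' @export
power_spectrum <- function(trace, method = c("welch", "periodogram"),
                           seg_len = 2^13, overlap = 0.5, fs_Hz = NULL) {
  method <- match.arg(method)
  if (inherits(trace, "qpd_trace")) {
    x <- trace$signal; fs <- trace$fs_Hz
  } else {
    x <- as.numeric(trace); fs <- fs_Hz
    if (is.null(fs)) stop("fs_Hz required for a bare vector", call. = FALSE)
  }
  n <- length(x)
  if (method == "periodogram") {
    x <- x - mean(x)
    X <- stats::fft(x)
    # one-sided PSD: units^2/Hz; bins 2..(n/2+1)
    half <- seq(2L, floor(n / 2) + 1L)
    psd <- (Mod(X[half])^2) / (n * fs)
    two_sided_double <- half < (n / 2 + 1) | (n %% 2 == 1)
    psd[two_sided_double] <- 2 * psd[two_sided_double]
    freq <- (half - 1) * fs / n
    return(data.frame(freq_Hz = freq, psd = psd))
  }
  seg_len <- min(seg_len, n)
  step <- max(1L, floor(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq(0, seg_len - 1) / (seg_len - 1)))  # Hann
  wnorm <- sum(w^2)
  half <- seq(2L, floor(seg_len / 2) + 1L)
  acc <- numeric(length(half))
  for (s0 in starts) {
    seg <- x[s0:(s0 + seg_len - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)
    acc <- acc + Mod(X[half])^2
  }
  psd <- acc / (length(starts) * wnorm * fs)
  dbl <- half < (seg_len / 2 + 1) | (seg_len %% 2 == 1)
  psd[dbl] <- 2 * psd[dbl]
  data.frame(freq_Hz = (half - 1) * fs / seg_len, psd = psd)
}

#' Calibrate trap stiffness from the position power spectrum
#'
#' Fits a Lorentzian \eqn{S(f) = A/(f_c^2 + f^2)} to the one-sided
#' Welch-averaged power spectrum of a trapped-bead trace and converts the
#' corner frequency to stiffness via \eqn{k = 2\pi f_c \gamma} with
#' \eqn{\gamma = 6\pi\eta R} from the bead radius and fluid viscosity.
#'
#' @param trace a [qpd_trace()] of at least 2^14 samples
#' @param fit_band_Hz frequency band used for the fit (exclude drive tones
#'   and low-frequency drift)
#' @param bead_radius_um,viscosity_Pa_s bead radius and viscosity used for
#'   the drag coefficient
#' @param seg_len Welch segment length
#' @return object of class `trap_calibration`: `corner_frequency_Hz`,
#'   `trap_stiffness_pN_per_um`, `drag_coefficient_pN_s_per_nm`,
#'   `fit_covariance`, `psd` (the fitted band)
#' @export
fit_power_spectrum <- function(trace, fit_band_Hz = c(2, 5000),
                               bead_radius_um = 1.5, viscosity_Pa_s = 8.9e-4,
                               seg_len = 2^13) {
  stopifnot(inherits(trace, "qpd_trace"))
  if (length(trace$signal) < 2^14) {
    stop("need at least 2^14 samples for a spectral calibration", call. = FALSE)
  }
  ps_welch <- power_spectrum(trace, "welch", seg_len = seg_len)
  ps <- power_spectrum(trace, "periodogram")
  sel <- ps$freq_Hz >= fit_band_Hz[1] & ps$freq_Hz <= fit_band_Hz[2]
  f <- ps$freq_Hz[sel]; S <- ps$psd[sel]
  # starting values: fc where the Welch PSD falls to half its plateau
  Sw <- ps_welch$psd[ps_welch$freq_Hz >= fit_band_Hz[1] &
                       ps_welch$freq_Hz <= fit_band_Hz[2]]
  fw <- ps_welch$freq_Hz[ps_welch$freq_Hz >= fit_band_Hz[1] &
                           ps_welch$freq_Hz <= fit_band_Hz[2]]
  plateau <- stats::median(Sw[seq_len(max(3, floor(length(Sw) * 0.02)))])
  fc0 <- max(fw[which.min(abs(Sw - plateau / 2))], fw[2])
  A0 <- plateau * fc0^2
  # Whittle likelihood: periodogram bins are ~independent exponentials with
  # mean S(f), so minimise sum(log S_model + S_obs/S_model); this is free of
  # the weighting bias a least-squares fit of a noisy PSD suffers
  nll <- function(p) {
    m <- exp(p[1]) / (exp(2 * p[2]) + f^2)
    sum(log(m) + S / m)
  }
  opt <- stats::optim(c(log(A0), log(fc0)), nll, method = "BFGS", hessian = TRUE)
  if (opt$convergence != 0) {
    stop("power-spectrum calibration failed to converge; residual code ",
         opt$convergence, call. = FALSE)
  }
  fc <- exp(opt$par[2])
  vc_log <- tryCatch(solve(opt$hessian), error = function(e) matrix(NA, 2, 2))
  rel_se <- sqrt(vc_log[2, 2])   # se of log(fc) = relative se of fc
  vc <- vc_log * outer(c(exp(opt$par[1]), fc), c(exp(opt$par[1]), fc))
  fit <- list(par = c(A = exp(opt$par[1]), fc = fc), logLik = -opt$value)
  if (!is.finite(fc) || fc <= f[1] || fc >= f[length(f)] ||
      !is.finite(rel_se) || rel_se > 0.2) {
    stop("corner frequency unconstrained by the data (no spectral knee in ",
         "the fit band)", call. = FALSE)
  }
  ps <- data.frame(freq_Hz = fw, psd = Sw)
  gam <- drag_translational(bead_radius_um, viscosity_Pa_s)
  out <- list(corner_frequency_Hz = fc,
              trap_stiffness_pN_per_um = 2 * pi * fc * gam * 1000,
              drag_coefficient_pN_s_per_nm = gam,
              fit_covariance = vc,
              psd = ps, fit = fit)
  class(out) <- "trap_calibration"
  out
}

#' @export
print.trap_calibration <- function(x, ...) {
  cat(sprintf("Trap calibration: fc = %.1f Hz, k = %.3g pN/um\n",
              x$corner_frequency_Hz, x$trap_stiffness_pN_per_um))
  invisible(x)
}

#' Phase lag of a driven response at the drive frequency
#'
#' Estimates the phase of the response channel relative to the drive at
#' `drive_freq_Hz`. The response is band-passed around the drive frequency
#' (FFT mask, half-octave each side) and correlated with its own time
#' reverse: for a tone A cos(2 pi f t + phi) the reversal correlation peaks
#' where the lag encodes 2 phi (modulo pi), which averages down noise that
#' is incoherent under time reversal. The residual modulo-pi ambiguity and
#' the sign are resolved against the quadrature demodulation of the
#' response versus the drive channel. A lag of the response behind the
#' drive is a positive phase.
#'
#' @param trace a [qpd_trace()] carrying a drive channel
#' @param drive_freq_Hz the drive frequency; the trace must hold at least
#'   10 drive periods
#' @param min_snr minimum power SNR at the drive frequency (default 3)
#' @return phase in radians
#' @export
phase_shift <- function(trace, drive_freq_Hz, min_snr = 3) {
  stopifnot(inherits(trace, "qpd_trace"))
  if (is.null(trace$drive)) stop("trace has no drive channel", call. = FALSE)
  fs <- trace$fs_Hz; y <- trace$signal; n <- length(y)
  if (n < 10 * fs / drive_freq_Hz) {
    stop("need at least 10 drive periods", call. = FALSE)
  }
  # SNR check on the periodogram around the drive bin
  ps <- power_spectrum(y, "periodogram", fs_Hz = fs)
  i0 <- which.min(abs(ps$freq_Hz - drive_freq_Hz))
  nb <- abs(ps$freq_Hz - drive_freq_Hz) < 5 * drive_freq_Hz &
    abs(ps$freq_Hz - drive_freq_Hz) > 0.5 * drive_freq_Hz
  snr <- ps$psd[i0] / stats::median(ps$psd[nb])
  if (!is.finite(snr) || snr < min_snr) {
    stop(sprintf("signal-to-noise %.2f at drive frequency below %g", snr, min_snr),
         call. = FALSE)
  }
  # band-pass via FFT mask
  Y <- stats::fft(y - mean(y))
  freqs <- (seq_len(n) - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs)  # fold to two-sided
  keep <- freqs >= drive_freq_Hz / sqrt(2) & freqs <= drive_freq_Hz * sqrt(2)
  yb <- Re(stats::fft(Y * keep, inverse = TRUE)) / n
  # time-reversal correlation over +/- one period of lags
  yr <- rev(yb)
  max_lag <- ceiling(fs / drive_freq_Hz)
  lags <- -max_lag:max_lag
  # linear cross-correlation via zero-padded FFT
  m <- 2^ceiling(log2(2 * n))
  fa <- stats::fft(c(yb, numeric(m - n)))
  fb <- stats::fft(c(yr, numeric(m - n)))
  r_full <- Re(stats::fft(fa * Conj(fb), inverse = TRUE)) / m
  cc <- r_full[ifelse(lags >= 0, lags + 1, m + lags + 1)]
  i_pk <- which.max(cc)
  # parabolic sub-sample refinement of the peak lag
  l_pk <- lags[i_pk]
  if (i_pk > 1 && i_pk < length(lags)) {
    d <- (cc[i_pk - 1] - cc[i_pk + 1]) / (2 * (cc[i_pk - 1] - 2 * cc[i_pk] + cc[i_pk + 1]))
    l_pk <- l_pk + d
  }
  w <- 2 * pi * drive_freq_Hz
  # reversal correlation peaks where w*dt*(l + n - 1) + 2*phi' = 0 (mod 2pi),
  # with the response written as cos(w t + phi'); the lag therefore pins
  # phi' modulo pi
  phi_rev <- -w * (l_pk + n - 1) / (2 * fs)
  # quadrature demodulation against the drive resolves branch and sign
  t <- (seq_len(n) - 1) / fs
  e <- exp(-1i * w * t)
  z_resp <- sum((y - mean(y)) * e)
  z_drive <- sum((trace$drive - mean(trace$drive)) * e)
  phi_demod <- -Arg(z_resp / z_drive)       # positive = response lags drive
  cands <- (-phi_rev) + pi * (-4:4)
  cands <- atan2(sin(cands), cos(cands))
  dist <- abs(atan2(sin(cands - phi_demod), cos(cands - phi_demod)))
  unname(cands[which.min(dist)])
}

#' Fit angular trap stiffness from phase-lag measurements
#'
#' Linear regression of phase lag versus drive frequency in the small-angle
#' regime; the angular stiffness follows from the rotational drag as
#' \eqn{k_\theta = 2\pi\, 8\pi\eta R^3 / |d\varphi/df|}. The 2 pi converts
#' the per-Hz slope to per-angular-frequency; without it the printed drag
#' and slope do not reproduce a stiffness of the observed magnitude.
#'
#' @param phases data.frame with columns `freq_Hz` and `phase_rad`; at
#'   least 3 frequencies with |phase| < 0.7 rad are required
#' @param bead_radius_um,viscosity_Pa_s bead radius and viscosity
#' @param min_r_squared reject fits with regression R^2 below this
#' @param use_tan regress `tan(phase)` on frequency (default), which is
#'   exact for the overdamped rotor at any angle and reduces to the phase
#'   slope in the small-angle limit; `FALSE` regresses the raw phase
#' @return object of class `angular_calibration`: `phase_slope_rad_per_Hz`
#'   (signed), `k_theta_pNnm_per_rad`, `r_squared`, inputs
#' @export
fit_angular_stiffness <- function(phases, bead_radius_um = 1.5,
                                  viscosity_Pa_s = 8.9e-4,
                                  min_r_squared = 0.9, use_tan = TRUE) {
  stopifnot(all(c("freq_Hz", "phase_rad") %in% names(phases)))
  small <- abs(phases$phase_rad) < 0.7
  if (sum(small) < 3) {
    stop("need at least 3 frequencies in the small-angle regime (|phase| < 0.7 rad)",
         call. = FALSE)
  }
  ph <- phases[small, ]
  ph$response <- if (use_tan) tan(ph$phase_rad) else ph$phase_rad
  fit <- stats::lm(response ~ freq_Hz, data = ph)
  r2 <- suppressWarnings(summary(fit))$r.squared  # noiseless input is legal
  if (!is.finite(r2) || r2 < min_r_squared) {
    stop(sprintf("phase-frequency regression R^2 = %.3f below %.2f", r2,
                 min_r_squared), call. = FALSE)
  }
  slope <- unname(stats::coef(fit)["freq_Hz"])
  gam_th <- drag_rotational(bead_radius_um, viscosity_Pa_s)
  out <- list(phase_slope_rad_per_Hz = slope,
              k_theta_pNnm_per_rad = 2 * pi * gam_th / abs(slope),
              bead_radius_um = bead_radius_um,
              viscosity_Pa_s = viscosity_Pa_s,
              r_squared = r2, fit = fit)
  class(out) <- "angular_calibration"
  out
}

#' @export
print.angular_calibration <- function(x, ...) {
  cat(sprintf("Angular calibration: slope %.3g rad/Hz, k_theta = %.3g pN.nm/rad (R^2 %.3f)\n",
              x$phase_slope_rad_per_Hz, x$k_theta_pNnm_per_rad, x$r_squared))
  invisible(x)
}

#' Fraction of spectral power below a cutoff frequency
#'
#' Computes the fraction of total one-sided spectral power below
#' `f_cut_Hz` from the plain periodogram (exact Parseval). Increases in
#' this fraction diagnose the emergence of slowly fluctuating supercoiled
#' structures with higher frictional drag, e.g. during buckling.
#'
#' @param trace a [qpd_trace()] or numeric vector
#' @param f_cut_Hz cutoff (default 60); sampling must exceed `2 * f_cut_Hz`
#' @param fs_Hz sampling rate when `trace` is a bare vector
#' @return fraction in [0, 1]
#' @export
low_freq_power_fraction <- function(trace, f_cut_Hz = 60, fs_Hz = NULL) {
  fs <- if (inherits(trace, "qpd_trace")) trace$fs_Hz else fs_Hz
  if (is.null(fs)) stop("fs_Hz required for a bare vector", call. = FALSE)
  if (fs <= 2 * f_cut_Hz) stop("sampling rate must exceed 2 * f_cut_Hz", call. = FALSE)
  ps <- power_spectrum(trace, "periodogram", fs_Hz = fs)
  sum(ps$psd[ps$freq_Hz <= f_cut_Hz]) / sum(ps$psd)
}

#' @describeIn low_freq_power_fraction percent change in the low-frequency
#'   fraction between two traces (e.g. during vs before buckling)
#' @param trace_before,trace_after traces to compare
#' @export
low_freq_power_change <- function(trace_before, trace_after, f_cut_Hz = 60,
                                  fs_Hz = NULL) {
  a <- low_freq_power_fraction(trace_before, f_cut_Hz, fs_Hz)
  b <- low_freq_power_fraction(trace_after, f_cut_Hz, fs_Hz)
  100 * (b - a) / a
}
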