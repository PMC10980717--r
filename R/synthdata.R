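#' Generate a synthetic worm-like-chain force-extension curve
#'
#' Samples extensions on a regular grid and evaluates the Marko-Siggia force
#' with multiplicative Gaussian noise, `F_obs = F * (1 + rel_noise * eps)`.
#' The generating parameters are attached as ground truth so recovery tests
#' are self-describing.
#'
#' @param Lc_nm,P_nm contour and persistence length (0 < P < Lc)
#' @param n_points number of samples (>= 10)
#' @param temperature_K temperature
#' @param rel_noise relative s.d. of the multiplicative force noise
#' @param seed integer seed
#' @param x_range extension range as fractions of Lc (kept below 0.97)
#' @return an [fx_curve()] with `ground_truth` attribute
#' @export
gen_wlc_curve <- function(Lc_nm, P_nm, n_points = 500, temperature_K = 298,
                          rel_noise = 0.05, seed = 1,
                          x_range = c(0.1, 0.95)) {
  .check_positive(Lc_nm, "Lc_nm"); .check_positive(P_nm, "P_nm")
  if (P_nm >= Lc_nm) stop("need 0 < P < Lc", call. = FALSE)
  stopifnot(n_points >= 10, x_range[1] > 0, x_range[2] < 0.97)
  x <- seq(x_range[1], x_range[2], length.out = n_points) * Lc_nm
  f <- wlc_force(x, Lc_nm, P_nm, temperature_K)
  rng <- .seeded_rng(seed)
  f_obs <- f * (1 + rel_noise * stats::rnorm(n_points))
  rng$restore()
  fx_curve(x, f_obs, direction = "stretch", temperature_K = temperature_K,
           ground_truth = list(Lc_nm = Lc_nm, P_nm = P_nm,
                               rel_noise = rel_noise, seed = seed))
}

#' Generate an optically trapped bead position trace
#'
#' Overdamped Langevin (Ornstein-Uhlenbeck) position series for a bead of
#' radius R in a harmonic trap of stiffness k, using the exact discrete
#' update \eqn{x_{n+1} = x_n e^{-\Delta t/\tau} + s\,\xi_n} with
#' \eqn{\tau = \gamma/k}, \eqn{s^2 = (k_BT/k)(1 - e^{-2\Delta t/\tau})},
#' which is free of time-step bias. The one-sided power spectrum is
#' asymptotically Lorentzian with corner frequency
#' \eqn{f_c = k/(2\pi\gamma)}, \eqn{\gamma = 6\pi\eta R}.
#'
#' @param k_trap_pN_per_um trap stiffness
#' @param bead_radius_um bead radius
#' @param viscosity_Pa_s fluid viscosity
#' @param temperature_K temperature
#' @param fs_Hz sampling rate; must exceed twice the corner frequency
#' @param duration_s trace duration; `fs_Hz * duration_s` must be >= 2^14
#' @param seed integer seed
#' @return a [qpd_trace()] (signal in nm) whose ground truth records
#'   `corner_frequency_Hz`, `k_trap_pN_per_nm`, `gamma_pN_s_per_nm` and
#'   `position_variance_nm2`
#' @export
gen_trapped_bead_trace <- function(k_trap_pN_per_um = 10, bead_radius_um = 1.5,
                                   viscosity_Pa_s = 8.9e-4,
                                   temperature_K = 298, fs_Hz = 50000,
                                   duration_s = 1, seed = 1) {
  .check_positive(k_trap_pN_per_um, "k_trap_pN_per_um")
  k <- k_trap_pN_per_um / 1000            # pN/nm
  gam <- drag_translational(bead_radius_um, viscosity_Pa_s)  # pN.s/nm
  fc <- k / (2 * pi * gam)
  if (fs_Hz <= 2 * fc) {
    stop(sprintf("sampling rate %g Hz too low for corner frequency %.1f Hz (aliasing)",
                 fs_Hz, fc), call. = FALSE)
  }
  n <- round(fs_Hz * duration_s)
  if (n < 2^14) stop("need at least 2^14 samples (raise duration or fs)", call. = FALSE)
  tau <- gam / k
  a <- exp(-1 / (fs_Hz * tau))
  var_eq <- kBT(temperature_K) / k        # nm^2
  s <- sqrt(var_eq * (1 - a^2))
  rng <- .seeded_rng(seed)
  innov <- stats::rnorm(n, sd = s)
  x0 <- stats::rnorm(1, sd = sqrt(var_eq))
  rng$restore()
  x <- as.numeric(stats::filter(innov, a, method = "recursive", init = x0))
  qpd_trace(x, fs_Hz = fs_Hz, unit = "nm",
            ground_truth = list(corner_frequency_Hz = fc,
                                k_trap_pN_per_nm = k,
                                gamma_pN_s_per_nm = gam,
                                relaxation_time_s = tau,
                                position_variance_nm2 = var_eq,
                                seed = seed))
}

#' Generate driven-rotor angular response traces
#'
#' Models a trapped bead with angular stiffness `k_theta` driven by a
#' rotating field at each frequency in `drive_freqs_Hz`. In the overdamped
#' small-angle regime the response is a sinusoid lagging the drive by
#' \eqn{\varphi(f) = \arctan(2\pi f\,\gamma_\theta/k_\theta)} with
#' \eqn{\gamma_\theta = 8\pi\eta R^3}; the small-angle slope is
#' \eqn{d\varphi/df = 2\pi\gamma_\theta/k_\theta}.
#'
#' @param k_theta_pNnm_per_rad angular trap stiffness
#' @param bead_radius_um,viscosity_Pa_s bead radius and fluid viscosity
#' @param drive_freqs_Hz drive frequencies, each within (0.5, 10] Hz
#' @param fs_Hz sampling rate
#' @param n_periods periods recorded per frequency
#' @param amplitude_rad drive amplitude (response is scaled down by the
#'   rotor transfer function)
#' @param noise_sd additive Gaussian noise on the response channel
#' @param seed integer seed
#' @return a list of [qpd_trace()] (one per frequency, with drive channel);
#'   ground truth records `phase_rad` per trace and the phase-frequency
#'   slope
#' @export
gen_driven_rotation_trace <- function(k_theta_pNnm_per_rad = 1100,
                                      bead_radius_um = 1.5,
                                      viscosity_Pa_s = 8.9e-4,
                                      drive_freqs_Hz = 1:8, fs_Hz = 1000,
                                      n_periods = 20, amplitude_rad = 0.2,
                                      noise_sd = 0.01, seed = 1) {
  .check_positive(k_theta_pNnm_per_rad, "k_theta_pNnm_per_rad")
  if (any(drive_freqs_Hz <= 0.5) || any(drive_freqs_Hz > 10)) {
    stop("drive frequencies must lie in (0.5, 10] Hz", call. = FALSE)
  }
  gam_th <- drag_rotational(bead_radius_um, viscosity_Pa_s)  # pN.nm.s
  slope <- 2 * pi * gam_th / k_theta_pNnm_per_rad            # rad/Hz (small angle)
  rng <- .seeded_rng(seed)
  traces <- lapply(drive_freqs_Hz, function(f) {
    n <- round(n_periods * fs_Hz / f)
    t <- (seq_len(n) - 1) / fs_Hz
    w <- 2 * pi * f
    phi <- atan(w * gam_th / k_theta_pNnm_per_rad)
    gain <- 1 / sqrt(1 + (w * gam_th / k_theta_pNnm_per_rad)^2)
    drive <- amplitude_rad * cos(w * t)
    resp <- amplitude_rad * gain * cos(w * t - phi) +
      stats::rnorm(n, sd = noise_sd)
    qpd_trace(resp, fs_Hz = fs_Hz, drive = drive, unit = "rad",
              ground_truth = list(drive_freq_Hz = f, phase_rad = phi,
                                  gamma_theta_pNnm_s = gam_th,
                                  k_theta_pNnm_per_rad = k_theta_pNnm_per_rad,
                                  phase_slope_rad_per_Hz = slope))
  })
  rng$restore()
  names(traces) <- paste0("f", drive_freqs_Hz)
  traces
}

#' Generate a synthetic hat-curve record
#'
#' Emulates the extension-versus-turns response of torsionally constrained
#' DNA at clamped force. Below the critical force the response is symmetric
#' (a plateau within +/- `buckle_turns`, then a linear extension loss on
#' both twist signs); at or above it the undertwisted side stays at the
#' plateau (melting) while the overtwisted side buckles. Gaussian extension
#' noise is added. The record is returned as raw turn-stamped samples in
#' four time-ordered segments mimicking an outward/inward sweep of each
#' twist sign, suitable for [build_hat_curve()].
#'
#' @param force_pN clamp force
#' @param Fc_pN critical force separating the symmetric and asymmetric
#'   regimes (default 0.65, the middle of the 0.6-0.7 pN range)
#' @param n_turns_max maximum |turns| (>= 50)
#' @param slope_nm_per_turn extension lost per turn past buckling
#' @param plateau_extension_nm extension of the torsionally relaxed plateau
#' @param buckle_turns |turns| at which buckling starts
#' @param noise_sd_nm extension noise s.d.
#' @param drift_nm_per_s optional linear drift added to the raw record (to
#'   exercise drift correction); sampling is 1 sample/turn at `sample_rate_hz`
#' @param sample_rate_hz turns per second (sets timestamps)
#' @param seed integer seed
#' @return data.frame (`turns`, `extension_nm`, `segment`, `time_s`) with
#'   `ground_truth` attribute
#' @export
gen_hat_curve <- function(force_pN, Fc_pN = 0.65, n_turns_max = 200,
                          slope_nm_per_turn = 15, plateau_extension_nm = 4500,
                          buckle_turns = 40, noise_sd_nm = 20,
                          drift_nm_per_s = 0, sample_rate_hz = 1, seed = 1) {
  stopifnot(n_turns_max >= 50)
  turn_path <- c(seq(0, n_turns_max),                 # outward overtwist
                 seq(n_turns_max, 0),                 # inward
                 seq(0, -n_turns_max),                # outward undertwist
                 seq(-n_turns_max, 0))                # inward
  segment <- rep(1:4, times = c(n_turns_max + 1, n_turns_max + 1,
                                n_turns_max + 1, n_turns_max + 1))
  shape <- function(n) {
    over <- pmax(abs(n) - buckle_turns, 0)
    if (force_pN >= Fc_pN) {
      ifelse(n < 0, plateau_extension_nm,
             plateau_extension_nm - slope_nm_per_turn * over)
    } else {
      plateau_extension_nm - slope_nm_per_turn * over
    }
  }
  time_s <- (seq_along(turn_path) - 1) / sample_rate_hz
  rng <- .seeded_rng(seed)
  ext <- shape(turn_path) + stats::rnorm(length(turn_path), sd = noise_sd_nm) +
    drift_nm_per_s * time_s
  rng$restore()
  out <- data.frame(turns = turn_path, extension_nm = ext,
                    segment = segment, time_s = time_s)
  attr(out, "ground_truth") <- list(force_pN = force_pN, Fc_pN = Fc_pN,
                                    symmetric = force_pN < Fc_pN,
                                    slope_nm_per_turn = slope_nm_per_turn,
                                    plateau_extension_nm = plateau_extension_nm,
                                    buckle_turns = buckle_turns,
                                    noise_sd_nm = noise_sd_nm,
                                    drift_nm_per_s = drift_nm_per_s, seed = seed)
  out
}

#' Render a synthetic fluorescence movie of a tether with diffusing puncta
#'
#' The tether is drawn as a line of uniform integrated intensity between two
#' endpoints; each punctum is a 2D Gaussian carrying `bp_fraction` of the
#' total tether-integrated intensity and performing 1D Brownian motion along
#' the tether (reflective at the ends). Pixel noise is Poisson shot noise
#' plus additive Gaussian read noise. Image coordinates follow the raster
#' convention: origin at the top-left pixel centre, x rightward along
#' columns, y downward along rows, pixel centres at integer multiples of the
#' pixel size; all positions are stored in nm.
#'
#' @param n_frames,frame_interval_s movie length and frame interval
#' @param pixel_size_nm camera pixel size (default 55)
#' @param image_size_px c(ny, nx)
#' @param tether_endpoints_nm 2x2 matrix, rows = the two endpoints (x, y) nm
#' @param puncta data.frame with columns `bp_fraction`, `D_nm2_per_s` and
#'   optionally `start_fraction` (initial position along the tether)
#' @param psf_sigma_nm Gaussian PSF sigma
#' @param total_intensity total tether-integrated signal per frame (counts)
#' @param background background level per pixel (counts)
#' @param read_noise_sd Gaussian read noise s.d. (counts)
#' @param seed integer seed
#' @return list with `stack` (array ny x nx x n_frames), `ground_truth`
#'   (per-frame punctum positions in nm, parameters) and the geometry
#' @export
gen_tether_movie <- function(n_frames = 20, frame_interval_s = 0.04,
                             pixel_size_nm = 55, image_size_px = c(48, 128),
                             tether_endpoints_nm = rbind(c(550, 1300), c(6050, 1300)),
                             puncta = data.frame(bp_fraction = 0.4,
                                                 D_nm2_per_s = 1900),
                             psf_sigma_nm = 110, total_intensity = 2e5,
                             background = 100, read_noise_sd = 3, seed = 1) {
  ny <- image_size_px[1]; nx <- image_size_px[2]
  p1 <- tether_endpoints_nm[1, ]; p2 <- tether_endpoints_nm[2, ]
  fov <- c((nx - 1) * pixel_size_nm, (ny - 1) * pixel_size_nm)
  if (any(c(p1, p2) < 0) || p1[1] > fov[1] || p2[1] > fov[1] ||
      p1[2] > fov[2] || p2[2] > fov[2]) {
    stop("tether endpoints must lie inside the field of view", call. = FALSE)
  }
  if (nrow(puncta) > 0) {
    if (sum(puncta$bp_fraction) >= 1) stop("bp fractions must sum below 1", call. = FALSE)
    if (any(puncta$bp_fraction < 0)) stop("bp fractions must be non-negative", call. = FALSE)
    if (is.null(puncta$start_fraction)) {
      puncta$start_fraction <- seq(0.3, 0.7, length.out = nrow(puncta))
    }
    if (any(puncta$start_fraction <= 0) || any(puncta$start_fraction >= 1)) {
      stop("puncta must start on the tether (0 < start_fraction < 1)", call. = FALSE)
    }
  }
  axis_vec <- p2 - p1
  L <- sqrt(sum(axis_vec^2))
  u <- axis_vec / L
  # pixel-centre coordinate grids (nm)
  xs <- (seq_len(nx) - 1) * pixel_size_nm
  ys <- (seq_len(ny) - 1) * pixel_size_nm

  splat <- function(img, x0, y0, amp) {
    # add an integrated-2D-Gaussian of total `amp` centred at (x0, y0)
    gx <- exp(-(xs - x0)^2 / (2 * psf_sigma_nm^2))
    gy <- exp(-(ys - y0)^2 / (2 * psf_sigma_nm^2))
    norm <- amp * (pixel_size_nm^2) / (2 * pi * psf_sigma_nm^2)
    img + norm * outer(gy, gx)
  }

  rng <- .seeded_rng(seed)
  # Brownian positions along the tether, reflected into [0, L]
  npx <- nrow(puncta)
  pos_s <- matrix(NA_real_, n_frames, max(npx, 1))
  if (npx > 0) {
    for (k in seq_len(npx)) {
      steps <- stats::rnorm(n_frames - 1,
                            sd = sqrt(2 * puncta$D_nm2_per_s[k] * frame_interval_s))
      s <- cumsum(c(puncta$start_fraction[k] * L, steps))
      # reflect into [0, L]
      s <- abs(s); s <- L - abs(L - (s %% (2 * L)))
      pos_s[, k] <- s
    }
  }
  tether_total <- total_intensity * (1 - if (npx > 0) sum(puncta$bp_fraction) else 0)
  n_line <- max(50L, ceiling(L / (psf_sigma_nm / 3)))
  line_f <- (seq_len(n_line) - 0.5) / n_line
  stack <- array(0, c(ny, nx, n_frames))
  for (fr in seq_len(n_frames)) {
    img <- matrix(background, ny, nx)
    for (j in seq_len(n_line)) {
      pt <- p1 + line_f[j] * axis_vec
      img <- splat(img, pt[1], pt[2], tether_total / n_line)
    }
    if (npx > 0) {
      for (k in seq_len(npx)) {
        pt <- p1 + (pos_s[fr, k] / L) * axis_vec
        img <- splat(img, pt[1], pt[2], total_intensity * puncta$bp_fraction[k])
      }
    }
    noisy <- stats::rpois(length(img), lambda = img) +
      stats::rnorm(length(img), sd = read_noise_sd)
    stack[, , fr] <- matrix(pmax(round(noisy), 0), ny, nx)
  }
  rng$restore()
  truth <- list(puncta = puncta, positions_along_tether_nm = pos_s,
                tether_endpoints_nm = tether_endpoints_nm,
                tether_length_nm = L, psf_sigma_nm = psf_sigma_nm,
                pixel_size_nm = pixel_size_nm, total_intensity = total_intensity,
                background = background, frame_interval_s = frame_interval_s,
                seed = seed)
  list(stack = stack, ground_truth = truth)
}

#' Simulate pure-Brownian punctum tracks
#'
#' Direct position-level simulation of 2D Brownian motion with optional
#' localisation noise, used to validate the MSD diffusion estimator at
#' scale without rendering movies. The tether axis is taken along x.
#'
#' @param n_tracks,n_frames number and length of tracks
#' @param D_nm2_per_s true diffusion coefficient
#' @param frame_interval_s frame interval
#' @param loc_noise_nm localisation noise s.d. added to each coordinate
#' @param seed integer seed
#' @return list of `punctum_track` data.frames (columns `frame`, `x_nm`,
#'   `y_nm`) with the tether axis attached
#' @export
gen_diffusion_tracks <- function(n_tracks = 100, n_frames = 41,
                                 D_nm2_per_s = 1900, frame_interval_s = 0.04,
                                 loc_noise_nm = 0, seed = 1) {
  rng <- .seeded_rng(seed)
  out <- lapply(seq_len(n_tracks), function(i) {
    sd_step <- sqrt(2 * D_nm2_per_s * frame_interval_s)
    x <- cumsum(c(0, stats::rnorm(n_frames - 1, sd = sd_step)))
    y <- cumsum(c(0, stats::rnorm(n_frames - 1, sd = sd_step)))
    if (loc_noise_nm > 0) {
      x <- x + stats::rnorm(n_frames, sd = loc_noise_nm)
      y <- y + stats::rnorm(n_frames, sd = loc_noise_nm)
    }
    tr <- data.frame(frame = seq_len(n_frames), x_nm = x, y_nm = y)
    attr(tr, "tether_axis") <- rbind(c(0, 0), c(1e4, 0))
    class(tr) <- c("punctum_track", "data.frame")
    tr
  })
  rng$restore()
  attr(out, "ground_truth") <- list(D_nm2_per_s = D_nm2_per_s,
                                    frame_interval_s = frame_interval_s,
                                    loc_noise_nm = loc_noise_nm, seed = seed)
  out
}

#' Generate a base-pair-parameter trajectory with planted bubbles
#'
#' Background frames draw the three angular base-pair parameters (propeller,
#' opening, buckle) from per-parameter Gaussians with the Watson-Crick
#' H-bond flag set; base pairs inside a planted bubble have the flag cleared
#' and parameters displaced by `displacement_sd` baseline standard
#' deviations.
#'
#' @param n_bp,n_frames grid size
#' @param dt_ns time per frame in ns
#' @param baseline_means,baseline_sds named numeric vectors for
#'   `propeller`, `opening`, `buckle` (degrees)
#' @param planted_bubbles data.frame with columns `start_bp`, `length_bp`,
#'   `t_start_ns`, `duration_ns` (must not overlap)
#' @param displacement_sd how many baseline s.d. the bubble parameters are
#'   displaced (>= 3 so calls at the 2 s.d. threshold are unambiguous)
#' @param seed integer seed
#' @return a `bp_trajectory` with ground truth attached
#' @export
gen_bp_param_trajectory <- function(n_bp = 30, n_frames = 500, dt_ns = 0.1,
                                    baseline_means = c(propeller = -12,
                                                       opening = 2, buckle = 0),
                                    baseline_sds = c(propeller = 8,
                                                     opening = 4, buckle = 6),
                                    planted_bubbles = NULL,
                                    displacement_sd = 4, seed = 1) {
  stopifnot(displacement_sd >= 3)
  pb <- planted_bubbles
  if (!is.null(pb) && nrow(pb) > 0) {
    if (any(pb$start_bp < 1) || any(pb$start_bp + pb$length_bp - 1 > n_bp) ||
        any(pb$t_start_ns < 0) ||
        any(pb$t_start_ns + pb$duration_ns > n_frames * dt_ns + 1e-9)) {
      stop("planted bubbles must lie within sequence and time bounds", call. = FALSE)
    }
    if (nrow(pb) > 1) {
      for (i in seq_len(nrow(pb) - 1)) for (j in (i + 1):nrow(pb)) {
        bp_ov <- pb$start_bp[i] <= pb$start_bp[j] + pb$length_bp[j] - 1 &&
          pb$start_bp[j] <= pb$start_bp[i] + pb$length_bp[i] - 1
        t_ov <- pb$t_start_ns[i] < pb$t_start_ns[j] + pb$duration_ns[j] &&
          pb$t_start_ns[j] < pb$t_start_ns[i] + pb$duration_ns[i]
        if (bp_ov && t_ov) stop("planted bubbles overlap", call. = FALSE)
      }
    }
  }
  rng <- .seeded_rng(seed)
  params <- lapply(c(propeller = "propeller", opening = "opening",
                     buckle = "buckle"), function(p) {
    matrix(stats::rnorm(n_frames * n_bp, baseline_means[[p]], baseline_sds[[p]]),
           n_frames, n_bp)
  })
  hbond <- matrix(TRUE, n_frames, n_bp)
  if (!is.null(pb) && nrow(pb) > 0) {
    for (i in seq_len(nrow(pb))) {
      bps <- pb$start_bp[i]:(pb$start_bp[i] + pb$length_bp[i] - 1)
      fr0 <- floor(pb$t_start_ns[i] / dt_ns) + 1
      fr1 <- min(n_frames, fr0 + ceiling(pb$duration_ns[i] / dt_ns) - 1)
      frs <- fr0:fr1
      hbond[frs, bps] <- FALSE
      for (p in names(params)) {
        shift <- displacement_sd * baseline_sds[[p]]
        params[[p]][frs, bps] <- baseline_means[[p]] + shift +
          stats::rnorm(length(frs) * length(bps), sd = 0.2 * baseline_sds[[p]])
      }
    }
  }
  rng$restore()
  traj <- bp_trajectory(propeller = params$propeller, opening = params$opening,
                        buckle = params$buckle, hbond = hbond, dt_ns = dt_ns)
  attr(traj, "ground_truth") <- list(baseline_means = baseline_means,
                                     baseline_sds = baseline_sds,
                                     planted_bubbles = pb,
                                     displacement_sd = displacement_sd,
                                     seed = seed)
  traj
}

#' Simulate a discrete force clamp
#'
#' Emulates the feedback loop that keeps tether tension constant by
#' repositioning the nanostage. Each control tick the stage is moved by the
#' proportional term (force error divided by trap stiffness) scaled by
#' `kp`, plus integral and derivative terms. The plant is linear: the
#' measured force is the trap stiffness times the bead displacement implied
#' by the stage position and the disturbance.
#'
#' @param set_force_pN force setpoint
#' @param trap_stiffness_pN_per_um trap stiffness (default 10)
#' @param gains list with `kp`, `ki`, `kd` (dimensionless; `kp = 1` gives a
#'   one-step deadbeat correction). Defaults are tuned so the closed loop
#'   settles in about 1 s at the default 100 Hz update rate.
#' @param disturbance_pN either a function of time or a vector per tick,
#'   added to the plant force
#' @param duration_s simulated time
#' @param dt_s control-loop tick (default 0.01 s)
#' @param noise_sd_pN measurement noise on the force signal
#' @param start_at_setpoint start the plant at the setpoint (default TRUE)
#' @return data.frame (`time_s`, `force_pN`, `stage_nm`) with a
#'   `settling_time_s` attribute (first time the force stays within
#'   +/-0.1 pN of the setpoint)
#' @export
simulate_force_clamp <- function(set_force_pN, trap_stiffness_pN_per_um = 10,
                                 gains = list(kp = 0.02, ki = 0.001, kd = 0),
                                 disturbance_pN = 0, duration_s = 10,
                                 dt_s = 0.01, noise_sd_pN = 0,
                                 start_at_setpoint = TRUE) {
  .check_positive(trap_stiffness_pN_per_um, "trap_stiffness_pN_per_um")
  k <- trap_stiffness_pN_per_um / 1000   # pN/nm
  n <- round(duration_s / dt_s)
  t <- (seq_len(n) - 1) * dt_s
  dist <- if (is.function(disturbance_pN)) disturbance_pN(t) else
    rep_len(disturbance_pN, n)
  stage <- numeric(n); force <- numeric(n)
  stage[1] <- if (start_at_setpoint) set_force_pN / k else 0
  integ <- 0; prev_err <- 0
  for (i in seq_len(n)) {
    force[i] <- k * stage[i] + dist[i] +
      if (noise_sd_pN > 0) stats::rnorm(1, sd = noise_sd_pN) else 0
    if (!is.finite(force[i]) || abs(force[i] - set_force_pN) >
        1e3 * max(1, abs(set_force_pN))) {
      stop("force clamp diverged: unstable gain set (|F - Fset| exceeded ",
           "1000x the setpoint at t = ", signif(t[i], 3), " s)", call. = FALSE)
    }
    err <- force[i] - set_force_pN
    integ <- integ + err * dt_s
    deriv <- (err - prev_err) / dt_s
    prev_err <- err
    if (i < n) {
      stage[i + 1] <- stage[i] -
        (gains$kp * err + gains$ki * integ + gains$kd * deriv) / k
    }
  }
  out <- data.frame(time_s = t, force_pN = force, stage_nm = stage)
  inside <- abs(force - set_force_pN) <= 0.1
  settling <- if (all(!inside)) NA_real_ else {
    last_out <- max(c(0L, which(!inside)))
    if (last_out >= n) NA_real_ else t[last_out + 1L]
  }
  attr(out, "settling_time_s") <- settling
  attr(out, "gains") <- gains
  out
}
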