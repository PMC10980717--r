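# Image coordinate convention (shared with gen_tether_movie): origin at the
# top-left pixel centre, x rightward along columns, y downward along rows,
# pixel centres at integer multiples of the pixel size; positions in nm.

#' Detect and track fluorescent puncta in an image stack
#'
#' Per frame, candidate puncta are local maxima above the background by a
#' noise-scaled threshold; each candidate is refined by least-squares
#' fitting of a 2D Gaussian with a flat offset, giving sub-pixel position,
#' integrated background-corrected intensity (2 pi A sigma^2) and a
#' localisation precision from the fit covariance. Detections are linked
#' across frames by greedy nearest-neighbour association within
#' `link_radius_nm`; when two candidates compete for one track the tie is
#' broken by intensity similarity and the frame is flagged.
#'
#' @param stack numeric array ny x nx x n_frames (or a matrix for 1 frame)
#' @param pixel_size_nm camera pixel size (default 55)
#' @param expected_psf_sigma_nm starting value for the PSF sigma
#' @param link_radius_nm maximum frame-to-frame displacement for linking
#' @param threshold_sd detection threshold in robust noise units above
#'   background
#' @param min_separation_px suppress weaker maxima closer than this
#' @return list of `punctum_track` data.frames with columns `frame`,
#'   `x_nm`, `y_nm`, `intensity`, `background`, `sigma_nm`,
#'   `loc_precision_nm`, `ambiguous_link`
#' @export
track_puncta <- function(stack, pixel_size_nm = 55, expected_psf_sigma_nm = 110,
                         link_radius_nm = 500, threshold_sd = 6,
                         min_separation_px = NULL) {
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1L))
  ny <- dim(stack)[1]; nx <- dim(stack)[2]; nf <- dim(stack)[3]
  psf_px <- expected_psf_sigma_nm / pixel_size_nm
  if (is.null(min_separation_px)) min_separation_px <- 3 * psf_px
  win <- max(3L, ceiling(3 * psf_px))

  detect_frame <- function(img) {
    bg <- stats::median(img)
    noise <- stats::mad(img)
    if (noise == 0) noise <- stats::sd(img)
    if (!is.finite(noise) || noise == 0) return(NULL)
    thr <- bg + threshold_sd * noise
    cand <- which(img > thr, arr.ind = TRUE)
    if (nrow(cand) == 0) return(NULL)
    # keep 3x3 local maxima
    is_max <- vapply(seq_len(nrow(cand)), function(i) {
      r <- cand[i, 1]; c <- cand[i, 2]
      rr <- max(1, r - 1):min(ny, r + 1); cc <- max(1, c - 1):min(nx, c + 1)
      img[r, c] >= max(img[rr, cc])
    }, TRUE)
    cand <- cand[is_max, , drop = FALSE]
    if (nrow(cand) == 0) return(NULL)
    # non-maximum suppression at min_separation_px
    ord <- order(img[cand], decreasing = TRUE)
    cand <- cand[ord, , drop = FALSE]
    keep <- rep(TRUE, nrow(cand))
    for (i in seq_len(nrow(cand))) {
      if (!keep[i]) next
      if (i < nrow(cand)) {
        later <- (i + 1):nrow(cand)
        d2 <- (cand[later, 1] - cand[i, 1])^2 + (cand[later, 2] - cand[i, 2])^2
        keep[later][d2 < min_separation_px^2] <- FALSE
      }
    }
    cand <- cand[keep, , drop = FALSE]
    dets <- lapply(seq_len(nrow(cand)), function(i) {
      .fit_gaussian_2d(img, cand[i, 1], cand[i, 2], win, psf_px, bg)
    })
    dets <- do.call(rbind, dets[!vapply(dets, is.null, TRUE)])
    if (is.null(dets) || nrow(dets) == 0) return(NULL)
    dets$x_nm <- (dets$col - 1) * pixel_size_nm
    dets$y_nm <- (dets$row - 1) * pixel_size_nm
    dets$sigma_nm <- dets$sigma_px * pixel_size_nm
    dets$loc_precision_nm <- dets$loc_precision_px * pixel_size_nm
    dets
  }

  detections <- lapply(seq_len(nf), function(k) detect_frame(stack[, , k]))

  # greedy nearest-neighbour linking
  tracks <- list()
  active <- list()   # list of track indices with last position
  for (fr in seq_len(nf)) {
    det <- detections[[fr]]
    used <- if (is.null(det)) logical(0) else rep(FALSE, nrow(det))
    new_active <- list()
    for (tr in active) {
      if (is.null(det) || all(used)) next
      last <- tracks[[tr$id]][nrow(tracks[[tr$id]]), ]
      d <- sqrt((det$x_nm - last$x_nm)^2 + (det$y_nm - last$y_nm)^2)
      d[used] <- Inf
      within <- which(d <= link_radius_nm)
      if (length(within) == 0) next
      ambiguous <- length(within) > 1
      if (ambiguous) {
        # tie broken by intensity similarity
        sim <- abs(det$intensity[within] - last$intensity)
        j <- within[which.min(sim)]
      } else j <- within[1]
      used[j] <- TRUE
      row <- data.frame(frame = fr, x_nm = det$x_nm[j], y_nm = det$y_nm[j],
                        intensity = det$intensity[j], background = det$background[j],
                        sigma_nm = det$sigma_nm[j],
                        loc_precision_nm = det$loc_precision_nm[j],
                        ambiguous_link = ambiguous)
      tracks[[tr$id]] <- rbind(tracks[[tr$id]], row)
      new_active[[length(new_active) + 1]] <- tr
    }
    # unmatched detections start new tracks
    if (!is.null(det)) {
      for (j in which(!used)) {
        id <- length(tracks) + 1
        tracks[[id]] <- data.frame(frame = fr, x_nm = det$x_nm[j],
                                   y_nm = det$y_nm[j],
                                   intensity = det$intensity[j],
                                   background = det$background[j],
                                   sigma_nm = det$sigma_nm[j],
                                   loc_precision_nm = det$loc_precision_nm[j],
                                   ambiguous_link = FALSE)
        new_active[[length(new_active) + 1]] <- list(id = id)
      }
    }
    active <- new_active
  }
  tracks <- lapply(tracks, function(tr) {
    rownames(tr) <- NULL
    class(tr) <- c("punctum_track", "data.frame")
    tr
  })
  # dominant objects first: longest tracks, brightest on ties (noise ripples
  # on the tether ridge produce short dim tracks that sort to the rear)
  ord <- order(vapply(tracks, nrow, 0L), vapply(tracks, function(t) mean(t$intensity), 0),
               decreasing = TRUE)
  tracks[ord]
}

# Least-squares 2D Gaussian refinement around a candidate pixel.
.fit_gaussian_2d <- function(img, r0, c0, win, psf_px, bg0) {
  ny <- nrow(img); nx <- ncol(img)
  rr <- max(1, r0 - win):min(ny, r0 + win)
  cc <- max(1, c0 - win):min(nx, c0 + win)
  z <- as.vector(img[rr, cc])
  ri <- rep(rr, times = length(cc))
  ci <- rep(cc, each = length(rr))
  a0 <- img[r0, c0] - bg0
  if (a0 <= 0) return(NULL)
  start <- c(A = a0, mr = r0, mc = c0, s = psf_px, b = bg0)
  obj <- function(p) {
    g <- p[5] + p[1] * exp(-((ri - p[2])^2 + (ci - p[3])^2) / (2 * p[4]^2))
    sum((z - g)^2)
  }
  fit <- tryCatch(stats::optim(start, obj, method = "BFGS",
                               control = list(maxit = 400, reltol = 1e-12)),
                  error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- fit$par
  p[4] <- abs(p[4])
  # reject degenerate fits: vanished amplitude, runaway width (the fit
  # latched onto the tether or the whole frame), or a centre that left the
  # fit window
  if (p[1] <= 0 || p[4] < 0.2 || p[4] > 2 * win ||
      abs(p[2] - r0) > win || abs(p[3] - c0) > win) return(NULL)
  # numeric Hessian -> covariance -> positional standard error
  noise_var <- fit$value / max(1, length(z) - 5)
  hess <- tryCatch(stats::optimHess(p, obj), error = function(e) NULL)
  loc_se <- NA_real_
  if (!is.null(hess)) {
    cov <- tryCatch(solve(hess / (2 * noise_var)), error = function(e) NULL)
    if (!is.null(cov)) {
      loc_se <- sqrt(mean(pmax(diag(cov)[2:3], 0)))
    }
  }
  data.frame(row = p[2], col = p[3], amplitude = p[1], sigma_px = abs(p[4]),
             background = p[5],
             intensity = 2 * pi * p[1] * p[4]^2,    # integrated above background
             loc_precision_px = loc_se)
}

#' Fraction of tether base pairs inside a punctum
#'
#' Integrates background-corrected pixel intensity in a disc around the
#' tracked punctum and normalises by the background-corrected intensity of
#' the whole tether (a band of half-width `tether_halfwidth_nm` around the
#' axis, including the punctum). Because intercalator staining is uniform
#' per bp, the intensity fraction estimates the fraction of construct base
#' pairs condensed into the punctum (plectoneme); `bp_content = fraction *
#' construct_bp`.
#'
#' @param track a `punctum_track`
#' @param stack the image stack the track came from
#' @param tether_endpoints_nm 2x2 matrix of tether endpoints (nm)
#' @param pixel_size_nm pixel size
#' @param punctum_radius_nm integration radius around the punctum
#' @param tether_halfwidth_nm half-width of the tether band
#' @param bg_annulus_sigmas inner/outer radii of the background annulus in
#'   units of the fitted PSF sigma (default 3-5)
#' @param construct_bp optional construct size to report bp content
#' @return list with `per_frame` data.frame (`frame`, `fraction`,
#'   `bp_content`), `mean_fraction`, `mean_bp_content`
#' @export
punctum_bp_fraction <- function(track, stack, tether_endpoints_nm,
                                pixel_size_nm = 55, punctum_radius_nm = 350,
                                tether_halfwidth_nm = 330,
                                bg_annulus_sigmas = c(3, 5),
                                construct_bp = NULL) {
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1L))
  ny <- dim(stack)[1]; nx <- dim(stack)[2]
  xs <- (seq_len(nx) - 1) * pixel_size_nm
  ys <- (seq_len(ny) - 1) * pixel_size_nm
  X <- matrix(xs, ny, nx, byrow = TRUE)
  Y <- matrix(ys, ny, nx)
  p1 <- tether_endpoints_nm[1, ]; p2 <- tether_endpoints_nm[2, ]
  axis_vec <- p2 - p1; L <- sqrt(sum(axis_vec^2)); u <- axis_vec / L
  # distance of each pixel to the tether segment
  relx <- X - p1[1]; rely <- Y - p1[2]
  s <- pmin(pmax(relx * u[1] + rely * u[2], 0), L)
  dperp <- sqrt((relx - s * u[1])^2 + (rely - s * u[2])^2)
  tether_mask <- dperp <= tether_halfwidth_nm
  res <- lapply(seq_len(nrow(track)), function(i) {
    fr <- track$frame[i]
    img <- stack[, , fr]
    d_pt <- sqrt((X - track$x_nm[i])^2 + (Y - track$y_nm[i])^2)
    sig <- if (is.finite(track$sigma_nm[i])) track$sigma_nm[i] else punctum_radius_nm / 3
    ann <- d_pt >= bg_annulus_sigmas[1] * sig & d_pt <= bg_annulus_sigmas[2] * sig &
      !tether_mask
    bg <- if (any(ann)) stats::median(img[ann]) else stats::median(img[!tether_mask])
    tot <- sum(img[tether_mask] - bg)
    if (tot <= 0) stop("whole-tether intensity non-positive after background ",
                       "correction", call. = FALSE)
    punc_raw <- sum(img[d_pt <= punctum_radius_nm] - bg)
    # the disc also collects the stretch of plain tether running through it;
    # estimate the tether's intensity per unit length away from the punctum
    # and subtract that stretch so only the punctum excess is counted
    disc_len <- min(2 * punctum_radius_nm, L)
    lin_density <- (tot - punc_raw) / max(L - disc_len, 1)
    punc <- punc_raw - lin_density * disc_len
    frac <- max(0, min(1, punc / tot))
    data.frame(frame = fr, fraction = frac,
               bp_content = if (is.null(construct_bp)) NA_real_ else
                 frac * construct_bp)
  })
  per_frame <- do.call(rbind, res)
  list(per_frame = per_frame,
       mean_fraction = mean(per_frame$fraction),
       mean_bp_content = if (is.null(construct_bp)) NA_real_ else
         mean(per_frame$bp_content))
}

#' Frame-to-frame rms displacements parallel and perpendicular to the tether
#'
#' Projects successive frame-to-frame displacements of a track onto the
#' tether axis and its normal and reports the 1D root-mean-square
#' displacement of each component plus the 2D total, which satisfy
#' `rmsd_tot^2 = rmsd_par^2 + rmsd_perp^2`.
#'
#' @param track a `punctum_track` (>= 2 frames)
#' @param tether_axis 2x2 matrix (two points on the axis, nm); defaults to
#'   the `tether_axis` attribute of the track
#' @return object of class `diffusion_summary` with `rmsd_parallel_nm`,
#'   `rmsd_perp_nm`, `rmsd_tot_nm`, `n_steps`
#' @export
rmsd_components <- function(track, tether_axis = attr(track, "tether_axis")) {
  if (nrow(track) < 2) stop("need at least 2 frames", call. = FALSE)
  if (is.null(tether_axis)) stop("tether axis required", call. = FALSE)
  v <- tether_axis[2, ] - tether_axis[1, ]
  L <- sqrt(sum(v^2))
  if (L == 0) stop("degenerate tether axis (zero length)", call. = FALSE)
  u <- v / L; nvec <- c(-u[2], u[1])
  dx <- diff(track$x_nm); dy <- diff(track$y_nm)
  dpar <- dx * u[1] + dy * u[2]
  dperp <- dx * nvec[1] + dy * nvec[2]
  out <- list(rmsd_parallel_nm = sqrt(mean(dpar^2)),
              rmsd_perp_nm = sqrt(mean(dperp^2)),
              rmsd_tot_nm = sqrt(mean(dpar^2 + dperp^2)),
              n_steps = length(dpar))
  class(out) <- "diffusion_summary"
  out
}

#' Combine printed 1D rms displacements into the 2D total
#'
#' Quadrature sum `sqrt(rmsd_par^2 + rmsd_perp^2)`, the relation linking
#' the parallel/perpendicular columns of a mobility table to its total
#' column.
#'
#' @param rmsd_parallel_nm,rmsd_perp_nm 1D rms displacements
#' @return total 2D rms displacement in nm
#' @export
#' @examples
#' rmsd_total(108, 96)  # ~144
rmsd_total <- function(rmsd_parallel_nm, rmsd_perp_nm) {
  sqrt(rmsd_parallel_nm^2 + rmsd_perp_nm^2)
}

#' Diffusion coefficient from MSD regression
#'
#' Computes the mean square displacement at lags `1..max_lag` and fits
#' `MSD = 4 D (lag * dt)` by ordinary least squares through the origin (2D
#' diffusion), with a confidence interval from the regression. A ballistic
#' (quadratic-in-lag) component is flagged by comparing the linear fit with
#' a quadratic one.
#'
#' @param track a `punctum_track` with at least `max_lag + 2` frames
#' @param frame_interval_s frame interval (s)
#' @param max_lag largest lag used (default 5)
#' @param conf confidence level for the CI
#' @return object of class `diffusion_estimate`: `D_nm2_per_s`, `ci`,
#'   `msd` (data.frame lag/msd), `nonlinear` flag
#' @export
estimate_D <- function(track, frame_interval_s, max_lag = 5, conf = 0.95) {
  n <- nrow(track)
  if (n <= max_lag + 1) stop("track shorter than max_lag + 2 frames", call. = FALSE)
  msd <- vapply(seq_len(max_lag), function(l) {
    dx <- track$x_nm[(1 + l):n] - track$x_nm[1:(n - l)]
    dy <- track$y_nm[(1 + l):n] - track$y_nm[1:(n - l)]
    mean(dx^2 + dy^2)
  }, 0)
  tau <- seq_len(max_lag) * frame_interval_s
  fit <- stats::lm(msd ~ 0 + tau)
  D <- unname(stats::coef(fit)[1]) / 4
  ci <- tryCatch(stats::confint(fit, level = conf)[1, ] / 4,
                 error = function(e) c(NA, NA))
  nonlinear <- FALSE
  if (max_lag >= 3) {
    fq <- stats::lm(msd ~ 0 + tau + I(tau^2))
    sm <- suppressWarnings(summary(fq))$coefficients
    if (nrow(sm) == 2 && is.finite(sm[2, 4]) && sm[2, 4] < 0.01 &&
        abs(sm[2, 1]) * max(tau) > abs(sm[1, 1])) {
      nonlinear <- TRUE
    }
  }
  if (D < 0) {
    warning("negative fitted D clamped to 0", call. = FALSE)
    D <- 0
  }
  structure(list(D_nm2_per_s = D, ci = ci,
                 msd = data.frame(lag = seq_len(max_lag), tau_s = tau, msd_nm2 = msd),
                 nonlinear = nonlinear),
            class = "diffusion_estimate")
}

#' Ratio of diffusion coefficients
#'
#' Quotient of two diffusion coefficients (e.g. positively versus
#' negatively supercoiled plectonemes) with a nearest-integer rounding
#' helper for reporting.
#'
#' @param D_pos,D_neg diffusion coefficients; `D_neg` must be positive
#' @param round_to_integer report the nearest integer
#' @return the ratio
#' @export
#' @examples
#' ratio_of_D(1900, 310, round_to_integer = TRUE)  # 6
ratio_of_D <- function(D_pos, D_neg, round_to_integer = FALSE) {
  if (D_neg <= 0) stop("D_neg must be positive", call. = FALSE)
  r <- D_pos / D_neg
  if (round_to_integer) round(r) else r
}

#' Perpendicular FWHM line profiles along a tether
#'
#' Samples background-subtracted intensity profiles perpendicular to the
#' tether axis at regular axial positions (bilinear interpolation) and
#' measures the full width at half maximum of each by linear interpolation
#' at the half-maximum crossings. Blurred tether regions (e.g. rapidly
#' fluctuating single-stranded segments) widen the profile.
#'
#' @param image a single image (matrix)
#' @param tether_endpoints_nm 2x2 endpoints of the tether (nm)
#' @param pixel_size_nm pixel size
#' @param band_nm axial range to profile as a fraction offset from each end
#'   (avoids bead halos); profile positions step every `step_nm`
#' @param halfwidth_nm perpendicular extent sampled either side of the axis
#' @param step_nm axial spacing of profiles
#' @param min_peak_snr flag profiles whose peak is below this multiple of
#'   the background noise
#' @return data.frame (`axial_nm`, `fwhm_nm`, `ok`) with attribute
#'   `mean_fwhm_nm` (over valid profiles)
#' @export
line_profile_fwhm <- function(image, tether_endpoints_nm, pixel_size_nm = 55,
                              band_nm = 400, halfwidth_nm = 600,
                              step_nm = 55, min_peak_snr = 3) {
  p1 <- tether_endpoints_nm[1, ]; p2 <- tether_endpoints_nm[2, ]
  v <- p2 - p1; L <- sqrt(sum(v^2)); u <- v / L; nvec <- c(-u[2], u[1])
  interp <- function(x_nm, y_nm) {
    # bilinear interpolation on the pixel-centre grid
    cx <- x_nm / pixel_size_nm + 1; cy <- y_nm / pixel_size_nm + 1
    x0 <- floor(cx); y0 <- floor(cy)
    x0 <- pmin(pmax(x0, 1), ncol(image) - 1)
    y0 <- pmin(pmax(y0, 1), nrow(image) - 1)
    fx <- cx - x0; fy <- cy - y0
    image[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
      image[cbind(y0, x0 + 1)] * fx * (1 - fy) +
      image[cbind(y0 + 1, x0)] * (1 - fx) * fy +
      image[cbind(y0 + 1, x0 + 1)] * fx * fy
  }
  ax <- seq(band_nm, L - band_nm, by = step_nm)
  if (length(ax) == 0) stop("band excludes the whole tether", call. = FALSE)
  perp <- seq(-halfwidth_nm, halfwidth_nm, by = 5)
  dom <- which.max(abs(nvec))   # image axis most aligned with the normal
  rows <- lapply(ax, function(s) {
    ctr <- p1 + s * u
    # sample the coarse profile where the perpendicular crosses pixel
    # centres along the dominant axis, so no interpolation smears the peak,
    # then refine with a spline before the half-maximum crossing search
    m <- seq(floor((ctr[dom] - halfwidth_nm * abs(nvec[dom])) / pixel_size_nm),
             ceiling((ctr[dom] + halfwidth_nm * abs(nvec[dom])) / pixel_size_nm))
    t_c <- sort((m * pixel_size_nm - ctr[dom]) / nvec[dom])
    t_c <- t_c[t_c >= -halfwidth_nm & t_c <= halfwidth_nm]
    px <- ctr[1] + t_c * nvec[1]; py <- ctr[2] + t_c * nvec[2]
    prof_c <- interp(px, py)
    prof <- stats::spline(t_c, prof_c, xout = perp)$y
    ntail <- max(2, floor(length(prof) * 0.15))
    bg <- mean(c(utils::head(prof, ntail), utils::tail(prof, ntail)))
    noise <- stats::sd(c(utils::head(prof, ntail), utils::tail(prof, ntail)))
    prof <- prof - bg
    pk <- max(prof); ipk <- which.max(prof)
    if (!is.finite(pk) || (is.finite(noise) && noise > 0 && pk < min_peak_snr * noise)) {
      return(data.frame(axial_nm = s, fwhm_nm = NA_real_, ok = FALSE))
    }
    half <- pk / 2
    left <- NA_real_; right <- NA_real_
    for (i in seq(ipk, 2)) {
      if (prof[i - 1] <= half && prof[i] > half) {
        left <- perp[i - 1] + (half - prof[i - 1]) / (prof[i] - prof[i - 1]) *
          (perp[i] - perp[i - 1]); break
      }
    }
    for (i in seq(ipk, length(prof) - 1)) {
      if (prof[i + 1] <= half && prof[i] > half) {
        right <- perp[i] + (prof[i] - half) / (prof[i] - prof[i + 1]) *
          (perp[i + 1] - perp[i]); break
      }
    }
    if (!is.finite(left) || !is.finite(right)) {
      return(data.frame(axial_nm = s, fwhm_nm = NA_real_, ok = FALSE))
    }
    data.frame(axial_nm = s, fwhm_nm = right - left, ok = TRUE)
  })
  out <- do.call(rbind, rows)
  attr(out, "mean_fwhm_nm") <- mean(out$fwhm_nm[out$ok], na.rm = TRUE)
  out
}
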