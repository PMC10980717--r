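#' Heat-conduction model of a laser-heated magnetic bead
#'
#' A trapped magnetic bead absorbs NIR laser power in a thin magnetite
#' shell just inside its surface and dissipates the heat into the
#' surrounding water (and, nearby, the glass coverslip). This constructor
#' collects the geometry, conductivities and source strength; either the
#' absorbed power or the target surface temperature may be specified (the
#' other is derived from the infinite-water analytic relation
#' `Ts = T_inf + P / (4 pi k_water R)`).
#'
#' @param bead_radius_um bead radius (default 1.5)
#' @param shell_thickness_nm thickness of the absorbing shell (default 100)
#' @param absorbed_power_mW absorbed optical power; alternative to
#'   `surface_T_C`
#' @param surface_T_C target surface temperature; alternative to
#'   `absorbed_power_mW`
#' @param k_bead,k_water,k_glass thermal conductivities in W/m/K
#'   (polymer bead interior 0.2, water 0.6, glass 1.0 - literature values)
#' @param ambient_T_C far-field temperature (default 25)
#' @param coverslip_distance_um gap between bead surface and coverslip
#' @return object of class `bead_thermal_model`
#' @export
bead_thermal_model <- function(bead_radius_um = 1.5, shell_thickness_nm = 100,
                               absorbed_power_mW = NULL, surface_T_C = NULL,
                               k_bead = 0.2, k_water = 0.6, k_glass = 1.0,
                               ambient_T_C = 25, coverslip_distance_um = 2) {
  .check_positive(c(bead_radius_um, k_bead, k_water, k_glass), "conductivities/radius")
  if (shell_thickness_nm <= 0 || shell_thickness_nm >= bead_radius_um * 1000) {
    stop("shell must be a thin layer inside the bead", call. = FALSE)
  }
  R_m <- bead_radius_um * 1e-6
  if (is.null(absorbed_power_mW) && is.null(surface_T_C)) {
    stop("give either absorbed_power_mW or surface_T_C", call. = FALSE)
  }
  if (is.null(absorbed_power_mW)) {
    absorbed_power_mW <- (surface_T_C - ambient_T_C) * 4 * pi * k_water * R_m * 1e3
  }
  surface_T_C <- ambient_T_C + absorbed_power_mW * 1e-3 / (4 * pi * k_water * R_m)
  structure(list(bead_radius_um = bead_radius_um,
                 shell_thickness_nm = shell_thickness_nm,
                 absorbed_power_mW = absorbed_power_mW,
                 surface_T_C = surface_T_C,
                 k_bead = k_bead, k_water = k_water, k_glass = k_glass,
                 ambient_T_C = ambient_T_C,
                 coverslip_distance_um = coverslip_distance_um),
            class = "bead_thermal_model")
}

#' Analytic temperature profile (infinite water)
#'
#' With all power generated in a thin spherical shell and the coverslip
#' ignored, the steady state is isothermal inside the bead at the surface
#' temperature `Ts = T_inf + P/(4 pi k_water R)` and decays as 1/r outside:
#' `T(r) = T_inf + (Ts - T_inf) R / r`. Positions are distances from the
#' bead surface (negative = interior).
#'
#' @param model a [bead_thermal_model()]
#' @param x_um distances from the bead surface in micrometres
#' @return data.frame of class `temperature_profile` (`x_um`, `T_C`)
#' @export
#' @examples
#' m <- bead_thermal_model(surface_T_C = 45)
#' analytic_profile(m, c(0, 1.5, 5))  # 45, half-excess at r = 2R, ~29.6
analytic_profile <- function(model, x_um = seq(-1.4, 5, by = 0.05)) {
  stopifnot(inherits(model, "bead_thermal_model"))
  R <- model$bead_radius_um
  Ts <- model$surface_T_C; Tinf <- model$ambient_T_C
  T_C <- ifelse(x_um <= 0, Ts, Tinf + (Ts - Tinf) * R / (R + x_um))
  out <- data.frame(x_um = x_um, T_C = T_C)
  class(out) <- c("temperature_profile", "data.frame")
  out
}

# Build a 1D grid refined near the requested locations: spacing `h_fine`
# within `pad` of any point of interest, growing geometrically (factor
# `grow`) elsewhere, covering [lo, hi].
.graded_axis <- function(lo, hi, interest, h_fine, pad, h_max, grow = 1.25) {
  xs <- lo
  x <- lo
  while (x < hi) {
    d <- suppressWarnings(min(abs(x - interest), abs(x + h_fine - interest)))
    h <- if (d <= pad) h_fine else min(h_max, h_fine * grow^((d - pad) / pad))
    x <- x + h
    xs <- c(xs, min(x, hi))
  }
  unique(xs)
}

#' Numerical steady-state temperature field near a coverslip
#'
#' Finite-volume solution of steady heat conduction on an axisymmetric
#' (rho, z) grid: glass half-space below the coverslip plane z = 0, water
#' above, bead centred on the axis at `z = coverslip_distance + R`, heat
#' generated uniformly in the magnetite shell. The outer boundary takes the
#' analytic far-field profile as Dirichlet data. Returns the lateral
#' temperature profile at bead-centre height (distance from the bead
#' surface) with the full field and flux balance attached.
#'
#' @param model a [bead_thermal_model()]
#' @param h_fine_nm cell size near the bead surface; the shell must span
#'   at least 4 cells (default `shell/4`)
#' @param domain_factor domain half-width in bead radii (>= 10)
#' @param h_max_um coarsest cell far from the bead
#' @return a `temperature_profile` data.frame (`x_um`, `T_C`) with
#'   attributes `field` (list rho, z, T matrix), `interior_sd_C`,
#'   `flux_balance` (boundary flux / source power) and `grid_size`
#' @export
numeric_profile <- function(model, h_fine_nm = NULL, domain_factor = 12,
                            h_max_um = 1.5) {
  stopifnot(inherits(model, "bead_thermal_model"), domain_factor >= 10)
  R <- model$bead_radius_um
  shell <- model$shell_thickness_nm / 1000
  if (is.null(h_fine_nm)) h_fine_nm <- model$shell_thickness_nm / 4
  if (h_fine_nm > model$shell_thickness_nm / 4) {
    stop("h_fine_nm must resolve the shell with at least 4 cells", call. = FALSE)
  }
  h <- h_fine_nm / 1000
  z0 <- model$coverslip_distance_um + R      # bead centre height
  rho_max <- domain_factor * R
  z_max <- z0 + domain_factor * R
  z_min <- -3                                 # glass depth (um)
  # fine cells over the whole bead-bearing box (the shell crosses every
  # rho < R at some height, so banded refinement would leave it
  # under-resolved away from the equator), graded coarsening outside
  rho <- .graded_axis(0, rho_max, interest = seq(0, R, by = 0.2), h,
                      pad = 0.25, h_max_um)
  z <- .graded_axis(z_min, z_max,
                    interest = c(seq(z0 - R, z0 + R, by = 0.2), 0), h,
                    pad = 0.25, h_max_um)
  nr <- length(rho) - 1; nz <- length(z) - 1   # cell counts
  rc <- (rho[-1] + rho[-length(rho)]) / 2
  zc <- (z[-1] + z[-length(z)]) / 2
  drho <- diff(rho); dz <- diff(z)
  # cell material map
  RC <- matrix(rc, nr, nz); ZC <- matrix(zc, nr, nz, byrow = TRUE)
  rad <- sqrt(RC^2 + (ZC - z0)^2)
  kmap <- matrix(model$k_water, nr, nz)
  kmap[ZC < 0] <- model$k_glass
  kmap[rad <= R] <- model$k_bead
  # volumes (um^3) and uniform shell source totalling the absorbed power;
  # each candidate cell is weighted by the fraction of its volume inside
  # the shell (3x3 subsampling) so the staircased shell carries no lumping
  # error
  vol <- (2 * pi * RC) * matrix(drho, nr, nz) * matrix(dz, nr, nz, byrow = TRUE)
  P_W <- model$absorbed_power_mW * 1e-3
  near <- which(abs(rad - (R - shell / 2)) < shell, arr.ind = TRUE)
  wshell <- matrix(0, nr, nz)
  if (nrow(near) == 0) stop("grid does not resolve the shell", call. = FALSE)
  offs <- c(-1, 0, 1) / 3
  for (kk in seq_len(nrow(near))) {
    i <- near[kk, 1]; j <- near[kk, 2]
    rs <- rc[i] + offs * drho[i]
    zs <- zc[j] + offs * dz[j]
    rr <- sqrt(outer(rs^2, (zs - z0)^2, "+"))
    wshell[i, j] <- mean(rr <= R & rr >= R - shell)
  }
  src <- matrix(0, nr, nz)
  tot_w <- sum(wshell * vol)
  src[] <- P_W * wshell * vol / tot_w  # W per cell

  idx <- function(i, j) (j - 1L) * nr + i
  n_cells <- nr * nz
  # Dirichlet ghost data from the analytic far field
  bnd_T <- function(rr, zz) {
    r <- sqrt(rr^2 + (zz - z0)^2)
    Ts <- model$surface_T_C; Tinf <- model$ambient_T_C
    ifelse(r <= R, Ts, Tinf + (Ts - Tinf) * R / r)
  }
  # assemble: for conductance, distances in metres so flux is in W/K
  um <- 1e-6
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  diag_acc <- numeric(n_cells)
  rhs <- as.numeric(src)
  # radial faces between (i,j) and (i+1,j)
  for (i in seq_len(nr - 1)) {
    kf <- 2 * kmap[i, ] * kmap[i + 1, ] / (kmap[i, ] + kmap[i + 1, ])
    area <- 2 * pi * rho[i + 1] * dz * um^2           # m^2 (rho[i+1] = shared face)
    dist <- (rc[i + 1] - rc[i]) * um
    g <- kf * area / dist
    a <- idx(i, seq_len(nz)); b <- idx(i + 1, seq_len(nz))
    ii <- c(ii, a, b); jj <- c(jj, b, a); vv <- c(vv, -g, -g)
    diag_acc[a] <- diag_acc[a] + g
    diag_acc[b] <- diag_acc[b] + g
  }
  # axial faces between (i,j) and (i,j+1)
  for (j in seq_len(nz - 1)) {
    kf <- 2 * kmap[, j] * kmap[, j + 1] / (kmap[, j] + kmap[, j + 1])
    area <- 2 * pi * rc * drho * um^2
    dist <- (zc[j + 1] - zc[j]) * um
    g <- kf * area / dist
    a <- idx(seq_len(nr), j); b <- idx(seq_len(nr), j + 1)
    ii <- c(ii, a, b); jj <- c(jj, b, a); vv <- c(vv, -g, -g)
    diag_acc[a] <- diag_acc[a] + g
    diag_acc[b] <- diag_acc[b] + g
  }
  # Dirichlet boundaries (outer rho, top z, bottom z); axis rho = 0 is a
  # natural zero-flux boundary (face area zero)
  for (j in seq_len(nz)) {   # outer radial face
    g <- kmap[nr, j] * (2 * pi * rho[nr + 1] * dz[j] * um^2) /
      ((rho[nr + 1] - rc[nr]) * um)
    a <- idx(nr, j)
    diag_acc[a] <- diag_acc[a] + g
    rhs[a] <- rhs[a] + g * bnd_T(rho[nr + 1], zc[j])
  }
  for (i in seq_len(nr)) {   # top and bottom
    g_top <- kmap[i, nz] * (2 * pi * rc[i] * drho[i] * um^2) /
      ((z[nz + 1] - zc[nz]) * um)
    a <- idx(i, nz)
    diag_acc[a] <- diag_acc[a] + g_top
    rhs[a] <- rhs[a] + g_top * bnd_T(rc[i], z[nz + 1])
    g_bot <- kmap[i, 1] * (2 * pi * rc[i] * drho[i] * um^2) /
      ((zc[1] - z[1]) * um)
    a <- idx(i, 1)
    diag_acc[a] <- diag_acc[a] + g_bot
    rhs[a] <- rhs[a] + g_bot * bnd_T(rc[i], z[1])
  }
  A <- Matrix::sparseMatrix(i = c(ii, seq_len(n_cells)),
                            j = c(jj, seq_len(n_cells)),
                            x = c(vv, diag_acc),
                            dims = c(n_cells, n_cells))
  Tsol <- tryCatch(as.numeric(Matrix::solve(A, rhs)),
                   error = function(e) stop("heat solve failed: ",
                                            conditionMessage(e), call. = FALSE))
  resid <- as.numeric(A %*% Tsol - rhs)
  if (max(abs(resid)) > 1e-6 * max(abs(rhs))) {
    stop(sprintf("heat solve not converged: residual %.3g", max(abs(resid))),
         call. = FALSE)
  }
  Tm <- matrix(Tsol, nr, nz)
  # lateral profile at bead-centre height
  jz <- which.min(abs(zc - z0))
  prof_x <- rc - R
  out <- data.frame(x_um = prof_x, T_C = Tm[, jz])
  class(out) <- c("temperature_profile", "data.frame")
  interior <- rad < (R - 2 * shell)
  attr(out, "interior_sd_C") <- stats::sd(Tm[interior])
  attr(out, "interior_mean_C") <- mean(Tm[interior])
  # discrete flux balance through the Dirichlet boundary vs source power
  bflux <- 0
  for (j in seq_len(nz)) {
    g <- kmap[nr, j] * (2 * pi * rho[nr + 1] * dz[j] * um^2) /
      ((rho[nr + 1] - rc[nr]) * um)
    bflux <- bflux + g * (Tm[nr, j] - bnd_T(rho[nr + 1], zc[j]))
  }
  for (i in seq_len(nr)) {
    g_top <- kmap[i, nz] * (2 * pi * rc[i] * drho[i] * um^2) /
      ((z[nz + 1] - zc[nz]) * um)
    bflux <- bflux + g_top * (Tm[i, nz] - bnd_T(rc[i], z[nz + 1]))
    g_bot <- kmap[i, 1] * (2 * pi * rc[i] * drho[i] * um^2) /
      ((zc[1] - z[1]) * um)
    bflux <- bflux + g_bot * (Tm[i, 1] - bnd_T(rc[i], z[1]))
  }
  attr(out, "flux_balance") <- bflux / P_W
  attr(out, "field") <- list(rho_um = rc, z_um = zc, T_C = Tm, k = kmap)
  attr(out, "grid_size") <- c(nr = nr, nz = nz)
  out
}

#' Infer the bead surface temperature from wax melting interfaces
#'
#' Alkane waxes of known melting point melt out to an interface where the
#' local temperature equals the melting point; the observed interface
#' distances therefore sample the temperature profile. This fits the
#' analytic profile `T(x) = T_inf + (Ts - T_inf) R/(R + x)` to the
#' (distance, melting temperature) observations by least squares in Ts.
#'
#' @param observations data.frame with `interface_distance_um` and
#'   `melting_T_C` (>= 1 row; >= 2 for a confidence interval)
#' @param model a [bead_thermal_model()] providing R and the ambient
#'   temperature
#' @param conf confidence level
#' @return list with `surface_T_C`, `ci`, `fitted` (per-observation
#'   predictions) and `n_obs`
#' @export
invert_wax_interfaces <- function(observations, model, conf = 0.95) {
  stopifnot(all(c("interface_distance_um", "melting_T_C") %in% names(observations)))
  n <- nrow(observations)
  if (n < 1) stop("need at least one observation", call. = FALSE)
  x <- observations$interface_distance_um
  Tm <- observations$melting_T_C
  if (n >= 3 && !all(diff(Tm[order(x)]) <= 0)) {
    warning("observations are not monotone decreasing with distance; ",
            "fit returned anyway", call. = FALSE)
  }
  R <- model$bead_radius_um; Tinf <- model$ambient_T_C
  w <- R / (R + x)
  if (n == 1) {
    Ts <- Tinf + (Tm - Tinf) / w
    return(list(surface_T_C = Ts, ci = c(NA_real_, NA_real_),
                fitted = Tm, n_obs = 1L))
  }
  fit <- stats::lm(I(Tm - Tinf) ~ 0 + w)
  Ts <- Tinf + unname(stats::coef(fit)[1])
  ci <- Tinf + as.numeric(suppressWarnings(stats::confint(fit, level = conf)))
  list(surface_T_C = Ts, ci = ci,
       fitted = Tinf + stats::fitted(fit), n_obs = n,
       residual_sd_C = stats::sd(stats::resid(fit)))
}

#' Alkane wax melting points
#'
#' Standard-reference melting points of the n-alkane waxes used as local
#' temperature probes (synthetic convenience table, not a measured
#' dataset): C19 (nonadecane) 32 C, C20 (icosane) 36.7 C, C22 (docosane)
#' 44 C.
#'
#' @return data.frame (`wax`, `carbon_number`, `melting_T_C`)
#' @export
alkane_melting_points <- function() {
  data.frame(wax = c("C19", "C20", "C22"),
             carbon_number = c(19L, 20L, 22L),
             melting_T_C = c(32, 36.7, 44))
}
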