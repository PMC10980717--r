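#' Physical constants and unit helpers
#'
#' All mechanics in this package use pN, nm, s and K. `kBT` returns the
#' thermal energy in pN.nm at a given absolute temperature (kB = 0.0138065
#' pN.nm/K). The package default temperature is 310 K, the working
#' temperature of the heated-bead instrument the analyses target.
#'
#' @param temperature_K absolute temperature in kelvin
#' @return thermal energy in pN.nm
#' @export
#' @examples
#' kBT(298)  # ~4.11 pN.nm
kBT <- function(temperature_K = 310) {
  stopifnot(is.numeric(temperature_K), temperature_K > 0)
  0.0138065 * temperature_K
}

# Boltzmann constant, pN.nm/K
.kB <- 0.0138065

# kcal/mol in pN.nm (1 kcal/mol = 6.9477 pN.nm), used by the sequence models
.kcal_per_mol_pNnm <- 6.9477

# gas constant in kcal/(mol.K)
.R_kcal <- 0.0019872

# default helical repeat (bp/turn) and axial rise (nm/bp) of B-DNA
.default_helical_repeat <- 10.5
.default_rise_nm <- 0.34

#' Drag coefficients for a sphere in a viscous fluid
#'
#' Translational drag gamma = 6 pi eta R (returned in pN.s/nm) and rotational
#' drag gamma_theta = 8 pi eta R^3 (returned in pN.nm.s), for a bead of
#' radius `bead_radius_um` in a fluid of viscosity `viscosity_Pa_s`.
#'
#' @param bead_radius_um bead radius in micrometres
#' @param viscosity_Pa_s dynamic viscosity in Pa.s (default 8.9e-4, water at
#'   25 C; the bead-local temperature is elevated in practice so this is
#'   configurable everywhere it is used)
#' @return drag coefficient (see description for units)
#' @export
drag_translational <- function(bead_radius_um, viscosity_Pa_s = 8.9e-4) {
  stopifnot(bead_radius_um > 0, viscosity_Pa_s > 0)
  # 6 pi eta R: N.s/m -> pN.s/nm is a factor 1e3; R in m is R_um * 1e-6
  6 * pi * viscosity_Pa_s * (bead_radius_um * 1e-6) * 1e3
}

#' @rdname drag_translational
#' @export
drag_rotational <- function(bead_radius_um, viscosity_Pa_s = 8.9e-4) {
  stopifnot(bead_radius_um > 0, viscosity_Pa_s > 0)
  # 8 pi eta R^3: N.m.s -> pN.nm.s is a factor 1e21; R^3 in m^3 is R_um^3 * 1e-18
  8 * pi * viscosity_Pa_s * bead_radius_um^3 * 1e3
}

.check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be positive and finite", name), call. = FALSE)
  }
  invisible(x)
}
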