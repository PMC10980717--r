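---
title: "Models and methods behind supercoilr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind supercoilr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(supercoilr)
```

`supercoilr` analyses single-molecule experiments in which a DNA tether is
held between a surface-anchored bead and an optically trapped magnetic bead,
stretched by the trap, twisted by a rotating magnetic field, and imaged in
fluorescence. This vignette records the models the package implements, the
parameters that matter, what the synthetic-data generators do and do not
emulate, and the numerical choices that were genuinely open.

## Units and constants

All mechanics use pN, nm, s, K. Thermal energy is `kBT(T) = 0.0138065 * T`
pN.nm; the package default temperature for sequence models is 310 K, because
NIR absorption in the magnetite shell of the trapped bead holds its
surroundings near body temperature (see the heat model below). Bead drag
uses water at 8.9e-4 Pa.s by default; since the bead-local temperature is
elevated, viscosity is configurable in every calibration entry point.

## Trap and angular calibration

An optically trapped bead in a harmonic well is an overdamped
Ornstein-Uhlenbeck process; its one-sided position power spectrum is the
Lorentzian `S(f) = A/(fc^2 + f^2)` with corner frequency
`fc = k/(2 pi gamma)`, `gamma = 6 pi eta R`. `fit_power_spectrum()`
estimates `(A, fc)` by maximising the Whittle likelihood of the raw
periodogram (bins are asymptotically independent exponentials), which avoids
the bias that least-squares fits of a noisy power spectrum pick up from
data-derived weights. The Welch-averaged spectrum (Hann window, 2^13-sample
segments, 50% overlap) is attached for inspection; the Welch settings are
the package's own choice of spectral estimator. A trace with no resolvable
knee in the fit band (e.g. white noise) is rejected rather than returning an
arbitrary corner.

The rotating-field ("magnetic tweezers") arm is calibrated from the phase
lag of bead rotation behind the coil drive. For an overdamped rotor with
angular stiffness `k_theta` and rotational drag `gamma_theta = 8 pi eta R^3`,
`tan(phi) = 2 pi f gamma_theta / k_theta`. `phase_shift()` band-passes the
response around the drive frequency and correlates it with its own time
reverse — for a tone, the correlation peak lag encodes twice the phase, and
noise incoherent under time reversal averages out — then resolves the
modulo-pi ambiguity and the sign against quadrature demodulation of the
drive channel. A lag of the response behind the drive is a positive phase.
The exact form of this reversal estimator is under-specified in the
experimental literature; the operational definition above is this package's
documented choice.

`fit_angular_stiffness()` regresses `tan(phase)` on frequency by default.
This is exact for the rotor model at any angle and reduces to the phase
slope in the small-angle limit, so with small-angle data it reports the same
gradient an ordinary phase regression would (a `use_tan = FALSE` switch
restores the plain regression). The stiffness is
`k_theta = 2 pi gamma_theta / |slope|`: the `2 pi` converts the per-Hz
gradient to per-angular-frequency. The widely quoted shorthand
`k_theta = 8 pi eta R^3 / |gradient|` reproduces numbers of the observed
magnitude (~1.1e3 pN.nm/rad for a 0.429 rad/Hz gradient on a 1.5 um bead)
only when that factor is included, so the package includes it and documents
the discrepancy instead of guessing.

`low_freq_power_fraction()` uses the plain periodogram, which satisfies
Parseval exactly, so "fraction of power below 60 Hz" means exactly that.

## DNA mechanics

Force-extension curves are fitted with the inextensible Marko-Siggia
interpolation

$$F(x) = \frac{k_BT}{P}\left[\frac{1}{4(1-x/L_c)^2} - \frac14 +
\frac{x}{L_c}\right],$$

appropriate because the low-stiffness trap limits forces to roughly 10 pN —
far below overstretching — so no stretch-modulus term is used. Parameter
errors come from refitting 1% subsamples 1000 times (`bootstrap_wlc()`).
Supercoiling density is `sigma = turns * h / N_bp` with helical repeat
`h = 10.5` bp/turn and rise 0.34 nm/bp (standard B-DNA values, both
configurable); for the 15.6 kbp construct the torsionally active region is
its 14.6 kbp centre, because the 500 bp handles are multiply attached.
Torque accumulates at `C/L` per turn with torsional modulus `C = 410` pN.nm.
Note that 200 turns at `C/L = 0.08` pN.nm/turn implies a peak torque of
16 pN.nm; a quoted maximum of +/-1.6 pN.nm for the same rotation count is
inconsistent with the same rod model, and the package follows `tau = C/L`.

Hat curves (extension versus applied turns at clamped force) are assembled
by `build_hat_curve()`, which aligns successive rotation segments on their
overlapping turn ranges — slow stage drift (~15 nm/s lateral, ~7 nm/s axial
is a realistic scale) shows up as inter-segment offsets over the minutes a
full curve takes. The symmetry score compares extension at matched
+/-|turns| normalised by the larger one-sided extension drop, so 0 is a
perfect mirror and 1 a one-sided plateau; the asymmetric label defaults to
a 0.25 threshold. Buckling is found as the knee of a two-segment
piecewise-linear fit, with the post/pre ratio of detrended residual
standard deviations reported as the fluctuation ratio (buckled at >= 1.5 by
default). These detector thresholds are configuration: the experiments
report the phenomena, not a detector.

## Puncta (plectoneme) quantification

Plectonemes condense DNA locally, so on an intercalator-stained tether they
appear as bright diffraction-limited puncta. `track_puncta()` detects local
maxima above a robust threshold, refines each with a least-squares 2D
Gaussian (sub-pixel centre, width, flat offset), and links detections by
greedy nearest neighbour — adequate for the few, well-separated puncta of
these tethers; no gap closing is attempted. Because intercalation is
uniform per bp, the punctum's share of the tether-integrated
background-corrected intensity estimates its bp content; the integration
disc also collects the stretch of plain tether running through it, so that
stretch's expected intensity (estimated per unit length away from the
punctum) is subtracted. Background is the median of an annulus 3-5 PSF
sigmas from the punctum, a recipe chosen here since "background-corrected"
alone does not fix one.

Mobility is summarised two ways on purpose: `rmsd_components()` reports
lag-1 frame-to-frame rms displacements projected parallel/perpendicular to
the tether axis (with `rmsd_tot` their quadrature sum), while
`estimate_D()` regresses the mean square displacement over lags 1..5
through the origin against `4 D lag dt`. Confined or tether-coupled motion
makes these two summaries mutually inconsistent under free-diffusion
arithmetic, and they are reported independently rather than reconciled.
The number of MSD lags regressed is configuration (default 5).

## Sequence models

*Curvature and plectoneme positioning.* A plectoneme tip is a tightly bent
loop, so intrinsically curved sequence lowers its nucleation energy.
`intrinsic_curvature()` sums dinucleotide wedge vectors (a
reverse-complement-symmetric consensus wedge table, magnitudes in degrees)
at the helical phase of each step and reports the windowed resultant in
degrees per helical turn. `plectoneme_probability()` converts tip curvature
to a Boltzmann weight `exp(-E_tip/kBT)` with
`E_tip = tip_energy_kBT * max(0, 1 - c/curvature_scale)` (defaults: 6 kBT,
20 deg/turn — an absolute scale, so sequences without curvature contrast
score uniformly), averages over admissible plectoneme sizes (the
per-regime size caps are data, taken from experimental plectoneme bp
content: 8.3 kbp at sigma >= 0.12, 6.7 kbp at 0.08 <= sigma < 0.12, 1.9 kbp
at sigma < 0), and normalises to a density. The internal scoring of the
published curvature model it emulates is not fully specified anywhere we
can implement from, so this scoring is a faithful-in-spirit reconstruction,
validated on constructions (planted curvature peaks, mirror symmetry,
uniformity) and reported as relative peak positions only.

*Duplex opening (SIDD).* `sidd_profile()` implements an equilibrium
statistical-mechanical model of superhelically driven strand separation.
A state is at most two disjoint open runs; its energy is

$$E = a\,r + \sum_{\mathrm{open}} b_i + \tfrac12 K_{\mathrm{eff}}(n)
\left(\alpha + n/h\right)^2,$$

with run-initiation cost `a = 10.84` kcal/mol, per-bp separation energies
`b_AT = 0.26`, `b_GC = 1.30` kcal/mol near 310 K and 0.1 M salt (SIDD
literature defaults, salt-adjusted by 0.2 kcal/mol per decade), and
`K = 2200 RT / N` the superhelical stress coefficient. Open regions can
absorb twist through an effective single-strand torsional stiffness
(1.8 kcal/mol/rad^2/bp, about an order of magnitude below the duplex),
which caps bubble growth; `K_eff` is the series combination of that
spring with `K`. The partition function enumerates all single runs up to
`max_run_len` (vectorised over start positions with prefix sums) plus all
pairs drawn from runs within a 12 kcal/mol ceiling of the minimum — the
two-run limit is consistent with the large initiation cost making a single
bubble dominant. The implementation is verified against an exhaustive
independent enumeration to 1e-10 on sequences up to 120 bp. Profiles for
sigma >= 0 are computed identically and are near zero (no driving stress).
The model assumes all torsional stress partitions into twist — no
plectoneme coexistence — and therefore over-predicts opening when
plectonemes are present; results are interpreted as relative peak
positions, via `compare_profiles()`.

## MD trajectory analysis

`detect_bubbles()` applies a three-part criterion per frame and bp: no
Watson-Crick H-bond, and the angular base-pair parameters (propeller,
opening, buckle) at least 2 baseline standard deviations from the relaxed
(sigma = 0) average; runs of at least 3 consecutive disrupted bp that
persist for more than 1 ns are bubbles. The "2 s.d." test is read as all
three parameters deviating jointly (the conservative reading; `criterion =
"any"` is available since the phrasing is ambiguous). Candidates sharing at
least one bp between consecutive frames are one bubble; a gap of a full
frame ends it — persistence bridging is not defined by the criterion and is
not attempted. The caller is verified exactly against a brute-force
run-scan. The relaxed baseline excludes 2 bp at each end, where fraying
dominates. Prevalence is the fraction of frames in the final 400 ns with at
least one bubble; its error is the s.d. of 200 bootstrap replicates of 1%
of frames.

`gen_torsion_restraints()` emits the full restraint specification for
holding a duplex at set tension and twist in an MD engine: fixed-end
positional restraints on terminal O3'/O5', per-strand linear distance
restraints to reference points for tension, angle pairs confining the
mobile end to the tether axis, excluded-volume psi angles (lower bound 90
degrees) on every phosphorus to mimic a bead, anti-bending dihedrals over a
60 bp GC buffer, and coplanarity dihedrals pinning the twist at the first
core bp and the next-to-last bp. For a 300 bp core the construct is 362 bp
(60 GC mobile buffer + core + 2 GC fixed). The reference points' exact
coordinates are not published; they are placed on the tether axis at a
configurable 2 nm standoff and recorded in the output. The specification is
validated structurally (every record resolves against the emitted
sequence); no MD is run.

## Heat model of the trapped bead

The magnetic bead absorbs NIR laser power in a thin (~100 nm) magnetite
shell just inside its surface. With the coverslip ignored, the steady state
is isothermal inside at `Ts = T_inf + P/(4 pi k_w R)` and decays as `1/r`
outside; `analytic_profile()` evaluates this closed form.
`numeric_profile()` solves steady conduction by finite volumes on an
axisymmetric (rho, z) grid — glass half-space below the coverslip, water
above, uniform volumetric source in the shell (cells weighted by their
subsampled shell-volume fraction) — taking the analytic far field as
Dirichlet data. The grid is uniformly fine (shell/4, i.e. 25 nm by default)
over the bead-bearing box and coarsens geometrically outside; the discrete
fluxes balance the source power exactly by construction, and the solution
matches the analytic profile within 2% when glass and water conductivities
are equal. The interior runs ~2 C above the nominal surface value because
the low-conductivity bead material supports a gradient across the
volumetric shell — a physical feature of the shell source, absent from the
surface-source analytic form. Conductivities (water 0.6, glass 1.0, bead
polymer 0.2 W/m/K) and the 25 C ambient are literature/room defaults, all
configurable. `invert_wax_interfaces()` fits the analytic profile to
(interface distance, melting point) observations of alkane waxes — shipped
melting points for C19/C20/C22 are standard reference values, not
measurements — and returns the bead surface temperature with a regression
CI.

## Synthetic data: what it does and does not emulate

Every pipeline input has a seeded generator that persists its ground truth,
so each estimator ships with a recovery test:

* `gen_trapped_bead_trace()` uses the exact OU update (exponential decay
  with matched innovation variance), not Euler, so there is no time-step
  bias at any sampling rate.
* `gen_driven_rotation_trace()` produces the rotor's steady-state response
  with additive detector noise.
* `gen_wlc_curve()` applies multiplicative force noise to the Marko-Siggia
  curve.
* `gen_hat_curve()` draws the piecewise-linear hat shapes (symmetric below
  the 0.6-0.7 pN critical force, negative-side plateau above) with Gaussian
  extension noise and optional linear drift.
* `gen_tether_movie()` renders the tether as a uniform line source and
  puncta as 2D Gaussians carrying their bp fraction of the total intensity,
  diffusing in 1D along the tether with reflecting ends, under
  Poisson + Gaussian pixel noise. Image origin is the top-left pixel
  centre, x along columns, y down rows, pixel centres at integer multiples
  of the 55 nm/px default pitch.
* `gen_bp_param_trajectory()` plants bubbles displaced >= 3 baseline s.d.
  with cleared H-bond flags on a Gaussian background.
* `simulate_force_clamp()` runs the discrete stage-repositioning control
  loop; the experimental loop gains are not published, so the defaults
  (kp = 0.02, ki = 0.001 at 100 Hz) are tuned to the ~1 s response the
  instrument achieves, and a unit proportional gain corrects in one step by
  construction.

None of the generators model photophysics (bleaching, blinking), EMCCD gain,
3D PSFs, aliasing/anti-alias filters, QPD nonlinearity beyond a linear
conversion, or stress-relaxation hysteresis. Passing recovery tests
therefore demonstrates correctness of the estimators under the stated
statistical structure, not robustness to every artefact of real data.

## Problem sizes and test design

The test-suite and acceptance workloads are sized for a laptop-class run:
spectral calibration uses 16 s at 50 kHz (8e5 samples), diffusion recovery
1000 tracks of 41 frames, SIDD oracle equivalence up to 120 bp with
single-run states, rendered movies a few tens of frames at 48 x 128 px, and
the heat solver ~3e4 cells (12 bead radii of domain). These reproduce the
worked-example numbers and recovery tolerances; full-scale inputs (e.g.
15 kbp opening profiles) run through the same code paths with larger
`max_run_len` and domain settings.
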