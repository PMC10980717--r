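# Dinucleotide wedge angles (degrees per step), consensus values from the
# trinucleotide/dinucleotide wedge-model literature (Bolshoy et al.-style
# set). The table is reverse-complement symmetric, so a curvature profile
# mirrors when the sequence is reverse-complemented.
.wedge_deg <- c(AA = 7.2, TT = 7.2, AC = 1.1, GT = 1.1, AG = 8.4, CT = 8.4,
                AT = 2.6, CA = 3.5, TG = 3.5, CC = 2.1, GG = 2.1, CG = 6.7,
                GA = 5.3, TC = 5.3, GC = 5.0, TA = 0.9)

.check_sequence <- function(seq) {
  seq <- toupper(seq)
  if (length(seq) == 1 && nchar(seq) > 1) seq <- strsplit(seq, "")[[1]]
  bad <- !(seq %in% c("A", "C", "G", "T"))
  if (any(bad)) {
    stop("sequence contains characters outside {A,C,G,T}: ",
         paste(unique(seq[bad]), collapse = ","), call. = FALSE)
  }
  seq
}

#' Intrinsic (static) curvature profile of a DNA sequence
#'
#' Sums dinucleotide-step deflection vectors, each of magnitude given by a
#' published wedge-angle table and direction set by the accumulated helical
#' phase (one turn per `helical_repeat` bp), over a sliding window. The
#' modulus of the resultant is the net static bend of the window, reported
#' as degrees per helical turn. Phased A-tracts (period ~10.5 bp) add
#' coherently and produce curvature maxima; homopolymers give a flat
#' profile.
#'
#' @param seq DNA sequence (string or character vector over A,C,G,T)
#' @param window_bp sliding window (>= 10 bp)
#' @param helical_repeat helical repeat in bp/turn
#' @return data.frame (`position`, `curvature_deg_per_turn`), positions
#'   1-based at window centres; length = sequence length (NA where the
#'   window does not fit)
#' @export
intrinsic_curvature <- function(seq, window_bp = 120, helical_repeat = 10.5) {
  seq <- .check_sequence(seq)
  n <- length(seq)
  if (window_bp < 10) stop("window must be at least 10 bp", call. = FALSE)
  if (n < window_bp + 1) stop("sequence shorter than the window", call. = FALSE)
  steps <- paste0(seq[-n], seq[-1])
  w <- .wedge_deg[steps]
  phase <- 2 * pi * (seq_len(n - 1) - 1) / helical_repeat
  vx <- w * cos(phase); vy <- w * sin(phase)
  cx <- cumsum(vx); cy <- cumsum(vy)
  # resultant over windows of window_bp steps
  nw <- (n - 1) - window_bp + 1
  sx <- cx[window_bp:(n - 1)] - c(0, cx)[window_bp:(n - 1) - window_bp + 1]
  sy <- cy[window_bp:(n - 1)] - c(0, cy)[window_bp:(n - 1) - window_bp + 1]
  mag <- sqrt(sx^2 + sy^2) * helical_repeat / window_bp
  centre <- floor(window_bp / 2) + seq_len(nw)
  out <- data.frame(position = seq_len(n), curvature_deg_per_turn = NA_real_)
  out$curvature_deg_per_turn[centre] <- mag
  out
}

# Default plectoneme size cutoffs (bp) per supercoiling regime: the largest
# plectoneme admitted when averaging over sizes, set from experimental
# estimates of plectoneme bp content at each sigma.
.plectoneme_size_cutoff <- function(sigma) {
  if (sigma >= 0.12) 8300 else if (sigma >= 0.08) 6700 else if (sigma < 0) 1900
  else 1000
}

#' Plectoneme-centre probability density from intrinsic curvature
#'
#' A curvature-biased tip model: a plectoneme tip is a tightly bent loop,
#' so its bending energy at centre i is reduced where the sequence is
#' intrinsically curved. Each candidate centre is scored by the Boltzmann
#' weight exp(-E_tip/kBT) with
#' `E_tip(i) = tip_energy_kBT * max(0, 1 - c_tip(i) / curvature_scale)`,
#' where `c_tip` is the tip-window-averaged intrinsic curvature in degrees
#' per helical turn and `curvature_scale` the static bend (default 20
#' deg/turn) at which the tip loop costs no extra energy - an absolute
#' scale, so a sequence without curvature contrast scores uniformly.
#' The weight is averaged over plectoneme sizes
#' from `min_size_bp` up to `size_cutoff_bp` (only sizes that fit within
#' the sequence at that centre count), then normalised to a probability
#' density over feasible centres. The size cutoffs default to 8.3 kbp for
#' sigma >= 0.12, 6.7 kbp for 0.08 <= sigma < 0.12, 1.9 kbp for sigma < 0
#' and 1 kbp otherwise.
#'
#' @param seq DNA sequence
#' @param sigma supercoiling density (selects the default size cutoff)
#' @param size_cutoff_bp largest plectoneme size; must be below the
#'   sequence length
#' @param min_size_bp smallest plectoneme admitted
#' @param tip_window_bp window over which tip curvature is averaged
#' @param tip_energy_kBT bending-energy scale of an uncurved tip, in kBT
#' @param curvature_scale static curvature (deg/turn) that fully offsets
#'   the tip bending cost
#' @param curvature_window_bp window for [intrinsic_curvature()]
#' @return object of class `plectoneme_profile`: data.frame (`position`,
#'   `density`) with the density summing to 1 over feasible centres (NA
#'   where no plectoneme fits), plus the settings as attributes
#' @export
plectoneme_probability <- function(seq, sigma, size_cutoff_bp = NULL,
                                   min_size_bp = 100, tip_window_bp = 75,
                                   tip_energy_kBT = 6, curvature_scale = 20,
                                   curvature_window_bp = 120) {
  seq <- .check_sequence(seq)
  n <- length(seq)
  if (is.null(size_cutoff_bp)) {
    # regime default, clamped for sequences shorter than the cutoff itself
    size_cutoff_bp <- min(.plectoneme_size_cutoff(sigma), n - 1)
  } else if (size_cutoff_bp >= n) {
    stop("size cutoff must be below the sequence length", call. = FALSE)
  }
  curv <- intrinsic_curvature(seq, curvature_window_bp)$curvature_deg_per_turn
  # tip-window running mean of the curvature (NA-padded ends filled with the
  # nearest defined value so terminal centres are still scored)
  filled <- curv
  defined <- which(!is.na(filled))
  filled[seq_len(min(defined) - 1)] <- filled[min(defined)]
  filled[seq(max(defined) + 1, length.out = n - max(defined))] <- filled[max(defined)]
  k <- max(1L, round(tip_window_bp))
  kern <- rep(1 / k, k)
  tipc <- stats::filter(filled, kern, sides = 2)
  tipc[is.na(tipc)] <- filled[is.na(tipc)]
  chat <- pmin(as.numeric(tipc) / curvature_scale, 1)
  weight <- exp(-tip_energy_kBT * (1 - chat))
  # feasibility: centre i can host a plectoneme of size s iff s/2 fits each side
  pos <- seq_len(n)
  room <- 2 * pmin(pos - 1, n - pos)
  feasible <- room >= min_size_bp
  # average weight over feasible sizes; the weight is size-independent, so
  # the average equals the weight wherever at least one size fits (this
  # keeps a uniform-curvature sequence uniform rather than edge-biased)
  dens <- ifelse(feasible, weight, NA_real_)
  dens <- dens / sum(dens, na.rm = TRUE)
  out <- data.frame(position = pos, density = dens)
  attr(out, "sigma") <- sigma
  attr(out, "size_cutoff_bp") <- size_cutoff_bp
  attr(out, "tip_energy_kBT") <- tip_energy_kBT
  attr(out, "min_size_bp") <- min_size_bp
  class(out) <- c("plectoneme_profile", "data.frame")
  out
}

#' Default SIDD energy parameters
#'
#' Energetics of superhelically driven duplex destabilisation, from the
#' statistical-mechanics SIDD literature: `a_kcal` is the cost of
#' initiating a run of strand separation (10.84 kcal/mol, independent of
#' run length); `b_AT_kcal`/`b_GC_kcal` are per-bp separation free energies
#' near 310 K at 0.1 M salt; `K_factor` sets the quadratic superhelical
#' stress coefficient `K = K_factor * RT / N` (kcal/mol per turn^2);
#' `c_ss_kcal` is the effective torsional stiffness of an open (single-
#' stranded) region in kcal/mol per rad^2 per bp - roughly an order of
#' magnitude below the ~170 kcal/mol/rad^2/bp of the intact duplex - which
#' lets open regions absorb some twist; `salt_slope_kcal` adjusts the
#' separation energies by `salt_slope_kcal * log10(salt_M / 0.1)`.
#'
#' @return named list of defaults, overridable via the `energy` argument of
#'   [sidd_profile()]
#' @export
sidd_params <- function() {
  list(a_kcal = 10.84, b_AT_kcal = 0.26, b_GC_kcal = 1.30,
       K_factor = 2200, c_ss_kcal = 1.8, salt_slope_kcal = 0.2)
}

# Effective quadratic stress coefficient when n bp are open: the open
# region (torsional stiffness c_ss per bp) in series with the residual
# superhelical stress spring K.
.K_eff <- function(n, K, c_ss) {
  if (c_ss <= 0) return(rep(K, length(n)))
  Ct <- c_ss * (2 * pi)^2          # kcal/mol per turn^2 per bp
  ifelse(n == 0, K, K * (Ct / n) / (K + Ct / n))
}

#' Superhelical duplex-opening probability profile (SIDD)
#'
#' Equilibrium per-bp probability of being inside a denatured run for a
#' circular-equivalent domain under superhelical stress. States are
#' configurations of at most `max_runs` disjoint open runs; a state with
#' runs of total length n at linking difference alpha = sigma N / h has
#' energy
#' \deqn{E = a r + \sum_{open} b_i + \tfrac12 K_{eff}(n)\,(\alpha + n/h)^2}
#' where `a` is the initiation cost per run, `b_i` the per-bp separation
#' energy (AT vs GC), and the quadratic term the residual superhelical
#' stress after the open bp untwist (with partition of twist into the open
#' region through its torsional stiffness, see [sidd_params()]). The
#' profile is the Boltzmann-weighted occupancy of each bp over all states
#' within `ceiling_kcal` of the minimum-energy state.
#'
#' @param seq DNA sequence (<= ~20 kbp; longer inputs are refused - split
#'   the domain instead)
#' @param sigma supercoiling density; opening needs sigma < 0 (sigma >= 0
#'   returns the near-zero equilibrium profile with a note attribute)
#' @param salt_M monovalent salt (default 0.1)
#' @param temperature_K temperature (default 310)
#' @param max_runs maximum simultaneous open runs (1 or 2; default 2)
#' @param max_run_len largest run length enumerated
#' @param ceiling_kcal energy ceiling above the minimum for states kept in
#'   the two-run enumeration shortlist
#' @param helical_repeat bp per turn of the intact duplex
#' @param energy overrides for [sidd_params()]
#' @return object of class `opening_profile`: data.frame (`position`,
#'   `p_open`), with attributes `run_length_mean` (probability-weighted
#'   mean open-run length), `run_table`, `settings`
#' @export
sidd_profile <- function(seq, sigma, salt_M = 0.1, temperature_K = 310,
                         max_runs = 2, max_run_len = 400,
                         ceiling_kcal = 12, helical_repeat = 10.5,
                         energy = list()) {
  seq <- .check_sequence(seq)
  n <- length(seq)
  if (n < 50) stop("sequence too short for a meaningful profile (need >= 50 bp)",
                   call. = FALSE)
  if (n > 20000) {
    stop("sequence longer than 20 kbp; run sidd_profile on subdomains instead",
         call. = FALSE)
  }
  stopifnot(max_runs %in% c(1L, 2L))
  par <- utils::modifyList(sidd_params(), energy)
  RT <- .R_kcal * temperature_K
  salt_shift <- par$salt_slope_kcal * log10(salt_M / 0.1)
  b <- ifelse(seq %in% c("A", "T"), par$b_AT_kcal, par$b_GC_kcal) + salt_shift
  K <- par$K_factor * RT / n
  alpha <- sigma * n / helical_repeat
  Lmax <- min(max_run_len, n - 1)
  bcum <- c(0, cumsum(b))
  # single-run states, vectorised per length
  stress0 <- 0.5 * K * alpha^2         # closed-state stress energy
  run_E <- vector("list", Lmax)
  for (len in seq_len(Lmax)) {
    starts <- seq_len(n - len + 1)
    bsum <- bcum[starts + len] - bcum[starts]
    E <- par$a_kcal + bsum +
      0.5 * .K_eff(len, K, par$c_ss_kcal) * (alpha + len / helical_repeat)^2
    run_E[[len]] <- E
  }
  Emin1 <- min(vapply(run_E, min, 0), stress0)
  # accumulate occupancy and run statistics
  dprof <- numeric(n + 1)
  Z <- exp(-(stress0 - Emin1) / RT)
  run_len_w <- 0; run_w <- 0
  run_rows <- list()
  for (len in seq_len(Lmax)) {
    wgt <- exp(-(run_E[[len]] - Emin1) / RT)
    Z <- Z + sum(wgt)
    starts <- seq_len(n - len + 1)
    # interval add via difference array
    dprof[starts] <- dprof[starts] + wgt
    dprof[starts + len] <- dprof[starts + len] - wgt
    run_len_w <- run_len_w + len * sum(wgt)
    run_w <- run_w + sum(wgt)
    keep <- which(run_E[[len]] <= Emin1 + ceiling_kcal)
    if (length(keep)) {
      run_rows[[length(run_rows) + 1]] <-
        data.frame(start = starts[keep], length = len, E = run_E[[len]][keep])
    }
  }
  shortlist <- if (length(run_rows)) do.call(rbind, run_rows) else
    data.frame(start = integer(), length = integer(), E = numeric())
  # two-run states from the shortlist (disjoint, separated by >= 1 closed bp)
  if (max_runs == 2L && nrow(shortlist) > 1) {
    if (nrow(shortlist) > 1500) {
      shortlist <- shortlist[order(shortlist$E)[seq_len(1500)], ]
    }
    m <- nrow(shortlist)
    ii <- rep(seq_len(m), times = m); jj <- rep(seq_len(m), each = m)
    sel <- ii < jj
    ii <- ii[sel]; jj <- jj[sel]
    s1 <- shortlist$start[ii]; l1 <- shortlist$length[ii]
    s2 <- shortlist$start[jj]; l2 <- shortlist$length[jj]
    disjoint <- (s1 + l1 < s2) | (s2 + l2 < s1)
    ii <- ii[disjoint]; jj <- jj[disjoint]
    if (length(ii)) {
      s1 <- shortlist$start[ii]; l1 <- shortlist$length[ii]
      s2 <- shortlist$start[jj]; l2 <- shortlist$length[jj]
      b1 <- bcum[s1 + l1] - bcum[s1]; b2 <- bcum[s2 + l2] - bcum[s2]
      ntot <- l1 + l2
      E2 <- 2 * par$a_kcal + b1 + b2 +
        0.5 * .K_eff(ntot, K, par$c_ss_kcal) * (alpha + ntot / helical_repeat)^2
      w2 <- exp(-(E2 - Emin1) / RT)
      Z <- Z + sum(w2)
      add <- function(s, l, w) {
        su <- rowsum(w, s)
        i1 <- as.integer(rownames(su))
        dprof[i1] <<- dprof[i1] + as.numeric(su)
        eu <- rowsum(w, s + l)
        i2 <- as.integer(rownames(eu))
        dprof[i2] <<- dprof[i2] - as.numeric(eu)
      }
      add(s1, l1, w2); add(s2, l2, w2)
      run_len_w <- run_len_w + sum((l1 + l2) * w2)
      run_w <- run_w + 2 * sum(w2)
    }
  }
  p <- cumsum(dprof[seq_len(n)]) / Z
  out <- opening_profile(p,
                         run_length_mean = if (run_w > 0) run_len_w / run_w else NA_real_,
                         settings = list(sigma = sigma, salt_M = salt_M,
                                         temperature_K = temperature_K,
                                         alpha = alpha, K = K, params = par,
                                         max_runs = max_runs,
                                         max_run_len = Lmax))
  if (sigma >= 0) attr(out, "note") <- "sigma >= 0: no driving stress, profile near zero"
  out
}

#' Construct an opening profile
#'
#' Container for a per-bp duplex-opening probability profile plus the
#' run-length statistics needed by [expected_bubble_size()].
#'
#' @param p_open per-bp opening probabilities in [0,1]
#' @param run_length_mean probability-weighted mean open-run length, or a
#'   `run_table` data.frame (`length`, `weight`) from which it is computed
#' @param run_table optional data.frame (`length`, `weight`)
#' @param settings optional list of model settings
#' @return data.frame of class `opening_profile`
#' @export
opening_profile <- function(p_open, run_length_mean = NULL, run_table = NULL,
                            settings = NULL) {
  stopifnot(all(p_open >= -1e-12), all(p_open <= 1 + 1e-12))
  out <- data.frame(position = seq_along(p_open), p_open = pmin(pmax(p_open, 0), 1))
  if (is.null(run_length_mean) && !is.null(run_table)) {
    run_length_mean <- stats::weighted.mean(run_table$length, run_table$weight)
  }
  attr(out, "run_length_mean") <- run_length_mean
  attr(out, "run_table") <- run_table
  attr(out, "settings") <- settings
  class(out) <- c("opening_profile", "data.frame")
  out
}

#' Expected denaturation-bubble size
#'
#' Probability-weighted mean length (nt) of the open runs underlying an
#' opening profile.
#'
#' @param profile an `opening_profile`
#' @return expected bubble size in nt
#' @export
expected_bubble_size <- function(profile) {
  stopifnot(inherits(profile, "opening_profile"))
  m <- attr(profile, "run_length_mean")
  if (is.null(m) || !is.finite(m)) {
    if (all(profile$p_open == 0)) {
      warning("all-zero opening profile: expected bubble size undefined",
              call. = FALSE)
      return(NA_real_)
    }
    stop("profile carries no run-length statistics", call. = FALSE)
  }
  m
}

#' Match peaks between a predicted profile and a measured trace
#'
#' Both inputs are mapped to bp coordinates and normalised to unit maximum;
#' a measured intensity trace can be smoothed with a regularised cubic
#' smoothing spline first. Local maxima above `min_height` (of the
#' normalised profile) separated by at least `min_separation_bp` are
#' matched greedily between the two profiles and the offsets reported as a
#' percentage of the sequence length.
#'
#' @param profile_a,profile_b numeric vectors over bp positions (an
#'   `opening_profile`/`plectoneme_profile` is accepted), assumed on the
#'   same coordinate system
#' @param smooth_b spline-smooth profile_b before peak finding (use for a
#'   measured intensity trace)
#' @param min_height minimum normalised peak height
#' @param min_separation_bp minimum distance between reported peaks
#' @return data.frame (`peak_a_bp`, `peak_b_bp`, `offset_bp`,
#'   `offset_percent`); zero rows when either profile has no peaks
#' @export
compare_profiles <- function(profile_a, profile_b, smooth_b = FALSE,
                             min_height = 0.2, min_separation_bp = 50) {
  getv <- function(p) {
    if (inherits(p, "opening_profile")) return(p$p_open)
    if (inherits(p, "plectoneme_profile")) return(p$density)
    as.numeric(p)
  }
  a <- getv(profile_a); bvec <- getv(profile_b)
  stopifnot(length(a) == length(bvec))
  n <- length(a)
  if (smooth_b) {
    ok <- is.finite(bvec)
    sp <- stats::smooth.spline(which(ok), bvec[ok])
    bvec <- stats::predict(sp, seq_len(n))$y
  }
  find_peaks <- function(v) {
    v[!is.finite(v)] <- 0
    v <- v - min(v); mx <- max(v)
    if (mx <= 0) return(integer(0))
    v <- v / mx
    cand <- which(diff(sign(diff(v))) == -2) + 1
    cand <- cand[v[cand] >= min_height]
    cand <- cand[order(v[cand], decreasing = TRUE)]
    keep <- integer(0)
    for (p in cand) {
      if (all(abs(p - keep) >= min_separation_bp)) keep <- c(keep, p)
    }
    sort(keep)
  }
  pa <- find_peaks(a); pb <- find_peaks(bvec)
  if (length(pa) == 0 || length(pb) == 0) {
    return(data.frame(peak_a_bp = integer(), peak_b_bp = integer(),
                      offset_bp = numeric(), offset_percent = numeric()))
  }
  rows <- lapply(pa, function(p) {
    j <- pb[which.min(abs(pb - p))]
    data.frame(peak_a_bp = p, peak_b_bp = j, offset_bp = j - p,
               offset_percent = 100 * abs(j - p) / n)
  })
  do.call(rbind, rows)
}

#' The reverse complement of a DNA sequence
#' @param seq character vector or string over A,C,G,T
#' @return character vector of the reverse complement
#' @export
reverse_complement <- function(seq) {
  seq <- .check_sequence(seq)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rev(unname(comp[seq]))
}
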