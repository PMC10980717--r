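# Independent brute-force oracles used by the property tests. These are
# deliberately written as plain double loops over explicit state
# enumerations, sharing no code with the package implementations.

# Exhaustive single-run SIDD enumeration: every (start, length) open window.
oracle_sidd_single_run <- function(seq, sigma, temperature_K = 310,
                                   salt_M = 0.1, helical_repeat = 10.5,
                                   params = sidd_params(), max_run_len = Inf) {
  seqv <- strsplit(toupper(seq), "")[[1]]
  n <- length(seqv)
  RT <- 0.0019872 * temperature_K
  b <- ifelse(seqv %in% c("A", "T"), params$b_AT_kcal, params$b_GC_kcal) +
    params$salt_slope_kcal * log10(salt_M / 0.1)
  K <- params$K_factor * RT / n
  alpha <- sigma * n / helical_repeat
  Ct <- params$c_ss_kcal * (2 * pi)^2
  E_closed <- 0.5 * K * alpha^2
  starts <- integer(0); lens <- integer(0); Es <- numeric(0)
  for (s in 1:n) {
    for (l in 1:min(n - s + 1, max_run_len)) {
      Keff <- if (params$c_ss_kcal <= 0) K else K * (Ct / l) / (K + Ct / l)
      E <- params$a_kcal + sum(b[s:(s + l - 1)]) +
        0.5 * Keff * (alpha + l / helical_repeat)^2
      starts <- c(starts, s); lens <- c(lens, l); Es <- c(Es, E)
    }
  }
  Emin <- min(c(Es, E_closed))
  w <- exp(-(Es - Emin) / RT)
  Z <- exp(-(E_closed - Emin) / RT) + sum(w)
  p <- numeric(n)
  for (i in seq_along(starts)) {
    idx <- starts[i]:(starts[i] + lens[i] - 1)
    p[idx] <- p[idx] + w[i]
  }
  list(p_open = p / Z,
       run_length_mean = sum(lens * w) / sum(w))
}

# Per-frame run-scan bubble caller: literal scan over every frame and bp.
oracle_detect_bubbles <- function(traj, baseline, min_len_bp = 3,
                                  z_thresh = 2, min_dur_ns = 1) {
  nf <- traj$n_frames; nb <- traj$n_bp
  disrupted <- matrix(FALSE, nf, nb)
  for (fr in 1:nf) for (bp in 1:nb) {
    devs <- sapply(c("propeller", "opening", "buckle"), function(p) {
      abs(traj[[p]][fr, bp] - baseline$mean[[p]]) >= z_thresh * baseline$sd[[p]]
    })
    disrupted[fr, bp] <- !traj$hbond[fr, bp] && all(devs)
  }
  # runs per frame
  runs <- list()
  for (fr in 1:nf) {
    bp <- 1
    while (bp <= nb) {
      if (disrupted[fr, bp]) {
        e <- bp
        while (e < nb && disrupted[fr, e + 1]) e <- e + 1
        if (e - bp + 1 >= min_len_bp) {
          runs[[length(runs) + 1]] <- c(fr, bp, e)
        }
        bp <- e + 1
      } else bp <- bp + 1
    }
  }
  if (length(runs) == 0) return(data.frame(start_bp = integer(),
                                           length_bp = integer(),
                                           t_start_ns = numeric(),
                                           duration_ns = numeric()))
  rn <- do.call(rbind, runs)
  # merge chains of overlapping runs across consecutive frames
  assigned <- rep(0L, nrow(rn)); gid <- 0L
  for (i in seq_len(nrow(rn))) {
    if (assigned[i] > 0) next
    gid <- gid + 1L; assigned[i] <- gid
    members <- i
    repeat {
      grew <- FALSE
      for (j in seq_len(nrow(rn))) {
        if (assigned[j] > 0) next
        for (k in members) {
          if (abs(rn[j, 1] - rn[k, 1]) == 1 &&
              rn[j, 2] <= rn[k, 3] && rn[j, 3] >= rn[k, 2]) {
            assigned[j] <- gid; members <- c(members, j); grew <- TRUE; break
          }
        }
      }
      if (!grew) break
    }
  }
  out <- NULL
  for (g in seq_len(gid)) {
    mem <- rn[assigned == g, , drop = FALSE]
    dur <- (max(mem[, 1]) - min(mem[, 1]) + 1) * traj$dt_ns
    if (dur > min_dur_ns) {
      out <- rbind(out, data.frame(start_bp = min(mem[, 2]),
                                   length_bp = max(mem[, 3]) - min(mem[, 2]) + 1,
                                   t_start_ns = (min(mem[, 1]) - 1) * traj$dt_ns,
                                   duration_ns = dur))
    }
  }
  if (is.null(out)) return(data.frame(start_bp = integer(), length_bp = integer(),
                                      t_start_ns = numeric(), duration_ns = numeric()))
  out[order(out$t_start_ns, out$start_bp), , drop = FALSE]
}

# Direct wedge-vector summation for a single window of a sequence (degrees
# per helical turn), used to validate the vectorised curvature profile.
oracle_curvature_window <- function(seqv, start, window_bp,
                                    helical_repeat = 10.5) {
  wedges <- c(AA = 7.2, TT = 7.2, AC = 1.1, GT = 1.1, AG = 8.4, CT = 8.4,
              AT = 2.6, CA = 3.5, TG = 3.5, CC = 2.1, GG = 2.1, CG = 6.7,
              GA = 5.3, TC = 5.3, GC = 5.0, TA = 0.9)
  vx <- 0; vy <- 0
  for (j in start:(start + window_bp - 1)) {
    st <- paste0(seqv[j], seqv[j + 1])
    th <- 2 * pi * (j - 1) / helical_repeat
    vx <- vx + wedges[[st]] * cos(th)
    vy <- vy + wedges[[st]] * sin(th)
  }
  sqrt(vx^2 + vy^2) * helical_repeat / window_bp
}

# The 300 bp duplex sequence used as the in-silico fixture throughout.
md_core_sequence <- function() {
  paste0("TGCAAGATTTGCAACCAGGCAGACTTAGCGGTAGGTCCTAGTGCAGCGGG",
         "ACTTTTTTTCTATAGTCGTTGAGAGGAGGAGTCGTCAGACCAGATACCTT",
         "TGATGTCCTGATTGGAAGGACCGTTGGCCCCCGACCCTTAGACAGTGTAC",
         "TCAGTTCTATAAACGAGCTATTAGATATGAGATCCGTAGATTGAAAAGGG",
         "TGACGGAATTCGCCCGGACGCAAAAGACGGACAGCTAGGTATCCTGAGCA",
         "CGGTTGCGCGTCCGAATCAAGCTCCTCTTTACAGGCCCCGGTTTCTGTTG")
}
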