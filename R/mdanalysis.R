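#' Construct a base-pair-parameter trajectory
#'
#' Per-frame, per-bp grid of the three angular base-pair parameters
#' (propeller twist, opening, buckle; degrees) and the Watson-Crick H-bond
#' presence flag, as produced by nucleic-acid structure analysis of an MD
#' trajectory.
#'
#' @param propeller,opening,buckle numeric matrices `[n_frames, n_bp]`
#' @param hbond logical matrix, TRUE where at least one WC H-bond is present
#' @param dt_ns time per frame in ns (> 0)
#' @return object of class `bp_trajectory`
#' @export
bp_trajectory <- function(propeller, opening, buckle, hbond, dt_ns) {
  dims <- dim(propeller)
  for (m in list(opening, buckle, hbond)) {
    if (!identical(dim(m), dims)) stop("parameter grids must be rectangular ",
                                       "and congruent", call. = FALSE)
  }
  .check_positive(dt_ns, "dt_ns")
  structure(list(propeller = propeller, opening = opening, buckle = buckle,
                 hbond = hbond, dt_ns = dt_ns,
                 n_frames = dims[1], n_bp = dims[2]),
            class = "bp_trajectory")
}

#' @export
print.bp_trajectory <- function(x, ...) {
  cat(sprintf("<bp_trajectory> %d frames x %d bp, dt = %g ns (%.4g ns total)\n",
              x$n_frames, x$n_bp, x$dt_ns, x$n_frames * x$dt_ns))
  invisible(x)
}

#' Read a per-base-pair structural parameter table
#'
#' Accepts two tabular dialects. The TSV dialect is a headered
#' tab-separated table with columns `frame`, `bp`, `propeller_deg`,
#' `opening_deg`, `buckle_deg`, `wc_hbonds`. The nastruct-style dialect is
#' a whitespace table whose header line begins with `#Frame` and carries
#' columns `BP`, `Opening`, `Propeller`, `Buckle`, `HB` (case-insensitive
#' prefixes are matched). The H-bond flag is `wc_hbonds >= 1`. The grid
#' must be rectangular: every frame must report the same base pairs.
#'
#' @param path file path
#' @param dt_ns time per frame in ns (the tables carry frame indices only)
#' @return a [bp_trajectory()]
#' @export
read_bp_params <- function(path, dt_ns = 0.1) {
  first <- readLines(path, n = 1L)
  if (grepl("^#Frame", first, ignore.case = TRUE)) {
    hdr <- strsplit(sub("^#", "", first), "\\s+")[[1]]
    df <- utils::read.table(path, col.names = hdr, comment.char = "",
                            skip = 1)
    names(df) <- tolower(names(df))
    pick <- function(prefix) {
      hit <- grep(paste0("^", prefix), names(df))
      if (length(hit) == 0) stop("nastruct-style table missing a column ",
                                 "starting with '", prefix, "'", call. = FALSE)
      df[[hit[1]]]
    }
    df <- data.frame(frame = pick("frame"), bp = pick("bp"),
                     propeller_deg = pick("prop"), opening_deg = pick("open"),
                     buckle_deg = pick("buck"), wc_hbonds = pick("hb"))
  } else {
    df <- utils::read.delim(path)
    need <- c("frame", "bp", "propeller_deg", "opening_deg", "buckle_deg",
              "wc_hbonds")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("bp-parameter TSV missing columns: ",
                           paste(miss, collapse = ", "), call. = FALSE)
  }
  frames <- sort(unique(df$frame))
  bps <- sort(unique(df$bp))
  counts <- table(df$frame)
  bad <- names(counts)[counts != length(bps)]
  if (length(bad)) {
    stop("ragged grid: frame ", bad[1], " reports ", counts[bad[1]],
         " base pairs, expected ", length(bps), call. = FALSE)
  }
  if (nrow(df) != length(frames) * length(bps)) {
    stop("ragged grid: duplicated or missing (frame, bp) records", call. = FALSE)
  }
  shape <- function(col) {
    m <- matrix(NA_real_, length(frames), length(bps))
    m[cbind(match(df$frame, frames), match(df$bp, bps))] <- col
    m
  }
  bp_trajectory(propeller = shape(df$propeller_deg),
                opening = shape(df$opening_deg),
                buckle = shape(df$buckle_deg),
                hbond = shape(as.numeric(df$wc_hbonds)) >= 1,
                dt_ns = dt_ns)
}

#' Write a trajectory to the TSV dialect of [read_bp_params()]
#' @param traj a `bp_trajectory`
#' @param path file path
#' @export
write_bp_params <- function(traj, path) {
  stopifnot(inherits(traj, "bp_trajectory"))
  grid <- expand.grid(bp = seq_len(traj$n_bp), frame = seq_len(traj$n_frames))
  idx <- cbind(grid$frame, grid$bp)
  df <- data.frame(frame = grid$frame, bp = grid$bp,
                   propeller_deg = traj$propeller[idx],
                   opening_deg = traj$opening[idx],
                   buckle_deg = traj$buckle[idx],
                   wc_hbonds = as.integer(traj$hbond[idx]))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Relaxed-DNA baseline statistics of the angular bp parameters
#'
#' Global mean and s.d. of each angular parameter over all frames and base
#' pairs of a torsionally relaxed (sigma = 0) trajectory, excluding the
#' terminal base pairs at each end where fraying inflates the variance.
#'
#' @param traj a `bp_trajectory` with at least 100 frames
#' @param exclude_terminal_bp terminal bp excluded at each end (default 2)
#' @return list with `mean` and `sd`, each named (propeller, opening, buckle)
#' @export
relaxed_baseline <- function(traj, exclude_terminal_bp = 2) {
  stopifnot(inherits(traj, "bp_trajectory"))
  if (traj$n_frames < 100) stop("baseline needs at least 100 frames", call. = FALSE)
  keep <- seq(exclude_terminal_bp + 1, traj$n_bp - exclude_terminal_bp)
  if (length(keep) < 1) stop("no bp left after terminal exclusion", call. = FALSE)
  stat <- function(m) c(mean = mean(m[, keep]), sd = stats::sd(m[, keep]))
  s <- vapply(traj[c("propeller", "opening", "buckle")], stat, c(mean = 0, sd = 0))
  list(mean = s["mean", ], sd = s["sd", ])
}

#' Call denaturation bubbles in a bp-parameter trajectory
#'
#' A base pair is disrupted in a frame when its WC H-bond flag is absent
#' and its angular parameters deviate from the relaxed baseline by at least
#' `z_thresh` baseline standard deviations - jointly for all three
#' parameters by default (`criterion = "all"`), or for any one of them
#' (`criterion = "any"`). Maximal runs of >= `min_len_bp` consecutive
#' disrupted bp are bubble candidates; candidates sharing at least one bp
#' between consecutive frames are merged into one bubble (a gap of a full
#' frame ends it), and bubbles lasting longer than `min_dur_ns` are
#' returned.
#'
#' @param traj a `bp_trajectory`
#' @param baseline output of [relaxed_baseline()] (from a matching duplex)
#' @param min_len_bp minimum run length (default 3)
#' @param z_thresh deviation threshold in baseline s.d. (default 2)
#' @param min_dur_ns minimum duration, exclusive (default 1)
#' @param criterion "all" (joint) or "any" deviation across the three
#'   angular parameters
#' @return data.frame of class `bubble_calls`: `start_bp`, `length_bp`
#'   (bounding range over the bubble's lifetime), `t_start_ns`,
#'   `duration_ns`, `first_frame`, `last_frame`
#' @export
detect_bubbles <- function(traj, baseline, min_len_bp = 3, z_thresh = 2,
                           min_dur_ns = 1, criterion = c("all", "any")) {
  stopifnot(inherits(traj, "bp_trajectory"))
  criterion <- match.arg(criterion)
  if (min_len_bp <= 0 || z_thresh <= 0 || min_dur_ns <= 0) {
    stop("thresholds must be positive", call. = FALSE)
  }
  dev <- lapply(c("propeller", "opening", "buckle"), function(p) {
    abs(traj[[p]] - baseline$mean[[p]]) >= z_thresh * baseline$sd[[p]]
  })
  ang <- if (criterion == "all") dev[[1]] & dev[[2]] & dev[[3]] else
    dev[[1]] | dev[[2]] | dev[[3]]
  disrupted <- !traj$hbond & ang
  # per-frame candidate runs of >= min_len_bp
  frame_runs <- lapply(seq_len(traj$n_frames), function(fr) {
    r <- rle(disrupted[fr, ])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    sel <- r$values & r$lengths >= min_len_bp
    if (!any(sel)) return(NULL)
    data.frame(start = starts[sel], end = ends[sel])
  })
  # merge across consecutive frames on bp overlap
  open <- list()   # each: start, end, first_frame, last_frame
  calls <- list()
  close_call <- function(b) {
    dur <- (b$last_frame - b$first_frame + 1) * traj$dt_ns
    if (dur > min_dur_ns) {
      calls[[length(calls) + 1]] <<- data.frame(
        start_bp = b$start, length_bp = b$end - b$start + 1,
        t_start_ns = (b$first_frame - 1) * traj$dt_ns, duration_ns = dur,
        first_frame = b$first_frame, last_frame = b$last_frame)
    }
  }
  for (fr in seq_len(traj$n_frames)) {
    runs <- frame_runs[[fr]]
    still_open <- list()
    matched_run <- if (is.null(runs)) logical(0) else rep(FALSE, nrow(runs))
    for (b in open) {
      hit <- if (is.null(runs)) integer(0) else
        which(runs$start <= b$end & runs$end >= b$start)
      if (length(hit) == 0) { close_call(b); next }
      # extend over all overlapping runs of this frame
      b$start <- min(b$start, runs$start[hit])
      b$end <- max(b$end, runs$end[hit])
      b$last_frame <- fr
      matched_run[hit] <- TRUE
      still_open[[length(still_open) + 1]] <- b
    }
    if (!is.null(runs)) {
      for (j in which(!matched_run)) {
        still_open[[length(still_open) + 1]] <-
          list(start = runs$start[j], end = runs$end[j],
               first_frame = fr, last_frame = fr)
      }
    }
    open <- still_open
  }
  for (b in open) close_call(b)
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(start_bp = integer(), length_bp = integer(),
               t_start_ns = numeric(), duration_ns = numeric(),
               first_frame = integer(), last_frame = integer())
  out <- out[order(out$t_start_ns, out$start_bp), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("bubble_calls", "data.frame")
  out
}

#' Bubble prevalence over the final analysis window
#'
#' Percentage of frames in the last `analysis_window_ns` of the trajectory
#' during which at least one called bubble is present.
#'
#' @param traj the `bp_trajectory` the calls came from
#' @param calls a `bubble_calls` data.frame
#' @param analysis_window_ns length of the final window (default 400)
#' @return percentage in [0, 100]
#' @export
bubble_prevalence <- function(traj, calls, analysis_window_ns = 400) {
  stopifnot(inherits(traj, "bp_trajectory"))
  total_ns <- traj$n_frames * traj$dt_ns
  if (analysis_window_ns > total_ns + 1e-9) {
    stop("analysis window longer than the trajectory", call. = FALSE)
  }
  n_win <- round(analysis_window_ns / traj$dt_ns)
  first <- traj$n_frames - n_win + 1
  active <- rep(FALSE, n_win)
  for (i in seq_len(nrow(calls))) {
    lo <- max(calls$first_frame[i], first)
    hi <- calls$last_frame[i]
    if (hi >= lo) active[(lo:hi) - first + 1] <- TRUE
  }
  100 * mean(active)
}

#' Per-frame bubble indicator over the final window
#'
#' Convenience companion to [bubble_prevalence()]: the logical per-frame
#' indicator that feeds [prevalence_bootstrap()].
#'
#' @inheritParams bubble_prevalence
#' @return logical vector, one element per frame of the window
#' @export
bubble_indicator <- function(traj, calls, analysis_window_ns = 400) {
  n_win <- round(analysis_window_ns / traj$dt_ns)
  first <- traj$n_frames - n_win + 1
  if (first < 1) stop("analysis window longer than the trajectory", call. = FALSE)
  active <- rep(FALSE, n_win)
  for (i in seq_len(nrow(calls))) {
    lo <- max(calls$first_frame[i], first)
    hi <- calls$last_frame[i]
    if (hi >= lo) active[(lo:hi) - first + 1] <- TRUE
  }
  active
}

#' Bootstrap standard deviation of bubble prevalence
#'
#' Resamples a small fraction of the per-frame indicator (default 1%,
#' with replacement) `n_boot` times and returns the s.d. of the replicate
#' prevalences.
#'
#' @param indicator logical/0-1 vector of per-frame bubble presence
#' @param n_boot number of replicates (default 200)
#' @param frac fraction of frames per replicate (default 0.01);
#'   `frac * length(indicator)` must be >= 10
#' @param seed integer seed
#' @return s.d. of the replicate prevalences, in percentage points
#' @export
prevalence_bootstrap <- function(indicator, n_boot = 200, frac = 0.01, seed = 1) {
  n <- length(indicator)
  m <- floor(frac * n)
  if (m < 10) stop("frac * n_frames must be at least 10", call. = FALSE)
  ind <- as.numeric(indicator)
  rng <- .seeded_rng(seed)
  reps <- vapply(seq_len(n_boot), function(b) {
    100 * mean(ind[sample.int(n, m, replace = TRUE)])
  }, 0)
  rng$restore()
  stats::sd(reps)
}

#' Cumulative running mean and convergence of an end-to-end series
#'
#' Convergence of a simulation is assessed by the cumulative mean of the
#' end-to-end distance: the run is converged when the running mean drifts
#' by less than `tol` (relative) across the final quarter of the series.
#'
#' @param series numeric vector (>= 100 samples)
#' @param tol relative drift tolerance (default 0.02)
#' @return list with `running_mean`, `drift` (relative), `converged`
#' @export
convergence_curve <- function(series, tol = 0.02) {
  n <- length(series)
  if (n < 100) stop("need at least 100 samples", call. = FALSE)
  rm_ <- cumsum(series) / seq_len(n)
  q <- floor(3 * n / 4)
  drift <- abs(rm_[n] - rm_[q]) / abs(rm_[n])
  list(running_mean = rm_, drift = drift, converged = is.finite(drift) && drift < tol)
}
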