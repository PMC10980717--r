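#' Construct a force-extension curve
#'
#' Container for paired extension (nm) / force (pN) samples from one
#' stretch or release half cycle of a tethered bead.
#'
#' @param extension_nm,force_pN numeric vectors of equal length
#' @param direction "stretch" or "release"
#' @param temperature_K temperature at which the data were taken
#' @param ground_truth optional list of generator parameters
#' @return a data.frame of class `fx_curve`
#' @export
fx_curve <- function(extension_nm, force_pN, direction = c("stretch", "release"),
                     temperature_K = 298, ground_truth = NULL) {
  direction <- match.arg(direction)
  stopifnot(length(extension_nm) == length(force_pN))
  if (any(extension_nm < 0)) stop("extensions must be non-negative", call. = FALSE)
  out <- data.frame(extension_nm = as.numeric(extension_nm),
                    force_pN = as.numeric(force_pN))
  attr(out, "direction") <- direction
  attr(out, "temperature_K") <- temperature_K
  attr(out, "ground_truth") <- ground_truth
  class(out) <- c("fx_curve", "data.frame")
  out
}

#' Construct a detector (QPD) time trace
#'
#' A fixed-rate time series of detector signal, optionally with the
#' coil-drive channel recorded alongside it.
#'
#' @param signal numeric vector, detector signal (nm or rad depending on use)
#' @param fs_Hz sampling rate in Hz
#' @param drive optional numeric vector, drive channel sampled synchronously
#' @param unit unit string for `signal`
#' @param ground_truth optional list of generator parameters
#' @return a list of class `qpd_trace`
#' @export
qpd_trace <- function(signal, fs_Hz, drive = NULL, unit = "nm",
                      ground_truth = NULL) {
  .check_positive(fs_Hz, "fs_Hz")
  if (!is.null(drive) && length(drive) != length(signal)) {
    stop("drive channel must match signal length", call. = FALSE)
  }
  structure(list(signal = as.numeric(signal), drive = drive,
                 fs_Hz = fs_Hz, unit = unit, ground_truth = ground_truth),
            class = "qpd_trace")
}

#' @export
print.qpd_trace <- function(x, ...) {
  cat(sprintf("<qpd_trace> %d samples @ %g Hz (%.3g s), unit %s%s\n",
              length(x$signal), x$fs_Hz, length(x$signal) / x$fs_Hz, x$unit,
              if (is.null(x$drive)) "" else ", with drive channel"))
  invisible(x)
}

#' Read and write headered TSV traces
#'
#' Traces are exchanged as plain tab-separated tables with a `time_s` column
#' and one column per channel; metadata (sampling rate, unit) travels in
#' `#key: value` comment lines before the header.
#'
#' @param trace a `qpd_trace`
#' @param path file path
#' @return `read_trace_tsv` returns a `qpd_trace`
#' @export
write_trace_tsv <- function(trace, path) {
  stopifnot(inherits(trace, "qpd_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#fs_Hz: %.10g", trace$fs_Hz), con)
  writeLines(sprintf("#unit: %s", trace$unit), con)
  df <- data.frame(time_s = (seq_along(trace$signal) - 1) / trace$fs_Hz,
                   signal = trace$signal)
  if (!is.null(trace$drive)) df$drive <- trace$drive
  utils::write.table(format(df, digits = 12, trim = TRUE), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_tsv
#' @export
read_trace_tsv <- function(path) {
  hdr <- readLines(path, n = 10L)
  meta <- grep("^#", hdr, value = TRUE)
  getm <- function(key, default) {
    m <- grep(paste0("^#", key, ":"), meta, value = TRUE)
    if (length(m) == 0) return(default)
    sub(paste0("^#", key, ":\\s*"), "", m[1])
  }
  fs <- as.numeric(getm("fs_Hz", NA))
  if (!is.finite(fs)) stop("trace TSV missing #fs_Hz metadata", call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#")
  qpd_trace(df$signal, fs_Hz = fs,
            drive = if ("drive" %in% names(df)) df$drive else NULL,
            unit = getm("unit", "nm"))
}

#' Read and write 16-bit multi-page TIFF image stacks
#'
#' Stacks are stored as numeric arrays `[row, col, frame]` in photon-count
#' like units; on disk they are 16-bit greyscale multi-page TIFFs.
#'
#' @param stack numeric array `[ny, nx, n_frames]` (a matrix is treated as a
#'   single frame)
#' @param path file path
#' @param max_count full-scale value mapped to 16-bit white (default: the
#'   stack maximum)
#' @return `read_stack_tiff` returns an `[ny, nx, n_frames]` array scaled
#'   back to `max_count`
#' @export
write_stack_tiff <- function(stack, path, max_count = max(stack)) {
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1L))
  stopifnot(length(dim(stack)) == 3)
  frames <- lapply(seq_len(dim(stack)[3]), function(k) {
    pmin(pmax(stack[, , k] / max_count, 0), 1)
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path, max_count = 2^16 - 1) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  out <- array(0, c(dim(frames[[1]]), length(frames)))
  for (k in seq_along(frames)) out[, , k] <- frames[[k]] * max_count
  out
}
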