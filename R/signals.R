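#' Time-series gait table
#'
#' A light container for sampled gait channels: a strictly increasing time
#' vector plus named numeric columns with per-column units.
#'
#' @param time Time stamps (s), strictly increasing.
#' @param data Named list / data.frame of numeric channels.
#' @param units Character vector of units, one per channel (recycled).
#' @return Object of class `timetable` (a data.frame with a `units`
#'   attribute; first column `time`).
#' @export
timetable <- function(time, data, units = NULL) {
  data <- as.data.frame(data)
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (any(vapply(data, length, 0L) != length(time)))
    stop("all channels must have the same length as time")
  out <- cbind(data.frame(time = time), data)
  if (is.null(units)) units <- rep("", ncol(data))
  attr(out, "units") <- setNames(rep(units, length.out = ncol(data)),
                                 names(data))
  class(out) <- c("timetable", "data.frame")
  out
}

#' @noRd
tt_channels <- function(x) setdiff(names(x), "time")

#' @noRd
tt_rate <- function(x) 1 / median(diff(x$time))

#' @noRd
tt_modify <- function(x, f) {
  for (ch in tt_channels(x)) x[[ch]] <- f(x[[ch]])
  x
}

#' Write / read OpenSim-style MOT/STO tables
#'
#' Tab-delimited tables with the OpenSim header dialect (`nRows`,
#' `nColumns`, `inDegrees`, `endheader`). Angles are written in degrees when
#' `in_degrees = TRUE` (the column units decide which columns convert: any
#' unit equal to `"rad"`).
#'
#' @param x A [timetable()].
#' @param path File path.
#' @param name Table name written in the header.
#' @param in_degrees Write `rad` columns as degrees (format convention).
#' @export
write_mot <- function(x, path, name = "hemigait", in_degrees = TRUE) {
  units <- attr(x, "units")
  out <- as.data.frame(x)
  if (in_degrees) {
    for (ch in tt_channels(x))
      if (identical(units[[ch]], "rad")) out[[ch]] <- out[[ch]] * 180 / pi
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(name, "version=1",
               paste0("nRows=", nrow(out)),
               paste0("nColumns=", ncol(out)),
               paste0("inDegrees=", if (in_degrees) "yes" else "no"),
               paste0("units=", paste(c("s", unname(units)), collapse = "\t")),
               "endheader",
               paste(names(out), collapse = "\t")), con)
  write.table(format(out, digits = 15, trim = TRUE, scientific = FALSE),
              con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_mot
#' @export
write_sto <- write_mot

#' @rdname write_mot
#' @export
read_mot <- function(path) {
  lines <- readLines(path)
  end <- which(trimws(lines) == "endheader")[1]
  if (is.na(end)) stop("not an OpenSim MOT/STO file (no endheader): ", path)
  hdr <- lines[seq_len(end - 1)]
  in_deg <- any(grepl("inDegrees\\s*=\\s*yes", hdr))
  units_line <- grep("^units=", hdr, value = TRUE)
  tab <- read.table(text = lines[(end + 1):length(lines)], header = TRUE,
                    sep = "\t", check.names = FALSE)
  units <- rep("", ncol(tab) - 1)
  if (length(units_line)) {
    u <- strsplit(sub("^units=", "", units_line[1]), "\t")[[1]]
    if (length(u) == ncol(tab)) units <- u[-1]
  }
  names(units) <- setdiff(names(tab), "time")
  if (in_deg) {
    for (ch in names(units))
      if (identical(units[[ch]], "rad")) tab[[ch]] <- tab[[ch]] * pi / 180
  }
  timetable(tab$time, tab[setdiff(names(tab), "time")], units)
}

#' @rdname write_mot
#' @export
read_sto <- read_mot

#' Write / read CSV with a units row
#'
#' Plain CSV mirror of the MOT dialect: header row, a second row of units,
#' then data; SI units throughout.
#' @param x A [timetable()].
#' @param path File path.
#' @export
write_gait_csv <- function(x, path) {
  units <- attr(x, "units")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(x), collapse = ","), con)
  writeLines(paste(c("s", unname(units)), collapse = ","), con)
  write.table(format(as.data.frame(x), digits = 15, trim = TRUE,
                     scientific = FALSE),
              con, sep = ",", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_gait_csv
#' @export
read_gait_csv <- function(path) {
  hdr <- strsplit(readLines(path, n = 2), ",")
  tab <- read.table(path, header = FALSE, sep = ",", skip = 2,
                    col.names = hdr[[1]], check.names = FALSE)
  units <- setNames(hdr[[2]][-1], hdr[[1]][-1])
  timetable(tab$time, tab[setdiff(names(tab), "time")], units)
}

#' Forward-backward filtering with odd-reflection edge padding
#'
#' `signal::filtfilt` applies no padding, so edge transients contaminate
#' the start and end of short records; mirror-padding by several filter
#' time constants removes them (constant signals pass through exactly).
#' @noRd
filtfilt_padded <- function(bf, x, fs, fc) {
  n <- length(x)
  npad <- min(n - 1L, max(10L, ceiling(6 * fs / fc)))
  head_pad <- 2 * x[1] - x[(npad + 1):2]
  tail_pad <- 2 * x[n] - x[(n - 1):(n - npad)]
  y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
  y[(npad + 1):(npad + n)]
}

#' Zero-phase Butterworth low-pass with a gait-cycle-scaled cutoff
#'
#' Forward-backward Butterworth filtering at a cutoff of `factor / tf` Hz,
#' where `tf` is the period of the gait cycle. The nominal filter order
#' counts the effective (net) order: a fourth-order zero-phase filter is a
#' second-order kernel applied forward and backward (the usual reading in
#' gait processing); set `kernel = "full"` to instead apply the full-order
#' kernel twice.
#'
#' @param x A [timetable()].
#' @param tf Gait-cycle period (s).
#' @param factor Cutoff scale (7 for kinematics/ground reactions,
#'   3.5 for EMG envelopes).
#' @param order Net filter order (even; default 4).
#' @param kernel `"half"` (default) or `"full"` (see above).
#' @return Filtered [timetable()].
#' @export
lowpass_variable_cutoff <- function(x, tf, factor = 7, order = 4,
                                    kernel = c("half", "full")) {
  kernel <- match.arg(kernel)
  stopifnot(tf > 0, factor > 0, order %% 2 == 0)
  fs <- tt_rate(x)
  fc <- factor / tf
  if (fc >= fs / 2)
    stop("cutoff ", fc, " Hz is at or above Nyquist (", fs / 2, " Hz)")
  ord <- if (kernel == "half") order / 2 else order
  bf <- signal::butter(ord, fc / (fs / 2), type = "low")
  tt_modify(x, function(ch) filtfilt_padded(bf, ch, fs, fc))
}

#' Process raw EMG to normalized envelopes
#'
#' High-pass filter (40 Hz, zero phase), demean, rectify, low-pass at
#' `3.5 / tf` Hz, then normalize each channel to the maximum over the
#' normalization set (the processed data itself when `maxima` is NULL).
#'
#' @param raw A [timetable()] of raw EMG (sampling rate >= 1000 Hz).
#' @param tf Gait-cycle period (s).
#' @param maxima Optional named vector of per-channel normalization maxima
#'   (from other trials).
#' @param highpass High-pass cutoff (Hz).
#' @param order Net filter order.
#' @return A [timetable()] of envelopes, with attribute `maxima`.
#' @export
process_emg <- function(raw, tf, maxima = NULL, highpass = 40, order = 4) {
  fs <- tt_rate(raw)
  if (fs < 1000)
    warning("EMG sampling rate ", round(fs), " Hz < 1000 Hz; the ",
            highpass, " Hz high-pass is poorly resolved")
  bh <- signal::butter(order / 2, highpass / (fs / 2), type = "high")
  x <- tt_modify(raw, function(ch) {
    y <- filtfilt_padded(bh, ch, fs, highpass)
    abs(y - mean(y))
  })
  x <- lowpass_variable_cutoff(x, tf, factor = 3.5, order = order)
  x <- tt_modify(x, function(ch) pmax(ch, 0))
  if (is.null(maxima)) {
    maxima <- vapply(tt_channels(x), function(ch) max(x[[ch]]), 0)
  }
  for (ch in tt_channels(x)) {
    mx <- maxima[[ch]]
    if (!is.finite(mx) || mx <= 0)
      stop("EMG normalization failed: channel '", ch,
           "' has non-positive maximum")
    x[[ch]] <- x[[ch]] / mx
  }
  attr(x, "maxima") <- maxima
  x
}

#' Resample a cycle window to 101 points
#'
#' Cubic-spline interpolation onto `n` equally spaced samples including both
#' window endpoints.
#'
#' @param x A [timetable()].
#' @param window Length-2 start/end times (s) within the data range.
#' @param n Number of output samples (101 by convention).
#' @return A [timetable()] with `n` rows.
#' @export
resample_cycle <- function(x, window, n = 101) {
  if (window[1] < min(x$time) - 1e-9 || window[2] > max(x$time) + 1e-9)
    stop("cycle window [", window[1], ", ", window[2],
         "] outside the data range")
  tq <- seq(window[1], window[2], length.out = n)
  out <- lapply(tt_channels(x), function(ch)
    spline(x$time, x[[ch]], xout = tq, method = "fmm")$y)
  names(out) <- tt_channels(x)
  timetable(tq, out, attr(x, "units"))
}

#' Detect heel-strike events from vertical ground reaction force
#'
#' Rising threshold crossings with a debounce window; crossing times are
#' refined by linear interpolation between samples.
#'
#' @param time Time vector (s).
#' @param fy Vertical GRF (N, >= 0).
#' @param threshold Force threshold (N).
#' @param debounce Minimum separation between events (s).
#' @return Numeric vector of event times (empty, with a warning, when the
#'   signal never crosses the threshold).
#' @export
detect_heel_strikes <- function(time, fy, threshold = 20, debounce = 0.05) {
  stopifnot(all(fy >= -1e-6))
  below <- fy < threshold
  idx <- which(below[-length(fy)] & !below[-1])
  if (!length(idx)) {
    warning("no threshold crossings found")
    return(numeric(0))
  }
  tms <- vapply(idx, function(i) {
    f0 <- fy[i]; f1 <- fy[i + 1]
    time[i] + (threshold - f0) / (f1 - f0) * (time[i + 1] - time[i])
  }, 0)
  keep <- c(TRUE, diff(tms) > debounce)
  tms[keep]
}

#' Detect toe-off events (falling crossings)
#' @inheritParams detect_heel_strikes
#' @export
detect_toe_offs <- function(time, fy, threshold = 20, debounce = 0.05) {
  stopifnot(all(fy >= -1e-6))
  below <- fy < threshold
  idx <- which(!below[-length(fy)] & below[-1])
  if (!length(idx)) {
    warning("no threshold crossings found")
    return(numeric(0))
  }
  tms <- vapply(idx, function(i) {
    f0 <- fy[i]; f1 <- fy[i + 1]
    time[i] + (threshold - f0) / (f1 - f0) * (time[i + 1] - time[i])
  }, 0)
  keep <- c(TRUE, diff(tms) > debounce)
  tms[keep]
}
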