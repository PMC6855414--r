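#' Load a continuous EEG recording
#'
#' Reads a single-channel recording either from a plain text file (one sample
#' per line) or from a 16-bit EDF file, in which case the channel analysed is
#' the differential montage between two named electrodes (frontal minus
#' parietal by default, the montage that picks up both cortical delta and
#' hippocampal theta). Non-finite samples are kept in place but masked as
#' unusable.
#'
#' A lights-on/lights-off schedule can be supplied as a TSV file with columns
#' `state` (`"light"`/`"dark"`), `start_s`, `end_s`, or is picked up
#' automatically from a sidecar file `<path>.schedule.tsv`. Bad intervals can
#' be supplied as a TSV of `start_s`, `end_s` pairs and are masked out.
#'
#' @param path file to read.
#' @param format `"csv"` for delimited text (one column of samples), `"edf"`
#'   for European Data Format, or `"auto"` to decide from the file extension.
#' @param fs sampling rate in Hz; required for text input, read from the
#'   header for EDF.
#' @param channels for EDF, a length-2 character vector naming the channels
#'   whose difference (first minus second) is analysed.
#' @param schedule optional schedule TSV path or data frame.
#' @param bad_intervals optional TSV path or data frame of bad intervals.
#' @return an object of class `raw_recording`: a list with elements `samples`,
#'   `fs`, `start_time` (seconds, 0 at record start), `schedule` (data frame)
#'   and `mask` (logical, `TRUE` = usable).
#' @export
load_recording <- function(path, format = c("auto", "csv", "edf"), fs = NULL,
                           channels = c("F", "P"), schedule = NULL,
                           bad_intervals = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (format == "csv") {
    if (is.null(fs)) stop("fs must be supplied for text input")
    samples <- scan(path, what = numeric(), quiet = TRUE, sep = "",
                    na.strings = c("NA", "NaN", "nan", "Inf", "-Inf"))
  } else {
    edf <- read_edf(path)
    fs <- edf$fs
    miss <- setdiff(channels, edf$labels)
    if (length(miss) > 0) stop("missing channel label(s): ",
                               paste(miss, collapse = ", "))
    samples <- edf$signals[[match(channels[1], edf$labels)]] -
      edf$signals[[match(channels[2], edf$labels)]]
  }
  if (length(samples) == 0) stop("empty recording: ", path)
  mask <- is.finite(samples)
  if (any(!mask)) {
    warning(sum(!mask), " non-finite sample(s) masked")
  }
  if (is.null(schedule)) {
    sidecar <- paste0(path, ".schedule.tsv")
    if (file.exists(sidecar)) schedule <- sidecar
  }
  schedule <- if (is.null(schedule)) {
    data.frame(state = character(), start_s = numeric(), end_s = numeric())
  } else if (is.character(schedule)) {
    utils::read.table(schedule, header = TRUE, sep = "\t",
                      col.names = c("state", "start_s", "end_s"))
  } else {
    as.data.frame(schedule)
  }
  rec <- new_raw_recording(samples, fs, schedule = schedule, mask = mask)
  if (!is.null(bad_intervals)) {
    if (is.character(bad_intervals)) {
      bad_intervals <- utils::read.table(bad_intervals, header = TRUE,
                                         sep = "\t",
                                         col.names = c("start_s", "end_s"))
    }
    for (i in seq_len(nrow(bad_intervals))) {
      lo <- max(1L, floor(bad_intervals$start_s[i] * fs) + 1L)
      hi <- min(length(samples), ceiling(bad_intervals$end_s[i] * fs))
      if (hi >= lo) rec$mask[lo:hi] <- FALSE
    }
  }
  rec
}

#' Construct a raw_recording
#'
#' @param samples numeric vector of EEG samples.
#' @param fs sampling rate in Hz.
#' @param start_time recording start in seconds (clock offset).
#' @param schedule data frame with columns `state`, `start_s`, `end_s`.
#' @param mask logical usability mask, same length as `samples`.
#' @return a `raw_recording`.
#' @export
new_raw_recording <- function(samples, fs, start_time = 0,
                              schedule = NULL, mask = NULL) {
  stopifnot(fs > 0, length(samples) > 0)
  if (is.null(mask)) mask <- is.finite(samples)
  stopifnot(length(mask) == length(samples))
  if (is.null(schedule)) {
    schedule <- data.frame(state = character(), start_s = numeric(),
                           end_s = numeric())
  }
  if (nrow(schedule) > 1) {
    o <- order(schedule$start_s)
    schedule <- schedule[o, , drop = FALSE]
    if (any(schedule$end_s[-nrow(schedule)] > schedule$start_s[-1] + 1e-9)) {
      stop("schedule intervals overlap")
    }
  }
  dur <- length(samples) / fs
  if (nrow(schedule) > 0 &&
      (min(schedule$start_s) < -1e-9 || max(schedule$end_s) > dur + 1e-9)) {
    stop("schedule intervals outside the recording span")
  }
  structure(list(samples = as.numeric(samples), fs = fs,
                 start_time = start_time, schedule = schedule,
                 mask = as.logical(mask)),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("raw_recording: %d samples at %g Hz (%.1f s), %d masked\n",
              length(x$samples), x$fs, length(x$samples) / x$fs,
              sum(!x$mask)))
  invisible(x)
}

# Minimal 16-bit EDF reader (standard header; no annotations).
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- function(n) trimws(rawToChar(readBin(con, "raw", n)))
  hdr(8); hdr(80); hdr(80); hdr(8); hdr(8)          # version, ids, date, time
  hdr(8)                                             # header bytes
  hdr(44)
  n_rec <- as.integer(hdr(8))
  rec_dur <- as.numeric(hdr(8))
  ns <- as.integer(hdr(4))
  if (is.na(ns) || ns < 1) stop("unreadable EDF header")
  fld <- function(n) vapply(seq_len(ns), function(i) hdr(n), character(1))
  labels <- fld(16)
  fld(80); fld(8)
  phys_min <- as.numeric(fld(8)); phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8)); dig_max <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8))
  fld(32)
  signals <- vector("list", ns)
  for (i in seq_len(ns)) signals[[i]] <- numeric(n_rec * spr[i])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2, endian = "little")
      phys <- phys_min[i] + (dig - dig_min[i]) *
        (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
      signals[[i]][((r - 1) * spr[i] + 1):(r * spr[i])] <- phys
    }
  }
  if (length(unique(spr)) != 1) {
    warning("EDF channels have different sampling rates; using the first")
  }
  list(labels = labels, signals = signals, fs = spr[1] / rec_dur)
}

#' Normalize and bandpass-filter a recording
#'
#' Usable samples are normalized to zero mean and unit standard deviation,
#' then the signal is bandpass filtered with a linear-phase windowed-sinc FIR
#' filter whose group delay is compensated so timestamps are preserved.
#' Masked samples are set to zero before filtering and stay masked.
#'
#' @param rec a `raw_recording`.
#' @param band lower and upper passband edges in Hz (default 0.5-25).
#' @param filter_len number of FIR taps (odd; default 513 at 256 Hz).
#' @return a `raw_recording` with filtered samples.
#' @export
preprocess <- function(rec, band = c(0.5, 25), filter_len = 513L) {
  stopifnot(inherits(rec, "raw_recording"))
  if (filter_len %% 2 == 0) filter_len <- filter_len + 1L
  if (sum(rec$mask) < filter_len) stop("too few usable samples")
  x <- rec$samples
  mu <- mean(x[rec$mask])
  sdv <- stats::sd(x[rec$mask])
  if (!is.finite(sdv) || sdv == 0) stop("constant signal")
  x <- (x - mu) / sdv
  x[!rec$mask] <- 0
  b <- signal::fir1(filter_len - 1L, band / (rec$fs / 2), type = "pass")
  gd <- (filter_len - 1L) %/% 2L
  y <- stats::filter(c(x, numeric(gd)), b, method = "convolution",
                     sides = 1)
  y <- as.numeric(y)[(gd + 1L):(gd + length(x))]
  y[is.na(y)] <- 0
  rec$samples <- y
  rec
}

# One-sided Welch PSD with Hann-tapered 50%-overlap segments.
# Returns freq grid and density such that sum(psd) * df ~ variance.
welch_psd <- function(x, fs, seg_len) {
  seg_len <- as.integer(seg_len)
  step <- seg_len %/% 2L
  n <- length(x)
  starts <- seq(1L, n - seg_len + 1L, by = step)
  h <- 0.5 * (1 - cos(2 * pi * seq_len(seg_len) / (seg_len + 1)))
  u <- sum(h^2)
  acc <- numeric(seg_len)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)] * h
    acc <- acc + Mod(stats::fft(seg))^2
  }
  pxx <- acc / (length(starts) * fs * u)
  nh <- seg_len %/% 2L
  freq <- (0:nh) * fs / seg_len
  p <- pxx[1:(nh + 1L)]
  # fold negative frequencies (one-sided)
  p[2:(nh + 1L)] <- p[2:(nh + 1L)] +
    rev(pxx[(seg_len - nh + 1L):seg_len])[1:nh]
  list(freq = freq, psd = p, df = fs / seg_len)
}

# integral of the PSD over [band[1], band[2]) with fractional coverage of
# edge bins (each bin spans [f - df/2, f + df/2))
band_integral <- function(psd, band) {
  lo_bin <- psd$freq - psd$df / 2
  hi_bin <- psd$freq + psd$df / 2
  ov <- pmin(hi_bin, band[2]) - pmax(lo_bin, band[1])
  sum(psd$psd[ov > 0] * ov[ov > 0])
}

#' Windowed band powers and the theta/delta ratio series
#'
#' Divides the recording into non-overlapping analysis windows of length `w`
#' seconds, anchored at the start of each contiguous usable segment (gaps
#' restart the tiling; the trailing partial window of each segment is
#' discarded). In each window the spectral power in the delta and theta bands
#' is the integral of the Welch power spectral density over the half-open band,
#' and the ratio R = S_theta / S_delta is formed. Windows containing any
#' masked sample are marked invalid.
#'
#' @param rec a `raw_recording` (normally after [preprocess()]).
#' @param w window length in seconds (default 5).
#' @param bands list with elements `delta` and `theta`, each `c(lo, hi)` in Hz.
#' @return an object of class `ratio_series`: a list with per-window vectors
#'   `S_delta`, `S_theta`, `R`, `t_start`, `segment`, `window_valid`, and
#'   scalars `w`, `fs`, plus the band definition.
#' @export
band_power_series <- function(rec, w = 5,
                              bands = list(delta = c(0.5, 4),
                                           theta = c(4, 8))) {
  stopifnot(inherits(rec, "raw_recording"))
  nw <- as.integer(round(w * rec$fs))
  if (nw < 64) stop("window too short: w * fs must be >= 64 samples")
  if (nw > length(rec$samples)) stop("window longer than the recording")
  r <- rle(rec$mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  S_delta <- numeric(0); S_theta <- numeric(0)
  t_start <- numeric(0); segment <- integer(0)
  seg_id <- 0L
  seg_len <- nw %/% 2L
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    seg_id <- seg_id + 1L
    n_win <- r$lengths[i] %/% nw
    if (n_win == 0) next
    for (k in seq_len(n_win)) {
      a <- starts[i] + (k - 1L) * nw
      win <- rec$samples[a:(a + nw - 1L)]
      psd <- welch_psd(win, rec$fs, seg_len)
      S_delta <- c(S_delta, band_integral(psd, bands$delta))
      S_theta <- c(S_theta, band_integral(psd, bands$theta))
      t_start <- c(t_start, (a - 1L) / rec$fs)
      segment <- c(segment, seg_id)
    }
  }
  valid <- S_delta > 0 & S_theta >= 0
  R <- ifelse(valid, S_theta / S_delta, NA_real_)
  structure(list(S_delta = S_delta, S_theta = S_theta, R = R,
                 t_start = t_start, segment = segment,
                 window_valid = valid, w = w, fs = rec$fs, bands = bands,
                 schedule = rec$schedule),
            class = "ratio_series")
}

#' @export
print.ratio_series <- function(x, ...) {
  cat(sprintf(
    "ratio_series: %d windows of %g s (%d valid), median R = %.3g\n",
    length(x$R), x$w, sum(x$window_valid),
    stats::median(x$R, na.rm = TRUE)))
  invisible(x)
}

#' Flag high-amplitude artifact segments
#'
#' Marks as unusable any stretch where the absolute z-scored amplitude exceeds
#' `z_max` continuously for longer than `min_dur` seconds. A reproducible
#' stand-in for manual inspection of noisy segments.
#'
#' @param rec a `raw_recording`.
#' @param z_max amplitude threshold in standard deviations (default 8).
#' @param min_dur minimum excursion duration in seconds (default 0.5).
#' @return the recording with an updated mask.
#' @export
flag_amplitude_artifacts <- function(rec, z_max = 8, min_dur = 0.5) {
  stopifnot(inherits(rec, "raw_recording"))
  x <- rec$samples
  # robust scale so the artifact does not inflate its own threshold
  mu <- stats::median(x[rec$mask]); sdv <- stats::mad(x[rec$mask])
  if (!is.finite(sdv) || sdv == 0) return(rec)
  hot <- abs((x - mu) / sdv) > z_max
  r <- rle(hot)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (r$values[i] && r$lengths[i] > min_dur * rec$fs) {
      rec$mask[starts[i]:ends[i]] <- FALSE
    }
  }
  rec
}

#' Write a ratio series to TSV
#'
#' @param rs a `ratio_series`.
#' @param path output file.
#' @export
write_ratio_series <- function(rs, path) {
  df <- data.frame(window_index = seq_along(rs$R) - 1L,
                   t_start_s = rs$t_start,
                   S_delta = rs$S_delta, S_theta = rs$S_theta,
                   R = rs$R, valid = rs$window_valid)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
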