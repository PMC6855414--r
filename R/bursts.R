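#' Construct a burst sequence
#'
#' A burst sequence is an ordered run-length encoding of the analysis windows:
#' each burst has a kind (`theta`, `delta` or `unassigned`), a window count
#' `n`, a duration `d = n * w` seconds, a start time, a `truncated` flag for
#' bursts censored by a record boundary, masked gap or period edge, and a
#' `chunk` id grouping bursts that are contiguous in time.
#'
#' @param kind character vector of burst kinds.
#' @param n integer vector of window counts (supply this or `d`).
#' @param w analysis window length in seconds.
#' @param d burst durations in seconds (multiples of `w`).
#' @param t_start burst start times in seconds; defaults to the cumulative
#'   duration.
#' @param truncated logical vector (default all `FALSE`).
#' @param chunk integer contiguity group (default all 1).
#' @param th_theta,th_delta thresholds the sequence was detected with.
#' @param period period label: `"h24"`, `"light"` or `"dark"`.
#' @return an object of class `burst_sequence`.
#' @export
new_burst_sequence <- function(kind, n = NULL, w = 5, d = NULL,
                               t_start = NULL, truncated = NULL,
                               chunk = NULL, th_theta = 1, th_delta = 1,
                               period = "h24", strict = TRUE) {
  if (is.null(n)) {
    stopifnot(!is.null(d))
    n <- as.integer(round(d / w))
    if (strict) {
      if (any(abs(n * w - d) > 1e-6 * w)) {
        stop("durations must be multiples of w")
      }
    } else {
      n <- pmax(1L, as.integer(ceiling(d / w)))
    }
  }
  stopifnot(all(n >= 1))
  if (is.null(d) || strict) d <- n * w
  if (is.null(t_start)) t_start <- cumsum(c(0, d[-length(d)]))
  if (is.null(truncated)) truncated <- rep(FALSE, length(kind))
  if (is.null(chunk)) chunk <- rep(1L, length(kind))
  structure(list(
    bursts = data.frame(kind = as.character(kind), n = as.integer(n),
                        d = d, t_start = t_start,
                        truncated = truncated, chunk = as.integer(chunk)),
    w = w, th_theta = th_theta, th_delta = th_delta, period = period),
    class = "burst_sequence")
}

#' @export
print.burst_sequence <- function(x, ...) {
  b <- x$bursts
  cat(sprintf(
    "burst_sequence (%s): %d bursts (%d theta, %d delta, %d unassigned), w = %g s\n",
    x$period, nrow(b), sum(b$kind == "theta"), sum(b$kind == "delta"),
    sum(b$kind == "unassigned"), x$w))
  invisible(x)
}

#' Burst durations of one kind
#'
#' @param bs a `burst_sequence`.
#' @param kind `"theta"` or `"delta"`.
#' @param drop_truncated drop boundary-censored bursts (default `TRUE`;
#'   truncated bursts have unknown true duration).
#' @return numeric vector of durations in seconds.
#' @export
burst_durations <- function(bs, kind = c("theta", "delta"),
                            drop_truncated = TRUE) {
  kind <- match.arg(kind)
  b <- bs$bursts
  sel <- b$kind == kind
  if (drop_truncated) sel <- sel & !b$truncated
  b$d[sel]
}

#' Detect theta- and delta-bursts in a ratio series
#'
#' A theta-burst is a maximal run of consecutive windows with
#' `R > th_theta`; a delta-burst a maximal run with `R < th_delta`; windows
#' with `th_delta <= R <= th_theta` form `unassigned` bursts. With the
#' headline thresholds `th_theta = th_delta = 1` every valid window belongs
#' to a theta- or delta-burst. Runs are broken by record boundaries, masked
#' gaps, invalid windows and (when a period filter is used) schedule edges;
#' bursts touching such a break are flagged `truncated`.
#'
#' @param rs a `ratio_series`.
#' @param th_theta theta threshold (>= 1).
#' @param th_delta delta threshold (<= 1, > 0). The single-threshold
#'   parameterization of the sweep is `th_theta = Th`, `th_delta = 1/Th`.
#' @param period `NULL`/`"h24"` for the whole record, `"light"` or `"dark"`
#'   to restrict to the matching schedule intervals.
#' @return a `burst_sequence`.
#' @export
detect_bursts <- function(rs, th_theta = 1, th_delta = 1, period = NULL) {
  stopifnot(inherits(rs, "ratio_series"))
  if (!(th_theta >= 1 && th_delta <= 1 && th_delta > 0)) {
    stop("need th_theta >= 1 >= th_delta > 0")
  }
  if (is.null(period)) period <- "h24"
  sel <- rs$window_valid
  if (period %in% c("light", "dark")) {
    sched <- rs$schedule[rs$schedule$state == period, , drop = FALSE]
    in_per <- rep(FALSE, length(rs$R))
    for (i in seq_len(nrow(sched))) {
      in_per <- in_per | (rs$t_start >= sched$start_s[i] - 1e-9 &
                            rs$t_start + rs$w <= sched$end_s[i] + 1e-9)
    }
    sel <- sel & in_per
  }
  idx <- which(sel)
  if (length(idx) == 0) {
    warning("no valid windows; empty burst sequence")
    return(new_burst_sequence(character(0), integer(0), w = rs$w,
                              th_theta = th_theta, th_delta = th_delta,
                              period = period))
  }
  # contiguity: consecutive window index AND same usable segment
  brk <- c(TRUE, diff(idx) != 1L | diff(rs$segment[idx]) != 0L)
  chunk_of <- cumsum(brk)
  cls <- ifelse(rs$R[idx] > th_theta, "theta",
                ifelse(rs$R[idx] < th_delta, "delta", "unassigned"))
  kind <- character(0); n <- integer(0); t0 <- numeric(0)
  trunc <- logical(0); chunk <- integer(0); start_win <- integer(0)
  for (ck in unique(chunk_of)) {
    pos <- idx[chunk_of == ck]
    r <- rle(cls[chunk_of == ck])
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    kind <- c(kind, r$values)
    n <- c(n, r$lengths)
    t0 <- c(t0, rs$t_start[pos[starts]])
    start_win <- c(start_win, pos[starts])
    tr <- rep(FALSE, length(r$values))
    tr[1] <- TRUE; tr[length(tr)] <- TRUE
    trunc <- c(trunc, tr)
    chunk <- c(chunk, rep(ck, length(r$values)))
  }
  bs <- new_burst_sequence(kind, n, w = rs$w, t_start = t0,
                           truncated = trunc, chunk = chunk,
                           th_theta = th_theta, th_delta = th_delta,
                           period = period)
  bs$bursts$start_window <- start_win
  bs
}

#' Quiet times between consecutive theta-bursts
#'
#' Events are the non-truncated theta-bursts with duration exceeding `D0`;
#' the quiet time between two consecutive events is the time from the end of
#' the first to the start of the next. Pairs of events separated by a masked
#' gap or period boundary (different chunks) are skipped. At `D0 = 0` on a
#' gap-free sequence detected at threshold 1, the quiet times are exactly the
#' delta-burst durations between consecutive theta events.
#'
#' @param bs a `burst_sequence`.
#' @param D0 duration threshold in seconds (default 0).
#' @return an object of class `quiet_time_set`: list with `D0`, `deltas`
#'   (quiet times in seconds) and `mean_dt`.
#' @export
quiet_times <- function(bs, D0 = 0) {
  stopifnot(inherits(bs, "burst_sequence"))
  b <- bs$bursts
  ev <- b[b$kind == "theta" & !b$truncated & b$d > D0, , drop = FALSE]
  if (nrow(ev) < 2) {
    return(structure(list(D0 = D0, deltas = numeric(0), mean_dt = NA_real_),
                     class = "quiet_time_set"))
  }
  dt <- ev$t_start[-1] - (ev$t_start[-nrow(ev)] + ev$d[-nrow(ev)])
  same_chunk <- diff(ev$chunk) == 0L
  dt <- dt[same_chunk & dt > 0]
  structure(list(D0 = D0, deltas = dt,
                 mean_dt = if (length(dt)) mean(dt) else NA_real_),
            class = "quiet_time_set")
}

#' Shuffle the windows of a ratio series (surrogate)
#'
#' Uniform random permutation of the valid windows, destroying all temporal
#' order while preserving the value distribution. Invalid windows keep their
#' positions and stay invalid. Burst durations of the surrogate follow
#' geometric run-length laws (exponential-like distributions).
#'
#' @param rs a `ratio_series`.
#' @param seed integer seed for reproducibility.
#' @return a shuffled `ratio_series`.
#' @export
shuffle_ratio_windows <- function(rs, seed = NULL) {
  stopifnot(inherits(rs, "ratio_series"))
  iv <- which(rs$window_valid)
  perm <- with_seed(seed, sample(iv))
  out <- rs
  out$R[iv] <- rs$R[perm]
  out$S_theta[iv] <- rs$S_theta[perm]
  out$S_delta[iv] <- rs$S_delta[perm]
  out
}

#' Shuffle burst durations (surrogates for timing and coupling)
#'
#' `theta_only` permutes the theta-burst durations in place while keeping
#' every delta-burst duration where it is: this destroys the association
#' between a theta-burst's duration and its time of occurrence but preserves
#' the quiet-time structure at `D0 = 0`. `full_order` independently permutes
#' the theta-duration list and the delta-duration list, breaking the pairing
#' between consecutive delta- and theta-bursts while preserving both
#' marginals and the alternation.
#'
#' @param bs a `burst_sequence` with strictly alternating theta/delta bursts.
#' @param mode `"theta_only"` or `"full_order"`.
#' @param seed integer seed.
#' @return a `burst_sequence` with shuffled durations and rebuilt timestamps.
#' @export
shuffle_burst_durations <- function(bs, mode = c("theta_only", "full_order"),
                                    seed = NULL) {
  mode <- match.arg(mode)
  b <- bs$bursts
  if (any(b$kind == "unassigned")) stop("sequence must be alternating theta/delta")
  if (any(diff(as.integer(b$kind == "theta")) == 0)) {
    stop("sequence must be alternating theta/delta")
  }
  it <- which(b$kind == "theta"); id <- which(b$kind == "delta")
  with_seed(seed, {
    b$d[it] <- b$d[it][sample(length(it))]
    if (mode == "full_order") b$d[id] <- b$d[id][sample(length(id))]
  })
  b$n <- as.integer(round(b$d / bs$w))
  b$t_start <- cumsum(c(0, b$d[-nrow(b)]))
  out <- bs
  out$bursts <- b
  out
}

#' Write a burst table to TSV
#'
#' @param bs a `burst_sequence`.
#' @param path output file.
#' @export
write_burst_table <- function(bs, path) {
  b <- bs$bursts
  df <- data.frame(kind = b$kind, t_start_s = b$t_start, duration_s = b$d,
                   n_windows = b$n, truncated = b$truncated,
                   period = bs$period)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
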