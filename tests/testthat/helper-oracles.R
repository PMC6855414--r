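# Independent oracles and fixture builders used across the suite.

# Literal transcription of the DFA recipe: integrate after mean subtraction,
# divide into non-overlapping boxes from the start, remove a per-box
# least-squares polynomial trend, r.m.s. over all covered points.
dfa_literal <- function(series, scales, order = 1) {
  prof <- cumsum(series - mean(series))
  Fv <- vapply(scales, function(n) {
    k <- length(prof) %/% n
    X <- cbind(1, stats::poly(seq_len(n), degree = order, raw = TRUE))
    H <- X %*% solve(crossprod(X), t(X))
    M <- matrix(prof[seq_len(k * n)], nrow = n)
    R <- M - H %*% M
    sqrt(mean(R^2))
  }, numeric(1))
  fit <- stats::lm(log10(Fv) ~ log10(scales))
  list(scales = scales, F = Fv, alpha = unname(coef(fit)[2]))
}

# Maximum-likelihood exponent for a power law truncated to [d_min, d_max].
ml_powerlaw <- function(d, d_min, d_max) {
  nll <- function(a) {
    lc <- log(a - 1) - log(d_min^(1 - a) - d_max^(1 - a))
    -(length(d) * lc - a * sum(log(d)))
  }
  stats::optimize(nll, c(1.05, 5))$minimum
}

# Maximum-likelihood generalized Gamma fit on raw samples (log-parameter
# Nelder-Mead from a neutral start).
ml_gengamma <- function(x, start = c(0.5, 0.5, 1)) {
  nll <- function(lp) {
    p <- exp(lp)
    -sum(log(dgengamma_burst(x, p[1], p[2], p[3])))
  }
  exp(stats::optim(log(start), nll)$par)
}

# Single-window periodogram band power (one-sided, integral over [lo, hi)).
periodogram_band <- function(x, fs, band) {
  n <- length(x)
  pg <- Mod(stats::fft(x))^2 / (fs * n)
  f <- (seq_len(n) - 1) * fs / n
  sel <- f >= band[1] & f < band[2] & f <= fs / 2
  2 * sum(pg[sel]) * fs / n
}

# Build a duration_distribution holding exact (bin-averaged) densities of a
# model law, for zero-noise inverse-problem tests.
exact_dist <- function(edges, cdf, n_fake = 1000L) {
  widths <- diff(edges)
  P <- (cdf(edges[-1]) - cdf(edges[-length(edges)])) / widths
  structure(list(centers = sqrt(edges[-length(edges)] * edges[-1]),
                 widths = widths, edges = edges, P = P,
                 dP = rep(0, length(P)),
                 counts = ifelse(P > 0, n_fake, 0L),
                 N = n_fake * length(P), underflow = 0L, overflow = 0L,
                 mean_d = sum(P * widths *
                                (edges[-1] + edges[-length(edges)]) / 2),
                 label = NULL, param = NULL),
            class = "duration_distribution")
}

# Minimal 16-bit EDF writer (round-trip fixture for the reader).
write_edf_fixture <- function(path, sigs, fs, labels,
                              phys = c(-100, 100)) {
  ns <- length(sigs)
  n_rec <- length(sigs[[1]]) %/% fs
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(x, w) {
    writeChar(substr(paste0(x, strrep(" ", w)), 1, w), con, w, eos = NULL)
  }
  pad("0", 8); pad("patient", 80); pad("recording", 80)
  pad("01.01.20", 8); pad("00.00.00", 8)
  pad(as.character(256 + ns * 256), 8); pad("", 44)
  pad(as.character(n_rec), 8); pad("1", 8); pad(as.character(ns), 4)
  for (l in labels) pad(l, 16)
  for (i in seq_len(ns)) pad("", 80)
  for (i in seq_len(ns)) pad("uV", 8)
  for (i in seq_len(ns)) pad(as.character(phys[1]), 8)
  for (i in seq_len(ns)) pad(as.character(phys[2]), 8)
  for (i in seq_len(ns)) pad("-32768", 8)
  for (i in seq_len(ns)) pad("32767", 8)
  for (i in seq_len(ns)) pad("", 80)
  for (i in seq_len(ns)) pad(as.character(fs), 8)
  for (i in seq_len(ns)) pad("", 32)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      seg <- sigs[[i]][((r - 1) * fs + 1):(r * fs)]
      dig <- as.integer(round((seg - phys[1]) / diff(phys) * 65535 - 32768))
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

# Error-bar-weighted misfit of a weighted log-log power-law fit; the
# duality discriminator for coarse-grained theta durations.
powerlaw_chi2 <- function(bs, min_count = 10L, bin_c = 0.18) {
  dt <- burst_durations(bs, "theta")
  dist <- suppressWarnings(
    empirical_pdf(dt, make_bins("logarithmic", w = bs$w, c = bin_c,
                                d_max = max(dt))))
  sel <- dist$counts >= min_count
  f <- stats::lm(log10(dist$P[sel]) ~ log10(dist$centers[sel]),
                 weights = dist$counts[sel])
  mean(((dist$P[sel] - 10^stats::fitted(f)) / dist$dP[sel])^2)
}
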