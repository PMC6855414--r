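#' Detrended fluctuation analysis
#'
#' Quantifies long-range power-law correlations in a sequence (here, of
#' consecutive burst durations). The series is integrated after mean
#' subtraction, the profile is divided into non-overlapping boxes of length
#' `n` (taken from both ends and averaged, so trailing data are used), a
#' least-squares polynomial of degree `order` is removed in each box, and the
#' r.m.s. fluctuation `F(n)` of the detrended profile is computed. A scaling
#' `F(n) ~ n^alpha_d` signals long-range correlations: `alpha_d = 0.5` for
#' uncorrelated noise, `> 0.5` persistent, `< 0.5` anti-persistent.
#'
#' @param series numeric vector.
#' @param scales integer box sizes; default about 20 log-spaced scales from
#'   `order + 3` (at least 4) to `length(series)/4`.
#' @param order detrending polynomial degree (default 1).
#' @param fit_range `c(n_min, n_max)` over which the exponent is fitted
#'   (default the full scale grid).
#' @return an object of class `dfa_result` with `scales`, `F`, `alpha_d`,
#'   `alpha_d_se`, `fit_range`.
#' @export
dfa <- function(series, scales = NULL, order = 1L, fit_range = NULL) {
  series <- as.numeric(series)
  N <- length(series)
  if (is.null(scales)) {
    lo <- max(4L, order + 3L)
    scales <- unique(round(10^seq(log10(lo), log10(N / 4), length.out = 20)))
  }
  scales <- sort(unique(as.integer(scales)))
  if (any(scales < order + 2L)) stop("scales must all be >= order + 2")
  if (N < 4L * max(scales)) stop("series too short for the largest scale")
  prof <- cumsum(series - mean(series))
  Fv <- vapply(scales, function(n) dfa_fluct(prof, n, order), numeric(1))
  res <- structure(list(scales = scales, F = Fv, order = order),
                   class = "dfa_result")
  if (all(Fv == 0)) {
    warning("constant series: F(n) = 0 everywhere, exponent undefined")
    res$alpha_d <- NA_real_; res$alpha_d_se <- NA_real_
    res$fit_range <- range(scales)
    return(res)
  }
  if (is.null(fit_range)) fit_range <- range(scales)
  sel <- scales >= fit_range[1] & scales <= fit_range[2] & Fv > 0
  fit <- stats::lm(log10(Fv[sel]) ~ log10(scales[sel]))
  res$alpha_d <- unname(stats::coef(fit)[2])
  res$alpha_d_se <- summary(fit)$coefficients[2, 2]
  res$fit_range <- fit_range
  res
}

# mean-square detrended fluctuation at one box size, forward + reverse pass
dfa_fluct <- function(prof, n, order) {
  N <- length(prof)
  k <- N %/% n
  X <- stats::poly(seq_len(n), degree = order, raw = TRUE)
  X <- cbind(1, X)
  H <- X %*% solve(crossprod(X), t(X))
  ms <- function(seg) {
    M <- matrix(seg, nrow = n)
    R <- M - H %*% M
    mean(R^2)
  }
  fwd <- ms(prof[seq_len(k * n)])
  rev <- ms(prof[(N - k * n + 1L):N])
  sqrt((fwd + rev) / 2)
}

#' @export
print.dfa_result <- function(x, ...) {
  cat(sprintf("DFA-%d: alpha_d = %.3f +/- %.3f over scales %g-%g\n",
              x$order, x$alpha_d, x$alpha_d_se,
              x$fit_range[1], x$fit_range[2]))
  invisible(x)
}

#' Write a DFA fluctuation function to TSV
#' @param res a `dfa_result`.
#' @param path output file.
#' @export
write_dfa <- function(res, path) {
  utils::write.table(data.frame(n = res$scales, F = res$F), path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

coupling_pairs <- function(bs, direction) {
  b <- bs$bursts[bs$bursts$kind != "unassigned", , drop = FALSE]
  first <- if (direction == "delta_then_theta") "delta" else "theta"
  second <- setdiff(c("delta", "theta"), first)
  i <- which(b$kind[-nrow(b)] == first & b$kind[-1] == second &
               diff(b$chunk) == 0L)
  data.frame(x = b$d[i], y = b$d[i + 1])
}

#' Spearman coupling between consecutive delta- and theta-burst durations
#'
#' Forms pairs of consecutive bursts (by default each delta-burst with the
#' immediately following theta-burst), ranks the two duration lists with
#' averaged tied ranks, and computes the Spearman correlation coefficient
#' (the Pearson correlation of the tied rankings). A negative value means
#' long delta-bursts tend to be followed by short theta-bursts.
#'
#' @param bs a `burst_sequence`.
#' @param direction `"delta_then_theta"` (default) or `"theta_then_delta"`.
#' @return an object of class `coupling_result` with `rho_s`, `n_pairs`,
#'   `direction`.
#' @export
spearman_coupling <- function(bs,
                              direction = c("delta_then_theta",
                                            "theta_then_delta")) {
  direction <- match.arg(direction)
  pr <- coupling_pairs(bs, direction)
  if (nrow(pr) < 10) stop("fewer than 10 consecutive pairs")
  rx <- rank(pr$x, ties.method = "average")
  ry <- rank(pr$y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("zero rank variance: all durations identical")
  }
  structure(list(rho_s = stats::cor(rx, ry), n_pairs = nrow(pr),
                 direction = direction),
            class = "coupling_result")
}

#' @export
print.coupling_result <- function(x, ...) {
  cat(sprintf("Spearman coupling (%s): rho_s = %.3f over %d pairs\n",
              x$direction, x$rho_s, x$n_pairs))
  invisible(x)
}

#' Shuffling surrogate test for burst-duration coupling
#'
#' Compares the observed Spearman coupling with its distribution under
#' `n_surr` full-order reshuffles (independent permutations of the theta- and
#' delta-duration lists, which preserve both marginals and the alternation
#' but destroy the pairing).
#'
#' @param bs a `burst_sequence`.
#' @param n_surr number of surrogates (>= 100).
#' @param seed integer seed.
#' @param direction pairing direction, as in [spearman_coupling()].
#' @return an object of class `surrogate_coupling_test` with `observed`,
#'   `surrogate_mean`, `surrogate_sd`, `n_surr`, `z`.
#' @export
surrogate_coupling_test <- function(bs, n_surr = 1000, seed = NULL,
                                    direction = c("delta_then_theta",
                                                  "theta_then_delta")) {
  direction <- match.arg(direction)
  stopifnot(n_surr >= 100)
  obs <- spearman_coupling(bs, direction)
  b <- bs$bursts[bs$bursts$kind != "unassigned", , drop = FALSE]
  dth <- b$d[b$kind == "theta"]; ddl <- b$d[b$kind == "delta"]
  kinds <- b$kind
  rho <- with_seed(seed, {
    vapply(seq_len(n_surr), function(i) {
      d <- numeric(nrow(b))
      d[kinds == "theta"] <- sample(dth)
      d[kinds == "delta"] <- sample(ddl)
      first <- if (direction == "delta_then_theta") "delta" else "theta"
      j <- which(kinds[-length(kinds)] == first &
                   kinds[-1] != first & diff(b$chunk) == 0L)
      stats::cor(rank(d[j], ties.method = "average"),
                 rank(d[j + 1], ties.method = "average"))
    }, numeric(1))
  })
  structure(list(observed = obs$rho_s, surrogate_mean = mean(rho),
                 surrogate_sd = stats::sd(rho), n_surr = n_surr,
                 z = (obs$rho_s - mean(rho)) / stats::sd(rho),
                 n_pairs = obs$n_pairs),
            class = "surrogate_coupling_test")
}

#' @export
print.surrogate_coupling_test <- function(x, ...) {
  cat(sprintf(
    "coupling surrogate test: rho_s = %.3f vs %.2g +/- %.2g (%d surrogates), z = %.1f\n",
    x$observed, x$surrogate_mean, x$surrogate_sd, x$n_surr, x$z))
  invisible(x)
}

#' Conditional delta-burst duration distribution
#'
#' Distribution of delta-burst durations conditioned on the preceding
#' theta-burst lasting longer than `d_star`, compared bin-by-bin with the
#' unconditional distribution. The per-bin error is the binomial error of
#' the conditional density (with `N` the conditioning subset size); a bin is
#' flagged significant when the absolute difference between conditional and
#' baseline density exceeds it. Under anti-correlated coupling, raising
#' `d_star` shifts probability mass towards short delta-bursts.
#'
#' @param bs a `burst_sequence`.
#' @param d_star threshold on the preceding theta-burst duration (seconds).
#' @param bins a `binning_scheme` (or edge vector) for the delta durations.
#' @return an object of class `conditional_result` with `d_star`, `cond`,
#'   `baseline` (both `duration_distribution`s), `eps_H`, `significant`.
#' @export
conditional_delta_pdf <- function(bs, d_star, bins) {
  pr <- coupling_pairs(bs, "theta_then_delta")   # x = theta_{i-1}, y = delta_i
  if (nrow(pr) < 50) stop("fewer than 50 qualifying pairs")
  sub <- pr$y[pr$x > d_star]
  if (length(sub) == 0) stop("empty conditioning subset")
  baseline <- empirical_pdf(pr$y, bins, label = "delta", param = 0)
  cond <- empirical_pdf(sub, bins, label = "delta", param = d_star)
  eps_H <- cond$dP
  significant <- abs(cond$P - baseline$P) > eps_H & eps_H > 0
  structure(list(d_star = d_star, cond = cond, baseline = baseline,
                 eps_H = eps_H, significant = significant,
                 n_cond = length(sub), n_pairs = nrow(pr)),
            class = "conditional_result")
}

#' @export
print.conditional_result <- function(x, ...) {
  cat(sprintf(
    "conditional P(d_delta | d_theta,prev > %g s): %d of %d pairs, %d significant bin(s)\n",
    x$d_star, x$n_cond, x$n_pairs, sum(x$significant)))
  invisible(x)
}
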