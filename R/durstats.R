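#' Build a binning scheme for burst durations
#'
#' Two schemes are supported. `logarithmic` bins are linear in log scale:
#' starting from the first edge `e1 = 0.5 w`, each edge is the previous one
#' times `10^c`. `recursive` bins grow geometrically in width: edge `n` is
#' `e1 + w * sum_{i=2..n} growth^(i-1)`. Edges are generated until they
#' exceed `d_max`.
#'
#' @param kind `"logarithmic"` or `"recursive"`.
#' @param w analysis window length in seconds (sets the first edge `0.5 w`).
#' @param c log-bin size for the logarithmic scheme (default 0.2).
#' @param growth geometric factor (> 1) for the recursive scheme (default 1.2).
#' @param d_max largest duration the bins must cover, in seconds.
#' @return an object of class `binning_scheme` with the edge vector.
#' @export
make_bins <- function(kind = c("logarithmic", "recursive"), w, c = 0.2,
                      growth = 1.2, d_max) {
  kind <- match.arg(kind)
  stopifnot(d_max > 0.5 * w)
  e1 <- 0.5 * w
  if (kind == "logarithmic") {
    stopifnot(c > 0)
    n_edge <- ceiling(log10(d_max / e1) / c) + 2L
    edges <- e1 * 10^(c * (0:(n_edge - 1L)))
  } else {
    stopifnot(growth > 1)
    edges <- e1
    i <- 2L
    while (edges[length(edges)] <= d_max) {
      edges <- c(edges, edges[length(edges)] + w * growth^(i - 1L))
      i <- i + 1L
    }
  }
  structure(list(edges = edges, kind = kind, c = c, growth = growth, w = w),
            class = "binning_scheme")
}

#' Binned empirical probability density with binomial errors
#'
#' Density in bin i is `count_i / (N * dD_i)` where `N` is the total number
#' of durations supplied (including any below the first edge or above the
#' last, which are tallied as underflow/overflow). The error bar on each bin
#' is the binomial standard error of the bin probability `p_i = P_i dD_i`,
#' `dP_i = sqrt(p_i (1 - p_i) / N) / dD_i`.
#'
#' @param durations numeric vector of durations (seconds, or dimensionless
#'   for rescaled axes).
#' @param bins a `binning_scheme`, or a numeric vector of edges.
#' @param label optional label (`"theta"`, `"delta"`, `"quiet"`, ...).
#' @param param optional family key (the Th, w or D0 value this distribution
#'   belongs to in a collapse family).
#' @return an object of class `duration_distribution` with `centers`,
#'   `widths`, `P`, `dP`, `counts`, `N`, `underflow`, `overflow`, `mean_d`.
#' @export
empirical_pdf <- function(durations, bins, label = NULL, param = NULL) {
  edges <- if (inherits(bins, "binning_scheme")) bins$edges else bins
  log_bins <- inherits(bins, "binning_scheme") && bins$kind == "logarithmic"
  stopifnot(length(durations) > 0, length(edges) >= 2)
  N <- length(durations)
  underflow <- sum(durations < edges[1])
  overflow <- sum(durations >= edges[length(edges)])
  if (underflow > 0) {
    warning(underflow, " duration(s) below the first bin edge (underflow)")
  }
  inside <- durations[durations >= edges[1] &
                        durations < edges[length(edges)]]
  counts <- if (length(inside)) {
    tabulate(findInterval(inside, edges), nbins = length(edges) - 1L)
  } else {
    integer(length(edges) - 1L)
  }
  widths <- diff(edges)
  centers <- if (log_bins) {
    sqrt(edges[-length(edges)] * edges[-1])
  } else {
    (edges[-length(edges)] + edges[-1]) / 2
  }
  p <- counts / N
  P <- p / widths
  dP <- sqrt(p * (1 - p) / N) / widths
  structure(list(centers = centers, widths = widths, edges = edges,
                 P = P, dP = dP,
                 counts = counts, N = N, underflow = underflow,
                 overflow = overflow, mean_d = mean(durations),
                 label = label, param = param),
            class = "duration_distribution")
}

#' @export
print.duration_distribution <- function(x, ...) {
  cat(sprintf(
    "duration_distribution%s: %d bins (%d occupied), N = %d, <d> = %.3g\n",
    if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
    length(x$P), sum(x$counts > 0), x$N, x$mean_d))
  invisible(x)
}

#' Write a distribution table to TSV
#' @param dist a `duration_distribution`.
#' @param path output file.
#' @export
write_distribution <- function(dist, path) {
  df <- data.frame(center_s = dist$centers, width_s = dist$widths,
                   P = dist$P, dP = dist$dP, n_in_bin = dist$counts)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

default_power_law_range <- function(dist) {
  # exclude the first bin (it starts at the half-window edge 0.5 w)
  lower <- if (length(dist$centers) > 1) dist$centers[2] else dist$centers[1]
  tail_counts <- rev(cumsum(rev(dist$counts)))
  ok <- which(tail_counts >= 10)
  upper <- if (length(ok)) dist$centers[max(ok)] else dist$centers[length(dist$centers)]
  c(lower, upper)
}

#' Least-squares power-law fit on log-binned densities
#'
#' Ordinary least squares of `log10 P` on `log10 d` over the occupied bins in
#' `fit_range`: `log(P(d)) = -alpha log(d) + C`. The default range starts at
#' one analysis window (the half-window first edge is excluded) and stops
#' where fewer than 10 events remain in the tail, before the exponential
#' cut-off dominates.
#'
#' @param dist a `duration_distribution`.
#' @param fit_range `c(d_min, d_max)` in the units of the distribution axis.
#' @return an object of class `power_law_fit` with `alpha`, `alpha_se`,
#'   `intercept`, `fit_range`, `n_bins`.
#' @export
fit_power_law <- function(dist, fit_range = NULL) {
  if (is.null(fit_range)) fit_range <- default_power_law_range(dist)
  sel <- dist$counts >= 1 & dist$centers >= fit_range[1] &
    dist$centers <= fit_range[2]
  if (sum(sel) < 4) stop("fewer than 4 occupied bins in the fit range")
  lx <- log10(dist$centers[sel]); ly <- log10(dist$P[sel])
  fit <- stats::lm(ly ~ lx)
  sm <- summary(fit)$coefficients
  structure(list(alpha = -unname(stats::coef(fit)[2]),
                 alpha_se = unname(sm[2, 2]),
                 intercept = unname(stats::coef(fit)[1]),
                 fit_range = fit_range, n_bins = sum(sel)),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power-law fit: alpha = %.3f +/- %.3f (%d bins, %.3g-%.3g)\n",
              x$alpha, x$alpha_se, x$n_bins, x$fit_range[1], x$fit_range[2]))
  invisible(x)
}

#' Weibull density
#'
#' `P(d) = (beta/lambda) (d/lambda)^(beta-1) exp(-(d/lambda)^beta)`:
#' shape `beta`, characteristic time scale `lambda`. `beta = 1` is the
#' exponential; `beta < 1` a stretched-exponential tail.
#'
#' @param d durations.
#' @param beta shape parameter (> 0).
#' @param lambda scale parameter (> 0).
#' @return density values.
#' @export
dweibull_burst <- function(d, beta, lambda) {
  stats::dweibull(d, shape = beta, scale = lambda)
}

#' Generalized Gamma density on a dimensionless axis
#'
#' `G(x; b, nu, p) = (p / b^nu) x^(nu-1) exp(-(x/b)^p) / Gamma(nu/p)`. The
#' family contains the Weibull (`nu = p`) and Gamma (`p = 1`) distributions;
#' it is the quiet-time master curve.
#'
#' @param x dimensionless quiet times (Delta t / mean Delta t).
#' @param b scale parameter (> 0).
#' @param nu,p shape parameters (> 0).
#' @return density values.
#' @export
dgengamma_burst <- function(x, b, nu, p) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- exp(log(p) - nu * log(b) + (nu - 1) * log(x[pos]) -
                    (x[pos] / b)^p - lgamma(nu / p))
  out
}

#' Generalized Gamma cumulative distribution function
#'
#' Uses the representation `(X/b)^p ~ Gamma(nu/p, 1)`.
#'
#' @param x quantiles.
#' @param b,nu,p distribution parameters.
#' @return cumulative probabilities.
#' @export
pgengamma_burst <- function(x, b, nu, p) {
  stats::pgamma((pmax(x, 0) / b)^p, shape = nu / p)
}

#' Draw from the generalized Gamma distribution
#'
#' Uses the representation `X = b * Y^(1/p)` with `Y ~ Gamma(nu/p, 1)`.
#'
#' @param n number of draws.
#' @param b,nu,p distribution parameters.
#' @param seed integer seed.
#' @return numeric vector of draws.
#' @export
rgengamma_burst <- function(n, b, nu, p, seed = NULL) {
  with_seed(seed, b * stats::rgamma(n, shape = nu / p, scale = 1)^(1 / p))
}

#' Draw from a truncated power law
#'
#' Inverse-CDF sampling of `P(d) ~ d^-alpha` on `[d_min, d_max]`.
#'
#' @param n number of draws.
#' @param alpha exponent (> 0, != 1).
#' @param d_min,d_max support bounds.
#' @param seed integer seed.
#' @return numeric vector of draws.
#' @export
rpowerlaw <- function(n, alpha, d_min, d_max, seed = NULL) {
  stopifnot(alpha != 1, d_max > d_min, d_min > 0)
  u <- with_seed(seed, stats::runif(n))
  a1 <- 1 - alpha
  (d_min^a1 + u * (d_max^a1 - d_min^a1))^(1 / a1)
}

# Weighted (relative) Levenberg-Marquardt fit of a positive density model.
# Residuals are (P - f)/P, i.e. weights W = 1/P^2; bins with fewer than
# 2 counts are dropped (the weight diverges as P -> 0). The model density
# is bin-averaged via its CDF (the binned estimate P_i has expectation
# exactly (F(hi) - F(lo))/dD, so the fit stays consistent for wide bins).
# Parameters are optimized on the log scale to enforce positivity.
fit_wls_density <- function(dist, cdf, starts, min_count = 2L) {
  sel <- dist$counts >= min_count & dist$P > 0
  if (sum(sel) < 4) stop("fewer than 4 bins with >= 2 counts")
  lo <- dist$edges[-length(dist$edges)][sel]
  hi <- dist$edges[-1][sel]
  y <- dist$P[sel]
  fn <- function(x_lo, x_hi, par) (cdf(x_hi, par) - cdf(x_lo, par)) /
    (x_hi - x_lo)
  resid_fn <- function(lpar) (y - fn(lo, hi, exp(lpar))) / y
  best <- NULL
  for (s in starts) {
    out <- tryCatch(
      minpack.lm::nls.lm(par = log(s), fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(out)) next
    ssr <- sum(out$fvec^2)
    if (!is.finite(ssr)) next
    if (is.null(best) || ssr < best$ssr) {
      best <- list(par = exp(out$par), ssr = ssr,
                   converged = out$info %in% 1:3)
    }
  }
  if (is.null(best)) stop("all starting points failed")
  best
}

#' Weighted Levenberg-Marquardt Weibull fit of a binned density
#'
#' Minimizes `sum W_i (P_i - f(d_i; beta, lambda))^2` with weights
#' `W = 1/P^2` (relative least squares), the weighting used for the
#' delta-burst duration distributions. Initial values combine a
#' method-of-moments seed with perturbed seeds to escape the multimodality
#' of the objective at small shape values.
#'
#' @param dist a `duration_distribution`.
#' @param start optional `c(beta, lambda)` initial guess.
#' @return an object of class `weibull_fit` with `beta`, `lam`, `converged`,
#'   `ssr`.
#' @export
fit_weibull <- function(dist, start = NULL) {
  if (is.null(start)) start <- weibull_moment_seed(dist)
  starts <- list(start,
                 start * c(0.5, 1), start * c(2, 1),
                 start * c(1, 0.5), start * c(1, 2))
  best <- fit_wls_density(
    dist, function(x, p) stats::pweibull(x, shape = p[1], scale = p[2]),
    starts)
  structure(list(beta = best$par[1], lam = best$par[2],
                 converged = best$converged, ssr = best$ssr),
            class = "weibull_fit")
}

weibull_moment_seed <- function(dist) {
  m1 <- sum(dist$centers * dist$P * dist$widths)
  m2 <- sum(dist$centers^2 * dist$P * dist$widths)
  tot <- sum(dist$P * dist$widths)
  if (tot <= 0) return(c(1, max(dist$mean_d, 1)))
  m1 <- m1 / tot; m2 <- m2 / tot
  cv2 <- max(m2 / m1^2 - 1, 1e-3)
  f <- function(b) gamma(1 + 2 / b) / gamma(1 + 1 / b)^2 - 1 - cv2
  beta <- tryCatch(stats::uniroot(f, c(0.15, 20))$root, error = function(e) 1)
  c(beta, m1 / gamma(1 + 1 / beta))
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf("Weibull fit: beta = %.3f, lambda = %.3g%s\n", x$beta, x$lam,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Weighted Levenberg-Marquardt generalized-Gamma fit
#'
#' Same weighted least-squares scheme as [fit_weibull()], applied to the
#' three-parameter generalized Gamma density on the dimensionless quiet-time
#' axis. Seeded from the Weibull special case (`nu = p = beta`, `b = lambda`)
#' plus perturbed starts.
#'
#' @param dist a `duration_distribution` on the rescaled axis.
#' @param start optional `c(b, nu, p)` initial guess.
#' @return an object of class `gengamma_fit` with `b`, `nu`, `p`,
#'   `converged`, `ssr`.
#' @export
fit_gen_gamma <- function(dist, start = NULL) {
  if (is.null(start)) {
    wb <- tryCatch(fit_weibull(dist), error = function(e) NULL)
    start <- if (is.null(wb)) c(0.5, 0.5, 1) else c(wb$lam, wb$beta, wb$beta)
  }
  starts <- list(start,
                 start * c(0.5, 1, 1), start * c(2, 1, 1),
                 start * c(1, 0.5, 1), start * c(1, 1, 0.5),
                 start * c(1, 2, 1), c(0.2, 0.4, 1))
  best <- fit_wls_density(
    dist, function(x, par) pgengamma_burst(x, par[1], par[2], par[3]),
    starts)
  structure(list(b = best$par[1], nu = best$par[2], p = best$par[3],
                 converged = best$converged, ssr = best$ssr),
            class = "gengamma_fit")
}

#' @export
print.gengamma_fit <- function(x, ...) {
  cat(sprintf("generalized Gamma fit: b = %.3f, nu = %.3f, p = %.3f%s\n",
              x$b, x$nu, x$p,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

rescale_curve <- function(dist, transform, exponent, alpha) {
  ok <- dist$P > 0
  x <- dist$centers[ok]; y <- dist$P[ok]
  switch(transform,
         theta_Th = list(x = x * dist$param^exponent, y = y * x^alpha),
         delta_mean = list(x = x / dist$mean_d^exponent,
                           y = y * dist$mean_d^exponent),
         theta_w = list(x = x / dist$param, y = y * dist$param),
         quiet_mean = list(x = x / dist$mean_d, y = y * dist$mean_d),
         stop("unknown transform"))
}

collapse_objective <- function(curves, n_grid = 50) {
  lo <- max(vapply(curves, function(cv) min(cv$x), numeric(1)))
  hi <- min(vapply(curves, function(cv) max(cv$x), numeric(1)))
  if (!(hi > lo)) return(list(objective = Inf, master = NULL))
  grid <- 10^seq(log10(lo), log10(hi), length.out = n_grid)
  ly <- vapply(curves, function(cv) loglog_interp(cv$x, cv$y, grid),
               numeric(n_grid))
  ok <- rowSums(is.na(ly)) == 0
  if (sum(ok) < 3) return(list(objective = Inf, master = NULL))
  ly <- ly[ok, , drop = FALSE]
  m <- rowMeans(ly)
  list(objective = mean((ly - m)^2),
       master = list(x = grid[ok], y = 10^m))
}

#' Scaling collapse of a family of duration distributions
#'
#' Rescales each member of a family of distributions (indexed by threshold
#' Th, window size w, or quiet-time threshold D0) onto a common master curve:
#' \describe{
#'   \item{`theta_Th`}{`x = d * Th^eps`, `y = P d^alpha`; free exponent eps.}
#'   \item{`delta_mean`}{`x = d / <d>^eta`, `y = P <d>^eta`; free exponent eta.}
#'   \item{`theta_w`}{`x = d / w`, `y = P w`; no free exponent.}
#'   \item{`quiet_mean`}{`x = dt / <dt>`, `y = P <dt>`; no free exponent.}
#' }
#' The collapse misfit is the mean squared deviation of the curves from
#' their pointwise log-space mean on a common logarithmic grid; a free
#' exponent is estimated by grid search followed by golden-section
#' refinement. For `theta_Th` the distributions' `param` field must hold the
#' threshold; for `theta_w` the window size.
#'
#' @param family list of `duration_distribution` objects with distinct
#'   family keys.
#' @param transform one of `"theta_Th"`, `"delta_mean"`, `"theta_w"`,
#'   `"quiet_mean"`.
#' @param alpha power-law exponent used in the `theta_Th` vertical rescaling
#'   (default 2.35).
#' @param exponent fix the rescaling exponent instead of estimating it.
#' @param exponent_grid search grid for the free exponent.
#' @return an object of class `collapse_result` with the exponent, the
#'   misfit `objective` and the `master_curve`.
#' @export
collapse <- function(family,
                     transform = c("theta_Th", "delta_mean", "theta_w",
                                   "quiet_mean"),
                     alpha = 2.35, exponent = NULL,
                     exponent_grid = seq(0, 3, by = 0.05)) {
  transform <- match.arg(transform)
  stopifnot(length(family) >= 2)
  free <- transform %in% c("theta_Th", "delta_mean") && is.null(exponent)
  obj_at <- function(e) {
    curves <- lapply(family, rescale_curve, transform = transform,
                     exponent = e, alpha = alpha)
    collapse_objective(curves)
  }
  exponent_name <- switch(transform, theta_Th = "epsilon",
                          delta_mean = "eta", theta_w = "none",
                          quiet_mean = "none")
  if (free) {
    vals <- vapply(exponent_grid, function(e) obj_at(e)$objective, numeric(1))
    if (all(!is.finite(vals))) stop("no overlapping support after rescaling")
    e0 <- exponent_grid[which.min(vals)]
    span <- diff(range(exponent_grid)) / (length(exponent_grid) - 1)
    opt <- stats::optimize(function(e) obj_at(e)$objective,
                           interval = c(e0 - 2 * span, e0 + 2 * span))
    exponent <- opt$minimum
    # a flat objective (e.g. identical curves) has no informative minimum
    if (vals[which.min(vals)] <= 1e-12) exponent <- e0
  } else if (is.null(exponent)) {
    exponent <- switch(transform, theta_w = 1, quiet_mean = 1, 1)
  }
  res <- obj_at(exponent)
  if (!is.finite(res$objective)) stop("no overlapping support after rescaling")
  structure(list(transform = transform, exponent_name = exponent_name,
                 exponent_value = exponent, objective = res$objective,
                 master_curve = res$master, alpha = alpha,
                 n_curves = length(family)),
            class = "collapse_result")
}

#' @export
print.collapse_result <- function(x, ...) {
  cat(sprintf("collapse (%s): %s = %.3f, objective = %.3g (%d curves)\n",
              x$transform,
              if (x$exponent_name == "none") "fixed exponent" else x$exponent_name,
              x$exponent_value, x$objective, x$n_curves))
  invisible(x)
}
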