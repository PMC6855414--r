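test_that("binning schemes follow their recursions from the half-window edge", {
  lg <- make_bins("logarithmic", w = 5, c = 0.2, d_max = 50)
  expect_equal(lg$edges[1:3], c(2.5, 2.5 * 10^0.2, 2.5 * 10^0.4),
               tolerance = 1e-9)
  expect_equal(diff(log10(lg$edges)), rep(0.2, length(lg$edges) - 1),
               tolerance = 1e-12)
  rc <- make_bins("recursive", w = 5, growth = 1.2, d_max = 20)
  expect_equal(rc$edges[1:3], c(2.5, 2.5 + 5 * 1.2, 2.5 + 5 * 1.2 + 5 * 1.44),
               tolerance = 1e-9)
  expect_error(make_bins("recursive", w = 5, growth = 1, d_max = 20))
  expect_true(all(diff(lg$edges) > 0) && all(diff(rc$edges) > 0))
})

test_that("the empirical density normalizes and carries binomial errors", {
  d100 <- rep(1.5, 100)
  dist <- empirical_pdf(d100, c(1, 2, 3))
  expect_equal(dist$P, c(1, 0))
  # a bin holding a quarter of 100 events over width 1
  dist2 <- empirical_pdf(c(rep(1.5, 25), rep(2.5, 75)), c(1, 2, 3))
  expect_equal(dist2$dP[1], sqrt(0.25 * 0.75 / 100), tolerance = 1e-12)
  d <- with_seed(20, rweibull(5000, 0.7, 30)) + 2.5
  bins <- make_bins("recursive", w = 5, growth = 1.2, d_max = max(d))
  dist3 <- empirical_pdf(d, bins)
  expect_equal(sum(dist3$P * dist3$widths) + dist3$overflow / dist3$N, 1,
               tolerance = 1e-9)
  expect_warning(empirical_pdf(c(1, 10), c(2, 20)), "underflow")
})

test_that("power-law fitting is exact on exact log-linear data and null on flat data", {
  edges <- 2.5 * 10^(0.2 * 0:15)
  dist <- exact_dist(edges, function(x) {
    a <- 1 - 2.35
    (x^a - edges[1]^a) / (edges[length(edges)]^a - edges[1]^a)
  })
  # evaluate the fit on exact center densities rather than bin averages
  dist$P <- 0.37 * dist$centers^-2.35
  fit <- fit_power_law(dist, fit_range = range(dist$centers))
  expect_equal(fit$alpha, 2.35, tolerance = 1e-9)
  expect_lt(fit$alpha_se, 1e-9)

  dist$P <- rep(0.01, length(dist$P))
  expect_equal(fit_power_law(dist,
                             fit_range = range(dist$centers))$alpha, 0,
               tolerance = 1e-12)
  dist$counts <- rep(0L, length(dist$P))
  expect_error(fit_power_law(dist), "fewer than 4")
})

test_that("binned power-law fit agrees with a maximum-likelihood oracle on samples", {
  d <- rpowerlaw(1e5, 2.35, 5, 500, seed = 43)
  dist <- empirical_pdf(d, make_bins("logarithmic", w = 10, c = 0.2,
                                     d_max = max(d)))
  fit <- fit_power_law(dist, fit_range = c(5, 100))
  expect_lt(abs(fit$alpha - 2.35), 0.05)
  a_ml <- ml_powerlaw(d, 5, 500)
  expect_lt(abs(fit$alpha - a_ml),
            2 * sqrt(fit$alpha_se^2 + (0.35 / sqrt(length(d)))^2) + 0.02)
})

test_that("Weibull fitting solves the zero-noise inverse problem and the exponential case", {
  bins <- make_bins("recursive", w = 5, growth = 1.2, d_max = 200)
  dist <- exact_dist(bins$edges, function(x) pweibull(x, 0.5, 10))
  fit <- fit_weibull(dist)
  expect_equal(fit$beta, 0.5, tolerance = 1e-6)
  expect_equal(fit$lam, 10, tolerance = 1e-5)
  expect_true(fit$converged)

  d <- with_seed(21, rexp(1e5, rate = 1 / 20))
  de <- suppressWarnings(
    empirical_pdf(d, make_bins("recursive", w = 5, growth = 1.2,
                               d_max = max(d))))
  fe <- fit_weibull(de)
  expect_lt(abs(fe$beta - 1), 0.05)
})

test_that("Weibull fitting recovers the stretched-exponential regime, agreeing with ML", {
  d <- with_seed(42, rweibull(1e5, shape = 0.59, scale = 9.6))
  dist <- suppressWarnings(
    empirical_pdf(d, make_bins("recursive", w = 5, growth = 1.2,
                               d_max = max(d))))
  fit <- fit_weibull(dist)
  expect_lt(abs(fit$beta - 0.59), 0.05)
  ml <- MASS::fitdistr(d, "weibull")
  expect_lt(abs(fit$beta - unname(ml$estimate["shape"])), 0.05)
})

test_that("generalized-Gamma fitting reduces correctly and recovers exact densities", {
  edges <- 0.01 * 10^(0.15 * 0:20)
  # nu = p = 1 is the exponential with scale b; the family is nearly
  # degenerate there, so the recovered density (not the raw parameters)
  # is the meaningful check
  de <- exact_dist(edges, function(x) pexp(x, rate = 1 / 0.3))
  fe <- fit_gen_gamma(de)   # seeded from the Weibull special case
  xs <- de$centers[de$P > 0]
  expect_equal(dgengamma_burst(xs, fe$b, fe$nu, fe$p),
               dexp(xs, rate = 1 / 0.3), tolerance = 1e-3)
  dist <- exact_dist(edges, function(x) pgengamma_burst(x, 0.2, 0.4, 1))
  fit <- fit_gen_gamma(dist)
  expect_equal(c(fit$b, fit$nu, fit$p), c(0.2, 0.4, 1), tolerance = 1e-6)
})

test_that("generalized-Gamma fitting recovers the quiet-time master-curve shape from samples", {
  x <- rgengamma_burst(1e5, b = 0.15, nu = 0.31, p = 0.91, seed = 44)
  bins <- make_bins("logarithmic", w = 2 * quantile(x, 0.001), c = 0.2,
                    d_max = max(x))
  fit <- fit_gen_gamma(suppressWarnings(empirical_pdf(x, bins)))
  expect_lt(abs(fit$nu - 0.31), 0.05)
  ml <- ml_gengamma(x)
  expect_lt(abs(fit$nu - ml[2]), 0.05)
})

test_that("collapse misfit vanishes for identical families and recovers a built-in exponent", {
  g <- function(x) exp(-x / 50)
  mk <- function(Th) {
    d <- 10^seq(log10(2.5), 3, by = 0.1)
    edges <- c(d, d[length(d)] * 10^0.1)
    dist <- exact_dist(edges, function(x) x)   # placeholder, overwritten
    dist$centers <- d
    dist$P <- d^-2 * g(d * Th^0.8)
    dist$param <- Th
    dist$mean_d <- 10
    dist
  }
  fam <- lapply(c(1, 1.2, 1.5, 2), mk)
  cr <- collapse(fam, "theta_Th", alpha = 2)
  expect_lt(abs(cr$exponent_value - 0.8), 0.05)
  expect_lt(cr$objective, 1e-3)

  same <- list(mk(1), mk(1), mk(1))
  same <- lapply(same, function(d) { d$param <- 1; d })
  for (e in c(0.2, 0.7, 1.4)) {
    expect_equal(collapse(same, "theta_Th", alpha = 2,
                          exponent = e)$objective, 0, tolerance = 1e-20)
  }
  # relabeling the family keys leaves the objective unchanged
  relab <- fam
  relab[[1]]$param <- fam[[2]]$param; relab[[2]]$param <- fam[[1]]$param
  relab[[1]] <- fam[[2]]; relab[[2]] <- fam[[1]]
  expect_equal(collapse(relab, "theta_Th", alpha = 2,
                        exponent = 0.8)$objective,
               collapse(fam, "theta_Th", alpha = 2,
                        exponent = 0.8)$objective)
})

test_that("mean-rescaled exponential quiet times collapse onto exp(-x)", {
  fams <- lapply(c(10, 25, 60), function(mu) {
    x <- with_seed(round(mu), rexp(2e4, rate = 1 / mu))
    suppressWarnings(
      empirical_pdf(x, make_bins("logarithmic", w = 0.02 * mu, c = 0.15,
                                 d_max = max(x)), param = mu))
  })
  cr <- collapse(fams, "quiet_mean")
  expect_lt(cr$objective, 0.01)
  sel <- cr$master_curve$x > 0.2 & cr$master_curve$x < 3
  expect_equal(log(cr$master_curve$y[sel]), -cr$master_curve$x[sel],
               tolerance = 0.15)
})

test_that("pure-scaling collapse transforms preserve curve normalization", {
  mk <- function(w) {
    d <- with_seed(50 + w, rweibull(2e4, 0.7, 8 * w) + 0.5 * w)
    suppressWarnings(
      empirical_pdf(d, make_bins("logarithmic", w = w, c = 0.1,
                                 d_max = max(d)), param = w))
  }
  fam <- lapply(c(2, 5, 10), mk)
  for (tr in c("theta_w", "quiet_mean")) {
    for (dist in fam) {
      cv <- sleepcrit:::rescale_curve(dist, transform = tr, exponent = 1,
                                      alpha = 2.35)
      scale_fac <- if (tr == "theta_w") dist$param else dist$mean_d
      dx <- dist$widths[dist$P > 0] / scale_fac
      expect_equal(sum(cv$y * dx), 1, tolerance = 0.02)
    }
  }
})
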