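#' Configuration for the anti-correlated burst-pairing model
#'
#' The phenomenological model draws theta durations from a truncated power
#' law and delta durations from a Weibull law, ranks each list, chains them
#' by Gaussian rank mirroring (the next rank is drawn around `1 + N - k`
#' with standard deviation `sigma`, in rank units), renders the alternating
#' sequence as a binary window series and coarse-grains it by majority rule
#' over `Delta` windows. `sigma` is the single coupling knob: `sigma -> 0`
#' gives deterministic anti-monotone pairing (Spearman rho -> -1),
#' `sigma >> N` approaches random pairing.
#'
#' @param N number of pairing iterations (bursts generated).
#' @param sigma Gaussian rank standard deviation (rank units; default
#'   `N/20`, inside the regime where coarse-graining preserves the
#'   power-law/Weibull duality).
#' @param w window length in seconds (default 2, the model's native scale).
#' @param Delta coarse-graining factor in windows (odd; default 5).
#' @param theta_law list `(alpha, d_min, d_max)` for the theta power law.
#' @param delta_law list `(beta, lambda)` for the delta Weibull law
#'   (lambda in seconds).
#' @param seed integer seed.
#' @return an object of class `burst_model_config`.
#' @export
burst_model_config <- function(N = 10000L, sigma = N / 20, w = 2,
                               Delta = 5L,
                               theta_law = list(alpha = 2.35, d_min = w,
                                                d_max = 100),
                               delta_law = list(beta = 0.59, lambda = 9.6),
                               seed = NULL) {
  stopifnot(N >= 2, sigma >= 0, Delta %% 2 == 1, Delta >= 1)
  structure(list(N = as.integer(N), sigma = sigma, w = w,
                 Delta = as.integer(Delta), theta_law = theta_law,
                 delta_law = delta_law, seed = seed),
            class = "burst_model_config")
}

#' Draw and rank model durations
#'
#' Draws `N` theta durations from the configured truncated power law and `N`
#' delta durations from the configured Weibull law, quantizes each to a
#' multiple of `w` by rounding up (a burst spans at least one window), and
#' sorts both lists ascending so that list position equals rank (rank `N` is
#' the longest duration).
#'
#' @param cfg a `burst_model_config`.
#' @param seed overrides `cfg$seed` when given.
#' @return list with sorted numeric vectors `theta` and `delta`.
#' @export
draw_and_rank <- function(cfg, seed = cfg$seed) {
  with_seed(seed, {
    th <- rpowerlaw(cfg$N, cfg$theta_law$alpha, cfg$theta_law$d_min,
                    cfg$theta_law$d_max)
    dl <- stats::rweibull(cfg$N, shape = cfg$delta_law$beta,
                          scale = cfg$delta_law$lambda)
    list(theta = sort(ceiling(th / cfg$w) * cfg$w),
         delta = sort(pmax(ceiling(dl / cfg$w), 1) * cfg$w))
  })
}

#' Gaussian-rank anti-correlated pairing
#'
#' Builds an alternating theta/delta duration sequence of length `N`. The
#' first burst is a theta-burst with uniform random rank `k_1`; at each later
#' step the rank is drawn from a Gaussian with mean `1 + N - k_(i-1)` and
#' standard deviation `sigma`, rounded to the nearest integer and clipped to
#' `[1, N]`, and indexes the opposite-kind sorted list (ranks are sampled
#' with replacement).
#'
#' @param theta_ranked,delta_ranked ascending duration vectors of equal
#'   length (from [draw_and_rank()]).
#' @param sigma Gaussian rank standard deviation (>= 0).
#' @param w window length in seconds.
#' @param seed integer seed.
#' @return a `burst_sequence` of `N` alternating bursts.
#' @export
pair_anticorrelated <- function(theta_ranked, delta_ranked, sigma, w,
                                seed = NULL) {
  if (sigma < 0) stop("sigma must be >= 0")
  N <- length(theta_ranked)
  stopifnot(length(delta_ranked) == N)
  with_seed(seed, {
    k <- integer(N)
    k[1] <- sample.int(N, 1)
    if (N > 1) {
      eps <- stats::rnorm(N - 1, mean = 0, sd = sigma)
      for (i in 2:N) {
        k[i] <- min(max(round(1 + N - k[i - 1] + eps[i - 1]), 1L), N)
      }
    }
    kind <- rep(c("theta", "delta"), length.out = N)
    d <- ifelse(kind == "theta", theta_ranked[k], delta_ranked[k])
    new_burst_sequence(kind, d = d, w = w, strict = FALSE)
  })
}

#' Random (uncoupled) pairing control
#'
#' Alternating theta/delta sequence in which each duration is drawn
#' uniformly with replacement from its own sorted list; marginals are
#' preserved but consecutive durations are independent.
#'
#' @inheritParams pair_anticorrelated
#' @return a `burst_sequence` of `N` alternating bursts.
#' @export
pair_random <- function(theta_ranked, delta_ranked, w, seed = NULL) {
  N <- length(theta_ranked)
  stopifnot(length(delta_ranked) == N)
  with_seed(seed, {
    kind <- rep(c("theta", "delta"), length.out = N)
    k <- sample.int(N, N, replace = TRUE)
    d <- ifelse(kind == "theta", theta_ranked[k], delta_ranked[k])
    new_burst_sequence(kind, d = d, w = w, strict = FALSE)
  })
}

#' Binarize a burst sequence into window labels
#'
#' Each burst contributes `n = d/w` windows labelled `+1` (theta) or `-1`
#' (delta).
#'
#' @param bs a `burst_sequence` whose durations are multiples of `w`.
#' @param w window length in seconds (default the sequence's own).
#' @return integer vector of +1/-1 labels, one per window.
#' @export
binarize <- function(bs, w = bs$w) {
  b <- bs$bursts
  n <- b$d / w
  if (any(abs(n - round(n)) > 1e-8)) {
    stop("burst durations are not multiples of w")
  }
  rep(ifelse(b$kind == "theta", 1L, -1L), times = as.integer(round(n)))
}

#' Majority-rule coarse-graining of a binary window series
#'
#' Groups `Delta` consecutive windows (Delta odd, so no ties) and assigns
#' each group the majority label; the trailing partial group is dropped.
#'
#' @param binary integer vector of +1/-1 labels.
#' @param Delta odd group size.
#' @return coarse-grained +1/-1 vector of length `floor(length(binary)/Delta)`.
#' @export
coarse_grain <- function(binary, Delta) {
  Delta <- as.integer(Delta)
  if (Delta %% 2 == 0) stop("Delta must be odd (majority rule needs no ties)")
  ng <- length(binary) %/% Delta
  if (ng == 0) return(integer(0))
  M <- matrix(binary[seq_len(ng * Delta)], nrow = Delta)
  ifelse(colSums(M) > 0, 1L, -1L)
}

binary_to_bursts <- function(binary, w) {
  r <- rle(binary)
  kind <- ifelse(r$values > 0, "theta", "delta")
  trunc <- rep(FALSE, length(kind))
  if (length(kind) > 0) trunc[c(1, length(kind))] <- TRUE
  new_burst_sequence(kind, n = r$lengths, w = w, truncated = trunc)
}

#' Run the full pairing model
#'
#' Chains draw, Gaussian-rank (or random) pairing, binarization and
#' majority-rule coarse-graining, and extracts burst durations at both
#' levels. Coarse durations are in units of `Delta * w` seconds.
#'
#' @param cfg a `burst_model_config`.
#' @param pairing `"anticorrelated"` (default) or `"random"` (control).
#' @return list with elements `fine` and `coarse` (both `burst_sequence`s)
#'   and the `cfg` used.
#' @export
run_model <- function(cfg, pairing = c("anticorrelated", "random")) {
  pairing <- match.arg(pairing)
  drawn <- draw_and_rank(cfg)
  seed2 <- if (is.null(cfg$seed)) NULL else cfg$seed + 1L
  fine <- if (pairing == "anticorrelated") {
    pair_anticorrelated(drawn$theta, drawn$delta, cfg$sigma, cfg$w,
                        seed = seed2)
  } else {
    pair_random(drawn$theta, drawn$delta, cfg$w, seed = seed2)
  }
  cg <- coarse_grain(binarize(fine, cfg$w), cfg$Delta)
  coarse <- binary_to_bursts(cg, w = cfg$Delta * cfg$w)
  list(fine = fine, coarse = coarse, cfg = cfg, pairing = pairing)
}

#' Map the coupling knob sigma to the expected Spearman coupling
#'
#' Simulates the pairing chain on a grid of `sigma` values and reports the
#' mean fine-level Spearman coefficient, so a user can pick `sigma` to match
#' an empirical coupling value.
#'
#' @param cfg a `burst_model_config` (its `sigma` is ignored).
#' @param sigmas numeric grid of sigma values.
#' @param n_rep simulations per grid point.
#' @return data frame with columns `sigma`, `rho_mean`, `rho_sd`.
#' @export
calibrate_sigma <- function(cfg, sigmas = cfg$N * c(0.01, 0.05, 0.1, 0.2,
                                                    0.5, 1),
                            n_rep = 3) {
  drawn <- draw_and_rank(cfg)
  res <- lapply(seq_along(sigmas), function(i) {
    rho <- vapply(seq_len(n_rep), function(r) {
      s <- if (is.null(cfg$seed)) NULL else cfg$seed + 100L * i + r
      bs <- pair_anticorrelated(drawn$theta, drawn$delta, sigmas[i],
                                cfg$w, seed = s)
      spearman_coupling(bs)$rho_s
    }, numeric(1))
    data.frame(sigma = sigmas[i], rho_mean = mean(rho),
               rho_sd = stats::sd(rho))
  })
  do.call(rbind, res)
}
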