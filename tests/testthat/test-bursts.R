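# A ratio_series can be assembled directly for burst-logic tests.
fake_ratio_series <- function(R, w = 5, valid = NULL, segment = NULL,
                              schedule = NULL) {
  n <- length(R)
  if (is.null(valid)) valid <- rep(TRUE, n)
  if (is.null(segment)) segment <- rep(1L, n)
  if (is.null(schedule)) {
    schedule <- data.frame(state = character(), start_s = numeric(),
                           end_s = numeric())
  }
  structure(list(S_delta = rep(1, n), S_theta = R, R = R,
                 t_start = (seq_len(n) - 1) * w, segment = segment,
                 window_valid = valid, w = w, fs = 256,
                 bands = list(delta = c(0.5, 4), theta = c(4, 8)),
                 schedule = schedule),
            class = "ratio_series")
}

test_that("burst detection run-length-encodes the thresholded ratio", {
  bs <- detect_bursts(fake_ratio_series(c(2, 3, 0.5, 0.4, 0.6)), 1, 1)
  expect_equal(bs$bursts$kind, c("theta", "delta"))
  expect_equal(bs$bursts$d, c(10, 15))
  expect_true(all(bs$bursts$truncated))

  bs2 <- detect_bursts(fake_ratio_series(c(3, 1.5, 3)), 2, 0.5)
  expect_equal(bs2$bursts$kind, c("theta", "unassigned", "theta"))
  expect_equal(bs2$bursts$d, c(5, 5, 5))

  bs3 <- detect_bursts(fake_ratio_series(rep(1.5, 7)), 1, 1)
  expect_equal(nrow(bs3$bursts), 1)
  expect_equal(bs3$bursts$kind, "theta")
  expect_true(bs3$bursts$truncated)

  # values exactly at the threshold are unassigned (strict inequalities)
  bs4 <- detect_bursts(fake_ratio_series(c(2, 1, 0.5)), 1, 1)
  expect_equal(bs4$bursts$kind, c("theta", "unassigned", "delta"))
})

test_that("at thresholds 1/1 the valid windows are partitioned and kinds alternate", {
  R <- with_seed(10, exp(rnorm(500)))
  valid <- with_seed(11, runif(500) > 0.05)
  bs <- detect_bursts(fake_ratio_series(R, valid = valid), 1, 1)
  expect_equal(sum(bs$bursts$n), sum(valid))
  b <- bs$bursts[bs$bursts$kind != "unassigned", ]
  same_chunk <- diff(b$chunk) == 0
  expect_true(all(b$kind[-1][same_chunk] != b$kind[-nrow(b)][same_chunk]))
  # an invalid window splits runs and truncates the flanking bursts
  first_gap <- which(!valid)[1]
  expect_true(any(bs$bursts$truncated))
})

test_that("period filters cut bursts at schedule edges", {
  sched <- data.frame(state = c("light", "dark"),
                      start_s = c(0, 250), end_s = c(250, 500))
  R <- rep(c(2, 0.5), each = 5, length.out = 100)
  rs <- fake_ratio_series(R, schedule = sched)
  b_l <- detect_bursts(rs, period = "light")
  b_d <- detect_bursts(rs, period = "dark")
  b_a <- detect_bursts(rs)
  expect_equal(sum(b_l$bursts$n) + sum(b_d$bursts$n), sum(b_a$bursts$n))
  expect_true(all(b_l$bursts$t_start + b_l$bursts$d <= 250))
})

test_that("quiet times measure gaps between qualifying theta events", {
  bs <- new_burst_sequence(c("theta", "delta", "theta"), n = c(2, 3, 1),
                           w = 5)
  expect_equal(quiet_times(bs, 0)$deltas, 15)
  expect_equal(quiet_times(bs, 8)$deltas, numeric(0))
  expect_true(is.na(quiet_times(bs, 8)$mean_dt))
})

test_that("at D0 = 0 quiet times equal the delta durations between interior theta events", {
  bs <- generate_duration_sequence(N = 400, w = 5, seed = 31)
  rec <- synthesize_eeg(bs, eeg_synth_spec(seed = 32))
  det <- detect_bursts(band_power_series(preprocess(rec), w = 5), 1, 1)
  qt <- quiet_times(det, 0)
  b <- det$bursts
  # expected: delta bursts flanked by two non-truncated theta bursts
  inner <- which(b$kind == "delta" & !b$truncated)
  inner <- inner[b$kind[inner - 1] == "theta" & !b$truncated[inner - 1] &
                   b$kind[inner + 1] == "theta" & !b$truncated[inner + 1]]
  expect_gt(length(qt$deltas), 50)
  expect_equal(sort(qt$deltas), sort(b$d[inner]))
  expect_equal(qt$mean_dt, mean(qt$deltas))
})

test_that("window reshuffling preserves values, is seeded, and yields geometric runs", {
  R <- with_seed(12, exp(rnorm(2000)))
  valid <- rep(TRUE, 2000); valid[c(5, 600)] <- FALSE
  rs <- fake_ratio_series(R, valid = valid)
  s1 <- shuffle_ratio_windows(rs, seed = 9)
  s2 <- shuffle_ratio_windows(rs, seed = 9)
  expect_identical(s1$R, s2$R)
  expect_equal(sort(s1$R[valid]), sort(R[valid]))
  expect_identical(s1$window_valid, rs$window_valid)
  # run lengths above threshold 1 are geometric: mean run = 1 / (1 - p)
  p <- mean(s1$R[valid] > 1)
  bs <- detect_bursts(s1, 1, 1)
  th_runs <- bs$bursts$n[bs$bursts$kind == "theta"]
  expect_equal(mean(th_runs), 1 / (1 - p), tolerance = 0.1)
})

test_that("duration shuffles preserve marginals, alternation and determinism", {
  bs <- generate_duration_sequence(N = 2000, w = 5, seed = 13)
  to <- shuffle_burst_durations(bs, "theta_only", seed = 14)
  b0 <- bs$bursts; b1 <- to$bursts
  expect_identical(b1$d[b1$kind == "delta"], b0$d[b0$kind == "delta"])
  expect_equal(sort(b1$d[b1$kind == "theta"]),
               sort(b0$d[b0$kind == "theta"]))
  expect_identical(b1$kind, b0$kind)
  fo <- shuffle_burst_durations(bs, "full_order", seed = 15)
  expect_equal(sort(fo$bursts$d), sort(b0$d))
  expect_identical(shuffle_burst_durations(bs, "full_order", seed = 15),
                   fo)
  expect_error(shuffle_burst_durations(bs, "bogus"))
})

test_that("theta-only reshuffling pushes quiet times towards exponential statistics", {
  bs <- generate_duration_sequence(N = 4000, w = 5,
                                   coupling = "model", seed = 16)
  for (D0 in c(10, 20)) {
    orig <- quiet_times(bs, D0)$deltas
    sur <- quiet_times(shuffle_burst_durations(bs, "theta_only",
                                               seed = 17), D0)$deltas
    # the coupled sequence clusters its theta events: excess of very short
    # quiet times and large CV; reshuffling destroys the clustering
    cv <- function(x) sd(x) / mean(x)
    expect_gt(cv(orig), 2 * cv(sur) * 0.9)
    expect_gt(mean(orig < 0.1 * mean(orig)),
              2 * mean(sur < 0.1 * mean(sur)))
  }
  # an independent sequence has exponential-like quiet times (CV ~ 1)
  bi <- generate_duration_sequence(N = 4000, w = 5, seed = 18)
  for (D0 in c(10, 20)) {
    x <- quiet_times(bi, D0)$deltas
    expect_lt(abs(sd(x) / mean(x) - 1), 0.2)
  }
})
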