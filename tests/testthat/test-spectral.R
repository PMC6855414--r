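test_that("text loading reads samples, masks non-finite values and keeps fs arithmetic", {
  path <- withr::local_tempfile(fileext = ".csv")
  x <- with_seed(1, rnorm(2560))
  writeLines(format(x, digits = 12), path)
  rec <- load_recording(path, fs = 256)
  expect_equal(length(rec$samples) / rec$fs, 10)
  expect_true(all(rec$mask))

  x[100] <- NaN
  writeLines(format(x, digits = 12), path)
  expect_warning(rec <- load_recording(path, fs = 256), "masked")
  expect_equal(sum(!rec$mask), 1)
  expect_false(rec$mask[100])
  expect_error(load_recording(path), "fs must be supplied")
})

test_that("EDF reading returns the frontal-parietal differential", {
  t <- seq(0, 10 - 1 / 256, by = 1 / 256)
  f_sig <- 10 * sin(2 * pi * 3 * t)
  p_sig <- 5 * sin(2 * pi * 7 * t)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf_fixture(path, list(f_sig, p_sig), 256, c("F", "P"))
  rec <- load_recording(path, format = "edf", channels = c("F", "P"))
  expect_equal(rec$fs, 256)
  # 16-bit quantization over a 200 uV physical range
  expect_lt(max(abs(rec$samples - (f_sig - p_sig))), 0.01)
  expect_error(load_recording(path, format = "edf",
                              channels = c("F", "EMG")),
               "missing channel")
})

test_that("preprocess z-scores then bandpasses with a linear-phase FIR", {
  t <- seq(0, 40 - 1 / 256, by = 1 / 256)
  x <- with_seed(2, rnorm(length(t), mean = 3, sd = 5))
  rec <- preprocess(new_raw_recording(x, 256), band = c(0.5, 25))
  # normalization contract is checked on the pre-filter z-score
  z <- (x - mean(x)) / sd(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(sd(z) - 1), 1e-9)
  expect_error(preprocess(new_raw_recording(rep(2, 2560), 256)),
               "constant signal")

  # frequency response checked against the designed taps (independent oracle)
  b <- signal::fir1(512, c(0.5, 25) / 128, type = "pass")
  hf <- function(f) abs(sum(b * exp(-2i * pi * f / 256 * seq_along(b))))
  mid <- 2000:8000   # away from filter edge transients
  r30 <- preprocess(new_raw_recording(sin(2 * pi * 30 * t), 256))
  atten30 <- 20 * log10(sd(r30$samples[mid]) /
                          sd(scale(sin(2 * pi * 30 * t))[mid]))
  expect_lt(atten30, -20)
  expect_lt(abs(atten30 - 20 * log10(hf(30))), 1)
  r10 <- preprocess(new_raw_recording(sin(2 * pi * 10 * t), 256))
  atten10 <- 20 * log10(sd(r10$samples[mid]) /
                          sd(scale(sin(2 * pi * 10 * t))[mid]))
  expect_lt(abs(atten10), 1)
})

test_that("band powers put pure tones in the right band", {
  t <- seq(0, 60 - 1 / 256, by = 1 / 256)
  rs6 <- band_power_series(new_raw_recording(sin(2 * pi * 6 * t), 256), w = 5)
  expect_true(all(rs6$R > 1))
  rs2 <- band_power_series(new_raw_recording(sin(2 * pi * 2 * t), 256), w = 5)
  expect_true(all(rs2$R < 1))
  expect_equal(length(rs6$R), 12)   # floor(60 / 5) windows
})

test_that("white-noise band-power ratio matches the bandwidth ratio and a periodogram oracle", {
  rec <- new_raw_recording(with_seed(5, rnorm(256 * 600)), 256)
  rs <- band_power_series(rec, w = 5)
  # flat spectrum: S_theta / S_delta = (8-4) / (4-0.5)
  expect_equal(mean(rs$S_theta) / mean(rs$S_delta), 4 / 3.5,
               tolerance = 0.02)
  po_delta <- vapply(seq_len(120), function(k) {
    periodogram_band(rec$samples[((k - 1) * 1280 + 1):(k * 1280)], 256,
                     c(0.5, 4))
  }, numeric(1))
  expect_equal(mean(rs$S_delta) / mean(po_delta), 1, tolerance = 0.1)
})

test_that("band powers scale with amplitude squared while the ratio is invariant", {
  rec <- new_raw_recording(with_seed(6, rnorm(256 * 100)), 256)
  rs1 <- band_power_series(rec, w = 5)
  rs2 <- band_power_series(new_raw_recording(2 * rec$samples, 256), w = 5)
  expect_equal(rs2$S_theta, 4 * rs1$S_theta, tolerance = 1e-12)
  expect_equal(rs2$S_delta, 4 * rs1$S_delta, tolerance = 1e-12)
  expect_equal(rs2$R, rs1$R, tolerance = 1e-12)
})

test_that("masked gaps restart the window tiling and windows never span a gap", {
  x <- with_seed(7, rnorm(256 * 60))
  mask <- rep(TRUE, length(x))
  mask[(256 * 17 + 1):(256 * 19)] <- FALSE   # 2 s gap inside
  rec <- new_raw_recording(x, 256, mask = mask)
  rs <- band_power_series(rec, w = 5)
  # 17 s head -> 3 windows, 41 s tail -> 8 windows
  expect_equal(length(rs$R), 11)
  expect_equal(sort(unique(rs$segment)), c(1, 2))
  expect_error(band_power_series(rec, w = 100), "longer than")
})

test_that("the amplitude flagger masks sustained large excursions only", {
  x <- with_seed(8, rnorm(256 * 60))
  x[(256 * 10 + 1):(256 * 11)] <- 100     # 1 s excursion
  x[256 * 30] <- 100                       # single-sample spike
  rec <- flag_amplitude_artifacts(new_raw_recording(x, 256))
  expect_false(any(rec$mask[(256 * 10 + 2):(256 * 11 - 1)]))
  expect_true(rec$mask[256 * 30])
})
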