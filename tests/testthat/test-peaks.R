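fake_response <- function(vals, freqs) {
  structure(vals, fgrid = structure(freqs, class = "freq_grid"),
            tgrid = time_grid(), mode = "absolute")
}

test_that("a single suppression extremum is reported for alpha", {
  freqs <- seq(7, 14, by = 0.25)
  times <- as.numeric(time_grid())
  resp <- matrix(0, length(freqs), length(times))
  fi <- which(freqs == 12)
  ti <- which.min(abs(times - 0.4))
  resp[fi, ti] <- -1
  pk <- extract_band_peaks(fake_response(resp, freqs), band_definition("alpha"))
  expect_equal(pk$peak_freq, 12)
  expect_equal(pk$peak_amp, -1)
  expect_equal(pk$peak_time, 1000 * times[ti])
})

test_that("peak location is invariant to constant offsets and positive scaling", {
  freqs <- seq(40, 100, by = 2)
  set.seed(5)
  resp <- matrix(stats::rnorm(length(freqs) * 59), length(freqs), 59)
  b <- band_definition("gamma")
  p0 <- extract_band_peaks(fake_response(resp, freqs), b)
  p1 <- extract_band_peaks(fake_response(resp + 1e-6, freqs), b)
  p2 <- extract_band_peaks(fake_response(resp * 3.3, freqs), b)
  expect_equal(p1$peak_freq, p0$peak_freq)
  expect_equal(p1$peak_time, p0$peak_time)
  expect_equal(p2$peak_freq, p0$peak_freq)
  expect_equal(p2$peak_time, p0$peak_time)
})

test_that("peaks are searched only inside the band and 0-600 ms window", {
  freqs <- seq(36, 104, by = 2)
  times <- as.numeric(time_grid())
  resp <- matrix(0, length(freqs), length(times))
  resp[which(freqs == 36), 30] <- 10      # below gamma peak range (40-100)
  resp[which(freqs == 64), 5] <- 10       # pre-stimulus
  resp[which(freqs == 64), 30] <- 4       # the only admissible peak
  pk <- extract_band_peaks(fake_response(resp, freqs), band_definition("gamma"))
  expect_equal(pk$peak_freq, 64)
  expect_equal(pk$peak_amp, 4)
})

test_that("ties break towards lower frequency and earlier time", {
  freqs <- seq(40, 100, by = 2)
  resp <- matrix(0, length(freqs), 59)
  resp[which(freqs == 60), 30] <- 5
  resp[which(freqs == 80), 40] <- 5
  expect_message(
    pk <- extract_band_peaks(fake_response(resp, freqs),
                             band_definition("gamma")),
    "tie")
  expect_equal(pk$peak_freq, 60)
})

test_that("degenerate inputs are rejected", {
  freqs <- seq(40, 100, by = 2)
  zero <- fake_response(matrix(0, length(freqs), 59), freqs)
  expect_error(extract_band_peaks(zero, band_definition("gamma")),
               "no modulation")
  expect_error(extract_band_peaks(zero, band_definition("theta")),
               "no peak-extraction range")
})

test_that("an injected gamma response is recovered at its frequency and latency", {
  sub <- test_subject(seed = 15)
  sub$gamma_peak_freq <- 65
  sub$gamma_latency <- 300
  head <- small_head()
  grid <- small_grid()
  lf <- leadfield(head, grid)
  ts <- simulate_meg_recording(sub, head, grid, n_trials = 10, seed = 16,
                               lf = lf)
  resp <- analyze_meg_subject(ts, head, grid, fgrid = gamma_freq_grid(),
                              lf = lf)
  pk <- extract_band_peaks(v1_response(resp), band_definition("gamma"))
  expect_lte(abs(pk$peak_freq - 65), 2)
  expect_lte(abs(pk$peak_time - 300), 34)
  expect_gt(pk$peak_amp, 0)
})

test_that("alpha and beta suppressions yield negative peak amplitudes", {
  sub <- test_subject(seed = 17)
  head <- small_head()
  grid <- small_grid()
  lf <- leadfield(head, grid)
  ts <- simulate_meg_recording(sub, head, grid, n_trials = 10, seed = 18,
                               lf = lf)
  resp <- analyze_meg_subject(ts, head, grid,
                              fgrid = freq_grid(list(c(7, 30, 0.5))),
                              lf = lf)
  v1r <- v1_response(resp)
  pa <- extract_band_peaks(v1r, band_definition("alpha"))
  pb <- extract_band_peaks(v1r, band_definition("beta"))
  expect_lt(pa$peak_amp, 0)
  expect_lt(pb$peak_amp, 0)
})
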