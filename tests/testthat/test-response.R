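fake_power <- function(vals, freqs, n_t = 59) {
  structure(vals, class = "source_power",
            fgrid = structure(freqs, class = "freq_grid"),
            tgrid = time_grid(), lambda = 0.05)
}

test_that("temporal smoothing is a 13-bin moving average with shrinking edges", {
  p <- fake_power(array(2, c(3, 2, 59)), c(40, 42))
  expect_equal(unclass(temporal_smooth(p)), array(2, c(3, 2, 59)),
               ignore_attr = TRUE)

  imp <- array(0, c(1, 1, 59)); imp[1, 1, 30] <- 1
  sm <- temporal_smooth(fake_power(imp, 40))
  expect_equal(sm[1, 1, 30], 1 / 13)
  expect_equal(sm[1, 1, 24], 1 / 13)
  expect_equal(sm[1, 1, 23], 0)

  set.seed(1)
  x <- array(stats::rnorm(2 * 3 * 59), c(2, 3, 59))
  sm2 <- temporal_smooth(fake_power(x, c(40, 42, 44)))
  # brute-force window mean
  for (t in c(1, 4, 30, 59)) {
    win <- max(1, t - 6):min(59, t + 6)
    expect_equal(sm2[2, 3, t], mean(x[2, 3, win]), tolerance = 1e-12)
  }
})

test_that("8-Hz band averaging acts only at and above 40 Hz", {
  freqs <- seq(36, 104, by = 2)
  flat <- fake_power(array(5, c(2, length(freqs), 59)), freqs)
  expect_equal(unclass(band_average_high(flat)),
               array(5, c(2, length(freqs), 59)), ignore_attr = TRUE)

  x <- array(0, c(1, length(freqs), 59))
  x[1, , 10] <- seq_along(freqs)
  ba <- band_average_high(fake_power(x, freqs))
  i40 <- which(freqs == 40)
  expect_equal(ba[1, i40, 10], mean(x[1, which(freqs >= 36 & freqs <= 44), 10]))
  # bins below 40 Hz untouched
  expect_equal(ba[1, which(freqs == 36), 10], x[1, which(freqs == 36), 10])

  # a single nonzero 64 Hz bin spreads to centres 60-68 Hz only
  y <- array(0, c(1, length(freqs), 59))
  y[1, which(freqs == 64), ] <- 1
  bay <- band_average_high(fake_power(y, freqs))
  nz <- freqs[apply(bay[1, , , drop = FALSE], 2, max) > 0]
  expect_equal(nz, seq(60, 68, by = 2))
})

test_that("modulation is zero when power never changes", {
  freqs <- c(10, 42)
  grid <- small_grid()
  m <- length(grid$v1_indices) + 2
  vals <- array(rep(stats::runif(m * 2, 1, 2), times = 59), c(m, 2, 59))
  grid$points <- grid$points[seq_len(m), , drop = FALSE]
  grid$v1_indices <- seq_len(length(grid$v1_indices))
  p <- fake_power(vals, freqs)
  pa <- normalize_and_modulate(p, grid, "absolute")
  expect_equal(max(abs(pa)), 0)
  pc <- normalize_and_modulate(p, grid, "percent")
  expect_equal(max(abs(pc)), 0)
  # a flat power surface has no baseline variance to normalise by
  flat <- fake_power(array(1, c(m, 2, 59)), freqs)
  expect_error(normalize_and_modulate(flat, grid, "absolute"), "zero variance")
})

test_that("absolute-mode modulation is invariant to global gain rescaling", {
  sub <- test_subject()
  grid <- small_grid()
  head <- small_head()
  lf <- leadfield(head, grid)
  ts <- simulate_meg_recording(sub, head, grid, n_trials = 5, seed = 3, lf = lf)
  r1 <- analyze_meg_subject(ts, head, grid, fgrid = gamma_freq_grid(), lf = lf)
  ts2 <- ts
  ts2$data <- ts$data * 3.7
  r2 <- analyze_meg_subject(ts2, head, grid, fgrid = gamma_freq_grid(), lf = lf)
  expect_equal(unclass(r1), unclass(r2), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("percent mode computes percent signal change", {
  freqs <- c(42)
  vals <- array(2, c(3, 1, 59))
  post <- which(as.numeric(time_grid()) >= 0)
  vals[, , post] <- 3
  grid <- small_grid()
  grid$points <- grid$points[1:3, , drop = FALSE]
  grid$v1_indices <- 1:2
  pc <- normalize_and_modulate(fake_power(vals, freqs), grid, "percent")
  expect_equal(pc[1, 1, post[10]], 50)
  expect_equal(pc[1, 1, 3], 0)

  vals0 <- vals; vals0[1, 1, 1:12] <- 0   # zero baseline
  expect_error(normalize_and_modulate(fake_power(vals0, freqs), grid,
                                      "percent"), "baseline")
})
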