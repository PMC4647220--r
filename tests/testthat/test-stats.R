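test_that("Spearman's rho is 1 for monotone data and rank-invariant", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  y <- exp(x)
  expect_equal(cor_spearman(x, y)$rho, 1)
  set.seed(1)
  a <- stats::rnorm(10); b <- stats::rnorm(10)
  r0 <- cor_spearman(a, b)
  r1 <- cor_spearman(exp(a), b)
  r2 <- cor_spearman(a, 2 * b + 5)
  expect_equal(r1$rho, r0$rho)
  expect_equal(r2$rho, r0$rho)
})

test_that("Spearman's rho matches the direct rank-difference formula", {
  set.seed(2)
  for (k in 1:5) {
    x <- sample(10)
    y <- sample(10)
    d <- rank(x) - rank(y)
    expect_equal(cor_spearman(x, y)$rho,
                 1 - 6 * sum(d^2) / (10 * (10^2 - 1)))
  }
})

test_that("Pearson p-values follow the two-sided df = n-2 convention", {
  expect_lt(abs(p_from_r(0.75973, 10) - 0.0108), 1e-4)
  expect_lt(abs(p_from_r(-0.61411, 10) - 0.0589), 1e-4)
  expect_equal(p_from_r(0, 10), 1)
  expect_error(cor_pearson(rep(1, 5), 1:5), "variance")
})

test_that("t-approximation p-values agree with exact permutation p-values", {
  set.seed(6)
  for (k in 1:3) {
    x <- stats::rnorm(10)
    y <- 0.6 * x + stats::rnorm(10)
    sp <- cor_spearman(x, y)
    if (abs(sp$rho) > 0.8) next
    pp <- perm_spearman_p(x, y, nperm = 2e4, seed = k)
    expect_lt(abs(sp$p - pp), 0.02)
  }
})

test_that("the JZS Bayes factor reproduces its closed-case properties", {
  expect_equal(jzs_cor_bf(0.75973, 10), jzs_cor_bf(-0.75973, 10))
  expect_lt(jzs_cor_bf(0, 10), 1)
  expect_lt(jzs_cor_bf(0, 50), 1)
  # strictly increasing in |r| at fixed n, and in n at fixed |r| > 0
  bfs <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), jzs_cor_bf, numeric(1), n = 10)
  expect_true(all(diff(bfs) > 0))
  bfn <- vapply(c(5, 10, 20, 40), function(n) jzs_cor_bf(0.5, n), numeric(1))
  expect_true(all(diff(bfn) > 0))
  expect_error(jzs_cor_bf(1, 10), "degenerate")
  expect_error(jzs_cor_bf(0.5, 2), "n >= 3")
})

test_that("quadrature matches the Monte-Carlo oracle on an (r, n) lattice", {
  lattice <- expand.grid(r = c(-0.9, -0.5, -0.2, 0.2, 0.4, 0.6, 0.75973,
                               0.85, 0.95, 0.99),
                         n = c(5, 10))
  for (i in seq_len(nrow(lattice))) {
    q <- jzs_cor_bf(lattice$r[i], lattice$n[i])
    m <- oracle_bf_mc(lattice$r[i], lattice$n[i], nsamp = 1e6, seed = i)
    expect_lt(abs(q - m) / q, 0.01)
  }
})

test_that("leave-2-out bootstrap limits behave as specified", {
  x <- 1:10
  y <- x^2                                   # perfectly monotone
  ci <- bootstrap_ci(x, y, seed = 1)
  expect_equal(ci$ci_low, 1)
  expect_equal(ci$ci_high, 1)
  set.seed(3)
  a <- stats::rnorm(10); b <- a + stats::rnorm(10)
  c1 <- bootstrap_ci(a, b, seed = 42)
  c2 <- bootstrap_ci(a, b, seed = 42)
  expect_identical(c1, c2)
  expect_lte(c1$ci_low, c1$ci_high)
  expect_length(c1$values, 200)
  expect_error(bootstrap_ci(1:4, 1:4, leave_out = 2), "n - leave_out")
})

test_that("bootstrap limits cover the full-sample rho in most cohorts", {
  set.seed(7)
  rho_xy <- 0.7
  hits <- vapply(1:300, function(k) {
    x <- stats::rnorm(10)
    y <- rho_xy * x + sqrt(1 - rho_xy^2) * stats::rnorm(10)
    full <- cor_spearman(x, y)$rho
    ci <- bootstrap_ci(x, y, seed = k)
    ci$ci_low <= full && full <= ci$ci_high
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("confound regression returns exact, mean-zero residuals", {
  conf <- cbind(1:10, c(2, 5, 3, 8, 1, 9, 4, 7, 6, 10))
  vals <- 3 + 2 * conf[, 1] - 0.5 * conf[, 2]
  expect_lt(max(abs(regress_out(vals, conf))), 1e-10)

  set.seed(8)
  v <- stats::rnorm(10)
  r <- regress_out(v, stats::rnorm(10))
  expect_equal(mean(r), 0, tolerance = 1e-12)

  # removing a known additive confound strengthens the signal correlation
  sig <- stats::rnorm(30)
  cf <- stats::rnorm(30)
  obs <- sig + 2 * cf
  expect_gt(cor(regress_out(obs, cf), sig), cor(obs, sig))
})

test_that("the full analysis produces the documented report layout", {
  set.seed(9)
  ids <- sprintf("s%02d", 1:10)
  feats <- do.call(rbind, lapply(c("alpha", "beta", "gamma"), function(b)
    data.frame(subject_id = ids, band = b,
               peak_freq_hz = stats::rnorm(10, 60),
               peak_time_ms = stats::runif(10, 0, 600),
               peak_amp = stats::rnorm(10))))
  dens <- data.frame(subject_id = ids,
                     total_v1_bmax = stats::rnorm(10, 2000, 200),
                     whole_brain_bmax = stats::rnorm(10, 40000, 2000))
  conf <- data.frame(subject_id = ids,
                     v1_surface_area_mm2 = stats::rnorm(10, 2000, 100),
                     gm_density = stats::runif(10, 0.5, 0.8))
  rep <- run_full_analysis(feats, dens, conf, seed = 1)
  expect_equal(nrow(rep$report), 3 * 3 * 2)
  expect_true(all(c("spearman_rho", "spearman_p", "pearson_r", "pearson_p",
                    "bf10", "ci_low", "ci_high") %in% names(rep$report)))
  expect_true(all(rep$report$bf10 > 0))
  expect_true(all(rep$report$ci_low <= rep$report$ci_high))
  expect_gt(nrow(rep$controls), 0)

  dir <- withr::local_tempdir()
  write_correlation_report(rep, dir)
  back <- utils::read.csv(file.path(dir, "correlations.csv"))
  expect_equal(nrow(back), 18)

  bad <- dens
  bad$subject_id[1] <- "zz"
  expect_error(run_full_analysis(feats, bad, conf), "mismatch")
})
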