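test_that("compute_dff follows the percent-change definition", {
  expect_equal(compute_dff(2, 1), 100)
  expect_equal(compute_dff(1, 1), 0)
  expect_equal(compute_dff(1.5, 1), 50)
  expect_error(compute_dff(1, 0), "positive")
  expect_error(compute_dff(1, -2), "positive")
})

test_that("compute_snr uses sample sd of the baseline and is scale-invariant", {
  tr <- fluorescence_trace(1:5, c(0.9, 1.1, 1.0, 11, 2), baseline_window = 2)
  expect_equal(compute_snr(tr), (11 - 1) / sd(c(0.9, 1.1)))
  # Fmax equal to the baseline mean gives 0
  tr0 <- fluorescence_trace(1:4, c(0.9, 1.1, 0.8, 0.85), baseline_window = 2)
  expect_equal(compute_snr(tr0), (1.1 - 1) / sd(c(0.9, 1.1)))
  # doubling intensities leaves SNR unchanged
  tr2 <- fluorescence_trace(1:5, 2 * c(0.9, 1.1, 1.0, 11, 2),
                            baseline_window = 2)
  expect_equal(compute_snr(tr2), compute_snr(tr))
  flat <- fluorescence_trace(1:5, c(1, 1, 1, 2, 1), baseline_window = 2)
  expect_error(compute_snr(flat), "zero baseline")
})

test_that("fit_decay recovers lambda on exact exponentials", {
  t <- seq(0, 10, by = 0.05)
  # raw pure exponential, lambda = 0.5
  tr <- fluorescence_trace(t, exp(-0.5 * t), baseline_window = 2)
  fit <- fit_decay(tr, on = "raw")
  expect_equal(fit$lambda, 0.5, tolerance = 1e-9)
  expect_equal(fit$tau, 2.0, tolerance = 1e-9)
  # reciprocal relation at lambda = 2
  tr2 <- fluorescence_trace(t, exp(-2 * t), baseline_window = 2)
  expect_equal(fit_decay(tr2, on = "raw")$tau, 0.5, tolerance = 1e-6)
  # baseline-offset trace: dF fit recovers lambda exactly, via the
  # synthetic generator
  sim <- simulate_trace(synthetic_trace_config(lambda = 0.7))
  expect_equal(fit_decay(sim)$lambda, 0.7, tolerance = 1e-9)
  # nls route agrees on clean data
  expect_equal(fit_decay(sim, method = "nls")$lambda, 0.7, tolerance = 1e-7)
  # a rising trace peaks at its last sample: the >= 3 post-peak sample
  # precondition fails
  up <- fluorescence_trace(t, 1 + t, baseline_window = 2)
  expect_error(fit_decay(up, on = "raw"), ">= 3 samples")
})

test_that("fit_decay tolerates noise: tau within 2% at 1% peak noise", {
  errs <- vapply(1:25, function(s) {
    cfg <- synthetic_trace_config(lambda = 0.5, peak_dff_percent = 100,
                                  noise_sd = 0.02, sampling_rate_hz = 20,
                                  duration_s = 30, seed = s)
    fit <- fit_decay(simulate_trace(cfg))
    abs(fit$tau - 2) / 2
  }, 0)
  expect_lt(mean(errs), 0.02)
})

test_that("half_decay_time interpolates the half-max crossing", {
  # exact exponential: tau_half = ln(2) / lambda; dense sampling keeps the
  # interpolation error negligible
  cfg <- synthetic_trace_config(lambda = 0.5, sampling_rate_hz = 200,
                                duration_s = 20)
  hd <- half_decay_time(simulate_trace(cfg))
  expect_false(hd$censored)
  expect_equal(hd$tau_half, log(2) / 0.5, tolerance = 1e-4)
  # dF decaying linearly from 1 to 0 over 1 s crosses half-max at 0.5 s
  t <- seq(0, 1, by = 0.01)
  tr <- fluorescence_trace(c(-2, -1, t), c(1, 1, 2 - t),
                           baseline_window = 2)
  hd2 <- half_decay_time(tr)
  expect_equal(hd2$tau_half, 0.5, tolerance = 1e-9)
  # monotone-increasing trace is censored
  up <- fluorescence_trace(1:100, seq(1, 5, length.out = 100),
                           baseline_window = 5)
  expect_true(half_decay_time(up)$censored)
})

test_that("dynamic_range and the DR identity hold", {
  tr <- fluorescence_trace(1:10, c(rep(1, 5), 5, 3, 2, 1.5, 1.2),
                           baseline_window = 5)
  expect_equal(dynamic_range(tr), 5)
  flat <- fluorescence_trace(1:10, rep(2, 10), baseline_window = 5)
  expect_equal(dynamic_range(flat), 1)
  # DR = dff_max / 100 + 1 on random traces
  set.seed(141)
  for (i in 1:5) {
    y <- abs(rnorm(50, 10, 1)) + c(rep(0, 10), 20 * exp(-0.3 * (1:40)))
    trr <- fluorescence_trace(1:50, y, baseline_window = 10)
    expect_equal(dynamic_range(trr), dff_max(trr) / 100 + 1)
  }
})

test_that("performance_score rewards large fast responses", {
  expect_equal(performance_score(10, 2), 5)
  expect_equal(performance_score(0, 2), 0)
  expect_equal(performance_score(10, 4), performance_score(10, 2) / 2)
  expect_error(performance_score(10, 0), "positive")
})

test_that("trace_metrics integrates the full quantification", {
  cfg <- synthetic_trace_config(peak_dff_percent = 100, baseline_level = 1,
                                lambda = 0.5, noise_sd = 0.005, seed = 3)
  m <- trace_metrics(simulate_trace(cfg))
  expect_equal(m$fmax, 2, tolerance = 0.02)
  expect_equal(m$dff_max, 100, tolerance = 2)
  expect_equal(m$lambda, 0.5, tolerance = 0.05)
  expect_equal(m$dynamic_range, m$dff_max / 100 + 1)
  expect_equal(m$performance_score, m$snr / m$tau)
  # scale invariance of the unitless metrics; time-axis metrics unchanged
  cfg2 <- synthetic_trace_config(peak_dff_percent = 100, baseline_level = 5,
                                 lambda = 0.5, noise_sd = 0.025, seed = 3)
  m2 <- trace_metrics(simulate_trace(cfg2))
  expect_equal(m2$dff_max, m$dff_max, tolerance = 1e-9)
  expect_equal(m2$snr, m$snr, tolerance = 1e-9)
  expect_equal(m2$dynamic_range, m$dynamic_range, tolerance = 1e-9)
  expect_equal(m2$lambda, m$lambda, tolerance = 1e-9)
})

test_that("trace CSV reader splits ROIs and orders by time", {
  csv <- tempfile(fileext = ".csv")
  t <- seq(0, 5, by = 0.1)
  df <- rbind(data.frame(time = rev(t), intensity = rev(2 * exp(-t) + 1),
                         roi_id = "a"),
              data.frame(time = t, intensity = exp(-t) + 1, roi_id = "b"))
  write.csv(df, csv, row.names = FALSE)
  traces <- read_trace_csv(csv, baseline_window = 3)
  expect_named(traces, c("a", "b"))
  expect_true(all(diff(traces$a$times) > 0))
})
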