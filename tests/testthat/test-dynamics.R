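# -- first-peak metrics ----------------------------------------------------

test_that("the first peak of a noiseless trace is measured exactly", {
  tr <- simulate_trace(oscillation_params(amplitude = 0.5,
                                          first_peak_time = 30,
                                          noise_sd = 0))
  pk <- first_peak_metrics(tr)
  expect_true(pk$found)
  expect_equal(pk$amplitude, 0.5, tolerance = 0.01 / 0.5)
  expect_lte(abs(pk$time - 30), 5)
})

test_that("a monotone decreasing trace has no peak and is flagged", {
  tr <- translocation_trace(seq(0, 100, 5), seq(2, 1, length.out = 21))
  pk <- first_peak_metrics(tr)
  expect_false(pk$found)
  expect_equal(pk$flag, "no_peak")
})

test_that("with peaks at t = 30 and t = 150, the first is returned", {
  t <- seq(0, 300, 5)
  v <- 1 + 0.4 * exp(-0.5 * ((t - 30) / 10)^2) +
    0.6 * exp(-0.5 * ((t - 150) / 12)^2)
  pk <- first_peak_metrics(translocation_trace(t, v))
  expect_equal(pk$time, 30)
})

test_that("a trace still rising at the end is flagged as boundary", {
  tr <- translocation_trace(seq(0, 100, 5), seq(1, 2, length.out = 21))
  pk <- first_peak_metrics(tr)
  expect_false(pk$found)
  expect_equal(pk$flag, "boundary")
})

# -- wavelet spectrum ------------------------------------------------------

test_that("a pure sinusoid's dominant period matches the periodogram oracle", {
  t <- seq(0, 360, 5)
  for (p in c(60, 90, 115, 120)) {
    tr <- translocation_trace(t, 1 + 0.3 * sin(2 * pi * t / p))
    sp <- wavelet_periods(tr)
    grid_step <- sp$periods[2] / sp$periods[1]
    mid <- which.min(abs(sp$times - 180))
    expect_lt(abs(log(sp$dominant_period[mid] / p)), log(grid_step) + 1e-9)
    # independent oracle: FFT periodogram of the same samples
    oracle_p <- periodogram_period(tr$values, 5)
    # periodogram resolution is coarse (1/N df); compare on log scale
    expect_lt(abs(log(sp$dominant_period[mid] / oracle_p)), 0.2)
  }
})

test_that("noiseless sinusoid periods are recovered at all interior times", {
  # interior = times where the true period's scale is outside the COI
  t <- seq(0, 360, 5)
  for (p in c(60, 90, 115, 120)) {
    tr <- translocation_trace(t, 1 + 0.3 * sin(2 * pi * t / p))
    sp <- wavelet_periods(tr)
    grid_step <- sp$periods[2] / sp$periods[1]
    pid <- which.min(abs(sp$periods - p))
    interior <- which(!sp$coi[pid, ])
    expect_gt(length(interior), 5L)
    expect_true(all(abs(log(sp$dominant_period[interior] / p)) <=
                      log(grid_step) + 1e-9))
  }
})

test_that("a constant trace has no power and an undefined dominant period", {
  tr <- translocation_trace(seq(0, 360, 5), rep(1.2, 73))
  sp <- wavelet_periods(tr)
  expect_true(sp$flat)
  expect_true(all(is.na(sp$dominant_period)))
})

test_that("white noise has no stable dominant period", {
  # across independent noise traces the mid-trace dominant period is a
  # broad draw, whereas a true oscillation pins every trace to one value
  t <- seq(0, 360, 5)
  dp_null <- vapply(1:40, function(s) {
    set.seed(s)
    sp <- wavelet_periods(translocation_trace(t, 1 + rnorm(73, 0, 0.2)))
    sp$dominant_period[which.min(abs(sp$times - 180))]
  }, numeric(1))
  dp_osc <- vapply(1:10, function(s) {
    set.seed(s)
    sp <- wavelet_periods(translocation_trace(
      t, 1 + 0.3 * sin(2 * pi * t / 115) + rnorm(73, 0, 0.03)))
    sp$dominant_period[which.min(abs(sp$times - 180))]
  }, numeric(1))
  expect_gt(sd(dp_null), 20)
  expect_gt(length(unique(dp_null)), 5L)
  expect_equal(sd(dp_osc), 0, tolerance = 1e-9)
})

test_that("short traces are rejected with the required length stated", {
  tr <- translocation_trace(seq(0, 55, 5), rep(1, 12) + 0.1 * sin(1:12))
  expect_error(wavelet_periods(tr), "at least")
})

test_that("recovered amplitude scales linearly with the signal amplitude", {
  t <- seq(0, 360, 5)
  amp_of <- function(a) {
    tr <- translocation_trace(t, 2 + a * sin(2 * pi * t / 115))
    sp <- wavelet_periods(tr)
    mid <- which.min(abs(sp$times - 180))
    sp$dominant_amplitude[mid]
  }
  a1 <- amp_of(0.2); a3 <- amp_of(0.6)
  expect_equal(a3 / a1, 3, tolerance = 0.05)
})

test_that("damped oscillations yield a non-increasing amplitude envelope", {
  tr <- simulate_trace(oscillation_params(period = 115, amplitude = 0.5,
                                          damping_timescale = 120,
                                          noise_sd = 0))
  sp <- wavelet_periods(tr)
  grid_step <- sp$periods[2] / sp$periods[1]
  # after the first peak, where the oscillation's own scale is dominant
  ok <- which(is.finite(sp$dominant_period) & sp$times > 30 &
                abs(log(sp$dominant_period / 115)) <= log(grid_step))
  expect_gt(length(ok), 5L)
  env <- sp$dominant_amplitude[ok]
  # one-grid-step wobble allowed
  expect_true(all(diff(env) <= max(env) * 0.05))
})

# -- period-frequency comparison -------------------------------------------

test_that("identical traces concentrate all mass in one bin", {
  trs <- lapply(1:5, function(i)
    simulate_trace(oscillation_params(period = 120, amplitude = 0.5,
                                      noise_sd = 0, duration = 480),
                   cell_id = i, condition = "control"))
  h <- period_frequency_comparison(trs, t = 240)
  expect_equal(sum(h$count), 5L)
  expect_equal(sum(h$count > 0), 1L)
  modal <- h$bin_mid[which.max(h$frequency)]
  expect_lt(abs(log(modal / 120)), log(h$bin_hi[1] / h$bin_lo[1]))
})

test_that("planted 120 vs 60 min conditions separate into their modal bins", {
  mk <- function(p, cond) lapply(1:6, function(i)
    simulate_trace(oscillation_params(period = p, amplitude = 0.5,
                                      damping_timescale = 300,
                                      noise_sd = 0.01, duration = 480,
                                      seed = i * 13L),
                   cell_id = i, condition = cond))
  trs <- c(mk(120, "y27"), mk(60, "noc"))
  h <- period_frequency_comparison(trs, t = 240)
  bin_width <- log(h$bin_hi[1] / h$bin_lo[1])
  modal_y27 <- with(h[h$condition == "y27", ], bin_mid[which.max(frequency)])
  modal_noc <- with(h[h$condition == "noc", ], bin_mid[which.max(frequency)])
  expect_false(isTRUE(all.equal(modal_y27, modal_noc)))
  expect_lt(abs(log(modal_y27 / 120)), 1.5 * bin_width)
  expect_lt(abs(log(modal_noc / 60)), 1.5 * bin_width)
})

test_that("empty groups and uncovered times are handled gracefully", {
  h0 <- period_frequency_comparison(list(), t = 300)
  expect_equal(nrow(h0), 0L)
  tr <- simulate_trace(oscillation_params(duration = 240, noise_sd = 0))
  expect_warning(h <- period_frequency_comparison(list(tr), t = 300),
                 "outside coverage")
  expect_equal(nrow(h), 0L)
})
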