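test_that("run-length peak rule: monotone traces and the 6-up bump", {
  expect_length(run_length_peaks(seq_len(50), 6, 6), 0)
  # symmetric triangular bump with 6 rises and 6 falls amid a baseline
  bump6 <- c(rep(0, 10), 1:6, 5:0, rep(0, 10))
  expect_equal(run_length_peaks(bump6, 6, 6), 16)
  # the same bump with only 5 rises is rejected: the flat baseline does
  # not extend a rising run
  bump5 <- c(rep(0, 10), 1:5, 4:0, rep(0, 10))
  expect_length(run_length_peaks(bump5, 6, 6), 0)
  expect_equal(run_length_peaks(bump5, 5, 5), 15)
})

test_that("peak detection equals the brute-force scanner on random traces", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(60:200, 1)
    x <- cumsum(rnorm(n))
    if (rep %% 3 == 0) x <- round(x, 1)  # induce plateaus
    nu <- sample(1:6, 1); nd <- sample(1:6, 1)
    mh <- if (rep %% 2) -Inf else stats::quantile(x, 0.5)
    expect_identical(run_length_peaks(x, nu, nd, mh),
                     oracle_peaks(x, nu, nd, mh))
  }
})

test_that("peak tables carry times, heights and half-prominence widths", {
  t <- seq(0, 20, by = 0.1)
  x <- exp(-((t - 5) / 0.8)^2) + 0.5 * exp(-((t - 15) / 1.2)^2)
  tr <- toy_traces(matrix(x, nrow = 1), dt = 0.1)
  pk <- find_trace_peaks(tr, nups = 3, ndowns = 3, min_height = 0.1)
  expect_equal(nrow(pk$peaks), 2)
  expect_equal(pk$peaks$peak_time_h, c(5, 15), tolerance = 0.11)
  expect_equal(pk$peaks$height, c(1, 0.5), tolerance = 0.01)
  # FWHM of a Gaussian is 2*sigma*sqrt(log(4)); prominences here equal
  # the full heights, so half-prominence width equals the FWHM
  expect_equal(pk$peaks$width_h,
               c(0.8, 1.2) * sqrt(2) * sqrt(log(4)), tolerance = 0.05)
})

test_that("periods are first differences of peak times per community", {
  tr <- toy_traces(rbind(
    c(rep(0, 4), 1:4, 3:0, rep(0, 3), 1:4, 3:0, rep(0, 3), 1:4, 3:0),
    rep(0, 34)), dt = 0.5)
  pk <- find_trace_peaks(tr, nups = 4, ndowns = 4)
  per <- peak_periods(pk)
  expect_equal(length(per$periods$c01), 2)
  expect_equal(per$periods$c02, numeric(0))
  expect_equal(per$n_short, 1)
  expect_equal(per$median, stats::median(per$periods$c01))
})

test_that("identical peak trains give zero drift and synchrony one", {
  peaks <- structure(list(
    peaks = data.frame(
      community = rep(c("a", "b", "c"), each = 5),
      index = rep(1:5, 3),
      peak_time_h = rep(seq(1, 9, by = 2), 3),
      height = 1, width_h = 0.5, prominence = 1),
    ids = c("a", "b", "c"), dt = 1 / 6), class = "peak_set")
  dr <- phase_drift(peaks, expected_period = 2)
  expect_true(all(dr$table$drift_h == 0))
  sy <- synchrony_index(peaks, expected_period = 2)
  expect_true(all(sy$per_community$index == 1))
})

test_that("two offset communities split the drift about the median", {
  delta <- 0.4
  mk <- function(id, off) data.frame(
    community = id, index = 1:6,
    peak_time_h = seq(1, 11, by = 2) + off,
    height = 1, width_h = 0.5, prominence = 1)
  peaks <- structure(list(peaks = rbind(mk("a", 0), mk("b", delta)),
                          ids = c("a", "b"), dt = 1 / 6),
                     class = "peak_set")
  dr <- phase_drift(peaks, expected_period = 2)
  expect_equal(sort(unique(round(dr$table$drift_h, 10))),
               c(-delta / 2, delta / 2))
})

test_that("a community drifting by a fixed offset scores 1 - offset/T", {
  T <- 2; off <- 0.8
  mk <- function(id, o) data.frame(
    community = id, index = 1:8, peak_time_h = seq(1, 15, by = 2) + o,
    height = 1, width_h = 0.5, prominence = 1)
  peaks <- structure(list(
    peaks = rbind(mk("a", 0), mk("b", 0), mk("c", 0), mk("d", off)),
    ids = c("a", "b", "c", "d"), dt = 1 / 6), class = "peak_set")
  sy <- synchrony_index(peaks, expected_period = T)
  pc <- sy$per_community
  expect_equal(pc$index[pc$community == "d"], 1 - off / T)
  expect_true(all(pc$index[pc$community != "d"] == 1))
  # indices always within [0, 1]
  expect_true(all(pc$index >= 0 & pc$index <= 1))
})

test_that("drift matching agrees with the brute-force matcher", {
  set.seed(17)
  T <- 2
  mk <- function(id) {
    tt <- seq(1, 23, by = T) + rnorm(12, 0, 0.15)
    data.frame(community = id, index = seq_along(tt), peak_time_h = tt,
               height = 1, width_h = 0.5, prominence = 1)
  }
  tabs <- lapply(c("a", "b", "c", "d", "e"), mk)
  peaks <- structure(list(peaks = do.call(rbind, tabs),
                          ids = c("a", "b", "c", "d", "e"), dt = 1 / 6),
                     class = "peak_set")
  dr <- phase_drift(peaks, expected_period = T)
  for (id in peaks$ids) {
    got <- dr$table[dr$table$community == id, ]
    want <- oracle_match(sort(peaks$peaks$peak_time_h[
      peaks$peaks$community == id]), dr$references, T)
    expect_equal(got$cycle, want$cycle)
    expect_equal(got$peak_time_h, want$time)
  }
})

test_that("cumulative autocorrelation matches the direct-sum oracle", {
  set.seed(23)
  x <- matrix(rnorm(3 * 120), nrow = 3) +
    2 * sin(outer(rep(1, 3), (1:120) / 8))
  tr <- toy_traces(x)
  ac <- cumulative_autocorrelation(tr, max_lag = 5)
  L <- length(ac$lag_h) - 1
  want <- colMeans(t(apply(x, 1, oracle_acf, L = L)))
  expect_equal(ac$mean_acf, want, tolerance = 1e-10)
  expect_equal(ac$mean_acf[1], 1)
})

test_that("a cosine autocorrelates at its own period; noise stays bounded", {
  t <- seq(0, 24, by = 1 / 6)
  T <- 2
  tr <- toy_traces(matrix(cos(2 * pi * t / T), nrow = 1))
  ac <- cumulative_autocorrelation(tr, max_lag = 6)
  nz <- ac$lag_h > 0.5
  expect_equal(ac$lag_h[nz][which.max(ac$mean_acf[nz])], T)
  # biased estimator: the lag-T value carries a (1 - lag/n) factor
  expect_gt(max(ac$mean_acf[nz]), 0.85)
  set.seed(31)
  wn <- toy_traces(matrix(rnorm(30 * 240), nrow = 30))
  acw <- cumulative_autocorrelation(wn, max_lag = 10)
  expect_lt(max(abs(acw$mean_acf[-1])), 3 / sqrt(240))
  flat <- toy_traces(rbind(rnorm(50), rep(1, 50)))
  expect_warning(cumulative_autocorrelation(flat, max_lag = 2),
                 "constant")
})

test_that("power spectra match the direct DFT and satisfy Parseval", {
  set.seed(37)
  x <- matrix(rnorm(2 * 96), nrow = 2)
  tr <- toy_traces(x)
  ps <- power_spectrum(tr)
  for (i in 1:2)
    expect_equal(ps$per_community[i, ], oracle_psd(x[i, ]),
                 tolerance = 1e-10)
  for (i in 1:2) {
    v <- mean((x[i, ] - mean(x[i, ]))^2)
    expect_equal(sum(ps$per_community[i, ]), v, tolerance = 1e-8)
  }
  # a sine of period 2 h sampled at 10 min for 24 h
  t <- seq(0, 24 - 1e-9, by = 1 / 6)
  sine <- toy_traces(matrix(sin(2 * pi * t / 2), nrow = 1))
  expect_equal(power_spectrum(sine)$dominant_period_h, 2,
               tolerance = 0.01)
  const <- toy_traces(matrix(5, 1, 64))
  expect_true(all(power_spectrum(const)$mean_psd == 0))
})

test_that("analyze composes the stages without altering their results", {
  cfg <- generator_config(n_communities = 8, duration = 24, period = 2,
                          seed = 3, preset = "closed_loop")
  tr <- generate_traces(cfg)
  rep <- analyze_traces(tr, expected_period = 2)
  # manual composition
  x1 <- detrend_traces(tr)
  x2 <- smooth_traces(x1, 15, 4)
  x3 <- rescale01(x2)
  pk <- find_trace_peaks(x3, 6, 6, min_height = 0.2, heights_from = x2)
  expect_equal(rep$peaks$peaks, pk$peaks)
  expect_equal(rep$periods, peak_periods(pk)$periods)
  sy <- synchrony_index(pk, 2)
  expect_equal(rep$synchrony$per_community, sy$per_community)
  expect_equal(rep$acf$mean_acf,
               cumulative_autocorrelation(x2)$mean_acf)
  expect_equal(rep$psd$mean_psd, power_spectrum(x2)$mean_psd)
  expect_true(rep$structured)
  # stage errors are annotated with the stage name
  short <- toy_traces(matrix(rnorm(10), nrow = 2))
  expect_error(analyze_traces(short, expected_period = 2),
               "analyze\\[smooth\\]")
})
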