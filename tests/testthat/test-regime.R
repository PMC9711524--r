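test_that("removing positive feedback gives a steady circuit", {
  p <- pdef(); p$b1 <- 0
  cl <- classify_regime(p, window = 48)
  expect_equal(cl$label, "steady")
})

test_that("the calibrated default is excitable under a 50% kick", {
  cl <- classify_regime(pdef(), perturbation = 0.5)
  expect_equal(cl$label, "excitable")
  expect_gt(cl$diagnostics$excursion_ratio, 3)
  expect_true(cl$diagnostics$returned_to_rest)
})

test_that("labels agree with a long-horizon brute-force re-check", {
  # random perturbations of the default; the long run uses a window
  # several times larger and a naive peak counter
  set.seed(21)
  p0 <- pdef()
  for (i in 1:4) {
    p <- p0
    p$d2 <- p0$d2 * exp(runif(1, -0.7, 1.6))
    p$gamma <- p0$gamma * exp(runif(1, -0.2, 0.2))
    cl <- classify_regime(p)
    long_win <- 4 * max(48, 40 / min(p$d1, p$d2))
    rs <- rest_state(p, horizon = long_win)
    tr <- simulate_circuit(p, init = rs$state, duration = long_win,
                           output_dt = long_win / 2000)
    I <- tr$IacR
    rng <- max(I) - min(I)
    sustained <- diff(range(I[tr$time_h > 0.75 * long_win])) >
      0.02 * max(I[length(I)], 1e-9)
    if (cl$label == "oscillatory") expect_true(sustained)
    if (cl$label != "oscillatory") expect_false(sustained)
  }
})

test_that("turnover-ratio scan traverses all three regimes in order", {
  grid <- c(0.1, 0.5, 1.5, 3, 8, 20, 33, 37.5, 45)
  sc <- bifurcation_scan(pdef(), grid, mode = "vary-d2")
  expect_equal(nrow(sc), length(grid))
  # regression fixture of the band boundaries: a low-ratio steady band
  # (strong repressor turnover clamps MarR low and IacR high but
  # stable), a wide oscillatory band, the excitable band around the
  # calibrated ratio, and deep-repression steady beyond it
  expect_equal(sc$label,
               c("steady", "steady", "steady", "oscillatory",
                 "oscillatory", "oscillatory", "oscillatory",
                 "excitable", "steady"))
})

test_that("degenerate scan grids and endpoint consistency", {
  p <- pdef()
  one <- bifurcation_scan(p, 5, mode = "vary-d2")
  expect_equal(nrow(one), 1)
  direct <- p; direct$d2 <- p$d1 / 5
  expect_equal(one$label, classify_regime(direct)$label)
  expect_error(bifurcation_scan(p, c(2, 1)), "sorted")
  expect_error(bifurcation_scan(p, numeric(0)), "positive")
})

test_that("second auxin pulse after a short gap elicits almost no response", {
  p <- pdef()
  rp <- refractory_protocol(p, pulse_hours = 12, gap_hours = 2)
  amp <- rp$responses$amplitude
  expect_gt(amp[1], 0)
  expect_lt(amp[2] / amp[1], 0.2)
  # zero-amplitude stimulus produces no response at all
  rp0 <- refractory_protocol(p, gap_hours = 2, amplitude = 0)
  expect_lt(max(rp0$responses$amplitude),
            0.05 * rest_state(p)$state[["IacR"]])
})

test_that("long recovery gaps restore the full response", {
  p <- pdef()
  gap <- 5 / min(p$d1, p$d2)
  rp <- refractory_protocol(p, pulse_hours = 12, gap_hours = gap)
  amp <- rp$responses$amplitude
  expect_gt(amp[1], 0)
  expect_equal(amp[2] / amp[1], 1, tolerance = 0.1)
})
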