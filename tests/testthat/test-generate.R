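test_that("generator config validation lists offending fields", {
  expect_error(generator_config(n_communities = 0, skip_prob = 2),
               "n_communities.*skip_prob|skip_prob.*n_communities")
  expect_error(generator_config(duration = 3, period = 2),
               "duration")
})

test_that("a noise-free, jitter-free generator yields identical traces", {
  cfg <- generator_config(n_communities = 6, duration = 12, period = 2,
                          community_cv = 0, peak_cv = 0, jitter_sd = 0,
                          skip_prob = 0, noise_sd = 0, seed = 4)
  tr <- generate_traces(cfg)
  for (i in 2:6)
    expect_equal(tr$values[i, ], tr$values[1, ],
                 ignore_attr = TRUE)
  rep <- analyze_traces(tr, expected_period = 2)
  expect_true(all(rep$synchrony$per_community$index == 1))
  expect_equal(rep$period_pooled_median, 2)
})

test_that("generation is bit-reproducible under a fixed seed", {
  cfg <- generator_config(n_communities = 10, duration = 16, seed = 99,
                          preset = "closed_loop")
  a <- generate_traces(cfg)
  b <- generate_traces(cfg)
  expect_identical(a$values, b$values)
  # a different seed changes the data
  cfg2 <- generator_config(n_communities = 10, duration = 16, seed = 100,
                           preset = "closed_loop")
  expect_false(identical(generate_traces(cfg2)$values, a$values))
})

test_that("per-community substreams do not depend on cohort size", {
  c5 <- generator_config(n_communities = 5, duration = 12, seed = 31,
                         preset = "closed_loop")
  c3 <- generator_config(n_communities = 3, duration = 12, seed = 31,
                         preset = "closed_loop")
  expect_identical(generate_traces(c5)$values[1:3, ],
                   generate_traces(c3)$values)
})

test_that("closed-loop preset round-trips the stimulus period", {
  cfg <- generator_config(n_communities = 30, duration = 24, period = 2,
                          seed = 12, preset = "closed_loop")
  rep <- analyze_traces(generate_traces(cfg), expected_period = 2)
  expect_equal(rep$period_pooled_median, 2, tolerance = 0.05)
  expect_gt(rep$synchrony$summary$median, 0.9)
})

test_that("open-loop communities are less synchronous than closed-loop", {
  syn <- function(preset, seed) {
    cfg <- generator_config(n_communities = 12, duration = 24, period = 2,
                            seed = seed, preset = preset)
    rep <- suppressWarnings(analyze_traces(generate_traces(cfg),
                                           expected_period = 2))
    rep$synchrony$summary$median
  }
  seeds <- 1:10
  open <- vapply(seeds, function(s) syn("open_loop", s), numeric(1))
  closed <- vapply(seeds, function(s) syn("closed_loop", s), numeric(1))
  expect_lt(mean(open), mean(closed))
})

test_that("control preset shows no organised periodic structure", {
  cfg <- generator_config(n_communities = 15, duration = 24, period = 3,
                          seed = 8, preset = "control")
  rep <- suppressWarnings(analyze_traces(generate_traces(cfg),
                                         expected_period = 3))
  expect_false(rep$structured)
})

test_that("model-driven generation reduces to plain simulation", {
  p <- pdef()
  stim <- antithetic_stimulus(2, duration = 8)
  tr <- generate_from_model(p, stim, n_communities = 3,
                            heterogeneity = 0, noise_sd = 0, seed = 1)
  expect_equal(nrow(tr$values), 3)
  ref <- simulate_circuit(p, stim, duration = 8, output_dt = 1 / 6)
  for (i in 1:3)
    expect_equal(unname(tr$values[i, ]), ref$IacR, tolerance = 1e-10)
  one <- generate_from_model(p, stim, n_communities = 1,
                             heterogeneity = 0.1, seed = 2)
  expect_equal(nrow(one$values), 1)
})

test_that("parameter heterogeneity degrades synchrony monotonically", {
  p <- pdef()
  stim <- antithetic_stimulus(2, duration = 12)
  syn <- function(h, seed) {
    tr <- generate_from_model(p, stim, n_communities = 6,
                              heterogeneity = h, noise_sd = 0,
                              seed = seed)
    rep <- suppressWarnings(analyze_traces(tr, expected_period = 2))
    rep$synchrony$summary$median
  }
  lo <- mean(vapply(1:4, function(s) syn(0.05, s), numeric(1)))
  hi <- mean(vapply(1:4, function(s) syn(0.4, s), numeric(1)))
  expect_gt(lo, hi)
})
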