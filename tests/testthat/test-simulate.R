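test_that("vector field matches the hand-coded rate equations", {
  p <- pdef()
  # state-dependent terms vanish at the origin
  expect_equal(circuit_dynamics(c(0, 0), 0, p, iaa = 0, sa = 0),
               c(p$a1, p$a2))
  # linear fixed point when feedback is off
  q <- p; q$b1 <- 0; q$b2 <- 0
  expect_equal(circuit_dynamics(c(q$a1 / q$d1, q$a2 / q$d2), 0, q,
                                iaa = 0, sa = 0),
               c(0, 0), tolerance = 1e-12)
  # randomly seeded states against the duplicate-formula oracle
  set.seed(101)
  for (i in 1:25) {
    st <- runif(2, 0, 20)
    pp <- circuit_params(a1 = runif(1, 0, 1), a2 = runif(1, 0, 1),
                         b1 = runif(1, 0, 50), b2 = runif(1, 0, 10),
                         K_A = runif(1, 0.1, 3), K_B = runif(1, 0.1, 5),
                         gamma = runif(1, 0.1, 10), d1 = runif(1, 0.1, 5),
                         d2 = runif(1, 0.01, 2), eps_I = runif(1, 0, 100),
                         eps_M = runif(1, 0, 100))
    iaa <- runif(1); sa <- runif(1)
    got <- circuit_dynamics(st, 0, pp, iaa = iaa, sa = sa)
    want <- oracle_dynamics(st[1], st[2], iaa, sa, pp)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("decoupled linear system relaxes to a1/d1, a2/d2", {
  p <- circuit_params(a1 = 0.5, a2 = 0.2, b1 = 0, b2 = 0, K_A = 1,
                      K_B = 1, gamma = 1, d1 = 0.4, d2 = 0.25)
  tr <- simulate_circuit(p, init = c(0, 0),
                         duration = 10 / min(p$d1, p$d2),
                         output_dt = 0.5)
  n <- nrow(tr)
  expect_equal(tr$IacR[n], p$a1 / p$d1, tolerance = 0.01)
  expect_equal(tr$MarR[n], p$a2 / p$d2, tolerance = 0.01)
})

test_that("adaptive integration matches the fixed-step RK4 oracle", {
  p <- pdef()
  stim <- antithetic_stimulus(2, duration = 6)
  init <- c(0.5, 0.5)
  tr <- simulate_circuit(p, stim, init = init, duration = 6,
                         output_dt = 0.5)
  rk <- oracle_rk4(p, stim, init, duration = 6, out_dt = 0.5)
  scale <- pmax(abs(rk$I), 1e-6)
  expect_lt(max(abs(tr$IacR - rk$I) / scale), 1e-4)
  expect_lt(max(abs(tr$MarR - rk$M) / pmax(abs(rk$M), 1e-6)), 1e-4)
  # and for the smooth (sine) stimulus
  sstim <- stimulus_program("sine", period = 3, duration = 6)
  tr2 <- simulate_circuit(p, sstim, init = init, duration = 6,
                          output_dt = 0.5)
  rk2 <- oracle_rk4(p, sstim, init, duration = 6, out_dt = 0.5)
  expect_lt(max(abs(tr2$IacR - rk2$I) / pmax(abs(rk2$I), 1e-6)), 1e-4)
})

test_that("trajectories from nonnegative starts stay nonnegative", {
  set.seed(11)
  p <- pdef()
  for (i in 1:6) {
    init <- runif(2, 0, 5)
    stim <- antithetic_stimulus(sample(c(0.5, 1, 2, 3), 1), duration = 8)
    tr <- simulate_circuit(p, stim, init = init, duration = 8,
                           output_dt = 0.1)
    expect_true(all(tr$IacR >= 0) && all(tr$MarR >= 0))
    expect_true(all(diff(tr$time_h) > 0))
  }
})

test_that("the rest state solves the unforced steady-state equations", {
  rs <- rest_state(pdef())
  expect_true(rs$converged)
  expect_lt(max(abs(rs$residual)), 1e-5)
  # default initial condition is the rest state
  tr <- simulate_circuit(pdef(), duration = 1, output_dt = 0.5)
  expect_equal(unname(tr$IacR[1]), unname(rs$state[["IacR"]]),
               tolerance = 1e-8)
})
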