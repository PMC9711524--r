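#' Vector field of the dual-feedback circuit
#'
#' Right-hand side of the two coupled rate equations.  IacR activates
#' its own production and MarR's through Hill terms; MarR enters the
#' IacR Hill denominator (repression); the hormones act multiplicatively
#' on turnover:
#' \deqn{dIacR/dt = a_1 + b_1 IacR^2 / (K_A^2 + IacR^2 + (\gamma MarR)^2)
#'   - d_1 (1 + \epsilon_I IAA) IacR}
#' \deqn{dMarR/dt = a_2 + b_2 IacR^2 / (K_B^2 + IacR^2)
#'   - d_2 (1 + \epsilon_M SA) MarR}
#'
#' @param state numeric length-2 vector `(IacR, MarR)`.
#' @param t time in hours (used to evaluate the stimulus).
#' @param params a [circuit_params()] object.
#' @param stimulus a [stimulus_program()] or `NULL` (hormones off).
#' @param iaa,sa optional explicit stimulus values; when given they
#'   override `stimulus`.
#' @return Numeric length-2 vector `(dIacR/dt, dMarR/dt)`.
#' @export
circuit_dynamics <- function(state, t, params, stimulus = NULL,
                             iaa = NULL, sa = NULL) {
  validate_circuit_params(params)
  if (is.null(iaa) || is.null(sa)) {
    sv <- stimulus_values(stimulus, t)
    iaa <- sv$iaa; sa <- sv$sa
  }
  I <- state[1]; M <- state[2]
  dI <- params$a1 +
    params$b1 * I^2 / (params$K_A^2 + I^2 + (params$gamma * M)^2) -
    params$d1 * (1 + params$eps_I * iaa) * I
  dM <- params$a2 +
    params$b2 * I^2 / (params$K_B^2 + I^2) -
    params$d2 * (1 + params$eps_M * sa) * M
  c(dI, dM)
}

#' Simulate the circuit
#'
#' Integrates the circuit with an adaptive stiff-capable solver
#' (`deSolve::ode`, `lsoda`, relative tolerance `1e-8`, absolute
#' `1e-10`).  Square-wave / pulse edges are treated as breakpoints: the
#' integration restarts at every stimulus discontinuity so edges are
#' not smeared, and the stimulus is held at its within-segment value.
#'
#' @param params a [circuit_params()] object.
#' @param stimulus a [stimulus_program()] or `NULL` for the unforced
#'   system.
#' @param init numeric `(IacR, MarR)` initial state; default is the
#'   unforced rest state (relaxation from the origin), see
#'   [rest_state()].
#' @param duration simulation length in hours (default: stimulus
#'   duration, or 48 h unforced).
#' @param output_dt output sampling interval in hours (default `1/6`,
#'   the 10-minute imaging cadence).
#' @param rtol,atol solver tolerances.
#' @return A data.frame of class `circuit_trajectory` with columns
#'   `time_h`, `IacR`, `MarR`, `IAA`, `SA`; the parameter set and
#'   stimulus are attached as attributes.
#' @export
simulate_circuit <- function(params, stimulus = NULL, init = NULL,
                             duration = NULL, output_dt = 1 / 6,
                             rtol = 1e-8, atol = 1e-10) {
  validate_circuit_params(params)
  if (is.null(duration))
    duration <- if (!is.null(stimulus)) stimulus$duration else 48
  if (duration <= 0) stop("simulate_circuit: duration must be > 0")
  if (output_dt <= 0) stop("simulate_circuit: output_dt must be > 0")
  if (is.null(init)) init <- rest_state(params)$state
  if (any(init < 0)) stop("simulate_circuit: initial state must be >= 0")

  grid <- seq(0, duration, by = output_dt)
  if (abs(grid[length(grid)] - duration) > 1e-9)
    grid <- c(grid, duration)
  bps <- stimulus_breakpoints(stimulus, 0, duration)
  seg_bounds <- sort(unique(c(0, bps, duration)))

  out_t <- numeric(0); out_I <- numeric(0); out_M <- numeric(0)
  state <- c(I = init[1], M = init[2])
  piecewise_const <- is.null(stimulus) ||
    stimulus$kind %in% c("none", "square", "pulse_list")

  for (s in seq_len(length(seg_bounds) - 1)) {
    t0 <- seg_bounds[s]; t1 <- seg_bounds[s + 1]
    tt <- grid[grid > t0 + 1e-12 & tt_lt(grid, t1)]
    times <- sort(unique(c(t0, tt, t1)))
    if (piecewise_const) {
      sv <- stimulus_values(stimulus, (t0 + t1) / 2)
      rhs <- function(t, y, parms) {
        list(circuit_dynamics(y, t, params, iaa = sv$iaa, sa = sv$sa))
      }
    } else {
      rhs <- function(t, y, parms) {
        list(circuit_dynamics(y, t, params, stimulus = stimulus))
      }
    }
    sol <- deSolve::ode(y = state, times = times, func = rhs, parms = NULL,
                        method = "lsoda", rtol = rtol, atol = atol,
                        maxsteps = 100000)
    if (attr(sol, "istate")[1] < 0 || nrow(sol) < length(times))
      stop(sprintf(
        "simulate_circuit: integration failed near t = %.4g h",
        sol[nrow(sol), 1]))
    keep <- if (s == 1) seq_len(nrow(sol)) else -1
    sol_keep <- sol[keep, , drop = FALSE]
    on_grid <- vapply(sol_keep[, 1], function(x)
      min(abs(x - grid)) < 1e-9, logical(1))
    out_t <- c(out_t, sol_keep[on_grid, 1])
    out_I <- c(out_I, sol_keep[on_grid, 2])
    out_M <- c(out_M, sol_keep[on_grid, 3])
    state <- c(I = sol[nrow(sol), 2], M = sol[nrow(sol), 3])
  }

  # snap output times to the uniform grid; drop duplicates at breakpoints
  idx <- !duplicated(round(out_t / output_dt))
  out_t <- out_t[idx]; out_I <- out_I[idx]; out_M <- out_M[idx]
  # the vector field has nonnegative inflow at zero; clip solver noise
  if (min(out_I, out_M) < -1e6 * atol)
    stop("simulate_circuit: trajectory left the nonnegative quadrant")
  out_I <- pmax(out_I, 0); out_M <- pmax(out_M, 0)

  sv <- stimulus_values(stimulus, out_t)
  traj <- data.frame(time_h = out_t, IacR = out_I, MarR = out_M,
                     IAA = sv$iaa, SA = sv$sa)
  attr(traj, "params") <- params
  attr(traj, "stimulus") <- stimulus
  class(traj) <- c("circuit_trajectory", "data.frame")
  traj
}

tt_lt <- function(x, b) x < b - 1e-12

#' Unforced rest state
#'
#' Relaxes the hormone-free system from the origin for a long horizon
#' and reports the final state, together with a convergence flag
#' (vector-field residual below tolerance).  In the excitable and
#' steady regimes this is the lowest-IacR stable fixed point; in the
#' oscillatory regime the flag is `FALSE`.
#'
#' @param params a [circuit_params()] object.
#' @param horizon relaxation horizon in hours (default
#'   `max(100, 20/min(d1, d2))`).
#' @param tol residual tolerance for the convergence flag.
#' @return List with `state` (named numeric `(IacR, MarR)`),
#'   `converged` (logical) and `residual`.
#' @export
rest_state <- function(params, horizon = NULL, tol = 1e-6) {
  validate_circuit_params(params)
  if (is.null(horizon))
    horizon <- max(100, 20 / min(params$d1, params$d2))
  rhs <- function(t, y, parms)
    list(circuit_dynamics(y, t, params, iaa = 0, sa = 0))
  sol <- deSolve::ode(y = c(I = 0, M = 0), times = c(0, horizon / 2, horizon),
                      func = rhs, parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12, maxsteps = 500000)
  st <- pmax(as.numeric(sol[nrow(sol), 2:3]), 0)
  scale <- c(max(params$a1, params$d1 * st[1]),
             max(params$a2, params$d2 * st[2]))
  res <- circuit_dynamics(st, 0, params, iaa = 0, sa = 0)
  # polish with Newton iterations when the relaxation has essentially
  # settled (never from mid-orbit states in the oscillatory regime)
  if (all(abs(res) <= 1e-3 * pmax(scale, 1e-12))) {
    for (it in 1:20) {
      J <- unforced_jacobian(st, params)
      step <- tryCatch(solve(J, res), error = function(e) NULL)
      if (is.null(step)) break
      st2 <- pmax(st - step, 0)
      res2 <- circuit_dynamics(st2, 0, params, iaa = 0, sa = 0)
      if (!all(is.finite(res2))) break
      st <- st2; res <- res2
      if (max(abs(res)) < 1e-13) break
    }
  }
  converged <- all(abs(res) <= tol * pmax(scale, 1e-12))
  list(state = c(IacR = st[1], MarR = st[2]),
       converged = converged, residual = res)
}

# analytic Jacobian of the unforced vector field
unforced_jacobian <- function(st, p) {
  I <- st[1]; M <- st[2]
  den <- p$K_A^2 + I^2 + (p$gamma * M)^2
  matrix(c(
    p$b1 * 2 * I * (p$K_A^2 + (p$gamma * M)^2) / den^2 - p$d1,
    -p$b1 * I^2 * 2 * p$gamma^2 * M / den^2,
    p$b2 * 2 * I * p$K_B^2 / (p$K_B^2 + I^2)^2,
    -p$d2), nrow = 2, byrow = TRUE)
}

#' @export
print.circuit_trajectory <- function(x, ...) {
  cat(sprintf("<circuit_trajectory> %d samples, %.3g h, dt = %.4g h\n",
              nrow(x), x$time_h[nrow(x)], x$time_h[2] - x$time_h[1]))
  cat(sprintf("  IacR in [%.4g, %.4g], MarR in [%.4g, %.4g]\n",
              min(x$IacR), max(x$IacR), min(x$MarR), max(x$MarR)))
  invisible(x)
}
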