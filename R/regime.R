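#' Classify the dynamical regime of the unforced circuit
#'
#' Simulates the hormone-free system from its rest state and from a
#' perturbed state and assigns one of three labels:
#' \describe{
#'   \item{oscillatory}{the unforced system produces at least
#'     `min_peaks` peaks in the second half of the classification
#'     window with coefficient of variation of inter-peak intervals
#'     below `osc_cv`;}
#'   \item{excitable}{the unperturbed system settles, but a relative
#'     kick of size `perturbation` applied to the rest-state IacR
#'     triggers an excursion whose peak exceeds
#'     `excursion_threshold` times the rest-state IacR before the
#'     system returns to rest;}
#'   \item{steady}{otherwise.}
#' }
#'
#' @param params a [circuit_params()] object.
#' @param perturbation relative kick applied to the rest-state IacR
#'   (default 0.5, i.e. IacR is raised by 50%).
#' @param window classification window in hours.  The default,
#'   `max(48, 40/min(d1, d2))`, scales with the slowest turnover time
#'   so that slow relaxation oscillations still show at least three
#'   periods inside the window.
#' @param excursion_threshold excursion amplitude required for the
#'   excitable label, as a multiple of the rest-state IacR (default 3).
#' @param min_peaks,osc_cv oscillation criteria (defaults 3 peaks,
#'   CV < 0.1).
#' @param output_dt sampling interval of the internal simulations.
#' @return An object of class `regime_label`: list with `label`
#'   (`"steady"`, `"excitable"` or `"oscillatory"`) and `diagnostics`
#'   (peak count, inter-peak CV, excursion ratio, return-to-rest flag).
#' @export
classify_regime <- function(params, perturbation = 0.5, window = NULL,
                            excursion_threshold = 3, min_peaks = 3,
                            osc_cv = 0.1, output_dt = NULL) {
  validate_circuit_params(params)
  if (perturbation <= 0)
    stop("classify_regime: perturbation must be > 0")
  if (is.null(window))
    window <- max(48, 40 / min(params$d1, params$d2))
  if (is.null(output_dt)) output_dt <- window / 600
  rest <- rest_state(params)
  rI <- rest$state[["IacR"]]

  free <- simulate_circuit(params, stimulus = NULL, init = rest$state,
                           duration = window, output_dt = output_dt)
  I <- free$IacR
  rng <- max(I) - min(I)
  # peaks of the free run, second half of the window only
  half <- free$time_h >= window / 2
  pk_idx <- integer(0)
  if (rng > 0.01 * max(rI, 1e-9)) {
    floor_h <- min(I) + 0.25 * rng
    pk_idx <- local_maxima(I, min_height = floor_h)
    pk_idx <- pk_idx[half[pk_idx]]
  }
  pk_t <- free$time_h[pk_idx]
  ipi_cv <- NA_real_
  if (length(pk_t) >= 3) {
    ipi <- diff(pk_t)
    ipi_cv <- stats::sd(ipi) / mean(ipi)
  }
  if (length(pk_t) >= min_peaks && !is.na(ipi_cv) && ipi_cv < osc_cv) {
    return(structure(list(label = "oscillatory",
                          diagnostics = list(n_peaks = length(pk_t),
                                             ipi_cv = ipi_cv,
                                             excursion_ratio = NA,
                                             returned_to_rest = FALSE)),
                     class = "regime_label"))
  }

  pert_init <- c(IacR = rI * (1 + perturbation),
                 MarR = rest$state[["MarR"]])
  pert <- simulate_circuit(params, stimulus = NULL, init = pert_init,
                           duration = window, output_dt = output_dt)
  exc_ratio <- max(pert$IacR) / max(rI, 1e-12)
  final <- pert$IacR[nrow(pert)]
  returned <- abs(final - rI) <= 0.05 * max(rI, 1e-12)
  label <- if (exc_ratio > excursion_threshold && returned)
    "excitable" else "steady"
  structure(list(label = label,
                 diagnostics = list(n_peaks = length(pk_t),
                                    ipi_cv = ipi_cv,
                                    excursion_ratio = exc_ratio,
                                    returned_to_rest = returned)),
            class = "regime_label")
}

#' @export
print.regime_label <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("<regime_label> %s (peaks=%d, ipi_cv=%s, excursion=%sx)\n",
              x$label, d$n_peaks,
              format(d$ipi_cv, digits = 3),
              format(d$excursion_ratio, digits = 3)))
  invisible(x)
}

#' Scan the turnover ratio d1/d2
#'
#' The ratio of the two protein turnover rates is the key bifurcation
#' parameter of the circuit: varying it alone moves the system between
#' steady, excitable and oscillatory regimes.  `bifurcation_scan`
#' classifies the regime at each requested ratio, holding the other
#' rate at its base value.
#'
#' @param base a [circuit_params()] object.
#' @param ratio_grid positive, sorted vector of `d1/d2` ratios.
#' @param mode `"vary-d1"` (set `d1 = ratio * d2_base`) or `"vary-d2"`
#'   (set `d2 = d1_base / ratio`).
#' @param ... passed to [classify_regime()].
#' @return A data.frame with columns `ratio`, `d1`, `d2`, `label`.
#' @export
bifurcation_scan <- function(base, ratio_grid,
                             mode = c("vary-d1", "vary-d2"), ...) {
  mode <- match.arg(mode)
  validate_circuit_params(base)
  if (length(ratio_grid) == 0 || any(ratio_grid <= 0))
    stop("bifurcation_scan: ratio_grid must be positive")
  if (is.unsorted(ratio_grid))
    stop("bifurcation_scan: ratio_grid must be sorted increasing")
  res <- lapply(ratio_grid, function(r) {
    p <- base
    if (mode == "vary-d1") p$d1 <- r * base$d2 else p$d2 <- base$d1 / r
    cl <- classify_regime(p, ...)
    data.frame(ratio = r, d1 = p$d1, d2 = p$d2, label = cl$label,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Refractory-period protocol: two long auxin pulses
#'
#' Applies two IAA-only pulses (12 h each by default) separated by
#' `gap_hours` and measures the response elicited by each pulse.  In
#' the excitable regime the response is a transient IacR excursion
#' fired when auxin is removed: during the pulse IacR is degraded and
#' MarR relaxes to its basal level, and on removal IacR rebounds
#' through the positive feedback before MarR recovers.  The excursion
#' pumps MarR far above rest, so a second pulse arriving before MarR
#' has decayed back finds the circuit refractory and elicits a much
#' smaller response.
#'
#' The response amplitude of pulse `k` is the maximum IacR elevation
#' above rest in the window from that pulse's end to the start of the
#' next pulse (or the end of the simulation).
#'
#' @param params a [circuit_params()] object.
#' @param pulse_hours pulse length in hours (default 12).
#' @param gap_hours gap between the end of the first pulse and the
#'   start of the second (default 2).
#' @param amplitude IAA amplitude (default 1).
#' @param lead_hours hormone-free lead-in before the first pulse.
#' @param tail_hours hormone-free tail after the second pulse (default
#'   `max(12, 5/d1)` so the second response can develop).
#' @param output_dt output sampling interval in hours.
#' @return An object of class `refractory_result`: list with
#'   `trajectory` (a `circuit_trajectory`), `responses` (data.frame
#'   with one row per pulse: start/end, response window, peak time and
#'   amplitude) and `rest_IacR`.
#' @export
refractory_protocol <- function(params, pulse_hours = 12, gap_hours = 2,
                                amplitude = 1, lead_hours = 1,
                                tail_hours = NULL, output_dt = 1 / 6) {
  validate_circuit_params(params)
  if (pulse_hours <= 0) stop("refractory_protocol: pulse_hours must be > 0")
  if (gap_hours < 0) stop("refractory_protocol: gap_hours must be >= 0")
  if (is.null(tail_hours)) tail_hours <- max(12, 5 / params$d1)
  s1 <- lead_hours; e1 <- s1 + pulse_hours
  s2 <- e1 + gap_hours; e2 <- s2 + pulse_hours
  duration <- e2 + tail_hours
  pulses <- data.frame(start = c(s1, s2), end = c(e1, e2),
                       channel = c("iaa", "iaa"))
  stim <- stimulus_program("pulse_list", duration = duration,
                           amp_iaa = amplitude, amp_sa = 0,
                           pulses = pulses)
  rest <- rest_state(params)
  traj <- simulate_circuit(params, stim, init = rest$state,
                           duration = duration, output_dt = output_dt)
  rI <- rest$state[["IacR"]]
  win_end <- c(s2, duration)
  resp <- lapply(1:2, function(k) {
    lo <- c(e1, e2)[k]; hi <- win_end[k]
    sel <- traj$time_h > lo & traj$time_h <= hi
    if (!any(sel))
      return(data.frame(pulse = k, start = c(s1, s2)[k],
                        end = c(e1, e2)[k], window_end = hi,
                        peak_time = NA_real_, amplitude = 0))
    I <- traj$IacR[sel]; t <- traj$time_h[sel]
    j <- which.max(I)
    data.frame(pulse = k, start = c(s1, s2)[k], end = c(e1, e2)[k],
               window_end = hi, peak_time = t[j],
               amplitude = max(0, I[j] - rI))
  })
  structure(list(trajectory = traj, responses = do.call(rbind, resp),
                 rest_IacR = rI),
            class = "refractory_result")
}

#' @export
print.refractory_result <- function(x, ...) {
  cat("<refractory_result>\n")
  print(x$responses)
  r <- x$responses$amplitude
  if (r[1] > 0)
    cat(sprintf("  second/first response ratio: %.3f\n", r[2] / r[1]))
  invisible(x)
}
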