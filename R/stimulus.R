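#' Time-dependent phytohormone stimulus programs
#'
#' A `stimulus_program` describes the external auxin (IAA) and
#' salicylate (SA) waveforms applied to the circuit.  Three waveform
#' kinds are supported: periodic square waves, sines, and explicit
#' pulse lists (for protocols such as the two long auxin pulses of the
#' refractory assay).  Stimulus values are dimensionless, in
#' `[0, amplitude]`.
#'
#' Square-wave convention: the IAA channel is high on
#' `[k*T, k*T + duty*T)` for integer `k` (shifted by `phase_iaa`), the
#' SA channel likewise with its own phase.  Sine waves are rectified
#' raised sines `amplitude * (1 + sin(...))/2` so values stay
#' nonnegative.
#'
#' @param kind one of `"square"`, `"sine"`, `"pulse_list"`, `"none"`.
#' @param period forcing period `T_stim` in hours (square/sine).
#' @param duration total program duration in hours.
#' @param amp_iaa,amp_sa stimulus amplitudes (default 1).
#' @param duty duty cycle, fraction of the period a square wave is high
#'   (strictly between 0 and 1).
#' @param phase_iaa,phase_sa phase offsets (hours) of the IAA and SA
#'   waveforms.
#' @param pulses for `kind = "pulse_list"`: a data.frame with columns
#'   `start`, `end` (hours) and `channel` (`"iaa"` or `"sa"`);
#'   intervals must not overlap within a channel.
#'
#' @return An object of class `stimulus_program`.
#' @seealso [antithetic_stimulus()], [stimulus_values()]
#' @export
stimulus_program <- function(kind = c("square", "sine", "pulse_list", "none"),
                             period = NULL, duration = 24,
                             amp_iaa = 1, amp_sa = 1, duty = 0.5,
                             phase_iaa = 0, phase_sa = 0,
                             pulses = NULL) {
  kind <- match.arg(kind)
  if (amp_iaa < 0 || amp_sa < 0)
    stop("stimulus_program: amplitudes must be >= 0")
  if (!is.numeric(duration) || duration <= 0)
    stop("stimulus_program: duration must be > 0")
  if (kind %in% c("square", "sine")) {
    if (is.null(period) || period <= 0)
      stop("stimulus_program: a positive period is required for ", kind,
           " waveforms")
    if (kind == "square" && (duty <= 0 || duty >= 1))
      stop("stimulus_program: duty cycle must satisfy 0 < duty < 1")
  }
  if (kind == "pulse_list") {
    if (is.null(pulses) || nrow(pulses) == 0) {
      pulses <- data.frame(start = numeric(0), end = numeric(0),
                           channel = character(0))
    } else {
      stopifnot(all(c("start", "end", "channel") %in% names(pulses)))
      if (!all(pulses$channel %in% c("iaa", "sa")))
        stop("stimulus_program: pulse channel must be 'iaa' or 'sa'")
      if (any(pulses$end <= pulses$start))
        stop("stimulus_program: pulse end must exceed start")
      for (ch in unique(pulses$channel)) {
        pp <- pulses[pulses$channel == ch, , drop = FALSE]
        pp <- pp[order(pp$start), , drop = FALSE]
        if (nrow(pp) > 1 && any(pp$start[-1] < pp$end[-nrow(pp)]))
          stop("stimulus_program: overlapping pulses within channel '",
               ch, "'")
      }
    }
  }
  structure(list(kind = kind, period = period, duration = duration,
                 amp_iaa = amp_iaa, amp_sa = amp_sa, duty = duty,
                 phase_iaa = phase_iaa, phase_sa = phase_sa,
                 pulses = pulses),
            class = "stimulus_program")
}

#' Antithetic square-wave stimulation
#'
#' Builds the alternating IAA/SA program used for entrainment: both
#' channels are square waves with 50% duty, SA offset by half a period
#' relative to IAA, so that exactly one hormone is present at any time
#' (the alternating black/green boxes of the stimulation protocol).
#'
#' @param period forcing period in hours.
#' @param duration total duration in hours.
#' @param amplitude stimulus amplitude applied to both channels.
#' @param first which hormone is high during the first half-period.
#' @return A `stimulus_program` with `kind = "square"`.
#' @export
antithetic_stimulus <- function(period, duration, amplitude = 1,
                                first = c("iaa", "sa")) {
  first <- match.arg(first)
  off <- period / 2
  stimulus_program("square", period = period, duration = duration,
                   amp_iaa = amplitude, amp_sa = amplitude, duty = 0.5,
                   phase_iaa = if (first == "iaa") 0 else off,
                   phase_sa  = if (first == "iaa") off else 0)
}

#' Evaluate a stimulus program
#'
#' @param stim a `stimulus_program` (or `NULL` for no stimulus).
#' @param t numeric vector of times (hours).
#' @return A list with numeric vectors `iaa` and `sa`, the stimulus
#'   values at `t`.
#' @export
stimulus_values <- function(stim, t) {
  if (is.null(stim) || stim$kind == "none")
    return(list(iaa = numeric(length(t)) * 0, sa = numeric(length(t)) * 0))
  sq <- function(t, amp, phase) {
    if (amp == 0) return(rep(0, length(t)))
    u <- (t - phase) / stim$period
    frac <- u - floor(u)
    ifelse(frac < stim$duty - 1e-12 | frac > 1 - 1e-12, amp, 0)
  }
  sn <- function(t, amp, phase) {
    amp * (1 + sin(2 * pi * (t - phase) / stim$period)) / 2
  }
  pl <- function(t, ch, amp) {
    out <- rep(0, length(t))
    pp <- stim$pulses[stim$pulses$channel == ch, , drop = FALSE]
    if (nrow(pp)) {
      for (i in seq_len(nrow(pp)))
        out[t >= pp$start[i] - 1e-12 & t < pp$end[i] - 1e-12] <- amp
    }
    out
  }
  switch(stim$kind,
    square = list(iaa = sq(t, stim$amp_iaa, stim$phase_iaa),
                  sa  = sq(t, stim$amp_sa,  stim$phase_sa)),
    sine   = list(iaa = sn(t, stim$amp_iaa, stim$phase_iaa),
                  sa  = sn(t, stim$amp_sa,  stim$phase_sa)),
    pulse_list = list(iaa = pl(t, "iaa", stim$amp_iaa),
                      sa  = pl(t, "sa",  stim$amp_sa)))
}

#' Discontinuity times of a stimulus program
#'
#' Square-wave and pulse-list programs are discontinuous; the
#' integrator restarts at each edge so that edges are not smeared.
#'
#' @param stim a `stimulus_program` or `NULL`.
#' @param from,to time window (hours).
#' @return Sorted numeric vector of edge times strictly inside
#'   `(from, to)`.
#' @export
stimulus_breakpoints <- function(stim, from, to) {
  if (is.null(stim) || stim$kind %in% c("none", "sine")) return(numeric(0))
  edges <- numeric(0)
  if (stim$kind == "square") {
    add_edges <- function(amp, phase) {
      if (amp == 0) return(numeric(0))
      k <- floor((from - phase) / stim$period - 1):
           ceiling((to - phase) / stim$period + 1)
      c(phase + k * stim$period,
        phase + (k + stim$duty) * stim$period)
    }
    edges <- c(add_edges(stim$amp_iaa, stim$phase_iaa),
               add_edges(stim$amp_sa, stim$phase_sa))
  } else if (stim$kind == "pulse_list") {
    edges <- c(stim$pulses$start, stim$pulses$end)
  }
  edges <- sort(unique(edges))
  edges[edges > from + 1e-10 & edges < to - 1e-10]
}

#' @export
print.stimulus_program <- function(x, ...) {
  cat("<stimulus_program>", x$kind, "\n")
  if (x$kind %in% c("square", "sine"))
    cat(sprintf("  period %g h, duty %g, amp IAA=%g SA=%g, phase IAA=%g SA=%g\n",
                x$period, x$duty, x$amp_iaa, x$amp_sa,
                x$phase_iaa, x$phase_sa))
  if (x$kind == "pulse_list")
    print(x$pulses)
  cat(sprintf("  duration %g h\n", x$duration))
  invisible(x)
}
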