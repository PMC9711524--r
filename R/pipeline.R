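#' Reporter normalisation against a constitutive red channel
#'
#' Element-wise `green/(green + red)`, the correction used to discard
#' dead or non-growing material from the reporter signal: the
#' constitutive mCherry marker only contributes where cells are alive
#' and growing.  Grid cells where `green + red == 0` are set to 0 and
#' counted in a warning.
#'
#' @param green,red `community_traces` on identical grids with the same
#'   community set; `red` values must be >= 0.
#' @return A `community_traces` of normalised values in `[0, 1]`.
#' @export
normalize_reporter <- function(green, red) {
  stopifnot(is_community_traces(green), is_community_traces(red))
  check_same_grid(green, red, "reporter channels")
  if (any(red$values < 0))
    stop("normalize_reporter: red channel must be nonnegative")
  denom <- green$values + red$values
  zero <- denom == 0
  out <- green$values
  out[!zero] <- green$values[!zero] / denom[!zero]
  out[zero] <- 0
  if (any(zero))
    warning(sprintf("normalize_reporter: %d grid cell(s) had zero total signal",
                    sum(zero)))
  with_values(green, out)
}

#' Linear detrending
#'
#' Subtracts, per community, the least-squares straight line fitted to
#' that community's full trace (the linear `detrend` of the analysis
#' pipeline); the result has mean ~0 and no linear trend.
#'
#' @param traces a `community_traces` with at least 3 time points.
#' @return Detrended `community_traces`.
#' @export
detrend_traces <- function(traces) {
  stopifnot(is_community_traces(traces))
  if (ncol(traces$values) < 3)
    stop("detrend_traces: need at least 3 time points")
  # pracma::detrend works column-wise on a time x series matrix
  det <- pracma::detrend(t(traces$values), tt = "linear")
  with_values(traces, t(det))
}

# Savitzky-Golay coefficient row for the window centre (dorder = 0)
savgol_coef <- function(window, polyorder) {
  fc <- (window - 1) / 2
  X <- outer(-fc:fc, 0:polyorder, `^`)
  pracma::pinv(X)
}

#' Savitzky-Golay smoothing
#'
#' Local polynomial least-squares smoothing with the classic
#' Savitzky-Golay filter (default filter length 15, polynomial order
#' 4).  Interior points are the centre values of the moving windowed
#' fit; the first and last `(window-1)/2` points are taken from the
#' polynomial fitted to the first/last full window (polynomial
#' extrapolation of the boundary fits), so edges are not zero-padded.
#'
#' @param traces a `community_traces`; each series must be at least
#'   `window` long.
#' @param window odd filter length (default 15 samples).
#' @param polyorder polynomial order (default 4); must be `< window`.
#' @return Smoothed `community_traces`.
#' @export
smooth_traces <- function(traces, window = 15, polyorder = 4) {
  stopifnot(is_community_traces(traces))
  if (window %% 2 != 1 || window <= 1)
    stop("smooth_traces: window must be an odd integer > 1")
  if (polyorder >= window)
    stop("smooth_traces: window must exceed polyorder")
  n <- ncol(traces$values)
  if (n < window)
    stop("smooth_traces: series length must be >= window")
  fc <- (window - 1) / 2
  P <- savgol_coef(window, polyorder)     # (polyorder+1) x window
  w <- P[1, ]                             # centre smoothing weights
  powL <- outer(-fc:fc, 0:polyorder, `^`) # design, window positions
  sm_one <- function(x) {
    y <- numeric(n)
    for (i in (fc + 1):(n - fc))
      y[i] <- sum(w * x[(i - fc):(i + fc)])
    bl <- P %*% x[1:window]               # left boundary fit coefs
    br <- P %*% x[(n - window + 1):n]
    y[1:fc] <- powL[1:fc, , drop = FALSE] %*% bl
    y[(n - fc + 1):n] <-
      powL[(fc + 2):window, , drop = FALSE] %*% br
    y
  }
  with_values(traces, t(apply(traces$values, 1, sm_one)))
}

#' Rescale each community trace to [0, 1]
#'
#' Per community min-max normalisation `(x - min)/(max - min)`, as used
#' to build comparable heat maps across communities.  Flat traces
#' (zero range) map to all zeros with a warning.
#'
#' @param traces a `community_traces`.
#' @return Rescaled `community_traces`.
#' @export
rescale01 <- function(traces) {
  stopifnot(is_community_traces(traces))
  v <- traces$values
  rng <- apply(v, 1, function(x) diff(range(x)))
  flat <- rng == 0
  out <- v
  for (i in seq_len(nrow(v))) {
    if (flat[i]) out[i, ] <- 0
    else out[i, ] <- (v[i, ] - min(v[i, ])) / rng[i]
  }
  if (any(flat))
    warning(sprintf("rescale01: %d flat trace(s) mapped to 0",
                    sum(flat)))
  with_values(traces, out)
}

#' Run-length peak detection on community traces
#'
#' A sample is a peak iff it is preceded by at least `nups` consecutive
#' rising steps and followed by at least `ndowns` consecutive falling
#' steps (run-length semantics; defaults 6 and 6), and
#' its value is at least `min_height`.  Plateau summits are reported at
#' the maximum sample.  Peak width is the full width at half
#' prominence, where the prominence of a peak is its height above the
#' higher of the two minima separating it from its neighbouring
#' detected peaks (or the trace ends).
#'
#' @param traces a `community_traces` (normally smoothed and rescaled).
#' @param nups,ndowns minimum up/down run lengths (>= 1).
#' @param min_height minimum peak value in processed-signal units
#'   (default `-Inf`).
#' @param heights_from optional `community_traces` on the same grid
#'   from which peak heights are reported (e.g. the smoothed,
#'   pre-rescale signal so that amplitudes keep their units); widths
#'   and detection always use `traces`.
#' @return An object of class `peak_set`: list with `peaks` (data.frame
#'   `community`, `index`, `peak_time_h`, `height`, `width_h`,
#'   `prominence`), `ids`, `dt`.
#' @export
find_trace_peaks <- function(traces, nups = 6, ndowns = 6,
                             min_height = -Inf, heights_from = NULL) {
  stopifnot(is_community_traces(traces))
  if (!is.null(heights_from)) {
    stopifnot(is_community_traces(heights_from))
    check_same_grid(traces, heights_from, "height source")
  }
  tt <- trace_times(traces)
  rows <- lapply(seq_len(n_communities(traces)), function(i) {
    x <- traces$values[i, ]
    idx <- run_length_peaks(x, nups = nups, ndowns = ndowns,
                            min_height = min_height)
    if (!length(idx))
      return(NULL)
    pr <- peak_prominences(x, idx)
    wd <- peak_widths_hp(x, idx, pr) * traces$dt
    h <- if (is.null(heights_from)) x[idx] else heights_from$values[i, idx]
    data.frame(community = traces$ids[i], index = idx,
               peak_time_h = tt[idx], height = h, width_h = wd,
               prominence = pr, stringsAsFactors = FALSE)
  })
  peaks <- do.call(rbind, rows)
  if (is.null(peaks))
    peaks <- data.frame(community = character(0), index = integer(0),
                        peak_time_h = numeric(0), height = numeric(0),
                        width_h = numeric(0), prominence = numeric(0))
  structure(list(peaks = peaks, ids = traces$ids, dt = traces$dt),
            class = "peak_set")
}

# prominence of each detected peak: height above the higher of the two
# minima separating it from neighbouring detected peaks / trace ends
peak_prominences <- function(x, idx) {
  n <- length(x)
  vapply(seq_along(idx), function(k) {
    lo <- if (k == 1) 1 else idx[k - 1]
    hi <- if (k == length(idx)) n else idx[k + 1]
    left_min <- min(x[lo:idx[k]])
    right_min <- min(x[idx[k]:hi])
    x[idx[k]] - max(left_min, right_min)
  }, numeric(1))
}

# full width at half prominence, in samples (linear interpolation)
peak_widths_hp <- function(x, idx, prom) {
  n <- length(x)
  vapply(seq_along(idx), function(k) {
    p <- idx[k]
    level <- x[p] - prom[k] / 2
    i <- p
    while (i > 1 && x[i - 1] >= level) i <- i - 1
    left <- if (i == 1 || x[i] == level) i
            else i - (level - x[i]) / (x[i - 1] - x[i])
    j <- p
    while (j < n && x[j + 1] >= level) j <- j + 1
    right <- if (j == n || x[j] == level) j
             else j + (level - x[j]) / (x[j + 1] - x[j])
    right - left
  }, numeric(1))
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d peak(s) across %d communit%s\n",
              nrow(x$peaks), length(x$ids),
              if (length(x$ids) == 1) "y" else "ies"))
  invisible(x)
}

#' Inter-peak periods
#'
#' First differences of successive peak times, per community.
#' Communities with fewer than two peaks yield empty period lists and
#' are counted in the diagnostics.
#'
#' @param peaks a `peak_set`.
#' @return List with `periods` (named list, hours), `median` (pooled
#'   median period) and `n_short` (communities with < 2 peaks).
#' @export
peak_periods <- function(peaks) {
  stopifnot(inherits(peaks, "peak_set"))
  per <- lapply(peaks$ids, function(id) {
    tt <- sort(peaks$peaks$peak_time_h[peaks$peaks$community == id])
    if (length(tt) < 2) numeric(0) else diff(tt)
  })
  names(per) <- peaks$ids
  pooled <- unlist(per)
  list(periods = per,
       median = if (length(pooled)) stats::median(pooled) else NA_real_,
       n_short = sum(vapply(per, length, integer(1)) == 0))
}

#' Phase drift of community peaks against a common reference
#'
#' Matches peaks across communities to stimulus cycles and reports each
#' community's signed deviation (hours) from the per-cycle reference.
#' With `reference = "community"` (default) the reference of a cycle is
#' the cross-community median of the matched peak times; with
#' `reference = "clock"` it is the fixed stimulus clock
#' `clock_phase + k * T`.  Matching is nearest-peak within half a
#' period of the cycle reference.
#'
#' @param peaks a `peak_set`.
#' @param expected_period expected (stimulus) period `T` in hours.
#' @param reference `"community"` or `"clock"`.
#' @param clock_phase phase of the stimulus clock (hours), used with
#'   `reference = "clock"`.
#' @return List of class `phase_drift`: `table` (data.frame
#'   `community`, `cycle`, `peak_time_h`, `reference_h`, `drift_h`),
#'   `references` (per-cycle reference times) and `unmatched`
#'   (community x cycle combinations without a matchable peak).
#' @export
phase_drift <- function(peaks, expected_period,
                        reference = c("community", "clock"),
                        clock_phase = 0) {
  stopifnot(inherits(peaks, "peak_set"))
  reference <- match.arg(reference)
  T <- expected_period
  if (!is.numeric(T) || T <= 0)
    stop("phase_drift: expected_period must be > 0")
  pk <- peaks$peaks
  if (nrow(pk) == 0) {
    warning("phase_drift: no peaks to match")
    return(structure(list(table = data.frame(), references = numeric(0),
                          unmatched = data.frame()),
                     class = "phase_drift"))
  }

  # anchor the cycle grid: circular mean of peak phases (community
  # reference) or the supplied stimulus clock
  if (reference == "community") {
    th <- 2 * pi * (pk$peak_time_h %% T) / T
    ang <- atan2(mean(sin(th)), mean(cos(th)))
    t00 <- (ang / (2 * pi) * T) %% T
  } else {
    t00 <- clock_phase %% T
  }

  assign_cycles <- function(refs) {
    # nearest reference within T/2, one peak per community per cycle
    out <- lapply(peaks$ids, function(id) {
      tt <- sort(pk$peak_time_h[pk$community == id])
      if (!length(tt)) return(NULL)
      k <- vapply(tt, function(t) refs$cycle[which.min(abs(t - refs$time))],
                  numeric(1))
      d <- abs(tt - refs$time[match(k, refs$cycle)])
      keep <- d < T / 2
      df <- data.frame(community = id, cycle = k, peak_time_h = tt,
                       dist = d, stringsAsFactors = FALSE)[keep, ,
                                                           drop = FALSE]
      # at most one peak per cycle: keep the nearest
      df <- df[order(df$cycle, df$dist), , drop = FALSE]
      df[!duplicated(df$cycle), , drop = FALSE]
    })
    do.call(rbind, out)
  }

  kmin <- floor((min(pk$peak_time_h) - t00) / T + 0.5)
  kmax <- ceiling((max(pk$peak_time_h) - t00) / T - 0.5)
  refs0 <- data.frame(cycle = kmin:kmax, time = t00 + (kmin:kmax) * T)

  m1 <- assign_cycles(refs0)
  if (is.null(m1) || nrow(m1) == 0) {
    warning("phase_drift: no matchable cycles")
    return(structure(list(table = data.frame(), references = numeric(0),
                          unmatched = data.frame()),
                     class = "phase_drift"))
  }
  if (reference == "community") {
    med <- tapply(m1$peak_time_h, m1$cycle, stats::median)
    refs1 <- data.frame(cycle = as.numeric(names(med)),
                        time = as.numeric(med))
    m2 <- assign_cycles(refs1)
    med2 <- tapply(m2$peak_time_h, m2$cycle, stats::median)
    refs <- data.frame(cycle = as.numeric(names(med2)),
                       time = as.numeric(med2))
    m <- m2
  } else {
    refs <- refs0
    m <- m1
  }
  m$reference_h <- refs$time[match(m$cycle, refs$cycle)]
  m$drift_h <- m$peak_time_h - m$reference_h
  m$dist <- NULL

  grid <- expand.grid(community = peaks$ids, cycle = refs$cycle,
                      stringsAsFactors = FALSE)
  key <- paste(m$community, m$cycle)
  unmatched <- grid[!paste(grid$community, grid$cycle) %in% key, ,
                    drop = FALSE]
  structure(list(table = m, references = refs, unmatched = unmatched),
            class = "phase_drift")
}

#' Synchrony index
#'
#' For each community, `R` is the mean over matched cycles of the
#' absolute phase drift divided by the expected period, and the
#' synchrony index is `max(0, 1 - R)`: 1 means every peak sits exactly
#' on the common reference, 0 means drifts on the order of a full
#' period.  Communities with no matched peaks get index 0 and are
#' flagged.
#'
#' @inheritParams phase_drift
#' @param drift optionally a precomputed [phase_drift()] result.
#' @return List of class `synchrony_index`: `per_community` (data.frame
#'   `community`, `n_matched`, `R`, `index`, `flagged`) and `summary`
#'   (median and IQR of the indices).
#' @export
synchrony_index <- function(peaks, expected_period,
                            reference = c("community", "clock"),
                            clock_phase = 0, drift = NULL) {
  stopifnot(inherits(peaks, "peak_set"))
  if (!is.numeric(expected_period) || expected_period <= 0)
    stop("synchrony_index: expected_period must be > 0")
  if (is.null(drift))
    drift <- phase_drift(peaks, expected_period, reference = reference,
                         clock_phase = clock_phase)
  tab <- drift$table
  per <- lapply(peaks$ids, function(id) {
    d <- tab$drift_h[tab$community == id]
    if (!length(d))
      return(data.frame(community = id, n_matched = 0L, R = NA_real_,
                        index = 0, flagged = TRUE))
    R <- mean(abs(d)) / expected_period
    data.frame(community = id, n_matched = length(d), R = R,
               index = max(0, 1 - R), flagged = FALSE)
  })
  per <- do.call(rbind, per)
  idx <- per$index
  structure(list(per_community = per,
                 summary = list(median = stats::median(idx),
                                iqr = stats::IQR(idx))),
            class = "synchrony_index")
}

#' Cumulative autocorrelation across communities
#'
#' Computes, per community, the normalised autocorrelation of the
#' mean-centred trace (biased estimator: lag sums divided by `n`,
#' normalised to 1 at lag 0), then averages the per-community functions
#' ("cumulative" autocorrelation).  Constant traces have no defined
#' autocorrelation and are excluded with a warning.
#'
#' @param traces a `community_traces`.
#' @param max_lag maximum lag in hours; must be below half the record
#'   duration (default: just under half).
#' @return List of class `cumulative_acf`: `lag_h`, `mean_acf`,
#'   `per_community` (matrix communities x lags), `n_used`.
#' @export
cumulative_autocorrelation <- function(traces, max_lag = NULL) {
  stopifnot(is_community_traces(traces))
  n <- ncol(traces$values)
  duration <- (n - 1) * traces$dt
  if (is.null(max_lag)) max_lag <- (floor((n - 1) / 2) - 1) * traces$dt
  if (max_lag >= duration / 2)
    stop("cumulative_autocorrelation: max_lag must be < duration/2")
  L <- floor(max_lag / traces$dt)
  lags <- 0:L
  keep <- apply(traces$values, 1, function(x) stats::var(x) > 0)
  if (!all(keep))
    warning(sprintf("cumulative_autocorrelation: %d constant trace(s) excluded",
                    sum(!keep)))
  if (!any(keep))
    stop("cumulative_autocorrelation: no non-constant traces")
  acf_one <- function(x) {
    x <- x - mean(x)
    c0 <- sum(x * x) / n
    vapply(lags, function(l)
      sum(x[seq_len(n - l)] * x[seq_len(n - l) + l]) / n / c0,
      numeric(1))
  }
  per <- t(apply(traces$values[keep, , drop = FALSE], 1, acf_one))
  structure(list(lag_h = lags * traces$dt,
                 mean_acf = colMeans(per),
                 per_community = per, n_used = sum(keep)),
            class = "cumulative_acf")
}

#' Power spectral density via the FFT
#'
#' One-sided periodogram of each mean-centred community trace,
#' averaged across communities.  The normalisation is chosen so that
#' the PSD sums to the (biased) trace variance (Parseval identity).
#' The dominant period is the reciprocal of the frequency with maximal
#' mean power (the zero frequency is excluded).
#'
#' @param traces a `community_traces` with at least 8 time points.
#' @return List of class `power_spectrum`: `freq_per_h`, `mean_psd`,
#'   `per_community`, `dominant_period_h`.
#' @export
power_spectrum <- function(traces) {
  stopifnot(is_community_traces(traces))
  n <- ncol(traces$values)
  if (n < 8) stop("power_spectrum: need at least 8 time points")
  half <- floor(n / 2)
  kk <- seq_len(half)
  coef2 <- rep(2, half)
  if (n %% 2 == 0) coef2[half] <- 1   # Nyquist bin is not doubled
  ps_one <- function(x) {
    x <- x - mean(x)
    X <- stats::fft(x)
    coef2 * Mod(X[kk + 1])^2 / n^2
  }
  per <- t(apply(traces$values, 1, ps_one))
  freq <- kk / (n * traces$dt)
  mp <- colMeans(per)
  dom <- 1 / freq[which.max(mp)]
  structure(list(freq_per_h = freq, mean_psd = mp, per_community = per,
                 dominant_period_h = dom),
            class = "power_spectrum")
}

#' Run the full trace-analysis pipeline
#'
#' Composition of the analysis stages in the standard order: optional
#' reporter normalisation (green/(green+red)), linear detrending,
#' Savitzky-Golay smoothing (window 15, order 4), 0-1 rescaling,
#' run-length peak detection (nups = ndowns = 6, minimum height 0.2 on
#' the rescaled signal), then period, phase-drift, synchrony,
#' cumulative-autocorrelation and power-spectrum statistics.  Peak
#' heights are reported on the smoothed (pre-rescale) signal so that
#' amplitudes keep their units.
#'
#' The report is flagged `structured` when the mean autocorrelation has
#' a local maximum, beyond its first zero crossing, exceeding
#' `3/sqrt(n_timepoints)`; unstructured recordings (no periodic
#' content) fail this test.
#'
#' @param traces a `community_traces` (green/reporter channel).
#' @param expected_period expected stimulus period in hours.
#' @param red optional paired mCherry `community_traces` for
#'   normalisation.
#' @param window,polyorder Savitzky-Golay settings.
#' @param nups,ndowns,min_height peak-detection settings.
#' @param reference,clock_phase synchrony reference convention, see
#'   [phase_drift()].
#' @param max_lag autocorrelation lag range (hours).
#' @return An object of class `synchrony_report`; see Details.
#' @export
analyze_traces <- function(traces, expected_period, red = NULL,
                           window = 15, polyorder = 4,
                           nups = 6, ndowns = 6, min_height = 0.2,
                           reference = c("community", "clock"),
                           clock_phase = 0, max_lag = NULL) {
  stopifnot(is_community_traces(traces))
  reference <- match.arg(reference)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("analyze[", name, "]: ", conditionMessage(e), call. = FALSE))
  }
  x0 <- if (!is.null(red))
    stage("normalize", normalize_reporter(traces, red)) else traces
  x1 <- stage("detrend", detrend_traces(x0))
  x2 <- stage("smooth", smooth_traces(x1, window = window,
                                      polyorder = polyorder))
  x3 <- stage("rescale", rescale01(x2))
  pk <- stage("find_peaks",
              find_trace_peaks(x3, nups = nups, ndowns = ndowns,
                               min_height = min_height,
                               heights_from = x2))
  per <- stage("periods", peak_periods(pk))
  per_median <- vapply(per$periods, function(p)
    if (length(p)) stats::median(p) else NA_real_, numeric(1))
  dr <- stage("phase_drift",
              suppressWarnings(
                phase_drift(pk, expected_period, reference = reference,
                            clock_phase = clock_phase)))
  sy <- stage("synchrony",
              synchrony_index(pk, expected_period, drift = dr))
  ac <- stage("autocorrelation",
              cumulative_autocorrelation(x2, max_lag = max_lag))
  ps <- stage("power_spectrum", power_spectrum(x2))

  acp <- acf_dominant_peak(ac)
  nt <- ncol(traces$values)
  structured <- !is.na(acp$value) && acp$value > 3 / sqrt(nt)

  structure(list(
    expected_period = expected_period,
    peaks = pk,
    periods = per$periods,
    period_median = per_median,
    period_pooled_median = per$median,
    drift = dr,
    synchrony = sy,
    acf = ac,
    acf_dominant_period_h = acp$lag,
    psd = ps,
    dominant_period_h = ps$dominant_period_h,
    structured = structured,
    stages = list(input = traces, normalized = if (!is.null(red)) x0,
                  detrended = x1, smoothed = x2, rescaled = x3),
    config = list(window = window, polyorder = polyorder, nups = nups,
                  ndowns = ndowns, min_height = min_height,
                  reference = reference, clock_phase = clock_phase)),
    class = "synchrony_report")
}

# first local maximum of the mean ACF beyond its first zero crossing
acf_dominant_peak <- function(ac) {
  a <- ac$mean_acf
  zc <- which(a <= 0)[1]
  if (is.na(zc) || zc >= length(a))
    return(list(lag = NA_real_, value = NA_real_))
  seg <- a[zc:length(a)]
  lm <- local_maxima(seg)
  if (!length(lm)) {
    j <- which.max(seg)
    if (j == length(seg))
      return(list(lag = NA_real_, value = NA_real_))
    lm <- j
  }
  best <- lm[which.max(seg[lm])]
  list(lag = ac$lag_h[zc + best - 1], value = seg[best])
}

#' @export
print.synchrony_report <- function(x, ...) {
  cat("<synchrony_report>\n")
  cat(sprintf("  expected period     : %g h\n", x$expected_period))
  cat(sprintf("  pooled median period: %s h\n",
              format(x$period_pooled_median, digits = 4)))
  cat(sprintf("  dominant period     : %s h (PSD), %s h (ACF)\n",
              format(x$dominant_period_h, digits = 4),
              format(x$acf_dominant_period_h, digits = 4)))
  cat(sprintf("  synchrony index     : median %.3f (IQR %.3f)\n",
              x$synchrony$summary$median, x$synchrony$summary$iqr))
  cat(sprintf("  structured          : %s\n", x$structured))
  invisible(x)
}
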