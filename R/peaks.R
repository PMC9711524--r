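#' Run-length peak detection on a numeric vector
#'
#' Core primitive behind [find_trace_peaks()].  Index `i` is a peak
#' candidate iff it is preceded by at least `nups` consecutive rising
#' steps and followed by at least `ndowns` consecutive falling steps,
#' and `x[i] >= min_height`.  Steps of exactly zero break a run (the
#' convention of the classic `findpeaks` filters: a bump with only
#' five rises on a flat baseline does not qualify at `nups = 6`).
#' Contiguous candidates are merged into one peak reported at the
#' maximum sample (earliest index on ties).
#'
#' @param x numeric vector.
#' @param nups,ndowns minimum run lengths (>= 1).
#' @param min_height minimum peak value (default `-Inf`).
#' @return Integer vector of peak indices (possibly empty).
#' @export
run_length_peaks <- function(x, nups = 6, ndowns = 6, min_height = -Inf) {
  n <- length(x)
  if (nups < 1 || ndowns < 1)
    stop("run_length_peaks: nups and ndowns must be >= 1")
  if (n < nups + ndowns + 1) return(integer(0))
  d <- diff(x)
  up <- d > 0    # strictly rising step
  dn <- d < 0    # strictly falling step

  # up_run[i]: number of consecutive rising steps ending at i
  up_run <- integer(n)
  for (i in 2:n) up_run[i] <- if (up[i - 1]) up_run[i - 1] + 1L else 0L
  dn_run <- integer(n)
  for (i in (n - 1):1) dn_run[i] <- if (dn[i]) dn_run[i + 1] + 1L else 0L

  cand <- which(up_run >= nups & dn_run >= ndowns & x >= min_height)
  if (!length(cand)) return(integer(0))

  # merge candidates belonging to one plateau/summit region
  grp <- cumsum(c(1L, as.integer(diff(cand) > 1)))
  out <- integer(0)
  for (g in unique(grp)) {
    idx <- cand[grp == g]
    out <- c(out, idx[which.max(x[idx])])
  }
  out
}

# local maxima for regime classification on smooth ODE output:
# strict three-point maxima above a height floor
local_maxima <- function(x, min_height = -Inf) {
  n <- length(x)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  which(c(FALSE, x[i] > x[i - 1] & x[i] >= x[i + 1], FALSE) &
          x >= min_height)
}
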