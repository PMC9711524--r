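# Independent oracles used across the suite.  Each is a deliberately
# naive re-derivation (brute force / direct sums / textbook formulas),
# kept free of the package's implementation paths.

# hand-coded transcription of the two rate equations
oracle_dynamics <- function(I, M, iaa, sa, p) {
  dI <- p$a1 + p$b1 * I * I / (p$K_A * p$K_A + I * I +
                                 (p$gamma * M) * (p$gamma * M)) -
    p$d1 * (1 + p$eps_I * iaa) * I
  dM <- p$a2 + p$b2 * I * I / (p$K_B * p$K_B + I * I) -
    p$d2 * (1 + p$eps_M * sa) * M
  c(dI, dM)
}

# fixed-step classical RK4 with explicit restarts at stimulus edges
oracle_rk4 <- function(p, stim, init, duration, out_dt, h = 1e-3) {
  seg <- sort(unique(c(0, stimulus_breakpoints(stim, 0, duration),
                       duration)))
  out_t <- seq(0, duration, by = out_dt)
  res <- matrix(NA_real_, nrow = length(out_t), ncol = 2)
  res[1, ] <- init
  state <- init
  k <- 2
  continuous <- !is.null(stim) && stim$kind == "sine"
  for (s in seq_len(length(seg) - 1)) {
    t0 <- seg[s]; t1 <- seg[s + 1]
    svc <- stimulus_values(stim, (t0 + t1) / 2)
    f <- function(st, tt) {
      sv <- if (continuous) stimulus_values(stim, tt) else svc
      oracle_dynamics(st[1], st[2], sv$iaa, sv$sa, p)
    }
    t <- t0
    while (t < t1 - 1e-12) {
      hh <- min(h, t1 - t)
      k1 <- f(state, t)
      k2 <- f(state + hh / 2 * k1, t + hh / 2)
      k3 <- f(state + hh / 2 * k2, t + hh / 2)
      k4 <- f(state + hh * k3, t + hh)
      state <- state + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + hh
      while (k <= length(out_t) && out_t[k] <= t + 1e-9) {
        res[k, ] <- state
        k <- k + 1
      }
    }
  }
  list(time = out_t, I = res[, 1], M = res[, 2])
}

# exhaustive run-length peak scanner: checks every index directly
oracle_peaks <- function(x, nups, ndowns, min_height = -Inf) {
  n <- length(x)
  cand <- logical(n)
  for (i in seq_len(n)) {
    if (x[i] < min_height) next
    if (i - nups < 1 || i + ndowns > n) next
    up <- all(diff(x[(i - nups):i]) > 0)
    dn <- all(diff(x[i:(i + ndowns)]) < 0)
    cand[i] <- up && dn
  }
  idx <- which(cand)
  if (!length(idx)) return(integer(0))
  out <- integer(0)
  start <- 1
  for (j in seq_along(idx)) {
    last <- j == length(idx)
    if (last || idx[j + 1] - idx[j] > 1) {
      grp <- idx[start:j]
      out <- c(out, grp[which.max(x[grp])])
      start <- j + 1
    }
  }
  out
}

# windowed degree-`ord` least squares fit by normal equations,
# evaluated at the window centre
oracle_savgol_point <- function(x, i, fl, ord) {
  fc <- (fl - 1) / 2
  idx <- (i - fc):(i + fc)
  X <- outer(-fc:fc, 0:ord, `^`)
  beta <- solve(t(X) %*% X, t(X) %*% x[idx])
  beta[1]
}

# direct O(n^2) biased autocorrelation
oracle_acf <- function(x, L) {
  n <- length(x)
  x <- x - mean(x)
  c0 <- sum(x^2) / n
  sapply(0:L, function(l) {
    s <- 0
    for (i in seq_len(n - l)) s <- s + x[i] * x[i + l]
    (s / n) / c0
  })
}

# direct DFT periodogram (no FFT), one-sided, Parseval-normalised
oracle_psd <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  half <- floor(n / 2)
  sapply(seq_len(half), function(k) {
    re <- sum(x * cos(2 * pi * k * (0:(n - 1)) / n))
    im <- sum(x * sin(2 * pi * k * (0:(n - 1)) / n))
    cc <- if (n %% 2 == 0 && k == half) 1 else 2
    cc * (re^2 + im^2) / n^2
  })
}

# brute-force nearest-within-half-period peak-to-cycle matcher
oracle_match <- function(times, refs, T) {
  out <- data.frame(cycle = numeric(0), time = numeric(0))
  used <- rep(FALSE, nrow(refs))
  for (r in seq_len(nrow(refs))) {
    d <- abs(times - refs$time[r])
    ok <- which(d < T / 2)
    if (!length(ok)) next
    best <- ok[which.min(d[ok])]
    # a peak belongs to its nearest cycle only
    dr <- abs(refs$time - times[best])
    if (which.min(dr) != r) next
    out <- rbind(out, data.frame(cycle = refs$cycle[r],
                                 time = times[best]))
  }
  out
}

# small helpers for building fixtures
toy_traces <- function(vals, dt = 1 / 6)
  community_traces(vals, dt = dt, channel = "dEGFP")

# a cheap but representative excitable parameter set = package default
pdef <- function() default_circuit_params()
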