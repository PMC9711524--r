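#' Multi-community fluorescence traces
#'
#' Container for community-level fluorescence recordings: a rectangular
#' matrix with one row per community and one column per time point on a
#' shared uniform time grid.
#'
#' @param values numeric matrix, communities x time points; all values
#'   finite.
#' @param dt sampling interval in hours (> 0); default `1/6` (10-minute
#'   imaging cadence).
#' @param ids community identifiers (default `c01`, `c02`, ...).
#' @param channel reporter channel label.
#' @param t0 time of the first sample (hours).
#' @param meta free-form provenance list (generator config, seed, file
#'   path ...).
#' @return An object of class `community_traces`.
#' @export
community_traces <- function(values, dt = 1 / 6, ids = NULL,
                             channel = c("ThT", "dEGFP", "KcsA-EGFP",
                                         "mCherry"),
                             t0 = 0, meta = list()) {
  channel <- match.arg(channel)
  if (!is.matrix(values)) values <- matrix(values, nrow = 1)
  if (!all(is.finite(values)))
    stop("community_traces: values must all be finite")
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0)
    stop("community_traces: sampling interval dt must be > 0")
  if (is.null(ids)) ids <- sprintf("c%02d", seq_len(nrow(values)))
  if (length(ids) != nrow(values))
    stop("community_traces: ids length must match the number of communities")
  rownames(values) <- ids
  structure(list(values = values, dt = dt, ids = ids, channel = channel,
                 t0 = t0, meta = meta),
            class = "community_traces")
}

#' @rdname community_traces
#' @param x object to test / print.
#' @export
is_community_traces <- function(x) inherits(x, "community_traces")

#' Time grid of a `community_traces` object
#' @param traces a `community_traces` object.
#' @return Numeric vector of sample times (hours).
#' @export
trace_times <- function(traces) {
  traces$t0 + (seq_len(ncol(traces$values)) - 1) * traces$dt
}

n_communities <- function(traces) nrow(traces$values)

#' @export
print.community_traces <- function(x, ...) {
  cat(sprintf("<community_traces> %d communities x %d samples (%s), dt = %.4g h (%.3g h total)\n",
              nrow(x$values), ncol(x$values), x$channel, x$dt,
              (ncol(x$values) - 1) * x$dt))
  invisible(x)
}

check_same_grid <- function(a, b, what = "traces") {
  if (!identical(dim(a$values), dim(b$values)) ||
      abs(a$dt - b$dt) > 1e-9 || abs(a$t0 - b$t0) > 1e-9)
    stop("mismatched ", what,
         ": community sets and time grids must be identical")
  invisible(TRUE)
}

# rebuild a community_traces with new values, same metadata
with_values <- function(traces, values) {
  out <- traces
  out$values <- values
  rownames(out$values) <- traces$ids
  out
}
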