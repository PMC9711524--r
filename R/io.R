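#' Read and write circuit parameters as JSON
#'
#' Parameters are stored as a flat JSON object with the field names of
#' [circuit_params()]; files are validated on load.
#'
#' @param params a `circuit_params` object.
#' @param path file path.
#' @return `read_params_json` returns a validated `circuit_params`.
#' @export
write_params_json <- function(params, path) {
  validate_circuit_params(params)
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_params_json
#' @export
read_params_json <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(circuit_params, x[intersect(names(x),
    c("a1", "a2", "b1", "b2", "K_A", "K_B", "gamma",
      "d1", "d2", "eps_I", "eps_M"))])
}

#' Read and write stimulus programs as JSON
#'
#' @param stim a `stimulus_program`.
#' @param path file path.
#' @return `read_stimulus_json` returns a validated `stimulus_program`.
#' @export
write_stimulus_json <- function(stim, path) {
  stopifnot(inherits(stim, "stimulus_program"))
  x <- unclass(stim)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_stimulus_json
#' @export
read_stimulus_json <- function(path) {
  if (!file.exists(path)) stop("stimulus file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pulses <- x$pulses
  if (!is.null(pulses) && length(pulses) && !is.data.frame(pulses))
    pulses <- as.data.frame(pulses)
  stimulus_program(kind = x$kind, period = x$period,
                   duration = x$duration, amp_iaa = x$amp_iaa,
                   amp_sa = x$amp_sa, duty = x$duty,
                   phase_iaa = x$phase_iaa, phase_sa = x$phase_sa,
                   pulses = pulses)
}

#' Read and write trajectories as CSV
#'
#' CSV with header `time_h,IacR,MarR,IAA,SA`.
#'
#' @param traj a `circuit_trajectory` data.frame.
#' @param path file path.
#' @return `read_trajectory_csv` returns a `circuit_trajectory`.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "circuit_trajectory"))
  utils::write.csv(as.data.frame(traj)[c("time_h", "IacR", "MarR",
                                         "IAA", "SA")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  x <- utils::read.csv(path)
  need <- c("time_h", "IacR", "MarR", "IAA", "SA")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("trajectory CSV is missing column(s): ",
         paste(missing, collapse = ", "))
  structure(x[need], class = c("circuit_trajectory", "data.frame"))
}

#' Read and write community traces as CSV
#'
#' The trace table has a first column `time_h` followed by one column
#' per community (`c01`, `c02`, ...).  A metadata sidecar JSON
#' (`<path>.json`) records the sampling interval, channel label and
#' any generator provenance, so a written file round-trips exactly.
#'
#' @param traces a `community_traces`.
#' @param path CSV file path.
#' @return `read_traces_csv` returns a `community_traces`.
#' @export
write_traces_csv <- function(traces, path) {
  stopifnot(is_community_traces(traces))
  df <- data.frame(time_h = trace_times(traces),
                   t(traces$values), check.names = FALSE)
  names(df) <- c("time_h", traces$ids)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(dt = traces$dt, t0 = traces$t0, channel = traces$channel,
         ids = traces$ids, meta = traces$meta),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "time_h")
    stop("trace CSV must have 'time_h' as its first column (got '",
         names(df)[1], "')")
  if (ncol(df) < 2) stop("trace CSV has no community columns")
  tt <- df$time_h
  if (length(tt) > 1) {
    dts <- diff(tt)
    if (max(abs(dts - dts[1])) > 1e-6 * max(dts[1], 1e-12))
      stop("trace CSV time grid is not uniformly spaced")
    dt <- dts[1]
  } else dt <- 1 / 6
  vals <- t(as.matrix(df[-1]))
  channel <- "dEGFP"; meta <- list(path = path)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    sj <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(sj$channel)) channel <- sj$channel
    if (!is.null(sj$meta)) meta <- c(meta, list(source = sj$meta))
  }
  community_traces(vals, dt = dt, ids = names(df)[-1],
                   channel = channel, t0 = tt[1], meta = meta)
}

#' Write a peak table as CSV
#'
#' Columns `community,peak_time_h,height,width_h`.
#'
#' @param peaks a `peak_set`.
#' @param path file path.
#' @export
write_peaks_csv <- function(peaks, path) {
  stopifnot(inherits(peaks, "peak_set"))
  utils::write.csv(peaks$peaks[c("community", "peak_time_h", "height",
                                 "width_h")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a synchrony report as JSON
#'
#' Serialises the scalar summaries and the main arrays of a
#' [analyze_traces()] report (peak table, per-community periods and
#' synchrony indices, phase-drift table, mean autocorrelation, mean
#' power spectrum).
#'
#' @param report a `synchrony_report`.
#' @param path file path.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "synchrony_report"))
  out <- list(
    expected_period_h = report$expected_period,
    period_pooled_median_h = report$period_pooled_median,
    period_median_h = as.list(report$period_median),
    dominant_period_psd_h = report$dominant_period_h,
    dominant_period_acf_h = report$acf_dominant_period_h,
    structured = report$structured,
    synchrony = list(
      per_community = report$synchrony$per_community,
      median = report$synchrony$summary$median,
      iqr = report$synchrony$summary$iqr),
    peaks = report$peaks$peaks[c("community", "peak_time_h", "height",
                                 "width_h")],
    phase_drift = report$drift$table,
    acf = list(lag_h = report$acf$lag_h, mean = report$acf$mean_acf),
    psd = list(freq_per_h = report$psd$freq_per_h,
               mean = report$psd$mean_psd),
    config = report$config)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  invisible(path)
}

#' Write a run manifest
#'
#' Every CLI run writes a JSON manifest with the package version, the
#' resolved configuration, the RNG seed and a timestamp, sufficient to
#' re-run the result exactly.
#'
#' @param path manifest path.
#' @param subcommand subcommand name.
#' @param config resolved configuration (named list).
#' @param seed RNG seed used (or `NULL`).
#' @param outputs character vector of artifact paths written.
#' @export
write_manifest <- function(path, subcommand, config, seed = NULL,
                           outputs = character(0)) {
  man <- list(
    tool = "excitrace",
    version = as.character(utils::packageVersion("excitrace")),
    subcommand = subcommand,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    outputs = outputs)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
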