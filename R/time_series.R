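#' Uniformly sampled multichannel time series
#'
#' The common container passed between all pipeline stages: task inputs
#' `c(t)`, teacher states `x_hat(t)`, decoded states `x_tilde(t)` and
#' network outputs `y(t)` are all `time_series` objects.
#'
#' @param values numeric matrix, channels x steps (a vector is treated as a
#'   single channel).
#' @param dt sampling step in seconds; must be positive.
#' @param t0 time of the first sample in seconds.
#' @return an object of class `time_series` with fields `values`, `dt`, `t0`.
#' @examples
#' ts <- time_series(sin(seq(0, 2 * pi, length.out = 100)), dt = 1e-3)
#' n_steps(ts)
#' @export
time_series <- function(values, dt, t0 = 0) {
  if (is.vector(values)) values <- matrix(values, nrow = 1)
  stopifnot(is.matrix(values), is.numeric(values))
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) {
    stop("`dt` must be a single positive number")
  }
  structure(list(values = values, dt = dt, t0 = t0), class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> %d channel(s) x %d steps, dt = %g s, duration = %g s\n",
              nrow(x$values), ncol(x$values), x$dt, ncol(x$values) * x$dt))
  invisible(x)
}

#' Number of steps in a time series
#' @param x a `time_series`.
#' @export
n_steps <- function(x) ncol(x$values)

#' Sample times of a time series
#' @param x a `time_series`.
#' @return numeric vector of times (seconds) for each step.
#' @export
ts_times <- function(x) x$t0 + seq_len(ncol(x$values)) * x$dt

#' Spike raster
#'
#' Binary spike events, one row per neuron, one column per simulation step.
#' At most one spike per neuron per step by construction of the simulator.
#'
#' @param spikes binary (0/1 or logical) matrix, neurons x steps.
#' @param dt simulation step in seconds.
#' @export
spike_raster <- function(spikes, dt) {
  spikes <- matrix(as.integer(spikes), nrow = nrow(spikes))
  if (any(spikes != 0L & spikes != 1L)) stop("raster entries must be 0/1")
  if (dt <= 0) stop("`dt` must be positive")
  structure(list(spikes = spikes, dt = dt), class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster> %d neurons x %d steps, %d spikes, dt = %g s\n",
              nrow(x$spikes), ncol(x$spikes), sum(x$spikes), x$dt))
  invisible(x)
}

#' Write / read a time series as headered CSV
#'
#' The header records `dt` and `t0` as comment lines; rows are channels.
#'
#' @param x a `time_series`.
#' @param path file path.
#' @rdname time_series_io
#' @export
write_time_series <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dt=%.17g", x$dt), con)
  writeLines(sprintf("# t0=%.17g", x$t0), con)
  # %.17g round-trips doubles exactly through the text format
  writeLines(apply(x$values, 1, function(r) paste(sprintf("%.17g", r),
                                                  collapse = ",")), con)
  invisible(path)
}

#' @rdname time_series_io
#' @export
read_time_series <- function(path) {
  hdr <- readLines(path, n = 2)
  dt <- as.numeric(sub("# dt=", "", hdr[1], fixed = TRUE))
  t0 <- as.numeric(sub("# t0=", "", hdr[2], fixed = TRUE))
  vals <- as.matrix(utils::read.table(path, sep = ",", skip = 2,
                                      header = FALSE))
  dimnames(vals) <- NULL
  time_series(vals, dt = dt, t0 = t0)
}

#' Write a spike raster as sparse (neuron, step) pairs
#' @param x a `spike_raster`.
#' @param path file path.
#' @export
write_spike_raster <- function(x, path) {
  idx <- which(x$spikes == 1L, arr.ind = TRUE)
  df <- data.frame(neuron = idx[, 1], step = idx[, 2])
  df <- df[order(df$step, df$neuron), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dt=%.17g n_neurons=%d n_steps=%d", x$dt,
                     nrow(x$spikes), ncol(x$spikes)), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE)
  invisible(path)
}
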