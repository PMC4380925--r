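#' Parameters of a damped NF-kB translocation oscillation
#'
#' Describes a nuclear/perinuclear ratio time course after TNF-alpha
#' stimulation: a rise from baseline to a first peak (default around
#' 30 min), followed by damped oscillations (default period in the
#' 110-120 min band), sampled at 5-min intervals over 6 h.
#'
#' @param baseline Pre-stimulus ratio (value at t = 0).
#' @param first_peak_time Time of the first peak, min.
#' @param amplitude First-peak height above baseline, ratio units.
#' @param period Oscillation period, min; must exceed twice the sampling
#'   interval (Nyquist), otherwise an aliasing error is raised.
#' @param damping_timescale Exponential decay timescale of the
#'   oscillation envelope after the first peak, min.
#' @param noise_sd Additive Gaussian noise SD, ratio units.
#' @param dt Sampling interval, min.
#' @param duration Total duration, min; must be at least one period.
#' @param seed Integer seed.
#' @return Object of class \code{OscillationParams}.
#' @export
oscillation_params <- function(baseline = 1.0, first_peak_time = 30,
                               amplitude = 0.5, period = 115,
                               damping_timescale = 100, noise_sd = 0,
                               dt = 5, duration = 360, seed = 1L) {
  if (dt <= 0) stop("dt must be > 0")
  if (period <= 2 * dt)
    stop(sprintf("aliasing error: period (%g min) must exceed 2*dt (%g min)",
                 period, 2 * dt))
  if (duration < period) stop("duration must be at least one period")
  if (first_peak_time <= 0) stop("first_peak_time must be > 0")
  if (amplitude < 0 || noise_sd < 0) stop("amplitude and noise_sd must be >= 0")
  structure(list(baseline = baseline, first_peak_time = first_peak_time,
                 amplitude = amplitude, period = period,
                 damping_timescale = damping_timescale, noise_sd = noise_sd,
                 dt = dt, duration = duration, seed = as.integer(seed)),
            class = "OscillationParams")
}

#' Simulate a translocation ratio trace
#'
#' The deterministic part rises from the baseline at t = 0 along a
#' quarter-sine ramp to exactly \code{baseline + amplitude} at
#' \code{first_peak_time}, then oscillates as
#' \code{cos(2*pi*(t - first_peak_time)/period)} under an exponential
#' envelope \code{exp(-(t - first_peak_time)/damping_timescale)}, so the
#' first maximum sits exactly at the stated time/height and successive
#' maxima are spaced exactly one period apart. Gaussian noise is added on
#' top.
#'
#' @param params An \code{\link{oscillation_params}} object.
#' @param cell_id,condition Metadata stored on the trace.
#' @return Object of class \code{TranslocationTrace}: list with
#'   \code{times} (min) and \code{values} plus metadata.
#' @export
simulate_trace <- function(params, cell_id = 1L, condition = "control") {
  stopifnot(inherits(params, "OscillationParams"))
  t <- seq(0, params$duration, by = params$dt)
  t1 <- params$first_peak_time
  osc <- ifelse(t <= t1,
                sin(pi * t / (2 * t1)),
                cos(2 * pi * (t - t1) / params$period))
  env <- ifelse(t <= t1, 1, exp(-(t - t1) / params$damping_timescale))
  v <- params$baseline + params$amplitude * env * osc
  if (params$noise_sd > 0)
    v <- v + with_seed(params$seed,
                       stats::rnorm(length(t), 0, params$noise_sd))
  translocation_trace(t, v, cell_id = cell_id, condition = condition)
}

#' Construct a translocation trace
#'
#' @param times Strictly increasing, uniformly spaced times in minutes;
#'   at least 8 samples.
#' @param values Positive nuclear/perinuclear ratio values.
#' @param cell_id,condition Metadata.
#' @return Object of class \code{TranslocationTrace}.
#' @export
translocation_trace <- function(times, values, cell_id = 1L,
                                condition = "control") {
  stopifnot(length(times) == length(values), length(times) >= 8L)
  dtv <- diff(times)
  if (any(dtv <= 0)) stop("times must be strictly increasing")
  if (max(abs(dtv - dtv[1])) > 1e-6 * dtv[1])
    stop("times must be uniformly spaced")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 dt = dtv[1], cell_id = cell_id, condition = condition),
            class = "TranslocationTrace")
}

#' @export
print.TranslocationTrace <- function(x, ...) {
  cat(sprintf("TranslocationTrace: cell %s (%s), %d samples @ %g min\n",
              x$cell_id, x$condition, length(x$times), x$dt))
  invisible(x)
}

#' Traces to/from long-format data.frame
#'
#' @param traces List of \code{TranslocationTrace}.
#' @return data.frame with columns cell_id, condition, t_min, ratio.
#' @export
traces_to_frame <- function(traces) {
  do.call(rbind, lapply(traces, function(tr)
    data.frame(cell_id = tr$cell_id, condition = tr$condition,
               t_min = tr$times, ratio = tr$values,
               stringsAsFactors = FALSE)))
}

#' @rdname traces_to_frame
#' @param df Long-format data.frame as written by \code{traces_to_frame}.
#' @export
frame_to_traces <- function(df) {
  stopifnot(all(c("cell_id", "condition", "t_min", "ratio") %in% names(df)))
  key <- interaction(df$cell_id, df$condition, drop = TRUE)
  lapply(split(df, key), function(d)
    translocation_trace(d$t_min, d$ratio, cell_id = d$cell_id[1],
                        condition = d$condition[1]))
}
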