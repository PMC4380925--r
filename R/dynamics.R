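#' First-peak amplitude and time of a translocation trace
#'
#' Finds the first local maximum after t = 0 whose topographic prominence
#' exceeds \code{prominence_mult} times the robust noise SD (estimated
#' from first differences, MAD/sqrt(2)). Amplitude is the peak value
#' minus the pre-stimulus baseline (the value at t = 0); time is the peak
#' time.
#'
#' @param trace A \code{\link{translocation_trace}}.
#' @param prominence_mult Noise multiple a peak's prominence must exceed.
#' @return List with \code{amplitude}, \code{time}, \code{value},
#'   \code{found} and \code{flag} (\code{"ok"}, \code{"no_peak"} when no
#'   qualifying maximum exists, \code{"boundary"} when the largest value
#'   sits at the final sample).
#' @export
first_peak_metrics <- function(trace, prominence_mult = 3) {
  stopifnot(inherits(trace, "TranslocationTrace"))
  v <- trace$values; t <- trace$times
  n <- length(v)
  noise <- stats::mad(diff(v)) / sqrt(2)
  thr <- prominence_mult * noise
  null_res <- function(flag) list(amplitude = NA_real_, time = NA_real_,
                                  value = NA_real_, found = FALSE,
                                  flag = flag)
  for (i in 2:(n - 1L)) {
    if (v[i] > v[i - 1L] && v[i] >= v[i + 1L]) {
      left <- min(v[1:i])
      # right base: minimum until the next strictly higher sample (or end)
      j <- i
      while (j < n && v[j + 1L] <= v[i]) j <- j + 1L
      right <- min(v[i:j])
      prom <- v[i] - max(left, right)
      if (prom > 0 && prom >= thr)
        return(list(amplitude = v[i] - v[1L], time = t[i], value = v[i],
                    found = TRUE, flag = "ok"))
    }
  }
  # largest value at the final sample: peak truncated by the movie end
  if (which.max(v) == n) return(null_res("boundary"))
  null_res("no_peak")
}

#' Morlet continuous-wavelet spectrum of a translocation trace
#'
#' Linearly detrends the trace, then computes the continuous wavelet
#' transform with a Morlet mother wavelet (center frequency omega0 = 6)
#' over a logarithmic period grid, via the FFT formulation. The dominant
#' period at each time point is the power argmax over periods outside the
#' cone of influence (COI, e-folding time sqrt(2) x scale); instantaneous
#' amplitude is recovered from |W| at the dominant scale with the
#' analytic Morlet normalization, so a pure sinusoid of amplitude A
#' returns approximately A.
#'
#' @param trace A \code{\link{translocation_trace}}.
#' @param periods Analyzed period grid, min; default 60 log-spaced values
#'   spanning 30-240 min.
#' @param omega0 Morlet center frequency.
#' @return Object of class \code{WaveletSpectrum}: list with
#'   \code{times}, \code{periods}, \code{power} (periods x times, >= 0),
#'   \code{amplitude} (same shape), \code{coi} (logical mask, TRUE =
#'   inside the cone, unreliable), \code{dominant_period} and
#'   \code{dominant_amplitude} series (NA where every period is masked or
#'   the trace carries no power).
#' @export
wavelet_periods <- function(trace,
                            periods = exp(seq(log(30), log(240),
                                              length.out = 60L)),
                            omega0 = 6) {
  stopifnot(inherits(trace, "TranslocationTrace"))
  v <- trace$values; t <- trace$times
  n <- length(v)
  dt <- trace$dt
  duration <- t[n] - t[1]
  if (duration < 2 * min(periods))
    stop(sprintf(
      "trace too short: %g min; need at least %g min (twice the minimum analyzed period)",
      duration, 2 * min(periods)))

  # linear detrend
  x <- stats::residuals(stats::lm(v ~ t))
  flat <- stats::sd(x) < 1e-12 * max(abs(v), 1)

  npad <- 2^ceiling(log2(n))
  xp <- c(x, rep(0, npad - n))
  xh <- stats::fft(xp)
  k <- 0:(npad - 1)
  omega <- ifelse(k <= npad / 2, 2 * pi * k / (npad * dt),
                  -2 * pi * (npad - k) / (npad * dt))
  fourier_factor <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  scales <- periods / fourier_factor

  power <- amp <- matrix(0, length(periods), n)
  for (si in seq_along(scales)) {
    s <- scales[si]
    psi <- sqrt(2 * pi * s / dt) * pi^(-1 / 4) *
      exp(-0.5 * (s * omega - omega0)^2) * (omega > 0)
    w <- stats::fft(xh * psi, inverse = TRUE)[seq_len(n)] / npad
    power[si, ] <- Mod(w)^2
    amp[si, ] <- 2 * Mod(w) * pi^(1 / 4) / sqrt(2 * pi * s / dt)
  }

  # cone of influence: within sqrt(2)*scale of either edge
  efold <- sqrt(2) * scales
  dist_edge <- pmin(t - t[1], t[n] - t)
  coi <- outer(efold, dist_edge, ">")

  dom_period <- dom_amp <- rep(NA_real_, n)
  if (!flat) {
    for (ti in seq_len(n)) {
      ok <- which(!coi[, ti])
      if (length(ok) == 0L) next
      pw <- power[ok, ti]
      if (max(pw) <= 0) next
      best <- ok[which.max(pw)]
      dom_period[ti] <- periods[best]
      dom_amp[ti] <- amp[best, ti]
    }
  }
  structure(list(times = t, periods = periods, power = power,
                 amplitude = amp, coi = coi,
                 dominant_period = dom_period,
                 dominant_amplitude = dom_amp,
                 flat = flat, omega0 = omega0),
            class = "WaveletSpectrum")
}

#' @export
print.WaveletSpectrum <- function(x, ...) {
  cat(sprintf(
    "WaveletSpectrum: %d times x %d periods (%.0f-%.0f min)%s\n",
    length(x$times), length(x$periods), min(x$periods), max(x$periods),
    if (x$flat) " [flat trace: no power]" else ""))
  invisible(x)
}

#' Modal dominant period of a spectrum
#'
#' The most frequent dominant period across all time points outside the
#' cone of influence.
#'
#' @param spectrum A \code{WaveletSpectrum}.
#' @return Scalar period (min), or NA when no time point is usable.
#' @export
modal_period <- function(spectrum) {
  dp <- spectrum$dominant_period
  dp <- dp[is.finite(dp)]
  if (length(dp) == 0L) return(NA_real_)
  tb <- table(dp)
  as.numeric(names(tb)[which.max(tb)])
}

#' Per-condition histogram of dominant periods at one time point
#'
#' For each trace, the dominant wavelet period at time \code{t} is read
#' off its spectrum (traces for which \code{t} is inside the cone of
#' influence or uncovered are excluded with a warning); per condition,
#' periods are binned on a shared logarithmic grid and normalized to
#' frequencies.
#'
#' @param traces List of \code{TranslocationTrace}.
#' @param t Evaluation time, min.
#' @param breaks Shared bin edges, min; default 12 logarithmic bins over
#'   30-240 min.
#' @param ... Passed to \code{\link{wavelet_periods}}.
#' @return data.frame with condition, bin_lo, bin_hi, bin_mid, count,
#'   frequency; empty (zero rows) for an empty trace list.
#' @export
period_frequency_comparison <- function(traces, t = 300,
                                        breaks = exp(seq(log(30), log(240),
                                                         length.out = 13L)),
                                        ...) {
  res <- NULL
  for (tr in traces) {
    if (t < min(tr$times) || t > max(tr$times)) {
      warning(sprintf("trace %s/%s excluded: t = %g outside coverage",
                      tr$cell_id, tr$condition, t))
      next
    }
    sp <- wavelet_periods(tr, ...)
    ti <- which.min(abs(sp$times - t))
    dp <- sp$dominant_period[ti]
    if (!is.finite(dp)) {
      warning(sprintf("trace %s/%s excluded: t = %g inside cone of influence",
                      tr$cell_id, tr$condition, t))
      next
    }
    res <- rbind(res, data.frame(condition = tr$condition, period = dp,
                                 stringsAsFactors = FALSE))
  }
  if (is.null(res))
    return(data.frame(condition = character(0), bin_lo = numeric(0),
                      bin_hi = numeric(0), bin_mid = numeric(0),
                      count = integer(0), frequency = numeric(0)))
  out <- NULL
  mids <- sqrt(breaks[-length(breaks)] * breaks[-1])
  for (cond in unique(res$condition)) {
    pp <- res$period[res$condition == cond]
    ct <- as.integer(table(cut(pp, breaks, include.lowest = TRUE)))
    out <- rbind(out, data.frame(
      condition = cond, bin_lo = breaks[-length(breaks)],
      bin_hi = breaks[-1], bin_mid = mids, count = ct,
      frequency = ct / max(sum(ct), 1L), stringsAsFactors = FALSE))
  }
  out
}
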