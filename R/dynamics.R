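#' Extract per-frame time series from images and masks
#'
#' For every frame: vessel area = number of true vessel-mask pixels, lung
#' area likewise for the lung mask, vessel signal = mean image intensity
#' over the vessel mask.
#'
#' @param images An [image_series()] or rows x cols x frames array.
#' @param lungs,vessels Logical arrays aligned with `images`.
#' @param dt Frame interval in seconds; taken from `images` when it is an
#'   `image_series`.
#' @return A list of class `raw_timeseries` with `vessel_area`, `lung_area`,
#'   `vessel_signal`, `time` and `dt`.
#' @export
extract_timeseries <- function(images, lungs, vessels, dt = NULL) {
  if (inherits(images, "image_series")) {
    if (is.null(dt)) dt <- images$dt
    images <- images$data
  }
  if (is.null(dt)) stop_pv("`dt` is required when `images` is a bare array")
  if (!identical(dim(images), dim(lungs)) || !identical(dim(images), dim(vessels))) {
    stop_pv("images and mask series must share the same shape")
  }
  nt <- dim(images)[3]
  vessel_area <- apply(vessels, 3, sum)
  lung_area <- apply(lungs, 3, sum)
  empty <- which(vessel_area == 0)
  if (length(empty) > 0) {
    stop_pv("vessel mask is empty in frame ", empty[1],
            ": vessel signal is undefined")
  }
  vessel_signal <- vapply(seq_len(nt), function(ti) {
    f <- images[, , ti]
    mean(f[vessels[, , ti]])
  }, numeric(1))
  structure(list(vessel_area = as.numeric(vessel_area),
                 lung_area = as.numeric(lung_area),
                 vessel_signal = vessel_signal,
                 time = (seq_len(nt) - 1) * dt, dt = dt),
            class = "raw_timeseries")
}

#' Zero-phase high-pass filter
#'
#' 4th-order Butterworth high-pass applied forward and backward
#' (zero-phase), with odd-symmetric edge reflection to suppress boundary
#' transients. Used to remove respiratory-frequency content (default cutoff
#' 0.6 Hz) from the vessel-area and vessel-signal curves; the output is
#' centred around zero.
#'
#' @param x Numeric series (length >= 8 x filter order).
#' @param dt Sampling interval in seconds.
#' @param cutoff Cutoff frequency in Hz; must be below Nyquist.
#' @param order Butterworth order.
#' @return Filtered series of identical length with mean approximately 0.
#' @export
highpass <- function(x, dt, cutoff = 0.6, order = 4L) {
  if (!is.numeric(x)) stop_pv("`x` must be numeric")
  if (!is_num1(dt) || dt <= 0) stop_pv("`dt` must be positive")
  nyq <- 1 / (2 * dt)
  if (!is_num1(cutoff) || cutoff <= 0 || cutoff >= nyq) {
    stop_pv("`cutoff` must lie in (0, Nyquist = ", signif(nyq, 4), " Hz)")
  }
  n <- length(x)
  if (n < 8 * order) stop_pv("series too short: need at least ", 8 * order, " samples")
  bf <- signal::butter(order, cutoff / nyq, type = "high")
  pad <- min(n - 1L, 3L * 3L * max(length(bf$b), length(bf$a)))
  xp <- c(2 * x[1] - rev(x[2:(pad + 1)]), x, 2 * x[n] - rev(x[(n - pad):(n - 1)]))
  y <- signal::filtfilt(bf, xp)
  y[(pad + 1):(pad + n)]
}

#' Coefficient of variation in percent
#'
#' `100 * sd(fluctuation) / mean(baseline)` with the n-1 SD denominator.
#' After high-pass filtering the fluctuation series is centred around zero,
#' so its own mean cannot serve as the denominator; the mean of the raw
#' (unfiltered) series is used instead.
#'
#' @param fluctuation Numeric series whose SD forms the numerator.
#' @param baseline Numeric series whose mean forms the denominator
#'   (mean must be > 0).
#' @return CV in percent.
#' @export
cv_percent <- function(fluctuation, baseline) {
  m <- mean(baseline)
  if (!is.finite(m) || m <= 0) stop_pv("mean of `baseline` must be positive")
  100 * sd(fluctuation) / m
}

#' List of detected peaks
#'
#' @param times Peak times in seconds (strictly increasing, sub-frame
#'   refined).
#' @param indices Frame indices (1-based) nearest to each peak.
#' @return An object of class `peak_list`.
#' @export
peak_list <- function(times, indices) {
  if (length(times) != length(indices)) stop_pv("times/indices length mismatch")
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop_pv("peak times must be strictly increasing")
  }
  structure(list(times = as.numeric(times), indices = as.integer(indices)),
            class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("%d peaks", length(x$times)))
  if (length(x$times) >= 2) {
    cat(sprintf(", mean interval %.3f s", mean(diff(x$times))))
  }
  cat("\n")
  invisible(x)
}

#' @export
length.peak_list <- function(x) length(x$times)

# band-limited (FFT zero-padding) upsampling of a real series
fft_upsample <- function(x, factor) {
  n <- length(x)
  if (factor <= 1) return(x)
  X <- fft(x)
  m <- n * factor
  half <- floor(n / 2)
  Y <- complex(m)
  Y[1:(half + 1)] <- X[1:(half + 1)]
  if (n %% 2 == 0) {
    # split the Nyquist bin between positive and negative frequencies
    Y[half + 1] <- X[half + 1] / 2
    Y[m - half + 1] <- X[half + 1] / 2
    if (half > 1) Y[(m - half + 2):m] <- X[(half + 2):n]
  } else {
    Y[(m - half + 1):m] <- X[(half + 2):n]
  }
  Re(fft(Y, inverse = TRUE)) * factor / n
}

# dominant frequency of a zero-mean series within [lo, Nyquist)
dominant_frequency <- function(x, dt, lo = 0.6) {
  n <- length(x)
  if (sd(x) < 1e-12 * (max(abs(x)) + 1e-300) || sd(x) == 0) {
    stop_pv("no cardiac frequency detectable: series has no variation")
  }
  npad <- 8L * n
  X <- Mod(fft(c(x - mean(x), numeric(npad - n))))^2
  freqs <- (seq_len(npad) - 1) / (npad * dt)
  nyq <- 1 / (2 * dt)
  band <- which(freqs >= lo & freqs < nyq)
  if (length(band) == 0) stop_pv("no spectral bins in the cardiac band")
  if (max(X[band]) <= 1e-12 * sum(X[2:npad]) / 2) {
    stop_pv("no cardiac frequency detectable: no spectral peak in [",
            lo, ", ", signif(nyq, 4), ") Hz")
  }
  freqs[band[which.max(X[band])]]
}

#' Detect cardiac peaks in a filtered series
#'
#' Finds the systolic maxima of a high-pass-filtered vessel-signal or
#' vessel-area curve. The dominant spectral frequency in the cardiac band
#' `[band_lo, Nyquist)` sets a minimum peak separation of `0.6 / f_c`
#' seconds. Because the acquisition samples the cardiac frequency with only
#' a few frames per cycle, the series is first upsampled by band-limited
#' (FFT) interpolation; local maxima are then refined to sub-frame times by
#' 3-point parabolic interpolation.
#'
#' @param x Filtered (zero-mean) numeric series.
#' @param dt Sampling interval in seconds.
#' @param band_lo Lower bound of the cardiac band in Hz; reuses the 0.6 Hz
#'   respiratory/cardiac boundary by default.
#' @return A [peak_list()].
#' @export
detect_cardiac_peaks <- function(x, dt, band_lo = 0.6) {
  if (!is.numeric(x) || length(x) < 8) stop_pv("`x` must be a numeric series")
  fc <- dominant_frequency(x, dt, lo = band_lo)
  up <- max(4L, ceiling(16 * fc * dt))
  y <- fft_upsample(x - mean(x), up)
  dtu <- dt / up
  m <- length(y)
  # strict local maxima
  cand <- which(y[2:(m - 1)] > y[1:(m - 2)] & y[2:(m - 1)] >= y[3:m]) + 1L
  if (length(cand) == 0) stop_pv("no peaks found")
  min_sep <- 0.6 / fc
  # greedy selection by height honouring the minimum separation
  cand <- cand[order(y[cand], decreasing = TRUE)]
  acc <- numeric(0)
  for (ci in cand) {
    if (all(abs((ci - acc) * dtu) >= min_sep)) acc <- c(acc, ci)
  }
  acc <- sort(acc)
  # parabolic refinement around each maximum
  times <- vapply(acc, function(i) {
    if (i <= 1 || i >= m) return((i - 1) * dtu)
    denom <- y[i - 1] - 2 * y[i] + y[i + 1]
    delta <- if (abs(denom) < 1e-300) 0 else 0.5 * (y[i - 1] - y[i + 1]) / denom
    delta <- max(min(delta, 0.5), -0.5)
    (i - 1 + delta) * dtu
  }, numeric(1))
  keep <- !duplicated(round(times, 10))
  times <- times[keep]
  idx <- pmin(pmax(round(times / dt) + 1, 1), length(x))
  peak_list(times, idx)
}

#' Signal-to-expansion delay in percent of the RR-interval
#'
#' Each vessel-signal peak is paired with the earliest vessel-area peak at
#' the same or a later time; trailing signal peaks with no later area peak
#' are dropped. The mean pairwise delay is divided by the mean
#' inter-signal-peak interval (the RR-interval) and expressed in percent.
#'
#' @param signal_peaks [peak_list()] of the vessel-signal curve (>= 2 peaks).
#' @param area_peaks [peak_list()] of the vessel-area curve (>= 1 peak).
#' @return SE-delay in percent of RR.
#' @export
se_delay <- function(signal_peaks, area_peaks) {
  stopifnot(inherits(signal_peaks, "peak_list"), inherits(area_peaks, "peak_list"))
  st <- signal_peaks$times; at <- area_peaks$times
  if (length(st) < 2) stop_pv("need at least 2 signal peaks to define RR")
  if (length(at) < 1) stop_pv("need at least 1 area peak")
  delays <- vapply(st, function(s) {
    nxt <- at[at >= s]
    if (length(nxt) == 0) NA_real_ else nxt[1] - s
  }, numeric(1))
  delays <- delays[!is.na(delays)]
  if (length(delays) == 0) stop_pv("no signal peak has a later area peak to pair with")
  rr <- mean(diff(st))
  100 * mean(delays) / rr
}

#' Heart rate from signal peaks
#'
#' `60 / mean RR`, with RR the mean difference of consecutive signal-peak
#' times. The alternative estimate based on the peak count over the spanned
#' duration is available via `method = "count"`.
#'
#' @param signal_peaks A [peak_list()] with >= 2 peaks.
#' @param method `"interval"` (default, 60/mean RR) or `"count"`
#'   (`60 * (n-1) / spanned time`, identical for evenly listed peaks).
#' @return Heart rate in beats/min.
#' @export
heart_rate <- function(signal_peaks, method = c("interval", "count")) {
  stopifnot(inherits(signal_peaks, "peak_list"))
  method <- match.arg(method)
  st <- signal_peaks$times
  if (length(st) < 2) stop_pv("need at least 2 peaks to estimate heart rate")
  if (method == "interval") 60 / mean(diff(st))
  else 60 * (length(st) - 1) / (st[length(st)] - st[1])
}

#' Dynamic vessel analysis of a 2D+t series
#'
#' The core analysis: turns an image series plus per-frame lung and vessel
#' masks into the five headline dynamic parameters.
#' \itemize{
#'   \item CV vessel area and CV vessel signal: SD of the high-pass-filtered
#'     curve (cutoff `cutoff` Hz removes respiratory content) divided by the
#'     mean of the raw curve, in percent.
#'   \item CV lung area: SD/mean of the unfiltered lung-area curve -- an
#'     indicator of tidal breathing depth, which the high-pass would remove.
#'   \item SE-delay: mean lag from each filtered-signal peak to the next
#'     filtered-area peak, in percent of the RR-interval.
#'   \item Heart rate: 60 / mean RR from the signal peaks, in beats/min.
#' }
#' When masks are omitted they are computed with the baseline segmenters
#' ([segment_series()]).
#'
#' @param images An [image_series()] or rows x cols x frames array.
#' @param lungs,vessels Optional logical mask arrays aligned with `images`.
#' @param dt Frame interval in seconds (required for bare arrays).
#' @param cutoff High-pass cutoff in Hz.
#' @param ... Passed to [segment_series()] when masks are computed.
#' @return An object of class `vessel_dynamics`: list with `metrics` (the
#'   five parameters), `series` (raw curves), `filtered` (filtered vessel
#'   area/signal), `signal_peaks`, `area_peaks`, `dt`, `cutoff`.
#' @examples
#' ph <- generate_phantom(acquisition_config(n_frames = 120, dt = 0.3,
#'                                           matrix = c(96, 96)),
#'                        phantom_truth(heart_rate = 72, vessel_area_mean = 140,
#'                                      noise_sd = 0))
#' fit <- vessel_dynamics(ph$images, ph$lung_truth, ph$vessel_truth)
#' coef(fit)
#' @export
vessel_dynamics <- function(images, lungs = NULL, vessels = NULL, dt = NULL,
                            cutoff = 0.6, ...) {
  if (is.null(lungs) != is.null(vessels)) {
    stop_pv("provide both `lungs` and `vessels`, or neither")
  }
  if (is.null(lungs)) {
    seg <- segment_series(images, ...)
    lungs <- seg$lungs; vessels <- seg$vessels
  }
  ts <- extract_timeseries(images, lungs, vessels, dt = dt)
  fa <- highpass(ts$vessel_area, ts$dt, cutoff = cutoff)
  fs <- highpass(ts$vessel_signal, ts$dt, cutoff = cutoff)
  # relative pulsatility below numerical noise: no cardiac content
  if (sd(fs) < 1e-6 * mean(ts$vessel_signal) ||
      sd(fa) < 1e-6 * max(mean(ts$vessel_area), 1)) {
    stop_pv("no cardiac frequency detectable: vessel series are constant")
  }
  sp <- detect_cardiac_peaks(fs, ts$dt, band_lo = cutoff)
  ap <- detect_cardiac_peaks(fa, ts$dt, band_lo = cutoff)
  metrics <- dynamic_metrics(
    cv_vessel_area = cv_percent(fa, ts$vessel_area),
    cv_lung_area = cv_percent(ts$lung_area - mean(ts$lung_area), ts$lung_area),
    cv_vessel_signal = cv_percent(fs, ts$vessel_signal),
    se_delay = se_delay(sp, ap),
    heart_rate = heart_rate(sp))
  structure(list(metrics = metrics, series = ts,
                 filtered = list(vessel_area = fa, vessel_signal = fs),
                 signal_peaks = sp, area_peaks = ap,
                 dt = ts$dt, cutoff = cutoff),
            class = "vessel_dynamics")
}

#' The five headline dynamic metrics
#'
#' @param cv_vessel_area,cv_lung_area,cv_vessel_signal CVs in percent.
#' @param se_delay Delay in percent of the RR-interval.
#' @param heart_rate Beats per minute.
#' @return A named list of class `dynamic_metrics` with a `units` attribute.
#' @export
dynamic_metrics <- function(cv_vessel_area, cv_lung_area, cv_vessel_signal,
                            se_delay, heart_rate) {
  for (v in c(cv_vessel_area, cv_lung_area, cv_vessel_signal)) {
    if (!is_num1(v) || v < 0) stop_pv("CV metrics must be non-negative numbers")
  }
  structure(list(cv_vessel_area = cv_vessel_area, cv_lung_area = cv_lung_area,
                 cv_vessel_signal = cv_vessel_signal, se_delay = se_delay,
                 heart_rate = heart_rate),
            units = c(cv_vessel_area = "%", cv_lung_area = "%",
                      cv_vessel_signal = "%", se_delay = "% of RR-interval",
                      heart_rate = "min^-1"),
            class = "dynamic_metrics")
}

#' @export
print.dynamic_metrics <- function(x, digits = 3, ...) {
  u <- attr(x, "units")
  for (nm in names(x)) {
    cat(sprintf("  %-17s %s %s\n", nm, format(signif(x[[nm]], digits)), u[[nm]]))
  }
  invisible(x)
}

#' @export
print.vessel_dynamics <- function(x, ...) {
  cat("Dynamic vessel analysis\n")
  cat(sprintf("  %d frames, dt = %g s, high-pass cutoff %g Hz\n",
              length(x$series$vessel_area), x$dt, x$cutoff))
  print(x$metrics, ...)
  invisible(x)
}

#' @export
summary.vessel_dynamics <- function(object, ...) {
  print(object)
  cat(sprintf("  %d signal peaks, %d area peaks, mean RR %.3f s\n",
              length(object$signal_peaks), length(object$area_peaks),
              mean(diff(object$signal_peaks$times))))
  invisible(object)
}

#' @export
coef.vessel_dynamics <- function(object, ...) {
  unlist(object$metrics)
}

#' @export
plot.vessel_dynamics <- function(x, which = c("filtered", "raw"), ...) {
  which <- match.arg(which)
  t <- x$series$time
  if (which == "filtered") {
    old <- par(mfrow = c(2, 1), mar = c(4, 4, 2, 1)); on.exit(par(old))
    plot(t, x$filtered$vessel_signal, type = "l", col = "blue",
         xlab = "time (s)", ylab = "vessel signal (a.u.)",
         main = "filtered vessel signal")
    points(x$signal_peaks$times,
           approx(seq_along(x$filtered$vessel_signal) * x$dt - x$dt,
                  x$filtered$vessel_signal, x$signal_peaks$times)$y,
           col = "red", pch = 19, cex = 0.6)
    plot(t, x$filtered$vessel_area, type = "l", col = "purple",
         xlab = "time (s)", ylab = "vessel area (voxels)",
         main = "filtered vessel area")
    points(x$area_peaks$times,
           approx(seq_along(x$filtered$vessel_area) * x$dt - x$dt,
                  x$filtered$vessel_area, x$area_peaks$times)$y,
           col = "red", pch = 19, cex = 0.6)
  } else {
    old <- par(mfrow = c(3, 1), mar = c(4, 4, 2, 1)); on.exit(par(old))
    plot(t, x$series$vessel_signal, type = "l", col = "blue",
         xlab = "time (s)", ylab = "a.u.", main = "vessel signal")
    plot(t, x$series$vessel_area, type = "l", col = "purple",
         xlab = "time (s)", ylab = "voxels", main = "vessel area")
    plot(t, x$series$lung_area, type = "l", col = "darkgreen",
         xlab = "time (s)", ylab = "voxels", main = "lung area")
  }
  invisible(x)
}

#' @importFrom stats approx
NULL
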