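#' Acquisition configuration for a dynamic 2D+t series
#'
#' Describes the sampling of a single-slice free-breathing acquisition:
#' number of frames, frame interval (temporal resolution), in-plane matrix
#' and pixel spacing. Defaults correspond to a spoiled gradient-echo cine of
#' a single coronal slice: 250 frames of a 128 x 128 matrix at 384 ms per
#' frame and 1.95 x 1.95 mm^2 interpolated in-plane resolution.
#'
#' @param n_frames Number of frames (>= 2).
#' @param dt Frame interval in seconds (> 0).
#' @param matrix Integer vector `c(rows, cols)`, both >= 32.
#' @param pixel_spacing In-plane pixel spacing in mm (isotropic).
#' @return An object of class `acquisition_config`.
#' @seealso [acquisition_preset()], [temporal_resolution_ms()]
#' @export
acquisition_config <- function(n_frames = 250, dt = 0.384,
                               matrix = c(128L, 128L), pixel_spacing = 1.95) {
  if (!is_count(n_frames) || n_frames < 2) {
    stop_pv("`n_frames` must be an integer >= 2")
  }
  if (!is_num1(dt) || dt <= 0) stop_pv("`dt` must be a positive number of seconds")
  if (length(matrix) != 2 || !all(vapply(matrix, is_count, logical(1))) ||
      any(matrix < 32)) {
    stop_pv("`matrix` must be two integer dimensions, both >= 32")
  }
  if (!is_num1(pixel_spacing) || pixel_spacing <= 0) {
    stop_pv("`pixel_spacing` must be a positive number of mm")
  }
  structure(list(n_frames = as.integer(n_frames), dt = dt,
                 matrix = as.integer(matrix), pixel_spacing = pixel_spacing),
            class = "acquisition_config")
}

#' Temporal resolution of a segmented cine acquisition
#'
#' For a sequence acquiring one k-space line per repetition, the time to
#' complete one frame is `TR x` (number of phase-encode lines).
#'
#' @param tr_ms Repetition time in milliseconds.
#' @param n_phase_encode Number of phase-encode lines per frame.
#' @return Temporal resolution in milliseconds.
#' @examples
#' temporal_resolution_ms(3, 128) # 384 ms
#' temporal_resolution_ms(3, 96)  # 288 ms
#' @export
temporal_resolution_ms <- function(tr_ms, n_phase_encode) {
  if (!is_num1(tr_ms) || tr_ms <= 0) stop_pv("`tr_ms` must be positive")
  if (!is_count(n_phase_encode) || n_phase_encode < 1) {
    stop_pv("`n_phase_encode` must be a positive integer")
  }
  tr_ms * n_phase_encode
}

#' Acquisition presets for the study cohorts
#'
#' Two sampling regimes are used: a 128 x 128 matrix at TR = 3 ms giving
#' 384 ms temporal resolution and 250 frames (healthy and pulmonary
#' hypertension cohorts), and a 128 x 96 matrix giving 288 ms and 200
#' frames (COPD cohort). Temporal resolution is derived with
#' [temporal_resolution_ms()] from TR and the phase-encode count.
#'
#' @param cohort One of `"healthy"`, `"ph"`, `"copd"`.
#' @return An [acquisition_config()].
#' @export
acquisition_preset <- function(cohort = c("healthy", "ph", "copd")) {
  cohort <- match.arg(cohort)
  if (cohort == "copd") {
    acquisition_config(n_frames = 200L,
                       dt = temporal_resolution_ms(3, 96) / 1000,
                       matrix = c(128L, 96L))
  } else {
    acquisition_config(n_frames = 250L,
                       dt = temporal_resolution_ms(3, 128) / 1000,
                       matrix = c(128L, 128L))
  }
}

#' Ground-truth parameters for the dynamic phantom
#'
#' Generative counterparts of the five headline dynamic metrics: target
#' coefficients of variation (CV) of vessel area, lung area and vessel
#' signal, the signal-to-expansion delay as a fraction of the RR-interval,
#' and the heart rate. Defaults are representative of a healthy adult:
#' 78 bpm, 15 breaths/min (0.25 Hz), CV vessel area 3%, CV lung area 8%,
#' CV vessel signal 4%, SE-delay 0.63 RR.
#'
#' @param heart_rate Heart rate in beats/min, in (30, 200).
#' @param resp_rate Respiratory rate in breaths/min, below `heart_rate`.
#' @param vessel_area_mean Mean total vessel cross-section in voxels.
#' @param vessel_area_cv Target CV of vessel area, percent.
#' @param vessel_signal_mean Mean vessel signal, arbitrary units.
#' @param vessel_signal_cv Target CV of vessel signal, percent.
#' @param lung_area_cv Target CV of lung area, percent.
#' @param se_delay_frac Fraction of the RR-interval in `[0, 1)` by which
#'   vessel-area peaks lag vessel-signal peaks.
#' @param noise_sd Standard deviation of additive Gaussian image noise (a.u.).
#' @param seed Integer seed for the noise generator.
#' @return An object of class `phantom_truth`.
#' @export
phantom_truth <- function(heart_rate = 78, resp_rate = 15,
                          vessel_area_mean = 250, vessel_area_cv = 3,
                          vessel_signal_mean = 150, vessel_signal_cv = 4,
                          lung_area_cv = 8, se_delay_frac = 0.63,
                          noise_sd = 7.5, seed = 1L) {
  if (!is_num1(heart_rate) || heart_rate <= 30 || heart_rate >= 200) {
    stop_pv("`heart_rate` must lie in (30, 200) beats/min")
  }
  if (!is_num1(resp_rate) || resp_rate <= 0 || resp_rate >= heart_rate) {
    stop_pv("`resp_rate` must be positive and below `heart_rate`")
  }
  for (nm in c("vessel_area_cv", "vessel_signal_cv", "lung_area_cv", "noise_sd")) {
    v <- get(nm)
    if (!is_num1(v) || v < 0) stop_pv("`", nm, "` must be >= 0")
  }
  if (!is_num1(vessel_area_mean) || vessel_area_mean <= 0) {
    stop_pv("`vessel_area_mean` must be positive")
  }
  if (!is_num1(vessel_signal_mean) || vessel_signal_mean <= 0) {
    stop_pv("`vessel_signal_mean` must be positive")
  }
  if (!is_num1(se_delay_frac) || se_delay_frac < 0 || se_delay_frac >= 1) {
    stop_pv("`se_delay_frac` must lie in [0, 1)")
  }
  if (!is_count(seed)) stop_pv("`seed` must be an integer")
  structure(list(heart_rate = heart_rate, resp_rate = resp_rate,
                 vessel_area_mean = vessel_area_mean,
                 vessel_area_cv = vessel_area_cv,
                 vessel_signal_mean = vessel_signal_mean,
                 vessel_signal_cv = vessel_signal_cv,
                 lung_area_cv = lung_area_cv, se_delay_frac = se_delay_frac,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_truth")
}

#' Sinusoid with a prescribed coefficient of variation
#'
#' Returns `mean * (1 + sqrt(2) * (cv_pct/100) * sin(2*pi*freq*t + phase))`.
#' Sampled over an integer number of cycles, the coefficient of variation
#' (SD/mean) of the samples equals `cv_pct` percent, since the RMS of a unit
#' sine is `1/sqrt(2)`.
#'
#' @param t Time(s) in seconds (vectorised).
#' @param freq Frequency in Hz.
#' @param mean Mean level (> 0).
#' @param cv_pct Target coefficient of variation in percent (>= 0).
#' @param phase Phase offset in radians.
#' @return Numeric vector of the same length as `t`.
#' @export
sinusoid_with_cv <- function(t, freq, mean, cv_pct, phase = 0) {
  if (!is_num1(mean) || mean <= 0) stop_pv("`mean` must be positive")
  if (!is_num1(cv_pct) || cv_pct < 0) stop_pv("`cv_pct` must be >= 0")
  amp <- sqrt(2) * cv_pct / 100
  if (amp >= 1) {
    stop_pv("requested CV of ", cv_pct,
            "% implies a non-positive waveform (sqrt(2)*cv/100 >= 1)")
  }
  mean * (1 + amp * sin(2 * pi * freq * t + phase))
}

# Unit-RMS, zero-mean periodic cardiac waveform evaluated at phase theta.
# "sine" is sqrt(2)*sin(theta); "asymmetric" has a faster upstroke than
# decay (theta distorted by beta*sin(theta)) and is normalised numerically.
cardiac_waveform <- function(theta, shape = c("sine", "asymmetric"),
                             beta = 0.35) {
  shape <- match.arg(shape)
  if (shape == "sine") return(sqrt(2) * sin(theta))
  dense <- seq(0, 2 * pi, length.out = 4096L)[-4096L]
  ref <- sin(dense + beta * sin(dense))
  ref <- ref - mean(ref)
  w <- sin(theta + beta * sin(theta)) - mean(ref)
  w / sqrt(mean(ref^2))
}

# area of the superellipse |x/a|^n + |y/b|^n <= 1
superellipse_area <- function(a, b, n) {
  4 * a * b * gamma(1 + 1 / n)^2 / gamma(1 + 2 / n)
}

# Sub-pixel radial field of a superellipse over a clipped bounding box.
# The shape scaled isotropically by s occupies {rho <= s}; thresholding the
# precomputed field per frame avoids re-rasterising the geometry.
rho_field <- function(nrow_img, ncol_img, cy, cx, b, a, nexp, smax, ss) {
  r0 <- max(1L, floor(cy - b * smax - 1))
  r1 <- min(nrow_img, ceiling(cy + b * smax + 1))
  c0 <- max(1L, floor(cx - a * smax - 1))
  c1 <- min(ncol_img, ceiling(cx + a * smax + 1))
  rows <- r0:r1; cols <- c0:c1
  offs <- ((seq_len(ss) - (ss + 1) / 2)) / ss
  ys <- rep(rows, each = ss) + rep(offs, times = length(rows))
  xs <- rep(cols, each = ss) + rep(offs, times = length(cols))
  R <- outer((abs(ys - cy) / b)^nexp, (abs(xs - cx) / a)^nexp, "+")^(1 / nexp)
  list(rows = rows, cols = cols, ss = ss, R = R)
}

# anti-aliased coverage of an ellipse rasterised directly (used for the
# vessels, whose centres drift sub-pixel with the respiratory phase)
ellipse_coverage <- function(nrow_img, ncol_img, cy, cx, b, a, ss) {
  r0 <- max(1L, floor(cy - b - 1)); r1 <- min(nrow_img, ceiling(cy + b + 1))
  c0 <- max(1L, floor(cx - a - 1)); c1 <- min(ncol_img, ceiling(cx + a + 1))
  rows <- r0:r1; cols <- c0:c1
  offs <- (seq_len(ss) - (ss + 1) / 2) / ss
  ys <- rep(rows, each = ss) + rep(offs, times = length(rows))
  xs <- rep(cols, each = ss) + rep(offs, times = length(cols))
  inside <- outer(((ys - cy) / b)^2, ((xs - cx) / a)^2, "+") <= 1
  list(rows = rows, cols = cols,
       cov = block_mean(inside, ss, length(rows), length(cols)))
}

# mean over ss x ss sub-pixel blocks -> pixel coverage in [0, 1]
block_mean <- function(M, ss, nr, nc) {
  m1 <- colMeans(array(M, c(ss, nr * ss * nc)))        # average sub-rows
  m2 <- aperm(array(m1, c(nr, ss, nc)), c(2L, 1L, 3L)) # bring sub-cols first
  matrix(colMeans(array(m2, c(ss, nr * nc))), nr, nc)
}

# coverage image of a precomputed rho field thresholded at scale s
field_coverage <- function(fld, s) {
  nr <- length(fld$rows); nc <- length(fld$cols)
  block_mean(fld$R <= s, fld$ss, nr, nc)
}

# Fixed vessel layout: 12 ellipses per lung at positions (u, v) in the
# normalised lung frame, with area shares skewed towards a few central
# vessels and several smaller segmental ones; ellipses are elongated
# cranio-caudally (aspect 1.6).
vessel_layout <- function() {
  pos <- matrix(c(
     0.00, -0.65,  0.30, -0.35, -0.30, -0.30,  0.05, -0.05,
     0.45,  0.10, -0.40,  0.05,  0.15,  0.30, -0.15,  0.35,
     0.50,  0.45, -0.45,  0.45,  0.20,  0.62, -0.20,  0.65),
    ncol = 2, byrow = TRUE)
  colnames(pos) <- c("u", "v")
  w <- c(0.30, 0.18, 0.12, 0.09, 0.07, 0.06, 0.05, 0.04, 0.03, 0.02, 0.02, 0.02)
  list(pos = pos, weights = w / sum(w), aspect = 1.6)
}

#' Generate a synthetic free-breathing dynamic lung-MRI series
#'
#' Builds a 2D+t phantom with known ground truth: two dark lung fields
#' (superellipses) on a bright mediastinum/chest-wall background, containing
#' bright elliptical vessels. The total vessel area oscillates sinusoidally
#' at the cardiac frequency with a relative amplitude chosen so its CV
#' equals `truth$vessel_area_cv`; the vessel intensity oscillates at the same
#' frequency, leading the area by `truth$se_delay_frac` of the RR-interval
#' (flow-related enhancement precedes expansion). The lung outline scales
#' isotropically at the respiratory frequency so that the lung area
#' (lung-field pixels excluding vessels) attains the requested CV; the
#' amplitude is compensated for the cardiac vessel-area term so the compound
#' series matches the target. Vessel centres ride with the breathing
#' parenchyma (they scale with the lung outline), giving the sub-pixel
#' respiratory drift real vessels show; this also dithers the rasterisation
#' of the vessel masks so their area tracks the continuous waveform without
#' a fixed-grid staircase. Gaussian noise of SD `truth$noise_sd` is added
#' to the images only; truth masks are noise-free anti-aliased rasterisations
#' thresholded at 0.5 coverage.
#'
#' With the default 384 ms frame interval, cardiac frequencies above about
#' 78 beats/min exceed the Nyquist frequency; the generator then warns (the
#' sampling regime itself under-samples such rates) but does not error.
#'
#' @param config An [acquisition_config()].
#' @param truth A [phantom_truth()].
#' @param background_frac Background (mediastinum/chest wall) intensity as a
#'   fraction of `truth$vessel_signal_mean`.
#' @param lung_frac Lung parenchyma intensity as a fraction of
#'   `truth$vessel_signal_mean`.
#' @param waveform Cardiac waveform shape: `"sine"` (analytic CV and peak
#'   times) or `"asymmetric"` (fast upstroke).
#' @param supersample Sub-pixel sampling factor per axis for anti-aliased
#'   rasterisation (vessels use `2 * supersample`).
#' @return An object of class `lung_phantom`: a list with `images` (an
#'   [image_series()]), `lung_truth` and `vessel_truth` (logical
#'   rows x cols x frames arrays), `truth` and `config`.
#' @examples
#' ph <- generate_phantom(acquisition_config(n_frames = 40, matrix = c(64, 64)),
#'                        phantom_truth(vessel_area_mean = 140, noise_sd = 0))
#' dim(ph$images$data)
#' @export
generate_phantom <- function(config, truth,
                             background_frac = 0.5, lung_frac = 0.15,
                             waveform = c("sine", "asymmetric"),
                             supersample = 2L) {
  stopifnot(inherits(config, "acquisition_config"),
            inherits(truth, "phantom_truth"))
  waveform <- match.arg(waveform)
  nr <- config$matrix[1]; nc <- config$matrix[2]
  nt <- config$n_frames; dt <- config$dt

  fc <- truth$heart_rate / 60
  fr <- truth$resp_rate / 60
  if (fc >= 1 / (2 * dt)) {
    warning("cardiac frequency (", signif(fc, 4), " Hz) is at or above the ",
            "Nyquist frequency (", signif(1 / (2 * dt), 4),
            " Hz); the series under-samples the cardiac dynamics",
            call. = FALSE)
  }
  for (cv in c(truth$vessel_area_cv, truth$vessel_signal_cv, truth$lung_area_cv)) {
    if (sqrt(2) * cv / 100 >= 1) {
      stop_pv("CV of ", cv, "% implies a non-positive (negative-area) waveform")
    }
  }

  # lung geometry scales with the matrix
  a <- 0.16 * nc; b <- 0.33 * nr
  nexp <- 2.5
  cy <- 0.52 * nr
  cx <- c(0.32, 0.68) * nc
  B0 <- 2 * superellipse_area(a, b, nexp)
  V0 <- truth$vessel_area_mean
  if (V0 > 0.45 * B0) {
    stop_pv("matrix too small to contain lungs and vessels: requested vessel ",
            "area ", V0, " voxels exceeds 45% of the lung-field area (",
            round(B0), " voxels)")
  }

  t <- (0:(nt - 1)) * dt
  theta_sig <- 2 * pi * fc * t
  theta_area <- theta_sig - 2 * pi * truth$se_delay_frac
  w_sig <- cardiac_waveform(theta_sig, waveform)
  w_area <- cardiac_waveform(theta_area, waveform)
  sig_t <- truth$vessel_signal_mean * (1 + truth$vessel_signal_cv / 100 * w_sig)
  area_t <- V0 * (1 + truth$vessel_area_cv / 100 * w_area)
  if (any(sig_t <= 0) || any(area_t <= 0)) {
    stop_pv("cardiac amplitude implies non-positive vessel signal or area")
  }

  # respiratory amplitude compensated for the cardiac vessel-area component
  # so the lung area series (lung fields minus vessels) hits its target CV
  L0 <- B0 - V0
  sd_target <- truth$lung_area_cv / 100 * L0
  sd_vessel <- truth$vessel_area_cv / 100 * V0
  sd_blob <- sqrt(max(0, sd_target^2 - sd_vessel^2))
  blob_t <- B0 * (1 + sqrt(2) * sd_blob / B0 * sin(2 * pi * fr * t))
  if (any(blob_t <= 0)) stop_pv("lung-area amplitude implies non-positive area")
  s_lung <- sqrt(blob_t / B0)
  s_ves <- sqrt(area_t / V0)

  # precompute radial fields once; per frame only threshold + block-average
  ss_l <- as.integer(supersample)
  ss_v <- 2L * ss_l
  smax_l <- max(s_lung) * 1.02
  lung_fields <- lapply(cx, function(x0) {
    rho_field(nr, nc, cy, x0, b, a, nexp, smax_l, ss_l)
  })
  lay <- vessel_layout()
  n_per_lung <- nrow(lay$pos)
  area_each0 <- lay$weights * V0 / 2
  vax <- sqrt(area_each0 / (pi * lay$aspect))
  vay <- lay$aspect * vax
  if (min(vax) < 0.45) {
    stop_pv("matrix too small to contain lungs and vessels: smallest ",
            "vessel semi-axis below half a pixel")
  }

  bg <- background_frac * truth$vessel_signal_mean
  lung_int <- lung_frac * truth$vessel_signal_mean

  images <- array(0, c(nr, nc, nt))
  lung_truth <- array(FALSE, c(nr, nc, nt))
  vessel_truth <- array(FALSE, c(nr, nc, nt))
  for (ti in seq_len(nt)) {
    lcov <- matrix(0, nr, nc)
    for (fld in lung_fields) {
      lcov[fld$rows, fld$cols] <- lcov[fld$rows, fld$cols] +
        field_coverage(fld, s_lung[ti])
    }
    lcov <- pmin(lcov, 1)
    # vessels ride with the breathing parenchyma: centres scale with the
    # lung outline (sub-pixel respiratory drift), semi-axes with the
    # cardiac area factor
    vcov <- matrix(0, nr, nc)
    for (li in 1:2) {
      for (vi in seq_len(n_per_lung)) {
        vcx <- cx[li] + lay$pos[vi, "u"] * 0.66 * a * s_lung[ti]
        vcy <- cy + lay$pos[vi, "v"] * 0.66 * b * s_lung[ti]
        ec <- ellipse_coverage(nr, nc, vcy, vcx,
                               vay[vi] * s_ves[ti], vax[vi] * s_ves[ti], ss_v)
        vcov[ec$rows, ec$cols] <- vcov[ec$rows, ec$cols] + ec$cov
      }
    }
    vcov <- pmin(vcov, 1)
    frame <- bg * (1 - lcov) + lung_int * lcov
    frame <- frame * (1 - vcov) + sig_t[ti] * vcov
    images[, , ti] <- frame
    vmask <- vcov >= 0.5
    lung_truth[, , ti] <- (lcov >= 0.5) & !vmask
    vessel_truth[, , ti] <- vmask
  }
  if (truth$noise_sd > 0) {
    images <- images + with_seed(truth$seed,
      array(rnorm(length(images), sd = truth$noise_sd), dim(images)))
  }

  structure(list(
    images = image_series(images, dt = dt, pixel_spacing = config$pixel_spacing),
    lung_truth = lung_truth, vessel_truth = vessel_truth,
    truth = truth, config = config),
    class = "lung_phantom")
}

#' @export
print.lung_phantom <- function(x, ...) {
  d <- dim(x$images$data)
  cat("Synthetic dynamic lung phantom\n")
  cat(sprintf("  %d frames of %d x %d px, dt = %g s (%.1f s series)\n",
              d[3], d[1], d[2], x$images$dt, d[3] * x$images$dt))
  cat(sprintf("  heart rate %g bpm, resp rate %g /min, SE-delay %.0f%% of RR\n",
              x$truth$heart_rate, x$truth$resp_rate,
              100 * x$truth$se_delay_frac))
  cat(sprintf("  target CVs: vessel area %g%%, lung area %g%%, vessel signal %g%%\n",
              x$truth$vessel_area_cv, x$truth$lung_area_cv,
              x$truth$vessel_signal_cv))
  cat(sprintf("  noise SD %g a.u., seed %d\n", x$truth$noise_sd, x$truth$seed))
  invisible(x)
}

#' @export
plot.lung_phantom <- function(x, frame = 1L, masks = TRUE, ...) {
  img <- x$images$data[, , frame]
  # orient with row 1 at the top
  image(t(img)[, nrow(img):1], col = gray(seq(0, 1, length.out = 128)),
        axes = FALSE, asp = nrow(img) / ncol(img),
        main = sprintf("phantom frame %d", frame), ...)
  if (masks) {
    v <- x$vessel_truth[, , frame]
    ctr <- try(contourLines(seq_len(ncol(v)) / ncol(v),
                            seq(nrow(v), 1) / nrow(v), t(v) * 1, levels = 0.5),
               silent = TRUE)
    if (!inherits(ctr, "try-error")) {
      for (cl in ctr) lines(cl$x, cl$y, col = "red", lwd = 0.8)
    }
  }
  invisible(x)
}

#' Dynamic image series container
#'
#' A 2D+t intensity stack stored as a rows x cols x frames array, with the
#' frame interval in seconds and the in-plane pixel spacing in mm.
#'
#' @param data Numeric array with 3 dimensions (rows, cols, frames).
#' @param dt Frame interval in seconds.
#' @param pixel_spacing Pixel spacing in mm (may be `NA`).
#' @return An object of class `image_series`.
#' @export
image_series <- function(data, dt, pixel_spacing = NA_real_) {
  if (!is.array(data) || length(dim(data)) != 3) {
    stop_pv("`data` must be a rows x cols x frames array")
  }
  if (dim(data)[3] < 2) stop_pv("an image series needs at least 2 frames")
  if (!is_num1(dt) || dt <= 0) stop_pv("`dt` must be a positive number of seconds")
  structure(list(data = data, dt = dt, pixel_spacing = pixel_spacing),
            class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Image series: %d frames of %d x %d px, dt = %g s\n",
              d[3], d[1], d[2], x$dt))
  invisible(x)
}

#' @importFrom grDevices contourLines
#' @importFrom graphics image
NULL
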