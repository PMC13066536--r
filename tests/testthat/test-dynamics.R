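test_that("time-series extraction counts pixels and averages signal", {
  img <- array(7, c(8, 8, 5))
  lungs <- array(FALSE, c(8, 8, 5)); lungs[1:4, 1:4, ] <- TRUE
  vessels <- array(FALSE, c(8, 8, 5)); vessels[6:7, 6:7, ] <- TRUE
  ts <- extract_timeseries(img, lungs, vessels, dt = 0.5)
  expect_equal(ts$vessel_area, rep(4, 5))
  expect_equal(ts$lung_area, rep(16, 5))
  expect_equal(ts$vessel_signal, rep(7, 5))
  expect_equal(ts$time, (0:4) * 0.5)
  # an empty vessel mask makes the signal undefined, naming the frame
  vessels[, , 3] <- FALSE
  expect_error(extract_timeseries(img, lungs, vessels, dt = 0.5), "frame 3")
})

test_that("high-pass filter removes DC and slow content at zero phase", {
  t <- (0:249) * 0.384
  # constant series: output is numerically zero
  out <- highpass(rep(42, 250), 0.384)
  expect_lt(max(abs(out)), 1e-8 * 42)
  # 0.25 Hz respiratory sinusoid attenuated by >= 90% (FFT amplitude ratio)
  x <- sin(2 * pi * 0.25 * t)
  y <- highpass(x, 0.384)
  amp <- function(v, f, dt) {
    n <- length(v)
    fr <- (0:(n - 1)) / (n * dt)
    i <- which.min(abs(fr - f))
    2 * Mod(fft(v))[i] / n
  }
  expect_lt(amp(y, 0.25, 0.384) / amp(x, 0.25, 0.384), 0.1)
  # 1.2 Hz cardiac sinusoid passes with < 5% loss and no phase shift
  t2 <- (0:299) * 0.2
  x2 <- sin(2 * pi * 1.2 * t2)
  y2 <- highpass(x2, 0.2)
  cc <- ccf(x2, y2, lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  expect_gt(amp(y2, 1.2, 0.2) / amp(x2, 1.2, 0.2), 0.95)
  expect_lt(abs(mean(y2)), 0.01)
  # contract violations
  expect_error(highpass(x, 0.384, cutoff = 2), "Nyquist")
  expect_error(highpass(rnorm(10), 0.384), "too short")
})

test_that("cv_percent implements SD over baseline mean", {
  expect_equal(cv_percent(rep(0, 50), rep(10, 50)), 0)
  # sinusoid mean 100, peak amplitude 5, dense integer cycles: 100*(5/sqrt(2))/100
  t <- seq(0, 10, by = 1 / 1024)[-1]
  x <- 100 + 5 * sin(2 * pi * t)
  expect_equal(cv_percent(x - mean(x), x), 100 * (5 / sqrt(2)) / 100,
               tolerance = 1e-3)
  # homogeneity: doubling both series leaves the CV unchanged
  expect_equal(cv_percent(2 * (x - mean(x)), 2 * x),
               cv_percent(x - mean(x), x))
  expect_error(cv_percent(x, x - 200), "positive")
})

test_that("peak detection finds known sinusoid peaks at sub-frame accuracy", {
  t <- (0:299) * 0.1
  x <- sin(2 * pi * 1.0 * t)
  pk <- detect_cardiac_peaks(x, 0.1)
  expect_true(abs(length(pk) - 30) <= 1)
  expect_true(all(abs(diff(pk$times) - 1.0) < 0.1))
  # sub-frame refinement: true peaks at 0.25 + k
  interior <- pk$times[pk$times > 1 & pk$times < 29]
  frac <- (interior - 0.25) %% 1
  expect_lt(max(pmin(frac, 1 - frac)), 0.05)
  expect_error(detect_cardiac_peaks(rep(3, 100), 0.1), "no cardiac")
})

test_that("phantom signal peaks match the true cardiac cycle count", {
  tr <- phantom_truth(heart_rate = 78, noise_sd = 0)
  ph <- generate_phantom(acquisition_config(), tr)  # 250 frames x 0.384 s = 96 s
  ts <- extract_timeseries(ph$images, ph$lung_truth, ph$vessel_truth)
  pk <- detect_cardiac_peaks(highpass(ts$vessel_signal, ts$dt), ts$dt)
  duration <- (ts$time[length(ts$time)])
  true_cycles <- floor(78 / 60 * duration)
  expect_lte(abs(length(pk) - true_cycles), 2)
})

test_that("SE-delay follows the next-area-peak pairing rule", {
  sp <- peak_list(c(0, 1, 2, 3), 1:4)
  # coincident peaks: zero delay
  expect_equal(se_delay(sp, sp), 0)
  # area peaks midway between signal peaks: 50% of RR
  ap <- peak_list(c(0.5, 1.5, 2.5, 3.5), 1:4)
  expect_equal(se_delay(sp, ap), 50)
  # invariance under a common time shift
  sp2 <- peak_list(sp$times + 11.3, sp$indices)
  ap2 <- peak_list(ap$times + 11.3, ap$indices)
  expect_equal(se_delay(sp2, ap2), 50)
  # trailing signal peaks without a later area peak are dropped
  ap3 <- peak_list(0.5, 1L)
  expect_equal(se_delay(sp, ap3), 50)
  expect_error(se_delay(peak_list(5, 1L), ap3), "at least 2")
  expect_error(se_delay(sp, peak_list(numeric(0), integer(0))), "at least 1")
})

test_that("heart rate estimators agree with closed forms", {
  pk <- peak_list(0:47, 1:48)
  expect_equal(heart_rate(pk), 60)
  pk2 <- peak_list(seq(0, 12, by = 0.75), seq_len(17))
  expect_equal(heart_rate(pk2), 80)
  expect_equal(heart_rate(pk2, method = "count"), 80)
  expect_error(heart_rate(peak_list(1, 1L)), "at least 2")
})

test_that("vessel_dynamics recovers generator ground truth on true masks", {
  # study-scale phantom: 250 frames of 128 x 128 at 384 ms
  ph <- generate_phantom(acquisition_config(),
                         phantom_truth(heart_rate = 72, se_delay_frac = 0.4,
                                       noise_sd = 0))
  fit <- vessel_dynamics(ph$images, ph$lung_truth, ph$vessel_truth)
  m <- coef(fit)
  expect_lt(abs(m["cv_vessel_area"] - 3), 0.3)
  expect_lt(abs(m["cv_lung_area"] - 8), 1)
  expect_equal(unname(m["heart_rate"]), 72, tolerance = 0.03)
  expect_lt(abs(m["se_delay"] - 40), 5)
  expect_s3_class(fit, "vessel_dynamics")
  expect_named(m, c("cv_vessel_area", "cv_lung_area", "cv_vessel_signal",
                    "se_delay", "heart_rate"))
})

test_that("CVs are invariant under global intensity scaling", {
  ph <- small_phantom(small_config(n_frames = 60))
  f1 <- vessel_dynamics(ph$images, ph$lung_truth, ph$vessel_truth)
  scaled <- image_series(ph$images$data * 3.7, dt = ph$images$dt)
  f2 <- vessel_dynamics(scaled, ph$lung_truth, ph$vessel_truth)
  expect_equal(coef(f2), coef(f1), tolerance = 1e-10)
})

test_that("an all-constant series yields zero CVs and no detectable peaks", {
  ph <- small_phantom(small_config(n_frames = 40),
                      vessel_area_cv = 0, lung_area_cv = 0,
                      vessel_signal_cv = 0)
  ts <- extract_timeseries(ph$images, ph$lung_truth, ph$vessel_truth)
  expect_equal(cv_percent(ts$lung_area - mean(ts$lung_area), ts$lung_area), 0)
  expect_lt(cv_percent(highpass(ts$vessel_area, ts$dt), ts$vessel_area), 1e-4)
  expect_error(vessel_dynamics(ph$images, ph$lung_truth, ph$vessel_truth),
               "no cardiac")
})

test_that("the full pipeline runs from images alone", {
  ph <- small_phantom(noise_sd = 7.5, seed = 5)
  fit <- vessel_dynamics(ph$images)  # baseline segmentation inside
  m <- coef(fit)
  expect_equal(unname(m["heart_rate"]), 72, tolerance = 0.05)
  expect_lt(abs(m["cv_lung_area"] - 8) / 8, 0.25)
})
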