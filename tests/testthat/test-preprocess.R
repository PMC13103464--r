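# Signal conditioning: zero-phase filtering, resampling, channel hygiene,
# epoching, referencing, and the fNIRS optics chain.

sine_rec <- function(freqs, fs = 1000, dur = 20) {
  t <- seq(1 / fs, dur, by = 1 / fs)
  sensor_recording(t(vapply(freqs, function(f) sin(2 * pi * f * t),
                            numeric(length(t)))), fs, modality = "eeg")
}

mid_amp <- function(x) {
  n <- length(x)
  sqrt(2) * sd(x[round(0.25 * n):round(0.75 * n)])
}

test_that("EEG band-pass keeps the band and rejects stop-band and DC", {
  rec <- sine_rec(c(10, 60, 0.5))
  rec$data <- rbind(rec$data, 5)   # DC channel
  f <- eeg_bandpass(rec)
  expect_lt(abs(mid_amp(f$data[1, ]) - 1), 0.05)             # in-band
  expect_lt(20 * log10(mid_amp(f$data[2, ])), -40)           # 60 Hz line
  expect_lt(20 * log10(mid_amp(f$data[3, ])), -40)           # 0.5 * lo
  expect_lt(abs(mean(f$data[4, ])), 0.01)                    # high-passed DC
  expect_error(eeg_bandpass(sine_rec(10, fs = 80), 1, 45), "Nyquist")
})

test_that("all filters are zero-phase: in-band sinusoid delay is 0", {
  rec <- sine_rec(10)
  f <- eeg_bandpass(rec)
  lag <- which.max(ccf(f$data[1, ], rec$data[1, ], lag.max = 20,
                       plot = FALSE)$acf) - 21
  expect_equal(lag, 0)
  fs <- 11; t <- seq(1 / fs, 600, by = 1 / fs)
  od <- sensor_recording(rbind(sin(2 * pi * 0.05 * t)), fs,
                         modality = "fnirs")
  g <- fnirs_bandpass(od)
  lag2 <- which.max(ccf(g$data[1, ], od$data[1, ], lag.max = 20,
                        plot = FALSE)$acf) - 21
  expect_equal(lag2, 0)
})

test_that("downsampling preserves duration and in-band frequencies", {
  rec <- sine_rec(c(5, 2), dur = 10)
  d <- downsample(rec, 256)
  expect_true(abs(ncol(d$data) - 2560) <= 1)
  sp <- stats::spec.pgram(d$data[1, ], plot = FALSE)
  expect_lt(abs(sp$freq[which.max(sp$spec)] * 256 - 5),
            256 / ncol(d$data) + 1e-9)                       # within one bin
  const <- sensor_recording(matrix(3, 2, 1000), 1000, modality = "eeg")
  dc <- downsample(const, 256)
  expect_equal(max(abs(dc$data - 3)), 0, tolerance = 1e-9)
  expect_error(downsample(d, 256), "below")
})

test_that("bad channels are flagged by robust variance/kurtosis scores", {
  set.seed(1)
  x <- matrix(rnorm(12 * 2000), 12)
  rec <- sensor_recording(x, 256, modality = "eeg")
  expect_length(detect_bad_channels(rec), 0)
  x2 <- x; x2[4, ] <- 100 * x2[4, ]
  expect_equal(detect_bad_channels(sensor_recording(x2, 256, modality = "eeg")),
               4)
  x3 <- x; x3[7, ] <- 0
  expect_true(7 %in% detect_bad_channels(sensor_recording(x3, 256,
                                                          modality = "eeg")))
  expect_error(detect_bad_channels(sensor_recording(matrix(0, 8, 100), 256,
                                                    modality = "eeg")),
               "unusable")
})

test_that("spherical-spline interpolation reconstructs smooth fields", {
  lf <- make_toy_leadfield(32, 4, seed = 2)
  pos <- lf$sensor_positions
  ch <- data.frame(name = sprintf("E%02d", 1:32),
                   x = pos[, 1], y = pos[, 2], z = pos[, 3])
  field <- 3 * pos[, 1] + 2 * pos[, 2]^2 - pos[, 3]
  dat <- field %o% seq(1, 2, length.out = 40)
  rec <- sensor_recording(dat, 100, ch, modality = "eeg")
  truth <- rec$data[5, ]
  rec$data[5, ] <- -99
  out <- interpolate_channels(rec, 5)
  expect_gt(cor(out$data[5, ], truth), 0.95)
  expect_identical(interpolate_channels(rec, integer(0)), rec)
  const <- sensor_recording(matrix(7, 32, 10), 100, ch, modality = "eeg")
  ic <- interpolate_channels(const, 3)
  expect_equal(ic$data[3, ], rep(7, 10), tolerance = 1e-8)
  nopos <- sensor_recording(dat, 100, modality = "eeg")
  expect_error(interpolate_channels(nopos, 5), "positions")
})

test_that("epoching drops exactly the out-of-bound epochs", {
  fs <- 256
  x <- matrix(rnorm(2 * 10 * fs, sd = 10), 2)   # well within +/-100 uV
  rec <- sensor_recording(x, fs, modality = "eeg")
  ep <- epoch_and_reject(rec)
  expect_equal(dim(ep$epochs), c(5, 2, 512))
  expect_true(all(ep$kept_mask))
  x2 <- x; x2[1, 3 * 512 + 10] <- 150
  ep2 <- epoch_and_reject(sensor_recording(x2, fs, modality = "eeg"))
  expect_equal(which(!ep2$kept_mask), 4)
  expect_equal(ep2$rejection_log[4], "amplitude")
  expect_lte(max(abs(ep2$epochs)), 100)          # kept epochs obey the bound
  x3 <- matrix(200, 2, 2 * fs)
  expect_error(epoch_and_reject(sensor_recording(x3, fs, modality = "eeg")),
               "no clean data")
})

test_that("common average reference zeroes the spatial mean and is idempotent", {
  set.seed(2)
  ep <- epoch_and_reject(sensor_recording(matrix(rnorm(4 * 2048, sd = 5), 4),
                                          256, modality = "eeg"))
  car <- common_average_reference(ep)
  for (e in seq_len(dim(car$epochs)[1])) {
    expect_lt(max(abs(colMeans(car$epochs[e, , ]))), 1e-12)
  }
  car2 <- common_average_reference(car)
  expect_equal(car2$epochs, car$epochs, tolerance = 1e-12)
  same <- sensor_recording(matrix(1, 3, 10) * 5, 100, modality = "eeg")
  expect_true(all(common_average_reference(same)$data == 0))
})

test_that("optical-density conversion is the exact log-ratio transform", {
  rec <- sensor_recording(matrix(1e6, 2, 50), 11, modality = "fnirs")
  od <- intensity_to_od(rec)
  expect_true(all(od$data == 0))
  # planted zero-mean dOD comes back exactly
  d <- rbind(sin(seq_len(100)) - mean(sin(seq_len(100))))
  rec2 <- sensor_recording(1e6 * 10^(-d), 11, modality = "fnirs")
  expect_equal(intensity_to_od(rec2)$data, d, tolerance = 1e-12)
  bad <- sensor_recording(matrix(1, 2, 10), 11, modality = "fnirs")
  bad$data[2, 7] <- -1
  expect_error(intensity_to_od(bad), "channel 2, sample 7")
})

test_that("derivative-reweighting motion repair suppresses steps, not hemodynamics", {
  fs <- 11; t <- seq(1 / fs, 120, by = 1 / fs)
  smooth <- sin(2 * pi * 0.05 * t)
  mc <- motion_correct(sensor_recording(rbind(smooth), fs,
                                        modality = "fnirs"))
  expect_lt(max(abs(mc$data[1, ] - smooth)), 0.05 * sd(smooth) * 5)
  step <- smooth + 5 * sd(smooth) * (t > 60)
  mc2 <- motion_correct(sensor_recording(rbind(step), fs,
                                         modality = "fnirs"))
  resid <- mc2$data[1, ] - smooth
  step_after <- abs(mean(resid[t > 60]) - mean(resid[t <= 60]))
  expect_lt(step_after, 0.2 * 5 * sd(smooth))     # >= 80% suppressed
  z <- motion_correct(sensor_recording(matrix(0, 1, 60), fs,
                                       modality = "fnirs"))
  expect_true(all(z$data == 0))
})

test_that("fNIRS band-pass passes the slow band and kills cardiac", {
  fs <- 11; t <- seq(1 / fs, 600, by = 1 / fs)
  od <- sensor_recording(rbind(sin(2 * pi * 0.05 * t),
                               sin(2 * pi * 1.7 * t)), fs,
                         modality = "fnirs")
  f <- fnirs_bandpass(od)
  expect_lt(abs(mid_amp(f$data[1, ]) - 1), 0.05)
  expect_lt(20 * log10(mid_amp(f$data[2, ])), -40)
  expect_warning(fnirs_bandpass(sensor_recording(matrix(rnorm(110), 1), 11,
                                                 modality = "fnirs")),
                 "300 s")
})

test_that("Beer-Lambert inversion solves the two-wavelength system", {
  des <- study_design(n_subjects = 1, phases = "pre",
                      phase_durations = c(pre = 30), n_rois = 4, rng_seed = 2)
  hb <- generate_fnirs_hemodynamics(des)[[1]]$pre
  mont <- fnirs_montage(4, 4)
  raw <- hemodynamics_to_raw_intensity(hb, mont)
  od <- intensity_to_od(raw)
  # dOD = 0 -> dHb = 0
  od0 <- od; od0$data[] <- 0
  inv0 <- mbll_invert(od0)
  expect_true(all(inv0$hbo$data == 0) && all(inv0$hbr$data == 0))
  # linearity: doubling dOD doubles both chromophores
  inv1 <- mbll_invert(od)
  od2 <- od; od2$data <- 2 * od$data
  inv2 <- mbll_invert(od2)
  expect_equal(inv2$hbo$data, 2 * inv1$hbo$data, tolerance = 1e-12)
  expect_equal(inv2$hbr$data, 2 * inv1$hbr$data, tolerance = 1e-12)
  # missing second wavelength is an error
  half <- od; half$data <- od$data[1:4, ]; half$channels <- od$channels[1:4, ]
  expect_error(mbll_invert(half), "two distinct wavelengths")
})

test_that("modality alignment interpolates onto epoch centers without extrapolating", {
  fs <- 11
  t_hb <- seq(0, 30 - 1 / fs, by = 1 / fs)
  hb <- sensor_recording(rbind(2 * t_hb + 1), fs, modality = "hb")
  ep <- epoch_and_reject(sensor_recording(matrix(rnorm(20 * 256, sd = 5), 1,
                                                 20 * 256), 256,
                                          modality = "eeg"))
  al <- align_modalities(hb, ep)
  # linear ramp: interpolation is exact at epoch centers
  expect_equal(al$values[1, ], 2 * al$timestamps + 1, tolerance = 1e-9)
  expect_false(any(al$missing))
  # epoch centers beyond the fNIRS record are flagged missing
  ep40 <- epoch_and_reject(sensor_recording(matrix(rnorm(40 * 256, sd = 5), 1,
                                                   40 * 256), 256,
                                            modality = "eeg"))
  al2 <- align_modalities(hb, ep40)
  expect_true(any(al2$missing))
  expect_true(all(is.na(al2$values[1, al2$missing])))
  hb_late <- hb; ep_short <- ep
  ep_short$onsets <- ep_short$onsets + 1000
  expect_error(align_modalities(hb, ep_short), "overlap")
})
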