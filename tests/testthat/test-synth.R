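# Synthetic-data generator: determinism, forward models, and the link
# between planted coupling and downstream phase locking.

tiny_design <- function(..., seed = 1L) {
  study_design(n_subjects = 1, phases = "pre", phase_durations = c(pre = 60),
               eeg_rate = 256, n_rois = 2, rng_seed = seed, ...)
}

# generator -> theta-band PLV of ROI pair (continuous, single epoch)
theta_plv_of <- function(design, coupling, noise_scale = 1) {
  r <- generate_roi_oscillations(design,
                                 coupling = list(theta = coupling),
                                 noise_scale = noise_scale)[[1]]$pre
  rb <- band_filter(r, "theta")
  plv(analytic_phase(rb$data[1, ]), analytic_phase(rb$data[2, ]))
}

test_that("identical design and seed give identical datasets", {
  d <- tiny_design(seed = 7L)
  a <- generate_roi_oscillations(d)[[1]]$pre$data
  b <- generate_roi_oscillations(d)[[1]]$pre$data
  expect_identical(a, b)
  h1 <- generate_fnirs_hemodynamics(d)[[1]]$pre
  h2 <- generate_fnirs_hemodynamics(d)[[1]]$pre
  expect_identical(h1$hbo$data, h2$hbo$data)
  lf1 <- make_toy_leadfield(8, 12, seed = 3)
  lf2 <- make_toy_leadfield(8, 12, seed = 3)
  expect_identical(lf1$gain, lf2$gain)
})

test_that("coupling matrices are validated", {
  d <- tiny_design()
  bad <- matrix(c(1, 1.5, 1.5, 1), 2)
  expect_error(generate_roi_oscillations(d, coupling = list(theta = bad)),
               "\\[0, 1\\]")
  expect_error(generate_roi_oscillations(d, coupling = list(sigma = diag(2))),
               "unknown band")
  asym <- matrix(c(1, 0.2, 0.4, 1), 2)
  expect_error(generate_roi_oscillations(d, coupling = list(theta = asym)),
               "symmetric")
})

test_that("full coupling with no noise yields perfectly locked signals", {
  d <- tiny_design(seed = 2L)
  ones <- matrix(1, 2, 2)
  r <- generate_roi_oscillations(
    d, coupling = list(delta = ones, theta = ones, alpha = ones,
                       beta = ones, gamma = ones),
    noise_scale = 0)[[1]]$pre
  expect_equal(r$data[1, ], r$data[2, ])  # shared phase identity
  rb <- band_filter(r, "theta")
  expect_equal(plv(analytic_phase(rb$data[1, ]), analytic_phase(rb$data[2, ])),
               1)
})

test_that("uncoupled ROIs sit at the Monte-Carlo null level of PLV (60 s at 256 Hz)", {
  vals <- vapply(1:30, function(s) {
    theta_plv_of(tiny_design(seed = s), diag(2))
  }, numeric(1))
  expect_lt(mean(vals), 0.1)
})

test_that("estimated PLV is monotone in the planted coupling weight", {
  grid_c <- c(0, 0.25, 0.5, 0.75, 1)
  means <- vapply(grid_c, function(cpl) {
    cm <- matrix(c(1, cpl, cpl, 1), 2)
    mean(vapply(1:30, function(s)
      theta_plv_of(tiny_design(seed = 100 + s), cm, noise_scale = 0),
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > -0.01))   # non-decreasing up to MC jitter
  expect_gt(means[5], 0.9)
  expect_lt(means[1], 0.35)
})

test_that("a planted coupling increase raises PLV in the stated phase only", {
  des <- study_design(n_subjects = 8, phases = c("pre", "on"),
                      phase_durations = c(pre = 30, on = 30), eeg_rate = 256,
                      n_rois = 4, rng_seed = 42)
  ef <- list(planted_effect("eeg-band", band = "theta", edges = c(1, 2),
                            contrast = c("pre", "on"), effect_size = 0.5,
                            n_rois = 4))
  rois <- generate_roi_oscillations(des, effects = ef)
  diffs <- vapply(1:8, function(s) {
    p_of <- function(ph) {
      rb <- band_filter(epoch_roi(rois[[s]][[ph]]), "theta")
      plv_matrix(rb)[1, 2]
    }
    p_of("on") - p_of("pre")
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  # effect sizes that push coupling outside [0, 1] are rejected
  base <- matrix(c(1, 0.8, 0.8, 1), 2)
  ef2 <- list(planted_effect("eeg-band", band = "theta", edges = c(1, 2),
                             contrast = c("pre", "on"), effect_size = 0.5,
                             n_rois = 2))
  d2 <- study_design(n_subjects = 1, phases = c("pre", "on"),
                     phase_durations = c(pre = 2, on = 2), eeg_rate = 128,
                     n_rois = 2)
  expect_error(generate_roi_oscillations(d2, coupling = list(theta = base),
                                         effects = ef2),
               "outside \\[0, 1\\]")
})

test_that("toy leadfield has spherical geometry with depth-decaying gain", {
  lf <- make_toy_leadfield(16, 30, seed = 5)
  expect_equal(lf$rank, 16)
  expect_equal(unname(rowSums(lf$sensor_positions^2)), rep(1, 16))
  norms <- sqrt(colSums(lf$gain^2))
  # deeper sources have smaller gain column norms
  expect_lt(norms[which.max(lf$source_depths)],
            norms[which.min(lf$source_depths)])
  expect_lt(cor(lf$source_depths, norms, method = "spearman"), -0.5)
  expect_error(make_toy_leadfield(3, 5), "at least 4 sensors")
})

test_that("sensor projection is the linear forward model plus white noise", {
  lf <- structure(list(gain = diag(3),
                       sensor_positions = diag(3),
                       source_positions = diag(3),
                       source_depths = rep(0.5, 3), rank = 3),
                  class = "leadfield")
  x <- matrix(rnorm(3 * 200), 3)
  roi <- roi_timeseries(x, 100)
  rec <- project_to_sensors(roi, lf, noise_sd = 0)
  expect_equal(rec$data, x, ignore_attr = TRUE)
  # zero sources: output is pure noise with sample SD ~ noise_sd
  n <- 3 * 20000
  rec0 <- project_to_sensors(roi_timeseries(matrix(0, 3, 20000), 100), lf,
                             noise_sd = 2, seed = 4)
  expect_lt(abs(sd(rec0$data) - 2), 3 * 2 / sqrt(n))
  # single active source: sensor pattern proportional to that gain column
  lf2 <- make_toy_leadfield(8, 5, seed = 2)
  src <- matrix(0, 5, 50); src[3, ] <- sin(1:50 / 3)
  rec1 <- project_to_sensors(roi_timeseries(src, 100), lf2, noise_sd = 0)
  expect_equal(rec1$data, lf2$gain[, 3] %o% src[3, ], ignore_attr = TRUE)
  expect_error(project_to_sensors(roi_timeseries(matrix(0, 4, 10), 100), lf2),
               "source_map")
})

test_that("hemodynamic generator hits its target correlations", {
  des <- study_design(n_subjects = 1, phases = "pre",
                      phase_durations = c(pre = 300), n_rois = 3, rng_seed = 5)
  fc <- diag(3); fc[1, 2] <- fc[2, 1] <- 0.8
  hb <- generate_fnirs_hemodynamics(des, fc_target = list(hbo = fc),
                                    nuisance_amp = c(mayer = 0, cardiac = 0,
                                                     resp = 0))
  x <- hb[[1]]$pre$hbo$data
  expect_lt(abs(cor(x[1, ], x[2, ]) - 0.8), 0.1)
  # identity target: mean off-diagonal correlation ~ 0 across seeds
  offd <- vapply(1:20, function(s) {
    d <- study_design(n_subjects = 1, phases = "pre",
                      phase_durations = c(pre = 300), n_rois = 5, rng_seed = s)
    y <- generate_fnirs_hemodynamics(d, nuisance_amp = c(mayer = 0,
                                                         cardiac = 0,
                                                         resp = 0))[[1]]$pre$hbo$data
    cc <- cor(t(y))
    mean(cc[upper.tri(cc)])
  }, numeric(1))
  expect_lt(abs(mean(offd)), 0.05)
})

test_that("hemodynamic signals are band-limited and nuisance/PSD handling works", {
  des <- study_design(n_subjects = 1, phases = "pre",
                      phase_durations = c(pre = 300), n_rois = 2, rng_seed = 3)
  hb <- generate_fnirs_hemodynamics(des, nuisance_amp = c(mayer = 0,
                                                          cardiac = 0,
                                                          resp = 0))
  x <- hb[[1]]$pre$hbo$data[1, ]
  sp <- stats::spec.pgram(x, plot = FALSE, taper = 0, detrend = FALSE)
  f <- sp$freq * 11
  out_mass <- 1 - sum(sp$spec[f >= 0.008 & f <= 0.12]) / sum(sp$spec)
  expect_lt(out_mass, 0.05)
  bad <- matrix(0.9, 3, 3); diag(bad) <- 1
  bad[1, 2] <- bad[2, 1] <- -0.9   # infeasible correlation triangle
  expect_error(generate_fnirs_hemodynamics(
    study_design(n_subjects = 1, phases = "pre",
                 phase_durations = c(pre = 10), n_rois = 3),
    fc_target = list(hbo = bad)), "eigenvalue")
})

test_that("Beer-Lambert forward model is linear and exactly invertible", {
  des <- study_design(n_subjects = 1, phases = "pre",
                      phase_durations = c(pre = 30), n_rois = 6, rng_seed = 7)
  hb <- generate_fnirs_hemodynamics(des)[[1]]$pre
  mont <- fnirs_montage(5, 6)
  # zero concentration changes: intensity constant at baseline
  zero <- list(hbo = roi_timeseries(matrix(0, 6, 50), 11),
               hbr = roi_timeseries(matrix(0, 6, 50), 11))
  raw0 <- hemodynamics_to_raw_intensity(zero, mont, baseline_intensity = 1e6)
  expect_true(all(raw0$data == 1e6))
  # doubling DPF doubles the optical-density excursion
  r1 <- hemodynamics_to_raw_intensity(hb, mont, dpf = c("730" = 6, "850" = 6))
  r2 <- hemodynamics_to_raw_intensity(hb, mont, dpf = c("730" = 12, "850" = 12))
  od1 <- -log10(r1$data / 1e6); od2 <- -log10(r2$data / 1e6)
  expect_equal(od2, 2 * od1, tolerance = 1e-12)
  # forward -> OD -> inversion roundtrip recovers the planted series exactly
  inv <- mbll_invert(intensity_to_od(r1))
  expect_lt(max(abs(inv$hbo$data - hb$hbo$data[mont$roi, ])), 1e-10)
  expect_lt(max(abs(inv$hbr$data - hb$hbr$data[mont$roi, ])), 1e-10)
  expect_error(hemodynamics_to_raw_intensity(hb, mont,
                                             baseline_intensity = 0),
               "positive")
})
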