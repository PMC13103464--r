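## Synthetic multimodal study generator. Produces multi-subject, multi-phase
## EEG source oscillations with controllable pairwise phase coupling, slow
## correlated hemodynamic (HbO/HbR) signals with physiological nuisance, and
## the forward models (toy leadfield, modified Beer-Lambert law) that turn
## them into raw sensor data. Every stochastic draw is governed by an
## explicit integer seed; identical (design, seed) gives identical data.

#' Canonical EEG frequency bands
#'
#' @return data.frame with columns `band`, `lo`, `hi` (Hz): delta 1-4,
#'   theta 4-8, alpha 8-15, beta 15-25, gamma 25-45.
#' @export
eeg_bands <- function() {
  data.frame(band = c("delta", "theta", "alpha", "beta", "gamma"),
             lo = c(1, 4, 8, 15, 25),
             hi = c(4, 8, 15, 25, 45),
             stringsAsFactors = FALSE)
}

band_center <- function(band) {
  b <- eeg_bands()
  i <- match(band, b$band)
  abort_if(anyNA(i), "unknown band label '%s'", paste(band[is.na(i)], collapse = ", "))
  (b$lo[i] + b$hi[i]) / 2
}

#' Study design parameters
#'
#' Container for the acquisition and design constants of the stimulation
#' study: 16 subjects, three phases (2 min pre-stimulation, 1 min
#' stimulation, 2 min post-stimulation, repeated over 5 cycles), four
#' stimulation frequencies (5/20/70/100 Hz), 32 EEG channels at 1000 Hz
#' native (256 Hz working) and 45 fNIRS optical channels at 11 Hz, with 46
#' shared atlas ROIs.
#'
#' @param n_subjects Number of subjects.
#' @param phases Ordered phase labels.
#' @param stim_frequencies Stimulation frequencies (Hz).
#' @param n_cycles Stimulation cycles per frequency.
#' @param phase_durations Named seconds per phase.
#' @param eeg_rate Native EEG sampling rate (Hz).
#' @param eeg_rate_working Working EEG rate after downsampling (Hz).
#' @param fnirs_rate fNIRS sampling rate (Hz).
#' @param n_eeg_channels,n_fnirs_channels,n_rois Channel/ROI counts.
#' @param rng_seed Base seed for all generation.
#' @return Object of class `study_design`.
#' @export
study_design <- function(n_subjects = 16,
                         phases = c("pre", "on", "post"),
                         stim_frequencies = c(5, 20, 70, 100),
                         n_cycles = 5,
                         phase_durations = c(pre = 120, on = 60, post = 120),
                         eeg_rate = 1000,
                         eeg_rate_working = 256,
                         fnirs_rate = 11,
                         n_eeg_channels = 32,
                         n_fnirs_channels = 45,
                         n_rois = 46,
                         rng_seed = 1L) {
  counts <- c(n_subjects, n_cycles, n_eeg_channels, n_fnirs_channels, n_rois)
  abort_if(any(counts <= 0), "all counts must be positive")
  abort_if(anyDuplicated(phases) > 0, "phase labels must be unique")
  abort_if(any(c(eeg_rate, eeg_rate_working, fnirs_rate) <= 0),
           "rates must be positive")
  abort_if(!all(phases %in% names(phase_durations)),
           "phase_durations must name every phase")
  structure(list(n_subjects = n_subjects, phases = phases,
                 stim_frequencies = stim_frequencies, n_cycles = n_cycles,
                 phase_durations = phase_durations, eeg_rate = eeg_rate,
                 eeg_rate_working = eeg_rate_working, fnirs_rate = fnirs_rate,
                 n_eeg_channels = n_eeg_channels,
                 n_fnirs_channels = n_fnirs_channels, n_rois = n_rois,
                 rng_seed = as.integer(rng_seed)),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("<study_design> %d subjects, phases %s, stim %s Hz, %d ROIs, seed %d\n",
              x$n_subjects, paste(x$phases, collapse = "/"),
              paste(x$stim_frequencies, collapse = "/"), x$n_rois, x$rng_seed))
  invisible(x)
}

#' A planted condition effect
#'
#' Describes a ground-truth effect injected by the generator: a coupling
#' (EEG) or correlation (fNIRS) increment on a set of ROI pairs, applied in
#' one phase of a phase contrast.
#'
#' @param modality "eeg-band", "hbo" or "hbr".
#' @param band EEG band label (required when modality is "eeg-band").
#' @param edges Integer matrix, one ROI pair per row (1-based indices).
#' @param contrast Character length-2, e.g. `c("pre", "on")`; the effect is
#'   applied in the second phase only.
#' @param effect_size Coupling/correlation increment (positive number).
#' @param direction "increase" or "decrease".
#' @param n_rois Number of ROIs (for index validation).
#' @return Object of class `planted_effect`.
#' @export
planted_effect <- function(modality = c("eeg-band", "hbo", "hbr"),
                           band = NULL, edges, contrast = c("pre", "on"),
                           effect_size, direction = c("increase", "decrease"),
                           n_rois = 46) {
  modality <- match.arg(modality)
  direction <- match.arg(direction)
  edges <- matrix(as.integer(edges), ncol = 2)
  abort_if(any(edges < 1 | edges > n_rois),
           "ROI indices must lie in [1..%d]", n_rois)
  abort_if(any(edges[, 1] == edges[, 2]), "edges must join distinct ROIs")
  if (modality == "eeg-band") {
    abort_if(is.null(band), "band is required for eeg-band effects")
    band_center(band)  # validates the label
  }
  abort_if(!is.numeric(effect_size) || effect_size < 0,
           "effect_size must be non-negative")
  structure(list(modality = modality, band = band, edges = edges,
                 contrast = contrast, effect_size = effect_size,
                 direction = direction),
            class = "planted_effect")
}

#' Derive a reproducible sub-seed
#'
#' Mixes a base seed with stream indices so that each subject/phase/band
#' draw has its own deterministic stream. Always below 2^31.
#' @param seed Base integer seed.
#' @param ... Non-negative integer indices.
#' @return Integer seed.
#' @export
derive_seed <- function(seed, ...) {
  ix <- c(...)
  s <- as.double(seed) %% 2147483629
  for (k in ix) s <- (s * 48271 + as.double(k) + 1) %% 2147483629
  as.integer(s)
}

## coupling[i,j] -> per-ROI attachment to one shared driver per connected
## component of the coupling graph: a_i = max_j coupling[i,j]. Phase mixing
## phi_i = (1 - a_i) phi_own + a_i phi_shared makes the downstream PLV a
## monotone function of the coupling weight, with c = 1 giving identical
## phases and c = 0 independent ones.
validate_coupling <- function(cm, n_rois) {
  check_matrix(cm)
  abort_if(nrow(cm) != n_rois || ncol(cm) != n_rois,
           "coupling matrix must be %d x %d", n_rois, n_rois)
  abort_if(!is_symmetric(cm), "coupling matrix must be symmetric")
  abort_if(any(cm < 0 | cm > 1), "coupling entries must lie in [0, 1]")
  abort_if(any(abs(diag(cm) - 1) > 1e-12), "coupling diagonal must be 1")
  invisible(cm)
}

## Brownian-phase oscillator: 2*pi*f0*t + theta0 + random-walk jitter whose
## diffusion rate D (rad^2/s) sets the coherence time ~ 1/D.
brownian_phase <- function(n, fs, f0, diffusion) {
  t <- (seq_len(n) - 1) / fs
  jitter <- cumsum(stats::rnorm(n, 0, sqrt(diffusion / fs)))
  2 * pi * f0 * t + stats::runif(1, 0, 2 * pi) + jitter
}

## 1/f-amplitude background noise, band-limited to [lo, hi], unit SD.
pink_noise <- function(n, fs, lo = 1, hi = 45) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  f <- pmin(f, fs - f)  # two-sided frequency axis
  w <- ifelse(f >= lo & f <= hi, 1 / sqrt(pmax(f, lo)), 0)
  y <- Re(stats::fft(X * w, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s > 0) y / s else y
}

apply_eeg_effects <- function(coupling, effects, band, phase, n_rois) {
  cm <- coupling
  for (ef in effects) {
    if (ef$modality != "eeg-band" || !identical(ef$band, band)) next
    if (!identical(phase, ef$contrast[2])) next
    s <- if (ef$direction == "increase") 1 else -1
    for (r in seq_len(nrow(ef$edges))) {
      i <- ef$edges[r, 1]; j <- ef$edges[r, 2]
      v <- cm[i, j] + s * ef$effect_size
      abort_if(v < -1e-12 || v > 1 + 1e-12,
               "effect places coupling[%d,%d] = %.3f outside [0, 1]", i, j, v)
      cm[i, j] <- cm[j, i] <- min(max(v, 0), 1)
    }
  }
  cm
}

## One subject/phase realization of all-band ROI oscillations.
synth_roi_phase <- function(n_rois, n, fs, coupling_by_band, amplitude,
                            noise_scale, diffusion_scale, seed) {
  bands <- eeg_bands()
  x <- matrix(0, n_rois, n)
  for (bi in seq_len(nrow(bands))) {
    band <- bands$band[bi]
    f0 <- (bands$lo[bi] + bands$hi[bi]) / 2
    D <- diffusion_scale * f0    # rad^2/s; coherence time ~ 1/D
    cm <- coupling_by_band[[band]]
    off <- cm; diag(off) <- 0
    a <- apply(off, 1, max)
    comp <- igraph::components(
      igraph::graph_from_adjacency_matrix(off > 0, mode = "undirected"))$membership
    with_seed(derive_seed(seed, bi), {
      n_comp <- max(comp)
      shared <- matrix(0, n_comp, n)
      for (k in seq_len(n_comp)) shared[k, ] <- brownian_phase(n, fs, f0, D)
      for (i in seq_len(n_rois)) {
        own <- brownian_phase(n, fs, f0, D)
        phi <- (1 - a[i]) * own + a[i] * shared[comp[i], ]
        x[i, ] <- x[i, ] + amplitude * cos(phi)
      }
    })
  }
  if (noise_scale > 0) {
    band_rms <- amplitude / sqrt(2) * sqrt(nrow(bands))
    with_seed(derive_seed(seed, 99L), {
      for (i in seq_len(n_rois)) {
        x[i, ] <- x[i, ] + noise_scale * band_rms * pink_noise(n, fs)
      }
    })
  }
  x
}

#' Generate band-structured ROI oscillations with planted phase coupling
#'
#' For every subject and phase, each ROI signal is a sum over the five
#' canonical bands of a constant-amplitude oscillation with slowly diffusing
#' phase, plus 1/f background noise. Pairwise phase coupling is realized by
#' mixing each ROI's own band phase with a shared driver phase (one driver
#' per connected component of the coupling graph) with weight
#' `a_i = max_j coupling[i, j]`, so the downstream phase-locking value is a
#' monotone function of the coupling weight. Planted effects add their
#' increment to the coupling matrix in the stated phase only.
#'
#' @param design A [study_design()].
#' @param coupling Named list of per-band `n_rois x n_rois` symmetric
#'   coupling matrices with entries in `[0, 1]` and unit diagonal. Missing
#'   bands default to no coupling.
#' @param effects List of [planted_effect()] objects (eeg-band modality).
#' @param rate Sampling rate of the generated series; defaults to the
#'   design's native EEG rate.
#' @param amplitude Per-band oscillation amplitude (microvolts).
#' @param noise_scale 1/f background SD as a multiple of the summed band RMS.
#' @param diffusion_scale Phase-diffusion rate per Hz of band center
#'   frequency (rad^2/s/Hz); controls oscillator coherence time.
#' @param roi_labels Optional ROI labels (defaults to the shared ROI table
#'   abbreviations when `n_rois == 46`).
#' @return Nested list `[[subject]][[phase]]` of [roi_timeseries()] objects.
#' @export
generate_roi_oscillations <- function(design, coupling = list(),
                                      effects = list(),
                                      rate = design$eeg_rate,
                                      amplitude = 3,
                                      noise_scale = 1,
                                      diffusion_scale = 0.5,
                                      roi_labels = NULL) {
  n_rois <- design$n_rois
  bands <- eeg_bands()$band
  abort_if(!all(names(coupling) %in% bands),
           "unknown band label in coupling: %s",
           paste(setdiff(names(coupling), bands), collapse = ", "))
  base <- diag(n_rois)
  coupling_full <- lapply(bands, function(b) {
    cm <- if (!is.null(coupling[[b]])) coupling[[b]] else base
    validate_coupling(cm, n_rois)
  })
  names(coupling_full) <- bands
  if (is.null(roi_labels)) {
    roi_labels <- if (n_rois == 46) roi_table()$abbreviation else
      sprintf("roi%02d", seq_len(n_rois))
  }
  out <- vector("list", design$n_subjects)
  for (s in seq_len(design$n_subjects)) {
    per_phase <- list()
    for (phase_i in seq_along(design$phases)) {
      ph <- design$phases[phase_i]
      n <- round(design$phase_durations[[ph]] * rate)
      eff_coupling <- lapply(bands, function(b) {
        apply_eeg_effects(coupling_full[[b]], effects, b, ph, n_rois)
      })
      names(eff_coupling) <- bands
      x <- synth_roi_phase(n_rois, n, rate, eff_coupling, amplitude,
                           noise_scale, diffusion_scale,
                           derive_seed(design$rng_seed, s, phase_i))
      per_phase[[ph]] <- roi_timeseries(
        x, rate, roi_labels,
        meta = list(subject = s, phase = ph, modality = "eeg-source"))
    }
    out[[s]] <- per_phase
  }
  out
}

#' Analytic toy leadfield on a spherical geometry
#'
#' Sensors are placed quasi-uniformly on the unit sphere (Fibonacci
#' lattice); sources at seeded random interior positions with radii in
#' `[0.35, 0.9]`. The gain from source `j` to sensor `i` decays with their
#' distance as `d^(-falloff)`: the default `falloff = 2` is the
#' single-layer spherical conductor appropriate for electric potentials;
#' optical sensitivity profiles are much more compact, so fNIRS toy
#' sensitivities use a steeper exponent (4 in the pipeline).
#' Rank-deficient draws are regenerated with the next seed (warning).
#'
#' @param n_sensors Number of sensors (>= 4).
#' @param n_sources Number of sources.
#' @param seed Integer seed for source placement.
#' @param falloff Distance-decay exponent of the gain (default 2).
#' @return Object of class `leadfield`: list with `gain`
#'   (sensors x sources), `sensor_positions`, `source_positions`,
#'   `source_depths` (1 - radius), `rank`.
#' @export
make_toy_leadfield <- function(n_sensors, n_sources, seed = 1L, falloff = 2) {
  abort_if(n_sensors < 4, "need at least 4 sensors")
  abort_if(n_sources < 1, "need at least 1 source")
  i <- seq_len(n_sensors) - 0.5
  golden <- pi * (3 - sqrt(5))
  z <- 1 - 2 * i / n_sensors
  r <- sqrt(pmax(0, 1 - z^2))
  sens <- cbind(x = r * cos(golden * i), y = r * sin(golden * i), z = z)
  for (attempt in 0:9) {
    src <- with_seed(derive_seed(seed, attempt), {
      u <- matrix(stats::rnorm(3 * n_sources), n_sources, 3)
      u <- u / sqrt(rowSums(u^2))
      rad <- stats::runif(n_sources, 0.35, 0.9)
      u * rad
    })
    d2 <- outer(rowSums(sens^2), rowSums(src^2), "+") - 2 * sens %*% t(src)
    gain <- 1 / pmax(d2, 1e-12)^(falloff / 2)
    # overall scale: mean column norm 1, so projected amplitudes stay in a
    # physiological range; relative (depth-dependent) column norms preserved
    gain <- gain / mean(sqrt(colSums(gain^2)))
    rk <- qr(gain)$rank
    if (rk == min(n_sensors, n_sources)) {
      return(structure(list(gain = gain, sensor_positions = sens,
                            source_positions = src,
                            source_depths = 1 - sqrt(rowSums(src^2)),
                            rank = rk),
                       class = "leadfield"))
    }
    warning(sprintf("rank-deficient leadfield draw (rank %d); regenerating", rk))
  }
  stop("could not draw a full-rank leadfield in 10 attempts", call. = FALSE)
}

#' @export
print.leadfield <- function(x, ...) {
  cat(sprintf("<leadfield> %d sensors x %d sources, rank %d\n",
              nrow(x$gain), ncol(x$gain), x$rank))
  invisible(x)
}

#' Project ROI/source series to EEG sensors
#'
#' Sensor data = gain x source + white noise. When the leadfield has more
#' sources than the ROI series has rows, `source_map` assigns each source
#' to the ROI whose series it carries.
#'
#' @param roi A [roi_timeseries()] (ROIs x samples).
#' @param leadfield A [make_toy_leadfield()] object.
#' @param noise_sd SD of additive white sensor noise (same units as data).
#' @param seed Integer seed for the noise draw.
#' @param source_map Integer vector (length = n_sources) mapping each
#'   leadfield column to a ROI row; NULL requires n_sources == n_rois.
#' @param channels Optional channel table; defaults to sensor positions.
#' @return A [sensor_recording()] (modality "eeg").
#' @export
project_to_sensors <- function(roi, leadfield, noise_sd = 0, seed = 1L,
                               source_map = NULL, channels = NULL) {
  n_src <- ncol(leadfield$gain)
  n_roi <- nrow(roi$data)
  if (is.null(source_map)) {
    abort_if(n_src != n_roi,
             "leadfield has %d sources but ROI series has %d rows; give source_map",
             n_src, n_roi)
    src <- roi$data
  } else {
    abort_if(length(source_map) != n_src, "source_map length must equal n_sources")
    abort_if(any(source_map < 1 | source_map > n_roi), "source_map index out of range")
    src <- roi$data[source_map, , drop = FALSE]
  }
  y <- leadfield$gain %*% src
  if (noise_sd > 0) {
    y <- y + with_seed(derive_seed(seed, 7L),
                       matrix(stats::rnorm(length(y), 0, noise_sd), nrow(y)))
  }
  if (is.null(channels)) {
    channels <- data.frame(name = sprintf("E%02d", seq_len(nrow(y))),
                           x = leadfield$sensor_positions[, 1],
                           y = leadfield$sensor_positions[, 2],
                           z = leadfield$sensor_positions[, 3],
                           stringsAsFactors = FALSE)
  }
  ann <- data.frame(onset = 0, duration = ncol(y) / roi$rate,
                    label = if (!is.null(roi$meta$phase)) roi$meta$phase else "phase",
                    stringsAsFactors = FALSE)
  sensor_recording(y, roi$rate, channels, ann, modality = "eeg")
}

apply_fc_effects <- function(fc, effects, chromophore, phase) {
  for (ef in effects) {
    if (ef$modality != chromophore) next
    if (!identical(phase, ef$contrast[2])) next
    s <- if (ef$direction == "increase") 1 else -1
    for (r in seq_len(nrow(ef$edges))) {
      i <- ef$edges[r, 1]; j <- ef$edges[r, 2]
      v <- min(max(fc[i, j] + s * ef$effect_size, -0.999), 0.999)
      fc[i, j] <- fc[j, i] <- v
    }
  }
  fc
}

## Factor a correlation target, clipping tiny negative eigenvalues that can
## arise after planting effects; a genuinely non-PSD target is an error.
fc_factor <- function(fc, tol = 1e-8) {
  e <- eigen(fc, symmetric = TRUE)
  bad <- which(e$values < -tol * abs(e$values[1]))
  abort_if(length(bad) > 0,
           "target correlation matrix is not positive semi-definite (eigenvalue %d = %.3g)",
           bad[1], e$values[bad[1]])
  vals <- pmax(e$values, 0)
  e$vectors %*% diag(sqrt(vals), length(vals))
}

#' Generate correlated slow hemodynamic ROI signals
#'
#' Draws band-limited (0.01-0.1 Hz) signals whose ROI-pair correlations
#' match a target matrix (factor construction: unit-variance filtered noise
#' mixed by a square root of the target), then adds sinusoidal physiological
#' nuisance — Mayer waves (~0.1 Hz), cardiac (1.6-1.8 Hz) and respiratory
#' (0.2-0.3 Hz) oscillations — and optional step motion artifacts.
#'
#' @param design A [study_design()].
#' @param fc_target Named list with `hbo` and `hbr` target correlation
#'   matrices (symmetric PSD, unit diagonal); defaults to identity.
#' @param effects List of [planted_effect()] (hbo/hbr modality).
#' @param hb_sd Signal SD in mmol/L (default 1e-3, i.e. 1 umol/L); HbR is
#'   scaled by `hbr_scale` and sign-flipped relative to HbO typicality is
#'   left to `fc_target`.
#' @param hbr_scale HbR amplitude relative to HbO.
#' @param nuisance_amp Named amplitudes (fraction of `hb_sd`) for `mayer`,
#'   `cardiac`, `resp` components; set to 0 to disable.
#' @param motion_rate Poisson rate (events/s) of step artifacts; 0 disables.
#' @param motion_amp Step amplitude in multiples of the signal SD.
#' @return Nested list `[[subject]][[phase]]` of lists with `hbo` and `hbr`
#'   [roi_timeseries()] objects at the fNIRS rate.
#' @export
generate_fnirs_hemodynamics <- function(design, fc_target = list(),
                                        effects = list(),
                                        hb_sd = 1e-3, hbr_scale = 0.4,
                                        nuisance_amp = c(mayer = 0.4,
                                                         cardiac = 0.6,
                                                         resp = 0.3),
                                        motion_rate = 0, motion_amp = 5) {
  n_rois <- design$n_rois
  fs <- design$fnirs_rate
  ident <- diag(n_rois)
  targets <- list(hbo = if (!is.null(fc_target$hbo)) fc_target$hbo else ident,
                  hbr = if (!is.null(fc_target$hbr)) fc_target$hbr else ident)
  for (nm in names(targets)) {
    tm <- targets[[nm]]
    check_matrix(tm)
    abort_if(!is_symmetric(tm, 1e-8), "fc_target$%s must be symmetric", nm)
    abort_if(any(abs(diag(tm) - 1) > 1e-8), "fc_target$%s diagonal must be 1", nm)
    fc_factor(tm)  # PSD check up front
  }
  roi_labels <- if (n_rois == 46) roi_table()$abbreviation else
    sprintf("roi%02d", seq_len(n_rois))
  bp <- signal::butter(3, c(0.01, 0.1) / (fs / 2), type = "pass")
  nuis_freq <- c(mayer = 0.095, cardiac = 1.7, resp = 0.25)
  out <- vector("list", design$n_subjects)
  for (s in seq_len(design$n_subjects)) {
    per_phase <- list()
    for (phase_i in seq_along(design$phases)) {
      ph <- design$phases[phase_i]
      n <- round(design$phase_durations[[ph]] * fs)
      chrom <- list()
      for (ci in seq_along(targets)) {
        nm <- names(targets)[ci]
        fc <- apply_fc_effects(targets[[nm]], effects, nm, ph)
        L <- fc_factor(fc)
        amp <- hb_sd * if (nm == "hbr") hbr_scale else 1
        x <- with_seed(derive_seed(design$rng_seed, 500L, s, phase_i, ci), {
          z <- matrix(stats::rnorm(n_rois * n), n_rois, n)
          z <- t(apply(z, 1, function(row) {
            f <- signal::filtfilt(bp, row)
            f / stats::sd(f)
          }))
          sig <- L %*% z
          sig <- sig * amp
          for (comp in names(nuis_freq)) {
            a <- nuisance_amp[[comp]]
            if (is.na(a) || a == 0) next
            t <- (seq_len(n) - 1) / fs
            ph0 <- stats::runif(n_rois, 0, 2 * pi)
            sig <- sig + a * amp *
              sin(outer(ph0, 2 * pi * nuis_freq[[comp]] * t, "+"))
          }
          sig <- sig - rowMeans(sig)   # concentration changes about baseline
          if (motion_rate > 0) {
            n_ev <- stats::rpois(1, motion_rate * n / fs)
            if (n_ev > 0) {
              at <- sample.int(n, n_ev)
              ch <- sample.int(n_rois, n_ev, replace = TRUE)
              for (k in seq_len(n_ev)) {
                step <- motion_amp * amp * sign(stats::rnorm(1))
                sig[ch[k], at[k]:n] <- sig[ch[k], at[k]:n] + step
              }
            }
          }
          sig
        })
        chrom[[nm]] <- roi_timeseries(
          x, fs, roi_labels,
          meta = list(subject = s, phase = ph, chromophore = nm))
      }
      per_phase[[ph]] <- chrom
    }
    out[[s]] <- per_phase
  }
  out
}

#' Extinction coefficients used by the Beer-Lambert forward/inverse pair
#'
#' Base-10 molar extinction coefficients for oxy- and deoxyhemoglobin at the
#' two acquisition wavelengths (730 and 850 nm), in 1/(mM cm), from the
#' standard compiled in-vitro hemoglobin spectra.
#'
#' @return 2 x 2 matrix; rows "730"/"850" (nm), columns `hbo`/`hbr`.
#' @export
extinction_coefficients <- function() {
  matrix(c(0.3900, 1.1022,
           1.0580, 0.6913),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("730", "850"), c("hbo", "hbr")))
}

#' Synthetic fNIRS channel montage
#'
#' A synthetic source/detector layout: `n_channels` optical channels dealt
#' round-robin over 22 sources and 15 detectors, each channel sampling one
#' ROI.
#'
#' @param n_channels Number of optical channels.
#' @param n_rois Number of ROIs to cover.
#' @return data.frame with columns `channel`, `source`, `detector`, `roi`.
#' @export
fnirs_montage <- function(n_channels = 45, n_rois = 46) {
  data.frame(channel = seq_len(n_channels),
             source = ((seq_len(n_channels) - 1) %% 22) + 1,
             detector = ((seq_len(n_channels) - 1) %% 15) + 1,
             roi = ((seq_len(n_channels) - 1) %% n_rois) + 1)
}

#' Forward modified Beer-Lambert model: hemoglobin to raw intensity
#'
#' Per optical channel and wavelength,
#' `dOD = (eps_hbo * dHbO + eps_hbr * dHbR) * d * DPF` and
#' `I = baseline * 10^(-dOD)`. Exact inverse of [mbll_invert()] composed
#' with [intensity_to_od()].
#'
#' @param hb List with `hbo` and `hbr` [roi_timeseries()] (mmol/L).
#' @param montage Channel-to-ROI map from [fnirs_montage()].
#' @param dpf Differential pathlength factors, named by wavelength
#'   (`"730"`, `"850"`); default 6.0 both.
#' @param distance Source-detector separation (cm).
#' @param baseline_intensity Baseline detector counts (> 0).
#' @return A [sensor_recording()] (modality "fnirs") with
#'   `2 * n_channels` rows and channel table columns `name`, `wavelength`,
#'   `source`, `detector`, `roi`.
#' @export
hemodynamics_to_raw_intensity <- function(hb, montage = fnirs_montage(),
                                          dpf = c("730" = 6, "850" = 6),
                                          distance = 3.0,
                                          baseline_intensity = 1e6) {
  abort_if(baseline_intensity <= 0, "baseline intensity must be positive")
  eps <- extinction_coefficients()
  hbo <- hb$hbo$data[montage$roi, , drop = FALSE]
  hbr <- hb$hbr$data[montage$roi, , drop = FALSE]
  n_ch <- nrow(montage)
  rows <- vector("list", 2 * n_ch)
  tabs <- vector("list", 2 * n_ch)
  k <- 0
  for (wl in rownames(eps)) {
    for (c in seq_len(n_ch)) {
      k <- k + 1
      dod <- (eps[wl, "hbo"] * hbo[c, ] + eps[wl, "hbr"] * hbr[c, ]) *
        distance * dpf[[wl]]
      rows[[k]] <- baseline_intensity * 10^(-dod)
      tabs[[k]] <- data.frame(name = sprintf("S%d_D%d %snm",
                                             montage$source[c],
                                             montage$detector[c], wl),
                              wavelength = as.numeric(wl),
                              source = montage$source[c],
                              detector = montage$detector[c],
                              roi = montage$roi[c], stringsAsFactors = FALSE)
    }
  }
  data <- do.call(rbind, rows)
  channels <- do.call(rbind, tabs)
  ph <- hb$hbo$meta$phase
  ann <- data.frame(onset = 0, duration = ncol(data) / hb$hbo$rate,
                    label = if (!is.null(ph)) ph else "phase",
                    stringsAsFactors = FALSE)
  sensor_recording(data, hb$hbo$rate, channels, ann, modality = "fnirs")
}
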