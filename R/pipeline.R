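## End-to-end orchestration: synthetic study -> preprocessing -> inverse ->
## connectivity -> graph metrics -> group statistics, governed by a single
## validated configuration whose seed reaches every stochastic stage.

default_config <- function() {
  list(
    design = list(),                 # overrides for study_design()
    bands = c("delta", "theta", "alpha", "beta", "gamma"),
    modalities = c("eeg", "fnirs"),
    effects = list(),                # planted_effect objects; NULL/empty = default
    sensor_noise_sd = 1,             # uV white noise on EEG sensors
    fnirs = list(motion_rate = 0, nuisance = TRUE),
    preprocess = list(eeg_lo = 1, eeg_hi = 45, target_rate = 256,
                      epoch_length = 2, amplitude_limit = 100),
    inverse = list(snr = 3, gamma = 0.5),
    graph = list(lo = 0.09, hi = 0.50, step = 0.01, n_null = 100),
    stats = list(edge_alpha = 0.001, n_perm = 10000, comp_alpha = 0.05 / 3,
                 contrast = c("pre", "on"), run_nbs = TRUE, run_anova = TRUE),
    seed = 1L
  )
}

merge_checked <- function(defaults, user, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  abort_if(length(unknown) > 0, "unknown config key%s: %s",
           if (length(unknown) > 1) "s" else "",
           paste0(path, unknown, collapse = ", "))
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])) &&
        is.list(user[[nm]]) && nm != "design" && nm != "effects") {
      defaults[[nm]] <- merge_checked(defaults[[nm]], user[[nm]],
                                      paste0(path, nm, "$"))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Build a validated run configuration
#'
#' Unknown keys are rejected before any computation. See the package
#' vignette for the meaning and defaults of every parameter.
#'
#' @param ... Named overrides of the default configuration (nested lists
#'   for the `design`, `fnirs`, `preprocess`, `inverse`, `graph`, `stats`
#'   sections).
#' @return Object of class `run_config`.
#' @export
run_config <- function(...) {
  user <- list(...)
  cfg <- merge_checked(default_config(), user)
  abort_if(!all(cfg$bands %in% eeg_bands()$band), "unknown band in config")
  abort_if(!all(cfg$modalities %in% c("eeg", "fnirs")),
           "modalities must be a subset of eeg, fnirs")
  structure(cfg, class = "run_config")
}

## FNV-1a hash of the JSON-serialized config: a stable provenance tag.
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, force = TRUE)
  h <- 2166136261
  for (b in utf8ToInt(as.character(s))) {
    h <- bitwXor(as.integer(h %% 2^31), b) * 16777619
    h <- h %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Default planted effect set
#'
#' During stimulation ("on" vs "pre"): a theta-band coupling increase on
#' all pairs of a frontoparietal community (a quarter of the ROIs), and a
#' hemodynamic correlation increase on all pairs of a five-region
#' frontotemporal subnetwork for both chromophores (an equicorrelated
#' block, which stays a valid correlation matrix for any increment below
#' 1 and gives the network-based statistic a connected target). Under the shared-driver phase-mixing
#' generator, a within-community coupling increase expresses itself
#' downstream as higher phase-locking on the community edges and a higher
#' clustering coefficient of the thresholded graphs — the directional
#' signatures the end-to-end tests look for.
#'
#' @param n_rois Number of ROIs.
#' @param effect_size Coupling increment for the EEG community effect.
#' @param hb_effect Correlation increment for the hemodynamic path effect.
#' @return List of [planted_effect()] objects.
#' @export
default_effects <- function(n_rois = 46, effect_size = 0.5, hb_effect = 0.4) {
  members <- if (n_rois == 46) {
    # pars opercularis/triangularis, precuneus, superior frontal/parietal,
    # supramarginal: a bilateral frontoparietal community
    c(21, 22, 25, 26, 33, 34, 37, 38, 39, 40, 43, 44)
  } else {
    unique(round(seq(1, n_rois, length.out = max(4, n_rois %/% 4))))
  }
  comm <- t(utils::combn(members, 2))
  hb_nodes <- if (n_rois == 46) c(1, 22, 17, 26, 42) else
    members[seq_len(min(5, length(members)))]
  hb_path <- t(utils::combn(hb_nodes, 2))
  list(
    planted_effect("eeg-band", band = "theta", edges = comm,
                   contrast = c("pre", "on"), effect_size = effect_size,
                   direction = "increase", n_rois = n_rois),
    planted_effect("hbo", edges = hb_path, contrast = c("pre", "on"),
                   effect_size = hb_effect, direction = "increase",
                   n_rois = n_rois),
    planted_effect("hbr", edges = hb_path, contrast = c("pre", "on"),
                   effect_size = hb_effect, direction = "increase",
                   n_rois = n_rois)
  )
}

## EEG chain for one subject/phase: sensors -> clean epochs -> ROI epochs.
eeg_to_roi_epochs <- function(rec, lf, mask, cfg, inv_lambda) {
  pp <- cfg$preprocess
  rec <- eeg_bandpass(rec, pp$eeg_lo, pp$eeg_hi)
  if (pp$target_rate < rec$rate) rec <- downsample(rec, pp$target_rate)
  ep <- epoch_and_reject(rec, pp$epoch_length, pp$amplitude_limit)
  bad <- detect_bad_channels(ep)
  n_bad <- length(bad)
  if (n_bad > 0) ep <- interpolate_channels(ep, bad)
  ep <- common_average_reference(ep)
  inv <- sloreta(ep, lf, inv_lambda)
  d <- dim(ep$epochs)
  src_ep <- aperm(array(inv$sources, c(nrow(inv$sources), d[3], d[1])),
                  c(3, 1, 2))
  roi <- roi_timeseries(src_ep, ep$rate, mask$labels)
  list(roi = roi, n_bad = n_bad, retention = attr(ep, "retention"),
       onsets = ep$onsets, epoch_length = ep$epoch_length)
}

## fNIRS chain for one subject/phase: ROI hemodynamics -> channel optics ->
## channel hemoglobin -> wMNE ROI series.
fnirs_to_roi <- function(hb, lf_norm, cfg, inv_lambda) {
  n_ch <- nrow(lf_norm$gain)
  mixed <- list(
    hbo = roi_timeseries(lf_norm$gain %*% hb$hbo$data, hb$hbo$rate,
                         sprintf("ch%02d", seq_len(n_ch)), hb$hbo$meta),
    hbr = roi_timeseries(lf_norm$gain %*% hb$hbr$data, hb$hbr$rate,
                         sprintf("ch%02d", seq_len(n_ch)), hb$hbr$meta))
  raw <- hemodynamics_to_raw_intensity(mixed, fnirs_montage(n_ch, n_ch))
  od <- intensity_to_od(raw)
  od <- motion_correct(od)
  od <- suppressWarnings(fnirs_bandpass(od))
  hb_ch <- mbll_invert(od)
  list(hbo = wmne(hb_ch$hbo, lf_norm, inv_lambda, cfg$inverse$gamma)$sources,
       hbr = wmne(hb_ch$hbr, lf_norm, inv_lambda, cfg$inverse$gamma)$sources)
}

#' Run the full study pipeline on synthetic data
#'
#' Generates the synthetic study defined by the configuration, conditions
#' both modalities, solves the inverse problems, estimates band-wise PLV
#' and hemodynamic Fisher-z connectivity, integrates graph metrics over the
#' sparsity grid, and runs NBS and repeated-measures ANOVA group inference.
#'
#' @param config A [run_config()].
#' @return Object of class `study_result`: list with `connectivity`
#'   (per modality: list `[[subject]][[phase]]` of matrices), `metrics`
#'   (long data.frame of AUC values), `nodal_metrics`, `nbs` (per
#'   modality), `anova_global`, `anova_nodal`, `manifest`.
#' @export
run_study <- function(config = run_config()) {
  abort_if(!inherits(config, "run_config"), "config must come from run_config()")
  design <- do.call(study_design, config$design)
  if (is.null(design$rng_seed) || !("rng_seed" %in% names(config$design))) {
    design$rng_seed <- as.integer(config$seed)
  }
  effects <- if (length(config$effects) > 0) config$effects else
    default_effects(design$n_rois)
  mask <- apply_atlas_filter()
  if (design$n_rois != 46) {
    mask <- structure(list(labels = sprintf("roi%02d", seq_len(design$n_rois)),
                           index_in_full = seq_len(design$n_rois),
                           table = NULL), class = "atlas_mask")
  }
  mask <- assign_sources(mask, design$n_rois)
  grid <- sparsity_grid(config$graph$lo, config$graph$hi, config$graph$step)
  conn <- list()
  counts <- list(interpolated = 0, retention = c())

  if ("eeg" %in% config$modalities) {
    lf <- make_toy_leadfield(design$n_eeg_channels, design$n_rois,
                             derive_seed(config$seed, 1L))
    lambda <- default_lambda(lf, config$inverse$snr)
    rois <- generate_roi_oscillations(design, effects = effects)
    for (b in config$bands) conn[[paste0("plv-", b)]] <- list()
    for (s in seq_len(design$n_subjects)) {
      for (b in config$bands) conn[[paste0("plv-", b)]][[s]] <- list()
      for (ph in design$phases) {
        rec <- project_to_sensors(rois[[s]][[ph]], lf, config$sensor_noise_sd,
                                  derive_seed(config$seed, 2L, s))
        res <- eeg_to_roi_epochs(rec, lf, mask, config, lambda)
        counts$interpolated <- counts$interpolated + res$n_bad
        counts$retention <- c(counts$retention, res$retention)
        for (b in config$bands) {
          roi_b <- band_filter(res$roi, b)
          conn[[paste0("plv-", b)]][[s]][[ph]] <-
            plv_matrix(roi_b, b)
        }
      }
    }
  }

  if ("fnirs" %in% config$modalities) {
    lf_f <- make_toy_leadfield(design$n_fnirs_channels, design$n_rois,
                               derive_seed(config$seed, 3L), falloff = 4)
    lf_f$gain <- lf_f$gain / rowSums(lf_f$gain)
    lambda_f <- default_lambda(lf_f, config$inverse$snr)
    hbs <- generate_fnirs_hemodynamics(
      design, effects = effects,
      nuisance_amp = if (isTRUE(config$fnirs$nuisance))
        c(mayer = 0.4, cardiac = 0.6, resp = 0.3) else
          c(mayer = 0, cardiac = 0, resp = 0),
      motion_rate = config$fnirs$motion_rate)
    conn[["hbo-z"]] <- list(); conn[["hbr-z"]] <- list()
    for (s in seq_len(design$n_subjects)) {
      conn[["hbo-z"]][[s]] <- list(); conn[["hbr-z"]][[s]] <- list()
      for (ph in design$phases) {
        roi_hb <- fnirs_to_roi(hbs[[s]][[ph]], lf_f, config, lambda_f)
        for (cc in c("hbo", "hbr")) {
          rts <- roi_timeseries(roi_hb[[cc]], design$fnirs_rate, mask$labels,
                                meta = list(subject = s, phase = ph))
          r <- pearson_fc(rts, cc)
          conn[[paste0(cc, "-z")]][[s]][[ph]] <- fisher_z(r)
        }
      }
    }
  }

  # graph metrics over the sparsity grid, integrated to AUC
  metrics <- list(); nodal_rows <- list()
  auc_store <- list()
  for (mod in names(conn)) {
    for (s in seq_along(conn[[mod]])) {
      for (ph in names(conn[[mod]][[s]])) {
        gm <- graph_metrics(conn[[mod]][[s]][[ph]], grid,
                            n_null = config$graph$n_null,
                            seed = derive_seed(config$seed, 4L, s))
        for (m in names(gm$auc$global)) {
          metrics[[length(metrics) + 1]] <-
            data.frame(subject = s, phase = ph, modality = mod, metric = m,
                       auc = unname(gm$auc$global[[m]]))
        }
        auc_store[[mod]][[ph]][[s]] <- gm$auc
        for (m in names(gm$auc$nodal)) {
          nodal_rows[[length(nodal_rows) + 1]] <-
            data.frame(subject = s, phase = ph, modality = mod, metric = m,
                       roi = mask$labels, auc = gm$auc$nodal[[m]])
        }
      }
    }
  }
  metrics <- do.call(rbind, metrics)
  nodal_metrics <- do.call(rbind, nodal_rows)

  # group inference
  nbs_res <- list(); anova_global <- list(); anova_nodal <- list()
  if (isTRUE(config$stats$run_nbs)) {
    ctr <- config$stats$contrast
    for (mod in names(conn)) {
      a <- lapply(conn[[mod]], `[[`, ctr[1])
      b <- lapply(conn[[mod]], `[[`, ctr[2])
      nbs_res[[mod]] <- nbs(b, a, config$stats$edge_alpha,
                            config$stats$n_perm, config$stats$comp_alpha,
                            derive_seed(config$seed, 5L))
    }
  }
  if (isTRUE(config$stats$run_anova) && !is.null(metrics)) {
    for (mod in unique(metrics$modality)) {
      for (m in unique(metrics$metric)) {
        sub <- metrics[metrics$modality == mod & metrics$metric == m, ]
        tab <- stats::reshape(sub[, c("subject", "phase", "auc")],
                              idvar = "subject", timevar = "phase",
                              direction = "wide")
        vals <- as.matrix(tab[, -1])
        colnames(vals) <- sub("^auc\\.", "", colnames(vals))
        res <- rm_anova(vals)
        ph <- bonferroni_posthoc(vals)
        anova_global[[length(anova_global) + 1]] <-
          data.frame(modality = mod, metric = m, F = res$F, df1 = res$df1,
                     df2 = res$df2, p = res$p, epsilon = res$epsilon,
                     mean_diff_on_pre =
                       if (all(c("on", "pre") %in% colnames(vals)))
                         mean(vals[, "on"] - vals[, "pre"]) else NA_real_)
      }
      nod <- nodal_metrics[nodal_metrics$modality == mod, ]
      for (m in unique(nod$metric)) {
        sm <- nod[nod$metric == m, ]
        arr <- array(NA_real_,
                     c(max(sm$subject), length(design$phases),
                       design$n_rois),
                     dimnames = list(NULL, design$phases, mask$labels))
        for (r in seq_len(nrow(sm))) {
          arr[sm$subject[r], sm$phase[r], sm$roi[r]] <- sm$auc[r]
        }
        an <- nodal_rm_anova(arr)
        an$modality <- mod; an$metric <- m
        anova_nodal[[length(anova_nodal) + 1]] <- an
      }
    }
  }
  manifest <- list(
    config = unclass(config),
    config_hash = config_hash(config),
    seed = config$seed,
    design = unclass(design),
    effects = lapply(effects, unclass),
    counts = list(channels_interpolated = counts$interpolated,
                  mean_epoch_retention = if (length(counts$retention) > 0)
                    mean(counts$retention) else NA),
    package_version = as.character(utils::packageVersion("scsnet"))
  )
  structure(list(connectivity = conn, metrics = metrics,
                 nodal_metrics = nodal_metrics, nbs = nbs_res,
                 anova_global = if (length(anova_global) > 0)
                   do.call(rbind, anova_global) else NULL,
                 anova_nodal = if (length(anova_nodal) > 0)
                   do.call(rbind, anova_nodal) else NULL,
                 manifest = manifest),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d connectivity families, %s metric rows, %d NBS analyses (config %s)\n",
              length(x$connectivity),
              if (is.null(x$metrics)) 0 else nrow(x$metrics),
              length(x$nbs), x$manifest$config_hash))
  invisible(x)
}

#' Export a study result to tidy TSV files and a JSON manifest
#'
#' Writes `metrics_global.tsv`, `metrics_nodal.tsv`, `anova_global.tsv`,
#' `anova_nodal.tsv`, `nbs_components.tsv` (ROI labels from the shared
#' atlas table) and `manifest.json` into `out_dir`. Re-export is
#' idempotent.
#'
#' @param bundle A `study_result` from [run_study()].
#' @param out_dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
export_results <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <<- c(paths, p)
  }
  if (!is.null(bundle$metrics)) wr(bundle$metrics, "metrics_global.tsv")
  if (!is.null(bundle$nodal_metrics)) wr(bundle$nodal_metrics,
                                         "metrics_nodal.tsv")
  if (!is.null(bundle$anova_global)) wr(bundle$anova_global,
                                        "anova_global.tsv")
  if (!is.null(bundle$anova_nodal)) wr(bundle$anova_nodal, "anova_nodal.tsv")
  labels <- roi_table()$abbreviation
  nbs_rows <- list()
  for (mod in names(bundle$nbs)) {
    res <- bundle$nbs[[mod]]
    for (ci in seq_along(res$components)) {
      cp <- res$components[[ci]]
      n_lab <- max(cp$edges)
      lab <- if (n_lab <= length(labels)) labels else
        sprintf("roi%02d", seq_len(n_lab))
      nbs_rows[[length(nbs_rows) + 1]] <-
        data.frame(modality = mod, component = ci, size = cp$size,
                   p = cp$p, significant = cp$significant,
                   roi_a = lab[cp$edges[, 1]], roi_b = lab[cp$edges[, 2]])
    }
  }
  if (length(nbs_rows) > 0) wr(do.call(rbind, nbs_rows), "nbs_components.tsv")
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(bundle$manifest, mp, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null")
  paths <- c(paths, mp)
  invisible(paths)
}
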