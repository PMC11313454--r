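# End-to-end orchestration: simulate (or load) -> preprocess -> band power ->
# group statistics -> phase locking -> oscillation detection, with result
# tables and a parameter manifest.

#' Default pipeline configuration
#'
#' A single structured list mirroring every tunable default: the synthetic
#' generator settings, preprocessing choices, band definitions and window
#' grids, statistics and FDR settings.
#' @param seed integer seed used for every stochastic step
#' @return nested configuration list
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    synth = synth_config(rng_seed = seed, fs_raw = 500),
    preprocess = list(target_fs = 500, line_base_freq = 60,
                      line_alpha = 0.05, artifact_half_width = 0.025,
                      artifact_flank = 0.05, t0 = -0.5, duration = 2.5),
    bands = c("theta", "gamma", "hfa"),
    power = list(window_starts = power_window_starts(),
                 baseline_window = c(-0.5, -0.05), nw = 4,
                 min_concentration = 0.9),
    ipl = list(freqs = 3:8, nw = 4, n_cycles = 2, buffer = 0.45,
               window_starts = seq(0.1, 0.9, by = 0.1), window_width = 0.5),
    oscillations = list(window = c(0.05, 1.05), fit_range = c(3, 50),
                        peak_threshold = 3, width_limits = c(0.5, 12),
                        theta_range = c(3, 8), min_trials = 10,
                        absent_as_zero = TRUE,
                        rois = NULL),   # NULL = ROIs with theta in their label
    stats = list(alpha = 0.05, min_subjects = 5)
  )
}

#' Preprocess one subject's continuous recording into epochs
#'
#' Applies, in order: re-referencing (bipolar depth / common-average grid),
#' stimulation-artifact interpolation at every event on the continuous
#' record, multitaper F-test line-noise removal, downsampling to the target
#' rate, and epoching. Excluded channels never reach the output.
#'
#' @param recording a [continuous_recording()]
#' @param channels channel table rows for this recording
#' @param events event table rows for this recording
#' @param config pipeline configuration (see [default_config()])
#' @return list with the `epochs` and the derived `channels` table
#' @export
preprocess_subject <- function(recording, channels, events,
                               config = default_config()) {
  pp <- config$preprocess
  rr <- rereference(recording, channels)
  rec <- interpolate_artifacts(rr$recording, events,
                               half_width = pp$artifact_half_width,
                               flank = pp$artifact_flank)
  rec <- remove_line_noise_recording(rec, base_freq = pp$line_base_freq,
                                     alpha = pp$line_alpha)
  if (pp$target_fs < rec$fs) rec <- downsample(rec, pp$target_fs)
  epochs <- epoch_recording(rec, events, t0 = pp$t0, duration = pp$duration)
  list(epochs = epochs, channels = rr$channels)
}

#' Run the full analysis pipeline
#'
#' Simulates a dataset from `config$synth` (or uses a supplied one),
#' preprocesses every subject, and computes windowed band-power contrasts
#' with hierarchical group statistics, windowed ΔIPL statistics, and
#' region-level oscillation tests. All randomness derives from
#' `config$seed`; re-running with the same configuration reproduces the
#' outputs exactly.
#'
#' @param config pipeline configuration (see [default_config()])
#' @param dataset optional pre-generated dataset (output of
#'   [generate_dataset()] or loaded from disk); when `NULL` one is simulated
#' @param out_dir optional directory for result TSVs and the manifest JSON
#' @param stages character subset of `c("power", "ipl", "oscillations")`
#' @return list with `contact_stats`, `group` (per ROI x band x window),
#'   `ipl_contact`, `ipl_group`, `osc_contacts`, `osc_regions`, `manifest`
#' @export
run_pipeline <- function(config = default_config(), dataset = NULL,
                         out_dir = NULL,
                         stages = c("power", "ipl", "oscillations")) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.null(dataset)) dataset <- generate_dataset(config$synth)
  validate_channels(dataset$channels)
  validate_events(dataset$events)
  bands <- lapply(config$bands, band_spec)
  names(bands) <- config$bands
  alpha <- config$stats$alpha
  min_sub <- config$stats$min_subjects

  contact_rows <- list()
  ipl_rows <- list()
  osc_rows <- list()
  subjects <- names(dataset$recordings)
  for (si in seq_along(subjects)) {
    subj <- subjects[si]
    ch <- dataset$channels[dataset$channels$subject == subj, , drop = FALSE]
    ev <- dataset$events[dataset$events$subject == subj, , drop = FALSE]
    pre <- preprocess_subject(dataset$recordings[[subj]], ch, ev, config)
    epochs <- pre$epochs
    dch <- pre$channels

    if ("power" %in% stages) {
      for (bn in names(bands)) {
        bp <- band_power(epochs, bands[[bn]],
                         starts = config$power$window_starts,
                         baseline_window = config$power$baseline_window,
                         nw = config$power$nw,
                         min_concentration = config$power$min_concentration)
        tm <- suppressWarnings(power_tstats(bp))
        for (w in seq_along(bp$window_starts))
          contact_rows[[length(contact_rows) + 1L]] <- data.frame(
            subject = subj, contact = rownames(tm), roi = dch$roi,
            band = bn, target = ev$target[1],
            window_start = bp$window_starts[w], t = tm[, w],
            stringsAsFactors = FALSE, row.names = NULL)
      }
    }

    if ("ipl" %in% stages) {
      dipl <- with_seed(config$seed + si, compute_delta_ipl(
        epochs, freqs = config$ipl$freqs, nw = config$ipl$nw,
        n_cycles = config$ipl$n_cycles, buffer = config$ipl$buffer,
        baseline_window = config$power$baseline_window))
      wd <- windowed_delta_ipl(dipl, starts = config$ipl$window_starts,
                               width = config$ipl$window_width)
      for (w in seq_along(config$ipl$window_starts))
        ipl_rows[[length(ipl_rows) + 1L]] <- data.frame(
          subject = subj, contact = rownames(wd), roi = dch$roi,
          target = ev$target[1],
          window_start = config$ipl$window_starts[w], delta = wd[, w],
          stringsAsFactors = FALSE, row.names = NULL)
    }

    if ("oscillations" %in% stages) {
      oc <- config$oscillations
      rois <- oc$rois %||% unique(dch$roi[grepl("theta", dch$roi)])
      idx <- which(dch$roi %in% rois)
      if (length(idx)) {
        os <- oscillation_stats(epochs, idx, min_trials = oc$min_trials,
                                absent_as_zero = oc$absent_as_zero,
                                window = oc$window,
                                theta_range = oc$theta_range,
                                fit_range = oc$fit_range,
                                peak_threshold = oc$peak_threshold,
                                width_limits = oc$width_limits)
        if (!is.null(os)) {
          os$subject <- subj
          os$roi <- dch$roi[idx]
          osc_rows[[length(osc_rows) + 1L]] <- os
        }
      }
    }
  }

  res <- list(manifest = list(config = config, subjects = subjects,
                              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))

  if ("power" %in% stages) {
    res$contact_stats <- do.call(rbind, c(contact_rows, make.row.names = FALSE))
    grp <- list()
    for (bn in names(bands)) {
      sub <- res$contact_stats[res$contact_stats$band == bn, , drop = FALSE]
      g <- group_effects(sub, alpha = alpha, min_subjects = min_sub)
      g$band <- bn
      grp[[bn]] <- g
    }
    res$group <- do.call(rbind, c(grp, make.row.names = FALSE))
  }
  if ("ipl" %in% stages) {
    res$ipl_contact <- do.call(rbind, c(ipl_rows, make.row.names = FALSE))
    stats_df <- res$ipl_contact
    stats_df$t <- stats_df$delta          # group_effects models the values
    res$ipl_group <- group_effects(stats_df, alpha = alpha,
                                   min_subjects = min_sub)
    names(res$ipl_group)[names(res$ipl_group) == "intercept"] <- "intercept"
  }
  if ("oscillations" %in% stages && length(osc_rows)) {
    res$osc_contacts <- do.call(rbind, c(osc_rows, make.row.names = FALSE))
    regs <- unique(res$osc_contacts$roi)
    res$osc_regions <- do.call(rbind, lapply(regs, function(r) {
      d <- res$osc_contacts$diff[res$osc_contacts$roi == r]
      if (length(d) < 2L) return(NULL)
      tt <- region_oscillation_test(d)
      data.frame(roi = r, t = tt$t, p = tt$p, n_contacts = tt$n,
                 degenerate = tt$degenerate, stringsAsFactors = FALSE)
    }))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tables <- Filter(Negate(is.null),
                     res[intersect(c("contact_stats", "group", "ipl_contact",
                                     "ipl_group", "osc_contacts", "osc_regions"),
                                   names(res))])
    write_results(tables, out_dir)
    jsonlite::write_json(manifest_safe(res$manifest),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  res
}

# strip non-serializable bits (profiles are classed lists; unclass them)
manifest_safe <- function(m) {
  m$config$synth <- lapply(unclass(m$config$synth), function(x)
    if (is.list(x)) lapply(x, unclass) else x)
  m
}
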