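# Pipeline orchestration: configuration, validation, per-participant
# processing with on-disk caching, group-level screening and TSV writers.

#' Bundled demonstration configuration
#'
#' A run configuration emulating the study's shape: several simulated
#' participants, conditions A ("objects") and D ("interactions"), theta- and
#' beta-band occipital coupling, a mu-rhythm ERD and a condition-specific
#' early ERS over the left somatosensory set, and an asymmetric
#' parieto-occipital ERP.  Sizes default to a desk-scale profile
#' (`n_boot = 1000`); pass larger numbers for the full-scale analysis.
#'
#' @param n_participants simulated participants (outermost loop).
#' @param n_trials_per_condition trials per condition per participant.
#' @param n_boot bootstrap/permutation resamples for the screening stage.
#' @param time_stride screen every n-th PLV sample.
#' @param seed global seed; per-participant seeds are derived from it.
#' @return object of class `run_config` (a named list).
#' @export
demo_config <- function(n_participants = 19, n_trials_per_condition = 30,
                        n_boot = 1000, time_stride = 25, seed = 1L) {
  structure(list(
    profile = "demo",
    seed = as.integer(seed),
    n_participants = as.integer(n_participants),
    montage = "paper64",
    synth = list(
      sampling_rate = 500,
      n_trials_per_condition = as.integer(n_trials_per_condition),
      conditions = c("A", "D"),
      epoch_window = c(-0.2, 1.0),
      noise = list(alpha = 1, amplitude = 10),
      blink_rate = 6, outlier_trial_fraction = 0.02,
      coupling = list(
        list(target_channels = c("C3", "C4", "P4"), band_center = 5.5,
             concentration = 4, window = c(0.15, 0.40),
             conditions = c("A", "D"), amplitude = 15),
        list(target_channels = c("F5", "P6"), band_center = 20,
             concentration = 4, window = c(0.50, 0.90),
             conditions = "D", amplitude = 15)),
      power = list(
        list(channels = c("C5", "CP3", "CP5"), band = c(8, 13), gain = 0.5,
             window = c(0.35, 0.75), conditions = c("A", "D"),
             amplitude = 20),
        list(channels = c("C5", "CP3", "CP5"), band = c(8, 13), gain = 1.5,
             window = c(0.10, 0.20), conditions = "D", amplitude = 20)),
      erp = list(
        list(channels = c("PO7", "PO8"), latency = 0.26, width = 0.03,
             amplitude = c(PO7 = 3, PO8 = 6), conditions = "D"),
        list(channels = c("PO7", "PO8"), latency = 0.26, width = 0.03,
             amplitude = c(PO7 = 4, PO8 = 4), conditions = "A"))),
    preprocess = list(low = 1, high = 30, ica = TRUE,
                      eog_channels = c("Fp1", "Fpz", "Fp2"),
                      eog_threshold = 0.7, reject_uv = 100,
                      tmin = -0.2, tmax = 1.0),
    connectivity = list(seed_region = "OCC_SEED", alpha = 0.05,
                        n_boot = as.integer(n_boot), convention = "squared",
                        time_stride = as.integer(time_stride),
                        direction = "greater"),
    spectral = list(freqs = seq(4, 28, by = 2), mu_band = c(8, 13),
                    roi = "LS", snapshot_time = 0.4,
                    erp_left = "PO7", erp_right = "PO8",
                    erp_window = c(0.246, 0.300))),
    class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose top-level keys mirror [demo_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- unclass(demo_config())
  for (nm in names(cfg)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(cfg[[nm]])) {
      utils::modifyList(base[[nm]], cfg[[nm]])
    } else {
      cfg[[nm]]
    }
  }
  structure(base, class = "run_config")
}

#' Validate a run configuration
#'
#' Collects every configuration error without computing anything.
#'
#' @param config a `run_config`.
#' @return character vector of error messages (empty when valid).
#' @export
validate_config <- function(config) {
  errs <- character(0)
  add <- function(msg) errs <<- c(errs, msg)
  m <- tryCatch(generate_montage(config$montage),
                error = function(e) { add(conditionMessage(e)); NULL })
  cn <- config$connectivity
  if (!is.null(cn$alpha) && !(cn$alpha > 0 && cn$alpha < 1)) {
    add("alpha must be in (0,1)")
  }
  if (!is.null(cn$n_boot) && cn$n_boot < 1) add("n_boot must be >= 1")
  if (is.null(config$n_participants) || config$n_participants < 1) {
    add("n_participants must be >= 1")
  }
  pp <- config$preprocess
  if (!is.null(pp) && pp$tmin >= pp$tmax) add("tmin must precede tmax")
  if (!is.null(m)) {
    regs <- montage_regions(m)
    if (!is.null(cn$seed_region) && !(cn$seed_region %in% names(regs))) {
      add(paste0("unknown seed region ", cn$seed_region))
    }
    sp <- config$spectral
    roi_ch <- if (!is.null(sp$roi)) {
      if (sp$roi %in% names(regs)) regs[[sp$roi]] else sp$roi
    } else {
      character(0)
    }
    bad <- setdiff(c(roi_ch, sp$erp_left, sp$erp_right), m$channel)
    if (length(bad)) {
      add(paste0("unknown electrode(s) in spectral config: ",
                 paste(bad, collapse = ", ")))
    }
    for (cs in config$synth$coupling) {
      bad <- setdiff(cs$target_channels, m$channel)
      if (length(bad)) add(paste0("unknown coupling target(s): ",
                                  paste(bad, collapse = ", ")))
    }
  }
  errs
}

# Build the synth_config of one participant.
participant_synth_config <- function(config, montage, participant) {
  s <- config$synth
  synth_config(
    sampling_rate = s$sampling_rate %||% 500,
    montage = montage,
    n_trials_per_condition = s$n_trials_per_condition,
    conditions = s$conditions,
    session = sprintf("P%02d", participant),
    epoch_window = s$epoch_window %||% c(-0.2, 1.0),
    noise = s$noise %||% list(alpha = 1, amplitude = 10),
    coupling_specs = lapply(s$coupling %||% list(),
                            function(a) do.call(coupling_spec, a)),
    power_specs = lapply(s$power %||% list(),
                         function(a) do.call(power_mod_spec, a)),
    erp_specs = lapply(s$erp %||% list(),
                       function(a) do.call(erp_spec, a)),
    blink_rate = s$blink_rate %||% 0,
    outlier_trial_fraction = s$outlier_trial_fraction %||% 0,
    seed = config$seed + 1000L * participant)
}

# Keep a subset of epochs (used to propagate broadband rejection decisions
# into the band-filtered copies).
subset_epochs <- function(epochs, keep) {
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  epochs$conditions <- epochs$conditions[keep]
  epochs$sessions <- epochs$sessions[keep]
  epochs
}

# One participant: synth -> preprocess -> band split -> PLV / ERSP / ERP.
process_participant <- function(config, montage, participant) {
  pp <- config$preprocess
  cn <- config$connectivity
  sp <- config$spectral
  scfg <- participant_synth_config(config, montage, participant)
  rec <- generate_recording(scfg)
  rec <- rereference_common_average(rec)
  rec <- bandpass_zero_phase(rec, pp$low %||% 1, pp$high %||% 30)
  if (isTRUE(pp$ica)) {
    dec <- amuse_decompose(rec, lag = pp$ica_lag %||% 1L)
    rec <- remove_eog_components(dec, rec,
                                 eog_channels = pp$eog_channels %||%
                                   c("Fp1", "Fpz", "Fp2"),
                                 threshold = pp$eog_threshold %||% 0.7)
  }
  epochs <- extract_epochs(rec, pp$tmin %||% -0.2, pp$tmax %||% 1.0)
  epochs <- reject_amplitude(epochs, pp$reject_uv %||% 100)

  conds <- config$synth$conditions
  band_epochs <- filter_bands(epochs)
  plv <- lapply(band_epochs, function(band_ep) {
    lapply(stats::setNames(conds, conds), function(cc) {
      occipital_plv(subset_epochs(band_ep, band_ep$conditions == cc),
                    montage, cn$seed_region %||% "OCC_SEED",
                    cn$convention %||% "squared")
    })
  })

  ersp_by_cond <- lapply(stats::setNames(conds, conds), function(cc) {
    ersp(epochs, freqs = sp$freqs, conditions = cc)
  })

  erp <- erp_lateralization(epochs, sp$erp_left %||% "PO7",
                            sp$erp_right %||% "PO8",
                            sp$erp_window %||% c(0.246, 0.300))
  list(participant = participant,
       rejection_log = epochs$rejection_log,
       n_epochs = dim(epochs$data)[1],
       times = epochs$times,
       plv = plv,
       ersp = ersp_by_cond,
       erp_window_means = stats::setNames(erp$window_stats$mean,
                                          erp$window_stats$condition),
       erp_difference = erp$difference)
}

#' Run the full analysis pipeline
#'
#' Orchestrates synthesis, preprocessing, band splitting, occipital-seeded
#' PLV with ePLV screening, ERSP with mu-rhythm ERD/ERS and a Laplacian
#' topography snapshot, and the PO7-PO8 ERP lateralization analysis, for
#' every simulated participant; writes all tables and a manifest under
#' `outdir`.  Per-participant intermediates are cached in `outdir/cache` so
#' an interrupted run resumes without recomputation; fixed-seed stages are
#' byte-reproducible.
#'
#' @param config a `run_config` (see [demo_config], [read_run_config]).
#' @param outdir output directory (created if needed).
#' @param use_cache reuse cached per-participant intermediates.
#' @param figures write topography PNGs (optional; tables are always
#'   written).
#' @return object of class `eplv_results`, invisibly: masks, connection
#'   summaries, ERSP/ERP group results and the manifest.
#' @export
run_pipeline <- function(config, outdir, use_cache = TRUE, figures = FALSE) {
  errs <- validate_config(config)
  if (length(errs)) {
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cache_dir <- file.path(outdir, "cache")
  dir.create(cache_dir, showWarnings = FALSE)
  montage <- generate_montage(config$montage)
  cn <- config$connectivity
  sp <- config$spectral
  conds <- config$synth$conditions

  stage <- "participants"
  parts <- vector("list", config$n_participants)
  for (i in seq_len(config$n_participants)) {
    cpath <- file.path(cache_dir, sprintf("participant_%02d.rds", i))
    parts[[i]] <- if (use_cache && file.exists(cpath)) {
      readRDS(cpath)
    } else {
      res <- tryCatch(process_participant(config, montage, i),
                      error = function(e) {
                        stop("stage ", stage, " failed for participant ", i,
                             ": ", conditionMessage(e), call. = FALSE)
                      })
      saveRDS(res, cpath)
      res
    }
  }

  ## rejection report
  rej <- do.call(rbind, lapply(parts, function(p) {
    cbind(participant = p$participant, p$rejection_log)
  }))
  utils::write.table(rej, file.path(outdir, "rejection_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## group connectivity screen
  stage <- "connectivity"
  times <- parts[[1L]]$times
  masks <- list()
  summaries <- list()
  band_names <- names(parts[[1L]]$plv)
  k <- 0L
  for (b in band_names) {
    for (cc in conds) {
      k <- k + 1L
      plv_list <- lapply(parts, function(p) p$plv[[b]][[cc]])
      mask <- screen_eplv(plv_list, times = times,
                          alpha = cn$alpha %||% 0.05,
                          n_boot = cn$n_boot %||% 1000,
                          seed = config$seed + 7919L * k,
                          time_stride = cn$time_stride %||% 1L,
                          direction = cn$direction %||% "greater")
      masks[[paste(b, cc, sep = "_")]] <- mask
      cs <- connection_summary(mask)
      summaries[[paste(b, cc, sep = "_")]] <-
        cbind(band = b, condition = cc, cs$counts,
              peak_time = cs$peak_time)
      t_cols <- match(mask$times, times)
      per_part <- do.call(rbind, lapply(seq_along(plv_list), function(i) {
        data.frame(participant = i, band = b, condition = cc,
                   electrode = rep(rownames(plv_list[[i]]), length(t_cols)),
                   time = rep(mask$times, each = nrow(plv_list[[i]])),
                   plv = as.vector(plv_list[[i]][, t_cols]))
      }))
      utils::write.table(per_part,
                         file.path(outdir, sprintf("plv_%s_%s.tsv", b, cc)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      mean_plv <- Reduce(`+`, plv_list) / length(plv_list)
      long <- data.frame(
        band = b, condition = cc,
        electrode = rep(rownames(mask$significant), ncol(mask$significant)),
        time = rep(mask$times, each = nrow(mask$significant)),
        mean_plv = as.vector(mean_plv[, match(mask$times, times)]),
        p = as.vector(mask$p),
        significant = as.vector(mask$significant))
      utils::write.table(long,
                         file.path(outdir, sprintf("eplv_mask_%s_%s.tsv", b, cc)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  conn <- do.call(rbind, summaries)
  utils::write.table(conn, file.path(outdir, "connection_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## group ERSP
  stage <- "spectral"
  regs <- montage_regions(montage)
  roi <- if (sp$roi %in% names(regs)) regs[[sp$roi]] else sp$roi
  ersp_group <- list()
  roi_rows <- list()
  topo_rows <- list()
  ers_windows <- list()
  for (cc in conds) {
    maps <- lapply(parts, function(p) p$ersp[[cc]])
    gvals <- Reduce(`+`, lapply(maps, `[[`, "values")) / length(maps)
    gmap <- maps[[1L]]
    gmap$values <- gvals
    ersp_group[[cc]] <- gmap
    mu <- mu_erd_ers(gmap, roi, sp$mu_band %||% c(8, 13))
    roi_rows[[cc]] <- data.frame(condition = cc, time = mu$times,
                                 ersp_db = mu$timecourse)
    ## per-participant ROI means inside the group-level ERS window, for the
    ## condition contrast
    wsel <- abs(gmap$times - mu$ers$time) <= 0.05
    fsel <- gmap$freqs >= (sp$mu_band %||% c(8, 13))[1] &
      gmap$freqs <= (sp$mu_band %||% c(8, 13))[2]
    ers_windows[[cc]] <- vapply(maps, function(m) {
      mean(m$values[roi, fsel, wsel], na.rm = TRUE)
    }, numeric(1))
    ## Laplacian-sharpened topography snapshot at the configured time
    snap_i <- which.min(abs(gmap$times - (sp$snapshot_time %||% 0.4)))
    topo <- apply(gvals[, fsel, snap_i, drop = FALSE], 1L, mean)
    lap <- surface_laplacian(topo, montage)
    topo_rows[[cc]] <- data.frame(condition = cc, channel = names(topo),
                                  ersp_db = unname(topo),
                                  laplacian = unname(lap))
    if (figures) {
      grDevices::png(file.path(outdir, sprintf("topo_ersp_%s.png", cc)),
                     600, 600)
      plot_topography(lap, montage,
                      main = sprintf("mu ERSP Laplacian, condition %s", cc))
      grDevices::dev.off()
    }
  }
  utils::write.table(do.call(rbind, roi_rows),
                     file.path(outdir, "ersp_roi_timecourse.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(do.call(rbind, topo_rows),
                     file.path(outdir, "ersp_topography_laplacian.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ers_test <- if (length(conds) >= 2L && length(parts) >= 2L) {
    permutation_test_independent(ers_windows[[conds[2L]]],
                                 ers_windows[[conds[1L]]],
                                 n_resamples = cn$n_boot %||% 1000,
                                 seed = config$seed + 104729L)
  } else {
    NULL
  }

  ## group ERP lateralization
  stage <- "erp"
  erp_means <- do.call(rbind, lapply(parts, function(p) p$erp_window_means))
  erp_groups <- lapply(stats::setNames(conds, conds),
                       function(cc) erp_means[, cc])
  erp_anova <- if (length(conds) >= 2L && nrow(erp_means) >= 2L) {
    anova_one_way(erp_groups)
  } else {
    NULL
  }
  grand_diff <- Reduce(`+`, lapply(parts, `[[`, "erp_difference")) /
    length(parts)
  erp_long <- data.frame(
    condition = rep(rownames(grand_diff), ncol(grand_diff)),
    time = rep(times, each = nrow(grand_diff)),
    difference_uv = as.vector(grand_diff))
  utils::write.table(erp_long, file.path(outdir, "erp_difference.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ws <- data.frame(condition = conds,
                   mean = vapply(erp_groups, mean, numeric(1)),
                   se = vapply(erp_groups, function(g)
                     stats::sd(g) / sqrt(length(g)), numeric(1)),
                   n = vapply(erp_groups, length, integer(1)))
  utils::write.table(ws, file.path(outdir, "erp_window_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("eegplv")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    profile = config$profile,
    n_participants = config$n_participants,
    n_boot = cn$n_boot %||% 1000,
    config_hash = config_hash(config))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res <- structure(list(outdir = outdir, masks = masks,
                        connection_summary = conn,
                        ersp = ersp_group, ers_test = ers_test,
                        erp_anova = erp_anova, erp_window_stats = ws,
                        manifest = manifest),
                   class = "eplv_results")
  invisible(res)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA, force = TRUE), f)
  unname(tools::md5sum(f))
}

#' @export
print.eplv_results <- function(x, ...) {
  cat("<eplv_results> written to ", x$outdir, "\n", sep = "")
  cat("masks:", paste(names(x$masks), collapse = ", "), "\n")
  if (!is.null(x$erp_anova)) {
    cat("ERP lateralization ANOVA: F =", signif(x$erp_anova$F, 4),
        ", p =", signif(x$erp_anova$p, 4), "\n")
  }
  invisible(x)
}

#' Scalp topography plot
#'
#' Draws per-electrode values as scaled, colour-coded discs on the montage
#' layout (red positive, blue negative).
#'
#' @param values named numeric vector, one value per channel.
#' @param montage an [eeg_montage].
#' @param main plot title.
#' @export
plot_topography <- function(values, montage, main = "") {
  idx <- match(names(values), montage$channel)
  stopifnot(!anyNA(idx))
  graphics::plot(NA, xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.2), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", main = main)
  th <- seq(0, 2 * pi, length.out = 200)
  graphics::lines(cos(th), sin(th))
  graphics::lines(c(-0.08, 0, 0.08), c(0.995, 1.08, 0.995))  # nose
  s <- max(abs(values), 1e-12)
  cols <- ifelse(values >= 0, "firebrick", "steelblue")
  graphics::points(montage$x[idx], montage$y[idx],
                   cex = 0.5 + 2.5 * abs(values) / s, pch = 19, col = cols)
  graphics::text(montage$x[idx], montage$y[idx] + 0.06,
                 names(values), cex = 0.5)
  invisible(values)
}
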