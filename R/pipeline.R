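#' Per-subject ERPs from a cohort
#'
#' Applies the analysis front end to every subject and condition: keep
#' correctly detected target trials with no target among the previous
#' `lookback` word positions, baseline, and average into ERPs.  With
#' `source = "nontarget"` the matched non-target epochs are averaged instead
#' (no detection/lookback filter applies).
#'
#' @param cohort a [generate_cohort()] result (or an object of the same
#'   shape built from loaded data).
#' @param baseline_mode passed to [apply_baseline()].
#' @param source `"target"` or `"nontarget"`.
#' @param lookback repetition-priming lookback (default 4).
#' @return nested list: `erps[[subject_id]][[condition]]` is an [erp()].
#' @export
cohort_erps <- function(cohort, baseline_mode = "post_onset_50",
                        source = c("target", "nontarget"), lookback = 4) {
  source <- match.arg(source)
  pool <- if (source == "target") cohort$epochs else cohort$nontarget_epochs
  stop_if_not(!is.null(pool), "cohort has no %s epochs", source)
  out <- list()
  for (sid in names(pool)) {
    out[[sid]] <- list()
    for (cond in names(pool[[sid]])) {
      ep <- pool[[sid]][[cond]]$eeg
      if (source == "target") {
        keep_trials <- select_target_trials(cohort$events[[sid]][[cond]],
                                            lookback = lookback)
        rows <- match(keep_trials, attr(ep, "trial_index"))
        rows <- rows[!is.na(rows)]
        stop_if_not(length(rows) > 0,
                    "no analyzable target trials for %s/%s", sid, cond)
      } else {
        rows <- seq_len(dim(ep$data)[1])
      }
      out[[sid]][[cond]] <- average_erp(apply_baseline(ep, baseline_mode), rows)
    }
  }
  out
}

#' Per-subject classification maps for a feature mode
#'
#' Builds, for every subject, the channels x samples map that feeds the
#' classifier under the requested feature mode: the primary
#' scrambled-minus-comprehension difference-CSD, or one of the control
#' signals (difference-ERP without CSD, a single condition's CSD, or the
#' difference-CSD of non-target words).
#'
#' @param cohort a [generate_cohort()] result.
#' @param feature_mode see [feature_table()].
#' @param baseline_mode see [apply_baseline()].
#' @param params [spline_params()] for the CSD transform.
#' @return list with `maps` (named per-subject list), `labels` (good/poor
#'   factor), `gh` (the [build_gh_matrices()] used, NULL for ERP mode).
#' @export
cohort_maps <- function(cohort, feature_mode = "difference_csd",
                        baseline_mode = "post_onset_50",
                        params = spline_params()) {
  feature_mode <- match.arg(feature_mode,
                            c("difference_csd", "difference_erp", "scrambled_csd",
                              "comprehension_csd", "nontarget_difference_csd"))
  src <- if (feature_mode == "nontarget_difference_csd") "nontarget" else "target"
  erps <- cohort_erps(cohort, baseline_mode, source = src)
  gh <- NULL
  if (feature_mode != "difference_erp") gh <- build_gh_matrices(cohort$montage, params)
  maps <- lapply(erps, function(pair) {
    switch(feature_mode,
      difference_erp = {
        d <- pair$scrambled
        d$values <- pair$scrambled$values - pair$comprehension$values
        d$condition <- "difference"
        d
      },
      scrambled_csd = csd_transform(pair$scrambled, gh),
      comprehension_csd = csd_transform(pair$comprehension, gh),
      difference_csd = ,
      nontarget_difference_csd = difference_csd(csd_transform(pair$scrambled, gh),
                                                csd_transform(pair$comprehension, gh)))
  })
  labels <- factor(cohort$subjects$group, levels = c("poor", "good"))
  names(maps) <- cohort$subjects$subject_id
  list(maps = maps, labels = labels, gh = gh)
}

#' Pipeline run configuration
#'
#' Bundles every stage's configuration.  `cohort` may be a full
#' [cohort_config()] or a list of overrides applied to the defaults; the
#' global `seed` re-seeds the cohort and the titration unless those configs
#' set their own.
#'
#' @param cohort [cohort_config()] or list of overrides.
#' @param bins a [bin_spec()].
#' @param titration a [titration_config()].
#' @param spline a [spline_params()].
#' @param feature_mode,baseline_mode analysis variants (defaults
#'   `difference_csd`, `post_onset_50`).
#' @param index_site,index_bin_ms CSD-index site and bin (AFz, 400-500 ms).
#' @param input_dir read a written dataset instead of simulating (optional).
#' @param output_dir where to write the report bundle (optional).
#' @param seed global seed; fans out to stages via [derive_seed()].
#' @return object of class `run_config`.
#' @export
run_config <- function(cohort = list(), bins = bin_spec(),
                       titration = titration_config(),
                       spline = spline_params(),
                       feature_mode = "difference_csd",
                       baseline_mode = "post_onset_50",
                       index_site = "AFz", index_bin_ms = c(400, 500),
                       input_dir = NULL, output_dir = NULL, seed = 1) {
  if (!inherits(cohort, "cohort_config")) {
    cohort <- do.call(cohort_config,
                      utils::modifyList(list(seed = derive_seed(seed, 71)), cohort))
  }
  titration$seed <- as.integer(titration$seed %||% derive_seed(seed, 72))
  structure(list(cohort = cohort, bins = bins, titration = titration,
                 spline = spline, feature_mode = feature_mode,
                 baseline_mode = baseline_mode, index_site = index_site,
                 index_bin_ms = index_bin_ms, input_dir = input_dir,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [run_config()] arguments; `cohort`, `bins`,
#' `titration` and `spline` are mappings of overrides for the respective
#' constructors.
#'
#' @param path YAML file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  stop_if_not(file.exists(path), "no such config file: %s", path)
  y <- yaml::read_yaml(path)
  args <- list()
  args$seed <- y$seed %||% 1
  args$cohort <- y$cohort %||% list()
  if (!is.null(y$bins)) args$bins <- do.call(bin_spec, y$bins)
  if (!is.null(y$titration)) {
    args$titration <- do.call(titration_config,
                              utils::modifyList(list(seed = derive_seed(args$seed, 72)),
                                                y$titration))
  }
  if (!is.null(y$spline)) args$spline <- do.call(spline_params, y$spline)
  for (k in c("feature_mode", "baseline_mode", "index_site", "input_dir",
              "output_dir")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  if (!is.null(y$index_bin_ms)) args$index_bin_ms <- as.numeric(y$index_bin_ms)
  do.call(run_config, args)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> epoch/baseline/average -> CSD -> difference ->
#' bin -> two-stage titration with permutation null -> index statistics.
#' When `config$output_dir` is set the bundle is written there:
#' `classification_report.json`, `subjects.csv`, `stats.json`,
#' `ground_truth.json` (simulated data only) and a human-readable
#' `summary.txt` listing every default in force.  All numbers in the bundle
#' are produced by the module functions; nothing is recomputed at reporting
#' time.
#'
#' @param config a [run_config()].
#' @return the report bundle (list), invisibly: `cohort`, `report`
#'   (a [classify_bins()] result), `index` (per-subject CSD index),
#'   `correlation`, `unpack`, `behavior`, `order`, `saccades`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  cohort <- stage("simulate", {
    if (!is.null(config$input_dir)) load_cohort(config$input_dir, config$cohort)
    else generate_cohort(config$cohort)
  })
  mm <- stage("csd", cohort_maps(cohort, config$feature_mode,
                                 config$baseline_mode, config$spline))
  feats <- stage("bin_features",
                 bin_features(mm$maps, mm$labels, config$bins, config$feature_mode))
  report <- stage("classify", classify_bins(feats, config$titration))

  # index statistics always use the primary difference-CSD maps
  dmaps <- if (config$feature_mode == "difference_csd") mm
           else stage("csd", cohort_maps(cohort, "difference_csd",
                                         config$baseline_mode, config$spline))
  index <- stage("index", extract_csd_index(dmaps$maps, config$index_site,
                                            config$index_bin_ms))
  corr <- stage("stats", correlate_with_ellipse(index$csd_index,
                                                cohort$subjects$score))
  percond <- stage("stats", {
    sc <- cohort_maps(cohort, "scrambled_csd", config$baseline_mode, config$spline)
    co <- cohort_maps(cohort, "comprehension_csd", config$baseline_mode, config$spline)
    data.frame(subject_id = cohort$subjects$subject_id,
               scrambled = extract_csd_index(sc$maps, config$index_site,
                                             config$index_bin_ms)$csd_index,
               comprehension = extract_csd_index(co$maps, config$index_site,
                                                 config$index_bin_ms)$csd_index)
  })
  unpack <- stage("stats", condition_group_unpack(percond, cohort$subjects$group))
  behavior <- stage("stats", list(
    rt = behavioral_anova(data.frame(subject_id = cohort$subjects$subject_id,
                                     scrambled = cohort$subjects$rt_scrambled,
                                     comprehension = cohort$subjects$rt_comprehension),
                          cohort$subjects$group),
    error = behavioral_anova(data.frame(subject_id = cohort$subjects$subject_id,
                                        scrambled = cohort$subjects$err_scrambled,
                                        comprehension = cohort$subjects$err_comprehension),
                             cohort$subjects$group)))
  ord <- stage("stats", order_analysis(index$csd_index, cohort$subjects$score,
                                       cohort$subjects$order))
  sacc <- stage("stats", {
    do.call(rbind, lapply(names(cohort$epochs), function(sid) {
      do.call(rbind, lapply(names(cohort$epochs[[sid]]), function(cond) {
        cs <- count_saccades(cohort$epochs[[sid]][[cond]]$eog)
        data.frame(subject_id = sid, condition = cond,
                   mean_saccades = cs$mean)
      }))
    }))
  })

  bundle <- list(cohort = cohort, report = report, index = index,
                 correlation = corr, unpack = unpack, behavior = behavior,
                 order = ord, saccades = sacc, config = config)
  if (!is.null(config$output_dir)) write_bundle(bundle, config$output_dir)
  invisible(bundle)
}

report_json <- function(report) {
  list(feature_mode = report$feature_mode,
       summary = report$summary,
       best_bin = report$best_bin, best_site = report$best_site,
       per_bin = lapply(report$per_bin, function(b) {
         list(mean_accuracy = b$mean_accuracy, sd_accuracy = b$sd_accuracy,
              null_mean = b$null_mean, null_sd = b$null_sd,
              weights = as.list(b$weights), top_sites = b$top_sites,
              stats = b$stats)
       }))
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report_json(bundle$report),
                       file.path(dir, "classification_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  subj <- merge(bundle$cohort$subjects, bundle$index, by = "subject_id")
  write.csv(subj, file.path(dir, "subjects.csv"), row.names = FALSE)
  stats <- list(correlation = bundle$correlation,
                condition_group = bundle$unpack[c("cell_means", "paired_t", "interaction")],
                behavior = bundle$behavior,
                order = bundle$order[c("order_t")],
                saccades = bundle$saccades)
  jsonlite::write_json(stats, file.path(dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  if (!is.null(bundle$cohort$ledger)) {
    jsonlite::write_json(bundle$cohort$ledger, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  }
  cfg <- bundle$config
  summ <- c(
    "csdread pipeline summary",
    sprintf("seed: %d  feature_mode: %s  baseline_mode: %s",
            cfg$seed, cfg$feature_mode, cfg$baseline_mode),
    sprintf("cohort: %d subjects, %d/%d targets/words, fs %g Hz, effect %g uV at %s [%g, %g) ms",
            cfg$cohort$n_subjects, cfg$cohort$n_targets, cfg$cohort$n_words,
            cfg$cohort$fs_hz, cfg$cohort$effect_amplitude_uv,
            cfg$cohort$effect_site, cfg$cohort$effect_window_ms[1],
            cfg$cohort$effect_window_ms[2]),
    sprintf("spline: m=%d lambda=%g n_terms=%d head_radius=%g cm (CSD in uV/cm^2, sources positive, 1/r^2 scaling)",
            cfg$spline$m, cfg$spline$lambda, cfg$spline$n_terms,
            cfg$spline$head_radius_cm),
    sprintf("bins: %g-ms bins hopping %g ms over [%g, %g] ms (%d bins)",
            cfg$bins$width_ms, cfg$bins$hop_ms, cfg$bins$start_ms,
            cfg$bins$end_ms, nrow(cfg$bins$bins)),
    sprintf("titration: %d trees, %.0f%% per-tree training subjects, top %d sites, %d runs, %d null runs",
            cfg$titration$n_trees, 100 * cfg$titration$train_fraction,
            cfg$titration$top_k_sites, cfg$titration$n_runs,
            cfg$titration$n_null_runs),
    sprintf("target-trial filter: correctly detected, no target in previous 4 word positions"),
    sprintf("index: %s over [%g, %g) ms", cfg$index_site,
            cfg$index_bin_ms[1], cfg$index_bin_ms[2]),
    sprintf("best bin: %s ms (mean accuracy %.3f, null %.3f); top site %s",
            bundle$report$best_bin,
            max(bundle$report$summary$mean_accuracy),
            bundle$report$summary$null_mean[which.max(bundle$report$summary$mean_accuracy)],
            bundle$report$best_site),
    sprintf("index-score correlation: r_all %.3f (t(%d) = %.2f), trimmed %.3f (t(%d) = %.2f, %d outliers)",
            bundle$correlation$r_all, bundle$correlation$df_all,
            bundle$correlation$t_all, bundle$correlation$r_trimmed,
            bundle$correlation$df_trimmed, bundle$correlation$t_trimmed,
            length(bundle$correlation$outlier_ids)))
  writeLines(summ, file.path(dir, "summary.txt"))
  invisible(dir)
}

#' Load a written synthetic dataset
#'
#' Reads a dataset written by [generate_cohort()] in continuous mode:
#' `montage.sfp`, `subjects.csv`, per-subject EDF recordings and events TSVs
#' — and re-cuts the target epochs, reconstructing a cohort object for
#' [run_pipeline()].
#'
#' @param dir dataset directory.
#' @param cfg the [cohort_config()] the data were generated with (sampling
#'   rate and window are taken from it).
#' @return a `cohort`-shaped list (without ground-truth ledger unless
#'   `ground_truth.json` is present).
#' @export
load_cohort <- function(dir, cfg = cohort_config()) {
  stop_if_not(dir.exists(dir), "no such dataset directory: %s", dir)
  mont <- read_sfp(file.path(dir, "montage.sfp"))
  subjects <- utils::read.csv(file.path(dir, "subjects.csv"))
  events <- list()
  epochs <- list()
  for (sid in subjects$subject_id) {
    events[[sid]] <- list()
    epochs[[sid]] <- list()
    for (cond in c("scrambled", "comprehension")) {
      ev <- read_events_tsv(file.path(dir, sprintf("%s_%s_events.tsv", sid, cond)))
      rec <- read_edf(file.path(dir, sprintf("%s_%s.edf", sid, cond)))
      fs <- attr(rec, "fs_hz")
      eeg <- rec[mont$labels, , drop = FALSE]
      attr(eeg, "fs_hz") <- fs
      eog <- rec[intersect(eog_channels, rownames(rec)), , drop = FALSE]
      attr(eog, "fs_hz") <- fs
      tgt <- ev$trial_index[ev$is_target]
      events[[sid]][[cond]] <- ev
      epochs[[sid]][[cond]] <- list(
        eeg = extract_epochs(eeg, ev, tgt, cfg$window_ms, fs, sid, cond),
        eog = extract_epochs(eog, ev, tgt, cfg$window_ms, fs, sid, cond),
        saccade_counts = NULL)
    }
  }
  ledger <- NULL
  gt <- file.path(dir, "ground_truth.json")
  if (file.exists(gt)) ledger <- jsonlite::read_json(gt, simplifyVector = TRUE)
  structure(list(config = cfg, montage = mont, subjects = subjects,
                 events = events, epochs = epochs, nontarget_epochs = NULL,
                 ledger = ledger),
            class = "cohort")
}
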