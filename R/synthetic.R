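#' Synthetic-cohort configuration
#'
#' Defines the simulated study: a 28-subject cohort reads a 1182-word stream
#' (one word every 500 ms: 300 ms on + 200 ms off) in a scrambled and a
#' comprehension condition while detecting a rare target word (28 targets,
#' ~2.4\% of tokens).  Every word evokes a shared posterior visual response;
#' target words additionally evoke a frontal-midline component at
#' `effect_site` in the effect window whose amplitude is `effect_amplitude_uv`
#' (a current source) for everyone in the scrambled condition and
#' `effect_amplitude_uv * (1 - 2 * ability)` in the comprehension condition,
#' so a perfect comprehender flips the source into an equal-magnitude sink
#' and the scrambled-minus-comprehension difference grows as
#' `2 * effect_amplitude_uv * ability`.  Nuisance structure makes the
#' pipeline's preprocessing matter: a per-subject frontal gain shared by both
#' conditions (defeats single-condition classification; removed by the
#' difference), a channel-constant slow drift that differs between conditions
#' (defeats non-CSD difference-ERP classification; removed exactly by the
#' surface Laplacian), and spatially smeared background noise
#' (AR(1) + 10-Hz alpha + white, mixed across channels through the spherical
#' spline kernel to emulate volume conduction).
#'
#' Latent ability is bimodal — a poor and a good reader cluster mixed with
#' probability `target_good_fraction`.  Comprehension scores are produced by
#' answering a synthetic 4-question multi-select test: each question is
#' answered correctly with probability
#' `plogis(score_logit_a + score_logit_b * ability)`; the defaults give the
#' good cluster near-ceiling scores, the poor cluster scores mostly 0-2, and
#' an expected good (3-4) fraction of ~15/28.
#'
#' @param n_subjects cohort size (default 28).
#' @param target_good_fraction fraction of the cohort in the high-ability
#'   cluster (default 15/28, the study's good/poor split); the composition
#'   is exact per cohort, in a seeded random order.
#' @param ability_poor_range,ability_good_range latent-ability ranges of the
#'   two reader clusters (defaults `c(0.05, 0.35)` and `c(0.65, 0.95)`):
#'   reading skill is modeled as bimodal, matching the dichotomy the
#'   comprehension test is meant to pick up.
#' @param effect_site frontal-midline site of the comprehension effect
#'   (default `"AFz"`).
#' @param effect_window_ms half-open effect window (default `c(400, 500)`).
#' @param effect_amplitude_uv scalp amplitude of the frontal component
#'   (\eqn{\mu V}; default 10; 0 gives a null cohort with exchangeable groups).
#' @param frontal_gain_sd_uv SD of the per-subject frontal gain shared across
#'   conditions (default 16).
#' @param drift_uv amplitude of the channel-constant slow drift, drawn fresh
#'   per subject and condition (default 24).
#' @param source_width_deg angular width (degrees) of the injected
#'   current-source distributions in source space (default 10 — focal, so a
#'   component's difference-CSD concentrates at its site);
#'   `return_width_deg` the width of the surrounding return-current
#'   distribution (default 25), making each source a zero-sum
#'   center-surround patch whose return current stays local, as for a
#'   radial dipolar source.
#' @param posterior_evoked_uv,posterior_latency_ms,posterior_width_ms shared
#'   posterior visual response: Gaussian bump amplitude (default 10),
#'   latency (120) and width (25); `posterior_site` its center (`"POz"`).
#' @param evoked_gain_sd SD of the per-subject multiplicative gain on the
#'   evoked response (default 0.2).
#' @param noise_sd_uv stationary SD of the AR(1) background (default 3);
#'   `noise_ar_phi` its lag-1 coefficient (0.9); `alpha_uv` and `alpha_hz`
#'   the alpha-rhythm amplitude and frequency (4, 10); `white_sd_uv` white
#'   sensor noise (1); `spatial_mix` the weight of the volume-conduction
#'   smearing of the noise (0.85 — the brain background is almost entirely
#'   volume-conducted; only sensor noise is channel-independent).
#' @param n_words words per condition (default 1182).
#' @param n_targets target occurrences (default 28).
#' @param min_target_spacing minimum word positions between targets
#'   (default 0 = unconstrained).
#' @param soa_ms stimulus-onset asynchrony (default 500).
#' @param fs_hz sampling rate (default 256 for speed; 1024 supported).
#' @param window_ms epoch window (default `c(0, 500)`).
#' @param rt_mean_ms named condition means of target-detection RT
#'   (defaults scrambled 450, comprehension 520 — both groups slow down when
#'   also comprehending); `rt_subject_sd_ms` between-subject SD (30);
#'   `rt_noise_sd_ms` trial noise (10).
#' @param err_rate named condition error rates (defaults 0.02 / 0.07);
#'   `err_subject_sd` between-subject SD (0.02).
#' @param score_logit_a,score_logit_b ability-to-score logistic (defaults
#'   -6.9 and 16).
#' @param saccade_rate_per_epoch Poisson rate of injected EOG saccades
#'   (default 0.11); `eog_step_uv` their step amplitude (120);
#'   `eog_noise_sd_uv` EOG sensor noise (3; set 0 for noiseless EOG).
#' @param seed integer master seed; all randomness derives from it.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 28, target_good_fraction = 15 / 28,
                          effect_site = "AFz", effect_window_ms = c(400, 500),
                          effect_amplitude_uv = 16, frontal_gain_sd_uv = 16,
                          drift_uv = 24, source_width_deg = 10, return_width_deg = 25,
                          posterior_evoked_uv = 10, posterior_latency_ms = 120,
                          posterior_width_ms = 25, posterior_site = "POz",
                          evoked_gain_sd = 0.2,
                          noise_sd_uv = 3, noise_ar_phi = 0.9, alpha_uv = 4,
                          alpha_hz = 10, white_sd_uv = 1, spatial_mix = 0.85,
                          n_words = 1182, n_targets = 28,
                          min_target_spacing = 0, soa_ms = 500, fs_hz = 256,
                          window_ms = c(0, 500),
                          rt_mean_ms = c(scrambled = 450, comprehension = 520),
                          rt_subject_sd_ms = 30, rt_noise_sd_ms = 10,
                          err_rate = c(scrambled = 0.02, comprehension = 0.07),
                          err_subject_sd = 0.02,
                          ability_poor_range = c(0.05, 0.35),
                          ability_good_range = c(0.65, 0.95),
                          score_logit_a = -6.9, score_logit_b = 16,
                          saccade_rate_per_epoch = 0.11, eog_step_uv = 120,
                          eog_noise_sd_uv = 3, seed = 1) {
  stop_if_not(n_targets <= n_words, "n_targets must not exceed n_words")
  stop_if_not(n_subjects >= 2, "need at least 2 subjects")
  stop_if_not(effect_window_ms[1] >= window_ms[1] &&
                effect_window_ms[2] <= window_ms[2],
              "effect window must lie inside the epoch window")
  stop_if_not(all(c("scrambled", "comprehension") %in% names(rt_mean_ms)),
              "rt_mean_ms needs scrambled and comprehension entries")
  stop_if_not(all(c("scrambled", "comprehension") %in% names(err_rate)),
              "err_rate needs scrambled and comprehension entries")
  structure(as.list(environment()), class = "cohort_config")
}

soa_samples <- function(cfg) round(cfg$soa_ms / 1000 * cfg$fs_hz)
epoch_samples <- function(cfg) round(diff(cfg$window_ms) / 1000 * cfg$fs_hz)

#' Generate a word-stream event table
#'
#' Word onsets at the configured SOA with `n_targets` target positions drawn
#' uniformly at random subject to the minimum-spacing option.  In the
#' comprehension condition the target positions are those of the (fixed)
#' text, shared by all subjects; in the scrambled condition the word order is
#' subject-specific, so target positions are re-drawn per subject.
#'
#' @param cfg a [cohort_config()].
#' @param condition `"scrambled"` or `"comprehension"`.
#' @param subject subject index (used to re-draw scrambled-order targets).
#' @return an [event_table()]; onsets start after 1 s of lead-in.
#' @export
generate_word_stream <- function(cfg, condition = c("comprehension", "scrambled"),
                                 subject = 1) {
  stopifnot(inherits(cfg, "cohort_config"))
  condition <- match.arg(condition)
  stop_if_not(cfg$n_targets * (cfg$min_target_spacing + 1) <= cfg$n_words,
              "minimum target spacing infeasible: %d targets with spacing %d in %d words",
              cfg$n_targets, cfg$min_target_spacing, cfg$n_words)
  sseed <- if (condition == "comprehension") derive_seed(cfg$seed, 5)
           else derive_seed(cfg$seed, 6, subject)
  targets <- withr_seed(sseed, {
    repeat {
      cand <- sort(sample.int(cfg$n_words, cfg$n_targets))
      if (cfg$n_targets <= 1 || all(diff(cand) > cfg$min_target_spacing)) break
    }
    cand
  })
  is_t <- seq_len(cfg$n_words) %in% targets
  event_table(onset_sample = cfg$fs_hz + (seq_len(cfg$n_words) - 1) * soa_samples(cfg) + 1,
              trial_index = seq_len(cfg$n_words),
              label = ifelse(is_t, "and", "word"),
              is_target = is_t)
}

# Spatial patterns and noise-mixing matrix from the montage geometry.
# Each evoked component is injected as the scalp potential field of a focal
# radial current source at its site (a center-surround, zero-sum Gaussian
# patch in source space) under the spherical-spline volume-conduction
# model: solve H' c = source (with the zero-sum constraint) for the spline
# coefficients and spread them through the interpolation kernel,
# u = (G + lambda I) c.  The potential is broad
# (volume-conducted) while the component's current-source distribution — the
# quantity the surface Laplacian estimates — is focal at the site.  The
# background-noise smearing uses the broader order-3 interpolation kernel,
# so noise is spatially smoother than the components, as on the scalp.
cohort_patterns <- function(mont, cfg) {
  stop_if_not(cfg$effect_site %in% mont$labels,
              "effect_site '%s' not in montage", cfg$effect_site)
  stop_if_not(cfg$posterior_site %in% mont$labels,
              "posterior_site '%s' not in montage", cfg$posterior_site)
  gh <- build_gh_matrices(mont, spline_params())
  n <- length(mont$labels)
  Ms <- rbind(cbind(t(gh$H), 1), c(rep(1, n), 0))
  source_pattern <- function(site) {
    ang <- acos(pmin(pmax(tcrossprod(mont$positions)[, match(site, mont$labels)],
                          -1), 1)) * 180 / pi
    core <- exp(-ang^2 / (2 * cfg$source_width_deg^2))
    ret <- exp(-ang^2 / (2 * cfg$return_width_deg^2))
    src <- core - ret * sum(core) / sum(ret) # local return current, zero-sum
    co <- solve(Ms, c(src, 0))[seq_len(n)]
    u <- as.numeric((gh$G + diag(gh$params$lambda, n)) %*% co)
    u <- u - min(u)
    u / max(u)
  }
  C <- tcrossprod(mont$positions)
  C[C > 1] <- 1
  C[C < -1] <- -1
  W <- pmax(legendre_gh(C, m = 3, n_terms = 50)$g, 0)
  W <- W / rowSums(W)
  mix <- (1 - cfg$spatial_mix) * diag(n) + cfg$spatial_mix * W
  list(frontal = source_pattern(cfg$effect_site),
       posterior = source_pattern(cfg$posterior_site), mix = mix)
}

# temporal shapes on the epoch grid (n_samp samples over window_ms)
epoch_shapes <- function(cfg) {
  n <- epoch_samples(cfg)
  t_ms <- cfg$window_ms[1] + (seq_len(n) - 1) / cfg$fs_hz * 1000
  w <- cfg$effect_window_ms
  frontal <- ifelse(t_ms >= w[1] & t_ms < w[2],
                    sin(pi * (t_ms - w[1]) / (w[2] - w[1]))^2, 0)
  posterior <- exp(-(t_ms - cfg$posterior_latency_ms)^2 /
                     (2 * cfg$posterior_width_ms^2))
  list(t_ms = t_ms, frontal = frontal, posterior = posterior)
}

# background noise for one epoch block: n_samp x n_chan, spatially mixed
noise_block <- function(cfg, n_samp, n_chan, mix) {
  innov_sd <- cfg$noise_sd_uv * sqrt(1 - cfg$noise_ar_phi^2)
  innov <- matrix(rnorm(n_samp * n_chan, sd = innov_sd), n_samp, n_chan)
  ar <- stats::filter(innov, cfg$noise_ar_phi, method = "recursive")
  ar <- matrix(as.numeric(ar), n_samp, n_chan)
  tvec <- (seq_len(n_samp) - 1) / cfg$fs_hz
  ph <- runif(n_chan, 0, 2 * pi)
  # per-channel frequency jitter around alpha_hz: physiological alpha is not
  # a fixed line and must not phase-lock to the 500-ms stimulus cadence
  fr <- runif(n_chan, cfg$alpha_hz - 2, cfg$alpha_hz + 2)
  alpha <- cfg$alpha_uv * sin(outer(2 * pi * tvec, fr) +
                                matrix(ph, n_samp, n_chan, byrow = TRUE))
  smooth <- (ar + alpha) %*% t(mix)
  smooth + matrix(rnorm(n_samp * n_chan, sd = cfg$white_sd_uv), n_samp, n_chan)
}

# cohort-level cluster composition: exactly round(n * fraction) subjects in
# the good cluster, in a seeded random order (a fixed study cohort, not an
# iid draw, so degenerate splits cannot occur)
cluster_assignment <- function(cfg) {
  n_good <- round(cfg$n_subjects * cfg$target_good_fraction)
  withr_seed(derive_seed(cfg$seed, 4), {
    sample(rep(c(TRUE, FALSE), c(n_good, cfg$n_subjects - n_good)))
  })
}

# per-subject latent draws shared by both simulation paths
subject_params <- function(cfg, subject) {
  is_good <- cluster_assignment(cfg)[subject]
  withr_seed(derive_seed(cfg$seed, 7, subject), {
    list(
      ability = if (is_good) {
        runif(1, cfg$ability_good_range[1], cfg$ability_good_range[2])
      } else {
        runif(1, cfg$ability_poor_range[1], cfg$ability_poor_range[2])
      },
      frontal_gain = rnorm(1, 0, cfg$frontal_gain_sd_uv),
      evoked_gain = max(0.2, rnorm(1, 1, cfg$evoked_gain_sd)),
      rt_offset = rnorm(1, 0, cfg$rt_subject_sd_ms),
      err_offset = rnorm(1, 0, cfg$err_subject_sd),
      drift = lapply(c(scrambled = 1, comprehension = 2), function(k) {
        list(freq_hz = runif(1, 0.3, 1.2), phase = runif(1, 0, 2 * pi))
      })
    )
  })
}

# frontal component amplitude (uV) for one subject and condition
frontal_amplitude <- function(cfg, sp, condition) {
  base <- if (condition == "scrambled") cfg$effect_amplitude_uv
          else cfg$effect_amplitude_uv * (1 - 2 * sp$ability)
  base + sp$frontal_gain
}

eog_channels <- c("EOG_L", "EOG_R", "EOG_V")

# inject a step saccade into an eog epoch block (n_samp x 3), returns block
add_saccade_steps <- function(block, at_samp, direction, amp) {
  n <- nrow(block)
  for (i in seq_along(at_samp)) {
    step <- c(rep(0, at_samp[i] - 1), rep(1, n - at_samp[i] + 1))
    block[, 1] <- block[, 1] + direction[i] * amp / 2 * step
    block[, 2] <- block[, 2] - direction[i] * amp / 2 * step
    block[, 3] <- block[, 3] + amp / 4 * step
  }
  block
}

#' Simulate one subject's epochs directly (fast path)
#'
#' Generates the target-locked (or non-target) epochs for one subject and
#' condition without materializing the continuous recording: each epoch is
#' background noise plus the shared posterior evoked response plus — for
#' target trials — the frontal component with the subject's
#' condition-dependent amplitude, plus the condition drift evaluated at the
#' epoch's absolute onset time (so the fast path is distributionally a slice
#' of the continuous path).
#'
#' @param cfg a [cohort_config()].
#' @param mont the cohort [montage()].
#' @param patterns,shapes precomputed pattern/shape lists (internal; pass
#'   `NULL` to recompute).
#' @param subject subject index.
#' @param condition `"scrambled"` or `"comprehension"`.
#' @param events the subject/condition [event_table()].
#' @param trial_indices which `trial_index` values to simulate epochs for.
#' @param targetlike logical: add the frontal target component (default TRUE).
#' @param seed integer seed.
#' @return list with `eeg` ([epoch_set()], montage channels), `eog`
#'   ([epoch_set()], EOG channels), `saccade_counts` (injected, per epoch).
#' @export
simulate_subject_epochs <- function(cfg, mont, patterns, shapes, subject,
                                    condition, events, trial_indices,
                                    targetlike = TRUE,
                                    seed = derive_seed(cfg$seed, 8, subject)) {
  stop_if_not(cfg$fs_hz >= 100, "fs_hz = %g too low for the effect window", cfg$fs_hz)
  patterns <- patterns %||% cohort_patterns(mont, cfg)
  shapes <- shapes %||% epoch_shapes(cfg)
  sp <- subject_params(cfg, subject)
  n_samp <- epoch_samples(cfg)
  n_chan <- length(mont$labels)
  rows <- match(trial_indices, events$trial_index)
  stop_if_not(!anyNA(rows), "trial_indices not all present in events")
  onsets_s <- (events$onset_sample[rows] - 1) / cfg$fs_hz
  amp <- frontal_amplitude(cfg, sp, condition)
  dr <- sp$drift[[condition]]
  tvec <- (seq_len(n_samp) - 1) / cfg$fs_hz

  cseed <- derive_seed(seed, match(condition, c("scrambled", "comprehension")),
                       if (targetlike) 1 else 2)
  out <- withr_seed(cseed, {
    n_tr <- length(rows)
    arr <- array(0, c(n_tr, n_chan, n_samp))
    eog_arr <- array(0, c(n_tr, 3, n_samp))
    sacc <- integer(n_tr)
    det <- tcrossprod(shapes$posterior * sp$evoked_gain * cfg$posterior_evoked_uv,
                      patterns$posterior)
    if (targetlike) {
      det <- det + tcrossprod(shapes$frontal * amp, patterns$frontal)
    }
    # one long noise block for all epochs (the AR process simply continues
    # across epoch boundaries, as it would in a continuous recording)
    big <- noise_block(cfg, n_samp * n_tr, n_chan, patterns$mix)
    for (i in seq_len(n_tr)) {
      blk <- big[((i - 1) * n_samp + 1):(i * n_samp), , drop = FALSE] + det
      drift <- cfg$drift_uv * sin(2 * pi * dr$freq_hz * (onsets_s[i] + tvec) + dr$phase)
      arr[i, , ] <- t(blk + drift)
      eblk <- matrix(rnorm(n_samp * 3, sd = cfg$eog_noise_sd_uv), n_samp, 3)
      k <- stats::rpois(1, cfg$saccade_rate_per_epoch)
      if (k > 0) {
        at <- sort(sample(seq(5, n_samp - 5), k))
        eblk <- add_saccade_steps(eblk, at, sample(c(-1, 1), k, replace = TRUE),
                                  cfg$eog_step_uv)
      }
      sacc[i] <- k
      eog_arr[i, , ] <- t(eblk)
    }
    list(arr = arr, eog = eog_arr, sacc = sacc)
  })
  sid <- sprintf("s%02d", subject)
  list(eeg = epoch_set(out$arr, mont$labels, cfg$fs_hz, cfg$window_ms,
                       sid, condition),
       eog = epoch_set(out$eog, eog_channels, cfg$fs_hz, cfg$window_ms,
                       sid, condition),
       saccade_counts = out$sacc)
}

#' Simulate one subject's continuous EEG and EOG (slow path)
#'
#' Materializes the full continuous recording implied by the event stream:
#' spatially smeared background noise over the whole record, a posterior
#' evoked response after every word, the frontal target-locked component
#' with the subject's condition-dependent amplitude, the channel-constant
#' condition drift, and EOG channels with Poisson-injected saccade steps.
#' Mainly used to exercise the EDF/epoching front end; the fast path
#' ([simulate_subject_epochs()]) has the same distribution over epochs.
#'
#' @inheritParams simulate_subject_epochs
#' @return list with `eeg` (channels x samples matrix, attr `fs_hz`), `eog`
#'   (3 x samples matrix), `saccade_samples` (injected step positions).
#' @export
simulate_subject_eeg <- function(cfg, mont, patterns, shapes, subject,
                                 condition, events,
                                 seed = derive_seed(cfg$seed, 9, subject)) {
  stop_if_not(cfg$fs_hz >= 100, "fs_hz = %g too low for the effect window", cfg$fs_hz)
  patterns <- patterns %||% cohort_patterns(mont, cfg)
  shapes <- shapes %||% epoch_shapes(cfg)
  sp <- subject_params(cfg, subject)
  n_chan <- length(mont$labels)
  n_samp <- epoch_samples(cfg)
  total <- max(events$onset_sample) + soa_samples(cfg) + cfg$fs_hz
  amp <- frontal_amplitude(cfg, sp, condition)
  dr <- sp$drift[[condition]]
  cseed <- derive_seed(seed, 3, match(condition, c("scrambled", "comprehension")))
  res <- withr_seed(cseed, {
    sig <- noise_block(cfg, total, n_chan, patterns$mix)
    post_tc <- numeric(total)
    front_tc <- numeric(total)
    for (i in seq_len(nrow(events))) {
      sl <- events$onset_sample[i]:(events$onset_sample[i] + n_samp - 1)
      post_tc[sl] <- post_tc[sl] + shapes$posterior
      if (events$is_target[i]) front_tc[sl] <- front_tc[sl] + shapes$frontal
    }
    sig <- sig + tcrossprod(post_tc * sp$evoked_gain * cfg$posterior_evoked_uv,
                            patterns$posterior)
    sig <- sig + tcrossprod(front_tc * amp, patterns$frontal)
    tt <- (seq_len(total) - 1) / cfg$fs_hz
    sig <- sig + cfg$drift_uv * sin(2 * pi * dr$freq_hz * tt + dr$phase)
    eog <- matrix(rnorm(total * 3, sd = cfg$eog_noise_sd_uv), total, 3)
    rate_per_s <- cfg$saccade_rate_per_epoch / (diff(cfg$window_ms) / 1000)
    k <- stats::rpois(1, rate_per_s * total / cfg$fs_hz)
    at <- sort(sample(seq(5, total - 5), min(k, total - 10)))
    if (length(at)) {
      eog <- add_saccade_steps(eog, at, sample(c(-1, 1), length(at), TRUE),
                               cfg$eog_step_uv)
    }
    list(sig = sig, eog = eog, at = at)
  })
  eeg <- t(res$sig)
  rownames(eeg) <- mont$labels
  attr(eeg, "fs_hz") <- cfg$fs_hz
  eog <- t(res$eog)
  rownames(eog) <- eog_channels
  attr(eog, "fs_hz") <- cfg$fs_hz
  list(eeg = eeg, eog = eog, saccade_samples = res$at)
}

# draw a synthetic answer key and a subject's selections; each question is
# answered correctly with probability p, otherwise a wrong admissible
# (non-empty) pattern is drawn
generate_test_responses <- function(cfg, ability, seed) {
  withr_seed(seed, {
    p <- plogis(cfg$score_logit_a + cfg$score_logit_b * ability)
    key <- lapply(seq_len(4), function(q) {
      which(sample(c(TRUE, FALSE), 4, replace = TRUE) | c(TRUE, rep(FALSE, 3))[sample(4)])
    })
    sel <- lapply(key, function(k) {
      if (runif(1) < p) {
        k
      } else {
        repeat {
          s <- which(runif(4) < 0.5)
          if (length(s) > 0 && !setequal(s, k)) return(s)
        }
      }
    })
    list(key = key, selections = sel)
  })
}

#' Generate a full synthetic cohort
#'
#' Draws each subject's latent ability and nuisance gains, simulates the
#' comprehension test (scored with [score_test()]), target-detection
#' behavior (RTs slower and errors higher in the comprehension condition for
#' both groups, with no built-in group-by-condition interaction),
#' counterbalanced condition order, and the EEG/EOG epochs for both
#' conditions — plus matched non-target epochs for the control analyses.
#' A ground-truth ledger (abilities, true effect site/window/amplitudes,
#' injected saccade counts) accompanies the data so recovery is testable.
#'
#' @param cfg a [cohort_config()].
#' @param continuous simulate full continuous recordings and cut epochs from
#'   them (slow; default FALSE generates epochs directly).
#' @param include_nontarget also simulate matched non-target epochs
#'   (default TRUE).
#' @param output_dir if non-NULL, write the dataset there: EDF recordings
#'   (continuous mode only), per-subject events TSV, montage `.sfp`, subject
#'   table CSV and ground-truth ledger JSON.
#' @return object of class `cohort`: list with `config`, `montage`,
#'   `subjects` (data.frame: subject_id, ability, score, group, order,
#'   rt/error per condition), `events`, `epochs` (per subject, per
#'   condition: `eeg`, `eog`, `saccade_counts`), `nontarget_epochs`,
#'   `ledger`.
#' @export
generate_cohort <- function(cfg = cohort_config(), continuous = FALSE,
                            include_nontarget = TRUE, output_dir = NULL) {
  stopifnot(inherits(cfg, "cohort_config"))
  mont <- montage_biosemi64()
  patterns <- cohort_patterns(mont, cfg)
  shapes <- epoch_shapes(cfg)
  scheme <- scoring_scheme()
  n <- cfg$n_subjects
  if (!is.null(output_dir)) dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  order_lv <- c("scrambled_first", "comprehension_first")
  orders <- withr_seed(derive_seed(cfg$seed, 3), {
    sample(rep(order_lv, length.out = n))
  })

  subjects <- data.frame(subject_id = sprintf("s%02d", seq_len(n)),
                         ability = NA_real_, score = NA_integer_,
                         group = NA_character_, order = orders,
                         rt_scrambled = NA_real_, rt_comprehension = NA_real_,
                         err_scrambled = NA_real_, err_comprehension = NA_real_)
  events <- list()
  epochs <- list()
  nontarget <- list()
  sacc_ledger <- list()
  true_index <- numeric(n)

  for (s in seq_len(n)) {
    sp <- subject_params(cfg, s)
    subjects$ability[s] <- sp$ability
    resp <- generate_test_responses(cfg, sp$ability, derive_seed(cfg$seed, 13, s))
    subjects$score[s] <- score_test(resp$selections, resp$key, scheme)
    true_index[s] <- 2 * cfg$effect_amplitude_uv * sp$ability
    sid <- subjects$subject_id[s]
    events[[sid]] <- list()
    epochs[[sid]] <- list()
    nontarget[[sid]] <- list()
    sacc_ledger[[sid]] <- list()
    for (cond in c("scrambled", "comprehension")) {
      ev <- generate_word_stream(cfg, cond, subject = s)
      beh <- withr_seed(derive_seed(cfg$seed, 14, s, match(cond, c("scrambled", "comprehension"))), {
        tgt <- which(ev$is_target)
        er <- min(max(cfg$err_rate[[cond]] + sp$err_offset, 0), 1)
        ok <- runif(length(tgt)) >= er
        rt <- rnorm(length(tgt), cfg$rt_mean_ms[[cond]] + sp$rt_offset,
                    cfg$rt_noise_sd_ms)
        list(tgt = tgt, ok = ok, rt = rt)
      })
      ev$response_correct[beh$tgt] <- beh$ok
      ev$rt_ms[beh$tgt] <- ifelse(beh$ok, beh$rt, NA_real_)
      events[[sid]][[cond]] <- ev
      subjects[[paste0("rt_", cond)]][s] <- mean(beh$rt[beh$ok])
      subjects[[paste0("err_", cond)]][s] <- mean(!beh$ok)

      tgt_idx <- ev$trial_index[ev$is_target]
      if (continuous) {
        rec <- simulate_subject_eeg(cfg, mont, patterns, shapes, s, cond, ev)
        if (!is.null(output_dir)) {
          write_edf(rbind(rec$eeg, rec$eog), cfg$fs_hz,
                    file.path(output_dir, sprintf("%s_%s.edf", sid, cond)))
          write_events_tsv(ev, file.path(output_dir,
                                         sprintf("%s_%s_events.tsv", sid, cond)))
        }
        eeg_ep <- extract_epochs(rec$eeg, ev, tgt_idx, cfg$window_ms, cfg$fs_hz,
                                 sid, cond)
        eog_ep <- extract_epochs(rec$eog, ev, tgt_idx, cfg$window_ms, cfg$fs_hz,
                                 sid, cond)
        on1 <- ev$onset_sample[match(attr(eeg_ep, "trial_index"), ev$trial_index)]
        counts <- vapply(on1, function(o) {
          sum(rec$saccade_samples >= o & rec$saccade_samples < o + epoch_samples(cfg))
        }, integer(1))
        sim <- list(eeg = eeg_ep, eog = eog_ep, saccade_counts = counts)
      } else {
        sim <- simulate_subject_epochs(cfg, mont, patterns, shapes, s, cond,
                                       ev, tgt_idx)
        attr(sim$eeg, "trial_index") <- tgt_idx
        attr(sim$eog, "trial_index") <- tgt_idx
      }
      epochs[[sid]][[cond]] <- sim
      sacc_ledger[[sid]][[cond]] <- sim$saccade_counts
      if (include_nontarget) {
        nt_idx <- withr_seed(derive_seed(cfg$seed, 15, s), {
          sort(sample(ev$trial_index[!ev$is_target & ev$trial_index > 2 &
                                       ev$trial_index < cfg$n_words - 1],
                      length(tgt_idx)))
        })
        nt <- simulate_subject_epochs(cfg, mont, patterns, shapes, s, cond,
                                      ev, nt_idx, targetlike = FALSE)
        attr(nt$eeg, "trial_index") <- nt_idx
        nontarget[[sid]][[cond]] <- nt
      }
    }
  }
  subjects$group <- as.character(assign_groups(subjects$score, scheme))
  ledger <- list(seed = cfg$seed,
                 abilities = setNames(subjects$ability, subjects$subject_id),
                 effect_site = cfg$effect_site,
                 effect_window_ms = cfg$effect_window_ms,
                 effect_amplitude_uv = cfg$effect_amplitude_uv,
                 true_difference_amplitude_uv = setNames(true_index, subjects$subject_id),
                 group_sizes = as.list(table(subjects$group)),
                 saccade_counts = sacc_ledger)
  out <- structure(list(config = cfg, montage = mont, subjects = subjects,
                        events = events, epochs = epochs,
                        nontarget_epochs = if (include_nontarget) nontarget else NULL,
                        ledger = ledger),
                   class = "cohort")
  if (!is.null(output_dir)) {
    write_sfp(mont, file.path(output_dir, "montage.sfp"))
    write.csv(subjects, file.path(output_dir, "subjects.csv"), row.names = FALSE)
    jsonlite::write_json(ledger, file.path(output_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!continuous) {
      for (sid in names(events)) {
        for (cond in names(events[[sid]])) {
          write_events_tsv(events[[sid]][[cond]],
                           file.path(output_dir, sprintf("%s_%s_events.tsv", sid, cond)))
        }
      }
    }
  }
  out
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects (%s), %d targets/%d words, fs %g Hz, effect %g uV at %s %g-%g ms\n",
              nrow(x$subjects),
              paste(sprintf("%d %s", table(x$subjects$group),
                            names(table(x$subjects$group))), collapse = " / "),
              x$config$n_targets, x$config$n_words, x$config$fs_hz,
              x$config$effect_amplitude_uv, x$config$effect_site,
              x$config$effect_window_ms[1], x$config$effect_window_ms[2]))
  invisible(x)
}
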