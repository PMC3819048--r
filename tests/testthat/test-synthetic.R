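test_that("the default word stream has 28 rare targets among 1182 words", {
  ev <- generate_word_stream(cohort_config(seed = 2), "comprehension")
  expect_equal(nrow(ev), 1182)
  expect_equal(sum(ev$is_target), 28)
  expect_equal(round(100 * mean(ev$is_target), 1), 2.4)
  expect_equal(diff(ev$onset_sample), rep(128, 1181)) # 500 ms at 256 Hz
})

test_that("word streams are seeded, shared in comprehension, re-drawn in scrambled", {
  cfg <- quick_cfg(seed = 5)
  expect_identical(generate_word_stream(cfg, "comprehension", subject = 1),
                   generate_word_stream(cfg, "comprehension", subject = 2))
  s1 <- generate_word_stream(cfg, "scrambled", subject = 1)
  s2 <- generate_word_stream(cfg, "scrambled", subject = 2)
  expect_false(identical(which(s1$is_target), which(s2$is_target)))
  expect_identical(s1, generate_word_stream(cfg, "scrambled", subject = 1))
  none <- generate_word_stream(quick_cfg(n_targets = 0), "comprehension")
  expect_equal(sum(none$is_target), 0)
  expect_error(generate_word_stream(quick_cfg(n_targets = 30,
                                              min_target_spacing = 3)),
               "infeasible")
})

test_that("epoch simulation is seeded and rejects unusably low sampling rates", {
  cfg <- quick_cfg(seed = 6)
  mont <- montage_biosemi64()
  ev <- generate_word_stream(cfg, "comprehension")
  tgt <- ev$trial_index[ev$is_target]
  a <- simulate_subject_epochs(cfg, mont, NULL, NULL, 1, "comprehension", ev, tgt)
  b <- simulate_subject_epochs(cfg, mont, NULL, NULL, 1, "comprehension", ev, tgt)
  expect_identical(a$eeg$data, b$eeg$data)
  expect_identical(a$saccade_counts, b$saccade_counts)
  expect_equal(dim(a$eeg$data), c(length(tgt), 64, 128))
  low <- quick_cfg(fs_hz = 64)
  expect_error(simulate_subject_epochs(low, mont, NULL, NULL, 1,
                                       "comprehension", ev, tgt),
               "too low")
})

test_that("posterior sites show the evoked response in both conditions and groups", {
  cfg <- quick_cfg(seed = 8)
  coh <- generate_cohort(cfg, include_nontarget = FALSE)
  g <- coh$subjects$group
  pick <- c(which(g == "good")[1], which(g == "poor")[1])
  for (s in pick) {
    sid <- coh$subjects$subject_id[s]
    for (cond in c("scrambled", "comprehension")) {
      e <- average_erp(apply_baseline(coh$epochs[[sid]][[cond]]$eeg))
      # average-reference to remove the channel-constant drift before
      # looking for the posterior deflection
      ref <- e$values - matrix(colMeans(e$values), nrow(e$values),
                               ncol(e$values), byrow = TRUE)
      tr <- ref["POz", ]
      peak <- mean(tr[27:35]) # around the 120-ms latency
      tail_ <- mean(tr[90:120])
      expect_gt(peak - tail_, 3) # clear visual evoked deflection
    }
  }
})

test_that("the comprehension effect concentrates at the frontal site in the late window", {
  cfg <- quick_cfg(seed = 9, n_subjects = 4)
  coh <- generate_cohort(cfg, include_nontarget = FALSE)
  best <- which.max(coh$subjects$ability)
  sid <- coh$subjects$subject_id[best]
  es <- average_erp(apply_baseline(coh$epochs[[sid]]$scrambled$eeg))
  ec <- average_erp(apply_baseline(coh$epochs[[sid]]$comprehension$eeg))
  d <- es$values["AFz", ] - ec$values["AFz", ]
  bins <- sapply(seq(0, 400, by = 100), function(b0) {
    mean(d[(b0 * 256 / 1000 + 1):((b0 + 100) * 256 / 1000)])
  })
  expect_equal(which.max(bins), 5) # [400, 500) dominates
  expect_gt(bins[5], 0)            # scrambled-minus-comprehension is positive
})

test_that("a zero-amplitude effect leaves good and poor exchangeable at the index", {
  ps <- vapply(1:10, function(s) {
    coh <- generate_cohort(quick_cfg(seed = 600 + s, effect_amplitude_uv = 0),
                           include_nontarget = FALSE)
    mm <- cohort_maps(coh)
    idx <- extract_csd_index(mm$maps)$csd_index
    t.test(idx ~ coh$subjects$group)$p.value
  }, numeric(1))
  expect_gte(sum(ps > 0.01), 9) # at most one false positive in 10 seeds
})

test_that("behavior follows the configured model", {
  exact <- generate_cohort(quick_cfg(seed = 10, n_subjects = 4,
                                     rt_subject_sd_ms = 0, rt_noise_sd_ms = 0,
                                     err_rate = c(scrambled = 0, comprehension = 0),
                                     err_subject_sd = 0),
                           include_nontarget = FALSE)
  expect_equal(unique(exact$subjects$rt_scrambled), 450)
  expect_equal(unique(exact$subjects$rt_comprehension), 520)
  expect_equal(unique(exact$subjects$err_scrambled), 0)
})

test_that("cohorts are bit-reproducible and ship a complete ground-truth ledger", {
  cfg <- quick_cfg(seed = 12, n_subjects = 4)
  c1 <- generate_cohort(cfg, include_nontarget = FALSE)
  c2 <- generate_cohort(cfg, include_nontarget = FALSE)
  expect_identical(c1$subjects, c2$subjects)
  expect_identical(c1$epochs$s01$scrambled$eeg$data,
                   c2$epochs$s01$scrambled$eeg$data)
  led <- c1$ledger
  expect_named(led, c("seed", "abilities", "effect_site", "effect_window_ms",
                      "effect_amplitude_uv", "true_difference_amplitude_uv",
                      "group_sizes", "saccade_counts"), ignore.order = TRUE)
  expect_equal(led$true_difference_amplitude_uv,
               2 * cfg$effect_amplitude_uv * led$abilities)
  expect_identical(led$saccade_counts$s01$scrambled,
                   c1$epochs$s01$scrambled$saccade_counts)
})

test_that("the continuous path writes EDF/TSV and epochs like the fast path's model", {
  cfg <- quick_cfg(seed = 13, n_subjects = 2, n_words = 40, n_targets = 6)
  dir <- withr::local_tempdir()
  coh <- generate_cohort(cfg, continuous = TRUE, include_nontarget = FALSE,
                         output_dir = dir)
  expect_true(file.exists(file.path(dir, "s01_scrambled.edf")))
  expect_true(file.exists(file.path(dir, "s01_scrambled_events.tsv")))
  expect_true(file.exists(file.path(dir, "montage.sfp")))
  expect_true(file.exists(file.path(dir, "subjects.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  expect_equal(dim(coh$epochs$s01$comprehension$eeg$data), c(6, 64, 128))
  # reload from disk and re-cut: epochs agree within EDF quantization
  loaded <- load_cohort(dir, cfg)
  a <- coh$epochs$s01$comprehension$eeg$data
  b <- loaded$epochs$s01$comprehension$eeg$data
  expect_equal(dim(b), dim(a))
  expect_lt(max(abs(a - b)), 0.05)
})

test_that("the continuous path carries the late frontal effect like the fast path", {
  cfg <- quick_cfg(seed = 14, n_subjects = 2, n_words = 60, n_targets = 8,
                   ability_good_range = c(0.9, 0.95),
                   target_good_fraction = 1)
  coh <- generate_cohort(cfg, continuous = TRUE, include_nontarget = FALSE)
  es <- average_erp(apply_baseline(coh$epochs$s01$scrambled$eeg))
  ec <- average_erp(apply_baseline(coh$epochs$s01$comprehension$eeg))
  d <- es$values["AFz", ] - ec$values["AFz", ]
  expect_gt(mean(d[103:128]), mean(d[1:90]) + 5) # effect window stands out
})
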