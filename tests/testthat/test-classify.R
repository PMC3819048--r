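test_that("the default bin layout is eight overlapping 100-ms bins ending at 400-500", {
  bs <- bin_spec()
  expect_equal(nrow(bs$bins), 8)
  expect_equal(bs$bins$start_ms, seq(50, 400, by = 50))
  expect_equal(bs$bins$bin_id[8], "400-500")
  with_pre <- bin_spec(extra_prestim_bins = TRUE)
  expect_equal(nrow(with_pre$bins), 11)
  expect_equal(with_pre$bins$bin_id[1:3], c("-100-0", "-50-50", "0-100"))
})

test_that("bin features are half-open bin means of the difference maps", {
  mont <- montage_biosemi64()
  mk <- function(v) csd_map(matrix(v, 64, 128), mont$labels, 256, c(0, 500))
  labels <- rep(c("poor", "good"), each = 2)
  zero <- bin_features(list(a = mk(0), b = mk(0), c = mk(0), d = mk(0)), labels)
  expect_true(all(vapply(zero, function(f) all(f$matrix == 0), logical(1))))
  cst <- bin_features(list(a = mk(2.5), b = mk(2.5), c = mk(2.5), d = mk(2.5)),
                      labels)
  expect_true(all(abs(cst[["400-500"]]$matrix - 2.5) < 1e-12))
  expect_error(bin_features(list(a = mk(0)), "poor",
                            bin_spec(start_ms = -100, extra_prestim_bins = TRUE)),
               "outside the epoch window")
})

test_that("titration is deterministic given a seed and validates its inputs", {
  ft <- separable_features()
  r1 <- run_titration(ft, titration_config(n_trees = 100), seed = 11)
  r2 <- run_titration(ft, titration_config(n_trees = 100), seed = 11)
  expect_identical(r1$accuracy, r2$accuracy)
  expect_identical(r1$weights, r2$weights)
  one_class <- ft
  one_class$labels <- factor(rep("good", nrow(ft$matrix)),
                             levels = c("poor", "good"))
  expect_error(run_titration(one_class), "both classes")
  tiny <- feature_table(ft$matrix[c(1:3, 15:17), ],
                        ft$labels[c(1:3, 15:17)], "b")
  expect_error(run_titration(tiny), "at least 6")
  expect_error(run_titration(ft, titration_config(top_k_sites = 99)), "exceeds")
})

test_that("separable features classify almost perfectly and the informative site tops the weights", {
  ft <- separable_features(gap = 2, noise = 0.05)
  res <- titration_runs(ft, titration_config(top_k_sites = 3), n_runs = 10,
                        seed = 5)
  expect_gt(res$mean_accuracy, 0.95)
  expect_identical(res$top_sites[1], "site7")
})

test_that("pure-noise features stay near the majority base rate", {
  set.seed(77)
  X <- matrix(rnorm(28 * 20), 28, dimnames = list(NULL, paste0("s", 1:20)))
  ft <- feature_table(X, rep(c("poor", "good"), each = 14), "b")
  res <- titration_runs(ft, titration_config(), n_runs = 50, seed = 6)
  base <- 0.5
  expect_lt(abs(res$mean_accuracy - base), 3 * max(res$sd_accuracy, 0.02))
})

test_that("label scrambling preserves class counts, is reproducible, and is null-calibrated", {
  ft <- separable_features()
  n1 <- permutation_null(ft, titration_config(), n_runs = 5, seed = 3)
  n2 <- permutation_null(ft, titration_config(), n_runs = 5, seed = 3)
  expect_identical(n1, n2)
  expect_length(permutation_null(ft, titration_config(), n_runs = 0), 0)
  # separable features + scrambled labels ~ base rate
  nulls <- permutation_null(ft, titration_config(), n_runs = 30, seed = 4)
  expect_lt(abs(mean(nulls) - 0.5), 3 * sd(nulls))
})

test_that("significance statistics compare the two accuracy distributions", {
  set.seed(78)
  x <- rnorm(200, 0.8, 0.02)
  same <- compare_distributions(x, x)
  expect_equal(same$d, 0)
  expect_equal(same$hit_rate, same$fp_rate)
  sep <- compare_distributions(rep(0.9, 10), rep(0.5, 10))
  expect_equal(sep$hit_rate, 1)
  expect_equal(sep$fp_rate, 0)
  expect_true(is.infinite(sep$d) && sep$d > 0)
  expect_error(compare_distributions(rep(0.7, 5), rep(0.7, 5)), "undefined")
  expect_error(compare_distributions(numeric(0), x), "non-empty")
  # df bookkeeping matches the independent-groups layout
  cmp <- compare_distributions(rnorm(1000, 0.85, 0.02), rnorm(1000, 0.6, 0.02))
  expect_equal(cmp$df, 1998)
  expect_gt(cmp$d, 5)
})

test_that("per-bin reports pick the effect-bearing bin on constructed features", {
  set.seed(79)
  mont <- montage_biosemi64()
  n <- 28
  labels <- rep(c("poor", "good"), each = 14)
  maps <- lapply(seq_len(n), function(i) {
    v <- matrix(rnorm(64 * 128, sd = 0.5), 64, 128)
    # effect only at AFz in [400, 500) for the good half; moderate amplitude
    # so the overlapping 350-450 bin (half coverage) stays clearly weaker
    if (labels[i] == "good") {
      v[match("AFz", mont$labels), 103:128] <- v[match("AFz", mont$labels), 103:128] + 0.3
    }
    csd_map(v, mont$labels, 256, c(0, 500))
  })
  names(maps) <- sprintf("s%02d", seq_len(n))
  feats <- bin_features(maps, labels)
  rep <- classify_bins(feats, titration_config(n_runs = 10, n_null_runs = 5, seed = 2))
  expect_identical(rep$best_bin, "400-500")
  expect_identical(rep$best_site, "AFz")
  expect_true(all(rep$summary$mean_accuracy >= 0 & rep$summary$mean_accuracy <= 1))
  b <- rep$per_bin[["400-500"]]
  expect_true(all(b$weights >= 0))
  expect_gt(b$stats$d, 1)
})

test_that("the all-bins-jointly variant runs a single classifier over every site-bin pair", {
  set.seed(80)
  mont <- montage_biosemi64()
  maps <- lapply(1:16, function(i) {
    csd_map(matrix(rnorm(64 * 128, sd = 0.1), 64, 128), mont$labels, 256, c(0, 500))
  })
  names(maps) <- sprintf("s%02d", 1:16)
  feats <- bin_features(maps, rep(c("poor", "good"), each = 8))
  rep <- classify_bins(feats, titration_config(n_runs = 3, n_null_runs = 0,
                                               all_bins_jointly = TRUE, seed = 9))
  expect_identical(names(rep$per_bin), "all_bins")
  expect_length(rep$per_bin$all_bins$weights, 64 * 8)
})
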