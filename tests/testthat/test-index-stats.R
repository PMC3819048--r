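mont64 <- montage_biosemi64()

map_of <- function(v) csd_map(v, mont64$labels, 256, c(0, 500))

test_that("the CSD index is the bin mean at the requested site and is linear", {
  zero <- list(a = map_of(matrix(0, 64, 128)))
  expect_equal(extract_csd_index(zero)$csd_index, 0)
  v <- matrix(0, 64, 128)
  v[match("AFz", mont64$labels), 103:128] <- 3.25 # [400, 500) at 256 Hz
  one <- list(a = map_of(v))
  expect_equal(extract_csd_index(one)$csd_index, 3.25)
  two <- list(a = map_of(2 * v))
  expect_equal(extract_csd_index(two)$csd_index, 6.5)
  expect_error(extract_csd_index(one, site = "QQ"), "available: .*AFz")
  expect_error(extract_csd_index(one, bin_ms = c(400, 600)), "outside")
})

test_that("collinear points correlate perfectly with nothing trimmed", {
  x <- 1:10
  cc <- correlate_with_ellipse(x, 2 * x + 1)
  expect_equal(cc$r_all, 1)
  expect_equal(cc$r_trimmed, 1)
  expect_length(cc$outlier_ids, 0)
})

test_that("planted outliers are trimmed once with the study-design df bookkeeping", {
  set.seed(41)
  n <- 25
  x <- rnorm(n)
  y <- 0.9 * x + rnorm(n, sd = 0.3)
  xx <- c(x, 6, -6, 7)
  yy <- c(y, -6, 6, -7)
  cc <- correlate_with_ellipse(xx, yy)
  expect_length(cc$outlier_ids, 3)
  expect_equal(cc$df_all, 26)
  expect_equal(cc$df_trimmed, 23) # 28 subjects, 3 removed
  expect_gt(cc$r_trimmed, cc$r_all)
  expect_equal(cc$t_trimmed,
               cc$r_trimmed * sqrt(23) / sqrt(1 - cc$r_trimmed^2))
})

test_that("the flagged fraction matches the ellipse coverage on bivariate-normal data", {
  set.seed(42)
  n <- 10000
  x <- rnorm(n)
  y <- 0.5 * x + rnorm(n)
  cc <- correlate_with_ellipse(x, y, coverage = 0.95)
  frac <- length(cc$outlier_ids) / n
  expect_lt(abs(frac - 0.05), 0.02)
})

test_that("full-coverage trimming converges to the untrimmed correlation", {
  set.seed(43)
  x <- rnorm(40)
  y <- x + rnorm(40)
  cc <- correlate_with_ellipse(x, y, coverage = 1 - 1e-12)
  expect_equal(cc$r_trimmed, cc$r_all)
  expect_length(cc$outlier_ids, 0)
})

test_that("degenerate inputs are rejected", {
  expect_error(correlate_with_ellipse(1:3, c(2, 4, 6)), "at least 4")
  expect_error(correlate_with_ellipse(rep(1, 8), rnorm(8)), "zero variance")
})

test_that("condition-by-group unpacking produces cell means, paired t and interaction F", {
  # identical conditions: no within-subject effect anywhere
  same <- data.frame(subject_id = 1:10, scrambled = rnorm(10))
  same$comprehension <- same$scrambled
  up0 <- condition_group_unpack(same, rep(c("poor", "good"), each = 5))
  expect_equal(up0$paired_t$good$t, 0)
  expect_equal(up0$paired_t$poor$t, 0)
  expect_equal(up0$interaction$F, 0)

  # good group flips source into sink, poor stays a source
  set.seed(44)
  n <- 28
  g <- rep(c("poor", "good"), c(13, 15))
  scr <- rnorm(n, 1, 0.3)
  comp <- ifelse(g == "good", -1, 1) + rnorm(n, sd = 0.3)
  up <- condition_group_unpack(
    data.frame(subject_id = seq_len(n), scrambled = scr, comprehension = comp), g)
  expect_equal(up$interaction$df, c(1, 26))
  expect_gt(up$interaction$F, qf(0.999, 1, 26)) # significant at alpha = 0.001
  expect_gt(up$paired_t$good$t, 5)
  expect_lt(abs(up$paired_t$poor$t), 3)
  expect_gt(up$cell_means["poor", "comprehension"], 0)
  expect_lt(up$cell_means["good", "comprehension"], 0)
})

test_that("the mixed ANOVA matches aov's Error-strata decomposition on balanced data", {
  set.seed(45)
  n <- 16
  g <- rep(c("poor", "good"), each = n / 2)
  v <- matrix(rnorm(2 * n), n, 2)
  ours <- csdread:::mixed_anova_2x2(v, g)
  long <- data.frame(y = c(v[, 1], v[, 2]),
                     cond = rep(c("a", "b"), each = n),
                     gr = factor(rep(g, 2)),
                     id = factor(rep(seq_len(n), 2)))
  fit <- summary(aov(y ~ gr * cond + Error(id / cond), data = long))
  between <- fit[["Error: id"]][[1]]
  within <- fit[["Error: id:cond"]][[1]]
  expect_equal(ours$F_group, between["gr", "F value"], tolerance = 1e-8)
  expect_equal(ours$F_condition, within["cond", "F value"], tolerance = 1e-8)
  expect_equal(ours$F_interaction, within["gr:cond", "F value"], tolerance = 1e-8)
})

test_that("behavioral ANOVA isolates a pure condition effect", {
  g <- rep(c("poor", "good"), each = 14)
  base <- rnorm(28, 450, 5)
  beh <- data.frame(subject_id = 1:28, scrambled = base,
                    comprehension = base + 70)
  res <- behavioral_anova(beh, g)
  expect_equal(res$df, c(1, 26))
  expect_gt(res$F_condition, 100)
  expect_lt(res$F_group, qf(0.95, 1, 26))
  expect_lt(res$F_interaction, qf(0.95, 1, 26))
  same <- data.frame(subject_id = 1:28, scrambled = rep(1, 28),
                     comprehension = rep(1, 28))
  res0 <- behavioral_anova(same, g)
  expect_equal(res0$F_condition, 0)
  expect_equal(res0$F_group, 0)
  expect_equal(res0$F_interaction, 0)
})

test_that("order analyses separate index and order contributions", {
  set.seed(46)
  n <- 28
  ord <- rep(c("scrambled_first", "comprehension_first"), each = n / 2)
  idx <- rnorm(n)
  score <- 2 + 1.5 * idx + rnorm(n, sd = 0.4) # order-unrelated
  oa <- order_analysis(idx, score, ord)
  co <- oa$regression$coefficients
  expect_gt(abs(co["index", "t value"]), 4)
  expect_lt(abs(co["order", "t value"]), 2.5)
  expect_false(isTRUE(oa$by_order$scrambled_first$skipped))

  # score fully determined by order, index pure noise
  score2 <- ifelse(ord == "scrambled_first", 3, 1)
  oa2 <- order_analysis(rnorm(n), score2 + rnorm(n, sd = 1e-6), ord)
  expect_lt(abs(oa2$regression$coefficients["index", "t value"]), 2.5)
  expect_gt(abs(oa2$order_t$t), 100)

  # tiny subgroup is skipped with a notice
  ord3 <- c(rep("scrambled_first", 25), rep("comprehension_first", 3))
  oa3 <- order_analysis(idx, score, ord3)
  expect_true(oa3$by_order$comprehension_first$skipped)
  expect_match(oa3$by_order$comprehension_first$notice, "skipped")
})
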