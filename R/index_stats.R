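#' Extract the per-subject CSD index
#'
#' The CSD index is the mean of a subject's difference-CSD
#' (scrambled minus comprehension) at one scalp site over one time bin —
#' by default AFz over \[400, 500) ms, the site/bin the titration classifier
#' singles out.
#'
#' @param diff_csd named list of per-subject [csd_map()] difference maps.
#' @param site channel label (default `"AFz"`).
#' @param bin_ms half-open time interval in ms (default `c(400, 500)`).
#' @return data.frame with `subject_id` and `csd_index` (\eqn{\mu V/cm^2}).
#' @export
extract_csd_index <- function(diff_csd, site = "AFz", bin_ms = c(400, 500)) {
  stopifnot(length(diff_csd) >= 1)
  m1 <- diff_csd[[1]]
  if (!site %in% m1$channels) {
    stop(sprintf("site '%s' not in montage; available: %s", site,
                 paste(m1$channels, collapse = " ")), call. = FALSE)
  }
  stop_if_not(bin_ms[1] >= m1$window_ms[1] && bin_ms[2] <= m1$window_ms[2],
              "bin [%g, %g) ms outside epoch window [%g, %g) ms",
              bin_ms[1], bin_ms[2], m1$window_ms[1], m1$window_ms[2])
  idx <- ms_to_samples(bin_ms, m1$fs_hz, m1$window_ms)
  vals <- vapply(diff_csd, function(m) {
    mean(m$values[site, idx[1]:idx[2]])
  }, numeric(1))
  data.frame(subject_id = names(diff_csd) %||% paste0("s", seq_along(diff_csd)),
             csd_index = unname(vals))
}

#' Correlation with confidence-ellipse outlier trimming
#'
#' Pearson correlation between the CSD index and comprehension score,
#' reported both with all subjects and after removing, in a single pass,
#' the points whose Mahalanobis distance under a bivariate-normal fit
#' (sample mean and covariance) exceeds the chi-square(2) quantile at
#' `coverage` — i.e. the points outside the 95\% confidence ellipse.  For
#' each fit `t = r sqrt(df) / sqrt(1 - r^2)` with `df = n - 2`.
#'
#' @param index numeric vector (e.g. CSD index).
#' @param scores numeric vector, same length.
#' @param coverage ellipse coverage probability (default 0.95).
#' @return list with `r_all`, `t_all`, `df_all`, `r_trimmed`, `t_trimmed`,
#'   `df_trimmed`, `outlier_ids` (indices, possibly named), `coverage`.
#' @export
correlate_with_ellipse <- function(index, scores, coverage = 0.95) {
  stop_if_not(length(index) == length(scores), "index and scores must align")
  n <- length(index)
  stop_if_not(n >= 4, "need at least 4 subjects")
  stop_if_not(var(index) > 0 && var(scores) > 0,
              "zero variance in index or scores")
  xy <- cbind(index, scores)
  S <- stats::cov(xy)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev)) {
    # exactly collinear points: the ellipse degenerates; nothing to trim
    out <- integer(0)
  } else {
    md <- mahalanobis(xy, colMeans(xy), S)
    out <- which(md > qchisq(coverage, df = 2))
  }
  r_of <- function(keep) {
    k <- length(keep)
    r <- cor(index[keep], scores[keep])
    list(r = r, df = k - 2, t = r * sqrt(k - 2) / sqrt(1 - r^2))
  }
  all_f <- r_of(seq_len(n))
  trim_f <- r_of(setdiff(seq_len(n), out))
  list(r_all = all_f$r, t_all = all_f$t, df_all = all_f$df,
       r_trimmed = trim_f$r, t_trimmed = trim_f$t, df_trimmed = trim_f$df,
       outlier_ids = if (!is.null(names(index))) names(index)[out] else out,
       coverage = coverage)
}

# 2x2 mixed ANOVA (condition within subjects, group between), computed from
# the per-subject condition difference and mean with sum contrasts so that
# unequal group sizes are handled Type-III style; degenerate 0/0 F ratios
# are defined as 0.  values: subjects x 2 matrix (cols = conditions).
mixed_anova_2x2 <- function(values, groups) {
  stop_if_not(ncol(values) == 2, "need exactly two conditions")
  groups <- factor(groups)
  stop_if_not(nlevels(groups) == 2, "need exactly two groups")
  stop_if_not(all(table(groups) >= 2), "each group needs >= 2 subjects")
  stop_if_not(all(is.finite(values)), "missing cells in the 2x2 design")
  n <- nrow(values)
  g <- ifelse(groups == levels(groups)[1], -1, 1) # sum contrast
  f_from_lm <- function(y) {
    fit <- lm(y ~ g)
    co <- coef(fit)
    sig <- sqrt(sum(stats::residuals(fit)^2) / max(1, fit$df.residual))
    scale <- sqrt(mean(y^2)) + 1e-300
    if (sig < 1e-10 * scale) {
      # zero residual variance: F is 0 for a null effect, unbounded otherwise
      return(unname(ifelse(abs(co) < 1e-10 * scale, 0, Inf)))
    }
    tv <- summary(fit)$coefficients[, "t value"]
    tv[!is.finite(tv)] <- 0
    unname(tv^2)
  }
  # between stratum: subject means
  fb <- f_from_lm(rowMeans(values))
  # within stratum: condition differences (cond2 - cond1)
  fw <- f_from_lm(values[, 2] - values[, 1])
  list(F_condition = unname(fw[1]), F_group = unname(fb[2]),
       F_interaction = unname(fw[2]), df = c(1, n - 2))
}

#' Unpack the CSD index by condition and group
#'
#' Given each subject's single-condition CSD value at the index site/bin,
#' reports the four condition-by-group cell means, a paired t test of the
#' condition effect within each group, and the condition-by-group
#' interaction F from the 2x2 mixed ANOVA — the analysis showing good
#' comprehenders flipping the frontal source into a sink in the
#' comprehension condition while poor comprehenders do not.
#'
#' @param csd_by_condition data.frame with columns `subject_id`,
#'   `scrambled`, `comprehension` (CSD at the index site/bin per condition).
#' @param groups factor (`poor`/`good`), one entry per subject, same order.
#' @return list with `cell_means` (group x condition), `paired_t` (per
#'   group: t, df, p), `interaction` (F, df), `anova` (full mixed table).
#' @export
condition_group_unpack <- function(csd_by_condition, groups) {
  need <- c("scrambled", "comprehension")
  stop_if_not(all(need %in% names(csd_by_condition)),
              "need columns scrambled and comprehension")
  v <- as.matrix(csd_by_condition[, need])
  groups <- factor(groups, levels = c("poor", "good"))
  stop_if_not(nrow(v) == length(groups), "one group label per subject")
  cell_means <- rbind(
    poor = colMeans(v[groups == "poor", , drop = FALSE]),
    good = colMeans(v[groups == "good", , drop = FALSE]))
  paired_t <- lapply(levels(groups), function(gl) {
    x <- v[groups == gl, , drop = FALSE]
    d <- x[, "scrambled"] - x[, "comprehension"]
    if (sd(d) == 0) {
      list(t = 0, df = length(d) - 1, p = 1)
    } else {
      tt <- t.test(x[, "scrambled"], x[, "comprehension"], paired = TRUE)
      list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
    }
  })
  names(paired_t) <- levels(groups)
  an <- mixed_anova_2x2(v, groups)
  list(cell_means = cell_means, paired_t = paired_t,
       interaction = list(F = an$F_interaction, df = an$df), anova = an)
}

#' 2x2 mixed ANOVA on behavioral measures
#'
#' Condition (scrambled vs. comprehension) within subjects, comprehension
#' group between subjects; returns the F statistics for the condition main
#' effect, group main effect and interaction, each on (1, n - 2) df —
#' applied to target-detection response times and error rates.
#'
#' @param behavior data.frame with columns `subject_id`, `scrambled`,
#'   `comprehension` (one behavioral measure per condition).
#' @param groups factor (`poor`/`good`) per subject, same order.
#' @return list with `F_condition`, `F_group`, `F_interaction`, `df`.
#' @export
behavioral_anova <- function(behavior, groups) {
  need <- c("scrambled", "comprehension")
  stop_if_not(all(need %in% names(behavior)),
              "need columns scrambled and comprehension")
  v <- as.matrix(behavior[, need])
  mixed_anova_2x2(v, groups)
}

#' Condition-order control analyses
#'
#' Tests whether the CSD index predicts comprehension over and above the
#' order in which the two conditions were administered: (1) independent t
#' test of score by order, (2) the ellipse-trimmed correlation within each
#' order subgroup (skipped with a notice when a subgroup has fewer than 4
#' subjects), and (3) an ordinary least-squares regression
#' `score ~ index + order` with per-coefficient t statistics.
#'
#' @param index per-subject CSD index.
#' @param scores per-subject comprehension scores.
#' @param order factor with levels `scrambled_first`, `comprehension_first`.
#' @param coverage ellipse coverage for the subgroup correlations.
#' @return list with `order_t` (t, df, p), `by_order` (per level: a
#'   [correlate_with_ellipse()] result or a skip notice), `regression`
#'   (coefficient table with t per coefficient, residual df).
#' @export
order_analysis <- function(index, scores, order, coverage = 0.95) {
  order <- factor(order, levels = c("scrambled_first", "comprehension_first"))
  stop_if_not(all(table(order) > 0), "both orders must be represented")
  tt <- t.test(scores ~ order, var.equal = TRUE)
  by_order <- lapply(levels(order), function(ol) {
    sel <- order == ol
    if (sum(sel) < 4) {
      list(skipped = TRUE,
           notice = sprintf("subgroup %s has n = %d < 4; correlation skipped",
                            ol, sum(sel)))
    } else {
      correlate_with_ellipse(index[sel], scores[sel], coverage)
    }
  })
  names(by_order) <- levels(order)
  ord_num <- as.integer(order) - 1
  fit <- lm(scores ~ index + ord_num)
  co <- summary(fit)$coefficients
  rownames(co) <- c("(Intercept)", "index", "order")
  list(order_t = list(t = unname(tt$statistic), df = unname(tt$parameter),
                      p = tt$p.value),
       by_order = by_order,
       regression = list(coefficients = co, df_residual = fit$df.residual))
}
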