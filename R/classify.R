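#' Configuration of the two-stage random-forest titration
#'
#' Stage 1 grows an ensemble of `n_trees` decision trees, each trained on a
#' fresh random `train_fraction` of the subjects with random site
#' subsampling per split, and ranks all sites by permutation importance.
#' Stage 2 reruns the ensemble on the `top_k_sites` highest-weight sites.
#' A "run" is one pass through both stages; `n_runs` runs are averaged for
#' the correct-label accuracy and `n_null_runs` label-scrambled runs form
#' the permutation null.
#'
#' @param n_trees trees per ensemble (default 300).
#' @param train_fraction per-tree training fraction of subjects (default
#'   0.65; each tree's accuracy is evaluated on its held-out remainder).
#' @param top_k_sites sites kept for stage 2 (default 10).
#' @param n_runs correct-label runs to average (default 1000).
#' @param n_null_runs scrambled-label runs (default 1000).
#' @param all_bins_jointly feed all bins' sites to a single classifier
#'   instead of one classifier per bin.
#' @param seed integer seed; every run derives its own child seed from it.
#' @return object of class `titration_config`.
#' @export
titration_config <- function(n_trees = 300, train_fraction = 0.65,
                             top_k_sites = 10, n_runs = 1000,
                             n_null_runs = 1000, all_bins_jointly = FALSE,
                             seed = 1) {
  stop_if_not(n_trees >= 1, "n_trees must be >= 1")
  stop_if_not(train_fraction > 0 && train_fraction < 1,
              "train_fraction must be in (0, 1)")
  stop_if_not(top_k_sites >= 1, "top_k_sites must be >= 1")
  stop_if_not(n_runs >= 1, "n_runs must be >= 1")
  stop_if_not(n_null_runs >= 0, "n_null_runs must be >= 0")
  structure(list(n_trees = n_trees, train_fraction = train_fraction,
                 top_k_sites = top_k_sites, n_runs = n_runs,
                 n_null_runs = n_null_runs,
                 all_bins_jointly = isTRUE(all_bins_jointly),
                 seed = as.integer(seed)),
            class = "titration_config")
}

# one bagged ensemble: returns mean per-tree held-out accuracy and
# (optionally) permutation-importance site weights, clamped at zero
rf_stage <- function(X, y, cfg, seed, importance = FALSE) {
  rf <- ranger::ranger(
    x = as.data.frame(X), y = y,
    num.trees = cfg$n_trees,
    sample.fraction = cfg$train_fraction,
    replace = FALSE,
    mtry = ceiling(sqrt(ncol(X))),
    importance = if (importance) "permutation" else "none",
    keep.inbag = TRUE,
    num.threads = 1,
    seed = seed)
  pred <- stats::predict(rf, as.data.frame(X), predict.all = TRUE,
                         num.threads = 1)$predictions
  inbag <- matrix(unlist(rf$inbag.counts), nrow = nrow(X))
  yi <- as.integer(y)
  acc <- vapply(seq_len(ncol(pred)), function(t) {
    oob <- inbag[, t] == 0
    if (!any(oob)) return(NA_real_)
    mean(pred[oob, t] == yi[oob])
  }, numeric(1))
  w <- NULL
  if (importance) {
    w <- pmax(rf$variable.importance, 0)
    names(w) <- colnames(X)
  }
  list(accuracy = mean(acc, na.rm = TRUE), weights = w)
}

#' One run of the two-stage site titration
#'
#' Stage 1 classifies good vs. poor comprehenders from all sites and yields
#' per-site weights (permutation importance: held-out accuracy drop when a
#' site's values are shuffled, averaged over trees and clamped at zero).
#' Stage 2 repeats the ensemble on the `top_k_sites` by stage-1 weight (ties
#' broken by site order).  The run's accuracy is the mean over stage-2 trees
#' of each tree's accuracy on its own held-out 35\% of subjects.
#' Deterministic given `seed`.
#'
#' @param features a [feature_table()] (needs both classes, at least 6
#'   subjects per class).
#' @param cfg a [titration_config()].
#' @param seed overrides `cfg$seed` for this run.
#' @return list with `accuracy` (stage 2), `stage1_accuracy`, `weights`
#'   (stage-1, all sites), `top_sites`.
#' @export
run_titration <- function(features, cfg = titration_config(), seed = cfg$seed) {
  stopifnot(inherits(features, "feature_table"), inherits(cfg, "titration_config"))
  y <- features$labels
  stop_if_not(nlevels(droplevels(y)) == 2, "labels must contain both classes")
  stop_if_not(min(table(y)) >= 6, "need at least 6 subjects per class")
  X <- features$matrix
  stop_if_not(cfg$top_k_sites <= ncol(X),
              "top_k_sites (%d) exceeds available sites (%d)",
              cfg$top_k_sites, ncol(X))
  s1 <- rf_stage(X, y, cfg, derive_seed(seed, 1), importance = TRUE)
  ord <- order(-s1$weights, seq_along(s1$weights)) # ties: fixed site order
  top <- colnames(X)[ord[seq_len(cfg$top_k_sites)]]
  s2 <- rf_stage(X[, top, drop = FALSE], y, cfg, derive_seed(seed, 2))
  list(accuracy = s2$accuracy, stage1_accuracy = s1$accuracy,
       weights = s1$weights, top_sites = top)
}

#' Averaged titration over many runs
#'
#' Repeats [run_titration()] `n_runs` times with fresh per-run seeds and
#' returns the run-level accuracy distribution and the mean site weights —
#' the quantity the classification profile reports per time bin.
#'
#' @inheritParams run_titration
#' @param n_runs number of runs (default `cfg$n_runs`).
#' @return list with `accuracies` (length `n_runs`), `mean_accuracy`,
#'   `sd_accuracy`, `weights` (mean stage-1 weights), `top_sites` (by mean
#'   weight).
#' @export
titration_runs <- function(features, cfg = titration_config(),
                           n_runs = cfg$n_runs, seed = cfg$seed) {
  acc <- numeric(n_runs)
  wsum <- 0
  for (r in seq_len(n_runs)) {
    res <- run_titration(features, cfg, seed = derive_seed(seed, 101, r))
    acc[r] <- res$accuracy
    wsum <- wsum + res$weights
  }
  w <- wsum / n_runs
  list(accuracies = acc, mean_accuracy = mean(acc), sd_accuracy = sd(acc),
       weights = w,
       top_sites = names(w)[order(-w, seq_along(w))][seq_len(cfg$top_k_sites)])
}

#' Permutation null for the titration classifier
#'
#' Repeats the full two-stage titration with the good/poor labels randomly
#' scrambled on every run (a uniform permutation, so class counts are
#' preserved), giving the accuracy distribution expected when the features
#' carry no comprehension information.
#'
#' @inheritParams run_titration
#' @param n_runs number of scrambled-label runs (default `cfg$n_null_runs`).
#' @return numeric vector of null accuracies (length `n_runs`; empty when 0).
#' @export
permutation_null <- function(features, cfg = titration_config(),
                             n_runs = cfg$n_null_runs, seed = cfg$seed) {
  stopifnot(inherits(features, "feature_table"))
  if (n_runs == 0) return(numeric(0))
  acc <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    rs <- derive_seed(seed, 202, r)
    perm <- withr_seed(rs, sample.int(length(features$labels)))
    f2 <- features
    f2$labels <- features$labels[perm]
    acc[r] <- run_titration(f2, cfg, seed = rs)$accuracy
  }
  acc
}

# evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Compare correct-label and null accuracy distributions
#'
#' The three significance quantifications for a classification profile:
#' (1) independent-groups t test over individual run accuracies, (2) effect
#' size d = mean difference / pooled SD, and (3) hit and false-positive
#' proportions for deciding which distribution an accuracy came from, using
#' an unbiased criterion midway between the two means (hits: correct-label
#' runs above criterion; false positives: null runs above it).
#'
#' @param correct_acc numeric vector of correct-label run accuracies.
#' @param null_acc numeric vector of scrambled-label run accuracies.
#' @return list with `t`, `df`, `p`, `d`, `hit_rate`, `fp_rate`, `criterion`,
#'   and the two means.
#' @export
compare_distributions <- function(correct_acc, null_acc) {
  stop_if_not(length(correct_acc) > 0 && length(null_acc) > 0,
              "both accuracy distributions must be non-empty")
  v1 <- if (length(correct_acc) > 1) var(correct_acc) else 0
  v2 <- if (length(null_acc) > 1) var(null_acc) else 0
  n1 <- length(correct_acc)
  n2 <- length(null_acc)
  m1 <- mean(correct_acc)
  m2 <- mean(null_acc)
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / max(1, n1 + n2 - 2))
  if (sp == 0 && m1 == m2) {
    stop("effect size undefined: zero variance and equal means", call. = FALSE)
  }
  if (sp == 0) {
    # fully separated point masses: effect size unbounded, decisions perfect
    tt <- list(statistic = sign(m1 - m2) * Inf, parameter = n1 + n2 - 2,
               p.value = 0)
    d <- sign(m1 - m2) * Inf
  } else {
    tt <- t.test(correct_acc, null_acc, var.equal = TRUE)
    d <- (m1 - m2) / sp
  }
  crit <- (m1 + m2) / 2
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       d = d,
       hit_rate = mean(correct_acc > crit), fp_rate = mean(null_acc > crit),
       criterion = crit, mean_correct = m1, mean_null = m2)
}

#' Classification profile over time bins
#'
#' Runs the averaged titration and its permutation null for every bin's
#' feature table and assembles the per-bin report: accuracy mean/SD for
#' correct and scrambled labels, mean site weights, and the three
#' significance statistics.  With `cfg$all_bins_jointly` all bins' sites are
#' concatenated into a single classifier instead.
#'
#' @param feature_tables named list of [feature_table()]s (one per bin), as
#'   from [bin_features()].
#' @param cfg a [titration_config()].
#' @return object of class `classification_report`: list with `per_bin`
#'   (list per bin: `accuracies`, `null_accuracies`, `mean_accuracy`,
#'   `sd_accuracy`, `null_mean`, `null_sd`, `weights`, `stats`), `summary`
#'   data.frame, `best_bin`, `best_site`, `feature_mode`, `config`.
#' @export
classify_bins <- function(feature_tables, cfg = titration_config()) {
  stopifnot(length(feature_tables) >= 1)
  if (cfg$all_bins_jointly) {
    joint <- do.call(cbind, lapply(feature_tables, function(f) {
      m <- f$matrix
      colnames(m) <- paste(f$bin_id, colnames(m), sep = ":")
      m
    }))
    feature_tables <- list(all_bins = feature_table(
      joint, feature_tables[[1]]$labels, "all_bins",
      feature_tables[[1]]$feature_mode))
  }
  per_bin <- list()
  for (b in names(feature_tables)) {
    ft <- feature_tables[[b]]
    bseed <- derive_seed(cfg$seed, 11, match(b, names(feature_tables)))
    runs <- titration_runs(ft, cfg, seed = bseed)
    nulls <- permutation_null(ft, cfg, seed = derive_seed(bseed, 12))
    stats <- if (length(nulls) > 0) compare_distributions(runs$accuracies, nulls)
             else NULL
    per_bin[[b]] <- list(accuracies = runs$accuracies,
                         null_accuracies = nulls,
                         mean_accuracy = runs$mean_accuracy,
                         sd_accuracy = runs$sd_accuracy,
                         null_mean = if (length(nulls)) mean(nulls) else NA_real_,
                         null_sd = if (length(nulls)) sd(nulls) else NA_real_,
                         weights = runs$weights,
                         top_sites = runs$top_sites,
                         stats = stats)
  }
  summ <- data.frame(
    bin = names(per_bin),
    mean_accuracy = vapply(per_bin, `[[`, 1, "mean_accuracy"),
    sd_accuracy = vapply(per_bin, `[[`, 1, "sd_accuracy"),
    null_mean = vapply(per_bin, `[[`, 1, "null_mean"),
    null_sd = vapply(per_bin, `[[`, 1, "null_sd"),
    top_site = vapply(per_bin, function(x) x$top_sites[1], ""),
    row.names = NULL)
  best <- which.max(summ$mean_accuracy)
  structure(list(per_bin = per_bin, summary = summ,
                 best_bin = summ$bin[best], best_site = summ$top_site[best],
                 feature_mode = feature_tables[[1]]$feature_mode,
                 config = cfg),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> feature mode: %s\n", x$feature_mode))
  print(transform(x$summary,
                  mean_accuracy = round(mean_accuracy, 3),
                  sd_accuracy = round(sd_accuracy, 3),
                  null_mean = round(null_mean, 3),
                  null_sd = round(null_sd, 3)))
  cat(sprintf("best bin: %s ms; top site there: %s\n", x$best_bin, x$best_site))
  invisible(x)
}
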