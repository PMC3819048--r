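# small, fast fixtures shared across test files

eog3 <- c("EOG_L", "EOG_R", "EOG_V")

# reduced word stream: quick to simulate, still has epochable targets
quick_cfg <- function(seed = 1, ...) {
  args <- utils::modifyList(list(n_words = 60, n_targets = 8, seed = seed),
                            list(...))
  do.call(cohort_config, args)
}

# single-trial epoch set around a channels x samples matrix
one_epoch <- function(values, fs_hz = 256, window_ms = c(0, 500),
                      channels = rownames(values)) {
  arr <- array(0, c(1, nrow(values), ncol(values)))
  arr[1, , ] <- values
  epoch_set(arr, channels, fs_hz, window_ms)
}

# event table with targets at given word positions
events_with_targets <- function(targets, n = 120, fs = 256, correct = TRUE) {
  soa <- round(0.5 * fs)
  is_t <- seq_len(n) %in% targets
  ok <- rep(NA, n)
  ok[is_t] <- correct
  event_table(onset_sample = fs + (seq_len(n) - 1) * soa + 1,
              trial_index = seq_len(n), label = ifelse(is_t, "and", "word"),
              is_target = is_t, response_correct = ok)
}

# deterministic synthetic feature table: one informative site
separable_features <- function(n_per_class = 14, n_sites = 20, gap = 2,
                               noise = 0.05, seed = 42) {
  set.seed(seed)
  n <- 2 * n_per_class
  X <- matrix(rnorm(n * n_sites, sd = noise), n,
              dimnames = list(NULL, paste0("site", seq_len(n_sites))))
  y <- factor(rep(c("poor", "good"), each = n_per_class),
              levels = c("poor", "good"))
  X[, "site7"] <- X[, "site7"] + ifelse(y == "good", gap / 2, -gap / 2)
  feature_table(X, y, "test-bin")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
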