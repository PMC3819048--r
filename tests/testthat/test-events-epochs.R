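test_that("event tables enforce ordering and round-trip as TSV", {
  expect_error(event_table(c(10, 5), 1:2, "w", FALSE), "strictly increasing")
  ev <- events_with_targets(c(3, 9), n = 12)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_events_tsv(ev, f)
  ev2 <- read_events_tsv(f)
  expect_equal(ev2$onset_sample, ev$onset_sample)
  expect_equal(ev2$is_target, ev$is_target)
  expect_equal(ev2$response_correct, ev$response_correct)
})

test_that("target-trial selection applies the 4-trial lookback over word positions", {
  ev <- events_with_targets(c(10, 12, 100), n = 120)
  expect_equal(select_target_trials(ev), c(10, 100)) # 12 excluded: 10 in its previous 4
  expect_equal(select_target_trials(events_with_targets(integer(0))), integer(0))
  spaced <- events_with_targets(c(5, 10, 15, 20))
  expect_equal(select_target_trials(spaced), c(5, 10, 15, 20))
  expect_error(select_target_trials(ev, lookback = -1), ">= 0")
})

test_that("incorrectly detected targets are dropped unless asked otherwise", {
  ev <- events_with_targets(c(10, 40), n = 60)
  ev$response_correct[10] <- FALSE
  expect_equal(select_target_trials(ev), 40)
  expect_equal(select_target_trials(ev, require_correct = FALSE), c(10, 40))
})

test_that("selection ignores non-target labels entirely", {
  ev <- events_with_targets(c(10, 40), n = 60)
  ev2 <- ev
  ev2$label[!ev2$is_target] <- sample(letters, sum(!ev2$is_target), TRUE)
  expect_identical(select_target_trials(ev), select_target_trials(ev2))
})

test_that("epoch extraction is sample-accurate and reports boundary rejections", {
  fs <- 1024
  ev <- event_table(onset_sample = c(100, 5000), trial_index = 1:2,
                    label = "and", is_target = TRUE, response_correct = TRUE)
  eeg <- matrix(seq_len(2 * 5200), 2, 5200)
  rownames(eeg) <- c("A", "B")
  ep <- extract_epochs(eeg, ev, window_ms = c(0, 500), fs_hz = fs)
  expect_equal(dim(ep$data)[3], 512) # 0.5 s x 1024 Hz
  expect_equal(dim(ep$data)[1], 1)
  expect_equal(attr(ep, "trial_index"), 1L)
  expect_equal(attr(ep, "rejected")$trial_index, 2L)
  expect_equal(ep$data[1, 1, ], eeg[1, 100:611], ignore_attr = TRUE)
  expect_error(extract_epochs(eeg, ev, trial_subset = 99, fs_hz = fs),
               "empty event selection")
  attr(eeg, "fs_hz") <- 512
  expect_error(extract_epochs(eeg, ev, fs_hz = fs), "mismatch")
})

test_that("epoch extraction is translation-consistent", {
  fs <- 256
  set.seed(3)
  eeg <- matrix(rnorm(2 * 4000), 2, 4000)
  rownames(eeg) <- c("A", "B")
  ev <- event_table(c(300, 900), 1:2, "and", TRUE, TRUE)
  k <- 57
  eeg_shift <- cbind(matrix(0, 2, k), eeg)
  rownames(eeg_shift) <- c("A", "B")
  ev_shift <- event_table(c(300, 900) + k, 1:2, "and", TRUE, TRUE)
  e1 <- extract_epochs(eeg, ev, fs_hz = fs)
  e2 <- extract_epochs(eeg_shift, ev_shift, fs_hz = fs)
  expect_equal(e1$data, e2$data)
})

test_that("baseline modes satisfy their defining identities", {
  set.seed(4)
  arr <- array(rnorm(3 * 2 * 128, mean = 5), c(3, 2, 128))
  ep <- epoch_set(arr, c("A", "B"), 256, c(0, 500))
  b <- apply_baseline(ep, "post_onset_50")
  idx <- 1:12 # [0, 50) ms at 256 Hz, floor-aligned to the sample grid
  for (tr in 1:3) for (ch in 1:2) {
    expect_lt(abs(mean(b$data[tr, ch, idx])), 1e-9)
  }
  expect_identical(apply_baseline(ep, "none"), ep)
  cst <- epoch_set(array(7, c(1, 2, 128)), c("A", "B"), 256, c(0, 500))
  expect_equal(max(abs(apply_baseline(cst, "whole_epoch")$data)), 0)
  pre <- epoch_set(array(1, c(1, 2, 26)), c("A", "B"), 256, c(100, 201.5625))
  expect_error(apply_baseline(pre, "post_onset_50"), "baseline interval")
})

test_that("ERP averaging is exact for identical trials and shrinks noise as 1/sqrt(N)", {
  one <- matrix(rnorm(2 * 64), 2, 64)
  arr <- array(0, c(5, 2, 64))
  for (i in 1:5) arr[i, , ] <- one
  ep <- epoch_set(arr, c("A", "B"), 128, c(0, 500))
  expect_equal(average_erp(ep)$values, one, ignore_attr = TRUE)
  expect_equal(average_erp(ep, 2)$values, one, ignore_attr = TRUE)
  expect_equal(average_erp(ep)$n_trials, 5L)
  expect_error(average_erp(ep, integer(0)), "empty")

  set.seed(9)
  noise <- epoch_set(array(rnorm(100 * 2 * 64), c(100, 2, 64)),
                     c("A", "B"), 128, c(0, 500))
  e <- average_erp(noise)
  expect_lt(abs(sd(e$values) - 0.1) / 0.1, 0.2) # Monte-Carlo 1/sqrt(100)
})

test_that("ERP averaging is linear in the epoch data", {
  set.seed(10)
  a1 <- array(rnorm(4 * 2 * 32), c(4, 2, 32))
  a2 <- array(rnorm(4 * 2 * 32), c(4, 2, 32))
  mk <- function(a) epoch_set(a, c("A", "B"), 64, c(0, 500))
  lhs <- average_erp(mk(2 * a1 + 3 * a2))$values
  rhs <- 2 * average_erp(mk(a1))$values + 3 * average_erp(mk(a2))$values
  expect_equal(lhs, rhs)
})

test_that("long-format export carries tags, channels and time", {
  ep <- one_epoch(matrix(1:8, 2, 4, dimnames = list(c("A", "B"), NULL)),
                  fs_hz = 8, window_ms = c(0, 500))
  df <- as.data.frame(ep)
  expect_setequal(names(df), c("subject", "condition", "trial", "channel",
                               "time_ms", "value"))
  expect_equal(nrow(df), 8)
  expect_equal(sort(unique(df$time_ms)), c(0, 125, 250, 375))
})
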