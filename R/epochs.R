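#' Epoch set
#'
#' Trials x channels x samples tensor of amplitudes (\eqn{\mu V}) time-locked
#' to word onsets, with sampling metadata and tags.  The epoch window is
#' half-open: `window_ms = c(0, 500)` at 1024 Hz gives 512 samples covering
#' \[0, 500) ms.
#'
#' @param data 3-d numeric array (trials x channels x samples).
#' @param channels channel labels (length = dim 2).
#' @param fs_hz sampling rate (Hz).
#' @param window_ms epoch interval relative to onset, ms (default `c(0, 500)`).
#' @param subject_id,condition tags.
#' @param baseline_mode one of `"none"`, `"post_onset_50"`, `"whole_epoch"`.
#' @return object of class `epoch_set`.
#' @export
epoch_set <- function(data, channels, fs_hz, window_ms = c(0, 500),
                      subject_id = NA_character_, condition = NA_character_,
                      baseline_mode = "none") {
  data <- unclass(data)
  stop_if_not(length(dim(data)) == 3, "data must be trials x channels x samples")
  stop_if_not(dim(data)[2] == length(channels), "dim 2 must match channels")
  n_expect <- round(diff(window_ms) / 1000 * fs_hz)
  stop_if_not(dim(data)[3] == n_expect,
              "window [%g, %g) ms at %g Hz implies %d samples, got %d",
              window_ms[1], window_ms[2], fs_hz, n_expect, dim(data)[3])
  baseline_mode <- match.arg(baseline_mode, c("none", "post_onset_50", "whole_epoch"))
  dimnames(data) <- list(NULL, channels, NULL)
  structure(list(data = data, channels = as.character(channels), fs_hz = fs_hz,
                 window_ms = as.numeric(window_ms), subject_id = subject_id,
                 condition = condition, baseline_mode = baseline_mode),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %s/%s: %d trials x %d channels x %d samples @ %g Hz (baseline: %s)\n",
              x$subject_id, x$condition, dim(x$data)[1], dim(x$data)[2],
              dim(x$data)[3], x$fs_hz, x$baseline_mode))
  invisible(x)
}

n_epochs <- function(x) dim(x$data)[1]

#' Extract epochs from a continuous recording
#'
#' Cuts one epoch per selected event, sample-accurately, from a continuous
#' channels x samples matrix.  Events whose window would run past either end
#' of the recording are not cut; they are reported in the `rejected`
#' attribute of the result (trial index and reason) rather than silently
#' dropped.
#'
#' @param eeg channels x samples numeric matrix (rownames = channel labels).
#' @param events an [event_table()].
#' @param trial_subset optional vector of `trial_index` values to epoch
#'   (default: all events).
#' @param window_ms epoch interval (ms relative to onset, half-open).
#' @param fs_hz sampling rate of `eeg`; must equal `attr(eeg, "fs_hz")` when
#'   that attribute is present.
#' @param subject_id,condition tags carried into the result.
#' @return an [epoch_set()] with attribute `rejected` (data.frame of
#'   out-of-range events, possibly empty) and attribute `trial_index`
#'   (the trial index of each retained epoch).
#' @export
extract_epochs <- function(eeg, events, trial_subset = NULL,
                           window_ms = c(0, 500), fs_hz,
                           subject_id = NA_character_, condition = NA_character_) {
  stopifnot(inherits(events, "event_table"))
  eeg <- as.matrix(eeg)
  fs_attr <- attr(eeg, "fs_hz")
  if (!is.null(fs_attr) && !isTRUE(all.equal(fs_attr, fs_hz))) {
    stop(sprintf("sampling-rate mismatch: recording is %g Hz, request is %g Hz",
                 fs_attr, fs_hz), call. = FALSE)
  }
  sel <- if (is.null(trial_subset)) events$trial_index else trial_subset
  sel <- events[events$trial_index %in% sel, , drop = FALSE]
  if (nrow(sel) == 0) stop("empty event selection: no epochs to extract", call. = FALSE)
  n_samp <- round(diff(window_ms) / 1000 * fs_hz)
  offset <- round(window_ms[1] / 1000 * fs_hz)
  first <- sel$onset_sample + offset
  last <- first + n_samp - 1
  ok <- first >= 1 & last <= ncol(eeg)
  rejected <- data.frame(trial_index = sel$trial_index[!ok],
                         onset_sample = sel$onset_sample[!ok],
                         reason = rep("epoch window outside recording", sum(!ok)))
  if (!any(ok)) stop("all requested epochs fall outside the recording", call. = FALSE)
  arr <- array(NA_real_, c(sum(ok), nrow(eeg), n_samp))
  ki <- which(ok)
  for (i in seq_along(ki)) {
    arr[i, , ] <- eeg[, first[ki[i]]:last[ki[i]], drop = FALSE]
  }
  es <- epoch_set(arr, rownames(eeg) %||% paste0("ch", seq_len(nrow(eeg))),
                  fs_hz, window_ms, subject_id, condition)
  attr(es, "rejected") <- rejected
  attr(es, "trial_index") <- sel$trial_index[ok]
  es
}

#' Baseline-correct an epoch set
#'
#' `post_onset_50` subtracts, per trial and channel, the mean over the first
#' 50 ms after word onset (\[0, 50) ms, half-open on the sample grid) — used
#' because with one word every 500 ms the response to the previous word is
#' still unfolding before onset, making a pre-stimulus baseline unsuitable.
#' `whole_epoch` subtracts the mean over the full window; `none` is the
#' identity.
#'
#' @param epochs an [epoch_set()].
#' @param mode baseline mode.
#' @return a baselined [epoch_set()].
#' @export
apply_baseline <- function(epochs, mode = c("post_onset_50", "whole_epoch", "none")) {
  stopifnot(inherits(epochs, "epoch_set"))
  mode <- match.arg(mode)
  if (mode == "none") return(epochs)
  x <- epochs$data
  if (mode == "post_onset_50") {
    stop_if_not(epochs$window_ms[1] <= 0 && epochs$window_ms[2] >= 50,
                "window [%g, %g) ms does not contain the [0, 50) ms baseline interval",
                epochs$window_ms[1], epochs$window_ms[2])
    idx <- ms_to_samples(c(0, 50), epochs$fs_hz, epochs$window_ms)
    sl <- idx[1]:idx[2]
  } else {
    sl <- seq_len(dim(x)[3])
  }
  bl <- apply(x[, , sl, drop = FALSE], c(1, 2), mean)
  out <- sweep(x, c(1, 2), bl, `-`)
  epoch_set(out, epochs$channels, epochs$fs_hz, epochs$window_ms,
            epochs$subject_id, epochs$condition, baseline_mode = mode)
}

#' Event-related potential (trial average)
#'
#' @param values channels x samples mean amplitude (\eqn{\mu V}).
#' @param n_trials number of trials averaged (>= 1).
#' @param channels,fs_hz,window_ms,subject_id,condition as in [epoch_set()].
#' @return object of class `erp`.
#' @export
erp <- function(values, n_trials, channels, fs_hz, window_ms,
                subject_id = NA_character_, condition = NA_character_) {
  values <- as.matrix(values)
  stop_if_not(all(is.finite(values)), "ERP values must be finite")
  stop_if_not(n_trials >= 1, "n_trials must be >= 1")
  rownames(values) <- channels
  structure(list(values = values, n_trials = as.integer(n_trials),
                 channels = as.character(channels), fs_hz = fs_hz,
                 window_ms = window_ms, subject_id = subject_id,
                 condition = condition),
            class = "erp")
}

#' Average epochs into an ERP
#'
#' Pointwise arithmetic mean over the selected trials.
#'
#' @param epochs an [epoch_set()].
#' @param trial_subset trial (row) indices to average; default all.
#' @return an [erp()].
#' @export
average_erp <- function(epochs, trial_subset = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  idx <- trial_subset %||% seq_len(n_epochs(epochs))
  stop_if_not(length(idx) > 0, "cannot average an empty trial subset")
  stop_if_not(all(idx >= 1 & idx <= n_epochs(epochs)), "trial subset out of range")
  m <- apply(epochs$data[idx, , , drop = FALSE], c(2, 3), mean)
  erp(m, length(idx), epochs$channels, epochs$fs_hz, epochs$window_ms,
      epochs$subject_id, epochs$condition)
}

#' Export epochs or an ERP as a long-format data frame
#'
#' Long format: subject, condition, (trial,) channel, time_ms, value — the
#' CSV interchange layout.
#'
#' @param x an [epoch_set()], [erp()] or [csd_map()].
#' @param ... unused.
#' @return a `data.frame`.
#' @export
as.data.frame.erp <- function(x, ...) {
  t_ms <- x$window_ms[1] + (seq_len(ncol(x$values)) - 1) / x$fs_hz * 1000
  data.frame(subject = x$subject_id, condition = x$condition,
             channel = rep(x$channels, times = ncol(x$values)),
             time_ms = rep(t_ms, each = nrow(x$values)),
             value = as.vector(x$values))
}

#' @rdname as.data.frame.erp
#' @export
as.data.frame.csd_map <- function(x, ...) {
  t_ms <- x$window_ms[1] + (seq_len(ncol(x$values)) - 1) / x$fs_hz * 1000
  data.frame(subject = x$subject_id, condition = x$condition,
             channel = rep(x$channels, times = ncol(x$values)),
             time_ms = rep(t_ms, each = nrow(x$values)),
             value = as.vector(x$values))
}

#' @rdname as.data.frame.erp
#' @export
as.data.frame.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  t_ms <- x$window_ms[1] + (seq_len(d[3]) - 1) / x$fs_hz * 1000
  data.frame(subject = x$subject_id, condition = x$condition,
             trial = rep(seq_len(d[1]), times = d[2] * d[3]),
             channel = rep(rep(x$channels, each = d[1]), times = d[3]),
             time_ms = rep(t_ms, each = d[1] * d[2]),
             value = as.vector(x$data))
}
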