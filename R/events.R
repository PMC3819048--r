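#' Event table
#'
#' One row per presented word: sample-index onset, ordinal position in the
#' word stream, token label, target flag, detection correctness and response
#' time (targets only; `NA` otherwise).
#'
#' @param onset_sample integer sample indices (1-based, strictly increasing).
#' @param trial_index ordinal word positions (strictly increasing).
#' @param label word token or category.
#' @param is_target logical flag.
#' @param response_correct logical; `NA` for non-targets.
#' @param rt_ms numeric response latency; `NA` where absent.
#' @return a `data.frame` with class `event_table`.
#' @export
event_table <- function(onset_sample, trial_index, label, is_target,
                        response_correct = NA, rt_ms = NA_real_) {
  df <- data.frame(onset_sample = as.integer(onset_sample),
                   trial_index = as.integer(trial_index),
                   label = as.character(label),
                   is_target = as.logical(is_target),
                   response_correct = as.logical(response_correct),
                   rt_ms = as.numeric(rt_ms),
                   stringsAsFactors = FALSE)
  stop_if_not(!is.unsorted(df$onset_sample, strictly = TRUE),
              "onset_sample must be strictly increasing")
  stop_if_not(!is.unsorted(df$trial_index, strictly = TRUE),
              "trial_index must be strictly increasing")
  class(df) <- c("event_table", "data.frame")
  df
}

#' Read / write an event table as tab-separated text
#'
#' Columns: `onset_sample`, `trial_index`, `label`, `is_target`,
#' `response_correct`, `rt_ms` (header required).
#'
#' @param path file path.
#' @return `read_events_tsv` returns an [event_table()].
#' @export
read_events_tsv <- function(path) {
  stop_if_not(file.exists(path), "no such events file: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("onset_sample", "trial_index", "label", "is_target",
            "response_correct", "rt_ms")
  stop_if_not(all(need %in% names(df)),
              "events file lacks columns: %s",
              paste(setdiff(need, names(df)), collapse = ", "))
  event_table(df$onset_sample, df$trial_index, df$label,
              df$is_target, df$response_correct, df$rt_ms)
}

#' @rdname read_events_tsv
#' @param events an [event_table()].
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select analyzable target trials
#'
#' Returns the trial indices of target words that (a) were correctly
#' detected (when `require_correct`) and (b) have no other target among the
#' `lookback` immediately preceding word positions — the repetition-priming
#' guard.  The lookback counts word positions in the stream, not target
#' occurrences.
#'
#' @param events an [event_table()] ordered by `trial_index`.
#' @param lookback number of preceding word positions to inspect (default 4).
#' @param require_correct keep only correctly detected targets (default TRUE).
#' @return integer vector of retained `trial_index` values.
#' @export
select_target_trials <- function(events, lookback = 4, require_correct = TRUE) {
  stopifnot(inherits(events, "event_table"))
  stop_if_not(lookback >= 0, "lookback must be >= 0")
  tgt <- events$trial_index[events$is_target]
  if (length(tgt) == 0) return(integer(0))
  keep <- vapply(tgt, function(ti) {
    !any(tgt > ti - lookback - 1 & tgt < ti)
  }, logical(1))
  if (require_correct) {
    ok <- events$response_correct[match(tgt, events$trial_index)]
    keep <- keep & !is.na(ok) & ok
  }
  tgt[keep]
}
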