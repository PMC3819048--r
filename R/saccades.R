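#' Count saccades in EOG epochs
#'
#' Step detector for ocular artifacts: for each EOG channel a two-sided
#' sliding step estimate is computed — the mean over the following
#' `smooth_ms` minus the mean over the preceding `smooth_ms` (a smoothed
#' first derivative scaled to amplitude units, so a clean step of s
#' \eqn{\mu V} yields an estimate of s at the step).  Estimates exceeding
#' `step_uv` mark saccade onsets; crossings closer together than the
#' refractory period — pooled across channels, since one saccade deflects
#' all EOG channels at once — are merged into one saccade.  Counts are
#' returned per epoch together with their mean, the per-subject/condition
#' summary the eye-movement control analysis uses.
#'
#' @param eog_epochs an [epoch_set()] whose channels are EOG channels (or an
#'   epoch set from which `channels` selects them).
#' @param channels which channels to treat as EOG (default: all channels of
#'   `eog_epochs`; error if any is missing).
#' @param step_uv amplitude threshold for a step, in \eqn{\mu V} (default 40).
#' @param smooth_ms averaging window on each side of the step estimate
#'   (default 30 ms).
#' @param refractory_ms minimum separation between distinct saccades
#'   (default 80 ms).
#' @return list with `per_epoch` (integer counts) and `mean` (mean count per
#'   epoch).
#' @export
count_saccades <- function(eog_epochs, channels = NULL, step_uv = 40,
                           smooth_ms = 30, refractory_ms = 80) {
  stopifnot(inherits(eog_epochs, "epoch_set"))
  chans <- channels %||% eog_epochs$channels
  keep <- match(chans, eog_epochs$channels)
  if (length(keep) == 0 || anyNA(keep)) {
    stop("EOG channels missing from epoch set: ",
         paste(chans[is.na(keep)], collapse = ", "), call. = FALSE)
  }
  fs <- eog_epochs$fs_hz
  w <- max(1L, round(smooth_ms / 1000 * fs))
  refr <- max(1L, round(refractory_ms / 1000 * fs))
  n_tr <- dim(eog_epochs$data)[1]
  n_s <- dim(eog_epochs$data)[3]
  stop_if_not(n_s > 2 * w, "epochs too short for a %g-ms step window", smooth_ms)
  counts <- integer(n_tr)
  idx <- w:(n_s - w) # step placed between x[idx] and x[idx + 1]
  for (tr in seq_len(n_tr)) {
    onsets <- integer(0)
    for (ch in keep) {
      x <- eog_epochs$data[tr, ch, ]
      cum <- c(0, cumsum(x))
      fwd <- (cum[idx + 1 + w] - cum[idx + 1]) / w
      bwd <- (cum[idx + 1] - cum[idx + 1 - w]) / w
      hit <- which(abs(fwd - bwd) > step_uv)
      onsets <- c(onsets, idx[hit])
    }
    if (length(onsets)) {
      onsets <- sort(onsets)
      n <- 1L
      last <- onsets[1]
      for (o in onsets[-1]) {
        if (o - last > refr) {
          n <- n + 1L
          last <- o
        }
      }
      counts[tr] <- n
    }
  }
  list(per_epoch = counts, mean = mean(counts))
}
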