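#' Time-bin specification for classification features
#'
#' Default: eight 100-ms bins overlapping by 50 ms across the 50-500 ms
#' post-onset range (50-150, 100-200, ..., 400-500 ms).  With
#' `extra_prestim_bins` three further bins (-100-0, -50-50, 0-100 ms) are
#' added, the layout used by the alternative-baseline control analyses.
#'
#' @param width_ms bin width (default 100).
#' @param hop_ms hop between bin starts (default 50).
#' @param start_ms,end_ms range covered (defaults 50 and 500).
#' @param extra_prestim_bins add the three pre-stimulus/early bins.
#' @return object of class `bin_spec`; `bins` is a data.frame with
#'   `start_ms`, `end_ms`, `bin_id` (half-open intervals).
#' @export
bin_spec <- function(width_ms = 100, hop_ms = 50, start_ms = 50, end_ms = 500,
                     extra_prestim_bins = FALSE) {
  stop_if_not(width_ms > 0 && hop_ms > 0, "bin width and hop must be positive")
  stop_if_not(end_ms - start_ms >= width_ms, "range shorter than one bin")
  starts <- seq(start_ms, end_ms - width_ms, by = hop_ms)
  bins <- data.frame(start_ms = starts, end_ms = starts + width_ms)
  if (extra_prestim_bins) {
    bins <- rbind(data.frame(start_ms = c(-100, -50, 0), end_ms = c(0, 50, 100)),
                  bins)
  }
  bins$bin_id <- sprintf("%g-%g", bins$start_ms, bins$end_ms)
  structure(list(width_ms = width_ms, hop_ms = hop_ms, start_ms = start_ms,
                 end_ms = end_ms, extra_prestim_bins = extra_prestim_bins,
                 bins = bins), class = "bin_spec")
}

#' Feature table for one time bin
#'
#' Subjects x sites matrix of bin-averaged values plus good/poor labels.
#'
#' @param matrix subjects x sites numeric matrix (rownames subjects,
#'   colnames sites).
#' @param labels factor of group labels, levels `poor`/`good`.
#' @param bin_id bin identifier.
#' @param feature_mode which signal produced the features: one of
#'   `difference_csd`, `difference_erp`, `scrambled_csd`, `comprehension_csd`,
#'   `nontarget_difference_csd`.
#' @return object of class `feature_table`.
#' @export
feature_table <- function(matrix, labels, bin_id,
                          feature_mode = "difference_csd") {
  matrix <- as.matrix(matrix)
  stop_if_not(all(is.finite(matrix)), "feature matrix must be finite")
  labels <- factor(labels, levels = c("poor", "good"))
  stop_if_not(length(labels) == nrow(matrix), "one label per subject required")
  feature_mode <- match.arg(feature_mode,
                            c("difference_csd", "difference_erp", "scrambled_csd",
                              "comprehension_csd", "nontarget_difference_csd"))
  structure(list(matrix = matrix, labels = labels, bin_id = bin_id,
                 site_names = colnames(matrix), feature_mode = feature_mode),
            class = "feature_table")
}

#' Bin per-subject maps into classification features
#'
#' Averages each subject's channels x samples map (difference-CSD by
#' default, or any of the control signals) over each bin's half-open time
#' interval, yielding one subjects x sites [feature_table()] per bin.
#'
#' @param maps named list of per-subject [csd_map()] (or `erp`) objects with
#'   identical channels and sampling.
#' @param labels group labels, one per subject (same order as `maps`).
#' @param spec a [bin_spec()].
#' @param feature_mode recorded on each table (see [feature_table()]).
#' @return named list of [feature_table()]s, one per bin.
#' @export
bin_features <- function(maps, labels, spec = bin_spec(),
                         feature_mode = "difference_csd") {
  stopifnot(inherits(spec, "bin_spec"), length(maps) >= 1)
  m1 <- maps[[1]]
  win <- m1$window_ms
  stop_if_not(all(spec$bins$start_ms >= win[1]) && all(spec$bins$end_ms <= win[2]),
              "bins [%g, %g] ms fall outside the epoch window [%g, %g) ms",
              min(spec$bins$start_ms), max(spec$bins$end_ms), win[1], win[2])
  subj <- names(maps) %||% paste0("s", seq_along(maps))
  out <- list()
  for (b in seq_len(nrow(spec$bins))) {
    idx <- ms_to_samples(c(spec$bins$start_ms[b], spec$bins$end_ms[b]),
                         m1$fs_hz, win)
    feats <- t(vapply(maps, function(m) {
      stop_if_not(identical(m$channels, m1$channels), "maps differ in channels")
      rowMeans(m$values[, idx[1]:idx[2], drop = FALSE])
    }, numeric(length(m1$channels))))
    rownames(feats) <- subj
    colnames(feats) <- m1$channels
    out[[spec$bins$bin_id[b]]] <- feature_table(feats, labels,
                                                spec$bins$bin_id[b], feature_mode)
  }
  out
}
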