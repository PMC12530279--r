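# Windowed read-depth profiling for collapsed duplicated (tetrasomic) region
# detection: regions present in four copies that an assembly merged into one
# sequence show roughly doubled mapped-read depth.

#' Windowed mean-depth profile, median-normalised
#'
#' Non-overlapping windows tiled from position 1; trailing partial windows are
#' averaged over their covered positions. Each window mean is divided by the
#' genome-wide *median* of window means, which is robust to the very regions
#' being flagged.
#'
#' @param depth data.frame with `chrom`, `pos` (1-based), `depth` (>= 0).
#' @param window window length in bp (default 50000).
#' @return data.frame: `chrom`, `start0`, `end`, `n_sites`, `mean_depth`,
#'   `norm_depth`.
#' @export
window_depth_profile <- function(depth, window = 50000L) {
  if (nrow(depth) == 0L) stop_param("empty depth track")
  if (any(depth$depth < 0)) stop_param("depth must be non-negative")
  k <- window_key(depth$chrom, depth$pos, window)
  agg <- rowsum(cbind(d = depth$depth, n = 1), k$key)
  meta <- do.call(rbind, strsplit(rownames(agg), "\r", fixed = TRUE))
  win <- as.integer(meta[, 2L])
  mean_depth <- agg[, "d"] / agg[, "n"]
  out <- data.frame(chrom = meta[, 1L],
                    start0 = win * as.integer(window),
                    end = (win + 1L) * as.integer(window),
                    n_sites = as.integer(agg[, "n"]),
                    mean_depth = mean_depth,
                    norm_depth = mean_depth / stats::median(mean_depth))
  out <- out[order(out$chrom, out$start0), ]
  rownames(out) <- NULL
  out
}

#' Flag sequences with collapsed-duplication depth signal
#'
#' A sequence is flagged when the median of its normalised window depths
#' reaches `factor`. The default 1.6 sits between the disomic (1x) and the
#' collapsed tetrasomic (2x) expectation.
#'
#' @param profile output of [window_depth_profile()].
#' @param factor trigger factor on normalised depth (default 1.6).
#' @return list: `flagged` (data.frame `chrom`, `median_norm_depth` of flagged
#'   sequences), `windows` (data.frame of individual elevated windows, BED-ready
#'   via [write_bed()] after converting `start0` back to 1-based).
#' @export
flag_collapsed <- function(profile, factor = 1.6) {
  med <- vapply(split(profile$norm_depth, profile$chrom), stats::median,
                numeric(1))
  flagged <- data.frame(chrom = names(med), median_norm_depth = as.numeric(med))
  flagged <- flagged[flagged$median_norm_depth >= factor, , drop = FALSE]
  rownames(flagged) <- NULL
  windows <- profile[profile$norm_depth >= factor, , drop = FALSE]
  rownames(windows) <- NULL
  list(flagged = flagged, windows = windows, factor = factor)
}
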