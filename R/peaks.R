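#' Call candidate peaks from a pair of strand-specific border profiles
#'
#' Candidate 5' borders are local maxima of the depth-normalized profile
#' whose height is at least `k` times the local background (mean over a
#' centered `bg_window` bp window, floored at the uniform expectation
#' `1e6 / genome length`).  Each forward border is then paired with the
#' nearest downstream reverse border at most `max_span` bp away; the peak
#' interval runs from the forward border to one past the reverse border
#' (0-based half-open), mirroring the footprint the exonuclease protected.
#' Unpaired borders are discarded.  The signal-to-noise ratio of each peak
#' is computed with [signal_to_noise()].
#'
#' @param fwd,rev depth-normalized [border_profile()]s for the two strands
#'   of one library.
#' @param k candidate threshold in multiples of local background.
#' @param bg_window width (bp) of the centered local-background window.
#' @param max_span maximum forward-to-reverse border distance (bp).
#' @param local_halfwidth half-width (bp) of the local-maximum window; a
#'   border must strictly exceed everything to its left and be at least as
#'   high as everything to its right within this window (leftmost-max
#'   tie-break).
#' @return data.frame of peaks: `peak_id`, `start`, `end`, `center`,
#'   `fwd_border`, `rev_border`, `sn`, `support`.
#' @export
call_candidate_peaks <- function(fwd, rev, k = 3, bg_window = 2000L,
                                 max_span = 100L, local_halfwidth = 20L) {
  stopifnot(inherits(fwd, "BorderProfile"), inherits(rev, "BorderProfile"))
  if (!fwd$normalized || !rev$normalized) {
    stop("profiles must be depth-normalized first (see normalize_depth)")
  }
  g <- length(fwd$counts)
  if (length(rev$counts) != g) stop("profiles have different genome lengths")
  fb <- .candidate_borders(fwd$counts, k, bg_window, local_halfwidth)
  rb <- .candidate_borders(rev$counts, k, bg_window, local_halfwidth)
  re_log("candidate borders: %d forward, %d reverse (k=%.2f, window=%d)",
         length(fb), length(rb), k, bg_window)
  if (length(fb) == 0 || length(rb) == 0) return(.empty_peaks())
  ## pair each forward border with nearest downstream reverse border
  rb <- sort(rb)
  out <- list()
  for (f in sort(fb)) {
    idx <- findInterval(f - 1L, rb) + 1L    # first rb >= f
    if (idx > length(rb)) next
    r <- rb[idx]
    if (r - f > max_span) next
    out[[length(out) + 1L]] <- c(f, r)
  }
  if (length(out) == 0) return(.empty_peaks())
  m <- do.call(rbind, out)
  peaks <- data.frame(
    peak_id = sprintf("peak_%04d", seq_len(nrow(m))),
    start = m[, 1], end = m[, 2] + 1L,
    center = floor((m[, 1] + m[, 2] + 1L) / 2),
    fwd_border = m[, 1], rev_border = m[, 2],
    sn = NA_real_, support = fwd$label,
    stringsAsFactors = FALSE)
  peaks$sn <- vapply(seq_len(nrow(peaks)), function(i) {
    signal_to_noise(peaks[i, ], fwd, rev)
  }, 0)
  peaks
}

.empty_peaks <- function() {
  data.frame(peak_id = character(0), start = integer(0), end = integer(0),
             center = integer(0), fwd_border = integer(0),
             rev_border = integer(0), sn = numeric(0),
             support = character(0), stringsAsFactors = FALSE)
}

## local maxima of v (1-based index) with height >= k * local background;
## returns 0-based genomic positions
.candidate_borders <- function(v, k, bg_window, local_halfwidth) {
  g <- length(v)
  half <- as.integer(bg_window / 2)
  cs <- c(0, cumsum(v))
  idx <- seq_len(g)
  lo <- pmax(1L, idx - half)
  hi <- pmin(g, idx + half)
  bg <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  floor_bg <- 1e6 / g
  thr <- k * pmax(bg, floor_bg)
  cand <- which(v >= thr & v > 0)
  if (length(cand) == 0) return(integer(0))
  keep <- vapply(cand, function(i) {
    a <- max(1L, i - local_halfwidth)
    b <- min(g, i + local_halfwidth)
    left_ok <- i == a || v[i] > max(v[a:(i - 1L)])
    right_ok <- i == b || v[i] >= max(v[(i + 1L):b])
    left_ok && right_ok
  }, logical(1))
  cand[keep] - 1L
}

#' Signal-to-noise ratio of a peak
#'
#' Mean combined-strand normalized border density within the peak interval
#' divided by the genome-wide mean combined density.  A peak whose density
#' merely matches the genome average scores exactly 1.
#'
#' @param peak one peak row (needs `start`, `end`, 0-based half-open).
#' @param fwd,rev depth-normalized [border_profile()]s.
#' @return the S/N ratio (dimensionless).
#' @export
signal_to_noise <- function(peak, fwd, rev) {
  combined <- fwd$counts + rev$counts
  gmean <- mean(combined)
  if (gmean <= 0) stop("zero genome-wide density")
  if (peak$end <= peak$start) stop("empty peak interval")
  idx <- (peak$start + 1L):peak$end
  mean(combined[idx]) / gmean
}

#' Intersect peak calls from two biological replicates
#'
#' Peaks are retained only when the replicate intervals overlap by at least
#' one bp; each overlapping pair is merged into the union interval with S/N
#' equal to the mean of the two replicate values.  The operation is
#' symmetric in its arguments.
#'
#' @param peaks_rep1,peaks_rep2 peak data.frames from
#'   [call_candidate_peaks()] run with identical parameters.
#' @return merged peak data.frame with `support = "both"`.
#' @export
reproducible_peaks <- function(peaks_rep1, peaks_rep2) {
  if (nrow(peaks_rep1) == 0 || nrow(peaks_rep2) == 0) return(.empty_peaks())
  ir1 <- IRanges::IRanges(peaks_rep1$start + 1L, peaks_rep1$end)
  ir2 <- IRanges::IRanges(peaks_rep2$start + 1L, peaks_rep2$end)
  hits <- IRanges::findOverlaps(ir1, ir2, minoverlap = 1L)
  if (length(hits) == 0) return(.empty_peaks())
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  start <- pmin(peaks_rep1$start[q], peaks_rep2$start[s])
  end <- pmax(peaks_rep1$end[q], peaks_rep2$end[s])
  sn <- (peaks_rep1$sn[q] + peaks_rep2$sn[s]) / 2
  merged <- data.frame(start = start, end = end, sn = sn,
                       stringsAsFactors = FALSE)
  merged <- unique(merged)
  merged <- merged[order(merged$start, merged$end), , drop = FALSE]
  data.frame(
    peak_id = sprintf("peak_%04d", seq_len(nrow(merged))),
    start = merged$start, end = merged$end,
    center = floor((merged$start + merged$end) / 2),
    fwd_border = merged$start, rev_border = merged$end - 1L,
    sn = merged$sn, support = "both", stringsAsFactors = FALSE)
}

#' Filter peaks by signal-to-noise and mock-IP overlap
#'
#' Removes peaks with S/N below `sn_min` (default 1.0) and peaks sharing at
#' least one bp with any mock-IP peak; signal present in the control
#' immunoprecipitation is treated as artifact.
#'
#' @param peaks peak data.frame.
#' @param mock_peaks peaks called on the mock-IP profiles with identical
#'   parameters.
#' @param sn_min minimum S/N ratio retained.
#' @return the filtered peak data.frame.
#' @export
filter_peaks <- function(peaks, mock_peaks, sn_min = 1.0) {
  if (nrow(peaks) == 0) return(peaks)
  keep <- peaks$sn >= sn_min
  if (!is.null(mock_peaks) && nrow(mock_peaks) > 0) {
    ir <- IRanges::IRanges(peaks$start + 1L, peaks$end)
    irm <- IRanges::IRanges(mock_peaks$start + 1L, mock_peaks$end)
    hit <- IRanges::findOverlaps(ir, irm, minoverlap = 1L)
    keep[unique(S4Vectors::queryHits(hit))] <- FALSE
  }
  re_log("filter_peaks: %d in, %d out (sn_min=%.2f, %d mock peaks)",
         nrow(peaks), sum(keep), sn_min,
         if (is.null(mock_peaks)) 0L else nrow(mock_peaks))
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write peaks as BED6+2
#'
#' Columns: chrom, start, end, name, score (S/N x 1000, capped at the BED
#' score range), strand (`"."`), forward border, reverse border.
#'
#' @param peaks peak data.frame.
#' @param path output path.
#' @param seqname chromosome name.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path, seqname = "chr") {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.\t%d\t%d", seqname, peaks$start,
                   peaks$end, peaks$peak_id,
                   pmin(1000L, as.integer(round(peaks$sn * 1000))),
                   peaks$fwd_border, peaks$rev_border)
  writeLines(lines, path)
  invisible(path)
}
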