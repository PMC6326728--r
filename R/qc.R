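#' Histogram of per-barcode log10 UMI totals
#'
#' Bins log10 of per-barcode total UMI counts on a uniform grid and smooths
#' the bin counts with a centered moving average. Barcodes with zero counts
#' are excluded (log10 undefined); an all-zero matrix is an error.
#'
#' @param counts genes x barcodes sparse count matrix.
#' @param bin_width histogram bin width in log10(UMI) units (default 0.05).
#' @param smooth_window odd moving-average window length (default 3);
#'   `1` leaves the raw counts untouched.
#' @param floor lowest log10(UMI) value at which a threshold may be called
#'   (default 2, i.e. 100 UMIs); stored for [find_umi_threshold()].
#' @return object of class `umi_histogram`: list with `bin_edges`,
#'   `bin_centers`, `raw_counts`, `smoothed_counts`, `floor`, `bin_width`.
#' @export
build_umi_histogram <- function(counts, bin_width = 0.05, smooth_window = 3L,
                                floor = 2.0) {
  if (bin_width <= 0) isr_stop("bin_width must be positive", "isrmap_config_error")
  if (smooth_window < 1L || smooth_window %% 2L == 0L)
    isr_stop("smooth_window must be odd and >= 1", "isrmap_config_error")
  totals <- Matrix::colSums(counts)
  totals <- totals[totals >= 1]
  if (!length(totals)) isr_stop("no nonempty barcodes", "isrmap_input_error")
  lt <- log10(totals)
  lo <- floor(min(lt) / bin_width) * bin_width
  hi <- ceiling(max(lt) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi + bin_width / 2, by = bin_width)
  raw <- as.vector(table(cut(lt, breaks = edges, include.lowest = TRUE,
                             right = FALSE)))
  smoothed <- moving_average(raw, smooth_window)
  structure(list(bin_edges = edges,
                 bin_centers = head(edges, -1) + bin_width / 2,
                 raw_counts = raw, smoothed_counts = smoothed,
                 floor = floor, bin_width = bin_width),
            class = "umi_histogram")
}

# centered moving average; edge bins keep partial windows so that low-index
# structure is not lost
moving_average <- function(x, window) {
  if (window == 1L) return(as.numeric(x))
  half <- (window - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

#' Barcode-filter threshold: first local minimum of the UMI histogram
#'
#' Returns the center of the lowest-index bin whose smoothed count is
#' strictly lower than both flanking (non-equal) values and whose center is
#' at or above the histogram's floor (default 2 in log10 units, i.e. the
#' "first local minimum above two" rule). On a plateau of equal counts lower
#' than both flanks, the left-most plateau bin wins.
#'
#' @param hist a [build_umi_histogram()] result.
#' @return threshold in log10(UMI) units.
#' @export
find_umi_threshold <- function(hist) {
  s <- hist$smoothed_counts
  centers <- hist$bin_centers
  n <- length(s)
  i <- 2L
  while (i <= n - 1L) {
    if (s[i] < s[i - 1L]) {
      j <- i
      while (j < n && s[j + 1L] == s[i]) j <- j + 1L  # span plateau
      if (j < n && s[j + 1L] > s[i] && centers[i] >= hist$floor) {
        return(centers[i])
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  isr_stop("no local minimum at or above the floor; lower `floor` explicitly",
           "isrmap_no_threshold")
}

#' Filter barcodes by a log10(UMI) threshold
#'
#' Retains exactly the barcodes whose log10 total UMI count is greater than
#' or equal to `threshold`; the gene axis is untouched. Idempotent, and
#' monotone in the threshold.
#'
#' @param counts genes x barcodes sparse count matrix.
#' @param threshold finite log10(UMI) cutoff.
#' @return the column-filtered count matrix.
#' @export
filter_barcodes <- function(counts, threshold) {
  if (!is.finite(threshold)) isr_stop("threshold must be finite", "isrmap_config_error")
  totals <- Matrix::colSums(counts)
  keep <- totals >= 1 & log10(pmax(totals, 1)) >= threshold
  if (!any(keep)) isr_stop("no barcodes pass the UMI threshold", "isrmap_input_error")
  counts[, keep, drop = FALSE]
}
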