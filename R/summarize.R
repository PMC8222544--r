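# Descriptive summaries: quantile-bin boundaries per file, cross-file
# aggregation with relative standard deviation, and rejection-by-cutoff
# tables. Zero values are removed before binning (they code for "not
# measured"), but never inside the cascade filters.

#' Upper boundaries of equal-count quantile bins
#'
#' Sorts `values` ascending and splits them into `n_bins` contiguous groups
#' of near-equal size (any remainder is spread over the lowest bins); the
#' boundary of a bin is the maximum value in its group, so the top-bin
#' boundary is always the input maximum. Tied values stay in their sorted
#' positions and may span bins; no interpolation is performed. Trailing empty
#' groups (possible when there are fewer values than bins) inherit the
#' previous boundary.
#'
#' @param values Non-negative numeric vector; may be empty.
#' @param n_bins Number of bins, `>= 1`. Default 20.
#' @return Numeric vector of length `n_bins`, non-decreasing.
#' @export
quantile_bin_boundaries <- function(values, n_bins = 20L) {
  if (!is.numeric(n_bins) || length(n_bins) != 1L || n_bins < 1) {
    stop("n_bins must be a single integer >= 1", call. = FALSE)
  }
  n_bins <- as.integer(n_bins)
  values <- as.numeric(values)
  if (!length(values)) {
    warning("empty input; returning all-zero boundaries", call. = FALSE)
    return(rep(0, n_bins))
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("values must be finite and non-negative", call. = FALSE)
  }
  v <- sort(values)
  n <- length(v)
  sizes <- rep(n %/% n_bins, n_bins)
  r <- n %% n_bins
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  ends <- cumsum(sizes)
  out <- numeric(n_bins)
  prev <- v[1L]
  for (i in seq_len(n_bins)) {
    out[i] <- if (sizes[i] > 0) v[ends[i]] else prev
    prev <- out[i]
  }
  out
}

.bin_labels <- function(n_bins) {
  pct <- round(seq(0, 100, length.out = n_bins + 1L), 6)
  sprintf("%g-%g", pct[-(n_bins + 1L)], pct[-1L])
}

#' Cross-file quantile-bin summary
#'
#' Computes per-file equal-count bin boundaries for a field (peak height or
#' S/N), after removing zero values, then aggregates across files: the mean
#' boundary per bin and its relative standard deviation
#' (sample SD / mean x 100). With fewer than two files the RSD is reported as
#' 0 with a warning.
#'
#' @param files List of [file_peak_list()] objects.
#' @param field `"height"` or `"sn"`.
#' @param n_bins Number of bins. Default 20.
#' @return A `bin_summary` data frame with columns `bin` (percentile range,
#'   ascending), `mean_upper_boundary`, `rsd_percent`.
#' @export
cross_file_bin_summary <- function(files, field = c("height", "sn"),
                                   n_bins = 20L) {
  field <- match.arg(field)
  stopifnot(length(files) >= 1L,
            all(vapply(files, inherits, TRUE, "file_peak_list")))
  n_bins <- as.integer(n_bins)
  boundaries <- vapply(files, function(pl) {
    v <- pl$peaks[[field]]
    quantile_bin_boundaries(v[v > 0], n_bins)
  }, numeric(n_bins))
  boundaries <- matrix(boundaries, nrow = n_bins)
  mean_b <- rowMeans(boundaries)
  if (length(files) < 2L) {
    warning("fewer than 2 files; RSD reported as 0", call. = FALSE)
    rsd <- rep(0, n_bins)
  } else {
    sd_b <- apply(boundaries, 1L, stats::sd)
    rsd <- ifelse(mean_b > 0, sd_b / mean_b * 100, 0)
  }
  out <- data.frame(bin = .bin_labels(n_bins), mean_upper_boundary = mean_b,
                    rsd_percent = rsd, stringsAsFactors = FALSE)
  class(out) <- c("bin_summary", "data.frame")
  attr(out, "field") <- field
  attr(out, "n_files") <- length(files)
  out
}

#' Default peak-height cutoffs for file-level rejection tables
#'
#' The canonical cutoff set used in per-file rejection summaries.
#' @return Numeric vector `c(100, 200, 500, 1000, 2500, 5000, 10000)`.
#' @export
default_rejection_cutoffs <- function() {
  c(100, 200, 500, 1000, 2500, 5000, 10000)
}

#' Per-file rejection aggregated across files
#'
#' Applies [file_level_rejection()] to every file at every cutoff and
#' aggregates the mean and sample SD of the rejection percentage across
#' files. The mean percentage is non-decreasing in the cutoff.
#'
#' @param files List of [file_peak_list()] objects.
#' @param cutoffs Ascending peak-height cutoffs (ion counts). Defaults to
#'   [default_rejection_cutoffs()].
#' @param sn_min Minimum S/N entering the accounting. Default 2.
#' @return `data.frame` with columns `cutoff`, `mean_rejected_pct`,
#'   `sd_rejected_pct`.
#' @export
rejection_table <- function(files, cutoffs = default_rejection_cutoffs(),
                            sn_min = 2) {
  stopifnot(length(files) >= 1L,
            all(vapply(files, inherits, TRUE, "file_peak_list")))
  if (is.unsorted(cutoffs, strictly = FALSE)) {
    stop("cutoffs must be sorted ascending", call. = FALSE)
  }
  pct <- vapply(cutoffs, function(ct) {
    per_file <- vapply(files, file_level_rejection, numeric(1),
                       height_cutoff = ct, sn_min = sn_min) * 100
    c(mean(per_file), if (length(files) > 1L) stats::sd(per_file) else 0)
  }, numeric(2))
  data.frame(cutoff = cutoffs, mean_rejected_pct = pct[1L, ],
             sd_rejected_pct = pct[2L, ])
}

#' Lowest reliable point of the dynamic range
#'
#' Given the maximum observed peak height and the instrument's dynamic range
#' in orders of magnitude, returns `floor(max_height / 10^orders)` — the
#' smallest peak height still inside the instrument's reliable range.
#'
#' @param max_height Maximum observed peak height (ion counts, `> 0`).
#' @param orders Orders of magnitude of dynamic range (`>= 0`).
#' @return Integer-valued ion count.
#' @export
dynamic_range_floor <- function(max_height, orders) {
  if (!is.numeric(max_height) || length(max_height) != 1L ||
      !is.finite(max_height) || max_height <= 0) {
    stop("max_height must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(orders) || length(orders) != 1L || !is.finite(orders) ||
      orders < 0) {
    stop("orders must be a single non-negative number", call. = FALSE)
  }
  floor(max_height / 10^orders)
}
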