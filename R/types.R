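#' Construct a per-file peak list
#'
#' Container for the peaks detected in a single LC/MS data file: one row per
#' chromatographic peak with its m/z (Da), retention time (minutes), peak
#' height and area (ion counts) and signal-to-noise ratio.
#'
#' @param file_id Single string identifying the source file.
#' @param peaks `data.frame` with numeric columns `mz`, `rt`, `height`,
#'   `area`, `sn`. Extra columns are kept untouched as opaque metadata.
#' @return An object of class `file_peak_list`.
#' @export
file_peak_list <- function(file_id, peaks) {
  stopifnot(is.character(file_id), length(file_id) == 1L)
  peaks <- as.data.frame(peaks)
  required <- c("mz", "rt", "height", "area", "sn")
  missing <- setdiff(required, names(peaks))
  if (length(missing)) {
    stop("peak list is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in required) {
    v <- peaks[[col]]
    if (!is.numeric(v)) stop("column '", col, "' must be numeric", call. = FALSE)
    if (nrow(peaks) && any(!is.finite(v))) {
      stop("column '", col, "' contains non-finite values", call. = FALSE)
    }
    if (nrow(peaks) && any(v < 0)) {
      stop("column '", col, "' contains negative values", call. = FALSE)
    }
  }
  if (nrow(peaks) && any(peaks$mz <= 0)) {
    stop("mz values must be strictly positive", call. = FALSE)
  }
  structure(list(file_id = file_id, peaks = peaks), class = "file_peak_list")
}

#' @export
print.file_peak_list <- function(x, ...) {
  cat("<file_peak_list> ", x$file_id, ": ", nrow(x$peaks), " peaks\n", sep = "")
  invisible(x)
}

#' Construct an aligned peak table
#'
#' Peaks-by-samples matrix of gap-filled peak heights, as exported by
#' alignment software. A height of zero means the peak was neither detected
#' nor recovered in that sample; `fill_fraction` is the per-peak fraction of
#' files in which the peak was detected with high confidence before gap
#' filling.
#'
#' @param peak_ids Character vector of unique peak identifiers.
#' @param mz,rt Numeric vectors (Da, minutes), one value per peak.
#' @param heights Numeric matrix `[n_peaks x n_samples]` of non-negative,
#'   finite ion counts.
#' @param fill_fraction Numeric vector in `[0, 1]`, one value per peak.
#' @param sample_ids Character vector of unique sample identifiers.
#' @return An object of class `aligned_peak_table`.
#' @export
aligned_peak_table <- function(peak_ids, mz, rt, heights, fill_fraction,
                               sample_ids) {
  peak_ids <- as.character(peak_ids)
  sample_ids <- as.character(sample_ids)
  heights <- as.matrix(heights)
  storage.mode(heights) <- "double"
  n_peaks <- length(peak_ids)
  n_samples <- length(sample_ids)
  if (anyDuplicated(peak_ids)) stop("peak_ids must be unique", call. = FALSE)
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique", call. = FALSE)
  if (!identical(dim(heights), c(n_peaks, n_samples))) {
    stop("heights must be a ", n_peaks, " x ", n_samples, " matrix", call. = FALSE)
  }
  if (length(mz) != n_peaks || length(rt) != n_peaks ||
      length(fill_fraction) != n_peaks) {
    stop("mz, rt and fill_fraction must have one value per peak", call. = FALSE)
  }
  if (n_peaks && (any(!is.finite(heights)) || any(heights < 0))) {
    stop("heights must be finite and non-negative", call. = FALSE)
  }
  if (n_peaks && (any(!is.finite(fill_fraction)) ||
                  any(fill_fraction < 0) || any(fill_fraction > 1))) {
    stop("fill_fraction must lie in [0, 1]", call. = FALSE)
  }
  dimnames(heights) <- list(peak_ids, sample_ids)
  structure(list(peak_ids = peak_ids, mz = as.numeric(mz), rt = as.numeric(rt),
                 heights = heights, fill_fraction = as.numeric(fill_fraction),
                 sample_ids = sample_ids),
            class = "aligned_peak_table")
}

#' @export
print.aligned_peak_table <- function(x, ...) {
  cat("<aligned_peak_table> ", length(x$peak_ids), " peaks x ",
      length(x$sample_ids), " samples; ",
      sprintf("%.1f%% zero cells\n", 100 * mean(x$heights == 0)), sep = "")
  invisible(x)
}

#' Number of peaks / samples in an aligned peak table
#' @param t An `aligned_peak_table`.
#' @return Integer count.
#' @export
n_peaks <- function(t) length(t$peak_ids)

#' @rdname n_peaks
#' @export
n_samples <- function(t) length(t$sample_ids)

#' Subset an aligned peak table by peaks
#'
#' @param t An `aligned_peak_table`.
#' @param keep Logical mask or vector of peak ids.
#' @return The subset `aligned_peak_table`.
#' @export
subset_peaks <- function(t, keep) {
  stopifnot(inherits(t, "aligned_peak_table"))
  if (is.logical(keep)) {
    stopifnot(length(keep) == n_peaks(t))
    idx <- which(keep)
  } else {
    idx <- match(as.character(keep), t$peak_ids)
    if (anyNA(idx)) stop("unknown peak id(s) in subset", call. = FALSE)
  }
  aligned_peak_table(t$peak_ids[idx], t$mz[idx], t$rt[idx],
                     t$heights[idx, , drop = FALSE],
                     t$fill_fraction[idx], t$sample_ids)
}

#' Construct a phenotype vector
#'
#' A continuous phenotype (e.g. birth weight in grams) keyed by sample id.
#' Missing values are allowed and flagged, but must be `NA`, not invented.
#'
#' @param sample_ids Character vector of unique sample identifiers.
#' @param values Numeric vector, same length; `NA` marks missing.
#' @return An object of class `phenotype`.
#' @export
phenotype <- function(sample_ids, values) {
  sample_ids <- as.character(sample_ids)
  values <- as.numeric(values)
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique", call. = FALSE)
  if (length(values) != length(sample_ids)) {
    stop("values must match sample_ids in length", call. = FALSE)
  }
  if (any(is.infinite(values))) stop("values must be finite or NA", call. = FALSE)
  structure(list(sample_ids = sample_ids, values = values,
                 n_missing = sum(is.na(values))),
            class = "phenotype")
}

#' @export
print.phenotype <- function(x, ...) {
  cat("<phenotype> ", length(x$sample_ids), " samples (",
      x$n_missing, " missing)\n", sep = "")
  invisible(x)
}

#' Threshold cascade configuration
#'
#' Parameters of the post-acquisition filter cascade. `th2_height` is the
#' chromatographic peak-height threshold (ion counts); `th3_min_fraction` the
#' minimum fraction of samples that must reach `th2_height` at alignment;
#' `th4_fill_fraction` the minimum post-gap-fill detection frequency;
#' `th5_intensity` the gap-fill intensity floor used when recomputing
#' detection frequency (0 = use the table's stored fill fraction); `sn_min`
#' the signal-to-noise floor used in file-level rejection accounting.
#' The scan-level acquisition threshold acts before peak tables exist and is
#' modelled only inside the simulator (as its limit of detection).
#'
#' @param th2_height Ion counts, `>= 0`.
#' @param th3_min_fraction Fraction in `[0, 1]`.
#' @param th4_fill_fraction Fraction in `[0, 1]`.
#' @param th5_intensity Ion counts, `>= 0`. Default 0 (inactive).
#' @param sn_min Minimum S/N ratio, `>= 0`. Default 2.
#' @return An object of class `threshold_config`.
#' @export
threshold_config <- function(th2_height = 0, th3_min_fraction = 0,
                             th4_fill_fraction = 0, th5_intensity = 0,
                             sn_min = 2) {
  chk_scalar <- function(x, nm, lo = 0, hi = Inf) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
      stop(nm, " must be a single finite value in [", lo, ", ", hi, "]",
           call. = FALSE)
    }
  }
  chk_scalar(th2_height, "th2_height")
  chk_scalar(th3_min_fraction, "th3_min_fraction", 0, 1)
  chk_scalar(th4_fill_fraction, "th4_fill_fraction", 0, 1)
  chk_scalar(th5_intensity, "th5_intensity")
  chk_scalar(sn_min, "sn_min")
  structure(list(th2_height = th2_height, th3_min_fraction = th3_min_fraction,
                 th4_fill_fraction = th4_fill_fraction,
                 th5_intensity = th5_intensity, sn_min = sn_min),
            class = "threshold_config")
}

#' @export
print.threshold_config <- function(x, ...) {
  cat(sprintf(
    "<threshold_config> height >= %g in >= %g%% samples; fill >= %g%% (floor %g); S/N >= %g\n",
    x$th2_height, 100 * x$th3_min_fraction, 100 * x$th4_fill_fraction,
    x$th5_intensity, x$sn_min))
  invisible(x)
}
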