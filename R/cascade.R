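# The alignment-level threshold cascade.
#
# Boundary convention throughout: every threshold passes on >= (height >=
# cutoff, qualifying-sample count >= required, fill >= minimum), matching the
# "at least" phrasing used for these filters in practice. The required sample
# count for a fractional threshold is max(1, ceiling(fraction * n_samples)):
# a fractional sample cannot satisfy "at least".

.retention_result <- function(mask, config = NULL, stages = NULL) {
  n_total <- length(mask)
  n_retained <- sum(mask)
  structure(list(n_total = n_total, n_retained = n_retained,
                 n_rejected = n_total - n_retained,
                 rejected_fraction = if (n_total) (n_total - n_retained) / n_total else 0,
                 mask = mask, config = config, stages = stages),
            class = "retention_result")
}

#' @export
print.retention_result <- function(x, ...) {
  cat(sprintf("<retention_result> %d / %d peaks retained (%.1f%% rejected)\n",
              x$n_retained, x$n_total, 100 * x$rejected_fraction))
  invisible(x)
}

#' File-level peak rejection fraction
#'
#' Fraction of adequately resolved peaks (S/N at or above `sn_min`) in one
#' file whose height falls below a candidate peak-height threshold. This is
#' the accounting behind per-file rejection tables: the denominator is the
#' peaks with `sn >= sn_min`, the numerator those among them with
#' `height < height_cutoff`.
#'
#' @param pl A [file_peak_list()].
#' @param height_cutoff Peak-height threshold (ion counts, `>= 0`).
#' @param sn_min Minimum S/N for a peak to enter the accounting. Default 2.
#' @return Rejected fraction in `[0, 1]`; 0 when no peak qualifies.
#' @export
file_level_rejection <- function(pl, height_cutoff, sn_min = 2) {
  stopifnot(inherits(pl, "file_peak_list"))
  if (!is.numeric(height_cutoff) || length(height_cutoff) != 1L ||
      !is.finite(height_cutoff) || height_cutoff < 0) {
    stop("height_cutoff must be a single non-negative number", call. = FALSE)
  }
  eligible <- pl$peaks$sn >= sn_min
  denom <- sum(eligible)
  if (denom == 0L) return(0)
  sum(pl$peaks$height[eligible] < height_cutoff) / denom
}

#' Alignment-level peak-height filter
#'
#' Retains a peak iff its maximum height over all samples reaches `th2`,
#' i.e. the peak was found in at least one file at that height.
#'
#' @param t An [aligned_peak_table()].
#' @param th2 Peak-height threshold (ion counts, `>= 0`).
#' @return A `retention_result` with the per-peak retention mask.
#' @export
alignment_height_filter <- function(t, th2) {
  stopifnot(inherits(t, "aligned_peak_table"))
  height_frequency_filter(t, th2, min_fraction = 0)
}

#' Height-in-minimum-fraction-of-samples filter
#'
#' Retains a peak iff the number of samples whose height reaches `th2` is at
#' least `max(1, ceiling(min_fraction * n_samples))`. With `min_fraction = 0`
#' this reduces to requiring the height in at least one sample.
#'
#' @param t An [aligned_peak_table()].
#' @param th2 Peak-height threshold (ion counts, `>= 0`).
#' @param min_fraction Minimum fraction of samples in `[0, 1]`.
#' @return A `retention_result`.
#' @export
height_frequency_filter <- function(t, th2, min_fraction) {
  stopifnot(inherits(t, "aligned_peak_table"))
  if (!is.numeric(th2) || length(th2) != 1L || !is.finite(th2) || th2 < 0) {
    stop("th2 must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(min_fraction) || length(min_fraction) != 1L ||
      !is.finite(min_fraction) || min_fraction < 0 || min_fraction > 1) {
    stop("min_fraction must lie in [0, 1]", call. = FALSE)
  }
  ns <- n_samples(t)
  required <- max(1L, as.integer(ceiling(min_fraction * ns)))
  qualifying <- if (n_peaks(t)) rowSums(t$heights >= th2) else integer(0)
  mask <- stats::setNames(qualifying >= required, t$peak_ids)
  .retention_result(mask,
                    config = list(th2 = th2, min_fraction = min_fraction,
                                  required_samples = required))
}

#' Post-gap-fill detection-frequency filter
#'
#' Retains a peak iff its effective detection frequency reaches `th4_fill`.
#' With `th5_intensity = 0` the table's stored `fill_fraction` (confident
#' detections before gap filling) is used; a positive `th5_intensity`
#' recomputes the frequency as the fraction of samples with height at or
#' above that gap-fill intensity floor.
#'
#' @param t An [aligned_peak_table()].
#' @param th4_fill Minimum detection frequency in `[0, 1]`.
#' @param th5_intensity Gap-fill intensity floor (ion counts, `>= 0`).
#'   Default 0 (use stored fill fraction).
#' @return A `retention_result`.
#' @export
fill_filter <- function(t, th4_fill, th5_intensity = 0) {
  stopifnot(inherits(t, "aligned_peak_table"))
  if (!is.numeric(th4_fill) || length(th4_fill) != 1L || !is.finite(th4_fill) ||
      th4_fill < 0 || th4_fill > 1) {
    stop("th4_fill must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(th5_intensity) || length(th5_intensity) != 1L ||
      !is.finite(th5_intensity) || th5_intensity < 0) {
    stop("th5_intensity must be a single non-negative number", call. = FALSE)
  }
  effective_fill <- if (th5_intensity > 0) {
    if (n_peaks(t)) rowMeans(t$heights >= th5_intensity) else numeric(0)
  } else {
    t$fill_fraction
  }
  mask <- stats::setNames(effective_fill >= th4_fill, t$peak_ids)
  .retention_result(mask,
                    config = list(th4_fill = th4_fill,
                                  th5_intensity = th5_intensity))
}

#' Apply the full threshold cascade
#'
#' Joint filter: a peak is retained iff it passes both the
#' height-in-minimum-fraction-of-samples filter (`th2_height`,
#' `th3_min_fraction`) and the detection-frequency filter
#' (`th4_fill_fraction`, `th5_intensity`). Per-stage counts are recorded in
#' `$stages`.
#'
#' @param t An [aligned_peak_table()].
#' @param cfg A [threshold_config()].
#' @return A `retention_result`; `$stages` holds the two stage results.
#' @export
apply_cascade <- function(t, cfg) {
  stopifnot(inherits(t, "aligned_peak_table"), inherits(cfg, "threshold_config"))
  s_height <- height_frequency_filter(t, cfg$th2_height, cfg$th3_min_fraction)
  s_fill <- fill_filter(t, cfg$th4_fill_fraction, cfg$th5_intensity)
  .retention_result(s_height$mask & s_fill$mask, config = cfg,
                    stages = list(height_frequency = s_height, fill = s_fill))
}

#' Retention / additional-loss curves over a threshold grid
#'
#' For each peak-height threshold in `th2_list`, the baseline is the number
#' of peaks found at that height in at least one sample (detection frequency
#' 0). For each frequency `f` in `freq_grid` the additional loss is
#' `(baseline_retained - retained(th2, f)) / n_total`. Two frequency
#' semantics are provided because exports conflate them: `"th4_fill"`
#' (default) additionally requires the stored fill fraction to reach `f`;
#' `"th3_count"` requires the height itself in at least
#' `max(1, ceiling(f * n_samples))` samples.
#'
#' @param t An [aligned_peak_table()].
#' @param th2_list Ascending peak-height thresholds.
#' @param freq_grid Ascending detection-frequency cutoffs in `[0, 1]`.
#' @param mode `"th4_fill"` or `"th3_count"`.
#' @return A `data.frame` with one row per `(th2, frequency)` pair: columns
#'   `th2`, `frequency`, `n_retained`, `retained_fraction`,
#'   `additional_loss_fraction`.
#' @export
retention_curve <- function(t, th2_list, freq_grid,
                            mode = c("th4_fill", "th3_count")) {
  stopifnot(inherits(t, "aligned_peak_table"))
  mode <- match.arg(mode)
  if (!length(th2_list) || !length(freq_grid)) {
    stop("th2_list and freq_grid must be non-empty", call. = FALSE)
  }
  if (is.unsorted(th2_list, strictly = FALSE) ||
      is.unsorted(freq_grid, strictly = FALSE)) {
    stop("th2_list and freq_grid must be sorted ascending", call. = FALSE)
  }
  nt <- n_peaks(t)
  rows <- vector("list", length(th2_list) * length(freq_grid))
  k <- 0L
  for (th2 in th2_list) {
    base_mask <- alignment_height_filter(t, th2)$mask
    baseline <- sum(base_mask)
    for (f in freq_grid) {
      mask <- switch(mode,
        th4_fill = base_mask & (t$fill_fraction >= f),
        th3_count = height_frequency_filter(t, th2, f)$mask)
      k <- k + 1L
      rows[[k]] <- data.frame(
        th2 = th2, frequency = f, n_retained = sum(mask),
        retained_fraction = if (nt) sum(mask) / nt else 0,
        additional_loss_fraction = if (nt) (baseline - sum(mask)) / nt else 0)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "mode") <- mode
  out
}
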