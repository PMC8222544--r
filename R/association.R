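# Metabolome-wide Spearman scan with Benjamini-Hochberg adjustment, and the
# intersection of the significant set with cascade retention masks.

# rho as Pearson on average ranks; p-value two-sided. For n > 10 the usual
# t approximation t = rho * sqrt((n-2)/(1-rho^2)) on n-2 df; for n <= 10 the
# exact permutation distribution of the rank statistic (ties kept as average
# ranks). rho = +/-1 has p = 0 under the t route by continuity.
.spearman_p <- function(rho, n, rank_x = NULL, rank_y = NULL) {
  if (is.na(rho)) return(NA_real_)
  if (n <= 10L) {
    return(exact_spearman_pvalue(rank_x, rank_y))
  }
  if (abs(rho) >= 1) return(0)
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(tval), df = n - 2)
}

.rank_corr <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sx <- sum((rx - mean(rx))^2)
  sy <- sum((ry - mean(ry))^2)
  if (sx == 0 || sy == 0) return(NA_real_)
  sum((rx - mean(rx)) * (ry - mean(ry))) / sqrt(sx * sy)
}

#' Metabolome-wide Spearman scan
#'
#' Computes, for every peak, the Spearman rank correlation between its
#' per-sample heights and a continuous phenotype, with a two-sided p-value.
#' Samples are matched by id (inner join); phenotype `NA`s are dropped.
#' Under `zero_policy = "include"` (default) gap-filled zeros enter the
#' ranking as the lowest tied values; `"exclude"` drops zero-height samples
#' for that peak. Peaks with fewer than 3 usable pairs or zero variance get
#' `rho = NA, p = NA` and are excluded from the number of hypotheses when
#' the result is adjusted.
#'
#' @param t An [aligned_peak_table()].
#' @param ph A [phenotype()].
#' @param zero_policy `"include"` or `"exclude"`.
#' @return An `association_result` data frame with columns `peak_id`, `rho`,
#'   `p_value`, `q_value` (NA until [bh_adjust_result()]), `n_used`.
#' @export
spearman_scan <- function(t, ph, zero_policy = c("include", "exclude")) {
  stopifnot(inherits(t, "aligned_peak_table"), inherits(ph, "phenotype"))
  zero_policy <- match.arg(zero_policy)
  idx <- match(t$sample_ids, ph$sample_ids)
  shared <- which(!is.na(idx))
  if (!length(shared)) stop("no overlapping samples between table and phenotype",
                            call. = FALSE)
  y <- ph$values[idx[shared]]
  keep <- !is.na(y)
  y <- y[keep]
  cols <- shared[keep]
  n <- length(y)
  np <- n_peaks(t)
  rho <- rep(NA_real_, np)
  pval <- rep(NA_real_, np)
  n_used <- rep(n, np)
  if (length(unique(y)) < 2L) {
    warning("phenotype is constant across usable samples; all results NA",
            call. = FALSE)
  } else if (np > 0L) {
    H <- t$heights[, cols, drop = FALSE]
    if (zero_policy == "include" && n > 10L) {
      # vectorised rank-Pearson across all peaks at once
      R <- matrix(0, np, n)
      for (i in seq_len(np)) R[i, ] <- rank(H[i, ])
      ry <- rank(y)
      Rc <- R - rowMeans(R)
      yc <- ry - mean(ry)
      ssx <- rowSums(Rc^2)
      ssy <- sum(yc^2)
      num <- as.numeric(Rc %*% yc)
      ok <- ssx > 0
      rho[ok] <- num[ok] / sqrt(ssx[ok] * ssy)
      rho[ok] <- pmin(1, pmax(-1, rho[ok]))
      tv <- rho[ok] * sqrt((n - 2) / pmax(1 - rho[ok]^2, .Machine$double.eps))
      pv <- 2 * stats::pt(-abs(tv), df = n - 2)
      pv[abs(rho[ok]) >= 1] <- 0
      pval[ok] <- pv
    } else {
      for (i in seq_len(np)) {
        xi <- H[i, ]
        yi <- y
        if (zero_policy == "exclude") {
          nz <- xi > 0
          xi <- xi[nz]
          yi <- yi[nz]
        }
        n_used[i] <- length(xi)
        if (length(xi) < 3L) next
        r <- .rank_corr(xi, yi)
        if (is.na(r)) next
        rho[i] <- r
        pval[i] <- .spearman_p(r, length(xi), rank(xi), rank(yi))
      }
    }
  }
  out <- data.frame(peak_id = t$peak_ids, rho = rho, p_value = pval,
                    q_value = NA_real_, significant = NA, n_used = n_used,
                    stringsAsFactors = FALSE)
  class(out) <- c("association_result", "data.frame")
  attr(out, "zero_policy") <- zero_policy
  attr(out, "n_samples") <- n
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment. `NA` p-values pass
#' through as `NA` and do not count toward the number of hypotheses.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (!is.numeric(p_values)) stop("p_values must be numeric", call. = FALSE)
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  q <- rep(NA_real_, length(p_values))
  q[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  q
}

#' Adjust an association result and flag significance
#'
#' Applies [bh_adjust()] to the scan's p-values (untestable peaks excluded
#' from the hypothesis count) and flags `q <= alpha`.
#'
#' @param res An `association_result` from [spearman_scan()].
#' @param alpha FDR level in `(0, 1)`. Default 0.05.
#' @return The result with `q_value` and `significant` filled in.
#' @export
bh_adjust_result <- function(res, alpha = 0.05) {
  stopifnot(inherits(res, "association_result"), alpha > 0, alpha < 1)
  res$q_value <- bh_adjust(res$p_value)
  res$significant <- !is.na(res$q_value) & res$q_value <= alpha
  attr(res, "alpha") <- alpha
  attr(res, "adjusted") <- TRUE
  res
}

#' Significant peak ids, ordered by ascending p-value
#'
#' @param res An adjusted `association_result`.
#' @param alpha FDR level in `(0, 1)`; defaults to the level stored on `res`,
#'   else 0.05.
#' @return Character vector of peak ids with `q <= alpha`, ties broken by
#'   peak order for determinism.
#' @export
significant_set <- function(res, alpha = NULL) {
  stopifnot(inherits(res, "association_result"))
  if (is.null(alpha)) alpha <- attr(res, "alpha")
  if (is.null(alpha)) alpha <- 0.05
  if (!isTRUE(attr(res, "adjusted"))) {
    stop("association result has no q-values; run bh_adjust_result() first",
         call. = FALSE)
  }
  hit <- which(!is.na(res$q_value) & res$q_value <= alpha)
  hit <- hit[order(res$p_value[hit], hit)]
  res$peak_id[hit]
}

#' Significant-peak loss under retention masks
#'
#' Counts, for each named retention mask, how many of the significant peaks
#' it rejects and retains. `loss_fraction` is rejected / significant (0 when
#' the significant set is empty).
#'
#' @param sig Character vector of significant peak ids.
#' @param masks A single `retention_result` or a named list of them, all over
#'   the same peak universe that produced `sig`.
#' @return An `insight_loss_result` data frame with one row per mask:
#'   `mask`, `n_significant`, `n_rejected`, `n_retained`, `loss_fraction`;
#'   the retained significant ids per mask are in the
#'   `"retained_significant_ids"` attribute.
#' @export
insight_loss <- function(sig, masks) {
  if (inherits(masks, "retention_result")) masks <- list(cascade = masks)
  stopifnot(length(masks) >= 1L,
            all(vapply(masks, inherits, TRUE, "retention_result")))
  if (is.null(names(masks)) || any(!nzchar(names(masks)))) {
    names(masks) <- paste0("mask_", seq_along(masks))
  }
  sig <- as.character(sig)
  rows <- lapply(names(masks), function(nm) {
    m <- masks[[nm]]$mask
    if (length(sig) && anyNA(match(sig, names(m)))) {
      stop("significant set contains peak id(s) unknown to mask '", nm, "'",
           call. = FALSE)
    }
    retained <- sig[m[sig]]
    data.frame(mask = nm, n_significant = length(sig),
               n_rejected = length(sig) - length(retained),
               n_retained = length(retained),
               loss_fraction = if (length(sig))
                 (length(sig) - length(retained)) / length(sig) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("insight_loss_result", "data.frame")
  attr(out, "retained_significant_ids") <-
    stats::setNames(lapply(masks, function(m) sig[m$mask[sig]]), names(masks))
  out
}

#' Additional-loss curve restricted to the significant set
#'
#' The analogue of [retention_curve()] computed only over the significant
#' peaks: for each peak-height threshold, the baseline is the number of
#' significant peaks found at that height in at least one sample, and the
#' additional loss at each frequency cutoff counts significant peaks only.
#'
#' @param t An [aligned_peak_table()].
#' @param sig Character vector of significant peak ids (subset of
#'   `t$peak_ids`).
#' @param th2_list,freq_grid,mode As in [retention_curve()].
#' @return A `data.frame` with columns `th2`, `frequency`,
#'   `n_significant_retained`, `additional_loss_count`,
#'   `additional_loss_fraction` (of the significant set).
#' @export
insight_loss_curve <- function(t, sig, th2_list, freq_grid,
                               mode = c("th4_fill", "th3_count")) {
  mode <- match.arg(mode)
  sig <- as.character(sig)
  if (length(sig) && anyNA(match(sig, t$peak_ids))) {
    stop("significant set contains unknown peak id(s)", call. = FALSE)
  }
  sub <- subset_peaks(t, sig)
  cv <- retention_curve(sub, th2_list, freq_grid, mode)
  nsig <- length(sig)
  loss_count <- round(cv$additional_loss_fraction * nsig)
  data.frame(th2 = cv$th2, frequency = cv$frequency,
             n_significant_retained = cv$n_retained,
             additional_loss_count = loss_count,
             additional_loss_fraction = cv$additional_loss_fraction)
}
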