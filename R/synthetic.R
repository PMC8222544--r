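# Synthetic aligned-peak-table generator. Emulates the statistical structure
# the cascade analysis assumes: log-normal peak abundances spanning several
# orders of magnitude, limit-of-detection censoring that couples abundance
# and detection prevalence (the abundance-prevalence triangle), probabilistic
# gap-filling below a confident-detection height, and a planted set of peaks
# rank-correlated with a continuous phenotype, enriched among low-abundance
# peaks.

#' Simulation parameters
#'
#' Defaults describe a mid-size cohort study on a high-resolution LC/MS
#' instrument: per-peak base abundances `10^Normal(3.5, 1)` (ion counts,
#' ~4 orders of magnitude across peaks), 50% per-sample biological
#' coefficient of variation, an acquisition limit of detection of 300 counts
#' (values below it are never observed - the scan-level threshold analogue),
#' a confident-detection height of 1,000 counts (values at or above it always
#' survive and count toward the fill fraction; values between the LoD and it
#' are recovered by gap filling with probability `p_gapfill`, else 0), and a
#' birth-weight-like phenotype Normal(3400, 500) grams.
#'
#' @param n_samples,n_peaks Study dimensions.
#' @param log10_abundance_mean,log10_abundance_sd Base-10 log-normal
#'   parameters of per-peak base abundance.
#' @param biological_cv Per-peak, per-sample multiplicative log-normal noise,
#'   as a coefficient of variation (fraction).
#' @param lod Acquisition limit of detection (ion counts).
#' @param confident_height Confident-detection height (ion counts,
#'   `>= lod`).
#' @param p_gapfill Probability that a value between `lod` and
#'   `confident_height` is recovered by gap filling.
#' @param n_associated Number of peaks planted with a phenotype association.
#' @param effect_size Target Spearman correlation of planted peaks, in
#'   `(0, 1]`.
#' @param low_abundance_enrichment Fraction of planted peaks drawn from the
#'   bottom tercile of base abundance.
#' @param pheno_mean,pheno_sd Phenotype marginal (grams).
#' @param seed Integer seed; one global stream drives all draws.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n_samples = 500L, n_peaks = 5000L,
                       log10_abundance_mean = 3.5, log10_abundance_sd = 1.0,
                       biological_cv = 0.5, lod = 300,
                       confident_height = 1000, p_gapfill = 0.7,
                       n_associated = 200L, effect_size = 0.25,
                       low_abundance_enrichment = 0.8,
                       pheno_mean = 3400, pheno_sd = 500, seed = 1L) {
  p <- list(n_samples = as.integer(n_samples), n_peaks = as.integer(n_peaks),
            log10_abundance_mean = log10_abundance_mean,
            log10_abundance_sd = log10_abundance_sd,
            biological_cv = biological_cv, lod = lod,
            confident_height = confident_height, p_gapfill = p_gapfill,
            n_associated = as.integer(n_associated),
            effect_size = effect_size,
            low_abundance_enrichment = low_abundance_enrichment,
            pheno_mean = pheno_mean, pheno_sd = pheno_sd,
            seed = as.integer(seed))
  if (p$n_samples < 2L || p$n_peaks < 1L) {
    stop("n_samples must be >= 2 and n_peaks >= 1", call. = FALSE)
  }
  if (p$biological_cv < 0 || p$lod < 0 || p$confident_height < 0 ||
      p$log10_abundance_sd < 0 || p$pheno_sd < 0) {
    stop("dispersion and threshold parameters must be non-negative",
         call. = FALSE)
  }
  if (p$lod > p$confident_height) {
    stop("lod must not exceed confident_height", call. = FALSE)
  }
  if (p$p_gapfill < 0 || p$p_gapfill > 1 ||
      p$low_abundance_enrichment < 0 || p$low_abundance_enrichment > 1) {
    stop("p_gapfill and low_abundance_enrichment must lie in [0, 1]",
         call. = FALSE)
  }
  if (p$n_associated < 0L || p$n_associated > p$n_peaks) {
    stop("n_associated must lie in [0, n_peaks]", call. = FALSE)
  }
  if (p$n_associated > 0L && (p$effect_size <= 0 || p$effect_size > 1)) {
    stop("effect_size must lie in (0, 1]", call. = FALSE)
  }
  structure(p, class = "sim_params")
}

#' Simulate an aligned study
#'
#' Deterministic given the seed. Generation order (one global RNG stream):
#' (1) per-peak base abundance `10^Normal(mean, sd)`;
#' (2) latent standard-normal phenotype scores, mapped to grams;
#' (3) the planted set: `round(n_associated * low_abundance_enrichment)`
#'     peaks sampled from the bottom tercile of base abundance, the rest from
#'     the remaining peaks;
#' (4) per-cell multiplicative log-normal noise at `biological_cv`;
#' (5) for each planted peak, its sample values are re-ordered by a Gaussian
#'     copula against the phenotype scores: the copula correlation
#'     `r = 2 sin(pi * effect_size / 6)` makes the target Spearman
#'     correlation equal `effect_size` while leaving the marginal abundance
#'     distribution untouched;
#' (6) values below `lod` are censored to 0; values in
#'     `[lod, confident_height)` survive with probability `p_gapfill`, else
#'     0; `fill_fraction` is the per-peak fraction of samples at or above
#'     `confident_height`.
#'
#' @param params A [sim_params()].
#' @return A list with components `table` ([aligned_peak_table()]),
#'   `phenotype` ([phenotype()]) and `truth` (class `sim_truth`: the
#'   pre-censoring abundance matrix, planted peak ids, per-peak mean true
#'   abundance and realised prevalence, and the LoD used).
#' @export
simulate_study <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  set.seed(p$seed)
  peak_ids <- sprintf("peak_%05d", seq_len(p$n_peaks))
  sample_ids <- sprintf("sample_%04d", seq_len(p$n_samples))

  base <- 10^stats::rnorm(p$n_peaks, p$log10_abundance_mean,
                          p$log10_abundance_sd)
  z_pheno <- stats::rnorm(p$n_samples)
  pheno_values <- p$pheno_mean + p$pheno_sd * z_pheno

  planted <- integer(0)
  if (p$n_associated > 0L) {
    tercile <- stats::quantile(base, 1 / 3, names = FALSE)
    low_pool <- which(base <= tercile)
    high_pool <- which(base > tercile)
    k_low <- round(p$n_associated * p$low_abundance_enrichment)
    k_high <- p$n_associated - k_low
    if (k_low > length(low_pool) || k_high > length(high_pool)) {
      stop("infeasible enrichment: pool smaller than requested planted count",
           call. = FALSE)
    }
    planted <- c(sample(low_pool, k_low), sample(high_pool, k_high))
    planted <- sort(planted)
  }

  sdlog <- sqrt(log(1 + p$biological_cv^2))
  noise <- matrix(stats::rnorm(p$n_peaks * p$n_samples, -sdlog^2 / 2, sdlog),
                  p$n_peaks, p$n_samples)
  true_abund <- base * exp(noise)

  if (length(planted)) {
    r <- 2 * sin(pi * p$effect_size / 6)
    for (i in planted) {
      eps <- stats::rnorm(p$n_samples)
      z_i <- r * z_pheno + sqrt(1 - r^2) * eps
      true_abund[i, ] <- sort(true_abund[i, ])[rank(z_i, ties.method = "first")]
    }
  }

  observed <- true_abund
  observed[observed < p$lod] <- 0
  window <- observed > 0 & observed < p$confident_height
  if (any(window)) {
    dropped <- stats::runif(sum(window)) > p$p_gapfill
    observed[window][dropped] <- 0
  }
  fill <- rowMeans(observed >= p$confident_height)

  # m/z and RT carry no information in the simulation; draw plausible values
  mz <- stats::runif(p$n_peaks, 85, 1200)
  rt <- stats::runif(p$n_peaks, 0.5, 10)

  tab <- aligned_peak_table(peak_ids, mz, rt, observed, fill, sample_ids)
  ph <- phenotype(sample_ids, pheno_values)
  truth <- structure(
    list(true_abundance = true_abund, associated_ids = peak_ids[planted],
         mean_abundance = rowMeans(true_abund),
         prevalence = rowMeans(observed > 0), lod = p$lod, params = p),
    class = "sim_truth")
  list(table = tab, phenotype = ph, truth = truth)
}

#' Planted-peak recovery report
#'
#' Runs the association scan and the threshold cascade on a simulated study
#' and joins both against the planted ground truth: which planted peaks were
#' detected as significant, and which the cascade rejects. The
#' `cascade_loss` attribute is the fraction of detected-significant planted
#' peaks that the cascade rejects - the simulated analogue of the fraction
#' of phenotype-associated peaks a study loses to its processing thresholds.
#'
#' @param t An [aligned_peak_table()] from [simulate_study()].
#' @param ph The matching [phenotype()].
#' @param truth The matching `sim_truth`.
#' @param cfg A [threshold_config()].
#' @param alpha FDR level for the significance call. Default 0.05.
#' @param zero_policy Passed to [spearman_scan()].
#' @return A `data.frame` with one row per planted peak: `peak_id`,
#'   `detected_significant`, `rejected_by_cascade`, `max_height`,
#'   `fill_fraction`. Attributes: `sensitivity` (detected / planted) and
#'   `cascade_loss` (rejected among detected-significant; 0 when none
#'   detected).
#' @export
planted_recovery_report <- function(t, ph, truth, cfg, alpha = 0.05,
                                    zero_policy = "include") {
  stopifnot(inherits(t, "aligned_peak_table"), inherits(truth, "sim_truth"),
            inherits(cfg, "threshold_config"))
  if (length(truth$associated_ids) &&
      anyNA(match(truth$associated_ids, t$peak_ids))) {
    stop("truth and table cover different peak universes", call. = FALSE)
  }
  res <- bh_adjust_result(spearman_scan(t, ph, zero_policy), alpha)
  sig <- significant_set(res, alpha)
  mask <- apply_cascade(t, cfg)$mask
  ids <- truth$associated_ids
  idx <- match(ids, t$peak_ids)
  out <- data.frame(
    peak_id = ids,
    detected_significant = ids %in% sig,
    rejected_by_cascade = !mask[ids],
    max_height = if (length(idx)) apply(t$heights[idx, , drop = FALSE], 1, max)
                 else numeric(0),
    fill_fraction = t$fill_fraction[idx],
    row.names = NULL, stringsAsFactors = FALSE)
  n_det <- sum(out$detected_significant)
  attr(out, "sensitivity") <- if (length(ids)) n_det / length(ids) else 0
  attr(out, "cascade_loss") <- if (n_det)
    sum(out$detected_significant & out$rejected_by_cascade) / n_det else 0
  attr(out, "n_significant_total") <- length(sig)
  out
}

#' Write a simulated study to disk
#'
#' Writes the alignment table in the MS-DIAL TSV dialect, the phenotype as a
#' two-column TSV, and the ground truth (planted ids, LoD, parameters) as
#' JSON, so the downstream pipeline runs on simulated studies unchanged.
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_simulated_study <- function(study, dir) {
  stopifnot(is.list(study),
            inherits(study$table, "aligned_peak_table"),
            inherits(study$phenotype, "phenotype"),
            inherits(study$truth, "sim_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(alignment = file.path(dir, "alignment.tsv"),
             phenotype = file.path(dir, "phenotype.tsv"),
             truth = file.path(dir, "truth.json"))
  write_msdial_alignment(study$table, paths[["alignment"]])
  write_phenotype(study$phenotype, paths[["phenotype"]])
  truth <- study$truth
  jsonlite::write_json(
    list(associated_ids = truth$associated_ids, lod = truth$lod,
         params = unclass(truth$params)),
    paths[["truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
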