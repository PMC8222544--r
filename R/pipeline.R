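# Pipeline orchestration: run every stage on an aligned table + phenotype
# and write the standard report bundle as byte-stable TSVs plus a JSON
# manifest.

#' Pipeline configuration
#'
#' @param alignment Path to an alignment TSV, or an [aligned_peak_table()].
#' @param phenotype Path to a phenotype TSV, or a [phenotype()]. Optional;
#'   without it the association stage is skipped.
#' @param peaklists Optional character vector of per-file peak-list paths
#'   (enables the file-level summary stages).
#' @param th2_list Peak-height threshold grid. Default
#'   `c(1000, 2000, 5000, 10000, 20000)`, the grid used for retention curves.
#' @param freq_grid Detection-frequency grid. Default `seq(0, 1, 0.05)`.
#' @param th4_fill,th5_intensity,sn_min Cascade parameters; see
#'   [threshold_config()]. Defaults 0.6, 0, 2.
#' @param th3_min_fraction Minimum fraction of samples at `th2` for the
#'   cascade and the pass/fail flag columns. Default 0.02.
#' @param cascade_th2 The single peak-height threshold used by the cascade
#'   and flag columns. Default 10000.
#' @param alpha FDR level. Default 0.05.
#' @param zero_policy Zero handling in the scan. Default `"include"`.
#' @param mode Frequency semantics for curves; see [retention_curve()].
#' @param out_dir Output directory.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(alignment, phenotype = NULL, peaklists = NULL,
                            th2_list = c(1000, 2000, 5000, 10000, 20000),
                            freq_grid = seq(0, 1, by = 0.05),
                            cascade_th2 = 10000, th3_min_fraction = 0.02,
                            th4_fill = 0.6, th5_intensity = 0, sn_min = 2,
                            alpha = 0.05, zero_policy = "include",
                            mode = "th4_fill", out_dir = ".") {
  structure(list(alignment = alignment, phenotype = phenotype,
                 peaklists = peaklists, th2_list = th2_list,
                 freq_grid = freq_grid, cascade_th2 = cascade_th2,
                 th3_min_fraction = th3_min_fraction, th4_fill = th4_fill,
                 th5_intensity = th5_intensity, sn_min = sn_min,
                 alpha = alpha, zero_policy = zero_policy, mode = mode,
                 out_dir = out_dir),
            class = "pipeline_config")
}

.write_tsv <- function(x, path, digits = NULL) {
  if (!is.null(digits)) {
    num <- vapply(x, is.numeric, TRUE)
    x[num] <- lapply(x[num], function(v) round(v, digits))
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", eol = "\n")
  path
}

#' Run the full threshold-cascade pipeline
#'
#' Stages, each written as a TSV in `out_dir`:
#' * `height_bins.tsv`, `sn_bins.tsv` - cross-file quantile-bin summaries
#'   (only when peak lists are configured);
#' * `rejection_table.tsv` - mean/SD file-level rejection per cutoff (ditto);
#' * `alignment_retention.tsv` - rejected count and percentage per
#'   peak-height threshold at the alignment level;
#' * `retention_curves.tsv` - the retention / additional-loss grid;
#' * `association.tsv` - per-peak RT, m/z, rho, p, q, max height and
#'   pass/fail flags for the configured detection-frequency and
#'   height-in-fraction-of-samples thresholds, ordered by ascending p
#'   (only when a phenotype is configured);
#' * `insight_loss.tsv` + `insight_loss_curves.tsv` - significant-peak loss
#'   under the cascade and per-stage masks (ditto);
#' * `manifest.json` - package version, configured values, a config hash and
#'   per-output row counts.
#'
#' Outputs are byte-stable: running twice on the same inputs and
#' configuration produces identical files.
#'
#' @param cfg A [pipeline_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  t <- if (inherits(cfg$alignment, "aligned_peak_table")) cfg$alignment
       else read_msdial_alignment(cfg$alignment)
  ph <- NULL
  if (!is.null(cfg$phenotype)) {
    ph <- if (inherits(cfg$phenotype, "phenotype")) cfg$phenotype
          else read_phenotype(cfg$phenotype)
  }
  manifest <- list(package = "thresholdscape",
                   version = as.character(utils::packageVersion("thresholdscape")),
                   config = cfg[setdiff(names(unclass(cfg)),
                                        c("alignment", "phenotype",
                                          "peaklists", "out_dir"))],
                   n_peaks = n_peaks(t), n_samples = n_samples(t),
                   outputs = list())
  add_output <- function(name, path, n) {
    manifest$outputs[[name]] <<- list(file = basename(path), rows = n)
  }

  if (!is.null(cfg$peaklists)) {
    files <- lapply(cfg$peaklists, read_msdial_peaklist)
    hb <- cross_file_bin_summary(files, "height")
    sb <- cross_file_bin_summary(files, "sn")
    rj <- rejection_table(files, sn_min = cfg$sn_min)
    rj$mean_rejected_pct <- round(rj$mean_rejected_pct, 2)
    rj$sd_rejected_pct <- round(rj$sd_rejected_pct, 2)
    add_output("height_bins", .write_tsv(as.data.frame(hb),
      file.path(cfg$out_dir, "height_bins.tsv"), digits = 1), nrow(hb))
    add_output("sn_bins", .write_tsv(as.data.frame(sb),
      file.path(cfg$out_dir, "sn_bins.tsv"), digits = 1), nrow(sb))
    add_output("rejection_table", .write_tsv(rj,
      file.path(cfg$out_dir, "rejection_table.tsv")), nrow(rj))
  }

  # alignment-level rejection per height threshold (percentages to 1 dp)
  ret <- do.call(rbind, lapply(rev(sort(cfg$th2_list)), function(th2) {
    r <- alignment_height_filter(t, th2)
    data.frame(th2 = th2, n_rejected = r$n_rejected,
               rejected_pct = round(100 * r$rejected_fraction, 1))
  }))
  add_output("alignment_retention", .write_tsv(ret,
    file.path(cfg$out_dir, "alignment_retention.tsv")), nrow(ret))

  curves <- retention_curve(t, sort(cfg$th2_list), cfg$freq_grid, cfg$mode)
  add_output("retention_curves", .write_tsv(curves,
    file.path(cfg$out_dir, "retention_curves.tsv"), digits = 6), nrow(curves))

  cascade_cfg <- threshold_config(cfg$cascade_th2, cfg$th3_min_fraction,
                                  cfg$th4_fill, cfg$th5_intensity, cfg$sn_min)
  cas <- apply_cascade(t, cascade_cfg)

  if (!is.null(ph)) {
    res <- bh_adjust_result(spearman_scan(t, ph, cfg$zero_policy), cfg$alpha)
    idx <- order(is.na(res$p_value), res$p_value, seq_len(nrow(res)))
    flags_freq <- fill_filter(t, cfg$th4_fill, cfg$th5_intensity)$mask
    flags_h <- height_frequency_filter(t, cfg$cascade_th2,
                                       cfg$th3_min_fraction)$mask
    assoc <- data.frame(
      peak_id = t$peak_ids, rt = t$rt, mz = t$mz, rho = res$rho,
      p_value = res$p_value, q_value = res$q_value,
      significant = res$significant,
      max_peak_height = apply(t$heights, 1, max),
      passed_fill_threshold = unname(flags_freq),
      passed_height_frequency_threshold = unname(flags_h),
      stringsAsFactors = FALSE)[idx, ]
    add_output("association", .write_tsv(assoc,
      file.path(cfg$out_dir, "association.tsv"), digits = 10), nrow(assoc))

    sig <- significant_set(res, cfg$alpha)
    il <- insight_loss(sig, list(cascade = cas,
                                 height_frequency = cas$stages$height_frequency,
                                 fill = cas$stages$fill))
    add_output("insight_loss", .write_tsv(as.data.frame(il),
      file.path(cfg$out_dir, "insight_loss.tsv"), digits = 6), nrow(il))
    ilc <- insight_loss_curve(t, sig, sort(cfg$th2_list), cfg$freq_grid,
                              cfg$mode)
    add_output("insight_loss_curves", .write_tsv(ilc,
      file.path(cfg$out_dir, "insight_loss_curves.tsv"), digits = 6),
      nrow(ilc))
  }

  cfg_path <- file.path(cfg$out_dir, "config.json")
  jsonlite::write_json(manifest$config, cfg_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest$config_hash <- unname(tools::md5sum(cfg_path))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
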