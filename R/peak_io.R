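# Readers and writers for the MS-DIAL tab-delimited export dialect.
#
# Column-name matching is case-insensitive with surrounding whitespace
# stripped; the synonym sets below document the exact names accepted.
# All files are plain TSV, UTF-8, LF endings.

.norm_names <- function(x) tolower(trimws(x))

.peaklist_synonyms <- list(
  mz     = c("mz", "m/z", "precursor m/z", "precursor mz", "average mz"),
  rt     = c("rt", "rt (min)", "rt(min)", "rt.min.", "retention time",
             "retention time (min)"),
  height = c("height", "peak height"),
  area   = c("area", "peak area"),
  sn     = c("s/n", "sn", "s/n ratio", "signal/noise", "signal to noise")
)

.alignment_synonyms <- list(
  id   = c("alignment id", "alignment_id", "peak id", "peak_id", "id"),
  rt   = c("average rt(min)", "average rt (min)", "average rt", "average_rt_min",
           "rt", "rt (min)"),
  mz   = c("average mz", "average_mz", "average m/z", "mz", "m/z"),
  fill = c("fill %", "fill%", "fill percent", "fill_percent", "fill",
           "fill fraction", "fill_fraction")
)

.find_column <- function(header, synonyms) {
  hit <- which(.norm_names(header) %in% synonyms)
  if (length(hit)) hit[1L] else NA_integer_
}

# Strict numeric conversion: any cell that does not parse to a finite number
# (including literal "NA") is a parse error naming the offending data row.
.parse_numeric_column <- function(x, col_name) {
  x <- trimws(x)
  v <- suppressWarnings(as.numeric(x))
  bad <- which(!is.finite(v))
  if (length(bad)) {
    stop("non-numeric value '", x[bad[1L]], "' in column '", col_name,
         "' at data row ", bad[1L], call. = FALSE)
  }
  v
}

.read_tsv_raw <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "", quote = "")
}

#' Read an MS-DIAL style per-file peak list
#'
#' Parses a tab-delimited peak-list export. The header must contain at least
#' m/z, retention time, peak height, peak area and S/N columns (synonyms are
#' matched case-insensitively). Unrecognised columns are preserved untouched
#' in the peak data frame as opaque metadata. The resolved column mapping is
#' recorded in the `"column_map"` attribute.
#'
#' @param path Path to a tab-delimited peak-list file.
#' @param file_id Identifier for the file; defaults to the base file name.
#' @return A [file_peak_list()].
#' @export
read_msdial_peaklist <- function(path, file_id = basename(path)) {
  raw <- .read_tsv_raw(path)
  header <- names(raw)
  idx <- vapply(.peaklist_synonyms, function(s) .find_column(header, s), 1L)
  if (anyNA(idx)) {
    stop("peak-list file is missing mandatory column(s): ",
         paste(names(idx)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  peaks <- data.frame(row.names = NULL)
  if (nrow(raw)) {
    peaks <- as.data.frame(lapply(names(idx), function(nm) {
      .parse_numeric_column(raw[[idx[[nm]]]], header[idx[[nm]]])
    }))
  } else {
    peaks <- as.data.frame(lapply(names(idx), function(nm) numeric(0)))
  }
  names(peaks) <- names(idx)
  extra <- setdiff(seq_along(header), idx)
  for (j in extra) peaks[[header[j]]] <- if (nrow(raw)) raw[[j]] else character(0)
  out <- file_peak_list(file_id, peaks)
  attr(out, "column_map") <- stats::setNames(header[idx], names(idx))
  out
}

#' Write a peak list in the same tab-delimited dialect
#'
#' @param pl A [file_peak_list()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msdial_peaklist <- function(pl, path) {
  stopifnot(inherits(pl, "file_peak_list"))
  out <- pl$peaks
  core <- c(mz = "Mz", rt = "RT (min)", height = "Height", area = "Area",
            sn = "S/N")
  for (nm in names(core)) out[[nm]] <- sprintf("%.17g", pl$peaks[[nm]])
  names(out)[match(names(core), names(out))] <- core
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Read an MS-DIAL style aligned peak table
#'
#' Expects per-peak metadata columns (alignment id, average RT, average m/z,
#' fill) followed by one height column per sample; every column that is not a
#' recognised metadata column is taken to be a sample. Zeros in the matrix are
#' preserved (zero = not measured / not recovered). The fill column accepts
#' both the percent (0-100) and fraction (0-1) encodings: if any value
#' exceeds 1 the column is interpreted as percent and divided by 100; the
#' choice is recorded in the `"fill_encoding"` attribute. If the fill column
#' is absent, `fill_fraction` is computed as the fraction of samples with
#' height > 0 and a warning is raised (`"fill_source"` attribute is then
#' `"computed"`).
#'
#' @param path Path to a tab-delimited alignment export.
#' @return An [aligned_peak_table()].
#' @export
read_msdial_alignment <- function(path) {
  raw <- .read_tsv_raw(path)
  header <- names(raw)
  idx <- vapply(.alignment_synonyms, function(s) .find_column(header, s), 1L)
  if (is.na(idx[["rt"]]) || is.na(idx[["mz"]])) {
    stop("alignment file is missing mandatory column(s): ",
         paste(c("rt", "mz")[is.na(idx[c("rt", "mz")])], collapse = ", "),
         call. = FALSE)
  }
  sample_cols <- setdiff(seq_along(header), idx[!is.na(idx)])
  if (!length(sample_cols)) stop("alignment file has no sample columns", call. = FALSE)
  if (anyDuplicated(header[sample_cols])) {
    dup <- unique(header[sample_cols][duplicated(header[sample_cols])])
    stop("duplicate sample column name(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(raw)
  rt <- .parse_numeric_column(raw[[idx[["rt"]]]], header[idx[["rt"]]])
  mz <- .parse_numeric_column(raw[[idx[["mz"]]]], header[idx[["mz"]]])
  peak_ids <- if (!is.na(idx[["id"]])) {
    trimws(raw[[idx[["id"]]]])
  } else {
    sprintf("peak_%d", seq_len(n))
  }
  heights <- matrix(0, n, length(sample_cols),
                    dimnames = list(NULL, header[sample_cols]))
  for (k in seq_along(sample_cols)) {
    heights[, k] <- .parse_numeric_column(raw[[sample_cols[k]]],
                                          header[sample_cols[k]])
  }
  fill_encoding <- NA_character_
  fill_source <- "file"
  if (!is.na(idx[["fill"]])) {
    fill <- .parse_numeric_column(raw[[idx[["fill"]]]], header[idx[["fill"]]])
    if (n && max(fill) > 1) {
      fill <- fill / 100
      fill_encoding <- "percent"
    } else {
      fill_encoding <- "fraction"
    }
  } else {
    fill <- if (n) rowMeans(heights > 0) else numeric(0)
    fill_source <- "computed"
    warning("fill column absent; fill_fraction computed as the fraction of ",
            "samples with height > 0", call. = FALSE)
  }
  out <- aligned_peak_table(peak_ids, mz, rt, heights, fill,
                            header[sample_cols])
  attr(out, "fill_encoding") <- fill_encoding
  attr(out, "fill_source") <- fill_source
  out
}

#' Write an aligned peak table in the MS-DIAL dialect
#'
#' Columns: `Alignment ID`, `Average Rt(min)`, `Average Mz`, `Fill %` (written
#' in the 0-1 fraction encoding, as MS-DIAL does), then one column per
#' sample. Heights are written with 17 significant digits so that a write /
#' read round trip reproduces them bit-exactly.
#'
#' @param t An [aligned_peak_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msdial_alignment <- function(t, path) {
  stopifnot(inherits(t, "aligned_peak_table"))
  out <- data.frame(`Alignment ID` = t$peak_ids,
                    `Average Rt(min)` = sprintf("%.17g", t$rt),
                    `Average Mz` = sprintf("%.17g", t$mz),
                    `Fill %` = sprintf("%.17g", t$fill_fraction),
                    check.names = FALSE, stringsAsFactors = FALSE)
  for (k in seq_along(t$sample_ids)) {
    out[[t$sample_ids[k]]] <- sprintf("%.17g", t$heights[, k])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Read / write a phenotype table
#'
#' Two-column TSV: `sample_id`, `value`. Empty cells and literal `NA` are
#' read as missing values.
#'
#' @param path Path to a phenotype TSV.
#' @return A [phenotype()].
#' @export
read_phenotype <- function(path) {
  raw <- .read_tsv_raw(path)
  if (!all(c("sample_id", "value") %in% .norm_names(names(raw)))) {
    stop("phenotype file must have columns 'sample_id' and 'value'",
         call. = FALSE)
  }
  names(raw) <- .norm_names(names(raw))
  vals <- trimws(raw[["value"]])
  vals[vals %in% c("", "NA")] <- NA_character_
  num <- suppressWarnings(as.numeric(vals))
  bad <- which(!is.na(vals) & is.na(num))
  if (length(bad)) {
    stop("non-numeric phenotype value '", vals[bad[1L]], "' at data row ",
         bad[1L], call. = FALSE)
  }
  phenotype(trimws(raw[["sample_id"]]), num)
}

#' @rdname read_phenotype
#' @param ph A [phenotype()].
#' @export
write_phenotype <- function(ph, path) {
  stopifnot(inherits(ph, "phenotype"))
  out <- data.frame(sample_id = ph$sample_ids,
                    value = ifelse(is.na(ph$values), "NA",
                                   sprintf("%.17g", ph$values)),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Packaged fixture: top significant birth-weight peaks
#'
#' The published table of the 49 most significant birth-weight-associated
#' peaks (the printed table is headed "Top 50" but contains 49 data rows; the
#' fixture carries the rows as printed). Columns: retention time (min), m/z,
#' Spearman p-value against birth weight, maximum peak height over the 499
#' files, and whether the peak passed (a) the 60% post-gap-fill detection
#' frequency threshold and (b) the height-10,000-in-at-least-2%-of-samples
#' threshold.
#'
#' @return A `data.frame` with 49 rows and columns `rt`, `mz`, `p_value`,
#'   `max_peak_height`, `passed_th4_60pct`, `passed_th3_10k_2pct` (logicals).
#' @export
load_table5_fixture <- function() {
  path <- system.file("extdata", "table5_birthweight_peaks.tsv",
                      package = "thresholdscape", mustWork = TRUE)
  x <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  x$passed_th4_60pct <- x$passed_th4_60pct == "Yes"
  x$passed_th3_10k_2pct <- x$passed_th3_10k_2pct == "Yes"
  stopifnot(nrow(x) == 49L)
  x
}

#' Packaged fixture: peak-height quantile-bin boundaries
#'
#' The published 20-bin distribution of peak heights across the study's 499
#' files: per bin, the cross-file mean upper boundary and its relative
#' standard deviation. The top (95-100%) bin boundary is the study's maximum
#' observed peak height.
#'
#' @return A `data.frame` with columns `bin`, `mean_upper_boundary`,
#'   `rsd_percent`, ordered from the top bin down as printed.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_height_bins.tsv",
                      package = "thresholdscape", mustWork = TRUE)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
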