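test_that("peak list round trip preserves values and extra columns", {
  pl <- file_peak_list("f1", data.frame(
    mz = c(100.05, 250.1, 799.9), rt = c(0.5, 3.2, 9.9),
    height = c(120, 5300, 99000), area = c(240, 10600, 198000),
    sn = c(2.5, 30, 410), note = c("a", "b", "c")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_msdial_peaklist(pl, path)
  back <- read_msdial_peaklist(path, file_id = "f1")
  expect_equal(back$peaks$mz, pl$peaks$mz)
  expect_equal(back$peaks$height, pl$peaks$height)
  expect_equal(back$peaks$sn, pl$peaks$sn)
  expect_equal(back$peaks$note, pl$peaks$note)
  expect_named(attr(back, "column_map"),
               c("mz", "rt", "height", "area", "sn"))
})

test_that("header-only peak list yields an empty list without error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("Mz\tRT (min)\tHeight\tArea\tS/N", path)
  pl <- read_msdial_peaklist(path)
  expect_s3_class(pl, "file_peak_list")
  expect_equal(nrow(pl$peaks), 0L)
})

test_that("peak list parse and format errors name the offender", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Mz\tRT (min)\tHeight\tArea\tS/N",
               "100\t1\t500\t900\t4",
               "200\t2\tNA\t900\t4"), path)
  expect_error(read_msdial_peaklist(path), "row 2")
  writeLines(c("Mz\tRT (min)\tArea\tS/N", "100\t1\t900\t4"), path)
  expect_error(read_msdial_peaklist(path), "height")
})

test_that("alignment round trip is bit-exact for heights", {
  t <- random_table(42)
  t$heights[3, 5] <- 12345.678901234567  # non-integer heights survive too
  path <- withr::local_tempfile(fileext = ".tsv")
  write_msdial_alignment(t, path)
  back <- read_msdial_alignment(path)
  expect_identical(unname(back$heights), unname(t$heights))
  expect_equal(back$fill_fraction, t$fill_fraction, tolerance = 1e-9)
  expect_equal(back$peak_ids, t$peak_ids)
  expect_equal(back$sample_ids, t$sample_ids)
})

test_that("fill column percent encoding is detected and divided by 100", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Alignment ID\tAverage Rt(min)\tAverage Mz\tFill %\ts1\ts2",
               "p1\t1.0\t100\t60\t0\t5000",
               "p2\t2.0\t200\t100\t300\t400"), path)
  t <- read_msdial_alignment(path)
  expect_equal(t$fill_fraction, c(0.60, 1.00))
  expect_identical(attr(t, "fill_encoding"), "percent")
})

test_that("missing fill column is computed from nonzero heights with warning", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Alignment ID\tAverage Rt(min)\tAverage Mz\ts1\ts2\ts3",
               "p1\t1.0\t100\t0\t5\t7"), path)
  expect_warning(t <- read_msdial_alignment(path), "fill")
  expect_equal(t$fill_fraction, 2 / 3)
  expect_identical(attr(t, "fill_source"), "computed")
})

test_that("duplicate sample columns are a format error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Alignment ID\tAverage Rt(min)\tAverage Mz\tFill %\ts1\ts1",
               "p1\t1.0\t100\t0.5\t1\t2"), path)
  expect_error(read_msdial_alignment(path), "duplicate sample")
})

test_that("packaged significant-peak fixture matches the published rows", {
  t5 <- load_table5_fixture()
  expect_equal(nrow(t5), 49L)
  expect_equal(t5$rt[1], 3.664)
  expect_equal(t5$mz[1], 549.1632)
  expect_equal(t5$max_peak_height[1], 3703)
  expect_false(t5$passed_th4_60pct[1])
  expect_false(t5$passed_th3_10k_2pct[1])
  r <- t5[t5$mz == 412.3035, ]
  expect_equal(r$max_peak_height, 11160)
  expect_true(r$passed_th4_60pct)
  expect_false(r$passed_th3_10k_2pct)
  r <- t5[t5$mz == 287.2457 & t5$rt == 0.606, ]
  expect_equal(r$max_peak_height, 116177)
  expect_true(r$passed_th4_60pct)
  expect_true(r$passed_th3_10k_2pct)
})

test_that("fixture files are byte-identical to the pinned transcriptions", {
  md5 <- tools::md5sum(system.file(
    "extdata", c("table5_birthweight_peaks.tsv", "table1_height_bins.tsv"),
    package = "thresholdscape"))
  expect_equal(unname(md5), c("58648349a60873512ffdf9208cf58605",
                              "5cc5a1115ecf9445c6c70724386aedfa"))
})

test_that("packaged height-bin fixture carries the study maximum on top", {
  t1 <- load_table1_fixture()
  expect_equal(nrow(t1), 21L)
  expect_equal(t1$mean_upper_boundary[t1$bin == "95-100"], 12392001)
  expect_equal(t1$mean_upper_boundary[t1$bin == "75-80"], 8428)
})

test_that("phenotype TSV round trips including missing values", {
  ph <- phenotype(c("a", "b", "c"), c(3100, NA, 3650.5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_phenotype(ph, path)
  back <- read_phenotype(path)
  expect_equal(back$sample_ids, ph$sample_ids)
  expect_equal(back$values, ph$values)
  expect_equal(back$n_missing, 1L)
})
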