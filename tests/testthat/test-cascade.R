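test_that("file-level rejection counts below-cutoff peaks among adequate S/N", {
  pl <- make_peaklist(c(100, 600, 1500, 6000, 20000))
  expect_equal(file_level_rejection(pl, 1000, sn_min = 2), 0.4)
  expect_equal(file_level_rejection(pl, 0, sn_min = 2), 0)
  pl2 <- make_peaklist(c(100, 20000), sn = c(1, 5))
  expect_equal(file_level_rejection(pl2, 1000, sn_min = 2), 0)
  expect_error(file_level_rejection(pl, -5), "non-negative")
})

test_that("alignment height filter keeps peaks reaching th2 in any sample", {
  h <- rbind(c(500, 100, 0), c(10000, 50, 0), c(20000, 19000, 5))
  t <- aligned_peak_table(c("a", "b", "c"), 1:3, 1:3, h, rep(1, 3),
                          c("s1", "s2", "s3"))
  r <- alignment_height_filter(t, 10000)
  expect_equal(r$n_rejected, 1L)                 # boundary value retained
  expect_equal(unname(r$mask), c(FALSE, TRUE, TRUE))
  expect_equal(alignment_height_filter(t, 0)$rejected_fraction, 0)
})

test_that("height-frequency filter requires ceil(fraction * n) samples", {
  h <- matrix(0, 2, 10)
  h[1, 1:2] <- 5000   # exactly 2 qualifying samples
  h[2, 1] <- 5000     # 1 qualifying sample
  t <- aligned_peak_table(c("a", "b"), 1:2, 1:2, h, c(1, 1),
                          sprintf("s%d", 1:10))
  r <- height_frequency_filter(t, 5000, 0.2)
  expect_true(r$mask[["a"]])    # ceil(0.2 * 10) = 2
  expect_false(r$mask[["b"]])   # 1 < 2
  expect_equal(height_frequency_filter(t, 5000, 0)$mask,
               alignment_height_filter(t, 5000)$mask)
  expect_error(height_frequency_filter(t, 5000, 1.2), "\\[0, 1\\]")
})

test_that("fill filter uses stored fill, or recomputes above the th5 floor", {
  h <- rbind(c(10, 20, 30), c(40, 50, 60))
  t <- aligned_peak_table(c("a", "b"), 1:2, 1:2, h, c(0.59, 0.60),
                          c("s1", "s2", "s3"))
  r <- fill_filter(t, 0.60)
  expect_false(r$mask[["a"]])   # 0.59 < 0.60
  expect_true(r$mask[["b"]])    # boundary passes
  expect_true(all(fill_filter(t, 0)$mask))
  t2 <- aligned_peak_table("a", 1, 1, matrix(c(0, 50, 5000), 1), 1,
                           c("s1", "s2", "s3"))
  expect_false(fill_filter(t2, 0.5, th5_intensity = 100)$mask[["a"]])  # 1/3
})

test_that("the cascade is the AND of its stages and is idempotent", {
  # stage 1 (height >= 1000 in >= 2 of 4 samples) rejects exactly A;
  # stage 2 (fill >= 0.5) rejects exactly B and C
  h <- rbind(A = c(1500, 0, 0, 0), B = c(2000, 2000, 0, 0),
             C = c(3000, 3000, 3000, 0), D = c(4000, 4000, 4000, 4000),
             E = c(5000, 5000, 0, 0))
  t <- aligned_peak_table(rownames(h), 1:5, 1:5, h,
                          c(A = 0.9, B = 0.25, C = 0.4, D = 1, E = 0.5),
                          sprintf("s%d", 1:4))
  cfg <- threshold_config(th2_height = 1000, th3_min_fraction = 0.5,
                          th4_fill_fraction = 0.5)
  r <- apply_cascade(t, cfg)
  expect_equal(names(which(!r$mask)), c("A", "B", "C"))
  expect_equal(names(which(!r$stages$height_frequency$mask)), "A")
  expect_equal(names(which(!r$stages$fill$mask)), c("B", "C"))
  # identity cascade retains everything
  expect_equal(apply_cascade(t, threshold_config())$n_rejected, 0L)
  # re-applying to the retained sub-table rejects nothing further
  sub <- subset_peaks(t, r$mask)
  expect_equal(apply_cascade(sub, cfg)$n_rejected, 0L)
})

test_that("retention curves report additional loss beyond the th2 baseline", {
  t <- aligned_peak_table(sprintf("p%d", 1:4), 1:4, 1:4,
                          matrix(1000, 4, 4), c(1.0, 0.7, 0.4, 0.1),
                          sprintf("s%d", 1:4))
  cv <- retention_curve(t, th2_list = 0, freq_grid = 0.5, mode = "th4_fill")
  expect_equal(cv$additional_loss_fraction, 0.5)  # 2 of 4 below fill 0.5
  t_full <- aligned_peak_table(sprintf("p%d", 1:3), 1:3, 1:3,
                               matrix(500, 3, 4), rep(1, 3),
                               sprintf("s%d", 1:4))
  cv2 <- retention_curve(t_full, 0, seq(0, 1, 0.25), mode = "th4_fill")
  expect_true(all(cv2$additional_loss_fraction == 0))
  expect_error(retention_curve(t, c(100, 50), 0.5), "sorted")
})

test_that("retained counts are monotone along both curve axes", {
  for (seed in c(7, 19, 37)) {
    t <- random_table(seed)
    for (mode in c("th4_fill", "th3_count")) {
      cv <- retention_curve(t, c(0, 100, 1000, 10000),
                            seq(0, 1, 0.2), mode = mode)
      by_th2 <- split(cv$n_retained, cv$th2)
      for (v in by_th2) expect_true(all(diff(v) <= 0))
      by_f <- split(cv, cv$frequency)
      ths <- sort(unique(cv$th2))
      for (b in by_f) expect_true(all(diff(b$n_retained[order(b$th2)]) <= 0))
    }
  }
})

test_that("a zero-peak table passes through every filter untouched", {
  t0 <- aligned_peak_table(character(0), numeric(0), numeric(0),
                           matrix(numeric(0), 0, 3), numeric(0),
                           c("s1", "s2", "s3"))
  for (r in list(alignment_height_filter(t0, 1000),
                 height_frequency_filter(t0, 1000, 0.5),
                 fill_filter(t0, 0.6),
                 apply_cascade(t0, threshold_config(1000, 0.1, 0.6)))) {
    expect_equal(r$n_total, 0L)
    expect_equal(r$rejected_fraction, 0)
    expect_length(r$mask, 0L)
  }
})
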