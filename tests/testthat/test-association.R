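make_scan_table <- function(heights_by_peak, sample_ids) {
  h <- do.call(rbind, heights_by_peak)
  aligned_peak_table(names(heights_by_peak),
                     seq_along(heights_by_peak), seq_along(heights_by_peak),
                     h, rep(1, length(heights_by_peak)), sample_ids)
}

test_that("spearman scan recovers perfect and textbook correlations", {
  sid <- sprintf("s%02d", 1:10)
  y <- c(3100, 2900, 3300, 3600, 2700, 3450, 3050, 3550, 2850, 3250)
  t <- make_scan_table(list(up = y, down = max(y) + min(y) - y), sid)
  res <- spearman_scan(t, phenotype(sid, y))
  expect_equal(res$rho, c(1, -1))
  sid5 <- sprintf("s%d", 1:5)
  t5 <- make_scan_table(list(a = c(1, 2, 3, 4, 5)), sid5)
  res5 <- spearman_scan(t5, phenotype(sid5, c(3, 1, 2, 5, 4)))
  expect_equal(res5$rho, 0.6)  # 1 - 6*8/(5*24)
  expect_equal(res5$p_value,
               perm_pvalue_oracle(c(1, 2, 3, 4, 5), c(3, 1, 2, 5, 4)))
})

test_that("rho matches the rank-Pearson oracle on random vectors with ties", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(11:40, 1)
    sid <- sprintf("s%02d", seq_len(n))
    hs <- lapply(1:6, function(i) round(10^runif(n, 0, 3)))
    names(hs) <- sprintf("p%d", 1:6)
    y <- round(rnorm(n, 3400, 300), -1)  # ties in the phenotype too
    res <- spearman_scan(make_scan_table(hs, sid), phenotype(sid, y))
    for (i in 1:6) {
      expect_equal(res$rho[i], spearman_oracle(hs[[i]], y), tolerance = 1e-12)
    }
  }
})

test_that("rho is invariant under strictly monotone transforms", {
  set.seed(99)
  n <- 30
  sid <- sprintf("s%02d", 1:n)
  x <- 10^runif(n, 1, 4)
  y <- rnorm(n, 3400, 400)
  base <- spearman_scan(make_scan_table(list(a = x), sid), phenotype(sid, y))
  tr <- spearman_scan(make_scan_table(list(a = exp(x / 1000)), sid),
                      phenotype(sid, y^3))
  expect_equal(base$rho, tr$rho, tolerance = 1e-12)
})

test_that("exact permutation p-values agree with full enumeration", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(4:7, 1)
    sid <- sprintf("s%d", seq_len(n))
    x <- sample(c(1, 2, 2, 4, 5, 7, 9), n)       # ties possible
    y <- rnorm(n)
    res <- spearman_scan(make_scan_table(list(a = x), sid), phenotype(sid, y))
    if (is.na(res$rho[1])) next
    expect_equal(res$p_value[1], perm_pvalue_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("zero policy, degenerate peaks and input errors behave as specified", {
  sid <- sprintf("s%02d", 1:12)
  y <- seq(3000, 4100, by = 100)
  x <- c(0, 0, 0, 40, 35, 50, 60, 55, 70, 80, 75, 90)
  t <- make_scan_table(list(a = x, flat = rep(5, 12)), sid)
  inc <- spearman_scan(t, phenotype(sid, y), zero_policy = "include")
  exc <- spearman_scan(t, phenotype(sid, y), zero_policy = "exclude")
  expect_equal(inc$n_used[1], 12L)
  expect_equal(exc$n_used[1], 9L)
  expect_equal(exc$rho[1], spearman_oracle(x[x > 0], y[x > 0]),
               tolerance = 1e-12)
  expect_true(is.na(inc$rho[2]))        # zero variance
  expect_true(is.na(exc$rho[2]))
  few <- make_scan_table(list(a = c(5, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0)), sid)
  expect_true(is.na(spearman_scan(few, phenotype(sid, y),
                                  zero_policy = "exclude")$rho[1]))
  expect_error(spearman_scan(t, phenotype(c("zz"), 1)), "overlapping")
  expect_warning(spearman_scan(t, phenotype(sid, rep(3400, 12))), "constant")
})

test_that("BH adjustment follows the step-up with NA passthrough", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.037), 0.037)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  q <- bh_adjust(c(0.01, NA, 0.04))
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], c(0.02, 0.04))  # m = 2, not 3
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  for (seed in 1:20) {
    set.seed(seed)
    m <- sample(1:200, 1)
    p <- round(runif(m)^2, 3)  # ties likely
    expect_identical(bh_adjust(p), bh_bruteforce(p))
  }
})

test_that("significant set applies q <= alpha and orders by ascending p", {
  sid <- sprintf("s%02d", 1:20)
  y <- rnorm(20)
  t <- make_scan_table(list(a = rank(y) + 0.0, b = 10^runif(20, 1, 4),
                            c = 10^runif(20, 1, 4)), sid)
  res <- bh_adjust_result(spearman_scan(t, phenotype(sid, y)), alpha = 0.05)
  expect_true(all(res$significant == (res$q_value <= 0.05), na.rm = TRUE))
  res_all1 <- res
  res_all1$q_value <- rep(1, 3)
  expect_length(significant_set(res_all1), 0L)
  res_mix <- res
  res_mix$p_value <- c(0.002, 0.0001, 0.03)
  res_mix$q_value <- c(0.05, 0.01, 0.06)
  expect_equal(significant_set(res_mix, 0.05), c("b", "a"))
  expect_error(significant_set(spearman_scan(t, phenotype(sid, y))),
               "bh_adjust_result")
})

test_that("insight loss counts rejected significant peaks per mask", {
  t <- random_table(8, np = 10, ns = 6)
  all_mask <- apply_cascade(t, threshold_config())
  sig <- t$peak_ids[1:10]
  expect_equal(insight_loss(sig, all_mask)$loss_fraction, 0)
  # craft a filter rejecting exactly 8 of the 10 significant peaks
  t$fill_fraction <- c(rep(0.1, 8), rep(0.9, 2))
  m <- fill_filter(t, 0.5)
  il <- insight_loss(sig, list(fill = m))
  expect_equal(il$loss_fraction, 0.8)
  expect_equal(il$n_rejected + il$n_retained, il$n_significant)
  expect_equal(insight_loss(character(0), m)$loss_fraction, 0)
  expect_equal(insight_loss(character(0), m)$n_significant, 0L)
  expect_error(insight_loss(c("nope"), m), "unknown")
})

test_that("significant-peak loss is non-decreasing for nested masks", {
  t <- random_table(21, np = 40, ns = 15)
  sig <- t$peak_ids[seq(1, 40, by = 3)]
  losses <- sapply(c(0, 500, 2000, 10000, 50000), function(th2)
    insight_loss(sig, alignment_height_filter(t, th2))$loss_fraction)
  expect_true(all(diff(losses) >= 0))
})

test_that("insight-loss curve counts additional losses within the significant set", {
  t <- aligned_peak_table(sprintf("p%d", 1:4), 1:4, 1:4,
                          matrix(1000, 4, 4), c(1.0, 0.7, 0.4, 0.1),
                          sprintf("s%d", 1:4))
  sig <- c("p1", "p2", "p3")
  cv <- insight_loss_curve(t, sig, th2_list = 0, freq_grid = c(0, 0.5))
  expect_equal(cv$n_significant_retained, c(3, 2))
  expect_equal(cv$additional_loss_count, c(0, 1))
  expect_equal(cv$additional_loss_fraction, c(0, 1 / 3))
})
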