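brute_force_ks <- function(p, q) {
  # independent oracle: explicit scan of all 256 strict-CDF gaps
  best <- 0
  for (g in 0:255) {
    fp <- sum(as.numeric(p)[seq_len(g)])
    fq <- sum(as.numeric(q)[seq_len(g)])
    best <- max(best, abs(fp - fq))
  }
  best
}

test_that("KS statistic matches definition and brute-force oracle", {
  h <- hist_from(c(`0` = 0.5, `1` = 0.5))
  expect_equal(ks_compare(h, h, 10, 10)$statistic, 0)
  expect_equal(ks_compare(h, h, 10, 10)$p_value, 1)

  d <- ks_compare(point_mass(0), point_mass(255), 5, 5)
  expect_equal(d$statistic, 1)

  q <- hist_from(c(`0` = 0.25, `1` = 0.75))
  expect_equal(ks_compare(h, q, 100, 100)$statistic, 0.25)

  set.seed(31)
  for (i in 1:25) {
    p1 <- random_histogram(sample(2:40, 1))
    p2 <- random_histogram(sample(2:40, 1))
    expect_equal(ks_compare(p1, p2, 7, 8)$statistic, brute_force_ks(p1, p2),
                 tolerance = 1e-12)
  }

  expect_error(ks_compare(h, q, 0, 5), "positive")
})

test_that("asymptotic KS p-values agree with stats::ks.test on samples", {
  # the Kolmogorov survival series is cross-checked against the asymptotic
  # two-sample ks.test on continuous samples of several sizes
  set.seed(32)
  for (sizes in list(c(30, 40), c(150, 120), c(500, 500))) {
    x <- runif(sizes[1]); y <- runif(sizes[2], 0.05, 1.05)
    ref <- stats::ks.test(x, y, exact = FALSE)
    n <- prod(sizes) / sum(sizes)
    ours <- escortHist:::ks_asymptotic_pvalue(sqrt(n) * ref$statistic)
    expect_equal(ours, ref$p.value, tolerance = 1e-6)
  }
})

test_that("escort family honors its anchor values and hand arithmetic", {
  set.seed(33)
  for (i in 1:10) {
    h <- random_histogram(sample(3:30, 1))
    expect_identical(escort(h, 1), h)          # beta = 1 is the identity
    u <- escort(h, 0)                          # beta = 0 is uniform
    k <- length(attr(h, "support"))
    expect_equal(as.numeric(u)[attr(h, "support") + 1L], rep(1 / k, k))
  }

  e2 <- escort(hist_from(c(`0` = 0.8, `1` = 0.2)), 2)
  expect_equal(as.numeric(e2)[1:2], c(16 / 17, 1 / 17), tolerance = 1e-12)

  expect_error(escort(hist_from(c(`0` = 1e-300, `5` = 1 - 1e-300)), 1e307),
               "overflow")
})

test_that("escort composition law holds on a fixed support", {
  set.seed(34)
  for (i in 1:20) {
    h <- random_histogram(sample(3:30, 1))
    a <- runif(1, -3, 3); b <- runif(1, -3, 3)
    lhs <- escort(escort(h, a), b)
    rhs <- escort(h, a * b)
    expect_equal(as.numeric(lhs), as.numeric(rhs), tolerance = 1e-9)
  }
})

test_that("Hellinger distance matches closed forms and is a metric", {
  h <- random_histogram(10)
  expect_equal(hellinger(h, h), 0)

  # disjoint supports are maximally distant
  expect_equal(hellinger(point_mass(0), point_mass(255)), 1)

  p <- point_mass(0)
  q <- hist_from(c(`0` = 0.5, `1` = 0.5))
  expect_equal(hellinger(p, q), sqrt(1 - sqrt(2) / 2), tolerance = 1e-12)

  set.seed(35)
  for (i in 1:15) {
    a <- random_histogram(8); b <- random_histogram(8); c <- random_histogram(8)
    expect_equal(hellinger(a, b), hellinger(b, a), tolerance = 1e-12)
    expect_gte(hellinger(a, b) + hellinger(b, c) + 1e-9, hellinger(a, c))
    expect_true(hellinger(a, b) >= 0 && hellinger(a, b) <= 1)
  }

  # literal squared-difference variant, for sensitivity checks
  expect_equal(hellinger(p, q, method = "squared_diff"),
               sqrt(0.5 * (0.25 + 0.25)), tolerance = 1e-12)
})

test_that("Shannon entropy has its closed forms and escort bounds", {
  expect_equal(shannon_entropy(point_mass(7)), 0)
  u <- hist_from(stats::setNames(rep(1 / 16, 16), seq(0, 150, 10)))
  expect_equal(shannon_entropy(u), log(16), tolerance = 1e-12)
  expect_equal(shannon_entropy(hist_from(c(`0` = 0.5, `1` = 0.25,
                                           `2` = 0.25))),
               1.5 * log(2), tolerance = 1e-12)

  # 0 <= S(escort(h, beta)) <= ln|support|, maximum attained at beta = 0
  set.seed(36)
  for (i in 1:10) {
    h <- random_histogram(sample(4:40, 1))
    smax <- log(length(attr(h, "support")))
    for (beta in c(-3, -1, -0.5, 0, 0.5, 1, 2, 5)) {
      s <- shannon_entropy(escort(h, beta))
      expect_gte(s, 0)
      expect_lte(s, smax + 1e-12)
    }
    expect_equal(shannon_entropy(escort(h, 0)), smax, tolerance = 1e-12)
  }
})

test_that("entropy difference vanishes when forced and takes closed forms", {
  h <- random_histogram(12)
  for (beta in c(-2, 0, 1, 3))
    expect_equal(entropy_difference(h, h, beta), 0)

  # equal support sizes at beta = 0: both escorts uniform
  set.seed(37)
  a <- random_histogram(9); b <- random_histogram(9)
  expect_equal(entropy_difference(a, b, 0), 0, tolerance = 1e-12)

  u4 <- hist_from(stats::setNames(rep(0.25, 4), c(10, 20, 30, 40)))
  expect_equal(entropy_difference(u4, point_mass(3), 1), log(4),
               tolerance = 1e-12)
})

test_that("beta scans hit their anchors and stay in range", {
  grid <- beta_grid(-5, 5, 41)
  expect_true(all(c(0, 1) %in% grid))
  expect_true(all(diff(grid) > 0))
  expect_error(beta_grid(2, 1), "below")
  expect_error(beta_scan(random_histogram(5), random_histogram(5),
                         grid = c(0.5, 2)), "anchor")

  set.seed(38)
  cells <- random_histogram(15)
  ctrl <- random_histogram(15)
  scan <- beta_scan(cells, ctrl, grid, staining = "S", channel = "red")
  expect_true(all(scan$hellinger >= 0 & scan$hellinger <= 1))
  expect_identical(attr(scan, "staining"), "S")

  # beta = 1 matches the direct call bit-for-bit
  expect_identical(scan$hellinger[scan$beta == 1], hellinger(cells, ctrl))
  expect_identical(scan$delta_entropy[scan$beta == 1],
                   shannon_entropy(cells) - shannon_entropy(ctrl))

  # equal supports at beta = 0: escorts coincide, H vanishes
  sup <- sample(0:255, 12)
  a <- hist_from(stats::setNames(runif(12, 0.5, 2) |> (\(w) w / sum(w))(), sup))
  b <- hist_from(stats::setNames(runif(12, 0.5, 2) |> (\(w) w / sum(w))(), sup))
  scan_eq <- beta_scan(a, b, grid)
  expect_equal(scan_eq$hellinger[scan_eq$beta == 0], 0)
  expect_equal(scan_eq$delta_entropy[scan_eq$beta == 0], 0)

  # identical inputs: flat zero curves everywhere
  scan_id <- beta_scan(cells, cells, grid)
  expect_true(all(scan_id$hellinger == 0))
  expect_true(all(scan_id$delta_entropy == 0))
})

test_that("profile classification separates the three qualitative shapes", {
  g4 <- c(-1, 0, 1, 2)
  expect_equal(classify_profile(c(0, 0.1, 0.2, 0.3), g4)$class,
               "monotonic_growth")
  expect_equal(classify_profile(rep(0.2, 4), g4)$class, "flat")
  bump <- classify_profile(c(0, 0.3, 0.1), c(-1, 0, 1))
  expect_equal(bump$class, "non_monotonic")
  expect_equal(bump$argmax_beta, 0)

  # all-zero curve counts as flat, not monotonic
  expect_equal(classify_profile(rep(0, 5), 1:5)$class, "flat")
  expect_error(classify_profile(c(0, 1), c(0, 1)), "at least 3")
})
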