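test_that("Cliff's delta matches brute-force dominance and is antisymmetric", {
  expect_equal(cliffs_delta(c(1, 2, 3), c(4, 5, 6))$delta, -1)
  expect_equal(cliffs_delta(c(1, 3), c(2, 4))$delta, -0.5)
  x <- c(3, 1, 4, 1, 5)
  expect_equal(cliffs_delta(x, x)$delta, 0)
  set.seed(101)
  for (i in 1:200) {
    nx <- sample(2:12, 1); ny <- sample(2:12, 1)
    x <- sample(1:8, nx, replace = TRUE)     # ties likely
    y <- sample(1:8, ny, replace = TRUE)
    d <- cliffs_delta(x, y)
    expect_identical(d$delta, oracle_cliff(x, y))
    expect_identical(d$delta, -cliffs_delta(y, x)$delta)
    expect_true(d$ci_low >= -1 && d$ci_high <= 1)
    expect_true(d$ci_low <= d$delta && d$delta <= d$ci_high)
  }
})

test_that("Cliff's delta equals the rescaled Mann-Whitney U with half-ties", {
  set.seed(55)
  for (i in 1:50) {
    x <- sample(1:10, sample(3:15, 1), replace = TRUE)
    y <- sample(1:10, sample(3:15, 1), replace = TRUE)
    u <- unname(suppressWarnings(wilcox.test(x, y)$statistic))  # counts x > y, ties as 1/2
    expect_equal(cliffs_delta(x, y)$delta,
                 2 * u / (length(x) * length(y)) - 1, tolerance = 1e-12)
  }
})

test_that("Spearman correlation matches Pearson-on-ranks with a t-based p", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(spearman_corr(x, x^3)$rho, 1)
  expect_equal(spearman_corr(x, rev(x))$rho, -1)
  set.seed(7)
  a <- rnorm(6); b <- rnorm(6)
  s <- spearman_corr(a, b)
  expect_equal(s$rho, cor(rank(a), rank(b)), tolerance = 1e-12)
  tval <- s$rho * sqrt(4 / (1 - s$rho^2))
  expect_equal(s$p, 2 * pt(-abs(tval), 4), tolerance = 1e-12)
  expect_error(spearman_corr(rep(1, 5), 1:5), "constant")
  expect_error(spearman_corr(1:2, 1:2), "at least 3")
})

test_that("Zou's interval behaves like the Fisher z-test and tightens with n", {
  same <- zou_diff(0.4, 50, 0.4, 50)
  expect_equal(same$delta_r, 0)
  expect_equal(same$ci_low, -same$ci_high, tolerance = 1e-12)
  # CI excludes 0 iff the two-sample Fisher z-test rejects at alpha = .05
  for (r2 in c(0.1, 0.2, 0.3, 0.45)) {
    zi <- zou_diff(0.6, 50, r2, 50)
    z <- (atanh(0.6) - atanh(r2)) / sqrt(1 / 47 + 1 / 47)
    rejects <- abs(z) > qnorm(0.975)
    excludes <- zi$ci_low > 0 || zi$ci_high < 0
    expect_identical(excludes, rejects)
  }
  w <- function(n) { z <- zou_diff(0.5, n, 0.2, n); z$ci_high - z$ci_low }
  widths <- vapply(c(10, 30, 100, 300), w, numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_error(zou_diff(1, 10, 0.5, 10), "strictly inside")
})

test_that("the 2x2 chi-square equals its closed form, uncorrected", {
  even <- chisq_2x2(matrix(10, 2, 2))
  expect_equal(even$chi2, 0)
  expect_equal(even$p, 1)
  tab <- matrix(c(20, 10, 10, 20), 2, byrow = TRUE)
  hand <- 60 * (20 * 20 - 10 * 10)^2 / (30 * 30 * 30 * 30)
  got <- chisq_2x2(tab)
  expect_equal(got$chi2, hand, tolerance = 1e-12)
  expect_equal(chisq_2x2(2 * tab)$chi2, 2 * hand, tolerance = 1e-12)
  # equals the square of the uncorrected two-proportion z statistic
  p1 <- 20 / 30; p2 <- 10 / 30; pp <- 30 / 60
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / 30 + 1 / 30))
  expect_equal(got$chi2, z^2, tolerance = 1e-12)
  expect_error(chisq_2x2(matrix(c(0, 0, 1, 2), 2)), "margin")
})

test_that("ICC(3,k) recovers perfect agreement, noise, and a hand-worked ANOVA", {
  m <- matrix(rnorm(20), 5, 4)
  expect_equal(icc_consistency(cbind(m[, 1], m[, 1], m[, 1]))$icc, 1)
  set.seed(12)
  noise <- matrix(rnorm(2000), 500, 4)
  expect_lt(abs(icc_consistency(noise)$icc), 0.1)
  # 4 x 3 toy matrix against an aov()-based decomposition
  toy <- matrix(c(9, 2, 5, 8,
                  6, 1, 3, 2,
                  8, 4, 6, 7), 4, 3)
  df <- data.frame(y = as.vector(toy),
                   target = factor(rep(1:4, 3)), rater = factor(rep(1:3, each = 4)))
  ms <- summary(aov(y ~ target + rater, df))[[1]][, "Mean Sq"]
  icc_hand <- (ms[1] - ms[3]) / ms[1]
  expect_equal(icc_consistency(toy)$icc, icc_hand, tolerance = 1e-12)
  r <- icc_consistency(toy)
  expect_true(r$ci_low <= r$icc && r$icc <= r$ci_high)
  expect_error(icc_consistency(toy[1, , drop = FALSE]), "at least 2")
})

test_that("higher within-observer consistency raises the block-threshold ICC", {
  # between-observer spread held in alpha so the slope only sharpens blocks
  iccs <- vapply(c(1.0, 3.0), function(beta) {
    set.seed(40)
    co <- tibble::tibble(
      id = sprintf("i%03d", 1:120),
      alpha = pmin(pmax(10^rnorm(120, log10(0.02), 0.2), 0.008), 2),
      beta = beta, lam = 1.5, lapse = 0,
      counterbalance = rep(c("ascending_first", "descending_first"), 60))
    tr <- simulate_sessions(co, seed = 41)
    blocks <- block_summaries(tr)
    wide <- tidyr::pivot_wider(blocks[, c("id", "block", "threshold_g")],
                               names_from = "block", values_from = "threshold_g")
    icc_consistency(log10(as.matrix(wide[, -1])))$icc
  }, numeric(1))
  expect_true(all(iccs > 0))
  expect_gt(iccs[2], iccs[1])
})

test_that("group comparison tables carry the table sign convention", {
  set.seed(3)
  d <- tibble::tibble(
    diagnosis = rep(c("NT", "ASD"), each = 40),
    threshold_g = c(rnorm(40, 1), rnorm(40, 2)),   # ASD higher
    fsiq = c(rnorm(40, 110, 5), rnorm(40, 100, 5)))  # NT higher
  tab <- compare_groups(d, c("threshold_g", "fsiq"), ref = "NT")
  expect_lt(tab$delta[tab$variable == "threshold_g"], 0)
  expect_gt(tab$delta[tab$variable == "fsiq"], 0)
  expect_error(compare_groups(d, "fsiq", ref = "missing"), "not found")
})
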