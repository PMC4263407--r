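test_that("region mean is the unweighted per-CpG average", {
  expect_equal(region_mean_level(c(2, 4), c(4, 4)), 75.0)
  expect_equal(region_mean_level(0, 7), 0.0)
  expect_true(is.na(region_mean_level(integer(0), integer(0))))
  # zero-coverage CpGs are ignored, not averaged in
  expect_equal(region_mean_level(c(2, 0), c(4, 0)), 50.0)
  # weighted variant pools reads
  expect_equal(region_mean_level(c(1, 9), c(10, 10), weighted = TRUE), 50.0)
  expect_equal(region_mean_level(c(1, 9), c(10, 10)), 50.0)
  expect_equal(region_mean_level(c(1, 9), c(2, 18), weighted = TRUE), 50.0)
  expect_equal(region_mean_level(c(1, 9), c(2, 18)), 50.0)

  set.seed(31)
  m <- rbinom(1000, 20, 0.6)
  expect_equal(region_mean_level(m, rep(20, 1000)), 60, tolerance = 1.5 / 60)
})

test_that("t-test handles identical, degenerate and undersized inputs", {
  x <- c(10, 20, 30, 40)
  expect_equal(student_t_test(x, x)$p_value, 1.0)
  expect_equal(student_t_test(x, x, mode = "paired")$statistic, 0)
  expect_equal(student_t_test(x, x, mode = "paired")$p_value, 1.0)

  r <- student_t_test(c(0, 0, 0, 0), c(100, 100, 100, 100))
  expect_lt(r$p_value, 1e-6)
  expect_equal(r$flag, "zero_variance")

  expect_null(student_t_test(5, c(1, 2, 3)))
  expect_null(student_t_test(5, 7, mode = "paired"))   # a single pair
  expect_error(student_t_test(c(1, 2), 7, mode = "paired"), "equal-length")

  # p symmetric in argument order
  set.seed(8)
  a <- rnorm(12, 50, 10); b <- rnorm(15, 60, 10)
  expect_equal(student_t_test(a, b)$p_value, student_t_test(b, a)$p_value)
})

test_that("t-test type-I error is calibrated at the nominal level", {
  set.seed(44)
  n_rep <- 10000
  A <- matrix(rnorm(10 * n_rep), nrow = 10)
  B <- matrix(rnorm(10 * n_rep), nrow = 10)
  p <- vapply(seq_len(n_rep), function(i)
    student_t_test(A[, i], B[, i])$p_value, 0)
  expect_equal(mean(p < 0.05), 0.05, tolerance = 0.01 / 0.05)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  # independent step-up oracle written from the definition:
  # q_(i) = min_{j >= i} min(1, m/j * p_(j)) in sorted order
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q_sorted <- rev(cummin(rev(pmin(1, p[o] * m / seq_len(m)))))
    q <- numeric(m); q[o] <- q_sorted
    q
  }
  set.seed(12)
  for (i in 1:5) {
    p <- runif(50)^2
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    expect_true(all(q <= 1))
    # monotone non-decreasing after sorting by p
    expect_true(all(diff(q[order(p)]) >= -1e-12))
    # thresholding q at alpha reproduces the step-up rejection set
    for (alpha in c(0.01, 0.05, 0.2)) {
      ps <- sort(p)
      k <- which(ps <= alpha * seq_along(ps) / length(ps))
      n_reject <- if (length(k) == 0) 0L else max(k)
      expect_equal(sum(q <= alpha), n_reject)
    }
  }
})

test_that("chi-square matches a parametric simulation oracle and its symmetries", {
  expect_equal(chi_square_2x2(10, 10, 20, 20)$statistic, 0)
  expect_equal(chi_square_2x2(10, 10, 20, 20)$p_value, 1)

  # invariant under row and column swaps
  base <- chi_square_2x2(12, 30, 7, 41)
  expect_equal(chi_square_2x2(7, 41, 12, 30)$statistic, base$statistic)
  expect_equal(chi_square_2x2(30, 12, 41, 7)$statistic, base$statistic)

  expect_error(chi_square_2x2(0, 0, 5, 5), "marginal")
  expect_lt(chi_square_2x2(5, 15, 15, 5, correction = "yates")$statistic,
            chi_square_2x2(5, 15, 15, 5)$statistic)

  # oracle: binomial sampling under the pooled null proportion
  obs <- chi_square_2x2(520, 480, 480, 520)
  stat2 <- function(a, c, n1, n2) {
    m <- matrix(c(a, n1 - a, c, n2 - c), 2, byrow = TRUE)
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    sum((m - e)^2 / e)
  }
  set.seed(3)
  a <- rbinom(40000, 1000, 0.5); c <- rbinom(40000, 1000, 0.5)
  p_sim <- mean(mapply(stat2, a, c, 1000, 1000) >= obs$statistic - 1e-9)
  expect_equal(obs$p_value, p_sim, tolerance = 0.01 / obs$p_value)
})

test_that("Mann-Whitney exact path matches full enumeration", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)

  expect_equal(mann_whitney_u(c(3, 1, 2), c(2, 3, 1))$p_value, 1.0)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")

  set.seed(17)
  for (i in 1:20) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    x <- rnorm(n1); y <- rnorm(n2, sample(c(0, 1.5), 1))
    expect_equal(mann_whitney_u(x, y)$p_value, mw_enumeration_p(x, y),
                 info = sprintf("case %d (n1=%d, n2=%d)", i, n1, n2))
  }
})

test_that("Mann-Whitney has power against a one-SD shift", {
  set.seed(23)
  rej <- vapply(1:1000, function(i)
    mann_whitney_u(rnorm(50), rnorm(50, 1))$p_value < 0.05, NA)
  expect_gt(mean(rej), 0.9)
})

test_that("Pearson correlation matches the covariance formula", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_r(x, 2 * x + 1), 1.0)
  expect_equal(pearson_r(x, -x), -1.0)
  expect_true(is.na(pearson_r(x, rep(2, 5))))
  expect_error(pearson_r(1:2, 1:2), "3 complete pairs")

  set.seed(2)
  a <- rnorm(30); b <- rnorm(30)
  direct <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_r(a, b), direct, tolerance = 1e-12)

  # listwise deletion of incomplete pairs
  a2 <- c(a, NA); b2 <- c(b, 5)
  expect_equal(pearson_r(a2, b2), pearson_r(a, b))
})

test_that("passive dilution model reproduces the 25% bound and halving law", {
  expect_identical(passive_demethylation_expectation(1, 0, 1), 25)
  for (m in c(0, 0.3, 1))
    expect_equal(passive_demethylation_expectation(m, m, 0), 100 * m)

  # non-increasing in rounds; halving on the maternal term
  for (mm in c(0.2, 0.8)) for (mp in c(0, 0.5)) {
    vals <- vapply(0:5, function(k)
      passive_demethylation_expectation(mm, mp, k), 0)
    expect_true(all(diff(vals) <= 1e-12))
    mat_part <- vals - 100 * mp / 2
    expect_equal(mat_part[-1], mat_part[-6] / 2)
  }
  # co-dilution halves both alleles
  expect_equal(passive_demethylation_expectation(1, 1, 1,
                                                 codilute_paternal = TRUE), 50)
  expect_error(passive_demethylation_expectation(1.2, 0, 1))
})
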