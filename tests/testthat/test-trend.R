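test_that("trend z matches hand evaluation and the base-R trend test", {
  z <- cochran_armitage(10, 20, 10, 30, 40, 10)
  expect_equal(z, 800 / sqrt(56000), tolerance = 1e-12)
  # independent oracle: chi-square trend test on the same 2x3 table
  ct <- suppressWarnings(stats::prop.trend.test(c(10, 20, 10),
                                                c(30, 40, 10), score = 0:2))
  expect_equal(z^2, unname(ct$statistic), tolerance = 1e-10)

  # proportional table: null, z = 0
  expect_equal(cochran_armitage(15, 20, 5, 30, 40, 10), 0)
})

test_that("trend test validates its table", {
  expect_error(cochran_armitage(5, 0, 0, 10, 0, 0),
               class = "npbat_error_monomorphic")
  expect_error(cochran_armitage(5, 0, 0, 4, 0, 0),
               class = "npbat_error_input")
  expect_error(cochran_armitage(3, 0, 0, 3, 0, 0),
               class = "npbat_error_degenerate")
})

test_that("binary-coded score test equals the trend test times the closed-form ratio", {
  set.seed(13)
  for (i in 1:200) {
    tb <- random_trend_table()
    mu_y <- runif(1, 0.1, 0.9)
    z_trend <- cochran_armitage(tb$r[1], tb$r[2], tb$r[3],
                                tb$n[1], tb$n[2], tb$n[3])
    y <- as.numeric(tb$status == "case")
    g <- coded_genotypes(tb$x)
    res <- npbat_statistic(g, y - mu_y, ex = mean(tb$x))
    ratio <- statistic_ratio(tb$N, tb$gamma, mu_y)
    expect_equal(z_trend, res$z_raw * ratio,
                 tolerance = 1e-10 * max(1, abs(z_trend)))
  }
})

test_that("at the efficient offset the two tests are numerically indistinguishable", {
  set.seed(99)
  N <- 1000
  x <- rbinom(N, 2, 0.3)
  status <- sample(rep(c("case", "control"), c(500, 500)))
  n_k <- tabulate(factor(x, levels = 0:2), 3)
  r_k <- tabulate(factor(x[status == "case"], levels = 0:2), 3)
  z_trend <- cochran_armitage(r_k[1], r_k[2], r_k[3],
                              n_k[1], n_k[2], n_k[3])
  tc <- code_binary_trait(sample_table(status))
  res <- npbat_statistic(coded_genotypes(x), tc, ex = mean(x))
  expect_equal(statistic_ratio(1000, 1, 0.5), sqrt(1000 / 999),
               tolerance = 1e-12)
  expect_equal(z_trend, res$z_raw * sqrt(1000 / 999),
               tolerance = 1e-10 * max(1, abs(z_trend)))
  expect_lt(abs(res$p_value - 2 * pnorm(-abs(z_trend))), 1e-4)
})

test_that("the ratio is minimised at the case-fraction offset", {
  for (gamma in c(1 / 3, 1, 2.5)) {
    mu_opt <- gamma / (1 + gamma)
    expect_equal(statistic_ratio(200, gamma, mu_opt), sqrt(200 / 199),
                 tolerance = 1e-12)
    grid <- seq(0.05, 0.95, by = 0.05)
    vals <- vapply(grid, statistic_ratio, 0, N = 200, gamma = gamma)
    expect_true(all(vals >= sqrt(200 / 199) - 1e-12))
  }
  expect_equal(optimal_binary_offset(500, 500), 0.5)
  expect_equal(optimal_binary_offset(250, 750), 0.25)
  expect_equal(optimal_binary_offset(1, 3), 0.25)
  expect_error(optimal_binary_offset(0, 10),
               class = "npbat_error_degenerate")
})
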