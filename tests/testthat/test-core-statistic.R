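test_that("the score statistic matches hand evaluation", {
  g <- coded_genotypes(c(0, 2, 0, 2))
  res <- npbat_statistic(g, c(-1, 1, -1, 1), ex = 1)
  expect_equal(res$S, 4)
  expect_equal(res$sum_T2, 4)
  expect_equal(res$sigma2_x, 4 / 3)
  expect_equal(res$z_raw, sqrt(3), tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pnorm(-sqrt(3)), tolerance = 1e-12)

  # symmetric cancellation
  res0 <- npbat_statistic(coded_genotypes(c(0, 1, 2, 1)),
                          c(1, -1, 1, -1), ex = 1)
  expect_equal(res0$S, 0)
  expect_equal(res0$z_raw, 0)
})

test_that("degenerate inputs are rejected with typed errors", {
  expect_error(npbat_statistic(coded_genotypes(c(1, 1, 1)), c(1, 0, -1),
                               ex = 1),
               class = "npbat_error_monomorphic")
  expect_error(npbat_statistic(coded_genotypes(c(0, 1, 2)), c(0, 0, 0),
                               ex = 1),
               class = "npbat_error_degenerate")
  expect_error(npbat_statistic(coded_genotypes(c(0, NA)), c(1, 1), ex = 0.5),
               class = "npbat_error_degenerate")
})

test_that("individuals missing genotype or trait drop from all sums", {
  g <- coded_genotypes(c(0, 2, 0, 2, NA, 1))
  t_full <- c(-1, 1, -1, 1, 3, NA)
  res <- npbat_statistic(g, t_full, ex = 1)
  ref <- npbat_statistic(coded_genotypes(c(0, 2, 0, 2)), c(-1, 1, -1, 1),
                         ex = 1)
  expect_equal(res$z_raw, ref$z_raw)
  expect_identical(res$n_used, 4L)
})

test_that("all-subjects scaling restores the centered-trait norm", {
  s <- sample_table(c(2, 1), phenotype = c(1, 3))
  tc <- code_continuous_trait(s, 0)
  g <- coded_genotypes(c(0, 2))
  res <- npbat_all_subjects_pvalue(npbat_statistic(g, tc, ex = 1))
  expect_equal(res$sum_T2, 10)
  expect_equal(res$norm_Tmu2, 2)
  expect_equal(res$scale, sqrt(5), tolerance = 1e-12)
  expect_equal(res$z_scaled, sqrt(5) * res$z_raw, tolerance = 1e-12)

  # offset at the sample mean: scale is exactly one
  tc_mu <- code_continuous_trait(s, mean(s$phenotype))
  res_mu <- npbat_all_subjects_pvalue(npbat_statistic(g, tc_mu, ex = 1))
  expect_equal(res_mu$scale, 1, tolerance = 1e-12)

  # large-offset behaviour: ||T|| ~ sqrt(n)|offset|, so scale/|offset|
  # approaches sqrt(n)/||T_mu||
  set.seed(4)
  y <- rnorm(30)
  s_big <- sample_table(rep(2, 30), phenotype = y)
  g_big <- coded_genotypes(rbinom(30, 2, 0.4))
  off <- 1e6
  res_big <- npbat_all_subjects_pvalue(
    npbat_statistic(g_big, code_continuous_trait(s_big, off), ex = 0.8)
  )
  expect_equal(res_big$scale / off,
               sqrt(30 / sum((y - mean(y))^2)), tolerance = 1e-4)
})

test_that("secondary-mode scaling accounts for control-estimated E_x", {
  g <- coded_genotypes(c(0, 2))
  y <- c(0, 2)

  # offset at the case mean: correction vanishes, statistic is raw
  res_mu <- npbat_secondary_pvalue(g, y - mean(y), ex = 0.5, n_ex_group = 2)
  expect_equal(res_mu$scale, 1, tolerance = 1e-12)
  expect_equal(res_mu$z_scaled, res_mu$z_raw)

  # offset 0 with m = 2 controls: factor ||T||^2 + (sum T)^2/m = 4 + 2 = 6
  res0 <- npbat_secondary_pvalue(g, y - 0, ex = 0.5, n_ex_group = 2)
  expect_equal(res0$scale, sqrt(4 / 6), tolerance = 1e-12)

  # known E_x: no correction at any offset
  res_inf <- npbat_secondary_pvalue(g, y - 0, ex = 0.5, n_ex_group = Inf)
  expect_equal(res_inf$scale, 1)

  # group size picked up from resolve_ex()
  s <- sample_table(c("case", "case", "control", "control", "control"))
  g5 <- coded_genotypes(c(0, 2, 1, 0, 2))
  ex <- resolve_ex(g5, s, source = "controls")
  res_ex <- npbat_secondary_pvalue(coded_genotypes(c(0, 2)), y - 0, ex)
  expect_equal(res_ex$scale, sqrt(4 / (4 + 4 / 3)), tolerance = 1e-12)

  # explicit sigma_x overrides the case-sample estimate
  res_sig <- npbat_secondary_pvalue(g, y - 0, ex = 0.5, sigma_x = 1,
                                    n_ex_group = Inf)
  expect_equal(res_sig$z_scaled, res0$S / sqrt(4), tolerance = 1e-12)
})

test_that("secondary-mode variance factor equals its norm decomposition", {
  # ||T||^2 + (sum T)^2/m  ==  ||T_mu||^2 + n(1 + n/m)(Ybar - offset)^2
  set.seed(11)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    m <- sample(3:50, 1)
    y <- rnorm(n, sd = runif(1, 0.5, 2))
    off <- runif(1, -5, 5)
    tvals <- y - off
    lhs <- sum(tvals^2) + sum(tvals)^2 / m
    rhs <- sum((y - mean(y))^2) + n * (1 + n / m) * (mean(y) - off)^2
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("statistics are location-equivariant and sign-equivariant", {
  set.seed(8)
  for (i in 1:10) {
    n <- 25
    g <- coded_genotypes(rbinom(n, 2, 0.3))
    y <- rnorm(n)
    off <- runif(1, -3, 3)
    shift <- runif(1, -10, 10)
    a <- npbat_secondary_pvalue(g, y - off, ex = 0.6, n_ex_group = 40)
    b <- npbat_secondary_pvalue(g, (y + shift) - (off + shift), ex = 0.6,
                                n_ex_group = 40)
    expect_equal(a$z_scaled, b$z_scaled, tolerance = 1e-10)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-10)

    neg <- npbat_statistic(g, -(y - off), ex = 0.6)
    pos <- npbat_statistic(g, y - off, ex = 0.6)
    expect_equal(neg$z_raw, -pos$z_raw, tolerance = 1e-12)
    expect_equal(neg$p_value, pos$p_value, tolerance = 1e-12)
  }
})

test_that("S averages to zero over exhaustive trait permutations", {
  set.seed(21)
  for (n in c(4, 6, 7)) {
    x <- rbinom(n, 2, 0.4)
    if (var(x) == 0) x[1] <- x[1] + 1
    tvals <- rnorm(n)
    ex <- mean(x)
    perms <- all_perms(n)
    s_perm <- vapply(perms, function(p) sum((x - ex) * tvals[p]), 0)
    expect_equal(mean(s_perm), 0, tolerance = 1e-12 * sd(s_perm))
  }
})

test_that("tidy and glance return one-row summaries", {
  g <- coded_genotypes(c(0, 2, 1, 1), marker_id = "rs9")
  res <- npbat_statistic(g, c(-1, 1, 0.5, -0.5), ex = 1)
  td <- tidy(res)
  expect_identical(nrow(td), 1L)
  expect_identical(td$marker_id, "rs9")
  expect_equal(td$z_raw, res$z_raw)
  expect_named(glance(res), c("n_used", "statistic", "p_value", "mode"))
})
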