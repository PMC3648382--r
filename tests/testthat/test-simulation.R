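test_that("heritability maps to the per-allele effect", {
  expect_equal(effect_size_from_heritability(0, 0.2), 0)
  expect_equal(effect_size_from_heritability(0.01, 0.2), 0.1776673,
               tolerance = 1e-6)
  expect_equal(effect_size_from_heritability(0.05, 0.2), 0.4055536,
               tolerance = 1e-6)
  hs <- seq(0, 0.9, by = 0.1)
  a <- vapply(hs, effect_size_from_heritability, 0, p = 0.2)
  expect_true(all(diff(a) > 0))
  expect_error(effect_size_from_heritability(1, 0.2),
               class = "npbat_error_input")
  expect_error(effect_size_from_heritability(0.1, 0),
               class = "npbat_error_input")
})

test_that("genotype simulation has binomial moments and is seeded", {
  g <- simulate_genotypes(1e5, 0.2, seed = 10)
  expect_true(all(g %in% 0:2))
  expect_lt(abs(mean(g) - 0.4), 3 * sqrt(2 * 0.2 * 0.8 / 1e5))
  expect_identical(as.numeric(simulate_genotypes(50, 0.2, seed = 3)),
                   as.numeric(simulate_genotypes(50, 0.2, seed = 3)))
})

test_that("the truncated phenotype matches half-normal moments under the null", {
  g <- simulate_genotypes(1e5, 0.2, seed = 1)
  y <- simulate_secondary_phenotype(g, a = 0, sigma = 1,
                                    truncation_fraction = 0.5, seed = 2)
  expect_true(all(y >= 0))
  half_normal_mean <- sqrt(2 / pi)
  half_normal_sd <- sqrt(1 - 2 / pi)
  expect_lt(abs(mean(y) - half_normal_mean),
            3 * half_normal_sd / sqrt(1e5))

  # no truncation: plain normal around a * X
  y_full <- simulate_secondary_phenotype(g, a = 0.4,
                                         truncation_fraction = 1, seed = 4)
  expect_lt(abs(mean(y_full) - 0.4 * mean(g)), 3 / sqrt(1e5))

  # under the null the two cutoff conventions coincide draw-for-draw
  y_pi <- simulate_secondary_phenotype(g, 0, cutoff = "per_individual",
                                       seed = 5)
  y_fx <- simulate_secondary_phenotype(g, 0, cutoff = "fixed", seed = 5)
  expect_identical(y_pi, y_fx)

  expect_error(simulate_secondary_phenotype(g, 0, truncation_fraction = 0),
               class = "npbat_error_input")
  expect_error(simulate_secondary_phenotype(g, 0, truncation_fraction = 1.2),
               class = "npbat_error_input")
})

test_that("joint ascertainment enriches the risk allele, null stays neutral", {
  asc0 <- simulate_ascertained_cases(2e4, 0.2, a = 0, seed = 6)
  expect_lt(abs(mean(asc0$genotype) - 0.4), 3 * sqrt(0.32 / 2e4))
  expect_true(all(asc0$phenotype >= 0))

  asc <- simulate_ascertained_cases(2e4, 0.2, a = 0.4, seed = 7)
  # closed-form reweighting: P(x) ~ dbinom(x, 2, p) * P(Y >= 0 | x)
  w <- dbinom(0:2, 2, 0.2) * pnorm(0, mean = 0.4 * (0:2), lower.tail = FALSE)
  mu_x <- sum((0:2) * w) / sum(w)
  expect_lt(abs(mean(asc$genotype) - mu_x), 3 * sqrt(0.32 / 2e4))
  expect_gt(mu_x, 0.4)
})

test_that("the study kernel agrees with the single-marker test functions", {
  cfg <- simulation_config(n_cases = 40, n_controls = 30,
                           heritability = 0.05, offset_grid = c(-2, 0, 3),
                           n_replicates = 5, seed = 9)
  d <- npbat:::sim_replicate(cfg, 0.05, seed = 1234)
  for (off in cfg$offset_grid) {
    z <- npbat:::variant_z(d$x, d$y, d$xk, off, "npbat_Ex_controls")
    ref <- npbat_secondary_pvalue(coded_genotypes(d$x), d$y - off,
                                  ex = mean(d$xk), n_ex_group = 30)
    expect_equal(z, ref$z_scaled, tolerance = 1e-12)

    z_cases <- npbat:::variant_z(d$x, d$y, d$xk, off, "npbat_Ex_cases")
    ref_cases <- npbat_all_subjects_pvalue(
      npbat_statistic(coded_genotypes(d$x), d$y - off, ex = mean(d$x))
    )
    expect_equal(z_cases, ref_cases$z_scaled, tolerance = 1e-12)
  }
})

test_that("run_study is deterministic and reports binomial standard errors", {
  cfg <- simulation_config(n_cases = 50, n_controls = 50,
                           heritability = c(0, 0.05),
                           offset_grid = c(-3, 0, 3), n_replicates = 40,
                           methods = c("npbat_Ex_controls", "regression",
                                       "trend_test"),
                           seed = 17)
  a <- run_study(cfg)
  b <- run_study(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(a$mc_se,
               sqrt(a$rejection_rate * (1 - a$rejection_rate) / 40))
  expect_setequal(unique(a$method),
                  c("npbat_Ex_controls", "regression", "trend_test"))
  # offset-free methods carry NA offsets
  expect_true(all(is.na(a$offset[a$method %in% c("regression",
                                                 "trend_test")])))
  expect_true(all(a$rejection_rate >= 0 & a$rejection_rate <= 1))
})

test_that("power increases with heritability at the recommended settings", {
  cfg <- simulation_config(n_cases = 150, n_controls = 150,
                           heritability = c(0, 0.05, 0.2),
                           offset_grid = 0, n_replicates = 150,
                           methods = c("npbat_Ex_controls",
                                       "npbat_Ex_cases"),
                           seed = 23)
  tab <- run_study(cfg)
  for (m in unique(tab$method)) {
    sub <- tab[tab$method == m, ]
    sub <- sub[order(sub$h), ]
    margin <- 2 * sqrt(pmax(sub$mc_se[-1]^2 + sub$mc_se[-nrow(sub)]^2, 1e-8))
    expect_true(all(diff(sub$rejection_rate) >= -margin))
  }
})

test_that("config validation and printing work", {
  expect_error(simulation_config(heritability = 1),
               "heritability")
  cfg <- simulation_config(n_replicates = 10)
  expect_identical(cfg$n_replicates, 10L)
  expect_identical(simulation_config()$n_replicates, 1000L)
  expect_identical(simulation_config(heritability = 0.05)$n_replicates,
                   500L)
  expect_output(print(cfg), "cases / ")
})
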