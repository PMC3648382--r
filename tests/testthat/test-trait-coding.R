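test_that("binary coding uses the case-fraction offset and sums to zero", {
  tc <- code_binary_trait(sample_table(c("case", "case", "control",
                                         "control")))
  expect_equal(tc$values, c(0.5, 0.5, -0.5, -0.5))
  expect_equal(tc$offset, 0.5)
  expect_identical(tc$scheme, "binary_offset")

  tc2 <- code_binary_trait(sample_table(c(2, 1, 1, 1)))
  expect_equal(tc2$values, c(0.75, -0.25, -0.25, -0.25))
  expect_equal(sum(tc2$values), 0)

  # unknown-status individuals drop out but the sum over the rest stays zero
  tc3 <- code_binary_trait(sample_table(c("case", "unknown", "control",
                                          "control")))
  expect_true(is.na(tc3$values[2]))
  expect_equal(sum(tc3$values, na.rm = TRUE), 0)
  expect_identical(tc3$n_used, 3L)
})

test_that("binary coding rejects designs without both groups", {
  expect_error(code_binary_trait(sample_table(rep("case", 4))),
               class = "npbat_error_degenerate")
  expect_error(code_binary_trait(sample_table(rep("control", 3))),
               class = "npbat_error_degenerate")
})

test_that("continuous coding subtracts the offset and tracks missingness", {
  s <- sample_table(c(2, 1), phenotype = c(3, 5))
  expect_equal(code_continuous_trait(s, 4)$values, c(-1, 1))
  expect_equal(sum(code_continuous_trait(s, mean(s$phenotype))$values), 0)

  s2 <- sample_table(c(2, 1, 1), phenotype = c(3, NA, 5))
  tc <- code_continuous_trait(s2, 0)
  expect_equal(tc$n_used, 2L)
  expect_true(is.na(tc$values[2]))

  s3 <- sample_table(c(2, 1), phenotype = c(NA, NA))
  expect_error(code_continuous_trait(s3, 0),
               class = "npbat_error_degenerate")
})

test_that("residual coding reproduces ordinary least squares", {
  # intercept only: mean centering
  s <- sample_table(rep(2, 4), phenotype = c(1, 2, 3, 6))
  expect_equal(code_residual_trait(s)$values, c(1, 2, 3, 6) - 3)

  # phenotype exactly linear in the covariate: all residuals zero
  s2 <- sample_table(rep(2, 4), phenotype = 2 * (1:4) + 1,
                     covariates = data.frame(z = 1:4))
  expect_equal(code_residual_trait(s2, "z")$values, rep(0, 4))

  # n = 5 line fit, frozen from an independent normal-equations solve
  s3 <- sample_table(rep(2, 5), phenotype = c(1, 2, 3, 5, 4),
                     covariates = data.frame(z = 1:5))
  expect_equal(code_residual_trait(s3, "z")$values,
               c(-0.2, -0.1, 0.0, 1.1, -0.8), tolerance = 1e-12)
  expect_equal(sum(code_residual_trait(s3, "z")$values), 0,
               tolerance = 1e-12)
})

test_that("residual coding rejects deficient designs", {
  s <- sample_table(rep(2, 4), phenotype = rnorm(4),
                    covariates = data.frame(z = 1:4, z2 = 2 * (1:4)))
  expect_error(code_residual_trait(s, c("z", "z2")),
               class = "npbat_error_degenerate")
  s2 <- sample_table(rep(2, 2), phenotype = c(1, 2),
                     covariates = data.frame(z = 1:2, w = c(2, 1)))
  expect_error(code_residual_trait(s2, c("z", "w")),
               class = "npbat_error_degenerate")
})

test_that("missing phenotype or covariates yield NA coded values", {
  s <- sample_table(rep(2, 5), phenotype = c(1, 2, NA, 5, 4),
                    covariates = data.frame(z = c(1, 2, 3, NA, 5)))
  tc <- code_residual_trait(s, "z")
  expect_true(all(is.na(tc$values[3:4])))
  expect_identical(tc$n_used, 3L)
})
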