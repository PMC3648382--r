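# Complete-case sums shared by every variant of the test.  An individual
# missing either the genotype or the coded trait drops out of all sums for
# that marker; `n` below is the complete-case count.
npbat_sums <- function(x, tvals, ex) {
  if (length(x) != length(tvals)) {
    abort("`genotypes` and `trait` must have the same length.",
          class = "npbat_error_input")
  }
  ok <- !is.na(x) & !is.na(tvals)
  n <- sum(ok)
  if (n < 2L) {
    abort("need at least two individuals with both genotype and coded trait.",
          class = "npbat_error_degenerate")
  }
  x <- x[ok]
  t <- tvals[ok]
  xc <- x - ex
  list(
    n = n, x = x, t = t,
    S = sum(xc * t),
    sum_T = sum(t),
    sum_T2 = sum(t * t),
    norm_Tmu2 = sum((t - mean(t))^2),
    sigma2_x = sum(xc * xc) / (n - 1)
  )
}

new_npbat_result <- function(sums, ex, sigma2_x, scale, mode,
                             marker_id = "marker") {
  var_S <- sums$sum_T2 * sigma2_x
  z_raw <- sums$S / sqrt(var_S)
  z_scaled <- scale * z_raw
  structure(
    list(marker_id = marker_id, S = sums$S, ex = ex_value(ex),
         sigma2_x = sigma2_x, sum_T2 = sums$sum_T2,
         norm_Tmu2 = sums$norm_Tmu2, sum_T = sums$sum_T, var_S = var_S,
         z_raw = z_raw, scale = scale, z_scaled = z_scaled,
         p_value = two_sided_p(z_scaled), n_used = sums$n, mode = mode),
    class = "npbat"
  )
}

#' The phenotype-conditioned score statistic
#'
#' Computes `S = sum_i (X_i - E_x) T_i` and the standardised statistic
#' `z = S / sqrt(var(S))` with `var(S) = (sum_i T_i^2) * sigma2_x`, where
#' `sigma2_x = sum_i (X_i - E_x)^2 / (n - 1)` is the sample variance of the
#' marker scores around the supplied `E_x`.  Conditioning treats the coded
#' trait as fixed and the genotype as random, so `E(S) = 0` under the null
#' of no association regardless of the phenotype's distribution.  The
#' two-sided p-value refers `z` to the standard normal; use
#' [npbat_all_subjects_pvalue()] or [npbat_secondary_pvalue()] for the
#' scalings that account for how `E_x` was estimated.
#'
#' @param genotypes A [coded_genotypes()] vector (or numeric scores).
#' @param trait A [trait_coding()][code_binary_trait] object or numeric
#'   coded-trait vector, aligned with `genotypes`.
#' @param ex The null expectation of the marker score, from [resolve_ex()]
#'   or a plain number.
#' @return An object of class `npbat` with elements `S`, `ex`, `sigma2_x`,
#'   `sum_T2`, `norm_Tmu2`, `var_S`, `z_raw`, `scale`, `z_scaled`,
#'   `p_value`, `n_used`; see [tidy.npbat()].
#' @examples
#' g <- coded_genotypes(c(0, 2, 0, 2))
#' npbat_statistic(g, c(-1, 1, -1, 1), ex = 1)  # z = sqrt(3)
#' @export
npbat_statistic <- function(genotypes, trait, ex) {
  x <- as_genotype_scores(genotypes)
  tvals <- as_trait_values(trait)
  sums <- npbat_sums(x, tvals, ex_value(ex))
  check_nondegenerate(sums)
  new_npbat_result(sums, ex, sums$sigma2_x, scale = 1, mode = "raw",
                   marker_id = genotype_marker_id(genotypes))
}

check_nondegenerate <- function(sums) {
  if (sums$sigma2_x == 0) {
    abort("zero genotype variance: marker is monomorphic at E_x.",
          class = "npbat_error_monomorphic")
  }
  if (sums$sum_T2 == 0) {
    abort("zero trait variance: all coded traits are zero.",
          class = "npbat_error_degenerate")
  }
  invisible(sums)
}

#' Rescale the statistic when the phenotype is observed on all subjects
#'
#' When the phenotype is available for every tested individual and `E_x` is
#' the genotype mean of that same sample, the exact null variance of `S` is
#' `sigma_x^2 ||T_mu||^2` with `T_mu = Y - mean(Y)`, not
#' `sigma_x^2 ||T||^2`.  Multiplying the raw statistic by
#' `||T|| / ||T_mu||` therefore restores a standard normal reference for
#' any offset choice; the scale equals one exactly when the offset is the
#' sample mean.
#'
#' @param result An `npbat` result from [npbat_statistic()].
#' @param trait The trait coding used (only needed when `result` lacks the
#'   stored norms; may be `NULL`).
#' @return The `npbat` result with updated `scale`, `z_scaled` and
#'   `p_value` (`mode = "all_subjects"`).
#' @export
npbat_all_subjects_pvalue <- function(result, trait = NULL) {
  stopifnot(inherits(result, "npbat"))
  if (result$norm_Tmu2 == 0) {
    abort("zero centered trait norm: phenotype is constant.",
          class = "npbat_error_degenerate")
  }
  result$scale <- sqrt(result$sum_T2 / result$norm_Tmu2)
  result$z_scaled <- result$scale * result$z_raw
  result$p_value <- two_sided_p(result$z_scaled)
  result$mode <- "all_subjects"
  result
}

#' Test a case-only secondary phenotype against control-estimated E_x
#'
#' The ascertained-secondary-phenotype mode: the phenotype is observed for
#' the cases only, sums run over the cases, and `E_x` is estimated from the
#' genotypes of the `m` controls (or fixed externally).  Estimating `E_x`
#' from an independent group adds `(sum_i T_i)^2 / m` to the conditional
#' null variance of `S`, so the calibrated statistic is
#'
#' \deqn{z = S / ( \hat\sigma_x \sqrt{\|T\|^2 + (\sum_i T_i)^2 / m} ),}
#'
#' equivalently `scale * z_raw` with
#' `scale = ||T|| / sqrt(||T_mu||^2 + n(1 + n/m)(Ybar - Yoffset)^2)`.  When
#' the offset equals the case sample mean the correction vanishes and the
#' raw statistic is already standard normal.  With `n_ex_group = Inf` the
#' supplied `E_x` is treated as known and no correction is applied.
#'
#' @param genotypes Case genotypes ([coded_genotypes()] or numeric).
#' @param trait Coded case phenotype (`Y - Y_offset`), aligned with
#'   `genotypes`.
#' @param ex Null marker-score expectation; if produced by [resolve_ex()]
#'   its estimation-group size is picked up automatically.
#' @param sigma_x Optional known marker-score standard deviation; by
#'   default the sample value around `ex` over the cases is used.
#' @param n_ex_group Size of the genotype group `E_x` was estimated from
#'   (number of controls); default taken from `ex`, `Inf` meaning known.
#' @return An `npbat` result (`mode = "secondary"`).
#' @examples
#' cases <- coded_genotypes(c(0, 1, 2, 1, 0, 1))
#' tr <- c(0.4, -0.2, 1.1, 0.3, -0.5, 0.1)
#' npbat_secondary_pvalue(cases, tr, ex = 0.4, n_ex_group = 500)
#' @export
npbat_secondary_pvalue <- function(genotypes, trait, ex, sigma_x = NULL,
                                   n_ex_group = NULL) {
  x <- as_genotype_scores(genotypes)
  tvals <- as_trait_values(trait)
  m <- n_ex_group %||% ex_group_size(ex)
  check_scalar_number(m, "n_ex_group", lower = 1, allow_infinite = TRUE)
  sums <- npbat_sums(x, tvals, ex_value(ex))
  sigma2 <- if (is.null(sigma_x)) sums$sigma2_x else sigma_x^2
  if (sigma2 == 0) {
    abort("zero genotype variance: marker is monomorphic at E_x.",
          class = "npbat_error_monomorphic")
  }
  var_factor <- sums$sum_T2 + sums$sum_T^2 / m
  if (var_factor == 0) {
    abort("degenerate trait coding: zero variance factor.",
          class = "npbat_error_degenerate")
  }
  if (sums$sum_T2 == 0) {
    abort("zero trait variance: all coded traits are zero.",
          class = "npbat_error_degenerate")
  }
  out <- new_npbat_result(sums, ex, sigma2,
                          scale = sqrt(sums$sum_T2 / var_factor),
                          mode = "secondary",
                          marker_id = genotype_marker_id(genotypes))
  out
}

#' @export
print.npbat <- function(x, ...) {
  cat(sprintf("<npbat> marker %s (%s mode)\n", x$marker_id, x$mode))
  cat(sprintf("  S = %.6g, E_x = %.6g, sigma2_x = %.6g, n_used = %d\n",
              x$S, x$ex, x$sigma2_x, x$n_used))
  cat(sprintf("  z_raw = %.6g, scale = %.6g, z = %.6g, p = %.4g\n",
              x$z_raw, x$scale, x$z_scaled, x$p_value))
  invisible(x)
}

#' Tidy an npbat result
#'
#' @param x An `npbat` result.
#' @param ... Unused.
#' @return A one-row tibble with the statistic, its scaling and p-value.
#' @export
tidy.npbat <- function(x, ...) {
  tibble(marker_id = x$marker_id, mode = x$mode, n_used = x$n_used,
         ex = x$ex, S = x$S, sigma2_x = x$sigma2_x, z_raw = x$z_raw,
         scale = x$scale, z_scaled = x$z_scaled, p_value = x$p_value)
}

#' @rdname tidy.npbat
#' @export
glance.npbat <- function(x, ...) {
  tibble(n_used = x$n_used, statistic = x$z_scaled, p_value = x$p_value,
         mode = x$mode)
}
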