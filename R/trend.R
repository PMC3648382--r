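#' Cochran-Armitage trend test z statistic
#'
#' The standard score test for a dose-response genotype effect on a binary
#' trait, written for a 2 x 3 genotype table.  With `r_k` cases and `n_k`
#' cases-plus-controls carrying `k` copies of the coded allele,
#' `R = sum(r_k)`, `S = N - R`:
#'
#' \deqn{z = \frac{N(r_1 + 2 r_2) - R(n_1 + 2 n_2)}
#'   {\sqrt{(S R / N)\,(N(n_1 + 4 n_2) - (n_1 + 2 n_2)^2)}}}
#'
#' This serves as the classical benchmark for the binary-coded
#' phenotype-conditioned test; the exact finite-sample ratio of the two is
#' [statistic_ratio()].
#'
#' @param r0,r1,r2 Case counts by genotype score 0/1/2.
#' @param n0,n1,n2 Total (case + control) counts by genotype score.
#' @return The z statistic (numeric scalar); square it for the usual
#'   1-df chi-square.
#' @examples
#' cochran_armitage(10, 20, 10, 30, 40, 10)
#' @export
cochran_armitage <- function(r0, r1, r2, n0, n1, n2) {
  counts <- c(r0, r1, r2, n0, n1, n2)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be non-negative integers.",
          class = "npbat_error_input")
  }
  r <- c(r0, r1, r2)
  n <- c(n0, n1, n2)
  if (any(r > n)) {
    abort("case counts cannot exceed totals.", class = "npbat_error_input")
  }
  N <- sum(n)
  R <- sum(r)
  S <- N - R
  if (R < 1 || S < 1) {
    abort("degenerate design: need at least one case and one control.",
          class = "npbat_error_degenerate")
  }
  D <- N * (n1 + 4 * n2) - (n1 + 2 * n2)^2
  if (D <= 0) {
    abort("zero genotype variance: marker is monomorphic.",
          class = "npbat_error_monomorphic")
  }
  (N * (r1 + 2 * r2) - R * (n1 + 2 * n2)) / sqrt((S * R / N) * D)
}

#' Exact ratio of the trend-test and conditional-score statistics
#'
#' For a binary phenotype coded `T_i = Y_i - mu_y` and `E_x` taken as the
#' full-sample genotype mean, the ratio of the Cochran-Armitage z to the
#' conditional score z is a closed form free of the genotype counts:
#'
#' \deqn{\sqrt{\frac{N}{N-1}\left[(1 + 1/\gamma)\mu_y^2 +
#'   (1+\gamma)(1-\mu_y)^2\right]}}
#'
#' with `gamma` the case:control ratio.  The bracket is minimised (at 1) by
#' `mu_y = gamma / (1 + gamma) = #cases / N`, the efficient offset, where
#' the two tests agree up to `sqrt(N / (N - 1))`.
#'
#' @param N Total sample size (cases + controls).
#' @param gamma Case:control ratio (`> 0`).
#' @param mu_y The offset used in the binary coding.
#' @return The ratio (numeric scalar, `>= sqrt(N/(N-1))`).
#' @examples
#' statistic_ratio(1000, 1, 0.5)  # sqrt(1000/999)
#' @export
statistic_ratio <- function(N, gamma, mu_y) {
  check_scalar_number(N, "N", lower = 2)
  check_scalar_number(gamma, "gamma")
  check_scalar_number(mu_y, "mu_y")
  if (gamma <= 0) {
    abort("`gamma` must be positive.", class = "npbat_error_input")
  }
  sqrt(N / (N - 1) *
         ((1 + 1 / gamma) * mu_y^2 + (1 + gamma) * (1 - mu_y)^2))
}

#' Efficient offset for a binary trait
#'
#' The offset that maximises the power of the binary-coded conditional
#' score test relative to the trend test: the case fraction
#' `#cases / (#cases + #controls)`.
#'
#' @param n_cases,n_controls Case and control counts (both `>= 1`).
#' @return The case fraction (numeric scalar).
#' @examples
#' optimal_binary_offset(500, 500)
#' @export
optimal_binary_offset <- function(n_cases, n_controls) {
  counts <- c(n_cases, n_controls)
  if (any(!is.finite(counts)) || any(counts < 1) ||
      any(counts != round(counts))) {
    abort("need at least one case and one control.",
          class = "npbat_error_degenerate")
  }
  n_cases / (n_cases + n_controls)
}
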