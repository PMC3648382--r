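#' Marker effect size implied by a heritability
#'
#' For an additive marker with allele frequency `p` explaining a fraction
#' `h` of the phenotypic variance, with residual standard deviation
#' `sigma`, the per-allele effect is
#' `a = sigma * sqrt(h / (2 p (1 - p) (1 - h)))`, monotone increasing in
#' `h` and zero iff `h = 0`.
#'
#' @param h Heritability attributable to the marker, in `[0, 1)`.
#' @param p Coded-allele frequency, in `(0, 1)`.
#' @param sigma Residual phenotype standard deviation (`> 0`).
#' @return The per-allele effect `a` (numeric scalar).
#' @examples
#' effect_size_from_heritability(0.05, 0.2)
#' @export
effect_size_from_heritability <- function(h, p, sigma = 1) {
  check_scalar_number(h, "h", lower = 0)
  if (h >= 1) {
    abort("`h` must be below 1.", class = "npbat_error_input")
  }
  check_scalar_number(p, "p")
  if (p <= 0 || p >= 1) {
    abort("`p` must be in (0, 1).", class = "npbat_error_input")
  }
  check_scalar_number(sigma, "sigma")
  if (sigma <= 0) {
    abort("`sigma` must be positive.", class = "npbat_error_input")
  }
  sigma * sqrt(h / (2 * p * (1 - p) * (1 - h)))
}

#' Simulate additive genotypes under Hardy-Weinberg equilibrium
#'
#' Scores are drawn independently as `Binomial(2, p)` counts of the coded
#' allele.
#'
#' @param n Number of individuals.
#' @param p Coded-allele frequency, in `(0, 1)`.
#' @param seed Optional integer seed (the caller's RNG state is restored).
#' @return A [coded_genotypes()] vector of length `n`.
#' @examples
#' simulate_genotypes(10, 0.2, seed = 1)
#' @export
simulate_genotypes <- function(n, p, seed = NULL) {
  check_scalar_number(n, "n", lower = 1)
  check_scalar_number(p, "p")
  if (p <= 0 || p >= 1) {
    abort("`p` must be in (0, 1).", class = "npbat_error_input")
  }
  scores <- with_seed(seed, stats::rbinom(n, 2L, p))
  coded_genotypes(scores, marker_id = "simulated")
}

# exact lower-truncated normal draws by inverse CDF (no rejection loop)
rtrunc_normal_lower <- function(mu, sigma, lower) {
  p_lo <- stats::pnorm(lower, mean = mu, sd = sigma)
  u <- stats::runif(length(mu))
  stats::qnorm(p_lo + (1 - p_lo) * u, mean = mu, sd = sigma)
}

#' Simulate an ascertained secondary phenotype for given case genotypes
#'
#' Each case's phenotype is drawn from a normal with mean `a * X_i` and
#' standard deviation `sigma`, restricted to its upper tail so that only
#' the top `truncation_fraction` of the distribution is observed - the
#' distortion induced by recruiting cases whose secondary phenotype is
#' severe.  Two cutoff conventions are supported:
#'
#' * `"per_individual"` (default): the cutoff is the
#'   `1 - truncation_fraction` quantile of each individual's own
#'   `N(a X_i, sigma^2)`, so exactly the top fraction of every conditional
#'   distribution is retained (under the null this is exactly a scaled
#'   half-normal for the default fraction 0.5);
#' * `"fixed"`: a single cutoff at the `1 - truncation_fraction` quantile
#'   of the null `N(0, sigma^2)`.
#'
#' Both conventions leave the genotype distribution untouched; see
#' [simulate_ascertained_cases()] for joint ascertainment that also
#' enriches the genotypes.  Sampling is by inverse CDF on the truncated
#' region (exact, no rejection loop).
#'
#' @param genotypes Case genotypes ([coded_genotypes()] or numeric scores).
#' @param a Per-allele effect (see [effect_size_from_heritability()]).
#' @param sigma Phenotype standard deviation before truncation (`> 0`).
#' @param truncation_fraction Fraction of the distribution retained, in
#'   `(0, 1]`; `1` means no truncation.
#' @param cutoff Cutoff convention, see above.
#' @param seed Optional integer seed.
#' @return Numeric phenotype vector aligned with `genotypes`.
#' @examples
#' g <- simulate_genotypes(100, 0.2, seed = 1)
#' y <- simulate_secondary_phenotype(g, a = 0.4, seed = 2)
#' @export
simulate_secondary_phenotype <- function(genotypes, a, sigma = 1,
                                         truncation_fraction = 0.5,
                                         cutoff = c("per_individual",
                                                    "fixed"),
                                         seed = NULL) {
  cutoff <- match.arg(cutoff)
  x <- as_genotype_scores(genotypes)
  check_scalar_number(a, "a", lower = 0)
  check_scalar_number(sigma, "sigma")
  if (sigma <= 0) {
    abort("`sigma` must be positive.", class = "npbat_error_input")
  }
  check_scalar_number(truncation_fraction, "truncation_fraction")
  if (truncation_fraction <= 0 || truncation_fraction > 1) {
    abort("`truncation_fraction` must be in (0, 1].",
          class = "npbat_error_input")
  }
  mu <- a * x
  lower <- if (truncation_fraction == 1) {
    rep(-Inf, length(x))
  } else if (cutoff == "per_individual") {
    mu + sigma * stats::qnorm(1 - truncation_fraction)
  } else {
    rep(sigma * stats::qnorm(1 - truncation_fraction), length(x))
  }
  with_seed(seed, rtrunc_normal_lower(mu, sigma, lower))
}

#' Simulate cases jointly ascertained on their secondary phenotype
#'
#' Models recruitment conditional on the secondary phenotype exceeding a
#' population cutoff `c` (the `1 - truncation_fraction` quantile of the
#' null `N(0, sigma^2)`): genotype and phenotype are drawn from the joint
#' law of `(X, Y)` given `Y >= c`, so the case genotype frequencies are
#' enriched in proportion to `P(Y >= c | X)`.  This is the only
#' convention under which ascertainment leaves a footprint on the
#' genotypes themselves; at `a = 0` it coincides with
#' [simulate_secondary_phenotype()].
#'
#' @param n Number of cases.
#' @param p Coded-allele frequency.
#' @inheritParams simulate_secondary_phenotype
#' @return A tibble with columns `genotype` and `phenotype`.
#' @examples
#' simulate_ascertained_cases(5, 0.2, a = 0.4, seed = 1)
#' @export
simulate_ascertained_cases <- function(n, p, a, sigma = 1,
                                       truncation_fraction = 0.5,
                                       seed = NULL) {
  check_scalar_number(n, "n", lower = 1)
  check_scalar_number(truncation_fraction, "truncation_fraction")
  if (truncation_fraction <= 0 || truncation_fraction > 1) {
    abort("`truncation_fraction` must be in (0, 1].",
          class = "npbat_error_input")
  }
  cutoff <- if (truncation_fraction == 1) {
    -Inf
  } else {
    sigma * stats::qnorm(1 - truncation_fraction)
  }
  scores <- 0:2
  w <- stats::dbinom(scores, 2L, p) *
    stats::pnorm(cutoff, mean = a * scores, sd = sigma, lower.tail = FALSE)
  with_seed(seed, {
    x <- sample(scores, n, replace = TRUE, prob = w)
    y <- rtrunc_normal_lower(a * x, sigma, rep(cutoff, n))
    tibble(genotype = x, phenotype = y)
  })
}
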