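#' Multivariate extension of the conditional score test
#'
#' Tests one marker against `m` phenotypes jointly.  With `T_i` the
#' `m`-vector of coded traits for individual `i`,
#' `S = sum_i (X_i - E_x) T_i` is `m x 1`,
#' `V_S = sigma2_x * sum_i T_i T_i'`, and the statistic is
#' `chi2 = S' V_S^{-1} S`.  Because `E_x` is estimated from the sample the
#' chi-square reference is not exact, so significance is assessed by a
#' seeded permutation test that re-pairs the trait rows with the fixed
#' genotypes; the asymptotic chi-square p-value is reported alongside as
#' advisory only.
#'
#' Collinear phenotypes make `V_S` singular; by default a Moore-Penrose
#' pseudo-inverse (relative singular-value tolerance `pinv_tol`) is used
#' with degrees of freedom equal to the rank and a warning; `strict = TRUE`
#' turns this into an error.
#'
#' @param genotypes A [coded_genotypes()] vector (or numeric scores).
#' @param traits Coded traits: an `n x m` numeric matrix, data frame, or a
#'   list of `trait_coding` objects / numeric vectors.
#' @param ex Null marker-score expectation ([resolve_ex()] or a number);
#'   held fixed across permutations.
#' @param n_permutations Number of permutations `B`; the p-value is
#'   `(b + 1) / (B + 1)` where `b` counts permuted statistics `>=` the
#'   observed one, so it is never zero.
#' @param seed Integer seed for the permutation stream (reproducible
#'   bit-for-bit); `NULL` uses the current RNG state.
#' @param strict Error instead of pseudo-inverting a singular `V_S`.
#' @param pinv_tol Relative tolerance on singular values.
#' @return An object of class `npbat_mv`: `S_vec`, `V_S`, `chi2`, `df`,
#'   `p_asymptotic` (advisory), `p_permutation`, `n_permutations`, `seed`,
#'   `n_used`, `m`.
#' @examples
#' g <- coded_genotypes(rbinom(50, 2, 0.3))
#' tr <- cbind(rnorm(50), rnorm(50))
#' npbat_multivariate(g, tr, ex = 0.6, n_permutations = 199, seed = 1)
#' @export
npbat_multivariate <- function(genotypes, traits, ex, n_permutations = 999,
                               seed = NULL, strict = FALSE,
                               pinv_tol = 1e-10) {
  x <- as_genotype_scores(genotypes)
  tmat <- as_trait_matrix(traits, n = length(x))
  m <- ncol(tmat)
  check_scalar_number(n_permutations, "n_permutations", lower = 1)
  ok <- !is.na(x) & stats::complete.cases(tmat)
  n <- sum(ok)
  if (n < m + 1L) {
    abort(sprintf("need at least m + 1 = %d complete cases, got %d.",
                  m + 1L, n),
          class = "npbat_error_degenerate")
  }
  x <- x[ok]
  tmat <- tmat[ok, , drop = FALSE]
  exv <- ex_value(ex)
  xc <- x - exv
  sigma2 <- sum(xc^2) / (n - 1)
  if (sigma2 == 0) {
    abort("zero genotype variance: marker is monomorphic at E_x.",
          class = "npbat_error_monomorphic")
  }
  V <- sigma2 * crossprod(tmat)
  inv <- pinv_sym(V, tol = pinv_tol)
  if (inv$rank < m) {
    if (strict) {
      abort("V_S is numerically singular.", class = "npbat_error_singular")
    }
    warn(sprintf("V_S is singular (rank %d of %d); using pseudo-inverse.",
                 inv$rank, m),
         class = "npbat_warn_singular")
  }
  S_obs <- drop(crossprod(tmat, xc))
  chi2 <- function(S) drop(t(S) %*% inv$inv %*% S)
  chi2_obs <- chi2(S_obs)
  # V_S is invariant to row permutation of the trait matrix, so only S
  # needs recomputing per permutation
  B <- as.integer(n_permutations)
  b <- with_seed(seed, {
    exceed <- 0L
    for (i in seq_len(B)) {
      Sp <- drop(crossprod(tmat[sample.int(n), , drop = FALSE], xc))
      if (chi2(Sp) >= chi2_obs) exceed <- exceed + 1L
    }
    exceed
  })
  structure(
    list(S_vec = S_obs, V_S = V, chi2 = chi2_obs, df = inv$rank,
         p_asymptotic = stats::pchisq(chi2_obs, df = inv$rank,
                                      lower.tail = FALSE),
         p_permutation = (b + 1) / (B + 1), n_permutations = B,
         seed = seed, n_used = n, m = m,
         marker_id = genotype_marker_id(genotypes)),
    class = "npbat_mv"
  )
}

as_trait_matrix <- function(traits, n) {
  if (inherits(traits, "trait_coding")) traits <- list(traits)
  if (is.list(traits) && !is.data.frame(traits)) {
    traits <- vapply(traits, as_trait_values, numeric(n))
  }
  if (is.data.frame(traits)) traits <- as.matrix(traits)
  if (is.numeric(traits) && is.null(dim(traits))) {
    traits <- matrix(traits, ncol = 1L)
  }
  if (!is.matrix(traits) || !is.numeric(traits) || nrow(traits) != n) {
    abort("`traits` must resolve to an n x m numeric matrix.",
          class = "npbat_error_input")
  }
  traits
}

# Moore-Penrose pseudo-inverse of a symmetric PSD matrix via eigen
pinv_sym <- function(V, tol = 1e-10) {
  e <- eigen(V, symmetric = TRUE)
  keep <- e$values > tol * max(e$values, 0)
  rank <- sum(keep)
  if (rank == 0L) {
    abort("V_S is identically zero.", class = "npbat_error_singular")
  }
  inv <- e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
  list(inv = inv, rank = rank)
}

#' @export
print.npbat_mv <- function(x, ...) {
  cat(sprintf("<npbat_mv> marker %s: m = %d phenotypes, n_used = %d\n",
              x$marker_id, x$m, x$n_used))
  cat(sprintf("  chi2 = %.6g on %d df; permutation p = %.4g (B = %d)\n",
              x$chi2, x$df, x$p_permutation, x$n_permutations))
  cat(sprintf("  asymptotic p = %.4g (advisory only; not exact)\n",
              x$p_asymptotic))
  invisible(x)
}

#' Tidy a multivariate result
#'
#' @param x An `npbat_mv` result.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
tidy.npbat_mv <- function(x, ...) {
  tibble(marker_id = x$marker_id, m = x$m, n_used = x$n_used,
         chi2 = x$chi2, df = x$df, p_permutation = x$p_permutation,
         p_asymptotic = x$p_asymptotic, n_permutations = x$n_permutations)
}

#' @rdname tidy.npbat_mv
#' @export
glance.npbat_mv <- function(x, ...) {
  tibble(statistic = x$chi2, df = x$df, p_value = x$p_permutation,
         n_used = x$n_used)
}
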