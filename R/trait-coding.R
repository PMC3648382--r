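new_trait_coding <- function(values, scheme, offset = NA_real_) {
  structure(
    list(values = as.numeric(values), scheme = scheme,
         offset = as.numeric(offset), n_used = sum(!is.na(values))),
    class = "trait_coding"
  )
}

#' @export
print.trait_coding <- function(x, ...) {
  cat(sprintf("<trait_coding> scheme = %s%s, n_used = %d\n", x$scheme,
              if (is.na(x$offset)) "" else sprintf(", offset = %g", x$offset),
              x$n_used))
  print(x$values, ...)
  invisible(x)
}

as_trait_values <- function(trait) {
  if (inherits(trait, "trait_coding")) {
    trait$values
  } else if (is.numeric(trait)) {
    as.numeric(trait)
  } else {
    abort("`trait` must be a `trait_coding` object or numeric vector.",
          class = "npbat_error_input")
  }
}

#' Code a binary trait with the efficient case-fraction offset
#'
#' Cases are coded `1 - R/n` and controls `-R/n`, where `R` is the number of
#' cases and `n` the number of cases plus controls.  With this offset the
#' coded trait sums to zero and the resulting score test is, up to an
#' explicit finite-sample factor (see [statistic_ratio()]), the
#' Cochran-Armitage trend test.  Individuals of unknown status get `NA` and
#' drop out of all sums.
#'
#' @param samples A sample table with a `status` column (see
#'   [sample_table()]).
#' @return A `trait_coding` object (`scheme = "binary_offset"`,
#'   `offset = R/n`).
#' @examples
#' code_binary_trait(sample_table(c("case", "control", "control", "control")))
#' @export
code_binary_trait <- function(samples) {
  check_samples(samples, "status")
  status <- normalize_status(samples$status)
  r <- sum(status == "case", na.rm = TRUE)
  s <- sum(status == "control", na.rm = TRUE)
  if (r == 0L || s == 0L) {
    abort("degenerate design: need at least one case and one control.",
          class = "npbat_error_degenerate")
  }
  mu <- r / (r + s)
  values <- rep(NA_real_, length(status))
  values[!is.na(status)] <- (status[!is.na(status)] == "case") - mu
  new_trait_coding(values, "binary_offset", offset = mu)
}

#' Code a continuous trait around a fixed offset
#'
#' The coded trait is `T_i = Y_i - offset`.  The recommended offset for an
#' unascertained sample is the phenotypic mean in the general population;
#' for case-only secondary phenotypes power is governed by the offset choice
#' while validity is not (see [npbat_secondary_pvalue()]).  Individuals with
#' missing phenotype get `NA` and drop out of all sums.
#'
#' @inheritParams code_binary_trait
#' @param offset Constant subtracted from the phenotype.
#' @return A `trait_coding` object (`scheme = "continuous_offset"`).
#' @examples
#' code_continuous_trait(sample_table(c(2, 1), phenotype = c(3, 5)), offset = 4)
#' @export
code_continuous_trait <- function(samples, offset) {
  check_samples(samples, "phenotype")
  check_scalar_number(offset, "offset")
  y <- as.numeric(samples$phenotype)
  if (all(is.na(y))) {
    abort("all phenotypes are missing.", class = "npbat_error_degenerate")
  }
  new_trait_coding(y - offset, "continuous_offset", offset = offset)
}

#' Code a trait as least-squares residuals on covariates
#'
#' The coded trait is `T_i = Y_i - Yhat_i`, the ordinary-least-squares
#' residual of the phenotype on the given covariate columns plus an
#' intercept.  The intercept is always included so that the coded trait sums
#' to zero, the centering the asymptotics assume.  Passing no covariates
#' gives mean-centering `T_i = Y_i - mean(Y)`.  This is the coding used to
#' adjust for population structure: supply principal components (or any
#' ancestry covariates) as columns of `samples`.
#'
#' @inheritParams code_binary_trait
#' @param covariates Character vector of covariate column names in
#'   `samples`; `NULL` for intercept-only (mean centering).
#' @return A `trait_coding` object (`scheme = "residual"`); individuals with
#'   a missing phenotype or any missing covariate get `NA`.
#' @examples
#' s <- sample_table(rep(2, 5), phenotype = c(1, 2, 3, 5, 4),
#'                   covariates = data.frame(age = 1:5))
#' code_residual_trait(s, covariates = "age")
#' @export
code_residual_trait <- function(samples, covariates = NULL) {
  check_samples(samples, c("phenotype", covariates))
  y <- as.numeric(samples$phenotype)
  n <- length(y)
  design <- cbind(`(Intercept)` = rep(1, n))
  for (v in covariates) {
    col <- samples[[v]]
    if (!is.numeric(col)) {
      abort(sprintf("covariate `%s` must be numeric.", v),
            class = "npbat_error_input")
    }
    design <- cbind(design, as.numeric(col))
  }
  colnames(design) <- c("(Intercept)", covariates)
  ok <- !is.na(y) & stats::complete.cases(design)
  if (sum(ok) < ncol(design)) {
    abort("fewer complete cases than regression parameters.",
          class = "npbat_error_degenerate")
  }
  fit <- stats::lm.fit(design[ok, , drop = FALSE], y[ok])
  if (fit$rank < ncol(design)) {
    abort("rank-deficient covariate design.",
          class = "npbat_error_degenerate")
  }
  values <- rep(NA_real_, n)
  values[ok] <- fit$residuals
  new_trait_coding(values, "residual")
}
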