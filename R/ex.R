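#' Resolve the null expectation of the marker score
#'
#' `E_x`, the expectation of the marker score under the null, is estimated
#' by the sample mean of the non-missing genotype scores in a chosen group
#' of individuals, or supplied as a fixed value (for instance `2 p` from a
#' reference allele frequency under the additive model).  For unascertained
#' continuous traits the natural group is everybody; for case-only
#' secondary phenotypes the recommended group is the controls, so that the
#' estimate is not contaminated by the ascertainment.
#'
#' The returned scalar carries the source and the size of the estimation
#' group as attributes; [npbat_secondary_pvalue()] uses the group size for
#' its variance correction.
#'
#' @param genotypes A [coded_genotypes()] vector (or plain numeric scores).
#' @param samples A sample table with a `status` column; only needed for
#'   `source = "cases"` or `"controls"`.
#' @param source Where to estimate from: `"all"`, `"cases"`, `"controls"`,
#'   or `"fixed"`.
#' @param value The fixed value, required iff `source = "fixed"`.
#' @return A numeric scalar of class `npbat_ex` with attributes `source` and
#'   `n_group` (`Inf` for a fixed value).
#' @examples
#' g <- coded_genotypes(c(0, 1, 2, 1))
#' resolve_ex(g, source = "all")
#' resolve_ex(g, source = "fixed", value = 0.4)
#' @export
resolve_ex <- function(genotypes, samples = NULL,
                       source = c("all", "cases", "controls", "fixed"),
                       value = NULL) {
  source <- match.arg(source)
  if (source == "fixed") {
    if (is.null(value)) {
      abort("`value` is required when `source = \"fixed\"`.",
            class = "npbat_error_input")
    }
    check_scalar_number(value, "value")
    model <- if (inherits(genotypes, "coded_genotypes")) {
      attr(genotypes, "model")
    } else {
      "additive"
    }
    max_score <- max(genotype_score_range(model))
    if (value < 0 || value > max_score) {
      abort(sprintf("fixed E_x must lie in [0, %d] for the %s model.",
                    max_score, model),
            class = "npbat_error_input")
    }
    return(new_ex(value, "fixed", Inf))
  }
  x <- as_genotype_scores(genotypes)
  keep <- switch(source,
    all = rep(TRUE, length(x)),
    cases = {
      check_samples(samples, "status")
      normalize_status(samples$status) %in% "case"
    },
    controls = {
      check_samples(samples, "status")
      normalize_status(samples$status) %in% "control"
    }
  )
  if (length(keep) != length(x)) {
    abort("`genotypes` and `samples` must have the same length.",
          class = "npbat_error_input")
  }
  xs <- x[keep & !is.na(x)]
  if (!length(xs)) {
    abort(sprintf("empty group: no non-missing genotypes among %s.", source),
          class = "npbat_error_degenerate")
  }
  new_ex(mean(xs), source, length(xs))
}

new_ex <- function(value, source, n_group) {
  structure(as.numeric(value), source = source, n_group = n_group,
            class = "npbat_ex")
}

#' @export
print.npbat_ex <- function(x, ...) {
  cat(sprintf("E_x = %g (source = %s, n = %s)\n", as.numeric(x),
              attr(x, "source"), format(attr(x, "n_group"))))
  invisible(x)
}

ex_value <- function(ex) {
  check_scalar_number(as.numeric(ex)[1L], "ex")
  as.numeric(ex)[1L]
}

ex_group_size <- function(ex) {
  attr(ex, "n_group") %||% Inf
}
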