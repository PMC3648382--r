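# Null variance factor of S when E_x is the genotype mean of a group G of
# size g: Var(S) / sigma_x^2 = sum(T^2) - 2*(sum T)*(sum_{tested & G} T)/g
# + (sum T)^2 / g.  Specialises to ||T_mu||^2 when G is the tested set, to
# sum(T^2) + (sum T)^2/m for a disjoint control group of size m, and to
# sum(T^2) when E_x is known (g = Inf).
general_var_factor <- function(sum_T2, sum_T, g, overlap_sum) {
  if (!is.finite(g)) return(sum_T2)
  sum_T2 - 2 * sum_T * overlap_sum / g + sum_T^2 / g
}

#' Tidy association scan over one or more markers
#'
#' Runs the phenotype-conditioned score test for each marker and returns
#' one row per marker.  The reference distribution accounts for how `E_x`
#' was estimated: the group-aware null variance of `S` reduces to the
#' all-subjects scaling of [npbat_all_subjects_pvalue()] when the
#' estimation group is the tested sample, and to the secondary-phenotype
#' correction of [npbat_secondary_pvalue()] when `E_x` comes from the
#' controls while only cases carry the phenotype.
#'
#' Monomorphic or otherwise degenerate markers yield a flagged `NA` row
#' rather than aborting the scan.
#'
#' @param samples A sample table (see [sample_table()]).
#' @param genotypes A [coded_genotypes()] vector, a named list of them, or
#'   a data frame of score columns (one column per marker).
#' @param mode Trait coding: `"binary"` (case/control with the efficient
#'   case-fraction offset), `"continuous"` (`Y - offset`, everyone with a
#'   phenotype), `"residual"` (OLS residuals on `covariates`), or
#'   `"secondary"` (`Y - offset`, cases only).
#' @param offset Offset for the continuous and secondary codings; defaults
#'   to the sample mean of the phenotypes used.
#' @param ex_source Group for `E_x`: `"all"`, `"cases"`, `"controls"`,
#'   `"fixed"`.  Defaults to `"controls"` in secondary mode and `"all"`
#'   otherwise.
#' @param ex_value Fixed `E_x` (with `ex_source = "fixed"`).
#' @param covariates Covariate column names for `mode = "residual"`.
#' @return A tibble with columns `marker_id`, `mode`, `n_used`, `ex`,
#'   `ex_source`, `offset`, `S`, `sigma2_x`, `z_raw`, `scale`, `z_scaled`,
#'   `p_value`, `note`.
#' @examples
#' s <- sample_table(rep(c(2, 1), each = 10),
#'                   phenotype = c(rnorm(10, 1), rep(NA, 10)))
#' g <- list(m1 = coded_genotypes(rbinom(20, 2, 0.3)),
#'           m2 = coded_genotypes(rbinom(20, 2, 0.5)))
#' npbat_assoc(s, g, mode = "secondary")
#' @export
npbat_assoc <- function(samples, genotypes,
                        mode = c("binary", "continuous", "residual",
                                 "secondary"),
                        offset = NULL,
                        ex_source = NULL, ex_value = NULL,
                        covariates = NULL) {
  mode <- match.arg(mode)
  check_samples(samples)
  markers <- as_marker_list(genotypes, n = nrow(samples))
  ex_source <- ex_source %||% if (mode == "secondary") "controls" else "all"
  trait <- switch(mode,
    binary = code_binary_trait(samples),
    continuous = {
      off <- offset %||% mean(samples$phenotype, na.rm = TRUE)
      code_continuous_trait(samples, off)
    },
    residual = code_residual_trait(samples, covariates = covariates),
    secondary = {
      check_samples(samples, c("status", "phenotype"))
      is_case <- normalize_status(samples$status) %in% "case"
      y <- ifelse(is_case, samples$phenotype, NA_real_)
      if (all(is.na(y))) {
        abort("no case has an observed phenotype.",
              class = "npbat_error_degenerate")
      }
      off <- offset %||% mean(y, na.rm = TRUE)
      new_trait_coding(y - off, "continuous_offset", offset = off)
    }
  )
  purrr::map(names(markers), function(id) {
    marker_row(markers[[id]], id, trait, samples, mode, ex_source, ex_value)
  }) |>
    purrr::list_rbind()
}

as_marker_list <- function(genotypes, n) {
  if (inherits(genotypes, "coded_genotypes") || (is.numeric(genotypes) &&
      is.null(dim(genotypes)))) {
    genotypes <- stats::setNames(list(genotypes),
                                 genotype_marker_id(genotypes))
  }
  if (is.data.frame(genotypes)) genotypes <- as.list(genotypes)
  if (!is.list(genotypes)) {
    abort("`genotypes` must be a vector, list or data frame of markers.",
          class = "npbat_error_input")
  }
  if (is.null(names(genotypes)) || anyDuplicated(names(genotypes))) {
    names(genotypes) <- paste0("marker", seq_along(genotypes))
  }
  bad <- vapply(genotypes, function(g) length(as_genotype_scores(g)) != n,
                logical(1))
  if (any(bad)) {
    abort("every marker must have one score per sample row.",
          class = "npbat_error_input")
  }
  genotypes
}

marker_row <- function(marker, id, trait, samples, mode, ex_source,
                       ex_value) {
  na_row <- function(note) {
    tibble(marker_id = id, mode = mode, n_used = NA_integer_,
           ex = NA_real_, ex_source = ex_source, offset = trait$offset,
           S = NA_real_, sigma2_x = NA_real_, z_raw = NA_real_,
           scale = NA_real_, z_scaled = NA_real_, p_value = NA_real_,
           note = note)
  }
  res <- tryCatch({
    x <- as_genotype_scores(marker)
    ex <- resolve_ex(marker, samples, source = ex_source, value = ex_value)
    sums <- npbat_sums(x, trait$values, ex_value(ex))
    if (sums$sigma2_x == 0) {
      abort("monomorphic", class = "npbat_error_monomorphic")
    }
    if (sums$sum_T2 == 0) {
      abort("zero trait variance", class = "npbat_error_degenerate")
    }
    group_mask <- ex_mask(ex_source, samples, x)
    tested <- !is.na(x) & !is.na(trait$values)
    vf <- general_var_factor(sums$sum_T2, sums$sum_T,
                             g = ex_group_size(ex),
                             overlap_sum = sum(trait$values[tested &
                                                              group_mask]))
    if (vf <= 0) {
      abort("degenerate variance factor", class = "npbat_error_degenerate")
    }
    z_raw <- sums$S / sqrt(sums$sum_T2 * sums$sigma2_x)
    scale <- sqrt(sums$sum_T2 / vf)
    z <- sums$S / sqrt(vf * sums$sigma2_x)
    tibble(marker_id = id, mode = mode, n_used = sums$n,
           ex = ex_value(ex), ex_source = ex_source, offset = trait$offset,
           S = sums$S, sigma2_x = sums$sigma2_x, z_raw = z_raw,
           scale = scale, z_scaled = z, p_value = two_sided_p(z),
           note = NA_character_)
  },
  npbat_error_monomorphic = function(e) na_row("monomorphic"),
  npbat_error_degenerate = function(e) na_row(conditionMessage(e)))
  res
}

ex_mask <- function(ex_source, samples, x) {
  ok_x <- !is.na(x)
  switch(ex_source,
    all = ok_x,
    cases = ok_x & normalize_status(samples$status) %in% "case",
    controls = ok_x & normalize_status(samples$status) %in% "control",
    fixed = rep(FALSE, length(x))
  )
}
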