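#' Configure a Monte-Carlo power / type-I-error study
#'
#' Captures the case-control secondary-phenotype simulation design: `n_cases`
#' cases and `n_controls` controls with Hardy-Weinberg genotypes at allele
#' frequency `allele_freq`; a secondary phenotype for the cases only, drawn
#' from a truncated normal with standard deviation `sigma`, mean `a * X`
#' (with `a` set by the heritability, see
#' [effect_size_from_heritability()]) and only the top
#' `truncation_fraction` observed; the conditional score test computed with
#' coded trait `Y - offset` over a grid of offsets and with `E_x` from
#' cases, controls or everyone.
#'
#' @param n_cases,n_controls Group sizes.
#' @param allele_freq Coded-allele frequency `p`.
#' @param heritability Heritability value(s) `h`; may be a vector, each
#'   entry simulated separately (`0` = null).
#' @param sigma Phenotype standard deviation before truncation.
#' @param truncation_fraction Observed upper fraction of the phenotype
#'   distribution.
#' @param truncation Truncation convention: `"per_individual"` or
#'   `"fixed"` (see [simulate_secondary_phenotype()]) or `"ascertained"`
#'   (joint conditioning, see [simulate_ascertained_cases()]).
#' @param offset_grid Offsets at which the coded trait `Y - offset` is
#'   evaluated.
#' @param n_replicates Monte-Carlo replicates per heritability value;
#'   default 1000 when every `heritability` is zero (type-I error runs),
#'   500 otherwise.
#' @param alpha Nominal test level.
#' @param methods Any of `"npbat_Ex_cases"`, `"npbat_Ex_controls"`,
#'   `"npbat_Ex_all"`, `"regression"` (OLS of `Y` on `X` among cases),
#'   `"trend_test"` (case/control trend test; offset-free).
#' @param seed Master seed; every replicate draws from its own derived
#'   substream so results are reproducible and arms do not perturb each
#'   other.
#' @return An object of class `npbat_sim_config`.
#' @export
simulation_config <- function(n_cases = 500, n_controls = 500,
                              allele_freq = 0.2, heritability = 0,
                              sigma = 1, truncation_fraction = 0.5,
                              truncation = c("per_individual", "fixed",
                                             "ascertained"),
                              offset_grid = seq(-5, 15, by = 1),
                              n_replicates = NULL, alpha = 0.05,
                              methods = c("npbat_Ex_cases",
                                          "npbat_Ex_controls",
                                          "npbat_Ex_all", "regression"),
                              seed = 1L) {
  truncation <- match.arg(truncation)
  methods <- match.arg(methods, several.ok = TRUE,
                       choices = c("npbat_Ex_cases", "npbat_Ex_controls",
                                   "npbat_Ex_all", "regression",
                                   "trend_test"))
  check_scalar_number(n_cases, "n_cases", lower = 2)
  check_scalar_number(n_controls, "n_controls", lower = 2)
  check_scalar_number(allele_freq, "allele_freq")
  stopifnot(is.numeric(heritability), all(heritability >= 0),
            all(heritability < 1), is.numeric(offset_grid),
            length(offset_grid) >= 1)
  check_scalar_number(alpha, "alpha")
  n_replicates <- n_replicates %||% if (all(heritability == 0)) 1000L
                                    else 500L
  check_scalar_number(n_replicates, "n_replicates", lower = 1)
  structure(
    list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
         allele_freq = allele_freq, heritability = heritability,
         sigma = sigma, truncation_fraction = truncation_fraction,
         truncation = truncation, offset_grid = as.numeric(offset_grid),
         n_replicates = as.integer(n_replicates), alpha = alpha,
         methods = methods, seed = as.integer(seed)),
    class = "npbat_sim_config"
  )
}

#' @export
print.npbat_sim_config <- function(x, ...) {
  cat("<npbat_sim_config>\n")
  cat(sprintf("  %d cases / %d controls, p = %g, sigma = %g\n", x$n_cases,
              x$n_controls, x$allele_freq, x$sigma))
  cat(sprintf("  heritability: %s; effect a: %s\n",
              paste(x$heritability, collapse = ", "),
              paste(signif(vapply(x$heritability,
                                  effect_size_from_heritability, 0,
                                  p = x$allele_freq, sigma = x$sigma), 4),
                    collapse = ", ")))
  cat(sprintf("  truncation: top %g%% (%s)\n",
              100 * x$truncation_fraction, x$truncation))
  cat(sprintf("  offsets: %g..%g (%d); %d replicates; alpha = %g; seed %d\n",
              min(x$offset_grid), max(x$offset_grid),
              length(x$offset_grid), x$n_replicates, x$alpha, x$seed))
  cat(sprintf("  methods: %s\n", paste(x$methods, collapse = ", ")))
  invisible(x)
}

# one replicate's data under a derived substream seed
sim_replicate <- function(config, h, seed) {
  a <- effect_size_from_heritability(h, config$allele_freq, config$sigma)
  with_seed(seed, {
    x_controls <- stats::rbinom(config$n_controls, 2L, config$allele_freq)
    if (config$truncation == "ascertained") {
      cases <- simulate_ascertained_cases(
        config$n_cases, config$allele_freq, a, config$sigma,
        config$truncation_fraction
      )
      list(x = cases$genotype, y = cases$phenotype, xk = x_controls)
    } else {
      x <- stats::rbinom(config$n_cases, 2L, config$allele_freq)
      y <- simulate_secondary_phenotype(
        x, a, config$sigma, config$truncation_fraction,
        cutoff = if (config$truncation == "fixed") "fixed"
                 else "per_individual"
      )
      list(x = x, y = y, xk = x_controls)
    }
  })
}

# z statistics of one conditional-score variant at every offset, from the
# replicate's sufficient sums; `g` is the E_x estimation-group size and
# `overlap` TRUE when the group contains the tested cases
variant_z <- function(x, y, xk, offsets, variant) {
  n <- length(x)
  m <- length(xk)
  e <- switch(variant,
    npbat_Ex_cases = mean(x),
    npbat_Ex_controls = mean(xk),
    npbat_Ex_all = (sum(x) + sum(xk)) / (n + m)
  )
  g <- switch(variant, npbat_Ex_cases = n, npbat_Ex_controls = m,
              npbat_Ex_all = n + m)
  sum_T <- sum(y) - n * offsets
  sum_T2 <- sum(y^2) - 2 * offsets * sum(y) + n * offsets^2
  S <- sum(x * y) - e * sum(y) - offsets * sum(x) + n * e * offsets
  sigma2 <- sum((x - e)^2) / (n - 1)
  overlap_sum <- if (variant == "npbat_Ex_controls") 0 else sum_T
  vf <- general_var_factor(sum_T2, sum_T, g, overlap_sum)
  S / sqrt(sigma2 * vf)
}

#' Run the Monte-Carlo power and type-I-error study
#'
#' For each replicate, genotypes are simulated for cases and controls and a
#' secondary phenotype for the cases only; each requested method is run at
#' each offset and a rejection at level `alpha` recorded.  Rates are
#' aggregated with binomial Monte-Carlo standard errors.  The conditional
#' score variants use the group-aware null variance (see [npbat_assoc()]),
#' so all three are calibrated at every offset; `"regression"` is the
#' two-sided OLS t-test of `Y` on `X` among the cases, and `"trend_test"`
#' the case/control Cochran-Armitage test (offset-free, reported with
#' `offset = NA`).
#'
#' @param config An [simulation_config()] object.
#' @return A `npbat_power` tibble with columns `method`, `offset`, `h`,
#'   `rejection_rate`, `mc_se`, `n_replicates`.
#' @examples
#' cfg <- simulation_config(n_cases = 50, n_controls = 50,
#'                          offset_grid = c(-2, 0, 2), n_replicates = 20,
#'                          seed = 7)
#' run_study(cfg)
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "npbat_sim_config"))
  npbat_variants <- intersect(config$methods,
                              c("npbat_Ex_cases", "npbat_Ex_controls",
                                "npbat_Ex_all"))
  zcrit <- stats::qnorm(1 - config$alpha / 2)
  B <- config$n_replicates
  offsets <- config$offset_grid
  seeds <- with_seed(config$seed,
                     matrix(draw_seeds(length(config$heritability) * B),
                            nrow = B))
  out <- purrr::map(seq_along(config$heritability), function(ih) {
    h <- config$heritability[ih]
    rej <- matrix(0, nrow = length(npbat_variants), ncol = length(offsets),
                  dimnames = list(npbat_variants, NULL))
    rej_reg <- 0
    rej_trend <- 0
    for (b in seq_len(B)) {
      d <- sim_replicate(config, h, seeds[b, ih])
      for (v in npbat_variants) {
        z <- variant_z(d$x, d$y, d$xk, offsets, v)
        rej[v, ] <- rej[v, ] + (abs(z) > zcrit)
      }
      if ("regression" %in% config$methods) {
        rej_reg <- rej_reg + regression_rejects(d$x, d$y, config$alpha)
      }
      if ("trend_test" %in% config$methods) {
        rej_trend <- rej_trend + trend_rejects(d$x, d$xk, config$alpha)
      }
    }
    rows <- list()
    if (length(npbat_variants)) {
      rows$npbat <- tibble(
        method = rep(npbat_variants, each = length(offsets)),
        offset = rep(offsets, times = length(npbat_variants)),
        h = h, rejection_rate = as.vector(t(rej)) / B
      )
    }
    if ("regression" %in% config$methods) {
      rows$reg <- tibble(method = "regression", offset = NA_real_, h = h,
                         rejection_rate = rej_reg / B)
    }
    if ("trend_test" %in% config$methods) {
      rows$trend <- tibble(method = "trend_test", offset = NA_real_, h = h,
                           rejection_rate = rej_trend / B)
    }
    purrr::list_rbind(rows)
  }) |>
    purrr::list_rbind()
  out <- dplyr::mutate(
    out,
    mc_se = sqrt(.data$rejection_rate * (1 - .data$rejection_rate) / B),
    n_replicates = B
  )
  structure(out, class = c("npbat_power", class(tibble())),
            alpha = config$alpha)
}

#' @importFrom rlang .data
regression_rejects <- function(x, y, alpha) {
  n <- length(x)
  sx <- stats::sd(x)
  if (sx == 0) return(0L)
  r <- stats::cor(x, y)
  tval <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  as.integer(2 * stats::pt(-abs(tval), df = n - 2) < alpha)
}

trend_rejects <- function(x, xk, alpha) {
  r <- tabulate(factor(x, levels = 0:2), 3L)
  s <- tabulate(factor(xk, levels = 0:2), 3L)
  n <- r + s
  z <- tryCatch(cochran_armitage(r[1], r[2], r[3], n[1], n[2], n[3]),
                npbat_error_monomorphic = function(e) 0)
  as.integer(two_sided_p(z) < alpha)
}

#' Write a power table as tab-separated text
#'
#' @param x A `npbat_power` tibble from [run_study()].
#' @param path Output file.
#' @return `x`, invisibly.
#' @export
write_power_table <- function(x, path) {
  readr::write_tsv(as_tibble(x), path)
  invisible(x)
}

#' Plot rejection rates by method, offset and heritability
#'
#' One panel per heritability value; offset-free methods (regression,
#' trend test) are drawn as horizontal reference lines.
#'
#' @param object A `npbat_power` tibble from [run_study()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.npbat_power <- function(object, ...) {
  alpha <- attr(object, "alpha") %||% 0.05
  dat <- as_tibble(object)
  with_offset <- dplyr::filter(dat, !is.na(.data$offset))
  flat <- dplyr::filter(dat, is.na(.data$offset))
  p <- ggplot2::ggplot(with_offset,
                       ggplot2::aes(.data$offset, .data$rejection_rate,
                                    colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = alpha, linetype = "dotted") +
    ggplot2::facet_wrap(~h, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "phenotype offset", y = "rejection rate",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (nrow(flat)) {
    p <- p + ggplot2::geom_hline(
      data = flat,
      ggplot2::aes(yintercept = .data$rejection_rate,
                   colour = .data$method),
      linetype = "dashed"
    )
  }
  p
}

#' @export
plot.npbat_power <- function(x, ...) print(autoplot(x, ...))
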