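#' Coded marker genotypes
#'
#' A numeric vector of per-individual marker scores under a genetic model:
#' under the additive model the score is the count (0/1/2) of the coded
#' allele, under the dominant and recessive models it is an indicator (0/1)
#' of carrying at least one, respectively two, copies.  `NA` marks a missing
#' genotype.
#'
#' @param scores Numeric vector of marker scores; `NA` for missing.
#' @param model Genetic model, one of `"additive"`, `"dominant"`,
#'   `"recessive"`.
#' @param marker_id Marker label.
#' @return A `coded_genotypes` vector (numeric with attributes `model` and
#'   `marker_id`).
#' @examples
#' coded_genotypes(c(0, 1, 2, NA, 1), marker_id = "rs42")
#' @export
coded_genotypes <- function(scores,
                            model = c("additive", "dominant", "recessive"),
                            marker_id = "marker") {
  model <- match.arg(model)
  if (!is.numeric(scores)) {
    abort("`scores` must be numeric.", class = "npbat_error_input")
  }
  scores <- as.numeric(scores)
  allowed <- genotype_score_range(model)
  bad <- !is.na(scores) & !scores %in% allowed
  if (any(bad)) {
    abort(
      sprintf(
        "Non-missing scores must lie in {%s} under the %s model (offending value: %s).",
        paste(allowed, collapse = ","), model, format(scores[which(bad)[1L]])
      ),
      class = "npbat_error_input"
    )
  }
  structure(scores,
            model = model,
            marker_id = as.character(marker_id),
            class = "coded_genotypes")
}

genotype_score_range <- function(model) {
  switch(model, additive = c(0, 1, 2), dominant = , recessive = c(0, 1))
}

#' @export
print.coded_genotypes <- function(x, ...) {
  cat(sprintf("<coded_genotypes> marker %s (%s model), n = %d, missing = %d\n",
              attr(x, "marker_id"), attr(x, "model"), length(x),
              sum(is.na(x))))
  print(as.numeric(x), ...)
  invisible(x)
}

#' @export
`[.coded_genotypes` <- function(x, i, ...) {
  out <- NextMethod()
  attributes(out) <- c(list(model = attr(x, "model"),
                            marker_id = attr(x, "marker_id")),
                       list(class = "coded_genotypes"))
  out
}

# accept a coded_genotypes object or a bare numeric vector
as_genotype_scores <- function(genotypes) {
  if (inherits(genotypes, "coded_genotypes")) {
    as.numeric(genotypes)
  } else if (is.numeric(genotypes)) {
    as.numeric(genotypes)
  } else {
    abort("`genotypes` must be a `coded_genotypes` object or numeric vector.",
          class = "npbat_error_input")
  }
}

genotype_marker_id <- function(genotypes) {
  attr(genotypes, "marker_id") %||% "marker"
}
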