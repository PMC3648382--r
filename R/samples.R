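#' Build a sample table
#'
#' A sample table is an ordinary data frame (tibble) with one row per
#' individual, a `status` column (`"case"`, `"control"` or `NA` for unknown),
#' an optional numeric `phenotype` column and any number of covariate
#' columns.  All trait-coding and testing functions take it as their first
#' argument, so calls chain with the pipe.
#'
#' @param status Per-individual affection status.  Accepts
#'   `"case"`/`"control"`/`"unknown"`/`NA` or the PLINK numeric convention
#'   (2 = case, 1 = control, 0/-9 = unknown).
#' @param phenotype Optional numeric secondary/quantitative phenotype
#'   (`NA` = missing).
#' @param covariates Optional data frame of covariate columns.
#' @param ids Optional individual labels (default `"id1"`, `"id2"`, ...).
#' @return A tibble with columns `id`, `status`, `phenotype` and any
#'   covariates.
#' @examples
#' sample_table(status = c(2, 2, 1, 1), phenotype = c(1.2, 0.3, NA, NA))
#' @export
sample_table <- function(status, phenotype = NULL, covariates = NULL,
                         ids = NULL) {
  status <- normalize_status(status)
  n <- length(status)
  ids <- ids %||% paste0("id", seq_len(n))
  phenotype <- phenotype %||% rep(NA_real_, n)
  if (length(ids) != n || length(phenotype) != n) {
    abort("`ids` and `phenotype` must match the length of `status`.",
          class = "npbat_error_input")
  }
  out <- tibble(id = as.character(ids), status = status,
                phenotype = as.numeric(phenotype))
  if (!is.null(covariates)) {
    covariates <- as_tibble(covariates)
    if (nrow(covariates) != n) {
      abort("`covariates` must have one row per individual.",
            class = "npbat_error_input")
    }
    out <- dplyr::bind_cols(out, covariates)
  }
  out
}

# normalise affection status to a character vector case/control/NA
normalize_status <- function(status) {
  if (is.factor(status)) status <- as.character(status)
  if (is.numeric(status)) {
    out <- rep(NA_character_, length(status))
    out[status == 2] <- "case"
    out[status == 1] <- "control"
    return(out)
  }
  if (!is.character(status)) {
    abort("`status` must be character, factor or numeric.",
          class = "npbat_error_input")
  }
  status <- tolower(status)
  ok <- status %in% c("case", "control", "unknown") | is.na(status)
  if (!all(ok)) {
    abort(sprintf("Unrecognised status value: \"%s\".",
                  status[which(!ok)[1L]]),
          class = "npbat_error_input")
  }
  status[status == "unknown"] <- NA_character_
  status
}

check_samples <- function(samples, need = character()) {
  if (!is.data.frame(samples)) {
    abort("`samples` must be a data frame (see `sample_table()`).",
          class = "npbat_error_input")
  }
  missing_cols <- setdiff(need, names(samples))
  if (length(missing_cols)) {
    abort(sprintf("`samples` is missing column(s): %s.",
                  paste0("`", missing_cols, "`", collapse = ", ")),
          class = "npbat_error_input")
  }
  invisible(samples)
}
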