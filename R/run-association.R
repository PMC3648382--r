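#' File-to-file association scan
#'
#' Reads PLINK-style text inputs, runs [npbat_assoc()] on every marker and
#' returns (and optionally writes) a per-marker results table.  Per-marker
#' failures (monomorphic markers, degenerate codings) become flagged rows,
#' never aborts.  When `out` is given, the table is written as
#' tab-separated text and a run manifest (`<out>.manifest`, `key=value`
#' lines with every option, the seed and input-file checksums) is written
#' beside it, so a run is fully reproducible from the manifest.
#'
#' @inheritParams read_ped_map_phe
#' @inheritParams npbat_assoc
#' @param pheno Name of the `.phe` column to use as the phenotype
#'   (default: the first one).
#' @param out Optional output TSV path.
#' @param seed Optional integer seed recorded in the manifest and used for
#'   any downstream randomness.
#' @return A tibble: `marker_id`, `chromosome`, `position`, then the
#'   [npbat_assoc()] columns.
#' @export
run_association <- function(ped, map, phe = NULL,
                            mode = c("binary", "continuous", "residual",
                                     "secondary"),
                            offset = NULL, ex_source = NULL,
                            ex_value = NULL, covariates = NULL,
                            pheno = NULL,
                            model = c("additive", "dominant", "recessive"),
                            missing_phenotype = -9,
                            coded_allele = c("second", "minor"),
                            out = NULL, seed = NULL, quiet = FALSE) {
  mode <- match.arg(mode)
  model <- match.arg(model)
  coded_allele <- match.arg(coded_allele)
  if (!is.null(seed)) set.seed(seed)
  data <- read_ped_map_phe(ped, map, phe, missing_phenotype = missing_phenotype,
                           coded_allele = coded_allele, model = model,
                           quiet = quiet)
  samples <- data$samples
  if (mode != "binary") {
    phe_cols <- setdiff(
      names(samples)[vapply(samples, is.numeric, logical(1))], "sex"
    )
    pheno <- pheno %||% phe_cols[1L]
    if (is.null(pheno) || is.na(pheno) || !pheno %in% names(samples)) {
      abort("no phenotype column available; supply a .phe file and `pheno`.",
            class = "npbat_error_input")
    }
    samples$phenotype <- samples[[pheno]]
  }
  res <- npbat_assoc(samples, data$genotypes, mode = mode, offset = offset,
                     ex_source = ex_source, ex_value = ex_value,
                     covariates = covariates)
  res <- dplyr::left_join(res,
                          data$map[c("marker_id", "chromosome", "position")],
                          by = "marker_id")
  res <- dplyr::relocate(res, "marker_id", "chromosome", "position")
  if (!is.null(out)) {
    readr::write_tsv(res, out)
    write_manifest(
      paste0(out, ".manifest"),
      options = list(ped = ped, map = map, phe = phe, mode = mode,
                     offset = offset, ex_source = ex_source %||%
                       if (mode == "secondary") "controls" else "all",
                     ex_value = ex_value,
                     covariates = paste(covariates, collapse = ","),
                     pheno = pheno, model = model,
                     missing_phenotype = missing_phenotype,
                     coded_allele = coded_allele, seed = seed, out = out),
      files = c(ped, map, phe)
    )
    if (!quiet) inform(sprintf("wrote %d marker rows to %s", nrow(res), out))
  }
  res
}

write_manifest <- function(path, options, files) {
  opts <- options[!vapply(options, is.null, logical(1))]
  lines <- c(
    sprintf("npbat_version=%s", as.character(utils::packageVersion("npbat"))),
    vapply(names(opts), function(k) {
      sprintf("%s=%s", k, paste(format(opts[[k]]), collapse = ","))
    }, ""),
    vapply(files, function(f) {
      sprintf("md5.%s=%s", basename(f), unname(tools::md5sum(f)))
    }, "")
  )
  writeLines(lines, path)
  invisible(path)
}
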