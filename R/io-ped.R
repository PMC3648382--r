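# whitespace-delimited text parsing shared by the readers: tolerant of
# duplicated whitespace and of blank lines
split_fields <- function(lines) {
  lines <- lines[trimws(lines) != ""]
  strsplit(trimws(lines), "[ \t]+")
}

#' Read PLINK-style pedigree, map and phenotype text files
#'
#' Reads the whitespace-delimited text dialect: a `.ped` file with columns
#' family id, individual id, father, mother, sex, affection status
#' (2 = case, 1 = control, 0/-9 = unknown) followed by two allele
#' characters per marker (`0` = missing allele); a `.map` file with
#' chromosome, marker id, genetic distance (optional) and 1-based position;
#' and an optional `.phe` file with a header line `FID IID <name>...` of
#' named phenotype/covariate columns.  Parental ids are ignored (the
#' design assumes unrelated individuals) with a logged note when any are
#' set.  Individuals are joined across files by (family id, individual
#' id); `.phe` rows without a `.ped` match are dropped with a warning.
#'
#' Genotypes are coded additively per marker by counting the coded allele;
#' the default coded allele is the second of the marker's sorted observed
#' allele pair, `coded_allele = "minor"` recodes to the minor allele
#' (orientation only flips the statistic's sign).
#'
#' @param ped,map Paths to the pedigree and map files.
#' @param phe Optional path to the phenotype file.
#' @param missing_phenotype Value coding a missing phenotype (default -9).
#' @param coded_allele `"second"` or `"minor"`.
#' @param model Genetic model for the scores.
#' @param quiet Suppress informational notes.
#' @return A list with `genotypes` (named list of [coded_genotypes()], one
#'   per marker), `samples` (tibble: `family_id`, `individual_id`, `id`,
#'   `status`, `sex` and any `.phe` columns) and `map` (tibble).
#' @export
read_ped_map_phe <- function(ped, map, phe = NULL, missing_phenotype = -9,
                             coded_allele = c("second", "minor"),
                             model = c("additive", "dominant", "recessive"),
                             quiet = FALSE) {
  coded_allele <- match.arg(coded_allele)
  model <- match.arg(model)
  for (path in c(ped, map, phe)) {
    if (!file.exists(path)) {
      abort(sprintf("file not found: %s", path), class = "npbat_error_io")
    }
  }
  map_tbl <- read_map(map)
  n_markers <- nrow(map_tbl)

  rows <- split_fields(readLines(ped))
  if (!length(rows)) {
    abort("empty ped file.", class = "npbat_error_parse")
  }
  expected <- 6L + 2L * n_markers
  lens <- lengths(rows)
  if (any(lens != expected)) {
    bad <- which(lens != expected)[1L]
    abort(sprintf(
      "ped line %d has %d fields, expected %d (6 + 2 x %d markers).",
      bad, lens[bad], expected, n_markers
    ), class = "npbat_error_parse")
  }
  mat <- do.call(rbind, rows)
  fam <- mat[, 1L]
  iid <- mat[, 2L]
  key <- paste(fam, iid, sep = "\r")
  if (anyDuplicated(key)) {
    abort(sprintf("duplicate individual id: %s %s.",
                  fam[duplicated(key)][1L], iid[duplicated(key)][1L]),
          class = "npbat_error_parse")
  }
  if (!quiet && any(mat[, 3L] != "0" | mat[, 4L] != "0")) {
    inform("parental ids present in ped file; ignored (unrelated-individuals design).")
  }
  status <- rep(NA_character_, nrow(mat))
  status[mat[, 6L] == "2"] <- "case"
  status[mat[, 6L] == "1"] <- "control"

  genotypes <- lapply(seq_len(n_markers), function(j) {
    a1 <- mat[, 5L + 2L * j]
    a2 <- mat[, 6L + 2L * j]
    code_allele_pairs(a1, a2, map_tbl$marker_id[j], coded_allele, model)
  })
  names(genotypes) <- map_tbl$marker_id

  samples <- tibble(family_id = fam, individual_id = iid,
                    id = paste(fam, iid, sep = ":"), status = status,
                    sex = suppressWarnings(as.integer(mat[, 5L])))
  if (!is.null(phe)) {
    samples <- join_phe(samples, phe, missing_phenotype, quiet)
  }
  list(genotypes = genotypes, samples = samples, map = map_tbl)
}

read_map <- function(path) {
  rows <- split_fields(readLines(path))
  if (!length(rows)) {
    abort("empty map file.", class = "npbat_error_parse")
  }
  lens <- lengths(rows)
  if (!all(lens %in% c(3L, 4L))) {
    abort(sprintf("map line %d has %d fields, expected 3 or 4.",
                  which(!lens %in% c(3L, 4L))[1L],
                  lens[!lens %in% c(3L, 4L)][1L]),
          class = "npbat_error_parse")
  }
  out <- tibble(
    chromosome = vapply(rows, `[`, "", 1L),
    marker_id = vapply(rows, `[`, "", 2L),
    genetic_distance = vapply(rows, function(r) {
      if (length(r) == 4L) as.numeric(r[3L]) else 0
    }, 0),
    position = vapply(rows, function(r) as.integer(r[length(r)]),
                      integer(1))
  )
  if (anyDuplicated(out$marker_id)) {
    abort(sprintf("duplicate marker id in map: %s.",
                  out$marker_id[duplicated(out$marker_id)][1L]),
          class = "npbat_error_parse")
  }
  out
}

code_allele_pairs <- function(a1, a2, marker_id, coded_allele, model) {
  missing <- a1 == "0" | a2 == "0"
  obs <- sort(unique(c(a1[!missing], a2[!missing])))
  if (length(obs) > 2L) {
    abort(sprintf("marker %s has more than two alleles (%s).", marker_id,
                  paste(obs, collapse = ", ")),
          class = "npbat_error_parse")
  }
  coded <- if (!length(obs)) {
    NA_character_
  } else if (coded_allele == "second" || length(obs) == 1L) {
    obs[length(obs)]
  } else {
    counts <- c(sum(c(a1, a2)[rep(!missing, 2L)] == obs[1L]),
                sum(c(a1, a2)[rep(!missing, 2L)] == obs[2L]))
    if (counts[1L] < counts[2L]) obs[1L] else obs[2L]
  }
  scores <- (a1 == coded) + (a2 == coded)
  scores[missing] <- NA_real_
  scores <- switch(model,
    additive = scores,
    dominant = as.numeric(scores >= 1),
    recessive = as.numeric(scores == 2)
  )
  coded_genotypes(scores, model = model, marker_id = marker_id)
}

join_phe <- function(samples, phe, missing_phenotype, quiet) {
  rows <- split_fields(readLines(phe))
  if (length(rows) < 1L) {
    abort("empty phe file.", class = "npbat_error_parse")
  }
  header <- rows[[1L]]
  if (length(header) < 3L) {
    abort("phe header must be `FID IID <name>...`.",
          class = "npbat_error_parse")
  }
  body <- rows[-1L]
  lens <- lengths(body)
  if (any(lens != length(header))) {
    abort(sprintf("phe line %d has %d fields, expected %d.",
                  which(lens != length(header))[1L] + 1L,
                  lens[lens != length(header)][1L], length(header)),
          class = "npbat_error_parse")
  }
  mat <- do.call(rbind, body)
  key_phe <- paste(mat[, 1L], mat[, 2L], sep = "\r")
  if (anyDuplicated(key_phe)) {
    abort("duplicate individual id in phe file.",
          class = "npbat_error_parse")
  }
  key_ped <- paste(samples$family_id, samples$individual_id, sep = "\r")
  unmatched <- !key_phe %in% key_ped
  if (any(unmatched)) {
    warn(sprintf("%d phe individual(s) not in ped file; excluded.",
                 sum(unmatched)),
         class = "npbat_warn_unmatched")
  }
  idx <- match(key_ped, key_phe)
  for (j in 3L:ncol(mat)) {
    vals <- suppressWarnings(as.numeric(mat[idx, j]))
    vals[!is.na(vals) & vals == missing_phenotype] <- NA_real_
    samples[[header[j]]] <- vals
  }
  samples
}

#' Write PLINK-style pedigree, map and phenotype text files
#'
#' Inverse of [read_ped_map_phe()] for additively coded markers: scores
#' 0/1/2 become allele pairs `1 1` / `1 2` / `2 2`, missing scores `0 0`.
#' Phenotype and covariate columns of `samples` (everything numeric except
#' `sex`) go to the `.phe` file with missing values written as
#' `missing_phenotype`.  Note that a marker whose observed scores are all
#' zero is written with only allele `1` present and will read back coded
#' on that allele.
#'
#' @param samples A sample table; columns `family_id`/`individual_id` are
#'   used if present, otherwise generated.
#' @param genotypes Named list of additive score vectors or
#'   [coded_genotypes()].
#' @param dir Output directory (created if needed).
#' @param basename Stem for `<basename>.ped/.map/.phe`.
#' @param map Optional map tibble (`chromosome`, `marker_id`,
#'   `genetic_distance`, `position`); autogenerated if `NULL`.
#' @param missing_phenotype Missing phenotype code to write.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_ped_map_phe <- function(samples, genotypes, dir,
                              basename = "npbat", map = NULL,
                              missing_phenotype = -9) {
  check_samples(samples, "status")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- nrow(samples)
  fam <- samples[["family_id"]] %||% rep("F0", n)
  iid <- samples[["individual_id"]] %||% samples[["id"]] %||%
    paste0("id", seq_len(n))
  status <- normalize_status(samples$status)
  status_code <- dplyr::case_match(status, "case" ~ "2", "control" ~ "1",
                                   .default = "0")
  sex <- samples[["sex"]] %||% rep(0L, n)

  allele_pair <- function(score) {
    dplyr::case_match(score, 0 ~ "1 1", 1 ~ "1 2", 2 ~ "2 2",
                      .default = "0 0")
  }
  geno_cols <- vapply(genotypes, function(g) {
    allele_pair(as_genotype_scores(g))
  }, character(n))
  if (n == 1L) geno_cols <- matrix(geno_cols, nrow = 1L)
  ped_lines <- paste(fam, iid, 0L, 0L, sex, status_code,
                     apply(geno_cols, 1L, paste, collapse = " "))

  marker_ids <- names(genotypes) %||% paste0("m", seq_along(genotypes))
  if (is.null(map)) {
    map <- tibble(chromosome = "1", marker_id = marker_ids,
                  genetic_distance = 0, position = seq_along(genotypes))
  }
  map_lines <- paste(map$chromosome, map$marker_id, map$genetic_distance,
                     map$position)

  pheno_cols <- setdiff(names(samples)[vapply(samples, is.numeric,
                                              logical(1))], "sex")
  phe_lines <- character()
  if (length(pheno_cols)) {
    vals <- vapply(pheno_cols, function(v) {
      x <- samples[[v]]
      ifelse(is.na(x), format(missing_phenotype), format(x, digits = 15,
                                                         trim = TRUE))
    }, character(n))
    if (n == 1L) vals <- matrix(vals, nrow = 1L)
    phe_lines <- c(paste(c("FID", "IID", pheno_cols), collapse = " "),
                   paste(fam, iid, apply(vals, 1L, paste, collapse = " ")))
  }

  paths <- file.path(dir, paste0(basename, c(".ped", ".map", ".phe")))
  names(paths) <- c("ped", "map", "phe")
  writeLines(ped_lines, paths[["ped"]])
  writeLines(map_lines, paths[["map"]])
  if (length(phe_lines)) writeLines(phe_lines, paths[["phe"]])
  invisible(paths)
}
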