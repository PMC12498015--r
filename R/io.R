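# File formats: tab-separated expression/clinical/class tables, GMT gene
# sets, JSON truth records and configs. Dialect: UTF-8, header row, "." for
# undefined numerics in result tables. All round trips are lossless.

#' Read and write expression matrices
#'
#' Tab-separated text; first column holds the gene identifier, remaining
#' columns one sample each. Duplicate gene ids are an error.
#'
#' @param path File path.
#' @return `read_expression`: numeric matrix, genes x samples.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop(sprintf("%s: expected gene id column plus samples", path))
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop(sprintf("%s: duplicate gene ids: %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop(sprintf("%s: non-numeric expression values", path))
  rownames(m) <- ids
  m
}

#' @rdname read_expression
#' @param expr Numeric matrix, genes x samples, with dimnames.
#' @export
write_expression <- function(expr, path) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write clinical outcome tables
#'
#' Columns: `patient_id`, `time_days` (positive), `status`
#' (0 = censored/alive, 1 = event/dead). Malformed rows raise line-numbered
#' errors (line numbers count the header as line 1).
#'
#' @param path File path.
#' @return `read_clinical`: a data frame.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("patient_id", "time_days", "status")
  if (!all(req %in% names(df)))
    stop(sprintf("%s: required columns: %s", path, paste(req, collapse = ", ")))
  bad <- which(!(df$status %in% c(0L, 1L)))
  if (length(bad) > 0)
    stop(sprintf("%s: line %d: status must be 0 or 1 (got %s)",
                 path, bad[1] + 1L, df$status[bad[1]]))
  bad <- which(!is.finite(df$time_days) | df$time_days <= 0)
  if (length(bad) > 0)
    stop(sprintf("%s: line %d: time_days must be finite and positive",
                 path, bad[1] + 1L))
  df$patient_id <- as.character(df$patient_id)
  df$status <- as.integer(df$status)
  df
}

#' @rdname read_clinical
#' @param clinical Data frame with `patient_id`, `time_days`, `status`.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(clinical[, c("patient_id", "time_days", "status")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write sample class labels
#'
#' Columns: `sample_id`, `class` (`tumor` or `normal`).
#'
#' @param path File path.
#' @return `read_classes`: named character vector, values `tumor`/`normal`.
#' @export
read_classes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "class") %in% names(df)))
    stop(sprintf("%s: required columns: sample_id, class", path))
  bad <- which(!(df$class %in% c("tumor", "normal")))
  if (length(bad) > 0)
    stop(sprintf("%s: line %d: class must be 'tumor' or 'normal'",
                 path, bad[1] + 1L))
  stats::setNames(df$class, as.character(df$sample_id))
}

#' @rdname read_classes
#' @param classes Named character vector as returned by `read_classes`.
#' @export
write_classes <- function(classes, path) {
  utils::write.table(
    data.frame(sample_id = names(classes), class = unname(classes)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write GMT gene-set collections
#'
#' Standard dialect: one set per line, `set_name<TAB>description<TAB>gene...`.
#'
#' @param path File path.
#' @return `read_gmt`: named list of character vectors with a
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop(sprintf("%s: line %d: GMT lines need name, description and >= 1 gene",
                   path, i))
    sets[[f[1]]] <- f[-(1:2)]
    desc[f[1]] <- f[2]
  }
  attr(sets, "descriptions") <- desc
  class(sets) <- "gene_sets"
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors (optionally with a
#'   `descriptions` attribute).
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(s) {
    d <- if (!is.null(desc) && s %in% names(desc)) desc[[s]] else "na"
    paste(c(s, d, sets[[s]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a cohort and truth record to a directory
#'
#' Emits `expression.tsv`, `clinical.tsv`, `classes.tsv` and (when a truth
#' record is given) `truth.json`.
#'
#' @param cohort A [cohort()].
#' @param dir Output directory (created if needed).
#' @param truth Optional `truth_record` from [generate_cohort()].
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir, truth = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  write_clinical(cohort$clinical, file.path(dir, "clinical.tsv"))
  write_classes(cohort$sample_class, file.path(dir, "classes.tsv"))
  if (!is.null(truth)) {
    tr <- list(
      de_genes = truth$de_genes,
      marginal = as.list(truth$marginal),
      interactions = as.list(truth$interactions),
      latent_z = truth$latent_z
    )
    jsonlite::write_json(tr, file.path(dir, "truth.json"),
                         auto_unbox = FALSE, digits = NA, matrix = "rowmajor")
  }
  invisible(dir)
}

#' Read a cohort from a directory of TSV files
#'
#' @param dir Directory holding `expression.tsv`, `clinical.tsv` and
#'   optionally `classes.tsv`.
#' @return A [cohort()].
#' @export
read_cohort <- function(dir) {
  expr <- read_expression(file.path(dir, "expression.tsv"))
  clin <- read_clinical(file.path(dir, "clinical.tsv"))
  cls_path <- file.path(dir, "classes.tsv")
  cls <- if (file.exists(cls_path)) read_classes(cls_path) else NULL
  cohort(expr, clin, cls)
}

#' Read a pipeline configuration file
#'
#' JSON (always available) or YAML (when the `yaml` package is installed),
#' chosen by file extension.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A named list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("read_config: the 'yaml' package is required for YAML configs")
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop(sprintf("read_config: unsupported config extension '.%s'", ext))
  }
}

# result-table writer: tab-separated, "." for undefined numerics
write_result_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) {
      v <- format(out[[j]], trim = TRUE, digits = 15, scientific = FALSE)
      v[is.na(out[[j]])] <- "."
      out[[j]] <- v
    } else if (is.character(out[[j]]) || is.logical(out[[j]])) {
      v <- as.character(out[[j]])
      v[is.na(v)] <- "."
      out[[j]] <- v
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
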