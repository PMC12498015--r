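# Single-gene candidate filters: tumour-vs-normal differential expression,
# survival association under median and quartile cutoffs, and the hazard-ratio
# band, plus a force-include list for genes kept on prior biological evidence.

#' Gene-screen criteria
#'
#' Thresholds for [run_gene_screen()]. A gene passes when its differential
#' expression p-value is below `de_alpha` AND, for at least one enabled
#' cutoff, the log-rank p-value is below `surv_alpha` with a hazard ratio
#' outside the `(hr_low, hr_high)` band (i.e. `HR <= hr_low` or
#' `HR >= hr_high`). Genes in `force_include` are kept regardless.
#'
#' @param de_alpha Differential-expression p threshold (default 0.001).
#' @param surv_alpha Survival log-rank p threshold (default 0.05).
#' @param hr_low,hr_high Hazard-ratio band bounds (defaults 0.8 and 1.2,
#'   inclusive at both bounds).
#' @param cutoffs Subset of `c("median", "quartile")`: which expression
#'   cutoffs are tried for the survival association.
#' @param force_include Character vector of genes kept regardless of filters.
#' @return An object of class `gene_screen_criteria`.
#' @export
gene_screen_criteria <- function(de_alpha = 0.001, surv_alpha = 0.05,
                                 hr_low = 0.8, hr_high = 1.2,
                                 cutoffs = c("median", "quartile"),
                                 force_include = character(0)) {
  stopifnot(de_alpha > 0, de_alpha < 1, surv_alpha > 0, surv_alpha < 1,
            hr_low > 0, hr_low < 1, hr_high > 1)
  cutoffs <- match.arg(cutoffs, c("median", "quartile"), several.ok = TRUE)
  obj <- list(de_alpha = de_alpha, surv_alpha = surv_alpha, hr_low = hr_low,
              hr_high = hr_high, cutoffs = cutoffs,
              force_include = as.character(force_include))
  class(obj) <- "gene_screen_criteria"
  obj
}

#' Tumour-vs-normal differential expression test
#'
#' Unmatched two-sample Mann-Whitney U test of a gene's expression in tumour
#' versus normal samples; the direction is the sign of the tumour-minus-normal
#' median difference.
#'
#' @param gene Gene identifier present in the expression matrix.
#' @param cohort A [cohort()] with at least 3 tumour and 3 normal samples.
#' @return A list with `p_value` and `direction` (`"up"`, `"down"` or
#'   `"none"`, referring to tumour relative to normal).
#' @export
de_test <- function(gene, cohort) {
  stopifnot(inherits(cohort, "cohort"))
  if (!gene %in% rownames(cohort$expression))
    stop(sprintf("de_test: gene %s not in expression matrix", gene))
  ts <- tumor_samples(cohort); ns <- normal_samples(cohort)
  if (length(ns) < 3L)
    stop(sprintf("de_test: gene %s: fewer than 3 normal samples available", gene))
  if (length(ts) < 3L)
    stop(sprintf("de_test: gene %s: fewer than 3 tumor samples available", gene))
  x <- cohort$expression[gene, ts]
  y <- cohort$expression[gene, ns]
  mw <- mann_whitney(x, y)
  d <- stats::median(x) - stats::median(y)
  direction <- if (d > 0) "up" else if (d < 0) "down" else "none"
  list(p_value = mw$p_value, direction = direction)
}

#' Single-gene survival association
#'
#' Median cutoff: patients are split at the gene's median expression (ties to
#' the low-expression group) and compared by log-rank, with the O/E hazard
#' ratio of high vs low. Quartile cutoff: only the highest (Q1) and lowest
#' (Q4) expression quartiles are compared (middle half excluded), with the
#' hazard ratio of Q1 vs Q4.
#'
#' @param gene Gene identifier.
#' @param cohort A [cohort()] with at least 8 patients with outcomes.
#' @param cutoff `"median"` or `"quartile"`.
#' @return A list with `p_value`, `hr` (high-expression vs low-expression
#'   O/E hazard ratio; `NA` when undefined), `hr_defined`, and `n` used.
#' @export
survival_association <- function(gene, cohort, cutoff = c("median", "quartile")) {
  stopifnot(inherits(cohort, "cohort"))
  cutoff <- match.arg(cutoff)
  cl <- cohort$clinical
  if (nrow(cl) < 8L) stop("survival_association: need at least 8 patients")
  vals <- patient_expression(cohort, gene)

  if (cutoff == "median") {
    med <- stats::median(vals)
    grp <- ifelse(vals <= med, "low", "high")
    keep <- rep(TRUE, length(grp))
  } else {
    qb <- quartile_bins(vals, gene)
    keep <- qb$bins %in% c("Q1", "Q4")
    grp <- ifelse(qb$bins == "Q1", "high", "low")
  }
  grp <- grp[keep]
  times <- cl$time_days[keep]
  status <- cl$status[keep]

  if (length(unique(grp)) < 2L || sum(status) == 0L)
    return(list(p_value = 1, hr = NA_real_, hr_defined = FALSE, n = sum(keep)))

  lr <- logrank(grp, times, status)
  hr <- hazard_ratio_oe(grp, times, status, group_a = "high", group_b = "low")
  list(p_value = lr$p_value, hr = hr$hr, hr_defined = hr$defined, n = sum(keep))
}

#' Run the single-gene candidate screen
#'
#' Applies the differential-expression filter, the survival-association
#' filter under the enabled cutoffs, and the hazard-ratio band to each gene.
#' Force-included genes are marked `forced` and pass regardless of their
#' statistics. When the cohort carries no normal samples the DE stage is
#' skipped (all `de_p` set to `NA`) and the DE condition is waived, with a
#' message.
#'
#' @param genes Character vector of gene identifiers (all must be present).
#' @param cohort A [cohort()].
#' @param criteria A [gene_screen_criteria()].
#' @return A data frame with one row per gene: `gene`, `de_p`,
#'   `de_direction`, `surv_p_median`, `hr_median`, `surv_p_quartile`,
#'   `hr_quartile`, `passed`, `forced`.
#' @export
run_gene_screen <- function(genes, cohort, criteria = gene_screen_criteria()) {
  stopifnot(inherits(cohort, "cohort"), inherits(criteria, "gene_screen_criteria"))
  genes <- as.character(genes)
  missing <- setdiff(genes, rownames(cohort$expression))
  if (length(missing) > 0)
    stop(sprintf("run_gene_screen: unknown gene ids: %s",
                 paste(missing, collapse = ", ")))

  have_normals <- length(normal_samples(cohort)) >= 3L
  if (!have_normals)
    message("run_gene_screen: no usable normal samples; DE stage skipped")

  res <- lapply(genes, function(g) {
    de_p <- NA_real_; de_dir <- NA_character_
    if (have_normals) {
      de <- de_test(g, cohort)
      de_p <- de$p_value; de_dir <- de$direction
    }
    row <- list(gene = g, de_p = de_p, de_direction = de_dir,
                surv_p_median = NA_real_, hr_median = NA_real_,
                surv_p_quartile = NA_real_, hr_quartile = NA_real_)
    for (cut in c("median", "quartile")) {
      if (!cut %in% criteria$cutoffs) next
      sa <- survival_association(g, cohort, cut)
      row[[paste0("surv_p_", cut)]] <- sa$p_value
      row[[paste0("hr_", cut)]] <- sa$hr
    }
    row
  })

  df <- do.call(rbind, lapply(res, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  df$forced <- df$gene %in% criteria$force_include
  df$passed <- vapply(seq_len(nrow(df)), function(i)
    gene_passes(df[i, ], criteria, have_normals), logical(1))
  df$passed <- df$passed | df$forced
  rownames(df) <- NULL
  df
}

# pure evaluation of the conjunction rule on one row of statistics
gene_passes <- function(row, criteria, have_normals = TRUE) {
  de_ok <- if (have_normals) isTRUE(row$de_p < criteria$de_alpha) else TRUE
  if (!de_ok) return(FALSE)
  surv_ok <- FALSE
  for (cut in criteria$cutoffs) {
    p <- row[[paste0("surv_p_", cut)]]
    hr <- row[[paste0("hr_", cut)]]
    if (is.na(p) || is.na(hr)) next
    band_out <- hr <= criteria$hr_low || hr >= criteria$hr_high
    if (p < criteria$surv_alpha && band_out) surv_ok <- TRUE
  }
  surv_ok
}
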