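# End-to-end pipeline: simulate-or-load -> gene screen -> pair screen ->
# correlated genes -> enrichment -> overlap -> report. Every stage logs the
# thresholds it applied; all outputs are deterministic given the seed (no
# timestamps), so repeated runs are byte-identical.

pipeline_defaults <- function() {
  list(
    expression = NULL, clinical = NULL, classes = NULL, gmt = NULL,
    simulate = NULL, genes = NULL,
    de_alpha = 0.001, surv_alpha = 0.05, hr_low = 0.8, hr_high = 1.2,
    cutoffs = c("median", "quartile"), force_include = character(0),
    horizon_days = 1825, min_cell_n = 5, hr_diff_threshold = 0.10,
    hr_diff_mode = "relative", trend_tol = 0,
    r_threshold = 0.3, same_sign = FALSE,
    min_set = 10, fdr_cut = 0.05, top_n = 10, min_pairs = 3,
    seed = 1
  )
}

#' Validate a pipeline configuration
#'
#' Fills defaults and rejects unknown keys and out-of-range thresholds.
#'
#' @param config Named list (e.g. from [read_config()]). Recognised keys are
#'   the input paths (`expression`, `clinical`, `classes`, `gmt`), an inline
#'   `simulate` block of [sim_config()] arguments, an optional `genes`
#'   restriction, all module thresholds (`de_alpha`, `surv_alpha`, `hr_low`,
#'   `hr_high`, `cutoffs`, `force_include`, `horizon_days`, `min_cell_n`,
#'   `hr_diff_threshold`, `hr_diff_mode`, `trend_tol`, `r_threshold`,
#'   `same_sign`, `min_set`, `fdr_cut`, `top_n`, `min_pairs`) and `seed`.
#' @return The completed configuration, classed `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0)
    stop(sprintf("pipeline_config: unknown keys: %s",
                 paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  stopifnot(cfg$de_alpha > 0, cfg$de_alpha < 1,
            cfg$surv_alpha > 0, cfg$surv_alpha < 1,
            cfg$hr_low > 0, cfg$hr_low < 1, cfg$hr_high > 1,
            cfg$horizon_days > 0, cfg$min_cell_n >= 1,
            cfg$hr_diff_threshold >= 0,
            cfg$hr_diff_mode %in% c("relative", "absolute"),
            cfg$trend_tol >= 0, cfg$r_threshold >= 0,
            cfg$min_set >= 1, cfg$fdr_cut > 0, cfg$fdr_cut <= 1,
            cfg$top_n >= 1, cfg$min_pairs >= 1)
  if (is.null(cfg$simulate) && (is.null(cfg$expression) || is.null(cfg$clinical)))
    stop("pipeline_config: either a 'simulate' block or expression+clinical paths are required")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full co-dysregulation screening pipeline
#'
#' Executes, in order: cohort acquisition (simulation or file input), the
#' single-gene screen, the gene-pair screen, correlated-gene discovery for
#' every selected pair, gene-set enrichment (when a GMT is supplied), and
#' the multi-pair overlap. Writes one TSV per stage plus `summary.json`
#' (machine-readable counts) and `pipeline.log` (every threshold applied)
#' into `out_dir`. Output is byte-identical across repeated runs with the
#' same configuration.
#'
#' @param config A [pipeline_config()] or plain list of its arguments.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with all stage results and the summary.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }

  # --- stage 1: cohort -------------------------------------------------
  truth <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    scfg <- do.call(sim_config, sim_args)
    say("stage cohort: simulating %d patients x %d genes (seed %d)",
        scfg$n_patients, scfg$n_genes, scfg$seed)
    sim <- generate_cohort(scfg)
    coh <- sim$cohort; truth <- sim$truth
    write_cohort(coh, file.path(out_dir, "cohort"), truth)
  } else {
    say("stage cohort: reading expression=%s clinical=%s",
        config$expression, config$clinical)
    expr <- read_expression(config$expression)
    clin <- read_clinical(config$clinical)
    cls <- if (!is.null(config$classes)) read_classes(config$classes) else NULL
    coh <- cohort(expr, clin, cls)
  }

  genes <- if (!is.null(config$genes)) as.character(config$genes)
           else rownames(coh$expression)

  # --- stage 2: gene screen -------------------------------------------
  crit <- gene_screen_criteria(
    de_alpha = config$de_alpha, surv_alpha = config$surv_alpha,
    hr_low = config$hr_low, hr_high = config$hr_high,
    cutoffs = config$cutoffs, force_include = config$force_include)
  say("stage gene_screen: de_alpha=%g surv_alpha=%g hr_band=[%g,%g] cutoffs=%s",
      crit$de_alpha, crit$surv_alpha, crit$hr_low, crit$hr_high,
      paste(crit$cutoffs, collapse = "+"))
  if (length(normal_samples(coh)) < 3L)
    say("stage gene_screen: no usable normal samples; DE stage skipped")
  gs <- suppressMessages(run_gene_screen(genes, coh, crit))
  write_result_tsv(gs, file.path(out_dir, "genes.tsv"))
  passed <- gs$gene[gs$passed]
  say("stage gene_screen: %d/%d genes passed", length(passed), nrow(gs))

  # --- stage 3: pair screen -------------------------------------------
  pairs <- NULL
  sel_pairs <- character(0)
  if (length(passed) >= 2L) {
    say("stage pair_screen: horizon=%g days, min_cell_n=%d, hr_diff>=%g (%s), trend_tol=%g",
        config$horizon_days, as.integer(config$min_cell_n),
        config$hr_diff_threshold, config$hr_diff_mode, config$trend_tol)
    pairs <- run_pair_screen(passed, coh, horizon = config$horizon_days,
                             min_cell_n = config$min_cell_n,
                             hr_diff_threshold = config$hr_diff_threshold,
                             hr_diff_mode = config$hr_diff_mode,
                             trend_tol = config$trend_tol, keep_grids = TRUE)
    grids <- attr(pairs, "grids")
    write_result_tsv(pairs, file.path(out_dir, "pairs.tsv"))
    grid_export <- lapply(grids, function(g) list(
      factor_gene = g$factor_gene, strata_gene = g$strata_gene,
      s5 = g$s5, cell_n = g$cell_n, defined = g$defined))
    jsonlite::write_json(grid_export, file.path(out_dir, "pair_grids.json"),
                         auto_unbox = TRUE, digits = NA, matrix = "rowmajor",
                         pretty = TRUE)
    sel <- pairs[pairs$selected, , drop = FALSE]
    sel_pairs <- paste(sel$gene_a, sel$gene_b, sep = "|")
    say("stage pair_screen: %d/%d pairs selected (%d reduced, %d increased)",
        nrow(sel), nrow(pairs),
        sum(sel$survival_direction == "reduced"),
        sum(sel$survival_direction == "increased"))
  } else {
    say("stage pair_screen: skipped (fewer than 2 passed genes)")
  }

  # --- stage 4: correlated genes --------------------------------------
  corr_sets <- list()
  if (length(sel_pairs) > 0L) {
    say("stage correlate: |r| > %g with both pair members (tumor samples)",
        config$r_threshold)
    sel <- pairs[pairs$selected, , drop = FALSE]
    corr_dir <- file.path(out_dir, "correlated")
    dir.create(corr_dir, showWarnings = FALSE)
    for (i in seq_len(nrow(sel))) {
      cs <- suppressMessages(correlated_genes(
        c(sel$gene_a[i], sel$gene_b[i]), coh,
        r_threshold = config$r_threshold, same_sign = config$same_sign))
      corr_sets[[paste(cs$pair, collapse = "|")]] <- cs
      write_result_tsv(cs$members,
                       file.path(corr_dir, sprintf("%s_%s.tsv",
                                                   cs$pair[1], cs$pair[2])))
    }
    say("stage correlate: set sizes %s",
        paste(vapply(corr_sets, function(s) nrow(s$members), integer(1)),
              collapse = ","))
  } else {
    say("stage correlate: skipped (no selected pairs)")
  }

  # --- stage 5: enrichment --------------------------------------------
  enrich_results <- list()
  if (length(corr_sets) > 0L && !is.null(config$gmt)) {
    annotation <- if (is.character(config$gmt)) read_gmt(config$gmt) else config$gmt
    background <- rownames(coh$expression)[
      apply(coh$expression[, tumor_samples(coh), drop = FALSE], 1,
            function(v) stats::var(v) > 0)]
    say("stage enrich: min_set=%d fdr<%g top_n=%d background=%d genes",
        as.integer(config$min_set), config$fdr_cut,
        as.integer(config$top_n), length(background))
    enr_dir <- file.path(out_dir, "enrichment")
    dir.create(enr_dir, showWarnings = FALSE)
    for (lab in names(corr_sets)) {
      q <- intersect(corr_sets[[lab]]$members$gene, background)
      tab <- withCallingHandlers(
        enrich(q, annotation, background, min_set = config$min_set,
               fdr_cut = config$fdr_cut, top_n = config$top_n),
        warning = function(w) invokeRestart("muffleWarning"))
      enrich_results[[lab]] <- tab
      write_result_tsv(tab, file.path(enr_dir, paste0(gsub("\\|", "_", lab), ".tsv")))
    }
  } else {
    say("stage enrich: skipped (%s)",
        if (is.null(config$gmt)) "no annotation supplied" else "no correlated sets")
  }

  # --- stage 6: overlap ------------------------------------------------
  overlap <- NULL
  if (length(corr_sets) >= config$min_pairs) {
    say("stage overlap: genes shared by >= %d pairs", as.integer(config$min_pairs))
    overlap <- overlap_sets(unname(corr_sets), min_pairs = config$min_pairs)
    write_result_tsv(overlap, file.path(out_dir, "overlap.tsv"))
  } else {
    say("stage overlap: skipped (fewer than %d correlated sets)",
        as.integer(config$min_pairs))
  }

  # --- report ----------------------------------------------------------
  summary <- list(
    n_genes_screened = nrow(gs),
    n_genes_passed = length(passed),
    n_pairs_evaluated = if (is.null(pairs)) 0L else nrow(pairs),
    n_pairs_selected = length(sel_pairs),
    n_pairs_reduced = if (is.null(pairs)) 0L else
      sum(pairs$selected & pairs$survival_direction == "reduced"),
    n_pairs_increased = if (is.null(pairs)) 0L else
      sum(pairs$selected & pairs$survival_direction == "increased"),
    correlated_set_sizes = lapply(corr_sets, function(s) nrow(s$members)),
    n_overlap_genes = if (is.null(overlap)) 0L else nrow(overlap),
    thresholds = config[c("de_alpha", "surv_alpha", "hr_low", "hr_high",
                          "horizon_days", "min_cell_n", "hr_diff_threshold",
                          "hr_diff_mode", "trend_tol", "r_threshold",
                          "min_set", "fdr_cut", "min_pairs")],
    seed = config$seed
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "pipeline.log"))

  invisible(list(cohort = coh, truth = truth, gene_screen = gs, pairs = pairs,
                 correlated = corr_sets, enrichment = enrich_results,
                 overlap = overlap, summary = summary))
}
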