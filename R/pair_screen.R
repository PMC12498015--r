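# Quartile-within-strata gene-pair survival screen.
#
# For an ordered pair (factor gene, strata gene) the cohort is cut into the
# 4 x 4 grid of expression quartiles; within each strata-gene quartile the
# factor gene's quartiles define four Kaplan-Meier curves, each summarised by
# its cumulative survival at the prognosis horizon (default 5 years = 1825
# days). A monotone 5-year-survival trend across factor quartiles inside the
# strata-high (Q1) or strata-low (Q4) subpopulation, concordant between the
# two orderings of the pair, plus a difference of at least 10% between the
# two strata-conditional Q1-vs-Q4 hazard ratios, selects the pair.

#' Quartile-by-strata survival grid for an ordered gene pair
#'
#' Computes the full 4 x 4 grid of 5-year survival estimates: factor-gene
#' quartiles (rows, Q1 = highest expression) crossed with strata-gene
#' quartiles (columns). Selection downstream uses only the strata-Q1 and
#' strata-Q4 columns; the middle columns are computed for completeness.
#'
#' @param factor_gene,strata_gene Gene identifiers.
#' @param cohort A [cohort()].
#' @param horizon Prognosis horizon in days (default 1825 = 5 years).
#' @param min_cell_n Cells with fewer patients are flagged undefined
#'   (default 5).
#' @param bins_factor,bins_strata Optional precomputed [quartile_bins()]
#'   objects (over the cohort's patients, in clinical order), to avoid
#'   recomputation when screening many pairs.
#' @return An object of class `pair_grid`: matrices `s5`, `cell_n`,
#'   `defined` (4 x 4, rows = factor quartiles, cols = strata quartiles),
#'   the two bin assignments, `marginal_s5` (cohort-wide survival at the
#'   horizon), and the call parameters.
#' @export
pair_grid <- function(factor_gene, strata_gene, cohort, horizon = 1825,
                      min_cell_n = 5L, bins_factor = NULL, bins_strata = NULL) {
  stopifnot(inherits(cohort, "cohort"), horizon > 0, min_cell_n >= 1L)
  cl <- cohort$clinical
  if (is.null(bins_factor))
    bins_factor <- quartile_bins(patient_expression(cohort, factor_gene), factor_gene)
  if (is.null(bins_strata))
    bins_strata <- quartile_bins(patient_expression(cohort, strata_gene), strata_gene)

  # rows: factor-gene quartiles; columns: strata-gene quartiles
  qs <- c("Q1", "Q2", "Q3", "Q4")
  s5 <- matrix(NA_real_, 4, 4, dimnames = list(qs, qs))
  cell_n <- matrix(0L, 4, 4, dimnames = list(qs, qs))
  defined <- matrix(FALSE, 4, 4, dimnames = list(qs, qs))

  for (j in qs) {
    in_stratum <- bins_strata$bins == j
    for (i in qs) {
      sel <- in_stratum & bins_factor$bins == i
      n_cell <- sum(sel)
      cell_n[i, j] <- n_cell
      if (n_cell == 0L) next
      curve <- suppressWarnings(km_fit(cl$time_days[sel], cl$status[sel]))
      sa <- survival_at(curve, horizon)
      s5[i, j] <- sa$estimate
      defined[i, j] <- n_cell >= min_cell_n && sa$defined
    }
  }

  marg <- survival_at(suppressWarnings(km_fit(cl$time_days, cl$status)), horizon)
  obj <- list(factor_gene = factor_gene, strata_gene = strata_gene,
              horizon = horizon, min_cell_n = as.integer(min_cell_n),
              s5 = s5, cell_n = cell_n, defined = defined,
              bins_factor = bins_factor, bins_strata = bins_strata,
              marginal_s5 = marg$estimate)
  class(obj) <- "pair_grid"
  obj
}

#' @export
print.pair_grid <- function(x, ...) {
  cat(sprintf("Pair grid: factor %s x strata %s, horizon %g days\n",
              x$factor_gene, x$strata_gene, x$horizon))
  print(round(x$s5, 3))
  invisible(x)
}

#' Classify a monotone survival trend across factor quartiles
#'
#' A column of four 5-year survival values, ordered factor Q1 (highest
#' expression) to Q4 (lowest), is `"decreasing"` when every successive value
#' drops by more than `tol`, `"increasing"` when every successive value rises
#' by more than `tol`, and `"none"` otherwise. Any undefined value yields
#' `"none"` (with an `incomplete` attribute).
#'
#' @param s5_column Numeric vector of length 4 (factor Q1..Q4).
#' @param tol Non-negative tolerance; the default 0 demands strict
#'   monotonicity of all four points.
#' @return `"decreasing"`, `"increasing"` or `"none"`.
#' @export
classify_trend <- function(s5_column, tol = 0) {
  stopifnot(length(s5_column) == 4L, tol >= 0)
  if (anyNA(s5_column)) {
    out <- "none"
    attr(out, "incomplete") <- TRUE
    return(out)
  }
  d <- diff(s5_column)
  if (all(d < -tol)) return("decreasing")
  if (all(d > tol)) return("increasing")
  "none"
}

# Read one qualifying stratum column: which expression combination it
# implicates, the survival direction, and the scenario.
#
# The column spans the factor-high (Q1) and factor-low (Q4) extremes inside a
# fixed stratum level; a monotone column therefore exhibits a worst and a
# best combination. Which of the two the screen reports ("reduced" survival
# at the worst cell vs "increased" survival at the best cell) is decided by
# which end deviates further from the cohort's marginal survival at the
# horizon. A combination where both genes are low is re-read from the other
# end of the same column (both-low and its opposite end describe the same
# monotone pattern), so every qualifying column maps onto one of the four
# canonical scenarios:
#   i  : reduced survival, one gene high and the other low
#   ii : reduced survival, both genes high
#   iii: increased survival, one gene high and the other low
#   iv : increased survival, both genes high
read_column <- function(s5_column, trend, stratum_level, marginal_s5) {
  if (trend == "none") return(NULL)
  if (trend == "decreasing") {
    worst <- list(value = s5_column[4], factor_level = "low")
    best <- list(value = s5_column[1], factor_level = "high")
  } else {
    worst <- list(value = s5_column[1], factor_level = "high")
    best <- list(value = s5_column[4], factor_level = "low")
  }
  dev_red <- marginal_s5 - worst$value
  dev_inc <- best$value - marginal_s5
  if (dev_red >= dev_inc) {
    direction <- "reduced"; combo <- c(worst$factor_level, stratum_level)
    strength <- dev_red
  } else {
    direction <- "increased"; combo <- c(best$factor_level, stratum_level)
    strength <- dev_inc
  }
  if (all(combo == "low")) { # fold both-low onto the opposite end
    if (direction == "reduced") {
      direction <- "increased"; combo <- c(best$factor_level, stratum_level)
      strength <- dev_inc
    } else {
      direction <- "reduced"; combo <- c(worst$factor_level, stratum_level)
      strength <- dev_red
    }
  }
  scenario <- if (direction == "reduced") {
    if (all(combo == "high")) "ii" else "i"
  } else {
    if (all(combo == "high")) "iv" else "iii"
  }
  list(direction = direction, scenario = scenario, strength = strength,
       stratum_level = stratum_level, trend = trend)
}

#' Classify the scenario of one ordering of a gene pair
#'
#' Examines the strata-high (Q1) and strata-low (Q4) columns of a
#' [pair_grid()]: each column with a monotone trend implicates an expression
#' combination and a survival direction (see the vignette for the mapping).
#' When both columns qualify with agreeing directions, the stronger column's
#' scenario is reported; a disagreement is resolved in favour of the column
#' whose implicated cell deviates further from the cohort's marginal
#' survival, and an exact tie yields `"none"`.
#'
#' @param grid A `pair_grid`.
#' @param tol Trend tolerance passed to [classify_trend()].
#' @return A list with `direction` (`"reduced"`, `"increased"` or `"none"`),
#'   `scenario` (`"i"`..`"iv"` or `"none"`), `trend_high`, `trend_low` (the
#'   per-stratum trends), and `strength`.
#' @export
classify_scenario <- function(grid, tol = 0) {
  stopifnot(inherits(grid, "pair_grid"))
  cols <- list(high = "Q1", low = "Q4")
  reads <- list()
  trends <- list(high = "none", low = "none")
  for (lev in names(cols)) {
    col <- grid$s5[, cols[[lev]]]
    col[!grid$defined[, cols[[lev]]]] <- NA_real_
    tr <- classify_trend(col, tol)
    trends[[lev]] <- as.character(tr)
    rd <- read_column(col, as.character(tr), lev, grid$marginal_s5)
    if (!is.null(rd)) reads[[length(reads) + 1L]] <- rd
  }
  if (length(reads) == 0L) {
    out <- list(direction = "none", scenario = "none", strength = 0)
  } else if (length(reads) == 1L) {
    out <- reads[[1L]]
  } else {
    dirs <- vapply(reads, `[[`, character(1), "direction")
    strengths <- vapply(reads, `[[`, numeric(1), "strength")
    if (dirs[1] == dirs[2] || strengths[1] != strengths[2]) {
      out <- reads[[which.max(strengths)]]
    } else {
      out <- list(direction = "none", scenario = "none", strength = 0)
    }
  }
  list(direction = out$direction, scenario = out$scenario,
       strength = out$strength,
       trend_high = trends$high, trend_low = trends$low)
}

#' Strata-conditional hazard-ratio difference
#'
#' Within each extreme stratum (strata gene Q1 and Q4), computes the O/E
#' hazard ratio of the factor gene's highest (Q1) vs lowest (Q4) expression
#' quartile, and their difference: relative (`|hr_q1 - hr_q4| /
#' min(hr_q1, hr_q4)`, the default) or absolute (`|hr_q1 - hr_q4|`).
#'
#' @param grid A [pair_grid()].
#' @param cohort The [cohort()] the grid was computed on.
#' @param mode `"relative"` or `"absolute"`.
#' @return A list with `hr_q1`, `hr_q4` (each an `hr_result` or `NULL`),
#'   `hr_rel_diff` (`NA` when either HR is undefined), `defined`, and
#'   `reason` when undefined.
#' @export
hr_difference <- function(grid, cohort, mode = c("relative", "absolute")) {
  stopifnot(inherits(grid, "pair_grid"), inherits(cohort, "cohort"))
  mode <- match.arg(mode)
  cl <- cohort$clinical
  hrs <- list()
  for (stratum in c("Q1", "Q4")) {
    sel <- grid$bins_strata$bins == stratum & grid$bins_factor$bins %in% c("Q1", "Q4")
    grp <- ifelse(grid$bins_factor$bins[sel] == "Q1", "high", "low")
    times <- cl$time_days[sel]; status <- cl$status[sel]
    if (length(unique(grp)) < 2L || sum(status) == 0L) {
      hrs[[stratum]] <- NULL
    } else {
      hrs[[stratum]] <- hazard_ratio_oe(grp, times, status,
                                        group_a = "high", group_b = "low")
    }
  }
  h1 <- hrs[["Q1"]]; h4 <- hrs[["Q4"]]
  ok <- !is.null(h1) && !is.null(h4) && h1$defined && h4$defined
  if (!ok) {
    return(list(hr_q1 = h1, hr_q4 = h4, hr_rel_diff = NA_real_,
                defined = FALSE, reason = "undefined HR in at least one stratum"))
  }
  diffval <- if (mode == "relative") {
    abs(h1$hr - h4$hr) / min(h1$hr, h4$hr)
  } else {
    abs(h1$hr - h4$hr)
  }
  list(hr_q1 = h1, hr_q4 = h4, hr_rel_diff = diffval, defined = TRUE,
       reason = NA_character_)
}

#' Run the gene-pair survival screen
#'
#' Evaluates every unordered pair of the supplied genes in both orderings
#' (each gene as factor within the other's extreme strata). A pair is
#' `concordant` when both orderings yield the same non-`"none"` survival
#' direction, and `selected` when it is concordant and the strata-conditional
#' hazard-ratio difference (computed on the lexicographically first ordering)
#' meets `hr_diff_threshold` (boundary inclusive). Output order is
#' deterministic: lexicographic by gene ids, regardless of input order.
#'
#' @param genes Character vector (>= 2) of usable genes.
#' @param cohort A [cohort()].
#' @param horizon Prognosis horizon in days (default 1825).
#' @param min_cell_n Minimum patients per grid cell (default 5).
#' @param hr_diff_threshold Minimum HR difference (default 0.10).
#' @param hr_diff_mode `"relative"` (default) or `"absolute"`; see
#'   [hr_difference()].
#' @param trend_tol Trend tolerance (default 0 = strict monotonicity).
#' @param keep_grids When `TRUE`, attach the full per-ordering grids as the
#'   `grids` attribute (named `"A|B"` for factor A within strata of B).
#' @return A data frame, one row per unordered pair: `gene_a`, `gene_b`
#'   (sorted), per-ordering trends (`trend_ab_high`, `trend_ab_low`,
#'   `trend_ba_high`, `trend_ba_low`), per-ordering directions (`dir_ab`,
#'   `dir_ba`), `scenario`, `survival_direction`, `hr_q1`, `hr_q4`,
#'   `hr_rel_diff`, `concordant`, `selected`, `excluded_reason`.
#' @export
run_pair_screen <- function(genes, cohort, horizon = 1825, min_cell_n = 5L,
                            hr_diff_threshold = 0.10,
                            hr_diff_mode = c("relative", "absolute"),
                            trend_tol = 0, keep_grids = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  hr_diff_mode <- match.arg(hr_diff_mode)
  genes <- sort(unique(as.character(genes)))
  missing <- setdiff(genes, rownames(cohort$expression))
  if (length(missing) > 0)
    stop(sprintf("run_pair_screen: unknown gene ids: %s",
                 paste(missing, collapse = ", ")))
  if (length(genes) < 2L) stop("run_pair_screen: need at least 2 usable genes")

  bins <- lapply(genes, function(g)
    quartile_bins(patient_expression(cohort, g), g))
  names(bins) <- genes

  grids <- list()
  rows <- list()
  for (ia in seq_len(length(genes) - 1L)) {
    for (ib in seq.int(ia + 1L, length(genes))) {
      a <- genes[ia]; b <- genes[ib]
      g_ab <- pair_grid(a, b, cohort, horizon, min_cell_n,
                        bins_factor = bins[[a]], bins_strata = bins[[b]])
      g_ba <- pair_grid(b, a, cohort, horizon, min_cell_n,
                        bins_factor = bins[[b]], bins_strata = bins[[a]])
      sc_ab <- classify_scenario(g_ab, trend_tol)
      sc_ba <- classify_scenario(g_ba, trend_tol)
      concordant <- sc_ab$direction != "none" && sc_ab$direction == sc_ba$direction
      hd <- hr_difference(g_ab, cohort, hr_diff_mode)

      selected <- concordant && hd$defined && hd$hr_rel_diff >= hr_diff_threshold
      reason <- if (concordant && !hd$defined) hd$reason else NA_character_

      rows[[length(rows) + 1L]] <- data.frame(
        gene_a = a, gene_b = b,
        trend_ab_high = sc_ab$trend_high, trend_ab_low = sc_ab$trend_low,
        trend_ba_high = sc_ba$trend_high, trend_ba_low = sc_ba$trend_low,
        dir_ab = sc_ab$direction, dir_ba = sc_ba$direction,
        scenario = if (concordant) sc_ab$scenario else "none",
        survival_direction = if (concordant) sc_ab$direction else "none",
        hr_q1 = if (!is.null(hd$hr_q1)) hd$hr_q1$hr else NA_real_,
        hr_q4 = if (!is.null(hd$hr_q4)) hd$hr_q4$hr else NA_real_,
        hr_rel_diff = hd$hr_rel_diff,
        concordant = concordant, selected = selected,
        excluded_reason = reason, stringsAsFactors = FALSE
      )
      if (keep_grids) {
        grids[[paste(a, b, sep = "|")]] <- g_ab
        grids[[paste(b, a, sep = "|")]] <- g_ba
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (keep_grids) attr(out, "grids") <- grids
  out
}
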