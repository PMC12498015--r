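# Downstream characterisation of selected pairs: correlated-gene discovery,
# hypergeometric gene-set enrichment with BH FDR, and multi-pair overlap.

#' Genes correlated with both members of a pair
#'
#' Scans every other gene in the expression matrix and keeps those whose
#' Pearson correlation with each pair member exceeds the threshold in
#' absolute value (strictly: `r > threshold` or `r < -threshold`,
#' independently per member unless `same_sign`). Correlations are computed
#' over tumour samples only by default. Regulation tags (up/down in tumour)
#' come from tumour-vs-normal median differences when at least 3 normal
#' samples exist; otherwise the sign consensus of the two correlations is
#' used and flagged as such (`regulation_source = "correlation_sign"`,
#' mixed signs tagged `"discordant"`).
#'
#' @param pair Character vector of two gene identifiers.
#' @param cohort A [cohort()] with at least 3 tumour samples.
#' @param r_threshold Correlation magnitude threshold (default 0.3,
#'   exclusive).
#' @param same_sign Require the two correlations to share a sign
#'   (default `FALSE`: each clears the threshold independently).
#' @param samples `"tumor"` (default) or `"all"`.
#' @return An object of class `correlated_set`: `pair`, `members` (data
#'   frame `gene`, `r_a`, `r_b`, `regulation`), `n_skipped_zero_var`,
#'   `regulation_source`, `r_threshold`.
#' @export
correlated_genes <- function(pair, cohort, r_threshold = 0.3,
                             same_sign = FALSE,
                             samples = c("tumor", "all")) {
  stopifnot(inherits(cohort, "cohort"), length(pair) == 2L,
            r_threshold >= 0)
  samples <- match.arg(samples)
  missing <- setdiff(pair, rownames(cohort$expression))
  if (length(missing) > 0)
    stop(sprintf("correlated_genes: unknown gene ids: %s",
                 paste(missing, collapse = ", ")))
  cols <- if (samples == "tumor") tumor_samples(cohort)
          else colnames(cohort$expression)
  if (length(cols) < 3L) stop("correlated_genes: need at least 3 samples")

  expr <- cohort$expression[, cols, drop = FALSE]
  xa <- expr[pair[1], ]; xb <- expr[pair[2], ]
  others <- setdiff(rownames(expr), pair)

  use_de <- length(normal_samples(cohort)) >= 3L
  reg_source <- if (use_de) "de_test" else "correlation_sign"

  n_skip <- 0L
  keep <- list()
  for (g in others) {
    v <- expr[g, ]
    if (stats::var(v) == 0) { n_skip <- n_skip + 1L; next }
    r_a <- suppressWarnings(pearson_r(v, xa))
    r_b <- suppressWarnings(pearson_r(v, xb))
    if (is.na(r_a) || is.na(r_b)) { n_skip <- n_skip + 1L; next }
    pass <- abs(r_a) > r_threshold && abs(r_b) > r_threshold
    if (pass && same_sign) pass <- sign(r_a) == sign(r_b)
    if (!pass) next
    reg <- if (use_de) {
      de_test(g, cohort)$direction
    } else if (r_a > 0 && r_b > 0) "up"
      else if (r_a < 0 && r_b < 0) "down"
      else "discordant"
    keep[[length(keep) + 1L]] <- data.frame(
      gene = g, r_a = r_a, r_b = r_b, regulation = reg,
      stringsAsFactors = FALSE)
  }
  members <- if (length(keep) > 0) do.call(rbind, keep) else
    data.frame(gene = character(0), r_a = numeric(0), r_b = numeric(0),
               regulation = character(0), stringsAsFactors = FALSE)
  members <- members[order(members$gene), , drop = FALSE]
  rownames(members) <- NULL
  obj <- list(pair = sort(pair), members = members,
              n_skipped_zero_var = n_skip, regulation_source = reg_source,
              r_threshold = r_threshold)
  class(obj) <- "correlated_set"
  obj
}

#' @export
print.correlated_set <- function(x, ...) {
  cat(sprintf("Correlated set for pair %s | %s: %d genes (|r| > %g with both; %d zero-variance skipped)\n",
              x$pair[1], x$pair[2], nrow(x$members), x$r_threshold,
              x$n_skipped_zero_var))
  invisible(x)
}

#' Hypergeometric gene-set enrichment
#'
#' Tests each annotation set for over-representation of the query genes with
#' the hypergeometric upper tail (sampling without replacement), after
#' dropping sets with fewer than `min_set` background members. BH FDR is
#' computed across the tested sets; survivors at `fdr < fdr_cut` are reduced
#' to the `top_n` most significant by FDR and sorted by fold enrichment
#' (descending). Fold enrichment is `(k/n_query) / (K/N)`.
#'
#' @param query Character vector of genes, a subset of `background`.
#' @param annotation Named list of gene sets (e.g. from [read_gmt()] or
#'   [generate_annotation()]).
#' @param background Character vector: the gene universe.
#' @param min_set Minimum background-restricted set size tested (default 10).
#' @param fdr_cut FDR threshold (default 0.05).
#' @param top_n Number of most significant survivors kept (default 10).
#' @return A data frame with columns `set_name`, `k`, `n_query`, `K`, `N`,
#'   `fold_enrichment`, `p`, `fdr`, sorted by decreasing fold enrichment.
#'   The unfiltered tested table is attached as attribute `all_tested`.
#' @export
enrich <- function(query, annotation, background, min_set = 10L,
                   fdr_cut = 0.05, top_n = 10L) {
  query <- unique(as.character(query))
  background <- unique(as.character(background))
  if (length(annotation) == 0L) stop("enrich: empty annotation collection")
  bad <- setdiff(query, background)
  if (length(bad) > 0)
    stop(sprintf("enrich: query genes outside the background: %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  empty <- data.frame(set_name = character(0), k = integer(0),
                      n_query = integer(0), K = integer(0), N = integer(0),
                      fold_enrichment = numeric(0), p = numeric(0),
                      fdr = numeric(0), stringsAsFactors = FALSE)
  if (length(query) == 0L) {
    warning("enrich: empty query; no enrichment computed")
    return(empty)
  }

  N <- length(background)
  nq <- length(query)
  rows <- list()
  for (s in names(annotation)) {
    members <- intersect(annotation[[s]], background)
    K <- length(members)
    if (K < min_set) next # dropped before testing
    k <- length(intersect(query, members))
    p <- hypergeom_tail(k, K, nq, N)
    rows[[length(rows) + 1L]] <- data.frame(
      set_name = s, k = k, n_query = nq, K = K, N = N,
      fold_enrichment = (k / nq) / (K / N), p = p,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  tab <- do.call(rbind, rows)
  tab$fdr <- bh_fdr(tab$p)
  all_tested <- tab[order(tab$p, tab$set_name), , drop = FALSE]
  rownames(all_tested) <- NULL

  tab <- tab[tab$fdr < fdr_cut, , drop = FALSE]
  tab <- tab[order(tab$fdr, tab$p, tab$set_name), , drop = FALSE]
  tab <- utils::head(tab, top_n)
  tab <- tab[order(-tab$fold_enrichment, tab$set_name), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "all_tested") <- all_tested
  tab
}

#' Shared correlated genes across multiple pairs
#'
#' Given the correlated sets of several gene pairs, reports every gene that
#' appears in at least `min_pairs` of them, keyed by the exact combination of
#' pairs containing it (a Venn-style decomposition). Regulation tags that
#' conflict across sets are reported as `"discordant"`, never silently
#' resolved.
#'
#' @param correlated_sets List of [correlated_genes()] results (at least
#'   `min_pairs` of them).
#' @param min_pairs Minimum number of sets a gene must appear in
#'   (default 3).
#' @return A data frame with columns `gene`, `regulation`, `n_pairs`,
#'   `combination` (pair labels joined by `";"`), ordered by combination
#'   then gene.
#' @export
overlap_sets <- function(correlated_sets, min_pairs = 3L) {
  stopifnot(min_pairs >= 1L)
  if (length(correlated_sets) < min_pairs)
    stop(sprintf("overlap_sets: need at least %d correlated sets", min_pairs))
  labels <- vapply(correlated_sets, function(s) {
    stopifnot(inherits(s, "correlated_set"))
    paste(s$pair, collapse = "|")
  }, character(1))
  if (anyDuplicated(labels)) stop("overlap_sets: duplicate pair labels")

  gene_hits <- list()
  for (i in seq_along(correlated_sets)) {
    m <- correlated_sets[[i]]$members
    for (j in seq_len(nrow(m))) {
      g <- m$gene[j]
      gene_hits[[g]] <- rbind(gene_hits[[g]],
                              data.frame(pair = labels[i],
                                         regulation = m$regulation[j],
                                         stringsAsFactors = FALSE))
    }
  }
  rows <- list()
  for (g in sort(names(gene_hits))) {
    hits <- gene_hits[[g]]
    if (nrow(hits) < min_pairs) next
    regs <- unique(hits$regulation)
    reg <- if (length(regs) == 1L) regs else "discordant"
    combo <- paste(sort(hits$pair), collapse = ";")
    rows[[length(rows) + 1L]] <- data.frame(
      gene = g, regulation = reg, n_pairs = nrow(hits),
      combination = combo, stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(gene = character(0), regulation = character(0),
               n_pairs = integer(0), combination = character(0),
               stringsAsFactors = FALSE)
  out <- out[order(out$combination, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
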