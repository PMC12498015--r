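# Synthetic survival cohorts with planted effects.
#
# The generator emulates the statistical structure the screens assume:
# log-normal-scale expression with block latent correlation, tumour-vs-normal
# location shifts for designated DE genes, and exponential survival whose
# log-hazard carries marginal gene effects and pairwise interaction effects,
# under independent exponential-plus-administrative censoring. All effects
# enter through latent z-scores so planted hazard ratios are scale-free; the
# downstream screens are quartile/rank based and invariant to monotone
# transforms of the observed scale.

#' Simulation configuration
#'
#' Builds and validates the configuration for [generate_cohort()]. Defaults
#' describe a TCGA-style breast-tumour cohort: 1,098 patients, roughly one
#' adjacent-normal sample per ten tumours, a constant baseline hazard giving
#' about 83% five-year survival, light random censoring, and a ten-year
#' administrative cutoff.
#'
#' @param n_patients Number of tumour patients with outcomes (>= 16 so that
#'   quartiles are non-empty).
#' @param n_genes Number of simulated genes.
#' @param n_normal Number of additional normal-tissue samples (no outcomes).
#' @param baseline_hazard Constant baseline hazard per day (lambda0).
#' @param censor_hazard Random-censoring hazard per day (lambdaC); `0`
#'   disables random censoring, leaving only the administrative cutoff.
#' @param admin_cutoff Administrative censoring time in days; may be `Inf`.
#' @param weibull_shape Weibull shape of the event-time distribution; the
#'   default `1` is the exponential (constant-hazard) model.
#' @param expr_location,expr_scale Log-scale mean and sd of observed
#'   expression, scalar or per-gene vectors.
#' @param corr_blocks List of blocks, each `list(genes = <ids or indices>,
#'   rho = <pairwise latent correlation in (-1, 1)>)`.
#' @param de_effects Named numeric: tumour-vs-normal shift delta on the log
#'   scale per designated DE gene (positive = up in tumour).
#' @param marginal_effects Named numeric: log-hazard slope beta per 1 SD of
#'   latent expression.
#' @param interaction_effects Named numeric: log-hazard coefficient gamma per
#'   unit product of latent z-scores, names of the form `"GENEA:GENEB"`.
#' @param gene_names Optional character vector of gene identifiers.
#' @param seed Integer seed; fully determines the generated cohort.
#' @return A validated object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 1098L, n_genes = 50L, n_normal = 110L,
                       baseline_hazard = 1e-4, censor_hazard = 2e-4,
                       admin_cutoff = 3650, weibull_shape = 1,
                       expr_location = 6, expr_scale = 1,
                       corr_blocks = list(),
                       de_effects = numeric(0),
                       marginal_effects = numeric(0),
                       interaction_effects = numeric(0),
                       gene_names = NULL, seed = 1L) {
  stopifnot(n_patients >= 16L, n_genes >= 1L, n_normal >= 0L,
            baseline_hazard > 0, censor_hazard >= 0,
            admin_cutoff > 0, weibull_shape > 0, all(expr_scale > 0),
            length(seed) == 1L, is.finite(seed))
  if (is.null(gene_names)) {
    gene_names <- sprintf("G%04d", seq_len(n_genes))
  }
  stopifnot(length(gene_names) == n_genes, !anyDuplicated(gene_names))

  resolve_genes <- function(g, what) {
    if (is.numeric(g)) {
      if (any(g < 1 | g > n_genes)) stop(sprintf("%s: gene index out of range", what))
      return(gene_names[g])
    }
    missing <- setdiff(g, gene_names)
    if (length(missing) > 0)
      stop(sprintf("%s: unknown genes: %s", what, paste(missing, collapse = ", ")))
    g
  }

  corr_blocks <- lapply(seq_along(corr_blocks), function(i) {
    b <- corr_blocks[[i]]
    if (is.null(b$genes) || is.null(b$rho))
      stop(sprintf("correlation block %d must have 'genes' and 'rho'", i))
    if (b$rho <= -1 || b$rho >= 1)
      stop(sprintf("correlation block %d: rho must lie in (-1, 1)", i))
    genes <- resolve_genes(b$genes, sprintf("correlation block %d", i))
    m <- length(genes)
    if (m < 2L) stop(sprintf("correlation block %d needs at least 2 genes", i))
    # equicorrelated block is positive definite iff rho > -1/(m-1)
    if (b$rho <= -1 / (m - 1))
      stop(sprintf(
        "correlation block %d implies a non-positive-definite latent covariance (rho = %g, size %d)",
        i, b$rho, m))
    list(genes = genes, rho = b$rho)
  })

  check_named <- function(v, what) {
    if (length(v) == 0L) return(stats::setNames(numeric(0), character(0)))
    if (is.null(names(v)) || any(names(v) == ""))
      stop(sprintf("%s must be a named numeric vector", what))
    resolve_genes(names(v), what)
    v
  }
  de_effects <- check_named(de_effects, "de_effects")
  marginal_effects <- check_named(marginal_effects, "marginal_effects")

  if (length(interaction_effects) > 0L) {
    if (is.null(names(interaction_effects)))
      stop("interaction_effects must be named 'GENEA:GENEB'")
    pairs <- strsplit(names(interaction_effects), ":", fixed = TRUE)
    if (any(lengths(pairs) != 2L))
      stop("interaction_effects names must be 'GENEA:GENEB'")
    for (p in pairs) {
      resolve_genes(p, "interaction_effects")
      if (p[1] == p[2]) stop("interaction_effects: a pair must name two distinct genes")
    }
    # canonicalise unordered pair names
    names(interaction_effects) <- vapply(pairs, function(p)
      paste(sort(p), collapse = ":"), character(1))
    if (anyDuplicated(names(interaction_effects)))
      stop("interaction_effects: duplicate pair after canonical ordering")
  } else {
    interaction_effects <- stats::setNames(numeric(0), character(0))
  }

  cfg <- list(
    n_patients = as.integer(n_patients), n_genes = as.integer(n_genes),
    n_normal = as.integer(n_normal), baseline_hazard = baseline_hazard,
    censor_hazard = censor_hazard, admin_cutoff = admin_cutoff,
    weibull_shape = weibull_shape,
    expr_location = rep_len(expr_location, n_genes),
    expr_scale = rep_len(expr_scale, n_genes),
    corr_blocks = corr_blocks, de_effects = de_effects,
    marginal_effects = marginal_effects,
    interaction_effects = interaction_effects,
    gene_names = gene_names, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

# Latent gene-gene correlation matrix from the block structure; the global
# Cholesky check catches non-PD combinations of overlapping blocks.
latent_sigma <- function(cfg) {
  G <- cfg$n_genes
  Sigma <- diag(G)
  dimnames(Sigma) <- list(cfg$gene_names, cfg$gene_names)
  for (i in seq_along(cfg$corr_blocks)) {
    b <- cfg$corr_blocks[[i]]
    idx <- match(b$genes, cfg$gene_names)
    Sigma[idx, idx] <- b$rho
    diag(Sigma)[idx] <- 1
  }
  R <- tryCatch(chol(Sigma), error = function(e)
    stop("correlation blocks jointly imply a non-positive-definite latent covariance",
         call. = FALSE))
  list(Sigma = Sigma, chol = R)
}

#' Generate a synthetic cohort with planted effects
#'
#' Draws latent standard-normal expression scores with the configured block
#' correlation, maps them to a log-normal observed scale (normal samples
#' shifted by `-delta` for DE genes), and simulates survival from a
#' proportional-hazards model whose log-hazard is
#' `log(lambda0) + sum(beta_g z_g) + sum(gamma_gh z_g z_h)`. Censoring is the
#' minimum of an independent exponential draw and the administrative cutoff.
#' The same seed always reproduces the identical cohort.
#'
#' @param config A [sim_config()] object.
#' @return A list with components `cohort` (a [cohort()] object) and `truth`
#'   (class `truth_record`: `de_genes`, `marginal`, `interactions`, and the
#'   `latent_z` matrix used in the hazard, patients x genes).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  sig <- latent_sigma(cfg)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(cfg$seed)

  n <- cfg$n_patients; G <- cfg$n_genes
  z <- matrix(stats::rnorm(n * G), n, G) %*% sig$chol
  patient_ids <- sprintf("P%05d", seq_len(n))
  dimnames(z) <- list(patient_ids, cfg$gene_names)

  # observed tumour expression on the RSEM-like scale
  expr_t <- exp(cfg$expr_location + cfg$expr_scale * t(z))

  delta <- stats::setNames(numeric(G), cfg$gene_names)
  delta[names(cfg$de_effects)] <- cfg$de_effects
  if (cfg$n_normal > 0L) {
    zn <- matrix(stats::rnorm(cfg$n_normal * G), cfg$n_normal, G) %*% sig$chol
    expr_n <- exp(cfg$expr_location + cfg$expr_scale * t(zn) - delta)
    colnames(expr_n) <- sprintf("N%05d", seq_len(cfg$n_normal))
  } else {
    expr_n <- matrix(numeric(0), nrow = G, ncol = 0)
  }

  eta <- numeric(n)
  for (g in names(cfg$marginal_effects))
    eta <- eta + cfg$marginal_effects[[g]] * z[, g]
  for (key in names(cfg$interaction_effects)) {
    p <- strsplit(key, ":", fixed = TRUE)[[1]]
    eta <- eta + cfg$interaction_effects[[key]] * z[, p[1]] * z[, p[2]]
  }

  rate <- cfg$baseline_hazard * exp(eta)
  # Weibull with shape k and the configured rate scale; shape 1 = exponential
  u <- stats::runif(n)
  t_event <- (-log(u) / rate)^(1 / cfg$weibull_shape)
  t_cens <- if (cfg$censor_hazard > 0) stats::rexp(n, cfg$censor_hazard) else rep(Inf, n)
  t_cens <- pmin(t_cens, cfg$admin_cutoff)
  time <- pmin(t_event, t_cens)
  status <- as.integer(t_event <= t_cens)

  expr <- cbind(expr_t, expr_n)
  rownames(expr) <- cfg$gene_names
  colnames(expr)[seq_len(n)] <- patient_ids
  sample_class <- stats::setNames(
    c(rep("tumor", n), rep("normal", cfg$n_normal)), colnames(expr))

  clinical <- data.frame(patient_id = patient_ids, time_days = time,
                         status = status, stringsAsFactors = FALSE)
  coh <- cohort(expression = expr, clinical = clinical,
                sample_class = sample_class)

  truth <- list(
    de_genes = names(cfg$de_effects)[cfg$de_effects != 0],
    marginal = cfg$marginal_effects,
    interactions = cfg$interaction_effects,
    latent_z = z
  )
  class(truth) <- "truth_record"
  list(cohort = coh, truth = truth)
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}

#' Cohort container
#'
#' Bundles an expression matrix (genes x samples, non-negative), a clinical
#' outcome table, and per-sample tumour/normal labels, validating their
#' cross-references.
#'
#' @param expression Numeric matrix, rows = genes (unique rownames), columns =
#'   samples (unique colnames), values >= 0.
#' @param clinical Data frame with columns `patient_id`, `time_days`
#'   (finite, > 0) and `status` (0 = censored, 1 = event); every `patient_id`
#'   must be an expression column.
#' @param sample_class Optional named character vector mapping every
#'   expression column to `"tumor"` or `"normal"`; when `NULL` all samples
#'   are treated as tumour.
#' @return An object of class `cohort`.
#' @export
cohort <- function(expression, clinical, sample_class = NULL) {
  stopifnot(is.matrix(expression), is.numeric(expression))
  if (is.null(rownames(expression)) || anyDuplicated(rownames(expression)))
    stop("cohort: expression rownames must be unique gene ids")
  if (is.null(colnames(expression)) || anyDuplicated(colnames(expression)))
    stop("cohort: expression colnames must be unique sample ids")
  if (any(expression < 0)) stop("cohort: expression values must be non-negative")
  req <- c("patient_id", "time_days", "status")
  if (!all(req %in% names(clinical)))
    stop("cohort: clinical table must have patient_id, time_days, status")
  if (anyDuplicated(clinical$patient_id)) stop("cohort: duplicate patient ids")
  orphans <- setdiff(clinical$patient_id, colnames(expression))
  if (length(orphans) > 0)
    stop(sprintf("cohort: clinical ids missing from expression: %s",
                 paste(utils::head(orphans, 5), collapse = ", ")))
  if (any(!is.finite(clinical$time_days)) || any(clinical$time_days <= 0))
    stop("cohort: time_days must be finite and positive")
  if (!all(clinical$status %in% c(0L, 1L)))
    stop("cohort: status must be 0 (censored) or 1 (event)")
  if (is.null(sample_class)) {
    sample_class <- stats::setNames(rep("tumor", ncol(expression)),
                                    colnames(expression))
  }
  if (!all(colnames(expression) %in% names(sample_class)))
    stop("cohort: sample_class must label every expression column")
  sample_class <- sample_class[colnames(expression)]
  if (!all(sample_class %in% c("tumor", "normal")))
    stop("cohort: sample_class values must be 'tumor' or 'normal'")

  obj <- list(expression = expression, clinical = clinical,
              sample_class = sample_class)
  class(obj) <- "cohort"
  obj
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Cohort: %d genes x %d samples (%d tumor, %d normal), %d patients with outcomes, %d events\n",
              nrow(x$expression), ncol(x$expression),
              sum(x$sample_class == "tumor"), sum(x$sample_class == "normal"),
              nrow(x$clinical), sum(x$clinical$status)))
  invisible(x)
}

#' @rdname cohort
#' @param x A `cohort` object.
#' @export
tumor_samples <- function(x) names(x$sample_class)[x$sample_class == "tumor"]

#' @rdname cohort
#' @export
normal_samples <- function(x) names(x$sample_class)[x$sample_class == "normal"]

# expression values for one gene over the patients with outcomes,
# in clinical-table order
patient_expression <- function(cohort, gene) {
  if (!gene %in% rownames(cohort$expression))
    stop(sprintf("gene %s not in expression matrix", gene))
  cohort$expression[gene, cohort$clinical$patient_id]
}

#' Generate a random gene-set annotation
#'
#' Produces a reproducible GMT-writable collection of gene sets over a
#' simulated gene universe, optionally planting one set whose members are
#' drawn preferentially from a designated gene list (for enrichment recovery
#' tests).
#'
#' @param n_genes Universe size (gene ids `G0001`...), or supply `universe`.
#' @param n_sets Number of random sets.
#' @param set_size_range Length-2 `c(min, max)` set size.
#' @param seed Integer seed.
#' @param universe Optional character vector overriding the default universe.
#' @param planted_genes Optional designated gene list feeding the planted set.
#' @param planted_bias Fraction of the planted set drawn from
#'   `planted_genes` (1 = entirely).
#' @param planted_size Size of the planted set (default
#'   `min(length(planted_genes), max(set_size_range))`).
#' @return Named list of character vectors (class `gene_sets`), with a
#'   `description` attribute per collection.
#' @export
generate_annotation <- function(n_genes, n_sets, set_size_range, seed = 1L,
                                universe = NULL, planted_genes = NULL,
                                planted_bias = 0, planted_size = NULL) {
  stopifnot(length(set_size_range) == 2L)
  if (set_size_range[1] > set_size_range[2])
    stop("generate_annotation: set_size_range is inverted")
  if (is.null(universe)) universe <- sprintf("G%04d", seq_len(n_genes))
  if (set_size_range[2] > length(universe))
    stop("generate_annotation: max set size exceeds the gene universe")

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(seed)

  sets <- list()
  if (n_sets > 0L) {
    sizes <- sample(seq.int(set_size_range[1], set_size_range[2]),
                    n_sets, replace = TRUE)
    sets <- lapply(seq_len(n_sets), function(i) sample(universe, sizes[i]))
    names(sets) <- sprintf("SET_%03d", seq_len(n_sets))
  }
  if (!is.null(planted_genes)) {
    stopifnot(all(planted_genes %in% universe),
              planted_bias >= 0, planted_bias <= 1)
    if (is.null(planted_size))
      planted_size <- min(length(planted_genes), set_size_range[2])
    k_in <- min(round(planted_bias * planted_size), length(planted_genes))
    inside <- if (k_in > 0) sample(planted_genes, k_in) else character(0)
    pool <- setdiff(universe, inside)
    outside <- if (planted_size - k_in > 0) sample(pool, planted_size - k_in)
               else character(0)
    sets[["PLANTED"]] <- c(inside, outside)
  }
  attr(sets, "universe") <- universe
  class(sets) <- "gene_sets"
  sets
}
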