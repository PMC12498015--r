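# Core survival and screening statistics.
#
# Everything the screens consume is implemented here from first principles
# (product-limit estimator, log-rank, O/E hazard ratio, Mann-Whitney U,
# Pearson r, hypergeometric tail, BH step-up, quartile binning); the
# 'survival' package is used only as an independent oracle in the test suite.

#' Kaplan-Meier product-limit estimate
#'
#' Fits the product-limit survival curve for one group of patients. At a tied
#' time, deaths are processed before censorings (the standard convention), so
#' subjects censored at `t` are still at risk for deaths at `t`.
#'
#' @param times Positive follow-up times in days, one per patient.
#' @param status Event indicator per patient: `1` (or `TRUE`) = death
#'   observed, `0` = censored at `times`.
#' @return An object of class `km_curve` with components:
#'   \describe{
#'     \item{event_times}{distinct times with at least one death, ascending}
#'     \item{at_risk}{number at risk just before each event time}
#'     \item{deaths}{deaths at each event time}
#'     \item{survival}{product-limit estimate just after each event time}
#'     \item{n_total}{number of patients}
#'     \item{n_events}{total deaths}
#'     \item{max_followup}{largest observed time (event or censoring)}
#'     \item{no_events}{`TRUE` when the curve is identically 1}
#'   }
#' @examples
#' km_fit(c(10, 20, 30, 40), c(1, 1, 1, 1))$survival
#' @export
km_fit <- function(times, status) {
  status <- as.integer(as.logical(status))
  if (length(times) == 0L) stop("km_fit: no patients supplied")
  if (length(status) != length(times))
    stop("km_fit: 'times' and 'status' lengths differ")
  if (anyNA(times) || anyNA(status)) stop("km_fit: missing values not allowed")
  if (any(!is.finite(times)) || any(times <= 0))
    stop("km_fit: all times must be finite and positive")

  no_events <- sum(status) == 0L
  if (no_events) {
    warning("km_fit: zero events; survival curve is identically 1")
    curve <- list(
      event_times = numeric(0), at_risk = integer(0), deaths = integer(0),
      survival = numeric(0), n_total = length(times), n_events = 0L,
      max_followup = max(times), no_events = TRUE
    )
    class(curve) <- "km_curve"
    return(curve)
  }

  et <- sort(unique(times[status == 1L]))
  # at_risk: everyone whose time >= t (censorings at t still at risk)
  sorted <- sort(times)
  n_at_risk <- length(times) - findInterval(et, sorted, left.open = TRUE)
  d <- as.integer(tabulate(match(times[status == 1L], et), length(et)))
  surv <- cumprod(1 - d / n_at_risk)

  curve <- list(
    event_times = et, at_risk = n_at_risk, deaths = d, survival = surv,
    n_total = length(times), n_events = sum(d), max_followup = max(times),
    no_events = FALSE
  )
  class(curve) <- "km_curve"
  curve
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d patients, %d events, max follow-up %g days\n",
              x$n_total, x$n_events, x$max_followup))
  invisible(x)
}

#' Survival probability at a horizon
#'
#' Evaluates a [km_fit()] curve at a time point as a right-continuous step
#' function. When the horizon exceeds the longest observed follow-up the last
#' estimate is carried forward and flagged as not directly supported.
#'
#' @param curve A `km_curve` object.
#' @param horizon Positive time in days (e.g. 1825 for five years).
#' @return A list with `estimate` (probability) and `defined` (`FALSE` when
#'   `horizon > max_followup`, i.e. the value is carried forward).
#' @export
survival_at <- function(curve, horizon) {
  stopifnot(inherits(curve, "km_curve"), is.numeric(horizon),
            length(horizon) == 1L, horizon > 0)
  k <- sum(curve$event_times <= horizon)
  est <- if (k == 0L) 1 else curve$survival[k]
  list(estimate = est, defined = horizon <= curve$max_followup)
}

# Per-event-time log-rank table for >= 2 groups: observed and expected deaths
# plus the hypergeometric variance-covariance of (O - E).
logrank_table <- function(groups, times, status) {
  groups <- as.factor(groups)
  levs <- levels(groups)
  g <- length(levs)
  et <- sort(unique(times[status == 1L]))
  nt <- length(et)
  obs <- vapply(levs, function(l) sum(status == 1L & groups == l), numeric(1))
  # per-event-time at-risk counts per group, via sorted group times
  n_gi <- matrix(0, nt, g, dimnames = list(NULL, levs))
  d_gi <- matrix(0, nt, g, dimnames = list(NULL, levs))
  for (l in levs) {
    tl <- times[groups == l]
    n_gi[, l] <- length(tl) - findInterval(et, sort(tl), left.open = TRUE)
    evl <- times[groups == l & status == 1L]
    d_gi[, l] <- tabulate(match(evl, et), nt)
  }
  n_i <- rowSums(n_gi)
  d_i <- rowSums(d_gi)
  P <- n_gi / n_i
  expd <- stats::setNames(colSums(d_i * P), levs)
  mult <- ifelse(n_i > 1, d_i * (n_i - d_i) / (n_i - 1), 0)
  WP <- mult * P
  V <- diag(colSums(WP), nrow = g) - crossprod(P, WP)
  dimnames(V) <- list(levs, levs)
  list(observed = obs, expected = expd, vcov = V, levels = levs)
}

#' Log-rank (Mantel-Cox) test
#'
#' Compares survival between two or more groups with the Mantel-Cox statistic:
#' observed versus expected deaths accumulated over event times, with the
#' hypergeometric variance. The p-value is the chi-square upper tail on
#' `#groups - 1` degrees of freedom.
#'
#' @param groups Group label per patient (coerced to factor); every level must
#'   be non-empty.
#' @param times,status As in [km_fit()].
#' @return An object of class `logrank_result`: `statistic`, `df`, `p_value`,
#'   and per-group `observed` / `expected` death counts.
#' @export
logrank <- function(groups, times, status) {
  status <- as.integer(as.logical(status))
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop("logrank: need at least two groups")
  if (any(tabulate(groups, nlevels(groups)) == 0L))
    stop("logrank: empty group level present")
  if (length(times) != length(groups) || length(status) != length(groups))
    stop("logrank: input lengths differ")

  g <- nlevels(groups)
  if (sum(status) == 0L) {
    res <- list(statistic = 0, df = g - 1L, p_value = 1,
                observed = stats::setNames(numeric(g), levels(groups)),
                expected = stats::setNames(numeric(g), levels(groups)))
    class(res) <- "logrank_result"
    return(res)
  }

  tab <- logrank_table(groups, times, status)
  u <- (tab$observed - tab$expected)[-g]
  V <- tab$vcov[-g, -g, drop = FALSE]
  stat <- drop(crossprod(u, pseudo_solve(V, u)))
  stat <- max(stat, 0)
  res <- list(statistic = stat, df = g - 1L,
              p_value = stats::pchisq(stat, df = g - 1L, lower.tail = FALSE),
              observed = tab$observed, expected = tab$expected)
  class(res) <- "logrank_result"
  res
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank test: chisq = %.4g on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

# Solve V x = b through an SVD pseudo-inverse; the log-rank covariance can be
# singular when a group has no one at risk at any event time.
pseudo_solve <- function(V, b) {
  s <- svd(V)
  tol <- max(dim(V)) * max(s$d, 0) * .Machine$double.eps
  pos <- s$d > tol
  if (!any(pos)) return(b * 0)
  s$v[, pos, drop = FALSE] %*% ((crossprod(s$u[, pos, drop = FALSE], b)) / s$d[pos])
}

#' Observed/expected (Mantel-Haenszel-style) hazard ratio
#'
#' Two-group hazard ratio computed as `(O_a/E_a) / (O_b/E_b)` from the
#' log-rank table, with `SE(log HR) = sqrt(1/E_a + 1/E_b)`. Deterministic (no
#' iterative fitting); swapping the group labels inverts the ratio exactly.
#'
#' @param groups Two-level label per patient; `group_a` is the numerator.
#' @param times,status As in [km_fit()].
#' @param group_a,group_b Labels naming numerator and denominator groups;
#'   default the first two factor levels.
#' @return An object of class `hr_result`: `hr`, `log_hr_se`, `group_a`,
#'   `group_b`, the underlying `o_a`, `e_a`, `o_b`, `e_b`, and `defined`
#'   (`FALSE` when an expected count is zero or the ratio is not finite and
#'   positive).
#' @export
hazard_ratio_oe <- function(groups, times, status, group_a = NULL, group_b = NULL) {
  status <- as.integer(as.logical(status))
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("hazard_ratio_oe: exactly two groups required")
  if (is.null(group_a)) group_a <- levels(groups)[1L]
  if (is.null(group_b)) group_b <- levels(groups)[2L]
  stopifnot(group_a %in% levels(groups), group_b %in% levels(groups),
            group_a != group_b)
  if (sum(status) == 0L) stop("hazard_ratio_oe: no events observed")

  tab <- logrank_table(groups, times, status)
  o_a <- tab$observed[[group_a]]; e_a <- tab$expected[[group_a]]
  o_b <- tab$observed[[group_b]]; e_b <- tab$expected[[group_b]]
  if (e_a == 0 || e_b == 0) {
    hr <- NA_real_; se <- NA_real_; defined <- FALSE
  } else {
    hr <- (o_a / e_a) / (o_b / e_b)
    se <- sqrt(1 / e_a + 1 / e_b)
    defined <- is.finite(hr) && hr > 0
  }
  res <- list(hr = hr, log_hr_se = se, group_a = group_a, group_b = group_b,
              o_a = o_a, e_a = e_a, o_b = o_b, e_b = e_b, defined = defined)
  class(res) <- "hr_result"
  res
}

#' @export
print.hr_result <- function(x, ...) {
  cat(sprintf("O/E hazard ratio (%s vs %s): %.4g (SE log HR %.3g)\n",
              x$group_a, x$group_b, x$hr, x$log_hr_se))
  invisible(x)
}

#' Quartile binning of expression values
#'
#' Assigns each patient to an expression quartile. Cutpoints are the 25/50/75
#' empirical percentiles under the linear-interpolation definition
#' (`quantile(type = 7)`). Following the screening convention, **Q1 is the
#' highest-expression quartile and Q4 the lowest**; a value exactly equal to a
#' cutpoint goes to the lower-expression bin.
#'
#' @param values Numeric expression values, one per patient (at least 8).
#' @param gene Optional gene identifier carried along for bookkeeping.
#' @return An object of class `quartile_assignment`: `gene`, `bins` (factor
#'   with levels Q1..Q4), `cutpoints` (named, 25/50/75 percentiles).
#' @examples
#' table(quartile_bins(1:8)$bins)
#' @export
quartile_bins <- function(values, gene = NA_character_) {
  if (length(values) < 8L) stop("quartile_bins: need at least 8 patients")
  if (anyNA(values)) stop("quartile_bins: missing values not allowed")
  if (max(values) == min(values))
    stop(sprintf("quartile_bins: gene %s has constant expression (uninformative)",
                 gene))
  cp <- stats::quantile(values, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  # ties at a cutpoint fall to the lower-expression bin
  idx <- 4L - (findInterval(values, cp, left.open = TRUE))
  bins <- factor(paste0("Q", idx), levels = c("Q1", "Q2", "Q3", "Q4"))
  res <- list(gene = gene, bins = bins,
              cutpoints = c(p25 = cp[1], p50 = cp[2], p75 = cp[3]))
  class(res) <- "quartile_assignment"
  res
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum test of a location difference between two samples. When both
#' samples have at most 8 observations and the pooled data are tie-free, the
#' p-value is computed by exact enumeration of all rank arrangements;
#' otherwise the normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param x,y Numeric samples, each non-empty.
#' @return A list with `U` (statistic for `x`), `p_value`, and `method`
#'   (`"exact"` or `"normal"`).
#' @export
mann_whitney <- function(x, y) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  if (anyNA(x) || anyNA(y)) stop("mann_whitney: missing values not allowed")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2

  has_ties <- anyDuplicated(pooled) > 0L
  if (n1 <= 8L && n2 <= 8L && !has_ties) {
    # exact null distribution of U by enumerating which ranks belong to x
    combos <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(seq_len(n1 + n2)[combos], nrow = n1)) -
      n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u - mu) - 1e-12)
    return(list(U = u, p_value = p, method = "exact"))
  }

  n <- n1 + n2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(list(U = u, p_value = 1, method = "normal"))
  z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  p <- 2 * stats::pnorm(z, lower.tail = FALSE)
  list(U = u, p_value = min(p, 1), method = "normal")
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length, at least 3 observations.
#' @return The correlation coefficient in `[-1, 1]`, or `NA` (with a warning)
#'   when either sample has zero variance.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (anyNA(x) || anyNA(y)) stop("pearson_r: missing values not allowed")
  dx <- x - mean(x); dy <- y - mean(y)
  sx <- sum(dx^2); sy <- sum(dy^2)
  if (sx == 0 || sy == 0) {
    warning("pearson_r: zero variance; correlation undefined")
    return(NA_real_)
  }
  r <- sum(dx * dy) / sqrt(sx * sy)
  min(1, max(-1, r))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforced; output order matches
#' input order.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  stopifnot(is.numeric(p))
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("bh_fdr: p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  q[o] <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q
}

#' Hypergeometric upper-tail probability
#'
#' Probability of drawing at least `k` marked elements when `n` elements are
#' sampled without replacement from a universe of `N` containing `K` marked
#' ones. Computed by direct summation of log-binomial terms.
#'
#' @param k Observed overlap (lower bound of the tail).
#' @param K Marked elements in the universe.
#' @param n Sample (query) size.
#' @param N Universe size.
#' @return `P(X >= k)`.
#' @export
hypergeom_tail <- function(k, K, n, N) {
  stopifnot(k >= 0, K >= 0, n >= 0, N >= max(K, n), k <= min(K, n) + 0)
  if (k <= max(0, n + K - N)) return(1)
  i <- seq.int(k, min(K, n))
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

#' Export a survival curve as a plain table
#'
#' @param curve A `km_curve` object.
#' @return A data frame with columns `time`, `at_risk`, `deaths`, `survival`,
#'   suitable for TSV export and plotting.
#' @export
km_table <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  data.frame(time = curve$event_times, at_risk = curve$at_risk,
             deaths = curve$deaths, survival = curve$survival)
}
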