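# Shared fixture builders. All randomness is seeded by the caller.

# small cohort straight from the generator
make_cohort <- function(seed, n_patients = 160, n_genes = 8, n_normal = 20, ...) {
  generate_cohort(sim_config(n_patients = n_patients, n_genes = n_genes,
                             n_normal = n_normal, seed = seed, ...))
}

# hand-rolled cohort from explicit pieces (for IO and container tests)
make_manual_cohort <- function(n = 24, n_genes = 3, seed = 1) {
  set.seed(seed)
  genes <- sprintf("GENE%02d", seq_len(n_genes))
  samples <- sprintf("S%03d", seq_len(n))
  expr <- matrix(rlnorm(n_genes * n, 4, 1), n_genes, n,
                 dimnames = list(genes, samples))
  clin <- data.frame(patient_id = samples,
                     time_days = round(rexp(n, 1e-3) + 1, 3),
                     status = rbinom(n, 1, 0.6))
  cohort(expr, clin)
}

# brute-force two-group log-rank from per-event-time 2x2 tables
logrank2_bruteforce <- function(groups, times, status) {
  levs <- sort(unique(groups))
  et <- sort(unique(times[status == 1]))
  o_minus_e <- 0; v <- 0
  for (t in et) {
    n1 <- sum(times >= t & groups == levs[1])
    n2 <- sum(times >= t & groups == levs[2])
    d1 <- sum(times == t & status == 1 & groups == levs[1])
    d2 <- sum(times == t & status == 1 & groups == levs[2])
    n <- n1 + n2; d <- d1 + d2
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  stat <- if (v > 0) o_minus_e^2 / v else 0
  list(statistic = stat, p_value = pchisq(stat, 1, lower.tail = FALSE))
}

# brute-force BH step-up rejection set at level alpha
bh_reject_bruteforce <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= alpha * seq_len(m) / m)
  if (length(k) == 0) return(integer(0))
  sort(o[seq_len(max(k))])
}

# exact hypergeometric upper tail by enumerating all n-subsets of 1..N
hyper_tail_enumerate <- function(k, K, n, N) {
  marked <- seq_len(K)
  combos <- utils::combn(N, n)
  mean(colSums(matrix(combos %in% marked, nrow = n)) >= k)
}
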