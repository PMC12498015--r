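# Pair screen: grids, trends, scenarios, HR differences, selection.

# minimal grid stub for classifier tests: only s5 / defined / marginal_s5
# are consulted by classify_scenario
stub_grid <- function(col_high, col_low, marginal) {
  s5 <- matrix(NA_real_, 4, 4,
               dimnames = list(factor = paste0("Q", 1:4),
                               strata = paste0("Q", 1:4)))
  s5[, "Q1"] <- col_high
  s5[, "Q4"] <- col_low
  structure(list(s5 = s5, defined = !is.na(s5), marginal_s5 = marginal),
            class = "pair_grid")
}

test_that("classify_trend demands all four points moving one way", {
  expect_equal(as.character(classify_trend(c(0.9, 0.8, 0.7, 0.6))), "decreasing")
  expect_equal(as.character(classify_trend(c(0.6, 0.7, 0.8, 0.9))), "increasing")
  expect_equal(as.character(classify_trend(c(0.5, 0.5, 0.5, 0.5))), "none")
  expect_equal(as.character(classify_trend(c(0.6, 0.7, 0.65, 0.8))), "none")
  # tolerance: small steps no longer qualify
  expect_equal(as.character(classify_trend(c(0.9, 0.8, 0.7, 0.6), tol = 0.15)),
               "none")
  incomplete <- classify_trend(c(0.9, NA, 0.7, 0.6))
  expect_equal(as.character(incomplete), "none")
  expect_true(attr(incomplete, "incomplete"))
})

test_that("classify_scenario maps qualifying columns onto scenarios i-iv", {
  none_col <- c(0.8, 0.7, 0.75, 0.8)
  # (i) reduced survival, factor-low within strata-high carries the deficit
  sc <- classify_scenario(stub_grid(c(0.90, 0.85, 0.80, 0.50), none_col, 0.8))
  expect_equal(sc$scenario, "i")
  expect_equal(sc$direction, "reduced")
  # (ii) reduced survival when both genes are high
  sc <- classify_scenario(stub_grid(c(0.50, 0.78, 0.85, 0.90), none_col, 0.8))
  expect_equal(sc$scenario, "ii")
  expect_equal(sc$direction, "reduced")
  # (iii) increased survival, factor-low within strata-high carries the gain
  sc <- classify_scenario(stub_grid(c(0.78, 0.80, 0.85, 0.95), none_col, 0.8))
  expect_equal(sc$scenario, "iii")
  expect_equal(sc$direction, "increased")
  # (iv) increased survival when both genes are high
  sc <- classify_scenario(stub_grid(c(0.95, 0.88, 0.83, 0.78), none_col, 0.8))
  expect_equal(sc$scenario, "iv")
  expect_equal(sc$direction, "increased")
  # no qualifying trend anywhere
  sc <- classify_scenario(stub_grid(none_col, none_col, 0.8))
  expect_equal(sc$scenario, "none")
  expect_equal(sc$direction, "none")
  # a both-low worst cell is re-read from the column's other end: best
  # survival at (factor high, strata low), i.e. scenario iii
  sc <- classify_scenario(stub_grid(none_col, c(0.90, 0.85, 0.80, 0.50), 0.8))
  expect_equal(sc$scenario, "iii")
  expect_equal(sc$direction, "increased")
  # conflicting strata: the stronger deviation wins
  sc <- classify_scenario(stub_grid(c(0.90, 0.85, 0.80, 0.40), # reduced, dev .4
                                    c(0.55, 0.78, 0.83, 0.88), # reduced (both-low? no: worst (high,low) mixed)
                                    0.8))
  expect_equal(sc$direction, "reduced")
})

test_that("pair_grid partitions the cohort and transposes exactly", {
  sim <- make_cohort(601, n_patients = 320, n_genes = 5, n_normal = 0)
  coh <- sim$cohort
  g_ab <- pair_grid("G0001", "G0002", coh)
  g_ba <- pair_grid("G0002", "G0001", coh)
  expect_equal(sum(g_ab$cell_n), nrow(coh$clinical))
  expect_identical(g_ab$cell_n, t(g_ba$cell_n))
  expect_identical(g_ab$s5, t(g_ba$s5))
  expect_identical(g_ab$defined, t(g_ba$defined))
  expect_true(all(g_ab$s5 >= 0 & g_ab$s5 <= 1, na.rm = TRUE))

  # raising min_cell_n only flips cells to undefined
  strict <- pair_grid("G0001", "G0002", coh, min_cell_n = 1000)
  expect_false(any(strict$defined))
  expect_identical(strict$s5, g_ab$s5)

  expect_error(pair_grid("G0001", "G0002",
                         local({
                           c2 <- coh
                           c2$expression["G0002", ] <- 1
                           c2
                         })), "constant")
})

test_that("null cohorts give flat grids near the marginal survival", {
  sim <- make_cohort(602, n_patients = 3000, n_genes = 2, n_normal = 0)
  g <- pair_grid("G0001", "G0002", sim$cohort)
  cells <- g$s5[, c("Q1", "Q4")]
  expect_lt(max(abs(cells - g$marginal_s5)), 0.08)
})

test_that("hr_difference agrees with direct O/E computations", {
  sim <- make_cohort(603, n_patients = 400, n_genes = 3, n_normal = 0,
                     marginal_effects = c(G0001 = 0.5))
  coh <- sim$cohort
  g <- pair_grid("G0001", "G0002", coh)
  hd <- hr_difference(g, coh)
  cl <- coh$clinical
  for (stratum in c("Q1", "Q4")) {
    sel <- g$bins_strata$bins == stratum & g$bins_factor$bins %in% c("Q1", "Q4")
    ref <- hazard_ratio_oe(ifelse(g$bins_factor$bins[sel] == "Q1", "high", "low"),
                           cl$time_days[sel], cl$status[sel], "high", "low")
    got <- if (stratum == "Q1") hd$hr_q1 else hd$hr_q4
    expect_equal(got$hr, ref$hr, tolerance = 1e-12)
  }
  expect_equal(hd$hr_rel_diff,
               abs(hd$hr_q1$hr - hd$hr_q4$hr) / min(hd$hr_q1$hr, hd$hr_q4$hr),
               tolerance = 1e-12)
  abs_mode <- hr_difference(g, coh, mode = "absolute")
  expect_equal(abs_mode$hr_rel_diff, abs(hd$hr_q1$hr - hd$hr_q4$hr),
               tolerance = 1e-12)
})

test_that("planted interactions produce monotone within-stratum trends", {
  # scaled-down version of the recovery property (full version in the
  # acceptance suite): gamma = 0.8, n = 1200, 8 seeds
  hits <- 0
  for (s in 1:8) {
    sim <- make_cohort(700 + s, n_patients = 1200, n_genes = 2, n_normal = 0,
                       interaction_effects = c("G0001:G0002" = 0.8))
    g <- pair_grid("G0001", "G0002", sim$cohort)
    trends <- c(as.character(classify_trend(g$s5[, "Q1"])),
                as.character(classify_trend(g$s5[, "Q4"])))
    hits <- hits + any(trends != "none")
  }
  expect_gte(hits, 5)
})

test_that("run_pair_screen output is deterministic and order-invariant", {
  sim <- make_cohort(604, n_patients = 240, n_genes = 5, n_normal = 0)
  genes <- rownames(sim$cohort$expression)
  a <- run_pair_screen(genes, sim$cohort)
  b <- run_pair_screen(rev(genes), sim$cohort)
  expect_identical(a, b)
  expect_equal(nrow(a), choose(5, 2))
  expect_true(all(a$gene_a < a$gene_b))
  # selected implies concordant and an HR difference over the threshold
  expect_true(all(!a$selected | (a$concordant & a$hr_rel_diff >= 0.10)))
  expect_error(run_pair_screen("G0001", sim$cohort), "at least 2")
})

test_that("tightening pair-screen knobs never enlarges the selected set", {
  sim <- make_cohort(605, n_patients = 600, n_genes = 6, n_normal = 0,
                     interaction_effects = c("G0001:G0002" = 0.8,
                                             "G0003:G0004" = 0.6))
  genes <- rownames(sim$cohort$expression)
  base <- run_pair_screen(genes, sim$cohort, hr_diff_threshold = 0.05)
  tight_hr <- run_pair_screen(genes, sim$cohort, hr_diff_threshold = 0.5)
  tight_cell <- run_pair_screen(genes, sim$cohort, hr_diff_threshold = 0.05,
                                min_cell_n = 15)
  key <- function(df) paste(df$gene_a, df$gene_b)[df$selected]
  expect_true(all(key(tight_hr) %in% key(base)))
  expect_true(all(key(tight_cell) %in% key(base)))
})
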