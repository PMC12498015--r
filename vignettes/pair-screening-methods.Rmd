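---
title: "Methods: quartile-stratified gene-pair survival screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quartile-stratified gene-pair survival screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survpairs)
```

## The problem

Single-gene survival association misses interactions: two genes may each be
prognostically silent while their *combined* dysregulation marks a
high-risk subpopulation. `survpairs` implements a screen for such pairs in
expression cohorts with overall-survival follow-up (the motivating setting
is TCGA-style breast-tumour transcriptomes): candidate genes are first
filtered individually, then every candidate pair is tested by conditioning
one gene's survival effect on the other's expression extremes.

## The statistics

All statistics consumed by the screens are implemented in the package
itself; the `survival` package is used only as an independent oracle in the
test suite.

**Product-limit estimator.** For distinct event times $t_1 < t_2 < \dots$
with $d_i$ deaths among $n_i$ at risk,
$\hat S(t) = \prod_{t_i \le t} (1 - d_i/n_i)$. Ties at a time are handled by
the standard convention: deaths are processed before censorings, so a
subject censored at $t_i$ is still at risk there. The screen's per-cell
endpoint is the *cumulative survival at the prognosis horizon*,
$\hat S(1825\,\mathrm{d})$, evaluated as a right-continuous step function;
when the horizon exceeds the longest follow-up in a cell the last estimate
is carried forward and the cell is flagged as not directly supported.

**Log-rank (Mantel–Cox) test.** Observed versus expected deaths accumulated
over event times with the hypergeometric variance–covariance; the statistic
is $(O-E)^\top V^{-}(O-E)$ on $g-1$ degrees of freedom (pseudo-inverse for
the occasional singular $V$). The two-group form reduces to
$(O_a-E_a)^2/V$.

**O/E hazard ratio.** $\widehat{HR} = (O_a/E_a)\,/\,(O_b/E_b)$ with
$SE(\log HR) = \sqrt{1/E_a + 1/E_b}$. This Mantel–Haenszel-style estimator
needs no iterative fitting and is fully deterministic; swapping groups
inverts it exactly. It is mildly conservative relative to a Cox estimate at
large effects (simulation at true HR 2, $n = 500$/arm, gives a mean near
1.9), which the test suite's recovery band accounts for. A Cox fit is used
only as a cross-check oracle in tests; users needing Cox-consistent values
can substitute one.

**Quartile binning.** Cutpoints are the 25/50/75 empirical percentiles
under the linear-interpolation definition (R's type-7 quantile). **Q1 is
the highest-expression quartile, Q4 the lowest** — the convention used
throughout — and a value exactly equal to a cutpoint goes to the
lower-expression bin. Because interpolated cutpoints always lie between the
same order statistics, bin membership is invariant under any strictly
monotone transform of the values; the whole screen inherits this
invariance (verified as an acceptance property).

**Mann–Whitney U** (tumour vs normal differential expression): exact
enumeration of all rank arrangements when both samples have $\le 8$
tie-free observations, otherwise the normal approximation with tie and
continuity corrections. The 8/8 switch point keeps the exact path
brute-force verifiable ($\binom{16}{8} = 12870$ arrangements).

**Hypergeometric enrichment and BH.** Enrichment $p$ is the exact
upper-tail sum $P(X \ge k)$ computed from log-binomial terms; fold
enrichment is $(k/n)/(K/N)$. FDR control is the Benjamini–Hochberg step-up
with enforced monotonicity.

## The gene screen

A gene is a candidate when (i) tumour vs normal Mann–Whitney
$p < 10^{-3}$, and (ii) under the median *or* the quartile expression
cutoff, the log-rank $p < 0.05$ with an O/E hazard ratio outside the
$(0.8, 1.2)$ band (inclusive at both bounds). The quartile cutoff compares
only Q1 vs Q4 patients (middle half excluded), matching the
"HR of the high-expression group" framing; the median split sends ties to
the low-expression group. A force-include list admits genes kept on prior
biological evidence regardless of their statistics. When a cohort carries
no normal samples the DE condition is waived with an explicit log line —
a documented degradation, not silent behaviour.

## The pair screen

For an ordered pair (factor gene $A$, strata gene $B$) the cohort is cut
into the $4 \times 4$ grid of quartile intersections. Within each stratum
column — primarily $B$-Q1 (high) and $B$-Q4 (low) — the four factor-quartile
cells are summarised by $\hat S(1825)$, with cells under `min_cell_n`
patients (default 5; expected cell size is $n/16$) flagged undefined.

**Trend.** A column qualifies only when *all four* values move one way
(strictly monotone at the default `tol = 0`; the tolerance is exposed for
noisy small cohorts). Any undefined cell disqualifies the column.

**Scenario and direction.** A monotone column exhibits a worst and a best
expression combination (its two ends). Which one the screen reports is
decided by deviation from the cohort's marginal $\hat S(1825)$: if the
worst cell falls further below the marginal than the best cell rises above
it, the column reads "reduced survival at (factor end, stratum level)",
otherwise "increased survival" at the other end. A both-low combination is
re-read from the opposite end of the same column (the two readings describe
the same pattern), so every qualifying column maps onto one of four
canonical scenarios:

| scenario | survival direction | implicated combination |
|---|---|---|
| i | reduced | one gene high, the other low |
| ii | reduced | both genes high |
| iii | increased | one gene high, the other low |
| iv | increased | both genes high |

One qualifying stratum suffices. When both strata qualify with conflicting
directions, the column whose implicated cell deviates further from the
marginal survival wins; an exact tie yields no call. This dominance rule is
a deliberate design choice: a pure interaction ($\gamma \ne 0$,
$\beta = 0$) *necessarily* flips the factor gene's effect sign between the
high and low strata of its partner, so the two columns always trend in
opposite directions — treating that as a disqualifying conflict would
reject exactly the pairs the screen exists to find.

**Concordance and selection.** The pair is evaluated in both orderings
($A$ as factor within $B$'s strata, and vice versa); it is *concordant*
when both orderings yield the same non-none survival direction. The second
filter computes, on the lexicographically first ordering, the two
strata-conditional O/E hazard ratios of factor Q1 vs Q4 and requires their
difference to reach 10%. The source description of this rule does not
define the comparison's denominator; the default reads it as a relative
difference, $|HR_{Q1} - HR_{Q4}| / \min(HR_{Q1}, HR_{Q4}) \ge 0.10$
(boundary inclusive), with an absolute-difference mode
(`hr_diff_mode = "absolute"`) selectable. A pair with an undefined HR in
either stratum is excluded with a recorded reason. Selected pairs carry
`survival_direction` "reduced" (scenarios i–ii) or "increased" (iii–iv).
No multiplicity correction is applied across the pair family, matching the
screening character of the procedure.

## Downstream characterisation

For each selected pair, `correlated_genes()` keeps every other gene whose
Pearson $r$ with *each* member exceeds 0.3 in magnitude (strict
inequality), computed over tumour samples. The literal rule does not force
the two correlations to share a sign; a `same_sign` mode is provided.
Regulation tags come from tumour-vs-normal testing when normals exist,
otherwise from the correlation-sign consensus (flagged as such, mixed signs
reported "discordant"). `enrich()` drops annotation sets with fewer than 10
background members *before* testing, applies BH across the tested sets,
keeps survivors at FDR < 0.05, retains the ten most significant by FDR and
sorts them by fold enrichment. The background universe defaults to all
non-constant genes in the expression matrix. `overlap_sets()` reports every
gene shared by at least three pairs' correlated sets, keyed by the exact
pair combination, with conflicting regulation surfaced rather than
resolved.

## The synthetic cohort: what it emulates and what it does not

`generate_cohort()` draws latent standard-normal scores $z$ with optional
equicorrelated blocks (Cholesky of the implied covariance; per-block and
joint positive-definiteness are validated with named errors), maps them to
an RSEM-like observed scale $\exp(\mu_g + \sigma_g z)$, shifts normal
samples by $-\delta_g$ on the log scale for designated DE genes, and
simulates event times from a proportional-hazards model with

$$\log \lambda_i = \log \lambda_0 + \sum_g \beta_g z_{ig}
  + \sum_{g<h} \gamma_{gh}\, z_{ig} z_{ih},$$

exponential by default (a Weibull shape is exposed, default 1). Censoring
is the minimum of an independent exponential draw and an administrative
cutoff — the simplest mechanism satisfying the non-informative-censoring
assumption of the product-limit estimator. Effects enter through latent
z-scores, not raw expression, so planted hazard ratios are scale-free;
this matches the screen itself, which is rank-based.

Defaults are fixed once as the stated world: 1,098 patients (the
motivating cohort's size), 110 normal samples (roughly the 1:10
tumour-to-normal ratio of TCGA-style breast collections),
$\lambda_0 = 10^{-4}/\mathrm{day}$ (five-year baseline survival
$e^{-0.1825} \approx 0.83$, typical of breast-cancer cohorts),
$\lambda_c = 2 \times 10^{-4}/\mathrm{day}$ (about 31% of event-free
patients censored before five years), administrative cutoff 3,650 days,
log-scale location 6 and scale 1 (median expression $\approx 400$ on the
observed scale). The generator seeds its own RNG stream and restores the
caller's, so identical configurations are bit-identical regardless of
ambient state.

Deliberately *not* modelled: negative-binomial count noise and library-size
effects, batch effects, competing risks, and subtype structure. A green
recovery test therefore establishes that the screen detects interactions of
the planted form under clean proportional-hazards sampling — not that it
would at a given power on real RNA-seq data, where extra dispersion and
non-proportional hazards can only reduce power.

## Numerical and degenerate-input choices

* Prognosis horizon fixed at 1825 days (5 × 365); configurable.
* Constant-expression genes are errors in `quartile_bins()` (uninformative)
  and skipped-with-count in `correlated_genes()`.
* Zero events: `km_fit()` returns the unit curve with a warning flag;
  `logrank()` returns statistic 0, $p = 1$; `hazard_ratio_oe()` with a zero
  expected count returns an undefined, flagged result that downstream
  filters exclude.
* `hr_rel_diff` uses the smaller HR as denominator, making the relative
  rule symmetric in the two strata.
* All result tables are written with `"."` for undefined numerics; pipeline
  outputs contain no timestamps, so repeated runs are byte-identical.

## Known limitations

The O/E hazard ratio is attenuated relative to Cox at large effects; the
selection rule tests it only against a band, so this affects reported
magnitudes, not verdicts. The trend rule at `tol = 0` is strict and loses
power in small cohorts (cells of ~15 patients or fewer rarely produce four
cleanly ordered estimates); raising `tol` trades false positives for power.
The 10% HR-difference rule inherits the ambiguity of its source — both
readings are provided, and the default (relative) is the more conservative
at small HRs. Enrichment assumes the annotation is given (GMT input);
no ontology-graph reasoning is performed.
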