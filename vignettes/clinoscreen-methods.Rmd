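---
title: "Methods: screening radiation x simulated-microgravity synergy in count data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening radiation x simulated-microgravity synergy in count data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clinoscreen)
```

## The experimental design and the question

`clinoscreen` analyses a two-stressor factorial RNA-seq design: cultured
cells kept standing at 1 G (`ST`) or clino-rotated to time-averaged
simulated microgravity (`RO`), crossed with radiation (none, X-ray `X`,
carbon ion `C`) and harvest time after irradiation (3 h, 24 h). The
non-irradiated cultures carry no harvest time, so the design has 10
conditions; the default layout has 6 replicates for `ST` and `RO` and 3
for each of the 8 irradiated conditions — 36 samples.

The target quantity is an *interaction*: a gene counts as a "synergy"
gene when its irradiated expression differs between gravity environments
after correcting for whatever microgravity does to the gene without
radiation. Main effects of radiation — however large — are deliberately
invisible to the screen.

## Statistical model

Counts are modelled negative-binomially: for gene $g$ in sample $s$ of
condition $c(s)$,
$$y_{gs} \sim \mathrm{NB}\big(\mu_{g,c(s)}\, \ell_s,\ \phi\big), \qquad
\mathrm{Var}(y) = \mu + \phi \mu^2,$$
with $\ell_s$ a sample-specific library-size factor and $\phi$ a common
dispersion shared across genes. A common (not gene-wise) dispersion is the
deliberate choice for designs with 3 replicates per cell: there is too
little replication to stabilize per-gene estimates, and the screen's
decisions ride on a handful of high-count genes where the common-$\phi$
approximation is mild. Tag-wise shrinkage is out of scope.

### Normalization

Scaling factors are trimmed weighted means of gene-wise log2 expression
ratios (M values) against a reference sample (the column whose
upper-quartile count proportion is closest to the mean upper-quartile),
with genes zero in either column excluded, the extreme 30% of M values
and 5% of A values trimmed on each side, and inverse delta-method-variance
weights; factors are rescaled to geometric mean 1 (`tmm_factors()`).
Normalized values are factor-adjusted counts per million
(`normalize_counts()`): `count / (lib_size * factor) * 1e6`. Genes with
all-zero counts are retained (value 0) so the gene universe stays aligned
across stages.

Two properties worth stating precisely: (i) when samples differ *only* in
depth, factors are exactly 1 and every column sums to exactly $10^6$;
(ii) on overdispersed data the inverse-variance weighting concentrates on
high-abundance genes, so factors — ours and any TMM implementation —
carry a few percent of sampling noise and column sums sit *near*, not at,
one million. The screen itself is scale-free (see below), so this noise
affects only the Step-2 threshold, which is user-settable.

The upstream tool that motivated this pipeline never documents its
normalization; TMM + CPM is adopted because the exact-test family assumes
relative-abundance scaling, and the choice is isolated behind
`tmm_factors()` so median-of-ratios or upper-quartile factors can be
swapped in without touching the screen.

### The exact conditional NB test

For a two-group comparison, counts are first placed on a common effective
library size — the geometric mean of `lib_size * factor` over the
contrast's samples — by a quantile-to-quantile NB adjustment
(`equalize_lib_sizes()`): each count is mapped through the average of a
variance-matched normal transform and a gamma quantile transform, taking
the tail the observation sits in so extreme counts keep quantile
precision. Using *effective* (factor-adjusted) library sizes matters:
group-specific transcriptional programs otherwise shift raw library
sizes, and after equalization every unchanged gene would appear shifted
the other way — a composition artifact that materializes as false
positives in the screen's Step 3.

Given adjusted group sums $z_A, z_B$ (rounded to integers) from $n_A,
n_B$ replicates, the test conditions on $z = z_A + z_B$. Under a common
mean the group sums are NB with means $n_A\mu, n_B\mu$ ($\mu = z/(n_A +
n_B)$) and sizes $n_A/\phi, n_B/\phi$; the two-sided p-value sums the
conditional probabilities of every split $k \in [0, z]$ whose probability
does not exceed that of the observed split, normalized by the total
(`exact_nb_test()`). Summation of small-probability outcomes — rather
than doubling one tail — is the convention adopted because it is
well-defined on asymmetric supports. At $\phi = 0$ the conditional law is
exactly binomial with success probability $n_A/(n_A+n_B)$, which is also
the implementation's code path, avoiding NB numerics in the Poisson
limit.

Numerical choices: probabilities are computed in log space and compared
with a $10^{-10}$ additive log tolerance so mathematically tied splits
(e.g. the symmetric case, which must give $p = 1$) are not broken by
floating-point noise; $z = 0$ returns $p = 1$ by convention (untestable
gene); the support is enumerated exhaustively up to $5 \times 10^6$ and
truncated beyond that where the excluded marginal mass is below
$10^{-12}$.

### Dispersion estimation

`estimate_common_dispersion()` maximizes the conditional log-likelihood
of within-group counts given group totals — for one group of $n$
replicates with $r = 1/\phi$:
$$\ell = \sum_i \log\Gamma(y_i + r) + \log\Gamma(nr) - \log\Gamma(z + nr)
- n \log\Gamma(r),$$
summed over genes and all groups with $\ge 2$ replicates — over $\phi \in
[0, 10]$ with `stats::optimize` (golden-section based, tolerance
$10^{-6}$). Because the library-size equalization itself needs a working
dispersion, adjustment and maximization are iterated twice from
$\phi_0 = 0.01$. Estimates below $10^{-5}$ snap to 0 (no detectable
excess variance); an optimum pinned at the upper boundary or a
non-finite likelihood falls back to a pooled method-of-moments estimate,
and a design with no replicated group anywhere is an error instructing
the caller to supply $\phi$.

## The five-step screen

`run_screen()` traces every panel gene through the funnel; by
construction `step1 ⊇ step2 ⊇ (step3-pass ∪ step4-pass) ⊇ selected`.

1. **Panel restriction.** Detected (≥ 1 nonzero count) genes of the
   designated panel.
2. **Expression filter.** Maximum normalized value across the standing
   (1 G) samples ≥ `step2_threshold` (default 1000 on the CPM scale).
   Two readings were genuinely open and both are implemented: the
   "standing sample" set defaults to *all* ST samples including
   irradiated ones (`step2_scope = "standing_all"`), since the source
   procedure's wording does not exclude them, and the maximum defaults to
   the replicate level (`step2_max = "replicate"`) rather than condition
   means. Because the original tool's normalization scale is unknowable,
   the threshold is a first-class parameter rather than a constant.
3. **Gravity effect under irradiation.** The 8 irradiated conditions form
   4 standing-vs-rotating pairs (X3, X24, C3, C24), each tested 3 vs 3
   with the exact test; a gene passes with $p < \alpha$ in at least one
   pair, and all per-pair p-values are kept in the record table.
4. **Microgravity alone.** Step-3 failures are tested `ST` vs `RO`
   (6 vs 6); passers re-enter the funnel and are classified identically
   to Step-3 entrants in Step 5 (in the motivating study zero genes took
   this path, so it is exercised only synthetically here).
5. **Gravity-corrected fold change.** With $r = \overline{ST} /
   \overline{RO}$ over non-irradiated replicates, the rotating irradiated
   mean is converted to the standing scale and compared:
   $\mathrm{afc}(c) = r \cdot \overline{RO\text{-}c} /
   \overline{ST\text{-}c}$. Strictly above 1 is `enhanced_increase`,
   strictly below 1 `enhanced_decrease`, exactly 1 `none` — a strict
   boundary because "changed" should mean changed. A zero non-irradiated
   `RO` mean makes the gene unclassifiable and unselectable. Adjusted
   fold changes are emitted for *all four* pairs (whether each passed
   Step 3 is recorded alongside), and the gene-level class is taken at
   the strongest-evidence pair: smallest Step-3 p-value, or largest
   $|\log_2 \mathrm{afc}|$ for Step-4 entrants.

Steps 3/4 aside (test statistics depend on counts), the Step-5 quantities
$r$, converted values, adjusted fold changes and classes — and the
relative-expression profiles — are invariant to any global rescaling of
the normalized matrix; only the Step-2 threshold is scale-bound, which is
why it is configurable.

`relative_expression()` reports each gene's condition means divided by
the gene's maximum condition mean (the top condition sits at exactly 1),
standard errors as the SD of max-scaled replicate values over $\sqrt{N}$,
and per-pair direction calls (up / down / ns) from the exact test.

## Heatmap transform and group allocation

`transform_values()` computes `log2(condition mean + 0.01)` — the
transform of the replicate mean, not the mean of transforms, because the
display shows one cell per condition and normalization precedes
transformation. `allocate_groups()` compares each condition with the
`ST` reference: $|\Delta| < 1$ is `no_change`, $\Delta \le -1$ down,
$\Delta \ge 1$ up. The source procedure leaves $\Delta = 1$ formally
unassigned ("smaller than 1" vs "larger than 1"); the inclusive-changed
convention is adopted since "smaller than 1.0" is exclusive, making its
complement inclusive. Export (`write_heatmap()`) writes
matrix-viewer-ready TSVs plus metadata recording the display bounds
(−7.00 / 0.00 / 13.00) and reference.

## Over-representation

`hypergeom_enrich()` is the plain upper-tail hypergeometric test of the
list-set overlap within a universe (default: all detected genes),
equivalent to a one-sided Fisher exact test — deliberately *not* a
reproduction of any web service's modified score, whose background and
database versions are unrecoverable. `top_pathways()` truncates to the
top `k = 3` sets with $p < 0.05$, without padding. Multiple-testing
correction across sets is optional (`bh = TRUE`) and off by default,
matching the screening procedure's use of unadjusted p-values; the same
flag exists on `run_contrast()` for reuse outside that procedure.

## What the simulator emulates — and what it does not

`sim_config()` defaults define the study conditions used throughout the
tests and the acceptance script:

* 2,000 genes as a desk-scale stand-in for a whole-transcriptome
  quantification (57,773 genes in the motivating design); 36 samples in
  the 6/6/8×3 layout.
* Gene baselines log-normal (median 60 expected counts, `sdlog` 1.1) —
  heavy-tailed abundance so the Step-2 threshold is a nontrivial filter.
* NB dispersion $\phi = 0.1$, a typical bulk RNA-seq cell-line value;
  library factors uniform on (0.7, 1.3) so normalization matters.
* An 84-gene panel of which 2 are undetected (82 detected) and 13 sit
  above the Step-2 threshold (baselines log-uniform on 1,500–6,000;
  the remaining detected panel genes are capped well below threshold so
  the Step-2 cut is decided by construction, not noise).
* 9 synergy genes among the 13: an extra $\pm 2$ log2 fold change under
  `RO` + irradiation, split 6 `enhanced_increase` / 3
  `enhanced_decrease` to mirror the promoting/suppressing split reported
  in the motivating study. The other 4 high-expression panel genes carry
  radiation responses but no interaction and no microgravity effect —
  the analogue of the four genes that failed Steps 3–4 there.
* A 30-gene non-panel microgravity-alone program (+1.5 log2 under `RO`),
  distinct from the synergy genes, exercising Step 4 and giving the
  enrichment stage a recoverable planted set; a 240-gene radiation
  program (half up, half down) plus alternating-sign radiation responses
  across the detected panel, emulating a radiation-dominated expression
  landscape.

What it does *not* emulate: batch effects beyond library size, gene-wise
dispersion variation, gene-length effects, correlated genes, or read- and
alignment-level artifacts (the pipeline starts from quantified counts by
design). Passing recovery tests on these fixtures therefore demonstrates
that the procedure's logic and statistics behave as specified under the
declared model — not that real data meet that model.

Problem sizes in the tests and acceptance script — 2,000-gene fixtures,
20 seeds for the recovery study, totals ≤ 50 for exhaustive exact-test
enumeration, 1,000 random tables for the Fisher cross-check — were chosen
as the package's own desk-scale defaults; all are parameters, not limits.

## Known limitations

* With four Step-3 tests per gene at $\alpha = 0.05$ and no multiplicity
  correction (faithful to the source procedure), a null high-expression
  panel gene passes Step 3 with probability $\approx 1 - 0.95^4$; on the
  default fixture the median false-positive count across seeds is ≤ 1,
  but individual seeds can admit more. `screen_config(alpha = )` and the
  `bh` flags are the levers for stricter reuse.
* The common-dispersion assumption understates uncertainty for genes far
  more variable than average.
* The Step-5 classification is a point-estimate rule on group means; it
  attaches no uncertainty to the adjusted fold change beyond the Step-3/4
  gate.
* Enrichment p-values are conditional on the user-supplied universe; with
  a biased universe the hypergeometric model is biased with it.
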