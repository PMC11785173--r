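---
title: "From burden tests and Perturb-seq to gene-program-trait graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From burden tests and Perturb-seq to gene-program-trait graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Rare loss-of-function (LoF) burden tests attach a signed, dosage-like
effect size γ to each gene: how much does losing one functional copy of
the gene move a quantitative trait? These estimates are causally
interpretable but say nothing about mechanism. Genome-scale CRISPRi
perturbation screens with single-cell readout (Perturb-seq) provide the
complementary information: the regulatory consequence β of knocking a
gene down, on every other gene and on every co-expression program of the
cell. This package connects the two, building a signed graph

    gene --(regulates)--> program --(affects)--> trait
    gene --(member of)--> program --(affects)--> trait

in which a gene can act on a trait either by *regulating* a program's
activity or by *being part of* a program's transcriptional output.

Everything runs offline: a synthetic-data generator plants a known
gene-program-trait structure and emits the same file formats the
real-data loaders accept (burden summary TSV, MTX + annotation sidecars,
narrowPeak, BED).

## Model components

### Signed empirical-Bayes shrinkage of burden effects

Burden-test estimates for constrained genes are noisy (few LoF carriers).
The prior on γ is a two-part signed distribution,

* sign(γ) ~ Bernoulli(p),
* |γ| ~ Gamma(shape α, scale θ),

with Normal measurement error `γ̂ ~ N(γ, SE²)`. The prior is fitted by
marginal maximum likelihood over (p, α, θ); `fit_prior()` accepts a
gene binning (e.g. shet deciles) to let the prior vary with constraint —
a deliberately lightweight stand-in for feature-conditional priors fit by
gradient boosting, keeping the empirical-Bayes structure without a
learned regressor. One (α, θ) pair is shared between the sign branches.

Posterior means and sign probabilities are computed by deterministic
composite Gauss–Legendre quadrature. Each sign branch is integrated on
log-spaced segments between the Gamma quantiles 1e-10 and 1 − 1e-10,
refined with extra segments across the likelihood window γ̂ ± 8·SE, with
15 nodes per segment. Log-spaced geometric segments absorb the
integrable singularity at 0 when α < 1, and the two branches never share
a segment, so the density kink at 0 is never straddled. An earlier
trapezoid design on a union grid plateaued around 1e-4 relative error in
cancellation-heavy cases (posterior mass nearly balanced across signs);
the segmented Gauss–Legendre rule reaches better than 1e-6 relative
agreement with adaptive quadrature at lower cost, which is why it is the
default. `se = 0` short-circuits to the observation itself.

### Perturbation effects

Cells are filtered (cells below a minimum number of expressed genes
first, then genes expressed in too few cells), and effects are estimated
per perturbation target by OLS on the target's cells plus the
non-targeting controls:

    response ~ intercept + is_perturbed + batch + n_genes_expressed + pct_mito

with exact t-tests on the `is_perturbed` coefficient. This replaces a
moderated-variance (limma-trend-style) fit; the point estimates are
identical and moderation matters mainly at very low cell counts, for
which a simple variance-squeeze flag (`moderate = TRUE`) is available.
Log fold changes are in natural-log units. FDR is Benjamini–Hochberg
within one of two declared families: across responses within a
perturbation (gene-level logFC scans) or across perturbations within a
response (program usages — this family defines each program's
"significant regulator" set). Cell-cycle-style phase assignment uses
mean z-scored marker expression with an argmax-if-positive rule, without
expression-matched control bins (a documented simplification), and
phase fractions carry leave-one-cell-out jackknife standard errors.

### Consensus NMF programs

Programs come from consensus non-negative matrix factorization of the
cell × gene matrix of depth-normalised counts (counts scaled to 10,000
per cell), with genes scaled to unit variance without centering. The
factorization is *not* run on log-transformed values: the planted (and
assumed) structure is a linear mixture `X ≈ usage · spectraᵀ`, which the
log distorts; switching from log to linear input was the single largest
driver of factorization quality in development. Replicate runs use
multiplicative updates — the first from a deterministic non-negative
double-SVD initialisation, later runs from random draws, because
run-to-run variability is what gives the consensus stability metric its
meaning. Pooled L2-normalised spectra pass a local density filter (mean
distance to the n_runs/3 nearest neighbours ≤ 0.5 by default), survivors
are k-means clustered, cluster medians form the consensus spectra, and
usages are refit per cell by non-negative least squares. Stability is
the mean silhouette of the surviving components; the number of programs
is chosen by inspecting stability against reconstruction error across
candidate k — never automatically.

In data with a shared baseline (housekeeping load, mito-like block),
one or two components above the planted program count absorb that
signal and leave the programs clean; the workflow uses k = programs + 1.

### Program-trait association

Two complementary statistics per program:

* **Program burden effect** — the mean posterior γ of the program's
  top-loading genes (loadings are non-negative, so the sign is
  directly interpretable). Because constraint and |γ| are correlated,
  the null is built from random gene sets matched *exactly* to the
  observed set's composition across 10 shet-decile bins (ties to the
  lower bin), with the two-sided +1-corrected permutation p-value
  `2·min(#{null ≥ obs}+1, #{null ≤ obs}+1)/(n_perm+1)` carrying the
  sign of the observed mean.
* **Regulator-burden correlation** — the coefficient of β in the
  regression `γ ~ β(x→P) + shet` across perturbed genes, reported as
  `-log10(p) × sign`, with the focal gene excluded when the response is
  a gene.

Two-sided QQ plots rank each sign's statistics against that tail's own
uniform order statistics, so null data sit on the diagonal in both tails
regardless of the sign split. Fisher's exact enrichment of hit sets in
top-ranked genes uses the sample odds ratio with a Haldane correction
for empty cells and a Woolf confidence interval.

### Causal direction between programs

For a program pair, regulators significant for each program (FDR < 0.05
within the per-response family) are ascertained separately; within each
ascertainment set the Spearman correlation of effects on the two
programs is Fisher-z transformed (`z ~ N(Z, 1/(N−3))`, average ranks for
ties, |ρ| = 1 clamped to 1 − 1e-12). Four Gaussian models — M1 (p1
drives p2), M2 (reverse), M3 (independent), M4 (shared correlation
regardless of ascertainment) — are compared by AIC, and the relative
likelihood `r = exp((AIC_causal − AIC_noncausal)/2)` declares a
direction when r < 0.01. Fewer than four significant regulators on
either side makes the pair untestable. Regulators significant for both
programs stay in both ascertainment sets.

### TF ChIP scores

Peak sets become per-gene scores `S = Σ_k P_k · exp(−x_k/d)` with
strength P (−log10 q), TSS distance x, and decay d of 5 kb or 50 kb.
Distances use the summit (column 10 of narrowPeak) when a non-negative
offset is present, otherwise the floored midpoint; coordinates are
0-based half-open throughout; cross-chromosome peaks contribute zero.
TFs are classified activator/inhibitor by Mann–Whitney tests of their
scores over down-/up-regulated knockdown DEGs against the background
with that TF's DEGs removed (the background exclusion is a documented
choice), keeping per TF the decay with the stronger DEG correspondence;
a TF may carry both flags. Program annotation tests whether a TF's
scores are higher on the program's top-loading genes.

### The five-step graph construction

1. **Regulator side.** Exhaustive best-subset regression of γ on program
   effect vectors (shet and intercept always included). The subset
   *size* is chosen by repeated 80/20 out-of-sample R² (smallest size
   within 0.001 of the best mean test R²). An in-sample elbow rule
   (stop when the R² gain drops below 10% of the total gain) is
   available but not the default: the estimated per-program effect
   vectors are compositional mixtures of the true ones — per-cell
   normalisation removes absolute scale — so in-sample gains pile onto
   the first column chosen and the elbow rule under-selects, while the
   per-gene totals in step 3 are invariant to that mixing only when all
   involved programs enter the joint model. Out-of-sample R² recovers
   the full set under the same conditions.
2. **Content side.** Programs ranked by the program-burden-effect
   permutation p; the kept count defaults to the Bonferroni-significant
   count. A Mann–Whitney fast path (top-loading genes vs the rest)
   replaces the permutation ranking inside label permutations — and, by
   default, inside LOOCV folds — where thousands of re-rankings would
   otherwise dominate runtime; the resulting permutation p is, if
   anything, conservative.
3. **Signs.** A regulator's total effect is `Σ_p w_p · β(x→p)` over the
   selected programs it significantly regulates; its predicted sign is
   the sign of that total, unassigned on cancellation below 1e-12.
   Content genes take their program's content sign (the sign of the top
   genes' mean γ); for a gene in several selected content programs, the
   most significant program wins, and content beats the regulator sign
   for dual-role genes (program function plausibly dominates).
4. **Validation.** Leave-one-out cross-validation refits the selection
   (sizes fixed at the full-data values) without each gene in the
   high-|γ| and minimal-|γ| strata and tests, by Fisher's exact test,
   whether correct sign predictions are enriched among high-effect
   genes. Separately, gene labels of γ are permuted (20,000 times at
   full scale) and the whole selection-and-assignment pipeline reruns
   per permutation with the observed subset sizes, yielding
   `(1 + #{perm Fisher p ≤ observed}) / (n_perm + 1)`.
5. **Graph.** Only high-|γ| genes whose predicted sign matches their γ
   enter the graph; multi-path regulators keep every edge; JSON
   serialization round-trips byte-identically.

## The generator, and what passing tests do not show

`simulate_truth()` plants disjoint regulator and member sets per
program, signed regulator effects, and a trait built as
`γ = Σ_p w_p β(x→p) + content_p·1[member] + ε`. shet has a Beta(2, 5)
marginal coupled to |γ| by a Gaussian copula. Burden SEs increase
linearly in shet across `se_range` — the real coupling between
constraint and LoF-carrier counts is unknown, so this monotone link is a
modelling choice. Cells carry one perturbation each; usages are
`max(0, Gamma-baseline + batch offset + β + noise)` with a Gamma(4, 4)
baseline (mean 1, CV 0.5) so program activities genuinely vary across
cells; expression is the loading-weighted usage mix rescaled to the
target depth, a mito-like block takes a Beta-distributed fraction of
each cell's counts, and counts are Poisson (overdispersion is
deliberately absent: the downstream regressions operate on normalised
values and Poisson is the simplest generator satisfying their
assumptions). Generator defaults mirror a genome-scale erythroid
CRISPRi screen — 166 cells per perturbation, ~11,500 UMIs per cell.

The workflow and the heavier tests run a scaled-down study chosen once:
300 genes, 3 programs, 20 regulators and 30 members each, 50 cells per
perturbation, 500 controls, depth 6,000, burden SEs 0.05–0.25, trait
noise 0.03, path weights (0.6, −0.5, 0.4) against content weights
(0.2, 0.15, 0.1) — program 2 deliberately discordant (regulation pulls
the trait down while content pushes it up). These sizes keep every
stage minutes-scale while leaving all effects comfortably detectable.

What the generator does not emulate — and what green tests therefore do
not establish about real data: guide-level variation and off-target
effects, doublets and ambient RNA, overdispersed counts, linkage and
variant-level structure behind the burden estimates, syntenic clustering
of co-regulated genes, and programs whose loadings overlap heavily. The
compositionality of expression *is* emulated (it is what motivated the
CV-based subset-size rule), but real datasets mix programs in ways a
three-program plant cannot represent.

## Numerical and degenerate-input choices

* Posterior quadrature as described above; normaliser underflow raises
  an error naming the gene rather than returning 0/0.
* Prior fitting: Nelder-Mead on (logit p, log α, log θ), three
  moment-informed starts, marginal likelihood by Gauss–Legendre on the
  prior probability scale (60 segments × 7 nodes); a flat profile in p
  (all-zero γ̂) raises a `p_unidentifiable` attribute instead of failing.
* Permutation p-values live on the +1-corrected lattice and are never 0;
  tie comparisons use a 1e-9 relative epsilon so exactly-equal null
  draws count as ties rather than falling to floating-point noise.
* Constraint deciles assign ties to the lower bin
  (`ceiling(10·rank_min/n)`); the gene universe is sorted before
  matched sampling, making the permutation p invariant to any joint
  permutation of the inputs.
* k-means uses 10 restarts under a fixed seed; program numbering is by
  decreasing cluster size with lexicographic spectrum tie-breaks, so a
  decomposition is a pure function of (matrix, parameters, seed).
* Rank-deficient designs (a batch confounded with a perturbation) skip
  the target with a log entry; constant responses return β = 0, p = 1.
* Best-subset search solves normal-equation subsystems from one
  precomputed cross-product matrix; LOOCV downdates it by rank-1 per
  fold rather than refitting from scratch.

## Known limitations

* Per-bin priors are coarser than feature-learned priors; with strong
  heterogeneity inside a bin the shrinkage is miscalibrated toward the
  bin average.
* The causal test inherits the Fisher-z variance approximation
  `1/(N−3)`; with correlated regulator sets or shared measurement noise
  between programs the null is optimistic. Its power is also modest at
  moderate correlations: with 50 regulators per side and a planted
  Spearman correlation of 0.70, the `r < 0.01` rule against the best
  non-causal alternative (the shared-correlation model is the binding
  one) recovers the true direction in roughly 83% of replicates, and
  crosses 90% only around a planted correlation of 0.74 — the test is
  built for strong asymmetries, not marginal ones. On cell-level data
  the compositional mixing of estimated usages further dilutes the
  ascertained regulator sets, so program pairs need pronounced one-way
  feedback before a direction is declared.
* The estimated w_p are mixtures of the true path weights whenever the
  factorization mixes programs; only per-gene totals (and hence signs),
  not individual w_p, should be interpreted.
* LOOCV fixes the subset sizes found on the full data; fully re-tuned
  folds would be quadratic in gene count.
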