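---
title: "Reference-gene stability: models, estimators and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-gene stability: models, estimators and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

# The problem

qRT-PCR quantifies a target transcript relative to reference genes that are
assumed stable across the conditions compared. In woody tissues undergoing
radial change — the cambium-to-transition-zone series of a tree stem, where
sapwood parenchyma progresses toward programmed cell death — classic
housekeeping genes can vary strongly, so candidates must be screened and
ranked empirically. `refstab` implements that evaluation chain on
quantification-cycle (Ct) matrices: genes in rows, samples in columns, tissue
groups as sample annotations, technical replicates as a third dimension that
is collapsed to the per-cell arithmetic mean before analysis (mean-of-Ct is
the convention the stability tools assume; no outlier rule is applied to
replicates).

# Data model and units

Everything downstream consumes a complete Ct matrix. One Ct unit corresponds
to one twofold abundance change at 100 % amplification efficiency, which is
why the package simulates and analyzes directly on the cycle scale. Missing
Ct values are rejected at import by default; the explicit `drop_sample`
policy removes an entire sample instead, because geNorm and BestKeeper
require complete matrices.

# Standard curves

`fitStandardCurve()` regresses Ct on log10 relative input of a serial
dilution (fivefold steps by convention, most concentrated point at 0 — only
the ratios matter for the slope) and reports the squared Pearson correlation
as R², with efficiency

$$E = (10^{-1/\text{slope}} - 1) \times 100\,\%.$$

A non-negative slope cannot come from a working assay; such fits are
returned flagged invalid rather than silently extrapolated. Noise-free
simulated series invert this mapping to machine precision for any E in
(50, 150), which the tests exercise.

# The three stability algorithms

**geNorm.** Quantities default to perfect doubling, $Q = 2^{Ct_{min} - Ct}$,
because the downstream $2^{-\Delta\Delta Ct}$ analysis makes the same
assumption; per-gene efficiencies from the standard-curve module may be
supplied optionally. $M_j$ is the mean over partners $k$ of
$SD_{samples}[\log_2(Q_j/Q_k)]$, making it invariant to per-sample additive
Ct shifts (loading/common variation). The stepwise ranking removes the
highest-M gene and recomputes; the final two genes are mutually unrankable
and share rank 1 — so 12 genes yield ranks 1..11. With exactly two genes, M
equals the pair's V for both and is emitted with a warning, matching the
original tool. Exclusion ties are broken by removing the later gene in input
order, so earlier input keeps the better rank; this makes output
deterministic. $V(n/n{+}1)$ compares normalization factors (per-sample
geometric means of the $n$ and $n{+}1$ most stable genes); the conventional
0.15 cutoff only drives an advisory recommendation, never a filter, as does
the advisory M < 1.5 annotation in the pipeline report.

**NormFinder.** On the log2-quantity scale ($y = -Ct$), the model per group
$g$ is $y_{igj} = \alpha_{ig} + \beta_{gj} + \varepsilon_{igj}$ with
$Var(\varepsilon) = \sigma^2_{ig}$. Two-way centering within each group gives
residual sums of squares $s^2_{ig}$ whose expectation mixes the gene's own
variance with the average over genes; the moment-corrected estimator

$$\hat\sigma^2_{ig} = \frac{z}{z-2}\Big(s^2_{ig} - \frac{\bar s^2_g}{z-1}\Big)$$

(with $z$ genes) undoes that mixing. It is unbiased, so for a truly
noise-free gene it dips negative about half the time; negative estimates are
clamped to zero and flagged. Inter-group deviations $d_{ig}$ (double-centered
group means) are shrunk toward zero by their sampling variance
$\hat\sigma^2_{ig}/n_g$ through the usual variance-ratio factor; when both
the between-gene signal variance and the sampling variance are zero the
shrinkage factor is defined as 0. The stability value is the mean over
groups of $|\tilde d_{ig}|$ plus the mean intra-group SD — lower is more
stable. Grouped mode needs ≥ 2 groups with ≥ 2 samples each; ungrouped mode
(≥ 3 samples) reports the model-based per-gene SD alone. Both modes are
exposed because tissue grouping is a design choice of the experiment, and
the consensus machinery accepts either.

**BestKeeper.** Descriptive statistics are computed on the Ct scale; the
BestKeeper index is the per-sample geometric mean Ct over all candidates (no
iterative exclusion), and each gene is scored by its Pearson r with the
index, higher being more stable. The dispersion column defaults to the
classical sample standard deviation — the definition matching a "standard
deviation" column — with `sdMethod = "mad_gm"` switching to the original
tool's mean absolute deviation from the geometric mean; published summary
tables generally cannot disambiguate the two. A gene with zero Ct variance
has undefined r and is reported as not rankable; consensus then either
errors or assigns it the last rank under an explicit policy.

# Consensus ranking

Metrics are converted to dense ranks: tied genes share a rank and the next
distinct metric gets the previous rank + 1. Dense ranking is the only
convention consistent with a tied geNorm top pair followed by third-listed
genes at rank 2 and fourth-listed at rank 3 — competition ranking would shift
them — and it is what makes a mean rank of (3 + 1 + 1)/3 = 1.7 possible for a
gene listed third under geNorm and first elsewhere. The consensus is the
arithmetic mean of the three ranks (geometric-mean aggregation is
deliberately not offered), reported rounded half-up to one decimal
(1.666… → 1.7, 3.333… → 3.3) while full precision orders the table;
remaining ties break by geNorm rank, then input order.

# Relative quantification

The normalization factor is the per-sample arithmetic mean Ct of the
reference set, which on the quantity scale is exactly the geometric mean of
the reference quantities: $2^{-\overline{Ct}} = \mathrm{geomean}(2^{-Ct})$.
ΔΔCt uses a calibrator sample, or the mean ΔCt of a calibrator group; fold
changes are $2^{-\Delta\Delta Ct}$ with efficiency fixed at 100 % — the
Pfaffl efficiency-corrected model is deliberately omitted to match the
printed method. Fold changes are invariant to per-sample loading shifts and
chain multiplicatively across calibrators.

# Screening, clustering and the DE filter

Candidate references are screened from FPKM tables by three simultaneous
rules: abundance ≥ 5 FPKM in every tissue, largest pairwise fold change
between tissue values < 2, and q ≥ 0.05 in every differential comparison.
When group labels are present, tissue values are group means. z-score
standardization uses the sample (n−1) SD by default (a population-SD switch
exists); constant rows map to zeros with a flag. K-means uses Lloyd
iterations from k-means++ seeds, best of `nRestarts` by inertia, with a
mandatory seed; k defaults in the pipeline to 12 for FPKM tables and 6 for
qPCR-derived tables. The differential filter enumerates all pairwise group
comparisons (six for four tissues), computes linear fold changes of group
means (direction-agnostic) and two-sided Welch t-tests on log2 values, and
flags genes passing fold > 2 and p < 0.05; a one-way ANOVA p per gene is
reported as the overall statistic. The test behind a printed "P < 0.05" in
RNA-seq pipelines is typically tool-internal; the Welch t is a documented
stand-in, and p values are not multiple-testing corrected by default (a
Benjamini–Hochberg option exists) to match the plain threshold rule.

# The synthetic-data generator

`simulateCtMatrix()` draws
$Ct_{igr} = \mu_i + \delta_{ig} + s_j + e_{ij} + \epsilon_r$ — gene baseline,
centered inter-group shift, a per-sample loading shift shared across genes,
intra-group noise $N(0, \sigma_i)$ and replicate noise $N(0, \sigma_{rep})$.
These are precisely the components the stability algorithms are built to
separate: the shared $s_j$ exercises geNorm's invariance to common
variation, and $(\sigma_i, \delta_{ig})$ are the intra-/inter-group terms of
the NormFinder model. Defaults emulate a tree-tissue reference screen: 12
candidate genes, 4 tissue groups (X1–X4) of 3 biological samples, 3
technical replicates, baselines spread over Ct 20–28, intra-group SDs
0.2–2 cycles, inter-group shift SDs 0–1.5 cycles, replicate SD 0.15 and
loading SD 0.3 — ranges consistent with published Ct summary tables for such
tissues. Each dataset carries a `SimulationTruth` whose ideal stability
ordering sorts genes by total perturbation $\sigma_i^2 + Var_g(\delta_{ig})$.

What the generator does **not** emulate: PCR kinetics (no per-cycle
amplification curves, no Cq calling), efficiency differences between genes
(Ct is simulated on the perfect-doubling scale), replicate outliers,
heteroscedastic high-Ct noise, and count-based RNA-seq error (FPKM tables
are log-normal). Passing tests therefore demonstrate correctness of the
estimators under their own model assumptions, not robustness to assay
artifacts.

# Validation design and numerical choices

The NormFinder recovery check uses 8 genes in 2 groups of 10 samples, with
true total perturbations forming a geometric ladder ($0.01 \times 2.2^k$,
$k = 0..7$) split randomly between the intra- and inter-group components and
inter-group shifts sign-balanced and centered across genes. Two properties
of the method dictate this design. First, normalization-based estimators see
only *relative* inter-group variation: a shift common to all genes is
absorbed into the group effect, exactly as a per-sample loading shift is
absorbed into the sample effect, so an identifiable truth must have
gene-centered shifts. Second, the stability value combines components on the
SD scale (an L1-type sum) while total perturbation adds variances (L2);
the two orderings provably agree when successive true perturbations are
separated by more than a factor of two, hence the geometric ladder. With
well-separated components the estimated ranking matches the truth at
Spearman ≥ 0.9 in well over 90 % of seeded runs; with near-duplicate
perturbations no method could resolve the order at this sample size.

Other choices: rank ties break by input gene order; mean ranks round
half-up (R's own `round()` is half-to-even); the BestKeeper index of a
single-gene candidate set is that gene's Ct (r = 1); simulations use one RNG
per dataset, seeded mandatorily, via isolated RNG state so library calls do
not perturb user sessions; test oracles (all-pairs log-ratio SDs, per-sample
geometric means, dense-rank enumeration) are written independently of the
implementation paths they check; problem sizes in the test suite (4×6 to
12×12 matrices, 100–1000 randomized trials, 500+ samples for
variance-component recovery) are chosen so every stochastic check is
decisively powered at a fixed seed.

The package's functions and `runPipeline()` are the interface; the pipeline
accepts a YAML/JSON config whose keys carry the conventional thresholds
(M < 1.5 advisory, fold > 2, p < 0.05, FPKM ≥ 5, q ≥ 0.05) as defaults, and
its outputs contain no timestamps so reruns under one seed are
byte-identical.

# Limitations

No efficiency-corrected (Pfaffl) quantification; no confidence intervals on
stability values or fold changes; no ΔCt-method fourth algorithm; no
RDML/thermocycler import; no raw fluorescence processing; no
negative-binomial count modeling upstream of FPKM tables; no
choice-of-k diagnostics beyond the inertia. Consensus values that depend on
unpublished portions of per-algorithm orderings (see
`?publishedRankings`) are internally consistent but are not reproductions
of reported numbers.
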