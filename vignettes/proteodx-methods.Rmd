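---
title: "proteodx: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{proteodx: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteodx)
```

## The problem

Inborn errors of immunity (IEI) are monogenic immune disorders, and a large
fraction of clinically diagnosed patients carry no pathogenic variant
detectable by exome or panel sequencing. Expression layers can close part of
that gap: when a causal gene is silenced or its product destabilized, the
deficit is visible as an outlying protein (and sometimes mRNA) level in that
one patient against the rest of a cohort. `proteodx` implements that
diagnostic route for paired PBMC data: a DIA-MS protein intensity matrix and
a targeted RNA-seq count matrix over the same samples, plus the exploratory
analyses that sit around it — protein–mRNA correlation profiling and
marker-based classification of B- and T-cell-deficient samples.

Everything is exercisable without access to any real cohort through a
synthetic-cohort generator with planted ground truth.

## Missingness model and its consequences

DIA proteomics missingness is missing-not-at-random: dropout is
left-censored, i.e. concentrated below a detection limit. The package's
working model, used both by the generator and implicitly by every
preprocessing choice, is logistic censoring in log2 abundance:

$$P(\text{missing} \mid a_{gs}) = \mathrm{logit}^{-1}\big((m - a_{gs})\,s\big)$$

with midpoint $m$ (log2 units) and steepness $s$ (1/log2 units). Two
diagnostics verify the regime on data: the per-sample regression of
missing-value proportion on total observed abundance (negative slope under
censoring) and the abundance distributions of proteins with vs without
missing values (the with-MV group sits lower). Note one caveat the test
suite makes explicit: the regression slope has a weak mechanical negative
bias even under abundance-independent (MCAR) dropout, because removing cells
directly lowers the observed total; the density ordering is the sharper
discriminator.

Imputation is arm-specific:

* **diagnostic arm** (`impute_missing(..., "zero")`): missing = below
  detection. Values are shifted so the smallest observed log2 value maps
  to 1 and missing cells get the hard floor 0. A knocked-out protein that
  drops below the limit lands exactly on the floor — these genes form the
  straight line in the lower-left of the patient-vs-control MA plot.
* **exploratory arm** (`impute_missing(..., "min_det")`): deterministic
  minimal-value imputation, each missing cell receiving a low quantile
  (default 0.01, type 7) of its sample's observed values. Distance-based
  methods (k-means) should not see a spike at an arbitrary floor.

## Normalization

Both published options are provided and assessed by
`assess_normalization()` (pooled intragroup CV and the MAD of per-sample
medians — an internal stand-in for an external normalization comparison
report):

* `quantile_normalize()` — classic rank-mean scheme with average-rank ties.
  It equalizes per-sample distributions exactly and is idempotent, but it
  compresses sparse tails; an extreme single-sample loss signal shrinks.
* `rlr_normalize()` — per-sample robust (Huber, $c = 1.345$) regression on
  the gene-median pseudo-reference, inverted to correct the sample. Affine
  distortions are removed exactly and within-sample gaps are preserved.

Because the diagnostic statistic *is* a within-sample gap, the diagnostic
arm pairs zero-imputation with RLR; quantile normalization serves the
exploratory arm, where only relative ordering across samples matters. This
assignment is a package design choice: the source study evaluated both
normalizations without stating a final per-arm pairing.

RNA counts get a variance-stabilizing transform built on median-of-ratios
size factors (genes with any zero excluded from the median), then
`log2(count/sf + 1)`. Size factors are rescaled to median 1. That anchor
matters for a subtle reason: no size-factor scheme whose reference is built
from the data can be *exactly* invariant to rescaling one sample — the
reference moves. Anchoring at the median confines the effect to the
re-identification of the median element, a drift of order
dispersion/$\sqrt{n_\text{genes}}$ log2 units, and the tests assert
invariance within that bound rather than pretending exactness.

## Single-case diagnosis

For each gene, the cohort z-score is $(x_{gs} - \bar{x}_g)/\mathrm{sd}_g$
with the $n-1$ denominator, computed over all non-excluded samples
*including* the case (the published per-case distributions include the
case; a leave-one-out variant is exposed as a flag). $|z| \ge 2$ is
significant, boundary inclusive. Genes with zero variance have undefined z
(`NA`), never 0. Genes absent from the targeted RNA panel have *absent*
mRNA z, which routes them to the `protein_only_down` archetype rather than
`concordant_down` — with a ~500-gene panel this distinction is load-bearing.

Against healthy controls, `case_vs_hc()` reports
$\mathrm{lfc} = \log_2 x_\text{case} - \overline{\log_2 x_\text{HC}}$ (the
HC aggregate is the arithmetic mean of log2 values, i.e. a geometric mean of
intensities) and flags $\mathrm{lfc} < -5$, strictly — a reduction to below
1/32 of the control mean. Candidates are ranked by protein z ascending with
a lexicographic tie-break, so reruns are reproducible.

One selection effect is worth knowing: conditional on a knocked-down
protein being *observed* (it sneaked above the detection limit), its value
is drawn from the upper noise tail, so its measured fold change is
systematically smaller than the planted effect. Recovery of an effect
equal to ~5 log2 units therefore hovers near the $-5$ threshold; the
recovery studies plant 7 log2 units, matching the near-complete protein
loss of real index cases.

## Protein–mRNA correlation

Per-gene Spearman correlation (average ranks) across shared samples on the
exploratory arm; zero-variance genes are excluded with a reason rather than
given an arbitrary value. Strength bins on $|\rho|$, left-inclusive:
$\ge 0.7$ strong, $[0.4, 0.7)$ moderate, $[0.2, 0.4)$ weak, $< 0.2$ none.
(The published prose is self-contradictory at exactly 0.2; the
left-inclusive convention puts 0.2 in "weak".) Summaries use type-7
(linear-interpolation) quartiles.

## Marker clustering and elbow validation

`select_markers()` ranks a cell type's annotated candidates by missing-value
fraction ascending, specificity descending, then gene id, and keeps 3 for
the protein layer (the RNA layer, target-enriched and complete, keeps all
candidates passing specificity). Specificity scores are user-supplied
annotation — in synthetic cohorts they come from the generator's truth; in
real use they would come from an expression atlas, which is deliberately
not bundled.

Samples are clustered in per-gene z-score space by k-means, $k = 2$, with
k-means++ seeding, 50 restarts, and a fixed seed; the cluster with the
lower mean marker z is the deficient cluster. The elbow over
$k = 1,\dots,8$ is the maximizer of the discrete second difference of the
within-cluster SS curve (ties toward smaller k), with a low-confidence flag
when the maximal curvature is under 10% of the total SS drop (a near-linear
curve has no meaningful elbow). Layer agreement is reported as
intersection/Jaccard/containment; containment $|P \cap R|/|P| = 1$ is the
published pattern of protein calls nested inside RNA calls.

## Differential expression and enrichment

`moderated_dea()` implements the standard empirical-Bayes moderated t:
prior df $d_0$ and prior variance $s_0^2$ estimated by moment matching on
$\log s^2_g$ (trigamma inversion by Newton), posterior variance
$(d_0 s_0^2 + d s^2)/(d_0 + d)$, p-values on $d_0 + d$ df. A degenerate fit
($d_0 \to \infty$) is capped at $10d$. At $d_0 = 0$ the statistic reduces
to the ordinary equal-variance t-test — a limit the tests verify against a
textbook oracle, alongside a cross-check of the full fit against limma.
Significant downregulation is *strict* on both criteria: $p < 0.05$ and
$\mathrm{lfc} < -1.5$.

Enrichment is the upper-tail hypergeometric test against the universe of
genes actually tested in the DEA (not the genome — the measured set is
composition-biased), BH-adjusted across sets, significant at adjusted
$p < 0.01$, with top-10 reporting. BH is the classic step-up with
monotonicity enforcement. The enrichment p-value is discrete, so its null
calibration is tested against the exact overlap distribution, not a
continuous-uniform KS test.

## The synthetic cohort: what it emulates, what it does not

Per gene $g$, sample $s$ (log2 scale):

$$a_{gs} = m_g + b_{\text{batch}(s)} + \gamma_g c_s +
  \sigma\big(\rho_g T_{gs} + \sqrt{1 - \rho_g^2}\, e_{gs}\big)$$

* $m_g \sim N(20, 2^2)$ — log2-normal intensities at a typical DIA report
  scale; the study does not state its intensity distribution, so
  log-normality is an assumption, not a fit.
* batch shifts $b \sim N(0, 0.3^2)$ over 3 patient batches + a control
  batch, emulating multi-site collection.
* $c_s \sim N(0, 0.5^2)$ is the latent B- (or T-) cell level; $\gamma_g$ is
  the 0/1 marker indicator. It enters both layers, so marker genes have
  high protein–mRNA correlation *structurally*, as observed for
  cell-type-specific genes. `rna_cell_gain` scales the RNA-side effect.
* the shared latent $T_{gs}$ gives gene $g$ a tunable protein–mRNA
  correlation $\rho_g$: 0.85 for markers, 0.3 for the background (the
  published cohort median correlation is ~0.29). Within-gene noise
  $\sigma = 0.6$ log2 units (~40–50% CV), typical of cohort DIA.
* censoring: midpoint 16 (2 gene-sd below the mean), steepness 3/log2 —
  a sharp detection limit, ~2–4% overall missingness at defaults. A steep
  limit is what makes single-case dropout informative: a high-abundance
  protein essentially never drops out by chance, so its absence in one
  patient is a diagnostic signal, not noise.
* RNA counts $\sim \mathrm{NB}(\text{libsize} \cdot 2^{r_{gs}},\ 1/0.1)$
  with log-normal library sizes — the standard bulk-count assumption; the
  study gives no RNA noise model.
* planted effects subtract their log2 effect *before* censoring, so a
  knockout can (and usually should) fall below the detection limit;
  `global_dropout_outlier` raises one sample's censoring midpoint, the
  stand-in for the excluded high-missingness samples.

Not emulated: peptide-level structure and rollup, shared-peptide artifacts,
spectral interference, RNA read-level effects (mapping, splicing, allele
bias), longitudinal dynamics. A green recovery test therefore establishes
that the *statistical pipeline* recovers planted signals under MNAR
censoring and batch structure — not that any upstream quantification issue
is handled.

Defaults were chosen once as the package's stated world and are not tuned
per test: cohort 63 + 6 mirrors the study; 2000 protein genes (vs 8857) and
500 targeted genes (vs 527) keep the suite at desk scale with the funnel's
shape intact.

## Numerical and degenerate-input policy

* Percentages are printed with round-half-up, matching clinical-report
  convention.
* Outlier flagging uses per-PC robust z-scores (median/MAD) at
  $k_{\mathrm{MAD}} = 4$, and an MV-proportion screen whose MAD is floored
  at the binomial sampling noise $\sqrt{p(1-p)/n_\text{genes}}$ — the raw
  MAD of a tightly clustered cohort underestimates that noise and
  over-flags. Flagging everything is an error, not a result.
* PCA for eligibility fills missing cells (projection only) with the
  per-gene observed *minimum*, the fill consistent with left-censoring;
  mean-filling would drag exactly the samples the screen must catch back
  into the centroid. Genes > 50% missing stay out of the projection.
* Exactly-affine samples bypass the IRLS fit in `rlr_normalize()` (the
  robust scale estimate degenerates); OLS is exact there. Genuine
  non-convergence falls back to OLS with a recorded warning.
* Ties everywhere break lexicographically by id; every stochastic step
  takes an explicit seed.

## Known limitations

* The seven-sample exclusion and the exact MV-filter threshold of the
  source study are unstated; the defaults here (robust rule at
  $k_{\mathrm{MAD}} = 4$, MV fraction ≤ 0.3) are reproducible stand-ins,
  not reconstructions.
* Correlations are computed on imputed exploratory-arm values; whether the
  study used observed-only pairs is unknown, and a flag switches arms.
* The DEA p-threshold (0.05) is applied to raw p-values; the published
  wording is ambiguous, and an adjusted-p mode is exposed.
* Single-timepoint protein–mRNA correlation underestimates the coupling of
  the two layers; nothing in this package addresses temporal context.
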