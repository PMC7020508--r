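---
title: "Expression-based sample QC: models, parameters and design choices"
author: "exprqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression-based sample QC: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exprqc)
```

## The problem

Read-level and alignment-level QC can miss a failed sample entirely: a library
that collapsed during preparation still produces well-formed, well-mapping
reads — just far fewer informative ones. The damage only becomes visible at
the expression-matrix level, as depressed counts, displaced multivariate
position, and a distorted GC response. `exprqc` works at that level. It takes
two tab-delimited files — a gene-by-sample count matrix from any
summarization tool (RSEM, HTSeq, featureCounts, Kallisto, Salmon, ...) and a
phenotype sheet (`sample`, `group`, plus any covariate columns) — and computes
an ensemble of complementary diagnostics. No single metric decides anything;
an outlier is a sample that departs from its phenotypic group on *several*
technically-oriented views at once, and a sample that moves only on
biology-dominated views is biology, not a defect.

Sample exclusion is deliberately file-driven: counts columns without a
phenotype row are dropped at assembly, so removing a suspect sample and
re-running the whole QC is a one-line edit of the phenotype sheet.

## The metric surface

**Summary statistics.** Per sample, on the raw count scale: detected genes,
mean, SD, median, min, max, range, skewness, kurtosis, library size (column
sum) and expressed genes (count > 0). Skewness is the population moment
coefficient $g_1 = m_3/m_2^{3/2}$ and kurtosis the population excess
$g_2 = m_4/m_2^2 - 3$, both defined as 0 when $m_2 = 0$; neither estimator is
bias-corrected. These conventions are stated because different ecosystems
default to different estimators, and moment values are not comparable across
them. Whether to compute moments on raw or transformed counts is a genuine
choice; we use raw counts, which makes depressed samples stand out directly
in the table.

**Counts distribution.** A five-number summary per sample of
$\log_2(\text{count}+1)$, using the linear-interpolation quartile convention
(`quantile` type 7) rather than Tukey hinges — box statistics differ across
conventions and ours is pinned.

**Mapped-read density.** Gaussian kernel density of per-sample expression on
a log2 scale. For human or mouse with a gene annotation the input is TPM:
$$\mathrm{TPM}(g,s) = \frac{c_{gs}/l_g}{\sum_{g'} c_{g's}/l_{g'}} \times 10^6,$$
with $c$ the reads mapped to a gene and $l$ the gene length (bp). Columns sum
to $10^6$ by construction; genes without annotation are dropped and the rates
renormalized over the annotated set (the drop is reported). For other
organisms — where no annotation route is bundled — a variance-stabilizing
fallback is used: median-of-ratios size factors $\hat{s}_j = \mathrm{median}_g
\left(c_{gj}/(\prod_k c_{gk})^{1/n}\right)$ over genes positive in all
samples, then $\log_2(c/\hat{s}+1)$. This is deliberately *not* the full
dispersion-trend variance-stabilizing transform; it keeps the two properties
that matter for a density comparison (depth removal, log compression), is
deterministic and has a ten-line definition a reviewer can check by hand. The
density bandwidth is Silverman's rule per sample; all samples are evaluated
on a shared 512-point grid spanning the global range padded by three
bandwidths, so curves are directly comparable and integrate to ≈ 1.

**Housekeeping profiles.** GAPDH and ACTB (human; `Gapdh`/`Actb` for mouse)
are stably and highly expressed almost everywhere, so a sample in which both
sit clearly below its peers is suspect for technical reasons. Profiles are
$\log_2(\text{count}+1)$ of the *input* matrix by default — deliberately
depth-sensitive. A depth-normalized option (`values = "normalized"`) exists,
but it is not the default precisely because within-sample normalization such
as TPM cancels the library collapse this check exists to reveal; a collapsed
library would look normal on the TPM scale. Lookup is by bundled Ensembl id
or symbol; with non-Ensembl identifiers the metric skips and points at
`gene_profile()` for a manual query.

**PCA, twice.** Samples are observations and genes variables; gene columns
are centered, never rescaled (rescaling is the z-score step's job).
The *z-scored* view first standardizes each gene row to mean 0, variance 1
($z = (x-\mu)/\sigma$, population $\sigma$; constant rows become zeros and
are counted rather than dropped so the matrix shape is stable), which equalizes
every gene's influence and shows biology-dominated structure. The
*un-normalized* view decomposes the raw counts, where a handful of
high-expression genes and — crucially — library-size differences dominate PC1;
that is exactly the mechanism by which a depth-collapsed sample separates, so
"PC1 extreme on raw counts but unremarkable after z-scoring" reads as
*technical*, and the reverse as *biological*. Component signs are fixed so the
largest-magnitude loading is positive, making score tables reproducible
across linear-algebra backends.

**Multiple factor analysis.** When the phenotype sheet carries covariates
(protocol, flow cell, extraction method, ...), the expression block (z-scored
genes) and one indicator block per covariate are analyzed jointly. Covariate
blocks are centered one-hot indicators with each level column scaled by
$1/\sqrt{p_j}$ (level frequency); every block is then divided by
$\sqrt{\lambda_1}$ of its own first separate eigenvalue — the
inverse-first-eigenvalue balancing that stops any one group from dominating —
and a global SVD yields sample scores and, from squared loadings, each
group's contribution to each component (contributions per component sum
to 1). The covariate whose group tops component 1 is the leading source of
variation. With no covariate columns the analysis returns a skip marker, not
an error: nothing to attribute. Full MFA duality (partial-axes geometry,
supplementary points) is intentionally out of scope; the weighting idea is
the part that does diagnostic work. Note that the expression block, having
thousands of variables, always carries most of the *total* contribution —
attribution questions are answered by comparing the covariate groups with
each other.

**Hierarchical clustering and correlations.** Agglomerative clustering of
samples under Euclidean distance on $\log_2(\text{count}+1)$, complete
linkage by default (`linkage =` exposes the alternatives). Pearson and
Spearman correlation matrices (average-rank ties) on the same log scale by
default — `corr_input` switches to raw or TPM, since the field has no single
convention; heatmap leaf order comes from Ward linkage on $1-r$.

**GC bias.** Per sample, a LOWESS fit (tricube-weighted local linear
regression, span $f = 2/3$, 3 robustness iterations — Cleveland's classic
defaults, exposed as parameters) of $\log_2(\text{count}+1)$ against gene GC
fraction, over the genes shared between matrix and annotation (at least 20
required). The log scale keeps the smoother out of the grip of the extreme
right tail of raw counts; this is a documented choice, not a claim about any
particular convention. A sample whose curve sits below the others,
especially on the high-GC side, points at amplification/library-preparation
trouble. Gene length and GC come from a user-supplied annotation table —
deterministic and offline, rather than a live annotation-service query.

## The outlier-flag heuristic

Reading the ensemble is a human judgment; `flag_outliers()` codifies the
obvious part of it as four independent advisory rules, each a robust z-score
$(x - \mathrm{median})/\max(\mathrm{MAD}, \text{floor})$ with threshold 2.5:

| rule | statistic | direction | MAD floor |
|---|---|---|---|
| `low_library_size` | $\log_2$ library size | below | 0.2 |
| `low_housekeeping` | mean log2 GAPDH/ACTB expression | below | 0.5 |
| `pc1_leverage` | PC1 sum of squares / total sum of squares | above | 0.10 |
| `gc_depressed` | mean of the GC curve | below | 0.25 |

The floors encode technical tolerance: when all samples agree to within the
floor, no one can be flagged regardless of how small the MAD happens to be in
that draw. They are on interpretable scales — 0.2 on log2 library size is
roughly ±15% sequencing-depth variation; 0.5 log2 on a two-gene average
allows ordinary biological wobble of individual genes.

The leverage statistic deserves its own note. A sample's share *of PC1* is
useless here: in a homogeneous experiment PC1 must point somewhere, so
whichever sample is most variable always owns a large share of it. The share
of the **total** variance carried along PC1
($s_{i1}^2 / \sum_{jk} s_{jk}^2$) behaves differently: under homogeneity it
stays near $1/(n \cdot \text{rank})$-scale values for everyone, while a
genuine depth outlier concentrates most of the entire between-sample variance
into its own first coordinate. We measured both candidates on the simulator's
homogeneous preset before fixing the rule; the per-PC1 share misfired in over
half the runs, the total-variance share in almost none.

Flags never remove anything. They are a pointer at which sample to inspect;
removal happens, if at all, by editing the phenotype sheet. Below 4 samples
the heuristic is skipped — a median/MAD over three points is noise.

## The simulator

`simulate_counts()` draws negative-binomial counts
$c_{gs} \sim \mathrm{NB}(\mu_{gs}, 1/\phi)$ with
$$\mu_{gs} = L_s\, \mu_g \exp\big(\beta_g x_s + \textstyle\sum_c
\gamma_{g,\ell_c(s)} + \delta_s (gc_g - 0.5) + \varepsilon_{gs}\big)$$
— per-sample library scale $L_s$, lognormal per-gene baselines $\mu_g$,
group effects $\beta_g$ on a subset of genes, gene-level covariate effects
$\gamma$, a per-sample linear GC artifact $\delta_s$ on the log mean
(multiplicative on the mean, so the LOWESS metric can see it by
construction), and optional extra per-sample lognormal noise
$\varepsilon$ that inflates within-group variability without any technical
defect. Gene lengths are lognormal (floored at 200 bp), GC fractions
Beta(5, 5); two top-abundance genes are named GAPDH and ACTB so housekeeping
and TPM paths are exercisable end to end.

Defaults, chosen once as the study conditions: 2,000 genes; 8 samples in two
groups of four; baselines lognormal(meanlog 3, sdlog 1.2); dispersion
$\phi = 0.1$; 10% of genes carry group effects $\sim N(0, 0.7)$ on the
natural-log scale. 2,000 genes is an order of magnitude below a full
transcriptome; it is enough for every multivariate property being tested to
hold with margin while keeping hundred-replicate recovery experiments quick,
and the vignette states it here as the package's chosen problem size. The
presets plant the structures the metrics exist to find:

* **A** — clean negative control.
* **B** — one control sample with library scale 0.05 and GC slope −1.5 (a
  failed prep), and one diseased sample with extra biological noise
  (sd 0.35). The point of the pair: the first must be flagged, the second
  must not.
* **C** — three growth conditions (12 samples) with a `protocol` covariate
  (gene-effect sd 0.5) and a `flow_cell` covariate (sd 0.15) dominating a
  weak condition effect; MFA should hand component 1 to protocol.
* **D** — two cell types crossed with an RNA `extraction` covariate (sd 0.6)
  that overwhelms the cell-type effect (sd 0.2); samples cluster by
  chemistry, not biology.

What the simulator does **not** emulate: gene–gene correlation, isoform
structure, zero inflation beyond the NB, GC effects that interact with
length, or adapter/duplication artifacts. Passing the recovery experiments
therefore shows the metrics detect the planted mechanisms at realistic
magnitudes — it does not certify behavior on every real-data pathology.

## Numerical choices and degenerate inputs

* TPM requires integral counts and errors on an all-zero sample (its rate
  sum is 0); size factors error when no gene is positive in every sample.
* Z-scoring divides by the *population* SD — that, not the sample SD, is
  what makes the variance exactly 1 — and maps constant rows to zeros.
* Zero-variance samples get `NA` correlations and an explicit flag rather
  than a silent 1 or 0; the heatmap ordering falls back to input order when
  any correlation is undefined.
* LOWESS calls use `delta = 0.01 × range` (the classic interpolation
  speedup) by default; `delta = 0` forces the exact fit at every point and
  is what the oracle comparison in the test suite uses, at `iter = 0`.
* Ensembl ".N" version suffixes are stripped at read time (toggleable);
  duplicate gene ids — including duplicates *created* by stripping — are
  rejected with the offending ids listed, rather than summed or averaged
  behind the user's back.
* Determinism: identical inputs and configuration produce byte-identical
  tables; PCA/MFA component signs are pinned by the largest-loading rule.

## Known limitations

The variance-stabilizing fallback is a size-factor log transform, not a
dispersion-aware VST; very low counts retain more variance than a full VST
would leave them. Housekeeping lookup covers human and mouse only. The flag
heuristic assumes a majority of well-behaved samples (median/MAD logic); in
an experiment where half the samples failed, read the plots, not the flags.
MFA treats covariates as categorical; continuous covariates must be binned
by the user. GC curves require at least 20 annotated genes and are evaluated
at observed GC values, not on an extrapolated grid.
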