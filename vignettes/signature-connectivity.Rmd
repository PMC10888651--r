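---
title: "Connectivity scoring of drug-response signatures: methods and design"
author: "sigconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectivity scoring of drug-response signatures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigconn)
```

# Scope and model

`sigconn` implements a five-step in-silico drug-synergism workflow on bulk
(or pseudobulk) expression data: (A) build a drug-response gene signature
from a treated-versus-control experiment; (B–C) score it against a
CMap-style compendium of level-5 z-score profiles with a local
connectivity engine; (D) extract genes coherently modulated by the query
drug and each connected compound; (E) annotate those genes by correlation,
Ward clustering and hypergeometric pathway enrichment. The premise is
guilt by association: compounds inducing transcriptional profiles similar
to the query drug plausibly share its mechanism of action and are
candidates for synergy.

The engine operates entirely on local files (GCT/TSV matrices, TSV
metadata, GMT gene sets), so any compendium following the GSE92742 column
conventions — or the bundled synthetic generator — can serve as reference.

# Differential expression

Analysis is per experiment, two groups only (control vs treated, at least
three samples each); multi-factor designs are out of scope. Matrices are
log2 intensities; `quantileNormalize()` forces a common value distribution
across samples (rank-mean algorithm, ties averaged — delegated to
`limma::normalizeQuantiles`).

`fitDifferential()` reports per gene the log2 fold change
$\mathrm{logFC}_g = \bar y_g - \bar x_g$ and a moderated t statistic. The
pooled variance $s_g^2$ on $d_g = n_1+n_2-2$ df is shrunk toward a prior:

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},\qquad
\tilde t_g = \frac{\mathrm{logFC}_g}{\tilde s_g\sqrt{1/n_1 + 1/n_2}}$$

on $d_g + d_0$ df. The hyperparameters $(d_0, s_0^2)$ are estimated in
closed form by method of moments on $z_g = \log s_g^2$: under the scaled
chi-square model, $\mathrm{Var}(z)$ equals
$\psi'(d_g/2) + \psi'(d_0/2)$ up to the between-gene variance of the true
log variances, so $d_0$ solves
$\psi'(d_0/2) = \mathrm{Var}(z) - \psi'(d_g/2)$ (the trigamma function is
strictly decreasing, inverted with a bracketed root search) and $s_0^2$
follows from the mean of $z$. This estimator is deliberately simple and
closed-form rather than a full empirical-Bayes F-distribution fit; on
simulated data its t statistics correlate with `limma::eBayes` at
$r > 0.999$ (checked in the test suite). Degenerate cases: when
$\mathrm{Var}(z)$ does not exceed the sampling term, $d_0 = \infty$ and
all genes share $s_0^2$; when no gene has a positive variance the fit
falls back to the ordinary pooled t with a warning; as $d_0 \to 0$ the
moderated t reduces to the ordinary t (asserted in the tests at
$d_0 = 10^{-8}$).

P-values are two-sided; q-values are Benjamini–Hochberg (via
`stats::p.adjust`). The DEG filter is **strict**, $q < 0.05$: the
convention "filtered at a q-value of 0.05" does not fix the boundary, so
the strict form was chosen and exposed (`qCutoff`).

# Signature construction

DEGs are sorted by logFC descending; `buildSignature()` takes the first
150 positive-logFC genes (up tags) and the first 150 negative-logFC genes
from the other end (down tags), 300 tags maximum — the caps of the CMap
query interface. Genes with logFC exactly 0 belong to neither list. Ties
in logFC break by ascending q then gene id, making the selection total and
deterministic.

An allowed-gene list (the BING, "best inferred genes", query space)
restricts the tags. Whether that restriction applies before or after the
top-150 truncation is genuinely ambiguous in the workflow this package
automates; the default is **after** selection (so signatures may hold
fewer than 150 tags per direction), and `allowedFilterOrder =
"before_selection"` provides the alternative, which refills from deeper
DEGs. Both are tested; neither is silently preferred.

# Connectivity engine

**Enrichment score.** The similarity statistic is the classic unweighted
Kolmogorov–Smirnov enrichment score of CMap's first generation: with $n$
genes ranked by descending z and a tag list occupying ascending positions
$V(j)$, $j = 1..t$,

$$a = \max_j\left(\tfrac{j}{t} - \tfrac{V(j)}{n}\right),\quad
  b = \max_j\left(\tfrac{V(j)}{n} - \tfrac{j-1}{t}\right),\quad
  ES = \begin{cases} a & a > b\\ -b & \text{otherwise.}\end{cases}$$

The unweighted form was chosen over z-weighted GSEA because it is exactly
brute-force checkable (the test suite verifies 1000 random draws against a
loop-based oracle); a weighted variant can be slotted in behind the same
interface. Ranking ties (equal z) break by gene id lexicographically.

**WTCS.** $\mathrm{WTCS} = (ES_{up} - ES_{down})/2$ when the two scores
have opposite signs, else 0 — the published CMap convention that an
incoherent signature (both tag lists drifting the same way) carries no
connectivity evidence. A direction with no usable tags contributes 0 to
the combination; its ES is reported as NA.

**NCS.** Within each cell line, scores are rescaled by the mean magnitude
of the same-sign scores, $\mathrm{NCS} = \mathrm{WTCS} /
\overline{|\mathrm{WTCS}|}_{\text{same sign, same cell}}$, making
magnitudes comparable across cell lines with different score dispersions.

**Replicate collapse, then tau.** Profiles of one (compound, cell line)
pair are collapsed to a single representative — by default the profile
with maximum |NCS| (`aggregate = "median"` keeps the middle one). The tau
percentile is computed **after** this collapse, among collapsed
representatives:

$$\tau = \mathrm{sign}(\mathrm{NCS}) \cdot 100 \cdot
  \frac{\#\{r : |r| < |\mathrm{NCS}|\}}{\#\{r\}}$$

with $r$ running over a *touchstone bank* of reference NCS values for the
same cell line (`buildTouchstone()` accumulates them from a panel of
queries; without a bank, the query's own representatives serve as
reference). Computing tau before collapsing and then keeping the max would
systematically inflate the null — picking the best of $k$ replicates
pushes the expected null percentile to $1 - 0.9^k$ — whereas
collapse-then-tau keeps the null calibrated (with no planted signal,
$\le 15\%$ of compounds exceed the connection threshold in the test
suite). This mirrors production CMap semantics, where tau is assigned to
replicate-collapsed signatures.

**Tau direction.** Verbal definitions of tau as "the fraction of reference
sets with *greater* similarity" would score the strongest connections near
0, contradicting the universal +100 = strong-connection reading of the
scale. The conventional complement — fraction with *lower* similarity — is
implemented, so stronger connections approach ±100. The comparison is
strict ($|r| < |\mathrm{NCS}|$), which caps |tau| at $100(N-1)/N$ under a
self-referential bank.

**Thresholds.** A record is *connected* when $|\tau| > 90$ (strict); the
default selection keeps the top $k = 10$ rows by descending tau, ties
broken by descending |NCS| then pert_id. `heatmapMatrix()` assembles the
per-query top lists into a compounds × (query, cell line) tau matrix with
NA for unscored pairs, ready for any heatmap renderer.

# Consensus gene selection

`subsetCompendium()` restricts the compendium to the selected compounds
(by pert_id and/or pert_iname), cell lines, and — by default — the 978
landmark genes (`pr_is_lm`), the directly measured space of the L1000
assay. `consensusSelect()` then retains an up tag for a compound when its
z-score is strictly positive in at least 70% of that compound's profiles
(symmetrically negative for down tags); $z = 0$ supports neither
direction, and the threshold is inclusive ($\ge 0.70$, "at least 70%").

Support is computed **per compound** by default. The alternative reading —
pooling all selected profiles regardless of compound — is available as
`mode = "pooled"`; the per-compound form was made the default because the
workflow's later stages (per-compound enrichment, the pathway × compound
matrix) are defined compound-wise.

# Correlation, clustering, enrichment

The feature vector of each dataset is its signature logFC restricted to
the union of consensus-selected genes, zero-filled for genes a dataset did
not select — a deliberate, recorded choice, since "clustering on the
selected genes" does not pin down the vector; z-score vectors can be
substituted by passing any matrix. `signatureCorrelation()` is plain
Pearson (constant vectors are an error naming the dataset);
`wardCluster()` standardizes each vector, takes Euclidean distances and
applies Ward linkage (`hclust`, `ward.D2`, whose merge heights are
non-decreasing). When the number of clusters is not given, the tree is cut
at the largest gap between consecutive merge heights — on two well-planted
blocks this recovers exactly two clusters in ≥19/20 seeded runs (test
suite).

`hypergeomEnrich()` computes the upper-tail hypergeometric probability
$P[X \ge \text{overlap}]$ via `stats::phyper`, BH-adjusts across sets, and
calls significance at $q < 0.05$. The enrichment universe defaults to the
measured (landmark) gene space of the consensus step — the natural
background for genes that could have been selected — and is configurable,
since no single universe is canonical. The implementation is verified
against exhaustive enumeration of all draws for universes up to 15 genes.

# Synthetic data: what it emulates, what it does not

`simulateExperiment()` draws gene baselines from $N(7, 1)$ (log2
microarray intensities), adds i.i.d. $N(0, \sigma)$ residual noise
(default $\sigma = 0.3$, a typical residual sd for replicate microarrays)
and shifts planted genes by ±2 log2 units in the treated group, with 3
samples per group — the workflow's minimum design. Defaults (5000 genes,
400+400 planted) give the moderated t sensitivity ≥ 0.9 at empirical FDR
≤ 0.07, which is what the recovery tests assert.

`simulateCompendium()` emulates the GSE92742 composition: 978 landmark
genes flagged inside a 12,328-gene space, sig_info/gene_info metadata with
the standard columns, background z-scores i.i.d. standard normal (the
natural null for replicate-collapsed differential z-scores), and — for a
planted connection of strength $s$ — a shift of $+s\delta$ on the query's
up tags and $-s\delta$ on its down tags in the planted compound's profiles
($\delta = 3$ by default: strength 1 makes tag directions agree with
probability $\Phi(3) \approx 0.999$, near-saturated but not degenerate).
Desk-scale defaults use 20 compounds × 3 cell lines × 3 replicates.

Neither generator models probe-level effects, batch structure, correlated
noise, dose/time series, or the half-million-profile scale of the real
compendium. Passing the planted-recovery tests therefore shows the
machinery is correct and calibrated under clean Gaussian conditions; it
does not certify performance on real microarray artifacts.

# Problem sizes and run cost

The test suite runs the planted-compound recovery on 20 seeded compendia
of 2000 genes (978 landmark) × 60 profiles, the ES oracle on 1000 random
draws, the consensus oracle on 500 random 20 × 12 matrices, and the full
pipeline on a 1000-gene two-experiment scenario — about a minute on one
CPU. The acceptance script scores 50 random 300-tag signatures against the
full-default compendium (12,328 genes × 180 profiles). These sizes were
chosen as the smallest at which every calibration property is
statistically unambiguous.

# Known limitations

- Exact tau values of the production CMap service are not reproducible:
  its Touchstone reference panel and weighted statistic are proprietary;
  this engine's tau is internally consistent, not numerically identical.
- Inputs must be gene-level and gene-unique; probe collapsing and
  identifier mapping are out of scope.
- Two-group designs only; no count-based (RNA-seq) error models.
- GCTX (HDF5) is not read; compendia travel as text GCT, which is
  practical at desk scale and diffable, but not at the scale of the full
  public compendium.
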