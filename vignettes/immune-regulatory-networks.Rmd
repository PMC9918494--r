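---
title: "Inferring immune regulatory networks at single-sample and cohort level"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring immune regulatory networks at single-sample and cohort level}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immureg)
library(dplyr)
```

# The scientific problem

Tumours evade immune attack at different steps of the cancer-immunity
cycle, and the step at which a given patient's defence fails is shaped by
which transcription factors (TFs) regulate which immune-related (IR) genes
in that patient's tumour. `immureg` infers such regulation from matched
bulk multi-omics data at two complementary resolutions:

* **Single-sample level.** For one patient at a time, the package links
  accessible-chromatin peaks near an IR gene's transcription start site to
  candidate TFs (by motif content), asks whether the peak signal, the TF's
  expression and the IR gene's expression all deviate from a normal
  reference cohort in that patient, and calls a signed regulatory edge when
  the pattern is interpretable.
* **Population level.** Within each tumour subtype, the expression of each
  IR gene is regressed on its candidate TFs with an L0 (best-subset)
  penalty; the selected TFs, their signed coefficients, and the refit $R^2$
  ("TF regulatory value") describe regulation at subtype resolution.

Around this core sit three supporting stages: immune-subtype discovery by
consensus non-negative matrix factorization (NMF), a stimulatory/inhibitory
signature-gene filter on per-cluster differential expression, and an
L1-penalized Cox model producing a per-patient Risk Score.

# Models and assumptions

## Single-sample regulatory calls

Peaks are linked to a gene when their interval overlaps the symmetric
window $[\mathrm{TSS} - w,\ \mathrm{TSS} + w)$ with $w = 20$ kb, on either
strand. Among linked peaks, the one with the largest $|\rho|$ (Spearman
correlation between peak signal and gene expression across matched ATAC
samples) at $p < 0.01$ is retained; ties break by distance to the TSS and
then peak id, so results are reproducible. The Spearman p-value uses the
t-approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$, adequate for the
$n \ge 8$ sample sizes the pipeline requires.

A single observation $v$ is compared against a reference cohort of size
$n$ with the prediction-variance-inflated statistic
$t = (v - \bar{x}) / (s\sqrt{1 + 1/n})$ on $n - 1$ degrees of freedom.
This is the form appropriate for asking whether one new observation is
exchangeable with the reference, rather than whether two means differ.
Gene and TF expression are tested against the normal cohort at
$p < 0.001$; peak signal is tested against the remaining ATAC samples
(leave-one-out) at the looser $p < 0.05$, because ATAC cohorts are an
order of magnitude smaller than RNA cohorts. Both thresholds are
arguments.

Sign inference encodes the biology that open chromatin is a prerequisite
for TF binding: a call requires peak high *and* TF high; the target's
direction then gives the sign (high → activation `+`, low → repression
`-`); all other combinations abstain. The interaction-score table acts as
a verification filter — candidate edges without a score are dropped, and
surviving edges carry the score as weight — and known TF–target databases
can be attached as boolean evidence flags.

## Best-subset regression at population level

For one target gene $y$ (centered) and its candidate TF matrix $X$
(columns standardized), the solver minimizes

$$\tfrac{1}{2}\lVert y - X\beta \rVert_2^2 + \gamma \lVert \beta \rVert_0,$$

by cyclic coordinate descent with hard-thresholding updates (a coordinate
enters iff $\tfrac12 z_j^2 \lVert x_j\rVert^2 > \gamma$, where $z_j$ is the
partial-residual OLS value), followed by a local combinatorial search over
small support moves — additions, deletions, swaps, pair deletions, and
pair-to-single replacements — with every candidate support scored by its
exact OLS refit.
The search runs from several starts (empty, hard-thresholded univariate,
and full OLS), so supports reachable only by joint moves are still found;
pair deletions cover the complementary failure mode where two coordinates
are jointly redundant. On random instances with $p \le 10$ the solver's
objective matches exhaustive best-subset enumeration (tested to $10^{-8}$
over hundreds of instances), and on orthonormal designs it equals the
hard-threshold closed form. The objective is non-increasing at every
accepted move and the search reaches a fixed point in finitely many steps;
very dense supports (> 20 coordinates, reached only at negligible
penalties along a path) skip the combinatorial stage.

The penalty $\gamma$ is chosen by K-fold cross-validation over a 50-point
log-spaced grid fitted with warm starts, taking the $\gamma$ minimizing
mean out-of-fold squared error (ties to the sparser model). Fold fits
re-standardize on the training part and use plain coordinate-descent paths
with OLS refits on each support for prediction; the final model at the
selected $\gamma$ uses the full search. The min-CV rule admits an
occasional spurious TF — in simulations at signal-to-noise 10 the planted
TFs are recovered in >95% of runs while the support is *exactly* the
planted one in roughly three quarters; a one-standard-error rule would
sharpen exactness but is deliberately not applied, keeping the selection
rule a pure CV minimum.

Per-TF p-values come from two-sided t-tests on the OLS refit of the
selected support. These are post-selection and therefore anti-conservative;
they rank and annotate edges but should not be read as calibrated
hypothesis tests. The refit $R^2$ on the cluster's data, clamped to
$[0, 1]$, is reported as the TF regulatory value.

## Subtype discovery

NMF uses Lee–Seung multiplicative updates on the Frobenius objective, whose
monotone non-increase is asserted in tests. Matrices with negative entries
(e.g. quantile-normalized expression) are shifted by their global minimum
first, since non-negativity is structural to NMF. Per consensus run, each
sample is labelled by the argmax row of $H$; the consensus matrix collects
co-clustering frequencies over seeded runs; final labels cut the
average-linkage dendrogram of $1 - C$; and the cophenetic coefficient
correlates the $1 - C$ distances with the dendrogram's cophenetic
distances.

The optimal rank is the rank at which the cophenetic profile stops rising —
its peak, with exact ties resolved to the larger rank (a dip followed by
full recovery is not a decline). A profile that never declines returns the
largest candidate rank with a warning. An earlier formalization ("first
decline exceeding a fixed tolerance δ") proved blind in practice: with 20
or more consensus runs on a few hundred samples, the unsplit clusters
contribute perfectly consistent co-clustering, pinning the cophenetic
coefficient near 1 at all ranks, so genuine post-peak declines are of
order 0.001–0.02 and no fixed δ separates them from plateaus. The peak
rule needs no tolerance; δ (default 0.005) is retained only to flag
shallow declines in the log. On the default synthetic cohort the profile
peaks at the planted rank 4 in 10 of 10 seeds at 30 runs per rank.

## Differential expression and the signature filter

Inputs are normalized continuous values, not raw counts, so per-cluster
differential expression uses a Welch t-test on $\log_2(x + 1)$ with
$\log_2$ fold-change computed as
$\log_2\!\big((\bar{x}_{cluster} + 1) / (\bar{x}_{normal} + 1)\big)$, and
Benjamini–Hochberg adjustment within cluster. Significance flags follow the
raw p-value at $\alpha = 0.05$ with $|\mathrm{log_2FC}| > 1$, matching the
stated decision rule; the adjusted p is reported alongside for users who
prefer it. Under a log-normal null the test's type-I error is calibrated
(checked at 2,000 replicates). The signature filter is deliberately
asymmetric: a stimulatory gene enters the signature set iff it is *not*
significantly up in any cluster (its failure to be induced marks an
escape), while an inhibitory gene enters iff it *is* significantly up in
at least one cluster.

## Survival modelling

The Risk Score is the exact linear form
$\sum_i \zeta_i \cdot \mathrm{Exp}_i$. Coefficients come from an
L1-penalized Cox model (Breslow ties, via glmnet) fitted on a 70% training
split with features z-scored on that split and the penalty chosen by
10-fold cross-validated partial-likelihood deviance; coefficients are
reported on both the standardized and the input expression scale. The
median split assigns exact-median ties (and the median sample for odd n)
to the low-risk group. Kaplan–Meier estimation and the log-rank test are
delegated to the survival package; a permutation oracle and hand-computed
product-limit fixtures verify them in tests. The time-dependent AUC is the
cumulative/dynamic form with inverse-probability-of-censoring weights from
the Kaplan–Meier estimate of the censoring distribution, evaluated with
left limits for cases (`1/G(T-)`) and right limits for controls (`1/G(t)`);
ties in score count one half.

# The synthetic cohort

Because the motivating cohorts (TCGA-scale tumour panels with matched
ATAC-seq and GTEx-scale normals) cannot ship with a package,
`simulate_cohort()` generates a full multi-omics cohort with planted
ground truth. Defaults mirror a 1/10-scale tumour study: 200 tumours in 4
subtypes of 50, 30 normals, 200 candidate genes plus 40 TFs, 20 ATAC
samples, 500 peaks, 16 regulated targets (about the number of IR genes a
full-scale analysis finds meaningful), each with 1–3 signed TF regulators
and effect sizes 0.8–1.5 on a unit-noise log2-like scale (baseline 8).

Structure planted, in brief: regulated targets are linear in their TFs
plus a CNV dosage term (coefficient 0.5 on 20 genes) and residual noise
scaled to signal-to-noise 10; each subtype up-shifts a 40-gene signature
block by 3, attenuated per sample by a tumour-purity-like factor
U(0.4, 1.6); each planted TF is activated (shift +5) in a sparse 10% of
tumour samples, giving the single-sample framework detectable deviations —
events are sample-specific rather than subtype-nested, because a
subtype-nested event set would itself constitute a fifth cluster; the
regulatory peak's signal equals its target's expression plus noise on the
ATAC samples, while decoy peaks are independent; peak sequences carry the
consensus motifs of the bound TFs (8-mers, count matrices 18:1:1:1);
interaction scores cover every planted pair plus twice as many decoy
pairs; survival times are exponential with hazard proportional to
$\exp(1.0\,x_{TF} - 0.8\,x_{gene})$ on two prognostic features, with
uniform censoring yielding roughly 40% censored records.

What the generator does *not* emulate: count noise and dispersion (values
are Gaussian on a log-like scale), batch effects, linkage between CNV
segments, sequence context beyond the planted motifs, competing risks, and
non-proportional hazards. Passing tests therefore demonstrate correctness
of the inference machinery under the model's own assumptions, not
robustness to the full messiness of real cohorts.

One planted asymmetry deserves note: because the regulatory peak tracks
its *target's* expression, a repressed target in a TF-activation sample
has a low peak and the single-sample framework abstains; cohort-level
single-sample recovery therefore exercises mostly activator edges, and the
repressor pathway ((peak high, TF high, gene low) → `-`) is verified by
the exhaustive 27-combination truth table and crafted call fixtures
instead. An occupancy-driven peak model was considered and rejected: for
targets with mixed-sign regulators its correlation with the target
cancels, destroying the peak–gene link that the method requires.

# Problem sizes and numerical choices

Tests and the acceptance script run the solver-equality battery at 100
random instances with $p \le 10$; network recovery on one default cohort;
rank selection on 10 cohort seeds at 30 consensus runs per rank;
Lasso-Cox recovery over 100 simulations at $n = 200$; calibration checks
at 2,000 replicates. These sizes make the whole suite complete in a few
minutes on a single core while keeping every Monte-Carlo margin well away
from its threshold.

Degenerate inputs are handled explicitly rather than by error where a
convention exists: constant vectors yield $\rho = 0$, $p = 1$ (flagged);
zero-variance genes give $p = 1$ in differential expression; a
zero-variance reference makes the deviation call by strict comparison with
$p \in \{0, 1\}$; empty L0 supports give $R^2 = 0$; a support reaching
$n$ is truncated by coefficient magnitude with a warning; zero total
events make the log-rank statistic 0 with $p = 1$.

# Limitations

Edge signs at single-sample level are qualitative (three-state calls), so
weak but real regulation below the deviation thresholds is invisible by
design. Post-selection p-values in the population framework are
anti-conservative, as discussed. The cophenetic-peak rank rule inherits
consensus NMF's known tendency to look stable one rank above the truth on
very clean data; it is the profile's peak, not a significance statement.
The Cox model assumes proportional hazards and independent censoring, and
the IPCW AUC is undefined beyond follow-up. All inference is on bulk
signals: averaging over subclones and immune infiltrate is inherited from
the data, not corrected.
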