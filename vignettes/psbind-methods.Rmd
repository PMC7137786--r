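---
title: "Methods and design of the psbind classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the psbind classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psbind)
```

`psbind` classifies short peptides as polystyrene-binding (PSBP) or not.
This vignette documents the statistical machinery, the parameters that
matter and their defaults, the choices made where the design was genuinely
open, the synthetic benchmark used for validation, and the package's known
limitations.

## The classification model

A peptide `p = A_1 A_2 … A_L` over the 20 canonical residues is mapped to a
420-dimensional composition vector: 20 weighted amino-acid composition
(AAC) entries

$$f_r = \frac{20}{420}\cdot\frac{\mathrm{count}(r)}{L},$$

followed by 400 weighted dipeptide composition (DPC) entries over ordered
adjacent pairs (overlapping windows),

$$f_{rs} = \frac{400}{420}\cdot\frac{\mathrm{count}(rs)}{L-1}.$$

The block weights 20/420 and 400/420 make the whole vector sum to 1, so it
behaves like a probability vector partitioned between the two composition
blocks; the AAC block sums to 20/420 and the DPC block to 400/420 for every
peptide. Feature order is fixed — residues in the order
G, A, V, L, I, P, F, Y, W, S, T, C, M, N, Q, D, E, K, R, H, then dipeptides
row-major over the same order — and is part of every on-disk format the
package writes.

Classification uses a soft-margin SVM with RBF kernel
$k(u,v) = \exp(-\gamma\lVert u-v\rVert^2)$ and penalty $C$, fitted by
libsvm via `e1071`. Because the selected features are few and the block
weights shrink every coordinate, squared distances between encoded peptides
are on the order of $10^{-3}$–$10^{-2}$; useful values of $\gamma$ are
therefore *large* (hundreds to thousands), which is worth keeping in mind
when reading the grids below.

## Feature selection

Each feature is scored by the classical two-group one-way ANOVA F
statistic. With group sizes $m_1, m_2$, group means $\bar x_1, \bar x_2$
and grand mean $\bar x$:

$$\mathrm{SSB} = \sum_i m_i(\bar x_i - \bar x)^2,\qquad
  \mathrm{SSW} = \sum_i \sum_j (x_{ij} - \bar x_i)^2,\qquad
  F = \frac{\mathrm{SSB}/1}{\mathrm{SSW}/(m_1+m_2-2)}.$$

Degenerate features follow a fixed convention: $F = 0$ when the group means
coincide (no information) and $F = \infty$ when a non-constant feature has
zero within-group variance (perfect separation). Ranking is by descending
$F$ with ties broken by ascending feature index, so it is fully
deterministic; a test verifies the scores against `anova(lm(...))` and a
hand-written textbook implementation to 1e-9.

Incremental feature selection (IFS) then evaluates the ranked prefixes
$k = 1, 2, \ldots, k_{\max}$: for each $k$ an RBF-SVM is tuned over a
coarse hyperparameter grid by stratified cross-validated accuracy, and the
chosen prefix is the *smallest* $k$ attaining the curve's maximum
(preferring fewer features guards against overfitting, and makes the
tie-break deterministic). One fold assignment, drawn once from the seed, is
shared by every prefix size and every grid point, so differences along the
curve are paired rather than resampling noise.

## Hyperparameter grids

Three presets ship with the package (all user-configurable via
`grid_spec()`):

* `grid_published()` — log₂C ∈ [−10, 20], log₂γ ∈ [6, 20], step 0.5 (1769
  points). This is the published search range for this identifier family;
  its strikingly large γ range is consistent with the small distance scale
  noted above.
* `grid_default()` — log₂C ∈ [−5, 15], log₂γ ∈ [−3, 13], step 2 (99
  points). The default for tuning the final model: it spans the published
  range's useful region plus smaller γ, at a tractable resolution.
* `grid_coarse()` — log₂C ∈ {−3, 1, 5, 9} × log₂γ ∈ {1, 5, 9, 13} (16
  points). The default *inside* IFS, where a search runs at every prefix
  size. The γ values are deliberately centred on the large-γ regime the
  weighted features require; grids centred on conventional γ ≈ 2⁻⁹…2³
  leave the kernel nearly constant on these features and underfit.

Grid search is exhaustive, reuses a single fold assignment across all
points (a paired comparison), and breaks ties toward smaller log₂C, then
smaller log₂γ, so the winner is independent of enumeration order.

## Cross-validation protocols

`cross_validate()` reports per-fold and mean SN, SP, ACC and AUC under two
protocols:

* **published-protocol mode** (default): feature ranking, IFS and hyperparameter tuning
  are performed once on the full dataset; each CV fold only refits the SVM.
  This reproduces the protocol commonly used in the identifier literature,
  but selection sees the test folds, so its estimates are optimistic.
* **nested mode**: ranking, IFS (with a 3-fold inner CV — a deliberate
  economy, since an inner search runs at every prefix size inside every
  outer fold) and the hyperparameter choice are redone within each training
  fold; the per-fold model reuses the inner-grid winner at the chosen
  prefix. This is the honest generalization estimate and is what the null
  calibration below uses.

Folds are stratified: within each class, shuffled members are spread as
evenly as possible and remainders go to the folds with the smallest running
totals, so 104+104 samples yield fold sizes 42, 42, 42, 41, 41 with 20–21
positives each. AUC is the normalized Mann–Whitney statistic (ties ½),
averaged across folds like the other metrics. All metrics are kept in
[0, 1] internally; percentages appear only in presentation output.

## Curation rules

Screening rejects, in order: ambiguity codes (B, J, O, U, X, Z),
non-alphabetic characters, sequences shorter than 2 residues (DPC needs
L ≥ 2), and — only when `drop_cysteine_peptides = TRUE` — cysteine-containing
peptides. Cysteine-dropping exists because circular phage-display peptides
carry flanking cysteines, but it is **off** by default: C is itself an
informative residue in this problem and the downstream analyses use it, so
removing C-peptides silently would contradict the package's own reports.
Whether to strip, drop or keep such peptides is irreconcilably ambiguous in
the identifier literature; both behaviours are exposed and neither is
claimed as canonical.

After screening: within-class exact duplicates are dropped (first kept);
sequences appearing in both classes are removed from the *negative* set
(the positive label is treated as the curated ground truth, and replacement
sampling of fresh negatives is out of scope); finally any negative with
generalized Jaccard similarity ≥ 0.90 to some positive is removed
("below 90%" survives). The generalized Jaccard is computed on residue
count multisets, Σ min / Σ max — the standard generalization to
non-negative vectors. The curation report accounts for every input
exactly, per class, and curation is idempotent.

## The synthetic benchmark

The published benchmark for this problem (104 PSBPs + 104 non-PSBPs drawn
from a biopanning database) lives on an external server whose availability
cannot be assumed, so the package ships a generator that emulates its
*statistical shape* rather than its sequences: two balanced classes of 104
peptides, lengths uniform on 7–12 (phage-display-insert-like; the real
benchmark's length distribution is unpublished), negatives i.i.d. uniform
over the 20 residues, and positives sampled with the weights of W, F and Y
multiplied by 8 and renormalized (≈ 19.5% each versus 5% background).
Residue-level signal is the natural choice because the residue-importance
analyses in this problem domain are themselves residue-level; a
dipeptide-motif mode (`motif`, `motif_prob`) exists to exercise the DPC
pathway. An enrichment factor of 1 gives exchangeable classes — the null
benchmark used for calibration.

What passing tests on this generator shows: the pipeline recovers planted
compositional signal (the W/F/Y AAC features rank at the top and held-out
accuracy is high), and reports chance-level accuracy when no signal exists.
What it does not show: performance on real biopanning data, whose residue
correlations, shared library provenance and length structure the generator
does not imitate.

`synth_separable()` provides the complementary geometric fixture: two unit-SD
Gaussian blobs separated by 6 SD along each of 2 informative dimensions
(~8.5 SD between centers) plus nuisance dimensions, on which grid search
must find a perfect five-fold CV classifier; with 0 informative dimensions
it degenerates to a pure-noise dataset.

## Problem sizes used in validation

The test-suite and acceptance-script pipeline runs use `k_max = 30` with
the coarse inner grid — on this benchmark the planted signal concentrates
in the first handful of ranked features, so longer prefixes only extend
the flat tail of the accuracy curve —
and evaluate 10 generator seeds for the signal-recovery and
null-calibration properties. The default `k_max` for real analyses remains
the full 420.

## Numerical choices and edge cases

* Encoding is exact integer counting scaled once; tests require bit-exact
  agreement with a naive counting oracle, and block sums hold to 1e-9.
* Column-wise ANOVA guards the `SSW = 0` branch: a column that is constant
  overall is forced to `F = 0` even when floating-point group means differ
  by rounding noise.
* Decision values are computed in-package from the extracted kernel payload
  (support vectors, coefficients, bias), normalized so positive scores mean
  the PSBP class; a test checks equality with the fitting library's own
  decision values. ROC scores are these raw decision values — no Platt
  scaling, since nothing downstream needs probabilities.
* Models persist as JSON text with 17 significant digits, which round-trips
  IEEE doubles exactly; reload is tested to give bit-identical predictions.
* All randomness (generator, fold assignments) flows from explicit integer
  seeds, and seeded code restores the caller's RNG state.

## Known limitations

* Performance numbers on the synthetic benchmark say nothing quantitative
  about real PSBP data (see above); the package reproduces the *method*,
  not the published benchmark values, which require the original dataset.
* Paper-mode CV is optimistically biased by construction; it is the default
  because it mirrors the protocol used in this literature, and nested mode
  is one argument away.
* The IFS curve is evaluated with the coarse inner grid; a prefix whose
  optimum lies far outside that grid could be mis-ranked. The final model
  always gets a finer search.
* Curation removes redundant *negatives* only; redundancy among positives
  (beyond exact duplicates) is preserved, matching the original protocol's
  asymmetric treatment.
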