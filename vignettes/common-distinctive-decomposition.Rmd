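---
title: "Separating common from distinctive variation: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating common from distinctive variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codivar)
```

## The model

Two numeric matrices `X1 (I × J1)` and `X2 (I × J2)` share their object
(row) mode. After column centering and scaling each block to unit total
sum of squares, every method in this package fits

$$X_k = C_k + D_k + E_k = T_c P_{c_k}' + T_{d_k} P_{d_k}' + E_k,$$

a low-rank *common* part whose score vectors are shared (DISCO, JIVE) or
strongly correlated across blocks (O2-PLS), a per-block low-rank
*distinctive* part, and a residual. The model order is
`(c_c, c_1, c_2)` — numbers of common and per-block distinctive
components.

The three methods are three different compromises between fit and
interpretability:

| forced to zero | DISCO | JIVE | O2-PLS |
|---|---|---|---|
| $C_k'D_k$ | yes | yes | yes |
| $E_k'C_k$ | yes | no | no |
| $E_k'D_k$ | yes | yes | yes |
| $C_k'D_l$, $D_k'D_l$, $E_k'C_l$, $E_k'D_l$ | yes | only $C_k'D_l$ | no |

`orthogonality_table()` audits a fitted decomposition against this
pattern. Two caveats discovered (and asserted) in the test suite:

* **DISCO with an imperfect rotation.** On noisy data the rotation target
  cannot be met exactly — the `c_t`-dimensional loading space of the SCA
  generically contains no direction that is exactly zero on one block. The
  left-over mass on pattern zeros (the *cross-over*) is kept in `E_k` so
  that `C_k + D_k + E_k` always reconstructs `X_k`. Consequence: the two
  cross-entries `E_k'D_l` are zero only up to the rotation imperfection
  (normalized magnitude around `1e-3` on the benchmark scenarios, machine
  zero on noiseless data). All other DISCO pairs are zero to machine
  precision regardless. This is a structural property, not a convergence
  failure, and is why one acceptance assertion (all seven DISCO pairs
  below `1e-8` on noisy data) is deliberately left failing.
* **JIVE at an exact fixed point** also satisfies `E_k'C_k ≈ 0` (the
  common scores are left singular vectors of the deflated concatenation),
  so the "not forced" entries of its column are only materially nonzero
  on data that violate the orthogonal-truth assumptions; the acceptance
  test uses a generic correlated data set for those assertions.

## Preprocessing

Column centering first, then block scaling to unit total sum of squares
(`preprocess()`). Centering first keeps the block sum of squares
interpretable as variance; equal block weights stop the larger block from
dominating the joint SVD. No per-variable autoscaling is applied by
default (both steps are flags on `preprocess()` and the CLI).

## Parameters that matter

* `find_rotation()`: `n_restarts = 20` random orthogonal starts plus the
  identity; per-sweep objective-decrease tolerance `1e-12`; cap 5000
  sweeps. The rotation objective is minimized by a monotone
  majorize-minimize iteration (the mass on pattern-ones is a convex
  function of `B`; maximizing its linearization over the orthogonal group
  is a polar projection). Verified against an exhaustive grid oracle for
  `c_t = 2` at `1e-8`.
* `jive_decompose()`: convergence when the relative Frobenius change of
  `[C | D]` drops below `1e-8`, cap 500 sweeps. On data where the joint
  step misidentifies a dominant distinctive component (see below) the
  alternation sits on a quasi-fixed point and exhausts the cap — the
  accompanying warning is expected there, not a defect.
* `jive_select_model()` / the O2-PLS common test: `n_perm = 100`
  permutations, `alpha = 0.05`, rank = number of *leading* observed
  squared singular values above the per-index `(1 − alpha)` null
  quantile (the scree is read from the top; the run stops at the first
  failure). The common-rank null permutes whole rows of block 2, which
  breaks the object link but preserves within-block correlation. The
  common test runs on the raw concatenation: testing on `X − D` retains
  the joint step's opportunistic alignment with block 2 while the null
  re-randomizes it against a much smaller residual, a measured bias of
  about +1% on the top squared singular value that flips low-common data
  to one spurious common component.
* `disco_select_model()`: step 1 takes the smallest `c_t` explaining at
  least `variance_threshold = 0.9` of *each* block; step 2 scores every
  split of `c_t` by total cross-over variance. Because common target
  columns are unconstrained, cross-over can only decrease with `c_c` and
  the all-common split trivially scores zero, so "minimize cross-over"
  alone is degenerate; the implemented rule is parsimony under adequacy:
  the smallest `c_c` whose best split stays below
  `crossover_tol = 0.01`. Forcing a genuinely common component into a
  distinctive slot costs its full loading mass on the other block
  (≥ 0.05 on all benchmark configurations), far above the tolerance.
* `o2pls_select_model()`: after removing the common subspace, per-block
  rank by element-wise PCA cross-validation — 7 row folds, each held-out
  element predicted from its row's other variables through the training
  loadings (a rank-one Sherman–Morrison downdate makes this exact and
  vectorizable), first minimum of the PRESS curve.
* `columnspace_residual()` and the type-III correction treat singular
  values below `1e-12` of the largest as zero when forming projectors.

## The synthetic-data generator

`generate_scenario()` emulates the benchmark design: `I = 70` objects,
blocks of 100 and 50 variables; latent score vectors drawn standard
normal, centered, then Gram–Schmidt orthonormalized (centering before
orthonormalization means planted structure passes through column
centering unchanged); smooth "spectral" loadings (2–3 Gaussian bumps on
the variable axis) of unit norm; i.i.d. Gaussian noise that is centered,
projected orthogonal to the planted scores and scaled so each block's
achieved variance fractions equal the stated ones *exactly* and each
block has exactly unit sum of squares. `scenario1()` plants abundant
common variation (0.66/0.28 and 0.85/0.13, remainder noise),
`scenario2()` low-abundance common variation (0.11 vs 0.78 + 0.10, and
0.62 vs 0.26 + 0.10). The 0.88 and 0.36 distinctive totals are split
0.78/0.10 and 0.26/0.10 so that the dominant distinctive component
(0.78) exceeds the combined common variation (0.73) — the regime where a
variance-greedy joint step misidentifies the common component.

### The loading-overlap calibration

Within a block the planted loadings are Gram–Schmidt orthogonalized and
the distinctive loadings are then tilted towards the leading common
loading with a fixed cosine of **0.02**. This single number is the most
consequential calibration in the generator, because it controls the only
coupling between otherwise exactly orthogonal planted parts:

* O2-PLS finds a block's distinctive weights from the SVD of
  `R_k' T_ck`, i.e. from the covariance of the residual with the common
  scores. With *exactly* orthogonal loadings that covariance is pure
  noise and distinctive recovery collapses (measured |corr| ≈ 0.15).
  Any overlap from about 0.02 up restores recovery to ≈ 0.998, because
  the score step `t = X_k w` re-amplifies the structured direction even
  from a noisy weight.
* JIVE's alternation, conversely, uses any coupling as an escape route
  out of a misidentified joint component. At overlap 0.2 it escapes in
  ~130 sweeps; at 0.05 in roughly 500; at 0.02 the block-2 common
  fraction is still below 0.01 after 2000 sweeps — far beyond the
  iteration cap, so misidentification persists, which is the documented
  behaviour of the method in this regime.

0.02 is therefore the regime in which all the documented qualitative
behaviours of the three methods coexist, and it was fixed once on that
ground. A green recovery test consequently establishes recovery *under
near-orthogonal planted structure with a small fixed overlap*; it says
nothing about strongly correlated loadings, heteroscedastic noise,
outliers, or blocks whose link is weaker than the within-block structure
— features of real multi-omics data the generator deliberately does not
emulate.

### The identification sweep

`jive_identification_sweep()` varies the combined common fraction against
a fixed dominant distinctive fraction (0.5). The variance budget left
over at low common fractions is filled with *structured* filler
components (staggered sizes, each ≤ 0.35) plus 2% noise — filling with
noise instead would couple the blocks strongly enough to blur the
threshold. Block 2 additionally receives one small (0.03) tail filler.
The reason is the mechanism of persistence itself: the per-block
distinctive step absorbs the `c_k` largest directions orthogonal to the
joint scores, so the misidentified state survives exactly when the
block-2 common variation is among the absorbed ("buried") directions —
as in the low-common benchmark scenario, where the rank-2 distinctive
estimate swallows the 0.62 common component. If the common part is
instead the direction left out, it stays exposed in the residual and the
alternation slowly reels it in. The tail filler guarantees the buried
regime across the whole grid. The resulting identification curve is a
step function: ~0 below equal common/dominant variance, ~1 above.

## Numerical choices

* SVD sign indeterminacy is fixed everywhere by making the
  largest-magnitude entry of each left singular vector (score column)
  positive, so repeated runs and exports are bit-identical.
* `truncated_svd()` uses an eigendecomposition of the `I × I` Gram matrix
  for wide matrices (the dominant cost of permutation tests and JIVE
  sweeps), falling back to the full LAPACK SVD whenever the requested
  trailing singular value is below `1e-5` of the leading one; agreement
  with the full SVD is tested at `1e-10`.
* Ties in DISCO step 2 (within `1e-9` of cross-over) resolve towards the
  larger `c_1`, making selection deterministic.
* Degenerate inputs: all-zero blocks are rejected at scaling; `J_k = 1`
  blocks are allowed (the target builder caps `c_k ≤ J_k`); O2-PLS
  refuses exactly orthogonal blocks (`X1'X2 = 0` carries no common
  variation) and `c_c = 0`.

## Known limitations

* Two blocks only; no missing data; dense storage.
* Score-recovery correlations on the abundant-common benchmark are
  noise-limited at ≈ 0.9985 (first-order perturbation
  `‖E v‖ / s` for the weakest planted component) — consistent with a
  reference value of 1 printed at two decimals, but below a literal
  0.999 threshold; the corresponding acceptance test is left failing
  rather than loosened.
* DISCO model selection under any cross-over-based criterion recovers the
  *true* model on the low-common benchmark; it cannot reproduce a
  reported selection of zero common components there (every 0-common
  split costs ≥ 0.10 cross-over while the true split costs ~1e-6). That
  expectation is likewise left failing, with the candidate table exposed
  for inspection.
* The O2-PLS model-selection criterion for `c_c` (permutation test on
  covariance singular values) is a declared choice validated against the
  benchmark scenarios, not a published procedure.
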