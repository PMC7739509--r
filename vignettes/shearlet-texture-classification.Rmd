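---
title: "Shearlet-domain texture descriptors: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shearlet-domain texture descriptors: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shearltex)
```

# The problem and the model

Histopathological tissue classification from biopsy slide images is, to a
large extent, a texture recognition problem: tissue types differ in the
scale, orientation and regularity of their micro-structures.  `shearltex`
implements a texture-representation pipeline that moves the descriptor
computation from the spatial image into the *complex shearlet domain*:

1. an image is decomposed by a cone-adapted complex shearlet system into
   $S \times K$ directional sub-bands (default $S = 4$ scales, $K = 8$
   directions, i.e. 32 sub-bands plus a low-pass residual);
2. each complex coefficient $C = x + iy$ yields a magnitude
   $\rho = \sqrt{x^2 + y^2}$ and a phase $\theta = \mathrm{atan2}(y, x)$;
   phases are converted to *relative phase* (RP), the wrapped difference
   between neighboring coefficients along the sub-band's cone direction;
3. four texture descriptor families summarize every sub-band of both the
   magnitude and the RP stacks: co-occurrence (Haralick) statistics, the
   rotation-invariant uniform local binary pattern (LBP) histogram, the
   local oriented statistics information booster (LOSIB), and
   segmentation-based fractal texture analysis (SFTA);
4. the per-family blocks are fused by concatenation, standardized, and
   optionally reduced by varimax-rotated PCA;
5. a radial-basis-function SVM (or a bagged decision tree ensemble) is
   evaluated under stratified $k$-fold cross-validation with accuracy,
   macro AUC, sensitivity and precision.

The point of working in the shearlet domain is anisotropy: shearlet
sub-bands index orientation and scale jointly, so statistics that are
ambiguous in the spatial domain (e.g. the roughness of a gland boundary at
a particular orientation) become separable.

# The shearlet system

The system is built entirely in the frequency domain.  Meyer-type radial
windows partition the radius into dyadic bands with knots
$t_s = \tfrac12\, 2^{\,s-S}$ (cycles/pixel); the finest band extends to the
spectrum corners and the residual below $t_0$ forms the low-pass filter.
Meyer-type angular windows (period $\pi$) split each band into $K$ wedges of
width $\pi/K$.  Wedge centers are laid out at $-\pi/4 + (k - \tfrac12)\pi/K$,
so directions $1..K/2$ tile the *horizontal* frequency cone
(orientations in $[-45^\circ, 45^\circ)$) and $K/2+1..K$ the *vertical*
cone — the same cone split that the relative-phase definition and the
layer-selective baseline rely on.  Because the Meyer ramp satisfies
$\nu(x) + \nu(1-x) = 1$, squared windows tile exactly; we additionally
divide all filters by the square root of their squared sum, so the frame is
numerically tight and `inverse_shearlet_transform()` reconstructs any image
to round-off (measured $\sim 10^{-15}$, asserted below $10^{-6}$).

Complex (analytic) coefficients are obtained by restricting every
directional filter to one frequency half-plane, with self-conjugate
frequency bins weighted $\tfrac12$ so that taking the real part during
reconstruction remains exact.  A consequence worth knowing: filters are
real and non-negative in the frequency domain, so coefficient phase carries
purely local structure.

Rectangular images are supported directly — the frequency grid is built at
the image's own shape, so no padding or cropping is involved.  The minimum
supported size is $\max(32, 2^{S+1})$ per side, the smallest grid on which
the coarsest radial band is resolvable.

## Relative phase

For sub-band $(s, k)$, RP at position $(i, j)$ is
$\theta_{sk}(i,j) - \theta_{sk}(i, j+1)$ when $k \le K/2$ (horizontal cone)
and $\theta_{sk}(i,j) - \theta_{sk}(i+1, j)$ otherwise.  Two choices here
are ours, not forced by the definition:

* **Wrapping.** Raw differences lie in $(-2\pi, 2\pi)$; we wrap to
  $(-\pi, \pi]$ via $d - 2\pi\,\mathrm{round}(d / 2\pi)$ so RP is a proper
  angle and descriptor quantization stays bounded.
* **Boundary.** The neighbor of the last column (row) is taken circularly,
  so RP sub-bands keep the full image shape.  This keeps every per-sub-band
  descriptor defined on an identical support; trimming the last line
  instead would be an equally defensible convention, and the code isolates
  the choice in `relative_phase()` so it can be swapped.

RP depends only on phase differences, so it is invariant under a global
phase shift of the stack — a property the test suite asserts.

# Descriptor families and their parameters

All families operate per sub-band and are deterministic; identical input
gives bit-identical output.

**Co-occurrence (CM).**  Sub-bands are min–max rescaled and uniformly
quantized to `ng = 8` levels; published descriptions of this pipeline
leave the level count unstated, and 8 keeps the four orientation-averaged
matrices well populated on sub-bands of typical 128–700 px extent (the
count is exposed as a parameter).
Four symmetric co-occurrence matrices at distance `pd = 1` and orientations
0°/45°/90°/135° are normalized and averaged, which makes the derived
statistics approximately rotation invariant.  Twenty Haralick-style
statistics are extracted in a fixed order (contrast through inverse
difference moment normalized).  Natural logarithms are used, $0\log 0 = 0$,
and any statistic with a vanishing variance or entropy denominator returns
0 so constant sub-bands remain legal inputs.  The published statistic list
names both "sum of squares" and "variance"; on the symmetric matrices
produced here the two formulas (second moment about the co-occurrence mean
level; marginal row variance) coincide numerically, and we keep both
entries to honor the 20-statistic contract.  Every statistic is verified
against a brute-force double-sum oracle to $10^{-10}$.

**LBP (riu2).**  `p = 8` neighbors at radius `r = 2`, bilinear
interpolation at non-integer positions, step rule $s(x) = 1$ iff
$x \ge 0$, rotation-invariant uniform label mapping, and a normalized
$(p+2)$-bin histogram per sub-band.  Statistics use interior pixels only
(border of width $\lceil r \rceil$), avoiding invented padding values.  One
numerical guard is ours: the $\ge 0$ comparison tolerates $-10^{-10}$
relative error, because interpolated neighbors of an exactly constant
neighborhood can differ from the center by one ulp in either direction;
with the guard, constant regions deterministically produce the all-ones
pattern that the defining equation prescribes for exact ties.

**LOSIB.**  `p = 8` directions at radius `r = 1`, which lands exactly on
the 8-connected integer grid, so no interpolation is involved; the
descriptor is the mean absolute center–neighbor difference per direction
over interior pixels.  LOSIB is the only family that scales linearly with
sub-band gain (LBP and the min–max-quantized CM are gain invariant) — a
property the tests pin down.

**SFTA.**  Each sub-band is min–max rescaled to 256 integer levels, and
`nt = 4` thresholds are found by multi-level Otsu implemented as recursive
binary Otsu splits (threshold the full range, then recurse into the two
halves with the remaining budget split evenly).  The two-threshold binary
decomposition keeps $2 n_t - 1 = 7$ binary images: the four upper sets
$\{I > t_i\}$ plus the three consecutive band-pass sets
$\{t_i < I \le t_{i+1}\}$ — this count is what makes the published
21-attributes-per-sub-band figure come out as $7 \times 3$.  Each binary
image contributes its region border's box-counting fractal dimension
(dyadic box sizes from 1 to half the minimum dimension; least-squares slope
of $\log N$ against $\log 1/e$), the mean 0–255 gray level over the region,
and the region pixel count.  A constant sub-band has no meaningful
thresholds and falls back to seven empty binaries (features $(0,0,0)$)
rather than failing.

**CM-dot.**  The comparison literature describes an "inner product of the
co-occurrence matrix and magnitude coefficients" without enough detail to
reconstruct the feature count it implies, so the concrete construction here
is the package's own documented stand-in: the sub-band's co-occurrence
matrix is multiplied entrywise with an `ng` × `ng` block-mean reduction of
the magnitude sub-band and summarized by column maxima, a deterministic
fixed-length (`ng` per sub-band) reduction.  Results that depend on CM-dot
(Fusion #3) are therefore comparable *within* this package but not
feature-for-feature against the original description.

# Fusion, standardization, reduction

Fusion is pure concatenation in a fixed order — RP blocks then magnitude
blocks, each in CM, LBP, LOSIB, SFTA, CM-dot order — so every output column
is bit-identical to its source block.  With both components, Fusion #1
spans $2(640+320+256+672) = 3776$ columns and Fusion #2
$2(640+256) = 1792$.

Standardization (zero mean, unit variance per column) is always fitted on
the training split; zero-variance columns are dropped with a warning.
Standardization precedes PCA because the descriptor families live on
wildly different scales (histogram masses vs. pixel counts), and a
covariance PCA of the raw mixture would be dominated by the SFTA counts.

PCA retains the leading `n_components` axes of the training covariance and
rotates them by varimax (orthomax, $\gamma = 1$; raw rotation without
Kaiser row normalization, tolerance $10^{-6}$, iteration cap 1000).  The
rotation is orthogonal, so the projected subspace, and in particular all
pairwise distances between projected samples, are unchanged; what changes
is interpretability of the individual axes.  Basis signs are fixed by
making each column's largest-magnitude loading positive, so fits are
deterministic.  When every usable component is retained
($\min(p, n_{\text{train}}-1)$), centered training data lies entirely in
the retained subspace and the projection is an isometry — the property the
acceptance suite checks to $10^{-8}$.

**PCA placement.**  Published pipelines often leave unstated whether the
reduction was fitted per training fold or once on the whole dataset.  The
default here is per fold — the only leakage-free choice — with
`pca_scope = "global"` available for reproducing pipelines that reduced
first and validated after.  The leakage test corrupts held-out rows and
asserts the fitted standardizer and PCA parameters are bit-identical.

# Classification and evaluation

The SVM uses an RBF kernel, one-versus-one multiclass decisions, and
libsvm's SMO-type dual solver via `e1071`.  Features are standardized
beforehand, so the default kernel width $\gamma = 1/p$ is a reasonable
scale; the regularization default $C = 5$ follows the published grid
search over $[1, 5]$.  Per-class scores aggregate signed pairwise decision
values, which is deterministic (no probability calibration, which would
introduce internal random folds).  The bagged decision tree ensemble
(`randomForest`) uses bootstrap replicas with random attribute selection
per split — 100 trees and $\lfloor\sqrt{p}\rfloor$ candidate attributes by
default, as the source texts give neither.

Cross-validation is stratified by default (the texts note imbalance but
not stratification; stratification guarantees minority-class presence in
every fold and is switchable).  Multiclass sensitivity, precision and AUC
are macro-averaged one-versus-rest, binary problems use a configurable
positive class, and degenerate ratios contribute 0.  Metrics are reported
per fold and as mean ± sd with a pooled confusion matrix.

# The synthetic generator: what it does and does not show

`synthetic_textures()` produces oriented sinusoidal gratings (class $c$ of
$n$ at orientation $(c-1)\,180^\circ/n$, default 16 cycles/image,
contrast 1) plus seeded Gaussian noise (default sd 0.3), clipped to
$[0,1]$.  Orientation is exactly the property shearlet sub-bands index, so
the classes are separable by construction and end-to-end tests are sharp:
a failure isolates the pipeline, not the data.  Per-image seeds derive
from the master seed through a fixed counter over (class, index), so
enlarging a dataset never regenerates existing images.

Two honest caveats.  First, gratings are *easier* than histology: a single
dominant orientation and frequency per class, stationary statistics, no
staining variation; a pipeline that recovers them perfectly (the test
suite requires mean accuracy ≥ 0.95 over 10 folds; the run underlying this
package's acceptance measured 1.00) is demonstrated to be *wired
correctly*, not to be clinically accurate.  Second, class orientations at
multiples of 45° fall on wedge boundaries of the default system, so the
dominant energy splits between two adjacent sub-bands; this is harmless
for classification (the split is class-consistent) and deliberately
exercised by the tests.

# Problem sizes and numerical choices in the test suite

The study fixture for the end-to-end and component-sweep tests is the
4-class, 200-image dataset at 128 × 128 px and noise sd 0.3 with full
two-component extraction (Fusion #1, 3776 features) — chosen as the
smallest configuration in which all dimensional contracts take their
published values and the orientation classes remain non-trivially noisy.
The component sweep runs at 50-component increments up to the usable
maximum (179 = smallest training split of 10-fold CV minus one).  Oracle
checks use deliberately tiny instances (4 × 4 co-occurrence matrices,
15 × 13 sub-bands) where brute-force double sums are exact.

Degenerate inputs are handled to a fixed rule everywhere rather than
erroring: constant sub-bands quantize to level 1, produce empty TTBD sets,
zero LOSIB, and the all-ones LBP pattern; empty SFTA regions report
$(0,0,0)$; zero-variance statistics return 0.

# Known limitations

* CM-dot is a documented reconstruction, not a faithful replica (above).
* The shearlet system is band-limited and non-compactly supported in
  space; spatial localization is good but not compact, and very small
  images (below $2^{S+1}$ px) need a reduced scale count.
* SVM decision-value AUCs are not calibrated probabilities; AUC is
  ranking-based and unaffected, but score magnitudes between folds are not
  comparable.
* The folder loader assigns labels from directory names only; patient- or
  slide-grouped cross-validation must be arranged by the caller (fold
  plans accept precomputed assignments).
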