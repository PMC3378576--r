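---
title: "Methods: structural class prediction from PSSM profiles"
author: "strucClass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural class prediction from PSSM profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strucClass)
```

# The problem and the model

The structural class of a protein domain — all-α, all-β, α/β (interspersed
helices and mostly parallel sheets) or α+β (segregated helices and mostly
anti-parallel sheets) — is the top level of structural classification and
a useful prior for secondary- and tertiary-structure prediction. This
package predicts it from sequence alone, using the evolutionary
information in a PSI-BLAST position-specific scoring matrix (PSSM).

The model is deliberately linear. A domain's PSSM is condensed into a
440-dimensional feature vector $V_{seq}$, and a $4 \times 441$ coefficient
matrix $A$ (the 441st column multiplies a constant intercept) maps it onto
a 4-dimensional structural feature vector:

$$ (x, y_1, y_2, z)^\top \;=\; A \,\cdot\, (V_{seq} \,\|\, 1). $$

Each structural coordinate is built to separate one pair of class groups
by sign — $x$: all-α (+) vs all-β (−); $y_1$: all-α (−) vs mixed αβ (+);
$y_2$: all-β (−) vs mixed αβ (+); $z$: α/β (+) vs α+β (−) — and a fixed
decision tree reads the class off the signs. The linearity assumption is
that class-discriminating information in the profile (composition,
periodicity, local persistence, positional layout of substitution
preferences) combines additively; everything nonlinear lives in the
feature construction.

## Training targets from secondary structure

Training domains carry a per-residue secondary-structure string over
`{H, A, P, C}` (helix, anti-parallel strand, parallel strand, coil).
The sliding-window composition
$$ \bar f_i(k) = \frac{1}{L-k+1} \sum_{t=1}^{L-k+1} \frac{n_{i,t}}{k} $$
averages the content of element $i$ over all length-$k$ windows; at
$k = L$ it reduces to the whole-sequence content, and for a uniformly
distributed element it equals that content at every $k$, so it encodes
spatial organisation as well as composition. The raw coordinate scores are

* $x = c_H - (c_A + c_P)$ — helix/sheet contrast,
* $y_1 = (c_A + c_P) - \theta$ — sheet presence above a mixed-content
  threshold,
* $y_2 = c_H - \theta$ — helix presence above the same threshold,
* $z = (c_P - c_A) / (c_P + c_A + \delta)$ — parallel vs anti-parallel
  sheet balance,

with $c_i = \bar f_i(\min(k_0, L))$. The $z$ contrast is chosen because
the two mixed classes differ precisely in sheet topology: parallel sheets
dominate α/β, anti-parallel sheets α+β.

A class-dependent adjustment then guarantees every training target sits on
its class's side of zero: a coordinate whose raw score violates (or
undershoots) the required sign is clamped to $\pm m$, the sign margin;
well-separated coordinates are left untouched. Realising the adjustment as
a per-domain clamp rather than a per-class additive constant is the
smallest intervention that enforces the sign constraints without
distorting domains that already satisfy them. The clamp is idempotent,
which the test suite asserts directly.

## The 440 features

Seven families, concatenated in a fixed documented order (20, 40, 20, 20,
140, 120, 80 features), all computed from the integer log-odds block
$P_{ij}$ with $P^+ = \max(P, 0)$ and $P^- = \min(P, 0)$:

1. **G1** — $\sqrt{N_j/L}$, the square-root amino-acid composition. The
   square root tempers the dominance of abundant residues; the squared
   values sum to one.
2. **G2** — per-type means of $P^+$ and $P^-$: how strongly the domain
   tends toward, and away from, each substitution target.
3. **G3/G4** — autocorrelations (lags 1–10) of the per-position
   profile-weighted hydrophobicity $h_i = \sum_j H_j P_{ij}$ and
   side-chain mass, positive and negative parts separately. Helix
   periodicity (≈3.6 residues) and strand alternation (2) leave opposite
   signatures in short-lag autocorrelation.
4. **G5** — raw per-column autocorrelation at lags 1–7, the finest-grained
   periodicity signal.
5. **G6** — mean squared window average of $P^\pm$ over windows of 4, 8
   and 16 residues: sustained local substitution preference at the scale
   of a strand, a helix turn pair, and a full helix.
6. **G7** — where along the chain each residue type is favoured: weighted
   mean position, positional spread, first-half/second-half bias and edge
   affinity of $P^+$, with the neutral values $(0.5, 0, 0, 0.25)$ when a
   column has no positive weight.

Raw integer scores are used without sigmoid rescaling; the regression's
feature standardization absorbs scale differences between groups. The lag
ranges 10/10/7 and the positive/negative split follow from the family
cardinalities; the three G6 window lengths and the four G7 statistics are
this package's design choices, made once and exposed in the registry.

Non-standard residues (`X`) keep their PSSM rows but count toward no
composition type, since $N_j$ is defined only over the 20 standard types.
Domains shorter than a lag or window emit zeros for the affected entries
(with a warning) so the vector length never varies — the $4 \times 441$
model requires fixed dimensionality.

# Fitting

## Standardization and least squares

Features are standardized (per-column mean/SD, fit once on the full
training set so prediction needs a single transform; zero-variance columns
get scale one). Each of the four coordinates is fit on its own class
subset — the full-class unions all-α ∪ all-β ($x$), all-α ∪ mixed ($y_1$),
all-β ∪ mixed ($y_2$), α/β ∪ α+β ($z$) — by QR-based least squares. If a
design is rank deficient the solver switches to a ridge-regularised solve
with $\lambda = 10^{-8}$ and says so; this keeps tiny fixtures and
under-determined subsets well-defined, but an interpolating fit is not a
good estimator (see *Feature selection*).

## Two-round iterative refinement

The initial target magnitudes are partly arbitrary (the clamp constant
$m$), so after a first least-squares round the targets are rebuilt from
the fitted values: where a fitted coordinate already carries the required
sign with magnitude at least $m$, the fitted value itself becomes the new
target; otherwise the target resets to $\pm m$. A second round refits.
Self-consistent refitting lets well-separated domains move to the
magnitudes the features actually support while the sign/margin guard keeps
every training domain on the correct side. On noiseless self-consistent
problems round two is a fixed point; across random separable problems the
test suite checks that refinement does not lose training-set sign
agreement in aggregate (single borderline rows may flip either way — the
per-seed property is not a theorem).

## Feature selection

Sequential forward stepwise selection, per dimension: the first feature
maximises $|r|$ with the target (zero-variance features score 0), each
later feature minimises the residual sum of squares of the enlarged model,
ties break to the lowest index. The implementation uses Gram–Schmidt
residualisation, which is algebraically identical to refitting at each
step but costs one pass over the remaining columns. With the full budget
it reproduces the full model's residual sum of squares exactly, which is
tested.

Selection matters whenever a subset's row count is comparable to the 441
coefficients. In that regime the unrestricted fit is rank deficient, the
ridge fallback interpolates, and held-out performance degrades — the
classical over-fitting regime for which the 120-features-per-dimension
protocol exists. The package therefore keeps "use all 440" as the default
(`select = NULL`) for large training sets, and uses `select = 120` in its
own end-to-end evaluation of the default synthetic dataset, whose subset
sizes (400–600 rows) are squarely in the limited-size regime. The
acceptance script reports both accuracies.

## Prediction

`predictVector()` applies the trained affine map; `decideClass()` routes
signs through the fixed tree, with exact zeros taking the `else` branch of
each comparison ($x = 0$ → β side, $y = 0$ → mixed, $z = 0$ → α+β). The
convention is arbitrary but total and deterministic, and the tests sweep a
$5^4$ sign/zero grid to confirm every point maps to exactly one class.

# Evaluation

Per-class one-vs-rest sensitivity $TP/(TP+FN)$, specificity $TN/(TN+FP)$
and Matthews correlation (defined as 0 when a denominator factor
vanishes), overall accuracy, and the generalized squared correlation
$GC^2 = \chi^2 / (N(K-1))$ with $K = 4$, expected counts from the
row/column marginals, and zero-expectation cells skipped. "Sp" here is
specificity, not precision; with four classes the true-negative pool is
large, which is why specificities run high even at moderate sensitivity.
$GC^2$ measures association, not accuracy — a label-permuted perfect
confusion matrix still scores 1 — and the suite tests exactly that, to
keep the two notions distinct. Confusion counts are cast to double before
the MCC product: four-factor count products overflow 32-bit integers at
realistic dataset sizes.

Cross-validation builds stratified folds (per-class sizes differing by at
most one) from a caller-supplied seed; the jackknife harness is plain
leave-one-out with a pooled confusion matrix.

# The synthetic generator

`simulateDataset()` makes the whole pipeline runnable without external
data. Per class it samples block-grammar secondary-structure strings
(helix blocks of 6–20 residues with coil for all-α; anti-parallel strands
of 3–10 for all-β; alternating helix/parallel-strand for α/β; a helical
region followed by an anti-parallel region for α+β), draws residues from
element-conditioned propensity tables (helix formers on `H`,
β-branched/aromatic on strands, turn formers on coil), and emits integer
log-odds PSSMs with own-residue dominance (≈ +4), mildly positive
same-group scores, negative otherwise, an element-conservation bonus of
`signalStrength` on the element's group columns, Gaussian noise of SD
`noiseSd`, and clipping to $[-10, 13]$.

Defaults: 250 domains per class (an 80/20 stratified split gives 200
train / 50 test per class), lengths 60–300 (domains under 30 residues are
excluded by construction, mirroring standard benchmark filtering),
`noiseSd = 1`, `signalStrength = 1`. These were chosen once as a
realistic-looking operating point for a desk-scale study and are not
tuned.

What the generator does **not** emulate: PSI-BLAST iteration effects,
alignment-depth-dependent score calibration, real fold-level sequence
diversity, domains embedded in multi-domain parents (synthetic domains are
their own parents), or sheet-topology annotation errors. Passing tests on
synthetic data therefore demonstrate that the pipeline recovers a planted
linear signal end-to-end — parameter recovery — not that it attains any
particular accuracy on real SCOP-derived benchmarks, which require real
profiles computed against a reference database.

# Numerical choices and degenerate inputs

* $k_0 = 8$ residues (window length): about two helix turns or a long
  strand — long enough to see local element mixing, short enough that
  $\min(k_0, L)$ rarely truncates. Whether one window length or several
  should be aggregated is an open question; one is used.
* $\theta = 0.1$ (mixed-content threshold): a domain with less than 10%
  sheet (helix) window content is treated as effectively sheet-free
  (helix-free).
* $\delta = 10^{-6}$: keeps $z$ defined for sheet-free domains, sending it
  smoothly to 0 rather than NaN.
* $m = 0.05$ (sign margin): small against typical composition contrasts
  (~0.3–0.9) so the clamp is a constraint, not the signal.
* Ridge $\lambda = 10^{-8}$: numerically stabilising only, three orders
  below the smallest meaningful eigenvalue scale of a standardized design.
* Zero-variance features: scale set to 1 (standardize to zero),
  correlation defined as 0 for selection.
* Model files store numbers at full precision (JSON, 17 significant
  digits) so a write/read round trip reproduces coefficients exactly.

# Problem sizes in the test suite

The suite exercises every oracle at small scale: 100-fixture round-trip
and brute-force-equivalence loops for parser and feature families (domain
lengths 17–40), regression oracles at $n \le 60$, and resampling harnesses
on 12–25 domains per class. The end-to-end recovery check runs the full
default dataset (1,000 domains). The jackknife/cross-validation agreement
check uses 80 training domains per seed — a size where single-seed
accuracy carries several domains' worth of binomial noise, so the two
protocols are compared on 5-seed means. These sizes are the package's own
choices to keep the suite fast while leaving every code path exercised.

# Known limitations

* The class decision is hard; no posterior probabilities or rejection
  option are provided.
* Sheet-topology labels (`A` vs `P`) must be supplied for training;
  deriving them from 3D coordinates (or DSSP output) is out of scope.
* Domains are assumed continuous intervals within their parent sequence.
* The seven minor structural classes are not modelled.
* Short domains ($L \le 16$) lose part of the autocorrelation/segment
  signal to zero padding.
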