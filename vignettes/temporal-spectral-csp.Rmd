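---
title: "Decoding motor imagery with temporal-spectral CSP, backward selection, and an exact-design RBF network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding motor imagery with temporal-spectral CSP, backward selection, and an exact-design RBF network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfbcsp)
```

## The decoding problem

Imagined limb movement (motor imagery, MI) modulates the power of
sensorimotor EEG rhythms: mu/alpha (8–13 Hz) and beta (14–30 Hz) band power
drops contralaterally to the imagined hand (event-related
desynchronization). A two-class MI decoder must find *where* (which
channels), *when* (which part of the trial), and *in which frequency band*
this modulation is expressed — all three vary strongly across subjects.

`tfbcsp` implements a decoder that makes the when and the in-which-band
explicit model dimensions. Each epoch is decomposed over a grid of
overlapping frequency bands crossed with overlapping time windows; each
grid cell yields Common Spatial Patterns (CSP) log-variance features; a
wrapper feature selection (Sequential Backward Selection, SBS) prunes the
cell grid with the classifier in the loop; and an exact-design radial basis
function network (RBFNN) performs the final classification.

## The processing chain

### Preprocessing

Epochs are bandpass filtered to 4–40 Hz with a fifth-order Butterworth
design applied forward and backward. Zero-phase application was chosen
because the analysis is offline and epoched: it preserves the temporal
alignment of the window grid, at the cost of doubling the effective
magnitude order (the stated order is the design order of the prototype).
Edges are padded with an odd reflection three polynomial-orders long, so
that 2-s windows are usable without startup transients. Two consequences
worth knowing:

* the time-reversal symmetry of zero-phase filtering holds exactly only in
  the epoch interior; within a couple of filter ring-down times of the
  epoch edges the padded forward and backward transients differ at the
  1e-3 level;
* the analysis window (500 ms onward) deliberately skips the reaction-time
  region at the trial start.

Cropping uses half-open `[start, end)` sample intervals with 0-based sample
arithmetic, so overlapping windows never double-count a boundary sample and
`round(duration × fs)` always gives the sample count.

### The temporal-spectral grid

Bands of width 4 Hz stepping by 2 Hz across 4–40 Hz give 17 overlapping
bands; five 2-s windows stepping by 500 ms across 500–4500 ms give the
default 85-cell grid. The conventional reduced grids (12 bands to 30 Hz,
three windows to 3500 ms) are available as `ablation_variants()`. Band
edges are reconstructed from the width/step/range description; this
reconstruction reproduces both the 17-band and the 12-band counts, which is
why it was adopted.

Each cell's segment is produced by filtering the *full* preprocessed epoch
with the cell's band filter and then cropping the window
(`order_mode = "filter_first"`). The alternative order (crop first, then
filter) is exposed as a switch, but filtering first is the default: all
windows of a band then share one transient-free filtered signal, whereas
filtering 2-s crops would put filter edge effects inside every window.

### CSP features

For a trial matrix $X \in \mathbb{R}^{N\times T}$ the trace-normalized
covariance is $C = XX^\top / \mathrm{tr}(XX^\top)$. Class-mean covariances
$\bar C_1, \bar C_2$ are summed to $C_c$, whitened through the
eigendecomposition $C_c = U_c \lambda_c U_c^\top$ with
$P = \lambda_c^{-1/2} U_c^\top$ (the $-1/2$ exponent is forced by the
whitening identity $P C_c P^\top = I$), and the whitened class covariance
$S_1 = P \bar C_1 P^\top$ is eigendecomposed as $S_1 = B \lambda B^\top$.
Because $S_1 + S_2 = I$, both classes share the eigenvectors $B$ and the
eigenvalue spectra are complementary ($\lambda_1 + \lambda_2 = 1$
componentwise). The projection is $W = B^\top P$, rows sorted by descending
first-class eigenvalue, each row's sign fixed so its largest-magnitude
entry is positive (the features are sign-invariant; the convention only
makes outputs reproducible). Ties in the eigenvalues are resolved by the
deterministic ordering of the symmetric eigensolver.

The retained components are the first and last $m$ rows — the most
discriminative tails. When $2m$ exceeds the channel count (3-channel
recordings with $m = 3$) the literal first/last rule duplicates middle
rows; the duplicates are kept by default because distinct results for
$m = 2$ and $m = 3$ on 3 channels imply the reference implementation kept
them, and `dedupe_components = TRUE` gives the alternative. Features are
$f_p = \log( \mathrm{var}(Z_p) / \sum_i \mathrm{var}(Z_i) )$ with
$Z = W X$ restricted to the retained rows and the sum running over those
rows only (the normalization makes each cell's feature vector a log-simplex
point: all entries are non-positive and their exponentials sum to 1).
Variances use the population denominator without mean removal — band-passed
signals are zero-mean to numerical precision — making the features exactly
invariant to global amplitude scaling. If the composite covariance is
ill-conditioned (condition number above 1e10, e.g. on degenerate synthetic
inputs), a ridge of `1e-8 × trace/N` is added with a warning.

### Sequential Backward Selection

SBS treats each grid cell as one feature unit. Every round evaluates all
leave-one-out candidate subsets of the active set and discards the cell
whose *removal* leaves the highest accuracy — the cell contributing least.
The description "the feature yielding the lowest accuracy was discarded"
and the worked example (the best-scoring leave-one-out candidate is
dropped) superficially disagree; the worked example is normative here,
and it is also the only reading under which the procedure is a standard
backward elimination. The full trajectory is recorded and the reported
subset is the argmax over *all* evaluated subsets, including the initial
full set. Counting the initial anchor evaluation plus every candidate, a
full run from $F$ cells performs $F(F+1)/2$ evaluations — 3,655 from the
85-cell grid — which is how `eval_count` is defined. Exact ties between
candidates discard the cell earliest in the original cell ordering, for
determinism. The evaluator is a callback, so the selection logic is
classifier-agnostic and is unit-tested against exhaustive enumeration with
additive stub evaluators (for which backward elimination is provably
optimal); for non-additive evaluators greedy elimination is heuristic, and
no optimality is claimed or tested.

### The exact-design RBF network

The classifier is the exact-design RBFNN: every (z-scored) training sample
is the center of one Gaussian hidden unit,
$F(x) = \sum_i w_i e^{-\lVert x - c_i \rVert^2 / 2\sigma_i^2} + b$, and the
linear output layer $[\Phi \,|\, 1][w; b] = y$ is solved in the ±1 label
coding by minimum-norm least squares (Gram fast path, SVD pseudoinverse
fallback when the design is rank-deficient or numerically flat). For
distinct training points the system is consistent, so the network
reproduces its training labels — the defining property of the exact design.
The default width is `spread = 16` applied to z-scored features, reading
the kernel's $\sigma_i$ literally as the spread value;
`sigma_mode = "matlab"` instead replicates the half-response-at-spread
convention of MATLAB's `newrbe`
($f = e^{-(0.8326\, d/\mathrm{spread})^2}$). Both readings are kept because
the reference description mixes the kernel formula with a MATLAB
hyperparameter; whether the value applies before or after scaling is not
stated, and the scaled reading was adopted since scaling precedes training
in the described protocol.

A numerical fact that shapes the tests: the Gaussian kernel matrix, while
positive definite in exact arithmetic for any width, becomes numerically
flat as the width grows — at `spread = 16` on z-scored features its
condition number can exceed the reciprocal machine precision, and exact
interpolation is then not always achievable in double precision (measured:
~45/50 random problems sign-exact at spread 16 versus 50/50 at spread ≤ 1).
The exact-interpolation property is therefore asserted in the
well-conditioned width regime, while score agreement with the term-by-term
radial-basis summation is asserted at all widths including 16.
Classification quality at spread 16 does not hinge on exact interpolation
(the sign pattern survives small residuals), which is why the wide default
still decodes well. Ties at score exactly 0 go to the positive class — the
first class in sort order, matching the metrics module's default.

### Metrics

Confusion counts feed PPV, NPV, TPR (sensitivity), TNR (specificity) and
Cohen's kappa $(P_o - P_e)/(1 - P_e)$ with the marginal chance agreement
$P_e = [(TP{+}FP)(TP{+}FN) + (TN{+}FN)(TN{+}FP)]/\mathrm{total}^2$ — the
standard Cohen construction, chosen because only the symbolic kappa formula
is given in the source description. Ratios with zero denominators are
reported as `NaN` with a warning, never silently coerced to 0. Swapping the
positive class swaps PPV↔NPV and TPR↔TNR and leaves accuracy and kappa
unchanged.

## Cross-validation protocol and leakage

The default protocol is fully nested: within each outer stratified fold,
CSP filters, the feature scaler, the SBS decisions, and the RBFNN all see
training trials only; the SBS evaluator is the mean inner-CV accuracy
(default 5 inner folds) on the training partition; the final network is
refitted on the whole training partition restricted to the selected cells
and evaluated once on the held-out fold. Every fitting call logs the trial
indices it received, and the run asserts that no held-out index ever
entered a fitting routine (`result$leakage$ok`).

The flat alternative (`protocol = "flat"`) scores each SBS subset on
the outer folds themselves and reports the best trajectory accuracy. This
reproduces the common (and optimistic) usage in which selection and
reporting share folds; it is kept as an explicit switch for comparison, and
its results are flagged as non-nested. Nested was made the default because
selection-induced optimism is exactly the kind of effect a wrapper selector
over 85 cells can exploit.

Stratified folds deal each class round-robin after a seeded shuffle,
rotating the starting fold between classes so fold sizes differ by at most
one trial. The seed is mandatory in the configuration and every derived
RNG stream (fold assignment, inner folds) is a deterministic function of
it, making runs bit-reproducible.

`sweep_m()` re-runs the pipeline for each CSP tail size on one shared fold
assignment (paired comparisons; the across-m standard deviation of the
means is reported, mirroring the usual sensitivity table), and
`run_ablation()` does the same across reduced grids, reporting accuracy
deltas against the full configuration.

## The synthetic generator

Real MI recordings cannot be bundled, so validation uses a generator whose
construction mirrors what the decoder assumes: each trial is pink
($1/f$-amplitude) background noise per channel plus white sensor noise,
plus one or more planted sources. A planted source is band-limited Gaussian
noise (fifth-order Butterworth to its band), amplitude-modulated to its
time window with 50-ms raised-cosine ramps (avoiding spectral splatter),
mixed to the channels by a focal spatial pattern, with the second class's
amplitude scaled by $e^{\mathrm{effect}/2}$ so the class log band-power
ratio in the planted cell equals `effect`. Band-limited noise rather than
sinusoids was chosen deliberately: CSP's objective is variance-based, and
narrowband noise exercises it the way rhythmic EEG does, whereas a
deterministic sinusoid would make the problem artificially easy.

Defaults mirror a 22-channel, 250 Hz, 72-trials-per-class, 7-s-epoch
layout. The generator emulates class-dependent band-power localization
under spatial mixing — the feature the decoder targets — but not volume
conduction from a head model, nonstationary ERD time courses, artifacts,
or inter-session drift. Passing the end-to-end tests therefore shows the
chain recovers planted band/window/space structure at realistic SNR; it
does not certify performance on real recordings.

Amplitude conventions (chosen once, on the microvolt scale of scalp EEG):
background sd 10, sensor noise sd 2, source sd 6. An `effect` of 2.2
(≈9× power ratio) is used as the "strong effect" condition in the
validation suite; `effect = 0` makes the classes draws from the identical
law.

## Problem sizes used in the validation suite

The bundled tests validate the full chain at sizes a single CPU handles
comfortably: the end-to-end checks use 200 trials/class, 8 channels, and a
6-band × 3-window grid (4–18 Hz × 500–3500 ms) for the accuracy and
label-permutation assertions, and 100 trials/class across 10 seeds for the
planted-cell recovery rate; unit tests run on toy problems of a few dozen
trials. The m-sweep and ablation drivers are exercised on reduced grids for
the same reason. These sizes are the package's own validation choices; the
drivers accept full-size problems unchanged.

## Known limitations

* Two classes only; multi-class CSP extensions are out of scope.
* The RBF linear layer is solved, not trained; iteratively trained RBF
  variants (center selection, gradient descent) are not implemented.
* Greedy backward elimination is not optimal for non-additive evaluators;
  the trajectory report exists precisely so selections can be audited.
* The generator's `effect` plants a stationary within-window power
  contrast; time-varying desynchronization profiles are not modeled.
* EDF/GDF ingestion is not bundled; external recordings enter through the
  documented plain epoch container (`write_epoch_container()` /
  `read_epoch_container()`).
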