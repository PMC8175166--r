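---
title: "Multilinear discriminative spatial patterns: model, algorithm, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilinear discriminative spatial patterns: model, algorithm, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Movement-related cortical potentials (MRCPs) are slow negative EEG shifts that
build up before a voluntary movement: a bereitschaftspotential starting 1–2 s
before the movement and a steeper negativity slope about 0.4 s before it. They
live below ~7 Hz, are strongest over central electrodes contralateral to the
moving limb, and are buried in broadband background activity, so detecting
them (e.g. left- vs right-finger taps in a brain–computer interface) requires
supervised spatial filtering.

The classical tool is discriminative spatial patterns (DSP): given trials
$X_i \in \mathbb{R}^{c \times t}$ (channels × time) with labels
$y_i \in \{1,\dots,p\}$, class means $M_j$ and grand mean $M$, form

$$S_w = \sum_j \sum_{i: y_i = j} (X_i - M_j)(X_i - M_j)^\top,\qquad
  S_b = \sum_j n_j (M_j - M)(M_j - M)^\top,$$

and take the spatial filters $U \in \mathbb{R}^{c \times d}$ maximizing the
Fisher ratio $\operatorname{tr}(U^\top S_b U)/\operatorname{tr}(U^\top S_w U)$,
i.e. the top generalized eigenvectors of $(S_b, S_w)$. DSP filters only the
channel mode; the time course and, after a time–frequency expansion, the
spectral content are left unfiltered.

## The multilinear model

MDSP generalizes this to trials that are order-$h$ tensors
$\mathbf{X}_i \in \mathbb{R}^{m_1 \times \cdots \times m_h}$ — here $h=2$
(channels × time) or $h=3$ (channels × time × wavelet scale) — by learning one
projection matrix per mode, $U_k \in \mathbb{R}^{m_k \times m_k'}$, jointly
maximizing

$$J(U_1,\dots,U_h) \;=\;
  \frac{\sum_j n_j \,\lVert (\mathbf{M}_j - \mathbf{M})
        \times_1 U_1 \cdots \times_h U_h \rVert_F^2}
       {\sum_j \sum_{i: y_i=j} \lVert (\mathbf{X}_i - \mathbf{M}_j)
        \times_1 U_1 \cdots \times_h U_h \rVert_F^2},$$

where $\times_k$ is the mode-$k$ tensor–matrix product. The subspaces are
*interrelated*: each $U_k$ is optimal only relative to the others, which
matches the structure of a time–frequency EEG tensor (a spatial filter is only
meaningful for the band and latency it is paired with).

There is no closed-form joint maximizer, so the package uses Gauss–Seidel
alternating optimization (`fit_mdsp()`): with all modes but $k$ fixed, the
criterion reduces to a DSP-type trace ratio in $U_k$ with partially projected
scatters

$$S_b^{(k)} = \sum_j n_j B_j^{(k)} B_j^{(k)\mathsf{H}},\qquad
  S_w^{(k)} = \sum_i W_i^{(k)} W_i^{(k)\mathsf{H}},$$

where $B_j$ and $W_i$ are the centered class means and trials projected
through every $U_d$, $d \ne k$, and $(\cdot)^{(k)}$ is the mode-$k$ unfolding.
`mode_scatter()` implements this reduction and the test suite verifies the
identity numerator/denominator-by-trace against the direct Frobenius forms.
Each update solves the symmetric-definite generalized eigenproblem via
Cholesky reduction (no explicit $S_w^{-1} S_b$), which is the
better-conditioned route to the same eigenvectors.

Convergence is monitored by the per-mode relative change

$$\mathrm{err}_k(t) = \frac{\lVert U_k^t - U_k^{t-1} \rVert_F}
                           {\lVert U_k^{t-1} \rVert_F^2},\qquad
  \mathrm{err}(t) = \sum_k \mathrm{err}_k(t),$$

with defaults $\varepsilon = 0.01$ and $t_{\max} = 50$ sweeps. Alternating
eigen-optimization has no convergence guarantee; a fit that does not reach
$\varepsilon$ is returned flagged (`converged = FALSE`) rather than raising,
and `grid_search()` excludes such parameter combinations from its ranking —
non-coordinating filter counts are treated as information, not as errors.

Classification (`predict()`) is nearest projected class mean: a trial is
projected through all $U_k$ and assigned to the class whose projected mean
tensor is closest in Frobenius norm. Note the deliberate asymmetry, kept from
the method's definition: DSP features subtract the training grand mean
(`dsp_features()`), but the tensor classifier projects the raw trial and
compares against projected class means without grand-mean centering.
Distance ties go to the lowest class id.

## Preprocessing chain

`tensorize_epochs()` implements the standard MRCP chain:

1. optional downsampling to 100 Hz (`eeg_resample()`), implemented as exact
   Fourier-domain resampling (zero delay; output length `round(T * p/q)`);
2. zero-phase low-pass Butterworth filtering (`eeg_lowpass()`), defaults
   order 5 and 7 Hz cutoff — the MRCP band; odd-reflection padding is applied
   around the forward–backward pass so epochs with offsets have no edge
   transients;
3. sliding windows (`sliding_windows()`), default 0.5 s length moved in
   0.1 s hops (i.e. 0.4 s overlap). The hop reading of the segmentation rule
   is the default; passing `step_s = 0.4` gives the literal 0.1 s-overlap
   alternative, so neither interpretation is lost;
4. continuous wavelet transform (`cwt_tensorize()`) with a complex Gaussian
   mother wavelet, turning each window into a channels × time × scales
   tensor. Default: `cgau4`, 10 scales, log-spaced so their pseudo-frequencies
   cover 0.5–7 Hz at the working rate. The exact scale values and derivative
   order are not canonical for this method; both are explicit, documented
   choices and fully configurable. By default the coefficient modulus is
   stored (`magnitude = TRUE`); complex coefficients can be kept, in which
   case scatters use Hermitian outer products and the (real) eigenproblems
   are solved on their real parts, keeping all projections real.

Windows cut from one epoch share a group label, and `cross_validate()`
assigns whole groups to folds by default, so temporally overlapping windows
never straddle a train/test split. The 5 × 5-fold protocol (5 folds, 5
repeats, stratified by class) is the default.

## Synthetic data: what it emulates and what it does not

Two seeded generators make the pipeline verifiable without any recordings.

**`planted_dataset()`** draws class mean tensors
$a \cdot \mathbf{C}_j \times_1 Q_1 \cdots \times_h Q_h$ with shared random
orthonormal bases $Q_k \in \mathbb{R}^{m_k \times r_k}$ and distinct random
cores, then adds iid Gaussian noise of sd $\sigma$ to every trial. This makes
the Fisher model exactly correct and gives ground truth for
`subspace_recovery_score()` (principal angles between estimated and planted
spans). Defaults: $a = 1$, $\sigma = 0.1$, 40 trials per class. A
`holdout_per_class` field draws extra trials from the same means for
held-out evaluation.

**`mrcp_trials()`** emulates the MRCP phenomenology: a linear negative ramp
reaching $-$`amplitude` at the movement event on a lateralized subset of
channels (mirrored central sites for left- vs right-finger classes), plus
1/f (pink) noise on every channel. Defaults echo a 19-channel, 100 Hz,
2 s-epoch, 40-trials-per-class recording session with ramp onset 0.4 s
before the event (the negativity-slope component) and pink-noise sd 2.

Neither generator models volume conduction, electrode covariance,
oscillatory ERD/ERS activity, artifacts, or inter-subject variability, so a
passing pipeline demonstrates correctness of the estimator and machinery,
not expected accuracy on recorded EEG.

For the end-to-end checks the test suite uses the *early-onset* variant
(onset equal to the full 2 s epoch, i.e. a bereitschaftspotential-like drift,
amplitude 8, noise sd 0.5): with the default late onset, the windows earlier
than $-0.9$ s contain no class signal at all, so window-level accuracy is
bounded well below 1 regardless of the estimator, and a window-level accuracy
criterion is only meaningful when every window carries signal.

## Numerical choices

* **Unfolding convention.** `tensor_unfold(x, k)` places element
  $(i_1,\dots,i_h)$ in row $i_k$ and column
  $1 + \sum_{d \ne k} (i_d - 1) \prod_{e < d, e \ne k} m_e$ (remaining modes
  ascending, lowest varying fastest). Any self-consistent convention yields
  identical subspaces; this one makes unfold/fold/mode-product mutually
  consistent and is pinned by a brute-force oracle test. Modes are 1-based
  throughout the user interface.
* **Eigenvector canonicalization.** Generalized eigenvectors are returned
  with unit Euclidean norm and sign chosen so the largest-magnitude entry is
  positive (ties to the lowest index). The Fisher ratio is scale-invariant,
  and without this normalization the convergence error would respond to
  arbitrary eigenvector scaling and sign flips instead of to subspace
  rotation. Under eigenvalue ties the spanned subspace, not the individual
  columns, is the contract.
* **Ridge.** Within-class scatters receive
  $(\mathrm{reg} \cdot \operatorname{tr} S_w / m
  + \epsilon_{\text{mach}} (\operatorname{tr} S_w + \operatorname{tr} S_b)/m)\, I$
  with default $\mathrm{reg} = 10^{-8}$. The relative term handles
  $n < c + p$ rank deficiency; the machine-epsilon floor matters only when
  $S_w$ is rounding-level garbage (noiseless synthetic data), where whitening
  against it would be meaningless. `reg = 0` reproduces the unregularized
  formulation verbatim and raises an informative error on singular input.
* **Sweep order and initialization.** Modes are updated in ascending index
  within each sweep, each update seeing the latest values of the others.
  $U_k$ starts as the first $m_k'$ columns of the identity (deterministic;
  makes the first channel-mode update coincide with a DSP solve on identity
  co-projections); a seeded random-orthonormal initialization is available
  for robustness studies. The convergence error is measured against the
  previous sweep.
* **Two scatter paths.** Small problems accumulate scatters trial by trial in
  class order — bit-identical to the 2-D `scatter_matrices()` in the $h=2$
  reduction. Large problems (over $10^5$ trial elements) use a stacked
  formulation: all mode-$k$ unfoldings are stacked once per fit, and each
  sweep computes $S_w^{(k)}$, $S_b^{(k)}$ via the identity
  $(\mathbf{X} \prod_{d \ne k} \times_d U_d)^{(k)} =
  \mathbf{X}^{(k)} (U_h \otimes \cdots \otimes U_1)_{d \ne k}$
  (Kronecker factors in descending mode order), reducing a sweep to a few
  BLAS products. The two paths agree to floating-point reassociation and are
  cross-checked in the tests; the per-sweep cost scales as
  $O(\sum_k m_k^3)$ plus a term linear in the data size, never as
  $O(\prod_k m_k^3)$.
* **Principal angles.** `subspace_recovery_score()` uses the cosine route
  (singular values of $Q^\top U$) for large angles and the sine route
  (spectral norm of $U - QQ^\top U$) once the cosine exceeds
  $1/\sqrt{2}$, because `acos` cannot resolve angles below about
  $10^{-8}$.
* **Signal processing.** Butterworth design and the forward–backward pass
  come from the `signal` package; resampling and the complex Gaussian CWT are
  implemented in-package (spectral resampling; wavelet evaluated through the
  derivative recursion $p_{n+1} = p_n' + (-i - 2x) p_n$ against
  $e^{-ix - x^2}$, numerically L2-normalized, applied by FFT convolution) and
  are pinned to direct-summation oracles in the tests.

## Known limitations

* **Estimator bias in subspace recovery.** For an exactly low-rank between
  scatter, the span of the top generalized eigenvectors is
  $S_w^{(k)-1}\operatorname{col}(S_b^{(k)})$, so any sampling fluctuation in
  the within-scatter tilts the recovered span away from the planted one by
  roughly its relative spectral error, $\sqrt{m_k / (n \prod_{d\ne k} m_d')}$
  — *independently of the noise amplitude*. With 40 trials per class and
  2 × 2 co-projections on a $16 \times 50 \times 10$ tensor this tilt is
  several tenths of a radian even though held-out classification is
  essentially perfect; recovering the subspace to better than ~0.15 rad at
  that geometry requires roughly an order of magnitude more trials (the
  $1/\sqrt{n}$ decay is verified in the test suite's scaling probes).
  Classification accuracy and subspace fidelity are therefore very different
  currencies for this estimator.
* **Redundant filters are near-neutral under iid noise.** With iid trial
  noise the nearest-prototype decision reduces to a projection onto the
  prototype difference, so filter counts above the true rank degrade accuracy
  only through prototype estimation noise. The practical preference for 2–4
  filters per mode shows up here as sufficiency (2–4 reaches the best grid
  accuracy) and as the convergence-discard rule removing saturated counts,
  not as a sharp accuracy peak; on recorded EEG, structured noise makes the
  penalty for redundant filters stronger.
* **Non-convergence is data-dependent.** Filter counts above the
  discriminative rank leave trailing eigenvectors free to wander in noise
  directions, and such fits routinely exhaust $t_{\max}$; they often still
  classify well. The grid-search discard rule is the intended control.
* Complex-coefficient CWT tensors are supported but the shipped default is
  the modulus; how complex coefficients should enter the scatters is not
  canonical, and the Hermitian-real treatment here is one documented choice.

## Problem sizes used by the checks

The packaged tests and `scripts/acceptance.R` size their simulations for a
single CPU: 50 random tensors (orders 2–4, sizes ≤ 5) for the algebra
oracles; 20 random 2-class instances for the DSP reduction; 10 seeds of the
$16 \times 50 \times 10$, 40-trials-per-class planted recovery; a 50-dataset
convergence suite at $8 \times 12 \times 6$ with $\sigma/a = 0.3$ (a
moderate-noise setting fixed a priori); one 19-channel, 80-epoch MRCP session
for the end-to-end pipeline (1280 windowed tensors); and a doubled-mode
timing probe at $24{\to}48 \times 20 \times 8$. A full run of the acceptance
script takes on the order of two minutes.

```{r example}
library(mdsp)

spec <- mrcp_spec(onset = 2, amplitude = 8, noise_sd = 0.5,
                  trials_per_class = 20, seed = 42)
tr <- mrcp_trials(spec)
tensors <- tensorize_epochs(tr$epochs, tr$labels)

fit <- fit_mdsp(tensors, dims = c(3, 3, 3))
glance(fit)
autoplot(fit)            # err(t) per sweep against the 0.01 threshold

cv <- cross_validate(tensors, dims = c(3, 3, 3), folds = 5, repeats = 5,
                     seed = 1)
glance(cv)
autoplot(cv)
```
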