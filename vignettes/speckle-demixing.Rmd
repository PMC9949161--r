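---
title: "Demixing and localizing fluctuating emitters behind scattering media"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demixing and localizing fluctuating emitters behind scattering media}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specklepipe)
```

## The problem

A group of fluctuating fluorescent emitters (beads driven with
calcium-indicator-like activity, or neurons expressing a genetically
encoded calcium indicator) sits behind a strongly scattering medium. No
image of the emitters reaches the camera; each emitter instead casts a
fixed, high-frequency speckle pattern — its *fingerprint* — and the camera
records the incoherent sum of all fingerprints weighted by the momentary
brightness of each emitter. A frame at time $t_k$ is

$$ I_k(x, y) = \sum_{s=1}^{N} w_s(x, y)\, h_s(t_k), $$

or in matrix form $I = W H$ with one flattened frame per column of $I$,
one fingerprint per column of $W$, and one nonnegative temporal trace per
row of $H$. Both factors are nonnegative (intensities of fluorescent
light), so the demixing problem is a non-negative matrix factorization
(NMF):

$$ \min_{W, H \ge 0} \tfrac12 \lVert I - W H \rVert_F^2
   + \lambda_W \lVert W \rVert_1 + \lambda_H \lVert H \rVert_1 . $$

Localization then exploits the *optical memory effect*: for a thin
scatterer, laterally displacing a source translates its speckle pattern,
with the correlation between the original and translated patterns decaying
over a characteristic distance $R$ (the memory-effect range). The
regularized (Wiener) deconvolution of fingerprint $w_j$ by $w_i$ is then a
delta-like peak whose offset from the image center equals the pixel shift
between the two emitters — for pairs within $R$. Distant pairs give only a
noise-like image. Summing the deconvolutions of one fingerprint against
all others gives that emitter's *partial location map*; composing pairwise
shifts across the whole ensemble stitches those maps into a global one,
valid well beyond $R$ provided nearest neighbors stay inside $R$.

## The pipeline

`run_pipeline()` chains five stages, all individually exposed:

1. **simulate** (`simulate_movie()`) — synthetic movies with ground truth;
2. **preprocess** (`preprocess_movie()`) — per-frame envelope removal by
   unsharp masking, with nonnegativity restoration;
3. **rank estimation** (`estimate_rank()`) — residual scan over candidate
   ranks;
4. **demix** (`factorize()`) — sparse NMF via fast HALS coordinate
   descent;
5. **localize** (`localize_fingerprints()`) — pairwise Wiener
   deconvolutions, shift graph, confidence-weighted least-squares
   synchronization, stitched map.

## What the simulator emulates — and what it does not

The generator reproduces the statistical structure the inverse method
relies on, not the optics that produce it:

* **Fully developed speckle.** Fingerprints are squared moduli of complex
  fields with uniform random phase on a circular pupil; a single pattern
  has contrast (sd/mean) 1, and an incoherent sum of $N$ independent
  patterns has contrast $1/\sqrt N$. (Speckle statistics give
  $1/\sqrt N$; the tests assert the monotone decrease and the
  $1/\sqrt N$ law rather than any other printed exponent.)
* **Memory effect.** The fingerprint of an emitter displaced by $d$ is the
  reference pattern translated by $d/\mathrm{pitch}$ pixels, with Pearson
  correlation $\alpha(d) = \exp(-(d/R)^2)$ — a conventional thin-diffuser
  decay law chosen for monotonicity; the method only needs *some* monotone
  decay. Decorrelation is implemented in the complex field domain
  ($\sqrt{g}$-weighted mixtures of independent fields with
  $g = \sqrt\alpha$), because for circular Gaussian speckle the intensity
  correlation is exactly the squared field correlation: an
  intensity-domain convex blend would give $\alpha/\sqrt{\alpha^2 +
  (1-\alpha)^2}$ instead — measurably wrong at $d = R$ (0.50 instead of
  0.37). Whole ensembles are drawn jointly as a Gaussian-process mixture
  over emitter positions (field covariance $\exp(-d_{ij}^2/2R^2)$, mixed
  via Cholesky), so the decay law holds for *every pair*, not only
  relative to one reference emitter — essential for stitching beyond $R$,
  where two nearby emitters far from the reference must still be mutually
  correlated.
* **Traces.** Poisson spike trains convolved with a one-sided exponential
  (defaults: rate 0.02 spikes/frame, decay 10 frames, baseline 0.1,
  amplitude 1), mimicking brief calcium-indicator rises with slow decays
  at realistic sparsity for ~500-frame recordings.
* **Background.** A temporally constant speckle pattern scaled to a target
  signal-to-background ratio (SBR), defined here as total time-averaged
  signal energy over total background energy. The reference description of
  SBR is ambiguous about per-source versus total bookkeeping; the total
  ratio is the primary readout and the per-source vector is available via
  `measure_sbr(gt, per_source = TRUE)`.
* **Noise.** Shot noise at a configurable photon budget (mean photons per
  pixel per frame) and Gaussian read noise, both seeded.

Not emulated: photon transport in tissue (scattering length and
anisotropy enter only through the phenomenological decorrelation law),
multiple depth planes and their scale changes, axial point-spread
structure, motion, photobleaching. A green test therefore establishes that
the *inverse machinery* is correct under the stated statistical model, not
that the model captures every feature of experimental data.

Seeds follow a counter scheme (`sub_seed()`): each consumer draws from its
own named stream derived from one master seed, so adding an emitter never
reshuffles the others' fingerprints or traces.

## Numerical and design choices

* **High-pass filter.** Unsharp mask, frame minus a truncated Gaussian
  blur (`sigma_px`, default 16 px = 4x the default grain). The filter's
  output is zero-mean, so nonnegativity must be restored: `"clip"`
  truncates at zero (preserves sparsity; module default), `"offset"`
  subtracts the frame minimum (preserves linearity up to a rank-one DC
  term). The *pipeline* default is `"offset"`: the synthetic world has no
  smooth envelope to remove, and clipping — a nonlinearity touching about
  half the pixels — measurably inflates the numerical rank and can push
  the factorization into poor local optima (a 19-source run that drops
  the weakest source). With experimental envelopes, `"clip"` remains the
  appropriate choice and both are exposed.
* **Rank estimation** runs on the movie *as recorded*, not on the
  clipped high-passed version, because rank is a property of the dataset
  and clipping inflates it. The elbow rule selects the first rank whose
  relative residual improvement over its predecessor falls below
  `epsilon` (default 5%), or whose residual is already below the
  noise-free floor `res_tol` (default `1e-3`); a non-decreasing residual
  stretch before the selection triggers an argmin fallback with a
  warning. The scan may run on a seeded random subset of pixel rows
  (default 8192), which preserves rank structure at a fraction of the
  cost. A temporally constant background legitimately adds one component,
  so with background the estimate is expected to be $N + 1$; matching
  absorbs the surplus component.
* **NMF solver.** Fast HALS coordinate descent with elementwise L1 on
  both factors; each row/column update is an exact nonnegative
  least-squares minimizer, so the penalized objective is monotone
  non-increasing (recorded per iteration, via trace identities — the
  data matrix is touched only twice per sweep). Multiplicative updates
  were tried first and converge too slowly to meet the noise-free
  `residual < 1e-3` contract within hundreds of iterations. Defaults
  $\lambda_H = 0.01 > \lambda_W = 0.001$ (relative to the mean movie
  intensity, hence scale-free): temporal sparsity is the stronger prior
  for spiking traces; mild spatial sparsity yields higher-contrast
  fingerprints. Initialization is deterministic nonnegative double SVD
  (computed from the frames' Gram matrix), with seeded random
  initialization available for robustness sweeps. Fingerprints are
  reported with unit L2 norm, scale folded into the traces; all accuracy
  statements are correlation-based after optimal (Hungarian) matching,
  since NMF is defined only up to permutation and scale.
* **Wiener deconvolution.** Fingerprints are mean-subtracted, apodized
  with a Tukey window (taper 0.25) against FFT edge artifacts, and
  deconvolved with regularization `balance * mean spectral power`
  (default balance 0.1). Sign convention, fixed and tested: if
  $w_i(x) = w_j(x - \Delta)$ then `deconvolve_pair(w_j, w_i)` peaks at
  $+\Delta$ from the center; equivalently the measured shift of the pair
  $(i, j)$ estimates $p_j - p_i$. The peak is accepted when its
  amplitude exceeds 5x the noise floor (median + 3 MAD excluding a
  window around the peak); the threshold is configurable because no
  numeric criterion is canonical. Sub-pixel (parabolic) refinement is
  deliberately absent: all placement tolerances are whole pixels.
* **Common-mode rejection.** NMF components share whatever structure the
  factorization could not attribute to one source (residual background, a
  split of the shared baseline). That common mode deconvolves to a
  spurious *zero-shift* peak between arbitrarily distant components. The
  across-component mean fingerprint is therefore subtracted before
  pairwise deconvolution (`common_mode = TRUE`). The mean leaks $1/n$ of
  each true pattern — for a handful of strongly correlated components it
  would subtract most of the signal itself — so the correction is applied
  only when at least five components are present.
* **Stitching.** Positions minimize
  $\sum_{(i,j)} c_{ij} \lVert (p_j - p_i) - s_{ij} \rVert^2$ over
  correlated edges, reference pinned at the origin — least-squares shift
  synchronization rather than anchoring every map to source 1, because
  the reference need not be within range of every other source; on trees
  it reduces to exact path composition. Edges whose residual against the
  solution exceeds `prune_px` (default 3 px) are removed iteratively,
  worst first, never disconnecting a placed node: a single confidently
  wrong edge (the zero-shift failure mode above) would otherwise bend the
  whole solution. Sources outside the reference's connected component are
  reported unplaced, never guessed.

## The reference simulations

Three presets (`run_config(preset = ...)`) pin the package's acceptance
surface at desk scale, preserving the reference experiment's ratios:

* `"plain"` — 19 sources, 500 frames, 256 x 256 px, all pairwise
  distances inside the memory-effect range (span 36 um vs R = 55 um),
  shot noise at 1000 photons/px/frame and 2-photon read noise, no
  background. Expected: estimated rank 19, every source placed at
  whole-pixel accuracy.
* `"background"` — 10 sources, 500 frames, 128 x 128 px, constant
  background speckle at SBR 1.6 (the lowest ratio at which the reference
  experiment still unmixed everything). The SBR sweep in
  `scripts/acceptance.R` walks 8, 4, 2, 1.6, 1.2 and reports the lowest
  fully successful level.
* `"beyond-me"` — 8 sources along a jittered chain spanning 1.7x the
  memory-effect range (span 51 um, R = 30 um), nearest-neighbor spacing
  about 7 um. Exercises stitching beyond R.

Frame sizes, grain size (4 px), memory-effect ranges and photon budgets
are desk-scale engineering choices made once: 10 um beads at unit
magnification on a ~1 um/px camera, memory-effect ranges a factor 2-5
above the bead spacing as in the reference geometry, and a photon budget
high enough that shot noise is visible but not dominant (~3% per-pixel
noise). Emitter density is the method's own stated requirement: stitching
requires nearest neighbors within the memory-effect range, and the
confidence threshold of 5 keeps only pairs with correlation roughly
$\alpha \gtrsim 0.5$, so the presets keep nearest-neighbor spacing below
about $0.7 R$ — the same density condition the reference experiments
satisfy.

## Degenerate inputs and edge behavior

Single-emitter movies short-circuit to a rank-1 factorization and a map
with one central peak at (0, 0). All-zero fingerprints, zero-mean frames,
rank requests beyond `min(pixels, frames)`, absent backgrounds in
`measure_sbr()`, and disconnected shift graphs are signalled rather than
silently absorbed. Non-convergence within `max_iter` returns the current
factors with a warning, never an error.

## Known limitations

* Placement accuracy is whole-pixel by design; emitters closer than one
  pixel pitch are not distinguishable.
* The rank scan can return $N + 1$ on background-corrupted movies (by
  design) and occasionally on clean ones when a weak source straddles the
  elbow threshold; matching and localization tolerate the surplus
  component, but reported component counts should be read with that in
  mind.
* Very weak sources (a handful of spikes in the whole recording) carry
  little energy; their trace correlations degrade first as noise grows.
* The decorrelation law is Gaussian by convention; real thin scatterers
  deviate in the tails, which mainly shifts where the confidence
  threshold cuts off usable pairs.
* The default confidence threshold (5) is calibrated for frames of
  128 px and larger: the peak-to-floor ratio of a true pair grows with
  the number of speckle grains, so 64 px frames sit below the threshold
  even for well-correlated pairs (measured: confidences 3-4.6 on
  ground-truth fingerprints). Lower the threshold or enlarge the frame
  for very small fields of view.
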