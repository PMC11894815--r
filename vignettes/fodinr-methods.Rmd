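---
title: "Continuous FOD fields from diffusion MRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous FOD fields from diffusion MRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Constrained spherical deconvolution (CSD) estimates, per voxel, a fiber
orientation distribution (FOD): a spherical function whose amplitude along a
direction reflects the density of axonal fibers oriented that way. The
measured diffusion-weighted signal is modelled as the spherical convolution
of the FOD with a *response function* — the signal of a single coherent
fiber population, axially symmetric, and therefore fully described by its
zonal (m = 0) spherical-harmonic coefficients. Multi-shell multi-tissue CSD
(MSMT-CSD) extends this with per-b-value, per-tissue responses and isotropic
volume-fraction terms for grey matter (GM) and cerebrospinal fluid (CSF).

Voxel-wise CSD ignores the spatial continuity of brain tissue: each voxel is
deconvolved independently, so noise propagates directly into the FOD, and
FODs off voxel centers require interpolation, which can hallucinate peaks
where fibers curve. `fodinr` instead represents the *entire* FOD field as a
single continuous function: a coordinate network (multi-layer perceptron
over a random Fourier encoding of position) maps any world-space location to
the SH coefficients of the FOD there. The network is trained, unsupervised,
on one dataset at a time, by passing its output through the CSD forward
model and penalizing the signal reconstruction error. Spatial correlation is
exploited implicitly — nearby coordinates share network weights — which acts
as a learned, data-adaptive regularizer.

# Spherical harmonics conventions

All spherical functions use the real, even-order basis in the MRtrix3
convention: for even order $l$ and phase $m$,

$$Y_l^m \mapsto \sqrt{2}\,\mathrm{Im}\,Y_l^{|m|} \; (m<0), \quad
Y_l^0 \; (m=0), \quad \sqrt{2}\,\mathrm{Re}\,Y_l^m \; (m>0),$$

with orthonormal complex harmonics (Condon–Shortley phase included), so the
real basis is orthonormal; coefficients are stored l-major with $m$
ascending, the MRtrix3 on-disk order, so SH images interoperate. A series up
to $l_{\max}$ has $(l_{\max}+1)(l_{\max}+2)/2$ coefficients — 45 at the
package default $l_{\max} = 8$. Spherical convolution with a zonal kernel
reduces to the per-coefficient product

$$s_{lm} = \sqrt{\tfrac{4\pi}{2l+1}}\, f_{lm}\, r_{l0},$$

the scale factor being the zonal coefficients of a band-limited Dirac delta.
This identity is verified in the test suite against brute-force quadrature
convolution (Gauss–Legendre in $\cos\theta$ times a trapezoid rule in
$\phi$, exact for band-limited integrands).

# The model

**Encoding.** A coordinate $x$ is normalized per axis to $[-1,1]$ over the
bounding box of the fitted volume's voxel centers (the only reference the
data offers), then mapped to
$\gamma(x) = [\cos(2\pi B\tilde x), \sin(2\pi B\tilde x)]$ with
$B \in \mathbb{R}^{n_p \times 3}$, $B_{ij} \sim N(0, \sigma^2)$, frozen
after creation. Defaults: $\sigma = 4$; $n_p = 1000$ for CPU fits (the
capacity knob; larger values sharpen the representable detail at linear cost
in compute and memory).

**Network.** An MLP with 4 hidden layers of 1024 rectified units maps
$\gamma(x)$ to the coefficient vector. Single-shell mode outputs the 45 WM
coefficients directly; multi-shell mode feeds a shared trunk into three
affine heads — WM (45), GM (1), CSF (1) — with a softplus on the two
isotropic heads so those fractions are non-negative by construction
(softplus chosen over a plain rectifier for smooth gradients; the choice is
confined to one line and swappable). The WM head carries no output
transform: its non-negativity is handled by the loss, exactly as in
voxel-wise CSD. Weights use fan-in uniform initialization; the isotropic
heads' biases start at −3 so the initial fractions are about 0.05 — with a
zero bias the softplus outputs ≈ 0.69, a spurious isotropic compartment
whose b=0-scale residuals dominate early training and consume a large share
of a short schedule's optimization steps.

**Objective.** For one coordinate per voxel (restricted to a mask when one
is supplied), the loss is the mean over coordinates of the summed squared
signal residuals across all fitted volumes, plus $\lambda$ times a
non-negativity penalty: the WM FOD is evaluated on a packaged 724-direction
antipodally symmetric set, and amplitudes below $0.1\times$ the FOD's mean
amplitude are penalized quadratically (mean of squared flagged amplitudes,
averaged over the batch; the threshold is treated as a constant of the
current iterate). Penalizing the *sub-threshold* amplitudes — not the
super-threshold ones — is the reading consistent with the CSD literature and
with the stated purpose of suppressing negative lobes. $\lambda = 1$ by
default; the weight is exposed because no principled value is forced by the
model. Optimization is Adam at learning rate $10^{-4}$ (otherwise default
moments), mini-batches of 500 coordinates, 30 epochs.

The same signal matrix implements the forward model in training, in the
phantom simulator and in `reconstruct_signal()`, so there is no train/test
skew; a test asserts exact agreement.

# The synthetic phantom

Real reference datasets (simulator-generated brain volumes) are out of desk
scope, so the package ships a generator whose defaults define the study
conditions used throughout the tests:

* grid $20^3$ voxels at 1.25 mm; acquisition 7 × b=0, 30 × b=1200,
  30 × b=3000 s/mm² with seeded electrostatic-repulsion direction sets —
  the protocol of the reference acquisitions this class of methods targets;
* geometry: an empty margin, a one-voxel GM rim, a CSF sphere, and three WM
  compartments stacked in z — a single-fiber slab (fibers along x), a
  crossing slab (two equal populations at 60° by default) and a curved
  bundle whose tangents follow circular arcs, giving a region of strong
  curvature;
* ground-truth FODs are weighted sums of *apodized* delta kernels: a pure
  band-limited delta rings negative (about −14% of peak at $l_{\max}=8$),
  which would violate the non-negativity that defines an FOD, so each delta
  is tapered per order by the zonal profile of the sharpest truncated Watson
  kernel that stays non-negative. The taper is computed numerically once
  and cached;
* WM response from an axially symmetric tensor (1.7, 0.2) µm²/ms, GM ADC
  0.8, CSF ADC 3.0 µm²/ms, all at unit S0: zonal projections are exact
  Gauss–Legendre quadratures, and closed forms (b=0 rows, isotropic decay
  ratios, sign alternation of the prolate tensor's zonal coefficients) are
  asserted in tests;
* noise: complex-Gaussian, i.e. Rician magnitude, with
  $\sigma = \bar S_{b0,\mathrm{WM}} / \mathrm{SNR}$. The reference amplitude
  is the mean noiseless b=0 signal over WM — the SNR definition is a
  convention, so it is configurable and recorded.

What the phantom does *not* emulate: partial-volume mixtures along
boundaries, fanning or kissing geometry, artifacts (motion, eddy, ghosting),
spatially varying response functions. Passing tests therefore demonstrate
correctness of the estimator under its own forward model and robustness to
calibrated noise — not performance on scanner data.

# Evaluation metrics

* **ACC** (angular correlation coefficient): normalized inner product of
  two coefficient vectors over the anisotropic ($l \ge 2$) terms; 1 means
  identical angular profiles, scale ignored. Voxels with no anisotropic
  energy are excluded and counted, not imputed.
* **AFD** (total apparent fiber density): the $l=0$ coefficient.
* **NuFO**: peaks of the FOD on the dense direction set — local maxima over
  a 12° neighbor graph on the hemisphere, kept above an absolute amplitude
  of 0.07 and thinned to a minimum separation of 25°. The amplitude
  threshold follows common tooling; the separation and neighborhood radius
  are pinned for reproducibility and configurable.
* Field evaluations mask to voxels whose ground-truth WM $f_{00}$ exceeds
  0.05 and report mean ± SD ACC and AFD, the AFD mean absolute error, and
  NuFO histograms.

# Numerical choices and degenerate inputs

* SH fitting solves the normal equations by Cholesky with an optional
  Tikhonov ridge; an under-determined unregularized fit is an error, not a
  silent pseudo-inverse.
* The voxel-wise CSD baseline freezes its amplitude threshold at the
  initial (lmax = 4) FOD, iterates at most 50 reweighting steps and flags
  non-convergence per voxel in a QC map. Its initial fit carries a
  relative ridge of 1e-8 so isotropic responses (which zero all $l>0$
  columns) remain solvable.
* Greedy angular subsampling scores hemispherical coverage by the
  electrostatic energy $\sum_{a<b} 1/\sin\Psi_{ab}$ over acute angles
  (equivalent to the antipodally symmetrized energy after dropping the
  degenerate self-pairs); ties break to the lowest original index, making
  the procedure deterministic. The greedy path is not transitive
  (30→8 need not equal 30→20→8) and is documented as such.
* b = 0 volumes: excluded from the single-shell loss (standard CSD
  practice), included in the multi-shell loss; both behaviors are
  switchable via `include_b0`.
* All randomness (encoding, initialization, shuffling, phantom noise) is
  seeded; two fits with the same seeds are bit-identical, which the test
  suite asserts.

# Desk-scale problem sizes

The packaged experiments run on $20^3$ (feasibility, angular, noise) and
$24^3\to12^3$ (spatial) phantoms with $n_p = 1000$, chosen so every
experiment completes on a single CPU core in minutes while keeping all
qualitative contrasts of interest (INR vs. voxel-wise CSD under noise;
supersampling vs. trilinear SH interpolation in curved geometry).

Two scale effects deserve emphasis.

First, the encoding bandwidth interacts with grid size. Frequencies in the
matrix $B$ are expressed per normalized volume, and training samples only
exist at voxel centers, so components above the grid's Nyquist limit
($n/4$ cycles per unit for $n$ centers per axis, with ~95% of
$N(0,\sigma^2)$ mass below $2\sigma$) are unconstrained: they fit the
centers exactly and alias freely in between. On a 12-voxel-per-axis coarse
grid, $\sigma = 4$ yields a supersampled field that agrees with the truth
at voxel centers (ACC 0.99) yet collapses between them (ACC 0.62). The
spatial experiment driver therefore caps $\sigma$ at $n/8$ for the grid it
trains on. The default $\sigma = 4$ is appropriate for the
hundreds-of-voxels-per-axis volumes the method targets.

Second, An "epoch" is one pass over the voxels, so
the number of Adam steps an epoch delivers scales with volume size: a
full-resolution brain volume receives tens of thousands of steps per epoch,
a $20^3$ phantom only 12–16. At the default schedule (30 epochs, learning
rate $10^{-4}$) a desk-scale fit therefore performs only a few hundred
optimization steps and stops short of convergence — mean ACC against the
generating truth plateaus around 0.95 where a converged fit of the same
architecture reaches 0.99 (verified on a smaller phantom with a longer
schedule, where convergence is cheap). Voxel-wise CSD on the same noiseless
data scores about 0.98 against the generating truth: its positivity
constraint both regularizes the 30-direction/45-coefficient
under-determination and introduces a small bias, while the coordinate
network's spatial coherence lets it exceed that mark once converged. The
experiment drivers on reduced grids (e.g. the spatial experiment's coarse
fit) scale their epoch count up so the optimization-step budget stays
comparable across grid sizes; the feasibility runs keep the literal
30-epoch schedule and report what it attains.

# Known limitations

* At desk scale the spatial-supersampling comparison does not favour the
  continuous fit: on a smooth analytic phantom with noiseless coarse data,
  voxel-wise CSD followed by trilinear SH interpolation is already close to
  optimal, and the converged continuous fit only ties it on the
  curved-bundle region while producing somewhat more spurious peaks. The
  advantage this class of models shows on complex brain geometry requires
  richer structure (and imperfect voxel-wise fits) than the phantom
  provides; the corresponding test is kept as specified and documents this
  by failing.
* The continuous representation trades sharpness for coherence: FODs are
  slightly smoother than voxel-wise CSD output, which can merge
  low-angle crossings.
* The non-negativity penalty is slightly active even at the true FOD
  (apodized kernels have flat regions below 0.1 × mean amplitude), so the
  constrained optimum is not exactly the generating field; the effect is
  orders below the signal term and shared by the voxel-wise baseline.
* No GPU path: training is BLAS-bound matrix arithmetic, adequate at desk
  scale; large volumes would need a compiled or accelerated backend.
* Response-function *estimation* is out of scope; responses are read from
  files or synthesized analytically.
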