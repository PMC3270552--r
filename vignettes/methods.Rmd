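---
title: "Probabilistic rigid registration of intraoperative ultrasound to MR: model and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic rigid registration of intraoperative ultrasound to MR: model and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The registration problem

During image-guided neurosurgery, the preoperative T1-weighted MR volume is
related to the patient by the neuronavigation system's surface-based rigid
registration, which carries a few millimetres of error. Before the dura is
opened, brain shift is negligible, so a *rigid* correction can be estimated
from a reconstructed 3D intraoperative ultrasound (US) sweep. Direct
intensity-based multimodal registration of US to MR is fragile: US contrast
comes from acoustic interfaces, not tissue classes. This package instead
matches the *structures* both modalities agree on: liquid interfaces (the
sulci and the cerebral falx) and hyperechogenic lesions such as cavernomas
or low-grade gliomas, which appear bright in B-mode US and can be
identified in MR.

Each modality is turned into a per-voxel probability of hyperechogenic
structure, and the rigid transform $\hat T$ maximizes the correlation of
the two maps,

$$\hat T = \arg\max_T \int_\Omega p(X \in \Phi_{US}) \;
  p(T(X) \in \Phi_{MR}) \, dX,$$

under the assumption that the two probabilities are independent. The
integral is discretized as the **mean** over US-grid voxels of
$p_{US}(X)\,p_{MR}(T(X))$, with the MR map trilinearly interpolated and
taken as 0 outside its support: probability mass that leaves the MR field
of view simply stops contributing, which is the natural treatment of
partially missing information. Using the mean rather than the sum makes
scores comparable across pyramid levels.

## Probability maps

**Ultrasound.** The map is the min-max rescaled intensity, nothing else:
$p(X \in \Phi_{US}) = U(X)$ after scaling to $[0,1]$. Acoustic shadows
(zeros) become probability exactly 0.

**MR.** Valleys of the intensity landscape — sulci and falx in T1-w MR —
are detected with the scale-space curvature operator `MLvv`, built from
the six first and second Gaussian derivatives at image scale $\sigma$
(voxels):

$$\mathrm{MLvv} = \frac{1}{2\|w\|^2}\Big[
   V_x^2(V_{yy}+V_{zz}) - 2V_yV_zV_{yz}
 + V_y^2(V_{xx}+V_{zz}) - 2V_xV_zV_{xz}
 + V_z^2(V_{xx}+V_{yy}) - 2V_xV_yV_{xy}\Big],$$

with $\|w\|^2 = V_x^2+V_y^2+V_z^2$. The sign convention is fixed once by
an analytic oracle: on the continuous valley $V = x^2+y^2$ the operator
must return $+1$ (valleys positive, crests negative); the discrete
implementation reproduces $\pm 1$ exactly because its derivative kernels
are polynomial-calibrated (a unit ramp has first derivative exactly 1,
$x^2/2$ has second derivative exactly 1). Two consequences worth knowing:

* a perfectly **planar** valley ($V = f(x)$) has *zero* response — the
  numerator only contains curvature transverse to the gradient, and a flat
  sheet has none. Real falx detection relies on the falx being curved.
* a spherical pocket ($V = x^2+y^2+z^2$) responds with $+2$, twice the
  tube value. Valley *junctions* therefore dominate the map's maximum.

Voxels with $\|w\|^2$ below a degeneracy floor of $10^{-12}\times$
(dynamic range)$^2$ (plus a rounding-level floor tied to the intensity
magnitude) are set to 0: flat regions are meaningless for ridge detection.

Only the positive (valley) part is kept and min-max scaled to $[0,1]$ over
its strictly positive support, so background stays exactly 0 and the
strongest valley voxel becomes 1. The map is then merged with the manual
lesion segmentation $M_2$ at probability $\Psi$: the final map is
$\max(\text{scaled MLvv}^+,\ \Psi\,\mathbb{1}_{M_2})$. The maximum, rather
than the printed sum of indicator terms, preserves probability semantics
when a sulcus borders the lesion. $\Psi = 1$ is the default, appropriate
for homogeneous hyperechogenic lesions.

## Preprocessing

Skull stripping is accepted as an input brain mask (the skull does not
appear in the craniotomy window). The masked MR volume is denoised with
classical non-local means before the valley operator is applied — noise
creates spurious curvature. Defaults: patch radius 1 ($3^3$ patches),
search radius 3 ($7^3$ window), bandwidth $h$ derived automatically as
$\sqrt2\,\hat\sigma$ from a pseudo-residual noise estimate. Outside-mask
voxels are excluded from all patch statistics so the mask boundary does
not generate halos. The originating study deferred its filter parameters
to an external implementation, so these defaults are this package's own
reasonable small-volume choices, overridable via config.

## Optimization

The objective is maximized by Nelder-Mead simplex search over the six
rigid parameters (3 translations in mm, 3 rotations in degrees, intrinsic
x-y-z order about the US volume's physical centre), inside a
multiresolution pyramid: factors 3 (anti-aliased Gaussian smoothing at
$\sigma = 0.5\times$factor, then decimation) and 1 (original resolution),
each level starting from the previous level's optimum. The stated settings
are stepsize 1.5, tolerance 0.1, at most 100 iterations per level.

The tolerance's units are not stated anywhere, so a choice had to be
made. An absolute objective-spread criterion was tried first and proved
wrong by implementation: the mean-normalized score of sparse probability
maps is of order $10^{-3}$, so any fixed spread floor comparable to
$10^{-4}$ halts the search after a handful of iterations and leaves
multi-millimetre residual error, whereas disabling it lets the same search
converge to about half a millimetre. The shipped interpretation reads
tolerance **in the simplex's parameter units**, the same units as the
stepsize: iteration stops once every vertex is within 0.1 mm / 0.1 degree
of the best vertex. This is scale-free with respect to the objective's
magnitude and is the package default; the score-spread criterion remains
available (`tolerance_type = "score"`).

The transform maps US world coordinates into MR space (the MR map is the
one resampled), matching the direction of the objective's second factor.

## Validation machinery

* **Initial error** — mean and sample standard deviation (always $n-1$
  denominators in this package) of distances between homologous expert
  landmarks.
* **Leave-one-out TRE** — for each of $n$ landmark pairs, a closed-form
  least-squares rigid fit (centroid alignment + SVD of the
  cross-covariance, determinant$+1$ correction so reflections are
  impossible) on the other $n-1$ pairs is applied to the held-out source
  point; the TRE is its distance to the held-out target.
* **Warping index** — $\omega = \frac{1}{|\Omega|}\sum_X \|T_{true}(X) -
  T_{est}(X)\|_2$ over a voxel domain. The published formula mixes one
  transform with the other's inverse; that reading double-counts the error
  and violates $\omega(T,T)=0$, so the consistent-direction comparison is
  implemented (equivalently $\|(T_{est}^{-1}\circ T_{true})(X) - X\|$).
* **Robustness study** — random rigid perturbations with each translation
  component Uniform$[0,5]$ mm and each rotation Uniform$[0,5]^\circ$ (the
  literal protocol; a symmetric signed mode is config-selectable) are
  composed into the MR frame by resampling the MR map through the
  perturbation; registration restarts from the unperturbed reference, and
  a trial succeeds when $\omega < 3.5$ mm over the US domain. Kruskal-
  Wallis comparisons of expert landmark samples are delegated to
  `stats::kruskal.test` when such samples exist; they are not part of the
  synthetic pipeline.

## The synthetic phantom

No clinical data are distributed, so every end-to-end claim is exercised
on synthetic phantoms with known ground truth (default $64^3$ voxels at
1 mm): a bright tissue block (level 0.7) carved by dark tubular valleys
(half along y, half along z so all rotations are constrained; Gaussian
profile half-width 2 voxels, matching the $\sigma = 2$ operator scale used
for sulci; floors near 0.15), an optional planar falx sheet, and a
hypointense spherical lesion (level 0.35, radius 8 mm). Valley profiles
combine by smooth probabilistic union so confluent valleys saturate at the
fluid level without intensity creases, and tube base positions are
stratified, as sulci are quasi-regularly spaced. Additive Gaussian MR
noise ($\sigma = 0.02$ on the 0-1 scale) is a realistic default; neither
the spec nor the source study states phantom noise levels.

The matched US volume is built from the ground-truth geometry — *not* from
the MLvv of the MR phantom, which would make the validation circular:
1-voxel-dilated centreline interfaces and the lesion interior are bright,
background weakly echogenic, all multiplied by unit-mean gamma speckle
(variance 0.2), optionally zeroed in an acoustic-shadow slab and cropped
to a limited field of view.

What the phantom does **not** model: wave propagation, attenuation,
refraction, anisotropic speckle correlation, reconstruction artifacts of
freehand sweeps, and real cortical anatomy. Passing tests therefore
demonstrate the correctness and basin-of-attraction behaviour of the
implementation under the stated appearance assumptions, not clinical
accuracy.

## Stated test floors and problem sizes

Two test calibrations were fixed from mechanism, not tuned: (1) the
valley-detection overlap check asserts precision $\ge 0.9$ of the
scaled-MLvv $> 0.5$ set against the 2-dilated centreline band and Dice
$\ge 0.25$ against the 1-voxel band, on falx-free phantoms — junctions
respond twice as strongly as tubes (see above), so min-max scaling
compresses non-junction valleys and a 0.5-threshold Dice near 1 is not
achievable by construction; the planar falx is excluded because its
response is identically zero. (2) The randomized recovery studies run 20
pooled trials (5 phantom seeds × 4 perturbations) for the clean condition
and 10 trials (2 × 5) with shadow + limited field of view; these sizes
are the package's chosen desk-scale analogue of the 100-trial clinical
protocol and keep the full suite fast, while the same functions scale to
any trial count.

Numerical conventions: trilinear interpolation with fill 0 everywhere;
derivatives in voxel units (volumes are assumed near-isotropic, as the
target data are); min-max rescale of a constant volume is all zeros;
4D NIfTI inputs with a trailing singleton dimension are squeezed, any
other 4D input is rejected; the simplex is fully deterministic, and all
phantom randomness derives from a single integer seed.

## Known limitations

* Rigid only: brain shift after dura opening needs nonrigid extension.
* The valley operator needs adaptation for non-T1 MR sequences or other
  anatomy; planar structures are invisible to it unless curved.
* The Euler parameterization is singular at a middle rotation of
  $\pm 90^\circ$ — irrelevant for the small corrections targeted here.
* Landmark-based TRE quantifies expert agreement only where landmarks can
  be confidently picked.
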