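---
title: "Mechanical characterisation of flowing microcapsules from steady footprint profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanical characterisation of flowing microcapsules from steady footprint profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capmech)
```

## The problem

A microcapsule — a liquid droplet enclosed by a thin hyper-elastic membrane,
the standard mechanical model for red blood cells, circulating tumour cells
and bio-artificial particles — deforms into a steady bullet- or
parachute-like shape when driven through a capillary tube. That steady shape
is set by a small number of dimensionless groups: the capillary numbers

$$Ca^{G_s} = \frac{\mu U}{G_s}, \qquad Ca^{K_s} = \frac{\mu U}{K_s},$$

comparing the viscous stress $\mu U$ to the membrane's shear modulus $G_s$
and area-dilatation modulus $K_s$; the confinement ratio $\beta = a/R$; and
the pre-inflation ratio $\alpha$ (osmotic swelling of the rest radius).
Because the map from membrane mechanics to steady shape is (locally)
invertible, a single camera image of the steady *footprint* profile — the
silhouette seen by the camera, preferred over the mid-plane cross section
because the capsule rear hides in its own shadow — carries enough
information to estimate the constitutive-law class and both moduli at once.
`capmech` implements that inverse map twice: as a small multilayer
perceptron (MLP) trained offline on synthetic profiles, and as a classical
library-scan baseline using the mean Hausdorff distance (MHD).

## Membrane constitutive laws

Three classical thin-membrane strain-energy densities are supported, written
in the shifted surface strain invariants
$I_1 = \lambda_1^2 + \lambda_2^2 - 2$ and
$I_2 = \lambda_1^2\lambda_2^2 - 1$ (principal stretches $\lambda_{1,2}$;
the rest state is $(0,0)$):

* **neo-Hookean (NH)**, strain-softening, volume-incompressible:
  $W = \tfrac{G_s}{2}\bigl(I_1 - 1 + \tfrac{1}{I_2 + 1}\bigr)$, with
  $K_s = 3G_s$ always;
* **Skalak (SK)**, strain-hardening, with area-dilatation parameter $C$:
  $W = \tfrac{G_s}{4}\bigl(I_1^2 + 2I_1 - 2I_2\bigr) + \tfrac{CG_s}{4}I_2^2$,
  with $K_s = (1 + 2C)G_s$;
* **generalised 2D Hooke (HK)**, linear-elastic with surface Poisson ratio
  $\nu_s$:
  $W = \tfrac{G_s}{4}\bigl(2I_1 - 2I_2 + \tfrac{I_1^2}{1-\nu_s}\bigr)$,
  with $K_s = (1+\nu_s)/(1-\nu_s)\,G_s$.

One genuinely open choice sits in the NH denominator. Under the shifted
invariant convention the variant $1/(I_2 - 1)$ is singular at rest, whereas
the SK and HK forms are zero at rest only under the shifted convention; the
package therefore uses $1/(I_2 + 1)$ — i.e. $1/\det$ of the surface
deformation, the standard 2D NH form, the unique choice making all three
laws consistent with $W(\text{rest}) = 0$. The as-printed variant remains
available through `strain_energy(..., as_printed = TRUE)` for comparison.

`Gs` is always the stored quantity and $K_s$ is always derived through
`area_dilatation_modulus()`, so a parameter set can never carry an
inconsistent modulus pair. `equivalent_parameters()` inverts the two $K_s$
relations at equal $K_s/G_s$ — e.g. a Skalak membrane with $C = 0.73$ and a
Hooke membrane with $\nu_s = 0.42$ have the same modulus pair, which is why
the two laws are nearly indistinguishable from shapes alone (below).

## The synthetic forward model

Training a network requires a large family of labelled steady profiles.
The full fluid–structure problem (in practice an immersed-boundary
lattice-Boltzmann or boundary-integral simulation) is out of scope here;
`capmech`
instead ships a *surrogate* forward model: an explicit smooth shape family
with the statistical structure the learning problem needs, so the entire
pipeline is generatable, trainable and testable in seconds on one CPU.

`steady_profile()` builds a star-shaped polar generatrix around the
centroid,

$$r(t) = a\,\bigl[\,1 + p_1\cos t + p_2\cos 2t - p_3\,
  e^{\kappa(\cos(t-\pi)-1)} + \eta\cos 3t\,\bigr],$$

with $a = (1+\alpha)\beta$ the inflated radius in tube-radius units and
fixed package constants

| term | value | role |
|------|-------|------|
| $p_1$ | $0.08\,v$ | nose/tail asymmetry (bullet front) |
| $p_2$ | $0.10\,v$ | axial elongation against tube clearance |
| $p_3$ | $0.12\,u + 0.02\,v$ | rear flattening, then concave dimple |
| $\kappa$ | $13$ | angular concentration of the rear feature |
| $\eta$ | $0.02\,(u+v)/2$, NH only | law signature (see below) |

where $u = Ca^{K_s}/0.055$ and $v = Ca^{G_s}/0.21$ are the capillary
numbers normalised by the upper edge of the validity box, so $Ca \to 0$
yields an exact circle. The curve is rescaled so that its solid of
revolution encloses the inflated-sphere volume $\tfrac43\pi a^3$ (the
internal liquid is conserved), sampled at `n_nodes` equal arc-length
increments starting from the leading tip, and centred on its area centroid.

The family was designed against explicit contracts rather than fitted to
any reference shapes:

* the tip-to-tail length is non-decreasing in $Ca^{G_s}$ at fixed
  $Ca^{K_s}$;
* the rear-cap signed curvature decreases with the load and becomes
  negative (parachute) in the upper part of the box;
* SK and HK profiles at matched $(Ca^{K_s}, Ca^{G_s})$ are *identical by
  construction* — the law class enters only through the small $\cos 3t$
  perturbation reserved for NH. This deliberately reproduces the physical
  near-degeneracy of SK and Hooke membranes at matched moduli under
  moderate deformation, so a classifier can and should recognise NH while
  confusing SK with HK;
* the coarse, low-harmonic deformation responds to $Ca^{G_s}$ only, while
  the localised rear dimple carries most of the $Ca^{K_s}$ signal. A dense
  node sampling resolves the dimple; a coarse one (10 nodes) straddles it,
  so part of the $Ca^{K_s}$ information degrades with the node count —
  mirroring the expected accuracy loss of coarse boundary discretisations;
* node-spacing coefficient of variation stays below 1% for every
  admissible profile and node count (this caps $\kappa$ at 13: a sharper
  dimple would violate the equal-spacing contract at 10 nodes).

What the surrogate does **not** emulate: wall lubrication films, membrane
wrinkling, bending resistance, transient dynamics, asymmetric or off-axis
shapes, and any quantitative correspondence with simulated or experimental
profiles. Conclusions from the test suite therefore concern the pipeline —
extraction fidelity, optimiser behaviour, identifiability structure — not
the biophysical accuracy of any particular capsule system.

`generate_dataset()` draws capillary numbers uniformly over the training
box $0.02 \le Ca^{K_s} \le 0.055$, $0.03 \le Ca^{G_s} \le 0.21$ at
$\beta = 0.77$, $\alpha = 3\%$ (the regime where classical bio-artificial
capsule experiments in glass tubes reach substantial deformation), with
equal thirds per law and each law's ratio constraint enforced: NH admits
only $Ca^{G_s} = 3\,Ca^{K_s}$; SK and HK pairs are redrawn until
$K_s/G_s > 1$ and the implied $C$ or $\nu_s$ is recorded. Datasets are
reproducible bit-for-bit from their manifest.

## Image processing

`rasterize_profile()` produces camera-style frames: a square grid spanning
the tube diameter, binary fore/background by the pixel-centre rule with no
anti-aliasing, optional seeded Gaussian pixel noise, and resolution
expressed as pixels per undeformed capsule diameter (42 / 68 / 138 are the
conventional levels). `extract_profile()` then runs the chain an
experimental image would take:

1. **`preprocess_image()`** — subtract the background frame when supplied,
   threshold (Otsu's rule by default; a fixed threshold is configurable),
   keep the largest connected component, and centre it in a square region
   of interest one tube diameter wide;
2. **`trace_boundary()`** — Suzuki-and-Abe-style border following
   (Moore-neighbour walk with an exact state-repeat stopping rule) giving
   the outer border pixels counter-clockwise;
3. **`smooth_and_resample()`** — the raw trace is a pixel staircase; each
   trace point is replaced by a least-squares quadratic fitted over a
   window of 9 consecutive points in a frame rotated onto the window
   chord, the smoothed polyline is re-parametrised by chord length and
   sampled at `n_nodes` equal arc increments from the leading tip;
4. **`to_feature_vector()`** — interleaved $(x_1,y_1,x_2,y_2,\dots)$
   coordinates in tube-radius units, centroid-centred.

Several conventions here are free choices the package fixes once: Otsu
binarisation; a 9 px smoothing window (small enough to keep corners, large
enough to cancel short staircase runs — the suite checks a $\ge 50\%$
error reduction on 2–3 px runs, while windows this size cannot cancel
longer-period jitter); tube-radius coordinate units (a fixed physical
scale is what makes vectors comparable across image resolutions);
counter-clockwise orientation with the start node at the maximum-$x$
crossing of the symmetry axis, ties towards smaller $y$ (an MLP is not
permutation-invariant, so node numbering must be canonical); interleaved
rather than block layout (keeps each node's coordinates adjacent for the
first layer); 0-based pixel-centre coordinates with the image y-axis in
mathematical orientation. Two systematic effects are knowingly accepted:
traced pixel centres sit about half a pixel inside the true continuous
boundary (no subpixel correction is applied — both training profiles and
extracted profiles are centred, so the residual is a small uniform scale
bias), and the quadratic smoother can overshoot at step edges with long
run lengths.

## The network

`capsule_mlp()` trains a fully connected feed-forward network: input
$2N$ (interleaved node coordinates), three hidden layers of 128 ReLU
units ($\sigma(x) = \max(0,x)$), and two output heads sharing the trunk —
a 3-way softmax $p_j = e^{x_j}/\sum_k e^{x_k}$ for the law class and a
2-unit linear head for $(Ca^{K_s}, Ca^{G_s})$. The loss is
$L = L^{cls} + \lambda L^{reg}$ with $\lambda = 1$, cross-entropy
$L^{cls} = -\sum_j z_j \log p_j$ and squared error
$L^{reg} = |y^{label} - y|^2$ summed over the two targets, each averaged
over the mini-batch. Whether classification and regression should share
one trunk was treated as open; the shared form is the default and
`mlp_control(two_networks = TRUE)` trains two independent networks
instead.

Training follows a standard small-tabular protocol: Adam at initial
learning rate $10^{-3}$, mini-batches of 128, 10% validation split,
batch normalisation before each activation, dropout 0.3 after it (none on
input or output layers), He-style seeded initialisation. Regression
targets are standardised to zero mean and unit variance over the training
split — raw capillary numbers of order $10^{-2}$ would make the squared
loss invisible next to the cross-entropy — and the statistics travel with
the fit. The learning rate is divided by 10 after 10 validation epochs
without improvement (absolute $10^{-6}$ on the combined loss) and training
stops after 20 further stagnant epochs, returning the best-validation
parameters; `max_epochs` (default 1500) is a safety cap that the plateau
rule normally undercuts by an order of magnitude. Mini-batches with fewer
than two samples are dropped (batch statistics are undefined there), and a
dataset whose training split is smaller than one batch is rejected.
Training is a deterministic function of the data and the seed. Inference
(`predict()`) is pure feed-forward arithmetic with frozen running batch
statistics and no dropout; predicted capillary numbers are de-standardised
and floored at $10^{-6}$, and a supplied `flow_condition()` converts them
to moduli via $G_s = \mu U / Ca^{G_s}$, $K_s = \mu U / Ca^{K_s}$.

```{r example, eval = FALSE}
train <- generate_dataset(n = 400, seed = 1)
fit <- capsule_mlp(train, mlp_control(seed = 1))
test <- generate_dataset(n = 100, seed = 7920)
pred <- predict(fit, test, flow = flow_condition(mu = 1, U = 1e-3))
mape(pred$ca_ks, as.data.frame(test)$ca_ks)
```

## The Hausdorff inverse baseline

The classical alternative scans a labelled library: for an observed
profile $R$ and each template $T$, both centred on their mass centres,
compute the directed mean Hausdorff distance

$$\bar h(R,T) = \frac{1}{m}\sum_{r \in R}\min_{t \in T} d(r,t),$$

and return the labels of the minimising entry (`inverse_predict()`,
lowest index on ties). The directed form is deliberate — it is zero
whenever the observation lies on the template — and a symmetric variant
($\max$ of the two directions) sits behind `symmetric = TRUE`. Distances
are computed on the $N$ resampled nodes rather than raw border pixels, so
both methods consume identical inputs and differ only in the prediction
step; the library is by default the 400-profile training set. Squared
distances are accumulated from explicit coordinate differences rather
than the expanded-product identity, so exact matches return exactly zero.
No spatial acceleration structure is used; a linear scan of 400 templates
is the point of comparison with the network's constant-time forward pass.

## Evaluation workbench

`mape()` implements the error measure used throughout,
$\mathrm{MAPE}(y) = \frac{100}{M}\sum_i |(y_{true,i} -
y_{pred,i})/y_{true,i}|$ (percent). `run_recovery_study()` orchestrates
the standard experiment grid: per (node count, resolution, seed) it
generates independent train/test sets, trains, and reports held-out MAPEs,
per-class confusion and — when a resolution is given — round-trips every
test profile through rasterisation and re-extraction, recording the mean
node-extraction error in pixels. Raw per-seed values are kept alongside
the seed-averaged summary, and every report is reproducible from its
manifest.

Problem sizes are package choices made once: studies default to 400
training and 100 test profiles per cell with three seeds (test-set sizes
behind the classical experiments being unreported, 100 gives the MAPE a
sub-percent standard error at the observed residual levels), and the test
suite exercises the full 400/100 × 3-seed protocol at 60 and 10 nodes.
Prediction latency is printed by the bundled command-line script
(`inst/cli/capmech.R`) for information only; it is hardware-dependent and
never asserted in tests.

## Known limitations

* Only the three classical laws are covered; the method cannot discover
  new constitutive behaviour, and SK-vs-HK discrimination is impossible by
  construction at matched moduli — the honest output there is the modulus
  pair, not the law label.
* The surrogate generator's quantitative accuracy claims stop at its own
  contracts; transferring the trained network to simulated or experimental
  images requires retraining on profiles from a mechanistic forward model.
* Single capsule per frame, axisymmetric steady shapes only, no video
  tracking, no mid-plane reconstruction.
* The MLP is implemented in plain R linear algebra; it is deliberately
  small (about 50k parameters) and CPU-bound, not a GPU training stack.
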