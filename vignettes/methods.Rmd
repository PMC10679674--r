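---
title: "Predicting seed vitality from hyperspectral plate images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting seed vitality from hyperspectral plate images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Seed vitality — operationalised here as seedling height in centimetres a
fixed number of days after sowing — varies between individual seeds of one
lot, and grading seeds non-destructively before sowing requires a proxy
measurement. Visible/near-infrared (VNIR) hyperspectral imaging of seeds
arranged on plates provides two such proxies at once: each seed's mean
reflectance spectrum (driven by its internal composition) and the spatial
texture of its image at individual wavelengths (driven by surface
structure). `vitaspec` implements the full chemometric pipeline from raw
camera counts to a fitted vitality regression, together with a synthetic
plate generator that plants a known, recoverable signal so that every stage
can be tested quantitatively without access to a camera or a proprietary
dataset.

## Pipeline and models

**Reflectance calibration.** Raw digital numbers `O` are converted to
reflectance with the standard two-point correction against a white
reference `X` and a dark frame `Y`:

$$S = \frac{O - Y}{X - Y}.$$

Pixels where `X = Y` carry no dynamic range; they are set to 0 and counted
in a warning rather than propagating NaN, so that downstream statistics
stay finite. Optionally the reference frames are averaged over scan lines
before use (they are physically plate-sized references whose own noise is a
nuisance).

**Per-seed extraction.** Each seed, identified by a label mask, contributes
one spectrum: the per-band mean over its pixels (a median is available as a
config option; the mean is standard practice for region-of-interest
spectra). Single-band images are plain spatial slices of the calibrated
cube.

**Pretreatments.** Three classical scatter/noise corrections are provided:
Savitzky–Golay smoothing (local polynomial least squares; default window
11, order 2 — common VNIR practice, both config-exposed; edges handled by
the terminal-window polynomial, so polynomials up to the fit order are
reproduced exactly), standard normal variate (per-spectrum centring and
scaling), and multiplicative scatter correction (per-spectrum affine
regression on a reference spectrum, inverted). The MSC reference is the
mean training spectrum, frozen at fit time and reused on test spectra:
preprocessing is always fit on the training fold and applied to the test
fold, a uniform contract that prevents information leakage even for
row-local transforms where it would be harmless.

**Partitioning.** Samples are split 7:3 by SPXY (sample-set partitioning
based on joint X–Y distance): Euclidean spectral distance and absolute
response distance are each normalised by their maximum and summed; the
training set is seeded with the most mutually distant pair and grown
greedily by the max–min rule. The split is computed once, on raw spectra,
before any pretreatment, and shared by every grid cell, so that
pretreatments and models are compared on identical folds. Ties are broken
by the smallest sample index; the procedure has no randomness.

**Wavelength selection.** Two selectors are implemented. The successive
projections algorithm (SPA) grows, from every candidate start wavelength, a
chain of minimally collinear wavelengths by repeated orthogonal projection;
each chain prefix is scored by the validation RMSE of a multiple linear
regression, and the prefix with minimal RMSE wins. The validation split is
an internal 80/20 SPXY split of the training fold (the choice of validation
data is otherwise open; using SPXY again keeps the package's one
partitioning idiom). Competitive adaptive reweighted sampling (CARS) runs
100 Monte-Carlo iterations of PLS fits on row subsamples, ranks wavelengths
by normalised absolute regression coefficients, enforces an exponentially
decreasing retention ratio with endpoints fixed at 1 and `2/p` (the two
endpoint conditions determine the schedule's constants uniquely), applies
weighted resampling with replacement among the kept wavelengths (duplicates
collapsed), and scores each retained set by 5-fold cross-validated RMSE;
the set at minimal RMSECV is returned. Tie-breaks everywhere favour the
lowest band index, for determinism.

**Segmentation and texture.** Seeds are segmented from a band image by a
deliberately deterministic stage: global Otsu threshold, 8-connected
components, an area floor, and row-major renumbering by centroid. A learned
segmenter would need annotated plates and pretrained weights; the
deterministic stage keeps the package data-free while retaining the
standard evaluation contract — pixel accuracy and mean
intersection-over-union against ground-truth masks, computed over the two
semantic classes (background, seed). The published form of the mean-IoU
prefactor (`1/(N+1)` with class indices running `0..N-1`) is internally
inconsistent; the package computes the standard mean over the N observed
classes. The pipeline segments each plate once, on the mean-over-bands
image (a robust, high-contrast composite), and reuses that mask across
band images; if segmentation does not recover the expected number of seeds
on a plate, the pipeline falls back to the reference mask for texture
extraction (the segmentation score is still reported as measured).

From each seed's masked bounding-box patch, a gray-level co-occurrence
matrix (GLCM) is accumulated at offset distance 1, angle 0°, 16 gray
levels, symmetrised and normalised; pairs touching background pixels are
excluded. Gray levels are equal-width bins spanning the patch range. Four
features are extracted per (seed, band): contrast
$\sum (i-j)^2 p_{ij}$, correlation
$\sum (i-\mu_i)(j-\mu_j) p_{ij} / (\sigma_i \sigma_j)$, energy
$\sum p_{ij}^2$, and entropy $-\sum p_{ij} \log_2 p_{ij}$. With all 520
bands this yields 2080 texture features per seed; over m selected
wavelengths, 4m.

**Fusion.** The fused feature set concatenates the m selected-wavelength
reflectance values with their 4m texture features (width 5m), band-major.
Because reflectance and the four GLCM features live on very different
numeric scales, the pipeline autoscales every feature matrix with training
statistics before model fitting; without this, variance alone would decide
which block a latent-variable model attends to.

**Models.** Three regressors are fitted per cell: PLSR (NIPALS, 3 latent
variables, centred internally; the coefficient vector is exposed because
CARS consumes it), epsilon-SVR with an RBF kernel (C = 10, epsilon = 0.1,
gamma = 1/p on standardised features; a small validation-split grid search
is available), and a one-dimensional CNN — two convolutional layers of 64
and 128 width-3 kernels with ReLU and same padding, each followed by
width-2 average pooling, then a 256-unit fully connected layer and a single
linear output, trained by SGD (learning rate 1e-4, up to 50 epochs, batch
size 4) on the mean square error. Kernel width, activation, padding and
pooling width are not dictated by the architecture's description and are
config-exposed defaults. The CNN standardises inputs and response
internally with training statistics and reports its per-epoch training MSE
(original units) as a loss curve; training is bit-reproducible given the
seed. When every residual fits inside the SVR's epsilon tube the solution
is flat; the package returns the train-mean predictor in that limit rather
than erroring.

**Evaluation.** Models are scored by the Pearson correlation coefficient R
between predictions and observations and by
$\mathrm{RMSE} = \sqrt{\sum_i(\hat y_i - y_i)^2/n}$, on the training fold
(R~C~, RMSE~C~) and the test fold (R~P~, RMSE~P~). A published variant of
the correlation formula reduces to a residual-to-total ratio that would
approach 0, not 1, for good fits; Pearson's R is what that criterion's
accompanying text describes, and is what the package computes.

## The synthetic plate generator

The generator emulates the study conditions the pipeline assumes: 8 plates
of 25 seeds in a 5×5 grid (200 seeds), 520 bands from 391 nm in 1.254 nm
steps (so the last band sits near 1042 nm; a 1.25 nm grid does not yield a
round band count, and the band count is taken as the fixed quantity),
vitality drawn from N(10, 2²) cm truncated positive. Seeds are ellipses on
a dark plate; shape realism is explicitly out of scope — the geometry only
has to support segmentation and texture windows.

Each seed's analytic reflectance is a smooth baseline times one minus a sum
of Gaussian absorption features whose depths are affine in vitality:

$$r_i(\lambda) = B(\lambda)\Big(1 - \sum_k \alpha_k(v_i)
  e^{-(\lambda-\mu_k)^2/2\sigma_k^2}\Big),
  \qquad \alpha_k(v) = a_k + b_k v.$$

Three features are planted by default (500, 711 and 950 nm; 711 nm is the
wavelength used in the package's worked texture examples), with slopes
chosen so that the product of baseline and slope — the effective signal —
is about equal across features: no feature dominates, and a selector that
works should find all three. The *informative band indices* recorded in the
ground truth are the bands within each feature's full width at half
maximum: adjacent bands inside one absorption feature are nearly collinear,
so "the selector found the feature" is the scientifically meaningful event,
not "the selector returned the centre index rather than its neighbour".

Observed spectra add per-seed multiplicative scatter (sd 0.03), a per-seed
additive offset (sd 0.01) and iid pixel noise (sd 0.01 reflectance units).
These magnitudes are the package's own choice — real cottonseed data are
not released, so no empirical values exist to copy — and were set so that
the planted signal is recoverable by the pipeline at desk scale while the
scatter corrections still have visible work to do. The raw capture is then
built by inverting the calibration equation (`O = Y + S(X - Y)`) around
constant white/dark levels, so calibration is exact by construction; with
all noise terms zero the calibrated mean spectra equal the analytic
$r_i(\lambda)$ to machine precision, which is the oracle the I/O tests use.

**Texture.** Each seed carries a multiplicative intra-seed pixel field of
fixed amplitude (sd 0.08) whose *roughness* — the mixing fraction between a
smooth directional gradient and an iid field — is a logistic function of a
per-seed texture latent. Roughness rather than amplitude carries the
latent for a structural reason: co-occurrence features quantised over the
patch range are invariant to pure amplitude scaling, so an amplitude-coded
latent would be invisible to GLCM by construction. The field is centred
within each seed so the mask-mean spectrum stays exactly analytic. Under
the default coupling the texture latent correlates 0.6 with standardised
vitality; in `fusion_sensitive` mode vitality is composed from a spectral
latent, the texture latent and noise with weights (0.75, 0.6, 0.2), so
spectra alone cap near R ≈ 0.77 and texture carries genuinely
complementary information — the regime in which feature fusion must help a
correct implementation.

**What the generator does not emulate.** Radiometric camera behaviour,
wavelength-dependent reference levels, seed shape and orientation
variation, spatially correlated sensor noise, and any germination biology.
Passing tests therefore demonstrate that the algorithms are implemented
correctly and recover planted structure under realistic noise — not that
any particular accuracy will be attained on real seeds.

## Numerical choices and degenerate inputs

* Sample standard deviations use the n−1 convention everywhere.
* SNV refuses constant spectra (naming the row); MSC refuses a zero-spread
  reference and a zero fitted slope; SG validates window/order/band-count
  relations.
* SPA treats a projected column norm below `1e-10` of the largest as
  exactly collinear: such columns are never selected, so duplicated columns
  are handled cleanly and the selected set always has a positive Gram
  determinant.
* CARS floors the retained count at the number of PLS components and stops
  early (truncating its paths, with a message) if resampling collapses the
  set below that.
* GLCM on a constant patch puts all mass on one cell (contrast 0, energy 1,
  entropy 0); a degenerate marginal makes correlation 0 with a warning
  rather than NaN.
* The CNN requires at least 4 input features so both pooling stages have
  nonempty output.
* Problem sizes in the test-suite: most unit tests run on 2-plate,
  120-band, 48-px datasets with absorption features moved into the short
  wavelength range; the acceptance checks use the full default conditions
  (200 seeds, 520 bands) and 10-repeat protocols for the stochastic
  claims. These sizes are the package's chosen desk-scale study conditions.

## Known limitations

* The segmentation stage is threshold-based; plates with touching seeds or
  uneven illumination would need the fallback reference masks (the pipeline
  reports measured PA/MIoU either way).
* GLCM parameters (16 levels, distance 1, angle 0°, symmetric) are single
  defaults, not averaged over angles.
* The SVR grid search is deliberately small; no nested cross-validation.
* `run_pipeline` fits every grid cell on one shared split; uncertainty in
  the reported R/RMSE from split variability is not quantified.
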