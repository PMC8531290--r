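---
title: "Spatiospectral reconstruction and K-edge analysis: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiospectral reconstruction and K-edge analysis: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectralct)
```

## The problem

A photon-counting (hyperspectral) X-ray detector bins every detected photon
into one of a few hundred narrow energy channels, so a single CT scan yields a
full attenuation spectrum $\mu(E)$ in every voxel. Sharp K-shell absorption
edges (iodine at 33.169 keV, cerium at 40.443 keV) then act as chemical
fingerprints: their presence identifies an element and the size of the
attenuation step is proportional to its local concentration. The price is
count starvation — the photons of a conventional scan are spread over ~200
channels, so each channel-wise image is extremely noisy unless exposure times
grow by orders of magnitude.

`spectralct` implements the reconstruction and analysis chain for this setting
at desk scale: a synthetic multi-material K-edge phantom simulator, standard
pre-processing, a channel-wise filtered back-projection (FBP) baseline, a
channel-coupled regularised reconstruction, and the downstream K-edge
analytics and image-quality metrics.

## The reconstruction model

The channel-coupled reconstruction solves

$$\min_u \; \|A u - b\|_2^2 \;+\; \alpha\,\mathrm{TV}_{xy}(u) \;+\;
\beta_{1,2}\,\mathrm{TGV}_c(u),$$

where $b$ are the log-normalised line integrals of all channels, $A$ applies
the (channel-independent) projection operator, $\mathrm{TV}_{xy}$ is the
isotropic spatial total variation applied per channel and summed over
channels, and $\mathrm{TGV}_c$ is a second-order total generalised variation
along the energy axis, applied per voxel:

$$\mathrm{TGV}_c(u) = \min_w \; \beta_1 \|D_c u - w\|_1 + \beta_2 \|D_c w\|_1 .$$

TV suppresses in-plane noise and streaks while preserving structural edges;
TGV along the channel axis exploits the strong correlation between
neighbouring channels: voxel spectra are locally affine in energy except at an
absorption edge, and TGV penalises deviation from piecewise-affine signals
without the staircasing TV would introduce. The data term is written exactly
as above, *without* a factor 1/2, so regularisation weights quoted on this
scale (for instance $\alpha = 0.002$, $\beta_1 = 0.18$, $\beta_2 = 0.25$ for a
powder phantom, or $\beta_1 = 0.25$, $\beta_2 = 0.35$ for a stained biological
sample) can be passed verbatim. A helper `tgv_ratio()` suggests the
$\beta_2/\beta_1 \in \{\sqrt2, 2\}$ ratios common in the denoising literature,
but nothing enforces them.

### Discretisation

Images are $n \times n$ single slices with $C$ channels. Spatial gradients
are forward differences with replicate (Neumann) boundary. The spectral
difference $D_c$ maps $C$ channel values to their $C-1$ interior differences;
the TGV slope field $w$ lives on that staggered grid, and $D_c w$ has $C-2$
components. This choice is what makes the defining TGV property exact in the
discrete setting: a spectrum affine in channel has $\mathrm{TGV}_c = 0$
(witnessed by $w \equiv$ its slope), and a single kink of slope change
$\Delta b$ costs exactly $\beta_2 |\Delta b|$. A zero-padded "same-shape"
difference would instead create a spurious boundary kink and break both
properties.

The projector $A$ uses Joseph's method: each ray is sampled at one-voxel
steps, with bilinear interpolation weights, assembled once per geometry into a
sparse matrix. Back-projection is the exact transpose, so the adjoint
identity $\langle Ax, y\rangle = \langle x, A^\top y\rangle$ holds to machine
precision — a property the saddle-point solver depends on and the test-suite
verifies to $10^{-6}$.

The geometry is 2D parallel-beam per slice. Real scanners in this field use
circular cone-beam trajectories reconstructed by FDK; the central-slice
parallel approximation preserves every comparison the package makes
(analytic baseline vs regularised iterative method on identical data) while
keeping problems desk-sized. This is a deliberate stand-in, not an
approximation of FDK itself; cone-beam support is out of scope.

### The solver

The composite problem is solved with the primal-dual hybrid gradient (PDHG,
Chambolle–Pock) method on the primal pair $(u, w)$ and one dual block per
term, with the stacked operator $K(u,w) = (Au,\ \nabla_{xy} u,\ D_c u - w,\
D_c w)$:

* the data dual has the closed-form prox of the conjugate of
  $\|\cdot - b\|_2^2$;
* the TV dual is projected pointwise onto the $\alpha$-ball of the pointwise
  2-norm; the two TGV duals are clamped to $[-\beta_1, \beta_1]$ and
  $[-\beta_2, \beta_2]$ (at exactly the threshold the projection maps to the
  boundary, matching the usual soft-threshold convention);
* both primal variables are initialised to zero, extrapolation parameter
  $\theta = 1$.

Step sizes default to $\sigma = \tau = 0.99 / \|K\|$, with $\|K\|$ estimated
by 20 power iterations; the constructor refuses $\sigma \tau \|K\|^2 > 1$.
Users may override $\sigma, \tau$; for consistent pure least-squares problems
(no regularisation) a balanced choice $\tau = \gamma\,0.99/\|K\|$,
$\sigma = 0.99/(\gamma \|K\|)$ with $\gamma \approx 10$ converges much faster,
because the optimal data dual is zero there. The tests use that override for
the least-squares oracle comparison.

Convergence is monitored by a primal-dual gap. With all nonsmooth terms split
into $F$ and $G = 0$, the naive dual value $-F^*(y)$ is not a finite lower
bound away from convergence, so the trace reports the Lagrangian value at the
current pair as the dual objective; the gap $P(u,w) - L(u,w,y)$ is then a sum
of Fenchel–Young terms — nonnegative up to rounding, zero exactly at the
saddle point. Iterations stop at the budget (default 1000, beyond which no
discernible image-quality gain was observed on the problems shipped here) or
when the gap falls below `gap_tol` (default $10^{-4}$) times the initial gap.

## The simulator

The simulator exists so every downstream stage is testable without scanner
data. It emulates:

* **Materials.** $\mu(E) = a E^{-p} + c + \Delta\mu \cdot
  \mathrm{sigmoid}((E - E_K)/\mathrm{width})$ — a photoelectric power-law
  decay plus, where an edge is in range, a logistic step broadened by the
  detector resolution. Presets cover an Al-like matrix, a CeO2-like powder
  ($E_K = 40.443$), edgeless ZnO-like and Fe-like powders, iodine-stained
  tissue ($E_K = 33.169$), water/agarose and an HA-like bone mineral. The
  parameter values are package defaults on the mm$^{-1}$ scale of the real
  materials at 30–50 keV, not measured constants; a CSV loader
  (`material_table_csv()`) is the extension point for tabulated data.
* **Phantoms.** A matrix disk with non-overlapping circular inserts; insert
  voxels carry the linear mixture $(1-f)\mu_\text{matrix} + f\mu_\text{insert}$
  with concentration fraction $f \in [0,1]$. Mixture linearity is exact, which
  is what makes the step-size map's concentration proportionality testable
  (1 : 2 : 4 for $f$ = 0.25/0.5/1).
* **Counting statistics.** Expected counts per (angle, bin, channel) are
  `exposure * source_counts * exp(-line integral)`; measurements are Poisson
  draws from one seeded RNG stream per scan, projections drawn before flats in
  a fixed order, so a scan is bit-reproducible. Flat-field frames are Poisson
  draws of the empty beam (default: 4 before + 4 after, pooled by averaging);
  dark frames are zeros. The default source is flat across channels at 30
  counts/s/channel, so the dense reference protocol (180 projections × 180 s)
  yields ~5400 expected counts per channel — low-noise, "ground-truth"-grade —
  while the fast protocol (30 × 30 s, a 36× total-exposure reduction) yields
  ~900 and visibly noisy, streaky channel-wise FBP.

Not emulated: charge sharing, pulse pile-up, scatter, detector blur, rings
(unless injected deliberately), cone-beam effects. Passing tests therefore
demonstrate algorithmic correctness under ideal counting statistics, not
robustness to every real-detector artefact.

## Pre-processing

`flat_field_correct()` forms $T = (\text{raw} - \bar d)/(\bar f - \bar d)$
and clips to $(\varepsilon, 1 + \delta]$ with $\varepsilon = 10^{-6}$
(bounding $-\log T$ at ~13.8 in photon-starved channels) and $\delta = 1$.
Detector bins whose mean flat does not exceed the mean dark are flagged and
imputed from neighbouring channels. `negative_log()` applies Beer–Lambert
linearisation.

`remove_rings_wavelet_fourier()` implements the combined wavelet–Fourier
stripe filter: per channel, the sinogram is decomposed with a periodised
orthonormal Daubechies filter bank (db8 default, 4 levels); at each level the
band that is high-pass along the detector axis and low-pass along the angle
axis — where ring stripes concentrate — is Fourier-transformed along the angle
axis and its low frequencies damped by $1 - e^{-k^2/2\sigma^2}$. With
$\sigma = 0$ the filter is the exact identity (the transform is
perfect-reconstruction). Longer Daubechies filters matter here: with a short
filter a narrow stripe leaks half its energy into the approximation band at
every level and survives the damping, while db8's sharper band split
concentrates it into the damped detail bands. What survives filtering is a
smooth, broad background perturbation; the quantity that actually
reconstructs into a visible ring — the stripe's local contrast against its
neighbouring detector bins — is suppressed by two orders of magnitude in the
shipped tests, at sub-percent distortion of smooth ring-free data. The
wavelet transform is implemented inside the package because no wavelet
library is among its dependencies; it is a standard periodised orthonormal
filter bank, verified by the identity and stripe-suppression tests.

## K-edge analytics

* `fit_edge_step()` fits ordinary least-squares lines in (keV, $\mu$) over
  windows before and after the edge and extrapolates both to $E_K$;
  $\Delta\mu_0$ is their difference there. It is exactly invariant to adding
  any affine-in-energy function to the spectrum, and deliberately not clipped
  at zero so noise propagates honestly. Default windows: 10 channels per
  side, separated from the edge by a 2-channel exclusion zone covering the
  detector-broadened transition. `step_size_map()` applies the (linear) fit
  functional to every voxel with two precomputed weight vectors.
* `estimate_edge_position()` takes the maximum forward difference of the
  (optionally smoothed) spectrum and reports the midpoint of the straddling
  channel centres; if the maximum does not exceed 5× the median absolute
  difference the edge is declared absent (`NA`).
* `kes_segment()` is classic K-edge subtraction: mean of a few channels above
  the edge minus mean of an equivalent set below; thresholding the difference
  map yields the stained mask, and unstained voxels with high pre-edge
  attenuation form the residual ("remaining material", e.g. bone) mask.
  Thresholds are user-set or Otsu-derived from the respective histograms —
  the exact windows/thresholds used on real instruments vary, so they are
  explicit configuration here, not constants.

## Image-quality metrics

`cnr_channelwise()` computes, per channel,
$\mathrm{CNR}(c) = |m_S(c) - m_B(c)| / \sqrt{\bar\sigma_S^2 + \bar\sigma_B^2}$
with $\bar\sigma$ the ROI standard deviations *averaged over all channels* —
spatial fluctuations are averaged by using 5×5 ROIs, spectral fluctuations by
the channel-averaged noise. Quadrature pooling of the two ROI noises is the
default; the arithmetic-mean variant is selectable because both forms
circulate in the CT literature and published figures rarely say which was
used. Channel-averaging the $\sigma$s (rather than the variances) is likewise
a documented choice. `rmse_channelwise()` squares, averages and roots the
voxel residuals against a reference per channel. `improvement_percent()` is
the plain percentage gain of one scalar metric over another.

## Problem sizes and determinism

The shipped benchmarks are sized for a single CPU: 64×64 voxel slices,
~50 energy channels, 30–180 projections, 1000 PDHG iterations (about a minute
per reconstruction). All randomness flows from explicit seeds through one RNG
stream per scan, so every simulation, test and the acceptance script are
reproducible run to run.

## Known limitations

* Single-slice 2D parallel geometry; no cone-beam/FDK, no helical support.
* The simulator's materials are parametric, not tabulated NIST data; absolute
  attenuation values are plausible rather than certified, and only the
  *relative* spectral structure (edges, power-law decay) is used by the
  analytics.
* No charge-sharing or pile-up model: measured spectra from real
  photon-counting detectors deviate from theoretical $\mu(E)$ in rate of
  change, which this package does not reproduce.
* Multi-edge joint material decomposition and absolute concentration
  calibration are out of scope; `step_size_map()` is proportional to
  concentration but uncalibrated.
* Optimal $(\alpha, \beta_1, \beta_2)$ depend on the noise level; no automatic
  parameter selection is provided.
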