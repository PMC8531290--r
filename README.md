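# spectralct

Hyperspectral (energy-channel-resolved) X-ray CT at desk scale: simulation,
reconstruction and K-edge analysis.

## The problem

Photon-counting detectors turn a single CT scan into ~200 narrow energy
channels, giving every voxel a full attenuation spectrum \(\mu(E)\). K-shell
absorption edges (iodine 33.169 keV, cerium 40.443 keV) then work as chemical
fingerprints: their position identifies the element, and the attenuation step
at the edge is proportional to local concentration. The catch is photon
starvation — each channel sees a tiny fraction of the photons, so channel-wise
analytic reconstruction (FBP/FDK) of fast, low-dose scans is dominated by
noise and streaks.

`spectralct` implements the channel-coupled regularised reconstruction that
addresses this, for users who want to study or prototype the method without
scanner data:

\[
\min_u \; \|A u - b\|_2^2 + \alpha\,\mathrm{TV}_{xy}(u)
        + \beta_{1,2}\,\mathrm{TGV}_c(u)
\]

— spatial total variation (noise/streak suppression with edge preservation)
plus second-order total generalised variation along the energy axis
(spectra are locally affine except at an absorption edge, which TGV preserves
without staircasing), solved with the primal-dual hybrid gradient (PDHG)
method. Around the solver sit a multi-material K-edge phantom simulator with
Poisson counting noise, flat-field/negative-log preprocessing, a combined
wavelet-Fourier ring filter, channel-wise FBP as the analytic baseline,
K-edge analytics (edge-position estimation, step-size Δμ₀ concentration maps,
K-edge subtraction segmentation) and channel-wise CNR/RMSE metrics.

## Worked example

Simulate an undersampled, low-dose scan of a cerium-insert phantom
(30 projections × 30 s against a 180 × 180 s dense reference — a 36× shorter
scan), reconstruct it both ways, and compare:

```r
library(spectralct)

fx <- make_fixtures(seed = 1)          # deterministic bundled scenes
sb <- fx$cerium$scan_b                 # the fast, noisy scan

b   <- negative_log(flat_field_correct(sb$scan$raw, sb$scan$flats))
fbp <- fbp_reconstruct(b, sb$geometry)

prob  <- recon_problem(b, sb$geometry, alpha = 0.002, beta1 = 0.18,
                       beta2 = 0.25, n_iter = 1000)
tvtgv <- pdhg_solve(prob)

rs <- roi(21, 39, 5, 5)                # insert ROI
rb <- roi(30, 28, 5, 5)                # matrix ROI
cnr_channelwise(fbp, rs, rb)$average
cnr_channelwise(tvtgv$volume, rs, rb)$average

spec <- extract_roi_spectrum(tvtgv$volume, rs)
estimate_edge_position(spec, tvtgv$volume$axis)
```

On the shipped 64×64, 56-channel benchmark this prints a channel-average CNR
of about `7.8` for channel-wise FBP against about `24` for TV-TGV — the
regularised reconstruction recovers the contrast the fast scan loses — and an
edge position of `40.5` keV, within one 0.3 keV channel of the tabulated
cerium K-edge (40.443 keV), so `kedge_lookup()` identifies the insert as Ce.
Per-channel RMSE against the noiseless truth is lower for TV-TGV in every
channel (`rmse_channelwise`).

Concentration mapping uses the fitted edge step:

```r
smap <- step_size_map(fx$iodine$truth, 33.169)  # Δμ0 per voxel
```

On the iodine phantom with insert concentrations 0.25 / 0.5 / 1.0 the mean
Δμ₀ per insert scales 1 : 2 : 4.

A config-driven end-to-end pipeline (`run_pipeline()`, YAML or list configs,
manifest + TIFF/CSV artefacts) and a thin CLI (`exec/spectralct`) wrap the
same functions.

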