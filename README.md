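# nbiseg — narrow-band spectral imaging analysis and tissue segmentation

`nbiseg` implements an end-to-end analysis pipeline for narrow-band
(hyperspectral) reflectance imaging of microsurgical tissue types — the
internal carotid artery with intact vs. peeled tunica adventitia, and the
facial nerve in its intracranial (proximal) vs. intratemporal (distal)
segments. Such tissues look nearly identical under white light; their
reflectance spectra over the visible range (400–720 nm, scanned in 2 nm
steps into a 161-band image cube) differ in narrow wavelength regions, and
the package's job is to find those regions, select the most informative
bands, and use them to segment tissue maps automatically.

The pipeline stages are:

1. **Calibration** — raw detector stacks `I` are converted to reflectance
   with white and dark reference stacks acquired at identical exposure:
   `R(x, y, λ) = (I − D) / (W − D)`, clipped to `[0, 2]` so specular grain
   survives.
2. **Annotation** — polygon regions in the VGG Image Annotator (VIA v2)
   JSON dialect are rasterized to integer label masks (even–odd fill,
   pixel-center convention, boundary pixels inside).
3. **Per-band screening** — each tissue sample contributes four
   disk-averaged spot spectra; per wavelength band, groups are compared with
   the two-sided Mann–Whitney U test (exact for small samples, normal
   approximation with tie/continuity correction otherwise), preceded by a
   Shapiro–Wilk normality screen. Runs of consecutive significant bands are
   consolidated into wavelength ranges at α = 0.05 and α = 0.001, and
   per-band descriptives (SPSS-rule quartiles, IQR, mean ± 95% CI) are
   tabulated.
4. **Band selection** — class mean spectra are denoised with a
   Savitzky–Golay filter, mutually similar bands are pruned by inter-band
   affinity (Pearson correlation over labelled pixels), anomalous samples
   (e.g. plaque) are excluded by a robust modified-z rule on spectral area,
   and the remaining bands are ranked by per-wavelength divergence
   `|mean_A(λ) − mean_B(λ)|` summed over class pairs; the top 68 of 161
   bands are kept by default.
5. **Segmentation** — a compact U-Net encoder–decoder (implemented in base
   R with BLAS matrix products; bilinear-plus-convolution decoder by
   default) is trained on the selected bands with a combined
   cross-entropy + soft-Jaccard loss and evaluated on a held-out scene by
   per-class Jaccard IoU (`|pred ∩ truth| / |pred ∪ truth|`) and pixel
   accuracy.

Because no reference image data are publicly deposited, the package ships a
first-class synthetic scene generator: smooth class-specific reflectance
curves (logistic rise plus Gaussian absorption dips), planted paired-class
contrasts in documented wavelength intervals, log-normal between-specimen
level scatter, sample anomalies (plaque, adventitia overlap,
discoloration), dark cardboard background, Gaussian noise and bright
specular grain — all with known ground-truth masks, so every stage is
testable without any download.

## Worked example

```r
library(nbiseg)

# synthetic specimen board: 4 tissue types x 5 specimens on dark cardboard
board <- generate_scene(board_scene_spec(seed = 1))

# four spot spectra per sample across all 161 bands
samples <- extract_sample_spectra(board$cube, board$region_mask,
                                  board$regions, n_spots = 4, seed = 1)
nrow(samples$values)            # 80 spot spectra (4 x 5 x 4)

# per-band screening of intact vs. peeled artery
bt <- mann_whitney_per_band(samples_for_tissue(samples, "ICA_NORMAL"),
                            samples_for_tissue(samples, "ICA_PEELED"),
                            samples$wavelengths)
consolidate_ranges(bt)
#>   lambda_start lambda_end n_bands alpha
#> 1          400        480      41  0.05

# band selection + U-Net segmentation on per-specimen scenes
scenes <- lapply(1:5, function(i)
  generate_scene(quadrant_scene_spec(specimen_id = i, size = 64, seed = 100 + i)))
bands <- select_optimal_bands(scenes[[1]]$cube, scenes[[1]]$mask, n_select = 68)
wl68 <- sort(bands$wavelength)
fit <- train_unet(build_unet(unet_spec(68, 5, depth = 2, base_channels = 8), seed = 1),
                  lapply(scenes[1:4], function(s) subset_bands(s$cube, wl68)),
                  lapply(scenes[1:4], `[[`, "mask"),
                  training_config(epochs = 50, seed = 1))
pred <- predict_unet(fit$model, subset_bands(scenes[[5]]$cube, wl68))
evaluate_segmentation(pred$labels, scenes[[5]]$mask)
#> segmentation_result: pixel accuracy 99.41%, mean IoU 0.987
```

The consolidated range recovers exactly the contrast planted in 400–480 nm
for the artery pair, and the held-out scene — a specimen never seen in
training — is segmented with better than 99% pixel accuracy on the
synthetic benchmark (the analogous quantity reported on real cadaveric
data is about 91%; synthetic scenes are cleaner than tissue).

The full pipeline (simulate → calibrate → extract → scan → select →
segment → evaluate) runs from one configuration:

```r
run_pipeline(default_pipeline_config(seed = 1), "runs/demo")
```

or from the shell via `Rscript inst/scripts/nbi-pipeline.R --seed 1 --out runs/demo`.

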