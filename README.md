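# photonstim

Quantitative analysis of biohybrid photonic platforms that stimulate
cultured neurons through the **evanescent field of low-index-contrast polymer
waveguides** and read their activity out with calcium imaging.

On such a platform, channelrhodopsin-2–expressing neurons grow directly on
4.5 µm × 340 nm polymer (OrmoClear/OrmoComp) rib waveguides on a transparent
fused-silica chip, in an aqueous medium that doubles as the waveguide
cladding. Light guided at ~490 nm leaks into the medium only as an
evanescent tail,

> I(y) = I_surf · exp(−y / d_p),  with  d_p = λ / (4π √(n_eff² − n_clad²)),

so only channels within a few tens of nanometres of the surface are driven —
the basis for subcellular stimulation resolution. This package implements
the full analysis chain around that physics:

| module | what it computes |
|---|---|
| evanescent optics | index contrast Δ = (n_core − n_clad)/n_core, penetration depths (guided-mode and objective-TIRF parameterizations), cladding-medium conversion, activation-threshold heights |
| mode solver | semi-vectorial finite-difference modes of the rib cross-section: effective indices, surface power density per mW, mode penetration depth, Gaussian fiber overlap integrals (edge coupling vs gap) |
| bead calibration | the fluorescent-microbead procedure: 2-D Gaussian bead localization, sphere-geometry height mapping y(r) = R − √(R² − r²), exponential fit of counts vs height, sucrose→water conversion |
| response mapping | per-pixel FFT of stimulation movies in the 21–31 s window, summed amplitudes at 1–5 Hz, normalization to the field-of-view maximum, ROI-averaged traces |
| loss characterization | cut-back OLS regression (dB vs cm), intercept decomposition into facet coupling and bend loss, Payne–Lacey roughness-scattering upper bound |
| synthetic data | bead images, calcium movies and cut-back tables with known ground truth and camera noise (Poisson shot noise + Gaussian read noise), bit-reproducible by seed |
| interface | lossless TIFF + JSON-sidecar I/O and a validated YAML-config pipeline runner |

## Worked example

```r
library(photonstim)

# guided modes of the default rib (4.5 um x 300 nm + 40 nm slab,
# OrmoClear / fused silica / water, 491 nm)
modes <- solve_modes(waveguide_geometry(), n_modes = 3)
modes[[1]]
#> <mode_solution> TE00  n_eff = 1.5104  d_p = 56.1 nm  I_surf = 3.27e+05 mW/mm2 per mW

# height at which the ChR-2 threshold (5 mW/mm2) is crossed at 1 mW input
threshold_height(surface_intensity(modes[[1]], 1), 5, modes[[1]]$d_p_nm)
#> [1] 621.6596   # nm

# bead calibration on a synthetic waveguide-excited bead (57 nm in water,
# measured in index-matched sucrose)
d_suc <- convert_penetration_depth(57, 1.340, 1.450, 491)$d_p_nm  # 96.8 nm
img <- generate_bead_image(d_p_true_nm = d_suc, noise = noise_model(seed = 1))
run_bead_calibration(img$stack, medium_index = 1.450)
#> <bead_fit> center (63.79, 63.32) px; d_p = 96.6 nm in medium (n = 1.450),
#>            57.0 nm in water (n = 1.340); 649 px

# stimulation-locked response map of a synthetic waveguide-stimulation movie
mv <- generate_calcium_movie(scene_layout(seed = 1),
                             stimulation_mode = "waveguide",
                             noise = noise_model(seed = 1))
map <- response_map(mv$movie, stim_protocol(), window_s = c(21, 31))
mean(map$scores[mv$responder_mask] > 0.5)   # stripe-adjacent cells respond
#> [1] 1
```

The numbers mean: the fundamental TE-like mode hugs the rib top (effective
index 1.5104), its intensity decays into the water with a 56 nm penetration
depth, and 1 mW of guided power produces ≈3.3·10⁵ mW/mm² at the surface —
five orders of magnitude above the channelrhodopsin-2 threshold, which is
crossed only ~620 nm above the chip. The bead fit recovers the decay length
it was generated with, and the frequency-domain map classifies exactly the
cells touching the waveguide stripe as responders.

## Analysis workflow

The `analysis/` directory holds numbered drivers that reproduce the study's
analyses end to end on synthetic data and write tables under `results/`:

```sh
Rscript analysis/01_waveguide_optics.R   # modes, d_p, I_surf, threshold, coupling
Rscript analysis/02_loss_budget.R        # cut-back fit, bend/coupling decomposition
Rscript analysis/03_bead_calibration.R   # 57 / 80 nm bead recovery, 20 noise seeds
Rscript analysis/04_response_mapping.R   # full-field vs waveguide response maps
```

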