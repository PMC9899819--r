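# octaclean

Two-stage image-quality improvement for *en face* OCTA (optical coherence
tomography angiography) images: **de-striping** followed by
**contrast re-enhancement**, with a synthetic phantom simulator and an
evaluation harness so the whole method runs end-to-end with known ground
truth.

OCTA acquisition takes seconds, so microsaccadic eye motion leaves bright
stripe artifacts across the scan direction, and poor illumination leaves
vessels at low contrast — both of which corrupt downstream vessel
segmentation. `octaclean` is aimed at researchers working on OCTA / AS-OCTA
image restoration and at anyone who needs a fully seeded, CPU-only
reference implementation of this family of methods.

## The method

**Stage 1 — de-striping.** A corrupted image is modelled as an exact
additive decomposition `I = N + C` of stripe noise and clean signal. A
U-shaped convolutional network predicts the noise map `N_out`, the clean
estimate is the residual `C_out = max(I − N_out, 0)`, and training
minimizes

    L = α·L_recon + β·L_stripe + γ·L_ATV        (α = 0.5, β = 2, γ = 1)

where `L_recon = ½‖I − (N_out + C_out)‖_F` enforces reconstruction,
`L_stripe = ‖Stripe(N_ref) − Stripe(N_out)‖_F` compares low-rank stripe
components after singular-value soft-thresholding
(`Stripe(N) = U·max(S − λ, 0)·Vᵀ`, λ = 0.002 — the proximal operator of the
nuclear norm, exploiting the low-rank structure of parallel stripes), and
`L_ATV` compares anisotropic total variation (edge sharpness). All
gradients, including the SVD backward pass, are analytic and
finite-difference-tested.

**Stage 2 — re-enhancing.** An unpaired bi-directional translation GAN
(two residual generators, two patch discriminators, least-squares
adversarial + cycle-consistency + identity losses) augmented with a
*cyclic perceptual loss* (feature-level cycle consistency at two extractor
depths, weight ξ = 0.5) and an SSIM-style *structure loss*
(`1 − mean window-wise σ_xy/(σ_x σ_y)` with stabilizer, weights
ρ₁ = ρ₂ = 0.5) that protects vasculature while contrast moves toward the
high-contrast domain.

**Synthetic data.** Vessel phantoms (spline vessels, exact masks) plus
additive bright stripe fields of guaranteed low rank; noise level *i*
means *i* independent stripe fields summed and clipped, with the additive
identity preserved exactly. Metrics: PSNR, SSIM (canonical constants),
and Dice / sensitivity / specificity / G-mean of a baseline threshold
segmenter against the phantom masks.

See `vignettes/octaclean-methods.Rmd` for the full model description,
parameter meanings, numerical choices and limitations.

## Worked example

```r
library(octaclean)

man <- make_dataset(40, levels = 2, seed = 11, out_dir = tempfile("octa-demo"))
cfg <- srnet_config(profile = "tiny", seed = 4)
fit <- train_srnet(man, cfg, epochs = 20)
report <- evaluate(man, models = list(srnet = fit$model),
                   conditions = c("corrupted", "destriped"))
print(report)
```

```
Metric report (8 images, split test)
 level condition n psnr_mean psnr_sd ssim_mean ssim_sd dice_mean dice_sd
     2 corrupted 8     18.38   1.630    0.9095 0.02218    0.9133 0.02515
     2 destriped 8     20.94   2.018    0.9325 0.02229    0.9195 0.02680
 sen_mean  sen_sd spe_mean  spe_sd gmean_mean gmean_sd
   0.9508 0.01254   0.9012 0.03235     0.9256  0.01992
   0.9362 0.02225   0.9254 0.02532     0.9307  0.02036
```

Forty phantoms are corrupted at stripe-noise level 2, a tiny de-striping
network is trained for 20 epochs on the train split, and the held-out
images are scored before and after de-striping: PSNR rises by ~2.6 dB,
SSIM by ~0.023, and the baseline segmenter's Dice and G-mean both improve
— stripes that would be segmented as false vessels are removed. Stage 2
(`train_psgan()` / `enhance()`) and the one-call chain (`run_pipeline()`)
follow the same pattern; `inst/cli/octaclean.R` exposes every step as a
shell subcommand.

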