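# tomopick

Macromolecule particle picking in cryo-electron tomograms with a 3D
shifted-window transformer U-Net.

## The problem

Cryo-electron tomography (cryo-ET) reconstructs the 3D density of a frozen
cellular sample. Downstream structural analysis (subtomogram averaging)
needs the coordinates — and ideally the classes — of the macromolecular
particles inside the tomogram, but tomograms are huge, extremely noisy
(power SNR often below 0.1) and anisotropic from the missing wedge, making
manual picking the throughput bottleneck. `tomopick` is an end-to-end
pipeline for researchers who want automated, reproducible picking:

1. **Standardization** — MRC I/O with exact metadata handling, isotropic
   trilinear resampling, percentile normalization
   `V' = clip(V / p95(V), 0, 1)`, per-dataset z-offset alignment of
   annotations, class-id remapping with occupancy-preserving masks.
2. **Feature extraction** — a fixed-order 4-channel stack per voxel:
   normalized density, Sobel gradient magnitude (per Å), combined
   white/black multi-scale top-hat, and a multi-scale
   difference-of-Gaussians blobness map
   `DoG_s = G(ks) − G(s)`, `DoG_max(x) = DoG_{s*}(x)`,
   `s* = argmax_s |DoG_s(x)|` over `s ∈ {1,2,4,8}` voxels.
3. **Gridding** — disjoint 48³ cores with 8 voxels of context per face
   (64³ windows), write-once exact stitching.
4. **Segmentation** — a four-stage 3D Swin-transformer U-Net (patch
   merging/expanding, windowed attention
   `Attn(Q,K,V) = softmax(QKᵀ/√d + B)V` with relative-position bias `B`,
   alternating cyclic shifts with wrap-around masking, additive skip
   fusion `LN(F_dec + F_enc)`), trained with class-weighted cross-entropy,
   Adam, and global-norm gradient clipping — implemented natively in R with
   finite-difference-verified backpropagation.
5. **Post-processing and evaluation** — per-class 18-connectivity
   components, inclusive minimum-size filtering, centroid extraction, and
   one-to-one Hungarian matching under a 5-voxel cutoff yielding
   TP/FP/FN, precision, recall, F1, miss rate and AD (mean matched
   distance).

A built-in simulator (`simulate_tomogram()`) generates tomograms with known
particle positions, occupancy masks and calibrated noise, so the entire
pipeline is testable without external data.

## Worked example

```r
library(tomopick)

# simulate a small tomogram with known ground truth
cfg <- sim_config(shape = c(72, 72, 72), noise_sigma = 0, seed = 42)
sim <- simulate_tomogram(cfg)
print(sim$density)
#> <tomo_volume> 72 x 72 x 72 voxels
#>   voxel size: 1 x 1 x 1 A
#>   origin: (0, 0, 0) A; axis map: (1,2,3)
#>   range: [0, 1]

# standardize and featurize
vn <- percentile_normalize(sim$density, nonzero_only = TRUE)
stack <- build_feature_stack(vn, feature_config(scales = c(1, 2, 4)))
print(stack)
#> <feature_stack> 4 channels, 72 x 72 x 72 voxels
#>   channels: [normalized, gradient magnitude, top-hat, DoG-max]

# window the label mask (oracle segmentation), stitch, extract particles
windows <- split_volume(sim$mask, grid_spec())   # 8 windows of 64^3
pred <- stitch(windows)
picks <- centroids(size_filter(connected_components(pred, 18), 5))

# score against the planted centres
hungarian_match(picks, sim$truth, d_max = 5, per_class = TRUE)
#> <match_result> TP 10  FP 0  FN 0
#>   precision 1.0000  recall 1.0000  F1 1.0000  AD 0.057 voxels
```

All ten planted particles are recovered with no false positives; the mean
centroid error (AD) of 0.057 voxels shows that component centroids localize
the planted centres to a small fraction of a voxel.

Training a (reduced) network on simulated data follows the classic
modelling idiom — a fitting function returning a classed object with
`print`, `summary`, `coef`, `predict` and `plot` methods:

```r
net <- swin3d_config(num_classes = 2, hidden_dim = 16,
                     depths = c(2, 2, 2, 2), heads = c(1, 2, 4, 8),
                     head_dim = 16, dropout = 0)
fit <- swin3d_fit(inputs, masks, net,
                  train_config(epochs = 60, lr = 3e-3, seed = 1))
plot(fit)                            # loss curve
vol <- predict(fit, feature_stack)   # stitched label volume
```

A thin command-line wrapper (`inst/cli/tomopick.R`) exposes the stages as
subcommands (`simulate`, `preprocess`, `featurize`, `grid`, `train`,
`predict`, `stitch`, `postprocess`, `evaluate`, `pipeline`), each writing a
resolved-configuration snapshot and a log next to its outputs:

```sh
Rscript inst/cli/tomopick.R simulate --out sim/ --seed 1 --shape 64,64,64
Rscript inst/cli/tomopick.R pipeline --oracle-mask sim/mask.mrc \
    --gt sim/truth.csv --out run/
```

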