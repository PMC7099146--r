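# dualpathseg

Automated segmentation of brain regions in volumetric micro-optical
images (nominal 10 µm isotropic, coronal slices), for neuroscientists who
need 3D region contours from cellular-resolution whole-brain data where
region boundaries are texture transitions between aggregates of discrete
cell bodies rather than intensity edges.

The package combines three feature levels:

* **Local + contextual:** a dual-pathway patch CNN classifies each pixel
  from two co-centred patches (51 × 51 and 77 × 77 px). Each pathway is
  `[5×5 conv s1 → ReLU → LRN → 3×3 maxpool s2] ×2 → 5×5 conv → ReLU`
  (valid convolutions, floor pooling: 51 → 47 → 23 → 19 → 9 → 5); the two
  pathway outputs concatenate to 128 maps of 5 × 5, a cascade 5 × 5 conv
  produces 512 maps of 1 × 1, and tapped fully connected layers feed a
  softmax-with-loss classifier
  ℓ(y, z) = log Σⱼ exp(zⱼ) − z_y = −log σ_y(z).
* **Global, initial:** multi-resolution mutual-information registration
  (affine + symmetric diffeomorphic demons-style nonlinear stage) maps an
  atlas region label onto the subject; the middle slice of the mapped
  region, dilated by a 50 px disk, becomes the first search mask
  (*Mask-init*).
* **Global, tracked:** each segmented slice, dilated by a 20 px disk
  (*Mask-track*), constrains prediction on its neighbour; prediction
  visits only a stride-2 subgrid of the mask (75% fewer classifications)
  and propagation runs to both volume ends, followed by 3D postprocessing
  (hole filling, small-component removal, smoothing).

Training data are class-balanced by the retention rule
`0.1·N1 + 3·x·N2 = 3·N3` over class-A negatives (patch contains no region
pixel), class-B negatives (patch touches the region) and positives, with
±20% intensity augmentation. Evaluation uses Dice = 2|I∩J|/(|I|+|J|),
Precision = |I∩J|/|I| and Recall = |I∩J|/|J|, plus localization recall /
redundancy for masks.

A seeded phantom generator (superellipse regions with bounded slice-to-
slice drift, Poisson-scattered cell-like blobs, optional stripe/vignette
noise, and atlas pairs related by a known fold-free warp) provides ground
truth for every stage. The CNN and all dense 3D operations are
implemented in C++ (Rcpp/RcppArmadillo).

## Worked example

```r
library(dualpathseg)

# a 30-slice phantom with drifting region and cell-like texture
spec <- phantom_spec(shape = c(30, 160, 160), radii = c(40, 30),
                     center = c(80, 80), d_max = 8, seed = 32)
ph <- make_phantom(spec)

# two-scale patch samples, balanced, augmented, capped at the desk scale
cand <- extract_candidates(ph$volume, ph$label, stride = 5,
                           slices = seq(1, 30, by = 2))
samples <- subsample_balanced(screen_and_augment(cand, seed = 33),
                              4800, seed = 34)
split <- split_train_val(samples, 0.8, seed = 35)
length(split$train$label)
#> [1] 3839

# train the dual-pathway CNN (reduced schedule)
model <- train_network(split$train, split$val, network_spec(),
                       train_config(epochs = 4, seed = 36), verbose = TRUE)
#> epoch 1: mean loss 0.5063, val acc 0.928
#> epoch 2: mean loss 0.1761, val acc 0.941
#> epoch 3: mean loss 0.1085, val acc 0.955
#> epoch 4: mean loss 0.1037, val acc 0.956

# held-out phantom + atlas pair related by a known 20 px warp
spec2 <- phantom_spec(shape = c(24, 160, 160), radii = c(38, 32),
                      center = c(82, 78), d_max = 8, seed = 42)
test <- make_phantom(spec2)
atlas <- make_atlas_pair(spec2, warp_amplitude = 20, seed = 43)
run <- run_pipeline(run_config(
  volume = test$volume, atlas_volume = atlas$volume,
  atlas_label = atlas$label, model = model, truth = test$label,
  init_radius = 50, track_radius = 20, stride = 2), verbose = TRUE)
#> localize: registering atlas to subject
#> track: start slice 12
round(run$metrics$volume$dice, 4)
#> [1] 0.9331
```

The printed numbers: the balanced set holds 3,839 training patches
(positives tripled by augmentation, negatives matched to them by the
retention rule); training reports per-epoch mean loss and validation
accuracy (0.956 after four epochs); the pipeline reports the volume Dice
of the postprocessed segmentation against ground truth — Dice ≥ 0.9 is
the headline working point at this scale.

`trace_shapes(network_spec())` prints the layer-by-layer geometry,
`mutual_information()`, `dice_precision_recall()` and
`localization_report()` expose the registration metric and the evaluation
measures, and `plot_slice(vol, s, mask, seg)` overlays masks and contours
for inspection. A thin command-line front end over these functions ships
in `inst/cli/deepbrainseg-cli.R` (subcommands `phantom`, `sample`,
`train`, `localize`, `segment`, `evaluate`, `run`).

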