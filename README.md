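# nucleifuse

Boundary-aware semantic segmentation of cell nuclei in
hematoxylin-and-eosin (H&E) histology images, for computational-pathology
pipelines that need both accurate nuclear regions and sharp nuclear
contours (morphometry, cell counting, biomarker quantification).
Everything — network, losses, training engine, metrics and a synthetic
data generator with exact ground truth — runs on a plain CPU with no
external datasets or deep-learning frameworks.

## The model

The segmentation network decouples context from detail and then fuses
them:

* **Dual-stream encoder.** A *global* stream stacks
  conv → batch-norm → deformable dilated conv → GELU blocks
  (dilations 1, 2, 4, … per level, learned sampling offsets) with 1×1
  residual projections, growing the receptive field without extra
  downsampling; a *local* stream takes the image concatenated with its
  Sobel gradient magnitude, `I_edge = [I, |∇I|]`, through shallow
  conv → batch-norm → GELU blocks. Both streams downsample stride-2 in
  lockstep, so per-level feature maps `F_l^g, F_l^l` share resolution.
* **Hyperfeature fusion.** Per level, 1×1 projections to a common width
  C are concatenated; channel-wise average/max descriptors feed a shared
  7×7 convolution + sigmoid producing a spatial attention map `A_l`
  that reweights the concatenated features. The attended maps are
  resampled to a base resolution, concatenated into a `2·C·L`-channel
  hypercolumn, and compressed by a depthwise-separable 3×3 block to D′
  channels.
* **Dual decoders.** Parallel transposed-conv (2×2) decoders with
  per-stage skip connections reconstruct a region probability map
  `Y_seg` and a boundary probability map `Y_edge`; at inference the
  region map is refined multiplicatively,
  `Y_R = clamp(Y_seg · (1 + λ·Y_edge), 0, 1)`.
* **Gradient-aligned objective.**
  `L = α·L_seg + β·L_edge + γ·L_glga` with α/β/γ = 0.6/0.2/0.2:
  a hybrid Dice + binary-cross-entropy region term, a boundary BCE term,
  and a gradient-alignment term
  `L_glga = mean( | |∇Y_seg| − |∇Y| | )` (Sobel operators, replicate
  padding) that pulls predicted contours onto the true ones.

Training uses AdamW (decoupled weight decay), cosine annealing with warm
restarts, global gradient-norm clipping at 5.0, per-epoch validation
Dice with best-checkpoint saving and early stopping. Every stage —
weight init, batch order, augmentation — draws from its own derived
seed stream, so runs are bit-reproducible.

Evaluation implements Dice, IoU, pixel precision/recall, boundary F1
with a pixel tolerance δ, and the exact symmetric Hausdorff distance
between boundary pixel sets, each verified against brute-force oracles
in the test suite.

Because real H&E collections cannot ship with the package, a synthetic
generator emulates dense fields of overlapping, rotated, lobulated
elliptical nuclei with textured background, stain jitter and Gaussian
noise — with exact region masks, instance labels and placement
provenance — so the full pipeline is testable end to end.

## Worked example

```r
library(nucleifuse)

spec <- scene_spec()          # the package's synthetic study conditions
spec
#> scene_spec: 64x64 px, E[nuclei] = 8, semi-axes [3, 8] px,
#>   overlap target 0.3, contrast 0.35, noise sd 0.05, grayscale

fields <- generate_dataset(spec, 250, seed = 1)
data   <- prepare_training_set(fields, preproc_config(target_size = 64))
train_set <- data[1:200]; val_set <- data[201:250]

model <- build_model(tiny_network_config(), seed = 42)
model
#> nf_model: 3 levels, streams=both, attention fusion, 50035 parameters (seed 42)

st <- train(model, train_set, val_set,
            tiny_train_config(max_epochs = 12, patience = 12),
            loss_weights(), verbose = TRUE)
#> epoch   1  loss 0.6540  val dice 0.6107 *
#> epoch   2  loss 0.5276  val dice 0.7748 *
#> ...
#> epoch  12  loss 0.1177  val dice 0.9718 *

best   <- load_checkpoint(st$checkpoint_path)
bundle <- forward(best, val_set[[1]]$x)
bundle
#> prediction_bundle: 64 x 64, seg [0.000, 0.999], edge [0.012, 1.000]
evaluate(bundle$y_refined, val_set[[1]]$region)
#> dice 0.9835 | iou 0.9676 | bf1 1.0000 | prec 0.9700 | rec 0.9975 | hd 1.00

reports <- lapply(val_set, function(s)
  evaluate(forward(best, s$x)$y_refined, s$region))
aggregate_reports(reports)
#>      metric      mean         sd  n
#> 1      dice 0.9674325 0.02014177 50
#> 2       iou 0.9376070 0.03598838 50
#> 3       bf1 0.9936267 0.01564414 50
#> 4 precision 0.9445110 0.03612724 50
#> 5    recall 0.9923659 0.01092499 50
#> 6 hausdorff 4.8404248 7.08334404 50
```

The per-image line reads: 98.3% region overlap (Dice), boundary-F1 of
1.0 at a 2-px tolerance, and a worst-case boundary error (Hausdorff) of
1 pixel. The aggregate table is the mean ± sd over the 50 held-out
fields.

A thin command-line wrapper over the same functions lives at
`inst/cli/nucleifuse.R`
(`generate | train | predict | evaluate | ablate | smoke`), e.g.

```sh
Rscript inst/cli/nucleifuse.R generate --n 64 --size 64 --seed 42 --out data/
Rscript inst/cli/nucleifuse.R smoke --seed 42
```

An ablation harness trains structural variants (single-stream encoder,
additive fusion instead of attention, no boundary decoder, no
gradient-aligned term) under identical data and seeds and tabulates
their metrics:

```r
run_ablation(c("full", "no_glga", "no_hfem"), train_set, val_set)
```

## Limitations

The synthetic generator is a geometric stand-in: it reproduces the
density, overlap and contrast regime of dense nuclear fields but not
chromatin texture, stain deconvolution physics or whole-slide artifacts.
Performance on the generator therefore demonstrates that the
architecture, losses and training engine work as specified — not
clinical-grade accuracy on real tissue. Instance-level separation of
touching nuclei (AJI/PQ evaluation) is out of scope; the model predicts
binary region and boundary maps.
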