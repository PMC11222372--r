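# dsnet — dual-branch 3D segmentation of hippocampal subfields

`dsnet` is an R implementation of a dual-branch volumetric
encoder–decoder network for segmenting hippocampal subfields — CA1-3,
CA4/DG and the subiculum (SUB) — from co-registered T1w/T2w MRI. The
hippocampus is small, its subfield boundaries are weakly contrasted
against surrounding tissue, and manual delineation is slow; this package
provides the full pipeline a segmentation study needs: preprocessing,
the network, training, sliding-window inference, post-processing,
evaluation, and a synthetic phantom generator so that everything is
testable end-to-end without any imaging data.

## The model

The network is a 5-stage 3D U-shaped encoder–decoder with three additions:

* **Transformer bottleneck.** The deepest feature map
  $F_5^{\text{local}}$ is flattened to tokens, projected with a learnable
  positional table ($F^{\text{token}} = F_5^{\text{local}} W + P$), and
  passed through pre-norm multi-head self-attention
  $\mathrm{head}^i = \mathrm{softmax}\!\big(Q_i K_i^\top / \sqrt{d_k}\big) V_i$
  with $N = 8$ heads and a GELU feed-forward block
  ($y = \mathrm{MSA}(\mathrm{LN}(F^{\text{token}})) + F^{\text{token}}$,
  $F^{\text{global}} = \mathrm{FFN}(\mathrm{LN}(y)) + y$), then projected
  back onto the grid.
* **CBAM skip gates.** Each skip connection is gated channel-wise,
  $M_c(F) = \sigma(\mathrm{MLP}(\mathrm{maxpool}(F)) +
  \mathrm{MLP}(\mathrm{avgpool}(F))) \otimes F$, then spatially,
  $M_s(F') = \sigma(\mathrm{Conv}_{7^3}([\mathrm{maxpool}_c(F'),
  \mathrm{avgpool}_c(F')])) \otimes F'$.
* **Dual-branch decoder.** After two up-samplings the decoder splits into
  a whole-hippocampus branch and a subfield branch; at every later stage
  the hippocampus branch's features are added residually into the
  subfield branch, so the easier binary task guides the harder 4-class
  one.

Training minimizes the dual soft Dice loss
$\mathcal{L}_{\text{total}} = \lambda_1 \mathcal{L}_1 + \lambda_2
\mathcal{L}_2$ ($\lambda_1 = \lambda_2 = 0.5$) with Adam, a polynomial
learning-rate schedule $\eta_0 (1 - t/T)^{0.9}$, random 128³ patches,
mirror/intensity/scale augmentation and L2 weight decay. Inference tiles
a volume with non-overlapping windows, averages the softmax outputs of
the last four epoch checkpoints, takes the voxel-wise argmax and removes
predicted components smaller than 1000 voxels (64 mm³ at 0.4 mm
spacing). Evaluation reports Dice and the 95th-percentile Hausdorff
distance (mm) per subfield and for the whole hippocampus.

All tensor operations — including every backward pass and the optimizer —
are implemented inside the package (C++ kernels for the convolutions, R
for the rest), verified against finite differences and literal
evaluations of the defining equations in the test suite.

## Worked example

Train the desk-scale `dsnet-tiny` preset to overfit two synthetic
phantom subjects, then segment one of them:

```r
library(dsnet)

cfg    <- phantom_config(grid_shape = c(32, 32, 32),
                         organ_axes = c(8, 6, 6), n_distractors = 0)
cohort <- generate_cohort(cfg, 2, seed = 11)   # two jittered subjects
rc     <- resolve_preset("dsnet-tiny")

tc <- rc$train
tc$max_epochs <- 250L; tc$seed <- 101L; tc$batch_size <- 1L
tc$mirror_prob <- 0; tc$intensity_shift_range <- c(0, 0)
tc$scale_range <- c(1, 1)                      # overfit: no augmentation

fit  <- dsnet_train(flip_double(cohort), rc$model, tc, rc$loss)
pred <- dsnet_predict(cohort[[1]]$volume, fit, min_voxels = 200L)
evaluate(pred, cohort[[1]]$labels)
```

On one CPU this takes about six minutes and prints:

```
    structure label dice hd95 hd95_defined
1       CA1-3     1    1    0         TRUE
2      CA4/DG     2    1    0         TRUE
3         SUB     3    1    0         TRUE
4 Hippocampus    NA    1    0         TRUE
```

Dice 1 / HD95 0 mm for every structure: the tiny network reproduces the
training labels exactly — the end-to-end check that the architecture,
loss, optimizer, inference and metrics all cooperate. The false-positive
filter is equally direct:

```r
ph   <- generate_phantom(phantom_config(seed = 31, n_distractors = 5))
noisy <- ph$labels
noisy$labels[ph$distractors == 1 & noisy$labels == 0] <- 1L
filtered <- cc_filter(noisy, min_voxels = 1000)
attr(filtered, "removed")
#>   size volume_mm3
#> 1   93      5.952
#> 2  305     19.520
#> 3  257     16.448
#> 4   93      5.952
#> 5   57      3.648
```

All five sub-threshold distractor blobs are relabelled to background
(each well under the 64 mm³ threshold); the organ, above threshold, is
untouched.

A command-line interface over the same functions lives in
`inst/cli/dsnet.R` (subcommands `generate-phantom`, `preprocess`,
`train`, `predict`, `evaluate`, `split-folds`).

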