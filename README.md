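# greyunet

Semantic segmentation **and** recognition of breast ultrasound images in one
pass: an *expanded U-Net* that is trained against **grey-level probability
labels** with a **ternary (expanded) cross-entropy loss**, and whose greyscale
output maps are scored with **grey-mass Dice/IOU** coefficients instead of
binary overlap. The package is aimed at people studying soft-label training
schemes for medical image segmentation; it contains everything needed to
exercise the method end to end on synthetic ultrasound-like phantoms, with no
clinical data required.

## The method

**Labels.** The three tissue classes are encoded as soft three-channel
targets rather than one-hot vectors:

| class          | ordinary label | three-channel grey      | grey-level probability |
|----------------|----------------|-------------------------|------------------------|
| normal tissue  | 0              | (0, 0, 0)               | (0, 0, 0)              |
| benign tumour  | 1              | (127.5, 127.5, 127.5)   | (0.5, 0.5, 0.5)        |
| malignant      | 2              | (255, 255, 255)         | (1, 1, 1)              |

**Loss.** With per-pixel entropy terms
`E = Σₖ y⁽ᵏ⁾ log p⁽ᵏ⁾` and `E′ = Σₖ (1 − y⁽ᵏ⁾) log(1 − p⁽ᵏ⁾)` summed over the
three output channels `k`, the training criterion over a batch of size N is

```
ECE = −(1/N) Σᵢ Σₖ [ yᵢ⁽ᵏ⁾ log pᵢ⁽ᵏ⁾ + (1 − yᵢ⁽ᵏ⁾) log(1 − pᵢ⁽ᵏ⁾) ]
```

Because the channel sum runs over all three channels, the loss and its
gradient at identical per-channel `(y, p)` are exactly **3×** the
single-channel binary cross-entropy — a 3× update rate without a larger
batch. Per channel the loss specializes to three cases: `−log p` (minimized
as `p → 1`), `−0.5 log[p(1 − p)]` (minimized at `p = 0.5`, floor `log 2`),
and `−log(1 − p)` (minimized as `p → 0`).

**Network.** A U-Net (depth 4, base 8 channels, doubling per level) with
seven dropout layers (after each of the four decoder fusions, the two deepest
encoder blocks and the bottleneck), batch normalization after every
convolution/deconvolution, leaky-ReLU activations, and a 1×1-convolution head
mapping the 8-channel feature vector to the 3-channel grey-level output map
(softmax by default, sigmoid available).

**Evaluation.** The grey output map is scored per class by total grey mass:
with grey reduction rate `α` (benign ≈ 0.667, malignant 1), ground-truth mass
`x_t` and the predicted mass `x_p` accumulated inside the class grey band
(benign (80, 90), malignant (170, 255)),

```
Dice = 2·min(α·x_t, x_p) / (α·x_t + x_p),    IOU = min(α·x_t, x_p) / max(α·x_t, x_p)
```

so `Dice = 2·IOU/(1 + IOU)` as for the classical coefficients. The benign
`α ≈ 0.667` is not a tuned number: under a softmax head the reachable optimum
for a benign pixel is `p = (1/3, 1/3, 1/3)`, i.e. output grey
`85 = 0.667 × 127.5` — the package derives this by constrained optimization
(`constrained_benign_minimum()`).

## Worked example

```r
library(greyunet)

constrained_benign_minimum()[c("p", "grey", "alpha")]
#> $p
#> [1] 0.3333333 0.3333333 0.3333334
#> $grey
#> [1] 85
#> $alpha
#> [1] 0.6666667

dir <- file.path(tempdir(), "phantoms")
generate_phantom_dataset(phantom_config(n_images = 32, seed = 515), dir)
fit <- train_unet(dir, train_config(epochs = 12, batch_size = 4, seed = 99,
                                    checkpoint = file.path(dir, "model.rds")))
round(fit$history$loss[c(1, 6, 12)], 4)
#> [1] 1.6198 1.4145 1.3772

predict_dir(fit$model, dir, file.path(dir, "pred"))
ev <- evaluate_dir(file.path(dir, "pred"), dir)
print(ev$summary, digits = 3)
#>       class  n dice_pct_mean dice_pct_sd iou_pct_mean iou_pct_sd
#> 1    benign 26          21.2        5.32        11.96       3.34
#> 2 malignant  6           0.0        0.00         0.00       0.00
#> 3   overall 32          17.2        9.68         9.72       5.62
```

The constrained optimum reproduces the analytic benign operating point: grey
85, reduction rate 2/3. In the phantom run the training loss falls
monotonically, and the evaluation table has the layout of a quantitative
results table (per-class Dice%/IOU% with mean and standard deviation). The
scores themselves illustrate the softmax head's analytic behaviour: every
pixel's constrained optimum is grey 85, so the benign band captures the whole
image (large `x_p`, hence deflated but nonzero benign Dice) while nothing
reaches the malignant band. Switching to `unet_config(head = "sigmoid")`
makes all three targets reachable and yields class-separated grey maps; the
methods vignette (`vignettes/expanded-unet.Rmd`) discusses this trade-off in
detail.

A command-line front end wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/greyunet", package = "greyunet"))')
Rscript $CLI synth    --out data --n 64 --size 64 --seed 1
Rscript $CLI train    --data data --checkpoint model.rds --epochs 20 --history loss.tsv
Rscript $CLI predict  --checkpoint model.rds --in data --out pred
Rscript $CLI evaluate --pred pred --truth data --report report.tsv
```

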