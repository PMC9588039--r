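# surfgcnn

Graph convolutional networks for predicting scalar cognitive traits from
registered cortical and subcortical surface meshes.

## The problem

Brain morphometry studies increasingly model the cortex and the subcortical
structures as registered triangulated surfaces: every subject carries the
same mesh topology, and only the vertex coordinates differ. `surfgcnn`
implements a surface-based deep learning pipeline for regressing a scalar
trait (for example a fluid-intelligence composite score) on this kind of
data:

- **Spectral graph convolution.** On a mesh graph G = {V, ε, A} with
  Laplacian L = I − D^(−1/2) A D^(−1/2), filtering a vertex signal x is
  approximated by a K-localized Chebyshev expansion

      g_θ(L) x = Σ_{k=0}^{K−1} θ_k T_k(L̃) x,    L̃ = 2L/λ_max − I,

  computed with the three-term recurrence T_k = 2 L̃ T_{k−1} − T_{k−2}.
  Each layer carries F_in × F_out × K trainable coefficients. A dense
  eigendecomposition oracle (`spectral_oracle`) verifies the recurrence.
- **Residual architecture.** A pre-convolution, a stack of residual blocks
  (two BN → ReLU → convolution subblocks with identity shortcuts), stride-2
  max pooling on a heavy-edge-matching mesh hierarchy after each block, a
  post residual block, and a single fully connected output.
- **Correlation-augmented loss.** L = MSE + λ₁·‖w‖² − λ₂·corr(ŷ, y), where
  the Pearson term counteracts regression-to-the-mean shrinkage.
- **Nested 6×5 cross-validation.** Outer folds estimate generalization;
  each outer fold's prediction is the average of five models early-stopped
  on the five inner folds.
- **Graph Grad-CAM.** Per-channel importance weights
  α_k = (1/N) Σ_n ∂ŷ/∂A_nk combine the last convolutional layer's feature
  maps into a nonnegative relevance map M = ReLU(Σ_k α_k A_k), interpolated
  back to full mesh resolution for anatomical reading.

Mesh I/O covers FreeSurfer binary surfaces, GIfTI `.surf.gii` and PLY.
A synthetic-cohort generator plants a localized shape–score effect on
icosphere stand-ins so the full pipeline is testable without any imaging
data.

## Worked example

```r
library(surfgcnn)

spec    <- synthetic_spec(n_subjects = 150, seed = 7)
tpl     <- generate_template(spec)            # shared triangulation
cohort  <- generate_cohort(tpl)               # planted shape-score effect
dataset <- prepare_dataset(cohort, tpl$template, mode = "combined",
                           num_levels = 2, seed = 7)

fit <- gcnn_fit(dataset,
                model_config = gcnn_tiny_model_config(seed = 7),
                train_config = gcnn_train_config(
                  batch_size = 32, max_epochs = 25, learning_rate = 1e-3,
                  lambda2 = 1, p_augment = 0, patience = 10, seed = 7))
print(fit)
#> Residual graph convolutional network fit
#> Call: gcnn_fit(x = dataset, model_config = gcnn_tiny_model_config(seed = 7), ...
#>   150 subjects (120 train / 30 validation), 25 epochs run (best 22)
#> gcnn_model_state: f=9, channels=8-8-16-16, K=3, 2 residual blocks + post, 12385 parameters

summary(fit)$val_metrics
#> MSE = 0.6335, R = 0.9065 (95% CI 0.8112-0.9549), n = 30
```

The validation R of 0.91 says the network recovered most of the planted
morphology→score relationship from vertex coordinates alone; the MSE is
in squared quantile-normalized score units (cohort variance 1). A full
nested-CV evaluation with ensembling and saliency mapping is one call:
`synthetic_benchmark(seed = 1)`.

Saliency for a fitted model:

```r
map  <- gradcam(fit, dataset$padded[, , 1])          # coarse relevance
full <- full_resolution_map(map, dataset$hierarchy)  # per-vertex, level 0
write_saliency_csv(full, dataset$template, "subject1_saliency.csv")
```

A command-line front end (`inst/cli/surfgcnn.R`) wraps simulation,
preparation from surface files on disk, training and saliency export.

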