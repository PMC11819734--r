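# equimoco

Momentum-contrast representation learning for equine posture imagery.

Horses express affective state largely through body posture — neck, head
and tail carriage — not just the face.  equimoco implements an end-to-end,
label-free pipeline for studying that signal:

1. **Retrieval** — sample video footage down to an effective 0.1 frames per
   second, detect animals with a pluggable detector, and keep only crops
   that pass a resolution filter (≥ 250×250 px) and an intensity-variability
   filter (standard deviation of [0,1]-scaled intensities σₓ < 0.4).
2. **Bookkeeping** — manifest CSVs and a stratified-by-breed split into
   pretraining / fine-tuning / test partitions (default fractions
   0.86/0.10/0.04, with exact target totals supported).
3. **Augmentation** — asymmetric query/key pipelines: random resized crop
   (area 0.66–1.0 for queries, 0.85–1.0 for keys), grayscale, a fair
   horizontal flip and occasional Gaussian blur on the query branch only,
   then a Sobel edge-magnitude filter and normalisation.  Every view has
   exactly one channel.
4. **Encoder** — a plain four-convolution single-channel CNN
   (1→32→64→128→256, 3×3 kernels, pooling after the 2nd and 4th
   convolutions, 2048-unit hidden layer, dropout 0.8, 64-D output).
5. **Contrastive pretraining** — momentum contrast: a momentum (EMA) key
   encoder, a FIFO queue of up to K = 65,536 negative keys, and the
   normalized temperature-scaled cross-entropy

   ```
   ℓ(i,j) = −log  exp(sim(z_i, z_j)/τ) / Σ_{k≠i} exp(sim(z_i, z_k)/τ),   τ = 0.07
   ```

   with unit-norm embeddings, trained by SGD (lr 1e-4, momentum 0.9,
   weight decay 1e-4, batch 32).
6. **Probing** — a frozen-encoder classification head
   (64→256→128→64→8 with batch norm and dropout 0.5/0.5/0.3) over the
   eight-emotion taxonomy (Care, Seeking, Fear, Lust, Play, Rage, Grief,
   Pain; uniform baseline 12.5%), plus t-SNE projections (perplexity 30)
   and silhouette-scored k-means cluster counting in embedding space.

Real wild-horse footage is proprietary, so the package ships a synthetic
posture-silhouette generator: each emotion class owns a distinct region of
(neck angle, head drop, tail angle) space, making every pipeline stage
testable end to end.  The neural-network layers (and their backward passes)
are implemented in base R and verified against finite differences; no
deep-learning framework is required.

## Worked example

A complete scaled-down study — generate fixtures, split, pretrain, compare
embedding structure, train and evaluate the frozen-encoder head:

```r
library(equimoco)

study <- run_desk_study(seed = 1)

lh <- study$loss_history
round(c(first = lh[1], final = lh[length(lh)]), 2)
#> first final
#>  4.08  3.12

round(c(untrained = study$silhouette_untrained,
        trained   = study$silhouette_trained), 3)
#> untrained   trained
#>     0.195     0.486

study$report$overall_accuracy
#> [1] 0.8923077
```

The pretraining loss falls from 4.08 to 3.12 over 50 epochs; the mean
silhouette width of the latent posture classes in embedding space rises
from 0.195 (untrained encoder) to 0.486 after contrastive pretraining —
the representation organises itself around posture without ever seeing a
label; and the frozen-encoder head classifies held-out fixtures at 89%,
about 7× the 12.5% chance level.

Individual stages are exposed as ordinary functions
(`generate_posture_dataset()`, `extract_dataset()`, `stratified_split()`,
`two_crops()`, `pretrain()`, `build_head()`/`train_head()`/`evaluate()`,
`project_embeddings()`, `estimate_cluster_count()`), and a thin
command-line front end lives at `inst/cli/equimoco.R`
(`extract`, `split`, `pretrain`, `finetune`, `evaluate`, `embed`,
`preview-augment`).

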