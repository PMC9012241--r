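# dsattn

Double-scale attention networks for protein sequence classification in R.

`dsattn` is for computational biologists who want an *interpretable*
sequence-level classifier for protein tasks such as enzyme-class (EC
number) prediction: alongside each prediction, the model exposes where in
the sequence — and at which sub-sequence length scale — its attention
went, which can be compared directly against annotated functional sites
and motifs.

## The model

A transformer encoder stack produces per-position global features
`F_global ∈ R^{l×f}` from token + sinusoidal positional embeddings
(masked multi-head self-attention with `d_k = d_v = f/h`, post-norm
residual layers). One 1-D convolution per kernel size `S_k ∈ {5, 10, 20}`
(the common lengths of annotated protein motifs) extracts scale-local
features `F_{S_k} ∈ R^{l×f}`, variance-rescaled by `1/√S_k`. A
*feature-agreement* score compares each scale's feature to the
position-wise consensus

    F_cent^j = (F_global^j + Σ_k F_{S_k}^j) / (N+1),
    A_kj     = (F_{S_k}^j · F_cent^j) / √f ,

and a single softmax over all `N×l` entries turns `A` into the
**double-scale attention matrix** `W`, a joint distribution over
(scale, position) with positional margin `v_j = Σ_k W_kj`. Features are
fused position-wise with the conditional weights `W_kj / v_j`, a shared
linear+softmax head yields positional class distributions `C ∈ R^{l×M}`,
and the final prediction is the mixture `p_d = Σ_j C_jd · v_j`. Training
is masked-LM pre-training (15% targets, 80/10/10 corruption) followed by
supervised fine-tuning, both with AdamW; forward *and backward* passes
are implemented in base-R matrix algebra, so no deep-learning framework
is needed.

An annotated region of length `L` counts as *matched* by the attention
matrix when the highest-attention scale at its middle position is the
kernel size closest to `L` and the margin there exceeds 1.5× the
sequence's mean margin; `match_rate()` compares the matched fraction
against a length-preserving permutation null.

## Worked example

Generate a two-class planted-motif benchmark (motif lengths 5 and 19,
5% substitution noise), pre-train, fine-tune, and inspect the attention:

```r
library(dsattn)

ds <- synth_dataset(synth_config(
  n_classes = 2, seqs_per_class = 600, motif_lengths = c(5, 19),
  insertion_prob = 1, noise = 0.05,
  split = c(train = 500/600, val = 50/600, test = 50/600), seed = 1))

cfg <- read_model_config(system.file("configs", "tiny.yaml",
                                     package = "dsattn"))

corpus <- synth_dataset(synth_config(n_classes = 2, seqs_per_class = 1000,
                                     motif_lengths = c(5, 19), seed = 2))
enc <- dsattn_pretrain(corpus$sequences, cfg$model, epochs = 2,
                       warmup_steps = 200, peak_lr = 1e-3, seed = 1)
enc
#> Masked-LM pre-trained encoder
#> <dsattn_config> l=128 f=64 h=2 layers=2 scales={5,10,20} classes=-
#> best validation loss 2.858 at epoch 2 (uniform baseline ln 22 = 3.091)

tr <- ds$split == "train"; va <- ds$split == "val"; te <- ds$split == "test"
fit <- dsattn(ds$sequences[tr], ds$labels[tr], cfg$model, encoder = enc,
              epochs = 3, initial_lr = 1e-3,
              validation = list(x = ds$sequences[va], labels = ds$labels[va]),
              seed = 1)

mean(predict(fit, ds$sequences[te]) == as.character(ds$labels[te]))
#> [1] 1
```

Held-out masked cross-entropy 2.86 beats the uniform-over-22-tokens
baseline ln 22 ≈ 3.09, and the fine-tuned classifier separates the two
motif classes perfectly. Now ask where the model looked:

```r
ann <- ds$annotations[ds$annotations$seq_id %in% names(ds$sequences)[te], ]
set.seed(1)
mr <- match_rate(fit, ds$sequences, ann, n_perm = 20)
c(observed = mr$observed, baseline = mr$baseline)
#>  observed  baseline
#>    0.0900    0.0105
```

9% of planted ground-truth annotations satisfy the full match criterion
(closest kernel *and* 1.5× central margin) against a ~1% chance level
under random relocation; across fine-tuning seeds the observed rate
averages ~0.40 (individual seeds range from 0.09 to 0.59 — see the
vignette on alignment symmetry). `dsattn_explain()` returns the `W`
matrix and margin `v` for a single sequence, `plot()` draws them, and
`write_explanation()` emits the per-position TSV report.

A command-line front end covering `simulate`, `pretrain`, `finetune`,
`predict`, `evaluate` and `explain` ships at `inst/cli/dsattn.R`.

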