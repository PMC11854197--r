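# igfuse

Dual-channel text classification with information-gain feature fusion, in R.

## What this is for

Clinicians and platform-safety researchers increasingly screen short
social-media posts (microblogs of a few dozen characters) for expressions
of suicidal ideation. The signal is carried both by *local* cues — single
high-risk words and short phrases — and by *sequential context* — how the
post unfolds. igfuse implements a classifier built around that observation:

* a **TextCNN channel** — parallel valid convolutions with several kernel
  sizes, ReLU, max-over-time pooling — extracts local n-gram features
  `x = p_1 ⊕ … ⊕ p_K`;
* a **BiLSTM channel** — independent forward/backward gated recurrences —
  produces per-timestep context vectors `H_t = [h_t→ ; h_t←]`;
* an **information-gain fusion network** weights each local dimension and
  each context timestep by its normalized information gain about the label
  (`w_i = IG(x_i)/Σ IG`), projects both channels to a common width, and
  pools the fused sequence with learnable-query attention
  (`score_t = qᵀ tanh(W F_t + b)`, `α = softmax(score)`,
  `c = Σ_t α_t F_t`);
* a **sigmoid head** turns `c` into `P(y = 1 | text)`; the label is
  positive iff the probability strictly exceeds 0.5.

Training is mini-batch Adam on binary cross-entropy over a stratified 80/20
split. The whole network, including backpropagation through time, is
implemented in R; no deep-learning runtime is required. Around the model the
package ships the full microblog preprocessing pipeline (HTML/URL/emoji
stripping, hashtag/mention/repost removal, length filtering, pluggable
segmentation, frequency-ranked vocabulary), a seeded synthetic-corpus
generator with planted lexical signal and a closed-form Bayes-accuracy
yardstick, evaluation metrics including a normalized prediction-entropy
confidence score `1 − mean(H₂(p_i))`, and corpus-level lexical analytics
(per-word information gain and signed log-likelihood-ratio keyword
contrast).

Everything is tidyverse-native: corpora and reports are tibbles, models have
`tidy()`/`glance()`/`autoplot()` methods, and the stages compose with the
pipe.

## Worked example

```r
library(igfuse)
library(tibble)

# a corpus with one planted signal word: present in 90% of positive and
# 10% of negative documents, so the Bayes-optimal accuracy is 0.9
spec <- corpus_spec(
  n_docs = 600, doc_length = c(5, 40),
  signal_words = tibble(word = "despair", p_pos = 0.9, p_neg = 0.1),
  seed = 42)
corpus <- generate_corpus(spec)
bayes_optimal_accuracy(spec)
#> [1] 0.9

prepped <- prep_corpus(corpus)   # clean, length-filter, tokenize
sum(prepped$kept)
#> [1] 581

cfg <- igfuse_config(
  vocab = list(n_top = 600),
  embedding = list(dim = 24, max_len = 44),
  cnn = list(kernel_sizes = c(2, 3), filters = 12),
  rnn = list(hidden = 16),
  idfn = list(fused_dim = 32, attn_dim = 16, ref_samples = 256),
  head = list(hidden = 8),
  train = list(lr = 0.005, epochs = 8))
model <- train_model(prepped, cfg, seed = 1)
model
#> <igfuse_model> vocab 502+2, emb 24, kernels (2, 3) x 12 filters,
#>   16 LSTM units/dir, fused dim 32, standard head
#>   final epoch loss 0.0613, train accuracy 0.989

test_docs <- prepped[prepped$doc_id %in% model$split$test_ids, ]
evaluate_model(model, test_docs)
#>     n  accuracy precision    recall        f1       auc entropy_score
#> 1 117 0.9230769 0.9433962 0.8928571 0.9174312 0.9118852      0.654245
```

Held-out accuracy (0.923) sits at the 0.9 Bayes optimum for this generator
(sampling noise of a 117-document test set); the entropy confidence score
says the model is fairly decisive. The planted word dominates the lexical
analytics:

```r
word_ig(prepped)
#> # A tibble: 502 × 6
#>   word    docfreq_pos docfreq_neg     ig   llr  rank
#> 1 despair      0.881       0.105  0.493  397.      1
#> 2 wafl         0.0722      0.0132 0.0170  13.7     2
#> ...
```

`autoplot(model)` draws the training history, `tidy(model)` exposes the
frozen fusion weights, and `autoplot(word_ig(prepped))` charts the
class-discriminative vocabulary.

A command-line wrapper over the same functions lives at
`inst/cli/igfuse.R`:

```sh
Rscript inst/cli/igfuse.R generate --seed 21 --out corpus.jsonl
Rscript inst/cli/igfuse.R prep --input corpus.jsonl --output clean.jsonl
Rscript inst/cli/igfuse.R train --corpus clean.jsonl --out model
Rscript inst/cli/igfuse.R evaluate --model model --corpus clean.jsonl --report report.json
```

Every stage writes a deterministic run manifest (config snapshot, seed,
input/output digests); identical configuration and seed reproduce every
artifact byte for byte.

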