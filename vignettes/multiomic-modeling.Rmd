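---
title: "Multi-omic masked language modeling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-omic masked language modeling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(momlm)
```

momlm is a desk-scale framework for studying one question: what does a single
transformer encoder learn when it is pretrained by masked language modeling
(MLM) jointly on protein and nucleic-acid sequences, and how does that joint
pretraining pay off on tasks that genuinely need both modalities — above all,
predicting the Gibbs free energy (dG, kcal/mol) of a protein-nucleic acid
binding interaction? Everything runs on one CPU in minutes, on synthetic data
with known ground truth, so every claim the package makes is testable
end-to-end.

## The model

The encoder is a pre-normalization transformer with a gated (SwiGLU-style)
feed-forward block, full non-causal self-attention, and rotary position
embeddings (RoPE, base 10000) applied to queries and keys, so attention
logits depend on relative offsets only. Two deliberate choices follow the
maximal update parameterization (muP):

* pre-softmax attention scores are scaled by `1/head_dim`, not
  `1/sqrt(head_dim)`;
* embeddings are initialized at width-independent scale and trained at a
  fixed rate (0.05), while all other parameters are initialized at variance
  `1/fan_in` (residual output projections additionally shrunk by
  `1/(2 n_layers)`) and trained at `0.05 * 32/width`.

The practical consequence, checked in the test suite, is that the residual
stream's activation scale and the optimal base learning rate are
approximately width-independent, so hyperparameters found on a small model
transfer to a wider one. The unembedding starts at zero, which makes the
initial MLM loss exactly `ln(vocab_size)` — a useful anchor for every
training run.

Tokenization is modality-disjoint: protein and nucleic sequences get
separate vocabularies (byte-pair encoded or single-character) whose id
ranges never overlap, so the string "ACGT" tokenizes differently as DNA and
as peptide. Every token carries its half-open character span; the four exact
residue/token transforms (mode/mean aggregation, duplication broadcast, and
the two contact-map transforms) are built on those spans and are verified
against brute-force references.

During pretraining, context rows are packed from same-modality sequences
only (cls at the row start, sep between sequences); the two modalities meet
only through the shared parameters, never inside one attention window.
Corruption follows the standard MLM recipe: rate 0.15, of which 80% becomes
the mask token, 10% a random in-modality piece, 10% unchanged. AdamW uses
betas (0.9, 0.95), eps 1e-8, weight decay 1e-2; all rates follow a one-cycle
schedule from scale 1e-5 up to 1 at the warmup peak and back down to 1e-5
(cosine ramps; only the endpoints and the peak are contractual).

## Fine-tuning heads

For dG regression, the input layout is `[cls] protein [sep] nucleic
([sep] second strand)`; a linear head reads the first-token embedding.
Training minimizes mean squared error with three learning-rate groups —
head 1e-2, embeddings 1e-3, all other parameters `1e-4 * 1024/width` — each
one-cycle decayed, for 64 epochs at batch size 256 by default. The
dual-encoder single-omic control encodes protein and nucleic sequences with
two separately pretrained encoders and concatenates their pooled embeddings
before the linear head; it is fine-tuned end-to-end with the same groups (a
choice: the published description does not say whether the control's
backbones stay frozen, and end-to-end is the stronger control).

Per-residue contact tagging applies a linear projection plus sigmoid to
every protein-position hidden state (nucleic tokens take part in attention
but receive no predictions), trained with binary cross-entropy for 32
epochs. With subword vocabularies, labels are coarsened to token space by
per-span mode and predictions broadcast back by duplication. The pairwise
contact head projects positions to 128 dimensions, builds the 256-channel
pair tensor by concatenation, and maps it through an 8-conv-layer residual
network (input conv to 32 channels, three 2-conv blocks, output conv; this
block layout is a design choice — the source description fixes only "8-layer
ResNet"); its loss is masked to residue pairs at least 12 apart.

## The two probes

**Contrastive modality-invariance probe.** Frozen pooled embeddings of genes
(X) and their translated proteins (Y) are projected by a rank-16 linear map
W (k = 16 < d/4 enforced) and compared by cosine similarity at temperature
0.07; the loss averages row-wise and column-wise cross-entropies of the
similarity matrix with the diagonal as correct labels. The probe trains with
AdamW at lr 0.01, linearly decayed over 10000 steps, on 5% of pairs, and is
evaluated on the held-out 95% by the AUROC of matched vs. mismatched
similarity. The single-omic control trains *two* projections (one per
modality) on embeddings from two separately pretrained encoders — a
deliberately looser parameterization that still fails if the two embedding
spaces share no structure.

**Frozen-attention convolutional probe.** All layer-by-head attention maps
of one forward pass are stacked into a channels x L x L tensor and fed to a
four-layer 3x3 convolutional net (channels -> 64 -> 64 -> 64 -> 1,
same-padded with zeros — padding is a design choice); the final map is
averaged over its last axis into L logits and a sigmoid yields per-residue
contact probabilities. The probe trains for 1000 steps with AdamW at lr
1e-3, linearly decayed, with the backbone entirely frozen.

## What the synthetic data emulates

The generators are the package's study conditions; their defaults were fixed
at design time and all experiments below run at these values.

**Gene-protein pairs** (`gen_gene_protein_pairs`): uniform random proteins
of 20-40 residues; genes assembled from uniformly sampled synonymous codons
(standard genetic code), GT..AG-bounded random introns inserted after codons
at rate 0.15, and a trailing stop. Translating the concatenated exons
reproduces the protein exactly, which an independent codon-table walker
verifies. What this does *not* emulate: codon-usage bias, realistic
exon/intron length distributions, or GenBank-scale compositional structure —
so a passing alignment probe shows the mechanism exists, not that it reaches
the strength seen with models trained on real corpora.

**Binding energy model** (`gen_binding_dataset`): proteins come in families
(default 6 families x 8 proteins of length 20); each protein starts with a
4-residue family tag followed by random residues, so family identity is
learnable from sequence while within-family identity stays low enough
(~25%) that the homology pin rule at normalized score 1.5 does not sweep
whole families out of the test folds. Each family f has a baseline energy
and a penalty matrix over a width-8 site: the consensus base costs 0, every
other base a uniform 0.25-1.75 kcal/mol penalty, so the consensus is
provably the strongest binder. Baselines are the evenly spaced quantiles of
N(-10, 2^2) kcal/mol, randomly assigned to families: with only a handful of
families, i.i.d. draws make the *realized* between-family spread — and with
it the recovery task's difficulty — swing wildly between seeds, whereas the
quantile design keeps difficulty stable while the assignment still
randomizes. By
default all families share one consensus: the site sequence alone then
carries no family information, and the family-by-site interaction term is
genuinely non-additive across modalities — the structural reason a joint
encoder should beat two single-omic encoders whose pooled embeddings enter
a linear head additively. Sites are sampled near the consensus (per-position
retention 0.7, 8 per protein) and labels get Gaussian noise (sigma 0.5
kcal/mol in the main study). Two planted point-mutant near-duplicates
exercise the pinning rule. The closed-form energy makes exact ddG oracles
available to the mutation-scan tests.

**Contact data** (`gen_contact_dataset`): one planted RKR motif per protein,
contacts = motif positions dilated by one residue; at the default length 17
the positive rate is exactly 5/17 = 0.294. Coordinate mode places protein
CA atoms on a 12-Angstrom grid with one nucleic phosphorus atom 3-7.5
Angstrom from each contacting residue, so 8-Angstrom distance labeling
reproduces the planted labels exactly. The geometry is deliberately toy —
it validates the labeling pipeline, not structural realism.

## Study conditions and problem sizes

Chosen once for a single-CPU desk budget and documented here as the
package's own scale:

* **dG recovery**: the binding dataset at 6 families x 8 proteins x 8 sites
  (about 400 complexes over 50 proteins, site fidelity 0.8), 10 folds with
  folds 1-3 trained and evaluated; the reported statistic is the median of
  the three per-fold held-out correlations (each fold's model carries its
  own calibration, so per-fold correlations are summarized rather than
  computed on pooled predictions, and the median is robust to the
  occasional fold whose few test proteins span little energy range).
  Encoder width 256, 2 layers, head_dim 32; MLM pretraining budget 1.5e5
  tokens (batch 1024, warmup 10%); fine-tuning 24 epochs at minibatch 8 —
  the small minibatch keeps the optimizer step count near the published
  fine-tune step budget (at minibatch 256 this dataset would collapse to a
  few dozen steps and nothing would train), and longer training at this
  dataset size only memorizes label noise.
* **joint vs. dual control**: a 5x5x8 dataset with baseline sd 1.0 kcal/mol
  (interaction-dominant energetics — the synergy comparison is informative
  only when the family-by-site term carries real weight; the dataset must
  also be large enough that the joint encoder does not simply overfit, at
  which point the additive dual control wins by default), width-64
  backbones (one joint, one protein-only, one nucleic-only, equal 3e4-token
  budgets), five fine-tune repetitions at minibatch 12 with paired seeds on
  the same fold.
* **alignment probe**: 300 gene-protein pairs, width-128 backbones (so
  k = 16 < d/4), 1.2e5-token budgets, probe trained 10000 steps on 5% of
  pairs, five paired train/test splits. Embeddings are mean-pooled final
  hidden states: the leading special token receives no direct
  masked-language-model gradient, so its vector is a poor summary for
  frozen-embedding probing, while the mean carries the learned
  representation of the whole sequence. At this pretraining scale the
  joint-over-dual advantage is small and not reliable across seeds — the
  shared-parameter mechanism needs far more pretraining before a rank-16
  probe can detect a stable modality-invariant subspace, and the package
  reports the comparison without claiming otherwise.
* **attention probe**: 192 records at protein length 8 (input length 13),
  width-64/2-head backbone (4 attention channels), probe batch 8 for 1000
  steps, input channels z-scored on the training stacks. The planted signal
  is each protein row's attention mass above the uniform value on one
  channel; rows in the top and bottom 35% are labeled and the middle 30%
  band is excluded so the rule has a decision margin (a margin-free median
  split makes held-out errors concentrate at the boundary and measures
  calibration, not signal recovery; and with far fewer records the probe
  simply memorizes its training stacks). The shuffled control is scored by
  its best-threshold F1 against the analytic ceiling 2p/(1+p).

## Numerical choices and degenerate inputs

RMSNorm uses eps 1e-8; softmax rows subtract their max; padded positions are
masked with additive -1e30 and excluded from every loss; Pearson/Spearman
correlations of constant vectors are reported as 0 with a warning, as is F1
with no positives anywhere; mode aggregation breaks ties toward the lowest
class id; consensus extraction breaks count ties alphabetically (A < C < G
< T); mutation scans resample until mutants are unique and differ from the
consensus (the raw binomial process is available via `force_change = FALSE`
for calibration checks); alignment normalization divides by alignment
length, which makes identical-sequence scores equal the mean self-
substitution score of their composition; gap costs default to open 11 /
extend 1 in the affine convention where a length-k gap costs open +
k*extend. The backward pass of every trainable component is verified against
central finite differences.

## Known limitations

The encoder trains in plain double-precision R with materialized attention
maps: fine for widths up to a few hundred and contexts of a few hundred
tokens, not for anything larger. The synthetic binding model is additive
per position given the family — real protein-nucleic acid energetics are
not — so recovery results demonstrate correctness of the machinery, not
biological transferability. Directional comparisons (joint vs. dual,
fine-tuned vs. base attention) are run at small sample sizes where
individual repetitions are noisy; conclusions rest on the paired means.
Headline numbers from large pretrained models on external binding, motif
and structure databases are out of reach at this scale by design; the
package provides the harnesses that would compute them.
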