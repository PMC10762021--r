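---
title: "Methods: transformer-based exon-level CNV calling from read depth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transformer-based exon-level CNV calling from read depth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Whole-exome sequencing covers only the captured exons, so copy-number
variants (CNVs) must be inferred from the read-depth signal over scattered
short intervals. cnvformer treats each capture target (exon) as one
classification problem: given the standardized per-base read depth across
the exon, its chromosome, and its absolute genomic coordinates, predict
deletion (DEL), duplication (DUP) or no-call (NOCALL). There is no matched
control sample and no segmentation heuristic; segments arise only afterwards
by merging consecutive same-call exons.

The classifier is a transformer encoder:

* **Depth embedding.** Each standardized depth value $x_j$ is lifted
  position-wise into $\mathbb{R}^H$ by one affine map $W x_j + b$
  ($W \in \mathbb{R}^{H\times 1}$). Standardization uses the global mean and
  standard deviation of per-base depth in the training corpus; these two
  numbers are stored in the model bundle and reused verbatim at inference.
  Zero-depth bases inside covered exons are included in the statistics
  (the convention is declared, since either choice is defensible).
* **Chromosome-specific classification token.** A learned matrix
  $C \in \mathbb{R}^{H \times 24}$ holds one token per chromosome (X = 23,
  Y = 24). The token for the exon's chromosome is prepended to the embedded
  sequence and its final state is the only input to the classification
  head, so chromosome identity conditions every call.
* **Absolute-coordinate positional encoding.** Interleaved
  $\sin(\mathrm{loc}/10^{9\cdot 2k/H})$ and $\cos(\mathrm{loc}/10^{9\cdot 2k/H})$
  rows, with the token slot at $\mathrm{loc}=0$ and the unpadded depth
  columns assigned locations spaced linearly from the exon start to its end.
  The $10^9$ base keeps genomic coordinates up to ~290 Mb on distinct
  phases, which a 1..1001 column index would never need — this is why the
  encoding consumes absolute coordinates rather than column positions.
* **Encoder blocks.** $L$ pre-norm residual blocks,
  $O' = \mathrm{MHA}(\mathrm{LN}(O)) + O$ followed by
  $O_{\ell} = \mathrm{MLP}(\mathrm{LN}(O')) + O'$, with exact softmax
  multi-head attention and a key-padding mask. At sequence lengths of at
  most 1001 tokens exact attention is affordable and better defined than
  kernel approximations; a kernel backend could be added behind the same
  contract.
* **Head.** Two affine layers with a GELU between them, then softmax over
  the three classes; the call is the arg-max. An optional `min_call_prob`
  demotes low-confidence DEL/DUP arg-maxes to NOCALL (off by default: pure
  arg-max).

Full-scale defaults are $H = 192$, $L = 3$, 8 heads and a maximum encoded
exon length of 1000 bp. Exons longer than the maximum fall back to their
nonzero-depth positions in genomic order; when even those do not fit, the
exon is treated as depth-less and resolved by the 3-nearest-neighbour vote.

### Choices the published description leaves open

Several details are not pinned down by the architecture as published; the
package resolves them as follows.

* The head reads the token column (column 0). Only one token is ever
  concatenated, so indexing the final state "by chromosome number" is read
  as notational shorthand for reading the token state; chromosome identity
  enters through *which* token vector was placed there.
* Sine rows sit on even feature indices and cosine rows on odd ones,
  sharing the frequency $10^{9\cdot 2k/H}$ — the standard interleaving, with
  the base swapped from $10^4$ to $10^9$.
* The positional encoding is added to the full matrix including the token
  column (at $\mathrm{loc} = 0$), and padded columns also receive an
  encoding; they are attention-masked, so their content is irrelevant (this
  equivalence is exact and tested: the implementation simply never
  materialises padded columns).
* Hidden widths of the encoder MLP and the head are unstated; both default
  to $H$.
* The loss is unweighted 3-class cross-entropy (optional class weights are
  exposed because NOCALL dominates real label distributions); no dropout.
* The pad sentinel −1 is applied after standardization. It is a mask
  marker, not a depth value; nothing downstream reads it.

## Training and fine-tuning

Training uses Adam with Xavier initialization, cosine-annealed learning
rate (annealed per optimizer step over the configured epoch budget, no warm
restarts) and a fixed epoch budget — "converged in N epochs" is treated as
a budget, not an early-stopping rule, for reproducibility. The full-scale
default learning rate is 5e-5 with batch size 256.

The desk-scale experiments in this package use a scaled-down model
($H = 32$, $L = 2$, 4 heads, `max_len` 200) trained at learning rate 1e-3
with batch size 32: at 2000 exons a full training run is ~1000 optimizer
steps, where 5e-5 barely moves a fresh initialization; 1e-3 is the
conventional small-model Adam regime. Exon lengths in these experiments are
clamped to 50–180 bp so every exon fits `max_len = 200` directly — the
scaled-down analogue of real capture designs against the 1000 bp input
window.

Fine-tuning continues training of a trained model on a small labelled set
(expert-curated or somatic regimes), with the same optimizer; provenance
records the base-model hash. Training labels for interval truth sets are
assigned per exon by the majority-base rule (the class covering most of the
exon's bases; exact ties and non-overlap give NOCALL).

## Depth-less exons and segments

About a fifth of real capture targets carry no read depth. Each such exon
receives the majority call among its 3 genomically nearest *model-called*
exons on the same chromosome (midpoint distance, distance ties toward the
lower start coordinate; imputed records never vote). A 1/1/1 split is
NOCALL; chromosomes with fewer than 3 called exons vote among what exists.
NOCALL participates in the vote because it is one of the three prediction
classes, and the conservative tie rule matches the evaluation convention.

Consecutive exons (adjacency in the sorted target list, regardless of gap
size) sharing a DEL or DUP call merge into one segment; an optional
`gap_cap` breaks runs across large gaps for users who prefer
distance-bounded segments.

## Evaluation

The evaluation unit is the exon. Per-class precision is TP/(TP+FP); recall
divides by the truth totals; *overall* precision and recall are unweighted
(macro) means over DEL and DUP; each class's F1 is the harmonic mean of its
own precision and recall; the overall F1 is the harmonic mean of the
overall precision and overall recall — not the mean of per-class F1 scores
(the two published benchmark tables are consistent with the former and
contradict the latter). NPA (specificity) and NPV use the standard
one-vs-rest definitions with true negatives being the exons where neither
side makes that call; they are macro-averaged the same way. Zero
denominators report 0 with a warning so reports remain comparable.
Segment-level callers are compared by projecting their segments onto the
exon universe (≥1 bp overlap takes the segment's call, conflicts by
majority base, exact ties NOCALL), and integer copy numbers discretize as
>2 DUP, <2 DEL, =2 NOCALL. Merged predicted segments are scored against the
consensus (majority-base) label of the truth calls they cover; NPA/NPV are
undefined at segment resolution (no finite no-call universe) and reported
as `NA`.

## The simulator

`simulate_sample()` emulates the depth signal the classifier consumes, not
the sequencing process: log-normal exon lengths (median ~150 bp, clamped to
50–4000 bp by default) and inter-exon gaps; negative-binomial per-base
depth around a 50x diploid mean (dispersion 10 by default — real WES depth
is overdispersed; Poisson is the dispersion→∞ limit); CNV events initiating
at 5% of exons per class and spanning a geometric number of consecutive
exons (mean 3); heterozygous multipliers 0.5x/1.5x with a 5% homozygous
fraction (0x/2x); 20% of exons emitted with no depth rows; and a 5-base
moving average so breakpoints appear as sharp shifts over locally
correlated noise. Event boundaries default to the flanks of the boundary
exons (`breakpoint_mode = "gap"`), the situation of truth intervals
reported at capture resolution; `breakpoint_mode = "exon"` draws the
boundaries uniformly inside the boundary exons, producing within-exon depth
steps and majority-base boundary labels. Cohorts share one capture design
with independent per-sample events; every sample is byte-reproducible from
its seed.

What the simulator does *not* emulate: GC and mappability bias, capture
batch effects, probe-level coverage profiles, allele-specific signals, or
read-level artefacts. Passing the in-silico experiments therefore shows
that the architecture, training loop and evaluation machinery recover
implanted multiplicative depth shifts under overdispersed noise — it does
not certify performance on real exomes, where the hard part is precisely
the structured noise omitted here.

## Desk-scale experiments and their honest limits

`benchmark_label_recovery()` is the principal experiment: a two-sample
cohort (2 chromosomes × 1000 exons), training on one sample and exon-level
evaluation on the other, depth-less exons imputed. Held-out macro F1
(mean of DEL and DUP F1) lands around 0.91: the residual is dominated by
depth-less exons inside short events, which the 3-NN vote cannot recover
when no called neighbour shares the event — with 20% missing depth and
mean event span 3 this bounds recall near 0.89 even for a perfect
classifier.

`benchmark_finetune_gain()` measures the somatic-style transfer (3.0x
duplications at 15% rate, 100 fine-tuning exons, 5 epochs). Under this
simulator the measured gain is ~0: the base model already classifies every
encodable exon of the shifted regime correctly, because a 3.0x duplication
lies *further* from its learned decision boundary than the 1.5x training
duplications, and the remaining deficit is imputation, which weights cannot
change. The shift direction that genuinely degrades a trained model is
boundary-ward — e.g. 0.7x deletions against a 0.5x-trained model — and
there fine-tuning does produce a strict held-out improvement (tested in the
training test suite). The transfer machinery is exercised either way; the
flat gain under the away-from-boundary shift is a property of the
separable simulation, not of the fine-tuning code.

`benchmark_breakpoint_localization()` trains on the within-exon-breakpoint
regime and asks how often the relevance arg-max falls within ±25 bp of a
single implanted 0.5x step in fresh 200 bp exons. Relevance maps
concentrate near the step (arg-max typically a few tens of bases from it;
the large majority of cases fall within ±50 bp) but the strict ±25 arg-max
rate is near 50%, not the 80% one might hope for: the classifier integrates
region-level evidence, so its attention is not forced to sharpen onto the
edge itself. This mirrors the caution that relevance ranges *may* —
not must — correspond to breakpoints.

## Explainability

`relevance_map()` implements gradient-weighted attention relevance for
softmax attention: per block, the post-softmax attention maps are weighted
by their gradients with respect to the target-class score, clipped at zero,
averaged over heads (gradient weighting, because a plain head average is
noisy), and accumulated as $R \leftarrow R + \bar{E}R$ starting from the
identity; the token row of $R$ scores the depth positions. Padded positions
score exactly 0 and the map is max-normalised. The map is class-conditional:
DEL- and DUP-targeted maps for the same exon generally differ. A
`from_block` argument restricts accumulation to later blocks; the default
uses all blocks, which localized strictly better in our measurements.

## Numerical and degenerate-input conventions

* Layer norm uses $\varepsilon = 10^{-5}$; softmax subtracts the row max.
* Non-finite activations or losses abort with the offending block or
  epoch/batch named.
* BED inputs are 0-based half-open; depth tables are 1-based positions
  (the common depth-tool dialect), converted on read. Unknown contigs are
  skipped with a count, not fatal, because the model defines tokens for 24
  chromosomes only.
* Empty depth vectors error; all-zero exons are flagged `no_depth`;
  single-base exons are legal (the location vector degenerates to the
  start coordinate).
* Exactly tied majority votes and coverage counts resolve to NOCALL at
  every layer (labels, projection, consensus, 3-NN), keeping all tie
  handling conservative and mutually consistent.
* All randomness (simulation, initialization, shuffling, subsampling) is
  seeded; training is deterministic for a fixed seed and thread count, and
  model bundles round-trip bit-exactly (weights as raw doubles, metadata as
  full-precision JSON).
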