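---
title: "Methods: sitewise mutation-selection models for antibody sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sitewise mutation-selection models for antibody sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette records the modeling assumptions, parameter choices, and
numerical decisions behind `abselect`, so that results produced with the
package can be interpreted (and criticized) without reading the source.

## The model

### Data unit: parent-child pairs

Affinity maturation data arrive as clonal families: sets of B-cell receptor
sequences descended from one naive ancestor, related by a phylogenetic tree.
The package's unit of training data is the **parent-child pair (PCP)**: the
two codon-aligned nucleotide sequences at the ends of one tree edge, plus that
edge's branch length. `extract_pcps()` emits one PCP per edge and by default
drops (a) edges incident to the naive root, whose "parent" is an inferred
rather than observed sequence and which carry most of the phylogenetic
reconstruction error, and (b) pairs with identical parent and child, which
contain no substitution signal for the selection model (their effect on
branch-length calibration is handled separately; see *Known limitations*).

### Neutral mutation model

Somatic hypermutation (SHM) is modeled as an independent Poisson process per
nucleotide site `i` with rate `lambda_i` and, conditional on mutating, a
substitution distribution `s_i` over the three alternative bases. Over a
branch of length `t`, the probability that a parent codon becomes a given
child codon is the product over its three positions of `exp(-lambda_i t)`
(position unchanged) or `(1 - exp(-lambda_i t)) * s_i[b]` (position changed to
base `b`). `codon_probs()` exposes this per-codon distribution;
`neutral_codon_probs()` vectorizes it over a sequence.

Rates come from a **provider**: `table_provider()` holds one rate and
substitution row per site of a fixed reference (appropriate when all
sequences align to one naive sequence), while `kmer_provider()` looks up the
k-mer context around each site with a global fallback row for unseen or
edge-truncated contexts, and `estimate_kmer_rates()` fits such a table from
PCPs by the occurrence/mutation ratio `rate = -log(1 - mutations/occurrences)`
with add-one smoothing on the substitution distribution only. No claim is
made that the bundled estimators reach the fidelity of dedicated SHM
targeting models; the provider interface exists so a better neutral model can
be dropped in.

### Selection factors

Selection is a per-codon-site multiplicative factor `f_j > 0` on the neutral
probability of *nonsynonymous* substitution. With neutral codon probabilities
`p_{j,c}`, the mutation-selection probabilities are

* `m_{j,c} = p_{j,c} * f_j` for codons coding a different amino acid,
* `m_{j,c} = p_{j,c}` for synonymous alternatives,
* `m_{j,c} = 0` for stop codons (functional antibodies have none), and
* wild type absorbing the remainder so each site's distribution sums to one.

The aggregate nonsynonymous probability `m_j = f_j * sum(p_{j,c} nonsyn)` is
clamped just below one: the cap is `max((1 - 1e-6) - syn_j, 0)`, i.e. the
clamp constant *minus the synonymous mass*, so that the full 64-codon
distribution stays a valid probability vector even at extreme factors. For a
codon with no synonymous alternatives (e.g. ATG) the cap is exactly
`1 - 1e-6`. `mutsel_probs()` implements this and reports when the clamp was
active; persistent clamping during training is a sign the branch lengths and
factors are fighting, and the fit trace counts such events.

### Selection models

Three interchangeable parameterizations implement `predict_selection()`:

* `single_factor_model()` — one global factor; the classical dN/dS-style
  baseline.
* `per_position_model()` — one factor per alignment position; position-aware
  but content-blind.
* a **transformer encoder** (`build_selection_model()` with a
  `selection_model_config("transformer", ...)`) mapping the parent
  *amino-acid* sequence to one factor per site, so the factor can depend on
  sequence context, not just position.

No deep-learning runtime is available to this package, so the transformer is
implemented in plain R: a shared embedding over 20 amino acids plus a padding
token, fixed sinusoidal positional encodings, and post-norm encoder layers
(multi-head attention with key-padding mask, residual, LayerNorm, ReLU
feed-forward, residual, LayerNorm), followed by a scalar linear head. The
backward pass is hand-written and is verified against finite differences in
the test suite (max abs error ~1e-10). Ambiguous residues (`X`) are treated
as padding and produce `NA` factors; padded positions provably do not affect
real sites (asserted bit-exactly in tests).

Raw head outputs pass through the **wiggle activation**
`exp_wiggle(x, beta)`: `exp(beta * (x - 1))` below 1 and `x^beta` above 1,
with `beta = 0.3`. It keeps factors positive, is continuous and increasing,
and grows sub-linearly above one so diversifying selection cannot run away;
`beta` is treated as a fixed shape constant, not a fitted parameter.

### Training objective and branch lengths

The selection model is trained with **binary cross-entropy** on per-site
amino-acid substitution indicators: site `j` of a PCP contributes
`-log m_j` if the amino acid changed and `-log(1 - m_j)` otherwise
(`pcp_loss()`).

Branch lengths are *not* optimized against that loss. BCE carries no
synonymous signal, and on substitution-free pairs it would push `t` to the
boundary. Instead, each PCP's branch length minimizes the full codon-level
categorical negative log-likelihood of the observed child under the
mutation-selection distribution, in which synonymous substitutions anchor the
time scale (`optimize_branch_length()`). Only the product `lambda * t` is
identified; rescaling all rates rescales the branch lengths inversely and
leaves fitted factors unchanged (tested).

`fit()` alternates: (1) branch-length optimization for every PCP under the
current selection model, (2) recomputation of cached neutral nonsynonymous
sums, (3) one or more epochs of minibatch gradient training (RMSprop,
`alpha = 0.99`, `eps = 1e-8`, global gradient-norm clipping at 1, gradients
normalized by batch site count). PCPs sharing a parent sequence share one
forward/backward pass. The reported training loss per epoch is a *running
average over batches* (each batch evaluated under the weights of its moment),
whereas the validation loss is a full pass under the end-of-epoch weights, so
early in training the two are not directly comparable.

## Numerical choices

* Probabilities are floored at `1e-300` inside logs to avoid `-Inf` from
  underflow; a genuinely impossible observation (`m = 0` with an observed
  substitution) still reports `Inf` loss deliberately.
* LayerNorm uses `eps = 1e-5`; weights are initialized N(0, 0.02) from a
  per-model seed, so builds are reproducible.
* Branch-length optimization runs Brent's method on `log t` over the bracket
  `[1e-6, 5]` with tolerance `1e-8`; identical pairs pin to the lower bound
  and are flagged (`attr(t, "pinned")`). A bracketed solver needs no
  initialization heuristic.
* For speed, the neutral codon matrix is factored over the 8 patterns of
  changed/unchanged codon positions, making each likelihood evaluation
  O(sites x 8) instead of O(sites x 64); the factorization is tested to
  1e-16 against the direct matrix.
* Dropout (default 0.1) applies only during training; prediction is
  deterministic and bit-stable.

## Evaluation metrics

* `site_obs_exp()` aggregates, per aligned site (optionally through a
  user-supplied site map, e.g. IMGT numbering), observed amino-acid
  substitution counts and their analytic expectations `sum m_j`, with
  Bernoulli-sum standard deviations `sqrt(sum m_j (1 - m_j))`.
* `overlap()` is the histogram overlap `sum(min(o, e)) / (0.5 * (sum o + sum e))`,
  1 for perfect agreement.
* `log_factor_r2()` measures agreement of two models' log selection factors
  against the *identity line*, symmetrically in its arguments:
  `1 - sum((a - b)^2) / sum((a - g)^2 + (b - g)^2)` with `g` the pooled grand
  mean. Unlike a regression R-squared, it penalizes constant offsets and
  slope differences. Sites where either factor is 0 or masked are excluded
  and counted.
* `weighted_entropy()` reports Shannon entropy in bits of a (weighted) count
  vector or matrix.

## Synthetic data and study conditions

The generators exist so the whole pipeline can be validated end-to-end
without external repertoire data. They emulate the *shape* of the problem,
not immunological detail:

* `gen_naive()` draws stop-free random coding sequences (real naive sequences
  have V(D)J structure; none is claimed).
* `gen_tree()` draws random topologies with exponential branch lengths (real
  clonal families have expansion-skewed shapes).
* `gen_rate_table()` draws lognormal per-site rates (mimicking SHM hot/cold
  spots positionally, not by motif) and Dirichlet substitution rows.
* `gen_ground_truth()` provides analytic selection-factor families —
  `constant`, `sinusoid` over positions, and `context_rule` (hydrophobic
  residues A, C, F, I, L, M, V penalized by a factor, default 0.5) — chosen
  because they are exactly recoverable oracles; `context_rule` preserves the
  essential property that factors depend on sequence *content*.

Default study conditions, used throughout the tests and chosen by this
package to fit a one-CPU budget: 25-leaf trees, mean branch length 0.06,
unit mean neutral rate. The self-consistency check simulates 45,000 PCPs of
100 codons; the recovery experiment trains an 85,873-parameter transformer
(4 heads of dimension 12, 3 layers, feed-forward multiplier 4) on nested
datasets of 800 / 3,200 / 12,800 PCPs of 60 codons and evaluates
`log_factor_r2` against truth on a 200-sequence held-out panel.

## Known limitations

* The positional `table_provider` ties the neutral model to one reference
  alignment; the `kmer_provider` relaxes this, but the bundled k-mer
  estimator is a simple ratio estimator, not a calibrated SHM targeting
  model.
* Dropping identical pairs conditions the training sample on at least one
  substitution; at the branch lengths used here the induced bias in
  expected-count calibration is well under sampling noise, but it is a real
  conditioning effect.
* Simulation uses R's global RNG with a documented seeding discipline
  (byte-identical replay under one seed). There is no counter-based,
  per-edge RNG, so adding a tree to a dataset changes downstream draws.
* The naive/root sequence must be unambiguous for simulation; ambiguous
  codons in *observed* PCPs are handled (masked) throughout fitting and
  evaluation.
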