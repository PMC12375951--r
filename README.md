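# abselect

Sitewise mutation–selection models for antibody affinity maturation.

## The problem

During affinity maturation, B-cell receptor genes mutate at an unusually high
rate (somatic hypermutation, SHM) and the resulting variants are selected for
antigen binding. Given **parent–child pairs (PCPs)** — the sequences at the
two ends of an edge of a clonal-family tree — `abselect` separates those two
processes: a fixed *neutral* model describes how mutations arise, and a
fitted *selection* model describes which amino-acid changes survive.

The neutral model treats each nucleotide site `i` as an independent Poisson
process with rate `λᵢ` and substitution distribution `sᵢ`, so over a branch
of length `t` a parent codon moves to a child codon with probability

```
p(child | parent, t) = Π over the 3 positions of
    exp(-λᵢ t)              if the position is unchanged
    (1 - exp(-λᵢ t)) sᵢ[b]  if it changed to base b
```

Selection enters as one positive factor `f_j` per codon site: nonsynonymous
codon probabilities are scaled by `f_j` (clamped so each site's distribution
stays valid), synonymous ones are untouched, stop codons get probability 0,
and the wild type absorbs the remainder. `f_j > 1` is diversifying selection,
`f_j < 1` purifying. The factors come from an interchangeable model: a single
global factor, a per-position table, or a transformer encoder over the parent
amino-acid sequence (implemented in plain R, trained with hand-written
backprop). Training minimizes binary cross-entropy on per-site amino-acid
substitution indicators, alternating with per-PCP branch-length optimization
under the full codon likelihood (synonymous substitutions anchor the time
scale). Simulation down trees, goodness-of-fit metrics, and synthetic-data
generators complete the loop, so the whole pipeline is testable with no
external data. See the vignette
(`vignettes/mutation-selection-methods.Rmd`) for the full methods story.

## Worked example

Simulate a small dataset from an analytic ground truth (hydrophobic residues
purified with factor 0.5), fit the single-factor baseline, and check
calibration of the truth model:

```r
library(abselect)
set.seed(1)
truth <- gen_ground_truth(selection_spec("context_rule"))
ds <- simulate_dataset(400, truth, n_codons = 30, n_leaves = 10)
nrow(ds$pcps)
#> [1] 403

head(predict_selection(truth, aa_sequence(ds$naive)), 8)
#> [1] 1.0 1.0 0.5 1.0 1.0 0.5 1.0 0.5

st <- fit(ds$pcps, single_factor_model(), ds$provider,
          cycles = 2, epochs = 2, lr = 0.15, batch_size = 256,
          val_frac = 0, seed = 1)
st
#> train_state: 403 PCPs, 4 logged epochs; final train loss 0.306488

# the fitted global factor: a compromise between the 1.0 and 0.5 sites
exp_wiggle(st$model$params$theta, 0.3)
#> [1] 0.8623484

# observed vs expected per-site substitution counts under the true model
agg <- site_obs_exp(ds$pcps, truth, ds$provider)
head(agg, 3)
#>   group position observed expected       sd
#> 1   all        1       58 60.75192 6.807193
#> 2   all        2       43 43.44411 5.970066
#> 3   all        3       26 23.59827 4.623475

overlap(agg$observed, agg$expected)
#> [1] 0.9465977
```

(At this small size the overlap is noise-limited; it exceeds 0.99 by 20,000
PCPs.) To fit the context-sensitive model instead, replace the model
argument:

```r
cfg <- selection_model_config("transformer", heads = 4, d_head = 12, layers = 3)
st <- fit(ds$pcps, build_selection_model(cfg, seed = 1), ds$provider)
```

A command-line interface wrapping the same pipeline is installed at
`system.file("cli", "abselect", package = "abselect")` with subcommands
`extract-pcps`, `make-fixtures`, `simulate`, `fit`, `predict`, `evaluate`.

## Running the tests

```sh
NOT_CRAN=true Rscript -e 'testthat::test_dir("tests/testthat", package = "abselect", load_package = "installed")'
```

The suite includes the acceptance criteria (simulation self-consistency,
ground-truth recovery by the transformer with monotone improvement in
training-set size, baseline ordering, neutral-limit equivalence, oracle
checks, branch-length recovery, CLI determinism) and takes roughly 20
minutes on one CPU, most of it transformer training.

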