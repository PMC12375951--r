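test_that("mutation-selection composition scales only nonsynonymous codons", {
  set.seed(40)
  seq <- random_coding_seq(6)
  prov <- gen_rate_table(seq, mean_rate = 1)
  # keep t small so the doubled aggregate stays below the clamp cap
  ncp <- neutral_codon_probs(seq, prov, 0.08)
  # neutral limit: f = 1 reproduces neutral probabilities at non-stop codons
  ms1 <- mutsel_probs(ncp, rep(1, 6))
  stops <- is.na(abselect:::CODON_AA_IDX)
  expect_true(all(ms1$M[, stops] == 0))
  nonstop_nonwt <- !stops
  for (j in 1:6) {
    cols <- which(nonstop_nonwt)
    cols <- setdiff(cols, ncp$codon_idx[j])
    expect_equal(ms1$M[j, cols], ncp$P[j, cols], tolerance = 1e-12)
    # WT codon absorbs the stop mass
    expect_equal(ms1$M[j, ncp$codon_idx[j]],
                 ncp$P[j, ncp$codon_idx[j]] + sum(ncp$P[j, stops]),
                 tolerance = 1e-12)
  }
  # aggregate nonsynonymous probability scales linearly in f below the clamp
  ms2 <- mutsel_probs(ncp, rep(2, 6))
  expect_equal(ms2$m, 2 * ms1$m, tolerance = 1e-12)
  expect_equal(rowSums(ms2$M), rep(1, 6), tolerance = 1e-12)
  expect_error(mutsel_probs(ncp, rep(1, 5)), "does not match")
})

test_that("aggregate probabilities clamp a little below one", {
  # methionine codon: no synonymous alternatives, so the cap is the clamp
  prov <- uniform_provider(3, lambda = 5)
  ncp <- neutral_codon_probs("ATG", prov, 3)
  aa64 <- STANDARD_CODE[abselect:::CODONS]
  ns <- sum(ncp$P[1, aa64 != "M" & aa64 != "*"])
  f_big <- 2 / ns  # raw aggregate would be 2
  ms <- mutsel_probs(ncp, f_big)
  expect_equal(ms$m, 1 - 1e-6, tolerance = 1e-12)
  expect_true(ms$clamped)
  expect_equal(sum(ms$M[1, ]), 1, tolerance = 1e-12)
  expect_true(ms$M[1, ncp$codon_idx[1]] > 0)
})

test_that("binary cross-entropy loss matches the Bernoulli closed form", {
  set.seed(41)
  seq <- random_coding_seq(8)
  prov <- gen_rate_table(seq, mean_rate = 1)
  model <- single_factor_model(factor = 1.3)
  t <- 0.25
  # independently: per-site m and substitution indicators
  f <- predict_selection(model, paste(aa_sequence(seq), collapse = ""))
  ncp <- neutral_codon_probs(seq, prov, t)
  m <- mutsel_probs(ncp, f)$m
  child <- as.character(sample_child(seq, model, prov, t))
  y <- aa_sequence(seq) != aa_sequence(child)
  want <- -sum(ifelse(y, log(m), log(1 - m)))
  got <- pcp_loss(list(parent = seq, child = child), model, prov, t)
  expect_equal(got, want, tolerance = 1e-10)
  # worked closed-form values on constructed probabilities
  expect_equal(abselect:::.bce_terms(0.25, 0L, TRUE), -log(0.75),
               tolerance = 1e-12)
  expect_equal(abselect:::.bce_terms(c(0.25, 0.5), c(1L, 0L), c(TRUE, TRUE)),
               -log(0.25) - log(0.5), tolerance = 1e-12)
  # an impossible observed substitution surfaces as infinite loss
  expect_equal(abselect:::.bce_terms(0, 1L, TRUE), Inf)
})

test_that("branch lengths are recovered from neutral simulations", {
  set.seed(42)
  naive <- gen_naive(300)
  prov <- gen_rate_table(naive, mean_rate = 1)
  neutral <- gen_ground_truth(selection_spec("constant", value = 1))
  ts <- runif(40, 0.02, 0.3)
  rel_err <- vapply(ts, function(tt) {
    child <- as.character(sample_child(naive, neutral, prov, tt))
    tstar <- optimize_branch_length(list(parent = naive, child = child),
                                    neutral, prov)
    (as.numeric(tstar) - tt) / tt
  }, 0)
  expect_lt(median(abs(rel_err)), 0.1)
  expect_lt(abs(median(rel_err)), 0.1)  # no systematic bias
})

test_that("only the product of rate and branch length is identified", {
  set.seed(43)
  naive <- gen_naive(200)
  prov <- gen_rate_table(naive, mean_rate = 1)
  # same provider with doubled rates
  prov2 <- table_provider(2 * prov$lambda, prov$sub)
  neutral <- gen_ground_truth(selection_spec("constant", value = 1))
  child <- as.character(sample_child(naive, neutral, prov, 0.2))
  t1 <- optimize_branch_length(list(parent = naive, child = child),
                               neutral, prov)
  t2 <- optimize_branch_length(list(parent = naive, child = child),
                               neutral, prov2)
  expect_equal(as.numeric(t2), as.numeric(t1) / 2, tolerance = 1e-4)
})

test_that("a PCP with no substitutions pins to the minimum with a flag", {
  naive <- "ATGAAACCCGGG"
  prov <- uniform_provider(12)
  t <- optimize_branch_length(list(parent = naive, child = naive),
                              single_factor_model(), prov, lower = 1e-6)
  expect_equal(as.numeric(t), 1e-6)
  expect_true(attr(t, "pinned"))
})

test_that("training alternates, caches, and leaves cycles = 0 untouched", {
  set.seed(44)
  truth <- gen_ground_truth(selection_spec("constant", value = 1))
  ds <- simulate_dataset(150, truth, n_codons = 40, n_leaves = 10)
  model <- single_factor_model(factor = 0.8)
  st0 <- fit(ds$pcps, model, ds$provider, cycles = 0, val_frac = 0, seed = 1)
  expect_identical(st0$model$params, model$params)
  expect_length(st0$branch_lengths, nrow(ds$pcps))
  expect_true(all(st0$branch_lengths >= 1e-6 & st0$branch_lengths <= 5))
  st <- fit(ds$pcps, model, ds$provider, cycles = 2, epochs = 2,
            lr = 0.05, batch_size = 64, val_frac = 0.2, seed = 1)
  expect_equal(nrow(st$trace), 4L)
  expect_true(all(is.finite(st$trace$train)))
  expect_true(all(is.finite(st$trace$val)))
  # loss over cycles does not increase (within tolerance for SGD noise)
  percycle <- tapply(st$trace$train, st$trace$cycle, mean)
  expect_lt(percycle[length(percycle)], percycle[1] + 0.01)
  expect_error(fit(ds$pcps[0, ], model, ds$provider), "empty")
})

test_that("branch-length rescaling does not leak into selection factors", {
  set.seed(45)
  truth <- gen_ground_truth(selection_spec("constant", value = 1))
  ds <- simulate_dataset(250, truth, n_codons = 40, n_leaves = 10)
  fit_factor <- function(provider) {
    st <- fit(ds$pcps, single_factor_model(factor = 0.9), provider,
              cycles = 2, epochs = 2, lr = 0.05, batch_size = 64,
              val_frac = 0, seed = 3)
    exp_wiggle(st$model$params$theta, 0.3)
  }
  f_base <- fit_factor(ds$provider)
  # doubling every neutral rate halves every fitted branch length but the
  # synonymous signal anchors the factors
  f_scaled <- fit_factor(table_provider(2 * ds$provider$lambda,
                                        ds$provider$sub))
  expect_equal(f_scaled, f_base, tolerance = 0.02)
})
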