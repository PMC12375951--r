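test_that("wiggle activation matches its closed form", {
  expect_equal(exp_wiggle(1, 0.3), 1)
  expect_equal(exp_wiggle(1, 1.7), 1)
  expect_equal(exp_wiggle(2, 0.3), 2^0.3, tolerance = 1e-15)
  expect_equal(exp_wiggle(0, 0.3), exp(-0.3), tolerance = 1e-15)
  expect_equal(wiggle(2, 0.3), 0.3 * log(2))
  expect_equal(wiggle(0.5, 0.3), 0.3 * (0.5 - 1))
  # continuity at the branch point
  eps <- 1e-9
  expect_lt(abs(exp_wiggle(1 - eps, 0.3) - exp_wiggle(1 + eps, 0.3)), 1e-8)
  # strict monotonicity on a random grid
  set.seed(20)
  x <- sort(runif(200, -5, 5))
  expect_true(all(diff(exp_wiggle(x, 0.3)) > 0))
  expect_true(all(exp_wiggle(x, 0.3) > 0))
  expect_error(exp_wiggle(1, 0), "positive")
  expect_error(wiggle(1, -1), "positive")
})

test_that("baseline models give constant and positional profiles", {
  m <- single_factor_model(factor = 1)
  f <- predict_selection(m, "ACDEFGHIKLMNPQRSTVWY")
  expect_equal(f, rep(1, 20))
  expect_equal(n_parameters(m), 1L)
  # profile independent of sequence content
  expect_equal(predict_selection(m, "WWWWW"), rep(1, 5))
  pp <- per_position_model(max_len = 10, factor = 0.5)
  expect_equal(predict_selection(pp, "ACDEF"), rep(0.5, 5))
  expect_equal(n_parameters(pp), 10L)
  expect_error(predict_selection(pp, paste(rep("A", 11), collapse = "")),
               "exceeds")
  expect_error(predict_selection(m, "ACDB"), "unknown amino-acid")
  # ambiguous sites are masked
  expect_true(is.na(predict_selection(m, "AXC")[2]))
})

test_that("transformer construction is seeded and sized as configured", {
  cfg <- selection_model_config("transformer", heads = 4, d_head = 12,
                                layers = 3, ff_mult = 4, max_len = 128)
  m1 <- build_selection_model(cfg, seed = 5)
  m2 <- build_selection_model(cfg, seed = 5)
  expect_identical(m1$params, m2$params)
  m3 <- build_selection_model(cfg, seed = 6)
  expect_false(identical(m1$params, m3$params))
  # parameter count: embedding + 3 encoder layers + scalar head
  d <- 48; dff <- 192
  per_layer <- 4 * (d * d + d) + 2 * d + 2 * (d * dff) + dff + d + 2 * d
  expect_equal(n_parameters(m1), 21 * d + 3 * per_layer + d + 1)
  expect_error(selection_model_config("transformer", heads = 0), "heads")
  expect_error(selection_model_config(beta = -1), "positive")
})

test_that("transformer profiles are context-sensitive and deterministic", {
  cfg <- selection_model_config("transformer", heads = 2, d_head = 8,
                                layers = 2, max_len = 64)
  m <- build_selection_model(cfg, seed = 9)
  s1 <- "ACDEFGHIKLMNPQRSTVWY"
  s2 <- "ACDEFGHIKLMNPQRSTVWW"
  f1 <- predict_selection(m, s1)
  f2 <- predict_selection(m, s2)
  expect_length(f1, 20)
  expect_true(all(f1 > 0))
  # factors depend on the whole sequence, not only the position
  expect_false(isTRUE(all.equal(f1[1:19], f2[1:19])))
  # evaluation mode is bit-identical across calls
  expect_identical(f1, predict_selection(m, s1))
  # appending padding (ambiguous) sites never changes real-site factors
  f3 <- predict_selection(m, paste0(s1, "XXXX"))
  expect_identical(f1, f3[1:20])
  expect_error(predict_selection(m, strrep("A", 65)), "exceeds")
})

test_that("transformer backprop matches finite differences", {
  cfg <- selection_model_config("transformer", heads = 2, d_head = 3,
                                layers = 2, ff_mult = 2, dropout = 0,
                                max_len = 16)
  m <- build_selection_model(cfg, seed = 7)
  set.seed(42)
  tok <- abselect:::.aa_tokens("ACDKXLMW")
  cvec <- rnorm(length(tok))
  cvec[5] <- 0  # masked site contributes no gradient
  fw <- abselect:::.preactivation(m, tok, train = FALSE)
  g <- abselect:::.flatten_params(abselect:::.model_backward(m, fw$cache,
                                                             cvec))
  theta <- abselect:::.flatten_params(m$params)
  skel <- m$params
  lossfn <- function(th) {
    m2 <- m
    m2$params <- abselect:::.unflatten_params(th, skel)
    sum(cvec * abselect:::.preactivation(m2, tok, FALSE)$x)
  }
  eps <- 1e-6
  idx <- sort(sample(length(theta), 80))
  num <- vapply(idx, function(i) {
    tp <- theta
    tp[i] <- tp[i] + eps
    up <- lossfn(tp)
    tp[i] <- tp[i] - 2 * eps
    (up - lossfn(tp)) / (2 * eps)
  }, 0)
  expect_lt(max(abs(num - g[idx])), 1e-7)
})

test_that("batched passes agree with per-sequence passes", {
  cfg <- selection_model_config("transformer", heads = 4, d_head = 6,
                                layers = 2, dropout = 0, max_len = 64)
  m <- build_selection_model(cfg, seed = 11)
  set.seed(30)
  alphabet <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")
  seqs <- replicate(6, paste(sample(alphabet, 30, TRUE), collapse = ""))
  tokmat <- do.call(rbind, lapply(seqs, abselect:::.aa_tokens))
  fwb <- abselect:::.preactivation_batch(m, tokmat, FALSE)
  dxmat <- matrix(rnorm(30 * 6), 30, 6)
  gsum <- 0
  for (k in 1:6) {
    fw <- abselect:::.preactivation(m, tokmat[k, ], FALSE)
    expect_lt(max(abs(fw$x - fwb$x[, k])), 1e-12)
    gsum <- gsum + abselect:::.flatten_params(
      abselect:::.model_backward(m, fw$cache, dxmat[, k]))
  }
  gb <- abselect:::.flatten_params(
    abselect:::.model_backward_batch(m, fwb$cache, dxmat))
  expect_lt(max(abs(gb - gsum)), 1e-10)
})

test_that("model checkpoints round-trip through disk", {
  dir <- withr::local_tempdir()
  sf <- single_factor_model(factor = 1.7)
  save_selection_model(sf, file.path(dir, "sf"))
  expect_equal(predict_selection(load_selection_model(file.path(dir, "sf")),
                                 "ACD"),
               predict_selection(sf, "ACD"), tolerance = 1e-12)
  pp <- per_position_model(max_len = 7, factor = 0.3)
  save_selection_model(pp, file.path(dir, "pp"))
  expect_equal(predict_selection(load_selection_model(file.path(dir, "pp")),
                                 "ACDEF"),
               rep(0.3, 5), tolerance = 1e-12)
  gt <- gen_ground_truth(selection_spec("context_rule"))
  save_selection_model(gt, file.path(dir, "gt"))
  expect_identical(predict_selection(load_selection_model(
    file.path(dir, "gt")), "LSLS"),
    predict_selection(gt, "LSLS"))
  cfg <- selection_model_config("transformer", heads = 2, d_head = 4,
                                layers = 1, max_len = 32)
  tf <- build_selection_model(cfg, seed = 2)
  save_selection_model(tf, file.path(dir, "tf"))
  expect_identical(predict_selection(load_selection_model(
    file.path(dir, "tf")), "ACDEFGH"),
    predict_selection(tf, "ACDEFGH"))
})
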