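test_that("codon transition distribution matches brute-force enumeration", {
  set.seed(10)
  for (rep in 1:10) {
    lambda <- runif(3, 0, 2)
    sub <- matrix(rgamma(12, 1), 3, 4, dimnames = list(NULL, NT))
    parent <- sample(names(STANDARD_CODE), 1)
    pc <- match(strsplit(parent, "")[[1]], NT)
    for (i in 1:3) sub[i, pc[i]] <- 0
    sub <- sub / rowSums(sub)
    t <- runif(1, 0, 1.5)
    got <- codon_probs(lambda, sub, t, parent)
    want <- enumerate_codon_probs(lambda, sub, t, parent)
    expect_lt(max(abs(got[names(want)] - want)), 1e-12)
    expect_equal(sum(got), 1, tolerance = 1e-12)
  }
})

test_that("codon distribution degenerates correctly at t = 0", {
  lambda <- c(0.1, 0.2, 0.3)
  sub <- matrix(1 / 3, 3, 4)
  nt <- match(c("A", "T", "G"), NT)
  for (i in 1:3) sub[i, nt[i]] <- 0
  p <- codon_probs(lambda, sub, 0, "ATG")
  expect_equal(unname(p["ATG"]), 1)
  expect_equal(sum(p), 1)
  expect_error(codon_probs(lambda, sub, -1, "ATG"), "nonnegative")
  expect_error(codon_probs(lambda, sub, 1, "ATN"), "unambiguous")
  expect_error(codon_probs(c(0.1, 0.2), sub[1:2, ], 1, "ATG"), "length 3")
})

test_that("nonsynonymous profile sums the right codons", {
  prov <- uniform_provider(3, lambda = c(0.1, 0.2, 0.3))
  # t = 0: no mutation possible anywhere
  expect_equal(nonsyn_profile("ATG", prov, 0), 0)
  # single methionine codon: compare against the enumeration oracle
  p <- nonsyn_profile("ATG", prov, 1)
  rates <- neutral_rates(prov, "ATG")
  want <- enumerate_codon_probs(rates$lambda, rates$sub, 1, "ATG")
  nonsyn <- names(want)[STANDARD_CODE[names(want)] != "M" &
                          STANDARD_CODE[names(want)] != "*"]
  expect_equal(p, sum(want[nonsyn]), tolerance = 1e-12)
  # ambiguous codon masked; fully ambiguous profile warns
  prov6 <- uniform_provider(6)
  p2 <- nonsyn_profile("ATGNTT", prov6, 0.5)
  expect_true(is.na(p2[2]) && !is.na(p2[1]))
  expect_warning(nonsyn_profile("NNNNNN", prov6, 0.5), "masked")
})

test_that("neutral distributions stay normalized across random inputs", {
  set.seed(11)
  for (rep in 1:8) {
    L <- sample(2:20, 1)
    seq <- random_coding_seq(L)
    prov <- gen_rate_table(seq, mean_rate = runif(1, 0.2, 3))
    t <- runif(1, 0, 4)
    ncp <- neutral_codon_probs(seq, prov, t)
    expect_equal(rowSums(ncp$P), rep(1, L), tolerance = 1e-9)
    expect_true(all(ncp$P >= 0))
  }
})

test_that("small-t slope of the nonsynonymous profile is sum of single-hit rates", {
  set.seed(12)
  seq <- random_coding_seq(5)
  prov <- gen_rate_table(seq, mean_rate = 1)
  rates <- neutral_rates(prov, seq)
  h <- 1e-7
  slope_fd <- (nonsyn_profile(seq, prov, h) - nonsyn_profile(seq, prov, 0)) / h
  # analytic: sum over single-nucleotide nonsynonymous changes of lambda * s
  nt <- strsplit(seq, "")[[1]]
  slope <- numeric(5)
  for (j in 1:5) {
    for (pos in 1:3) {
      i <- 3 * (j - 1) + pos
      for (b in setdiff(NT, nt[i])) {
        mutated <- nt
        mutated[i] <- b
        codon <- paste(mutated[(3 * j - 2):(3 * j)], collapse = "")
        aa <- STANDARD_CODE[codon]
        parent_aa <- STANDARD_CODE[paste(nt[(3 * j - 2):(3 * j)],
                                         collapse = "")]
        if (aa != "*" && aa != parent_aa) {
          slope[j] <- slope[j] + rates$lambda[i] * rates$sub[i, b]
        }
      }
    }
  }
  expect_equal(slope_fd, slope, tolerance = 1e-5)
})

test_that("providers are deterministic and child-independent", {
  set.seed(13)
  seq <- random_coding_seq(10)
  prov <- gen_rate_table(seq, mean_rate = 1)
  r1 <- neutral_rates(prov, seq)
  r2 <- neutral_rates(prov, seq)
  expect_identical(r1, r2)
  expect_error(neutral_rates(prov, random_coding_seq(11)), "does not match")
})

test_that("k-mer rate estimation matches closed forms", {
  # context observed 6 times, mutated once: rate = -log(1 - 1/6)
  parent <- paste(rep("ACGTA", 6), collapse = "")
  child <- paste(c("ACTTA", rep("ACGTA", 5)), collapse = "")
  tab <- estimate_kmer_rates(pcp_table(parent, child), k = 5)
  row <- tab[tab$kmer == "ACGTA", ]
  expect_equal(row$rate, -log(5 / 6), tolerance = 1e-12)
  # substitution smoothing: counts (A:2, G:1, T:1) -> (3/7, 2/7, 2/7)
  parent2 <- paste(rep("AACGG", 9), collapse = "")
  kids <- c("AAAGG", "AAAGG", "AAGGG", "AATGG", rep("AACGG", 5))
  tab2 <- estimate_kmer_rates(pcp_table(parent2, paste(kids, collapse = "")),
                              k = 5)
  row2 <- tab2[tab2$kmer == "AACGG", ]
  expect_equal(row2$rate, -log(1 - 4 / 9), tolerance = 1e-12)
  expect_equal(unlist(row2[c("s_A", "s_G", "s_T")]),
               c(s_A = 3 / 7, s_G = 2 / 7, s_T = 2 / 7), tolerance = 1e-12)
  # a context never mutated has rate 0; smoothing applies to the
  # substitution distribution only
  never <- tab2[tab2$kmer == "ACGGA", ]
  expect_equal(nrow(never), 1L)
  expect_equal(never$rate, 0)
  expect_error(estimate_kmer_rates(pcp_table(parent, child), k = 4), "odd")
  expect_error(estimate_kmer_rates(pcp_table(character(0), character(0))),
               "no PCPs")
})

test_that("k-mer provider looks up contexts with global fallback", {
  tab <- data.frame(kmer = c("AACGG", "*"),
                    rate = c(0.5, 0.1),
                    s_A = c(0.6, 0.3), s_C = c(0, 0.1),
                    s_G = c(0.2, 0.3), s_T = c(0.2, 0.3))
  prov <- kmer_provider(tab)
  r <- neutral_rates(prov, "AAACGGTCC")
  # site 4 (0-based center of AACGG at positions 2..6) has the table rate
  expect_equal(r$lambda[4], 0.5)
  # edges and unseen contexts use the fallback
  expect_equal(r$lambda[1], 0.1)
  expect_equal(r$lambda[7], 0.1)
  # current-base mass is zero after renormalization
  nt <- strsplit("AAACGGTCC", "")[[1]]
  for (i in 1:9) expect_equal(unname(r$sub[i, nt[i]]), 0)
  expect_equal(unname(rowSums(r$sub)), rep(1, 9))
})

test_that("rate tables round-trip through TSV", {
  set.seed(14)
  seq <- random_coding_seq(4)
  prov <- gen_rate_table(seq, mean_rate = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rate_table(prov, path)
  back <- read_rate_table(path)
  expect_equal(back$lambda, prov$lambda, tolerance = 1e-15)
  expect_equal(back$sub, prov$sub, tolerance = 1e-15)
  # k-mer table round trip
  ktab <- estimate_kmer_rates(
    pcp_table("ACGTACGTACGTACG", "ACGTACTTACGTACG"), k = 3)
  kpath <- withr::local_tempfile(fileext = ".tsv")
  write_rate_table(kmer_provider(ktab), kpath)
  kback <- read_rate_table(kpath)
  expect_s3_class(kback, "kmer_provider")
  expect_equal(sort(names(kback$rate)), sort(ktab$kmer))
})
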