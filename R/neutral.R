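## Neutral somatic-hypermutation machinery: per-nucleotide Poisson rates
## composed into codon-level transition probabilities and per-codon-site
## nonsynonymous substitution probabilities.

## Probabilities below this are flushed to zero to avoid underflow in products.
.PROB_FLOOR <- 1e-300

## 20 x 64 logical: [a, c] TRUE when codon c codes an amino acid != a
## (stop codons excluded from every nonsynonymous sum).
NONSYN_MASK_BY_AA <- {
  m <- matrix(FALSE, 20L, 64L)
  for (a in seq_len(20L)) {
    m[a, ] <- !is.na(CODON_AA_IDX) & CODON_AA_IDX != a
  }
  m
}

## 20 x 64 logical: [a, c] TRUE when codon c codes amino acid a
SYN_MASK_BY_AA <- {
  m <- matrix(FALSE, 20L, 64L)
  for (a in seq_len(20L)) m[a, ] <- !is.na(CODON_AA_IDX) & CODON_AA_IDX == a
  m
}

#' Per-nucleotide neutral rates
#'
#' Bundles, for each nucleotide site `i` of a parent sequence, the Poisson
#' mutation rate `lambda[i]` (events per unit branch length) and the
#' conditional substitution distribution `sub[i, ]` over the four bases
#' (probability 0 for the parent base, the three alternates summing to 1).
#'
#' @param lambda nonnegative numeric vector.
#' @param sub numeric matrix with one row per site and columns A,C,G,T.
#' @return An object of class `nucleotide_rates`.
#' @export
nucleotide_rates <- function(lambda, sub) {
  lambda <- as.numeric(lambda)
  sub <- as.matrix(sub)
  if (any(lambda < 0)) stop("lambda must be nonnegative")
  if (nrow(sub) != length(lambda) || ncol(sub) != 4L) {
    stop("sub must be a ", length(lambda), " x 4 matrix")
  }
  rs <- rowSums(sub)
  if (any(abs(rs - 1) > 1e-8)) {
    stop("substitution distributions must sum to 1 at every site")
  }
  colnames(sub) <- NT_BASES
  structure(list(lambda = lambda, sub = sub), class = "nucleotide_rates")
}

## ---- neutral providers -----------------------------------------------------

#' Neutral-rate providers
#'
#' A neutral provider deterministically maps a parent nucleotide sequence to
#' [nucleotide_rates()]; it never depends on the child sequence. Two
#' implementations ship: a positional table provider (one rate and
#' substitution distribution per alignment position) and a k-mer context
#' provider (rates keyed by the centered k-mer around each site).
#'
#' @param lambda,sub positional rate vector and 4-column substitution matrix.
#' @return A provider object for use with [neutral_rates()].
#' @export
table_provider <- function(lambda, sub) {
  base <- nucleotide_rates(lambda, sub)
  structure(list(lambda = base$lambda, sub = base$sub),
            class = c("table_provider", "neutral_provider"))
}

#' @param kmer_table data.frame with columns `kmer`, `rate`, `s_A`, `s_C`,
#'   `s_G`, `s_T`; a row with kmer `"*"` provides the fallback for unseen or
#'   edge contexts.
#' @rdname table_provider
#' @export
kmer_provider <- function(kmer_table) {
  need <- c("kmer", "rate", "s_A", "s_C", "s_G", "s_T")
  if (!all(need %in% names(kmer_table))) {
    stop("kmer table must have columns ", paste(need, collapse = ", "))
  }
  k <- unique(nchar(setdiff(kmer_table$kmer, "*")))
  if (length(k) != 1L || k %% 2L != 1L) {
    stop("all k-mers must share one odd length")
  }
  if (!"*" %in% kmer_table$kmer) stop("kmer table must include a '*' fallback row")
  sub <- as.matrix(kmer_table[, c("s_A", "s_C", "s_G", "s_T")])
  colnames(sub) <- NT_BASES
  rownames(sub) <- kmer_table$kmer
  rate <- stats::setNames(kmer_table$rate, kmer_table$kmer)
  structure(list(k = as.integer(k), rate = rate, sub = sub),
            class = c("kmer_provider", "neutral_provider"))
}

#' Evaluate a neutral provider on a parent sequence
#'
#' @param provider a [table_provider()] or [kmer_provider()].
#' @param seq parent nucleotide sequence.
#' @return [nucleotide_rates()] aligned to `seq`, with the substitution
#'   distribution renormalized to place zero mass on each site's current base.
#' @export
neutral_rates <- function(provider, seq) UseMethod("neutral_rates")

#' @export
neutral_rates.table_provider <- function(provider, seq) {
  nt <- .encode_nt(seq)
  if (length(nt) != length(provider$lambda)) {
    stop("sequence length ", length(nt), " does not match rate table length ",
         length(provider$lambda))
  }
  .zero_parent_base(provider$lambda, provider$sub, nt)
}

#' @export
neutral_rates.kmer_provider <- function(provider, seq) {
  nt <- .encode_nt(seq)
  n <- length(nt)
  k <- provider$k
  half <- (k - 1L) %/% 2L
  chars <- strsplit(toupper(seq), "")[[1]]
  keys <- rep("*", n)
  if (n >= k) {
    for (i in seq.int(half + 1L, n - half)) {
      ctx <- chars[(i - half):(i + half)]
      if (!anyNA(match(ctx, NT_BASES))) {
        keys[i] <- paste(ctx, collapse = "")
      }
    }
  }
  keys[!keys %in% names(provider$rate)] <- "*"
  lambda <- unname(provider$rate[keys])
  sub <- provider$sub[keys, , drop = FALSE]
  .zero_parent_base(lambda, sub, nt)
}

#' @noRd
.zero_parent_base <- function(lambda, sub, nt) {
  sub <- as.matrix(sub)
  rownames(sub) <- NULL
  ok <- which(!is.na(nt))
  sub[cbind(ok, nt[ok])] <- 0
  rs <- rowSums(sub)
  degenerate <- ok[rs[ok] <= 0]
  if (length(degenerate)) {
    # all mass sat on the current base: fall back to uniform alternates
    for (i in degenerate) {
      sub[i, ] <- 1 / 3
      sub[i, nt[i]] <- 0
    }
    rs <- rowSums(sub)
  }
  nonz <- rs > 0
  sub[nonz, ] <- sub[nonz, , drop = FALSE] / rs[nonz]
  structure(list(lambda = lambda, sub = sub), class = "nucleotide_rates")
}

## ---- codon-level probabilities --------------------------------------------

#' Neutral codon transition distribution (single codon)
#'
#' Under an independent Poisson mutation process at each of a codon's three
#' nucleotide positions, the probability of reaching target codon
#' `(b1,b2,b3)` from the parent codon after time `t` is the product over
#' positions of `exp(-lambda_i t)` when the base is unchanged and
#' `(1 - exp(-lambda_i t)) * s[i, b]` when it mutates to `b`.
#'
#' @param lambda length-3 nonnegative rates for the codon's positions.
#' @param sub 3 x 4 substitution matrix (rows: positions; cols A,C,G,T).
#' @param t nonnegative branch length.
#' @param parent_codon unambiguous 3-mer.
#' @return Named numeric vector of length 64 summing to 1.
#' @export
codon_probs <- function(lambda, sub, t, parent_codon) {
  if (t < 0) stop("t must be nonnegative")
  if (length(lambda) != 3L) stop("lambda must have length 3")
  sub <- as.matrix(sub)
  if (!all(dim(sub) == c(3L, 4L))) stop("sub must be 3 x 4")
  nt <- .encode_nt(parent_codon)
  if (anyNA(nt) || length(nt) != 3L) stop("parent codon must be unambiguous")
  pstay <- exp(-lambda * t)
  Q <- (1 - pstay) * sub
  Q[cbind(1:3, nt)] <- pstay
  p <- Q[1L, CODON_BASE_IDX[, 1L]] *
    Q[2L, CODON_BASE_IDX[, 2L]] *
    Q[3L, CODON_BASE_IDX[, 3L]]
  p[p < .PROB_FLOOR] <- 0
  names(p) <- CODONS
  p
}

#' @noRd
#' L x 64 matrix of neutral codon probabilities for a whole sequence.
#' Rows for codons containing an ambiguous base are NA.
.neutral_codon_matrix <- function(nt, rates, t) {
  n <- length(nt)
  L <- n %/% 3L
  pstay <- exp(-rates$lambda * t)
  Q <- (1 - pstay) * rates$sub
  ok <- which(!is.na(nt))
  Q[cbind(ok, nt[ok])] <- pstay[ok]
  i1 <- seq.int(1L, n, by = 3L)
  Q1 <- Q[i1, , drop = FALSE]
  Q2 <- Q[i1 + 1L, , drop = FALSE]
  Q3 <- Q[i1 + 2L, , drop = FALSE]
  P <- matrix(0, L, 64L)
  for (c in seq_len(64L)) {
    P[, c] <- Q1[, CODON_BASE_IDX[c, 1L]] *
      Q2[, CODON_BASE_IDX[c, 2L]] *
      Q3[, CODON_BASE_IDX[c, 3L]]
  }
  P[P < .PROB_FLOOR] <- 0
  amb <- is.na(nt[i1]) | is.na(nt[i1 + 1L]) | is.na(nt[i1 + 2L])
  if (any(amb)) P[amb, ] <- NA_real_
  P
}

#' Per-site neutral nonsynonymous substitution probability
#'
#' For each codon site `j` of the parent, the probability under the neutral
#' model of ending at any codon coding a different (non-stop) amino acid
#' after time `t`. This is the neutral factor that selection factors scale.
#'
#' @param parent in-frame nucleotide sequence.
#' @param provider a neutral provider (see [table_provider()]).
#' @param t nonnegative branch length.
#' @return Numeric vector over codon sites; `NA` at sites whose codon
#'   contains an ambiguous base.
#' @export
nonsyn_profile <- function(parent, provider, t) {
  nt <- .check_codon_seq(parent, "parent")
  rates <- neutral_rates(provider, parent)
  p <- .nonsyn_from_matrix(.neutral_codon_matrix(nt, rates, t),
                           .aa_indices(.codon_indices(nt)))
  if (all(is.na(p))) warning("all codon sites are ambiguous; profile fully masked")
  p
}

#' @noRd
.nonsyn_from_matrix <- function(P, aa_idx) {
  L <- nrow(P)
  p <- rep(NA_real_, L)
  ok <- which(!is.na(aa_idx) & !is.na(P[, 1L]))
  if (length(ok)) {
    mask <- NONSYN_MASK_BY_AA[aa_idx[ok], , drop = FALSE]
    p[ok] <- rowSums(P[ok, , drop = FALSE] * mask)
  }
  p
}

## ---- k-mer rate estimation -------------------------------------------------

#' Estimate a k-mer neutral rate table from out-of-frame PCPs
#'
#' Builds a context-dependent neutral SHM model from pairs of nonfunctional
#' (out-of-frame) sequences, on the convention that each input pair spans one
#' unit of branch length. For each observed k-mer context the rate is
#' `-log(1 - mutated/occurrences)`; the substitution distribution over the
#' three alternate bases uses add-one smoothing. Contexts never observed fall
#' back to the global average (the `"*"` row).
#'
#' @param pcps a [pcp_table] of aligned, gap-free pairs.
#' @param k odd context width (default 5).
#' @return A data.frame with columns `kmer`, `rate`, `s_A`, `s_C`, `s_G`,
#'   `s_T`, suitable for [kmer_provider()].
#' @export
estimate_kmer_rates <- function(pcps, k = 5L) {
  if (k %% 2L == 0L) stop("k must be odd")
  if (nrow(pcps) == 0L) stop("no PCPs supplied")
  half <- (k - 1L) %/% 2L
  occ <- new.env(parent = emptyenv())
  mut <- new.env(parent = emptyenv())
  subc <- new.env(parent = emptyenv())
  bump <- function(env, key, by) {
    assign(key, (if (exists(key, env, inherits = FALSE))
      get(key, env, inherits = FALSE) else 0) + by, env)
  }
  for (r in seq_len(nrow(pcps))) {
    pc <- strsplit(toupper(pcps$parent[r]), "")[[1]]
    cc <- strsplit(toupper(pcps$child[r]), "")[[1]]
    n <- length(pc)
    if (n < k) next
    for (i in seq.int(half + 1L, n - half)) {
      ctx <- pc[(i - half):(i + half)]
      if (anyNA(match(ctx, NT_BASES))) next
      key <- paste(ctx, collapse = "")
      bump(occ, key, 1)
      if (!is.na(match(cc[i], NT_BASES)) && cc[i] != pc[i]) {
        bump(mut, key, 1)
        bump(subc, paste0(key, ":", cc[i]), 1)
      }
    }
  }
  kmers <- sort(ls(occ))
  if (!length(kmers)) stop("no usable contexts found")
  occs <- vapply(kmers, get, 0, envir = occ)
  muts <- vapply(kmers, function(x)
    if (exists(x, mut, inherits = FALSE)) get(x, mut) else 0, 0)
  rate <- -log(1 - muts / occs)
  sub <- matrix(0, length(kmers), 4L, dimnames = list(kmers, NT_BASES))
  for (j in seq_along(kmers)) {
    center <- substr(kmers[j], half + 1L, half + 1L)
    alt <- setdiff(NT_BASES, center)
    cnt <- vapply(alt, function(b) {
      key <- paste0(kmers[j], ":", b)
      if (exists(key, subc, inherits = FALSE)) get(key, subc) else 0
    }, 0)
    sub[j, alt] <- (cnt + 1) / (sum(cnt) + 3)  # add-one smoothing
  }
  # global-average fallback row
  fb_rate <- -log(1 - sum(muts) / sum(occs))
  fb_sub <- colSums(sub * occs) / sum(occs)
  fb_sub <- fb_sub / sum(fb_sub)
  data.frame(kmer = c(kmers, "*"),
             rate = c(rate, fb_rate),
             s_A = c(sub[, "A"], fb_sub["A"]),
             s_C = c(sub[, "C"], fb_sub["C"]),
             s_G = c(sub[, "G"], fb_sub["G"]),
             s_T = c(sub[, "T"], fb_sub["T"]),
             row.names = NULL, stringsAsFactors = FALSE)
}

## ---- rate-table I/O ---------------------------------------------------------

#' Read / write neutral rate tables
#'
#' Positional tables are TSV with columns `site` (1-based), `lambda`, `s_A`,
#' `s_C`, `s_G`, `s_T`; k-mer tables are TSV with columns `kmer`, `rate`,
#' `s_A`, `s_C`, `s_G`, `s_T` (including the `"*"` fallback row). The reader
#' dispatches on the header.
#'
#' @param path file path.
#' @return A [table_provider()] or [kmer_provider()].
#' @export
read_rate_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if ("kmer" %in% names(df)) {
    kmer_provider(df)
  } else {
    df <- df[order(df$site), ]
    sub <- as.matrix(df[, c("s_A", "s_C", "s_G", "s_T")])
    rownames(sub) <- NULL
    table_provider(df$lambda, sub)
  }
}

#' @param provider a [table_provider()], or a k-mer table data.frame as
#'   produced by [estimate_kmer_rates()].
#' @rdname read_rate_table
#' @export
write_rate_table <- function(provider, path) {
  if (inherits(provider, "table_provider")) {
    df <- data.frame(site = seq_along(provider$lambda),
                     lambda = provider$lambda,
                     s_A = provider$sub[, "A"], s_C = provider$sub[, "C"],
                     s_G = provider$sub[, "G"], s_T = provider$sub[, "T"])
  } else if (inherits(provider, "kmer_provider")) {
    df <- data.frame(kmer = names(provider$rate), rate = unname(provider$rate),
                     s_A = provider$sub[, "A"], s_C = provider$sub[, "C"],
                     s_G = provider$sub[, "G"], s_T = provider$sub[, "T"])
  } else if (is.data.frame(provider)) {
    df <- provider
  } else {
    stop("unsupported provider type")
  }
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x)
    format(x, digits = 17, scientific = FALSE, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
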