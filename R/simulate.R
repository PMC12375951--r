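## Sequence-evolution simulation under the mutation-selection model.
## Children are drawn per codon site from the analytic mutation-selection transition
## distribution (stop codons have probability 0 by construction), and
## simulation cascades down trees: the child on one edge is the parent on
## its daughter edges. Draws consume the global R RNG, so a fixed
## `set.seed()` plus the deterministic edge traversal order makes every
## simulated dataset exactly reproducible.

#' Sample a child sequence from a parent
#'
#' For each codon site independently, draws the child codon from the
#' mutation-selection transition distribution at branch length `t` (WT codon
#' carries the remainder mass; stop codons are unreachable). Sites whose
#' parent codon contains an ambiguous base are copied unchanged.
#'
#' @param parent in-frame nucleotide sequence without stop codons.
#' @param model selection model (trainable or analytic ground truth).
#' @param provider neutral provider.
#' @param t nonnegative branch length.
#' @param clamp aggregate-probability cap.
#' @return Child nucleotide sequence, with attribute `n_clamped` counting
#'   sites whose aggregate probability had to be capped.
#' @export
sample_child <- function(parent, model, provider, t,
                         clamp = .DEFAULT_CLAMP) {
  if (t < 0) stop("t must be nonnegative")
  neutral <- neutral_codon_probs(parent, provider, t)
  aa_chr <- ifelse(is.na(neutral$aa_idx), NA_character_,
                   AA_ALPHABET[neutral$aa_idx])
  f <- predict_selection(model, aa_chr)
  ms <- mutsel_probs(neutral, f, clamp)
  .draw_child(parent, ms)
}

#' @noRd
.draw_child <- function(parent, ms) {
  L <- length(ms$codon_idx)
  child_cod <- ms$codon_idx
  ok <- which(!is.na(ms$m))
  if (length(ok)) {
    p_wt <- ms$M[cbind(ok, ms$codon_idx[ok])]
    u <- stats::runif(length(ok))
    changed <- ok[u > p_wt]
    for (j in changed) {
      pr <- ms$M[j, ]
      pr[ms$codon_idx[j]] <- 0
      child_cod[j] <- sample.int(64L, 1L, prob = pr)
    }
  }
  chars <- strsplit(toupper(parent), "")[[1]]
  out <- matrix(chars, nrow = 3L)
  repl <- which(child_cod != ms$codon_idx)
  if (length(repl)) {
    out[, repl] <- t(matrix(NT_BASES[CODON_BASE_IDX[child_cod[repl], ,
                                                    drop = FALSE]],
                            ncol = 3L))
  }
  structure(paste(out, collapse = ""),
            n_clamped = sum(ms$clamped, na.rm = TRUE))
}

#' Simulate PCPs down a phylogenetic tree
#'
#' Starting from the naive sequence at the root, draws a child for every
#' edge in cladewise (parent-before-child) order so that the child of one
#' edge serves as the parent of its daughter edges, then applies the
#' training-data filters (drop naive edges, drop identical pairs).
#'
#' @param phy an [ape::phylo] tree with branch lengths.
#' @param naive unambiguous in-frame naive sequence placed at the root.
#' @param model selection model.
#' @param provider neutral provider.
#' @param drop_naive,drop_identical filters applied to the emitted PCPs.
#' @param clone_id identifier stored with the emitted PCPs.
#' @param clamp aggregate-probability cap.
#' @return A [pcp_table] with optimization-free branch lengths copied from
#'   the tree, plus attribute `n_clamped`.
#' @export
simulate_down_tree <- function(phy, naive, model, provider,
                               drop_naive = TRUE, drop_identical = TRUE,
                               clone_id = "sim", clamp = .DEFAULT_CLAMP) {
  stopifnot(inherits(phy, "phylo"))
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (anyNA(phy$edge.length)) stop("missing branch length on an edge")
  nt <- .check_codon_seq(naive, "naive")
  if (anyNA(nt)) stop("naive sequence must be unambiguous")
  phy <- stats::reorder(phy, "cladewise")
  n_nodes <- ape::Ntip(phy) + phy$Nnode
  seqs <- character(n_nodes)
  root <- ape::Ntip(phy) + 1L
  seqs[root] <- naive
  n_edges <- nrow(phy$edge)
  parent_out <- character(n_edges)
  child_out <- character(n_edges)
  n_clamped <- 0L
  for (e in seq_len(n_edges)) {
    pn <- phy$edge[e, 1L]
    cn <- phy$edge[e, 2L]
    child <- sample_child(seqs[pn], model, provider, phy$edge.length[e],
                          clamp)
    n_clamped <- n_clamped + attr(child, "n_clamped")
    seqs[cn] <- as.character(child)
    parent_out[e] <- seqs[pn]
    child_out[e] <- seqs[cn]
  }
  df <- pcp_table(parent = parent_out, child = child_out,
                  clone_id = clone_id,
                  is_naive_edge = phy$edge[, 1L] == root,
                  branch_length = phy$edge.length)
  structure(.filter_pcps(df, drop_naive, drop_identical),
            n_clamped = n_clamped)
}
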