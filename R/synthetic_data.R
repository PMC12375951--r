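## Synthetic-data generators: naive sequences, random clonal trees, neutral
## rate tables, and analytic ground-truth selection functions, so that the
## whole pipeline (simulation, fitting, evaluation) is testable without any
## external data. Everything draws from the global R RNG: set a seed first.

#' Generate a naive (unmutated ancestor) sequence
#'
#' Samples an in-frame nucleotide sequence with the requested GC content and
#' no stop codons (stop codons are rejection-sampled away codon by codon).
#'
#' @param n_codons number of codons (>= 1).
#' @param gc_bias target GC fraction in `(0, 1)`.
#' @return Nucleotide string of length `3 * n_codons`.
#' @export
gen_naive <- function(n_codons, gc_bias = 0.5) {
  stopifnot(n_codons >= 1L, gc_bias > 0, gc_bias < 1)
  p <- c(A = (1 - gc_bias) / 2, C = gc_bias / 2,
         G = gc_bias / 2, T = (1 - gc_bias) / 2)
  nt <- sample(NT_BASES, 3L * n_codons, replace = TRUE, prob = p)
  repeat {
    cod <- .codon_indices(match(nt, NT_BASES))
    stops <- which(CODON_AA[cod] == "*")
    if (!length(stops)) break
    for (j in stops) {
      nt[(3L * (j - 1L) + 1L):(3L * j)] <-
        sample(NT_BASES, 3L, replace = TRUE, prob = p)
    }
  }
  paste(nt, collapse = "")
}

#' Generate a random clonal-family tree
#'
#' Random rooted binary topology with independent exponential branch lengths
#' and the naive outgroup at the root (root node labelled `"naive"`).
#'
#' @param n_leaves number of tips (>= 2).
#' @param mean_branch mean of the exponential branch-length distribution.
#' @return An [ape::phylo] tree with `2 * n_leaves - 2` edges.
#' @export
gen_tree <- function(n_leaves, mean_branch = 0.05) {
  stopifnot(n_leaves >= 2L, mean_branch > 0)
  phy <- ape::rtree(n_leaves, rooted = TRUE)
  phy$edge.length <- stats::rexp(nrow(phy$edge), rate = 1 / mean_branch)
  phy$node.label <- c("naive",
                      if (phy$Nnode > 1L) paste0("N", seq_len(phy$Nnode - 1L) + 1L))
  phy
}

#' Generate a positional neutral rate table
#'
#' Per-nucleotide-site lognormal mutation rates (mimicking SHM hot and cold
#' spots) and Dirichlet substitution distributions over the three bases other
#' than the reference base at each site.
#'
#' @param ref_seq unambiguous reference (naive) nucleotide sequence.
#' @param mean_rate mean mutation rate per site (arbitrary units; only the
#'   product rate x branch length is identified).
#' @param sdlog lognormal dispersion of rates across sites.
#' @return A [table_provider()].
#' @export
gen_rate_table <- function(ref_seq, mean_rate = 1, sdlog = 0.5) {
  nt <- .encode_nt(ref_seq)
  if (anyNA(nt)) stop("reference sequence must be unambiguous")
  n <- length(nt)
  lambda <- stats::rlnorm(n, meanlog = log(mean_rate) - sdlog^2 / 2,
                          sdlog = sdlog)
  g <- matrix(stats::rgamma(3L * n, shape = 1), n, 3L)
  g <- g / rowSums(g)
  sub <- matrix(0, n, 4L, dimnames = list(NULL, NT_BASES))
  for (i in seq_len(n)) {
    sub[i, -nt[i]] <- g[i, ]
  }
  table_provider(lambda, sub)
}

## ---- ground-truth selection functions ---------------------------------------

#' Ground-truth selection specification
#'
#' Analytic selection functions used as simulation ground truth. Three
#' families: `constant` (factor `value` everywhere), `sinusoid`
#' (position-dependent: `baseline * (1 + amplitude * sin(2*pi*(j-1)/period))`),
#' and `context_rule` (sequence-dependent: `baseline`, multiplied by
#' `hydrophobic_penalty` at sites whose current amino acid is hydrophobic,
#' so profiles differ between sequences differing at a single position).
#' Induced factors must be strictly positive and within `bounds`.
#'
#' @param family one of `"constant"`, `"sinusoid"`, `"context_rule"`.
#' @param value constant-family factor.
#' @param baseline,amplitude,period sinusoid parameters (`0 <= amplitude < 1`).
#' @param hydrophobic_penalty context-rule multiplier for hydrophobic sites.
#' @param bounds admissible factor range.
#' @return A `selection_spec`.
#' @export
selection_spec <- function(family = c("constant", "sinusoid", "context_rule"),
                           value = 1, baseline = 1, amplitude = 0.5,
                           period = 25, hydrophobic_penalty = 0.5,
                           bounds = c(0.05, 3)) {
  family <- match.arg(family)
  spec <- list(family = family, value = value, baseline = baseline,
               amplitude = amplitude, period = period,
               hydrophobic_penalty = hydrophobic_penalty, bounds = bounds)
  extremes <- switch(family,
                     constant = c(value, value),
                     sinusoid = baseline * (1 + c(-1, 1) * amplitude),
                     context_rule = baseline * c(1, hydrophobic_penalty))
  if (any(extremes <= 0)) {
    stop("specification implies nonpositive selection factors")
  }
  if (any(extremes < bounds[1L]) || any(extremes > bounds[2L])) {
    stop("specification implies factors outside bounds [",
         bounds[1L], ", ", bounds[2L], "]")
  }
  structure(spec, class = "selection_spec")
}

#' Build a ground-truth selection model from a specification
#'
#' The returned object satisfies the [predict_selection()] contract:
#' deterministic, bounded, strictly positive factors (`NA` at ambiguous
#' sites).
#'
#' @param spec a [selection_spec()].
#' @return A ground-truth selection model.
#' @export
gen_ground_truth <- function(spec) {
  stopifnot(inherits(spec, "selection_spec"))
  structure(list(spec = spec),
            class = c("ground_truth_model", "selection_model"))
}

#' @export
predict_selection.ground_truth_model <- function(model, aa_seq, ...) {
  tok <- .aa_tokens(aa_seq)
  L <- length(tok)
  sp <- model$spec
  f <- switch(sp$family,
              constant = rep(sp$value, L),
              sinusoid = sp$baseline *
                (1 + sp$amplitude * sin(2 * pi * (seq_len(L) - 1) / sp$period)),
              context_rule = {
                hydro <- AA_ALPHABET[tok] %in% HYDROPHOBIC_AA
                sp$baseline * ifelse(hydro, sp$hydrophobic_penalty, 1)
              })
  f[tok == .PAD_TOKEN] <- NA_real_
  f
}

#' @export
n_parameters.ground_truth_model <- function(model) 0L

## ---- whole-dataset convenience ----------------------------------------------

#' Simulate a complete synthetic PCP dataset
#'
#' Draws a naive sequence, a positional neutral rate table, and random
#' clonal trees, then simulates PCPs down the trees under a ground-truth
#' selection model until at least `n_pcps` PCPs survive the training filters
#' (naive edges and identical pairs dropped).
#'
#' @param n_pcps minimum number of PCPs to emit.
#' @param truth ground-truth selection model (see [gen_ground_truth()]).
#' @param n_codons sequence length in codons.
#' @param n_leaves tips per simulated tree.
#' @param mean_branch mean exponential branch length.
#' @param mean_rate mean neutral mutation rate per nucleotide site.
#' @param provider optional pre-built neutral provider (default: a fresh
#'   [gen_rate_table()] for the naive sequence).
#' @param naive optional naive sequence (default: [gen_naive()]).
#' @return List with elements `pcps` ([pcp_table]), `provider`, `naive`,
#'   `truth`.
#' @export
simulate_dataset <- function(n_pcps, truth, n_codons = 100L, n_leaves = 25L,
                             mean_branch = 0.06, mean_rate = 1,
                             provider = NULL, naive = NULL) {
  if (is.null(naive)) naive <- gen_naive(n_codons)
  if (is.null(provider)) provider <- gen_rate_table(naive, mean_rate)
  out <- list()
  total <- 0L
  tree_i <- 0L
  while (total < n_pcps) {
    tree_i <- tree_i + 1L
    phy <- gen_tree(n_leaves, mean_branch)
    sim <- simulate_down_tree(phy, naive, truth, provider,
                              clone_id = paste0("tree", tree_i))
    out[[tree_i]] <- sim
    total <- total + nrow(sim)
  }
  pcps <- do.call(rbind, out)
  class(pcps) <- c("pcp_table", "data.frame")
  list(pcps = pcps, provider = provider, naive = naive, truth = truth)
}
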