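#' Translate a single codon
#'
#' Maps a 3-mer nucleotide string to its one-letter amino acid under the
#' standard nuclear genetic code. Stop codons (TAA, TAG, TGA) return `"*"`.
#' A codon containing an ambiguous base (`N`) returns `NA_character_`, never
#' a silently guessed amino acid.
#'
#' @param codon character scalar of length 3 over `A,C,G,T,N`.
#' @return One-letter amino acid, `"*"` for stop, or `NA_character_` if the
#'   codon contains an ambiguous base.
#' @examples
#' translate_codon("ATG")  # "M"
#' translate_codon("TAA")  # "*"
#' translate_codon("ATN")  # NA
#' @export
translate_codon <- function(codon) {
  if (!is.character(codon) || length(codon) != 1L || nchar(codon) != 3L) {
    stop("codon must be a single 3-character string")
  }
  idx <- .codon_indices(.encode_nt(codon))
  if (is.na(idx)) NA_character_ else CODON_AA[idx]
}

#' Translate an in-frame nucleotide sequence to amino acids
#'
#' @param seq nucleotide string whose length is a multiple of 3.
#' @return Character vector of per-codon amino acids; `"*"` for stops and
#'   `NA` for codons containing ambiguous bases.
#' @export
aa_sequence <- function(seq) {
  nt <- .encode_nt(seq)
  if (length(nt) %% 3L != 0L) {
    stop("sequence length ", length(nt), " is not a multiple of 3")
  }
  idx <- .codon_indices(nt)
  out <- rep(NA_character_, length(idx))
  ok <- !is.na(idx)
  out[ok] <- CODON_AA[idx[ok]]
  out
}

#' @noRd
.check_codon_seq <- function(seq, what = "sequence") {
  nt <- .encode_nt(seq)
  if (length(nt) %% 3L != 0L) {
    stop(what, " length ", length(nt), " is not a multiple of 3")
  }
  invisible(nt)
}

#' Productive-sequence filter
#'
#' A BCR sequence is considered productive when the conserved cysteine and
#' tryptophan codons flanking the CDR3 are in the reading frame that starts
#' at the first nucleotide of the V segment, and the sequence contains no
#' stop codon among its fully unambiguous codons. The flank residues
#' themselves may be mutated; only their frame matters.
#'
#' @param seq nucleotide string (length a multiple of 3, frame starting at
#'   position 1).
#' @param flank_nt_start integer vector of length 2: 0-based nucleotide start
#'   positions of the CDR3-flanking cysteine and tryptophan codons.
#' @return `TRUE` or `FALSE`.
#' @export
is_productive <- function(seq, flank_nt_start) {
  nt <- .check_codon_seq(seq)
  if (length(flank_nt_start) != 2L) {
    stop("flank_nt_start must give the two flank codon start positions")
  }
  if (any(flank_nt_start < 0L) || any(flank_nt_start + 3L > length(nt))) {
    stop("flank positions out of range for sequence of length ", length(nt))
  }
  if (any(flank_nt_start %% 3L != 0L)) {
    return(FALSE)
  }
  codon_idx <- .codon_indices(nt)
  !any(CODON_AA[codon_idx[!is.na(codon_idx)]] == "*")
}

#' Construct an annotated tree
#'
#' Couples a rooted tree topology with a nucleotide sequence for every node
#' (tips and internal nodes, all of identical length) and the label of the
#' naive (unmutated-ancestor) node used as outgroup/root.
#'
#' @param phy an [ape::phylo] tree; internal nodes must be labelled.
#' @param seqs named character vector of nucleotide sequences keyed by node
#'   label, covering every node in `phy`.
#' @param naive label of the naive node (default: the root's label).
#' @return An object of class `annotated_tree`.
#' @export
annotated_tree <- function(phy, seqs, naive = NULL) {
  stopifnot(inherits(phy, "phylo"))
  if (is.null(phy$node.label) || any(phy$node.label == "")) {
    stop("internal nodes must be named")
  }
  labels <- c(phy$tip.label, phy$node.label)
  if (anyDuplicated(labels)) stop("node labels must be unique")
  missing <- setdiff(labels, names(seqs))
  if (length(missing)) {
    stop("node(s) missing a sequence: ", paste(missing, collapse = ", "))
  }
  seqs <- seqs[labels]
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("all node sequences must have identical length")
  }
  if (lens[1L] %% 3L != 0L) stop("sequence length is not a multiple of 3")
  root_label <- labels[ape::Ntip(phy) + 1L]
  if (is.null(naive)) naive <- root_label
  if (!naive %in% labels) stop("naive label not found in tree: ", naive)
  structure(list(phy = phy, seqs = seqs, naive = naive),
            class = "annotated_tree")
}

#' @export
print.annotated_tree <- function(x, ...) {
  cat("annotated_tree:", ape::Ntip(x$phy), "tips,",
      nchar(x$seqs[[1L]]), "nt per node, naive =", x$naive, "\n")
  invisible(x)
}

#' Construct a PCP table
#'
#' A PCP (parent-child pair) is one directed edge of a clonal-family tree:
#' the parent codon sequence, the child codon sequence, and an optional
#' branch length (NA meaning "to be optimized").
#'
#' @param parent,child character vectors of aligned nucleotide sequences.
#' @param clone_id clone identifiers (recycled).
#' @param is_naive_edge logical flag: edge incident to the naive node.
#' @param branch_length numeric; `NA` for branch lengths to be optimized.
#' @return A `data.frame` with class `pcp_table`.
#' @export
pcp_table <- function(parent, child, clone_id = "clone1",
                      is_naive_edge = FALSE, branch_length = NA_real_) {
  n <- length(parent)
  df <- data.frame(parent = as.character(parent),
                   child = as.character(child),
                   clone_id = rep_len(as.character(clone_id), n),
                   is_naive_edge = rep_len(as.logical(is_naive_edge), n),
                   branch_length = rep_len(as.numeric(branch_length), n),
                   stringsAsFactors = FALSE)
  .validate_pcps(df)
  class(df) <- c("pcp_table", "data.frame")
  df
}

#' @noRd
.validate_pcps <- function(df) {
  lp <- nchar(df$parent)
  lc <- nchar(df$child)
  bad <- which(lp != lc)
  if (length(bad)) {
    stop("row ", bad[1L], ": parent and child lengths differ (",
         lp[bad[1L]], " vs ", lc[bad[1L]], ")")
  }
  bad <- which(lp %% 3L != 0L)
  if (length(bad)) {
    stop("row ", bad[1L], ": sequence length is not a multiple of 3")
  }
  invisible(df)
}

#' Extract parent-child pairs from an annotated tree
#'
#' Emits one PCP per directed edge of the tree. With `drop_naive`, edges
#' incident to the naive/outgroup node are excluded; with `drop_identical`,
#' PCPs whose parent and child sequences are identical are excluded. These
#' are the training-data filters applied to both real and simulated data.
#'
#' @param tree an [annotated_tree].
#' @param drop_naive,drop_identical logical filters (default `TRUE`).
#' @param clone_id clone identifier stored with each PCP.
#' @return A [pcp_table].
#' @export
extract_pcps <- function(tree, drop_naive = TRUE, drop_identical = TRUE,
                         clone_id = "clone1") {
  stopifnot(inherits(tree, "annotated_tree"))
  phy <- tree$phy
  labels <- c(phy$tip.label, phy$node.label)
  parent_lab <- labels[phy$edge[, 1L]]
  child_lab <- labels[phy$edge[, 2L]]
  df <- pcp_table(parent = unname(tree$seqs[parent_lab]),
                  child = unname(tree$seqs[child_lab]),
                  clone_id = clone_id,
                  is_naive_edge = parent_lab == tree$naive |
                    child_lab == tree$naive,
                  branch_length = if (is.null(phy$edge.length))
                    NA_real_ else phy$edge.length)
  .filter_pcps(df, drop_naive, drop_identical)
}

#' @noRd
.filter_pcps <- function(df, drop_naive, drop_identical) {
  keep <- rep(TRUE, nrow(df))
  if (drop_naive) keep <- keep & !df$is_naive_edge
  if (drop_identical) keep <- keep & df$parent != df$child
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pcp_table", "data.frame")
  out
}

#' Read / write PCP tables
#'
#' PCP tables are UTF-8 TSV files with columns `parent`, `child`,
#' `clone_id`, `is_naive_edge`, `branch_length`; a missing/empty branch
#' length means "to be optimized". Writing then reading reproduces the
#' records exactly.
#'
#' @param path file path.
#' @param drop_identical,drop_naive apply the training filters on load.
#' @return A [pcp_table].
#' @export
read_pcp_table <- function(path, drop_identical = FALSE, drop_naive = FALSE) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c(parent = "character",
                                         child = "character",
                                         clone_id = "character",
                                         is_naive_edge = "logical",
                                         branch_length = "numeric"),
                          stringsAsFactors = FALSE)
  need <- c("parent", "child", "clone_id", "is_naive_edge", "branch_length")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("PCP table missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- df[need]
  .validate_pcps(df)
  class(df) <- c("pcp_table", "data.frame")
  .filter_pcps(df, drop_naive, drop_identical)
}

#' @param pcps a [pcp_table].
#' @rdname read_pcp_table
#' @export
write_pcp_table <- function(pcps, path) {
  .validate_pcps(pcps)
  df <- as.data.frame(pcps)
  df$branch_length <- ifelse(is.na(df$branch_length), NA,
                             format(df$branch_length, digits = 17,
                                    scientific = FALSE, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write FASTA sequence files
#'
#' Thin wrappers around ape's FASTA support returning plain named character
#' vectors of uppercase nucleotide sequences.
#'
#' @param path file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- ape::read.FASTA(path)
  out <- toupper(vapply(as.character(x), paste, "", collapse = ""))
  names(out) <- names(x)
  out
}

#' @param seqs named character vector of sequences.
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(c(paste0(">", names(seqs)[i]), seqs[[i]]), con)
  }
  invisible(path)
}

#' Read an annotated tree from newick + FASTA
#'
#' The newick file holds the topology with named internal nodes; the FASTA
#' file holds one sequence per node label.
#'
#' @param tree_path newick file.
#' @param seqs_path FASTA file of per-node sequences.
#' @param naive naive-node label (default: root label).
#' @return An [annotated_tree].
#' @export
read_annotated_tree <- function(tree_path, seqs_path, naive = NULL) {
  phy <- ape::read.tree(tree_path)
  seqs <- read_fasta(seqs_path)
  annotated_tree(phy, seqs, naive = naive)
}

#' Write an annotated tree to newick + FASTA
#'
#' @param tree an [annotated_tree].
#' @rdname read_annotated_tree
#' @export
write_annotated_tree <- function(tree, tree_path, seqs_path) {
  ape::write.tree(tree$phy, file = tree_path)
  write_fasta(tree$seqs, seqs_path)
  invisible(tree_path)
}
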