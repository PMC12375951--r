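## Internal codon/amino-acid machinery shared by all modules.
## Codons are indexed 1..64 in lexicographic order over bases A,C,G,T.

NT_BASES <- c("A", "C", "G", "T")

#' @noRd
.codon_strings <- function() {
  g <- expand.grid(b3 = NT_BASES, b2 = NT_BASES, b1 = NT_BASES,
                   stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3)
}

CODONS <- .codon_strings()

## 64-vector of amino acids (one-letter), "*" for stop, in CODONS order.
## The standard nuclear genetic code, taken from Biostrings.
CODON_AA <- {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[CODONS])
}

## The 20 canonical amino acids in alphabetical one-letter order.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## codon index (1..64) -> integer 1..20 for coding codons, NA for stops
CODON_AA_IDX <- match(CODON_AA, AA_ALPHABET)

## base composition of each codon: 64 x 3 integer matrix of base indices 1..4
CODON_BASE_IDX <- {
  m <- matrix(0L, 64L, 3L)
  for (c in seq_len(64L)) {
    m[c, ] <- match(strsplit(CODONS[c], "")[[1]], NT_BASES)
  }
  m
}

STOP_CODONS <- CODONS[CODON_AA == "*"]

#' @noRd
.encode_nt <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  bad <- !(chars %in% c(NT_BASES, "N"))
  if (any(bad)) {
    if (any(chars == "-")) {
      stop("gapped input is not supported; sequences must be gap-free")
    }
    stop("invalid nucleotide symbol(s): ",
         paste(unique(chars[bad]), collapse = ", "))
  }
  idx <- match(chars, NT_BASES)  # NA for N
  idx
}

#' @noRd
.codon_indices <- function(nt_idx) {
  stopifnot(length(nt_idx) %% 3L == 0L)
  n <- length(nt_idx) %/% 3L
  m <- matrix(nt_idx, nrow = 3L)
  # NA (ambiguous base) propagates to NA codon index
  (m[1L, ] - 1L) * 16L + (m[2L, ] - 1L) * 4L + m[3L, ]
}

#' @noRd
.aa_indices <- function(codon_idx) {
  out <- rep(NA_integer_, length(codon_idx))
  ok <- !is.na(codon_idx)
  out[ok] <- CODON_AA_IDX[codon_idx[ok]]
  out
}
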