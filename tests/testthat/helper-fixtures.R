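# Shared fixture builders (all generated in code; no data files).

NT <- c("A", "C", "G", "T")

# Hand-entered NCBI standard genetic code, independent of the implementation.
STANDARD_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

# provider with flat rates; the flat 1/4 rows become uniform thirds over the
# alternates once the current base is zeroed out
uniform_provider <- function(n_nt, lambda = 0.2) {
  sub <- matrix(1 / 4, n_nt, 4, dimnames = list(NULL, NT))
  table_provider(rep_len(lambda, n_nt), sub)
}

# brute-force 64-codon transition distribution by enumerating the product of
# the three independent per-position distributions (the independent oracle)
enumerate_codon_probs <- function(lambda, sub, t, parent_codon) {
  pc <- strsplit(parent_codon, "")[[1]]
  pos_dist <- lapply(1:3, function(i) {
    d <- (1 - exp(-lambda[i] * t)) * sub[i, ]
    d[pc[i]] <- exp(-lambda[i] * t)
    d
  })
  out <- numeric(0)
  for (b1 in NT) for (b2 in NT) for (b3 in NT) {
    out[paste0(b1, b2, b3)] <-
      pos_dist[[1]][b1] * pos_dist[[2]][b2] * pos_dist[[3]][b3]
  }
  out
}

# random in-frame, stop-free sequence (independent of gen_naive)
random_coding_seq <- function(n_codons) {
  codons <- names(STANDARD_CODE)[STANDARD_CODE != "*"]
  paste(sample(codons, n_codons, replace = TRUE), collapse = "")
}
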