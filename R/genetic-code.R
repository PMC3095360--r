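# Internal codon-space machinery shared by the GY94 and NG86 estimators and
# by the sequence simulator. The state space is the 61 sense codons of the
# standard (universal) genetic code; stop codons are excluded throughout.

.nucs <- c("A", "C", "G", "T")

# TRUE when the a->b nucleotide change is a transition (purine<->purine or
# pyrimidine<->pyrimidine).
.is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}

# Build (once) and cache the codon tables: sense codons, encoded amino acids,
# and the list of ordered single-nucleotide-difference codon pairs with their
# transition and synonymy flags.
codon_tables <- function() {
  if (!is.null(.homoeolog_cache$codon_tables)) {
    return(.homoeolog_cache$codon_tables)
  }
  code <- Biostrings::GENETIC_CODE
  all_codons <- names(code)
  sense <- all_codons[code != "*"]
  stops <- all_codons[code == "*"]
  aa <- code[sense]
  n <- length(sense) # 61

  # Decompose codons into positional nucleotides
  mat <- do.call(rbind, strsplit(sense, ""))

  # Ordered pairs (i, j), i != j, differing at exactly one position
  from <- integer(0)
  to <- integer(0)
  pos <- integer(0)
  ts <- logical(0)
  syn <- logical(0)
  for (i in seq_len(n)) {
    diffs <- sweep(mat, 2, mat[i, ], FUN = "!=")
    ndiff <- rowSums(diffs)
    js <- which(ndiff == 1)
    for (j in js) {
      p <- which(diffs[j, ])
      from <- c(from, i)
      to <- c(to, j)
      pos <- c(pos, p)
      ts <- c(ts, .is_transition(mat[i, p], mat[j, p]))
      syn <- c(syn, aa[i] == aa[j])
    }
  }

  tabs <- list(
    codons = sense, stops = stops, aa = unname(aa), n = n,
    codon_index = stats::setNames(seq_len(n), sense),
    nuc_mat = mat,
    pair_from = from, pair_to = to, pair_pos = pos,
    pair_ts = ts, pair_syn = syn
  )
  .homoeolog_cache$codon_tables <- tabs
  tabs
}

# Split an in-frame DNA string into codon triplets, dropping any trailing
# partial codon.
split_codons <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character(0))
  substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# Translate codon triplets to one-letter amino acids; "*" for stops, "X" for
# codons containing non-ACGT characters.
translate_codons <- function(codons) {
  code <- Biostrings::GENETIC_CODE
  out <- unname(code[codons])
  out[is.na(out)] <- "X"
  out
}
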