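# Small fixtures built in code.

# A region with evenly spaced single-exon genes of given CDSs; gene i gets
# function fns[i]. Intergenic filler is deterministic.
toy_region <- function(name, cds_list, fns = NULL, strands = NULL,
                       spacer = 40L, sub_genome = "unknown") {
  n <- length(cds_list)
  if (is.null(fns)) fns <- paste("protein", seq_len(n))
  if (is.null(strands)) strands <- rep("+", n)
  filler <- strrep("ACGT", ceiling(spacer / 4))
  filler <- substring(filler, 1, spacer)
  seq <- filler
  genes <- list()
  for (i in seq_len(n)) {
    cds <- cds_list[[i]]
    genomic <- if (strands[i] == "-") {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
    } else {
      cds
    }
    s <- nchar(seq) + 1L
    seq <- paste0(seq, genomic, filler)
    genes[[i]] <- gene_model(sprintf("%s_g%d", name, i), strands[i],
                             cbind(s, s + nchar(cds) - 1L), fn = fns[i])
  }
  annotated_region(name, seq, genes = genes, sub_genome = sub_genome)
}

# Deterministic sense-codon CDS of n codons (ATG start, no stops)
toy_cds <- function(n_codons, shift = 0L) {
  tabs <- homoeolog:::codon_tables()
  body_pool <- setdiff(tabs$codons, c("ATG"))
  idx <- ((seq_len(n_codons - 1L) * 7L + shift) %% length(body_pool)) + 1L
  paste(c("ATG", body_pool[idx]), collapse = "")
}
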