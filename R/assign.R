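# Sub-genome assignment of candidate haplotypes: by overall nucleotide
# identity to a diploid-progenitor reference (highest identity -> O), and by
# genotyping diagnostic homoeologous sequence variants (HSVs).

#' Diagnostic variant set for a locus
#'
#' Positions in a progenitor reference where the two sub-genomes carry fixed
#' alternative alleles, usable as diagnostic markers.
#'
#' @param locus Locus name.
#' @param reference Progenitor reference sequence for the locus (a
#'   T. occidentale-like surrogate for the O sub-genome ancestor).
#' @param positions Strictly increasing 1-based positions in `reference`.
#' @param allele_O,allele_P Diagnostic alleles at each position
#'   (single bases, `allele_O != allele_P` throughout).
#' @return An object of class `diagnostic_variants`.
#' @export
diagnostic_variants <- function(locus, reference, positions, allele_O, allele_P) {
  reference <- toupper(reference)
  positions <- as.integer(positions)
  stopifnot(length(positions) == length(allele_O),
            length(positions) == length(allele_P))
  if (any(diff(positions) <= 0)) stop("positions must be strictly increasing")
  if (any(positions < 1L) || any(positions > nchar(reference))) {
    stop("variant position outside reference")
  }
  allele_O <- toupper(allele_O)
  allele_P <- toupper(allele_P)
  if (any(allele_O == allele_P)) stop("allele_O must differ from allele_P at every position")
  structure(
    list(locus = locus, reference = reference,
         variants = data.frame(pos = positions, allele_O = allele_O,
                               allele_P = allele_P, stringsAsFactors = FALSE)),
    class = "diagnostic_variants"
  )
}

#' Read a diagnostic variant table (TSV)
#'
#' Expects columns `locus`, `pos`, `allele_O`, `allele_P`.
#'
#' @param path TSV path.
#' @param reference Reference sequence of the locus.
#' @return A [diagnostic_variants()] object (single-locus tables only).
#' @export
read_variant_table <- function(path, reference) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("locus", "pos", "allele_O", "allele_P")
  if (!all(need %in% names(tab))) {
    stop("variant table must have columns ", paste(need, collapse = ", "))
  }
  if (length(unique(tab$locus)) != 1L) stop("variant table must cover one locus")
  diagnostic_variants(tab$locus[1], reference, tab$pos, tab$allele_O, tab$allele_P)
}

#' Assign candidate haplotypes to sub-genomes by identity to a progenitor
#'
#' Globally aligns each candidate to the progenitor reference; the candidate
#' with the unique highest nucleotide identity is designated O and the
#' others P'. A tie on the maximum makes all calls ambiguous.
#'
#' @param candidates Named character vector of at least two candidate
#'   sequences for one locus.
#' @param reference Progenitor (T. occidentale-like) reference sequence.
#' @param params [alignment_params()].
#' @param tie_tol Identities within this margin of each other count as tied.
#' @return Data frame `candidate`, `identity_to_reference`, `call`
#'   (`"O"`, `"P'"` or `"ambiguous"`), in the input order.
#' @export
assign_by_identity <- function(candidates, reference,
                               params = alignment_params(), tie_tol = 1e-9) {
  if (length(candidates) < 2L) stop("need at least 2 candidate sequences")
  stopifnot(!is.null(names(candidates)))
  ident <- vapply(candidates, function(s) {
    global_align(s, reference, params)$identity_pct
  }, numeric(1))
  top <- max(ident)
  is_top <- ident >= top - tie_tol
  call <- if (sum(is_top) > 1L) {
    rep("ambiguous", length(ident))
  } else {
    ifelse(is_top, "O", "P'")
  }
  data.frame(
    candidate = names(candidates),
    identity_to_reference = unname(ident),
    call = call, stringsAsFactors = FALSE
  )
}

#' Genotype a candidate at diagnostic variant positions
#'
#' Globally aligns the candidate to the variant set's reference, reads the
#' candidate allele at each variant position (positions falling in an
#' alignment gap are excluded from both counts), and calls the sub-genome
#' by majority vote with a required margin.
#'
#' @param candidate Candidate sequence (string).
#' @param variant_set A [diagnostic_variants()] object.
#' @param params [alignment_params()].
#' @param min_coverage Minimum fraction of variant positions that must be
#'   aligned (default 0.5); below it an error is thrown.
#' @param margin Minimum vote margin for an unambiguous call (default 2).
#' @return List of class `subgenome_call`: `hsv_matches_O`,
#'   `hsv_matches_P`, `n_variants`, `coverage`, `call`.
#' @export
genotype_hsvs <- function(candidate, variant_set,
                          params = alignment_params(),
                          min_coverage = 0.5, margin = 2L) {
  stopifnot(inherits(variant_set, "diagnostic_variants"))
  candidate <- toupper(candidate)
  aln <- global_align(variant_set$reference, candidate, params)
  ra <- strsplit(aln$aligned_a, "")[[1]] # reference with gaps
  ca <- strsplit(aln$aligned_b, "")[[1]] # candidate with gaps
  ref_coord <- cumsum(ra != "-")
  v <- variant_set$variants
  # candidate base aligned to each reference variant position ("-" if gapped)
  obs <- vapply(v$pos, function(p) {
    col <- which(ref_coord == p & ra != "-")[1]
    if (is.na(col)) "-" else ca[col]
  }, character(1))
  informative <- obs != "-"
  coverage <- mean(informative)
  if (coverage < min_coverage) {
    stop("candidate aligns to only ", round(100 * coverage), "% of variant positions")
  }
  n_O <- sum(obs[informative] == v$allele_O[informative])
  n_P <- sum(obs[informative] == v$allele_P[informative])
  call <- if (n_O - n_P >= margin) "O" else if (n_P - n_O >= margin) "P'" else "ambiguous"
  structure(
    list(locus = variant_set$locus, hsv_matches_O = n_O, hsv_matches_P = n_P,
         n_variants = nrow(v), coverage = coverage, call = call),
    class = "subgenome_call"
  )
}

#' @export
print.subgenome_call <- function(x, ...) {
  cat(sprintf("subgenome_call (%s): O alleles %d, P' alleles %d (coverage %.0f%%) -> %s\n",
              x$locus, x$hsv_matches_O, x$hsv_matches_P, 100 * x$coverage, x$call))
  invisible(x)
}
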