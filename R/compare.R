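# Homoeologue pairing between two sub-genome regions, per-element identity
# comparison, region summary statistics and per-pair aggregation.

.norm_fn <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

# Genes whose span intersects an interval (NULL interval = all genes)
.genes_in_interval <- function(region, interval = NULL) {
  if (is.null(interval)) return(region$genes)
  Filter(function(g) {
    sp <- gene_span(g)
    sp[["start"]] <= interval[2] && sp[["end"]] >= interval[1]
  }, region$genes)
}

# Longest order-preserving chain of candidate pairs (i, j), maximising chain
# length and breaking ties by total weight. Classic quadratic DP over pairs
# sorted by (i, j).
.order_preserving_matching <- function(cand) {
  if (nrow(cand) == 0L) return(integer(0))
  o <- order(cand$i, cand$j)
  cand <- cand[o, ]
  n <- nrow(cand)
  len <- rep(1L, n)
  wt <- cand$w
  prev <- rep(NA_integer_, n)
  for (k in seq_len(n)) {
    for (m in seq_len(k - 1L)) {
      if (cand$i[m] < cand$i[k] && cand$j[m] < cand$j[k]) {
        cl <- len[m] + 1L
        cw <- wt[m] + cand$w[k]
        if (cl > len[k] || (cl == len[k] && cw > wt[k])) {
          len[k] <- cl
          wt[k] <- cw
          prev[k] <- m
        }
      }
    }
  }
  best <- which(len == max(len))
  best <- best[which.max(wt[best])]
  chain <- integer(0)
  k <- best
  while (!is.na(k)) {
    chain <- c(k, chain)
    k <- prev[k]
  }
  o[chain]
}

#' Pair homoeologous genes between two sub-genome regions
#'
#' Candidate pairs are genes sharing the same normalised putative-function
#' string (lower-cased, whitespace collapsed); duplicates are disambiguated
#' by protein identity, and the final pairing is the longest chain of
#' candidates that preserves genomic order in both regions (ties broken by
#' higher total protein identity). Genes in the compared intervals that end
#' up unpaired are reported as unique to their sub-genome.
#'
#' @param region_o,region_p [annotated_region()] objects for the two
#'   sub-genomes.
#' @param params [alignment_params()] for the disambiguating protein
#'   alignments.
#' @param overlap_o,overlap_p Optional `c(start, end)` intervals restricting
#'   the comparison to the overlapping parts of the two clones (defaults to
#'   the full regions).
#' @return An object of class `region_comparison`: `pairs` (data frame
#'   `gene_o`, `gene_p`, `protein_identity`), `unique_o`, `unique_p`
#'   (character vectors of gene ids), the regions and overlap intervals.
#' @export
pair_homoeologues <- function(region_o, region_p, params = alignment_params(),
                              overlap_o = NULL, overlap_p = NULL) {
  stopifnot(inherits(region_o, "annotated_region"),
            inherits(region_p, "annotated_region"))
  genes_o <- .genes_in_interval(region_o, overlap_o)
  genes_p <- .genes_in_interval(region_p, overlap_p)
  fo <- vapply(genes_o, function(g) .norm_fn(g$fn), character(1))
  fp <- vapply(genes_p, function(g) .norm_fn(g$fn), character(1))

  cand <- do.call(rbind, lapply(seq_along(genes_o), function(i) {
    js <- which(fp == fo[i] & nzchar(fo[i]))
    if (length(js) == 0L) return(NULL)
    data.frame(i = i, j = js)
  }))
  if (is.null(cand)) cand <- data.frame(i = integer(0), j = integer(0))

  # disambiguation weight: protein identity of the candidate pair (only
  # computed where a function string is shared)
  cand$w <- vapply(seq_len(nrow(cand)), function(k) {
    cds_o <- spliced_cds(region_o, genes_o[[cand$i[k]]])
    cds_p <- spliced_cds(region_p, genes_p[[cand$j[k]]])
    aa_o <- paste(translate_codons(split_codons(cds_o)), collapse = "")
    aa_p <- paste(translate_codons(split_codons(cds_p)), collapse = "")
    aa_o <- gsub("\\*+$", "", aa_o)
    aa_p <- gsub("\\*+$", "", aa_p)
    if (!nzchar(aa_o) || !nzchar(aa_p)) return(0)
    global_align(aa_o, aa_p, params, type = "protein")$identity_pct
  }, numeric(1))

  sel <- .order_preserving_matching(cand)
  pairs <- cand[sel, , drop = FALSE]
  ids_o <- vapply(genes_o, `[[`, character(1), "id")
  ids_p <- vapply(genes_p, `[[`, character(1), "id")
  pair_df <- data.frame(
    gene_o = ids_o[pairs$i], gene_p = ids_p[pairs$j],
    protein_identity = pairs$w, stringsAsFactors = FALSE
  )
  structure(
    list(
      region_o = region_o, region_p = region_p,
      overlap_o = overlap_o, overlap_p = overlap_p,
      pairs = pair_df,
      unique_o = setdiff(ids_o, pair_df$gene_o),
      unique_p = setdiff(ids_p, pair_df$gene_p)
    ),
    class = "region_comparison"
  )
}

#' @export
print.region_comparison <- function(x, ...) {
  cat(sprintf("region_comparison %s vs %s: %d homoeologue pairs, %d/%d unique genes\n",
              x$region_o$name, x$region_p$name, nrow(x$pairs),
              length(x$unique_o), length(x$unique_p)))
  invisible(x)
}

#' Detect the overlapping interval of two clone sequences
#'
#' Either takes the span of the order-preserving homoeologue pairing
#' (`method = "genes"`, cheap and usable at any scale) or the band of the
#' best local alignment of the two sequences (`method = "align"`, for
#' clone-sized inputs). Manual intervals always take precedence via the
#' `overlap_o` / `overlap_p` arguments of downstream functions.
#'
#' @param region_o,region_p [annotated_region()] objects.
#' @param method `"genes"` or `"align"`.
#' @param params [alignment_params()] (alignment method only).
#' @param pad Bases of flanking sequence added around the paired-gene span
#'   (genes method).
#' @return List with `overlap_o` and `overlap_p`, each `c(start, end)`.
#' @export
detect_overlap <- function(region_o, region_p, method = c("genes", "align"),
                           params = alignment_params(), pad = 1000L) {
  method <- match.arg(method)
  if (method == "align") {
    aln <- local_align(region_o$sequence, region_p$sequence, params)
    if (aln$score <= 0) stop("no local similarity between the two regions")
    return(list(overlap_o = c(aln$start_a, aln$end_a),
                overlap_p = c(aln$start_b, aln$end_b)))
  }
  cmp <- pair_homoeologues(region_o, region_p, params)
  if (nrow(cmp$pairs) == 0L) stop("no homoeologue pairs; cannot infer overlap")
  span <- function(region, ids) {
    sp <- vapply(ids, function(id) gene_span(region_gene(region, id)), numeric(2))
    c(max(1L, min(sp) - pad), min(nchar(region$sequence), max(sp) + pad))
  }
  list(overlap_o = span(region_o, cmp$pairs$gene_o),
       overlap_p = span(region_p, cmp$pairs$gene_p))
}

#' Per-element comparison of a homoeologous gene pair
#'
#' Globally aligns exons element-wise (matched positionally from the 5' end
#' of the transcript), introns likewise, and the two proteins; computes
#' percent identities, protein similarity and the structure-match flag
#' (equal exon counts). Surplus elements of the gene with more exons or
#' introns are reported unmatched and excluded from means. Single-intron
#' comparisons on single-exon genes are reported as missing (`NA`), not 0.
#'
#' @param comparison A [pair_homoeologues()] result (for the regions), or
#'   `NULL` if both regions are given explicitly.
#' @param gene_o,gene_p Gene ids of the pair to compare.
#' @param region_o,region_p Regions (defaulting to those in `comparison`).
#' @param params [alignment_params()].
#' @return An object of class `homoeolog_pair`: element identity vectors,
#'   their means, protein identity/similarity, `structure_match`, surplus
#'   element counts and the spliced CDSs (for downstream Ks/Ka estimation).
#' @export
compare_gene_structure <- function(comparison = NULL, gene_o, gene_p,
                                   region_o = comparison$region_o,
                                   region_p = comparison$region_p,
                                   params = alignment_params()) {
  go <- region_gene(region_o, gene_o)
  gp <- region_gene(region_p, gene_p)

  exon_seq <- function(region, gene) {
    s <- substring(region$sequence, gene$exons[, 1], gene$exons[, 2])
    if (gene$strand == "-") s <- rev(vapply(s, .revcomp, character(1)))
    unname(s)
  }
  eo <- exon_seq(region_o, go)
  ep <- exon_seq(region_p, gp)
  io <- gene_introns(region_o, go)
  ip <- gene_introns(region_p, gp)

  elem_ident <- function(a, b) {
    n <- min(length(a), length(b))
    if (n == 0L) return(numeric(0))
    vapply(seq_len(n), function(k) {
      global_align(a[k], b[k], params)$identity_pct
    }, numeric(1))
  }
  exon_id <- elem_ident(eo, ep)
  intron_id <- elem_ident(io, ip)

  cds_o <- spliced_cds(region_o, go)
  cds_p <- spliced_cds(region_p, gp)
  aa_o <- gsub("\\*+$", "", paste(translate_codons(split_codons(cds_o)), collapse = ""))
  aa_p <- gsub("\\*+$", "", paste(translate_codons(split_codons(cds_p)), collapse = ""))
  if (!nzchar(aa_o) || !nzchar(aa_p)) stop("untranslatable CDS in pair ",
                                           gene_o, "/", gene_p)
  paln <- global_align(aa_o, aa_p, params, type = "protein")

  structure(
    list(
      gene_o = gene_o, gene_p = gene_p,
      exon_identities = exon_id,
      intron_identities = if (length(intron_id)) intron_id else NA_real_,
      mean_exon_identity = if (length(exon_id)) mean(exon_id) else NA_real_,
      mean_intron_identity = if (length(intron_id)) mean(intron_id) else NA_real_,
      protein_identity = paln$identity_pct,
      protein_similarity = paln$similarity_pct,
      structure_match = nrow(go$exons) == nrow(gp$exons),
      surplus_exons_o = max(0L, length(eo) - length(ep)),
      surplus_exons_p = max(0L, length(ep) - length(eo)),
      cds_o = cds_o, cds_p = cds_p,
      kaks = NULL
    ),
    class = "homoeolog_pair"
  )
}

#' @export
print.homoeolog_pair <- function(x, ...) {
  cat(sprintf("homoeolog_pair %s/%s: exon %.1f%%, intron %s, protein %.1f%% (sim %.1f%%)%s\n",
              x$gene_o, x$gene_p, x$mean_exon_identity,
              if (is.na(x$mean_intron_identity)) "-" else
                sprintf("%.1f%%", x$mean_intron_identity),
              x$protein_identity, x$protein_similarity,
              if (x$structure_match) "" else " [exon count differs]"))
  invisible(x)
}

#' Region summary statistics
#'
#' Length, gene count, gene incidence (bp per gene) and the percentage of
#' the region covered by gene space (genomic span from first to last exon,
#' introns included, overlapping spans merged), plus mean exon and intron
#' lengths — the per-clone characteristics table of a BAC comparison.
#'
#' @param region An [annotated_region()].
#' @param restrict_to Optional `c(start, end)` interval; genes whose span
#'   intersects it are counted, spans clipped to it.
#' @return An object of class `region_summary` (a one-row data frame with
#'   `name`, `length_bp`, `n_genes`, `gene_incidence_bp`, `gene_space_pct`,
#'   `mean_exon_len`, `mean_intron_len`).
#' @export
region_summary <- function(region, restrict_to = NULL) {
  stopifnot(inherits(region, "annotated_region"))
  len_total <- nchar(region$sequence)
  if (is.null(restrict_to)) {
    interval <- c(1L, len_total)
  } else {
    interval <- as.integer(restrict_to)
    if (interval[1] < 1L || interval[2] > len_total || interval[1] > interval[2]) {
      stop("restrict_to interval outside region")
    }
  }
  length_bp <- interval[2] - interval[1] + 1L
  genes <- .genes_in_interval(region, interval)
  n_genes <- length(genes)
  if (n_genes > 0L) {
    spans <- t(vapply(genes, gene_span, numeric(2)))
    spans[, 1] <- pmax(spans[, 1], interval[1])
    spans[, 2] <- pmin(spans[, 2], interval[2])
    merged <- IRanges::reduce(IRanges::IRanges(spans[, 1], spans[, 2]))
    covered <- sum(BiocGenerics::width(merged))
    exon_lens <- unlist(lapply(genes, function(g) g$exons[, 2] - g$exons[, 1] + 1L))
    intron_lens <- unlist(lapply(genes, function(g) {
      if (nrow(g$exons) < 2L) return(integer(0))
      g$exons[-1, 1] - g$exons[-nrow(g$exons), 2] - 1L
    }))
    gene_incidence <- round(length_bp / n_genes)
    gene_space <- 100 * covered / length_bp
    mean_exon <- mean(exon_lens)
    mean_intron <- if (length(intron_lens)) mean(intron_lens) else NA_real_
  } else {
    gene_incidence <- NA_real_
    gene_space <- 0
    mean_exon <- NA_real_
    mean_intron <- NA_real_
  }
  out <- data.frame(
    name = region$name, sub_genome = region$sub_genome,
    length_bp = length_bp, n_genes = n_genes,
    gene_incidence_bp = gene_incidence, gene_space_pct = gene_space,
    mean_exon_len = mean_exon, mean_intron_len = mean_intron,
    stringsAsFactors = FALSE
  )
  class(out) <- c("region_summary", "data.frame")
  out
}

#' Aggregate statistics over homoeologue pairs
#'
#' Column means of exon identity, intron identity, protein identity,
#' protein similarity, Ks and Ka over a set of homoeologue pairs. Pairs
#' lacking the protein-level statistics (e.g. compared over partial
#' alignments only) are excluded entirely when `exclude_incomplete = TRUE`
#' (the convention of the published summary row); pairs missing an
#' individual statistic (e.g. intron identity of single-exon genes) are
#' excluded from that mean only. Identities are reported at 2 decimal
#' places and Ks/Ka at 4, the table print precision.
#'
#' @param pairs A data frame with columns `exon_identity`,
#'   `intron_identity`, `protein_identity`, `protein_similarity`, `Ks`,
#'   `Ka` (extra columns ignored), or a list of `homoeolog_pair` objects.
#' @param exclude_incomplete Drop rows with missing protein identity before
#'   averaging (default `TRUE`).
#' @return One-row data frame of the six means.
#' @export
aggregate_pair_stats <- function(pairs, exclude_incomplete = TRUE) {
  if (is.list(pairs) && !is.data.frame(pairs)) {
    stopifnot(all(vapply(pairs, inherits, logical(1), "homoeolog_pair")))
    pairs <- do.call(rbind, lapply(pairs, function(p) {
      data.frame(
        exon_identity = p$mean_exon_identity,
        intron_identity = p$mean_intron_identity,
        protein_identity = p$protein_identity,
        protein_similarity = p$protein_similarity,
        Ks = if (is.null(p$kaks)) NA_real_ else p$kaks$Ks,
        Ka = if (is.null(p$kaks)) NA_real_ else p$kaks$Ka
      )
    }))
  }
  if (nrow(pairs) == 0L) stop("no pairs to aggregate")
  if (exclude_incomplete) {
    pairs <- pairs[!is.na(pairs$protein_identity), , drop = FALSE]
    if (nrow(pairs) == 0L) stop("no complete pairs to aggregate")
  }
  data.frame(
    mean_exon_identity = round(mean(pairs$exon_identity, na.rm = TRUE), 2),
    mean_intron_identity = round(mean(pairs$intron_identity, na.rm = TRUE), 2),
    mean_protein_identity = round(mean(pairs$protein_identity, na.rm = TRUE), 2),
    mean_protein_similarity = round(mean(pairs$protein_similarity, na.rm = TRUE), 2),
    mean_Ks = round(mean(pairs$Ks, na.rm = TRUE), 4),
    mean_Ka = round(mean(pairs$Ka, na.rm = TRUE), 4)
  )
}
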