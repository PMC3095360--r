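# Domain types (annotated_region, gene_model, feature_interval) and file IO:
# FASTA, GFF3 and tabular/JSON result writing. All coordinates are 1-based
# closed (GFF3 convention) everywhere in the package; conversion to other
# conventions happens only inside alignment kernels.

#' Gene model
#'
#' A protein-coding gene: an ordered set of exons (1-based closed genomic
#' intervals), a strand, a free-text putative function used for homoeologue
#' pairing, and a CDS phase.
#'
#' @param id Gene identifier (unique within a region).
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix or data frame of exon `start`, `end`
#'   (1-based closed), sorted in genomic order, non-overlapping.
#' @param fn Putative function (free text); homoeologue matching compares it
#'   after lower-casing and whitespace collapsing only.
#' @param cds_phase Phase of the first codon (0, 1 or 2).
#' @return An object of class `gene_model`.
#' @examples
#' gene_model("g1", "+", cbind(c(1, 201), c(100, 400)), "protein kinase")
#' @export
gene_model <- function(id, strand, exons, fn = "", cds_phase = 0L) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  exons <- as.matrix(exons)
  if (ncol(exons) != 2L) stop("exons must have two columns (start, end)")
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  if (any(exons[, 1] > exons[, 2])) stop("exon start > end")
  if (nrow(exons) > 1L) {
    o <- order(exons[, 1])
    exons <- exons[o, , drop = FALSE]
    if (any(exons[-1, 1] <= exons[-nrow(exons), 2])) {
      stop("exons overlap in gene ", id)
    }
  }
  if (sum(exons[, 2] - exons[, 1] + 1L) < 3L) {
    stop("spliced CDS of gene ", id, " is shorter than one codon")
  }
  if (!cds_phase %in% 0:2) stop("cds_phase must be 0, 1 or 2")
  structure(
    list(id = id, strand = strand, exons = exons, fn = fn,
         cds_phase = as.integer(cds_phase)),
    class = "gene_model"
  )
}

#' Feature interval (e.g. a transposable element annotation)
#'
#' @param label Feature class label (e.g. `"Copia"`, `"Gypsy"`,
#'   `"DNA transposon"`, `"non-LTR"`).
#' @param start,end 1-based closed coordinates, `start <= end`.
#' @param strand `"+"`, `"-"` or `"."`.
#' @return An object of class `feature_interval`.
#' @export
feature_interval <- function(label, start, end, strand = ".") {
  stopifnot(start <= end, start >= 1)
  if (!strand %in% c("+", "-", ".")) stop("strand must be '+', '-' or '.'")
  structure(
    list(label = label, start = as.integer(start), end = as.integer(end),
         strand = strand),
    class = "feature_interval"
  )
}

#' Annotated genomic region
#'
#' A contiguous DNA sequence with gene models, optional transposable-element
#' features and a sub-genome label — the unit every analysis stage consumes.
#'
#' @param name Region name.
#' @param sequence DNA string (A, C, G, T, N).
#' @param genes List of [gene_model()] objects (sorted by start on
#'   construction; identifiers must be unique).
#' @param tes List of [feature_interval()] objects.
#' @param sub_genome `"O"`, `"P'"` or `"unknown"`.
#' @return An object of class `annotated_region`.
#' @examples
#' g <- gene_model("g1", "+", cbind(4, 12), "toy")
#' r <- annotated_region("r", "AAAATGGCTTGATTTT", genes = list(g))
#' @export
annotated_region <- function(name, sequence, genes = list(), tes = list(),
                             sub_genome = c("unknown", "O", "P'")) {
  sub_genome <- match.arg(sub_genome)
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) {
    stop("sequence of region ", name, " contains non-ACGTN characters")
  }
  len <- nchar(sequence)
  stopifnot(all(vapply(genes, inherits, logical(1), "gene_model")))
  stopifnot(all(vapply(tes, inherits, logical(1), "feature_interval")))
  for (g in genes) {
    if (min(g$exons[, 1]) < 1L || max(g$exons[, 2]) > len) {
      stop("gene ", g$id, " lies outside region ", name)
    }
  }
  for (te in tes) {
    if (te$start < 1L || te$end > len) {
      stop("TE feature lies outside region ", name)
    }
  }
  ids <- vapply(genes, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate gene identifiers in region ", name)
  if (length(genes) > 1L) {
    genes <- genes[order(vapply(genes, function(g) min(g$exons[, 1]), numeric(1)))]
  }
  structure(
    list(name = name, sub_genome = sub_genome, sequence = sequence,
         genes = genes, tes = tes),
    class = "annotated_region"
  )
}

#' @export
print.annotated_region <- function(x, ...) {
  cat(sprintf("annotated_region '%s' (%s sub-genome): %d bp, %d genes, %d TE features\n",
              x$name, x$sub_genome, nchar(x$sequence), length(x$genes),
              length(x$tes)))
  invisible(x)
}

# Genomic span of a gene (first exon start to last exon end)
gene_span <- function(gene) {
  c(start = as.numeric(min(gene$exons[, 1])),
    end = as.numeric(max(gene$exons[, 2])))
}

# Look a gene up by id
region_gene <- function(region, id) {
  for (g in region$genes) if (g$id == id) return(g)
  stop("no gene '", id, "' in region ", region$name)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Extract the spliced CDS of a gene
#'
#' Concatenates exon sequences in transcript (5' to 3') order, reverse
#' complementing for minus-strand genes.
#'
#' @param region An [annotated_region()].
#' @param gene A [gene_model()] belonging to `region`, or a gene id.
#' @return The spliced CDS as a single string.
#' @export
spliced_cds <- function(region, gene) {
  if (is.character(gene)) gene <- region_gene(region, gene)
  parts <- substring(region$sequence, gene$exons[, 1], gene$exons[, 2])
  cds <- paste(parts, collapse = "")
  if (gene$strand == "-") cds <- .revcomp(cds)
  if (gene$cds_phase > 0L) cds <- substring(cds, gene$cds_phase + 1L)
  cds
}

# Extract intron sequences in transcript order (empty for single-exon genes)
gene_introns <- function(region, gene) {
  if (is.character(gene)) gene <- region_gene(region, gene)
  n <- nrow(gene$exons)
  if (n < 2L) return(character(0))
  starts <- gene$exons[-n, 2] + 1L
  ends <- gene$exons[-1, 1] - 1L
  introns <- substring(region$sequence, starts, ends)
  if (gene$strand == "-") introns <- rev(vapply(introns, .revcomp, character(1)))
  unname(introns)
}

#' Read a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of upper-cased sequences; names are
#'   truncated at the first whitespace. Errors on empty files, duplicate
#'   names and non-IUPAC characters.
#' @export
read_fasta <- function(path) {
  # read byte-faithfully (readDNAStringSet silently drops invalid letters),
  # then validate against the IUPAC DNA alphabet
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ", conditionMessage(e))
  )
  if (length(set) == 0L) stop("FASTA file '", path, "' contains no records")
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm)) stop("duplicate record names in '", path, "'")
  seqs <- toupper(as.character(set))
  if (any(grepl("[^ACGTUNMRWSYKVHDB-]", seqs))) {
    stop("malformed FASTA '", path, "': non-IUPAC characters in sequence")
  }
  stats::setNames(seqs, nm)
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# Parse the attribute column of a GFF3 row into a named character vector
.parse_gff_attrs <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  kv <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
  vals <- vapply(kv, function(p) if (length(p) >= 2) utils::URLdecode(p[2]) else "",
                 character(1))
  stats::setNames(vals, vapply(kv, `[[`, character(1), 1))
}

#' Read gene models and TE features from a GFF3 file
#'
#' Assembles an [annotated_region()] from `gene` / `mRNA` / `exon` (or `CDS`)
#' rows and optional `repeat_region` rows of a GFF3 file. Exon rows may be
#' parented on the gene directly or via an mRNA row. The putative function is
#' read from the gene row's `function`, `Note` or `description` attribute.
#'
#' @param path Path to a GFF3 file (the `##gff-version` header is required).
#' @param sequence The region's DNA sequence (string), e.g. from
#'   [read_fasta()].
#' @param name Region name; defaults to the GFF3 seqid.
#' @param sub_genome Sub-genome label for the region.
#' @return An [annotated_region()].
#' @export
read_gff3 <- function(path, sequence, name = NULL,
                      sub_genome = c("unknown", "O", "P'")) {
  sub_genome <- match.arg(sub_genome)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !grepl("^##gff-version", lines[1])) {
    stop("'", path, "' is missing the ##gff-version header")
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) == 0L) {
    return(annotated_region(name %||% "region", sequence, sub_genome = sub_genome))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(f) != 9L)) stop("GFF3 rows must have 9 tab-separated columns")
  tab <- data.frame(
    seqid = vapply(f, `[[`, character(1), 1),
    type = vapply(f, `[[`, character(1), 3),
    start = as.integer(vapply(f, `[[`, character(1), 4)),
    end = as.integer(vapply(f, `[[`, character(1), 5)),
    strand = vapply(f, `[[`, character(1), 7),
    phase = vapply(f, `[[`, character(1), 8),
    attrs = vapply(f, `[[`, character(1), 9),
    stringsAsFactors = FALSE
  )
  attrs <- lapply(tab$attrs, .parse_gff_attrs)
  ids <- vapply(attrs, .attr_get, character(1), "ID")
  parents <- vapply(attrs, .attr_get, character(1), "Parent")

  if (is.null(name)) name <- tab$seqid[1]
  seqlen <- nchar(sequence)

  # map mRNA id -> gene id so exons can be parented either way
  mrna_parent <- stats::setNames(
    parents[tab$type == "mRNA"], ids[tab$type == "mRNA"]
  )
  gene_rows <- which(tab$type == "gene")
  genes <- list()
  for (gi in gene_rows) {
    gid <- ids[gi]
    if (is.na(gid)) stop("gene row without ID attribute in '", path, "'")
    fn <- .attr_get(attrs[[gi]], "function", "Note", "description")
    if (is.na(fn)) fn <- ""
    child_types <- c("exon", "CDS")
    kid <- which(tab$type %in% child_types &
                   (parents == gid |
                      (!is.na(parents) & parents %in% names(mrna_parent) &
                         mrna_parent[parents] == gid)))
    # prefer exon rows; fall back to CDS rows
    ek <- kid[tab$type[kid] == "exon"]
    if (length(ek) == 0L) ek <- kid[tab$type[kid] == "CDS"]
    if (length(ek) == 0L) stop("gene ", gid, " has no exon or CDS rows")
    ex <- cbind(tab$start[ek], tab$end[ek])
    if (max(ex[, 2]) > seqlen || min(ex[, 1]) < 1L) {
      stop("exon of gene ", gid, " lies outside the sequence (length ",
           seqlen, ")")
    }
    phase <- suppressWarnings(as.integer(tab$phase[ek[1]]))
    if (is.na(phase)) phase <- 0L
    genes[[length(genes) + 1L]] <- gene_model(
      gid, tab$strand[gi], ex, fn = fn, cds_phase = phase
    )
  }
  # orphan exon check
  exon_rows <- which(tab$type %in% c("exon", "CDS"))
  known <- c(ids[gene_rows], names(mrna_parent))
  bad <- exon_rows[!is.na(parents[exon_rows]) & !(parents[exon_rows] %in% known)]
  if (length(bad)) {
    stop("exon row(s) with missing parent feature: ",
         paste(unique(parents[bad]), collapse = ", "))
  }
  tes <- lapply(which(tab$type == "repeat_region"), function(i) {
    lab <- .attr_get(attrs[[i]], "class", "Name")
    if (is.na(lab)) lab <- "repeat"
    feature_interval(lab, tab$start[i], tab$end[i], tab$strand[i])
  })
  annotated_region(name, sequence, genes = genes, tes = tes,
                   sub_genome = sub_genome)
}

#' Write an annotated region's features to a GFF3 file
#'
#' @param region An [annotated_region()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(region, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("##sequence-region %s 1 %d", region$name,
                     nchar(region$sequence)), con)
  for (g in region$genes) {
    sp <- gene_span(g)
    writeLines(sprintf("%s\thomoeolog\tgene\t%d\t%d\t.\t%s\t.\tID=%s;function=%s",
                       region$name, sp[["start"]], sp[["end"]], g$strand, g$id,
                       utils::URLencode(g$fn, reserved = TRUE)), con)
    for (i in seq_len(nrow(g$exons))) {
      writeLines(sprintf("%s\thomoeolog\texon\t%d\t%d\t.\t%s\t%d\tID=%s.exon%d;Parent=%s",
                         region$name, g$exons[i, 1], g$exons[i, 2], g$strand,
                         if (i == 1L) g$cds_phase else 0L, g$id, i, g$id), con)
    }
  }
  for (te in region$tes) {
    writeLines(sprintf("%s\thomoeolog\trepeat_region\t%d\t%d\t.\t%s\t.\tclass=%s",
                       region$name, te$start, te$end, te$strand,
                       utils::URLencode(te$label, reserved = TRUE)), con)
  }
  invisible(path)
}

# Fixed print precision used for result tables: identities and other
# percentages at 2 dp, evolutionary rates and likelihoods at 4 dp.
.round_result_columns <- function(df) {
  pct_pat <- "identity|similarity|quality|pct|space"
  rate_pat <- "^(ks|ka|omega|kappa|t|lnl|median_ks|mean_ks|sd_ks)$"
  for (nm in names(df)) {
    if (!is.numeric(df[[nm]])) next
    low <- tolower(nm)
    if (grepl(pct_pat, low)) {
      df[[nm]] <- round(df[[nm]], 2)
    } else if (grepl(rate_pat, low)) {
      df[[nm]] <- round(df[[nm]], 4)
    }
  }
  df
}

#' Write result tables to TSV or JSON
#'
#' Writes analysis tables with deterministic column order and fixed numeric
#' precision: percentage columns at 2 decimal places, `Ks`/`Ka`/`omega`/
#' `kappa`/`t`/`lnL` columns at 4 (the precision the per-gene tables are
#' reported at).
#'
#' @param tables A data frame, or a named list of data frames / lists (JSON
#'   only).
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(tables, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    if (!is.data.frame(tables)) stop("TSV output requires a single data frame")
    df <- .round_result_columns(as.data.frame(tables))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    obj <- if (is.data.frame(tables)) {
      .round_result_columns(as.data.frame(tables))
    } else if (is.list(tables)) {
      lapply(tables, function(t) if (is.data.frame(t)) .round_result_columns(t) else t)
    } else {
      tables
    }
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# First present attribute among `keys`, else NA
.attr_get <- function(a, ...) {
  for (k in c(...)) if (k %in% names(a)) return(a[[k]])
  NA_character_
}
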