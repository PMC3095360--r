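# End-to-end orchestration: run the homoeologue comparison or the synteny
# scan from a configuration list or plain key=value file, writing result
# tables and a reproducibility manifest.

#' Read a pipeline configuration file
#'
#' Plain `key = value` text format (one pair per line, `#` comments).
#' Values that parse as numbers become numeric; `true`/`false` become
#' logical.
#'
#' @param path Path to the configuration file.
#' @return Named list of configuration values.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else
      if (tolower(val) %in% c("true", "false")) as.logical(toupper(val)) else val
  }
  out
}

.config_get <- function(config, key, default) {
  if (!is.null(config[[key]])) config[[key]] else default
}

# Reproducibility manifest: configuration echo + hash, package version, seed
.write_manifest <- function(config, out_dir, extra = list()) {
  cfg <- config[!vapply(config, function(x) is.environment(x) ||
                          inherits(x, "annotated_region"), logical(1))]
  tmp <- tempfile()
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest <- c(list(
    package_version = as.character(utils::packageVersion("homoeolog")),
    config = cfg,
    config_md5 = unname(tools::md5sum(tmp))
  ), extra)
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
}

.load_region <- function(config, prefix) {
  obj <- config[[paste0("region_", prefix)]]
  if (inherits(obj, "annotated_region")) return(obj)
  fasta <- config[[paste0("fasta_", prefix)]]
  gff <- config[[paste0("gff_", prefix)]]
  if (is.null(fasta) || is.null(gff)) {
    stop("config must provide region_", prefix, " or fasta_", prefix,
         " + gff_", prefix)
  }
  seqs <- read_fasta(fasta)
  read_gff3(gff, seqs[[1]], name = names(seqs)[1],
            sub_genome = if (prefix == "o") "O" else "P'")
}

#' Run the homoeologous-region comparison pipeline
#'
#' Pairs homoeologues between two annotated regions, computes per-pair exon
#' /intron/protein identities, GY94 Ks/Ka, the clock-based divergence-time
#' summary, region summaries, and (optionally) the sliding-window identity
#' profile of the aligned overlap; writes per-pair and summary tables plus
#' a reproducibility manifest to `out_dir`.
#'
#' @param config Named list (or a file read with
#'   [read_pipeline_config()]): `region_o` / `region_p`
#'   ([annotated_region()] objects) or `fasta_o`+`gff_o` /
#'   `fasta_p`+`gff_p` paths; optional `out_dir` (default: no files
#'   written), `clock_rate` (6.1e-9), `gap_open`, `gap_extend`,
#'   `window_size` (100), `step` (25), `profile` (compute the identity
#'   profile; default `TRUE` for regions up to `profile_max_len`, 200 kb),
#'   `seed`.
#' @return List: `comparison`, `pairs` (per-pair data frame), `aggregate`,
#'   `clock` (or `NULL` with a warning when no pairs), `summaries`,
#'   `profile`.
#' @export
run_compare <- function(config) {
  region_o <- .load_region(config, "o")
  region_p <- .load_region(config, "p")
  params <- alignment_params(
    gap_open = .config_get(config, "gap_open", 10),
    gap_extend = .config_get(config, "gap_extend", 0.5)
  )
  rate <- .config_get(config, "clock_rate", 6.1e-9)
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  overlap_o <- config$overlap_o
  overlap_p <- config$overlap_p
  cmp <- pair_homoeologues(region_o, region_p, params,
                           overlap_o = overlap_o, overlap_p = overlap_p)

  pair_objs <- list()
  rows <- list()
  for (k in seq_len(nrow(cmp$pairs))) {
    hp <- compare_gene_structure(cmp, cmp$pairs$gene_o[k], cmp$pairs$gene_p[k],
                                 params = params)
    kaks <- tryCatch({
      ca <- build_codon_alignment(hp$cds_o, hp$cds_p,
                                  ids = c(hp$gene_o, hp$gene_p),
                                  params = params)
      estimate_gy94(ca)
    }, error = function(e) {
      warning("Ks/Ka unavailable for ", hp$gene_o, "/", hp$gene_p, ": ",
              conditionMessage(e))
      NULL
    })
    hp$kaks <- kaks
    pair_objs[[k]] <- hp
    rows[[k]] <- data.frame(
      gene_o = hp$gene_o, gene_p = hp$gene_p,
      n_exons_o = length(hp$exon_identities) + hp$surplus_exons_o,
      structure_match = hp$structure_match,
      exon_identity = hp$mean_exon_identity,
      intron_identity = hp$mean_intron_identity,
      protein_identity = hp$protein_identity,
      protein_similarity = hp$protein_similarity,
      Ks = if (is.null(kaks)) NA_real_ else kaks$Ks,
      Ka = if (is.null(kaks)) NA_real_ else kaks$Ka,
      omega = if (is.null(kaks)) NA_real_ else kaks$omega,
      stringsAsFactors = FALSE
    )
  }
  pairs_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_o = character(0), gene_p = character(0))

  agg <- if (length(rows)) aggregate_pair_stats(pairs_df) else NULL
  ks <- pairs_df$Ks[!is.na(pairs_df$Ks)]
  clock <- NULL
  if (length(ks) > 0L) {
    clock <- clock_report(stats::setNames(
      ks, paste(pairs_df$gene_o, pairs_df$gene_p, sep = "/")[!is.na(pairs_df$Ks)]
    ), rate)
  } else {
    warning("no Ks estimates; clock summary skipped")
  }

  summaries <- rbind(region_summary(region_o, overlap_o),
                     region_summary(region_p, overlap_p))

  profile <- NULL
  max_len <- .config_get(config, "profile_max_len", 2e5)
  want_profile <- .config_get(config, "profile", TRUE)
  if (want_profile &&
      nchar(region_o$sequence) <= max_len &&
      nchar(region_p$sequence) <= max_len) {
    seq_o <- region_o$sequence
    seq_p <- region_p$sequence
    if (!is.null(overlap_o)) seq_o <- substring(seq_o, overlap_o[1], overlap_o[2])
    if (!is.null(overlap_p)) seq_p <- substring(seq_p, overlap_p[1], overlap_p[2])
    aln <- global_align(seq_o, seq_p, params)
    profile <- sliding_identity_profile(
      aln,
      window_size = .config_get(config, "window_size", 100),
      step = .config_get(config, "step", 25)
    )
  }

  if (!is.null(out_dir)) {
    write_results(pairs_df, file.path(out_dir, "homoeolog_pairs.tsv"), "tsv")
    write_results(as.data.frame(summaries),
                  file.path(out_dir, "region_summaries.tsv"), "tsv")
    if (!is.null(agg)) {
      write_results(agg, file.path(out_dir, "aggregate_stats.tsv"), "tsv")
    }
    if (!is.null(clock)) {
      jsonlite::write_json(
        list(n_pairs = clock$summary$n_pairs,
             median_ks = clock$summary$median_ks,
             mean_ks = clock$summary$mean_ks,
             sd_ks = clock$summary$sd_ks,
             rate = clock$summary$rate_r,
             T_mya = clock$summary$T_mya),
        file.path(out_dir, "clock_summary.json"),
        auto_unbox = TRUE, digits = NA
      )
    }
    if (!is.null(profile)) {
      write_results(as.data.frame(profile),
                    file.path(out_dir, "identity_profile.tsv"), "tsv")
    }
    .write_manifest(config, out_dir,
                    extra = list(n_pairs = nrow(pairs_df),
                                 unique_o = cmp$unique_o,
                                 unique_p = cmp$unique_p))
  }

  list(comparison = cmp, pairs = pairs_df, pair_objects = pair_objs,
       aggregate = agg, clock = clock, summaries = summaries,
       profile = profile)
}

#' Run the microsynteny scan of a region against reference gene sets
#'
#' Matches the query region's CDSs against each reference CDS set, applies
#' the synteny rule (at least `min_genes` matches at E-value at most
#' `max_evalue`), computes synteny quality, and writes one row per
#' reference.
#'
#' @param config Named list: `region` (an [annotated_region()]), or
#'   `query_cds` (named character vector); `references` (named list of
#'   named CDS vectors); optional `min_genes` (3), `max_evalue` (0.01),
#'   `quality_formula` (`"symmetric"`), `out_dir`.
#' @return Data frame with one row per reference: shared gene count,
#'   quality percentage (NA when no synteny), formula tag.
#' @export
run_synteny <- function(config) {
  if (!is.null(config$region)) {
    region <- config$region
    query <- stats::setNames(
      lapply(region$genes, function(g) spliced_cds(region, g)),
      vapply(region$genes, `[[`, character(1), "id")
    )
    query <- unlist(query)
  } else if (!is.null(config$query_cds)) {
    query <- config$query_cds
  } else {
    stop("config must provide region or query_cds")
  }
  refs <- config$references
  if (is.null(refs) || length(refs) == 0L) stop("config must provide references")
  if (is.null(names(refs))) names(refs) <- paste0("ref", seq_along(refs))
  # search scoring: BLAST-like gaps + calibrated gapped E-value parameters
  base <- synteny_search_params()
  params <- alignment_params(
    gap_open = .config_get(config, "gap_open", base$gap_open),
    gap_extend = .config_get(config, "gap_extend", base$gap_extend),
    ka_lambda = base$ka_lambda, ka_K = base$ka_K
  )
  min_genes <- .config_get(config, "min_genes", 3)
  max_e <- .config_get(config, "max_evalue", 0.01)
  formula <- .config_get(config, "quality_formula", "symmetric")

  rows <- lapply(names(refs), function(nm) {
    m <- match_genes(query, refs[[nm]], params)
    block <- detect_syntenic_region(m, min_genes = min_genes,
                                    max_evalue = max_e,
                                    query_region = "query",
                                    target_region = nm)
    if (is.null(block)) {
      data.frame(reference = nm, n_query_genes = length(query),
                 n_target_genes = length(refs[[nm]]),
                 shared_genes = sum(m$evalue <= max_e),
                 quality_pct = NA_real_, formula = formula,
                 syntenic = FALSE, stringsAsFactors = FALSE)
    } else {
      q <- synteny_quality(block, formula)
      data.frame(reference = nm, n_query_genes = block$n_query_genes,
                 n_target_genes = block$n_target_genes,
                 shared_genes = nrow(block$shared_genes),
                 quality_pct = as.numeric(q), formula = formula,
                 syntenic = TRUE, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (!is.null(config$out_dir)) {
    if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
    write_results(out, file.path(config$out_dir, "synteny_quality.tsv"), "tsv")
    .write_manifest(config, config$out_dir)
  }
  out
}
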