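# Simulator of paired homoeologous regions with known ground truth.
#
# An ancestral region with realistic gene structure is generated first; the
# two sub-genomes then evolve on independent branches: CDSs by sampling
# substitution paths from the GY94 codon chain (61 sense codons, so
# stop-creating changes are structurally impossible), introns and intergenic
# sequence by a kappa-weighted nucleotide process with geometric indels
# (indels never hit coding sequence). Optional segmental deletions with a
# planted breakpoint repeat and sub-genome-specific TE insertions mirror the
# divergence mechanisms observed between allopolyploid sub-genomes.
#
# All sampling for one operation is drawn from a single seeded RNG stream in
# fixed order, so identical parameters give byte-identical output.

#' Simulation parameters
#'
#' Defaults parameterise the generator to the observed structure of
#' homoeologous white clover regions: mean exon length 348 bp, mean intron
#' length 314 bp, 1-5 exons per gene, one gene per 9148 bp, and a genic
#' branch length tuned so the expected Ks between homoeologues is
#' `target_ks` (0.05 by default, giving a realised median Ks near 0.05).
#' Intergenic sequence diverges faster (`intergenic_sub_rate` expected
#' substitutions per site between the sub-genomes) and accumulates
#' geometric indels.
#'
#' @param n_genes Number of genes in the ancestral region.
#' @param mean_exon_len,mean_intron_len Mean element lengths in bp
#'   (geometric-style draws clipped at `min_exon_len` / `min_intron_len`).
#' @param min_exon_len,min_intron_len Lower clips (20 and 50 bp).
#' @param exons_per_gene Integer vector sampled uniformly for the exon
#'   count of each gene.
#' @param target_gene_incidence Region length per gene in bp.
#' @param genic_kappa,genic_omega GY94 parameters of genic evolution.
#' @param target_ks Expected synonymous divergence between homoeologues;
#'   used to derive `genic_t` when the latter is `NULL`.
#' @param genic_t Total genic branch length in expected substitutions per
#'   codon (split equally between the two branches); derived from
#'   `target_ks` by default.
#' @param intergenic_sub_rate Expected substitutions per site between the
#'   two sub-genomes in non-coding sequence (split across both branches).
#' @param indel_rate Expected indel events per non-coding site between the
#'   sub-genomes.
#' @param indel_mean_len Mean indel length (geometric).
#' @param deletion_spec Optional `list(genes = <ancestor gene ids>,
#'   repeat_len = 32)`: a segmental deletion removing those genes from the
#'   P' sub-genome, with a `repeat_len`-bp sequence repeat planted at the
#'   breakpoint.
#' @param te_spec Optional list of `list(class =, length =, sub_genome =)`
#'   entries: TE insertions placed post-divergence into intergenic sequence
#'   of the named sub-genome.
#' @param seed Integer seed; fixed seed implies byte-identical output.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n_genes = 10L, mean_exon_len = 348, mean_intron_len = 314,
                       min_exon_len = 20L, min_intron_len = 50L,
                       exons_per_gene = 1:5, target_gene_incidence = 9148,
                       genic_kappa = 2, genic_omega = 0.2,
                       target_ks = 0.05, genic_t = NULL,
                       intergenic_sub_rate = 0.10, indel_rate = 0.02,
                       indel_mean_len = 5, deletion_spec = NULL,
                       te_spec = NULL, seed = 1L) {
  if (is.null(genic_t)) {
    genic_t <- genic_t_for_ks(target_ks, genic_kappa, genic_omega)
  }
  stopifnot(n_genes >= 1, mean_exon_len >= min_exon_len,
            mean_intron_len >= min_intron_len,
            genic_t >= 0, genic_kappa > 0, genic_omega > 0,
            intergenic_sub_rate >= 0, indel_rate >= 0, indel_mean_len >= 1)
  structure(
    list(n_genes = as.integer(n_genes), mean_exon_len = mean_exon_len,
         mean_intron_len = mean_intron_len, min_exon_len = min_exon_len,
         min_intron_len = min_intron_len, exons_per_gene = exons_per_gene,
         target_gene_incidence = target_gene_incidence,
         genic_kappa = genic_kappa, genic_omega = genic_omega,
         target_ks = target_ks, genic_t = genic_t,
         intergenic_sub_rate = intergenic_sub_rate,
         indel_rate = indel_rate, indel_mean_len = indel_mean_len,
         deletion_spec = deletion_spec, te_spec = te_spec,
         seed = as.integer(seed)),
    class = "sim_params"
  )
}

#' Genic branch length giving a target Ks
#'
#' Inverts the GY94 Ks definition at uniform codon frequencies:
#' `t = Ks * 3 * rho1_S / rho_S`, where `rho_S` is the synonymous share of
#' substitution flow at (`kappa`, `omega`) and `rho1_S` the same share at
#' `omega = 1`.
#'
#' @param ks Target synonymous divergence.
#' @param kappa,omega GY94 parameters.
#' @return Branch length `t` in expected substitutions per codon.
#' @export
genic_t_for_ks <- function(ks, kappa = 2, omega = 0.2) {
  stopifnot(ks >= 0, kappa > 0, omega > 0)
  rhoS <- attr(gy94_rate_matrix(kappa, omega), "rho_syn")
  rho1 <- attr(gy94_rate_matrix(kappa, 1), "rho_syn")
  ks * 3 * rho1 / rhoS
}

# Geometric-style length draw with mean `mean_len`, clipped at `min_len`
.rlen <- function(n, mean_len, min_len) {
  excess <- max(mean_len - min_len, 1)
  min_len + stats::rgeom(n, 1 / excess)
}

.rand_dna <- function(n) {
  paste(sample(.nucs, n, replace = TRUE), collapse = "")
}

.rand_cds <- function(n_codons) {
  tabs <- codon_tables()
  mid <- sample(tabs$codons, n_codons - 2L, replace = TRUE)
  paste(c("ATG", mid, sample(tabs$stops, 1L)), collapse = "")
}

#' Simulate an ancestral annotated region
#'
#' Generates `n_genes` gene models with geometric-style exon/intron lengths,
#' in-frame CDSs with start and stop codons and no internal stops, random
#' strands, and intergenic filler sized so the region length is
#' `n_genes * target_gene_incidence`.
#'
#' @param params A [sim_params()] object.
#' @param set_seed Seed the RNG from `params$seed` first (default `TRUE`).
#' @return An [annotated_region()] named `"ancestor"`.
#' @export
simulate_ancestor <- function(params, set_seed = TRUE) {
  stopifnot(inherits(params, "sim_params"))
  if (set_seed) set.seed(params$seed)
  n <- params$n_genes

  genes <- vector("list", n)
  gene_strings <- character(n)
  for (i in seq_len(n)) {
    k <- if (length(params$exons_per_gene) == 1L) params$exons_per_gene else
      sample(params$exons_per_gene, 1L)
    ex_len <- .rlen(k, params$mean_exon_len, params$min_exon_len)
    # CDS length: multiple of 3, at least 12 codons
    total <- sum(ex_len)
    rem <- total %% 3L
    if (rem > 0L) {
      j <- which.max(ex_len)
      ex_len[j] <- ex_len[j] - rem
    }
    while (sum(ex_len) < 36L) ex_len[which.min(ex_len)] <- ex_len[which.min(ex_len)] + 3L
    in_len <- if (k > 1L) .rlen(k - 1L, params$mean_intron_len, params$min_intron_len)
      else integer(0)
    cds <- .rand_cds(sum(ex_len) %/% 3L)
    introns <- vapply(in_len, .rand_dna, character(1))
    strand <- sample(c("+", "-"), 1L)
    genes[[i]] <- list(
      id = sprintf("g%02d", i), fn = sprintf("simulated protein %d", i),
      strand = strand, exon_lens = ex_len, introns = introns, cds = cds
    )
  }

  gene_total <- sum(vapply(genes, function(g) {
    sum(g$exon_lens) + sum(nchar(g$introns))
  }, numeric(1)))
  intergenic_total <- round(n * params$target_gene_incidence) - gene_total
  if (intergenic_total < 10 * (n + 1)) {
    stop("infeasible target_gene_incidence: genes do not fit in the region")
  }
  w <- stats::runif(n + 1L) + 0.1
  ig_len <- floor(intergenic_total * w / sum(w))
  ig_len[n + 1L] <- intergenic_total - sum(ig_len[seq_len(n)])
  intergenic <- vapply(ig_len, .rand_dna, character(1))

  parts <- .parts_interleave(intergenic, genes)
  .assemble_region("ancestor", parts, sub_genome = "unknown")
}

# Interleave intergenic strings and gene blueprints into a parts list
.parts_interleave <- function(intergenic, genes) {
  parts <- list()
  for (i in seq_along(genes)) {
    parts[[length(parts) + 1L]] <- list(kind = "intergenic", seq = intergenic[[i]])
    parts[[length(parts) + 1L]] <- c(list(kind = "gene"), genes[[i]])
  }
  parts[[length(parts) + 1L]] <- list(kind = "intergenic",
                                      seq = intergenic[[length(intergenic)]])
  parts
}

# Build the genomic string of one gene blueprint and its exon intervals
# relative to the gene start (1-based)
.gene_genomic <- function(g) {
  k <- length(g$exon_lens)
  ex_chunks <- character(k)
  off <- 0L
  for (j in seq_len(k)) {
    ex_chunks[j] <- substring(g$cds, off + 1L, off + g$exon_lens[j])
    off <- off + g$exon_lens[j]
  }
  pieces <- character(0)
  rel <- matrix(0L, nrow = k, ncol = 2)
  pos <- 0L
  for (j in seq_len(k)) {
    rel[j, ] <- c(pos + 1L, pos + g$exon_lens[j])
    pieces <- c(pieces, ex_chunks[j])
    pos <- pos + g$exon_lens[j]
    if (j < k) {
      pieces <- c(pieces, g$introns[j])
      pos <- pos + nchar(g$introns[j])
    }
  }
  seq <- paste(pieces, collapse = "")
  if (g$strand == "-") {
    L <- nchar(seq)
    seq <- .revcomp(seq)
    rel <- cbind(L - rel[, 2] + 1L, L - rel[, 1] + 1L)
    rel <- rel[rev(seq_len(k)), , drop = FALSE]
  }
  list(seq = seq, rel_exons = rel)
}

# Assemble a parts list into an annotated_region, attaching the parts as a
# blueprint attribute for downstream evolution
.assemble_region <- function(name, parts, sub_genome = "unknown") {
  seqs <- character(length(parts))
  gene_models <- list()
  tes <- list()
  pos <- 0L
  for (p in seq_along(parts)) {
    part <- parts[[p]]
    if (part$kind == "gene") {
      gg <- .gene_genomic(part)
      seqs[p] <- gg$seq
      gene_models[[length(gene_models) + 1L]] <- gene_model(
        part$id, part$strand, gg$rel_exons + pos, fn = part$fn
      )
      pos <- pos + nchar(gg$seq)
    } else if (part$kind == "te") {
      seqs[p] <- part$seq
      tes[[length(tes) + 1L]] <- feature_interval(
        part$class, pos + 1L, pos + nchar(part$seq), "+"
      )
      pos <- pos + nchar(part$seq)
    } else {
      seqs[p] <- part$seq
      pos <- pos + nchar(part$seq)
    }
  }
  region <- annotated_region(name, paste(seqs, collapse = ""),
                             genes = gene_models, tes = tes,
                             sub_genome = sub_genome)
  attr(region, "blueprint") <- parts
  region
}

# Recover a parts blueprint from any annotated region (genes must be
# non-overlapping, phase 0)
.region_blueprint <- function(region) {
  if (!is.null(attr(region, "blueprint"))) return(attr(region, "blueprint"))
  parts <- list()
  pos <- 1L
  for (g in region$genes) {
    sp <- gene_span(g)
    if (sp[["start"]] > pos) {
      parts[[length(parts) + 1L]] <- list(
        kind = "intergenic",
        seq = substring(region$sequence, pos, sp[["start"]] - 1L)
      )
    } else {
      parts[[length(parts) + 1L]] <- list(kind = "intergenic", seq = "")
    }
    ex_rel <- g$exons - sp[["start"]] + 1L
    in_seqs <- gene_introns(region, g)
    parts[[length(parts) + 1L]] <- list(
      kind = "gene", id = g$id, fn = g$fn, strand = g$strand,
      exon_lens = {
        lens <- g$exons[, 2] - g$exons[, 1] + 1L
        if (g$strand == "-") rev(lens) else lens
      },
      introns = in_seqs,
      cds = spliced_cds(region, g)
    )
    pos <- sp[["end"]] + 1L
  }
  parts[[length(parts) + 1L]] <- list(
    kind = "intergenic",
    seq = if (pos <= nchar(region$sequence))
      substring(region$sequence, pos, nchar(region$sequence)) else ""
  )
  parts
}

# Precompute per-state transition structure of a GY94 rate matrix for path
# sampling: exit rates, target states, target probabilities, synonymy flags
.path_tables <- function(Q) {
  tabs <- codon_tables()
  rate_out <- -diag(Q)
  targets <- vector("list", tabs$n)
  probs <- vector("list", tabs$n)
  syn <- vector("list", tabs$n)
  for (i in seq_len(tabs$n)) {
    sel <- tabs$pair_from == i
    tg <- tabs$pair_to[sel]
    r <- Q[cbind(i, tg)]
    targets[[i]] <- tg
    probs[[i]] <- r / sum(r)
    syn[[i]] <- tabs$pair_syn[sel]
  }
  list(rate_out = rate_out, targets = targets, probs = probs, syn = syn)
}

# Sample a substitution path of length t (expected substitutions per codon)
# for each codon site; returns evolved codons and realised event counts
.sim_codon_path <- function(codons, pt, t, tabs = codon_tables()) {
  idx <- tabs$codon_index[codons]
  n_syn <- 0L
  n_nonsyn <- 0L
  for (s in seq_along(idx)) {
    i <- idx[s]
    if (is.na(i)) next # non-sense codon (stop, ambiguity): held fixed
    time <- 0
    repeat {
      time <- time + stats::rexp(1L, pt$rate_out[i])
      if (time > t) break
      k <- sample.int(length(pt$targets[[i]]), 1L, prob = pt$probs[[i]])
      if (pt$syn[[i]][k]) n_syn <- n_syn + 1L else n_nonsyn <- n_nonsyn + 1L
      i <- pt$targets[[i]][k]
    }
    idx[s] <- i
  }
  out <- codons
  ok <- !is.na(tabs$codon_index[codons])
  out[ok] <- tabs$codons[idx[ok]]
  list(codons = out, n_syn = n_syn, n_nonsyn = n_nonsyn)
}

# Evolve a non-coding sequence: per-site substitutions (transition
# probability kappa/(kappa+2)) plus Poisson-count geometric indels
.sim_nt_seq <- function(seq, sub_rate, kappa, indel_rate, indel_mean) {
  n <- nchar(seq)
  if (n == 0L) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(n) < sub_rate)
  if (length(hit)) {
    ts_map <- c(A = "G", G = "A", C = "T", T = "C")
    is_ts <- stats::runif(length(hit)) < kappa / (kappa + 2)
    for (m in seq_along(hit)) {
      b <- chars[hit[m]]
      if (!b %in% .nucs) next
      chars[hit[m]] <- if (is_ts[m]) ts_map[[b]] else
        sample(setdiff(.nucs, c(b, ts_map[[b]])), 1L)
    }
  }
  n_ind <- stats::rpois(1L, n * indel_rate)
  s <- paste(chars, collapse = "")
  if (n_ind > 0L) {
    for (m in seq_len(n_ind)) {
      L <- nchar(s)
      if (L < 2L) break
      len <- 1L + stats::rgeom(1L, 1 / .sim_indel_excess(indel_mean))
      pos <- sample.int(L, 1L)
      if (stats::runif(1L) < 0.5) {
        s <- paste0(substring(s, 1L, pos), .rand_dna(len),
                    substring(s, pos + 1L, L))
      } else {
        s <- paste0(substring(s, 1L, pos - 1L),
                    substring(s, pos + len, L))
      }
    }
  }
  s
}

.sim_indel_excess <- function(mean_len) max(mean_len - 1, 0.5)

# Evolve one blueprint along one branch; returns the evolved parts plus
# per-gene realised substitution counts
.evolve_parts <- function(parts, params, branch_t, branch_sub, branch_indel, pt) {
  counts <- list()
  out <- parts
  for (p in seq_along(parts)) {
    part <- parts[[p]]
    if (part$kind == "gene") {
      cods <- split_codons(part$cds)
      res <- .sim_codon_path(cods, pt, branch_t)
      part$cds <- paste(res$codons, collapse = "")
      part$introns <- vapply(
        part$introns,
        function(i) .sim_nt_seq(i, branch_sub, params$genic_kappa,
                                branch_indel, params$indel_mean_len),
        character(1), USE.NAMES = FALSE
      )
      # exon lengths unchanged (codon process is substitution-only) but
      # intron lengths may change; exon_lens stay valid
      counts[[part$id]] <- c(syn = res$n_syn, nonsyn = res$n_nonsyn,
                             n_codons = length(cods))
      out[[p]] <- part
    } else if (part$kind == "intergenic") {
      out[[p]]$seq <- .sim_nt_seq(part$seq, branch_sub, params$genic_kappa,
                                  branch_indel, params$indel_mean_len)
    }
  }
  list(parts = out, counts = counts)
}

# Apply a segmental deletion (by ancestor gene ids) to a parts list,
# planting a breakpoint repeat; returns the new parts and the deleted ids
.apply_deletion <- function(parts, gene_ids, repeat_len) {
  gene_pos <- which(vapply(parts, function(p) p$kind == "gene", logical(1)))
  ids <- vapply(parts[gene_pos], `[[`, character(1), "id")
  hit <- gene_pos[ids %in% gene_ids]
  if (length(hit) == 0L) stop("deletion_spec genes not found in region")
  if (!all(diff(hit) == 2L) && length(hit) > 1L) {
    stop("deletion_spec genes must be consecutive")
  }
  left_ig <- min(hit) - 1L
  right_ig <- max(hit) + 1L
  left_seq <- parts[[left_ig]]$seq
  right_seq <- parts[[right_ig]]$seq
  cut_l <- nchar(left_seq) %/% 2L
  cut_r <- nchar(right_seq) %/% 2L
  keep_left <- substring(left_seq, 1L, cut_l)
  keep_right <- substring(right_seq, cut_r + 1L, nchar(right_seq))
  rep_seq <- if (nchar(keep_left) >= repeat_len) {
    substring(keep_left, nchar(keep_left) - repeat_len + 1L, nchar(keep_left))
  } else {
    keep_left
  }
  merged <- list(kind = "intergenic",
                 seq = paste0(keep_left, rep_seq, keep_right))
  new_parts <- c(parts[seq_len(left_ig - 1L)], list(merged),
                 parts[seq(right_ig + 1L, length(parts))])
  list(parts = new_parts, deleted = ids[ids %in% gene_ids])
}

# Insert a TE part at a random position inside a random intergenic part
.apply_te <- function(parts, te) {
  ig <- which(vapply(parts, function(p) {
    p$kind == "intergenic" && nchar(p$seq) > 2L
  }, logical(1)))
  sel <- if (length(ig) == 1L) ig else sample(ig, 1L)
  seq <- parts[[sel]]$seq
  pos <- sample.int(nchar(seq) - 1L, 1L)
  te_part <- list(kind = "te", class = te$class, seq = .rand_dna(te$length))
  before <- list(kind = "intergenic", seq = substring(seq, 1L, pos))
  after <- list(kind = "intergenic", seq = substring(seq, pos + 1L, nchar(seq)))
  c(parts[seq_len(sel - 1L)], list(before, te_part, after),
    if (sel < length(parts)) parts[seq(sel + 1L, length(parts))] else NULL)
}

#' Diverge an ancestral region into a homoeologous pair with ground truth
#'
#' Evolves the ancestor along two independent branches of length
#' `genic_t / 2` (CDSs, by GY94 path sampling) and `intergenic_sub_rate / 2`
#' (introns and intergenic sequence, with indels), then applies any
#' segmental deletion (P' sub-genome, breakpoint repeat planted) and TE
#' insertions. Gene ids are suffixed `_O` / `_P`; annotations are lifted
#' through all indels by construction.
#'
#' @param ancestor An [annotated_region()], typically from
#'   [simulate_ancestor()].
#' @param params The [sim_params()] used.
#' @param set_seed Seed the RNG from `params$seed + 1` first (default
#'   `TRUE`).
#' @return List with `region_o`, `region_p` ([annotated_region()]s) and
#'   `truth`: `homoeolog_map` (gene id pairs), per-gene realised `true_ks`
#'   / `true_ka` (substitution counts over model-based site counts),
#'   `expected_ks`, `deleted_genes`, `te_intervals`, and the ancestor.
#' @export
diverge_pair <- function(ancestor, params, set_seed = TRUE) {
  stopifnot(inherits(ancestor, "annotated_region"),
            inherits(params, "sim_params"))
  if (set_seed) set.seed((params$seed + 1L) %% .Machine$integer.max)
  parts <- .region_blueprint(ancestor)
  Q <- gy94_rate_matrix(params$genic_kappa, params$genic_omega)
  pt <- .path_tables(Q)
  branch_t <- params$genic_t / 2
  branch_sub <- params$intergenic_sub_rate / 2
  branch_indel <- params$indel_rate / 2

  ev_o <- .evolve_parts(parts, params, branch_t, branch_sub, branch_indel, pt)
  ev_p <- .evolve_parts(parts, params, branch_t, branch_sub, branch_indel, pt)

  deleted <- character(0)
  parts_p <- ev_p$parts
  if (!is.null(params$deletion_spec)) {
    repeat_len <- params$deletion_spec$repeat_len %||% 32L
    del <- .apply_deletion(parts_p, params$deletion_spec$genes, repeat_len)
    parts_p <- del$parts
    deleted <- del$deleted
  }
  parts_o <- ev_o$parts
  if (!is.null(params$te_spec)) {
    for (te in params$te_spec) {
      if (identical(te$sub_genome, "O")) {
        parts_o <- .apply_te(parts_o, te)
      } else {
        parts_p <- .apply_te(parts_p, te)
      }
    }
  }

  rename <- function(parts, suffix) {
    lapply(parts, function(p) {
      if (p$kind == "gene") p$id <- paste0(p$id, suffix)
      p
    })
  }
  region_o <- .assemble_region(paste0(ancestor$name, "_O"),
                               rename(parts_o, "_O"), sub_genome = "O")
  region_p <- .assemble_region(paste0(ancestor$name, "_P"),
                               rename(parts_p, "_P"), sub_genome = "P'")

  # truth: realised counts over model-based site counts
  rho1 <- attr(gy94_rate_matrix(params$genic_kappa, 1), "rho_syn")
  anc_ids <- names(ev_o$counts)
  survivors <- setdiff(anc_ids, deleted)
  true_ks <- true_ka <- stats::setNames(numeric(length(anc_ids)), anc_ids)
  for (id in anc_ids) {
    co <- ev_o$counts[[id]]
    cp <- ev_p$counts[[id]]
    S_sites <- 3 * co[["n_codons"]] * rho1
    N_sites <- 3 * co[["n_codons"]] - S_sites
    true_ks[id] <- (co[["syn"]] + cp[["syn"]]) / S_sites
    true_ka[id] <- (co[["nonsyn"]] + cp[["nonsyn"]]) / N_sites
  }
  rhoS <- attr(Q, "rho_syn")
  expected_ks <- params$genic_t * rhoS / (3 * rho1)

  te_intervals <- do.call(rbind, c(
    lapply(region_o$tes, function(te) data.frame(
      region = region_o$name, class = te$label, start = te$start, end = te$end
    )),
    lapply(region_p$tes, function(te) data.frame(
      region = region_p$name, class = te$label, start = te$start, end = te$end
    ))
  ))

  truth <- list(
    homoeolog_map = data.frame(
      ancestor_id = survivors,
      gene_o = paste0(survivors, "_O"),
      gene_p = paste0(survivors, "_P"),
      stringsAsFactors = FALSE
    ),
    true_ks = true_ks, true_ka = true_ka,
    expected_ks = expected_ks,
    deleted_genes = deleted,
    te_intervals = te_intervals,
    ancestral_region = ancestor
  )
  list(region_o = region_o, region_p = region_p, truth = truth)
}

#' Simulate a full homoeologous region pair
#'
#' Convenience wrapper: [simulate_ancestor()] then [diverge_pair()].
#'
#' @param params A [sim_params()] object.
#' @return List `ancestor`, `region_o`, `region_p`, `truth`.
#' @export
simulate_homoeolog_pair <- function(params = sim_params()) {
  anc <- simulate_ancestor(params)
  div <- diverge_pair(anc, params)
  c(list(ancestor = anc), div)
}

#' Evolve a reference orthologue CDS set from an ancestor
#'
#' Emulates a model-genome orthologue set: each ancestral CDS is evolved at
#' a larger divergence `ortholog_t`, then retained with probability
#' `retention_prob` (draft-genome gaps); gene order can be shuffled into
#' islands to emulate unordered assembly fragments.
#'
#' @param ancestor An [annotated_region()].
#' @param ortholog_t Branch length (expected substitutions per codon)
#'   separating the reference from the ancestor.
#' @param retention_prob Probability each orthologue is present.
#' @param seed Integer seed.
#' @param kappa,omega GY94 parameters of the orthologue branch.
#' @param shuffle Permute the output order (unordered draft islands).
#' @return Named character vector of CDSs (names `<ancestor id>_ref`) with
#'   attributes `strands` (named by the same ids) and `source_ids`.
#' @export
make_reference_set <- function(ancestor, ortholog_t = 0.8, retention_prob = 1,
                               seed = 1L, kappa = 2, omega = 0.2,
                               shuffle = FALSE) {
  stopifnot(inherits(ancestor, "annotated_region"))
  set.seed(seed)
  Q <- gy94_rate_matrix(kappa, omega)
  pt <- .path_tables(Q)
  keep <- stats::runif(length(ancestor$genes)) < retention_prob
  out <- character(0)
  strands <- character(0)
  src <- character(0)
  for (i in seq_along(ancestor$genes)) {
    g <- ancestor$genes[[i]]
    cds <- spliced_cds(ancestor, g)
    evolved <- paste(.sim_codon_path(split_codons(cds), pt, ortholog_t)$codons,
                     collapse = "")
    if (!keep[i]) next
    nm <- paste0(g$id, "_ref")
    out[nm] <- evolved
    strands[nm] <- g$strand
    src[nm] <- g$id
  }
  if (shuffle && length(out) > 1L) {
    o <- sample(length(out))
    out <- out[o]
    strands <- strands[o]
    src <- src[o]
  }
  attr(out, "strands") <- strands
  attr(out, "source_ids") <- src
  out
}
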