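test_that("identical annotations pair completely with no uniques", {
  cds <- lapply(c(20, 25, 30), toy_cds)
  r1 <- toy_region("o", cds, sub_genome = "O")
  r2 <- toy_region("p", cds, sub_genome = "P'")
  cmp <- pair_homoeologues(r1, r2)
  expect_equal(nrow(cmp$pairs), 3)
  expect_length(cmp$unique_o, 0)
  expect_length(cmp$unique_p, 0)
  expect_true(all(cmp$pairs$protein_identity == 100))
})

test_that("sub-genome-specific genes are reported unique", {
  shared <- paste("shared protein", 1:5)
  fns_o <- c(shared[1:2], "o only 1", shared[3], "o only 2", shared[4:5], "o only 3")
  fns_p <- c(shared[1:2], "p only 1", shared[3:5], "p only 2")
  r_o <- toy_region("o", lapply(seq_along(fns_o), function(i) toy_cds(20, i)),
                    fns = fns_o)
  r_p <- toy_region("p", lapply(seq_along(fns_p), function(i) toy_cds(20, i)),
                    fns = fns_p)
  cmp <- pair_homoeologues(r_o, r_p)
  expect_equal(nrow(cmp$pairs), 5)
  expect_length(cmp$unique_o, 3)
  expect_length(cmp$unique_p, 2)
  # partition property: every gene is paired or unique, exactly once
  expect_equal(nrow(cmp$pairs) + length(cmp$unique_o), length(r_o$genes))
  expect_equal(nrow(cmp$pairs) + length(cmp$unique_p), length(r_p$genes))
})

test_that("pairing preserves genomic order in both regions", {
  set.seed(66)
  p <- sim_params(n_genes = 6, target_gene_incidence = 2600, seed = 13)
  sim <- simulate_homoeolog_pair(p)
  cmp <- pair_homoeologues(sim$region_o, sim$region_p)
  idx_o <- match(cmp$pairs$gene_o,
                 vapply(sim$region_o$genes, `[[`, character(1), "id"))
  idx_p <- match(cmp$pairs$gene_p,
                 vapply(sim$region_p$genes, `[[`, character(1), "id"))
  expect_true(all(diff(idx_o) > 0))
  expect_true(all(diff(idx_p) > 0))
})

test_that("duplicated function labels resolve like exhaustive matching", {
  set.seed(12)
  for (rep in 1:5) {
    n_i <- sample(3:5, 1)
    n_j <- sample(3:5, 1)
    cand <- expand.grid(i = seq_len(n_i), j = seq_len(n_j))
    keep <- sample(nrow(cand), sample(3:min(8, nrow(cand)), 1))
    cand <- cand[keep, ]
    cand$w <- round(runif(nrow(cand), 50, 100), 3)
    sel <- homoeolog:::.order_preserving_matching(cand)
    ref <- brute_best_chain(cand)
    expect_equal(length(sel), ref$len)
    expect_equal(sum(cand$w[sel]), ref$w, tolerance = 1e-9)
  }
})

test_that("per-element comparison matches manual column counts", {
  # two-exon gene with known mismatches: exon1 1/10 mismatch, exon2 exact,
  # intron 2/12 mismatches
  e1o <- "ATGGCTGCTA"; e1p <- "ATGGCTGCTC"
  e2 <- "TGGCTGCAGCTT"
  int_o <- "GTAAGTTTTTAG"; int_p <- "GTAAGTAATTAG"
  seq_o <- paste0("AAAA", e1o, int_o, e2, "AAAA")
  seq_p <- paste0("AAAA", e1p, int_p, e2, "AAAA")
  mk <- function(nm, seq, e1, int) {
    g <- gene_model(paste0(nm, "_g"), "+",
                    cbind(c(5, 5 + nchar(e1) + nchar(int)),
                          c(4 + nchar(e1), 4 + nchar(e1) + nchar(int) + nchar(e2))),
                    fn = "toy")
    annotated_region(nm, seq, genes = list(g))
  }
  r_o <- mk("o", seq_o, e1o, int_o)
  r_p <- mk("p", seq_p, e1p, int_p)
  hp <- compare_gene_structure(NULL, "o_g", "p_g", r_o, r_p)
  expect_equal(hp$exon_identities, c(90, 100))
  expect_equal(hp$intron_identities, 100 * 10 / 12, tolerance = 1e-9)
  expect_true(hp$structure_match)

  # identical gene models: everything 100
  hp2 <- compare_gene_structure(NULL, "o_g", "o_g", r_o, r_o)
  expect_equal(hp2$mean_exon_identity, 100)
  expect_equal(hp2$protein_identity, 100)
})

test_that("an extra exon breaks the structure flag and is surplus", {
  cds <- toy_cds(30) # 90 nt
  # o: 3 exons of 30; p: 2 exons (30, 60) of the same CDS
  int <- strrep("GTACGTACAG", 6)
  seq_o <- paste0("AA", substr(cds, 1, 30), int, substr(cds, 31, 60), int,
                  substr(cds, 61, 90), "AA")
  g_o <- gene_model("go", "+", cbind(
    c(3, 3 + 30 + 60, 3 + 30 + 60 + 30 + 60),
    c(2 + 30, 2 + 30 + 60 + 30, 2 + 30 + 60 + 30 + 60 + 30)
  ), fn = "toy")
  r_o <- annotated_region("o", seq_o, genes = list(g_o))
  seq_p <- paste0("AA", substr(cds, 1, 30), int, substr(cds, 31, 90), "AA")
  g_p <- gene_model("gp", "+", cbind(c(3, 93), c(32, 152)), fn = "toy")
  r_p <- annotated_region("p", seq_p, genes = list(g_p))
  hp <- compare_gene_structure(NULL, "go", "gp", r_o, r_p)
  expect_false(hp$structure_match)
  expect_equal(hp$surplus_exons_o, 1)
  expect_equal(hp$protein_identity, 100)
})

test_that("region summaries compute incidence and merged gene space", {
  # 61 kb with 10 genes: incidence 6100
  genes <- lapply(1:10, function(i) {
    s <- 1000 + (i - 1) * 6000
    gene_model(sprintf("g%02d", i), "+", cbind(s, s + 2999), fn = "x")
  })
  r <- annotated_region("bac", strrep("ACGT", 15250), genes = genes)
  rs <- region_summary(r)
  expect_equal(rs$length_bp, 61000)
  expect_equal(rs$gene_incidence_bp, 6100)

  # 2 kb, 2 genes covering 500 bp -> incidence 1000, gene space 25%
  g1 <- gene_model("a", "+", cbind(101, 400), fn = "x")
  g2 <- gene_model("b", "+", cbind(1201, 1400), fn = "y")
  r2 <- annotated_region("r2", strrep("A", 2000), genes = list(g1, g2))
  rs2 <- region_summary(r2)
  expect_equal(rs2$gene_incidence_bp, 1000)
  expect_equal(rs2$gene_space_pct, 25)

  # overlapping spans merge before coverage
  g3 <- gene_model("c", "+", cbind(301, 500), fn = "z")
  r3 <- annotated_region("r3", strrep("A", 1000), genes = list(g1, g3))
  expect_equal(region_summary(r3)$gene_space_pct, 40)
  expect_error(region_summary(r3, c(0, 500)), "outside")
})

test_that("gene space agrees with base-by-base counting on random fixtures", {
  set.seed(88)
  for (k in 1:6) {
    n <- sample(2:6, 1)
    genes <- list()
    for (i in seq_len(n)) {
      s <- sample(1:900, 1)
      e <- min(1000, s + sample(20:300, 1))
      genes[[i]] <- tryCatch(
        gene_model(sprintf("g%d", i), "+", cbind(s, e), fn = "x"),
        error = function(e) NULL
      )
    }
    genes <- Filter(Negate(is.null), genes)
    r <- annotated_region("rr", strrep("A", 1000), genes = genes)
    expect_equal(region_summary(r)$gene_space_pct, brute_gene_space(r),
                 tolerance = 1e-9)
    itv <- c(101, 800)
    expect_equal(region_summary(r, itv)$gene_space_pct,
                 brute_gene_space(r, itv), tolerance = 1e-9)
  }
})

test_that("pair aggregation averages complete pairs and is order-invariant", {
  df <- data.frame(
    exon_identity = c(99, 97, 95), intron_identity = c(98, NA, 90),
    protein_identity = c(99.5, 97.5, 94), protein_similarity = c(100, 98, 95),
    Ks = c(0.01, 0.05, 0.09), Ka = c(0.001, 0.004, 0.008)
  )
  agg <- aggregate_pair_stats(df)
  expect_equal(agg$mean_exon_identity, 97)
  expect_equal(agg$mean_intron_identity, 94)
  expect_equal(agg$mean_Ks, 0.05)
  expect_equal(aggregate_pair_stats(df[c(3, 1, 2), ]), agg)

  # single pair: means equal that pair
  expect_equal(aggregate_pair_stats(df[1, ])$mean_Ks, 0.01)

  # incomplete pairs drop out entirely by default
  df2 <- rbind(df, data.frame(exon_identity = 10, intron_identity = NA,
                              protein_identity = NA, protein_similarity = NA,
                              Ks = NA, Ka = NA))
  expect_equal(aggregate_pair_stats(df2), agg)
  expect_error(aggregate_pair_stats(df[0, ]), "no pairs")
})

test_that("overlap detection brackets the paired genes", {
  p <- sim_params(n_genes = 4, target_gene_incidence = 2400, seed = 3)
  sim <- simulate_homoeolog_pair(p)
  ov <- detect_overlap(sim$region_o, sim$region_p)
  sp_o <- range(vapply(sim$region_o$genes, function(g) unname(gene_span(g)),
                       numeric(2)))
  expect_lte(ov$overlap_o[1], sp_o[1])
  expect_gte(ov$overlap_o[2], sp_o[2])
})
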