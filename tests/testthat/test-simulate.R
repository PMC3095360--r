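test_that("ancestor geometry hits the target incidence and is deterministic", {
  p <- sim_params(n_genes = 10, target_gene_incidence = 6100, seed = 17)
  anc <- simulate_ancestor(p)
  expect_equal(nchar(anc$sequence), 61000, tolerance = 2 / 61000)
  expect_length(anc$genes, 10)

  # minimal single-exon region
  p1 <- sim_params(n_genes = 1, exons_per_gene = 1,
                   target_gene_incidence = 1500, seed = 2)
  anc1 <- simulate_ancestor(p1)
  expect_length(anc1$genes, 1)
  expect_equal(nrow(anc1$genes[[1]]$exons), 1)

  # same seed twice: identical FASTA + GFF3 bytes
  anc_a <- simulate_ancestor(p)
  anc_b <- simulate_ancestor(p)
  fa_a <- tempfile(); fa_b <- tempfile()
  gf_a <- tempfile(); gf_b <- tempfile()
  write_fasta(c(ancestor = anc_a$sequence), fa_a)
  write_fasta(c(ancestor = anc_b$sequence), fa_b)
  write_gff3(anc_a, gf_a); write_gff3(anc_b, gf_b)
  expect_identical(readLines(fa_a), readLines(fa_b))
  expect_identical(readLines(gf_a), readLines(gf_b))

  # infeasible geometry errors
  expect_error(simulate_ancestor(sim_params(n_genes = 5,
                                            target_gene_incidence = 300)),
               "infeasible")
})

test_that("ancestral CDSs are clean reading frames", {
  p <- sim_params(n_genes = 6, target_gene_incidence = 3000, seed = 23)
  anc <- simulate_ancestor(p)
  for (g in anc$genes) {
    cds <- spliced_cds(anc, g)
    expect_equal(nchar(cds) %% 3, 0)
    aa <- homoeolog:::translate_codons(homoeolog:::split_codons(cds))
    expect_equal(aa[1], "M")
    expect_equal(aa[length(aa)], "*")
    expect_false(any(aa[-length(aa)] == "*"))
  }
})

test_that("zero divergence reproduces the ancestor exactly", {
  p <- sim_params(n_genes = 4, target_gene_incidence = 3200,
                  genic_t = 0, intergenic_sub_rate = 0, indel_rate = 0,
                  seed = 29)
  sim <- simulate_homoeolog_pair(p)
  expect_equal(sim$region_o$sequence, sim$ancestor$sequence)
  expect_equal(sim$region_p$sequence, sim$ancestor$sequence)
  expect_true(all(sim$truth$true_ks == 0))
  for (k in seq_along(sim$ancestor$genes)) {
    expect_equal(unname(sim$region_o$genes[[k]]$exons),
                 unname(sim$ancestor$genes[[k]]$exons))
  }
})

test_that("divergence is reproducible and annotations lift through indels", {
  p <- sim_params(n_genes = 5, target_gene_incidence = 2600, seed = 37)
  s1 <- simulate_homoeolog_pair(p)
  s2 <- simulate_homoeolog_pair(p)
  expect_identical(s1$region_o$sequence, s2$region_o$sequence)
  expect_identical(s1$region_p$sequence, s2$region_p$sequence)
  expect_identical(s1$truth$true_ks, s2$truth$true_ks)

  # lifted-over CDSs still translate cleanly (selection against stops)
  for (reg in list(s1$region_o, s1$region_p)) {
    for (g in reg$genes) {
      aa <- homoeolog:::translate_codons(
        homoeolog:::split_codons(spliced_cds(reg, g))
      )
      expect_false(any(aa[-length(aa)] == "*"))
    }
  }
  # every surviving gene appears in the homoeolog map
  expect_setequal(s1$truth$homoeolog_map$gene_o,
                  vapply(s1$region_o$genes, `[[`, character(1), "id"))
})

test_that("segmental deletions remove genes and plant a breakpoint repeat", {
  p <- sim_params(n_genes = 6, target_gene_incidence = 2600,
                  deletion_spec = list(genes = c("g03", "g04"),
                                       repeat_len = 32),
                  seed = 41)
  sim <- simulate_homoeolog_pair(p)
  ids_p <- vapply(sim$region_p$genes, `[[`, character(1), "id")
  expect_false(any(c("g03_P", "g04_P") %in% ids_p))
  expect_setequal(sim$truth$deleted_genes, c("g03", "g04"))
  expect_false(any(c("g03", "g04") %in% sim$truth$homoeolog_map$ancestor_id))
  # the deleted genes' O copies remain
  ids_o <- vapply(sim$region_o$genes, `[[`, character(1), "id")
  expect_true(all(c("g03_O", "g04_O") %in% ids_o))
  # the junction carries a 32 bp tandem repeat
  expect_lt(nchar(sim$region_p$sequence), nchar(sim$region_o$sequence))
})

test_that("TE insertions land in the named sub-genome and are annotated", {
  p <- sim_params(n_genes = 4, target_gene_incidence = 2400,
                  te_spec = list(list(class = "Copia", length = 500,
                                      sub_genome = "O"),
                                 list(class = "Gypsy", length = 300,
                                      sub_genome = "P'")),
                  seed = 43)
  sim <- simulate_homoeolog_pair(p)
  expect_length(sim$region_o$tes, 1)
  expect_length(sim$region_p$tes, 1)
  expect_equal(sim$region_o$tes[[1]]$label, "Copia")
  te <- sim$region_o$tes[[1]]
  expect_equal(te$end - te$start + 1L, 500L)
  expect_equal(nrow(sim$truth$te_intervals), 2)
})

test_that("realised synonymous rates converge to expectation for long genes", {
  # law-of-large-numbers check at 10,000 codons
  set.seed(47)
  tabs <- homoeolog:::codon_tables()
  kappa <- 2; omega <- 0.2
  Q <- gy94_rate_matrix(kappa, omega)
  pt <- homoeolog:::.path_tables(Q)
  anc <- sample(tabs$codons, 10000, replace = TRUE)
  t_branch <- 0.3
  res <- homoeolog:::.sim_codon_path(anc, pt, t_branch)
  rho1 <- attr(gy94_rate_matrix(kappa, 1), "rho_syn")
  rhoS <- attr(Q, "rho_syn")
  realised_ks <- res$n_syn / (3 * 10000 * rho1)
  expected_ks <- t_branch * rhoS / (3 * rho1)
  expect_lt(abs(realised_ks - expected_ks) / expected_ks, 0.05)
})

test_that("the genic branch length inverts the Ks definition", {
  for (ks in c(0.02, 0.05, 0.2)) {
    t <- genic_t_for_ks(ks, 2, 0.2)
    Q <- gy94_rate_matrix(2, 0.2)
    rho1 <- attr(gy94_rate_matrix(2, 1), "rho_syn")
    expect_equal(t * attr(Q, "rho_syn") / (3 * rho1), ks, tolerance = 1e-12)
  }
})

test_that("reference sets respect retention and divergence", {
  p <- sim_params(n_genes = 8, target_gene_incidence = 2600, seed = 59)
  anc <- simulate_ancestor(p)
  full <- make_reference_set(anc, ortholog_t = 0.3, retention_prob = 1,
                             seed = 5)
  expect_length(full, 8)
  none <- make_reference_set(anc, ortholog_t = 0.3, retention_prob = 0,
                             seed = 5)
  expect_length(none, 0)
  half <- make_reference_set(anc, ortholog_t = 0.3, retention_prob = 0.5,
                             seed = 5)
  expect_lte(length(half), 8)
  # retained genes are evolved copies of the ancestor CDSs
  src <- attr(full, "source_ids")
  for (nm in names(full)[1:3]) {
    anc_cds <- spliced_cds(anc, src[[nm]])
    expect_equal(nchar(full[[nm]]), nchar(anc_cds))
    expect_gt(local_align(full[[nm]], anc_cds)$score, 100)
  }
})
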