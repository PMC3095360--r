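test_that("codon alignment construction handles indels and bad input", {
  cds <- toy_cds(20)
  ca <- build_codon_alignment(cds, cds)
  expect_equal(ca$n_codons, 20)
  expect_true(all(ca$codon_pairs[, 1] == ca$codon_pairs[, 2]))

  # 3-nt in-frame deletion drops exactly one codon column
  del <- paste0(substr(cds, 1, 30), substr(cds, 34, nchar(cds)))
  ca2 <- build_codon_alignment(cds, del)
  expect_equal(ca2$n_codons, 19)

  # frame-preserving 6-nt insertion: pairs limited by the shorter protein
  ins <- paste0(substr(cds, 1, 30), "GCTGCA", substr(cds, 31, nchar(cds)))
  ca3 <- build_codon_alignment(cds, ins)
  expect_equal(ca3$n_codons, 20)

  # trailing partial codon trimmed; terminal stop trimmed
  ca4 <- build_codon_alignment(paste0(cds, "TAA"), paste0(cds, "TA"))
  expect_equal(ca4$n_codons, 20)

  # internal stop dropped with warning
  bad <- paste0(substr(cds, 1, 30), "TAA", substr(cds, 34, nchar(cds)))
  expect_warning(ca5 <- build_codon_alignment(bad, cds), "internal stop")
  expect_equal(ca5$n_codons, 19)

  expect_error(build_codon_alignment("ATGGCT", "ATGGCT"),
               "insufficient alignable codons")
})

test_that("GY94 rate matrix satisfies its structural properties", {
  tabs <- homoeolog:::codon_tables()
  for (par in list(c(1, 1), c(2, 0.2), c(5, 3))) {
    Q <- gy94_rate_matrix(par[1], par[2])
    pi <- attr(Q, "codon_freqs")
    # rows sum to zero, scaled to one substitution per codon per unit t
    expect_lt(max(abs(rowSums(Q))), 1e-12)
    expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)
    # detailed balance (time reversibility)
    PQ <- pi * Q
    expect_lt(max(abs(PQ - t(PQ))), 1e-14)
    # multi-nucleotide changes have rate zero
    off <- Q
    off[cbind(tabs$pair_from, tabs$pair_to)] <- 0
    diag(off) <- 0
    expect_equal(max(abs(off)), 0)
  }
  # kappa=1, omega=1, uniform pi: all single-step rates equal
  Q1 <- gy94_rate_matrix(1, 1)
  rates <- Q1[cbind(tabs$pair_from, tabs$pair_to)]
  expect_lt(diff(range(rates)), 1e-14)
})

test_that("transition probabilities are stochastic and start at identity", {
  Q <- gy94_rate_matrix(2, 0.5)
  P0 <- homoeolog:::.gy94_pmat(Q, 0)
  expect_equal(P0, diag(61), tolerance = 1e-10, ignore_attr = TRUE)
  for (t in c(0.01, 0.3, 2)) {
    P <- homoeolog:::.gy94_pmat(Q, t)
    expect_equal(unname(rowSums(P)), rep(1, 61), tolerance = 1e-10)
    expect_true(all(P >= 0))
  }
})

test_that("identical sequences give zero divergence under both estimators", {
  cds <- toy_cds(40)
  ca <- build_codon_alignment(cds, cds)
  gy <- estimate_gy94(ca)
  ng <- estimate_ng86(ca)
  expect_equal(gy$Ks, 0)
  expect_equal(gy$Ka, 0)
  expect_equal(gy$t, 0)
  expect_equal(ng$Ks, 0)
  expect_equal(ng$Ka, 0)
  # site counts partition the codon positions
  expect_equal(gy$S_sites + gy$N_sites, 3 * ca$n_codons)
  expect_equal(ng$S_sites + ng$N_sites, 3 * ca$n_codons, tolerance = 1e-9)
})

test_that("the GY94 optimum is a local maximum of the likelihood", {
  rep <- sim_gy94_replicate(400, 0.2, 2, 0.3, seed = 91)
  est <- rep$est
  pi <- est$codon_freqs
  tabs <- homoeolog:::codon_tables()
  lnl <- function(t, kappa, omega) {
    Q <- gy94_rate_matrix(kappa, omega, pi)
    P <- homoeolog:::.gy94_pmat(Q, t)
    ia <- tabs$codon_index[rep$aln$codon_pairs[, 1]]
    ib <- tabs$codon_index[rep$aln$codon_pairs[, 2]]
    sum(log(pi[ia]) + log(pmax(P[cbind(ia, ib)], 1e-300)))
  }
  expect_equal(lnl(est$t, est$kappa, est$omega), est$lnL, tolerance = 1e-6)
  for (d in c(-0.05, 0.05)) {
    expect_lte(lnl(est$t * (1 + d), est$kappa, est$omega), est$lnL + 1e-6)
    expect_lte(lnl(est$t, est$kappa * (1 + d), est$omega), est$lnL + 1e-6)
    expect_lte(lnl(est$t, est$kappa, est$omega * (1 + d)), est$lnL + 1e-6)
  }
})

test_that("estimates are invariant to sequence order", {
  rep <- sim_gy94_replicate(300, 0.15, 2, 0.3, seed = 55)
  swapped <- structure(
    list(codon_pairs = rep$aln$codon_pairs[, 2:1],
         n_codons = rep$aln$n_codons,
         source_gene_ids = rev(rep$aln$source_gene_ids)),
    class = "codon_alignment"
  )
  est2 <- estimate_gy94(swapped)
  expect_equal(est2$Ks, rep$est$Ks, tolerance = 1e-5)
  expect_equal(est2$Ka, rep$est$Ka, tolerance = 1e-5)
})

test_that("NG86 counts one synonymous third-position transition exactly", {
  # 100 alanine codons; one GCT->GCC change: pos-3 of GCT is a 4-fold
  # degenerate site, so S = 100 sites, Sd = 1
  a <- strrep("GCT", 100)
  b <- paste0(strrep("GCT", 50), "GCC", strrep("GCT", 49))
  ca <- build_codon_alignment(a, b)
  ng <- estimate_ng86(ca)
  expect_equal(ng$S_sites, 100)
  expect_equal(ng$Ka, 0)
  pS <- 1 / 100
  expect_equal(ng$Ks, -0.75 * log(1 - 4 * pS / 3), tolerance = 1e-12)
})

test_that("Ks increases with generating branch length", {
  grid <- c(0.05, 0.1, 0.2, 0.35, 0.5, 0.7)
  ks <- vapply(seq_along(grid), function(k) {
    sim_gy94_replicate(600, grid[k], 2, 0.2, seed = 700 + k)$est$Ks
  }, numeric(1))
  expect_gt(cor(grid, ks, method = "spearman"), 0.95)
})

test_that("saturated alignments are refused", {
  # every aligned codon fully diverged: nucleotide p-distance 1
  ca <- build_codon_alignment(strrep("AAA", 50), strrep("CCC", 50))
  expect_equal(ca$n_codons, 50)
  expect_error(estimate_gy94(ca), "saturated")
})
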