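test_that("global alignment identity behaves on forced cases", {
  expect_equal(global_align("ACGT", "ACGT")$identity_pct, 100)
  expect_equal(global_align("ACGT", "ACGA")$identity_pct, 75)
  expect_error(global_align("", "ACGT"), "non-empty")
  # N is never an identity, even against N
  expect_lt(global_align("ACGN", "ACGN")$identity_pct, 100)
})

test_that("local alignment returns the empty alignment when nothing scores", {
  aln <- local_align("AAAA", "TTTT")
  expect_equal(aln$score, 0)
  expect_equal(aln$aligned_a, "")
  full <- local_align("ACGTACGT", "ACGTACGT")
  expect_equal(full$identity_pct, 100)
  expect_equal(c(full$start_a, full$end_a), c(1, 8))
})

test_that("alignment scores match the enumeration oracle on small pairs", {
  set.seed(101)
  for (k in 1:25) {
    a <- rand_dna(sample(1:6, 1))
    b <- rand_dna(sample(1:6, 1))
    expect_equal(global_align(a, b)$score, brute_global_score(a, b),
                 tolerance = 1e-9, info = paste(a, b))
    expect_equal(local_align(a, b)$score, brute_local_score(a, b),
                 tolerance = 1e-9, info = paste(a, b))
  }
})

test_that("global identity is symmetric in the sequence order", {
  set.seed(202)
  for (k in 1:20) {
    a <- rand_dna(sample(5:40, 1))
    b <- rand_dna(sample(5:40, 1))
    expect_equal(global_align(a, b)$score, global_align(b, a)$score)
    expect_equal(global_align(a, b)$identity_pct,
                 global_align(b, a)$identity_pct, tolerance = 1e-9)
  }
})

test_that("self-alignment identity is 100 for any gap parameters", {
  set.seed(303)
  for (go in c(5, 10, 25)) {
    s <- rand_dna(60)
    p <- alignment_params(gap_open = go, gap_extend = 0.5)
    expect_equal(global_align(s, s, p)$identity_pct, 100)
  }
})

test_that("identity and similarity count columns as defined", {
  # protein self-alignment
  aln <- global_align("MKVAWL", "MKVAWL", type = "protein")
  expect_equal(unname(identity_and_similarity(aln)), c(100, 100))

  # 12 residues, 2 conservative substitutions (W->F, T->S both score +1):
  # identity 10/12, similarity 12/12 (hand-counted columns)
  aln2 <- global_align("MKVLWAALLVTF", "MKVLFAALLVSF", type = "protein")
  ids <- identity_and_similarity(aln2)
  expect_equal(unname(ids["identity_pct"]), 100 * 10 / 12, tolerance = 1e-9)
  expect_equal(unname(ids["similarity_pct"]), 100)

  # 10 columns, 9 identical, 1 conservative -> (90, 100)
  aln3 <- global_align("MKVLWAALLV", "MKVLFAALLV", type = "protein")
  ids3 <- identity_and_similarity(aln3)
  expect_equal(unname(ids3["identity_pct"]), 90, tolerance = 1e-9)
  expect_equal(unname(ids3["similarity_pct"]), 100)

  # identity <= similarity for proteins
  set.seed(7)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")
  for (k in 1:5) {
    x <- paste(sample(aa, 30, replace = TRUE), collapse = "")
    y <- paste(sample(aa, 30, replace = TRUE), collapse = "")
    v <- identity_and_similarity(global_align(x, y, type = "protein"))
    expect_lte(v[["identity_pct"]], v[["similarity_pct"]])
  }
})

test_that("sliding identity profile reports per-window identity", {
  s <- rand_dna(400)
  set.seed(11)
  aln <- global_align(s, s)
  prof <- sliding_identity_profile(aln, 100, 25)
  expect_true(all(prof$identity_pct == 100))
  expect_equal(prof$start[1], 1)

  # alignment whose first 100 columns are identical and next 100 all
  # mismatch; window == step == 100 -> c(100, 0)
  fixed <- structure(
    list(aligned_a = paste0(strrep("A", 100), strrep("C", 100)),
         aligned_b = paste0(strrep("A", 100), strrep("G", 100)),
         score = 0, mode = "global", type = "dna",
         identity_pct = 50, similarity_pct = 50,
         params = alignment_params()),
    class = "pairwise_alignment"
  )
  prof2 <- sliding_identity_profile(fixed, 100, 100)
  expect_equal(prof2$identity_pct, c(100, 0))

  expect_error(sliding_identity_profile(fixed, 10, 25), "window_size")
  expect_error(sliding_identity_profile(local_align("ACGTACGT", "CGTA"),
                                        100, 25), "global")
})

test_that("profile mean equals overall identity for gapless tilings", {
  set.seed(17)
  a <- rand_dna(200)
  b <- strsplit(a, "")[[1]]
  flip <- seq(5, 200, by = 10) # isolated mismatches keep the alignment gapless
  b[flip] <- vapply(b[flip], function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1),
                    character(1))
  b <- paste(b, collapse = "")
  aln <- global_align(a, b)
  # equal-length high-identity pair aligns without gaps
  expect_false(grepl("-", aln$aligned_a, fixed = TRUE))
  prof <- sliding_identity_profile(aln, 50, 50)
  expect_equal(mean(prof$identity_pct), aln$identity_pct, tolerance = 1e-9)
})

test_that("E-values follow the Karlin-Altschul form", {
  p <- alignment_params()
  expect_equal(evalue(0, 100, 200, p), p$ka_K * 100 * 200)
  expect_equal(evalue(30, 100, 400, p), 2 * evalue(30, 100, 200, p))
  s <- seq(0, 200, by = 10)
  e <- evalue(s, 300, 300, p)
  expect_true(all(diff(e) < 0))
  expect_error(evalue(10, 0, 100, p), "positive")

  # lambda satisfies the moment equation and matches the published value
  lam <- ka_lambda_solve(5, -4)
  expect_equal(0.25 * exp(5 * lam) + 0.75 * exp(-4 * lam), 1, tolerance = 1e-8)
  expect_equal(lam, 0.1915, tolerance = 1e-3)
  expect_error(ka_lambda_solve(4, -1), "non-negative")
})

test_that("alignment parameter validation rejects bad penalties", {
  expect_error(alignment_params(gap_open = 1, gap_extend = 2))
  expect_error(alignment_params(gap_extend = -1))
})
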