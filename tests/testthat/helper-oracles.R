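# Independent oracles used across the test suite. These deliberately avoid
# the package's own computational paths: alignment scores come from full
# enumeration of the alignment space, coverage from base-by-base counting,
# matchings and subsequences from exhaustive search over small inputs.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Optimal global affine-gap score by exhaustive enumeration of all gapped
# alignments (EMBOSS gap cost open + (len-1)*extend; N scored as mismatch).
brute_global_score <- function(a, b, match = 5, mismatch = -4,
                               open = 10, ext = 0.5) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  na <- length(A)
  nb <- length(B)
  best <- -Inf
  rec <- function(i, j, prev, sc) {
    if (i > na && j > nb) {
      if (sc > best) best <<- sc
      return(invisible())
    }
    if (i <= na && j <= nb) {
      s <- if (A[i] == B[j] && A[i] != "N") match else mismatch
      rec(i + 1, j + 1, "M", sc + s)
    }
    if (i <= na) rec(i + 1, j, "X", sc - if (prev == "X") ext else open)
    if (j <= nb) rec(i, j + 1, "Y", sc - if (prev == "Y") ext else open)
  }
  rec(1, 1, "-", 0)
  best
}

# Optimal local score: enumerate paths from every start cell and track the
# running maximum over all path prefixes (a stop is allowed anywhere);
# the empty alignment scores 0.
brute_local_score <- function(a, b, match = 5, mismatch = -4,
                              open = 10, ext = 0.5) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  na <- length(A)
  nb <- length(B)
  best <- 0
  rec <- function(i, j, prev, sc) {
    if (sc > best) best <<- sc
    if (i <= na && j <= nb) {
      s <- if (A[i] == B[j] && A[i] != "N") match else mismatch
      rec(i + 1, j + 1, "M", sc + s)
    }
    if (i <= na) rec(i + 1, j, "X", sc - if (prev == "X") ext else open)
    if (j <= nb) rec(i, j + 1, "Y", sc - if (prev == "Y") ext else open)
  }
  for (i0 in seq_len(na)) {
    for (j0 in seq_len(nb)) rec(i0, j0, "-", 0)
  }
  best
}

# Base-by-base gene-space coverage of a region over an interval
brute_gene_space <- function(region, interval = NULL) {
  len <- nchar(region$sequence)
  if (is.null(interval)) interval <- c(1L, len)
  covered <- logical(len)
  for (g in region$genes) {
    s <- min(g$exons[, 1])
    e <- max(g$exons[, 2])
    if (e < interval[1] || s > interval[2]) next
    covered[max(s, interval[1]):min(e, interval[2])] <- TRUE
  }
  100 * sum(covered[interval[1]:interval[2]]) / (interval[2] - interval[1] + 1)
}

# Best order-preserving matching by exhaustive search over all subsets of
# candidate pairs (small inputs only): maximise pair count, then weight.
brute_best_chain <- function(cand) {
  n <- nrow(cand)
  best_len <- 0
  best_w <- -Inf
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(sel) < best_len) next
    ii <- cand$i[sel]
    jj <- cand$j[sel]
    o <- order(ii)
    if (anyDuplicated(ii) || anyDuplicated(jj)) next
    if (length(sel) > 1 && any(diff(jj[o]) <= 0)) next
    w <- sum(cand$w[sel])
    if (length(sel) > best_len || (length(sel) == best_len && w > best_w)) {
      best_len <- length(sel)
      best_w <- w
    }
  }
  list(len = best_len, w = best_w)
}

# Longest increasing subsequence length by exhaustive subset search
brute_lis <- function(x) {
  n <- length(x)
  best <- 0
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(sel) <= best) next
    if (all(diff(x[sel]) > 0)) best <- length(sel)
  }
  best
}

# Simulate one codon-path replicate and return truth + estimates; shared by
# engine-correctness tests
sim_gy94_replicate <- function(n_codons, t, kappa, omega, seed,
                               fix_kappa = NULL) {
  set.seed(seed)
  tabs <- homoeolog:::codon_tables()
  Q <- gy94_rate_matrix(kappa, omega)
  pt <- homoeolog:::.path_tables(Q)
  anc <- sample(tabs$codons, n_codons, replace = TRUE)
  a <- homoeolog:::.sim_codon_path(anc, pt, t / 2)
  b <- homoeolog:::.sim_codon_path(anc, pt, t / 2)
  rho1 <- attr(gy94_rate_matrix(kappa, 1), "rho_syn")
  S <- 3 * n_codons * rho1
  N <- 3 * n_codons - S
  ca <- build_codon_alignment(paste(a$codons, collapse = ""),
                              paste(b$codons, collapse = ""))
  est <- estimate_gy94(ca, fix_kappa = fix_kappa)
  list(
    true_ks = (a$n_syn + b$n_syn) / S,
    true_ka = (a$n_nonsyn + b$n_nonsyn) / N,
    est = est,
    aln = ca
  )
}
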