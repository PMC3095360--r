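# Ks/Ka estimation for pairs of homoeologous CDSs.
#
# The likelihood engine is the Goldman-Yang (GY94) codon substitution model
# over the 61 sense codons of the standard genetic code: single-nucleotide
# changes occur at rate pi_j, multiplied by kappa for transitions and by
# omega for non-synonymous changes; multi-nucleotide changes have rate 0.
# The matrix is scaled to one expected substitution per codon per unit of
# branch length t, so t is in expected substitutions per codon. Ks and Ka
# are obtained by partitioning t into its synonymous and non-synonymous flow
# and dividing by the per-codon synonymous/non-synonymous site fractions
# computed at omega = 1 (the CODEML convention).
#
# Nei-Gojobori (NG86) pathway counting with Jukes-Cantor correction is
# provided as an independent, likelihood-free estimator for cross-checks.

#' Build a codon alignment from two CDSs
#'
#' Translates both CDSs, globally aligns the proteins (BLOSUM62, affine
#' gaps), back-maps the protein alignment onto codons, and keeps only
#' columns that are gap-free sense codons on both sides. Trailing partial
#' codons and terminal stop codons are trimmed; up to one internal stop
#' codon per CDS is dropped with a warning.
#'
#' @param cds_a,cds_b Coding sequences (strings, in frame after trimming any
#'   trailing partial codon).
#' @param ids Character vector of length 2, identifiers of the source genes.
#' @param params [alignment_params()] used for the protein alignment.
#' @return An object of class `codon_alignment`: list with `codon_pairs`
#'   (2-column character matrix), `n_codons` and `source_gene_ids`. At least
#'   10 clean codon pairs are required.
#' @examples
#' ca <- build_codon_alignment(strrep("ATGGCT", 10), strrep("ATGGCT", 10))
#' ca$n_codons
#' @export
build_codon_alignment <- function(cds_a, cds_b, ids = c("a", "b"),
                                  params = alignment_params()) {
  clean <- function(cds, id) {
    cod <- split_codons(cds)
    if (length(cod) == 0L) stop("CDS ", id, " has no complete codon")
    aa <- translate_codons(cod)
    # trailing stop is the normal end of a CDS
    if (aa[length(aa)] == "*") {
      cod <- cod[-length(cod)]
      aa <- aa[-length(aa)]
    }
    internal_stops <- which(aa == "*")
    if (length(internal_stops) > 1L) {
      stop("CDS ", id, " contains ", length(internal_stops), " internal stop codons")
    }
    if (length(internal_stops) == 1L) {
      warning("dropping internal stop codon at codon ", internal_stops,
              " of CDS ", id)
      cod <- cod[-internal_stops]
      aa <- aa[-internal_stops]
    }
    list(codons = cod, aa = aa)
  }
  a <- clean(cds_a, ids[1])
  b <- clean(cds_b, ids[2])
  aln <- global_align(paste(a$aa, collapse = ""), paste(b$aa, collapse = ""),
                      params = params, type = "protein")
  ca <- strsplit(aln$aligned_a, "")[[1]]
  cb <- strsplit(aln$aligned_b, "")[[1]]
  ia <- cumsum(ca != "-")
  ib <- cumsum(cb != "-")
  keep <- ca != "-" & cb != "-"
  pairs <- cbind(a$codons[ia[keep]], b$codons[ib[keep]])
  # only gap-free, unambiguous sense codons survive
  tabs <- codon_tables()
  ok <- pairs[, 1] %in% tabs$codons & pairs[, 2] %in% tabs$codons
  pairs <- pairs[ok, , drop = FALSE]
  if (nrow(pairs) < 10L) stop("insufficient alignable codons (",
                              nrow(pairs), " < 10)")
  structure(
    list(codon_pairs = pairs, n_codons = nrow(pairs),
         source_gene_ids = ids),
    class = "codon_alignment"
  )
}

# F3x4 codon frequencies from the pooled positional nucleotide composition
# of both sequences, floored at 1e-6 and renormalised over sense codons.
.f3x4_freqs <- function(codon_pairs) {
  tabs <- codon_tables()
  all_codons <- c(codon_pairs[, 1], codon_pairs[, 2])
  posfreq <- matrix(0, nrow = 3, ncol = 4, dimnames = list(NULL, .nucs))
  for (p in 1:3) {
    nts <- substring(all_codons, p, p)
    tb <- table(factor(nts, levels = .nucs))
    posfreq[p, ] <- as.numeric(tb) / sum(tb)
  }
  pi <- posfreq[1, tabs$nuc_mat[, 1]] *
    posfreq[2, tabs$nuc_mat[, 2]] *
    posfreq[3, tabs$nuc_mat[, 3]]
  pi <- pmax(pi, 1e-6)
  pi / sum(pi)
}

#' GY94 instantaneous rate matrix
#'
#' Builds the 61x61 Goldman-Yang rate matrix: `q_ij = pi_j` for a synonymous
#' transversion, times `kappa` for transitions, times `omega` for
#' non-synonymous changes; zero for codons differing at more than one
#' position. Rows sum to zero and the matrix is scaled to one expected
#' substitution per codon per unit time
#' (`-sum(pi_i * q_ii) == 1`).
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Non-synonymous/synonymous rate ratio (> 0).
#' @param codon_freqs Equilibrium frequencies over the 61 sense codons
#'   (default uniform); floored at 1e-6 and renormalised.
#' @return A 61x61 matrix with codon row/column names; attributes
#'   `codon_freqs` and `rho_syn` (the fraction of the total substitution
#'   flow that is synonymous).
#' @examples
#' Q <- gy94_rate_matrix(2, 0.2)
#' max(abs(rowSums(Q))) < 1e-12
#' @export
gy94_rate_matrix <- function(kappa, omega, codon_freqs = NULL) {
  stopifnot(kappa > 0, omega > 0)
  tabs <- codon_tables()
  n <- tabs$n
  if (is.null(codon_freqs)) codon_freqs <- rep(1 / n, n)
  stopifnot(length(codon_freqs) == n)
  pi <- pmax(codon_freqs, 1e-6)
  pi <- pi / sum(pi)
  Q <- matrix(0, n, n, dimnames = list(tabs$codons, tabs$codons))
  rate <- pi[tabs$pair_to] *
    ifelse(tabs$pair_ts, kappa, 1) *
    ifelse(tabs$pair_syn, 1, omega)
  Q[cbind(tabs$pair_from, tabs$pair_to)] <- rate
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q <- Q / scale
  attr(Q, "codon_freqs") <- pi
  # synonymous share of the substitution flow (after scaling, total flow = 1)
  attr(Q, "rho_syn") <- sum(pi[tabs$pair_from][tabs$pair_syn] *
                              rate[tabs$pair_syn]) / scale
  Q
}

# Transition probability matrix P(t) = exp(Qt) of a reversible Q via
# symmetric eigendecomposition: B = D^{1/2} Q D^{-1/2} is symmetric.
.gy94_pmat <- function(Q, t) {
  pi <- attr(Q, "codon_freqs")
  sq <- sqrt(pi)
  B <- Q * (sq %o% (1 / sq)) # B_ij = sq_i * q_ij / sq_j, symmetric for reversible Q
  B <- (B + t(B)) / 2 # symmetrise numerically
  e <- eigen(B, symmetric = TRUE)
  M <- e$vectors %*% (exp(e$values * t) * t(e$vectors))
  P <- (1 / sq) * M # row i scaled by 1/sq_i
  P <- t(t(P) * sq) # column j scaled by sq_j
  P[P < 0] <- 0
  P / rowSums(P)
}

# 61x61 matrix of codon-pair counts from a codon alignment
.pair_counts <- function(aln) {
  tabs <- codon_tables()
  ia <- tabs$codon_index[aln$codon_pairs[, 1]]
  ib <- tabs$codon_index[aln$codon_pairs[, 2]]
  N <- matrix(0, tabs$n, tabs$n)
  for (k in seq_along(ia)) N[ia[k], ib[k]] <- N[ia[k], ib[k]] + 1
  N
}

.kaks_estimate <- function(Ks, Ka, kappa, omega, t, lnL, S_sites, N_sites,
                           codon_freqs, n_codons, method, ids,
                           converged = TRUE) {
  structure(
    list(Ks = Ks, Ka = Ka, kappa = kappa, omega = omega, t = t, lnL = lnL,
         S_sites = S_sites, N_sites = N_sites, codon_freqs = codon_freqs,
         n_codons = n_codons, method = method, source_gene_ids = ids,
         converged = converged),
    class = "kaks_estimate"
  )
}

#' @export
print.kaks_estimate <- function(x, ...) {
  cat(sprintf("%s estimate (%s vs %s, %d codons): Ks = %.4f, Ka = %.4f",
              x$method, x$source_gene_ids[1], x$source_gene_ids[2],
              x$n_codons, x$Ks, x$Ka))
  if (!is.na(x$omega)) cat(sprintf(", omega = %.4f", x$omega))
  cat("\n")
  invisible(x)
}

# Site fractions at omega = 1: rho1_syn is the per-codon fraction of
# mutational opportunity that is synonymous under the mutation process alone.
.rho1_syn <- function(kappa, pi) {
  attr(gy94_rate_matrix(kappa, 1, pi), "rho_syn")
}

#' Maximum-likelihood Ks/Ka under the GY94 codon model
#'
#' Maximises the pairwise likelihood
#' `L = prod_c pi[a_c] * P(t)[a_c, b_c]` over branch length `t`, `kappa` and
#' `omega` (bounded quasi-Newton on log parameters), with codon frequencies
#' fixed at their F3x4 estimate from the pooled sequences. `Ks` is the
#' synonymous flow `t * rho_S` divided by the synonymous sites per codon
#' `3 * rho1_S` (and analogously `Ka`), where `rho_S` is the synonymous
#' share of substitution flow at the MLE and `rho1_S` the same share at
#' `omega = 1`.
#'
#' @param aln A [build_codon_alignment()] result.
#' @param fix_kappa,fix_omega Optionally fix `kappa` and/or `omega` instead
#'   of estimating them.
#' @return A `kaks_estimate` with fields `Ks`, `Ka`, `kappa`, `omega`, `t`
#'   (expected substitutions per codon), `lnL`, `S_sites`, `N_sites`,
#'   `codon_freqs`, `method = "GY94"` and a `converged` flag.
#' @export
estimate_gy94 <- function(aln, fix_kappa = NULL, fix_omega = NULL) {
  stopifnot(inherits(aln, "codon_alignment"))
  tabs <- codon_tables()
  pairs <- aln$codon_pairs
  n_cod <- aln$n_codons

  # nucleotide p-distance over the aligned codons (saturation guard)
  nd <- sum(vapply(seq_len(n_cod), function(k) {
    sum(strsplit(pairs[k, 1], "")[[1]] != strsplit(pairs[k, 2], "")[[1]])
  }, numeric(1)))
  p_nt <- nd / (3 * n_cod)
  if (p_nt > 0.75) stop("saturated alignment (nucleotide p-distance ",
                        round(p_nt, 3), " > 0.75)")

  pi <- .f3x4_freqs(pairs)
  rho1 <- .rho1_syn(if (is.null(fix_kappa)) 2 else fix_kappa, pi)
  S_sites <- 3 * n_cod * rho1
  N_sites <- 3 * n_cod - S_sites

  if (nd == 0) {
    # identical sequences: t = 0 exactly
    ia <- tabs$codon_index[pairs[, 1]]
    lnL <- sum(log(pi[ia]))
    return(.kaks_estimate(0, 0, fix_kappa %||% NA_real_,
                          fix_omega %||% NA_real_, 0, lnL,
                          S_sites, N_sites, pi, n_cod, "GY94",
                          aln$source_gene_ids))
  }

  Nmat <- .pair_counts(aln)
  obs <- which(Nmat > 0, arr.ind = TRUE)
  wts <- Nmat[obs]
  log_pi_a <- log(pi[obs[, 1]])

  free <- c(t = TRUE, kappa = is.null(fix_kappa), omega = is.null(fix_omega))
  unpack <- function(par) {
    full <- numeric(3)
    full[free] <- par
    list(
      t = exp(full[1]),
      kappa = if (free[2]) exp(full[2]) else fix_kappa,
      omega = if (free[3]) exp(full[3]) else fix_omega
    )
  }
  nll <- function(par) {
    p <- unpack(par)
    Q <- gy94_rate_matrix(p$kappa, p$omega, pi)
    P <- .gy94_pmat(Q, p$t)
    pr <- pmax(P[obs], 1e-300)
    -sum(wts * (log_pi_a + log(pr)))
  }

  p_cod <- sum(pairs[, 1] != pairs[, 2]) / n_cod
  start_full <- log(c(max(3 * p_cod, 1e-3), 2, 0.4))
  lower_full <- log(c(1e-6, 0.05, 1e-4))
  upper_full <- log(c(20, 100, 50))

  run_opt <- function(start) {
    stats::optim(start[free], nll, method = "L-BFGS-B",
                 lower = lower_full[free], upper = upper_full[free],
                 control = list(factr = 1e7, maxit = 500))
  }
  fit <- run_opt(start_full)
  converged <- fit$convergence == 0
  if (!converged) {
    # deterministic perturbed restarts
    for (mult in list(c(2, 1, 1), c(0.5, 2, 0.5), c(3, 0.5, 2))) {
      alt <- tryCatch(run_opt(start_full + log(mult)), error = function(e) NULL)
      if (!is.null(alt) && (alt$value < fit$value || fit$convergence != 0)) {
        fit <- alt
      }
      if (fit$convergence == 0) break
    }
    converged <- fit$convergence == 0
  }
  p <- unpack(fit$par)
  Qhat <- gy94_rate_matrix(p$kappa, p$omega, pi)
  rhoS <- attr(Qhat, "rho_syn")
  rho1 <- .rho1_syn(p$kappa, pi)
  S_sites <- 3 * n_cod * rho1
  N_sites <- 3 * n_cod - S_sites
  Ks <- p$t * rhoS / (3 * rho1)
  Ka <- p$t * (1 - rhoS) / (3 * (1 - rho1))
  .kaks_estimate(Ks, Ka, p$kappa, p$omega, p$t, -fit$value,
                 S_sites, N_sites, pi, n_cod, "GY94",
                 aln$source_gene_ids, converged = converged)
}

# NG86 per-codon site counts: for each position, the fraction of the three
# possible changes that are synonymous. Changes creating stop codons count
# as non-synonymous opportunity.
.ng86_codon_sites <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  aa <- code[[codon]]
  s <- 0
  for (p in 1:3) {
    ref <- substr(codon, p, p)
    for (nt in setdiff(.nucs, ref)) {
      alt <- codon
      substr(alt, p, p) <- nt
      if (!is.na(code[alt]) && code[[alt]] == aa && code[[alt]] != "*") {
        s <- s + 1 / 3
      }
    }
  }
  c(S = s, N = 3 - s)
}

# NG86 pathway-averaged synonymous/non-synonymous difference counts between
# two codons. Pathways passing through stop codons are excluded; if every
# pathway is blocked, all pathways are used with stop-passing steps counted
# as non-synonymous.
.ng86_codon_diffs <- function(ca, cb) {
  if (ca == cb) return(c(Sd = 0, Nd = 0))
  code <- Biostrings::GENETIC_CODE
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  perms <- if (length(pos) == 1L) list(pos) else {
    if (length(pos) == 2L) list(pos, rev(pos)) else {
      do.call(c, lapply(seq_along(pos), function(i) {
        rest <- pos[-i]
        lapply(list(rest, rev(rest)), function(r) c(pos[i], r))
      }))
    }
  }
  walk <- function(order) {
    cur <- ca
    sd <- 0; nd <- 0; blocked <- FALSE
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (code[[nxt]] == "*") blocked <- TRUE
      if (code[[cur]] == code[[nxt]] && code[[nxt]] != "*") sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd, blocked)
  }
  res <- t(vapply(perms, walk, numeric(3)))
  open <- res[res[, 3] == 0, , drop = FALSE]
  if (nrow(open) == 0L) open <- res
  c(Sd = mean(open[, 1]), Nd = mean(open[, 2]))
}

#' Nei-Gojobori (NG86) Ks/Ka with Jukes-Cantor correction
#'
#' Counts synonymous and non-synonymous sites and differences by averaging
#' over minimal mutational pathways between each codon pair, then applies
#' the Jukes-Cantor multiple-hit correction
#' `d = -3/4 * log(1 - 4p/3)`. Used as an independent cross-check of the
#' likelihood estimates.
#'
#' @param aln A [build_codon_alignment()] result.
#' @return A `kaks_estimate` with `method = "NG86"` (`kappa` and `t` are
#'   `NA`; `omega = Ka/Ks` when defined). Errors when `pS` or `pN`
#'   reaches 0.75 (saturation).
#' @export
estimate_ng86 <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  pairs <- aln$codon_pairs
  sites_a <- rowSums(vapply(pairs[, 1], .ng86_codon_sites, numeric(2)))
  sites_b <- rowSums(vapply(pairs[, 2], .ng86_codon_sites, numeric(2)))
  S <- (sites_a[["S"]] + sites_b[["S"]]) / 2
  N <- (sites_a[["N"]] + sites_b[["N"]]) / 2
  diffs <- rowSums(vapply(seq_len(nrow(pairs)), function(k) {
    .ng86_codon_diffs(pairs[k, 1], pairs[k, 2])
  }, numeric(2)))
  pS <- diffs[["Sd"]] / S
  pN <- diffs[["Nd"]] / N
  if (pS >= 0.75 || pN >= 0.75) {
    stop("saturated alignment (pS = ", round(pS, 3), ", pN = ",
         round(pN, 3), ")")
  }
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  Ks <- jc(pS)
  Ka <- jc(pN)
  omega <- if (Ks > 0) Ka / Ks else NA_real_
  .kaks_estimate(Ks, Ka, NA_real_, omega, NA_real_, NA_real_,
                 S, N, NULL, aln$n_codons, "NG86", aln$source_gene_ids)
}
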