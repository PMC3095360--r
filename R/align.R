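# Pairwise alignment surface: global/local affine-gap alignment of DNA and
# protein, percent identity/similarity, sliding-window identity profiles, and
# Karlin-Altschul score-to-E-value conversion.
#
# Gap costs follow the EMBOSS convention: a gap of length L costs
# open + (L - 1) * extend, i.e. the first gapped position pays the full
# opening penalty. The DP engine is Biostrings::pairwiseAlignment, whose gap
# parameterisation (open' + L * extend) is mapped onto the EMBOSS one via
# open' = open - extend.

#' Alignment parameters
#'
#' Scoring parameters for pairwise DNA and protein alignment, with the EMBOSS
#' defaults used throughout the package: gap opening 10, gap extension 0.5,
#' DNA match +5 / mismatch -4, BLOSUM62 for proteins. `N` is scored as a
#' universal mismatch (never an identity), so assembly gaps cannot inflate
#' identity. Karlin-Altschul parameters `ka_lambda` and `ka_K` convert
#' ungapped-theory scores to approximate E-values; `ka_lambda` defaults to
#' the exact positive root of the moment equation for the DNA scores at equal
#' base frequencies, `ka_K` to 0.1.
#'
#' @param gap_open Gap opening penalty (>= 0); a gap of length L costs
#'   `gap_open + (L - 1) * gap_extend`.
#' @param gap_extend Gap extension penalty (>= 0, <= `gap_open`).
#' @param dna_match Match score for DNA.
#' @param dna_mismatch Mismatch score for DNA (negative).
#' @param protein_matrix Name of the protein substitution matrix
#'   (a matrix shipped with Biostrings, e.g. `"BLOSUM62"`).
#' @param ka_lambda Karlin-Altschul lambda (> 0); computed from the DNA
#'   scores when `NULL`.
#' @param ka_K Karlin-Altschul K (> 0, approximate).
#' @return An object of class `alignment_params`.
#' @examples
#' p <- alignment_params()
#' p$gap_open
#' @export
alignment_params <- function(gap_open = 10, gap_extend = 0.5,
                             dna_match = 5, dna_mismatch = -4,
                             protein_matrix = "BLOSUM62",
                             ka_lambda = NULL, ka_K = 0.1) {
  stopifnot(gap_open >= gap_extend, gap_extend >= 0)
  if (is.null(ka_lambda)) {
    ka_lambda <- ka_lambda_solve(dna_match, dna_mismatch)
  }
  stopifnot(ka_lambda > 0, ka_K > 0)
  structure(
    list(
      gap_open = gap_open, gap_extend = gap_extend,
      dna_match = dna_match, dna_mismatch = dna_mismatch,
      protein_matrix = protein_matrix,
      ka_lambda = ka_lambda, ka_K = ka_K
    ),
    class = "alignment_params"
  )
}

#' Solve the Karlin-Altschul lambda for simple match/mismatch scoring
#'
#' Finds the unique positive root of
#' `sum_ij p_i p_j exp(lambda * s_ij) = 1` for a match/mismatch scoring
#' scheme at the given background base frequencies. For +5/-4 at equal
#' frequencies the root is 0.1915, matching the published ungapped value.
#'
#' @param match,mismatch Match and mismatch scores (match > 0 > mismatch).
#' @param freqs Background base frequencies (length 4, summing to 1).
#' @return The positive root `lambda`.
#' @examples
#' ka_lambda_solve(5, -4)
#' @export
ka_lambda_solve <- function(match = 5, mismatch = -4, freqs = rep(0.25, 4)) {
  stopifnot(match > 0, mismatch < 0, length(freqs) == 4,
            abs(sum(freqs) - 1) < 1e-8)
  p_match <- sum(freqs^2)
  f <- function(l) p_match * exp(l * match) + (1 - p_match) * exp(l * mismatch) - 1
  # Mean score must be negative for a positive root to exist
  if (p_match * match + (1 - p_match) * mismatch >= 0) {
    stop("expected score is non-negative; no Karlin-Altschul lambda exists")
  }
  stats::uniroot(f, lower = 1e-8, upper = 10, tol = 1e-12)$root
}

# DNA scoring matrix over A,C,G,T,N with N scored as mismatch against
# everything, including itself.
.dna_score_matrix <- function(params) {
  bases <- c("A", "C", "G", "T", "N")
  m <- matrix(params$dna_mismatch, 5, 5, dimnames = list(bases, bases))
  diag(m) <- params$dna_match
  m["N", "N"] <- params$dna_mismatch
  m
}

.protein_score_matrix <- function(params) {
  key <- paste0("protmat_", params$protein_matrix)
  if (!is.null(.homoeolog_cache[[key]])) return(.homoeolog_cache[[key]])
  env <- new.env()
  utils::data(list = params$protein_matrix, package = "Biostrings", envir = env)
  m <- get(params$protein_matrix, envir = env)
  .homoeolog_cache[[key]] <- m
  m
}

.check_seq <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L) {
    stop(what, " must be a single non-empty sequence string")
  }
  toupper(x)
}

.align_engine <- function(a, b, params, type, mode) {
  if (type == "dna") {
    sm <- .dna_score_matrix(params)
    pa_a <- a
    pa_b <- b
  } else {
    sm <- .protein_score_matrix(params)
    pa_a <- Biostrings::AAString(a)
    pa_b <- Biostrings::AAString(b)
  }
  Biostrings::pairwiseAlignment(
    pattern = pa_a, subject = pa_b,
    type = mode,
    substitutionMatrix = sm,
    gapOpening = params$gap_open - params$gap_extend,
    gapExtension = params$gap_extend
  )
}

.wrap_alignment <- function(pa, a, b, params, type, mode) {
  sc <- score(pa)
  if (mode == "local" && sc <= 0) {
    # no positive-scoring local alignment: report the empty alignment
    aln <- structure(
      list(
        aligned_a = "", aligned_b = "", score = 0,
        mode = mode, type = type,
        start_a = NA_integer_, end_a = NA_integer_,
        start_b = NA_integer_, end_b = NA_integer_,
        identity_pct = NA_real_, similarity_pct = NA_real_,
        params = params
      ),
      class = "pairwise_alignment"
    )
    return(aln)
  }
  ga <- as.character(alignedPattern(pa))
  gb <- as.character(alignedSubject(pa))
  aln <- structure(
    list(
      aligned_a = unname(ga), aligned_b = unname(gb), score = sc,
      mode = mode, type = type,
      start_a = start(pattern(pa)), end_a = end(pattern(pa)),
      start_b = start(subject(pa)), end_b = end(subject(pa)),
      identity_pct = NA_real_, similarity_pct = NA_real_,
      params = params
    ),
    class = "pairwise_alignment"
  )
  idsim <- identity_and_similarity(aln, params)
  aln$identity_pct <- idsim[["identity_pct"]]
  aln$similarity_pct <- idsim[["similarity_pct"]]
  aln
}

#' Global affine-gap pairwise alignment
#'
#' Optimal Needleman-Wunsch/Gotoh global alignment with affine gap costs in
#' the EMBOSS convention (`gap_open + (L - 1) * gap_extend` for a gap of
#' length L); end gaps are penalised.
#'
#' @param a,b Sequences (single strings). DNA by default.
#' @param params An [alignment_params()] object.
#' @param type `"dna"` or `"protein"`.
#' @return A `pairwise_alignment` object: gapped strings `aligned_a` /
#'   `aligned_b`, `score`, `identity_pct` and (for proteins)
#'   `similarity_pct`.
#' @examples
#' global_align("ACGT", "ACGA")$identity_pct # 75
#' @export
global_align <- function(a, b, params = alignment_params(),
                         type = c("dna", "protein")) {
  type <- match.arg(type)
  a <- .check_seq(a, "a"); b <- .check_seq(b, "b")
  pa <- .align_engine(a, b, params, type, "global")
  .wrap_alignment(pa, a, b, params, type, "global")
}

#' Local affine-gap pairwise alignment (Smith-Waterman)
#'
#' Optimal local alignment under the same affine-gap scoring as
#' [global_align()]. When no positive-scoring pair of substrings exists the
#' empty alignment with score 0 is returned.
#'
#' @inheritParams global_align
#' @return A `pairwise_alignment` object (see [global_align()]); additionally
#'   `start_a`/`end_a`, `start_b`/`end_b` give the aligned substring
#'   coordinates (1-based, closed).
#' @examples
#' local_align("AAAA", "TTTT")$score # 0
#' @export
local_align <- function(a, b, params = alignment_params(),
                        type = c("dna", "protein")) {
  type <- match.arg(type)
  a <- .check_seq(a, "a"); b <- .check_seq(b, "b")
  pa <- .align_engine(a, b, params, type, "local")
  .wrap_alignment(pa, a, b, params, type, "local")
}

#' Percent identity and similarity of an alignment
#'
#' Identity is the percentage of alignment columns whose two characters are
#' identical (with `N` never counting as identical); gap columns count in the
#' denominator. For protein alignments, similarity is the percentage of
#' columns with a positive substitution-matrix score (EMBOSS semantics);
#' for DNA, similarity equals identity.
#'
#' @param alignment A `pairwise_alignment` object.
#' @param params An [alignment_params()] object (for the protein matrix).
#' @return Named numeric vector `c(identity_pct, similarity_pct)`.
#' @examples
#' identity_and_similarity(global_align("ACGT", "ACGA"))
#' @export
identity_and_similarity <- function(alignment, params = alignment_params()) {
  stopifnot(inherits(alignment, "pairwise_alignment"))
  ca <- strsplit(alignment$aligned_a, "")[[1]]
  cb <- strsplit(alignment$aligned_b, "")[[1]]
  ncol <- length(ca)
  if (ncol == 0L) stop("alignment is empty")
  both <- ca != "-" & cb != "-"
  ident <- both & ca == cb & ca != "N" & ca != "X"
  identity_pct <- 100 * sum(ident) / ncol
  if (alignment$type == "protein") {
    sm <- .protein_score_matrix(params)
    pos <- both
    idx <- which(both)
    if (length(idx)) {
      sc <- sm[cbind(ca[idx], cb[idx])]
      pos[idx] <- sc > 0
    }
    similarity_pct <- 100 * sum(pos) / ncol
  } else {
    similarity_pct <- identity_pct
  }
  c(identity_pct = identity_pct, similarity_pct = similarity_pct)
}

#' Sliding-window identity profile (VISTA-style)
#'
#' Computes percent identity in sliding windows along the first sequence of a
#' global alignment, the conservation profile usually drawn as a VISTA plot.
#' Each alignment column is assigned the coordinate of the most recent
#' non-gap position of the first sequence; windows containing no aligned
#' column are omitted.
#'
#' @param alignment A global `pairwise_alignment`.
#' @param window_size Window width in bp of the first sequence (default 100).
#' @param step Step between window starts in bp (default 25);
#'   `step <= window_size` required.
#' @return A data frame (`start`, `end`, `identity_pct`) of class
#'   `identity_profile`, coordinates in the first sequence.
#' @examples
#' aln <- global_align(strrep("ACGT", 50), strrep("ACGT", 50))
#' head(sliding_identity_profile(aln, 50, 25))
#' @export
sliding_identity_profile <- function(alignment, window_size = 100, step = 25) {
  stopifnot(inherits(alignment, "pairwise_alignment"))
  if (alignment$mode != "global") stop("identity profile requires a global alignment")
  if (window_size < step || step < 1) {
    stop("window_size must be >= step >= 1")
  }
  ca <- strsplit(alignment$aligned_a, "")[[1]]
  cb <- strsplit(alignment$aligned_b, "")[[1]]
  # coordinate in sequence a for every column (gap columns inherit the
  # previous coordinate; leading gap columns get coordinate 0 and are dropped)
  coord <- cumsum(ca != "-")
  keep <- coord >= 1L
  ca <- ca[keep]; cb <- cb[keep]; coord <- coord[keep]
  ident <- as.integer(ca == cb & ca != "-" & cb != "-" & ca != "N")
  len_a <- max(coord)
  starts <- seq(1L, max(1L, len_a - window_size + 1L), by = step)
  # per-coordinate tallies, then cumulative sums for O(1) window queries
  n_cols <- tabulate(coord, nbins = len_a)
  n_id <- as.integer(unname(tapply(ident, factor(coord, levels = seq_len(len_a)),
                                   sum, default = 0L)))
  n_id[is.na(n_id)] <- 0L
  cum_cols <- cumsum(n_cols)
  cum_id <- cumsum(n_id)
  res <- lapply(starts, function(s) {
    e <- min(s + window_size - 1L, len_a)
    tot <- cum_cols[e] - if (s > 1) cum_cols[s - 1] else 0
    idn <- cum_id[e] - if (s > 1) cum_id[s - 1] else 0
    if (tot == 0) return(NULL)
    data.frame(start = s, end = e, identity_pct = 100 * idn / tot)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) out <- data.frame(start = integer(0), end = integer(0),
                                      identity_pct = numeric(0))
  attr(out, "window_size") <- window_size
  attr(out, "step") <- step
  class(out) <- c("identity_profile", "data.frame")
  out
}

#' Karlin-Altschul E-value for an alignment score
#'
#' `E = K * m * n * exp(-lambda * S)` with the ungapped Karlin-Altschul
#' parameters carried in `params`. Used as an approximate, self-contained
#' significance surrogate for gapped local alignment scores; outputs carrying
#' these E-values are flagged approximate.
#'
#' @param score Alignment score (>= 0).
#' @param query_len,target_len Lengths m and n of the compared sequences
#'   (or of the search database), both > 0.
#' @param params An [alignment_params()] object.
#' @return The expected number of chance alignments with score >= `score`.
#' @examples
#' evalue(100, 500, 500)
#' @export
evalue <- function(score, query_len, target_len, params = alignment_params()) {
  if (any(score < 0)) stop("score must be >= 0")
  if (query_len <= 0 || target_len <= 0) stop("sequence lengths must be positive")
  params$ka_K * query_len * target_len * exp(-params$ka_lambda * score)
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("%s %s alignment: score %.2f", x$mode, x$type, x$score))
  if (!is.na(x$identity_pct)) {
    cat(sprintf(", identity %.2f%%", x$identity_pct))
    if (x$type == "protein") cat(sprintf(", similarity %.2f%%", x$similarity_pct))
  }
  cat("\n")
  if (nchar(x$aligned_a) > 0) {
    w <- min(60L, nchar(x$aligned_a))
    cat(substr(x$aligned_a, 1, w), "\n")
    cat(substr(x$aligned_b, 1, w), "\n")
  }
  invisible(x)
}
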