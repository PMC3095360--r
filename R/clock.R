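# Molecular-clock dating of sub-genome divergence from synonymous
# substitution rates. With a per-lineage rate r (substitutions per
# synonymous site per year), Ks accumulates on both lineages, so
# T = Ks / (2 r).

#' Median Ks
#'
#' @param ks_values Non-empty numeric vector of finite Ks values (>= 0).
#' @return The standard median (mean of the central two values for even n).
#' @examples
#' median_ks(c(0.04, 0.06, 0.05))
#' @export
median_ks <- function(ks_values) {
  if (length(ks_values) == 0L) stop("ks_values is empty")
  if (any(!is.finite(ks_values)) || any(ks_values < 0)) {
    stop("ks_values must be finite and >= 0")
  }
  stats::median(ks_values)
}

#' Divergence time from Ks under a molecular clock
#'
#' `T = Ks / (2 * rate_r)` years: the synonymous divergence accumulated on
#' both lineages divided by twice the per-lineage synonymous substitution
#' rate. The default rate is the legume estimate of 6.1e-9 substitutions per
#' synonymous site per year.
#'
#' @param ks Synonymous divergence (>= 0).
#' @param rate_r Per-lineage synonymous substitution rate per site per year
#'   (> 0).
#' @return An object of class `clock_estimate` with `T_years` and `T_mya`
#'   (the latter also rounded to 1 decimal place as `T_mya_1dp`).
#' @examples
#' divergence_time(0.05085)$T_mya
#' @export
divergence_time <- function(ks, rate_r = 6.1e-9) {
  stopifnot(length(ks) == 1L, is.finite(ks), ks >= 0)
  if (rate_r <= 0) stop("rate_r must be positive")
  T_years <- ks / (2 * rate_r)
  structure(
    list(median_ks = ks, rate_r = rate_r,
         T_years = T_years, T_mya = T_years / 1e6,
         T_mya_1dp = round(T_years / 1e6, 1)),
    class = "clock_estimate"
  )
}

#' @export
print.clock_estimate <- function(x, ...) {
  cat(sprintf("clock estimate: Ks = %.5f, r = %.3g /site/yr -> T = %.1f Mya\n",
              x$median_ks, x$rate_r, x$T_mya))
  invisible(x)
}

#' Clock report over a set of Ks/Ka estimates
#'
#' Summarises per-pair Ks values into a median-based divergence-time
#' estimate, with mean and standard deviation of Ks reported alongside and a
#' per-pair table of individual divergence times.
#'
#' @param pairs A numeric vector of Ks values, or a list of `kaks_estimate`
#'   objects.
#' @param rate_r Per-lineage synonymous substitution rate (see
#'   [divergence_time()]).
#' @return A list with `summary` (a [divergence_time()] result augmented
#'   with `n_pairs`, `mean_ks`, `sd_ks`) and `per_pair` (data frame
#'   `pair`, `Ks`, `T_years`, `T_mya`).
#' @examples
#' clock_report(c(0.04, 0.05, 0.06))$summary$T_mya
#' @export
clock_report <- function(pairs, rate_r = 6.1e-9) {
  if (is.list(pairs) && all(vapply(pairs, inherits, logical(1), "kaks_estimate"))) {
    ids <- vapply(pairs, function(p) paste(p$source_gene_ids, collapse = "/"),
                  character(1))
    ks <- vapply(pairs, `[[`, numeric(1), "Ks")
  } else {
    ks <- as.numeric(pairs)
    ids <- names(pairs) %||% paste0("pair", seq_along(ks))
  }
  if (length(ks) == 0L) stop("no Ks estimates supplied")
  med <- median_ks(ks)
  est <- divergence_time(med, rate_r)
  est$n_pairs <- length(ks)
  est$mean_ks <- mean(ks)
  est$sd_ks <- if (length(ks) > 1L) stats::sd(ks) else NA_real_
  per_pair <- data.frame(
    pair = ids, Ks = ks,
    T_years = ks / (2 * rate_r),
    T_mya = ks / (2 * rate_r) / 1e6,
    stringsAsFactors = FALSE
  )
  list(summary = est, per_pair = per_pair)
}
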