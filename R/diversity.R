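# Observed/expected heterozygosity and the inbreeding coefficient.
#
# Conventions (documented because popgen tools differ silently):
#   * H_O per locus = fraction of heterozygous calls among non-missing calls;
#     the group value is the per-locus mean over loci with data (identical to
#     the per-individual mean when data are complete).
#   * H_E per locus = 2p(1-p); the unbiased variant multiplies by
#     2n/(2n-1) with n = individuals called at that locus.
#   * F_IS: ratio-of-means 1 - mean(H_O)/mean(H_E) by default; the
#     mean-of-ratios variant averages 1 - h_o/h_e over loci with h_e > 0.
#     Both are exposed because reported tables from different tools are not
#     reproducible without knowing the aggregation.

resolve_samples <- function(gm, sample_ids) {
  sample_ids <- sample_ids %||% gm$sample_ids
  unknown <- setdiff(sample_ids, gm$sample_ids)
  if (length(unknown)) stop("unknown sample id(s): ", id_preview(unknown))
  sample_ids
}

#' Per-individual observed heterozygosity
#'
#' Fraction of heterozygous calls among the individual's non-missing calls.
#'
#' @param gm a [genotype_matrix].
#' @param sample_id one sample id.
#' @return A fraction in \[0, 1\].
#' @export
individual_ho <- function(gm, sample_id) {
  stopifnot(inherits(gm, "genotype_matrix"), length(sample_id) == 1L)
  if (!sample_id %in% gm$sample_ids) stop("unknown sample id: ", sample_id)
  g <- gm$calls[sample_id, ]
  called <- !is.na(g)
  if (!any(called)) stop("sample '", sample_id, "' has no called loci")
  sum(g[called] == 1L) / sum(called)
}

#' Per-locus alternate-allele frequencies
#'
#' `p = (2 * n_hom_alt + n_het) / (2 * n_called)` per locus over the given
#' samples; `NA` where no individual is called.
#'
#' @param gm a [genotype_matrix].
#' @param sample_ids samples to use (default all).
#' @return Named numeric vector, one entry per locus.
#' @export
allele_freq <- function(gm, sample_ids = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  sample_ids <- resolve_samples(gm, sample_ids)
  calls <- gm$calls[sample_ids, , drop = FALSE]
  n_called <- colSums(!is.na(calls))
  p <- colSums(calls, na.rm = TRUE) / (2 * n_called)
  p[n_called == 0L] <- NA_real_
  p
}

#' Group observed heterozygosity
#'
#' Mean over loci of the per-locus heterozygote fraction among non-missing
#' calls. Loci with no calls in the group are skipped.
#'
#' @param gm a [genotype_matrix].
#' @param sample_ids samples forming the group (default all).
#' @return A fraction in \[0, 1\].
#' @export
group_ho <- function(gm, sample_ids = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  sample_ids <- resolve_samples(gm, sample_ids)
  calls <- gm$calls[sample_ids, , drop = FALSE]
  n_called <- colSums(!is.na(calls))
  h <- colSums(calls == 1L, na.rm = TRUE) / n_called
  mean(h[n_called > 0L])
}

#' Group expected heterozygosity
#'
#' Per-locus Hardy-Weinberg expectation `2p(1-p)` averaged over loci with
#' data; the unbiased small-sample variant scales each locus by
#' `2n/(2n-1)` (n = called individuals at that locus).
#'
#' @param gm a [genotype_matrix].
#' @param sample_ids samples forming the group (default all).
#' @param unbiased logical; apply the small-sample correction (default TRUE).
#' @return Mean expected heterozygosity.
#' @export
group_he <- function(gm, sample_ids = NULL, unbiased = TRUE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  sample_ids <- resolve_samples(gm, sample_ids)
  calls <- gm$calls[sample_ids, , drop = FALSE]
  n_called <- colSums(!is.na(calls))
  p <- colSums(calls, na.rm = TRUE) / (2 * n_called)
  he <- 2 * p * (1 - p)
  if (unbiased) he <- he * (2 * n_called) / (2 * n_called - 1)
  mean(he[n_called > 0L])
}

#' Group inbreeding coefficient
#'
#' Deficit of observed relative to expected heterozygosity. The default
#' aggregation is the ratio of means, `1 - mean(H_O) / mean(H_E)`; the
#' `"per_locus"` variant averages `1 - h_o/h_e` over loci where `h_e > 0`.
#' When the reference H_E is zero everywhere the coefficient is undefined
#' and `NA` is returned (never 0).
#'
#' @param gm a [genotype_matrix].
#' @param sample_ids samples forming the group (default all).
#' @param method `"ratio"` (ratio of means, default) or `"per_locus"`.
#' @param unbiased use the unbiased H_E as reference (default TRUE).
#' @return F_IS in \[-1, 1\], or `NA` when undefined.
#' @export
group_fis <- function(gm, sample_ids = NULL, method = c("ratio", "per_locus"),
                      unbiased = TRUE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  method <- match.arg(method)
  sample_ids <- resolve_samples(gm, sample_ids)
  calls <- gm$calls[sample_ids, , drop = FALSE]
  n_called <- colSums(!is.na(calls))
  use <- n_called > 0L
  ho <- (colSums(calls == 1L, na.rm = TRUE) / n_called)[use]
  p <- (colSums(calls, na.rm = TRUE) / (2 * n_called))[use]
  he <- 2 * p * (1 - p)
  if (unbiased) he <- he * (2 * n_called[use]) / (2 * n_called[use] - 1)
  if (method == "ratio") {
    if (mean(he) == 0) return(NA_real_)
    1 - mean(ho) / mean(he)
  } else {
    poly <- he > 0
    if (!any(poly)) return(NA_real_)
    mean(1 - ho[poly] / he[poly])
  }
}

#' Per-group diversity table
#'
#' H_O, H_E (biased and unbiased) and F_IS (both aggregations) for each
#' management group, in the layout of a standard diversity summary table.
#'
#' @param gm a [genotype_matrix]; normally already QC-filtered, so that
#'   dataset-monomorphic loci are gone and all groups are averaged over the
#'   same locus set.
#' @param groups named list mapping group label to sample ids.
#' @return A `diversity_table` data.frame with columns `group`,
#'   `n_individuals`, `n_loci_used`, `ho`, `he`, `uhe`, `fis`
#'   (ratio-of-means on unbiased H_E) and `fis_per_locus`.
#' @export
diversity_table <- function(gm, groups) {
  stopifnot(inherits(gm, "genotype_matrix"), is.list(groups),
            !is.null(names(groups)))
  rows <- lapply(names(groups), function(g) {
    ids <- resolve_samples(gm, groups[[g]])
    calls <- gm$calls[ids, , drop = FALSE]
    data.frame(
      group = g,
      n_individuals = length(ids),
      n_loci_used = sum(colSums(!is.na(calls)) > 0L),
      ho = group_ho(gm, ids),
      he = group_he(gm, ids, unbiased = FALSE),
      uhe = group_he(gm, ids, unbiased = TRUE),
      fis = group_fis(gm, ids, method = "ratio"),
      fis_per_locus = group_fis(gm, ids, method = "per_locus"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("diversity_table", "data.frame")
  out
}

#' @export
print.diversity_table <- function(x, digits = 3, ...) {
  cat("Per-group diversity (H_O, H_E, F_IS):\n")
  y <- x
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits = digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
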