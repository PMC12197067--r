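#' Construct a genotype matrix
#'
#' The central container of the package: a samples x loci matrix of biallelic
#' SNP calls coded as alternate-allele dosage (0 = homozygous reference,
#' 1 = heterozygous, 2 = homozygous alternate, `NA` = missing), together with
#' per-locus quality-control metadata. Missingness is always a distinct state,
#' never conflated with the reference homozygote.
#'
#' @param calls integer or numeric matrix with unique rownames (sample ids)
#'   and unique colnames (locus ids); entries must be 0, 1, 2 or `NA`.
#' @param locus_meta optional data.frame with one row per locus and columns
#'   `locus_id`, `fragment_id` (sequenced-fragment identifier grouping a
#'   primary SNP with its secondaries), `reproducibility` (fraction in
#'   \[0, 1\]), `mean_read_depth` (non-negative). When omitted, each locus is
#'   placed on its own fragment and reproducibility/depth are `NA` (filters
#'   that need them will refuse to run). The per-locus call rate is always
#'   recomputed from `calls`, never trusted from file metadata.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls`, `sample_ids`, `locus_ids`, `locus_meta`, `n_samples`, `n_loci`.
#' @examples
#' gm <- genotype_matrix(matrix(c(0, 1, 2, NA), 2, 2,
#'   dimnames = list(c("s1", "s2"), c("L1", "L2"))))
#' gm
#' @export
genotype_matrix <- function(calls, locus_meta = NULL) {
  if (!is.matrix(calls)) stop("`calls` must be a matrix")
  if (is.null(rownames(calls)) || is.null(colnames(calls))) {
    stop("`calls` must carry sample ids as rownames and locus ids as colnames")
  }
  storage.mode(calls) <- "integer"
  sample_ids <- rownames(calls)
  locus_ids <- colnames(calls)
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         id_preview(unique(sample_ids[duplicated(sample_ids)])))
  }
  if (anyDuplicated(locus_ids)) {
    stop("duplicate locus ids: ",
         id_preview(unique(locus_ids[duplicated(locus_ids)])))
  }
  bad <- !is.na(calls) & !(calls %in% c(0L, 1L, 2L))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "invalid genotype code %s at sample '%s', locus '%s' (allowed: 0, 1, 2, missing)",
      calls[w[1L], w[2L]], sample_ids[w[1L]], locus_ids[w[2L]]))
  }
  if (is.null(locus_meta)) {
    locus_meta <- data.frame(
      locus_id = locus_ids,
      fragment_id = locus_ids,
      reproducibility = NA_real_,
      mean_read_depth = NA_real_,
      stringsAsFactors = FALSE
    )
  }
  locus_meta <- validate_locus_meta(locus_meta, locus_ids)
  locus_meta$call_rate <- unname(colMeans(!is.na(calls)))
  structure(
    list(
      calls = calls,
      sample_ids = sample_ids,
      locus_ids = locus_ids,
      locus_meta = locus_meta,
      n_samples = nrow(calls),
      n_loci = ncol(calls)
    ),
    class = "genotype_matrix"
  )
}

validate_locus_meta <- function(locus_meta, locus_ids) {
  req <- c("locus_id", "fragment_id", "reproducibility", "mean_read_depth")
  miss <- setdiff(req, names(locus_meta))
  if (length(miss)) stop("locus_meta lacks column(s): ", id_preview(miss))
  if (anyDuplicated(locus_meta$locus_id)) {
    stop("locus_meta has duplicated locus_id entries")
  }
  if (!setequal(locus_meta$locus_id, locus_ids)) {
    stop("locus_meta must have exactly one record per locus in `calls`")
  }
  locus_meta <- locus_meta[match(locus_ids, locus_meta$locus_id),
                           req, drop = FALSE]
  rownames(locus_meta) <- NULL
  rp <- locus_meta$reproducibility
  if (any(!is.na(rp) & (rp < 0 | rp > 1))) {
    stop("reproducibility values must lie in [0, 1]")
  }
  dp <- locus_meta$mean_read_depth
  if (any(!is.na(dp) & dp < 0)) stop("mean_read_depth must be non-negative")
  locus_meta
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d biallelic loci\n",
              x$n_samples, x$n_loci))
  miss <- mean(is.na(x$calls)) * 100
  cat(sprintf("  missing calls: %.2f%%\n", miss))
  nf <- length(unique(x$locus_meta$fragment_id))
  cat(sprintf("  fragments: %d (%d secondaries)\n", nf, x$n_loci - nf))
  invisible(x)
}

#' @export
summary.genotype_matrix <- function(object, ...) {
  p <- allele_freq(object)
  out <- list(
    n_samples = object$n_samples,
    n_loci = object$n_loci,
    missing_pct = mean(is.na(object$calls)) * 100,
    locus_call_rate = summary(object$locus_meta$call_rate),
    alt_freq = summary(p[!is.na(p)]),
    n_monomorphic = sum(is.na(p) | p == 0 | p == 1)
  )
  class(out) <- "summary.genotype_matrix"
  out
}

#' @export
print.summary.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d loci, %.2f%% missing\n",
              x$n_samples, x$n_loci, x$missing_pct))
  cat("locus call rate:\n"); print(x$locus_call_rate)
  cat("alt allele frequency:\n"); print(x$alt_freq)
  invisible(x)
}

#' Subset a genotype matrix by sample and locus ids
#'
#' Rows and columns are returned in the requested order; locus metadata is
#' carried over and per-locus call rates are recomputed on the retained
#' samples (this is what makes a two-pass "recall on the target samples"
#' workflow possible).
#'
#' @param gm a [genotype_matrix].
#' @param samples,loci character vectors of ids to keep (default: all, in
#'   current order). Unknown ids are a hard error, never silently dropped.
#' @return A [genotype_matrix].
#' @export
subset_genotypes <- function(gm, samples = NULL, loci = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  samples <- samples %||% gm$sample_ids
  loci <- loci %||% gm$locus_ids
  unknown_s <- setdiff(samples, gm$sample_ids)
  if (length(unknown_s)) stop("unknown sample id(s): ", id_preview(unknown_s))
  unknown_l <- setdiff(loci, gm$locus_ids)
  if (length(unknown_l)) stop("unknown locus id(s): ", id_preview(unknown_l))
  if (anyDuplicated(samples) || anyDuplicated(loci)) {
    stop("requested ids contain duplicates")
  }
  calls <- gm$calls[samples, loci, drop = FALSE]
  meta <- gm$locus_meta[match(loci, gm$locus_meta$locus_id),
                        c("locus_id", "fragment_id", "reproducibility",
                          "mean_read_depth"), drop = FALSE]
  genotype_matrix(calls, meta)
}

#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  samples <- if (missing(i)) x$sample_ids else x$sample_ids[i]
  loci <- if (missing(j)) x$locus_ids else x$locus_ids[j]
  subset_genotypes(x, samples, loci)
}

#' Per-locus and per-sample call rates
#'
#' Fraction of non-missing calls, computed from the stored calls.
#'
#' @param gm a [genotype_matrix].
#' @return Named numeric vector.
#' @export
locus_call_rate <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  colMeans(!is.na(gm$calls))
}

#' @rdname locus_call_rate
#' @export
sample_call_rate <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  rowMeans(!is.na(gm$calls))
}
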