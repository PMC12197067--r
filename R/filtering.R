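# Quality-control cascade. Every threshold is inclusive on the "keep" side:
# "below X" removes strictly < X, "outside [lo, hi]" removes strictly outside.

is_monomorphic_locus <- function(calls) {
  # TRUE when only one allele is observed among non-missing calls at each
  # locus (all hom-ref, all hom-alt, a single homozygote, or no calls at
  # all). A single heterozygote shows both alleles, hence polymorphic.
  ref <- colSums(calls == 0L | calls == 1L, na.rm = TRUE) > 0L
  alt <- colSums(calls == 1L | calls == 2L, na.rm = TRUE) > 0L
  !(ref & alt)
}

check_nonempty <- function(ids, what, step) {
  if (!length(ids)) {
    stop(sprintf("filter step '%s' would remove every %s", step, what))
  }
  ids
}

#' QC filter steps
#'
#' Individual steps of the quality-control cascade; [run_cascade()] chains
#' them in a fixed, recorded order. Each returns a filtered
#' [genotype_matrix]; removing everything is a hard error.
#'
#' * `filter_individual_callrate()`: keep samples whose fraction of
#'   non-missing calls is at least `min_rate`.
#' * `filter_locus_reproducibility()`: keep loci with
#'   `reproducibility >= min_rep` (errors if reproducibility metadata is
#'   absent).
#' * `filter_read_depth()`: keep loci with `min_depth <= mean_read_depth <=
#'   max_depth` (inclusive; errors if depth metadata is absent).
#' * `filter_locus_callrate()`: keep loci whose call rate over the *current*
#'   samples is at least `min_rate` (always recomputed, so the step reacts to
#'   earlier sample removal).
#' * `filter_monomorphic()`: drop loci where only one allele is observed;
#'   entirely-missing loci count as monomorphic.
#' * `filter_secondaries()`: keep one locus per sequenced fragment. Tie-break:
#'   highest call rate, then highest reproducibility, then first in current
#'   order.
#'
#' @param gm a [genotype_matrix].
#' @param min_rate minimum call-rate fraction in \[0, 1\].
#' @param min_rep minimum reproducibility fraction in \[0, 1\].
#' @param min_depth,max_depth inclusive mean-read-depth bounds.
#' @return A filtered [genotype_matrix].
#' @name qc_filters
NULL

#' @rdname qc_filters
#' @export
filter_individual_callrate <- function(gm, min_rate) {
  stopifnot(inherits(gm, "genotype_matrix"),
            is.numeric(min_rate), min_rate >= 0, min_rate <= 1)
  keep <- gm$sample_ids[sample_call_rate(gm) >= min_rate]
  subset_genotypes(gm, samples = check_nonempty(keep, "sample",
                                                "individual call rate"))
}

#' @rdname qc_filters
#' @export
filter_locus_reproducibility <- function(gm, min_rep) {
  stopifnot(inherits(gm, "genotype_matrix"),
            is.numeric(min_rep), min_rep >= 0, min_rep <= 1)
  rp <- gm$locus_meta$reproducibility
  if (anyNA(rp)) {
    stop("reproducibility metadata is missing for ",
         sum(is.na(rp)), " locus/loci; cannot apply the filter")
  }
  keep <- gm$locus_ids[rp >= min_rep]
  subset_genotypes(gm, loci = check_nonempty(keep, "locus", "reproducibility"))
}

#' @rdname qc_filters
#' @export
filter_read_depth <- function(gm, min_depth, max_depth) {
  stopifnot(inherits(gm, "genotype_matrix"),
            is.numeric(min_depth), is.numeric(max_depth),
            min_depth <= max_depth)
  dp <- gm$locus_meta$mean_read_depth
  if (anyNA(dp)) {
    stop("read-depth metadata is missing for ",
         sum(is.na(dp)), " locus/loci; cannot apply the filter")
  }
  keep <- gm$locus_ids[dp >= min_depth & dp <= max_depth]
  subset_genotypes(gm, loci = check_nonempty(keep, "locus", "read depth"))
}

#' @rdname qc_filters
#' @export
filter_locus_callrate <- function(gm, min_rate) {
  stopifnot(inherits(gm, "genotype_matrix"),
            is.numeric(min_rate), min_rate >= 0, min_rate <= 1)
  keep <- gm$locus_ids[locus_call_rate(gm) >= min_rate]
  subset_genotypes(gm, loci = check_nonempty(keep, "locus", "locus call rate"))
}

#' @rdname qc_filters
#' @export
filter_monomorphic <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  keep <- gm$locus_ids[!is_monomorphic_locus(gm$calls)]
  subset_genotypes(gm, loci = check_nonempty(keep, "locus", "monomorphic"))
}

#' @rdname qc_filters
#' @export
filter_secondaries <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  meta <- gm$locus_meta
  cr <- locus_call_rate(gm)
  rp <- meta$reproducibility
  rp[is.na(rp)] <- -Inf
  ord <- order(match(meta$fragment_id, unique(meta$fragment_id)),
               -cr, -rp, seq_len(nrow(meta)))
  first <- !duplicated(meta$fragment_id[ord])
  keep_ids <- meta$locus_id[ord][first]
  # preserve original column order among the survivors
  keep <- gm$locus_ids[gm$locus_ids %in% keep_ids]
  subset_genotypes(gm, loci = keep)
}

#' Default QC cascade configuration
#'
#' Thresholds of the two-pass workflow: the first pass (all species) keeps
#' loci with call rate >= 0.97, the second pass (after restriction to the
#' target species, with call rates recomputed on those samples) relaxes the
#' locus call-rate threshold to 0.95. All other steps are shared: individual
#' call rate 0.25, reproducibility 0.99, mean read depth within \[5, 500\],
#' then removal of monomorphic loci and secondaries.
#'
#' @param pass `1` or `2`.
#' @return A named list understood by [run_cascade()]. Set a threshold to
#'   `NULL` (or a flag to `FALSE`) to disable a step.
#' @export
default_filter_config <- function(pass = 1) {
  stopifnot(pass %in% c(1, 2))
  list(
    individual_callrate = 0.25,
    locus_reproducibility = 0.99,
    read_depth = c(5, 500),
    locus_callrate = if (pass == 1) 0.97 else 0.95,
    monomorphic = TRUE,
    secondaries = TRUE
  )
}

#' Run the QC cascade
#'
#' Applies the filter steps in a fixed order -- individual call rate,
#' locus reproducibility, read depth, locus call rate, monomorphic loci,
#' secondaries -- and records per-step retention in a `filter_report`.
#' The order matters: locus call rates are recomputed after sample removal.
#'
#' @param gm a [genotype_matrix].
#' @param config a list as returned by [default_filter_config()].
#' @return A list with elements `genotypes` (the filtered [genotype_matrix])
#'   and `report` (a `filter_report` data.frame: step, threshold, samples and
#'   loci retained, with the final missing-call percentage and per-step
#'   removed ids as attributes).
#' @export
run_cascade <- function(gm, config = default_filter_config(1)) {
  stopifnot(inherits(gm, "genotype_matrix"))
  steps <- list()
  removed <- list()
  record <- function(name, threshold, obj) {
    steps[[length(steps) + 1L]] <<- data.frame(
      step = name, threshold = threshold,
      n_samples = obj$n_samples, n_loci = obj$n_loci,
      stringsAsFactors = FALSE)
  }
  record("input", NA_character_, gm)
  cur <- gm
  apply_step <- function(name, threshold_label, fn) {
    prev <- cur
    cur <<- fn(cur)
    removed[[name]] <<- list(
      samples = setdiff(prev$sample_ids, cur$sample_ids),
      loci = setdiff(prev$locus_ids, cur$locus_ids))
    record(name, threshold_label, cur)
  }
  if (!is.null(config$individual_callrate)) {
    apply_step("individual_callrate",
               format(config$individual_callrate),
               function(g) filter_individual_callrate(g, config$individual_callrate))
  }
  if (!is.null(config$locus_reproducibility)) {
    apply_step("locus_reproducibility",
               format(config$locus_reproducibility),
               function(g) filter_locus_reproducibility(g, config$locus_reproducibility))
  }
  if (!is.null(config$read_depth)) {
    apply_step("read_depth",
               paste(config$read_depth, collapse = "-"),
               function(g) filter_read_depth(g, config$read_depth[1],
                                             config$read_depth[2]))
  }
  if (!is.null(config$locus_callrate)) {
    apply_step("locus_callrate",
               format(config$locus_callrate),
               function(g) filter_locus_callrate(g, config$locus_callrate))
  }
  if (isTRUE(config$monomorphic)) {
    apply_step("monomorphic", "polymorphic only", filter_monomorphic)
  }
  if (isTRUE(config$secondaries)) {
    apply_step("secondaries", "one per fragment", filter_secondaries)
  }
  report <- do.call(rbind, steps)
  attr(report, "final_missing_pct") <- mean(is.na(cur$calls)) * 100
  attr(report, "removed") <- removed
  class(report) <- c("filter_report", "data.frame")
  list(genotypes = cur, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("QC filter cascade:\n")
  print.data.frame(x, row.names = FALSE)
  cat(sprintf("final missing data: %.2f%%\n", attr(x, "final_missing_pct")))
  invisible(x)
}
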