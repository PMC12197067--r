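# Clone (multilocus genotype) detection. Ramets of one genet differ only by
# genotyping error, so a small dissimilarity threshold separates clone-mates
# from distinct genets, replacing likelihood pedigree reconstruction for the
# clone-calling step.

#' Pairwise genotype dissimilarity
#'
#' Fraction of loci called in both samples whose codes differ. Pairs sharing
#' fewer than `min_shared` called loci are incomparable and return `NA`
#' (never 0: absence of data is not similarity).
#'
#' @param gm a [genotype_matrix].
#' @param a,b sample ids.
#' @param min_shared minimum number of loci called in both (default 50).
#' @return A fraction in \[0, 1\], with attributes `n_shared` and
#'   `n_mismatch`; `NA` if incomparable.
#' @export
pairwise_dissimilarity <- function(gm, a, b, min_shared = 50) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!a %in% gm$sample_ids) stop("unknown sample id: ", a)
  if (!b %in% gm$sample_ids) stop("unknown sample id: ", b)
  ga <- gm$calls[a, ]
  gb <- gm$calls[b, ]
  shared <- !is.na(ga) & !is.na(gb)
  n_shared <- sum(shared)
  if (n_shared < min_shared) {
    return(structure(NA_real_, n_shared = n_shared, n_mismatch = NA_integer_))
  }
  n_mismatch <- sum(ga[shared] != gb[shared])
  structure(n_mismatch / n_shared, n_shared = n_shared,
            n_mismatch = n_mismatch)
}

#' Full dissimilarity matrix
#'
#' @inheritParams pairwise_dissimilarity
#' @param sample_ids samples to compare (default all).
#' @return A symmetric matrix with zero diagonal; `NA` marks incomparable
#'   pairs (fewer than `min_shared` shared called loci).
#' @export
dissimilarity_matrix <- function(gm, sample_ids = NULL, min_shared = 50) {
  stopifnot(inherits(gm, "genotype_matrix"))
  sample_ids <- resolve_samples(gm, sample_ids)
  x <- gm$calls[sample_ids, , drop = FALSE]
  n <- nrow(x)
  d <- matrix(0, n, n, dimnames = list(sample_ids, sample_ids))
  for (i in seq_len(n)) {
    gi <- x[i, ]
    for (j in seq_len(n)) {
      if (j >= i) break
      shared <- !is.na(gi) & !is.na(x[j, ])
      ns <- sum(shared)
      d[i, j] <- d[j, i] <-
        if (ns < min_shared) NA_real_ else sum(gi[shared] != x[j, shared]) / ns
    }
  }
  d
}

#' Call clones (collapse ramets into genets)
#'
#' Complete-linkage agglomerative clustering on the pairwise dissimilarity
#' matrix, cut at `threshold`: within a genet every pair of members differs
#' at no more than `threshold` of their shared loci (the complete-linkage
#' guarantee; single linkage could chain two true genets through an
#' intermediate erroneous sample). Samples are processed in lexicographic id
#' order, so the result is deterministic. Genets are numbered by first
#' member appearance and given a per-genet consensus genotype (per-locus
#' majority code; ties and no-data loci become missing).
#'
#' @param gm a [genotype_matrix].
#' @param threshold maximum within-genet dissimilarity (default 0.05,
#'   calibrated so that clone-mates differing only by a per-call error rate
#'   well under 2.5% stay together while distinct genets, typically >20%
#'   apart in low-diversity SNP panels, split).
#' @param sample_ids samples to assign (default all).
#' @param min_shared minimum shared called loci per pair; an incomparable
#'   pair is a hard error, since no merge decision about it is defensible.
#' @return A `clone_assignment` list: `assignments` (data.frame sample_id,
#'   genet), `genets` (named list of member ids), `consensus`
#'   (genets x loci matrix), `threshold`, `dissimilarity`.
#' @export
call_clones <- function(gm, threshold = 0.05, sample_ids = NULL,
                        min_shared = 50) {
  stopifnot(inherits(gm, "genotype_matrix"), threshold >= 0, threshold <= 1)
  sample_ids <- sort(resolve_samples(gm, sample_ids))
  d <- dissimilarity_matrix(gm, sample_ids, min_shared = min_shared)
  if (anyNA(d)) {
    w <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
    pairs <- paste(rownames(d)[w[, 1]], colnames(d)[w[, 2]], sep = " ~ ")
    stop("incomparable sample pair(s) (fewer than ", min_shared,
         " shared called loci): ", id_preview(pairs))
  }
  cluster <- if (length(sample_ids) == 1L) {
    stats::setNames(1L, sample_ids)
  } else {
    hc <- stats::hclust(stats::as.dist(d), method = "complete")
    stats::cutree(hc, h = threshold)
  }
  # renumber genets by order of first appearance of a member
  first <- tapply(seq_along(cluster), cluster, min)
  relab <- rank(first)
  genet_ids <- paste0("MLG", relab[as.character(cluster)])
  names(genet_ids) <- sample_ids
  members <- split(sample_ids, genet_ids)
  members <- members[order(as.integer(sub("^MLG", "", names(members))))]
  consensus <- t(vapply(members, function(ms) consensus_genotype(gm, ms),
                        integer(gm$n_loci)))
  colnames(consensus) <- gm$locus_ids
  structure(
    list(
      assignments = data.frame(sample_id = sample_ids,
                               genet = unname(genet_ids),
                               stringsAsFactors = FALSE),
      genets = members,
      consensus = consensus,
      threshold = threshold,
      dissimilarity = d
    ),
    class = "clone_assignment"
  )
}

#' @export
print.clone_assignment <- function(x, ...) {
  sizes <- lengths(x$genets)
  cat(sprintf(
    "Clone assignment: %d samples -> %d genets (threshold %.3f)\n",
    nrow(x$assignments), length(x$genets), x$threshold))
  cat(sprintf("  ramets per genet: %s\n",
              paste(sprintf("%s(%d)", names(sizes), sizes), collapse = ", ")))
  invisible(x)
}

#' Consensus genotype of a set of samples
#'
#' Per locus, the majority code among the members' non-missing calls; ties
#' and loci with no data become missing. With a single member this is the
#' member's own vector.
#'
#' @param gm a [genotype_matrix].
#' @param members sample ids belonging to one genet.
#' @return Integer vector of length `n_loci` (codes 0/1/2 or `NA`).
#' @export
consensus_genotype <- function(gm, members) {
  stopifnot(inherits(gm, "genotype_matrix"))
  members <- resolve_samples(gm, members)
  x <- gm$calls[members, , drop = FALSE]
  counts <- rbind(colSums(x == 0L, na.rm = TRUE),
                  colSums(x == 1L, na.rm = TRUE),
                  colSums(x == 2L, na.rm = TRUE))
  top <- apply(counts, 2, max)
  n_top <- colSums(counts == matrix(top, 3, ncol(counts), byrow = TRUE))
  code <- max.col(t(counts), ties.method = "first") - 1L
  out <- as.integer(code)
  out[top == 0L | n_top > 1L] <- NA_integer_
  out
}
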