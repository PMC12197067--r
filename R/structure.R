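# Population structure: pairwise Weir-Cockerham FST (with equal-n
# subsampling to remove sample-size bias) and principal coordinates analysis.

# Per-locus WC84 variance components for two populations, vectorised over
# loci. Returns numerator (a) and denominator (a+b+c) sums over usable loci.
wc_components <- function(calls_a, calls_b) {
  n1 <- colSums(!is.na(calls_a))
  n2 <- colSums(!is.na(calls_b))
  use <- n1 >= 1L & n2 >= 1L & (n1 + n2) > 2L  # need nbar > 1
  if (!any(use)) return(list(num = 0, den = 0, n_loci = 0L))
  n1 <- n1[use]; n2 <- n2[use]
  ca <- calls_a[, use, drop = FALSE]
  cb <- calls_b[, use, drop = FALSE]
  p1 <- colSums(ca, na.rm = TRUE) / (2 * n1)
  p2 <- colSums(cb, na.rm = TRUE) / (2 * n2)
  h1 <- colSums(ca == 1L, na.rm = TRUE) / n1
  h2 <- colSums(cb == 1L, na.rm = TRUE) / n2
  r <- 2
  nbar <- (n1 + n2) / 2
  nC <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- (nbar / nC) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  list(num = sum(a), den = sum(a + b + cc), n_loci = sum(use))
}

#' Weir-Cockerham FST between two groups
#'
#' The Weir & Cockerham (1984) theta estimator for two populations of a
#' biallelic SNP matrix: per-locus among-population (a) and within-population
#' (b, c) variance components from sample sizes, allele frequencies and
#' observed heterozygote counts, combined across loci as
#' `sum(a) / sum(a + b + c)`. Loci with fewer than one called individual in
#' either group (or fewer than three overall) are excluded; negative
#' estimates are reported as-is (clipping would bias subsampled means
#' upward near zero differentiation). When the denominator is zero across
#' all loci -- both groups monomorphic and identical everywhere -- the
#' estimate is undefined and `NA` is returned.
#'
#' @param gm a [genotype_matrix].
#' @param ids_a,ids_b sample ids of the two groups (each with at least two
#'   individuals carrying data).
#' @return A single numeric value (theta), or `NA` when undefined.
#' @references Weir, B.S. & Cockerham, C.C. (1984) Estimating F-statistics
#'   for the analysis of population structure. Evolution 38:1358-1370.
#' @export
fst_wc <- function(gm, ids_a, ids_b) {
  stopifnot(inherits(gm, "genotype_matrix"))
  ids_a <- resolve_samples(gm, ids_a)
  ids_b <- resolve_samples(gm, ids_b)
  if (length(ids_a) < 2L || length(ids_b) < 2L) {
    stop("each group needs at least 2 individuals")
  }
  comp <- wc_components(gm$calls[ids_a, , drop = FALSE],
                        gm$calls[ids_b, , drop = FALSE])
  if (comp$den == 0) return(NA_real_)
  comp$num / comp$den
}

#' Subsampled pairwise FST
#'
#' Repeatedly subsamples each group to `n_sub` individuals without
#' replacement, computes [fst_wc()] on each draw and reports the mean over
#' iterations with a defined estimate. Equalising n removes the sample-size
#' bias that otherwise dominates comparisons of very unequal groups. Groups
#' at or below `n_sub` are used whole.
#'
#' @param gm a [genotype_matrix].
#' @param ids_a,ids_b sample ids of the two groups.
#' @param n_sub subsample size per group (default 3; must be >= 2).
#' @param iterations number of subsampling draws (default 1000).
#' @param seed RNG seed for the draws.
#' @return An `fst_result` list: `pair`, `point` (full-group theta), `mean`
#'   (mean over defined iterations), `values` (per-iteration thetas),
#'   `n_undefined`, `n_sub`, `iterations`, `seed`.
#' @export
fst_subsampled <- function(gm, ids_a, ids_b, n_sub = 3, iterations = 1000,
                           seed = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (n_sub < 2) stop("n_sub must be at least 2")
  ids_a <- resolve_samples(gm, ids_a)
  ids_b <- resolve_samples(gm, ids_b)
  point <- fst_wc(gm, ids_a, ids_b)
  values <- with_seed(seed, {
    vapply(seq_len(iterations), function(i) {
      sa <- if (length(ids_a) > n_sub) sample(ids_a, n_sub) else ids_a
      sb <- if (length(ids_b) > n_sub) sample(ids_b, n_sub) else ids_b
      comp <- wc_components(gm$calls[sa, , drop = FALSE],
                            gm$calls[sb, , drop = FALSE])
      if (comp$den == 0) NA_real_ else comp$num / comp$den
    }, numeric(1))
  })
  structure(
    list(
      pair = c(a = attr(ids_a, "label") %||% "A",
               b = attr(ids_b, "label") %||% "B"),
      point = point,
      mean = if (all(is.na(values))) NA_real_ else mean(values, na.rm = TRUE),
      values = values,
      n_undefined = sum(is.na(values)),
      n_sub = n_sub,
      iterations = iterations,
      seed = seed
    ),
    class = "fst_result"
  )
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf(
    "Subsampled FST (%s vs %s): mean %.4f over %d iterations (n_sub = %d)\n",
    x$pair[["a"]], x$pair[["b"]], x$mean, x$iterations, x$n_sub))
  cat(sprintf("  point estimate on full groups: %.4f; undefined draws: %d\n",
              x$point, x$n_undefined))
  invisible(x)
}

#' Pairwise subsampled FST over several groups
#'
#' Runs [fst_subsampled()] for every unordered pair of groups and assembles
#' the lower-triangle mean-FST matrix. Each pair gets a deterministic seed
#' derived from `seed` and the sorted group labels, so adding a group never
#' perturbs the other pairs.
#'
#' @param gm a [genotype_matrix].
#' @param groups named list mapping group label to sample ids.
#' @inheritParams fst_subsampled
#' @return An `fst_pairwise` list: `mean_matrix` (lower triangle filled),
#'   `results` (per-pair `fst_result`s), `n_sub`, `iterations`, `seed`.
#' @export
fst_pairwise <- function(gm, groups, n_sub = 3, iterations = 1000,
                         seed = NULL) {
  stopifnot(is.list(groups), length(groups) >= 2L, !is.null(names(groups)))
  labels <- names(groups)
  m <- matrix(NA_real_, length(labels), length(labels),
              dimnames = list(labels, labels))
  results <- list()
  for (i in seq_along(labels)[-1L]) {
    for (j in seq_len(i - 1L)) {
      pa <- sort(c(labels[i], labels[j]))
      pseed <- if (is.null(seed)) NULL else derive_seed(seed, "fst", pa)
      res <- fst_subsampled(gm, groups[[labels[i]]], groups[[labels[j]]],
                            n_sub = n_sub, iterations = iterations,
                            seed = pseed)
      res$pair <- c(a = labels[i], b = labels[j])
      m[i, j] <- res$mean
      results[[paste(labels[i], labels[j], sep = " vs ")]] <- res
    }
  }
  structure(list(mean_matrix = m, results = results, n_sub = n_sub,
                 iterations = iterations, seed = seed),
            class = "fst_pairwise")
}

#' @export
print.fst_pairwise <- function(x, digits = 3, ...) {
  cat(sprintf("Pairwise mean FST (%d iterations, n_sub = %d):\n",
              x$iterations, x$n_sub))
  print(round(x$mean_matrix, digits), na.print = "")
  invisible(x)
}

#' Principal coordinates analysis of genotypes
#'
#' Classical metric multidimensional scaling on Euclidean distances between
#' dosage vectors. Missing calls are mean-imputed per locus (neutral with
#' respect to cluster placement) before distances are computed; the
#' double-centred Gram matrix is eigendecomposed via [stats::cmdscale()].
#' Percent variation per axis is its eigenvalue over the sum of positive
#' eigenvalues.
#'
#' @param gm a [genotype_matrix].
#' @param sample_ids samples to ordinate (default all).
#' @param k number of axes requested (truncated with a warning when fewer
#'   positive eigenvalues exist).
#' @return A `pcoa_result` list: `points` (samples x axes), `eig` (all
#'   eigenvalues), `percent` (per returned axis), `k`.
#' @export
pcoa_genotypes <- function(gm, sample_ids = NULL, k = 2) {
  stopifnot(inherits(gm, "genotype_matrix"), k >= 1)
  sample_ids <- resolve_samples(gm, sample_ids)
  x <- gm$calls[sample_ids, , drop = FALSE]
  storage.mode(x) <- "double"
  mu <- colMeans(x, na.rm = TRUE)
  keep <- !is.nan(mu)
  x <- x[, keep, drop = FALSE]
  mu <- mu[keep]
  idx <- which(is.na(x), arr.ind = TRUE)
  if (nrow(idx)) x[idx] <- mu[idx[, 2L]]
  d <- stats::dist(x)
  mds <- suppressWarnings(
    stats::cmdscale(d, k = min(k, nrow(x) - 1L), eig = TRUE))
  eig <- mds$eig
  tol <- max(abs(eig)) * 1e-8
  pos <- eig > max(tol, 0)
  n_pos <- sum(pos)
  if (n_pos == 0L) {
    warning("no positive eigenvalues: all samples are equidistant/identical")
    pts <- matrix(numeric(0), nrow = length(sample_ids), ncol = 0,
                  dimnames = list(sample_ids, NULL))
    return(structure(list(points = pts, eig = eig, percent = numeric(0),
                          k = 0L), class = "pcoa_result"))
  }
  if (k > n_pos) {
    warning(sprintf("only %d positive eigenvalue(s); axes truncated", n_pos))
    k <- n_pos
  }
  pts <- mds$points[, seq_len(k), drop = FALSE]
  rownames(pts) <- sample_ids
  colnames(pts) <- paste0("axis", seq_len(k))
  percent <- eig[seq_len(k)] / sum(eig[pos]) * 100
  structure(list(points = pts, eig = eig, percent = percent, k = k),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("PCoA: %d samples, %d axes\n", nrow(x$points), x$k))
  if (x$k) {
    cat("percent of positive variation per axis:",
        paste(sprintf("%.1f%%", x$percent), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.pcoa_result <- function(x, groups = NULL, axes = c(1, 2), ...) {
  if (x$k < max(axes)) stop("requested axes not available")
  col <- 1L
  pch <- 19L
  if (!is.null(groups)) {
    f <- factor(groups[rownames(x$points)])
    col <- as.integer(f)
  }
  graphics::plot(x$points[, axes[1]], x$points[, axes[2]], col = col,
                 pch = pch,
                 xlab = sprintf("Axis %d (%.1f%%)", axes[1], x$percent[axes[1]]),
                 ylab = sprintf("Axis %d (%.1f%%)", axes[2], x$percent[axes[2]]),
                 ...)
  if (!is.null(groups)) {
    graphics::legend("topright", legend = levels(f), col = seq_along(levels(f)),
                     pch = pch, cex = 0.8)
  }
  invisible(x)
}
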