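# Opposing-homozygote parentage exclusion. At any locus a true parent and
# offspring share at least one allele, so one individual homozygous for the
# reference and the other homozygous for the alternate is Mendelian-
# impossible absent genotyping error. The per-pair rate of such loci is a
# symmetric statistic: low within true pedigrees, high between species --
# which is what makes it a hybridisation check for seedlings of unknown
# paternity.

#' Opposing-homozygote violation rate for a pair
#'
#' Rate of loci, among those called in both samples, where one sample is
#' homozygous reference (0) and the other homozygous alternate (2). The
#' relation is symmetric: no parent/offspring direction is assumed.
#'
#' @param gm a [genotype_matrix].
#' @param a,b sample ids.
#' @param min_shared minimum comparable loci (default 50); below it the pair
#'   is flagged incomparable (`rate = NA`), since rates on a handful of loci
#'   are noise.
#' @return A `violation_result` list: `pair`, `n_comparable`, `n_violations`,
#'   `rate`, `incomparable`.
#' @export
violation_rate <- function(gm, a, b, min_shared = 50) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!a %in% gm$sample_ids) stop("unknown sample id: ", a)
  if (!b %in% gm$sample_ids) stop("unknown sample id: ", b)
  ga <- gm$calls[a, ]
  gb <- gm$calls[b, ]
  comparable <- !is.na(ga) & !is.na(gb)
  n_comp <- sum(comparable)
  viol <- (ga == 0L & gb == 2L) | (ga == 2L & gb == 0L)
  n_viol <- sum(viol[comparable])
  incomparable <- n_comp < min_shared
  structure(
    list(pair = c(a = a, b = b),
         n_comparable = n_comp,
         n_violations = if (incomparable) NA_integer_ else n_viol,
         rate = if (incomparable) NA_real_ else n_viol / n_comp,
         incomparable = incomparable),
    class = "violation_result"
  )
}

#' @export
print.violation_result <- function(x, ...) {
  if (x$incomparable) {
    cat(sprintf("violation_rate(%s, %s): incomparable (%d shared loci)\n",
                x$pair[["a"]], x$pair[["b"]], x$n_comparable))
  } else {
    cat(sprintf("violation_rate(%s, %s): %.4f (%d/%d loci)\n",
                x$pair[["a"]], x$pair[["b"]], x$rate, x$n_violations,
                x$n_comparable))
  }
  invisible(x)
}

#' All cross-pair violation rates between two groups
#'
#' @param gm a [genotype_matrix].
#' @param ids_a,ids_b sample ids of the two groups.
#' @param min_shared minimum comparable loci per pair.
#' @return A data.frame with one row per (a, b) pair (`a`, `b`,
#'   `n_comparable`, `n_violations`, `rate`) and attribute `mean_rate`, the
#'   mean over pairs with a defined rate.
#' @export
violation_matrix <- function(gm, ids_a, ids_b, min_shared = 50) {
  stopifnot(inherits(gm, "genotype_matrix"))
  ids_a <- resolve_samples(gm, ids_a)
  ids_b <- resolve_samples(gm, ids_b)
  grid <- expand.grid(a = ids_a, b = ids_b, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- mapply(function(a, b) {
    v <- violation_rate(gm, a, b, min_shared = min_shared)
    c(n_comparable = v$n_comparable, n_violations = v$n_violations,
      rate = v$rate)
  }, grid$a, grid$b)
  out <- cbind(grid, as.data.frame(t(rows)))
  rownames(out) <- NULL
  attr(out, "mean_rate") <- mean(out$rate, na.rm = TRUE)
  out
}

#' Rank candidate parental groups for a set of seedlings
#'
#' For each candidate group, the mean opposing-homozygote violation rate of
#' all seedling x candidate pairs; groups are ranked ascending, the lowest
#' mean being the inferred parental group. The `margin` column reports the
#' distance to the next-best group -- the decision is descriptive (rate
#' ordering with margins), not a significance test. A hybrid seedling cohort
#' shows both contributing groups below unrelated groups; the statistic
#' cannot separate the two parents' groups from each other.
#'
#' @param gm a [genotype_matrix].
#' @param seedling_ids sample ids of the offspring cohort.
#' @param candidate_groups named list mapping group label to sample ids.
#' @param min_shared minimum comparable loci per pair.
#' @return A `parental_ranking` data.frame: `group`, `mean_rate`, `n_pairs`,
#'   `rank`, `margin`, sorted by rank.
#' @export
assign_parental_group <- function(gm, seedling_ids, candidate_groups,
                                  min_shared = 50) {
  stopifnot(inherits(gm, "genotype_matrix"), is.list(candidate_groups),
            !is.null(names(candidate_groups)))
  rows <- lapply(names(candidate_groups), function(g) {
    vm <- violation_matrix(gm, seedling_ids, candidate_groups[[g]],
                           min_shared = min_shared)
    data.frame(group = g,
               mean_rate = attr(vm, "mean_rate"),
               n_pairs = sum(!is.na(vm$rate)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mean_rate), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$margin <- c(diff(out$mean_rate), NA_real_)
  rownames(out) <- NULL
  class(out) <- c("parental_ranking", "data.frame")
  out
}

#' @export
print.parental_ranking <- function(x, digits = 4, ...) {
  cat("Candidate parental groups by mean opposing-homozygote rate:\n")
  y <- x
  y$mean_rate <- round(y$mean_rate, digits)
  y$margin <- round(y$margin, digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
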