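# Mendelian cross simulation and breeding-pair ranking. Loci are treated as
# unlinked (no genetic map exists for the species this workflow targets);
# each simulated offspring receives one independently drawn allele per
# parent per locus. Missing parental calls beget missing offspring calls --
# a management tool must never manufacture genotype information.

# One gamete per offspring per locus from a dosage vector: homozygotes
# transmit their allele, heterozygotes transmit ref/alt with probability 1/2.
# Consumes n * L uniforms regardless of genotype so the RNG layout is stable.
draw_gametes <- function(geno, n) {
  L <- length(geno)
  u <- matrix(stats::runif(n * L), n, L)
  base <- matrix(ifelse(geno == 2L, 1L, 0L), n, L, byrow = TRUE)
  het <- which(geno == 1L)
  if (length(het)) base[, het] <- (u[, het, drop = FALSE] < 0.5) * 1L
  base
}

#' Simulate Mendelian offspring of a cross
#'
#' Each offspring receives, at every locus, one allele drawn independently
#' from each parent. Loci where either parent is missing are missing in
#' every offspring.
#'
#' @param p1,p2 parental genotype vectors (dosage 0/1/2/`NA`) on the same
#'   locus set.
#' @param n number of offspring (>= 1).
#' @param seed RNG seed for reproducible draws.
#' @return An `n` x `L` integer matrix of offspring dosages.
#' @export
simulate_offspring <- function(p1, p2, n, seed = NULL) {
  if (length(p1) != length(p2)) stop("parents must share one locus set")
  if (n < 1) stop("n must be at least 1")
  check_geno_vector(p1, "p1")
  check_geno_vector(p2, "p2")
  off <- with_seed(seed, {
    draw_gametes(as.integer(p1), n) + draw_gametes(as.integer(p2), n)
  })
  off[, is.na(p1) | is.na(p2)] <- NA_integer_
  storage.mode(off) <- "integer"
  if (!is.null(names(p1))) colnames(off) <- names(p1)
  off
}

check_geno_vector <- function(g, what) {
  if (!is.numeric(g)) stop("`", what, "` must be a numeric genotype vector")
  bad <- !is.na(g) & !(g %in% c(0, 1, 2))
  if (any(bad)) stop("`", what, "` contains invalid code(s): ",
                     id_preview(unique(g[bad])))
}

#' Mean observed heterozygosity of simulated offspring
#'
#' Simulates `n` offspring of the pair and reports each offspring's observed
#' heterozygosity (heterozygous / called loci) and their arithmetic mean --
#' the quantity used to rank candidate breeding pairs. Parents are put in a
#' canonical order first, so the result is identical under argument swap.
#'
#' @inheritParams simulate_offspring
#' @param n number of offspring (default 10, the typical seed yield per
#'   cross in the management setting this mirrors).
#' @return A `cross_report` list: `ho` (per-offspring values), `mean_ho`,
#'   `n`, `seed`.
#' @export
cross_mean_ho <- function(p1, p2, n = 10, seed = NULL) {
  k1 <- paste(ifelse(is.na(p1), "m", p1), collapse = "")
  k2 <- paste(ifelse(is.na(p2), "m", p2), collapse = "")
  if (k2 < k1) { tmp <- p1; p1 <- p2; p2 <- tmp }
  off <- simulate_offspring(p1, p2, n, seed = seed)
  called <- rowSums(!is.na(off))
  ho <- rowSums(off == 1L, na.rm = TRUE) / called
  ho[called == 0L] <- NA_real_
  structure(list(ho = ho,
                 mean_ho = if (all(is.na(ho))) NA_real_ else mean(ho, na.rm = TRUE),
                 n = n, seed = seed),
            class = "cross_report")
}

#' @export
print.cross_report <- function(x, ...) {
  cat(sprintf("Simulated cross: mean offspring H_O = %.4f over %d offspring\n",
              x$mean_ho, x$n))
  invisible(x)
}

#' Simulate all permissible crosses among genets
#'
#' Every unordered pair of genets is crossed except self-pairs (the target
#' taxa are dioecious and cannot self) and pairs where both sexes are known
#' and equal; genets of unknown sex pair with everyone. Each pair draws its
#' offspring under a seed derived from `seed` and the sorted genet ids, so
#' adding a genet to the collection never perturbs other pairs' results.
#'
#' @param genets a genets x loci dosage matrix with genet ids as rownames
#'   (e.g. the `consensus` element of [call_clones()]).
#' @param sexes named character vector (`"male"`, `"female"`, `"unknown"`)
#'   covering every genet; missing names default to unknown.
#' @param n offspring per cross (default 10).
#' @param seed master seed.
#' @return A `cross_matrix` list: `mean_ho` (symmetric genets x genets
#'   matrix, `NA` on the diagonal and for impermissible pairs), `pairs`
#'   (data.frame p1, p2, permissible, mean_ho), `n_offspring`, `seed`.
#' @export
all_crosses <- function(genets, sexes = NULL, n = 10, seed = NULL) {
  if (!is.matrix(genets) || is.null(rownames(genets))) {
    stop("`genets` must be a matrix with genet ids as rownames")
  }
  ids <- rownames(genets)
  if (length(ids) < 2L) stop("need at least two genets")
  sx <- stats::setNames(rep("unknown", length(ids)), ids)
  if (!is.null(sexes)) {
    bad <- !names(sexes) %in% ids
    if (any(bad)) stop("sexes given for unknown genet(s): ",
                       id_preview(names(sexes)[bad]))
    if (!all(sexes %in% c("male", "female", "unknown"))) {
      stop("sexes must be male/female/unknown")
    }
    sx[names(sexes)] <- sexes
  }
  combs <- utils::combn(ids, 2L)
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  rows <- vector("list", ncol(combs))
  for (k in seq_len(ncol(combs))) {
    a <- combs[1L, k]; b <- combs[2L, k]
    same_known <- sx[[a]] != "unknown" && sx[[a]] == sx[[b]]
    if (same_known) {
      rows[[k]] <- data.frame(p1 = a, p2 = b, permissible = FALSE,
                              mean_ho = NA_real_, stringsAsFactors = FALSE)
      next
    }
    pr <- sort(c(a, b))
    pseed <- if (is.null(seed)) NULL else derive_seed(seed, "cross", pr)
    cr <- cross_mean_ho(genets[a, ], genets[b, ], n = n, seed = pseed)
    m[a, b] <- m[b, a] <- cr$mean_ho
    rows[[k]] <- data.frame(p1 = a, p2 = b, permissible = TRUE,
                            mean_ho = cr$mean_ho, stringsAsFactors = FALSE)
  }
  structure(list(mean_ho = m, pairs = do.call(rbind, rows),
                 n_offspring = n, seed = seed),
            class = "cross_matrix")
}

#' @export
print.cross_matrix <- function(x, ...) {
  np <- sum(x$pairs$permissible)
  cat(sprintf(
    "Cross matrix: %d genets, %d simulated pairs (%d excluded by sex), %d offspring each\n",
    nrow(x$mean_ho), np, nrow(x$pairs) - np, x$n_offspring))
  rng <- range(x$pairs$mean_ho, na.rm = TRUE)
  cat(sprintf("  mean offspring H_O range: %.3f - %.3f\n", rng[1], rng[2]))
  invisible(x)
}

#' Heat map of the cross matrix
#'
#' @param x a `cross_matrix`.
#' @param ... passed to [graphics::image()].
#' @export
plot.cross_matrix <- function(x, ...) {
  m <- x$mean_ho
  n <- nrow(m)
  graphics::image(seq_len(n), seq_len(n), t(m[n:1, , drop = FALSE]),
                  axes = FALSE, xlab = "", ylab = "",
                  main = "Mean simulated-offspring H_O", ...)
  graphics::axis(1, at = seq_len(n), labels = colnames(m), las = 2, cex.axis = 0.7)
  graphics::axis(2, at = seq_len(n), labels = rev(rownames(m)), las = 1,
                 cex.axis = 0.7)
  invisible(x)
}

#' Rank breeding pairs by simulated-offspring heterozygosity
#'
#' @param cm a `cross_matrix` from [all_crosses()].
#' @param top number of top pairs to return (default all).
#' @return A data.frame of permissible pairs sorted by `mean_ho` descending
#'   (ties broken by sorted pair id), with a `rank` column.
#' @export
rank_pairs <- function(cm, top = Inf) {
  stopifnot(inherits(cm, "cross_matrix"))
  p <- cm$pairs[cm$pairs$permissible & !is.na(cm$pairs$mean_ho), , drop = FALSE]
  key <- paste(pmin(p$p1, p$p2), pmax(p$p1, p$p2))
  p <- p[order(-p$mean_ho, key), , drop = FALSE]
  p$rank <- seq_len(nrow(p))
  rownames(p) <- NULL
  utils::head(p, top)
}

#' Group-by-group summary of a cross matrix
#'
#' Mean of member-pair mean H_O for every pair of management groups --
#' the coarse view used when pair-level decisions are impractical.
#'
#' @param cm a `cross_matrix`.
#' @param genet_groups named character vector mapping genet id to group.
#' @return A data.frame `group1`, `group2`, `mean_ho`, `n_pairs`.
#' @export
cross_group_summary <- function(cm, genet_groups) {
  stopifnot(inherits(cm, "cross_matrix"))
  p <- cm$pairs[cm$pairs$permissible, , drop = FALSE]
  g1 <- unname(genet_groups[p$p1])
  g2 <- unname(genet_groups[p$p2])
  if (anyNA(g1) || anyNA(g2)) stop("genet_groups must cover every genet")
  key <- paste(pmin(g1, g2), pmax(g1, g2), sep = " | ")
  agg <- tapply(p$mean_ho, key, function(v) c(mean(v, na.rm = TRUE),
                                              sum(!is.na(v))))
  out <- data.frame(
    group1 = sub(" \\|.*$", "", names(agg)),
    group2 = sub("^.*\\| ", "", names(agg)),
    mean_ho = vapply(agg, `[`, numeric(1), 1L),
    n_pairs = vapply(agg, `[`, numeric(1), 2L),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(-out$mean_ho), , drop = FALSE]
}
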