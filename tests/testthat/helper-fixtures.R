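# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately written as plain loops, independent of the package's
# vectorised implementations, so the two routes can cross-check.

make_gm <- function(calls, fragment = NULL, reproducibility = NULL,
                    depth = NULL) {
  if (is.null(rownames(calls))) {
    rownames(calls) <- paste0("s", seq_len(nrow(calls)))
  }
  if (is.null(colnames(calls))) {
    colnames(calls) <- paste0("L", seq_len(ncol(calls)))
  }
  meta <- data.frame(
    locus_id = colnames(calls),
    fragment_id = fragment %||% colnames(calls),
    reproducibility = reproducibility %||% rep(1, ncol(calls)),
    mean_read_depth = depth %||% rep(50, ncol(calls)),
    stringsAsFactors = FALSE
  )
  genotype_matrix(calls, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random genotype matrix with missingness, for property tests
random_gm <- function(n, L, miss = 0.1) {
  calls <- matrix(sample(c(0L, 1L, 2L), n * L, replace = TRUE), n, L)
  calls[matrix(runif(n * L) < miss, n, L)] <- NA_integer_
  make_gm(calls)
}

# brute-force per-locus tallies (loops, no vectorisation)
bf_group_ho <- function(calls) {
  per_locus <- c()
  for (j in seq_len(ncol(calls))) {
    g <- calls[, j]
    g <- g[!is.na(g)]
    if (length(g)) per_locus <- c(per_locus, sum(g == 1) / length(g))
  }
  mean(per_locus)
}

bf_allele_freq <- function(calls) {
  p <- numeric(ncol(calls))
  for (j in seq_len(ncol(calls))) {
    g <- calls[, j]
    g <- g[!is.na(g)]
    p[j] <- if (length(g)) sum(g) / (2 * length(g)) else NA_real_
  }
  p
}

bf_group_he <- function(calls, unbiased = FALSE) {
  per_locus <- c()
  for (j in seq_len(ncol(calls))) {
    g <- calls[, j]
    g <- g[!is.na(g)]
    n <- length(g)
    if (!n) next
    p <- sum(g) / (2 * n)
    he <- 2 * p * (1 - p)
    if (unbiased) he <- he * 2 * n / (2 * n - 1)
    per_locus <- c(per_locus, he)
  }
  mean(per_locus)
}

# brute-force two-population WC84 theta (per-locus loop)
bf_fst_wc <- function(A, B) {
  num <- 0
  den <- 0
  for (l in seq_len(ncol(A))) {
    a1 <- A[, l][!is.na(A[, l])]
    b1 <- B[, l][!is.na(B[, l])]
    n1 <- length(a1); n2 <- length(b1); r <- 2
    if (n1 < 1 || n2 < 1 || n1 + n2 <= 2) next
    p1 <- sum(a1) / (2 * n1); p2 <- sum(b1) / (2 * n2)
    h1 <- mean(a1 == 1); h2 <- mean(b1 == 1)
    nbar <- (n1 + n2) / 2
    nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
    a <- (nbar / nc) *
      (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  if (den == 0) NA_real_ else num / den
}

# Hardy-Weinberg genotype draws at frequency p (n x L matrix)
hw_matrix <- function(n, L, p) {
  matrix(rbinom(n * L, 1L, p) + rbinom(n * L, 1L, p), n, L)
}
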