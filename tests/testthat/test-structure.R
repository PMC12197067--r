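# Weir-Cockerham FST (hand-evaluated oracle, fixation, null), subsampling
# behaviour, and PCoA geometry.

test_that("fst_wc matches the hand-evaluated worked toy to 1e-12", {
  # A: (0,1), (0,0); B: (1,2), (2,2). Per-locus WC84 components evaluated
  # by hand give a = 0.25, b = 0, c = 0.125 at both loci -> theta = 2/3.
  calls <- rbind(a1 = c(0L, 1L), a2 = c(0L, 0L),
                 b1 = c(1L, 2L), b2 = c(2L, 2L))
  gm <- make_gm(calls)
  th <- fst_wc(gm, c("a1", "a2"), c("b1", "b2"))
  expect_equal(th, 2 / 3, tolerance = 1e-12)
  expect_equal(th, bf_fst_wc(calls[1:2, , drop = FALSE],
                             calls[3:4, , drop = FALSE]), tolerance = 1e-12)
})

test_that("complete fixation gives exactly 1, identical monomorphic groups are undefined", {
  fixed <- make_gm(rbind(matrix(0L, 3, 50), matrix(2L, 3, 50)))
  expect_identical(fst_wc(fixed, paste0("s", 1:3), paste0("s", 4:6)), 1)
  mono <- make_gm(matrix(0L, 6, 20))
  expect_true(is.na(fst_wc(mono, paste0("s", 1:3), paste0("s", 4:6))))
})

test_that("theta is near zero for two samples of one population", {
  set.seed(21)
  pool <- hw_matrix(100, 500, 0.3)
  rownames(pool) <- paste0("s", 1:100)
  gm <- make_gm(pool)
  th <- fst_wc(gm, paste0("s", 1:50), paste0("s", 51:100))
  expect_lt(abs(th), 0.02)
})

test_that("fst_wc is symmetric and invariant to allele-label swaps", {
  set.seed(13)
  for (rep in 1:5) {
    gm <- random_gm(8, 60, miss = 0.1)
    a <- paste0("s", 1:4); b <- paste0("s", 5:8)
    expect_equal(fst_wc(gm, a, b), fst_wc(gm, b, a))
    swapped <- gm$calls
    flip <- sample(ncol(swapped), 30)
    swapped[, flip] <- 2L - swapped[, flip]
    gm2 <- make_gm(swapped)
    expect_equal(fst_wc(gm2, a, b), fst_wc(gm, a, b), tolerance = 1e-12)
  }
})

test_that("theta recovered from divergence simulations is monotone in F", {
  set.seed(77)
  L <- 2000
  p <- generate_base_frequencies(L, 0.1, 0.5, seed = 101)
  thetas <- vapply(c(0.05, 0.2, 0.5), function(F) {
    q <- generate_congener_frequencies(p, F, seed = 200 + round(100 * F))
    A <- t(vapply(1:50, function(i) rbinom(L, 1, p) + rbinom(L, 1, p),
                  numeric(L)))
    B <- t(vapply(1:50, function(i) rbinom(L, 1, q) + rbinom(L, 1, q),
                  numeric(L)))
    m <- rbind(A, B)
    rownames(m) <- paste0("s", 1:100)
    gm <- make_gm(m)
    fst_wc(gm, paste0("s", 1:50), paste0("s", 51:100))
  }, numeric(1))
  expect_false(is.unsorted(thetas))
  expect_gt(thetas[3], 0.15)
})

test_that("subsampling with n_sub = group size reproduces the point estimate each iteration", {
  calls <- rbind(a1 = c(0L, 1L), a2 = c(0L, 0L), a3 = c(1L, 1L),
                 b1 = c(1L, 2L), b2 = c(2L, 2L), b3 = c(2L, 1L))
  gm <- make_gm(calls)
  res <- fst_subsampled(gm, c("a1", "a2", "a3"), c("b1", "b2", "b3"),
                        n_sub = 3, iterations = 50, seed = 1)
  expect_true(all(res$values == res$point))
  expect_equal(res$mean, res$point)
  fixed <- make_gm(rbind(matrix(0L, 5, 30), matrix(2L, 5, 30)))
  res2 <- fst_subsampled(fixed, paste0("s", 1:5), paste0("s", 6:10),
                         n_sub = 3, iterations = 20, seed = 2)
  expect_true(all(res2$values == 1))
  expect_error(fst_subsampled(gm, c("a1", "a2"), c("b1", "b2"), n_sub = 1),
               "n_sub")
})

test_that("two master seeds agree within Monte-Carlo error at 1000 iterations", {
  set.seed(31)
  A <- hw_matrix(12, 300, 0.25)
  B <- hw_matrix(10, 300, 0.45)
  m <- rbind(A, B)
  rownames(m) <- paste0("s", 1:22)
  gm <- make_gm(m)
  ga <- paste0("s", 1:12); gb <- paste0("s", 13:22)
  r1 <- fst_subsampled(gm, ga, gb, n_sub = 3, iterations = 1000, seed = 101)
  r2 <- fst_subsampled(gm, ga, gb, n_sub = 3, iterations = 1000, seed = 707)
  se <- stats::sd(r1$values, na.rm = TRUE) / sqrt(sum(!is.na(r1$values)))
  expect_lt(abs(r1$mean - r2$mean), 2 * (se + stats::sd(r2$values, na.rm = TRUE) /
                                           sqrt(sum(!is.na(r2$values)))))
  # same seed reproduces exactly
  r3 <- fst_subsampled(gm, ga, gb, n_sub = 3, iterations = 1000, seed = 101)
  expect_identical(r1$values, r3$values)
})

test_that("variance of the subsampled mean shrinks roughly as 1/iterations", {
  set.seed(99)
  m <- rbind(hw_matrix(8, 200, 0.2), hw_matrix(8, 200, 0.5))
  rownames(m) <- paste0("s", 1:16)
  gm <- make_gm(m)
  ga <- paste0("s", 1:8); gb <- paste0("s", 9:16)
  means_small <- vapply(1:20, function(i)
    fst_subsampled(gm, ga, gb, n_sub = 3, iterations = 10, seed = i)$mean,
    numeric(1))
  means_big <- vapply(1:20, function(i)
    fst_subsampled(gm, ga, gb, n_sub = 3, iterations = 160, seed = 1000 + i)$mean,
    numeric(1))
  expect_lt(stats::var(means_big), stats::var(means_small))
})

test_that("PCoA separates two clone clusters on axis 1 with 100% of positive variation", {
  g1 <- rep(c(0L, 2L, 0L, 1L), 10)
  g2 <- rep(c(2L, 0L, 2L, 1L), 10)
  calls <- rbind(matrix(rep(g1, 3), 3, byrow = TRUE),
                 matrix(rep(g2, 3), 3, byrow = TRUE))
  rownames(calls) <- paste0("s", 1:6)
  gm <- make_gm(calls)
  pc <- suppressWarnings(pcoa_genotypes(gm, k = 2))
  expect_equal(pc$percent[1], 100, tolerance = 1e-8)
  # within-cluster coordinates identical
  expect_equal(pc$points["s1", 1], pc$points["s2", 1], tolerance = 1e-10)
  expect_gt(abs(pc$points["s1", 1] - pc$points["s4", 1]), 1)
})

test_that("PCoA on identical samples warns and returns no axes", {
  gm <- make_gm(matrix(1L, 4, 30))
  expect_warning(pc <- pcoa_genotypes(gm, k = 2), "identical")
  expect_equal(pc$k, 0L)
  expect_equal(ncol(pc$points), 0L)
})

test_that("PCoA eigenvalues match the hand-built 3-point configuration", {
  # dosage rows (0,0), (1,1), (-1 impossible) -> use (0,0),(1,1),(2,2)*?
  # squared distances (2, 2, 8): points 0, +sqrt(2), -sqrt(2) on a line.
  # Gram eigenvalues computed by hand: (4, 0, 0).
  calls <- rbind(s1 = c(1L, 1L), s2 = c(2L, 2L), s3 = c(0L, 0L))
  gm <- make_gm(calls)
  pc <- suppressWarnings(pcoa_genotypes(gm, k = 2))
  expect_equal(pc$eig[1], 4, tolerance = 1e-10)
  expect_equal(pc$percent[1], 100, tolerance = 1e-8)
  expect_equal(unname(sort(abs(pc$points[, 1]))), c(0, sqrt(2), sqrt(2)),
               tolerance = 1e-10)
})

test_that("distances among PCoA coordinates reproduce input distances (Gower)", {
  set.seed(17)
  for (rep in 1:5) {
    gm <- random_gm(6, 40, miss = 0)
    d_in <- dist(gm$calls)
    pc <- suppressWarnings(pcoa_genotypes(gm, k = 5))
    expect_equal(as.numeric(dist(pc$points)), as.numeric(d_in),
                 tolerance = 1e-8)
  }
})
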