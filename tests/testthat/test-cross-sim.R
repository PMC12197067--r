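# Mendelian cross simulator: forced outcomes, segregation ratios,
# closed-form offspring heterozygosity, pair enumeration and ranking.

test_that("forced crosses produce the only possible offspring", {
  L <- 50
  off <- simulate_offspring(rep(0L, L), rep(2L, L), 5, seed = 1)
  expect_true(all(off == 1L))
  off0 <- simulate_offspring(rep(0L, L), rep(0L, L), 5, seed = 2)
  expect_true(all(off0 == 0L))
  # missing parent loci beget missing offspring loci
  p1 <- c(0L, NA, 1L); p2 <- c(2L, 1L, NA)
  offm <- simulate_offspring(p1, p2, 4, seed = 3)
  expect_true(all(is.na(offm[, 2:3])))
  expect_true(all(offm[, 1] == 1L))
  expect_error(simulate_offspring(p1, p2, 0), "at least 1")
  expect_error(simulate_offspring(p1, c(0L, 1L), 1), "locus set")
})

test_that("het x het segregates 1:2:1", {
  off <- simulate_offspring(1L, 1L, 10000, seed = 42)
  counts <- table(factor(off, levels = 0:2))
  p <- chisq.test(counts, p = c(0.25, 0.5, 0.25))$p.value
  expect_gt(p, 0.001)
})

test_that("cross mean H_O matches closed forms exactly for forced categories", {
  L <- 200
  opp <- cross_mean_ho(rep(0L, L), rep(2L, L), n = 10, seed = 1)
  expect_identical(opp$mean_ho, 1)
  same <- cross_mean_ho(rep(2L, L), rep(2L, L), n = 10, seed = 2)
  expect_identical(same$mean_ho, 0)
  # het x het: expected 1/2, binomial tolerance at n offspring x L loci
  hh <- cross_mean_ho(rep(1L, 1000), rep(1L, 1000), n = 10, seed = 3)
  expect_lt(abs(hh$mean_ho - 0.5), 3 * sqrt(0.25 / (10 * 1000)))
  # het x hom: expected 1/2 as well
  hm <- cross_mean_ho(rep(1L, 1000), rep(0L, 1000), n = 10, seed = 4)
  expect_lt(abs(hm$mean_ho - 0.5), 3 * sqrt(0.25 / (10 * 1000)))
})

test_that("cross_mean_ho is exactly symmetric in its arguments", {
  set.seed(9)
  p1 <- sample(c(0L, 1L, 2L, NA), 300, TRUE)
  p2 <- sample(c(0L, 1L, 2L, NA), 300, TRUE)
  a <- cross_mean_ho(p1, p2, n = 10, seed = 77)
  b <- cross_mean_ho(p2, p1, n = 10, seed = 77)
  expect_identical(a$ho, b$ho)
})

test_that("offspring of a cross never violate the opposing-homozygote rule with either parent", {
  set.seed(18)
  L <- 1000
  for (rep in 1:10) {
    p1 <- rbinom(L, 1, runif(1, 0.1, 0.9)) + rbinom(L, 1, runif(1, 0.1, 0.9))
    p2 <- rbinom(L, 1, runif(1, 0.1, 0.9)) + rbinom(L, 1, runif(1, 0.1, 0.9))
    off <- simulate_offspring(p1, p2, 3, seed = 400 + rep)
    for (i in 1:3) {
      expect_false(any((p1 == 0 & off[i, ] == 2) | (p1 == 2 & off[i, ] == 0)))
      expect_false(any((p2 == 0 & off[i, ] == 2) | (p2 == 2 & off[i, ] == 0)))
    }
  }
})

test_that("all_crosses enumerates pairs under the sex constraint", {
  L <- 60
  make_genets <- function(n) {
    m <- matrix(sample(c(0L, 1L, 2L), n * L, TRUE), n, L)
    rownames(m) <- paste0("g", seq_len(n))
    m
  }
  set.seed(2)
  # 17 genets: 1 known female, 4 known males, 12 unknown -> C(17,2) - C(4,2)
  g17 <- make_genets(17)
  sexes <- setNames(rep("unknown", 17), rownames(g17))
  sexes[1] <- "female"
  sexes[2:5] <- "male"
  cm <- all_crosses(g17, sexes, n = 2, seed = 5)
  expect_equal(sum(cm$pairs$permissible), 130L)
  expect_equal(nrow(cm$pairs), 136L)
  # all unknown among 3 genets -> 3 pairs
  g3 <- make_genets(3)
  expect_equal(sum(all_crosses(g3, n = 2, seed = 1)$pairs$permissible), 3L)
  # two known males -> nothing to simulate
  g2 <- make_genets(2)
  cm2 <- all_crosses(g2, setNames(c("male", "male"), rownames(g2)),
                     n = 2, seed = 1)
  expect_equal(sum(cm2$pairs$permissible), 0L)
  expect_true(all(is.na(cm2$pairs$mean_ho)))
})

test_that("the cross matrix is symmetric with an empty diagonal and stable per-pair seeds", {
  set.seed(10)
  L <- 100
  g <- matrix(sample(c(0L, 1L, 2L), 5 * L, TRUE), 5, L,
              dimnames = list(paste0("g", 1:5), NULL))
  cm <- all_crosses(g, n = 5, seed = 99)
  expect_true(all(is.na(diag(cm$mean_ho))))
  expect_identical(cm$mean_ho, t(cm$mean_ho))
  # adding a genet leaves existing pairs untouched
  g6 <- rbind(g, g6 = sample(c(0L, 1L, 2L), L, TRUE))
  cm6 <- all_crosses(g6, n = 5, seed = 99)
  expect_identical(cm6$mean_ho[1:5, 1:5], cm$mean_ho)
})

test_that("rank_pairs sorts by mean H_O with deterministic ties and a highly heterozygous genet dominates", {
  m <- matrix(NA_real_, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  pairs <- data.frame(p1 = c("a", "a", "b"), p2 = c("b", "c", "c"),
                      permissible = TRUE, mean_ho = c(0.2, 0.5, 0.2))
  cm <- structure(list(mean_ho = m, pairs = pairs, n_offspring = 10,
                       seed = 1), class = "cross_matrix")
  rk <- rank_pairs(cm)
  expect_equal(rk$mean_ho, c(0.5, 0.2, 0.2))
  expect_equal(rk$p1, c("a", "a", "b"))  # tie broken by pair id
  expect_equal(rank_pairs(cm, top = 1)$p1, "a")

  # a genet heterozygous everywhere pushes its crosses to the top
  set.seed(44)
  L <- 400
  g <- rbind(
    het = rep(1L, L),
    h1 = rbinom(L, 1, 0.1) + rbinom(L, 1, 0.1),
    h2 = rbinom(L, 1, 0.1) + rbinom(L, 1, 0.1),
    h3 = rbinom(L, 1, 0.1) + rbinom(L, 1, 0.1))
  cm2 <- all_crosses(g, n = 10, seed = 7)
  rk2 <- rank_pairs(cm2)
  expect_true(all(rk2$p1[1:3] == "het" | rk2$p2[1:3] == "het"))
})

test_that("group summary averages member-pair means", {
  pairs <- data.frame(p1 = c("a", "a", "b"), p2 = c("b", "c", "c"),
                      permissible = c(TRUE, TRUE, TRUE),
                      mean_ho = c(0.1, 0.3, 0.5))
  cm <- structure(list(mean_ho = NULL, pairs = pairs, n_offspring = 10,
                       seed = 1), class = "cross_matrix")
  gs <- cross_group_summary(cm, c(a = "G1", b = "G1", c = "G2"))
  expect_equal(gs$mean_ho[gs$group1 == "G1" & gs$group2 == "G2"],
               mean(c(0.3, 0.5)))
  expect_equal(gs$mean_ho[gs$group1 == "G1" & gs$group2 == "G1"], 0.1)
})

test_that("variance of mean offspring H_O shrinks with more offspring", {
  set.seed(55)
  L <- 200
  p1 <- rbinom(L, 1, 0.5) + rbinom(L, 1, 0.5)
  p2 <- rbinom(L, 1, 0.5) + rbinom(L, 1, 0.5)
  v_small <- var(vapply(1:30, function(i)
    cross_mean_ho(p1, p2, n = 2, seed = i)$mean_ho, numeric(1)))
  v_big <- var(vapply(1:30, function(i)
    cross_mean_ho(p1, p2, n = 32, seed = 1000 + i)$mean_ho, numeric(1)))
  expect_lt(v_big, v_small)
})
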