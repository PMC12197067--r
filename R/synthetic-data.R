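# Synthetic study-like data with full known truth. The generator emulates
# the structure of a minimal clonal collection: four wild clonal patches, a
# small ex situ collection with heavy ramet redundancy and a single female
# genet descended from an extinct source subpopulation, F1 seedlings bred
# within the collection, and a ladder of divergent congener species. Truth
# (founder genotypes, ramet map, pedigree, sexes, divergences, QC-failing
# loci) is returned alongside the data so every pipeline stage can be tested
# against a known answer.

#' Draw base alternate-allele frequencies
#'
#' Uniform on `[maf_low, maf_high]`, then each locus is flipped about 0.5
#' with probability 1/2 so neither allele label is systematically minor.
#'
#' @param n_loci number of loci.
#' @param maf_low,maf_high frequency band before symmetrisation.
#' @param seed RNG seed.
#' @return Numeric vector of length `n_loci` in (0, 1).
#' @export
generate_base_frequencies <- function(n_loci, maf_low = 0.02, maf_high = 0.3,
                                      seed = NULL) {
  stopifnot(n_loci >= 1, maf_low <= maf_high, maf_low >= 0, maf_high <= 1)
  with_seed(seed, {
    p <- stats::runif(n_loci, maf_low, maf_high)
    flip <- stats::runif(n_loci) < 0.5
    p[flip] <- 1 - p[flip]
    p
  })
}

#' Drift allele frequencies to a diverged population
#'
#' Balding-Nichols model: per locus, the diverged population's frequency is
#' drawn from `Beta(p(1-F)/F, (1-p)(1-F)/F)`, whose mean is the ancestral
#' `p` and whose spread grows with the divergence parameter `F` (the
#' expected fixation index between ancestor and descendant).
#'
#' @param base_freq ancestral frequencies in \[0, 1\].
#' @param F divergence parameter in (0, 1): a scalar, or one value per locus;
#'   values below 1e-8 return the corresponding `base_freq` unchanged
#'   (degenerate Beta limit).
#' @param seed RNG seed.
#' @return Numeric vector of drifted frequencies in \[0, 1\].
#' @export
generate_congener_frequencies <- function(base_freq, F, seed = NULL) {
  stopifnot(all(F >= 0), all(F < 1),
            length(F) == 1L || length(F) == length(base_freq))
  F <- rep_len(F, length(base_freq))
  with_seed(seed, {
    out <- base_freq
    drift <- F >= 1e-8
    out[drift] <- stats::rbeta(sum(drift),
                               base_freq[drift] * (1 - F[drift]) / F[drift],
                               (1 - base_freq[drift]) * (1 - F[drift]) / F[drift])
    out
  })
}

hw_genotype <- function(p) {
  # one multilocus genotype drawn under Hardy-Weinberg at frequencies p
  stats::rbinom(length(p), 1L, p) + stats::rbinom(length(p), 1L, p)
}

#' Default parameters of the study-like generator
#'
#' The composition mirrors a minimal clonal collection: 20 wild samples in four
#' clonal patches (2/7/3/8) realising 7 genets; 12 ex situ adult samples
#' realising 5 genets (one female, four male, two shared with the wild
#' patches); 7 F1 seedlings mothered by the single female genet; and four
#' congener groups (3+2+2+2 samples) at divergences 0.5/0.7/0.85/0.95
#' spanning the observed between-species FST ladder. Allele frequencies are
#' hierarchical Balding-Nichols draws: the target species' own branch
#' drifts from the ancestral pool (strongly at a `diagnostic_fraction` of
#' species-diagnostic loci, which is what keeps within-species diversity
#' low while between-species differentiation stays high), then the
#' wild/male pool and the extinct-source female pool drift a little
#' further apart. Genotyping noise: symmetric nearest-state miscalls at
#' rate 0.005 and 1% missing data. QC metadata is drawn so a known, stored
#' set of loci fails each cascade step (30 low-reproducibility loci, 30
#' out-of-depth loci, 20 forced low-call-rate loci, ~8% secondaries).
#'
#' @return Named list of generator parameters; override entries and pass to
#'   [generate_study_like_dataset()].
#' @export
default_sim_params <- function() {
  list(
    n_loci = 1800,   # pre-QC; the default cascade retains ~1200-1300
    maf_low = 0.10,
    maf_high = 0.50,
    diagnostic_fraction = 0.3,    # loci near-fixed within the target species
    target_divergence = c(variable = 0.35, diagnostic = 0.95),
    within_divergence = 0.15,     # wild/male pool vs extinct-source female pool
    congener_divergence = c(congener_A = 0.5, congener_B = 0.7,
                            congener_C = 0.85, congener_D = 0.95),
    congener_sizes = c(congener_A = 3L, congener_B = 2L,
                       congener_C = 2L, congener_D = 2L),
    n_seedlings = 7L,
    error_rate = 0.005,
    missing_rate = 0.01,
    n_bad_reproducibility = 30L,
    n_bad_depth = 30L,
    n_low_callrate = 20L,
    forced_callrate = 0.90,       # call rate forced onto low-call-rate loci
    secondary_fraction = 0.08,
    species_target = "target_species"
  )
}

# in-situ ramet layout: patch, sample id, genet. Patch A one genet, B one
# genet, C two genets (C1+C3 vs C2), D three genets (six ramets + two
# singletons D3, D7).
insitu_layout <- function() {
  data.frame(
    sample_id = c("A1", "A2",
                  paste0("B", 1:7),
                  "C1", "C2", "C3",
                  paste0("D", 1:8)),
    patch = c("A", "A", rep("B", 7), "C", "C", "C", rep("D", 8)),
    genet = c("G1", "G1", rep("G2", 7), "G3", "G4", "G3",
              "G5", "G5", "G6", "G5", "G5", "G5", "G7", "G5"),
    stringsAsFactors = FALSE
  )
}

# ex-situ adult layout: 12 ramets, 5 genets. F1 = the female genet (extinct
# source pool); G2 and G5 are shared with the wild patches; M1 and M2 are
# ex-situ-only males.
exsitu_layout <- function() {
  data.frame(
    sample_id = c(paste0("Clone", 1:6), "Clone7", "Clone8", "Clone9",
                  "Clone10", "Clone11", "Purchased"),
    genet = c(rep("FEM1", 6), "M1", "M2", "G5", "G2", "M1", "G5"),
    sex = c(rep("female", 6), rep("male", 6)),
    stringsAsFactors = FALSE
  )
}

#' Generate a study-like synthetic dataset with known truth
#'
#' Builds the full synthetic collection described in [default_sim_params()]:
#' founder genotypes are Hardy-Weinberg draws from two within-species
#' frequency pools (a wild/male pool and a drifted extinct-source pool that
#' contributes the single female genet, which is what separates the sexes
#' along the first PCoA axis), seedlings are true Mendelian F1s of the
#' female by ex-situ males, congeners are drawn from Balding-Nichols-drifted
#' frequencies, and every call is then subjected to miscall and missingness
#' noise. Locus QC metadata is drawn so that a known set of loci fails each
#' metadata-driven filter step.
#'
#' @param params list from [default_sim_params()] (entries may be overridden).
#' @param seed master seed; every stage derives its own sub-seed from it, and
#'   regeneration with the same params and seed is bit-identical.
#' @return A list with elements `genotypes` (a [genotype_matrix]), `meta`
#'   (sample metadata data.frame) and `truth` (list: `params`, `seed`,
#'   `genet_genotypes` (error-free founder matrix), `sample_genet`,
#'   `pedigree`, `genet_sexes`, `expected_removed` per cascade step,
#'   `expected_kept_loci`).
#' @export
generate_study_like_dataset <- function(params = default_sim_params(),
                                        seed = 1) {
  p <- utils::modifyList(default_sim_params(), params)
  if (length(p$congener_sizes) != length(p$congener_divergence)) {
    stop("congener_sizes and congener_divergence must align")
  }
  L <- p$n_loci
  base <- generate_base_frequencies(L, p$maf_low, p$maf_high,
                                    seed = derive_seed(seed, "base"))
  # target species branch: strong drift at species-diagnostic loci, mild at
  # within-species-variable loci
  diag_mask <- with_seed(derive_seed(seed, "diagnostic"),
                         stats::runif(L) < p$diagnostic_fraction)
  f_target <- ifelse(diag_mask, p$target_divergence[["diagnostic"]],
                     p$target_divergence[["variable"]])
  freq_target <- generate_congener_frequencies(base, f_target,
                                               seed = derive_seed(seed, "target"))
  freq_male <- generate_congener_frequencies(freq_target, p$within_divergence,
                                             seed = derive_seed(seed, "pool_male"))
  freq_fem <- generate_congener_frequencies(freq_target, p$within_divergence,
                                            seed = derive_seed(seed, "pool_fem"))

  ins <- insitu_layout()
  exs <- exsitu_layout()
  male_genets <- c(paste0("G", 1:7), "M1", "M2")
  genets <- with_seed(derive_seed(seed, "genets"), {
    g <- t(vapply(male_genets, function(id) hw_genotype(freq_male),
                  numeric(L)))
    rbind(g, FEM1 = hw_genotype(freq_fem))
  })
  storage.mode(genets) <- "integer"

  # F1 seedlings: mother FEM1, father sampled among ex-situ male genets
  exsitu_males <- setdiff(unique(exs$genet), "FEM1")
  seed_ids <- paste0("S", seq_len(p$n_seedlings))
  fathers <- with_seed(derive_seed(seed, "pedigree"),
                       sample(exsitu_males, p$n_seedlings, replace = TRUE))
  seedlings <- t(vapply(seq_len(p$n_seedlings), function(i) {
    simulate_offspring(genets["FEM1", ], genets[fathers[i], ], 1,
                       seed = derive_seed(seed, "seedling", seed_ids[i]))[1L, ]
  }, integer(L)))
  rownames(seedlings) <- seed_ids
  pedigree <- data.frame(offspring = seed_ids, mother = "FEM1",
                         father = fathers, stringsAsFactors = FALSE)

  # congener samples: each its own genet from drifted frequencies
  cong_names <- names(p$congener_divergence)
  cong_rows <- list()
  for (cn in cong_names) {
    f <- generate_congener_frequencies(base, p$congener_divergence[[cn]],
                                       seed = derive_seed(seed, "congfreq", cn))
    nk <- p$congener_sizes[[cn]]
    g <- with_seed(derive_seed(seed, "conggeno", cn),
                   t(vapply(seq_len(nk), function(i) hw_genotype(f),
                            numeric(L))))
    rownames(g) <- paste0(cn, "_", seq_len(nk))
    cong_rows[[cn]] <- g
  }
  cong <- do.call(rbind, cong_rows)
  storage.mode(cong) <- "integer"

  # assemble ramets
  calls <- rbind(
    genets[ins$genet, , drop = FALSE],
    genets[exs$genet, , drop = FALSE],
    seedlings,
    cong
  )
  rownames(calls) <- c(ins$sample_id, exs$sample_id, seed_ids, rownames(cong))
  sample_genet <- c(stats::setNames(ins$genet, ins$sample_id),
                    stats::setNames(exs$genet, exs$sample_id),
                    stats::setNames(seed_ids, seed_ids),
                    stats::setNames(rownames(cong), rownames(cong)))

  # genotyping noise: symmetric nearest-state miscalls, then missingness
  calls <- with_seed(derive_seed(seed, "noise"), {
    n_cells <- length(calls)
    err <- which(stats::runif(n_cells) < p$error_rate & !is.na(calls))
    if (length(err)) {
      g <- calls[err]
      shift <- ifelse(g == 0L, 1L,
                      ifelse(g == 2L, -1L,
                             ifelse(stats::runif(length(g)) < 0.5, -1L, 1L)))
      calls[err] <- g + shift
    }
    miss <- stats::runif(n_cells) < p$missing_rate
    calls[miss] <- NA_integer_
    calls
  })

  # QC metadata with a designed set of failing loci (disjoint sets)
  locus_ids <- sprintf("L%04d", seq_len(L))
  colnames(calls) <- locus_ids
  qc <- with_seed(derive_seed(seed, "qc"), {
    n_designed <- p$n_bad_reproducibility + p$n_bad_depth + p$n_low_callrate
    designed <- sample(L, n_designed)
    bad_rep <- designed[seq_len(p$n_bad_reproducibility)]
    bad_depth <- designed[p$n_bad_reproducibility + seq_len(p$n_bad_depth)]
    low_cr <- designed[p$n_bad_reproducibility + p$n_bad_depth +
                         seq_len(p$n_low_callrate)]
    rep_vals <- stats::runif(L, 0.99, 1.0)
    rep_vals[bad_rep] <- stats::runif(length(bad_rep), 0.90, 0.9899)
    depth_vals <- stats::runif(L, 8, 120)
    half <- length(bad_depth) %/% 2L
    depth_vals[bad_depth[seq_len(half)]] <- stats::runif(half, 0.5, 4.9)
    depth_vals[bad_depth[-seq_len(half)]] <-
      stats::runif(length(bad_depth) - half, 501, 900)
    # force extra missingness on the designated low-call-rate loci
    n_force <- ceiling((1 - p$forced_callrate) * nrow(calls))
    for (j in low_cr) {
      rows <- sample(nrow(calls), n_force)
      calls[rows, j] <- NA_integer_
    }
    # secondaries: a fraction of loci share a fragment with an earlier locus
    frag <- paste0("FRAG", sprintf("%04d", seq_len(L)))
    n_sec <- round(p$secondary_fraction * L)
    eligible <- setdiff(seq_len(L)[-1L], c(bad_rep, bad_depth))
    sec <- sort(sample(eligible, min(n_sec, length(eligible))))
    for (j in sec) {
      cand <- setdiff(seq_len(j - 1L), sec)
      host <- cand[sample.int(length(cand), 1L)]
      frag[j] <- frag[host]
    }
    list(calls = calls, bad_rep = bad_rep, bad_depth = bad_depth,
         low_cr = low_cr, rep_vals = rep_vals, depth_vals = depth_vals,
         frag = frag)
  })
  calls <- qc$calls

  locus_meta <- data.frame(
    locus_id = locus_ids,
    fragment_id = qc$frag,
    reproducibility = qc$rep_vals,
    mean_read_depth = qc$depth_vals,
    stringsAsFactors = FALSE
  )
  gm <- genotype_matrix(calls, locus_meta)

  meta <- data.frame(
    sample_id = rownames(calls),
    species = c(rep(p$species_target, nrow(ins) + nrow(exs) + p$n_seedlings),
                rep(cong_names, p$congener_sizes[cong_names])),
    group = c(rep("in_situ", nrow(ins)),
              rep("ex_situ_adult", nrow(exs)),
              rep("ex_situ_seedling", p$n_seedlings),
              rep(cong_names, p$congener_sizes[cong_names])),
    patch = c(ins$patch, rep(NA_character_, nrow(exs) + p$n_seedlings +
                               nrow(cong))),
    sex = c(rep("unknown", nrow(ins)), exs$sex,
            rep("unknown", p$n_seedlings + nrow(cong))),
    stringsAsFactors = FALSE
  )

  truth <- list(
    params = p,
    seed = seed,
    genet_genotypes = rbind(genets, seedlings),
    sample_genet = sample_genet,
    pedigree = pedigree,
    genet_sexes = c(stats::setNames(rep("male", length(male_genets) - 2L),
                                    setdiff(male_genets, c("G2", "G5"))),
                    G2 = "male", G5 = "male", FEM1 = "female",
                    stats::setNames(rep("unknown", p$n_seedlings), seed_ids)),
    expected_removed = expected_cascade_removals(
      calls, locus_meta, default_filter_config(1)),
    base_freq = base,
    diagnostic_loci = locus_ids[diag_mask]
  )
  truth$genet_sexes[setdiff(male_genets, unique(exs$genet))] <- "unknown"
  truth$expected_kept_loci <- setdiff(locus_ids,
                                      unlist(truth$expected_removed))
  list(genotypes = gm, meta = meta, truth = truth)
}

# Independent tally of which loci each cascade step removes, written with
# plain vector arithmetic on the emitted calls (deliberately not by calling
# the filtering module, so the two can cross-check each other).
expected_cascade_removals <- function(calls, locus_meta, config) {
  ids <- locus_meta$locus_id
  removed <- list()
  alive <- rep(TRUE, length(ids))
  rem <- function(cond) {
    out <- ids[alive & cond]
    alive[alive & cond] <<- FALSE
    out
  }
  removed$locus_reproducibility <-
    rem(locus_meta$reproducibility < config$locus_reproducibility)
  removed$read_depth <- rem(locus_meta$mean_read_depth < config$read_depth[1] |
                              locus_meta$mean_read_depth > config$read_depth[2])
  cr <- colMeans(!is.na(calls))
  removed$locus_callrate <- rem(cr < config$locus_callrate)
  ref <- colSums(calls == 0L | calls == 1L, na.rm = TRUE) > 0L
  alt <- colSums(calls == 1L | calls == 2L, na.rm = TRUE) > 0L
  removed$monomorphic <- rem(!(ref & alt))
  # secondaries among survivors: keep best call rate, then reproducibility,
  # then first occurrence, within each fragment
  surv <- which(alive)
  ord <- surv[order(match(locus_meta$fragment_id[surv],
                          unique(locus_meta$fragment_id[surv])),
                    -cr[surv], -locus_meta$reproducibility[surv], surv)]
  dup <- duplicated(locus_meta$fragment_id[ord])
  removed$secondaries <- ids[sort(ord[dup])]
  removed
}
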