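# Config-driven orchestration of the full analysis, in field order:
# pass-1 QC on all species -> hybridisation checks (FST, PCoA, parentage)
# -> restriction to the target species -> pass-2 QC -> clone calling ->
# genet-level diversity -> within-species subsampled FST -> cross matrix.

#' Default run configuration
#'
#' @param seed master seed; every stochastic stage derives a sub-seed.
#' @return Named list of settings for [run_full_analysis()]: filter
#'   thresholds per pass ([default_filter_config()]), clone threshold,
#'   subsampled-FST settings, cross settings, group labels and flags.
#' @export
default_run_config <- function(seed = 1) {
  list(
    seed = seed,
    filter_pass1 = default_filter_config(1),
    filter_pass2 = default_filter_config(2),
    clone_threshold = 0.05,
    clone_min_shared = 50,
    fst_n_sub = 3,
    fst_iterations = 1000,
    cross_n_offspring = 10,
    crosses_enabled = TRUE,
    collapse_clones = TRUE,
    species_target = "target_species",
    group_seedling = "ex_situ_seedling",
    pcoa_axes = 2
  )
}

#' Read a run configuration from YAML
#'
#' Unknown keys are an error (they are usually typos); missing keys take
#' the defaults of [default_run_config()].
#'
#' @param path YAML file.
#' @return A config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  user <- yaml::read_yaml(path)
  base <- default_run_config()
  unknown <- setdiff(names(user), names(base))
  if (length(unknown)) stop("unknown config key(s): ", id_preview(unknown))
  cfg <- utils::modifyList(base, user)
  if (!is.null(user$filter_pass1)) {
    cfg$filter_pass1 <- utils::modifyList(default_filter_config(1),
                                          user$filter_pass1)
  }
  if (!is.null(user$filter_pass2)) {
    cfg$filter_pass2 <- utils::modifyList(default_filter_config(2),
                                          user$filter_pass2)
  }
  cfg
}

#' Run the full conservation-genetics analysis
#'
#' Executes every stage of the pipeline on a genotype matrix plus sample
#' metadata and returns a consolidated report bundle. Stages, in order:
#'
#' 1. pass-1 QC cascade on all samples (all species);
#' 2. between-group subsampled FST, PCoA, and seedling parentage-group
#'    ranking on the pass-1 matrix (the hybridisation check);
#' 3. restriction to the target species and pass-2 QC cascade (call rates
#'    recomputed on the retained samples);
#' 4. clone calling and collapse to genet consensus genotypes;
#' 5. per-management-group diversity on genets (one representative per
#'    genet, configurable via `collapse_clones`);
#' 6. within-species subsampled FST between management groups;
#' 7. simulated crosses among genets with sex constraints, pair ranking and
#'    group summary (skipped when `crosses_enabled` is FALSE).
#'
#' Genet sex is the consensus of member-sample sexes (conflicts degrade to
#' unknown). When `output_dir` is given, every table, the config and a run
#' log (seeds, retention counts, excluded pairs) are written there as
#' CSV/YAML text files.
#'
#' @param gm a [genotype_matrix] of all samples (pre-QC).
#' @param meta sample metadata (data.frame as from [read_sample_meta()]).
#' @param config list from [default_run_config()]/[read_run_config()].
#' @param output_dir optional directory for the report bundle.
#' @return A `conservation_run` list: `config`, `filter_pass1`,
#'   `filter_pass2`, `fst_all_groups`, `pcoa`, `parentage`, `clones`,
#'   `diversity`, `genet_ho`, `fst_within`, `crosses`, `ranked_pairs`,
#'   `group_crosses`, `log`.
#' @export
run_full_analysis <- function(gm, meta, config = default_run_config(),
                              output_dir = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  meta <- validate_sample_meta(meta)
  missing_meta <- setdiff(gm$sample_ids, meta$sample_id)
  if (length(missing_meta)) {
    stop("samples lacking metadata: ", id_preview(missing_meta))
  }
  cfg <- utils::modifyList(default_run_config(), config)
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  note("master seed: %s", cfg$seed)

  ## 1. pass-1 QC on all species
  p1 <- stage("filter_pass1", run_cascade(gm, cfg$filter_pass1))
  note("pass-1 QC: %d samples, %d loci retained (%.2f%% missing)",
       p1$genotypes$n_samples, p1$genotypes$n_loci,
       attr(p1$report, "final_missing_pct"))

  meta1 <- meta[match(p1$genotypes$sample_ids, meta$sample_id), ]
  groups_all <- split(meta1$sample_id, meta1$group)

  ## 2. hybridisation check: FST between all groups, PCoA, parentage
  fst_all <- stage("fst_all_groups",
                   fst_pairwise(p1$genotypes, groups_all, n_sub = cfg$fst_n_sub,
                                iterations = cfg$fst_iterations,
                                seed = derive_seed(cfg$seed, "fst_all")))
  pc <- stage("pcoa", pcoa_genotypes(p1$genotypes, k = cfg$pcoa_axes))
  seedlings <- groups_all[[cfg$group_seedling]]
  parent_rank <- NULL
  if (!is.null(seedlings) && length(seedlings)) {
    candidates <- groups_all[setdiff(names(groups_all), cfg$group_seedling)]
    parent_rank <- stage("parentage",
                         assign_parental_group(p1$genotypes, seedlings,
                                               candidates,
                                               min_shared = cfg$clone_min_shared))
    note("parentage: best candidate group '%s' (mean rate %.4f)",
         parent_rank$group[1], parent_rank$mean_rate[1])
  }

  ## 3. restrict to target species, pass-2 QC
  target_ids <- meta$sample_id[meta$species == cfg$species_target]
  target_ids <- intersect(p1$genotypes$sample_ids, target_ids)
  if (length(target_ids) < 2L) {
    stop("fewer than two samples of target species '", cfg$species_target, "'")
  }
  gm_t <- subset_genotypes(gm, samples = target_ids)
  p2 <- stage("filter_pass2", run_cascade(gm_t, cfg$filter_pass2))
  note("pass-2 QC (target species): %d samples, %d loci (%.2f%% missing)",
       p2$genotypes$n_samples, p2$genotypes$n_loci,
       attr(p2$report, "final_missing_pct"))

  ## 4. clone calling on the target species
  clones <- stage("clones",
                  call_clones(p2$genotypes, threshold = cfg$clone_threshold,
                              min_shared = cfg$clone_min_shared))
  note("clones: %d samples collapse to %d genets at threshold %.3f",
       nrow(clones$assignments), length(clones$genets), cfg$clone_threshold)

  meta2 <- meta[match(p2$genotypes$sample_ids, meta$sample_id), ]

  ## genet-level bookkeeping: group and sex per genet
  genet_of <- stats::setNames(clones$assignments$genet,
                              clones$assignments$sample_id)
  genet_group <- vapply(clones$genets, function(ms) {
    gr <- unique(meta2$group[match(ms, meta2$sample_id)])
    if (length(gr) == 1L) gr else "shared"
  }, character(1))
  genet_sex <- vapply(clones$genets, function(ms) {
    sx <- setdiff(unique(meta2$sex[match(ms, meta2$sample_id)]), "unknown")
    if (length(sx) == 1L) sx else "unknown"
  }, character(1))

  ## 5. diversity per management group
  if (isTRUE(cfg$collapse_clones)) {
    # one representative per genet within each group (first member by id)
    reps <- vapply(clones$genets, function(ms) sort(ms)[1L], character(1))
    div_groups <- lapply(split(meta2$sample_id, meta2$group), function(ids) {
      gs <- unique(genet_of[ids])
      unname(reps[gs])
    })
  } else {
    div_groups <- split(meta2$sample_id, meta2$group)
  }
  diversity <- stage("diversity", diversity_table(p2$genotypes, div_groups))
  genet_reps <- vapply(clones$genets, function(ms) sort(ms)[1L], character(1))
  genet_ho <- data.frame(
    genet = names(clones$genets),
    group = unname(genet_group),
    sex = unname(genet_sex),
    n_ramets = unname(lengths(clones$genets)),
    ho = vapply(genet_reps, function(s) individual_ho(p2$genotypes, s),
                numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(genet_ho) <- NULL

  ## 6. within-species subsampled FST between management groups
  groups_t <- split(meta2$sample_id, meta2$group)
  fst_within <- NULL
  if (length(groups_t) >= 2L) {
    fst_within <- stage("fst_within",
                        fst_pairwise(p2$genotypes, groups_t,
                                     n_sub = cfg$fst_n_sub,
                                     iterations = cfg$fst_iterations,
                                     seed = derive_seed(cfg$seed, "fst_within")))
  }

  ## 7. crosses among genets
  crosses <- ranked <- group_crosses <- NULL
  if (isTRUE(cfg$crosses_enabled) && length(clones$genets) >= 2L) {
    crosses <- stage("crosses",
                     all_crosses(clones$consensus, sexes = genet_sex,
                                 n = cfg$cross_n_offspring,
                                 seed = derive_seed(cfg$seed, "crosses")))
    ranked <- rank_pairs(crosses)
    group_crosses <- cross_group_summary(crosses, genet_group)
    excluded <- crosses$pairs[!crosses$pairs$permissible, , drop = FALSE]
    note("crosses: %d pairs simulated, %d excluded by sex (%s)",
         sum(crosses$pairs$permissible), nrow(excluded),
         if (nrow(excluded)) paste(excluded$p1, excluded$p2, sep = "x",
                                   collapse = ", ") else "none")
  }

  run <- structure(
    list(config = cfg,
         filter_pass1 = p1$report, filter_pass2 = p2$report,
         fst_all_groups = fst_all, pcoa = pc, parentage = parent_rank,
         clones = clones, diversity = diversity, genet_ho = genet_ho,
         fst_within = fst_within, crosses = crosses, ranked_pairs = ranked,
         group_crosses = group_crosses, log = log_lines),
    class = "conservation_run"
  )
  if (!is.null(output_dir)) write_run_bundle(run, output_dir)
  run
}

#' @export
print.conservation_run <- function(x, ...) {
  cat("Conservation-genetics analysis run\n")
  for (l in x$log) cat(" -", l, "\n")
  invisible(x)
}

write_run_bundle <- function(run, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(output_dir, ...)
  yaml::write_yaml(run$config, out("config.yaml"))
  utils::write.csv(as.data.frame(run$filter_pass1), out("filter_pass1.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(run$filter_pass2), out("filter_pass2.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(run$fst_all_groups$mean_matrix),
                   out("fst_all_groups.csv"))
  if (!is.null(run$fst_within)) {
    utils::write.csv(as.data.frame(run$fst_within$mean_matrix),
                     out("fst_within.csv"))
  }
  utils::write.csv(data.frame(sample_id = rownames(run$pcoa$points),
                              run$pcoa$points),
                   out("pcoa_coordinates.csv"), row.names = FALSE)
  if (!is.null(run$parentage)) {
    utils::write.csv(as.data.frame(run$parentage), out("parentage_groups.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(run$clones$assignments, out("clone_assignments.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(run$clones$dissimilarity),
                   out("dissimilarity_matrix.csv"))
  utils::write.csv(as.data.frame(run$diversity), out("diversity.csv"),
                   row.names = FALSE)
  utils::write.csv(run$genet_ho, out("genet_ho.csv"), row.names = FALSE)
  if (!is.null(run$crosses)) {
    utils::write.csv(as.data.frame(run$crosses$mean_ho), out("cross_matrix.csv"))
    utils::write.csv(run$ranked_pairs, out("ranked_pairs.csv"),
                     row.names = FALSE)
    utils::write.csv(run$group_crosses, out("cross_group_summary.csv"),
                     row.names = FALSE)
  }
  writeLines(run$log, out("run_log.txt"))
  invisible(output_dir)
}
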