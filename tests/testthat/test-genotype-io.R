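# Genotype container and readers: validation, subsetting, round trips,
# format dialects.

test_that("genotype_matrix validates codes, ids and metadata", {
  calls <- matrix(c(0L, 1L, 2L, NA), 2, 2,
                  dimnames = list(c("a", "b"), c("L1", "L2")))
  gm <- genotype_matrix(calls)
  expect_s3_class(gm, "genotype_matrix")
  expect_identical(dim(gm), c(2L, 2L))
  expect_equal(gm$locus_meta$call_rate, c(1, 0.5))

  bad <- calls; bad[1, 1] <- 3L
  expect_error(genotype_matrix(bad), "invalid genotype code 3.*'a'.*'L1'")
  dup <- calls; rownames(dup) <- c("a", "a")
  expect_error(genotype_matrix(dup), "duplicate sample ids")
  dupl <- calls; colnames(dupl) <- c("L1", "L1")
  expect_error(genotype_matrix(dupl), "duplicate locus ids")
  expect_error(
    genotype_matrix(calls, data.frame(locus_id = "L1", fragment_id = "f",
                                      reproducibility = 1,
                                      mean_read_depth = 1)),
    "exactly one record per locus")
})

test_that("plain genotype CSV reads cells strictly and recomputes call rate", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,L1,L2,L3",
               "s1,0,0,0",
               "s2,0,0,0"), f)
  gm <- read_genotype_csv(f)
  expect_equal(sum(gm$calls == 0L), 6L)
  expect_equal(unname(locus_call_rate(gm)), rep(1, 3))

  writeLines(c("sample_id,L1,L2",
               "s1,NA,1",
               "s2,0,2"), f)
  gm <- read_genotype_csv(f, missing_token = "NA")
  expect_true(is.na(gm$calls["s1", "L1"]))
  expect_equal(gm$locus_meta$call_rate, c(0.5, 1))

  writeLines(c("sample_id,L1,L2",
               "s1,0,3",
               "s2,0,2"), f)
  expect_error(read_genotype_csv(f), "'3'.*'s1'.*'L2'")
})

test_that("write/read round trip reproduces calls, ids and metadata exactly", {
  set.seed(7)
  gm <- make_gm(matrix(sample(c(0L, 1L, 2L, NA), 30, replace = TRUE), 5, 6),
                fragment = c("f1", "f1", "f2", "f3", "f4", "f4"),
                reproducibility = round(runif(6, 0.9, 1), 3),
                depth = round(runif(6, 5, 400), 2))
  f <- tempfile(fileext = ".csv")
  write_genotype_csv(gm, f)
  back <- read_genotype_csv(f, locus_meta_path = paste0(f, ".loci.csv"))
  expect_identical(back$calls, gm$calls)
  expect_identical(back$sample_ids, gm$sample_ids)
  expect_equal(back$locus_meta, gm$locus_meta)
})

test_that("DArT one-row reports map the 0/1/2/'-' dialect and QC columns", {
  f <- tempfile(fileext = ".csv")
  writeLines(c(
    "AlleleID,CloneID,RepAvg,AvgReadDepth,ind1,ind2,ind3",
    "c1-snp1,c1,1.0,20,0,1,2",
    "c1-snp2,c1,0.99,30,0,0,-",
    "c1-snp3,c1,0.995,40,2,2,2",
    "c2-snp1,c2,0.97,600,1,0,0"), f)
  gm <- read_dart_report(f)
  expect_equal(gm$n_loci, 4L)
  expect_equal(gm$n_samples, 3L)
  # 3 SNPs on clone c1 share a fragment id
  expect_equal(sum(gm$locus_meta$fragment_id == "c1"), 3L)
  # dialect: 0 -> hom ref (0), 1 -> hom alt (2), 2 -> het (1), '-' -> missing
  expect_equal(unname(gm$calls[, "c1-snp1"]), c(0L, 2L, 1L))
  expect_true(is.na(gm$calls["ind3", "c1-snp2"]))
  expect_equal(gm$locus_meta$reproducibility[2], 0.99)
  expect_equal(gm$locus_meta$mean_read_depth[4], 600)

  writeLines(c("AlleleID,CloneID,ind1", "c1-snp1,c1,0"), f)
  expect_error(read_dart_report(f), "RepAvg")
  writeLines(c(
    "AlleleID,CloneID,RepAvg,AvgReadDepth,ind1",
    "c1-snp1,c1,1.0,20,5"), f)
  expect_error(read_dart_report(f), "unrecognised DArT genotype '5'")
})

test_that("DArT depth falls back to AvgCountRef + AvgCountSnp", {
  f <- tempfile(fileext = ".csv")
  writeLines(c(
    "AlleleID,CloneID,RepAvg,AvgCountRef,AvgCountSnp,ind1,ind2",
    "c1-snp1,c1,1.0,12.5,7.5,0,1"), f)
  gm <- read_dart_report(f)
  expect_equal(gm$locus_meta$mean_read_depth, 20)
})

write_test_vcf <- function(records) {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           "s1\ts2\ts3\ts4"),
    records), f)
  f
}

test_that("VCF GT maps to dosage, ignores phase, rejects multi-allelic sites", {
  f <- write_test_vcf(c(
    "1\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1\t./.",
    "1\t200\tv2\tC\tT\t.\tPASS\t.\tGT\t0|1\t1|1\t0/0\t0/1"))
  gm <- read_vcf(f)
  expect_equal(unname(gm$calls[, "v1"]), c(0L, 1L, 2L, NA))
  expect_equal(unname(gm$calls["s1", "v2"]), 1L)  # phased 0|1 is a het

  f2 <- write_test_vcf("1\t300\tv3\tA\tG,T\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1\t2/2")
  expect_error(read_vcf(f2), "multi-allelic record at 1:300")
})

test_that("equivalent CSV and VCF encodings yield identical matrices", {
  f <- write_test_vcf(c(
    "1\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1\t./.",
    "1\t200\tv2\tC\tT\t.\tPASS\t.\tGT\t0/1\t1/1\t0/0\t0/1"))
  from_vcf <- read_vcf(f)
  g <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,v1,v2",
               "s1,0,1", "s2,1,2", "s3,2,0", "s4,NA,1"), g)
  from_csv <- read_genotype_csv(g)
  expect_identical(from_csv$calls, from_vcf$calls)
})

test_that("subsetting preserves order, carries metadata, recomputes call rate", {
  calls <- rbind(s1 = c(0L, 1L, NA), s2 = c(0L, 0L, 2L), s3 = c(2L, NA, 0L))
  colnames(calls) <- c("L1", "L2", "L3")
  gm <- make_gm(calls, fragment = c("f1", "f2", "f3"))
  full <- subset_genotypes(gm)
  expect_identical(full$calls, gm$calls)

  sub <- subset_genotypes(gm, samples = c("s3", "s1"), loci = c("L3", "L1"))
  expect_identical(sub$sample_ids, c("s3", "s1"))
  expect_identical(sub$locus_ids, c("L3", "L1"))
  expect_identical(sub$locus_meta$fragment_id, c("f3", "f1"))

  one <- subset_genotypes(gm, samples = "s1")
  expect_true(all(one$locus_meta$call_rate %in% c(0, 1)))

  # removing the only alt-carrying sample makes L1 monomorphic
  no_alt <- subset_genotypes(gm, samples = c("s1", "s2"))
  p <- allele_freq(no_alt)
  expect_equal(unname(p[["L1"]]), 0)
  expect_error(subset_genotypes(gm, samples = "nope"), "unknown sample id")
  expect_error(subset_genotypes(gm, loci = "nope"), "unknown locus id")
})

test_that("sample metadata validation enforces columns and sex values", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,species,group,sex",
               "s1,sp,wild,male",
               "s2,sp,wild,"), f)
  meta <- read_sample_meta(f)
  expect_equal(meta$sex, c("male", "unknown"))
  writeLines(c("sample_id,species", "s1,sp"), f)
  expect_error(read_sample_meta(f), "group")
  writeLines(c("sample_id,species,group,sex", "s1,sp,wild,hermaphrodite"), f)
  expect_error(read_sample_meta(f), "invalid sex")
})
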