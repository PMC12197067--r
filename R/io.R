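# Readers and writers for the supported genotype formats. All readers funnel
# into genotype_matrix(), so validation is identical regardless of source.

#' Read a plain genotype CSV
#'
#' Expects a samples x loci table: header row of locus ids, first column of
#' sample ids, cells in `{0, 1, 2, missing_token}` (alt-allele dosage).
#' Unparseable cells are a hard error naming the offending sample and locus;
#' they are never silently coerced to missing.
#'
#' @param path path to the CSV file.
#' @param missing_token string representing a missing call (default `"NA"`).
#' @param locus_meta_path optional path to a locus-metadata CSV with columns
#'   `locus_id`, `fragment_id`, `reproducibility`, `mean_read_depth`
#'   (the format written by [write_genotype_csv()]).
#' @return A [genotype_matrix].
#' @seealso [write_genotype_csv()] for the round-trip writer.
#' @export
read_genotype_csv <- function(path, missing_token = "NA",
                              locus_meta_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         na.strings = character(0))
  if (ncol(raw) < 2L) stop("genotype CSV needs >= 1 locus column: ", path)
  sample_ids <- raw[[1L]]
  locus_ids <- names(raw)[-1L]
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  calls <- matrix(NA_integer_, nrow(cells), ncol(cells),
                  dimnames = list(sample_ids, locus_ids))
  is_missing <- cells == missing_token
  ok <- cells %in% c("0", "1", "2")
  bad <- !ok & !is_missing
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "cell '%s' at sample '%s', locus '%s' is not 0/1/2 or the missing token '%s'",
      cells[w[1L], w[2L]], sample_ids[w[1L]], locus_ids[w[2L]], missing_token))
  }
  calls[ok] <- as.integer(cells[ok])
  meta <- NULL
  if (!is.null(locus_meta_path)) {
    meta <- utils::read.csv(locus_meta_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  }
  genotype_matrix(calls, meta)
}

#' Write a genotype matrix (and its locus metadata) to CSV
#'
#' Writes the samples x loci call table with `missing_token` for missing
#' calls, and a companion locus-metadata CSV so that a write/read round trip
#' reproduces the object exactly.
#'
#' @param gm a [genotype_matrix].
#' @param path output CSV path for the call table.
#' @param missing_token token used for missing calls.
#' @param locus_meta_path output path for the metadata CSV; default
#'   `paste0(path, ".loci.csv")`. `NULL` suppresses the metadata file.
#' @return Invisibly, `path`.
#' @export
write_genotype_csv <- function(gm, path, missing_token = "NA",
                               locus_meta_path = paste0(path, ".loci.csv")) {
  stopifnot(inherits(gm, "genotype_matrix"))
  tab <- gm$calls
  out <- cbind(sample_id = gm$sample_ids,
               as.data.frame(ifelse(is.na(tab), missing_token, tab)))
  colnames(out) <- c("sample_id", gm$locus_ids)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (!is.null(locus_meta_path)) {
    meta <- gm$locus_meta[, c("locus_id", "fragment_id", "reproducibility",
                              "mean_read_depth")]
    utils::write.csv(meta, locus_meta_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

# Column names recognised as locus metadata in DArT one-row SNP reports;
# anything else is treated as a per-sample genotype column.
.dart_meta_cols <- c(
  "AlleleID", "CloneID", "AlleleSequence", "TrimmedSequence", "SNP",
  "SnpPosition", "CallRate", "OneRatioRef", "OneRatioSnp", "FreqHomRef",
  "FreqHomSnp", "FreqHets", "PICRef", "PICSnp", "AvgPIC", "AvgCountRef",
  "AvgCountSnp", "AvgReadDepth", "RepAvg"
)

#' Read a DArT one-row SNP report
#'
#' Parses the one-row-per-SNP CSV export of DArT-style reduced-representation
#' genotyping. Genotypes follow the one-row convention: `0` = homozygous
#' reference, `1` = homozygous alternate, `2` = heterozygous, `"-"` = missing;
#' they are remapped to the package's dosage coding (0/1/2/`NA`). Locus
#' metadata is taken from `CloneID` (fragment id, grouping a primary SNP with
#' its secondaries), `RepAvg` (reproducibility) and `AvgReadDepth` (or, when
#' absent, `AvgCountRef + AvgCountSnp`).
#'
#' @param path path to the report CSV.
#' @param missing_token per-sample token for a failed call (default `"-"`).
#' @return A [genotype_matrix] (loci become columns; locus ids come from
#'   `AlleleID` when present, else `CloneID` made unique by row number).
#' @export
read_dart_report <- function(path, missing_token = "-") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         na.strings = character(0))
  need <- c("CloneID", "RepAvg")
  miss <- setdiff(need, names(raw))
  depth_ok <- "AvgReadDepth" %in% names(raw) ||
    all(c("AvgCountRef", "AvgCountSnp") %in% names(raw))
  if (!depth_ok) miss <- c(miss, "AvgReadDepth (or AvgCountRef+AvgCountSnp)")
  if (length(miss)) {
    stop("DArT report lacks required metadata column(s): ", id_preview(miss))
  }
  sample_cols <- setdiff(names(raw), .dart_meta_cols)
  if (!length(sample_cols)) stop("DArT report has no per-sample columns")
  locus_ids <- if ("AlleleID" %in% names(raw)) {
    raw$AlleleID
  } else {
    paste0(raw$CloneID, "_", seq_len(nrow(raw)))
  }
  if (anyDuplicated(locus_ids)) stop("duplicate locus ids in DArT report")
  cells <- t(as.matrix(raw[, sample_cols, drop = FALSE]))
  dimnames(cells) <- list(sample_cols, locus_ids)
  # one-row coding -> dosage: 0 -> 0 (hom ref), 1 -> 2 (hom alt), 2 -> 1 (het)
  calls <- matrix(NA_integer_, nrow(cells), ncol(cells),
                  dimnames = dimnames(cells))
  calls[cells == "0"] <- 0L
  calls[cells == "1"] <- 2L
  calls[cells == "2"] <- 1L
  bad <- !(cells == "0" | cells == "1" | cells == "2" |
             cells == missing_token)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("unrecognised DArT genotype '%s' for sample '%s', locus '%s'",
                 cells[w[1L], w[2L]], rownames(cells)[w[1L]],
                 colnames(cells)[w[2L]]))
  }
  depth <- if ("AvgReadDepth" %in% names(raw)) {
    as.numeric(raw$AvgReadDepth)
  } else {
    as.numeric(raw$AvgCountRef) + as.numeric(raw$AvgCountSnp)
  }
  meta <- data.frame(
    locus_id = locus_ids,
    fragment_id = raw$CloneID,
    reproducibility = as.numeric(raw$RepAvg),
    mean_read_depth = depth,
    stringsAsFactors = FALSE
  )
  genotype_matrix(calls, meta)
}

#' Read biallelic SNPs from a VCF
#'
#' Maps the GT field to alt-allele dosage; phase separators are ignored and
#' any missing allele makes the call missing. Multi-allelic records are
#' rejected with an error naming the record -- the downstream statistics are
#' defined for biallelic SNPs only, and silent splitting would change allele
#' frequencies.
#'
#' @param path path to a VCF (v4.x, plain or bgzipped).
#' @return A [genotype_matrix]. Locus ids are `ID` when informative, else
#'   `CHROM_POS`; fragment ids default to the locus id and
#'   reproducibility/depth to `NA` (VCFs carry no DArT-style QC metadata).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    i <- which(multi)[1L]
    stop(sprintf("multi-allelic record at %s:%s (ALT '%s'); split or drop it upstream",
                 fix[i, "CHROM"], fix[i, "POS"], fix[i, "ALT"]))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || !ncol(gt)) stop("VCF contains no genotype (GT) data")
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(ids) | ids == "."]
  alleles <- gsub("\\|", "/", gt)
  dose <- function(x) {
    parts <- strsplit(x, "/", fixed = TRUE)
    vapply(parts, function(p) {
      if (length(p) != 2L || any(p == ".") || anyNA(p)) return(NA_integer_)
      if (!all(p %in% c("0", "1"))) {
        stop("unsupported GT allele code(s): ", paste(p, collapse = "/"))
      }
      sum(as.integer(p))
    }, integer(1))
  }
  calls <- apply(alleles, 2, dose)
  if (is.null(dim(calls))) calls <- matrix(calls, nrow = 1)
  calls[is.na(gt)] <- NA_integer_
  dimnames(calls) <- list(ids, colnames(gt))
  genotype_matrix(t(calls))
}

#' Read sample metadata
#'
#' A CSV with required columns `sample_id`, `species`, `group` (management
#' group: wild in-situ, ex-situ adults, ex-situ seedlings, or a congener
#' label) and optional `patch` and `sex`. Missing `sex` values become
#' `"unknown"`; anything other than male/female/unknown is an error.
#'
#' @param path path to the metadata CSV.
#' @return A validated data.frame (one row per sample).
#' @export
read_sample_meta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sample_meta(meta)
}

validate_sample_meta <- function(meta) {
  req <- c("sample_id", "species", "group")
  miss <- setdiff(req, names(meta))
  if (length(miss)) stop("sample metadata lacks column(s): ", id_preview(miss))
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in metadata")
  if (any(is.na(meta$group) | meta$group == "")) {
    stop("every sample needs a non-empty management group")
  }
  if (!"patch" %in% names(meta)) meta$patch <- NA_character_
  if (!"sex" %in% names(meta)) meta$sex <- "unknown"
  meta$sex[is.na(meta$sex) | meta$sex == ""] <- "unknown"
  bad <- !meta$sex %in% c("male", "female", "unknown")
  if (any(bad)) {
    stop("invalid sex value(s): ", id_preview(unique(meta$sex[bad])),
         " (allowed: male, female, unknown)")
  }
  meta
}
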