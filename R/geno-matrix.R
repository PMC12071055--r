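#' In-memory genotype matrix for biallelic SNPs
#'
#' Container for a samples x sites matrix of alt-allele dosages
#' (0 = homozygous reference, 1 = heterozygous, 2 = homozygous alternate,
#' `NA` = missing) together with per-site and per-sample metadata.
#' Coordinates are 1-based inclusive (VCF convention); sites are stored in
#' genome order (chromosome order of first appearance, then position).
#'
#' @param calls integer matrix, samples in rows and sites in columns, values
#'   in `{0, 1, 2, NA}`.
#' @param sites data.frame with columns `chrom`, `pos`, `site_id`, `ref`,
#'   `alt`; one row per column of `calls`.
#' @param samples data.frame with columns `sample_id`, `breed` and optionally
#'   `sex`; one row per row of `calls`.
#'
#' @return An object of class `geno_matrix`: a list with elements `calls`,
#'   `sites`, `samples` and `chrom_levels` (the chromosome ordering).
#' @export
geno_matrix <- function(calls, sites, samples) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!"sex" %in% names(samples)) samples$sex <- NA_character_
  if (!"site_id" %in% names(sites)) {
    sites$site_id <- paste(sites$chrom, sites$pos, sep = "_")
  }
  stopifnot(
    nrow(calls) == nrow(samples),
    ncol(calls) == nrow(sites),
    all(c("chrom", "pos") %in% names(sites)),
    all(c("sample_id", "breed") %in% names(samples))
  )
  if (!"ref" %in% names(sites)) sites$ref <- "A"
  if (!"alt" %in% names(sites)) sites$alt <- "G"
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  if (any(sites$pos < 1L)) stop("positions must be >= 1")
  if (any(sites$ref == sites$alt)) stop("ref and alt alleles must differ")
  if (anyDuplicated(samples$sample_id)) stop("sample_id must be unique")

  chrom_levels <- unique(sites$chrom)
  ord <- genome_order(sites$chrom, sites$pos, chrom_levels)
  sites <- sites[ord, , drop = FALSE]
  calls <- calls[, ord, drop = FALSE]
  if (anyDuplicated(sites[, c("chrom", "pos")])) {
    stop("(chrom, pos) must be unique within a genotype matrix")
  }
  if (anyDuplicated(sites$site_id)) {
    sites$site_id <- paste(sites$chrom, sites$pos, sep = "_")
  }
  rownames(sites) <- NULL
  rownames(samples) <- NULL
  dimnames(calls) <- list(samples$sample_id, sites$site_id)
  bad <- calls[!is.na(calls)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L))) {
    stop("genotype codes must be 0, 1, 2 or NA")
  }
  structure(
    list(calls = calls, sites = sites, samples = samples,
         chrom_levels = chrom_levels),
    class = "geno_matrix"
  )
}

#' @exportS3Method base::print
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "geno_matrix: %d samples x %d sites on %d chromosome(s); %d breed(s)\n",
    n_samples(x), n_sites(x), length(x$chrom_levels),
    length(unique(x$samples$breed))
  ))
  invisible(x)
}

#' @rdname geno_matrix
#' @param gm a `geno_matrix`.
#' @export
n_sites <- function(gm) ncol(gm$calls)

#' @rdname geno_matrix
#' @export
n_samples <- function(gm) nrow(gm$calls)

#' Subset a genotype matrix by site index or by sample id
#'
#' @param gm a [geno_matrix()].
#' @param i logical or integer index over sites (for `subset_sites`).
#' @param sample_ids character vector of sample ids (for `subset_samples`).
#' @return A new `geno_matrix`.
#' @export
subset_sites <- function(gm, i) {
  geno_matrix(gm$calls[, i, drop = FALSE], gm$sites[i, , drop = FALSE],
              gm$samples)
}

#' @rdname subset_sites
#' @export
subset_samples <- function(gm, sample_ids) {
  miss <- setdiff(sample_ids, gm$samples$sample_id)
  if (length(miss)) {
    stop("unknown sample id(s): ", paste(miss, collapse = ", "))
  }
  idx <- match(sample_ids, gm$samples$sample_id)
  geno_matrix(gm$calls[idx, , drop = FALSE], gm$sites,
              gm$samples[idx, , drop = FALSE])
}

# ---------------------------------------------------------------------------
# VCF ingestion

gt_to_dosage <- function(gt) {
  # map diploid GT strings to alt-allele dosage; any "." allele => missing;
  # phased and unphased genotypes are treated identically
  u <- unique(as.vector(gt))
  code <- vapply(u, function(g) {
    if (is.na(g)) return(NA_integer_)
    alleles <- strsplit(sub(":.*$", "", g), "[/|]")[[1]]
    if (length(alleles) == 0 || any(alleles == ".")) return(NA_integer_)
    sum(alleles == "1")
  }, integer(1))
  out <- code[match(as.vector(gt), u)]
  matrix(out, nrow = nrow(gt), dimnames = dimnames(gt))
}

#' Read biallelic SNP genotypes from a VCF
#'
#' Loads biallelic SNP records from a plain or bgzipped VCF into a
#' [geno_matrix()].  Indels, multiallelic records and duplicated
#' (chrom, pos) records are skipped and counted in the attached read log.
#'
#' @param path path to a VCF (`.vcf` or `.vcf.gz`).
#' @param sample_table optional path to (or data.frame of) a tab-separated
#'   table with columns `sample_id`, `breed` and optionally `sex`, mapping
#'   every VCF sample to a breed.  When `NULL` all samples get breed
#'   `"unknown"`.
#' @return A `geno_matrix` with attribute `read_log` (counts of skipped
#'   records).
#' @export
read_vcf <- function(path, sample_table = NULL) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(fix) || nrow(fix) == 0) stop("no records in VCF: ", path)
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  bases <- c("A", "C", "G", "T")
  keep <- !is.na(ref) & !is.na(alt) & ref %in% bases & alt %in% bases
  n_skip_bial <- sum(!keep)

  chrom <- fix[keep, "CHROM"]
  pos <- as.integer(fix[keep, "POS"])
  # chromosome order: contig order in the header when present, otherwise
  # order of first appearance in the records
  meta_contigs <- grep("^##contig=", v@meta, value = TRUE)
  hdr_order <- sub(".*ID=([^,>]+).*", "\\1", meta_contigs)
  chrom_levels <- if (length(hdr_order) && all(chrom %in% hdr_order)) {
    hdr_order[hdr_order %in% chrom]
  } else {
    unique(chrom)
  }
  dup <- duplicated(paste(chrom, pos))
  n_skip_dup <- sum(dup)

  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no genotype (GT) field: ", path)
  gt <- gt[keep, , drop = FALSE][!dup, , drop = FALSE]
  calls <- t(gt_to_dosage(gt))
  if (ncol(calls) == 0) stop("no usable biallelic SNP records in ", path)

  ids <- fix[keep, "ID"][!dup]
  ids[is.na(ids) | ids == "."] <- paste(chrom[!dup], pos[!dup],
                                        sep = "_")[is.na(ids) | ids == "."]
  sites <- data.frame(
    chrom = chrom[!dup], pos = pos[!dup], site_id = ids,
    ref = ref[keep][!dup], alt = alt[keep][!dup],
    stringsAsFactors = FALSE
  )
  sites$chrom <- factor(sites$chrom, levels = chrom_levels)
  ord <- order(as.integer(sites$chrom), sites$pos)
  sites$chrom <- as.character(sites$chrom)
  sites <- sites[ord, , drop = FALSE]
  calls <- calls[, ord, drop = FALSE]

  vcf_samples <- rownames(calls)
  if (is.null(sample_table)) {
    samples <- data.frame(sample_id = vcf_samples, breed = "unknown",
                          sex = NA_character_, stringsAsFactors = FALSE)
  } else {
    tab <- if (is.data.frame(sample_table)) sample_table else
      utils::read.delim(sample_table, stringsAsFactors = FALSE)
    if (!all(c("sample_id", "breed") %in% names(tab))) {
      stop("sample table needs columns `sample_id` and `breed`")
    }
    missing <- setdiff(vcf_samples, tab$sample_id)
    if (length(missing)) {
      stop("VCF sample(s) absent from sample table: ",
           paste(missing, collapse = ", "))
    }
    samples <- tab[match(vcf_samples, tab$sample_id), , drop = FALSE]
  }
  gm <- geno_matrix(calls, sites, samples)
  attr(gm, "read_log") <- list(
    n_loaded = n_sites(gm),
    n_skipped_not_biallelic_snp = n_skip_bial,
    n_skipped_duplicate_position = n_skip_dup
  )
  gm
}

#' Write a genotype matrix to VCF
#'
#' @param gm a [geno_matrix()].
#' @param path output path; written bgzip-compressed, so use a `.vcf.gz`
#'   extension.
#' @return `path`, invisibly.
#' @importClassesFrom vcfR vcfR
#' @importFrom methods new
#' @export
write_vcf <- function(gm, path) {
  n <- n_sites(gm)
  fix <- cbind(
    CHROM = gm$sites$chrom,
    POS = as.character(gm$sites$pos),
    ID = gm$sites$site_id,
    REF = gm$sites$ref,
    ALT = gm$sites$alt,
    QUAL = ".", FILTER = "PASS", INFO = "."
  )
  gt_strings <- c("0/0", "0/1", "1/1")
  g <- gm$calls
  gt <- matrix("./.", nrow = n, ncol = n_samples(gm))
  ok <- !is.na(t(g))
  gt[ok] <- gt_strings[t(g)[ok] + 1L]
  colnames(gt) <- gm$samples$sample_id
  gt <- cbind(FORMAT = "GT", gt)
  meta <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", gm$chrom_levels, ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
  )
  out <- methods::new("vcfR", meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(out, file = path)
  invisible(path)
}

#' Write the sample table companion of a genotype matrix
#'
#' @param gm a [geno_matrix()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(gm, path) {
  utils::write.table(gm$samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Per-site statistics and QC filters

#' Per-site allele and genotype statistics
#'
#' Missing-excluded alt-allele frequency, minor allele frequency, missingness
#' and observed heterozygosity per site.  Sites where every call is missing
#' are flagged `defined = FALSE` (statistics `NaN`) rather than silently 0.
#'
#' @param gm a [geno_matrix()].
#' @param sample_subset optional character vector of sample ids to restrict
#'   the computation to.
#' @return data.frame with one row per site: `chrom`, `pos`, `site_id`,
#'   `p_alt`, `maf`, `missing_rate`, `het_rate`, `n_called`, `defined`.
#' @export
site_stats <- function(gm, sample_subset = NULL) {
  calls <- gm$calls
  if (!is.null(sample_subset)) {
    if (length(sample_subset) == 0) stop("empty sample subset")
    miss <- setdiff(sample_subset, gm$samples$sample_id)
    if (length(miss)) stop("unknown sample id(s): ", paste(miss, collapse = ", "))
    calls <- calls[match(sample_subset, gm$samples$sample_id), , drop = FALSE]
  }
  n <- nrow(calls)
  n_called <- colSums(!is.na(calls))
  p_alt <- colSums(calls, na.rm = TRUE) / (2 * n_called)  # NaN when n_called=0
  het_rate <- colSums(calls == 1L, na.rm = TRUE) / n_called
  data.frame(
    chrom = gm$sites$chrom, pos = gm$sites$pos, site_id = gm$sites$site_id,
    p_alt = p_alt, maf = pmin(p_alt, 1 - p_alt),
    missing_rate = 1 - n_called / n, het_rate = het_rate,
    n_called = n_called, defined = n_called > 0,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' QC-filter sites on missingness and minor allele frequency
#'
#' Retains sites with `missing_rate < max_missing` and `maf >= min_maf`
#' (so the boundary `maf == min_maf` is kept; removal condition is
#' `maf < min_maf`).  Sites with no non-missing call are removed.
#'
#' @param gm a [geno_matrix()].
#' @param max_missing maximum tolerated missingness (exclusive), default 0.1.
#' @param min_maf minimum minor allele frequency (inclusive), default 0.05.
#' @return Filtered `geno_matrix` with attribute `filter_log` giving per-rule
#'   removal counts.  Removing every site yields an empty matrix with a
#'   warning, not an error.
#' @export
filter_sites <- function(gm, max_missing = 0.1, min_maf = 0.05) {
  stopifnot(max_missing >= 0, max_missing <= 1, min_maf >= 0, min_maf <= 1)
  st <- site_stats(gm)
  pass_missing <- st$missing_rate < max_missing
  pass_maf <- st$defined & st$maf >= min_maf
  keep <- pass_missing & pass_maf
  log <- list(
    n_in = n_sites(gm), n_out = sum(keep),
    removed_missing = sum(!pass_missing),
    removed_maf = sum(pass_missing & !pass_maf)
  )
  if (!any(keep)) warning("all sites removed by QC filters")
  out <- subset_sites(gm, keep)
  attr(out, "filter_log") <- log
  out
}

#' Per-sample call-rate summary
#'
#' @param gm a [geno_matrix()].
#' @return data.frame with `sample_id`, `breed`, `sex`, `n_called`,
#'   `call_rate`, `missing_rate`.
#' @export
sample_qc <- function(gm) {
  n_called <- rowSums(!is.na(gm$calls))
  data.frame(
    sample_id = gm$samples$sample_id, breed = gm$samples$breed,
    sex = gm$samples$sex, n_called = n_called,
    call_rate = n_called / n_sites(gm),
    missing_rate = 1 - n_called / n_sites(gm),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
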