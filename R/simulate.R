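#' Configuration for the multi-breed genotype simulator
#'
#' Balding-Nichols simulation settings.  Defaults emulate a small multi-breed
#' cattle study at desk scale: four breeds of 25 animals, 2,000 biallelic
#' sites over two chromosomes, breed differentiation `F = 0.1` (typical of
#' related cattle breeds) and per-call missingness 0.5% (panel-grade call
#' rates above 99%).
#'
#' @param n_breeds number of breeds (>= 1).
#' @param samples_per_breed animals per breed (recycled).
#' @param n_sites total number of biallelic sites.
#' @param chrom_lengths named vector of chromosome lengths (bp); sites are
#'   allocated proportionally to length and placed uniformly.
#' @param F Balding-Nichols differentiation parameter per breed, each in
#'   (0, 1); recycled across breeds.
#' @param missing_rate per-call missingness probability in `[0, 1)`.
#' @param dup_fraction fraction of sites duplicated at a nearby position
#'   (with per-call copy errors) to create high-LD pairs; default 0 (no
#'   linkage, sites independent).
#' @param dup_max_dist maximum offset of a duplicated site, bp.
#' @param dup_error_rate per-call resampling probability for duplicated
#'   sites.
#' @param seed mandatory integer seed; all randomness derives from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_breeds = 4, samples_per_breed = 25, n_sites = 2000,
                       chrom_lengths = c("1" = 6e7, "2" = 4e7),
                       F = 0.1, missing_rate = 0.005,
                       dup_fraction = 0, dup_max_dist = 5000,
                       dup_error_rate = 0.02, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  F <- rep_len(F, n_breeds)
  if (any(F <= 0 | F >= 1)) stop("F must lie strictly inside (0, 1)")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  stopifnot(n_breeds >= 1, samples_per_breed >= 1, n_sites >= 1,
            dup_fraction >= 0, dup_fraction < 1)
  structure(
    list(n_breeds = n_breeds,
         samples_per_breed = rep_len(samples_per_breed, n_breeds),
         n_sites = n_sites, chrom_lengths = as_chrom_lengths(chrom_lengths),
         F = F, missing_rate = missing_rate, dup_fraction = dup_fraction,
         dup_max_dist = dup_max_dist, dup_error_rate = dup_error_rate,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate ancestral and per-breed allele frequencies
#'
#' Ancestral frequencies are Uniform(0.05, 0.95); each breed's frequency at
#' a site is Beta(`p(1-F)/F`, `(1-p)(1-F)/F`) (the Balding-Nichols model),
#' so `Var(p_breed) = F p (1 - p)`.  Fully reproducible from the seed.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_freqs`: `p_anc` (length `n_sites`), `p_breed`
#'   (sites x breeds matrix) and `config`.
#' @export
simulate_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  p <- stats::runif(config$n_sites, 0.05, 0.95)
  p_breed <- vapply(seq_len(config$n_breeds), function(b) {
    f <- config$F[b]
    stats::rbeta(config$n_sites, p * (1 - f) / f, (1 - p) * (1 - f) / f)
  }, numeric(config$n_sites))
  colnames(p_breed) <- paste0("breed", seq_len(config$n_breeds))
  structure(list(p_anc = p, p_breed = p_breed, config = config),
            class = "sim_freqs")
}

#' Simulate a multi-breed genotype matrix
#'
#' Genotypes are Binomial(2, `p_breed`) per sample and site, with a
#' Bernoulli missingness mask.  Site positions are drawn uniformly (without
#' replacement) per chromosome, proportional to chromosome length, and
#' sorted.  With `dup_fraction > 0` a fraction of sites is copied to a
#' nearby position with rare per-call errors, creating high-r2 pairs for LD
#' analyses.  Optionally writes the VCF and sample-table companions.
#'
#' @param freqs a [simulate_frequencies()] result.
#' @param vcf_path optional output VCF path (`.vcf.gz`).
#' @param sample_table_path optional output sample TSV path.
#' @return A [geno_matrix()]; when paths are given the files are written
#'   too.
#' @export
simulate_genotypes <- function(freqs, vcf_path = NULL,
                               sample_table_path = NULL) {
  stopifnot(inherits(freqs, "sim_freqs"))
  config <- freqs$config
  set.seed(config$seed + 1L)
  len <- config$chrom_lengths
  n_chr <- length(len)
  alloc <- floor(config$n_sites * len / sum(len))
  rem <- config$n_sites - sum(alloc)
  if (rem > 0) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1
  chrom <- rep(names(len), alloc)
  pos <- unlist(lapply(names(len), function(ch) {
    sort(sample.int(len[[ch]], alloc[[ch]]))
  }), use.names = FALSE)
  ord <- genome_order(chrom, pos, names(len))
  chrom <- chrom[ord]; pos <- pos[ord]

  breeds <- rep(paste0("breed", seq_len(config$n_breeds)),
                config$samples_per_breed)
  n_ind <- length(breeds)
  sample_id <- sprintf("%s_%02d", breeds,
                       unlist(lapply(config$samples_per_breed, seq_len)))
  sex <- rep_len(c("M", "F"), n_ind)

  calls <- matrix(NA_integer_, n_ind, config$n_sites)
  for (b in seq_len(config$n_breeds)) {
    rows <- which(breeds == paste0("breed", b))
    pb <- freqs$p_breed[, b]
    g <- stats::rbinom(length(rows) * config$n_sites, 2,
                       rep(pb, each = length(rows)))
    calls[rows, ] <- matrix(g, length(rows), config$n_sites)
  }

  if (config$dup_fraction > 0) {
    n_dup <- floor(config$n_sites * config$dup_fraction)
    src <- sample.int(config$n_sites, n_dup)
    off <- sample.int(config$dup_max_dist, n_dup, replace = TRUE)
    new_pos <- pmin(pos[src] + off, len[chrom[src]])
    dup_calls <- calls[, src, drop = FALSE]
    err <- matrix(stats::runif(n_ind * n_dup) < config$dup_error_rate,
                  n_ind, n_dup)
    p_err <- rep(freqs$p_anc[src], each = n_ind)[as.vector(err)]
    dup_calls[err] <- stats::rbinom(sum(err), 2, p_err)
    key <- paste(chrom, pos)
    fresh <- !(paste(chrom[src], new_pos) %in% key) &
      !duplicated(paste(chrom[src], new_pos))
    calls <- cbind(calls, dup_calls[, fresh, drop = FALSE])
    chrom <- c(chrom, chrom[src][fresh])
    pos <- c(pos, new_pos[fresh])
  }

  if (config$missing_rate > 0) {
    calls[matrix(stats::runif(length(calls)) < config$missing_rate,
                 nrow(calls), ncol(calls))] <- NA_integer_
  }

  ref_alt <- matrix(c("A", "G"), length(pos), 2, byrow = TRUE)
  gm <- geno_matrix(
    calls,
    data.frame(chrom = chrom, pos = pos,
               site_id = paste0("snp", seq_along(pos)),
               ref = ref_alt[, 1], alt = ref_alt[, 2],
               stringsAsFactors = FALSE),
    data.frame(sample_id = sample_id, breed = breeds, sex = sex,
               stringsAsFactors = FALSE)
  )
  if (!is.null(vcf_path)) write_vcf(gm, vcf_path)
  if (!is.null(sample_table_path)) write_sample_table(gm, sample_table_path)
  gm
}

#' Plant a homozygous tract in one sample
#'
#' Within `[start, end]` on `chrom`, the sample's calls are replaced by
#' homozygous genotypes (the allele drawn per site with probability equal
#' to its observed alt frequency: no heterozygotes remain); missing calls
#' are preserved.  The tract is recorded in the `planted_tracts` attribute
#' as ground truth for ROH recovery checks.
#'
#' @param gm a [geno_matrix()].
#' @param sample_id target sample.
#' @param chrom,start,end tract location (1-based inclusive); must contain
#'   at least 2 sites.
#' @param seed integer seed for the per-site allele draws.
#' @return The modified `geno_matrix` with an updated `planted_tracts`
#'   attribute.
#' @export
plant_roh <- function(gm, sample_id, chrom, start, end, seed) {
  row <- match(sample_id, gm$samples$sample_id)
  if (is.na(row)) stop("unknown sample: ", sample_id)
  idx <- which(gm$sites$chrom == chrom & gm$sites$pos >= start &
                 gm$sites$pos <= end)
  if (length(idx) < 2) stop("tract region must contain at least 2 sites")
  set.seed(seed)
  p <- site_stats(gm)$p_alt[idx]
  p[!is.finite(p)] <- 0.5
  hom <- ifelse(stats::runif(length(idx)) < p, 2L, 0L)
  keep_na <- is.na(gm$calls[row, idx])
  hom[keep_na] <- NA_integer_
  gm$calls[row, idx] <- hom
  truth <- rbind(attr(gm, "planted_tracts"),
                 data.frame(sample_id = sample_id, chrom = chrom,
                            start = start, end = end,
                            first_snp = gm$sites$pos[idx[1]],
                            last_snp = gm$sites$pos[idx[length(idx)]],
                            n_snps = length(idx), stringsAsFactors = FALSE))
  attr(gm, "planted_tracts") <- truth
  gm
}

#' Label random candidate categories on simulated sites
#'
#' Draws disjoint random site subsets as `trait_related` and `common`
#' candidates; the remaining sites with observed MAF > 0.2 become
#' `wgs_polymorphic` candidates.
#'
#' @param gm a [geno_matrix()].
#' @param fractions named fractions for `trait_related` and `common`
#'   (summing to at most 1).
#' @param seed integer seed.
#' @return data.frame (`chrom`, `pos`, `site_id`, `category`, `maf`)
#'   suitable for [assign_priorities()].
#' @export
label_candidates <- function(gm, fractions = c(trait_related = 0.1, common = 0.2),
                             seed) {
  stopifnot(all(names(fractions) %in% c("trait_related", "common")),
            sum(fractions) <= 1)
  set.seed(seed)
  n <- n_sites(gm)
  st <- site_stats(gm)
  n_trait <- floor(n * fractions[["trait_related"]])
  n_common <- floor(n * fractions[["common"]])
  perm <- sample.int(n)
  trait <- perm[seq_len(n_trait)]
  common <- perm[n_trait + seq_len(n_common)]
  rest <- perm[-seq_len(n_trait + n_common)]
  wgs <- rest[st$defined[rest] & st$maf[rest] > 0.2]
  pick <- function(idx, cat) {
    data.frame(chrom = gm$sites$chrom[idx], pos = gm$sites$pos[idx],
               site_id = gm$sites$site_id[idx], category = cat,
               maf = st$maf[idx], stringsAsFactors = FALSE)
  }
  out <- rbind(pick(trait, "trait_related"), pick(common, "common"),
               pick(wgs, "wgs_polymorphic"))
  out <- out[genome_order(out$chrom, out$pos, gm$chrom_levels), , drop = FALSE]
  rownames(out) <- NULL
  out
}
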