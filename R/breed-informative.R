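#' Per-breed allele frequencies
#'
#' Missing-excluded alt-allele frequency and non-missing allele count per
#' site and breed.  At least two breeds are required, since every downstream
#' statistic compares breeds.
#'
#' @param gm a [geno_matrix()] whose samples all carry a breed label.
#' @return Object of class `breed_freq_table`: list with `p` (sites x breeds
#'   matrix of alt-allele frequencies, `NaN` where a breed has no non-missing
#'   call), `n` (non-missing *allele* counts, i.e. 2 x called samples),
#'   `sites` and `breeds`.
#' @export
breed_freqs <- function(gm) {
  breeds <- unique(gm$samples$breed)
  if (any(is.na(breeds))) stop("every sample needs a breed label")
  if (length(breeds) < 2) {
    stop("at least two breeds are required for breed comparisons")
  }
  p <- matrix(NA_real_, n_sites(gm), length(breeds),
              dimnames = list(gm$sites$site_id, breeds))
  n <- p
  for (b in breeds) {
    calls <- gm$calls[gm$samples$breed == b, , drop = FALSE]
    nc <- colSums(!is.na(calls))
    p[, b] <- colSums(calls, na.rm = TRUE) / (2 * nc)
    n[, b] <- 2 * nc
  }
  structure(list(p = p, n = n, sites = gm$sites, breeds = breeds),
            class = "breed_freq_table")
}

#' Wright's Fst for two populations
#'
#' Heterozygosity-based fixation index `(HT - HS) / HT` with
#' `HT = 2 p_bar (1 - p_bar)`, `p_bar = (p1 + p2) / 2`, and
#' `HS = (2 p1 (1 - p1) + 2 p2 (1 - p2)) / 2` (unweighted, no sample-size
#' correction).  Returns 0 when `HT = 0` (both populations fixed for the
#' same allele).  Vectorised over sites.
#'
#' @param p1,p2 allele frequencies in `[0, 1]`.
#' @return Fst values in `[0, 1]`.
#' @export
wright_fst <- function(p1, p2) {
  stop_if_not_prob(p1, "p1"); stop_if_not_prob(p2, "p2")
  pbar <- (p1 + p2) / 2
  ht <- 2 * pbar * (1 - pbar)
  hs <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
  out <- ifelse(ht > 0, (ht - hs) / ht, 0)
  pmin(pmax(out, 0), 1)
}

#' Multi-locus Wright's Fst
#'
#' Ratio-of-sums average over loci, `sum(HT - HS) / sum(HT)`, the standard
#' way of combining the per-locus heterozygosity components.  Under the
#' Balding-Nichols model with two populations of differentiation parameter
#' `F`, the expected value of this estimator is `F / (2 - F)`.
#'
#' @inheritParams wright_fst
#' @return A single Fst value in `[0, 1]`.
#' @export
multilocus_fst <- function(p1, p2) {
  stop_if_not_prob(p1, "p1"); stop_if_not_prob(p2, "p2")
  pbar <- (p1 + p2) / 2
  ht <- 2 * pbar * (1 - pbar)
  hs <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
  if (sum(ht) <= 0) return(0)
  min(max(sum(ht - hs) / sum(ht), 0), 1)
}

#' Absolute allele-frequency difference (delta)
#'
#' @inheritParams wright_fst
#' @return `|p1 - p2|`, vectorised.
#' @export
delta_stat <- function(p1, p2) {
  stop_if_not_prob(p1, "p1"); stop_if_not_prob(p2, "p2")
  abs(p1 - p2)
}

#' Rosenberg's informativeness for assignment (In)
#'
#' Entropy-based marker informativeness across `K` populations.  Over both
#' alleles `j` with across-population mean frequency `p_bar_j`,
#' `In = sum_j ( -p_bar_j ln p_bar_j + (1/K) sum_i p_ij ln p_ij )`, with the
#' convention `0 ln 0 = 0` and natural logarithms.  For `K = 2` the maximum
#' is `ln 2`, attained at fixed differences.
#'
#' @param p numeric vector of length `K >= 2` (one site) or a sites x `K`
#'   matrix of allele frequencies.
#' @return Non-negative In value(s); one per row when `p` is a matrix.
#' @export
informativeness_in <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  if (ncol(p) < 2) stop("In requires frequencies from at least 2 populations")
  stop_if_not_prob(as.vector(p), "p")
  pbar <- rowMeans(p)
  res <- -xlogx(pbar) - xlogx(1 - pbar) +
    rowMeans(matrix(xlogx(p), nrow = nrow(p))) +
    rowMeans(matrix(xlogx(1 - p), nrow = nrow(p)))
  pmax(res, 0)
}

#' Score every site for every breed pair with the three statistics
#'
#' @param bf a [breed_freqs()] table.
#' @param statistics subset of `c("fst", "delta", "in")`.
#' @param comparisons optional 2-column character matrix of breed pairs; by
#'   default all unordered pairs are scored.
#' @return Long data.frame: `chrom`, `pos`, `site_id`, `statistic`,
#'   `comparison` (`"breedA|breedB"`), `value`.  Sites where either breed has
#'   no non-missing call get `NA` values.
#' @export
score_breed_sites <- function(bf, statistics = c("fst", "delta", "in"),
                              comparisons = NULL) {
  stopifnot(inherits(bf, "breed_freq_table"))
  statistics <- match.arg(statistics, c("fst", "delta", "in"), several.ok = TRUE)
  if (is.null(comparisons)) {
    comparisons <- t(utils::combn(bf$breeds, 2))
  }
  out <- vector("list", nrow(comparisons) * length(statistics))
  k <- 0
  for (i in seq_len(nrow(comparisons))) {
    b1 <- comparisons[i, 1]; b2 <- comparisons[i, 2]
    p1 <- bf$p[, b1]; p2 <- bf$p[, b2]
    ok <- is.finite(p1) & is.finite(p2)
    cmp <- paste(b1, b2, sep = "|")
    for (s in statistics) {
      val <- rep(NA_real_, length(p1))
      val[ok] <- switch(s,
        fst = wright_fst(p1[ok], p2[ok]),
        delta = delta_stat(p1[ok], p2[ok]),
        `in` = informativeness_in(cbind(p1[ok], p2[ok]))
      )
      k <- k + 1
      out[[k]] <- data.frame(
        chrom = bf$sites$chrom, pos = bf$sites$pos,
        site_id = bf$sites$site_id, statistic = s, comparison = cmp,
        value = val, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Top-N sites per statistic and comparison, pooled by union
#'
#' For each (statistic, comparison) stratum the `n` highest-scoring sites are
#' taken (ties broken deterministically by chromosome index, then position);
#' the candidate pool is the union of sites across strata, so markers
#' informative for any contrast are preserved.
#'
#' @param scores long score table from [score_breed_sites()].
#' @param n number of sites per stratum; when `n` exceeds the available sites
#'   all are returned with a warning.
#' @return data.frame of unique sites (`chrom`, `pos`, `site_id`,
#'   `n_strata` = number of top-N lists containing the site), genome-ordered.
#' @export
rank_top_sites <- function(scores, n) {
  stopifnot(n >= 1)
  scores <- scores[!is.na(scores$value), , drop = FALSE]
  chrom_levels <- unique(scores$chrom)
  strata <- split(scores, paste(scores$statistic, scores$comparison))
  picks <- lapply(strata, function(s) {
    if (n > nrow(s)) {
      warning(sprintf("requested top %d of %d available sites", n, nrow(s)))
    }
    ord <- order(-s$value, match(s$chrom, chrom_levels), s$pos)
    s[utils::head(ord, n), c("chrom", "pos", "site_id"), drop = FALSE]
  })
  all <- do.call(rbind, picks)
  key <- paste(all$chrom, all$pos)
  counts <- table(key)
  uniq <- all[!duplicated(key), , drop = FALSE]
  uniq$n_strata <- as.integer(counts[paste(uniq$chrom, uniq$pos)])
  uniq <- uniq[genome_order(uniq$chrom, uniq$pos, chrom_levels), , drop = FALSE]
  rownames(uniq) <- NULL
  uniq
}

#' Breed-separation report for a candidate subset
#'
#' Runs scaled-genotype PCA on the subset and scores how well the first two
#' principal components separate breed labels (mean silhouette width).
#'
#' @param gm a [geno_matrix()] with at least two breeds.
#' @param subset character vector of site ids, or a data.frame with `chrom`
#'   and `pos` columns.
#' @return list with `n_sites`, `pct_var` (PC1/PC2 percent variance) and
#'   `silhouette` (mean silhouette width of breed labels in PC1-PC2 space).
#' @export
evaluate_subset <- function(gm, subset) {
  if (is.data.frame(subset)) {
    idx <- match(paste(subset$chrom, subset$pos),
                 paste(gm$sites$chrom, gm$sites$pos))
  } else {
    idx <- match(subset, gm$sites$site_id)
  }
  if (any(is.na(idx))) stop("subset contains sites absent from the matrix")
  if (length(idx) < 2) stop("subset must contain at least 2 sites")
  sub <- subset_sites(gm, idx)
  pca <- pca_genotypes(sub, n_components = 2)
  lab <- as.integer(factor(sub$samples$breed))
  if (length(unique(lab)) < 2) stop("silhouette needs at least two breeds")
  sil <- cluster::silhouette(lab, stats::dist(pca$scores[, 1:2, drop = FALSE]))
  list(n_sites = length(idx), pct_var = pca$pct_var[1:2],
       silhouette = mean(sil[, "sil_width"]))
}

#' Choose the candidate-pool size by the silhouette plateau rule
#'
#' Evaluates [rank_top_sites()] pools at several sizes and picks the smallest
#' size whose breed silhouette is within `tol` of the maximum across the
#' tested sizes.
#'
#' @param gm a [geno_matrix()].
#' @param scores score table from [score_breed_sites()].
#' @param sizes candidate per-stratum sizes, default `c(1000, 2000, 3000,
#'   4000, 5000)`.
#' @param tol silhouette plateau tolerance, default 0.02.
#' @return list with `chosen_n`, `table` (size / pool size / silhouette) and
#'   `sites` (the chosen pool).
#' @export
select_candidate_pool <- function(gm, scores, sizes = c(1000, 2000, 3000, 4000, 5000),
                                  tol = 0.02) {
  rows <- lapply(sizes, function(nn) {
    pool <- rank_top_sites(scores, nn)
    ev <- evaluate_subset(gm, pool)
    data.frame(n = nn, pool_size = nrow(pool), silhouette = ev$silhouette)
  })
  tab <- do.call(rbind, rows)
  best <- max(tab$silhouette)
  chosen <- tab$n[which(tab$silhouette >= best - tol)[1]]
  list(chosen_n = chosen, table = tab,
       sites = rank_top_sites(scores, chosen))
}
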