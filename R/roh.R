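#' Sliding-window ROH detection parameters
#'
#' PLINK-style parameter set for runs-of-homozygosity detection: minimum run
#' length 1 Mb, maximum gap between consecutive SNPs 1 Mb, minimum density
#' of 1 SNP per 100 kb, 50-SNP sliding windows tolerating 1 heterozygous and
#' 5 missing calls, window hit-proportion threshold 0.01, and significance
#' level 0.05 for the minimum-SNP-count equation.
#'
#' @param min_len_bp minimum run length in bp.
#' @param max_gap_bp maximum gap between consecutive SNPs in a run, bp.
#' @param min_density_bp_per_snp maximum bp per SNP inside a run.
#' @param window_snps sliding window size, in SNPs.
#' @param max_het_per_window heterozygous calls tolerated per window.
#' @param max_missing_per_window missing calls tolerated per window.
#' @param window_threshold minimum proportion of homozygous windows covering
#'   a SNP for it to be considered part of a run.
#' @param alpha significance level feeding [min_snp_count()].
#' @return list of class `roh_params`.
#' @export
roh_params <- function(min_len_bp = 1e6, max_gap_bp = 1e6,
                       min_density_bp_per_snp = 1e5, window_snps = 50,
                       max_het_per_window = 1, max_missing_per_window = 5,
                       window_threshold = 0.01, alpha = 0.05) {
  p <- list(min_len_bp = min_len_bp, max_gap_bp = max_gap_bp,
            min_density_bp_per_snp = min_density_bp_per_snp,
            window_snps = as.integer(window_snps),
            max_het_per_window = max_het_per_window,
            max_missing_per_window = max_missing_per_window,
            window_threshold = window_threshold, alpha = alpha)
  pos_pars <- c("min_len_bp", "max_gap_bp", "min_density_bp_per_snp",
                "window_snps", "alpha")
  if (any(unlist(p[pos_pars]) <= 0)) {
    stop("ROH length/gap/density/window/alpha parameters must be positive")
  }
  if (p$max_het_per_window < 0 || p$max_missing_per_window < 0) {
    stop("per-window het/missing allowances must be non-negative")
  }
  if (p$window_threshold <= 0 || p$window_threshold > 1) {
    stop("window_threshold must be in (0, 1]")
  }
  class(p) <- "roh_params"
  p
}

#' Minimum number of SNPs required to call a ROH
#'
#' `L = ceiling( ln(alpha / (ns * ni)) / ln(1 - het) )`, where `ns` is the
#' number of genotyped SNPs per animal, `ni` the number of animals, `alpha`
#' the tolerated probability of a chance run, and `het` the mean
#' heterozygosity across SNPs.  The ceiling keeps the probability guarantee
#' conservative.
#'
#' @param ns genotyped SNPs per animal (>= 1).
#' @param ni number of genotyped animals (>= 1).
#' @param het mean heterozygosity across SNPs, strictly inside (0, 1).
#' @param alpha significance level in (0, 1), default 0.05.
#' @return Integer minimum SNP count `L`.
#' @export
min_snp_count <- function(ns, ni, het, alpha = 0.05) {
  stopifnot(ns >= 1, ni >= 1, alpha > 0, alpha < 1)
  if (!is.finite(het) || het <= 0 || het >= 1) {
    stop("`het` must lie strictly inside (0, 1)")
  }
  # small tolerance so exact integer ratios are not pushed up by the
  # floating-point representation of 1 - het
  as.integer(ceiling(log(alpha / (ns * ni)) / log(1 - het) - 1e-9))
}

#' Per-SNP homozygosity flags from 50-SNP sliding windows
#'
#' Slides a `window_snps`-wide window over one sample's calls on one
#' chromosome.  A window is homozygous when it contains at most
#' `max_het_per_window` heterozygous and at most `max_missing_per_window`
#' missing calls.  Each SNP is scored by the proportion of windows covering
#' it that are homozygous, and flagged when that proportion reaches
#' `window_threshold`.  Chromosomes with fewer SNPs than the window size are
#' scored against the single truncated window instead of being dropped.
#'
#' @param calls integer vector of genotype codes (`0/1/2/NA`) for one sample
#'   on one chromosome.
#' @param positions strictly increasing bp positions aligned to `calls`.
#' @param params a [roh_params()] set.
#' @return Logical vector of per-SNP flags with attribute `score` (the hit
#'   proportions).
#' @export
window_homozygosity_flags <- function(calls, positions, params = roh_params()) {
  n <- length(calls)
  stopifnot(n == length(positions), n >= 1)
  if (is.unsorted(positions, strictly = TRUE)) {
    stop("positions must be strictly increasing")
  }
  het <- !is.na(calls) & calls == 1L
  mis <- is.na(calls)
  k <- params$window_snps
  if (n < k) {
    pass <- sum(het) <= params$max_het_per_window &&
      sum(mis) <= params$max_missing_per_window
    score <- rep(as.numeric(pass), n)
  } else {
    w <- n - k + 1
    ch <- cumsum(het); cm <- cumsum(mis)
    het_in <- ch[k:n] - c(0, ch)[1:w]
    mis_in <- cm[k:n] - c(0, cm)[1:w]
    pass <- het_in <= params$max_het_per_window &
      mis_in <= params$max_missing_per_window
    cp <- c(0, cumsum(pass))
    i <- seq_len(n)
    lo <- pmax(1L, i - k + 1L)        # first window index covering SNP i
    hi <- pmin(w, i)                  # last window index covering SNP i
    score <- (cp[hi + 1L] - cp[lo]) / (hi - lo + 1L)
  }
  flags <- score >= params$window_threshold
  attr(flags, "score") <- score
  flags
}

#' Call ROH segments from per-SNP flags
#'
#' Maximal stretches of flagged SNPs are split where the gap between
#' consecutive SNPs exceeds `max_gap_bp`; segment ends are trimmed to
#' homozygous calls when `calls` are supplied (runs of homozygosity start
#' and end on a homozygous genotype); surviving stretches are kept when they
#' span at least `min_len_bp`, contain at least `L` SNPs and satisfy the
#' density bound `length / n_snps <= min_density_bp_per_snp`.
#'
#' @param flags logical per-SNP flags from [window_homozygosity_flags()].
#' @param positions bp positions aligned to `flags`.
#' @param params a [roh_params()] set.
#' @param L minimum SNP count (from [min_snp_count()]).
#' @param calls optional genotype codes used to trim segment ends to
#'   homozygous calls; `NULL` disables trimming.
#' @return data.frame of segments: `start`, `end`, `n_snps`, `length_bp`.
#' @export
call_roh <- function(flags, positions, params = roh_params(), L = 1L,
                     calls = NULL) {
  stopifnot(length(flags) == length(positions))
  if (!length(flags) || !any(flags)) {
    return(data.frame(start = integer(0), end = integer(0),
                      n_snps = integer(0), length_bp = numeric(0)))
  }
  idx <- which(flags)
  brk <- c(TRUE, diff(idx) > 1 | diff(positions[idx]) > params$max_gap_bp)
  grp <- cumsum(brk)
  segs <- lapply(split(idx, grp), function(ii) {
    if (!is.null(calls)) {
      hom <- !is.na(calls[ii]) & calls[ii] != 1L
      if (!any(hom)) return(NULL)
      ii <- ii[seq(which(hom)[1], utils::tail(which(hom), 1))]
    }
    n <- length(ii)
    len <- positions[ii[n]] - positions[ii[1]] + 1
    if (len >= params$min_len_bp && n >= L &&
        len / n <= params$min_density_bp_per_snp) {
      data.frame(start = positions[ii[1]], end = positions[ii[n]],
                 n_snps = n, length_bp = len)
    } else NULL
  })
  out <- do.call(rbind, segs)
  if (is.null(out)) {
    out <- data.frame(start = integer(0), end = integer(0),
                      n_snps = integer(0), length_bp = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Detect runs of homozygosity across a genotype matrix
#'
#' Applies [window_homozygosity_flags()] and [call_roh()] per sample and
#' autosome.  The minimum SNP count `L` defaults to [min_snp_count()] with
#' `ns` = number of sites, `ni` = number of samples and `het` = mean per-site
#' observed heterozygosity.
#'
#' @param gm a [geno_matrix()].
#' @param params a [roh_params()] set.
#' @param L minimum SNP count; computed from the data when `NULL`.
#' @param exclude_chroms chromosomes excluded from calling (sex chromosomes
#'   and mitochondrion by default; the analysis targets autosomes).
#' @param trim_ends trim segment ends to homozygous calls (default `TRUE`).
#' @return data.frame of segments (`sample_id`, `breed`, `chrom`, `start`,
#'   `end`, `n_snps`, `length_bp`) with attributes `L`, `het` and `params`.
#' @export
detect_roh <- function(gm, params = roh_params(), L = NULL,
                       exclude_chroms = c("X", "Y", "MT", "chrX", "chrY", "chrM"),
                       trim_ends = TRUE) {
  keep <- !(gm$sites$chrom %in% exclude_chroms)
  if (!all(keep)) gm <- subset_sites(gm, keep)
  st <- site_stats(gm)
  het <- mean(st$het_rate[st$defined])
  if (is.null(L)) L <- min_snp_count(n_sites(gm), n_samples(gm), het, params$alpha)
  chroms <- gm$chrom_levels[gm$chrom_levels %in% unique(gm$sites$chrom)]
  res <- list()
  for (ch in chroms) {
    ci <- which(gm$sites$chrom == ch)
    pos <- gm$sites$pos[ci]
    for (s in seq_len(n_samples(gm))) {
      calls <- gm$calls[s, ci]
      flags <- window_homozygosity_flags(calls, pos, params)
      seg <- call_roh(flags, pos, params, L,
                      calls = if (trim_ends) calls else NULL)
      if (nrow(seg)) {
        seg$sample_id <- gm$samples$sample_id[s]
        seg$breed <- gm$samples$breed[s]
        seg$chrom <- ch
        res[[length(res) + 1]] <- seg
      }
    }
  }
  out <- if (length(res)) do.call(rbind, res) else {
    data.frame(start = integer(0), end = integer(0), n_snps = integer(0),
               length_bp = numeric(0), sample_id = character(0),
               breed = character(0), chrom = character(0))
  }
  out <- out[, c("sample_id", "breed", "chrom", "start", "end", "n_snps",
                 "length_bp")]
  rownames(out) <- NULL
  attr(out, "L") <- L
  attr(out, "het") <- het
  attr(out, "params") <- params
  out
}

#' Per-sample and per-breed ROH summaries
#'
#' @param segments segment table from [detect_roh()].
#' @param samples sample table (`sample_id`, `breed`); samples without
#'   segments appear with zero counts rather than being dropped.
#' @param autosome_len total autosomal length in bp (coverage denominator).
#' @return list with `per_sample` (count, total/mean length, coverage) and
#'   `per_breed` (means of the per-sample quantities).
#' @export
roh_summary <- function(segments, samples, autosome_len) {
  stopifnot(autosome_len > 0)
  per <- lapply(seq_len(nrow(samples)), function(i) {
    seg <- segments[segments$sample_id == samples$sample_id[i], , drop = FALSE]
    tot <- sum(seg$length_bp)
    data.frame(
      sample_id = samples$sample_id[i], breed = samples$breed[i],
      n_roh = nrow(seg), total_bp = tot,
      mean_bp = if (nrow(seg)) tot / nrow(seg) else 0,
      coverage = tot / autosome_len, stringsAsFactors = FALSE
    )
  })
  per_sample <- do.call(rbind, per)
  agg <- function(v) tapply(v, per_sample$breed, mean)
  per_breed <- data.frame(
    breed = names(agg(per_sample$n_roh)),
    mean_n_roh = as.numeric(agg(per_sample$n_roh)),
    mean_total_bp = as.numeric(agg(per_sample$total_bp)),
    mean_coverage = as.numeric(agg(per_sample$coverage)),
    stringsAsFactors = FALSE
  )
  list(per_sample = per_sample, per_breed = per_breed)
}

#' Per-SNP ROH incidence across individuals
#'
#' For every panel SNP, the fraction of individuals having at least one ROH
#' segment covering its position (segment coverage is `[start, end]`
#' inclusive).
#'
#' @param segments segment table from [detect_roh()].
#' @param sites site table (`chrom`, `pos`), genome-sorted as in a
#'   [geno_matrix()].
#' @param n_individuals denominator (>= 1).
#' @return data.frame: `chrom`, `pos`, `incidence` in `[0, 1]`.
#' @export
snp_incidence <- function(segments, sites, n_individuals) {
  stopifnot(n_individuals >= 1)
  counts <- numeric(nrow(sites))
  for (ch in unique(segments$chrom)) {
    ci <- which(sites$chrom == ch)
    if (!length(ci)) next
    pos <- sites$pos[ci]
    seg <- segments[segments$chrom == ch, , drop = FALSE]
    # within one sample segments are disjoint, so summing segment coverage
    # counts each individual at most once per SNP
    for (j in seq_len(nrow(seg))) {
      lo <- findInterval(seg$start[j] - 0.5, pos) + 1L
      hi <- findInterval(seg$end[j] + 0.5, pos)
      if (hi >= lo) counts[ci[lo:hi]] <- counts[ci[lo:hi]] + 1
    }
  }
  data.frame(chrom = sites$chrom, pos = sites$pos,
             incidence = counts / n_individuals, stringsAsFactors = FALSE)
}

#' Call ROH islands above the top-1% incidence threshold
#'
#' The threshold is the `1 - top_pct` empirical quantile of the per-SNP
#' incidence values; islands are maximal runs of consecutive panel SNPs (in
#' genome order) with incidence strictly above it, requiring at least
#' `min_snps` SNPs.  Island bounds are the positions of the first and last
#' constituent SNPs.  When all incidence values are equal nothing exceeds
#' the threshold and no island is returned.
#'
#' @param incidence data.frame from [snp_incidence()].
#' @param top_pct upper tail defining the threshold, default 0.01.
#' @param min_snps minimum SNPs per island, default 2.
#' @param gap_split_bp optional bp gap above which a run of consecutive
#'   panel SNPs is split (`NULL`, the default, never splits).
#' @return list with `threshold` and `islands` (data.frame `chrom`, `start`,
#'   `end`, `n_snps`, `peak_incidence`).
#' @export
island_call <- function(incidence, top_pct = 0.01, min_snps = 2,
                        gap_split_bp = NULL) {
  if (nrow(incidence) < 100) {
    warning("fewer than 100 SNPs; the top-quantile threshold is unstable")
  }
  thr <- stats::quantile(incidence$incidence, 1 - top_pct, names = FALSE)
  above <- incidence$incidence > thr
  islands <- list()
  for (ch in unique(incidence$chrom)) {
    ci <- which(incidence$chrom == ch)
    a <- above[ci]
    if (!any(a)) next
    idx <- which(a)
    brk <- c(TRUE, diff(idx) > 1)
    if (!is.null(gap_split_bp)) {
      brk <- brk | c(FALSE, diff(incidence$pos[ci][idx]) > gap_split_bp)
    }
    for (ii in split(idx, cumsum(brk))) {
      if (length(ii) < min_snps) next
      islands[[length(islands) + 1]] <- data.frame(
        chrom = ch, start = incidence$pos[ci[ii[1]]],
        end = incidence$pos[ci[utils::tail(ii, 1)]],
        n_snps = length(ii),
        peak_incidence = max(incidence$incidence[ci[ii]]),
        stringsAsFactors = FALSE
      )
    }
  }
  islands <- if (length(islands)) do.call(rbind, islands) else {
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               n_snps = integer(0), peak_incidence = numeric(0))
  }
  rownames(islands) <- NULL
  list(threshold = thr, islands = islands)
}
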