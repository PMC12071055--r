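#' Principal component analysis of scaled genotypes
#'
#' PLINK-style genotype PCA: missing calls are mean-imputed per site, each
#' site is centred by `2p` and scaled by `sqrt(2p(1-p))` (`p` the observed
#' alt-allele frequency), monomorphic sites are dropped, and the sample
#' covariance matrix is eigendecomposed.  Component signs are fixed by
#' forcing the largest-magnitude coordinate of each component positive, so
#' results are deterministic and invariant (up to row permutation) to sample
#' order.
#'
#' @param gm a [geno_matrix()] with at least 2 samples and 2 polymorphic
#'   sites.
#' @param n_components number of components to return (default 10, capped at
#'   `n_samples - 1`).
#' @return list of class `geno_pca`: `scores` (samples x components,
#'   eigenvector scaled by the square root of its eigenvalue), `pct_var`
#'   (percent variance explained, non-increasing), `values` (eigenvalues)
#'   and `n_sites_used`.
#' @export
pca_genotypes <- function(gm, n_components = 10) {
  if (n_samples(gm) < 2) stop("PCA needs at least 2 samples")
  X <- gm$calls
  p <- colMeans(X, na.rm = TRUE) / 2
  v <- apply(X, 2, stats::var, na.rm = TRUE)
  poly <- is.finite(p) & p > 0 & p < 1 & is.finite(v) & v > 0
  if (sum(poly) < 2) stop("PCA needs at least 2 polymorphic sites")
  X <- X[, poly, drop = FALSE]
  p <- p[poly]
  mu <- 2 * p
  sdv <- sqrt(2 * p * (1 - p))
  Xs <- sweep(X, 2, mu, "-")
  Xs[is.na(Xs)] <- 0  # mean imputation after centring
  Xs <- sweep(Xs, 2, sdv, "/")
  m <- ncol(Xs)
  C <- tcrossprod(Xs) / m
  ee <- eigen(C, symmetric = TRUE)
  vals <- pmax(ee$values, 0)
  k <- min(n_components, n_samples(gm) - 1)
  vec <- ee$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (vec[which.max(abs(vec[, j])), j] < 0) vec[, j] <- -vec[, j]
  }
  scores <- sweep(vec, 2, sqrt(vals[seq_len(k)]), "*")
  rownames(scores) <- gm$samples$sample_id
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(
    list(scores = scores, pct_var = 100 * vals / sum(vals),
         values = vals, n_sites_used = m),
    class = "geno_pca"
  )
}

#' Pairwise p-distance matrix
#'
#' Allele-sharing distance: `d(i, j)` is the mean over sites where both
#' samples are called of `|g_i - g_j| / 2`.  Identical samples are at
#' distance 0 and opposite homozygotes at 1.
#'
#' @param gm a [geno_matrix()] with at least 2 samples.
#' @param allow_missing_pairs when `FALSE` (default) a sample pair with no
#'   jointly called site is an error naming the pair; when `TRUE` such pairs
#'   get `NA`.
#' @return Symmetric numeric matrix with zero diagonal, dimnames the sample
#'   ids.
#' @export
p_distance <- function(gm, allow_missing_pairs = FALSE) {
  if (n_samples(gm) < 2) stop("p-distance needs at least 2 samples")
  G <- gm$calls
  A <- list(`0` = (!is.na(G)) & G == 0L,
            `1` = (!is.na(G)) & G == 1L,
            `2` = (!is.na(G)) & G == 2L)
  A <- lapply(A, function(m) { storage.mode(m) <- "double"; m })
  nm <- A[[1]] + A[[2]] + A[[3]]
  joint <- tcrossprod(nm)
  # |gi - gj| summed over jointly-called sites, from genotype-pair counts
  n01 <- tcrossprod(A[["0"]], A[["1"]]); n12 <- tcrossprod(A[["1"]], A[["2"]])
  n02 <- tcrossprod(A[["0"]], A[["2"]])
  dsum <- (n01 + t(n01)) + (n12 + t(n12)) + 2 * (n02 + t(n02))
  D <- dsum / (2 * joint)
  diag(D) <- 0
  und <- joint == 0 & upper.tri(joint)
  if (any(und)) {
    if (!allow_missing_pairs) {
      idx <- which(und, arr.ind = TRUE)[1, ]
      stop(sprintf(
        "no jointly called sites for sample pair (%s, %s); see allow_missing_pairs",
        gm$samples$sample_id[idx[1]], gm$samples$sample_id[idx[2]]))
    }
    D[joint == 0] <- NA_real_
    diag(D) <- 0
  }
  dimnames(D) <- list(gm$samples$sample_id, gm$samples$sample_id)
  D
}

#' Write a square distance matrix in PHYLIP format
#'
#' @param dm square matrix with sample-id dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(dm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(dm)), con)
  for (i in seq_len(nrow(dm))) {
    writeLines(paste(c(format(rownames(dm)[i], width = 10),
                       sprintf("%.6f", dm[i, ])), collapse = "  "), con)
  }
  invisible(path)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration.  Negative branch lengths are clamped
#' to 0 with the deficit moved to the sister branch, so pairwise path
#' lengths are preserved.  On additive matrices the generating topology and
#' branch lengths are recovered exactly.
#'
#' @param dm symmetric square distance matrix with zero diagonal and taxon
#'   dimnames; at least 3 taxa.
#' @return Newick tree string with branch lengths (trifurcating root, the
#'   conventional unrooted representation).
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric")
  }
  labs <- rownames(dm)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  D <- dm
  node <- labs
  while (length(node) > 3) {
    m <- length(node)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    k <- arrayInd(which.min(Q), dim(Q))  # deterministic: first minimum
    i <- min(k); j <- max(k)
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_lab <- sprintf("(%s:%.17g,%s:%.17g)", node[i], li, node[j], lj)
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    node <- c(node[keep], new_lab)
  }
  # final three nodes: three-point formulas around the central vertex
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  b <- pmax(c(b1, b2, b3), 0)
  sprintf("(%s:%.17g,%s:%.17g,%s:%.17g);",
          node[1], b[1], node[2], b[2], node[3], b[3])
}

#' Linkage-disequilibrium decay curve
#'
#' Genotype-correlation LD: for every pair of sites on the same chromosome
#' within `max_dist`, r-squared is the squared Pearson correlation of the
#' dosage vectors (pairwise-complete); pairs involving a monomorphic site
#' are skipped.  Pair r-squared values are averaged within physical-distance
#' bins, and the decay distance is the linear interpolation of the first bin
#' where the mean crosses below `r2_target`.
#'
#' @param gm a [geno_matrix()].
#' @param breed optional breed label restricting the samples (>= 2 samples).
#' @param max_dist maximum pair distance in bp, default 500 kb.
#' @param bin_width distance bin width in bp, default 10 kb.
#' @param r2_target threshold whose crossing distance is reported, default
#'   0.2.
#' @return list of class `ld_curve`: `curve` (data.frame `bin_start`,
#'   `bin_mid`, `mean_r2`, `n_pairs`) and `dist_at_target` (bp, `NA` when
#'   the curve never crosses the target).
#' @export
ld_decay <- function(gm, breed = NULL, max_dist = 5e5, bin_width = 1e4,
                     r2_target = 0.2) {
  if (!is.null(breed)) {
    ids <- gm$samples$sample_id[gm$samples$breed == breed]
    if (length(ids) < 2) stop("breed must have at least 2 samples")
    gm <- subset_samples(gm, ids)
  }
  dists <- numeric(0)
  r2s <- numeric(0)
  for (ch in unique(gm$sites$chrom)) {
    ci <- which(gm$sites$chrom == ch)
    pos <- gm$sites$pos[ci]
    G <- gm$calls[, ci, drop = FALSE]
    sds <- apply(G, 2, stats::sd, na.rm = TRUE)
    m <- length(ci)
    for (a in seq_len(m - 1)) {
      if (is.na(sds[a]) || sds[a] == 0) next
      b <- a + 1
      while (b <= m && pos[b] - pos[a] <= max_dist) {
        if (!is.na(sds[b]) && sds[b] > 0) {
          r <- suppressWarnings(
            stats::cor(G[, a], G[, b], use = "pairwise.complete.obs"))
          if (is.finite(r)) {
            dists <- c(dists, pos[b] - pos[a])
            r2s <- c(r2s, r^2)
          }
        }
        b <- b + 1
      }
    }
  }
  if (!length(dists)) {
    warning("no usable site pairs within max_dist")
    return(structure(list(curve = data.frame(bin_start = numeric(0),
                                             bin_mid = numeric(0),
                                             mean_r2 = numeric(0),
                                             n_pairs = integer(0)),
                          dist_at_target = NA_real_), class = "ld_curve"))
  }
  breaks <- seq(0, max_dist + bin_width, by = bin_width)
  bin <- findInterval(dists, breaks, rightmost.closed = TRUE)
  mean_r2 <- tapply(r2s, bin, mean)
  npair <- tapply(r2s, bin, length)
  bidx <- as.integer(names(mean_r2))
  curve <- data.frame(
    bin_start = breaks[bidx], bin_mid = breaks[bidx] + bin_width / 2,
    mean_r2 = as.numeric(mean_r2), n_pairs = as.integer(npair)
  )
  curve <- curve[order(curve$bin_start), , drop = FALSE]
  rownames(curve) <- NULL
  dist_at <- NA_real_
  below <- which(curve$mean_r2 < r2_target)
  if (length(below) && below[1] > 1) {
    i <- below[1]
    x0 <- curve$bin_mid[i - 1]; x1 <- curve$bin_mid[i]
    y0 <- curve$mean_r2[i - 1]; y1 <- curve$mean_r2[i]
    dist_at <- x0 + (y0 - r2_target) / (y0 - y1) * (x1 - x0)
  } else if (length(below) && below[1] == 1) {
    dist_at <- curve$bin_mid[1]
  }
  structure(list(curve = curve, dist_at_target = dist_at), class = "ld_curve")
}
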