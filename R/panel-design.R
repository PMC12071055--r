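PRIORITY_MAP <- c(breed_specific = 1L, trait_related = 1L,
                  common = 2L, wgs_polymorphic = 3L)

#' Assign hierarchical priorities to categorised candidate sites
#'
#' Categories map to priority tiers: breed-specific and trait-related sites
#' are tier 1, common commercial-chip sites tier 2, and WGS polymorphic
#' sites (which must have MAF > 0.2) tier 3.  A physical site appearing in
#' several categories is kept once, under its highest-priority (lowest tier
#' number) category.
#'
#' @param candidates data.frame with columns `chrom`, `pos`, `category` and
#'   (required for `wgs_polymorphic` rows) `maf`; optional `site_id`, `ref`,
#'   `alt`.
#' @return data.frame of deduplicated candidates with a `priority` column,
#'   genome-ordered; attribute `n_rejected_wgs_maf` counts wgs_polymorphic
#'   rows dropped for MAF <= 0.2.
#' @export
assign_priorities <- function(candidates) {
  stopifnot(all(c("chrom", "pos", "category") %in% names(candidates)))
  bad_cat <- setdiff(unique(candidates$category), names(PRIORITY_MAP))
  if (length(bad_cat)) {
    stop("unknown candidate category: ", paste(bad_cat, collapse = ", "))
  }
  n_rej <- 0L
  is_wgs <- candidates$category == "wgs_polymorphic"
  if (any(is_wgs)) {
    if (!"maf" %in% names(candidates)) {
      stop("wgs_polymorphic candidates require a `maf` column")
    }
    reject <- is_wgs & !(candidates$maf > 0.2)
    n_rej <- sum(reject)
    if (n_rej > 0) {
      warning(sprintf("rejected %d wgs_polymorphic site(s) with MAF <= 0.2", n_rej))
      candidates <- candidates[!reject, , drop = FALSE]
    }
  }
  candidates$priority <- unname(PRIORITY_MAP[candidates$category])
  chrom_levels <- unique(as.character(candidates$chrom))
  ord <- order(match(candidates$chrom, chrom_levels), candidates$pos,
               candidates$priority)
  candidates <- candidates[ord, , drop = FALSE]
  dup <- duplicated(paste(candidates$chrom, candidates$pos))
  candidates <- candidates[!dup, , drop = FALSE]
  if (!"maf" %in% names(candidates)) candidates$maf <- NA_real_
  if (!"site_id" %in% names(candidates)) {
    candidates$site_id <- paste(candidates$chrom, candidates$pos, sep = "_")
  }
  rownames(candidates) <- NULL
  attr(candidates, "n_rejected_wgs_maf") <- n_rej
  candidates
}

#' Tile chromosomes into fixed-width windows
#'
#' Windows are 0-based half-open `[start, end)` intervals tiling each
#' chromosome from position 0; the last window of a chromosome may be short.
#'
#' @param chrom_lengths named numeric vector or data.frame (`chrom`,
#'   `length`) of chromosome lengths in bp.
#' @param width window width in bp, default 50,000.
#' @return data.frame: `window_id`, `chrom`, `start`, `end`.
#' @export
make_windows <- function(chrom_lengths, width = 50000) {
  if (!is.numeric(width) || length(width) != 1 || width <= 0) {
    stop("window width must be a positive number")
  }
  len <- as_chrom_lengths(chrom_lengths)
  out <- lapply(names(len), function(ch) {
    k <- ceiling(len[[ch]] / width)
    start <- (seq_len(k) - 1) * width
    data.frame(
      window_id = sprintf("%s:%d", ch, seq_len(k) - 1L),
      chrom = ch, start = start, end = pmin(start + width, len[[ch]]),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Positional-variance spacing criterion for a pair of SNPs in a window
#'
#' For a window spanning `[S, E]` and two SNP positions `Ni < Nj` inside it,
#' returns the population variance of the four positions,
#' `((S - m)^2 + (Ni - m)^2 + (Nj - m)^2 + (E - m)^2) / 4` with
#' `m = (S + Ni + Nj + E) / 4`.  The pair retained in a window is the one
#' minimising this quantity.  Vectorised.
#'
#' @param s,e window start and end (bp).
#' @param ni,nj SNP positions with `s <= ni < nj <= e`.
#' @return Non-negative spacing score(s).
#' @export
sd2_spacing <- function(s, e, ni, nj) {
  if (any(ni >= nj)) stop("sd2_spacing requires ni < nj")
  if (any(ni < s | nj > e)) stop("SNP positions must lie within [s, e]")
  m <- (s + ni + nj + e) / 4
  ((s - m)^2 + (ni - m)^2 + (nj - m)^2 + (e - m)^2) / 4
}

# exhaustive SD2 minimisation over candidate pairs in one window;
# ties: higher-priority pair (smaller tier sum), then leftmost (Ni, then Nj)
best_sd2_pair <- function(s, e, pos, priority) {
  pairs <- utils::combn(seq_along(pos), 2)
  i <- pairs[1, ]; j <- pairs[2, ]
  swap <- pos[i] > pos[j]
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  sd2 <- sd2_spacing(s, e, pos[i], pos[j])
  psum <- priority[i] + priority[j]
  ord <- order(sd2, psum, pos[i], pos[j])
  k <- ord[1]
  list(idx = c(i[k], j[k]), sd2 = sd2[k])
}

#' Apply the per-window selection rule
#'
#' One candidate: kept (`kept_single`).  Two or more: the pair minimising
#' [sd2_spacing()] over all candidate pairs (`sd2_pair`; ties broken by
#' higher priority sum, then leftmost pair).  None: the single
#' highest-priority site from the supplement pool, ties by higher MAF then
#' leftmost (`filled`); with an empty pool the window stays `empty`.
#'
#' @param window one-row data.frame (or list) with `chrom`, `start`, `end`.
#' @param candidates data.frame of candidate sites inside the window
#'   (columns `pos`, `priority`, ...).
#' @param supplement_pool optional data.frame of QC-passing non-candidate
#'   sites inside the window (columns `pos`, `priority`, `maf`, ...).
#' @return list with `selected` (data.frame of chosen rows), `rule` and
#'   `sd2` (`NA` unless the pair rule fired).
#' @export
select_window_sites <- function(window, candidates, supplement_pool = NULL) {
  s <- window$start; e <- window$end
  in_win <- function(df) all(df$pos > s & df$pos <= e)
  if (nrow(candidates) && !in_win(candidates)) {
    stop("candidate positions outside the window")
  }
  if (!is.null(supplement_pool) && nrow(supplement_pool) &&
      !in_win(supplement_pool)) {
    stop("supplement positions outside the window")
  }
  n <- nrow(candidates)
  if (n == 1) {
    return(list(selected = candidates, rule = "kept_single", sd2 = NA_real_))
  }
  if (n >= 2) {
    best <- best_sd2_pair(s, e, candidates$pos, candidates$priority)
    sel <- candidates[best$idx, , drop = FALSE]
    sel <- sel[order(sel$pos), , drop = FALSE]
    return(list(selected = sel, rule = "sd2_pair", sd2 = best$sd2))
  }
  if (!is.null(supplement_pool) && nrow(supplement_pool) > 0) {
    maf <- supplement_pool$maf
    if (is.null(maf)) maf <- rep(NA_real_, nrow(supplement_pool))
    ord <- order(supplement_pool$priority, -ifelse(is.na(maf), -Inf, maf),
                 supplement_pool$pos)
    return(list(selected = supplement_pool[ord[1], , drop = FALSE],
                rule = "filled", sd2 = NA_real_))
  }
  list(selected = candidates[0, , drop = FALSE], rule = "empty",
       sd2 = NA_real_)
}

#' Build a reduced panel by windowed priority filling
#'
#' Tiles the genome into windows ([make_windows()]), then applies
#' [select_window_sites()] to every window: singleton candidates are kept,
#' crowded windows are thinned to the SD2-minimising pair, and candidate-free
#' windows are filled with one site from the supplement pool (highest
#' priority, then MAF, then position) when one is supplied.
#'
#' @param candidates candidate table from [assign_priorities()].
#' @param chrom_lengths chromosome lengths (vector or data.frame); every
#'   candidate chromosome must be present.
#' @param width window width in bp, default 50,000.
#' @param supplement optional data.frame of QC-passing non-candidate sites
#'   (`chrom`, `pos`, `priority`, `maf`) used to fill empty windows.
#' @param cap_exempt_priority1 when `TRUE`, priority-1 sites are all kept and
#'   the two-per-window rule is applied to priority 2-3 candidates only (in
#'   windows with no priority-1 site).  Default `FALSE` (literal rule).
#' @return Object of class `panel_design`: list with `selected` (panel
#'   table: site columns plus `window_id`, `rule`), `audit` (one row per
#'   window: rule applied, SD2 value, candidate count), `windows`, `counts`
#'   (per category) and `params`.
#' @export
build_panel <- function(candidates, chrom_lengths, width = 50000,
                        supplement = NULL, cap_exempt_priority1 = FALSE) {
  len <- as_chrom_lengths(chrom_lengths)
  bad <- setdiff(unique(candidates$chrom), names(len))
  if (length(bad)) {
    stop("candidate chromosome(s) absent from chromosome lengths: ",
         paste(bad, collapse = ", "))
  }
  if (!"priority" %in% names(candidates)) {
    stop("candidates must carry a `priority` column; run assign_priorities()")
  }
  windows <- make_windows(len, width)

  exempt <- NULL
  if (cap_exempt_priority1) {
    exempt <- candidates[candidates$priority == 1L, , drop = FALSE]
    candidates <- candidates[candidates$priority != 1L, , drop = FALSE]
  }

  win_of <- function(df) {
    wi <- (df$pos - 1) %/% width
    sprintf("%s:%d", df$chrom, wi)
  }
  if (cap_exempt_priority1 && nrow(exempt)) {
    # a priority-1 site claims its window; lower tiers there are not considered
    candidates <- candidates[!(win_of(candidates) %in% win_of(exempt)), ,
                             drop = FALSE]
  }

  cand_win <- win_of(candidates)
  widx <- match(cand_win, windows$window_id)
  if (any(is.na(widx))) stop("candidate position beyond chromosome length")

  sel_list <- list()
  audit <- data.frame(
    window_id = windows$window_id, chrom = windows$chrom,
    start = windows$start, end = windows$end,
    n_candidates = 0L, rule = "empty", sd2 = NA_real_,
    stringsAsFactors = FALSE
  )
  cnt <- tabulate(widx, nbins = nrow(windows))
  audit$n_candidates <- cnt

  # fast path: windows with exactly one candidate
  one <- cnt[widx] == 1L
  if (any(one)) {
    keep <- candidates[one, , drop = FALSE]
    keep$window_id <- cand_win[one]
    keep$rule <- "kept_single"
    sel_list[["single"]] <- keep
    audit$rule[cnt == 1L] <- "kept_single"
  }

  # fast path: windows with exactly two candidates (the pair is forced)
  two <- cnt[widx] == 2L
  if (any(two)) {
    c2 <- candidates[two, , drop = FALSE]
    w2 <- widx[two]
    ord <- order(w2, c2$pos)
    c2 <- c2[ord, , drop = FALSE]; w2 <- w2[ord]
    first <- seq(1, nrow(c2), by = 2)
    sd2 <- sd2_spacing(windows$start[w2[first]], windows$end[w2[first]],
                       c2$pos[first], c2$pos[first + 1])
    c2$window_id <- windows$window_id[w2]
    c2$rule <- "sd2_pair"
    sel_list[["pairs"]] <- c2
    audit$rule[w2[first]] <- "sd2_pair"
    audit$sd2[w2[first]] <- sd2
  }

  # general path: three or more candidates, exhaustive pair search
  many_w <- which(cnt >= 3L)
  if (length(many_w)) {
    groups <- split(which(widx %in% many_w), widx[widx %in% many_w])
    many_sel <- lapply(names(groups), function(wid) {
      w <- as.integer(wid)
      rows <- candidates[groups[[wid]], , drop = FALSE]
      res <- select_window_sites(windows[w, ], rows)
      out <- res$selected
      out$window_id <- windows$window_id[w]
      out$rule <- res$rule
      audit$rule[w] <<- res$rule
      audit$sd2[w] <<- res$sd2
      out
    })
    sel_list[["many"]] <- do.call(rbind, many_sel)
  }

  # empty-window fill from the supplement pool: one site per window,
  # ordered by priority tier, then MAF (desc), then position
  if (!is.null(supplement) && nrow(supplement)) {
    if (!"priority" %in% names(supplement)) supplement$priority <- 3L
    if (!"maf" %in% names(supplement)) supplement$maf <- NA_real_
    sup_win <- win_of(supplement)
    sup_idx <- match(sup_win, windows$window_id)
    blocked <- if (cap_exempt_priority1 && !is.null(exempt) && nrow(exempt)) {
      win_of(exempt)
    } else character(0)
    ok <- !is.na(sup_idx) & cnt[sup_idx] == 0L & !(sup_win %in% blocked)
    sup <- supplement[ok, , drop = FALSE]
    sup_idx <- sup_idx[ok]
    if (nrow(sup)) {
      ord <- order(sup_idx, sup$priority,
                   -ifelse(is.na(sup$maf), -Inf, sup$maf), sup$pos)
      sup <- sup[ord, , drop = FALSE]; sup_idx <- sup_idx[ord]
      first <- !duplicated(sup_idx)
      fill <- sup[first, , drop = FALSE]
      fill$window_id <- windows$window_id[sup_idx[first]]
      fill$rule <- "filled"
      if (!"category" %in% names(fill)) fill$category <- "supplement"
      sel_list[["filled"]] <- fill
      audit$rule[sup_idx[first]] <- "filled"
    }
  }

  if (cap_exempt_priority1 && nrow(exempt)) {
    exempt$window_id <- win_of(exempt)
    exempt$rule <- "kept_priority1"
    sel_list[["exempt"]] <- exempt
  }

  common_cols <- Reduce(intersect, lapply(sel_list, names))
  selected <- do.call(rbind, lapply(sel_list, function(d) d[, common_cols, drop = FALSE]))
  if (is.null(selected)) {
    selected <- cbind(candidates[0, , drop = FALSE],
                      window_id = character(0), rule = character(0))
  }
  selected <- selected[genome_order(selected$chrom, selected$pos, names(len)), ,
                       drop = FALSE]
  rownames(selected) <- NULL

  counts <- if ("category" %in% names(selected)) {
    table(selected$category)
  } else {
    table(selected$priority)
  }
  structure(
    list(selected = selected, audit = audit, windows = windows,
         counts = counts,
         params = list(width = width,
                       cap_exempt_priority1 = cap_exempt_priority1)),
    class = "panel_design"
  )
}

#' @exportS3Method base::print
print.panel_design <- function(x, ...) {
  cat(sprintf("panel_design: %d sites over %d windows (width %g bp)\n",
              nrow(x$selected), nrow(x$audit), x$params$width))
  cat("rules:\n")
  print(table(x$audit$rule))
  cat("categories:\n")
  print(x$counts)
  invisible(x)
}

#' Write panel outputs (TSV and 0-based half-open BED)
#'
#' @param panel a [build_panel()] result.
#' @param prefix output path prefix; writes `<prefix>.panel.tsv`,
#'   `<prefix>.panel.bed` and `<prefix>.audit.tsv`.
#' @return The three paths, invisibly.
#' @export
write_panel <- function(panel, prefix) {
  tsv <- paste0(prefix, ".panel.tsv")
  bed <- paste0(prefix, ".panel.bed")
  aud <- paste0(prefix, ".audit.tsv")
  utils::write.table(panel$selected, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  bed_df <- data.frame(chrom = panel$selected$chrom,
                       start = panel$selected$pos - 1L,
                       end = panel$selected$pos,
                       name = panel$selected$site_id)
  utils::write.table(bed_df, bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(panel$audit, aud, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(tsv, bed, aud))
}

MAF_BIN_BREAKS <- c(0, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5)

#' Summarise a designed panel
#'
#' Per-chromosome counts, the MAF histogram over the standard panel bins
#' (`[0,0.05) ... [0.4,0.5]`), per-window occupancy, and (when a gene
#' annotation is supplied) genomic-region classes of the panel sites.
#'
#' @param panel a [build_panel()] result.
#' @param gm optional [geno_matrix()] used to compute MAF when the panel
#'   table has no `maf` column.
#' @param annotation optional gene annotation (see
#'   [classify_site_region()]).
#' @return list of class `panel_report` with `n_sites`, `chrom_counts`,
#'   `maf_hist`, `window_occupancy` and optionally `region_counts`.
#' @export
panel_report <- function(panel, gm = NULL, annotation = NULL) {
  sel <- panel$selected
  maf <- sel$maf
  if ((is.null(maf) || all(is.na(maf))) && !is.null(gm)) {
    st <- site_stats(gm)
    maf <- st$maf[match(paste(sel$chrom, sel$pos), paste(st$chrom, st$pos))]
  }
  maf_hist <- if (!is.null(maf)) {
    table(cut(maf, MAF_BIN_BREAKS, right = FALSE, include.lowest = TRUE,
              labels = sprintf("[%.2f,%.2f)", utils::head(MAF_BIN_BREAKS, -1),
                               utils::tail(MAF_BIN_BREAKS, -1))))
  } else NULL
  per_win <- table(factor(sel$window_id, levels = panel$audit$window_id))
  occ <- table(as.integer(per_win))
  out <- list(
    n_sites = nrow(sel),
    chrom_counts = table(factor(sel$chrom, levels = unique(panel$windows$chrom))),
    maf_hist = maf_hist,
    window_occupancy = occ,
    mean_sites_per_window = nrow(sel) / nrow(panel$audit)
  )
  if (!is.null(annotation)) {
    out$region_counts <- table(classify_site_region(sel, annotation))
  }
  class(out) <- "panel_report"
  out
}

#' @exportS3Method base::print
print.panel_report <- function(x, ...) {
  cat(sprintf("panel_report: %d sites, %.3f sites/window\n",
              x$n_sites, x$mean_sites_per_window))
  if (!is.null(x$maf_hist)) { cat("MAF bins:\n"); print(x$maf_hist) }
  invisible(x)
}

#' Fraction of panel sites detected after genotyping
#'
#' @param n_detected number of panel SNPs observed in the genotyped cohort.
#' @param n_panel number of SNPs on the panel.
#' @return Detection percentage (0-100).
#' @export
panel_detection_rate <- function(n_detected, n_panel) {
  stopifnot(n_panel > 0, n_detected >= 0, n_detected <= n_panel)
  100 * n_detected / n_panel
}

#' Compare per-sample QC metrics between groups (Welch t-tests)
#'
#' @param values data.frame with columns `sample_id` and `value` (e.g. the
#'   call rate from [sample_qc()]).
#' @param groups vector of group labels (sex or breed), aligned to `values`.
#' @param alpha significance level, default 0.05.
#' @return data.frame of pairwise Welch two-sample t-tests: group means,
#'   p-values and a significance flag.  Groups with fewer than 2 samples are
#'   excluded with a warning.  Identical groups give p = 1.
#' @export
qc_compare_groups <- function(values, groups, alpha = 0.05) {
  stopifnot(nrow(values) == length(groups), "value" %in% names(values))
  tab <- table(groups)
  small <- names(tab)[tab < 2]
  if (length(small)) {
    warning("excluding group(s) with < 2 samples: ",
            paste(small, collapse = ", "))
  }
  keep_groups <- setdiff(names(tab), small)
  if (length(keep_groups) < 2) stop("need at least two groups with >= 2 samples")
  pairs <- utils::combn(keep_groups, 2)
  res <- apply(pairs, 2, function(pr) {
    x <- values$value[groups == pr[1]]
    y <- values$value[groups == pr[2]]
    p <- if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      if (mean(x) == mean(y)) 1 else 0
    } else {
      stats::t.test(x, y)$p.value
    }
    data.frame(group1 = pr[1], group2 = pr[2], n1 = length(x), n2 = length(y),
               mean1 = mean(x), mean2 = mean(y), p_value = p,
               significant = p < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
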