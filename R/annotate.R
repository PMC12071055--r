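# Interval annotation against gene/feature models.
# Internal convention is 1-based inclusive; BED inputs (0-based half-open)
# are converted on import by rtracklayer.

as_feature_granges <- function(features) {
  if (methods::is(features, "GRanges")) return(features)
  if (is.character(features) && length(features) == 1) {
    return(rtracklayer::import(features))
  }
  if (is.data.frame(features)) {
    req <- c("chrom", "start", "end")
    if (!all(req %in% names(features))) {
      stop("feature table needs columns chrom, start, end")
    }
    bad <- !is.finite(features$start) | !is.finite(features$end) |
      features$start > features$end | is.na(features$chrom)
    if (any(bad)) {
      warning(sprintf("skipping %d malformed feature line(s)", sum(bad)))
      features <- features[!bad, , drop = FALSE]
    }
    gr <- GenomicRanges::GRanges(
      features$chrom,
      IRanges::IRanges(features$start, features$end),
      strand = if ("strand" %in% names(features)) features$strand else "*"
    )
    nm <- if ("name" %in% names(features)) features$name else
      if ("gene" %in% names(features)) features$gene else
        paste0("feature", seq_len(nrow(features)))
    S4Vectors::mcols(gr)$Name <- nm
    return(gr)
  }
  stop("unsupported feature input")
}

feature_names <- function(gr) {
  mc <- S4Vectors::mcols(gr)
  for (col in c("Name", "gene_id", "ID", "gene_name", "name")) {
    if (col %in% names(mc) && !all(is.na(mc[[col]]))) {
      return(as.character(mc[[col]]))
    }
  }
  paste0("feature", seq_along(gr))
}

#' Annotate genomic intervals with overlapping features
#'
#' A feature overlaps an interval when their bp ranges intersect (1-based
#' inclusive).  Feature names per interval are sorted and deduplicated.
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (e.g. the
#'   islands from [island_call()]).
#' @param features gene/QTL intervals: a `GRanges`, a GFF3/BED path, or a
#'   data.frame (`chrom`, `start`, `end`, optional `name`/`strand`);
#'   malformed data.frame rows are skipped with a count.
#' @return `intervals` with added columns `genes` (comma-separated names)
#'   and `n_genes`.
#' @export
annotate_intervals <- function(intervals, features) {
  gr <- as_feature_granges(features)
  if (methods::is(gr, "GRanges") && "type" %in% names(S4Vectors::mcols(gr))) {
    genes <- gr[S4Vectors::mcols(gr)$type == "gene"]
    if (length(genes)) gr <- genes
  }
  nms <- feature_names(gr)
  q <- GenomicRanges::GRanges(intervals$chrom,
                              IRanges::IRanges(intervals$start, intervals$end))
  hits <- GenomicRanges::findOverlaps(q, gr, ignore.strand = TRUE)
  glist <- split(nms[S4Vectors::subjectHits(hits)], S4Vectors::queryHits(hits))
  intervals$genes <- ""
  intervals$n_genes <- 0L
  for (qi in names(glist)) {
    g <- sort(unique(glist[[qi]]))
    i <- as.integer(qi)
    intervals$genes[i] <- paste(g, collapse = ",")
    intervals$n_genes[i] <- length(g)
  }
  intervals
}

#' Classify sites into genomic region classes
#'
#' Precedence: exonic > intronic > upstream > downstream > intergenic.
#' Upstream/downstream means within `flank` bp (default 5,000) of the gene
#' start/end, respecting strand.  Sites on chromosomes absent from the
#' annotation are intergenic, with a warning.
#'
#' @param sites data.frame with `chrom` and `pos`.
#' @param annotation a GFF3 path or `GRanges` carrying `type` metadata with
#'   `gene` (and ideally `exon`) features.
#' @param flank upstream/downstream window in bp.
#' @return Character vector of region labels, one per site.
#' @export
classify_site_region <- function(sites, annotation, flank = 5000) {
  gr <- as_feature_granges(annotation)
  has_type <- "type" %in% names(S4Vectors::mcols(gr))
  genes <- if (has_type) gr[S4Vectors::mcols(gr)$type == "gene"] else gr
  exons <- if (has_type) gr[S4Vectors::mcols(gr)$type == "exon"] else gr[0]
  q <- GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(sites$pos, sites$pos))
  known <- as.character(sites$chrom) %in%
    as.character(GenomicRanges::seqnames(genes))
  if (!all(known)) {
    warning(sprintf("%d site(s) on chromosomes absent from the annotation",
                    sum(!known)))
  }
  hit <- function(subj) {
    if (!length(subj)) return(rep(FALSE, length(q)))
    # seqlevel-mismatch chatter is expected when sites sit on unannotated
    # chromosomes; the explicit warning above already covers it
    suppressWarnings(
      GenomicRanges::countOverlaps(q, subj, ignore.strand = TRUE) > 0)
  }
  up <- GenomicRanges::flank(genes, flank, start = TRUE)
  down <- GenomicRanges::flank(genes, flank, start = FALSE)
  out <- rep("intergenic", length(q))
  out[hit(down)] <- "downstream"
  out[hit(up)] <- "upstream"
  out[hit(genes)] <- "intronic"
  out[hit(exons)] <- "exonic"
  out
}
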