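#' @keywords internal
"_PACKAGE"

# x*log(x) with the 0*log(0) = 0 convention used by entropy-type statistics
xlogx <- function(x) {
  out <- numeric(length(x))
  ok <- x > 0
  out[ok] <- x[ok] * log(x[ok])
  out
}

stop_if_not_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` must lie in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

# chromosome-length input: named numeric vector or data.frame(chrom, length)
as_chrom_lengths <- function(chrom_lengths) {
  if (is.data.frame(chrom_lengths)) {
    if (!all(c("chrom", "length") %in% names(chrom_lengths))) {
      stop("chromosome-length table needs columns `chrom` and `length`")
    }
    out <- stats::setNames(as.numeric(chrom_lengths$length),
                           as.character(chrom_lengths$chrom))
  } else {
    if (is.null(names(chrom_lengths))) {
      stop("chromosome lengths must be named by chromosome")
    }
    out <- stats::setNames(as.numeric(chrom_lengths), names(chrom_lengths))
  }
  if (any(duplicated(names(out)))) stop("duplicated chromosome in lengths")
  if (any(!is.finite(out)) || any(out < 1)) stop("chromosome lengths must be >= 1")
  out
}

# genome-order index for (chrom, pos) given an ordered chromosome universe
genome_order <- function(chrom, pos, chrom_levels = unique(chrom)) {
  order(match(chrom, chrom_levels), pos)
}
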