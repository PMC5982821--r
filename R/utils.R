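# Internal coordinate convention: 0-based, half-open [start, end).
# GRanges is 1-based closed; conversion happens only in these helpers.

#' @noRd
intervals_to_granges <- function(tbl, seqlengths = NULL) {
  strand <- if ("strand" %in% names(tbl)) tbl$strand else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = tbl$chrom,
    ranges = IRanges::IRanges(start = tbl$start + 1L, end = tbl$end),
    strand = strand
  )
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
  }
  gr
}

#' @noRd
granges_to_intervals <- function(gr) {
  tibble(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Overlap join between two interval tables
#'
#' Returns row indices of `x` and `y` whose intervals share at least one base
#' (same chromosome). Used by all counting and proximity operations.
#' @noRd
interval_overlap_pairs <- function(x, y) {
  hits <- GenomicRanges::findOverlaps(
    intervals_to_granges(x), intervals_to_granges(y), ignore.strand = TRUE
  )
  tibble(
    x_idx = S4Vectors::queryHits(hits),
    y_idx = S4Vectors::subjectHits(hits)
  )
}

#' @noRd
check_fraction <- function(x, name) {
  if (any(!is.na(x) & (x < 0 | x > 1))) {
    abort(sprintf("`%s` must lie in [0, 1]", name))
  }
  invisible(x)
}

#' @noRd
tile_of <- function(pos, tile_width = 100L) {
  as.integer(floor(pos / tile_width) * tile_width)
}
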