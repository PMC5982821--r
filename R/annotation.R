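#' Remove helitron elements from a TE annotation
#'
#' Helitrons are excluded from all expression counting because their capture
#' of gene fragments makes read assignment unreliable. All other elements pass
#' through unchanged.
#'
#' @param tes TE element tibble (needs an `is_helitron` column).
#' @return The tibble without helitron rows.
#' @export
remove_helitrons <- function(tes) {
  out <- tes %>% filter(!.data$is_helitron)
  if (nrow(out) == 0 && nrow(tes) > 0) {
    warn("all TE elements were helitrons; annotation is now empty")
  }
  out
}

#' Resolve an overlapping TE annotation into disjoint single-owner intervals
#'
#' Every base covered by at least one TE element is assigned to exactly one
#' element. Contested bases go to the shorter element, on the rationale that
#' nested elements are younger insertions interrupting the older, longer copy;
#' exact length ties break lexicographically by `element_id`. The union of
#' output bases equals the union of input bases, so no covered base is lost.
#'
#' @param tes TE element tibble with helitrons already removed.
#' @return A `resolved_annotation`: list with `intervals` (tibble `chrom`,
#'   `start`, `end`, `owner_id`, `owner_kind`) and `elements` (per-element
#'   index with family hierarchy and a `fully_masked` flag for elements that
#'   retain zero countable bases).
#' @export
resolve_overlaps <- function(tes) {
  if (any(tes$is_helitron)) {
    abort("remove helitrons before resolving overlaps")
  }
  if (nrow(tes) == 0) {
    return(new_resolved(
      tibble(chrom = character(), start = integer(), end = integer(),
             owner_id = character(), owner_kind = character()),
      tes
    ))
  }
  gr <- intervals_to_granges(tes)
  frags <- GenomicRanges::disjoin(gr, ignore.strand = TRUE)
  ov <- GenomicRanges::findOverlaps(frags, gr, ignore.strand = TRUE)
  cand <- tibble(
    frag = S4Vectors::queryHits(ov),
    el = S4Vectors::subjectHits(ov),
    width = tes$end[S4Vectors::subjectHits(ov)] -
      tes$start[S4Vectors::subjectHits(ov)],
    element_id = tes$element_id[S4Vectors::subjectHits(ov)]
  )
  winner <- cand %>%
    arrange(.data$frag, .data$width, .data$element_id) %>%
    distinct(.data$frag, .keep_all = TRUE)
  frag_tbl <- granges_to_intervals(frags)[winner$frag, ] %>%
    mutate(owner_id = winner$element_id)
  intervals <- merge_adjacent_same_owner(frag_tbl) %>%
    mutate(owner_kind = "te_element")
  new_resolved(intervals, tes)
}

#' @noRd
merge_adjacent_same_owner <- function(tbl) {
  tbl %>%
    arrange(.data$chrom, .data$start) %>%
    group_by(.data$chrom, .data$owner_id) %>%
    mutate(gap = .data$start - dplyr::lag(.data$end, default = -1L),
           run = cumsum(.data$gap != 0L)) %>%
    group_by(.data$chrom, .data$owner_id, .data$run) %>%
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") %>%
    select("chrom", "start", "end", "owner_id") %>%
    arrange(.data$chrom, .data$start)
}

#' @noRd
new_resolved <- function(intervals, tes) {
  elements <- tes %>%
    select("element_id", "family", "superfamily", "te_class") %>%
    mutate(fully_masked = !(.data$element_id %in%
                              intervals$owner_id[intervals$owner_kind == "te_element"]))
  structure(list(intervals = intervals, elements = elements),
            class = "resolved_annotation")
}

#' Mask gene exons out of a resolved TE annotation
#'
#' Subtracts every exon interval from the TE-owned intervals (TE intervals may
#' be split), then adds the exon intervals themselves (merged per gene) as
#' `gene_exon` owners. Elements whose every base is masked stay in the element
#' index, flagged `fully_masked`, so family size statistics are unaffected.
#'
#' @param resolved A `resolved_annotation` from [resolve_overlaps()].
#' @param exons Exon tibble (`gene_id`, `chrom`, `start`, `end`).
#' @return A `resolved_annotation` whose intervals now contain both
#'   `te_element` and `gene_exon` owners, with no TE base inside any exon.
#' @export
mask_exons <- function(resolved, exons) {
  stopifnot(inherits(resolved, "resolved_annotation"))
  te_iv <- resolved$intervals %>% filter(.data$owner_kind == "te_element")
  if (nrow(exons) > 0 && nrow(te_iv) > 0) {
    te_gr <- intervals_to_granges(te_iv)
    exon_gr <- GenomicRanges::reduce(intervals_to_granges(exons),
                                     ignore.strand = TRUE)
    kept <- GenomicRanges::subtract(te_gr, exon_gr, ignore.strand = TRUE)
    lens <- S4Vectors::elementNROWS(kept)
    kept_flat <- unlist(kept)
    te_iv <- granges_to_intervals(kept_flat) %>%
      mutate(owner_id = rep(te_iv$owner_id, lens), owner_kind = "te_element")
  }
  exon_iv <- if (nrow(exons) > 0) {
    grl <- GenomicRanges::reduce(
      GenomicRanges::split(intervals_to_granges(exons), exons$gene_id),
      ignore.strand = TRUE
    )
    flat <- unlist(grl)
    granges_to_intervals(flat) %>%
      mutate(owner_id = names(flat), owner_kind = "gene_exon")
  } else {
    tibble(chrom = character(), start = integer(), end = integer(),
           owner_id = character(), owner_kind = character())
  }
  intervals <- bind_rows(te_iv, exon_iv) %>%
    arrange(.data$chrom, .data$start)
  elements <- resolved$elements %>%
    mutate(fully_masked = !(.data$element_id %in%
                              intervals$owner_id[intervals$owner_kind == "te_element"]))
  structure(list(intervals = intervals, elements = elements),
            class = "resolved_annotation")
}

#' Build the full disjoint, helitron-free, exon-masked annotation
#'
#' Convenience wrapper: [remove_helitrons()], [resolve_overlaps()], then
#' [mask_exons()].
#'
#' @param tes TE element tibble.
#' @param exons Exon tibble.
#' @return A `resolved_annotation`.
#' @export
resolve_te_annotation <- function(tes, exons) {
  tes %>% remove_helitrons() %>% resolve_overlaps() %>% mask_exons(exons)
}

#' @export
print.resolved_annotation <- function(x, ...) {
  cat("<resolved_annotation>", nrow(x$intervals), "disjoint intervals;",
      sum(x$intervals$owner_kind == "te_element"), "TE-owned;",
      nrow(x$elements), "elements (",
      sum(x$elements$fully_masked), "fully masked )\n")
  invisible(x)
}

#' Tidy a resolved annotation: disjoint intervals with family hierarchy
#'
#' @param x A `resolved_annotation`.
#' @param ... Unused.
#' @return The interval tibble with `family` joined on.
#' @export
#' @method tidy resolved_annotation
tidy.resolved_annotation <- function(x, ...) {
  x$intervals %>%
    left_join(x$elements %>% select("element_id", "family"),
              by = c(owner_id = "element_id"))
}

#' Write resolved intervals as BED6 plus a family-map TSV
#'
#' @param resolved A `resolved_annotation`.
#' @param bed_path BED6 output (name column carries the owner id).
#' @param family_map_path Optional TSV mapping element to family, superfamily
#'   and class.
#' @return `bed_path`, invisibly.
#' @export
write_resolved_bed <- function(resolved, bed_path, family_map_path = NULL) {
  iv <- resolved$intervals
  readr::write_tsv(
    tibble(chrom = iv$chrom, start = iv$start, end = iv$end,
           name = iv$owner_id, score = 0L,
           strand = ".", kind = iv$owner_kind),
    bed_path, col_names = FALSE
  )
  if (!is.null(family_map_path)) {
    readr::write_tsv(resolved$elements, family_map_path)
  }
  invisible(bed_path)
}
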