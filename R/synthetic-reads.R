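#' Simulate multi-hit alignment records with truth labels
#'
#' Emits one row per reported hit of each simulated read pair (mates are
#' represented as a single merged fragment). Reads originate from gene exons,
#' from TE families, from intergenic space, or are improperly paired; a small
#' fraction is deliberately placed across nested-element boundaries so that
#' their hits span two TE families. Reads simulated from a multi-copy family
#' carry one equally-scored hit per copy (exact-duplicate model); reads from
#' single-copy features carry one hit. Each read keeps its `truth_kind` /
#' `truth_id` labels so downstream assignment can be checked against an oracle
#' that never sees the assignment logic.
#'
#' TE-derived reads are only sampled at offsets that are "clean" in every copy
#' of the family: the fragment stays inside the element and, at every copy,
#' overlaps no other TE element and no exon. This guarantees that a read
#' labelled with family F can only ever touch F-owned bases of the resolved
#' annotation, so truth counts and assignment counts must agree exactly.
#'
#' @param annotation A `synth_annotation` from [generate_genome_annotation()].
#' @param config The [synth_config()] used to build it (`read_depth` pairs are
#'   drawn).
#' A configurable fraction of TE reads are *junction* reads: fragments
#' straddling the boundary between one copy and its locus-specific flanking
#' DNA. Such reads exist only at that copy, so they report a single hit and
#' are uniquely assignable to an element — exactly how element-level evidence
#' arises for repetitive families in real data. Families alternate between a
#' `locus_specific` regime (all junction reads drawn from one donor copy) and
#' a `coordinate` regime (junction reads spread over all copies with a clean
#' edge); the regime per family is returned in the `pattern_truth` attribute
#' for oracle tests of the expression-pattern classifier.
#'
#' @param fragment_bp Fragment (merged mate pair) length in bp.
#' @param junction_fraction Fraction of TE reads drawn as single-hit junction
#'   reads (the remainder are interior, fully multi-mapping reads).
#' @param seed Seed for this library; defaults to `config$seed + 1` so that
#'   different libraries can be drawn by passing different seeds.
#' @return Tibble with one row per hit: `read_id`, `chrom`, `start`, `end`,
#'   `strand`, `properly_paired`, `n_hits`, `truth_kind` (one of `gene`,
#'   `te_family`, `intergenic`, `ambiguous`, `improper`), `truth_id` and
#'   `truth_element` (the donor copy of a junction read). Attribute
#'   `pattern_truth` maps each family to its planted expression regime.
#' @export
simulate_alignments <- function(annotation, config, fragment_bp = 150,
                                junction_fraction = 0.6,
                                seed = config$seed + 1) {
  stopifnot(inherits(annotation, "synth_annotation"))
  if (config$read_depth <= 0) abort("read_depth must be > 0")
  withr::with_seed(seed, simulate_alignments_impl(annotation, config,
                                                  fragment_bp, junction_fraction))
}

#' @noRd
simulate_alignments_impl <- function(ann, config, frag, junction_fraction = 0.6) {
  n <- config$read_depth
  tes <- ann$tes %>% filter(!.data$is_helitron)
  blockers <- bind_rows(
    ann$tes %>% select("chrom", "start", "end") %>% mutate(id = ann$tes$element_id),
    ann$exons %>% mutate(id = .data$exon_id) %>% select("chrom", "start", "end", "id")
  )

  fam_offsets <- clean_family_offsets(tes, blockers, frag)
  sampleable <- names(fam_offsets)[purrr::map_lgl(fam_offsets, ~ length(.x) > 0)]

  amb <- find_ambiguous_site(tes, ann$exons, frag)

  n_improper <- round(0.05 * n)
  n_intergenic <- round(0.05 * n)
  n_amb <- if (is.null(amb)) 0L else round(0.03 * n)
  n_gene <- round(0.60 * n)
  n_te <- n - n_improper - n_intergenic - n_amb - n_gene

  out <- list()

  # gene reads: fragment fully inside one exon
  gw <- rlnorm(nrow(ann$genes), 0, 1)
  exw <- ann$exons %>%
    left_join(tibble(gene_id = ann$genes$gene_id, w = gw), by = "gene_id") %>%
    mutate(w = .data$w * (.data$end - .data$start))
  pick <- sample(nrow(exw), n_gene, replace = TRUE, prob = exw$w)
  ex <- exw[pick, ]
  room <- pmax(ex$end - ex$start - frag, 0L)
  st <- ex$start + floor(runif(n_gene) * (room + 1))
  out$gene <- tibble(
    read_id = sprintf("g%07d", seq_len(n_gene)),
    chrom = ex$chrom, start = as.integer(st),
    end = as.integer(pmin(st + frag, ex$end)),
    strand = sample(c("+", "-"), n_gene, replace = TRUE),
    properly_paired = TRUE, n_hits = 1L,
    truth_kind = "gene", truth_id = ex$gene_id, truth_element = NA_character_
  )

  # TE family reads: interior reads (one hit per copy) + junction reads
  # (single hit at one copy's element/flank boundary)
  if (length(sampleable) == 0) abort("no TE family has a clean offset window")
  edges <- clean_edge_starts(tes, blockers, ann$genes, frag)
  patterns <- tibble(
    family = sampleable,
    pattern = rep_len(c("locus_specific", "coordinate"), length(sampleable))
  ) %>%
    mutate(pattern = if_else(
      purrr::map_int(.data$family, ~ sum(edges$family == .x)) <
        if_else(.data$pattern == "coordinate", 2L, 1L),
      if_else(purrr::map_int(.data$family, ~ sum(edges$family == .x)) >= 1,
              "locus_specific", "multi_only"),
      .data$pattern
    ))
  fw <- rlnorm(length(sampleable), 0, 1)
  fam_draw <- sample(sampleable, n_te, replace = TRUE, prob = fw)
  te_tbl <- purrr::imap_dfr(table(fam_draw), function(cnt, f) {
    cnt <- as.integer(cnt)
    pat <- patterns$pattern[patterns$family == f]
    fedges <- edges %>% filter(.data$family == f)
    n_j <- if (pat == "multi_only") 0L else as.integer(round(junction_fraction * cnt))
    n_i <- cnt - n_j
    copies <- tes %>% filter(.data$family == f)
    k <- nrow(copies)
    interior <- if (n_i > 0) {
      offs <- sample_offsets(fam_offsets[[f]], n_i)
      tibble(
        read_key = rep(sprintf("%s_i%06d", f, seq_len(n_i)), each = k),
        chrom = rep(copies$chrom, times = n_i),
        start = as.integer(rep(copies$start, times = n_i) + rep(offs, each = k)),
        family = f, k = k, element = NA_character_
      )
    } else NULL
    junction <- if (n_j > 0) {
      donor <- if (pat == "locus_specific") rep(1L, n_j) else
        sample(nrow(fedges), n_j, replace = TRUE)
      tibble(
        read_key = sprintf("%s_j%06d", f, seq_len(n_j)),
        chrom = fedges$chrom[donor],
        start = fedges$frag_start[donor],
        family = f, k = 1L, element = fedges$element_id[donor]
      )
    } else NULL
    bind_rows(interior, junction)
  })
  if (nrow(te_tbl) > 0) {
    te_ids <- sprintf("t%07d", cumsum(!duplicated(te_tbl$read_key)))
    out$te <- tibble(
      read_id = te_ids,
      chrom = te_tbl$chrom, start = te_tbl$start,
      end = te_tbl$start + as.integer(frag),
      strand = "+",
      properly_paired = TRUE, n_hits = te_tbl$k,
      truth_kind = "te_family", truth_id = te_tbl$family,
      truth_element = te_tbl$element
    )
    out$te$strand <- rep(sample(c("+", "-"), length(unique(te_ids)), replace = TRUE),
                         times = rle(te_ids)$lengths)
  }

  # deliberately ambiguous reads across a nested-element boundary
  if (n_amb > 0) {
    host_copies <- tes %>% filter(.data$family == amb$host_family)
    k <- nrow(host_copies)
    out$amb <- tibble(
      read_id = rep(sprintf("a%07d", seq_len(n_amb)), each = k),
      chrom = rep(host_copies$chrom, times = n_amb),
      start = as.integer(rep(host_copies$start, times = n_amb) + amb$offset),
      end = as.integer(rep(host_copies$start, times = n_amb) + amb$offset + frag),
      strand = "+", properly_paired = TRUE, n_hits = k,
      truth_kind = "ambiguous", truth_id = amb$host_family
    )
  }

  # intergenic reads: overlap neither gene spans nor TE elements
  free <- free_space(ann, frag)
  pickw <- sample(nrow(free), n_intergenic, replace = TRUE,
                  prob = free$end - free$start - frag)
  fr <- free[pickw, ]
  st <- fr$start + floor(runif(n_intergenic) * (fr$end - fr$start - frag))
  out$inter <- tibble(
    read_id = sprintf("i%07d", seq_len(n_intergenic)),
    chrom = fr$chrom, start = as.integer(st), end = as.integer(st + frag),
    strand = sample(c("+", "-"), n_intergenic, replace = TRUE),
    properly_paired = TRUE, n_hits = 1L,
    truth_kind = "intergenic", truth_id = NA_character_
  )

  # improperly paired reads (dropped by the filter)
  chroms <- names(ann$seqlengths)
  ch <- sample(chroms, n_improper, replace = TRUE)
  st <- floor(runif(n_improper) * (ann$seqlengths[ch] - frag))
  out$improper <- tibble(
    read_id = sprintf("x%07d", seq_len(n_improper)),
    chrom = ch, start = as.integer(st), end = as.integer(st + frag),
    strand = "+", properly_paired = FALSE, n_hits = 1L,
    truth_kind = "improper", truth_id = NA_character_
  )

  res <- bind_rows(out)
  attr(res, "pattern_truth") <- patterns
  res
}

#' Fragment start positions straddling a clean element edge
#'
#' For every element, check the window centred on its start (and, failing
#' that, its end): the fragment must stay on the chromosome, overlap the
#' element, and overlap no other TE element, no exon and no gene span at that
#' locus, so a read drawn there is locus-unique by construction.
#' @noRd
clean_edge_starts <- function(tes, blockers, genes, frag) {
  half <- as.integer(frag / 2)
  span_blockers <- bind_rows(
    blockers,
    genes %>% mutate(id = .data$gene_id) %>%
      select("chrom", "start", "end", "id")
  )
  cand <- bind_rows(
    tes %>% mutate(frag_start = .data$start - half, edge = "left"),
    tes %>% mutate(frag_start = .data$end - half, edge = "right")
  ) %>%
    filter(.data$frag_start >= 0) %>%
    mutate(frag_end = .data$frag_start + as.integer(frag))
  if (nrow(cand) == 0) return(cand[0, ])
  pairs <- interval_overlap_pairs(
    cand %>% select("chrom", start = "frag_start", end = "frag_end"),
    span_blockers
  )
  dirty <- unique(pairs$x_idx[
    span_blockers$id[pairs$y_idx] != cand$element_id[pairs$x_idx]
  ])
  cand %>%
    mutate(.row = row_number()) %>%
    filter(!(.data$.row %in% dirty)) %>%
    distinct(.data$family, .data$element_id, .keep_all = TRUE) %>%
    select("family", "element_id", "chrom", "frag_start")
}

#' Per-family offsets clean in every copy
#' @noRd
clean_family_offsets <- function(tes, blockers, frag) {
  fams <- split(seq_len(nrow(tes)), tes$family)
  purrr::map(fams, function(rows) {
    L <- tes$end[rows[1]] - tes$start[rows[1]]
    if (L < frag) return(IRanges::IRanges())
    allowed <- IRanges::IRanges(start = 1L, end = L - frag + 1L)  # offset o+1
    for (r in rows) {
      bl <- blockers %>%
        filter(.data$chrom == tes$chrom[r], .data$id != tes$element_id[r],
               .data$start < tes$end[r], .data$end > tes$start[r])
      if (nrow(bl) == 0) next
      a <- pmax(bl$start, tes$start[r]) - tes$start[r]
      b <- pmin(bl$end, tes$end[r]) - tes$start[r]
      blocked <- IRanges::IRanges(start = pmax(a - frag + 1L, 0L) + 1L,
                                  end = pmin(b - 1L, L - frag) + 1L)
      blocked <- blocked[IRanges::width(blocked) > 0]
      if (length(blocked) > 0) allowed <- IRanges::setdiff(allowed, blocked)
    }
    allowed
  })
}

#' @noRd
sample_offsets <- function(ir, n) {
  w <- IRanges::width(ir)
  iv <- sample(length(ir), n, replace = TRUE, prob = w)
  IRanges::start(ir)[iv] - 1L + floor(runif(n) * w[iv])
}

#' Locate a nested cross-family pair and a boundary-spanning offset
#' @noRd
find_ambiguous_site <- function(tes, exons, frag) {
  ij <- interval_overlap_pairs(tes, tes)
  ij <- ij %>% filter(.data$x_idx != .data$y_idx)
  for (r in seq_len(nrow(ij))) {
    h <- ij$x_idx[r]; v <- ij$y_idx[r]
    if (tes$family[h] == tes$family[v]) next
    nested <- tes$start[v] > tes$start[h] && tes$end[v] < tes$end[h]
    if (!nested) next
    off <- max(0L, tes$start[v] - tes$start[h] - as.integer(frag / 2))
    # fragment must overlap both host and nested bases, and no exon in any copy
    if (off + frag <= tes$start[v] - tes$start[h]) next
    copies <- tes[tes$family == tes$family[h], ]
    hit <- tibble(chrom = copies$chrom, start = copies$start + off,
                  end = copies$start + off + as.integer(frag))
    if (nrow(interval_overlap_pairs(hit, exons)) > 0) next
    return(list(host_family = tes$family[h], offset = off))
  }
  NULL
}

#' Intervals of the genome covered by neither gene spans nor TE elements
#' @noRd
free_space <- function(ann, frag) {
  occupied <- bind_rows(
    ann$genes %>% select("chrom", "start", "end"),
    ann$tes %>% select("chrom", "start", "end")
  )
  gr <- GenomicRanges::reduce(intervals_to_granges(occupied, ann$seqlengths))
  gaps <- GenomicRanges::gaps(gr)
  gaps <- gaps[GenomicRanges::strand(gaps) == "*"]
  free <- granges_to_intervals(gaps)
  free %>% filter(.data$end - .data$start > frag + 10)
}
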