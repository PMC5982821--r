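# Relating expression changes to methylation features: metaprofiles, TSS
# methylation classes, island/DMR proximity, enrichment, and epiallele
# correlation across a genotype panel.

#' @noRd
windowed_level <- function(windows, tiles, tile_bp = 100) {
  # read-weighted methylation level of arbitrary windows from fixed tiles;
  # a tile's reads contribute in proportion to its overlap with the window
  ctxs <- unique(tiles$context)
  purrr::map_dfr(ctxs, function(ctx) {
    tl <- tiles %>% filter(.data$context == ctx) %>%
      mutate(tile_end = .data$tile_start + tile_bp)
    pairs <- interval_overlap_pairs(
      windows,
      tl %>% select("chrom", start = "tile_start", end = "tile_end")
    )
    if (nrow(pairs) == 0) {
      return(tibble(window_id = character(), context = character(),
                    level = numeric(), reads = numeric()))
    }
    tibble(
      window_id = windows$window_id[pairs$x_idx],
      w = (pmin(windows$end[pairs$x_idx], tl$tile_end[pairs$y_idx]) -
             pmax(windows$start[pairs$x_idx], tl$tile_start[pairs$y_idx])) / tile_bp,
      mc = tl$mc_reads[pairs$y_idx],
      tot = tl$total_reads[pairs$y_idx]
    ) %>%
      group_by(.data$window_id) %>%
      summarise(level = sum(.data$mc * .data$w) / sum(.data$tot * .data$w),
                reads = sum(.data$tot * .data$w), .groups = "drop") %>%
      mutate(context = ctx)
  })
}

#' Strand-aware methylation metaprofile around TSS and TTS
#'
#' For every gene in `gene_set`, methylation levels are collected in 100-bp
#' bins spanning 2 kb on each side of the TSS and of the TTS, oriented in the
#' direction of transcription (profiles of minus-strand genes are flipped).
#' Bins are in absolute coordinates — gene bodies are not rescaled — so genes
#' shorter than the windows simply contribute to fewer informative bins. The
#' profile reports the per-bin mean level over genes with data and its
#' standard error.
#'
#' @param genes Gene tibble (`gene_id`, `chrom`, `strand`, `tss`, `tts`).
#' @param tiles Tile table from [tile_methylation()].
#' @param gene_set Character vector of gene ids to profile (nonempty).
#' @param flank_bp Flank span on each side of the anchor.
#' @param bin_bp Bin width.
#' @return Tibble `anchor` (`TSS`/`TTS`), `offset_bp` (bin start relative to
#'   the anchor, transcribed orientation), `context`, `mean_level`, `se`,
#'   `n_genes`.
#' @export
metaprofile <- function(genes, tiles, gene_set, flank_bp = 2000, bin_bp = 100) {
  if (length(gene_set) == 0) abort("empty gene set")
  g <- genes %>% filter(.data$gene_id %in% gene_set)
  if (nrow(g) == 0) abort("no gene of the set is in the annotation")
  offs <- seq(-flank_bp, flank_bp - bin_bp, by = bin_bp)
  grid <- tidyr::expand_grid(
    g %>% select("gene_id", "chrom", "strand", "tss", "tts"),
    offset_bp = offs
  ) %>%
    tidyr::pivot_longer(c("tss", "tts"), names_to = "anchor",
                        values_to = "pos") %>%
    mutate(
      anchor = toupper(.data$anchor),
      start = if_else(.data$strand == "+",
                      .data$pos + .data$offset_bp,
                      .data$pos - .data$offset_bp - bin_bp),
      end = .data$start + bin_bp,
      window_id = paste(.data$gene_id, .data$anchor, .data$offset_bp)
    ) %>%
    filter(.data$start >= 0)
  lv <- windowed_level(grid, tiles, bin_bp)
  grid %>%
    inner_join(lv, by = "window_id") %>%
    group_by(.data$anchor, .data$offset_bp, .data$context) %>%
    summarise(
      mean_level = mean(.data$level),
      se = if (n() > 1) sd(.data$level) / sqrt(n()) else NA_real_,
      n_genes = n(),
      .groups = "drop"
    )
}

#' Classify genes by methylation just downstream of the TSS
#'
#' Read-weighted mean level over the first `window_bp` (default 400 bp)
#' downstream of the TSS in the direction of transcription: `high` above
#' `high_cutoff` (50%), `low` below `low_cutoff` (20%), `intermediate`
#' between, `no_data` when no covered site falls in the window.
#'
#' @param genes Gene tibble.
#' @param tiles Tile table.
#' @param context Context to classify on.
#' @param window_bp Window size downstream of the TSS.
#' @param high_cutoff,low_cutoff Classification thresholds (fractions,
#'   strict).
#' @return Tibble `gene_id`, `tss_level`, `tss_class`.
#' @export
tss_methylation_class <- function(genes, tiles, context, window_bp = 400,
                                  high_cutoff = 0.5, low_cutoff = 0.2) {
  windows <- genes %>%
    mutate(
      start = if_else(.data$strand == "+", .data$tss, .data$tss - window_bp),
      end = if_else(.data$strand == "+", .data$tss + window_bp, .data$tss),
      start = pmax(.data$start, 0),
      window_id = .data$gene_id
    )
  lv <- windowed_level(windows, tiles %>% filter(.data$context == .env$context))
  genes %>%
    select("gene_id") %>%
    left_join(lv %>% select("window_id", "level"),
              by = c(gene_id = "window_id")) %>%
    mutate(
      tss_level = .data$level,
      tss_class = case_when(
        is.na(.data$level) ~ "no_data",
        .data$level > high_cutoff ~ "high",
        .data$level < low_cutoff ~ "low",
        TRUE ~ "intermediate"
      )
    ) %>%
    select("gene_id", "tss_level", "tss_class")
}

#' Flag features with an mCHH island in or near them
#'
#' True iff at least one island tile intersects the feature span extended by
#' `flank_bp` (default 2 kb) on both sides.
#'
#' @param features Tibble with `feature_id`, `chrom`, `start`, `end`.
#' @param islands Island table from [call_mchh_islands()].
#' @param flank_bp Flank size.
#' @param tile_bp Island tile width.
#' @return `features` plus logical `has_island_2kb`.
#' @export
island_proximity <- function(features, islands, flank_bp = 2000, tile_bp = 100) {
  ext <- features %>%
    mutate(start = pmax(.data$start - flank_bp, 0), end = .data$end + flank_bp)
  isl <- islands %>%
    mutate(end = .data$tile_start + tile_bp) %>%
    select("chrom", start = "tile_start", "end")
  hit_idx <- unique(interval_overlap_pairs(ext, isl)$x_idx)
  features %>%
    mutate(has_island_2kb = row_number() %in% hit_idx)
}

#' Flag genes with a DMR near the transcription start site
#'
#' Per context: true iff any DMR tile of the catalog intersects the half-open
#' window `[TSS - window_bp, TSS + window_bp)`. The TSS of a minus-strand gene
#' is its annotation end.
#'
#' @param genes Gene tibble.
#' @param dmr_catalog Catalog tibble (`chrom`, `tile_start`, `context`), e.g.
#'   from [pairwise_panel_dmrs()].
#' @param window_bp Half-window around the TSS.
#' @param tile_bp DMR tile width.
#' @return Tibble `gene_id` plus one logical `dmr_<context>` column per
#'   context present in the catalog.
#' @export
dmr_near_tss <- function(genes, dmr_catalog, window_bp = 200, tile_bp = 100) {
  windows <- genes %>%
    mutate(start = pmax(.data$tss - window_bp, 0),
           end = .data$tss + window_bp)
  out <- genes %>% select("gene_id")
  for (ctx in sort(unique(dmr_catalog$context))) {
    dm <- dmr_catalog %>% filter(.data$context == ctx) %>%
      mutate(end = .data$tile_start + tile_bp) %>%
      select("chrom", start = "tile_start", "end")
    hit_idx <- unique(interval_overlap_pairs(windows, dm)$x_idx)
    out[[paste0("dmr_", ctx)]] <- seq_len(nrow(out)) %in% hit_idx
  }
  out
}

#' Chi-squared enrichment of a feature flag in a gene set vs background
#'
#' 2x2 chi-squared test without continuity correction. `enriched` is true only
#' when the p value is below `p_cutoff` *and* the set proportion exceeds the
#' background proportion (a significant depletion is not enrichment).
#'
#' @param set_flags,background_flags Logical vectors (both nonempty).
#' @param p_cutoff Significance threshold.
#' @return Tibble `chi2`, `df`, `p`, `set_prop`, `background_prop`,
#'   `enriched`.
#' @export
enrichment_test <- function(set_flags, background_flags, p_cutoff = 0.01) {
  if (length(set_flags) == 0 || length(background_flags) == 0) {
    abort("both groups must be nonempty")
  }
  tab <- rbind(
    c(sum(set_flags), sum(!set_flags)),
    c(sum(background_flags), sum(!background_flags))
  )
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) {
    abort("zero expected cell count; use an exact test")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  set_prop <- mean(set_flags)
  bg_prop <- mean(background_flags)
  tibble(
    chi2 = unname(ct$statistic), df = unname(ct$parameter),
    p = ct$p.value, set_prop = set_prop, background_prop = bg_prop,
    enriched = ct$p.value < p_cutoff & set_prop > bg_prop
  )
}

#' Pearson correlation of DMR methylation and expression across a panel
#'
#' Per gene: Pearson correlation of methylation level at the promoter DMR
#' with transcript abundance over the panel genotypes; significant iff the
#' two-sided p value is below `p_cutoff`. Genes with fewer than `min_n`
#' genotypes or zero variance in either vector are flagged undefined and never
#' significant.
#'
#' @param panel Tibble `gene_id`, `genotype`, `meth_level`, `expression`.
#' @param p_cutoff Significance threshold.
#' @param min_n Minimum genotypes with both measurements.
#' @return Tibble `gene_id`, `n`, `r`, `p`, `significant`, `note`.
#' @export
methylation_expression_correlation <- function(panel, p_cutoff = 0.05,
                                               min_n = 4) {
  panel %>%
    filter(!is.na(.data$meth_level), !is.na(.data$expression)) %>%
    group_by(.data$gene_id) %>%
    summarise(
      n = n(),
      r = if (n() < min_n || sd(.data$meth_level) == 0 ||
              sd(.data$expression) == 0) NA_real_ else
        suppressWarnings(stats::cor(.data$meth_level, .data$expression)),
      p = if (is.na(r)) NA_real_ else
        suppressWarnings(cor.test(.data$meth_level, .data$expression)$p.value),
      .groups = "drop"
    ) %>%
    mutate(
      significant = !is.na(.data$p) & .data$p < p_cutoff,
      note = case_when(
        .data$n < min_n ~ "too_few_genotypes",
        is.na(.data$r) ~ "zero_variance",
        TRUE ~ NA_character_
      )
    )
}
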