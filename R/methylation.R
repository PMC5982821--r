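#' Summarize per-cytosine calls into 100-bp tiles per context
#'
#' Methylated and total read counts are summed over all called cytosines of a
#' tile and context (both strands pooled; every called cytosine is its own
#' site), so the tile level is the read-weighted mean. The final partial tile
#' of each chromosome is retained. Only tiles with at least one covered site
#' appear in the output; the tiling grid is fixed by `seqlengths`, which is
#' stored as an attribute and checked when two genotypes are compared.
#'
#' @param calls Per-cytosine tibble (`chrom`, `pos`, `strand`, `context`,
#'   `mc_reads`, `total_reads`).
#' @param seqlengths Named chromosome lengths; positions at or beyond the
#'   chromosome end are an error.
#' @param tile_bp Tile width (default 100).
#' @param genotype Optional genotype label stored on the result.
#' @return Tibble `chrom`, `tile_start`, `context`, `n_sites`, `mc_reads`,
#'   `total_reads`, `level`, `mean_site_coverage` with attributes `seqlengths`
#'   and `genotype`.
#' @export
tile_methylation <- function(calls, seqlengths, tile_bp = 100, genotype = NULL) {
  bad <- !(calls$chrom %in% names(seqlengths)) |
    calls$pos >= seqlengths[calls$chrom] | calls$pos < 0
  if (any(bad)) {
    abort(sprintf("%d call position(s) outside chromosome bounds", sum(bad)))
  }
  if (any(calls$mc_reads > calls$total_reads)) {
    abort("mc_reads exceeds total_reads")
  }
  out <- calls %>%
    filter(.data$total_reads > 0) %>%
    mutate(tile_start = tile_of(.data$pos, tile_bp)) %>%
    group_by(.data$chrom, .data$tile_start, .data$context) %>%
    summarise(
      n_sites = n_distinct(.data$pos),
      mc_reads = sum(.data$mc_reads),
      total_reads = sum(.data$total_reads),
      .groups = "drop"
    ) %>%
    mutate(
      level = .data$mc_reads / .data$total_reads,
      mean_site_coverage = .data$total_reads / .data$n_sites
    ) %>%
    arrange(.data$chrom, .data$tile_start, .data$context)
  attr(out, "seqlengths") <- seqlengths
  attr(out, "genotype") <- genotype
  out
}

#' Call differentially methylated 100-bp tiles between two genotypes
#'
#' Gates (all strict): more than `min_sites` sites of the context in *both*
#' genotypes, mean per-site coverage above `min_coverage` in both, and for
#' CG/CHG a methylation difference of more than `min_diff_points` percentage
#' points. CHH tiles use the same site-number and coverage gates but a
#' low/high pattern instead of a difference: below `chh_low` (5%) in one
#' genotype and above `chh_high` (25%) in the other, reflecting the low
#' background CHH methylation of the maize genome. Calling is symmetric in
#' genotype order.
#'
#' @param tiles_a,tiles_b Tile tables from [tile_methylation()] on the same
#'   grid (mismatched `seqlengths` is an error).
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param min_sites Site-number gate (call requires `n_sites > min_sites`).
#' @param min_coverage Coverage gate (mean reads per site, strict).
#' @param min_diff_points CG/CHG difference gate in percentage points.
#' @param chh_low,chh_high CHH low/high thresholds (fractions).
#' @return Tibble `chrom`, `tile_start`, `context`, `level_a`, `level_b`,
#'   `difference` (percentage points).
#' @export
call_dmrs <- function(tiles_a, tiles_b, context,
                      min_sites = 6, min_coverage = 2, min_diff_points = 60,
                      chh_low = 0.05, chh_high = 0.25) {
  stopifnot(context %in% c("CG", "CHG", "CHH"))
  sa <- attr(tiles_a, "seqlengths"); sb <- attr(tiles_b, "seqlengths")
  if (!is.null(sa) && !is.null(sb) && !identical(sa, sb)) {
    abort("tile grids differ between genotypes")
  }
  a <- tiles_a %>% filter(.data$context == .env$context)
  b <- tiles_b %>% filter(.data$context == .env$context)
  joined <- inner_join(
    a %>% select("chrom", "tile_start", n_sites_a = "n_sites",
                 cov_a = "mean_site_coverage", level_a = "level"),
    b %>% select("chrom", "tile_start", n_sites_b = "n_sites",
                 cov_b = "mean_site_coverage", level_b = "level"),
    by = c("chrom", "tile_start")
  ) %>%
    filter(.data$n_sites_a > min_sites, .data$n_sites_b > min_sites,
           .data$cov_a > min_coverage, .data$cov_b > min_coverage)
  joined <- if (context == "CHH") {
    joined %>% filter(
      (.data$level_a < chh_low & .data$level_b > chh_high) |
        (.data$level_b < chh_low & .data$level_a > chh_high)
    )
  } else {
    joined %>% filter(abs(.data$level_a - .data$level_b) * 100 > min_diff_points)
  }
  joined %>%
    mutate(context = .env$context,
           difference = abs(.data$level_a - .data$level_b) * 100) %>%
    select("chrom", "tile_start", "context", "level_a", "level_b", "difference")
}

#' Call mCHH island tiles for one genotype
#'
#' A tile is an mCHH island if its CHH methylation level exceeds `min_level`
#' (strictly) with at least `min_reads` informative reads (total reads over
#' the tile's CHH sites).
#'
#' @param tiles Tile table from [tile_methylation()].
#' @param min_level CHH level threshold (fraction, strict).
#' @param min_reads Minimum informative reads (inclusive).
#' @return Tibble `chrom`, `tile_start`, `chh_level`, `informative_reads`,
#'   `genotype`.
#' @export
call_mchh_islands <- function(tiles, min_level = 0.25, min_reads = 10) {
  tiles %>%
    filter(.data$context == "CHH",
           .data$level > min_level,
           .data$total_reads >= min_reads) %>%
    mutate(genotype = attr(tiles, "genotype") %||% NA_character_) %>%
    select("chrom", "tile_start", chh_level = "level",
           informative_reads = "total_reads", "genotype")
}

#' Pairwise DMR catalog over a genotype panel
#'
#' Calls DMRs between a reference genotype and each other genotype (all three
#' contexts), then deduplicates into a per-(tile, context) catalog tagged with
#' the genotype pairs supporting each entry.
#'
#' @param tile_list Named list of tile tables; the first element (or
#'   `reference`) is the reference genotype.
#' @param reference Name of the reference genotype.
#' @param contexts Contexts to scan.
#' @param ... Gate parameters passed to [call_dmrs()].
#' @return List with `pairwise` (one row per tile/context/pair) and `catalog`
#'   (deduplicated by tile and context, with `n_pairs` and a collapsed
#'   `genotypes` tag).
#' @export
pairwise_panel_dmrs <- function(tile_list, reference = names(tile_list)[1],
                                contexts = c("CG", "CHG", "CHH"), ...) {
  if (length(tile_list) < 2) abort("need at least two genotypes")
  others <- setdiff(names(tile_list), reference)
  pairwise <- purrr::map_dfr(others, function(g) {
    purrr::map_dfr(contexts, function(ctx) {
      call_dmrs(tile_list[[reference]], tile_list[[g]], ctx, ...) %>%
        mutate(genotype_a = reference, genotype_b = g)
    })
  })
  catalog <- pairwise %>%
    group_by(.data$chrom, .data$tile_start, .data$context) %>%
    summarise(n_pairs = n(),
              genotypes = paste(sort(.data$genotype_b), collapse = ","),
              .groups = "drop")
  list(pairwise = pairwise, catalog = catalog)
}
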