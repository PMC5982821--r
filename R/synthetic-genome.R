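#' Generate a toy genome annotation with planted ground truth
#'
#' Builds gene models (with exon structure), a hierarchical TE annotation
#' (element -> family -> superfamily -> class) and a truth set of planted
#' differentially expressed features, differentially methylated tiles and mCHH
#' island tiles. The annotation is guaranteed to contain at least one helitron,
#' at least one TE nested strictly inside a TE of another family, and at least
#' one TE partially overlapping a gene exon, so every branch of the annotation
#' resolver is exercised.
#'
#' Multi-copy family members are treated as exact sequence duplicates: all
#' copies of a family share one element length, and simulated reads from a
#' family report one hit per copy at the same relative offset.
#'
#' @param config A [synth_config()].
#' @return A list of class `synth_annotation` with elements `genes`, `exons`,
#'   `tes` (tibbles), `truth` (list: `de_features`, `dmrs`, `islands`),
#'   `seqlengths` (named integer vector) and `config`.
#' @export
generate_genome_annotation <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (config$n_te_families == 0) abort("nothing to annotate")
  withr::with_seed(config$seed, generate_genome_annotation_impl(config))
}

#' @noRd
generate_genome_annotation_impl <- function(config) {
  seqlengths <- synth_seqlengths(config)
  chroms <- names(seqlengths)

  # --- gene skeletons: exon/intron layout drawn first, width follows ---
  gene_plans <- purrr::map(seq_len(config$n_genes), function(i) {
    n_exons <- sample(1:3, 1)
    exon_w <- sample(200:500, n_exons, replace = TRUE)
    intron_w <- if (n_exons > 1) sample(100:250, n_exons - 1, replace = TRUE) else integer()
    list(exon_w = exon_w, intron_w = intron_w,
         width = sum(exon_w) + sum(intron_w))
  })

  # --- TE family table; all copies of a family share one width ---
  superfams <- c("RLG", "RLC", "RLX", "DTA", "DTM", "DTT", "DTH", "DTC")
  fam_sf <- sample(superfams, config$n_te_families, replace = TRUE)
  fam <- tibble(
    family = sprintf("%s%05d", fam_sf, seq_len(config$n_te_families)),
    superfamily = fam_sf,
    width = sample(300:1500, config$n_te_families, replace = TRUE),
    n_copies = config$copies_per_family
  )
  n_te_elements <- sum(fam$n_copies)
  n_helitrons <- if (config$helitron_fraction > 0) {
    max(1L, as.integer(ceiling(config$helitron_fraction * n_te_elements)))
  } else 0L

  # --- sequential placement along chromosomes with random gaps ---
  entities <- tibble(
    kind = c(rep("gene", config$n_genes),
             rep("te", n_te_elements),
             rep("helitron", n_helitrons)),
    idx = c(seq_len(config$n_genes),
            seq_len(n_te_elements),
            seq_len(n_helitrons)),
    width = c(purrr::map_int(gene_plans, ~ as.integer(.x$width)),
              rep(fam$width, fam$n_copies),
              sample(500:2000, n_helitrons, replace = TRUE))
  )
  entities <- entities[sample(nrow(entities)), ]
  needed <- sum(entities$width) + nrow(entities) * 900
  if (needed > 0.85 * sum(seqlengths)) {
    abort("genome too small for the requested annotation density")
  }
  # round-robin assignment to chromosomes, cursor walk within each
  entities$chrom <- chroms[(seq_len(nrow(entities)) - 1) %% length(chroms) + 1]
  placed <- entities %>%
    group_by(.data$chrom) %>%
    mutate(
      gap = sample(300:900, n(), replace = TRUE),
      start = 1000L + cumsum(.data$gap) + cumsum(dplyr::lag(.data$width, default = 0L)) - .data$gap[1],
      end = .data$start + .data$width
    ) %>%
    ungroup()
  if (any(placed$end > seqlengths[placed$chrom])) {
    abort("genome too small for the requested annotation density")
  }

  # --- genes and exons ---
  gene_rows <- placed %>% filter(.data$kind == "gene") %>% arrange(.data$idx)
  genes <- gene_rows %>%
    mutate(
      gene_id = sprintf("GENE%04d", .data$idx),
      strand = sample(c("+", "-"), n(), replace = TRUE)
    ) %>%
    select("gene_id", "chrom", "start", "end", "strand")
  exons <- purrr::map2_dfr(gene_rows$idx, seq_len(nrow(gene_rows)), function(i, r) {
    plan <- gene_plans[[i]]
    offs <- cumsum(c(0L, head(rep(plan$exon_w, length.out = length(plan$exon_w)) +
                                c(plan$intron_w, 0L), -1)))
    tibble(
      gene_id = genes$gene_id[r],
      exon_id = sprintf("%s.e%d", genes$gene_id[r], seq_along(plan$exon_w)),
      chrom = genes$chrom[r],
      start = genes$start[r] + offs,
      end = genes$start[r] + offs + plan$exon_w,
      strand = genes$strand[r]
    )
  })
  genes <- genes %>%
    mutate(tss = if_else(.data$strand == "+", .data$start, .data$end),
           tts = if_else(.data$strand == "+", .data$end, .data$start))

  # --- TE elements ---
  fam_expanded <- fam[rep(seq_len(nrow(fam)), fam$n_copies), ] %>%
    group_by(.data$family) %>%
    mutate(copy = row_number()) %>%
    ungroup()
  te_rows <- placed %>% filter(.data$kind == "te") %>% arrange(.data$idx)
  tes <- fam_expanded %>%
    mutate(
      element_id = sprintf("%s_%02d", .data$family, .data$copy),
      chrom = te_rows$chrom,
      start = te_rows$start,
      end = te_rows$end,
      is_helitron = FALSE,
      te_class = if_else(startsWith(.data$superfamily, "R"), "I", "II"),
      ltr_similarity = if_else(startsWith(.data$superfamily, "RL"),
                               runif(n(), 0.80, 0.99), NA_real_),
      gc_content = runif(n(), 0.35, 0.55)
    ) %>%
    select("element_id", "family", "superfamily", "te_class", "chrom",
           "start", "end", "is_helitron", "ltr_similarity", "gc_content")

  hel_rows <- placed %>% filter(.data$kind == "helitron") %>% arrange(.data$idx)
  if (nrow(hel_rows) > 0) {
    helitrons <- hel_rows %>%
      mutate(
        family = sprintf("DHH%05d", .data$idx),
        element_id = sprintf("%s_01", .data$family),
        superfamily = "DHH",
        te_class = "II",
        is_helitron = TRUE,
        ltr_similarity = NA_real_,
        gc_content = runif(n(), 0.35, 0.55)
      ) %>%
      select("element_id", "family", "superfamily", "te_class", "chrom",
             "start", "end", "is_helitron", "ltr_similarity", "gc_content")
    tes <- bind_rows(tes, helitrons)
  }

  # --- plant nesting: move one copy of a narrow family inside a wide element ---
  n_nested <- if (config$nested_te_fraction > 0) {
    max(1L, as.integer(round(config$nested_te_fraction * config$n_te_families / 2)))
  } else 0L
  fam_by_width <- fam %>% arrange(dplyr::desc(.data$width))
  used <- character()
  for (i in seq_len(n_nested)) {
    host_fam <- fam_by_width$family[i]
    nest_fam <- fam_by_width$family[nrow(fam_by_width) - i + 1]
    if (host_fam == nest_fam) break
    host_w <- fam_by_width$width[i]
    nest_w <- fam_by_width$width[nrow(fam_by_width) - i + 1]
    if (nest_w > host_w - 100) next
    host_el <- which(tes$family == host_fam & !(tes$element_id %in% used))[1]
    nest_el <- which(tes$family == nest_fam & !(tes$element_id %in% used))[1]
    if (is.na(host_el) || is.na(nest_el)) next
    off <- sample(seq(50L, host_w - nest_w - 50L), 1)
    tes$start[nest_el] <- tes$start[host_el] + off
    tes$end[nest_el] <- tes$start[nest_el] + nest_w
    tes$chrom[nest_el] <- tes$chrom[host_el]
    used <- c(used, tes$element_id[c(host_el, nest_el)])
  }

  # --- plant one TE overlapping a gene exon (partially, extending 3') ---
  cand <- which(!tes$is_helitron & !(tes$element_id %in% used))
  gaps <- placed %>%
    group_by(.data$chrom) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    mutate(gap_after = dplyr::lead(.data$start, default = .env$config$chrom_length_bp) - .data$end) %>%
    ungroup() %>%
    filter(.data$kind == "gene")
  move_w <- tes$end[cand[1]] - tes$start[cand[1]]
  slot <- gaps %>% filter(.data$gap_after > move_w + 200)
  if (nrow(slot) > 0 && length(cand) > 0) {
    g <- genes %>% filter(.data$gene_id == sprintf("GENE%04d", slot$idx[1]))
    last_ex <- exons %>% filter(.data$gene_id == g$gene_id) %>%
      arrange(.data$end) %>% dplyr::slice_tail(n = 1)
    el <- cand[1]
    tes$chrom[el] <- last_ex$chrom
    tes$start[el] <- last_ex$end - 80L
    tes$end[el] <- tes$start[el] + move_w
  }

  # --- planted truth ---
  n_de_genes <- max(1L, round(config$de_fraction * config$n_genes))
  n_de_fams <- max(1L, round(config$de_fraction * config$n_te_families))
  de_genes <- sample(genes$gene_id, n_de_genes)
  de_fams <- sample(fam$family, n_de_fams)
  de_features <- tibble(
    feature_id = c(de_genes, de_fams),
    feature_type = c(rep("gene", n_de_genes), rep("te_family", n_de_fams)),
    direction = sample(c("up", "down"), n_de_genes + n_de_fams,
                       replace = TRUE, prob = c(2 / 3, 1 / 3)),
    log2fc = config$planted_log2fc
  )

  dmrs <- config$dmr_spec %||% default_dmr_spec(seqlengths)
  islands <- config$island_spec %||% default_island_spec(seqlengths)
  check_planted_tiles(dmrs, seqlengths)
  check_planted_tiles(islands, seqlengths)

  structure(
    list(genes = genes, exons = exons, tes = tes,
         truth = list(de_features = de_features, dmrs = dmrs,
                      islands = islands, epiallele = NULL),
         seqlengths = seqlengths, config = config),
    class = "synth_annotation"
  )
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
default_dmr_spec <- function(seqlengths) {
  c1 <- names(seqlengths)[1]
  cl <- names(seqlengths)[length(seqlengths)]
  L <- unname(seqlengths[1])
  tibble(
    chrom = c(c1, c1, c1, cl, cl),
    tile_start = tile_of(round(L * c(0.13, 0.27, 0.41, 0.19, 0.33))),
    context = c("CG", "CHG", "CHH", "CG", "CHG"),
    level_a = c(0.85, 0.85, 0.02, 0.90, 0.80),
    level_b = c(0.05, 0.10, 0.40, 0.10, 0.05)
  )
}

#' @noRd
default_island_spec <- function(seqlengths) {
  c1 <- names(seqlengths)[1]
  cl <- names(seqlengths)[length(seqlengths)]
  L <- unname(seqlengths[1])
  tibble(
    chrom = c(c1, c1, cl, cl),
    tile_start = tile_of(round(L * c(0.55, 0.72, 0.61, 0.83))),
    chh_level = 0.40
  )
}

#' @noRd
check_planted_tiles <- function(spec, seqlengths) {
  if (nrow(spec) == 0) return(invisible(spec))
  bad <- !(spec$chrom %in% names(seqlengths)) |
    spec$tile_start < 0 | spec$tile_start >= seqlengths[spec$chrom]
  if (any(bad)) abort("planted tile outside the genome")
  lv <- unlist(spec[intersect(c("level_a", "level_b", "chh_level"), names(spec))])
  if (any(lv < 0 | lv > 1)) abort("planted methylation level outside [0, 1]")
  invisible(spec)
}
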