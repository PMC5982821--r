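#' Summarize TE families: size class, LTR age proxy, GC, gene distance
#'
#' Per family: member count and size class (`single` = 1, `small` = 2-9,
#' `medium` = 10-99, `large` >= 100 members), mean LTR similarity over members
#' that have one (the age proxy: younger insertions have more similar LTRs),
#' mean GC content, and the mean over members of each member's distance to the
#' nearest gene span (0 for overlapping). Differential-expression status per
#' pathway is joined on when a consistent-set table is supplied.
#'
#' @param tes TE element tibble.
#' @param genes Gene coordinate tibble.
#' @param de_sets Optional output of [consistent_de()] (TE family rows).
#' @return Tibble `family`, `superfamily`, `te_class`, `n_members`,
#'   `size_class`, `mean_ltr_similarity`, `mean_gc`, `mean_distance_to_gene`,
#'   plus `de_<pathway>` columns when `de_sets` is given.
#' @export
family_summary <- function(tes, genes, de_sets = NULL) {
  if (nrow(tes) == 0) {
    warn("no TE elements; empty summary")
    return(tibble(family = character()))
  }
  dist <- element_gene_distance(tes, genes)
  out <- tes %>%
    left_join(dist, by = "element_id") %>%
    group_by(.data$family, .data$superfamily, .data$te_class) %>%
    summarise(
      n_members = n(),
      mean_ltr_similarity = if (all(is.na(.data$ltr_similarity))) NA_real_ else
        mean(.data$ltr_similarity, na.rm = TRUE),
      mean_gc = mean(.data$gc_content, na.rm = TRUE),
      mean_distance_to_gene = mean(.data$distance_to_gene),
      .groups = "drop"
    ) %>%
    mutate(size_class = size_class_of(.data$n_members))
  if (!is.null(de_sets)) {
    de_fam <- de_sets %>%
      filter(!("feature_type" %in% names(de_sets)) |
               .data$feature_type == "te_family") %>%
      select(family = "feature_id", "pathway", "direction") %>%
      tidyr::pivot_wider(names_from = "pathway", values_from = "direction",
                        names_prefix = "de_", values_fn = first)
    out <- out %>% left_join(de_fam, by = "family")
  }
  out %>% arrange(.data$family)
}

#' @noRd
size_class_of <- function(n) {
  case_when(
    n >= 100 ~ "large",
    n >= 10 ~ "medium",
    n >= 2 ~ "small",
    TRUE ~ "single"
  )
}

#' @noRd
element_gene_distance <- function(tes, genes) {
  if (nrow(genes) == 0) {
    return(tibble(element_id = tes$element_id, distance_to_gene = NA_real_))
  }
  te_gr <- intervals_to_granges(tes)
  gene_gr <- intervals_to_granges(genes)
  hits <- GenomicRanges::distanceToNearest(te_gr, gene_gr, ignore.strand = TRUE)
  d <- rep(NA_real_, nrow(tes))
  d[S4Vectors::queryHits(hits)] <- S4Vectors::mcols(hits)$distance
  tibble(element_id = tes$element_id, distance_to_gene = d)
}

#' Welch t-test of a feature subset against the genome-wide distribution
#'
#' Used to ask whether families with altered expression deviate from all
#' families in an attribute (LTR similarity, GC content, gene distance).
#'
#' @param values_subset,values_all Numeric vectors (>= 2 values each).
#' @param p_cutoff Significance threshold.
#' @return Tibble `t`, `df`, `p`, `mean_subset`, `mean_all`, `flag`.
#' @export
compare_feature_to_genomewide <- function(values_subset, values_all,
                                          p_cutoff = 0.01) {
  values_subset <- values_subset[!is.na(values_subset)]
  values_all <- values_all[!is.na(values_all)]
  if (length(values_subset) < 2 || length(values_all) < 2) {
    abort("need >= 2 values per group")
  }
  if (sd(values_subset) == 0 && sd(values_all) == 0) {
    abort("zero variance in both groups")
  }
  tt <- t.test(values_subset, values_all)
  tibble(
    t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
    mean_subset = mean(values_subset), mean_all = mean(values_all),
    flag = tt$p.value < p_cutoff
  )
}

#' Classify a family's expression as locus-specific or coordinate
#'
#' A family is testable if it has fewer than `max_members` members and at
#' least `min_unique_fraction` of its reads are uniquely assigned to specific
#' elements. For testable families, the unique reads are apportioned across
#' elements; if a single element holds at least `dominance` of them the
#' pattern is `locus_specific`, otherwise `coordinate` (expression of several
#' members).
#'
#' @param element_counts Per-element unique counts
#'   ([element_unique_counts()]-shaped: `element_id`, `family`,
#'   `unique_count`).
#' @param fam_counts Per-family counts ([family_counts()]-shaped: `family`,
#'   `unique_count`, `multi_count`, `count`).
#' @param max_members Families with this many members or more are untestable.
#' @param min_unique_fraction Minimum uniquely-assignable fraction of family
#'   reads.
#' @param dominance Fraction of unique reads one element must hold for
#'   `locus_specific`.
#' @return Tibble `family`, `n_members`, `unique_fraction`, `testable`,
#'   `pattern` (`locus_specific` / `coordinate` / `untestable`),
#'   `top_element`, `top_fraction`.
#' @export
classify_family_pattern <- function(element_counts, fam_counts,
                                    max_members = 10,
                                    min_unique_fraction = 0.5,
                                    dominance = 0.9) {
  members <- element_counts %>%
    group_by(.data$family) %>%
    summarise(
      n_members = n(),
      top_element = .data$element_id[which.max(.data$unique_count)],
      top_unique = max(.data$unique_count),
      sum_unique = sum(.data$unique_count),
      .groups = "drop"
    )
  fam_counts %>%
    left_join(members, by = "family") %>%
    mutate(
      unique_fraction = if_else(.data$count > 0,
                                .data$unique_count / .data$count, NA_real_),
      testable = .data$n_members < max_members &
        !is.na(.data$unique_fraction) &
        .data$unique_fraction >= min_unique_fraction &
        .data$sum_unique > 0,
      top_fraction = if_else(.data$sum_unique > 0,
                             .data$top_unique / .data$sum_unique, NA_real_),
      pattern = case_when(
        !.data$testable ~ "untestable",
        .data$top_fraction >= dominance ~ "locus_specific",
        TRUE ~ "coordinate"
      ),
      top_element = if_else(.data$testable, .data$top_element, NA_character_)
    ) %>%
    select("family", "n_members", "unique_fraction", "testable", "pattern",
           "top_element", "top_fraction")
}

#' Per-element share of a family's unique reads
#'
#' For testable families the fractions sum to one over the family's elements.
#'
#' @param element_counts Per-element unique counts.
#' @return `element_counts` plus `unique_fraction` within family.
#' @export
element_unique_fractions <- function(element_counts) {
  element_counts %>%
    group_by(.data$family) %>%
    mutate(unique_fraction = if (sum(.data$unique_count) > 0)
      .data$unique_count / sum(.data$unique_count) else NA_real_) %>%
    ungroup()
}
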