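#' Filter alignment records into unique and multi-mapped sets
#'
#' Drops improperly paired records and records with more than `max_hits`
#' reported hits. A record is unique if it reports a single hit; when a `mapq`
#' column is present (real aligner output), a MAPQ of at least 50 also counts
#' as unique, mirroring a `samtools -q 50` filter.
#'
#' @param records Hit-level alignment tibble (`read_id`, `chrom`, `start`,
#'   `end`, `strand`, `properly_paired`, `n_hits`, optionally `mapq`).
#' @param max_hits Maximum reported hits retained (aligner reporting cap).
#' @return List with tibbles `unique` and `multi`.
#' @export
filter_alignments <- function(records, max_hits = 20) {
  if (any(records$n_hits < 1)) abort("alignment record with zero hits")
  kept <- records %>% filter(.data$properly_paired, .data$n_hits <= max_hits)
  if ("mapq" %in% names(kept)) {
    uq <- kept %>% group_by(.data$read_id) %>%
      mutate(.unique = first(.data$n_hits) == 1L | max(.data$mapq) >= 50) %>%
      ungroup()
    list(unique = uq %>% filter(.data$.unique) %>% select(-".unique"),
         multi = uq %>% filter(!.data$.unique) %>% select(-".unique"))
  } else {
    list(unique = kept %>% filter(.data$n_hits == 1L),
         multi = kept %>% filter(.data$n_hits > 1L))
  }
}

#' @noRd
overlap_annotation <- function(records, resolved, stranded = "no") {
  iv <- resolved$intervals
  pairs <- interval_overlap_pairs(records, iv)
  ov <- tibble(
    read_id = records$read_id[pairs$x_idx],
    read_strand = records$strand[pairs$x_idx],
    owner_id = iv$owner_id[pairs$y_idx],
    owner_kind = iv$owner_kind[pairs$y_idx],
    ov_width = pmin(records$end[pairs$x_idx], iv$end[pairs$y_idx]) -
      pmax(records$start[pairs$x_idx], iv$start[pairs$y_idx])
  )
  ov
}

#' Count unique reads per gene (union mode)
#'
#' A unique record overlapping exons of exactly one gene increments that gene;
#' records overlapping exons of two or more genes are ambiguous and counted
#' nowhere; records overlapping no exon contribute nothing here.
#'
#' @param unique_records Unique records from [filter_alignments()].
#' @param resolved Exon-masked `resolved_annotation` (provides `gene_exon`
#'   intervals).
#' @return Tibble `gene_id`, `count` with a row for every gene in the
#'   annotation.
#' @export
count_genes <- function(unique_records, resolved) {
  all_genes <- unique(
    resolved$intervals$owner_id[resolved$intervals$owner_kind == "gene_exon"]
  )
  ov <- overlap_annotation(unique_records, resolved) %>%
    filter(.data$owner_kind == "gene_exon") %>%
    distinct(.data$read_id, .data$owner_id)
  counted <- ov %>%
    group_by(.data$read_id) %>%
    filter(n() == 1) %>%
    ungroup() %>%
    dplyr::count(.data$owner_id, name = "count")
  tibble(gene_id = all_genes) %>%
    left_join(counted, by = c(gene_id = "owner_id")) %>%
    mutate(count = dplyr::coalesce(.data$count, 0L)) %>%
    arrange(.data$gene_id)
}

#' Assign reads hierarchically to genes, TE elements and TE families
#'
#' Implements the hierarchical assignment rules: unique records overlapping a
#' single gene's exons are gene reads; unique records overlapping TE-owned
#' bases (and no exon) are element reads; multi-mapped records whose
#' TE-overlapping hits all fall in one family are family reads; hits in two or
#' more families are ambiguous and counted nowhere. Any record with at least
#' one hit overlapping a gene exon is excluded from TE counting (status
#' `gene_te_conflict` unless it is itself a countable gene read), preventing
#' gene transcription from being scored as TE expression.
#'
#' @param unique_records,multi_records Output of [filter_alignments()].
#' @param resolved Exon-masked, disjoint `resolved_annotation`.
#' @return Tibble `read_id`, `status` (`gene`, `te_element`,
#'   `te_family_multi`, `ambiguous_family`, `gene_te_conflict`, `unassigned`),
#'   `target_id`, `detail`. Every filtered record receives exactly one status.
#' @export
assign_te_reads <- function(unique_records, multi_records, resolved) {
  fam_of <- setNames(resolved$elements$family, resolved$elements$element_id)
  assign_one <- function(records, is_unique) {
    ids <- unique(records$read_id)
    if (length(ids) == 0) {
      return(tibble(read_id = character(), status = character(),
                    target_id = character(), detail = character()))
    }
    ov <- overlap_annotation(records, resolved)
    gene_ov <- ov %>% filter(.data$owner_kind == "gene_exon") %>%
      group_by(.data$read_id) %>%
      summarise(n_genes = n_distinct(.data$owner_id),
                gene_id = first(.data$owner_id), .groups = "drop")
    te_ov <- ov %>% filter(.data$owner_kind == "te_element") %>%
      mutate(family = unname(fam_of[.data$owner_id])) %>%
      group_by(.data$read_id) %>%
      summarise(
        n_fams = n_distinct(.data$family),
        family = first(.data$family),
        top_element = .data$owner_id[which.max(.data$ov_width)][1],
        .groups = "drop"
      )
    tibble(read_id = ids) %>%
      left_join(gene_ov, by = "read_id") %>%
      left_join(te_ov, by = "read_id") %>%
      mutate(
        status = case_when(
          is_unique & !is.na(.data$n_genes) & .data$n_genes == 1 ~ "gene",
          !is.na(.data$n_genes) & is_unique ~ "gene_te_conflict",
          !is.na(.data$n_genes) ~ "gene_te_conflict",
          is.na(.data$n_fams) ~ "unassigned",
          .data$n_fams >= 2 ~ "ambiguous_family",
          is_unique ~ "te_element",
          TRUE ~ "te_family_multi"
        ),
        target_id = case_when(
          .data$status == "gene" ~ .data$gene_id,
          .data$status == "te_element" ~ .data$top_element,
          .data$status == "te_family_multi" ~ .data$family,
          TRUE ~ NA_character_
        ),
        detail = case_when(
          .data$status == "gene_te_conflict" & is_unique &
            !is.na(.data$n_genes) & .data$n_genes > 1 ~ "ambiguous_gene",
          .data$status == "gene_te_conflict" ~ "exon_overlap",
          TRUE ~ NA_character_
        )
      ) %>%
      select("read_id", "status", "target_id", "detail")
  }
  bind_rows(
    assign_one(unique_records, TRUE),
    assign_one(multi_records, FALSE)
  )
}

#' Combine unique and multi-mapped assignments into per-family counts
#'
#' Family count = element-level unique reads in the family plus multi-mapped
#' reads assigned to the family. Families with no reads keep a zero row.
#'
#' @param assignments Output of [assign_te_reads()].
#' @param resolved The `resolved_annotation` (family index).
#' @return Tibble `family`, `unique_count`, `multi_count`, `count`.
#' @export
family_counts <- function(assignments, resolved) {
  fam_of <- setNames(resolved$elements$family, resolved$elements$element_id)
  uq <- assignments %>% filter(.data$status == "te_element") %>%
    mutate(family = unname(fam_of[.data$target_id])) %>%
    dplyr::count(.data$family, name = "unique_count")
  mu <- assignments %>% filter(.data$status == "te_family_multi") %>%
    dplyr::count(.data$target_id, name = "multi_count") %>%
    rename(family = "target_id")
  tibble(family = sort(unique(resolved$elements$family))) %>%
    left_join(uq, by = "family") %>%
    left_join(mu, by = "family") %>%
    mutate(
      unique_count = dplyr::coalesce(.data$unique_count, 0L),
      multi_count = dplyr::coalesce(.data$multi_count, 0L),
      count = .data$unique_count + .data$multi_count
    )
}

#' Per-element unique-read counts
#'
#' @inheritParams family_counts
#' @return Tibble `element_id`, `family`, `unique_count` covering every
#'   element of the annotation.
#' @export
element_unique_counts <- function(assignments, resolved) {
  uq <- assignments %>% filter(.data$status == "te_element") %>%
    dplyr::count(.data$target_id, name = "unique_count")
  resolved$elements %>%
    select("element_id", "family") %>%
    left_join(uq, by = c(element_id = "target_id")) %>%
    mutate(unique_count = dplyr::coalesce(.data$unique_count, 0L))
}

#' Quantify one or more libraries into a gene + TE family count table
#'
#' Runs [filter_alignments()], [count_genes()], [assign_te_reads()] and
#' [family_counts()] for each library and assembles the features-by-libraries
#' count table used by the differential expression stage.
#'
#' @param alignments Named list of hit-level alignment tibbles, one per
#'   library.
#' @param resolved Exon-masked `resolved_annotation`.
#' @return Tibble `feature_id`, `feature_type` (`gene` / `te_family`), one
#'   integer column per library.
#' @export
quantify_expression <- function(alignments, resolved) {
  stopifnot(is.list(alignments), !is.null(names(alignments)))
  per_lib <- purrr::imap(alignments, function(al, lib) {
    fl <- filter_alignments(al)
    g <- count_genes(fl$unique, resolved)
    a <- assign_te_reads(fl$unique, fl$multi, resolved)
    f <- family_counts(a, resolved)
    bind_rows(
      tibble(feature_id = g$gene_id, feature_type = "gene", n = g$count),
      tibble(feature_id = f$family, feature_type = "te_family", n = f$count)
    ) %>% mutate(library = lib)
  })
  bind_rows(per_lib) %>%
    tidyr::pivot_wider(names_from = "library", values_from = "n",
                       values_fill = 0L)
}

#' Normalize a count table to reads per million (RPM)
#'
#' The per-library denominator is the total of gene reads plus TE family
#' reads, so gene and family RPM values share one scale and each library's
#' column sums to 10^6 when all counted reads are in the table.
#'
#' @param counts Count tibble (`feature_id`, `feature_type`, library columns).
#' @return Tibble of the same shape with RPM values.
#' @export
rpm_normalize <- function(counts) {
  libs <- setdiff(names(counts), c("feature_id", "feature_type"))
  denom <- purrr::map_dbl(counts[libs], sum)
  if (any(denom == 0)) {
    abort(sprintf("zero counted reads in library: %s",
                  paste(libs[denom == 0], collapse = ", ")))
  }
  out <- counts
  for (l in libs) out[[l]] <- counts[[l]] / denom[[l]] * 1e6
  out
}

#' Flag expressed features
#'
#' A feature is expressed if its RPM exceeds `min_rpm` (strictly) in at least
#' `min_libraries` libraries, in any genotype.
#'
#' @param rpm RPM tibble from [rpm_normalize()].
#' @param min_rpm RPM threshold (strict).
#' @param min_libraries Minimum number of qualifying libraries.
#' @return The tibble's `feature_id`/`feature_type` columns plus
#'   `n_libraries_above` and logical `expressed`.
#' @export
flag_expressed <- function(rpm, min_rpm = 1, min_libraries = 3) {
  libs <- setdiff(names(rpm), c("feature_id", "feature_type"))
  if (length(libs) < min_libraries) {
    abort(sprintf("need at least %d libraries", min_libraries))
  }
  n_above <- rowSums(as.matrix(rpm[libs]) > min_rpm)
  rpm %>%
    select(any_of(c("feature_id", "feature_type"))) %>%
    mutate(n_libraries_above = as.integer(n_above),
           expressed = n_above >= min_libraries)
}

#' Fraction of counted reads assigned to TE families, per library
#'
#' @param counts Count tibble (`feature_id`, `feature_type`, library columns).
#' @return Tibble `library`, `te_reads`, `total_reads`, `fraction`.
#' @export
te_read_fraction <- function(counts) {
  libs <- setdiff(names(counts), c("feature_id", "feature_type"))
  te <- counts$feature_type == "te_family"
  purrr::map_dfr(libs, function(l) {
    tot <- sum(counts[[l]])
    tibble(library = l,
           te_reads = sum(counts[[l]][te]),
           total_reads = tot,
           fraction = if (tot > 0) sum(counts[[l]][te]) / tot else 0)
  })
}
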