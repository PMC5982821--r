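# Shared fixtures, built in code. tiny_* keep unit tests fast; the cached
# annotation avoids regenerating identical objects across test files.

tiny_config <- function(seed = 11, read_depth = 4000, ...) {
  synth_config(
    n_chromosomes = 2, chrom_length_bp = 60000, n_genes = 10,
    n_te_families = 5, copies_per_family = 3, read_depth = read_depth,
    seed = seed, ...
  )
}

.fixture_env <- new.env(parent = emptyenv())

tiny_annotation <- function() {
  if (is.null(.fixture_env$ann)) {
    .fixture_env$ann <- generate_genome_annotation(tiny_config())
  }
  .fixture_env$ann
}

# hand-built TE tibble row
te_row <- function(element_id, family, chrom = "chr1", start, end,
                   superfamily = "RLG", is_helitron = FALSE,
                   ltr_similarity = NA_real_, gc_content = 0.45) {
  tibble::tibble(
    element_id = element_id, family = family, superfamily = superfamily,
    te_class = ifelse(startsWith(superfamily, "R"), "I", "II"),
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    is_helitron = is_helitron, ltr_similarity = ltr_similarity,
    gc_content = gc_content
  )
}

# hand-built hit-level alignment record (one row per hit)
hit_rows <- function(read_id, chrom, starts, width = 100,
                     properly_paired = TRUE, strand = "+") {
  tibble::tibble(
    read_id = read_id, chrom = chrom, start = as.integer(starts),
    end = as.integer(starts + width), strand = strand,
    properly_paired = properly_paired, n_hits = length(starts)
  )
}

# per-base ownership bitmap oracle: named integer vector index -> owner
bitmap_owners <- function(intervals, chrom_len) {
  v <- rep(NA_character_, chrom_len)
  for (i in seq_len(nrow(intervals))) {
    idx <- (intervals$start[i] + 1):intervals$end[i]
    v[idx] <- intervals$owner_id[i]
  }
  v
}

# tile table builder for threshold tests
make_tiles <- function(..., seqlengths = c(chr1 = 10000), genotype = "g") {
  tl <- tibble::tibble(...)
  tl <- tl %>% dplyr::mutate(
    level = .data$mc_reads / .data$total_reads,
    mean_site_coverage = .data$total_reads / .data$n_sites
  )
  attr(tl, "seqlengths") <- seqlengths
  attr(tl, "genotype") <- genotype
  tl
}
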