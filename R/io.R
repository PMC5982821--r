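# File-format boundaries. Coordinates are 0-based half-open internally;
# GFF3/SAM are 1-based inclusive and conversion happens only here.

#' Write gene models (with exons) to GFF3
#'
#' @param genes,exons Tibbles as produced by [generate_genome_annotation()].
#' @param path Output file.
#' @param seqlengths Optional named vector of chromosome lengths.
#' @return `path`, invisibly.
#' @export
write_gene_gff3 <- function(genes, exons, path, seqlengths = NULL) {
  g <- intervals_to_granges(genes, seqlengths)
  S4Vectors::mcols(g) <- S4Vectors::DataFrame(
    source = "temeth", type = "gene", ID = genes$gene_id
  )
  e <- intervals_to_granges(exons, seqlengths)
  S4Vectors::mcols(e) <- S4Vectors::DataFrame(
    source = "temeth", type = "exon", ID = exons$exon_id, Parent = exons$gene_id
  )
  rtracklayer::export(c(g, e), path, format = "gff3")
  invisible(path)
}

#' Write a TE annotation to GFF3
#'
#' Elements carry their `family`, `superfamily` and `te_class` as attributes,
#' plus `ltr_similarity` and `gc_content` where present. Helitrons get the
#' feature type `helitron`; everything else `transposable_element`.
#'
#' @param tes TE element tibble.
#' @inheritParams write_gene_gff3
#' @return `path`, invisibly.
#' @export
write_te_gff3 <- function(tes, path, seqlengths = NULL) {
  gr <- intervals_to_granges(tes, seqlengths)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "temeth",
    type = ifelse(tes$is_helitron, "helitron", "transposable_element"),
    ID = tes$element_id,
    family = tes$family,
    superfamily = tes$superfamily,
    ltr_similarity = tes$ltr_similarity,
    gc_content = tes$gc_content
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read gene and TE annotations from GFF3
#'
#' Coordinates are converted from GFF3's 1-based inclusive convention to the
#' package-internal 0-based half-open convention. TE records must carry a
#' `family` attribute; the superfamily code determines the class (codes
#' starting with `R`, e.g. RLG/RLC, are class I retrotransposons; codes
#' starting with `D`, e.g. DTA/DTM/DHH, are class II DNA transposons).
#'
#' @param gene_gff3_path GFF3 with `gene` and `exon` (Parent-linked) records.
#' @param te_annotation_path GFF3 with TE element records.
#' @return List with tibbles `genes`, `exons`, `tes`.
#' @export
load_annotations <- function(gene_gff3_path, te_annotation_path) {
  gg <- rtracklayer::import(gene_gff3_path, format = "gff3")
  gene_rows <- gg[gg$type == "gene"]
  exon_rows <- gg[gg$type == "exon"]
  genes <- tibble(
    gene_id = as.character(gene_rows$ID),
    chrom = as.character(GenomeInfoDb::seqnames(gene_rows)),
    start = GenomicRanges::start(gene_rows) - 1L,
    end = GenomicRanges::end(gene_rows),
    strand = as.character(GenomicRanges::strand(gene_rows))
  ) %>%
    mutate(tss = if_else(.data$strand == "+", .data$start, .data$end),
           tts = if_else(.data$strand == "+", .data$end, .data$start))
  parents <- as.character(unlist(exon_rows$Parent))
  exons <- tibble(
    gene_id = parents,
    exon_id = as.character(exon_rows$ID),
    chrom = as.character(GenomeInfoDb::seqnames(exon_rows)),
    start = GenomicRanges::start(exon_rows) - 1L,
    end = GenomicRanges::end(exon_rows),
    strand = as.character(GenomicRanges::strand(exon_rows))
  )

  tg <- rtracklayer::import(te_annotation_path, format = "gff3")
  fam <- tg$family
  if (is.null(fam) || any(is.na(fam) | fam == "")) {
    bad <- if (is.null(fam)) as.character(tg$ID) else
      as.character(tg$ID)[is.na(fam) | fam == ""]
    abort(sprintf("TE record(s) missing family attribute: %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  opt_chr <- function(x) if (is.null(x)) rep(NA_character_, length(tg)) else
    as.character(x)
  opt_num <- function(x) if (is.null(x)) rep(NA_real_, length(tg)) else
    suppressWarnings(as.numeric(x))
  superfamily <- opt_chr(tg$superfamily)
  tes <- tibble(
    element_id = as.character(tg$ID),
    family = as.character(fam),
    superfamily = superfamily,
    chrom = as.character(GenomeInfoDb::seqnames(tg)),
    start = GenomicRanges::start(tg) - 1L,
    end = GenomicRanges::end(tg),
    is_helitron = as.character(tg$type) == "helitron" |
      (!is.na(superfamily) & startsWith(superfamily, "DHH")),
    ltr_similarity = opt_num(tg$ltr_similarity),
    gc_content = opt_num(tg$gc_content)
  ) %>%
    mutate(te_class = case_when(
      is.na(.data$superfamily) ~ NA_character_,
      startsWith(.data$superfamily, "R") ~ "I",
      TRUE ~ "II"
    ), .after = "superfamily")
  list(genes = genes, exons = exons, tes = tes)
}

#' Write merged-fragment alignment records as SAM
#'
#' Each hit becomes one SAM line; non-primary hits of a multi-mapping read are
#' flagged secondary. Unique hits get MAPQ 60, multi-hits MAPQ 1, and every
#' line carries an `NH` tag with the reported hit count, so the uniqueness
#' conventions of real aligner output (MAPQ filter or NH tag) apply.
#'
#' @param alignments Hit-level tibble from [simulate_alignments()].
#' @param seqlengths Named chromosome lengths for the header.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_alignments_sam <- function(alignments, seqlengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths), seqlengths), con)
  al <- alignments %>% group_by(.data$read_id) %>%
    mutate(.hit_i = row_number()) %>% ungroup()
  flag <- 1L + 64L +
    ifelse(al$properly_paired, 2L, 0L) +
    ifelse(al$strand == "-", 16L, 0L) +
    ifelse(al$.hit_i > 1, 256L, 0L)
  lines <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%dM\t=\t%d\t%d\t*\t*\tNH:i:%d",
    al$read_id, flag, al$chrom, al$start + 1L,
    ifelse(al$n_hits == 1L, 60L, 1L),
    al$end - al$start, al$start + 1L, al$end - al$start, al$n_hits
  )
  writeLines(lines, con)
  invisible(path)
}

#' Read merged-fragment alignment records from SAM
#'
#' Requires the Rsamtools package. Returns the same hit-level layout that
#' [simulate_alignments()] produces (without truth labels), plus a `mapq`
#' column used by [filter_alignments()]'s uniqueness rule for real aligner
#' output.
#'
#' @param path SAM file.
#' @return Hit-level tibble.
#' @export
read_alignments_sam <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    abort("reading SAM requires the Rsamtools package")
  }
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  res <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "qwidth", "mapq", "cigar"),
      tag = "NH"
    )
  )[[1]]
  span <- GenomicAlignments_width(res$cigar)
  tibble(
    read_id = res$qname,
    chrom = as.character(res$rname),
    start = res$pos - 1L,
    end = res$pos - 1L + span,
    strand = ifelse(bitwAnd(res$flag, 16L) > 0, "-", "+"),
    properly_paired = bitwAnd(res$flag, 2L) > 0,
    mapq = res$mapq,
    n_hits = res$tag$NH
  ) %>%
    group_by(.data$read_id) %>%
    mutate(n_hits = dplyr::coalesce(first(.data$n_hits), n())) %>%
    ungroup()
}

#' @noRd
GenomicAlignments_width <- function(cigar) {
  # reference span of a cigar like "150M"; only M/D/N consume reference here
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)
  purrr::map2_int(cigar, ops, function(cg, m) {
    pieces <- regmatches(cg, list(m))[[1]]
    consume <- grepl("[MDN=X]$", pieces)
    sum(as.integer(sub("[A-Z=]$", "", pieces[consume])))
  })
}

#' Write the planted truth of a synthetic annotation as JSON
#'
#' @param truth The `truth` element of a `synth_annotation`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
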