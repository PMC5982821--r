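# A small hand-built annotation used across the assignment tests:
#   gene g1 exon [1000, 1500)
#   family F1 = {e1 [3000,3500), e2 [5000,5500)}  (two copies)
#   family F2 = {e3 [7000,7400)}                  (single copy)
quantify_fixture <- function() {
  tes <- dplyr::bind_rows(
    te_row("e1", "F1", start = 3000, end = 3500),
    te_row("e2", "F1", start = 5000, end = 5500),
    te_row("e3", "F2", start = 7000, end = 7400)
  )
  exons <- tibble::tibble(gene_id = "g1", exon_id = "g1.e1", chrom = "chr1",
                          start = 1000L, end = 1500L, strand = "+")
  resolve_te_annotation(tes, exons)
}

test_that("alignment filtering separates unique from multi and drops the rest", {
  rec <- dplyr::bind_rows(
    hit_rows("u1", "chr1", 1000),
    hit_rows("m1", "chr1", c(3000, 5000, 7000)),
    hit_rows("x1", "chr1", 1000, properly_paired = FALSE),
    hit_rows("over", "chr1", seq(0, 3000, by = 100))   # 31 hits
  )
  fl <- filter_alignments(rec)
  expect_equal(unique(fl$unique$read_id), "u1")
  expect_equal(unique(fl$multi$read_id), "m1")
  expect_error(filter_alignments(dplyr::mutate(rec, n_hits = 0L)), "zero hits")
})

test_that("MAPQ-based uniqueness applies to real aligner output", {
  rec <- dplyr::bind_rows(
    hit_rows("hiq", "chr1", 1000) %>% dplyr::mutate(mapq = 60L),
    hit_rows("loq", "chr1", c(3000, 5000)) %>% dplyr::mutate(mapq = 1L)
  )
  fl <- filter_alignments(rec)
  expect_equal(unique(fl$unique$read_id), "hiq")
  expect_equal(unique(fl$multi$read_id), "loq")
})

test_that("gene counting is union mode", {
  res <- quantify_fixture()
  # one exon -> counted; two genes -> ambiguous; intergenic -> nothing
  two_gene_exons <- tibble::tibble(
    gene_id = c("g1", "g2"), exon_id = c("g1.e1", "g2.e1"), chrom = "chr1",
    start = c(1000L, 1450L), end = c(1500L, 1900L), strand = "+"
  )
  res2 <- resolve_te_annotation(
    te_row("e9", "F9", start = 9000, end = 9300), two_gene_exons)
  rec <- dplyr::bind_rows(
    hit_rows("in_gene", "chr1", 1100),
    hit_rows("spans_two", "chr1", 1440, width = 50),
    hit_rows("intergenic", "chr1", 8000)
  )
  counts <- count_genes(rec, res2)
  expect_equal(counts$count[counts$gene_id == "g1"], 1L)
  expect_equal(counts$count[counts$gene_id == "g2"], 0L)
  expect_equal(sum(counts$count), 1L)
})

test_that("TE assignment follows the hierarchical rules", {
  res <- quantify_fixture()
  unique_recs <- dplyr::bind_rows(
    hit_rows("in_e3", "chr1", 7100),           # unique in single-copy element
    hit_rows("in_gene", "chr1", 1100),         # exon -> gene, not TE
    hit_rows("nowhere", "chr1", 9500)
  )
  multi_recs <- dplyr::bind_rows(
    hit_rows("fam_F1", "chr1", c(3100, 5100)),       # both hits in F1
    hit_rows("two_fams", "chr1", c(3100, 7100)),     # F1 and F2
    hit_rows("te_and_gene", "chr1", c(3100, 1100))   # exon hit -> conflict
  )
  asg <- assign_te_reads(unique_recs, multi_recs, res)
  get <- function(id) asg[asg$read_id == id, ]
  expect_equal(get("in_e3")$status, "te_element")
  expect_equal(get("in_e3")$target_id, "e3")
  expect_equal(get("in_gene")$status, "gene")
  expect_equal(get("nowhere")$status, "unassigned")
  expect_equal(get("fam_F1")$status, "te_family_multi")
  expect_equal(get("fam_F1")$target_id, "F1")
  expect_equal(get("two_fams")$status, "ambiguous_family")
  expect_true(is.na(get("two_fams")$target_id))
  expect_equal(get("te_and_gene")$status, "gene_te_conflict")
  # statuses partition the filtered read set
  expect_setequal(asg$read_id, c(unique(unique_recs$read_id),
                                 unique(multi_recs$read_id)))
  expect_equal(anyDuplicated(asg$read_id), 0L)
})

test_that("family counts combine unique and multi reads and keep zero rows", {
  res <- quantify_fixture()
  unique_recs <- purrr::map_dfr(1:10, ~ hit_rows(paste0("u", .x), "chr1", 7100))
  multi_recs <- purrr::map_dfr(1:5, ~ hit_rows(paste0("m", .x), "chr1",
                                               c(3100, 5100)))
  asg <- assign_te_reads(unique_recs, multi_recs, res)
  fc <- family_counts(asg, res)
  expect_equal(fc$count[fc$family == "F2"], 10L)
  expect_equal(fc$unique_count[fc$family == "F2"], 10L)
  expect_equal(fc$count[fc$family == "F1"], 5L)
  expect_equal(fc$multi_count[fc$family == "F1"], 5L)
  expect_true(all(fc$count == fc$unique_count + fc$multi_count))
  # per-element unique counts sum to the family unique count
  ec <- element_unique_counts(asg, res)
  sums <- ec %>% dplyr::group_by(.data$family) %>%
    dplyr::summarise(s = sum(.data$unique_count))
  expect_equal(sums$s[sums$family == "F2"], 10L)
  expect_equal(sums$s[sums$family == "F1"], 0L)
})

test_that("RPM normalization scales to a million over genes plus families", {
  counts <- tibble::tibble(
    feature_id = c("g1", "g2", "F1"),
    feature_type = c("gene", "gene", "te_family"),
    lib1 = c(600000L, 300000L, 100000L),
    lib2 = c(6L, 3L, 1L)
  )
  rpm <- rpm_normalize(counts)
  expect_equal(sum(rpm$lib1), 1e6)
  expect_equal(sum(rpm$lib2), 1e6)
  expect_equal(rpm$lib1[rpm$feature_id == "F1"], 1e5)
  # scale invariance: doubling all counts leaves RPM unchanged
  doubled <- counts %>% dplyr::mutate(dplyr::across(c("lib1", "lib2"), ~ .x * 2L))
  expect_equal(rpm_normalize(doubled), doubled %>%
                 dplyr::mutate(lib1 = rpm$lib1, lib2 = rpm$lib2))
  expect_error(rpm_normalize(counts %>% dplyr::mutate(lib1 = 0L)), "zero")
})

test_that("expression flagging uses strict RPM > 1 in at least 3 libraries", {
  rpm <- tibble::tibble(
    feature_id = c("a", "b", "c"),
    feature_type = "gene",
    l1 = c(1.2, 1.2, 1.0), l2 = c(1.5, 0.9, 1.0),
    l3 = c(2.0, 0.8, 1.0), l4 = c(0.3, 0.2, 1.0)
  )
  fl <- flag_expressed(rpm)
  expect_true(fl$expressed[fl$feature_id == "a"])
  expect_false(fl$expressed[fl$feature_id == "b"])
  expect_false(fl$expressed[fl$feature_id == "c"])  # exactly 1.0 never counts
  expect_error(flag_expressed(rpm %>% dplyr::select(1:4)), "at least 3")
})

test_that("TE read fraction is families over genes plus families", {
  counts <- tibble::tibble(
    feature_id = c("g1", "F1"), feature_type = c("gene", "te_family"),
    l1 = c(900000L, 100000L), l2 = c(10L, 0L)
  )
  fr <- te_read_fraction(counts)
  expect_equal(fr$fraction[fr$library == "l1"], 0.10)
  expect_equal(fr$fraction[fr$library == "l2"], 0)
  expect_true(all(fr$fraction >= 0 & fr$fraction <= 1))
})

test_that("adding reads never decreases any count", {
  res <- quantify_fixture()
  base <- dplyr::bind_rows(
    hit_rows("u1", "chr1", 7100),
    hit_rows("m1", "chr1", c(3100, 5100))
  )
  more <- dplyr::bind_rows(base, hit_rows("u2", "chr1", 7200))
  f1 <- family_counts(assign_te_reads(
    base %>% dplyr::filter(.data$n_hits == 1),
    base %>% dplyr::filter(.data$n_hits > 1), res), res)
  f2 <- family_counts(assign_te_reads(
    more %>% dplyr::filter(.data$n_hits == 1),
    more %>% dplyr::filter(.data$n_hits > 1), res), res)
  expect_true(all(f2$count >= f1$count))
})
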