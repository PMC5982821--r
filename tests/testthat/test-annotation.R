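test_that("GFF3 round trip converts coordinates and hierarchy faithfully", {
  ann <- tiny_annotation()
  gdir <- withr::local_tempdir()
  gpath <- file.path(gdir, "genes.gff3")
  tpath <- file.path(gdir, "tes.gff3")
  write_gene_gff3(ann$genes, ann$exons, gpath, ann$seqlengths)
  write_te_gff3(ann$tes, tpath, ann$seqlengths)
  back <- load_annotations(gpath, tpath)
  expect_equal(back$genes %>% dplyr::arrange(.data$gene_id),
               ann$genes %>% dplyr::arrange(.data$gene_id))
  expect_equal(
    back$tes %>% dplyr::arrange(.data$element_id),
    ann$tes %>% dplyr::arrange(.data$element_id) %>%
      dplyr::select(dplyr::all_of(names(back$tes)))
  )
})

test_that("GFF3 1-based inclusive becomes 0-based half-open internally", {
  dir <- withr::local_tempdir()
  tpath <- file.path(dir, "te.gff3")
  writeLines(c(
    "##gff-version 3",
    paste("chr1", "src", "transposable_element", "101", "200", ".", "+", ".",
          "ID=el1;family=RLC00001;superfamily=RLC", sep = "\t")
  ), tpath)
  gpath <- file.path(dir, "g.gff3")
  writeLines(c(
    "##gff-version 3",
    paste("chr1", "src", "gene", "1", "50", ".", "+", ".", "ID=g1", sep = "\t"),
    paste("chr1", "src", "exon", "1", "50", ".", "+", ".",
          "ID=g1.e1;Parent=g1", sep = "\t")
  ), gpath)
  out <- load_annotations(gpath, tpath)
  expect_equal(out$tes$start, 100L)
  expect_equal(out$tes$end, 200L)
  expect_equal(out$tes$te_class, "I")   # RLC = LTR-Copia, retrotransposon
  expect_equal(out$genes$start, 0L)
})

test_that("superfamily codes map to TE classes", {
  dir <- withr::local_tempdir()
  tpath <- file.path(dir, "te.gff3")
  writeLines(c(
    "##gff-version 3",
    paste("chr1", "s", "transposable_element", "1", "100", ".", "+", ".",
          "ID=a;family=DTA00001;superfamily=DTA", sep = "\t"),
    paste("chr1", "s", "transposable_element", "201", "300", ".", "+", ".",
          "ID=b;family=RLC00001;superfamily=RLC", sep = "\t")
  ), tpath)
  gpath <- file.path(dir, "g.gff3")
  writeLines("##gff-version 3", gpath)
  out <- load_annotations(gpath, tpath)
  expect_equal(out$tes$te_class[out$tes$element_id == "a"], "II")  # TIR-hAT
  expect_equal(out$tes$te_class[out$tes$element_id == "b"], "I")
})

test_that("a TE record without a family attribute is rejected by name", {
  dir <- withr::local_tempdir()
  tpath <- file.path(dir, "te.gff3")
  writeLines(c(
    "##gff-version 3",
    paste("chr1", "s", "transposable_element", "1", "100", ".", "+", ".",
          "ID=orphan;superfamily=RLG", sep = "\t")
  ), tpath)
  gpath <- file.path(dir, "g.gff3")
  writeLines("##gff-version 3", gpath)
  expect_error(load_annotations(gpath, tpath), "orphan")
})

test_that("helitron removal drops exactly the helitrons", {
  tes <- dplyr::bind_rows(
    te_row("h1", "DHH00001", start = 0, end = 100,
           superfamily = "DHH", is_helitron = TRUE),
    te_row("g1", "RLG00001", start = 200, end = 300)
  )
  out <- remove_helitrons(tes)
  expect_equal(out$element_id, "g1")
  expect_equal(remove_helitrons(tes[0, ]), tes[0, ])
  expect_warning(remove_helitrons(tes[1, ]), "helitron")
})

test_that("nested and partially overlapping elements resolve by shorter-wins", {
  # nested: B inside A -> B owns its span, A keeps the flanks
  tes <- dplyr::bind_rows(
    te_row("A", "F1", start = 100, end = 500),
    te_row("B", "F2", start = 200, end = 300)
  )
  r <- resolve_overlaps(tes)
  iv <- r$intervals %>% dplyr::arrange(.data$start)
  expect_equal(iv$owner_id, c("A", "B", "A"))
  expect_equal(iv$start, c(100L, 200L, 300L))
  expect_equal(iv$end, c(200L, 300L, 500L))

  # partial overlap, |B| < |A| -> B keeps all of itself
  tes2 <- dplyr::bind_rows(
    te_row("A", "F1", start = 0, end = 300),
    te_row("B", "F2", start = 200, end = 400)
  )
  iv2 <- resolve_overlaps(tes2)$intervals %>% dplyr::arrange(.data$start)
  expect_equal(iv2$owner_id, c("A", "B"))
  expect_equal(iv2$end, c(200L, 400L))

  # non-overlapping input is returned unchanged
  tes3 <- dplyr::bind_rows(
    te_row("A", "F1", start = 0, end = 100),
    te_row("B", "F2", start = 500, end = 600)
  )
  iv3 <- resolve_overlaps(tes3)$intervals
  expect_equal(nrow(iv3), 2)
  expect_setequal(iv3$owner_id, c("A", "B"))

  # equal lengths: lexicographic tie-break, loser keeps nothing in the overlap
  tes4 <- dplyr::bind_rows(
    te_row("B", "F2", start = 100, end = 300),
    te_row("A", "F1", start = 100, end = 300)
  )
  iv4 <- resolve_overlaps(tes4)$intervals
  expect_equal(iv4$owner_id, "A")
  expect_true(r$elements$fully_masked[r$elements$element_id == "B"] == FALSE)
  expect_true(resolve_overlaps(tes4)$elements$fully_masked[
    resolve_overlaps(tes4)$elements$element_id == "B"])
})

test_that("helitrons must be removed before resolution", {
  tes <- te_row("h1", "DHH1", start = 0, end = 100,
                superfamily = "DHH", is_helitron = TRUE)
  expect_error(resolve_overlaps(tes), "helitron")
})

test_that("exon masking splits TEs and keeps fully-masked elements indexed", {
  tes <- te_row("A", "F1", start = 100, end = 400)
  exons <- tibble::tibble(gene_id = "g1", exon_id = "g1.e1", chrom = "chr1",
                          start = 200L, end = 250L, strand = "+")
  r <- mask_exons(resolve_overlaps(tes), exons)
  te_iv <- r$intervals %>% dplyr::filter(.data$owner_kind == "te_element") %>%
    dplyr::arrange(.data$start)
  expect_equal(te_iv$start, c(100L, 250L))
  expect_equal(te_iv$end, c(200L, 400L))
  ex_iv <- r$intervals %>% dplyr::filter(.data$owner_kind == "gene_exon")
  expect_equal(ex_iv$owner_id, "g1")

  # exon covering a short TE entirely: zero bases, flagged, still indexed
  tes2 <- te_row("S", "F2", start = 210, end = 240)
  r2 <- mask_exons(resolve_overlaps(tes2), exons)
  expect_false("S" %in% r2$intervals$owner_id)
  expect_true(r2$elements$fully_masked[r2$elements$element_id == "S"])
  expect_true("S" %in% r2$elements$element_id)

  # no overlap: unchanged
  tes3 <- te_row("T", "F3", start = 1000, end = 1200)
  r3 <- mask_exons(resolve_overlaps(tes3), exons)
  iv3 <- r3$intervals %>% dplyr::filter(.data$owner_kind == "te_element")
  expect_equal(iv3$start, 1000L)
  expect_equal(iv3$end, 1200L)
})

test_that("resolved annotations are disjoint and conserve covered bases", {
  for (seed in c(21, 22, 23)) {
    ann <- generate_genome_annotation(tiny_config(seed = seed))
    tes <- remove_helitrons(ann$tes)
    r <- resolve_overlaps(tes)
    gr <- intervals <- r$intervals
    # pairwise disjoint per chromosome
    g <- GenomicRanges::GRanges(intervals$chrom,
                                IRanges::IRanges(intervals$start + 1, intervals$end))
    ov <- GenomicRanges::findOverlaps(g, drop.self = TRUE)
    expect_length(ov, 0)
    # base conservation against union of inputs
    input_union <- GenomicRanges::reduce(
      GenomicRanges::GRanges(tes$chrom, IRanges::IRanges(tes$start + 1, tes$end)))
    expect_equal(sum(intervals$end - intervals$start),
                 sum(GenomicRanges::width(input_union)))
    # after masking: covered = union minus exon overlap, no TE base in exons
    m <- mask_exons(r, ann$exons)
    te_iv <- m$intervals %>% dplyr::filter(.data$owner_kind == "te_element")
    exon_union <- GenomicRanges::reduce(
      GenomicRanges::GRanges(ann$exons$chrom,
                             IRanges::IRanges(ann$exons$start + 1, ann$exons$end)))
    stolen <- sum(GenomicRanges::width(
      GenomicRanges::intersect(input_union, exon_union)))
    expect_equal(sum(te_iv$end - te_iv$start),
                 sum(GenomicRanges::width(input_union)) - stolen)
    te_g <- GenomicRanges::GRanges(te_iv$chrom,
                                   IRanges::IRanges(te_iv$start + 1, te_iv$end))
    expect_length(GenomicRanges::findOverlaps(te_g, exon_union), 0)
  }
})

test_that("per-base bitmap oracle agrees with the resolver on a toy chromosome", {
  ann <- generate_genome_annotation(tiny_config(seed = 31))
  tes <- remove_helitrons(ann$tes) %>% dplyr::filter(.data$chrom == "chr1")
  r <- resolve_overlaps(tes)
  # oracle: paint bases element by element in priority order (shorter first,
  # ties by id), never repainting a claimed base
  len <- 60000L
  claimed <- rep(NA_character_, len)
  ord <- order(tes$end - tes$start, tes$element_id)
  for (i in ord) {
    idx <- (tes$start[i] + 1):tes$end[i]
    free <- is.na(claimed[idx])
    claimed[idx][free] <- tes$element_id[i]
  }
  resolved_map <- bitmap_owners(
    r$intervals %>% dplyr::filter(.data$chrom == "chr1"), len)
  expect_identical(resolved_map, claimed)
})

test_that("resolution is idempotent", {
  ann <- tiny_annotation()
  r1 <- resolve_overlaps(remove_helitrons(ann$tes))
  # feed the resolved intervals back in as pseudo-elements
  pseudo <- r1$intervals %>%
    dplyr::mutate(element_id = sprintf("iv%04d", dplyr::row_number()),
                  family = "F", superfamily = "RLX", te_class = "I",
                  is_helitron = FALSE, ltr_similarity = NA_real_,
                  gc_content = 0.5)
  r2 <- resolve_overlaps(pseudo)
  expect_equal(
    r2$intervals %>% dplyr::select("chrom", "start", "end"),
    r1$intervals %>% dplyr::select("chrom", "start", "end") %>%
      dplyr::arrange(.data$chrom, .data$start)
  )
})
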