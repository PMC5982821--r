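uniform_tiles <- function(level, contexts = "CG", chrom = "chr1",
                          len = 20000L, reads = 100L) {
  grid <- tidyr::expand_grid(tile_start = seq(0L, len - 100L, by = 100L),
                             context = contexts)
  make_tiles(chrom = chrom, tile_start = grid$tile_start,
             context = grid$context, n_sites = 10L,
             mc_reads = as.integer(round(level * reads)),
             total_reads = reads, seqlengths = setNames(len, chrom))
}

gene1 <- function(strand = "+", start = 10000L, end = 12000L) {
  tibble::tibble(gene_id = "g1", chrom = "chr1", start = start, end = end,
                 strand = strand,
                 tss = if (strand == "+") start else end,
                 tts = if (strand == "+") end else start)
}

test_that("a uniform methylome gives a flat metaprofile", {
  tl <- uniform_tiles(0.8)
  prof <- metaprofile(gene1(), tl, "g1")
  expect_true(all(abs(prof$mean_level - 0.8) < 1e-12))
  expect_setequal(unique(prof$anchor), c("TSS", "TTS"))
  expect_error(metaprofile(gene1(), tl, character()), "empty")
})

test_that("minus-strand profiles are flipped to transcribed orientation", {
  # methylation only upstream of the minus-strand TSS (coordinates > gene end)
  len <- 20000L
  tl <- make_tiles(
    chrom = "chr1", tile_start = seq(0L, len - 100L, by = 100L),
    context = "CG", n_sites = 10L,
    mc_reads = as.integer(ifelse(seq(0L, len - 100L, by = 100L) >= 12000L, 100L, 0L)),
    total_reads = 100L, seqlengths = c(chr1 = len)
  )
  prof <- metaprofile(gene1(strand = "-"), tl, "g1")
  tssp <- prof %>% dplyr::filter(.data$anchor == "TSS")
  up <- tssp$mean_level[tssp$offset_bp < 0]
  down <- tssp$mean_level[tssp$offset_bp >= 0]
  expect_true(all(up == 1))     # upstream flank = coordinates beyond gene end
  expect_true(all(down == 0))
})

test_that("profile of a set is the mean of single-gene profiles", {
  len <- 20000L
  g2 <- tibble::tibble(gene_id = "g2", chrom = "chr1", start = 4000L,
                       end = 6000L, strand = "+", tss = 4000L, tts = 6000L)
  genes <- dplyr::bind_rows(gene1(), g2)
  tl <- make_tiles(
    chrom = "chr1", tile_start = seq(0L, len - 100L, by = 100L),
    context = "CG", n_sites = 10L,
    mc_reads = as.integer(round(runif(len / 100) * 100)),
    total_reads = 100L, seqlengths = c(chr1 = len)
  )
  both <- metaprofile(genes, tl, c("g1", "g2"))
  p1 <- metaprofile(genes, tl, "g1")
  p2 <- metaprofile(genes, tl, "g2")
  j <- both %>%
    dplyr::inner_join(p1, by = c("anchor", "offset_bp", "context")) %>%
    dplyr::inner_join(p2, by = c("anchor", "offset_bp", "context"))
  expect_equal(j$mean_level.x, (j$mean_level.y + j$mean_level) / 2)
})

test_that("TSS methylation classes follow the 50/20 thresholds", {
  expect_equal(
    tss_methylation_class(gene1(), uniform_tiles(0.75, "CHG"), "CHG")$tss_class,
    "high")
  expect_equal(
    tss_methylation_class(gene1(), uniform_tiles(0.10, "CHG"), "CHG")$tss_class,
    "low")
  expect_equal(
    tss_methylation_class(gene1(), uniform_tiles(0.35, "CHG"), "CHG")$tss_class,
    "intermediate")
  # no covered sites in the window
  far <- make_tiles(chrom = "chr1", tile_start = 0L, context = "CHG",
                    n_sites = 5L, mc_reads = 1L, total_reads = 2L,
                    seqlengths = c(chr1 = 20000L))
  expect_equal(tss_methylation_class(gene1(), far, "CHG")$tss_class, "no_data")
})

test_that("island proximity uses the 2-kb flank and the feature body", {
  feats <- tibble::tibble(feature_id = "f", chrom = "chr1",
                          start = 10000L, end = 12000L)
  isl <- function(tile_start) {
    tibble::tibble(chrom = "chr1", tile_start = as.integer(tile_start),
                   chh_level = 0.4, informative_reads = 50L, genotype = "g")
  }
  expect_true(island_proximity(feats, isl(8500))$has_island_2kb)   # 1.5 kb up
  expect_false(island_proximity(feats, isl(7400))$has_island_2kb)  # 2.5 kb up
  expect_true(island_proximity(feats, isl(11000))$has_island_2kb)  # inside
  # translation invariance of the whole chromosome
  shift <- 54321L
  expect_equal(
    island_proximity(feats %>% dplyr::mutate(start = start + shift,
                                             end = end + shift),
                     isl(8500 + shift))$has_island_2kb,
    island_proximity(feats, isl(8500))$has_island_2kb
  )
})

test_that("DMR-near-TSS flags use a 200-bp half-open window around the TSS", {
  catalog <- function(tile_start, context = "CHG") {
    tibble::tibble(chrom = "chr1", tile_start = as.integer(tile_start),
                   context = context)
  }
  g <- gene1()   # TSS at 10000
  expect_true(dmr_near_tss(g, catalog(10000))$dmr_CHG)     # overlaps TSS
  expect_true(dmr_near_tss(g, catalog(9900))$dmr_CHG)      # [9900,10000) touches window
  expect_false(dmr_near_tss(g, catalog(10300))$dmr_CHG)    # 300 bp downstream
  expect_false(dmr_near_tss(g, catalog(9700))$dmr_CHG)     # [9700,9800) misses
  # minus-strand gene: window centred on the annotation end
  gm <- gene1(strand = "-")   # TSS at 12000
  expect_true(dmr_near_tss(gm, catalog(12100))$dmr_CHG)
  expect_false(dmr_near_tss(gm, catalog(12300))$dmr_CHG)
  # per-context columns
  flags <- dmr_near_tss(g, dplyr::bind_rows(catalog(10000, "CG"),
                                            catalog(50, "CHH")))
  expect_true(flags$dmr_CG)
  expect_false(flags$dmr_CHH)
})

test_that("the chi-squared enrichment test matches the closed form", {
  # expected counts from margins: chi2 = sum (O-E)^2 / E = 24 for this table
  set_flags <- rep(c(TRUE, FALSE), c(10, 90))
  bg_flags <- rep(c(TRUE, FALSE), c(40, 60))
  r <- enrichment_test(set_flags, bg_flags)
  expect_equal(r$chi2, 24)
  expect_equal(r$df, 1)
  expect_false(r$enriched)    # set proportion lower: depletion, not enrichment
  r2 <- enrichment_test(bg_flags, set_flags)
  expect_equal(r2$chi2, 24)
  expect_true(r2$enriched)
  # equal proportions: statistic 0
  r3 <- enrichment_test(rep(c(TRUE, FALSE), 50), rep(c(TRUE, FALSE), 200))
  expect_equal(r3$chi2, 0)
  expect_false(r3$enriched)
  expect_error(enrichment_test(rep(TRUE, 10), rep(TRUE, 10)), "expected")
})

test_that("enrichment matches a brute-force chi-squared oracle on random tables", {
  withr::with_seed(99, {
    for (i in 1:20) {
      a <- rbinom(1, 200, 0.3) + 1; b <- rbinom(1, 200, 0.5) + 1
      set_flags <- rep(c(TRUE, FALSE), c(a, 201 - a))
      bg_flags <- rep(c(TRUE, FALSE), c(b, 201 - b))
      tab <- rbind(c(a, 201 - a), c(b, 201 - b))
      E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      expect_equal(enrichment_test(set_flags, bg_flags)$chi2,
                   sum((tab - E)^2 / E))
    }
  })
})

test_that("Pearson correlation matches the hand computation", {
  panel <- tibble::tibble(
    gene_id = "g", genotype = paste0("x", 1:4),
    meth_level = c(0, 0, 100, 100), expression = c(5, 6, 0, 0)
  )
  r <- methylation_expression_correlation(panel)
  expect_equal(r$r, -550 / sqrt(10000 * 30.75), tolerance = 1e-10)
  expect_lt(abs(r$r - (-0.992)), 0.001)
  # perfectly anti-monotone linear pair
  lin <- tibble::tibble(gene_id = "g", genotype = paste0("x", 1:5),
                        meth_level = 1:5, expression = 10 - (1:5))
  expect_equal(methylation_expression_correlation(lin)$r, -1)
  # constant expression: undefined, flagged, never significant
  const <- tibble::tibble(gene_id = "g", genotype = paste0("x", 1:5),
                          meth_level = 1:5, expression = 3)
  rc <- methylation_expression_correlation(const)
  expect_true(is.na(rc$r))
  expect_false(rc$significant)
  expect_equal(rc$note, "zero_variance")
  # too few genotypes
  few <- panel[1:3, ]
  expect_equal(methylation_expression_correlation(few)$note,
               "too_few_genotypes")
})
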