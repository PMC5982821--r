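#' Pipeline configuration with the study's criteria as defaults
#'
#' Collects every threshold used across the stages. The defaults are the
#' published criteria: log2 fold-change cutoff 1 with FDR 0.05; expressed =
#' RPM > 1 in at least 3 libraries; 100-bp tiles; CG/CHG DMRs need > 6 sites,
#' > 2x coverage and > 60 percentage points difference; CHH DMRs < 5% vs
#' > 25%; mCHH islands > 25% CHH with >= 10 informative reads; island
#' proximity within 2 kb; DMR-near-TSS within 200 bp; TSS methylation class
#' over 400 bp; linked-gene exclusion within 40 Mb; 2-Mb DE bins; enrichment
#' p < 0.01; correlation p < 0.05.
#'
#' @param synth A [synth_config()] for the demo data.
#' @param out_dir Output directory.
#' @param lfc_cutoff,fdr_cutoff DE gates.
#' @param min_rpm,min_libraries Expression gates.
#' @param tile_bp Methylation tile width.
#' @param dmr_min_sites,dmr_min_coverage,dmr_min_diff_points,chh_low,chh_high
#'   DMR gates.
#' @param island_min_level,island_min_reads Island gates.
#' @param island_flank_bp,tss_dmr_window_bp,tss_class_window_bp Association
#'   windows.
#' @param linked_window_bp Linked-locus exclusion window.
#' @param de_bin_bp DE bin width.
#' @param p_enrichment,p_correlation Association significance cutoffs.
#' @param dominance Locus-specific dominance threshold.
#' @param seed Master seed (propagated to the synthetic generators).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(seed = seed),
                            out_dir = tempfile("temeth_run_"),
                            lfc_cutoff = 1, fdr_cutoff = 0.05,
                            min_rpm = 1, min_libraries = 3,
                            tile_bp = 100,
                            dmr_min_sites = 6, dmr_min_coverage = 2,
                            dmr_min_diff_points = 60,
                            chh_low = 0.05, chh_high = 0.25,
                            island_min_level = 0.25, island_min_reads = 10,
                            island_flank_bp = 2000, tss_dmr_window_bp = 200,
                            tss_class_window_bp = 400,
                            linked_window_bp = 40e6, de_bin_bp = 2e6,
                            p_enrichment = 0.01, p_correlation = 0.05,
                            dominance = 0.9, seed = 1) {
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Run every stage end-to-end on synthetic data
#'
#' Generates the demo genome, writes its annotations, resolves them, simulates
#' and assigns reads, builds count and RPM tables, calls differential
#' expression over two contrasts per pathway with consistency filtering, tiles
#' methylation for two genotypes, calls DMRs and mCHH islands, computes
#' proximity flags, enrichment and panel correlations, characterizes TE
#' families, and writes every table under `config$out_dir` together with a
#' manifest (parameters, seed, file checksums). Reruns with the same
#' configuration are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all in-memory results and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  res <- list()

  # annotation
  ann <- generate_genome_annotation(config$synth)
  write_gene_gff3(ann$genes, ann$exons, out("genes.gff3"), ann$seqlengths)
  write_te_gff3(ann$tes, out("tes.gff3"), ann$seqlengths)
  write_truth_json(ann$truth, out("truth.json"))
  resolved <- resolve_te_annotation(ann$tes, ann$exons)
  write_resolved_bed(resolved, out("resolved.bed"), out("family_map.tsv"))
  res$annotation <- ann
  res$resolved <- resolved

  # alignment-based quantification (one library exercising assignment)
  al <- simulate_alignments(ann, config$synth)
  write_alignments_sam(al, ann$seqlengths, out("demo_library.sam"))
  counts1 <- quantify_expression(list(demo = al), resolved)
  readr::write_tsv(counts1, out("demo_library_counts.tsv"))

  # count simulation across contrasts, DE, consistency
  sim <- simulate_counts(ann, config$synth,
                         contrast_names = c("mutantA", "mutantB"))
  readr::write_tsv(sim$counts, out("counts.tsv"))
  rpm <- rpm_normalize(sim$counts)
  readr::write_tsv(rpm, out("rpm.tsv"))
  expressed <- flag_expressed(rpm, config$min_rpm, config$min_libraries)
  readr::write_tsv(expressed, out("expressed.tsv"))
  readr::write_tsv(te_read_fraction(sim$counts), out("te_read_fraction.tsv"))
  de_list <- purrr::map(c(mutantA = "mutantA", mutantB = "mutantB"), function(cn) {
    libs <- sim$samples %>% filter(.data$contrast == cn)
    ct <- de_contrast(cn,
                      mutant_libs = libs$library[libs$role == "mutant"],
                      control_libs = libs$library[libs$role == "control"],
                      pathway = "CMT")
    de_analysis(sim$counts, ct, config$lfc_cutoff, config$fdr_cutoff)
  })
  purrr::iwalk(de_list, function(de, nm) {
    readr::write_tsv(tidy(de), out(sprintf("de_%s.tsv", nm)))
  })
  consistent <- consistent_de(de_list)
  readr::write_tsv(consistent, out("consistent_de.tsv"))
  res$de <- de_list
  res$consistent <- consistent

  # methylation: tiles, DMRs, islands
  calls <- simulate_methylation(ann, config$synth,
                                genotypes = c("wildtype", "mutant"))
  tiles <- purrr::imap(calls, function(cl, g) {
    tile_methylation(cl, ann$seqlengths, config$tile_bp, genotype = g)
  })
  purrr::iwalk(tiles, function(tl, g) {
    readr::write_tsv(tl, out(sprintf("tiles_%s.tsv", g)))
  })
  dmrs <- purrr::map_dfr(c("CG", "CHG", "CHH"), function(ctx) {
    call_dmrs(tiles[[1]], tiles[[2]], ctx,
              min_sites = config$dmr_min_sites,
              min_coverage = config$dmr_min_coverage,
              min_diff_points = config$dmr_min_diff_points,
              chh_low = config$chh_low, chh_high = config$chh_high)
  })
  readr::write_tsv(dmrs, out("dmrs.tsv"))
  islands <- call_mchh_islands(tiles[[1]], config$island_min_level,
                               config$island_min_reads)
  readr::write_tsv(islands, out("mchh_islands.tsv"))
  res$tiles <- tiles
  res$dmrs <- dmrs
  res$islands <- islands

  # association
  profile <- metaprofile(ann$genes, tiles[[1]], ann$genes$gene_id)
  readr::write_tsv(profile, out("metaprofile.tsv"))
  tss_class <- tss_methylation_class(ann$genes, tiles[[1]], "CHG",
                                     config$tss_class_window_bp)
  readr::write_tsv(tss_class, out("tss_class.tsv"))
  prox <- island_proximity(
    ann$genes %>% select(feature_id = "gene_id", "chrom", "start", "end"),
    islands, config$island_flank_bp
  )
  readr::write_tsv(prox, out("island_proximity.tsv"))
  near <- dmr_near_tss(ann$genes, dmrs, config$tss_dmr_window_bp)
  readr::write_tsv(near, out("dmr_near_tss.tsv"))
  panel <- simulate_epiallele_panel(config$synth)
  corr <- methylation_expression_correlation(panel$panel, config$p_correlation)
  readr::write_tsv(corr, out("panel_correlation.tsv"))
  res$correlation <- corr

  # TE family characterization
  fams <- family_summary(ann$tes %>% filter(!.data$is_helitron), ann$genes,
                         de_sets = consistent)
  readr::write_tsv(fams, out("family_summary.tsv"))
  fl <- filter_alignments(al)
  asg <- assign_te_reads(fl$unique, fl$multi, resolved)
  fc <- family_counts(asg, resolved)
  ec <- element_unique_counts(asg, resolved)
  patterns <- classify_family_pattern(ec, fc, dominance = config$dominance)
  readr::write_tsv(patterns, out("family_patterns.tsv"))
  res$family_summary <- fams
  res$patterns <- patterns

  # manifest
  files <- sort(setdiff(list.files(config$out_dir), "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("temeth")),
    seed = config$synth$seed,
    parameters = config[setdiff(names(config), c("synth", "out_dir"))],
    synth = unclass(config$synth)[setdiff(names(config$synth),
                                          c("dmr_spec", "island_spec"))],
    files = as.list(tools::md5sum(file.path(config$out_dir, files)))
  )
  names(manifest$files) <- files
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
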