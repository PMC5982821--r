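#' Configuration for the synthetic data generator
#'
#' Bundles every tunable of the synthetic genome, read, count and methylation
#' generators. The defaults emulate the study conditions the package is
#' validated against: a small multi-chromosome genome densely populated with
#' genes and multi-copy TE families (including helitrons and nested
#' insertions), three biological replicates per genotype, negative-binomial
#' counts with a planted two-fold-change (log2 scale) for differentially
#' expressed features, and per-cytosine methylation with maize-like background
#' levels per context (CG 0.80, CHG 0.65, CHH 0.02).
#'
#' @param n_chromosomes Number of chromosomes in the toy genome.
#' @param chrom_length_bp Length of every chromosome, in bp.
#' @param n_genes Total number of gene models placed across the genome.
#' @param n_te_families Number of (non-helitron) TE families; each receives
#'   `copies_per_family` identical copies.
#' @param copies_per_family Copies per TE family (>= 1). Reads simulated from a
#'   family report one alignment hit per copy, emulating exact-duplicate
#'   multi-mapping.
#' @param helitron_fraction Fraction of TE elements that are helitrons
#'   (removed before counting, as in the resolved annotation).
#' @param nested_te_fraction Fraction of TE families that receive one member
#'   nested strictly inside a member of another family.
#' @param n_libraries_per_genotype RNA-seq libraries per genotype side of a
#'   contrast (biological replicates).
#' @param planted_log2fc Absolute log2 fold change planted for differentially
#'   expressed features.
#' @param de_fraction Fraction of genes and of TE families planted as
#'   differentially expressed.
#' @param dmr_spec Tibble with columns `chrom`, `tile_start`, `context`,
#'   `level_a`, `level_b` describing planted differentially methylated 100-bp
#'   tiles (genotype A gets `level_a`, genotype B `level_b`). `NULL` plants a
#'   small default panel; use `dmr_spec = tibble::tibble()[0, ]`-style empty
#'   frames to plant none.
#' @param island_spec Tibble with columns `chrom`, `tile_start`, `chh_level`
#'   describing planted mCHH island tiles (all genotypes). `NULL` plants a
#'   default set.
#' @param read_depth Number of read pairs simulated per library by
#'   [simulate_alignments()].
#' @param dispersion Negative-binomial dispersion alpha, with
#'   variance mu + alpha * mu^2.
#' @param mean_expression Median of the log-normal distribution of baseline
#'   expression means (counts).
#' @param expression_lsd Standard deviation (log scale) of baseline expression
#'   means; 0 makes every feature's mean exactly `mean_expression`.
#' @param coverage_mean Mean per-site read coverage of the methylation
#'   generator (Poisson).
#' @param seed Integer seed; fully determines all generator output.
#'
#' @return A list of class `synth_config`.
#' @export
#' @examples
#' cfg <- synth_config(seed = 1)
#' ann <- generate_genome_annotation(cfg)
#' nrow(ann$tes)
synth_config <- function(n_chromosomes = 2,
                         chrom_length_bp = 100000,
                         n_genes = 30,
                         n_te_families = 8,
                         copies_per_family = 4,
                         helitron_fraction = 0.08,
                         nested_te_fraction = 0.25,
                         n_libraries_per_genotype = 3,
                         planted_log2fc = 2,
                         de_fraction = 0.2,
                         dmr_spec = NULL,
                         island_spec = NULL,
                         read_depth = 50000,
                         dispersion = 0.1,
                         mean_expression = 100,
                         expression_lsd = 1,
                         coverage_mean = 20,
                         seed = 1) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length_bp = as.integer(chrom_length_bp),
    n_genes = as.integer(n_genes),
    n_te_families = as.integer(n_te_families),
    copies_per_family = as.integer(copies_per_family),
    helitron_fraction = helitron_fraction,
    nested_te_fraction = nested_te_fraction,
    n_libraries_per_genotype = as.integer(n_libraries_per_genotype),
    planted_log2fc = planted_log2fc,
    de_fraction = de_fraction,
    dmr_spec = dmr_spec,
    island_spec = island_spec,
    read_depth = as.integer(read_depth),
    dispersion = dispersion,
    mean_expression = mean_expression,
    expression_lsd = expression_lsd,
    coverage_mean = coverage_mean,
    seed = as.integer(seed)
  )
  check_fraction(cfg$helitron_fraction, "helitron_fraction")
  check_fraction(cfg$nested_te_fraction, "nested_te_fraction")
  check_fraction(cfg$de_fraction, "de_fraction")
  if (cfg$n_chromosomes < 1 || cfg$chrom_length_bp < 10000) {
    abort("need at least one chromosome of >= 10 kb")
  }
  if (cfg$copies_per_family < 1) abort("copies_per_family must be >= 1")
  if (cfg$dispersion <= 0) abort("dispersion must be > 0")
  structure(cfg, class = "synth_config")
}

#' @noRd
synth_seqlengths <- function(config) {
  setNames(
    rep(config$chrom_length_bp, config$n_chromosomes),
    paste0("chr", seq_len(config$n_chromosomes))
  )
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>", x$n_chromosomes, "chromosome(s) x",
      x$chrom_length_bp, "bp;", x$n_genes, "genes;",
      x$n_te_families, "TE families x", x$copies_per_family, "copies; seed",
      x$seed, "\n")
  invisible(x)
}
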