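#' Simulate negative-binomial count tables with planted fold changes
#'
#' Draws integer counts for every gene and (non-helitron) TE family of a
#' synthetic annotation across one or more mutant-vs-control contrasts.
#' Counts follow a negative binomial with variance `mu + alpha * mu^2`
#' (`alpha = config$dispersion`). Features planted as differentially expressed
#' in the annotation's truth set have their mutant-side mean multiplied by
#' `2^log2fc` (up) or `2^-log2fc` (down); baseline means are shared across
#' contrasts so that planted features are recoverable by the consistency rule.
#'
#' @param annotation A `synth_annotation`.
#' @param config The [synth_config()] (uses `n_libraries_per_genotype`,
#'   `dispersion`, `mean_expression`, `expression_lsd`).
#' @param contrast_names Character vector naming the contrasts to draw.
#' @param seed Seed; defaults to `config$seed + 2`.
#' @return List with `counts` (tibble: `feature_id`, `feature_type`, one
#'   integer column per library named `<contrast>_<mut|ctl>_<i>`) and
#'   `samples` (tibble: `library`, `contrast`, `role`).
#' @export
simulate_counts <- function(annotation, config,
                            contrast_names = c("contrast1", "contrast2"),
                            seed = config$seed + 2) {
  stopifnot(inherits(annotation, "synth_annotation"))
  if (config$dispersion <= 0) abort("dispersion must be > 0")
  withr::with_seed(seed, {
    fams <- annotation$tes %>% filter(!.data$is_helitron) %>%
      distinct(.data$family) %>% pull("family")
    features <- tibble(
      feature_id = c(annotation$genes$gene_id, fams),
      feature_type = c(rep("gene", nrow(annotation$genes)),
                       rep("te_family", length(fams)))
    )
    base_mu <- config$mean_expression *
      exp(rnorm(nrow(features), 0, config$expression_lsd))
    truth <- annotation$truth$de_features
    fold <- rep(1, nrow(features))
    m <- match(features$feature_id, truth$feature_id)
    planted <- !is.na(m)
    fold[planted] <- ifelse(truth$direction[m[planted]] == "up",
                            2^truth$log2fc[m[planted]],
                            2^-truth$log2fc[m[planted]])
    nl <- config$n_libraries_per_genotype
    size <- 1 / config$dispersion
    cols <- list()
    samples <- list()
    for (cn in contrast_names) {
      for (i in seq_len(nl)) {
        lib <- sprintf("%s_ctl_%d", cn, i)
        cols[[lib]] <- rnbinom(nrow(features), mu = base_mu, size = size)
        samples[[lib]] <- tibble(library = lib, contrast = cn, role = "control")
      }
      for (i in seq_len(nl)) {
        lib <- sprintf("%s_mut_%d", cn, i)
        cols[[lib]] <- rnbinom(nrow(features), mu = base_mu * fold, size = size)
        samples[[lib]] <- tibble(library = lib, contrast = cn, role = "mutant")
      }
    }
    list(
      counts = bind_rows_counts(features, cols),
      samples = bind_rows(samples)
    )
  })
}

#' @noRd
bind_rows_counts <- function(features, cols) {
  out <- features
  for (nm in names(cols)) out[[nm]] <- as.integer(cols[[nm]])
  out
}

#' Simulate a methylation/expression panel with planted epialleles
#'
#' Emulates a diversity panel of inbred genotypes scored, per gene, for
#' methylation level at a promoter-proximal differentially methylated region
#' and for transcript abundance. Planted epiallele genes show the on/off
#' pattern seen at natural epialleles: a subset of genotypes is highly
#' methylated and transcriptionally silent, the rest are unmethylated and
#' expressed. Null genes carry the same bimodal methylation but expression
#' drawn independently of it.
#'
#' @param config A [synth_config()] (only `seed` is used by default).
#' @param n_genes Total panel genes.
#' @param n_planted Number of genes planted with the anti-correlated pattern.
#' @param n_genotypes Panel size (>= 4).
#' @param seed Seed; defaults to `config$seed + 3`.
#' @return List with `panel` (tibble: `gene_id`, `genotype`, `meth_level`,
#'   `expression`) and `truth` (tibble: `gene_id`, `planted`).
#' @export
simulate_epiallele_panel <- function(config, n_genes = 50, n_planted = 20,
                                     n_genotypes = 10,
                                     seed = config$seed + 3) {
  if (n_genotypes < 4) abort("need >= 4 genotypes")
  if (n_planted > n_genes) abort("n_planted exceeds n_genes")
  withr::with_seed(seed, {
    genos <- sprintf("inbred%02d", seq_len(n_genotypes))
    gene_ids <- sprintf("PANEL%04d", seq_len(n_genes))
    planted <- seq_len(n_genes) <= n_planted
    rows <- purrr::map_dfr(seq_len(n_genes), function(g) {
      k_high <- sample(3:(n_genotypes - 3), 1)
      high <- sample(n_genotypes, k_high)
      meth <- ifelse(seq_len(n_genotypes) %in% high,
                     pmin(1, 0.85 + rnorm(n_genotypes, 0, 0.04)),
                     pmax(0, 0.04 + rnorm(n_genotypes, 0, 0.02)))
      expr <- if (planted[g]) {
        ifelse(seq_len(n_genotypes) %in% high,
               abs(rnorm(n_genotypes, 0, 0.3)),
               rlnorm(n_genotypes, log(20), 0.3))
      } else {
        rlnorm(n_genotypes, log(10), 0.5)
      }
      tibble(gene_id = gene_ids[g], genotype = genos,
             meth_level = meth, expression = expr)
    })
    list(panel = rows,
         truth = tibble(gene_id = gene_ids, planted = planted))
  })
}
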