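#' Define a mutant-vs-control contrast
#'
#' @param name Contrast name (e.g. the mutant allele).
#' @param mutant_libs,control_libs Library column names (>= 2 each, needed for
#'   dispersion estimation).
#' @param pathway Silencing pathway of the mutated gene: `"CMT"` or `"RdDM"`.
#' @param locus_chrom,locus_pos Position of the mutated locus, used by
#'   [exclude_linked()] to drop cis-linked differential expression introduced
#'   by introgression. Leave `NULL` for uncharacterized backgrounds.
#' @return List of class `de_contrast`.
#' @export
de_contrast <- function(name, mutant_libs, control_libs,
                        pathway = c("CMT", "RdDM"),
                        locus_chrom = NULL, locus_pos = NULL) {
  pathway <- match.arg(pathway)
  if (length(mutant_libs) < 2 || length(control_libs) < 2) {
    abort("need >= 2 libraries per side to estimate dispersion")
  }
  structure(list(name = name, mutant_libs = mutant_libs,
                 control_libs = control_libs, pathway = pathway,
                 locus_chrom = locus_chrom, locus_pos = locus_pos),
            class = "de_contrast")
}

#' Negative-binomial Wald test for one contrast
#'
#' A deliberately small NB engine: library size factors by median-of-ratios;
#' per-feature dispersion alpha (variance mu + alpha mu^2) by pooled
#' within-group method of moments. With three replicates per side the
#' per-feature estimate has only four degrees of freedom, so it is moderated
#' against the across-feature median: floored at the median (and at 1e-8) and
#' capped at twice it, which keeps the Wald test calibrated without giving
#' individual features implausibly small or large dispersions. Fold change is
#' log2((mutant mean + 0.5) / (control mean + 0.5)) on normalized counts;
#' two-sided Wald p against a normal reference. Features with all-zero counts
#' in both groups get `log2fc = 0`, `p = 1`.
#'
#' @param counts Count tibble (`feature_id`, optional `feature_type`, library
#'   columns).
#' @param contrast A [de_contrast()].
#' @param pseudocount Added to each group mean for the fold change.
#' @return Tibble `feature_id` (+ `feature_type`), `base_mean`, `log2fc`, `p`.
#' @export
nb_test <- function(counts, contrast, pseudocount = 0.5) {
  stopifnot(inherits(contrast, "de_contrast"))
  libs <- c(contrast$mutant_libs, contrast$control_libs)
  missing <- setdiff(libs, names(counts))
  if (length(missing) > 0) {
    abort(sprintf("libraries not in count table: %s", paste(missing, collapse = ", ")))
  }
  m <- as.matrix(counts[libs])
  sf <- size_factors(m)
  norm <- sweep(m, 2, sf, "/")
  im <- match(contrast$mutant_libs, libs)
  ic <- match(contrast$control_libs, libs)
  nM <- length(im); nC <- length(ic)
  muM <- rowMeans(norm[, im, drop = FALSE])
  muC <- rowMeans(norm[, ic, drop = FALSE])
  vM <- apply(norm[, im, drop = FALSE], 1, var)
  vC <- apply(norm[, ic, drop = FALSE], 1, var)
  mu <- (muM * nM + muC * nC) / (nM + nC)
  v <- (vM * (nM - 1) + vC * (nC - 1)) / (nM + nC - 2)
  alpha_raw <- pmax((v - mu) / mu^2, 1e-8)
  alpha_raw[!is.finite(alpha_raw)] <- 1e-8
  alpha_mid <- median(alpha_raw[mu > 0], na.rm = TRUE)
  alpha <- pmin(pmax(alpha_raw, alpha_mid), 2 * alpha_mid)
  lfc <- log2((muM + pseudocount) / (muC + pseudocount))
  se2 <- (1 / log(2))^2 *
    ((1 / (muM + pseudocount) + alpha) / nM +
       (1 / (muC + pseudocount) + alpha) / nC)
  p <- 2 * pnorm(-abs(lfc / sqrt(se2)))
  zero <- muM == 0 & muC == 0
  lfc[zero] <- 0
  p[zero] <- 1
  out <- counts %>% select(any_of(c("feature_id", "feature_type")))
  out %>% mutate(base_mean = mu, log2fc = lfc, p = p)
}

#' Median-of-ratios size factors
#' @noRd
size_factors <- function(m) {
  logc <- log(m)
  loggm <- rowMeans(logc)
  ok <- is.finite(loggm)
  if (!any(ok)) abort("no feature with positive counts in every library; size factors not computable")
  apply(m[ok, , drop = FALSE], 2, function(col) {
    median(exp(log(col) - loggm[ok]))
  })
}

#' Benjamini-Hochberg adjusted p values
#'
#' @param p Vector of p values in `[0, 1]`.
#' @return FDR-adjusted values (monotone step-up).
#' @export
adjust_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Call differential expression with fold-change and FDR cutoffs
#'
#' Strict inequalities on both gates: `up` iff `fdr < fdr_cutoff` and
#' `log2fc > lfc_cutoff`; `down` symmetric; `ns` otherwise.
#'
#' @param results Output of [nb_test()].
#' @param contrast The [de_contrast()] tested (stored as attribute).
#' @param lfc_cutoff log2 fold-change cutoff.
#' @param fdr_cutoff FDR cutoff.
#' @return Tibble of class `temeth_de` with added `fdr` and `call`.
#' @export
call_de <- function(results, contrast = NULL, lfc_cutoff = 1, fdr_cutoff = 0.05) {
  out <- results %>%
    mutate(
      fdr = adjust_fdr(.data$p),
      call = case_when(
        .data$fdr < fdr_cutoff & .data$log2fc > lfc_cutoff ~ "up",
        .data$fdr < fdr_cutoff & .data$log2fc < -lfc_cutoff ~ "down",
        TRUE ~ "ns"
      )
    )
  class(out) <- c("temeth_de", class(out))
  attr(out, "contrast") <- contrast
  out
}

#' Differential expression analysis for one contrast
#'
#' Convenience wrapper: [nb_test()] then [call_de()].
#'
#' @inheritParams nb_test
#' @inheritParams call_de
#' @return A `temeth_de` tibble.
#' @export
de_analysis <- function(counts, contrast, lfc_cutoff = 1, fdr_cutoff = 0.05,
                        pseudocount = 0.5) {
  nb_test(counts, contrast, pseudocount = pseudocount) %>%
    call_de(contrast, lfc_cutoff = lfc_cutoff, fdr_cutoff = fdr_cutoff)
}

#' Tidy a differential expression result into a plain tibble
#'
#' @param x A `temeth_de` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
#' @method tidy temeth_de
tidy.temeth_de <- function(x, ...) {
  as_tibble(unclass_de(x))
}

#' One-row summary of a differential expression result
#'
#' @param x A `temeth_de` object.
#' @param ... Unused.
#' @return A one-row tibble with contrast, pathway and call counts.
#' @export
#' @method glance temeth_de
glance.temeth_de <- function(x, ...) {
  ct <- attr(x, "contrast")
  tibble(
    contrast = if (is.null(ct)) NA_character_ else ct$name,
    pathway = if (is.null(ct)) NA_character_ else ct$pathway,
    n_features = nrow(x),
    n_up = sum(x$call == "up"),
    n_down = sum(x$call == "down")
  )
}

#' @noRd
unclass_de <- function(x) {
  class(x) <- setdiff(class(x), "temeth_de")
  attr(x, "contrast") <- NULL
  x
}

#' Exclude differential expression linked to the mutated locus
#'
#' Mutations introgressed from another background drag along cis-regulatory
#' variation; DE genes whose midpoint lies within `window_bp` of the declared
#' mutation locus on the same chromosome are therefore reset to `ns` with
#' reason `"linked"`. TE families are exempt (they are not point-localized).
#' If the contrast declares no locus (uncharacterized background), the calls
#' pass through with a warning.
#'
#' @param de A `temeth_de` result.
#' @param contrast The [de_contrast()] carrying `locus_chrom` / `locus_pos`.
#' @param genes Gene coordinate tibble (`gene_id`, `chrom`, `start`, `end`).
#' @param window_bp Exclusion half-window around the locus (default 40 Mb).
#' @return The result with linked calls set to `ns` and a `reason` column.
#' @export
exclude_linked <- function(de, contrast, genes, window_bp = 40e6) {
  if (is.null(contrast$locus_chrom) || is.null(contrast$locus_pos)) {
    warn(sprintf("contrast %s declares no mutation locus; linked-gene exclusion skipped",
                 contrast$name))
    return(de %>% mutate(reason = NA_character_))
  }
  pos <- genes %>%
    mutate(midpoint = (.data$start + .data$end) / 2) %>%
    select("gene_id", "chrom", "midpoint")
  out <- de %>%
    left_join(pos, by = c(feature_id = "gene_id")) %>%
    mutate(
      linked = !is.na(.data$chrom) & .data$call != "ns" &
        .data$chrom == contrast$locus_chrom &
        abs(.data$midpoint - contrast$locus_pos) < window_bp &
        (!("feature_type" %in% names(de)) | .data$feature_type == "gene"),
      reason = if_else(.data$linked, "linked", NA_character_),
      call = if_else(.data$linked, "ns", .data$call)
    ) %>%
    select(-"chrom", -"midpoint", -"linked")
  class(out) <- class(de)
  attr(out, "contrast") <- attr(de, "contrast")
  out
}

#' Features with consistent differential expression within a pathway
#'
#' A feature belongs to a pathway's `up` set if it is called up in at least
#' `min_contrasts` contrasts of that pathway (and analogously `down`).
#' Opposite-direction calls never merge: a feature up in one contrast and down
#' in another contributes to neither set.
#'
#' @param de_list Named list of `temeth_de` results, one per contrast; each
#'   must carry its contrast attribute (from [call_de()] / [de_analysis()]).
#' @param min_contrasts Minimum agreeing contrasts (default 2).
#' @return Tibble `feature_id` (+ `feature_type`), `pathway`, `direction`,
#'   `n_contrasts`.
#' @export
consistent_de <- function(de_list, min_contrasts = 2) {
  calls <- purrr::imap_dfr(de_list, function(de, nm) {
    ct <- attr(de, "contrast")
    if (is.null(ct)) abort(sprintf("result %s carries no contrast", nm))
    unclass_de(de) %>%
      filter(.data$call != "ns") %>%
      select(any_of(c("feature_id", "feature_type", "call"))) %>%
      mutate(pathway = ct$pathway, contrast = ct$name)
  })
  if (nrow(calls) == 0) {
    return(tibble(feature_id = character(), pathway = character(),
                  direction = character(), n_contrasts = integer()))
  }
  calls %>%
    distinct(dplyr::across(any_of(c("feature_id", "feature_type", "call",
                                    "pathway", "contrast")))) %>%
    group_by(dplyr::across(any_of(c("feature_id", "feature_type", "call", "pathway")))) %>%
    summarise(n_contrasts = n_distinct(.data$contrast), .groups = "drop") %>%
    filter(.data$n_contrasts >= min_contrasts) %>%
    rename(direction = "call") %>%
    arrange(.data$pathway, .data$direction, .data$feature_id)
}

#' Count differentially expressed genes in fixed genomic bins
#'
#' Genes are binned by midpoint into non-overlapping bins (default 2 Mb) per
#' chromosome; used to spot clusters of cis-linked differential expression
#' around introgressed loci.
#'
#' @param de A `temeth_de` result (or any tibble with `feature_id`, `call`).
#' @param genes Gene coordinate tibble.
#' @param bin_bp Bin width.
#' @param seqlengths Optional named chromosome lengths; when given, empty bins
#'   are reported as zero counts.
#' @return Tibble `chrom`, `bin_start`, `bin_end`, `n_de`.
#' @export
bin_de_counts <- function(de, genes, bin_bp = 2e6, seqlengths = NULL) {
  de_genes <- de %>% filter(.data$call != "ns") %>% pull("feature_id")
  hits <- genes %>%
    filter(.data$gene_id %in% de_genes) %>%
    mutate(bin_start = floor((.data$start + .data$end) / 2 / bin_bp) * bin_bp) %>%
    dplyr::count(.data$chrom, .data$bin_start, name = "n_de")
  if (!is.null(seqlengths)) {
    grid <- purrr::imap_dfr(as.list(seqlengths), function(len, ch) {
      tibble(chrom = ch, bin_start = seq(0, len - 1, by = bin_bp))
    })
    hits <- grid %>%
      left_join(hits, by = c("chrom", "bin_start")) %>%
      mutate(n_de = dplyr::coalesce(.data$n_de, 0L))
  }
  hits %>%
    mutate(bin_end = .data$bin_start + bin_bp) %>%
    select("chrom", "bin_start", "bin_end", "n_de") %>%
    arrange(.data$chrom, .data$bin_start)
}
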