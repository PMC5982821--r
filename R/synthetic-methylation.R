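#' Simulate per-cytosine methylation call tables for several genotypes
#'
#' Generates methratio-style call tables (one per genotype) over the synthetic
#' genome. Cytosine site positions are drawn once per seed and shared by all
#' genotypes (they are properties of the genome); read coverage and methylated
#' read counts are drawn per genotype. Background methylation levels are
#' maize-like per context (CG 0.80, CHG 0.65, CHH 0.02). Tiles listed in the
#' truth set's `dmrs` are methylated at `level_a` in the first genotype (and
#' any genotype beyond the second) and `level_b` in the second genotype; tiles
#' in `islands` carry the specified CHH level in every genotype. Planted tiles
#' are given at least 8 sites in the relevant context and per-site coverage of
#' at least 3 reads so that they always clear the site-number and coverage
#' gates of the callers; whether they are *called* still depends on the
#' realized methylated-read draws.
#'
#' @param annotation A `synth_annotation` (source of genome and planted truth).
#' @param config A [synth_config()] (`coverage_mean`, `seed`).
#' @param genotypes Character vector of genotype names (>= 1). The first two
#'   play the roles of the planted DMR pair.
#' @param background Named levels per context.
#' @param seed Seed; defaults to `config$seed + 4`.
#' @return Named list (one per genotype) of call tibbles with columns
#'   `chrom`, `pos`, `strand`, `context`, `mc_reads`, `total_reads`.
#' @export
simulate_methylation <- function(annotation, config,
                                 genotypes = c("genoA", "genoB"),
                                 background = c(CG = 0.80, CHG = 0.65, CHH = 0.02),
                                 seed = config$seed + 4) {
  stopifnot(inherits(annotation, "synth_annotation"))
  check_fraction(background, "background")
  dmrs <- annotation$truth$dmrs
  islands <- annotation$truth$islands
  if (nrow(dmrs) > 0 &&
      any(dmrs$level_a < 0 | dmrs$level_a > 1 | dmrs$level_b < 0 | dmrs$level_b > 1)) {
    abort("planted methylation level outside [0, 1]")
  }
  withr::with_seed(seed, {
    sites <- draw_cytosine_sites(annotation$seqlengths, dmrs, islands)
    purrr::map(setNames(genotypes, genotypes), function(g) {
      role <- if (length(genotypes) >= 2 && g == genotypes[2]) "b" else "a"
      draw_genotype_calls(sites, dmrs, islands, background, role,
                          config$coverage_mean)
    })
  })
}

#' Site positions per 100-bp tile per context; planted tiles get >= 8 sites
#' @noRd
draw_cytosine_sites <- function(seqlengths, dmrs, islands) {
  per_chrom <- purrr::imap_dfr(as.list(seqlengths), function(len, ch) {
    tiles <- seq(0L, len - 1L, by = 100L)
    purrr::map_dfr(c("CG", "CHG", "CHH"), function(ctx) {
      n_per <- if (ctx == "CHH") 12L + rpois(length(tiles), 6) else
        8L + rpois(length(tiles), 4)
      planted <- tiles %in% c(
        dmrs$tile_start[dmrs$chrom == ch & dmrs$context == ctx],
        if (ctx == "CHH") islands$tile_start[islands$chrom == ch] else integer()
      )
      n_per <- pmax(n_per, ifelse(planted, 10L, 0L))
      tile_w <- pmin(tiles + 100L, len) - tiles
      n_per <- pmin(n_per, tile_w)  # cannot exceed tile width
      pos <- purrr::map2(tiles, n_per, function(t0, k) {
        w <- min(100L, len - t0)
        t0 + sample.int(w, k) - 1L
      })
      tibble(
        chrom = ch,
        pos = unlist(pos),
        context = ctx,
        tile_start = rep(tiles, n_per)
      )
    })
  })
  per_chrom$strand <- sample(c("+", "-"), nrow(per_chrom), replace = TRUE)
  per_chrom
}

#' @noRd
draw_genotype_calls <- function(sites, dmrs, islands, background, role, cov_mean) {
  level <- unname(background[sites$context])
  if (nrow(dmrs) > 0) {
    key <- paste(sites$chrom, sites$tile_start, sites$context)
    dkey <- paste(dmrs$chrom, dmrs$tile_start, dmrs$context)
    m <- match(key, dkey)
    hit <- !is.na(m)
    level[hit] <- if (role == "b") dmrs$level_b[m[hit]] else dmrs$level_a[m[hit]]
  }
  if (nrow(islands) > 0) {
    ikey <- paste(islands$chrom, islands$tile_start)
    hit <- sites$context == "CHH" &
      paste(sites$chrom, sites$tile_start) %in% ikey
    m <- match(paste(sites$chrom, sites$tile_start)[hit], ikey)
    level[hit] <- islands$chh_level[m]
  }
  planted <- level != unname(background[sites$context])
  cov <- rpois(nrow(sites), cov_mean)
  cov[planted] <- pmax(cov[planted], 3L)
  mc <- rbinom(nrow(sites), cov, level)
  tibble(
    chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
    context = sites$context, mc_reads = mc, total_reads = cov
  ) %>%
    filter(.data$total_reads > 0) %>%
    arrange(.data$chrom, .data$pos, .data$context)
}
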