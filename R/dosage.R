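#' Alternate-allele frequency from read counts
#'
#' @param ref,alt Non-negative read counts supporting the reference and
#'   alternate allele.
#'
#' @return `alt / (ref + alt)`, or `NA` where total depth is zero. Vectorised.
#' @export
#' @examples
#' allele_frequency(25, 75) # 0.75
allele_frequency <- function(ref, alt) {
  if (any(ref < 0, na.rm = TRUE) || any(alt < 0, na.rm = TRUE)) {
    abort("read counts must be non-negative")
  }
  tot <- ref + alt
  ifelse(tot == 0, NA_real_, alt / tot)
}

#' Dosage-calling and site-filter configuration
#'
#' Thresholds applied when converting read evidence to tetraploid allele
#' dosages and when filtering sites before association scans: a minimum depth
#' per call, a maximum per-site missing fraction, and a minimum number of
#' samples carrying the minor allele. `min_minor` counts carrier samples
#' (any sample whose genotype contains at least one copy of the minor
#' allele), the reading of the filter adopted here for the standard
#' `min.DP = 2, max.missing = 0.05, min.minor = 5` defaults.
#'
#' @param min_dp Minimum read depth for a dosage call (default 2).
#' @param max_missing Maximum fraction of missing calls per retained site
#'   (default 0.05).
#' @param min_minor Minimum number of samples carrying the minor allele
#'   (default 5).
#'
#' @return A list of class `dosage_filter_config`.
#' @export
dosage_filter_config <- function(min_dp = 2, max_missing = 0.05, min_minor = 5) {
  if (max_missing < 0 || max_missing > 1) abort("max_missing must be in [0, 1]")
  if (min_dp < 0 || min_minor < 0) abort("counts must be non-negative")
  structure(
    list(min_dp = min_dp, max_missing = max_missing, min_minor = min_minor),
    class = "dosage_filter_config"
  )
}

#' Call tetraploid allele dosage from an allele frequency
#'
#' Assigns the dosage k in 0..4 whose expected alternate-allele frequency
#' k/4 is nearest the observed frequency; exact ties break toward the lower
#' dosage (conservative toward homozygosity for the reference allele). Calls
#' below the depth floor are missing.
#'
#' @param freq Observed alternate-allele frequency in \[0, 1\] (vectorised).
#' @param depth Total read depth per call.
#' @param cfg A [dosage_filter_config()]; only `min_dp` is used.
#'
#' @return Integer dosage 0..4, `NA` where depth < `min_dp` or `freq` is `NA`.
#' @export
#' @examples
#' call_dosage(0.73, 30)  # 3
#' call_dosage(0.375, 40) # 1 (equidistant; lower dosage wins)
call_dosage <- function(freq, depth, cfg = dosage_filter_config()) {
  if (any(freq < 0 | freq > 1, na.rm = TRUE)) abort("freq must be in [0, 1]")
  k <- 0:4
  out <- vapply(freq, function(f) {
    if (is.na(f)) return(NA_integer_)
    k[which.min(abs(f - k / 4))]
  }, integer(1))
  out[is.na(depth) | depth < cfg$min_dp] <- NA_integer_
  out
}

#' Filter sites on missingness and minor-allele carrier count
#'
#' Drops sites whose missing-call fraction exceeds `max_missing`, then sites
#' where fewer than `min_minor` samples carry the minor allele. The minor
#' allele at a site is the one with the smaller total dosage across samples
#' (ties resolve to the alternate allele); a sample carries the alt allele
#' when its dosage is 1..4 and the ref allele when its dosage is 0..3.
#' The filter is idempotent.
#'
#' @param variants A long variant tibble with columns `chrom`, `pos`,
#'   `sample`, `dosage` (and any others, which are preserved).
#' @param cfg A [dosage_filter_config()].
#'
#' @return The filtered tibble, with a `drop_counts` attribute: a named
#'   integer vector `c(missing = , min_minor = )` whose sum equals the number
#'   of sites removed.
#' @export
site_filters <- function(variants, cfg = dosage_filter_config()) {
  if (nrow(variants) == 0) {
    attr(variants, "drop_counts") <- c(missing = 0L, min_minor = 0L)
    return(variants)
  }
  site_stats <- variants %>%
    group_by(.data$chrom, .data$pos) %>%
    summarise(
      n = dplyr::n(),
      n_miss = sum(is.na(.data$dosage)),
      alt_total = sum(.data$dosage, na.rm = TRUE),
      ref_total = sum(4 - .data$dosage, na.rm = TRUE),
      alt_carriers = sum(.data$dosage >= 1, na.rm = TRUE),
      ref_carriers = sum(.data$dosage <= 3, na.rm = TRUE),
      .groups = "drop"
    ) %>%
    mutate(
      miss_frac = .data$n_miss / .data$n,
      minor_carriers = ifelse(.data$alt_total <= .data$ref_total,
        .data$alt_carriers, .data$ref_carriers
      ),
      fail_missing = .data$miss_frac > cfg$max_missing,
      fail_minor = !.data$fail_missing & .data$minor_carriers < cfg$min_minor
    )
  keep <- site_stats %>% filter(!.data$fail_missing, !.data$fail_minor)
  out <- dplyr::semi_join(variants, keep, by = c("chrom", "pos"))
  attr(out, "drop_counts") <- c(
    missing = sum(site_stats$fail_missing),
    min_minor = sum(site_stats$fail_minor)
  )
  out
}

#' Uniform random down-sample of sites
#'
#' Optionally thins a variant table to at most `n_sites` sites drawn
#' uniformly without replacement (all samples of a chosen site are kept).
#'
#' @param variants Long variant tibble with `chrom`, `pos` columns.
#' @param n_sites Number of sites to retain.
#' @param seed Integer seed for reproducibility.
#'
#' @return The thinned tibble.
#' @export
downsample_sites <- function(variants, n_sites, seed = 1L) {
  sites <- distinct(variants, .data$chrom, .data$pos)
  if (nrow(sites) <= n_sites) return(variants)
  set.seed(seed)
  keep <- sites[sample.int(nrow(sites), n_sites), ]
  dplyr::semi_join(variants, keep, by = c("chrom", "pos"))
}
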