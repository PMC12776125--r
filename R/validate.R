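#' Bulked-segregant recovery experiment on simulated selfed families
#'
#' One replicate simulates a selfed triplex family on a 40 Mb / 2 Morgan
#' chromosome with 20,000 SNPs and the causal locus at 33.7 Mb, takes the
#' first 32 affected and 65 unaffected progeny as the two bulks (progeny
#' are oversampled so both bulks fill), pools reads to ~300x per bulk with
#' a 0.5% error rate, runs the recessive-filter window scan and the
#' enriched-interval call, and records whether the interval contains the
#' causal position.
#'
#' @param seed Integer seed for one replicate.
#' @param n_mut,n_wt Bulk sizes (default 32 affected / 65 unaffected).
#' @param bulk_depth Pooled depth per bulk (default 300).
#' @param error Per-read error rate (default 0.005).
#' @param cfg Base [sim_config()]; `n_progeny` is raised as needed to fill
#'   the bulks.
#'
#' @return One-row tibble: `seed`, `recovered` (logical), `width_bp`,
#'   `start`, `end`, `causal_pos`.
#' @export
bsa_recovery_replicate <- function(seed, n_mut = 32, n_wt = 65,
                                   bulk_depth = 300, error = 0.005,
                                   cfg = sim_config()) {
  cfg$seed <- as.integer(seed)
  cfg$n_progeny <- max(cfg$n_progeny, ceiling((n_mut + n_wt) * 2))
  pop <- self_cross(cfg)
  aff <- which(pop$truth$phenotype == 1L)
  un <- which(pop$truth$phenotype == 0L)
  while (length(aff) < n_mut || length(un) < n_wt) {
    cfg$n_progeny <- cfg$n_progeny * 2
    pop <- self_cross(cfg)
    aff <- which(pop$truth$phenotype == 1L)
    un <- which(pop$truth$phenotype == 0L)
  }
  sel <- c(aff[seq_len(n_mut)], un[seq_len(n_wt)])
  pop$dosage <- pop$dosage[sel, , drop = FALSE]
  pop$truth <- pop$truth[sel, ]
  mut_ids <- pop$truth$sample[pop$truth$phenotype == 1L]
  wt_ids <- pop$truth$sample[pop$truth$phenotype == 0L]
  counts <- simulate_reads(
    pop,
    read_model(depth = bulk_depth / n_mut, error = error,
      seed = as.integer(seed) + 1L),
    bulks = list(mut = mut_ids, wt = wt_ids)
  )
  windows <- make_windows(genome_layout(cfg$chrom, cfg$chrom_length))
  profile <- bsa_scan(counts, windows)
  interval <- call_enriched_interval(profile)
  hit <- nrow(interval) == 1 && interval$start <= cfg$causal_pos &&
    cfg$causal_pos <= interval$end
  tibble(
    seed = as.integer(seed), recovered = hit,
    width_bp = if (nrow(interval)) interval$width_bp else NA_real_,
    start = if (nrow(interval)) interval$start else NA_real_,
    end = if (nrow(interval)) interval$end else NA_real_,
    causal_pos = cfg$causal_pos
  )
}

#' IBD homozygosity-mapping recovery experiment on simulated panels
#'
#' One replicate builds a panel of affected relatives sharing an ancestral
#' causal haplotype ([sim_ibd_panel()]), runs the full homozygosity-mapping
#' chain ([ibd_map()]), and records whether the final interval contains the
#' causal position and how wide it is.
#'
#' @param seed Integer seed for one replicate.
#' @param n_meioses Independent meioses separating each descended homolog
#'   from the ancestor (default 8).
#' @param ... Further arguments to [sim_ibd_panel()].
#'
#' @return One-row tibble: `seed`, `n_meioses`, `recovered`, `width_bp`.
#' @export
ibd_recovery_replicate <- function(seed, n_meioses = 8, ...) {
  panel <- sim_ibd_panel(n_meioses = n_meioses, seed = as.integer(seed), ...)
  windows <- make_windows(genome_layout(panel$chrom, panel$chrom_length))
  res <- ibd_map(panel$variants, panel$phenotypes, windows)
  iv <- res$interval
  hit <- nrow(iv) == 1 && iv$left <= panel$causal_pos &&
    panel$causal_pos <= iv$right
  tibble(
    seed = as.integer(seed), n_meioses = n_meioses, recovered = hit,
    width_bp = if (nrow(iv)) iv$width_bp else NA_real_
  )
}

#' Empirical gamete-dosage frequencies from repeated meioses
#'
#' Draws `n` meioses of a parent with the given causal-locus dosage through
#' the haplotype-level simulator and tabulates the gamete alt-dosage
#' frequencies — the Monte Carlo counterpart of [gamete_dosage_pmf()].
#'
#' @param d Parent alt dosage (0..4).
#' @param n Number of meioses.
#' @param seed Integer seed.
#' @param genetic_length Map length in Morgans (does not affect the
#'   single-locus dosage law).
#'
#' @return Named numeric vector of frequencies over gamete dosages 0..2.
#' @export
empirical_gamete_freqs <- function(d, n = 1e5, seed = 1L,
                                   genetic_length = 2) {
  cfg <- sim_config(n_snps = 1, chrom_length = 1e6, causal_pos = 5e5,
    genetic_length = genetic_length, parent_dosage = d, seed = seed)
  ind <- list(
    haps = matrix(c(rep(1L, d), rep(0L, 4 - d)), 4, 1),
    positions = 5e5
  )
  set.seed(seed)
  dos <- vapply(seq_len(n), function(i) sum(simulate_meiosis(ind, cfg)),
    numeric(1))
  setNames(tabulate(dos + 1, nbins = 3) / n, c("0", "1", "2"))
}
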