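#' Thresholds for the recessive-inheritance bulk filter
#'
#' Sites consistent with a recessive causal allele show a near-fixed causal
#' allele in the affected (mutant) bulk and an intermediate frequency in the
#' control bulk. The defaults are the standard recessive-BSA cutoffs:
#' affected-bulk frequency at least 0.95 and control-bulk frequency at most
#' 0.85, with a minimum pooled depth of 10 reads per bulk for a site to be
#' evaluated at all.
#'
#' @param af_mut_min Minimum causal-allele frequency in the mutant bulk.
#' @param af_wt_max Maximum causal-allele frequency in the control bulk.
#' @param min_bulk_depth Minimum pooled depth per bulk per site.
#'
#' @return A list of class `bsa_thresholds`.
#' @export
bsa_thresholds <- function(af_mut_min = 0.95, af_wt_max = 0.85,
                           min_bulk_depth = 10) {
  if (!(af_wt_max >= 0 && af_wt_max < af_mut_min && af_mut_min <= 1)) {
    abort("need 0 <= af_wt_max < af_mut_min <= 1")
  }
  structure(
    list(af_mut_min = af_mut_min, af_wt_max = af_wt_max,
      min_bulk_depth = min_bulk_depth),
    class = "bsa_thresholds"
  )
}

#' Recessive-inheritance allele-frequency filter
#'
#' A site passes when the causal-allele frequency is at least `af_mut_min`
#' in the mutant bulk and at most `af_wt_max` in the control bulk. Missing
#' frequencies (zero depth) fail with reason `"missing"`.
#'
#' @param af_mut,af_wt Causal-allele frequencies in the two bulks
#'   (vectorised).
#' @param thr A [bsa_thresholds()].
#'
#' @return Logical vector; `FALSE` where either frequency is missing.
#' @export
#' @examples
#' recessive_filter(0.96, 0.80) # TRUE
#' recessive_filter(0.96, 0.86) # FALSE
recessive_filter <- function(af_mut, af_wt, thr = bsa_thresholds()) {
  pass <- af_mut >= thr$af_mut_min & af_wt <= thr$af_wt_max
  pass[is.na(af_mut) | is.na(af_wt)] <- FALSE
  pass
}

#' Orient each site's candidate-causal allele
#'
#' With a reference genome carrying the dominant (functional) allele the
#' causal allele is the alternate allele at every site (`mode = "alt"`, the
#' default). In `"auto"` mode the allele at higher frequency in the mutant
#' bulk is taken as candidate-causal, with ties going to the alternate
#' allele.
#'
#' @param counts Bulk-count tibble with columns `mut_ref`, `mut_alt` (and
#'   any others, preserved).
#' @param mode `"alt"` or `"auto"`.
#'
#' @return `counts` with an added `orientation` column (`"ref"`/`"alt"`).
#' @export
polarize <- function(counts, mode = c("alt", "auto")) {
  mode <- match.arg(mode)
  if (mode == "alt") {
    return(mutate(counts, orientation = "alt"))
  }
  mutate(counts,
    orientation = ifelse(
      !is.na(.data$mut_ref + .data$mut_alt) & .data$mut_ref > .data$mut_alt,
      "ref", "alt"
    )
  )
}

#' Windowed count of recessive-filter-passing variants
#'
#' The bulked-segregant statistic: for each sliding window, the number of
#' variants passing the recessive-inheritance filter. Causal-allele
#' frequencies are computed from pooled read counts per bulk; sites below
#' the per-bulk depth floor in either bulk are excluded before filtering.
#' A site contributes to every overlapping window that contains it.
#'
#' @param counts Bulk-count tibble with columns `chrom`, `pos`, `mut_ref`,
#'   `mut_alt`, `wt_ref`, `wt_alt` and optionally `orientation` from
#'   [polarize()] (defaults to alt-causal).
#' @param windows Window tibble from [make_windows()].
#' @param thr A [bsa_thresholds()].
#'
#' @return A `bsa_profile` tibble: `chrom`, `start`, `end`, `count`, one row
#'   per window, with the thresholds in attribute `thresholds`.
#' @export
bsa_scan <- function(counts, windows, thr = bsa_thresholds()) {
  if (!"orientation" %in% names(counts)) counts <- polarize(counts, "alt")
  counts <- counts %>%
    mutate(
      mut_dp = .data$mut_ref + .data$mut_alt,
      wt_dp = .data$wt_ref + .data$wt_alt,
      af_mut_alt = allele_frequency(.data$mut_ref, .data$mut_alt),
      af_wt_alt = allele_frequency(.data$wt_ref, .data$wt_alt),
      af_mut = ifelse(.data$orientation == "alt", .data$af_mut_alt,
        1 - .data$af_mut_alt),
      af_wt = ifelse(.data$orientation == "alt", .data$af_wt_alt,
        1 - .data$af_wt_alt),
      pass = .data$mut_dp >= thr$min_bulk_depth &
        .data$wt_dp >= thr$min_bulk_depth &
        recessive_filter(.data$af_mut, .data$af_wt, thr)
    )
  passing <- counts %>% filter(.data$pass)
  hits <- window_membership(passing$chrom, passing$pos, windows)
  profile <- windows %>%
    mutate(count = tabulate(hits$window, nbins = dplyr::n()))
  attr(profile, "thresholds") <- thr
  class(profile) <- c("bsa_profile", class(profile))
  profile
}

#' Call the interval enriched for the causal allele
#'
#' Windows whose passing-variant count reaches `max(min_count, f *
#' global max)` are marked; runs of marked windows separated by at most
#' `max_gap` unmarked windows are bridged; the run carrying the greatest
#' total passing-variant count (ties resolved toward the run containing
#' the leftmost global maximum, then leftmost) is reported, spanning from
#' its first marked window's start to its last marked window's end. An
#' all-zero profile yields an explicit no-signal result.
#'
#' The default marking threshold is dominated by the absolute floor
#' `min_count` for sparse marker panels, where per-window counts in the
#' enriched region are small Poisson numbers: a threshold placed near the
#' typical enriched-window count (as a large fraction of the observed
#' maximum tends to be) fragments the region at sampling zeroes, and a
#' single noisy maximum is an unreliable anchor. Short-gap bridging plus
#' mass-based run selection recovers the contiguous enriched block and
#' still isolates it from scattered background windows, whose pass
#' probability is orders of magnitude lower; for dense panels the
#' fractional term engages and tightens the call.
#'
#' @param profile A `bsa_profile` from [bsa_scan()] (single chromosome).
#' @param f Fraction of the global maximum a window must reach
#'   (default 0.1).
#' @param min_count Absolute floor on the window count (default 2).
#' @param max_gap Maximum number of consecutive sub-threshold windows
#'   bridged inside a run (default 8; 400 kb at the default layout).
#'
#' @return A one-row tibble of class `bsa_interval` with `chrom`, `start`,
#'   `end`, `width_bp`, `width_kb`, `width_mb`, `max_count`, `n_windows`;
#'   zero rows (class preserved) when there is no signal.
#' @export
call_enriched_interval <- function(profile, f = 0.1, min_count = 2,
                                   max_gap = 8) {
  if (nrow(profile) == 0) abort("empty profile")
  empty <- tibble(
    chrom = character(), start = numeric(), end = numeric(),
    width_bp = numeric(), width_kb = numeric(), width_mb = numeric(),
    max_count = numeric(), n_windows = integer()
  )
  mx <- max(profile$count)
  if (mx == 0) {
    class(empty) <- c("bsa_interval", class(empty))
    return(empty)
  }
  threshold <- max(min_count, f * mx)
  marked <- profile$count >= threshold
  # bridge runs of marked windows separated by short unmarked gaps
  bridged <- marked
  runs0 <- rle(marked)
  ends0 <- cumsum(runs0$lengths)
  starts0 <- ends0 - runs0$lengths + 1L
  interior <- which(!runs0$values & runs0$lengths <= max_gap &
    seq_along(runs0$values) > 1 & seq_along(runs0$values) < length(runs0$values))
  for (i in interior) bridged[starts0[i]:ends0[i]] <- TRUE
  runs <- rle(bridged)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- which(runs$values)
  if (length(cand) == 0) {
    class(empty) <- c("bsa_interval", class(empty))
    return(empty)
  }
  # select the run carrying the most passing-variant mass; single-window
  # excursions cannot outvote a sustained enriched block. Ties go to the
  # run containing the (leftmost) global maximum, then leftmost.
  mass <- vapply(cand, function(i) {
    sum(profile$count[starts[i]:ends[i]][marked[starts[i]:ends[i]]])
  }, numeric(1))
  peak <- which.max(profile$count) # leftmost global max
  has_peak <- vapply(cand, function(i) starts[i] <= peak && ends[i] >= peak,
    logical(1))
  best <- which(mass == max(mass))
  if (length(best) > 1 && any(has_peak[best])) best <- best[has_peak[best]]
  run_i <- cand[best[1]]
  # trim bridged gaps at the run edges: span marked windows only
  lo <- starts[run_i]
  hi <- ends[run_i]
  while (!marked[lo]) lo <- lo + 1L
  while (!marked[hi]) hi <- hi - 1L
  out <- tibble(
    chrom = profile$chrom[lo],
    start = profile$start[lo],
    end = profile$end[hi],
    width_bp = end - start,
    width_kb = interval_width(start, end, "kb"),
    width_mb = interval_width(start, end, "Mb"),
    max_count = mx,
    n_windows = hi - lo + 1L
  )
  attr(out, "rule") <- list(f = f, min_count = min_count, max_gap = max_gap)
  class(out) <- c("bsa_interval", class(out))
  out
}

#' Read pooled bulk counts from TSV or a two-sample VCF
#'
#' The TSV form has columns `chrom, pos, mut_ref, mut_alt, wt_ref, wt_alt`.
#' The VCF form must contain exactly two samples with `AD` depths; `mut`
#' and `wt` name which sample is which bulk.
#'
#' @param path Input file.
#' @param format `"tsv"` or `"vcf"`.
#' @param mut,wt Sample names of the mutant and control bulk (VCF form).
#'
#' @return A bulk-count tibble.
#' @export
read_bulk_counts <- function(path, format = c("tsv", "vcf"),
                             mut = NULL, wt = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- readr::read_tsv(path, show_col_types = FALSE)
    need <- c("chrom", "pos", "mut_ref", "mut_alt", "wt_ref", "wt_alt")
    if (!all(need %in% names(tab))) {
      abort(paste("bulk TSV must have columns:", paste(need, collapse = ", ")))
    }
    return(tab[, need])
  }
  v <- read_vcf(path)
  samples <- attr(v, "samples")
  if (length(samples) != 2) abort("bulk VCF must contain exactly two samples")
  if (is.null(mut)) mut <- samples[1]
  if (is.null(wt)) wt <- samples[2]
  wide <- v %>%
    select("chrom", "pos", "sample", "ad_ref", "ad_alt") %>%
    tidyr::pivot_wider(
      names_from = "sample", values_from = c("ad_ref", "ad_alt")
    )
  tibble(
    chrom = wide$chrom, pos = wide$pos,
    mut_ref = wide[[paste0("ad_ref_", mut)]],
    mut_alt = wide[[paste0("ad_alt_", mut)]],
    wt_ref = wide[[paste0("ad_ref_", wt)]],
    wt_alt = wide[[paste0("ad_alt_", wt)]]
  )
}
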