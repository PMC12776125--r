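#' Per-sample heterozygous-site counts in sliding windows
#'
#' A tetraploid call is heterozygous when its alt dosage is 1, 2 or 3 and
#' homozygous at dosage 0 or 4; missing calls are excluded. Each site
#' contributes to every overlapping window containing it.
#'
#' @param variants Long dosage tibble with columns `sample`, `chrom`, `pos`,
#'   `dosage`.
#' @param windows Window tibble from [make_windows()].
#' @param samples Optional subset of sample ids (default: all in `variants`).
#'
#' @return A `het_profile` tibble: `sample`, `chrom`, `start`, `end`,
#'   `het_count`, one row per sample per window.
#' @export
het_profile <- function(variants, windows, samples = NULL) {
  if (is.null(samples)) samples <- unique(variants$sample)
  het <- variants %>%
    filter(.data$sample %in% samples, !is.na(.data$dosage),
      .data$dosage %in% 1:3)
  windows <- windows %>% mutate(.window = row_number())
  hits <- window_membership(het$chrom, het$pos, windows)
  counted <- tibble(
    sample = het$sample[hits$site],
    .window = hits$window
  ) %>%
    dplyr::count(.data$sample, .data$.window, name = "het_count")
  grid <- tidyr::expand_grid(sample = samples, .window = windows$.window) %>%
    left_join(counted, by = c("sample", ".window")) %>%
    mutate(het_count = dplyr::coalesce(.data$het_count, 0L)) %>%
    left_join(windows, by = ".window") %>%
    select("sample", "chrom", "start", "end", "het_count") %>%
    arrange(.data$sample, .data$chrom, .data$start)
  class(grid) <- c("het_profile", class(grid))
  grid
}

#' Excess-homozygosity metric per window
#'
#' The plotted homozygosity statistic: minus the window's heterozygous-site
#' count divided by the median count over windows, so that typical windows
#' sit near -1 and fully homozygous windows at 0. The median is taken per
#' sample over all windows of the chromosome (zero-count windows included)
#' or genome-wide; a zero median is floored to 1 so the metric stays
#' defined for near-fully-homozygous samples.
#'
#' @param profile A [het_profile()].
#' @param scope `"per_chromosome"` (default) or `"genome_wide"` median.
#'
#' @return The profile with added columns `normalizer` and `metric`
#'   (`metric = -het_count / normalizer`, always <= 0).
#' @export
homozygosity_metric <- function(profile,
                                scope = c("per_chromosome", "genome_wide")) {
  scope <- match.arg(scope)
  grouping <- if (scope == "per_chromosome") c("sample", "chrom") else "sample"
  out <- profile %>%
    group_by(across(all_of(grouping))) %>%
    mutate(
      normalizer = {
        md <- median(.data$het_count)
        if (md == 0) 1 else md
      },
      metric = -.data$het_count / .data$normalizer
    ) %>%
    ungroup()
  class(out) <- unique(c("het_profile", class(out)))
  out
}

#' Homozygous intervals shared by all affected samples
#'
#' Per sample, maximal runs of consecutive windows whose heterozygous-site
#' count is at most `h_max` become candidate intervals (first window start
#' to last window end); the result is the intersection of these interval
#' sets across all samples in the profile. `h_max = 1` tolerates one
#' heterozygous call per window as genotyping-error slack.
#'
#' @param profile A [het_profile()] restricted to the affected samples.
#' @param h_max Per-window heterozygous-site tolerance (default 1).
#'
#' @return A tibble `chrom`, `start`, `end` (0-based half-open) of shared
#'   homozygous intervals; zero rows when the intersection is empty.
#' @export
shared_homozygous_intervals <- function(profile, h_max = 1) {
  samples <- unique(profile$sample)
  if (length(samples) == 0) abort("no affected samples in profile")
  per_chrom <- split(profile, profile$chrom)
  out <- purrr::map_dfr(per_chrom, function(pc) {
    chrom <- pc$chrom[1]
    ranges_of <- function(sub) {
      sub <- arrange(sub, .data$start)
      ok <- sub$het_count <= h_max
      if (!any(ok)) return(IRanges::IRanges())
      runs <- rle(ok)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      keep <- which(runs$values)
      IRanges::reduce(IRanges::IRanges(
        start = sub$start[starts[keep]] + 1L,
        end = sub$end[ends[keep]]
      ))
    }
    shared <- ranges_of(filter(pc, .data$sample == samples[1]))
    for (s in samples[-1]) {
      shared <- IRanges::intersect(
        shared, ranges_of(filter(pc, .data$sample == s))
      )
      if (length(shared) == 0) break
    }
    if (length(shared) == 0) {
      return(tibble(chrom = character(), start = numeric(), end = numeric()))
    }
    tibble(
      chrom = chrom,
      start = IRanges::start(shared) - 1,
      end = as.numeric(IRanges::end(shared))
    )
  })
  arrange(out, .data$chrom, .data$start)
}

#' Classify sites against the diagnostic-SNP rule
#'
#' A site is a diagnostic SNP when every affected sample is homozygous
#' (dosage 0 or 4) for the same allele A and no unaffected sample is
#' homozygous for A (each unaffected sample carries at most 3 copies of A —
#' "no more than heterozygous"). Missing calls in any required sample
#' disqualify the site. Sites where all required calls are present and the
#' panel is polymorphic are `informative`; informative sites failing the
#' rule are the inconsistent evidence used to place breakpoints.
#'
#' @param variants Long dosage tibble (`sample`, `chrom`, `pos`, `dosage`).
#' @param affected,unaffected Character vectors of sample ids (non-empty).
#'
#' @return A tibble per site: `chrom`, `pos`, `allele` (`"ref"`/`"alt"`/`NA`),
#'   `informative`, `consistent`. Diagnostic SNPs are the rows with
#'   `consistent == TRUE`.
#' @export
diagnostic_snps <- function(variants, affected, unaffected) {
  if (length(affected) == 0 || length(unaffected) == 0) {
    abort("affected and unaffected sets must be non-empty")
  }
  aff <- variants %>%
    filter(.data$sample %in% affected) %>%
    group_by(.data$chrom, .data$pos) %>%
    summarise(
      aff_complete = !anyNA(.data$dosage),
      all_alt = all(.data$dosage == 4L),
      all_ref = all(.data$dosage == 0L),
      .groups = "drop"
    )
  un <- variants %>%
    filter(.data$sample %in% unaffected) %>%
    group_by(.data$chrom, .data$pos) %>%
    summarise(
      un_complete = !anyNA(.data$dosage),
      any_hom_alt = any(.data$dosage == 4L),
      any_hom_ref = any(.data$dosage == 0L),
      .groups = "drop"
    )
  poly <- variants %>%
    filter(.data$sample %in% c(affected, unaffected)) %>%
    group_by(.data$chrom, .data$pos) %>%
    summarise(
      polymorphic = dplyr::n_distinct(.data$dosage, na.rm = TRUE) > 1,
      .groups = "drop"
    )
  left_join(aff, un, by = c("chrom", "pos")) %>%
    left_join(poly, by = c("chrom", "pos")) %>%
    mutate(
      aff_complete = dplyr::coalesce(.data$aff_complete, FALSE),
      un_complete = dplyr::coalesce(.data$un_complete, FALSE),
      allele = case_when(
        .data$aff_complete & isTRUE_v(.data$all_alt) ~ "alt",
        .data$aff_complete & isTRUE_v(.data$all_ref) ~ "ref",
        TRUE ~ NA_character_
      ),
      informative = .data$aff_complete & .data$un_complete &
        dplyr::coalesce(.data$polymorphic, FALSE),
      consistent = .data$informative & !is.na(.data$allele) & dplyr::case_when(
        .data$allele == "alt" ~ !.data$any_hom_alt,
        .data$allele == "ref" ~ !.data$any_hom_ref,
        TRUE ~ FALSE
      )
    ) %>%
    select("chrom", "pos", "allele", "informative", "consistent") %>%
    arrange(.data$chrom, .data$pos)
}

# vectorised isTRUE that maps NA to FALSE
isTRUE_v <- function(x) !is.na(x) & x

#' Confirm or relocate an interval boundary with a 20 kb diagnostic-SNP scan
#'
#' At a candidate boundary, a window of `l_scan` bp is examined on each
#' side: the boundary is accepted when at least `n_confirm` diagnostic
#' (consistent) SNPs lie within `l_scan` on the interval side and at least
#' `n_confirm` informative SNPs within `l_scan` on the far side are
#' inconsistent. When the interval-side evidence holds but the far side is
#' still clean, the candidate slides outward to the next informative SNP
#' and the scan repeats, so the boundary settles on the position where
#' inconsistent evidence first appears; when either side lacks
#' `n_confirm` informative SNPs in range the boundary is flagged
#' unconfirmed.
#'
#' @param candidate Candidate boundary position (bp).
#' @param snps Tibble from [diagnostic_snps()] (single chromosome):
#'   `pos`, `informative`, `consistent`.
#' @param side `"left"` (interval extends to the right of the boundary) or
#'   `"right"`.
#' @param l_scan Scan distance in bp on each side (default 20000).
#' @param n_confirm SNPs required on each side (default 3).
#'
#' @return One-row tibble: `boundary`, `status` (`"confirmed"` /
#'   `"unconfirmed"`), `n_consistent_inside`, `n_inconsistent_outside`,
#'   `nearest_inconsistent_outside` (bp or `NA`).
#' @export
refine_breakpoint <- function(candidate, snps, side = c("left", "right"),
                              l_scan = 20000, n_confirm = 3) {
  side <- match.arg(side)
  info <- snps %>% filter(.data$informative) %>% arrange(.data$pos)
  dir <- if (side == "left") 1 else -1 # interval direction
  cand <- candidate
  repeat {
    inside <- info %>% filter(
      dir * (.data$pos - cand) >= 0, dir * (.data$pos - cand) <= l_scan
    )
    outside <- info %>% filter(
      dir * (.data$pos - cand) < 0, dir * (.data$pos - cand) >= -l_scan
    )
    n_in <- sum(inside$consistent)
    n_out <- sum(!outside$consistent)
    near_out <- outside %>% filter(!.data$consistent)
    nearest <- if (nrow(near_out)) {
      near_out$pos[which.min(abs(near_out$pos - cand))]
    } else {
      NA_real_
    }
    if (n_in >= n_confirm && n_out >= n_confirm) {
      return(tibble(
        boundary = cand, status = "confirmed",
        n_consistent_inside = n_in, n_inconsistent_outside = n_out,
        nearest_inconsistent_outside = nearest
      ))
    }
    if (n_in < n_confirm || nrow(outside) >= n_confirm) {
      # interval-side support failed, or the far side has informative SNPs
      # but they do not contradict the pattern strongly enough: give up here
      if (nrow(outside) >= n_confirm && n_in >= n_confirm) {
        # enough informative far-side SNPs but too few inconsistent:
        # slide outward past them
        nxt <- info %>% filter(dir * (.data$pos - cand) < 0)
        if (nrow(nxt) == 0) break
        cand <- nxt$pos[which.max(dir * nxt$pos)] # nearest outward SNP
        next
      }
      break
    }
    # too few informative SNPs on the far side: slide outward if possible
    nxt <- info %>% filter(dir * (.data$pos - cand) < 0)
    if (nrow(nxt) == 0) break
    cand <- nxt$pos[which.max(dir * nxt$pos)]
  }
  tibble(
    boundary = cand, status = "unconfirmed",
    n_consistent_inside = sum(
      info$consistent & dir * (info$pos - cand) >= 0 &
        dir * (info$pos - cand) <= l_scan
    ),
    n_inconsistent_outside = NA_integer_,
    nearest_inconsistent_outside = NA_real_
  )
}

#' Assemble the final fine-mapping interval report
#'
#' @param left,right Confirmed boundary positions (bp), `left < right`.
#' @param chrom Chromosome name.
#' @param provenance Optional tibble of boundary evidence (side, sample,
#'   SNP position), stored as an attribute.
#'
#' @return One-row tibble of class `ibd_interval`: `chrom`, `left`, `right`,
#'   `width_bp`, `width_kb`, `width_mb`.
#' @export
#' @examples
#' final_interval(30482969, 30807700, "Ri04") # 324731 bp = 324 kb
final_interval <- function(left, right, chrom = "chr", provenance = NULL) {
  if (right <= left) abort("boundaries are crossed: need left < right")
  out <- tibble(
    chrom = chrom, left = left, right = right,
    width_bp = right - left,
    width_kb = interval_width(left, right, "kb"),
    width_mb = interval_width(left, right, "Mb")
  )
  attr(out, "provenance") <- provenance
  class(out) <- c("ibd_interval", class(out))
  out
}

#' Family-based IBD homozygosity mapping, end to end
#'
#' Runs the full mapping chain on a genotyped panel: per-affected-sample
#' heterozygosity windows, shared homozygous intervals across affecteds,
#' diagnostic-SNP classification, breakpoint refinement of the widest
#' shared interval, and the final interval report with boundary provenance
#' (the affected sample heterozygous at the nearest inconsistent SNP
#' outside each boundary).
#'
#' @param variants Long dosage tibble (`sample`, `chrom`, `pos`, `dosage`).
#' @param phenotypes Phenotype tibble (`sample`, `status`; 1 = affected).
#' @param windows Window tibble from [make_windows()].
#' @param h_max Per-window heterozygosity tolerance (default 1).
#' @param l_scan Breakpoint scan distance (default 20000 bp).
#' @param n_confirm SNP support per boundary side (default 3).
#'
#' @return A list of class `ibd_result`: `het` (profile with metric),
#'   `shared` (all shared intervals), `left`, `right` (refinement records),
#'   `interval` (an `ibd_interval`, or zero-row tibble when no signal),
#'   `snps` (diagnostic-SNP table).
#' @export
ibd_map <- function(variants, phenotypes, windows, h_max = 1,
                    l_scan = 20000, n_confirm = 3) {
  affected <- phenotypes$sample[phenotypes$status == 1L]
  unaffected <- phenotypes$sample[phenotypes$status == 0L]
  if (length(affected) == 0) abort("no affected samples")
  prof <- het_profile(variants, windows, samples = affected)
  prof <- homozygosity_metric(prof)
  shared <- shared_homozygous_intervals(prof, h_max = h_max)
  if (nrow(shared) == 0) {
    return(structure(
      list(het = prof, shared = shared, left = NULL, right = NULL,
        interval = final_interval_empty(), snps = NULL),
      class = "ibd_result"
    ))
  }
  main <- shared %>%
    mutate(w = .data$end - .data$start) %>%
    arrange(dplyr::desc(.data$w), .data$start) %>%
    slice(1)
  snps <- diagnostic_snps(
    filter(variants, .data$chrom == main$chrom),
    affected, unaffected
  )
  left <- refine_breakpoint(main$start, snps, "left",
    l_scan = l_scan, n_confirm = n_confirm)
  right <- refine_breakpoint(main$end, snps, "right",
    l_scan = l_scan, n_confirm = n_confirm)
  prov <- bind_rows(
    boundary_provenance(left, "left", variants, affected, main$chrom),
    boundary_provenance(right, "right", variants, affected, main$chrom)
  )
  interval <- final_interval(
    left$boundary, right$boundary, chrom = main$chrom, provenance = prov
  )
  structure(
    list(het = prof, shared = shared, left = left, right = right,
      interval = interval, snps = snps),
    class = "ibd_result"
  )
}

final_interval_empty <- function() {
  out <- tibble(
    chrom = character(), left = numeric(), right = numeric(),
    width_bp = numeric(), width_kb = numeric(), width_mb = numeric()
  )
  class(out) <- c("ibd_interval", class(out))
  out
}

# which affected sample is heterozygous at the nearest inconsistent SNP
# outside a boundary: that sample's recombination set the border
boundary_provenance <- function(refined, side, variants, affected, chrom) {
  snp_pos <- refined$nearest_inconsistent_outside
  if (is.na(snp_pos)) {
    return(tibble(side = side, sample = NA_character_, pos = NA_real_))
  }
  het_there <- variants %>%
    filter(.data$chrom == !!chrom, .data$pos == snp_pos,
      .data$sample %in% affected, !is.na(.data$dosage),
      .data$dosage %in% 1:3)
  tibble(
    side = side,
    sample = if (nrow(het_there)) het_there$sample[1] else NA_character_,
    pos = snp_pos
  )
}
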