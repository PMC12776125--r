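test_that("recessive_filter applies the bulk frequency cutoffs", {
  expect_true(recessive_filter(0.96, 0.80))
  expect_false(recessive_filter(0.96, 0.86)) # control bound violated
  expect_true(recessive_filter(1.0, 0.0))
  expect_false(recessive_filter(0.94, 0.80))
  expect_false(recessive_filter(NA, 0.5))
  expect_false(recessive_filter(0.99, NA))
  expect_error(bsa_thresholds(af_mut_min = 0.8, af_wt_max = 0.85))
})

test_that("polarize orients the candidate-causal allele", {
  counts <- tibble::tibble(mut_ref = c(3, 97, 50), mut_alt = c(97, 3, 50))
  expect_equal(polarize(counts, "alt")$orientation, rep("alt", 3))
  auto <- polarize(counts, "auto")$orientation
  expect_equal(auto, c("alt", "ref", "alt")) # tie goes to alt
})

test_that("bsa_scan counts passing variants per overlapping window", {
  windows <- make_windows(genome_layout("c", 200000), 100000, 50000)
  counts <- tibble::tibble(
    chrom = "c",
    pos = c(10001, 60001, 120001, 150001),
    mut_ref = c(1, 0, 2, 2),
    mut_alt = c(99, 100, 98, 98),
    wt_ref = c(40, 50, 45, 10),
    wt_alt = c(60, 50, 55, 90) # last site fails the control bound
  )
  prof <- bsa_scan(counts, windows)
  expect_equal(prof$count, c(2, 2, 1, 0))

  # a site in an overlap region lands in exactly two windows
  one <- bsa_scan(counts[2, ], windows)
  expect_equal(sum(one$count), 2)

  # no passing sites: all-zero profile
  none <- counts
  none$wt_alt <- 95
  none$wt_ref <- 5
  expect_true(all(bsa_scan(none, windows)$count == 0))
})

test_that("bsa_scan equals a brute-force membership double loop", {
  set.seed(21)
  windows <- make_windows(genome_layout("c", 1e6), 100000, 50000)
  n <- 600
  counts <- tibble::tibble(
    chrom = "c",
    pos = sort(sample.int(1e6, n)),
    mut_ref = rbinom(n, 100, 0.1),
    mut_alt = 100 - rbinom(n, 100, 0.1),
    wt_ref = rbinom(n, 100, 0.4),
    wt_alt = 100 - rbinom(n, 100, 0.4)
  )
  thr <- bsa_thresholds()
  prof <- bsa_scan(counts, windows, thr)
  af_mut <- counts$mut_alt / (counts$mut_ref + counts$mut_alt)
  af_wt <- counts$wt_alt / (counts$wt_ref + counts$wt_alt)
  pass <- af_mut >= thr$af_mut_min & af_wt <= thr$af_wt_max &
    counts$mut_ref + counts$mut_alt >= thr$min_bulk_depth &
    counts$wt_ref + counts$wt_alt >= thr$min_bulk_depth
  expect_equal(prof$count, brute_force_window_counts(counts$pos[pass], windows))
})

test_that("tightening either threshold never increases a window count", {
  set.seed(22)
  windows <- make_windows(genome_layout("c", 5e5), 100000, 50000)
  n <- 300
  counts <- tibble::tibble(
    chrom = "c", pos = sort(sample.int(5e5, n)),
    mut_ref = rbinom(n, 80, 0.05), mut_alt = rbinom(n, 80, 0.9) + 10,
    wt_ref = rbinom(n, 80, 0.3) + 5, wt_alt = rbinom(n, 80, 0.7) + 5
  )
  base <- bsa_scan(counts, windows, bsa_thresholds(0.90, 0.85))$count
  higher_mut <- bsa_scan(counts, windows, bsa_thresholds(0.95, 0.85))$count
  lower_wt <- bsa_scan(counts, windows, bsa_thresholds(0.90, 0.75))$count
  expect_true(all(higher_mut <= base))
  expect_true(all(lower_wt <= base))
})

test_that("swapped complementary bulks with flipped polarity match", {
  set.seed(23)
  windows <- make_windows(genome_layout("c", 5e5), 100000, 50000)
  n <- 200
  counts <- tibble::tibble(
    chrom = "c", pos = sort(sample.int(5e5, n)),
    mut_ref = rbinom(n, 60, 0.1), mut_alt = rbinom(n, 60, 0.9) + 12,
    wt_ref = rbinom(n, 60, 0.5) + 12, wt_alt = rbinom(n, 60, 0.5) + 12
  )
  fwd <- bsa_scan(dplyr::mutate(counts, orientation = "alt"), windows)
  # swap bulks and swap ref/alt counts: the causal allele is now "ref"
  swapped <- tibble::tibble(
    chrom = counts$chrom, pos = counts$pos,
    mut_ref = counts$wt_alt, mut_alt = counts$wt_ref,
    wt_ref = counts$mut_alt, wt_alt = counts$mut_ref,
    orientation = "ref"
  )
  # swapping mut/wt roles swaps which threshold applies, so compare on
  # symmetric thresholds
  thr <- bsa_thresholds(0.9, 0.85)
  swapped_back <- tibble::tibble(
    chrom = counts$chrom, pos = counts$pos,
    mut_ref = counts$mut_alt, mut_alt = counts$mut_ref,
    wt_ref = counts$wt_alt, wt_alt = counts$wt_ref,
    orientation = "ref"
  )
  expect_equal(bsa_scan(swapped_back, windows, thr)$count,
    bsa_scan(dplyr::mutate(counts, orientation = "alt"), windows, thr)$count)
  expect_s3_class(fwd, "bsa_profile")
})

test_that("call_enriched_interval merges the run around the maximum", {
  mk <- function(counts) {
    p <- tibble::tibble(
      chrom = "c",
      start = (seq_along(counts) - 1) * 50000,
      end = (seq_along(counts) - 1) * 50000 + 100000,
      count = counts
    )
    class(p) <- c("bsa_profile", class(p))
    p
  }
  iv <- call_enriched_interval(mk(c(0, 1, 8, 9, 10, 2, 0)), f = 0.5)
  expect_equal(iv$start, 100000) # third window
  expect_equal(iv$end, 300000) # fifth window
  expect_equal(iv$max_count, 10)

  single <- call_enriched_interval(mk(4))
  expect_equal(nrow(single), 1)
  expect_equal(c(single$start, single$end), c(0, 100000))

  expect_equal(nrow(call_enriched_interval(mk(c(0, 0, 0)))), 0)
  expect_error(call_enriched_interval(mk(numeric())))

  # gap bridging joins marked runs split by short sampling dips, and the
  # reported run is the one with the larger total mass
  bridged <- call_enriched_interval(mk(c(3, 4, 0, 0, 5, 4, 3, 0, 0, 0)),
    f = 0.1, min_count = 2, max_gap = 2)
  expect_equal(c(bridged$start, bridged$end), c(0, 400000))
  split <- call_enriched_interval(mk(c(3, 4, 0, 0, 5, 4, 3, 0, 0, 0)),
    f = 0.1, min_count = 2, max_gap = 1)
  expect_equal(c(split$start, split$end), c(200000, 400000))
})

test_that("bulk counts read back identically from the TSV interface", {
  counts <- tibble::tibble(
    chrom = "c", pos = c(100L, 900L),
    mut_ref = c(1L, 2L), mut_alt = c(30L, 40L),
    wt_ref = c(20L, 25L), wt_alt = c(15L, 30L)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(counts, path)
  expect_equal(as.data.frame(read_bulk_counts(path, "tsv")),
    as.data.frame(counts))
  bad <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(counts[, 1:3], bad)
  expect_error(read_bulk_counts(bad, "tsv"), "columns")
})
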