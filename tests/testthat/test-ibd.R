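test_that("het_profile counts heterozygous calls per window", {
  windows <- make_windows(genome_layout("c", 200000), 100000, 50000)
  dos <- matrix(c(2L, 4L, 1L), nrow = 1,
    dimnames = list("s1", NULL))
  variants <- dosage_tibble(dos, c(10001, 60001, 120001), chrom = "c")
  prof <- het_profile(variants, windows)
  expect_equal(prof$het_count, c(1, 1, 1, 0))

  # homozygous-only dosages give an all-zero profile
  hom <- dosage_tibble(matrix(c(0L, 4L, 4L), 1, dimnames = list("s1", NULL)),
    c(10001, 60001, 120001), chrom = "c")
  expect_true(all(het_profile(hom, windows)$het_count == 0))

  # missing calls are excluded
  mis <- dosage_tibble(matrix(c(NA, NA, NA), 1, dimnames = list("s1", NULL)),
    c(10001, 60001, 120001), chrom = "c")
  expect_true(all(het_profile(mis, windows)$het_count == 0))
})

test_that("the homozygosity metric normalises by the per-chromosome median", {
  prof <- tibble::tibble(
    sample = "s1", chrom = "c",
    start = c(0, 50000, 100000), end = c(100000, 150000, 200000),
    het_count = c(2L, 4L, 6L)
  )
  m <- homozygosity_metric(prof)
  expect_equal(m$metric, c(-0.5, -1.0, -1.5))

  # degenerate zero median floors the normaliser at 1
  z <- dplyr::mutate(prof, het_count = 0L)
  expect_equal(homozygosity_metric(z)$metric, c(0, 0, 0))

  one <- prof[2, ]
  expect_equal(homozygosity_metric(one)$metric, -1)

  # scale invariance: doubling every count doubles the median too
  doubled <- dplyr::mutate(prof, het_count = het_count * 2L)
  expect_equal(homozygosity_metric(doubled)$metric,
    homozygosity_metric(prof)$metric)
  # metric is never positive and zero exactly at zero het
  expect_true(all(m$metric <= 0))
})

test_that("shared_homozygous_intervals intersects per-sample runs", {
  windows <- make_windows(genome_layout("c", 250000), 100000, 50000)[1:4, ]
  mk_prof <- function(id, counts) {
    tibble::tibble(sample = id, chrom = "c",
      start = windows$start, end = windows$end, het_count = counts)
  }
  one <- mk_prof("s1", c(5L, 0L, 0L, 5L))
  iv <- shared_homozygous_intervals(one, h_max = 0)
  expect_equal(nrow(iv), 1)
  expect_equal(c(iv$start, iv$end), c(50000, 200000)) # windows 2-3

  # disjoint runs (no overlapping span even through shared window bases)
  two <- dplyr::bind_rows(mk_prof("s1", c(0L, 9L, 9L, 9L)),
    mk_prof("s2", c(9L, 9L, 9L, 0L)))
  expect_equal(nrow(shared_homozygous_intervals(two, h_max = 0)), 0)

  # identical profiles: intersection is idempotent
  twin <- dplyr::bind_rows(mk_prof("s1", c(5L, 0L, 0L, 5L)),
    mk_prof("s2", c(5L, 0L, 0L, 5L)))
  expect_equal(as.data.frame(shared_homozygous_intervals(twin, h_max = 0)),
    as.data.frame(iv))
})

test_that("adding a sample can only shrink the shared intervals", {
  set.seed(31)
  windows <- make_windows(genome_layout("c", 1e6), 100000, 50000)
  profs <- lapply(1:4, function(i) {
    tibble::tibble(sample = paste0("s", i), chrom = "c",
      start = windows$start, end = windows$end,
      het_count = sample(0:3, nrow(windows), replace = TRUE))
  })
  covered_bp <- function(iv) sum(iv$end - iv$start)
  for (k in 2:4) {
    iv_k <- shared_homozygous_intervals(dplyr::bind_rows(profs[1:k]))
    iv_k1 <- shared_homozygous_intervals(dplyr::bind_rows(profs[1:(k - 1)]))
    expect_lte(covered_bp(iv_k), covered_bp(iv_k1))
  }
  expect_error(shared_homozygous_intervals(profs[[1]][0, ]))
})

test_that("diagnostic_snps applies the shared-homozygote rule", {
  mk <- function(aff_dos, un_dos, pos = 100) {
    dos <- matrix(c(aff_dos, un_dos), ncol = 1)
    rownames(dos) <- c(paste0("a", seq_along(aff_dos)),
      paste0("u", seq_along(un_dos)))
    dosage_tibble(dos, pos)
  }
  aff <- c("a1", "a2", "a3")
  un <- c("u1", "u2", "u3")

  # all affected quadriplex, no unaffected homozygous for alt: qualifies
  d <- diagnostic_snps(mk(c(4L, 4L, 4L), c(3L, 2L, 1L)), aff, un)
  expect_true(d$consistent)
  expect_equal(d$allele, "alt")

  # one unaffected also quadriplex: fails the "no more than het" bound
  d2 <- diagnostic_snps(mk(c(4L, 4L, 4L), c(3L, 2L, 4L)), aff, un)
  expect_false(d2$consistent)

  # affected split between the two homozygous classes: no shared allele
  d3 <- diagnostic_snps(mk(c(0L, 4L, 4L), c(3L, 2L, 1L)), aff, un)
  expect_false(d3$consistent)
  expect_true(is.na(d3$allele))

  # ref-oriented diagnostic site
  d4 <- diagnostic_snps(mk(c(0L, 0L, 0L), c(1L, 2L, 3L)), aff, un)
  expect_true(d4$consistent)
  expect_equal(d4$allele, "ref")

  # a missing call in a required sample disqualifies
  d5 <- diagnostic_snps(mk(c(4L, 4L, NA), c(3L, 2L, 1L)), aff, un)
  expect_false(d5$consistent)

  expect_error(diagnostic_snps(mk(c(4L), c(1L)), character(), "u1"))
})

test_that("diagnostic_snps equals a brute-force per-site rule check", {
  set.seed(32)
  n_sites <- 300
  aff <- paste0("a", 1:4)
  un <- paste0("u", 1:4)
  dos <- matrix(sample(c(0:4, NA), 8 * n_sites, replace = TRUE,
    prob = c(rep(0.18, 5), 0.1)), nrow = 8,
    dimnames = list(c(aff, un), NULL))
  variants <- dosage_tibble(dos, seq_len(n_sites) * 10)
  got <- diagnostic_snps(variants, aff, un)
  oracle <- vapply(seq_len(n_sites), function(j) {
    a <- dos[aff, j]
    u <- dos[un, j]
    if (anyNA(a) || anyNA(u)) return(FALSE)
    if (all(a == 4L)) return(all(u <= 3L))
    if (all(a == 0L)) return(all(u >= 1L))
    FALSE
  }, logical(1))
  expect_equal(got$consistent[order(got$pos)], oracle)
})

test_that("refine_breakpoint confirms boundaries with two-sided evidence", {
  # left boundary at 100000: interval side is to the right
  snps <- tibble::tibble(
    pos = c(82000, 86000, 90000, 104000, 108000, 112000),
    informative = TRUE,
    consistent = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  )
  r <- refine_breakpoint(100000, snps, "left")
  expect_equal(r$status, "confirmed")
  expect_equal(r$boundary, 100000)
  expect_equal(r$n_consistent_inside, 3)
  expect_equal(r$n_inconsistent_outside, 3)

  # a single far-side SNP is not enough support
  sparse <- tibble::tibble(pos = c(95000, 104000, 108000, 112000),
    informative = TRUE, consistent = c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(refine_breakpoint(100000, sparse, "left")$status, "unconfirmed")

  # no informative SNPs anywhere near: unconfirmed at the candidate
  empty <- tibble::tibble(pos = numeric(), informative = logical(),
    consistent = logical())
  r3 <- refine_breakpoint(100000, empty, "left")
  expect_equal(r3$status, "unconfirmed")
  expect_equal(r3$boundary, 100000)

  # candidate placed inside the clean region slides outward until the
  # inconsistent evidence appears
  inward <- tibble::tibble(
    pos = c(88000, 92000, 96000, seq(104000, 160000, by = 4000)),
    informative = TRUE,
    consistent = c(FALSE, FALSE, FALSE, rep(TRUE, 15))
  )
  r4 <- refine_breakpoint(140000, inward, "left")
  expect_equal(r4$status, "confirmed")
  expect_lte(r4$boundary, 108000)

  # mirrored right boundary
  right <- tibble::tibble(
    pos = c(188000, 192000, 196000, 210000, 214000, 218000),
    informative = TRUE,
    consistent = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  )
  r5 <- refine_breakpoint(200000, right, "right")
  expect_equal(r5$status, "confirmed")
})

test_that("final_interval reports widths in the published format", {
  iv <- final_interval(30482969, 30807700, "Ri04")
  expect_equal(iv$width_bp, 324731)
  expect_equal(iv$width_kb, 324)
  iv2 <- final_interval(32950000, 34250000, "Ra04")
  expect_equal(iv2$width_mb, 1.3)
  iv3 <- final_interval(100, 200)
  expect_equal(c(iv3$width_bp, iv3$width_kb), c(100, 0))
  expect_error(final_interval(200, 100))
})

test_that("ibd_map recovers a shared causal segment end to end", {
  panel <- sim_ibd_panel(seed = 33)
  windows <- make_windows(genome_layout(panel$chrom, panel$chrom_length))
  res <- ibd_map(panel$variants, panel$phenotypes, windows)
  expect_s3_class(res, "ibd_result")
  expect_equal(nrow(res$interval), 1)
  expect_lte(res$interval$left, panel$causal_pos)
  expect_gte(res$interval$right, panel$causal_pos)
  g <- glance(res)
  expect_equal(g$width_bp, res$interval$width_bp)
  # no affected samples is a usage error
  none <- dplyr::mutate(panel$phenotypes, status = 0L)
  expect_error(ibd_map(panel$variants, none, windows), "affected")
})
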