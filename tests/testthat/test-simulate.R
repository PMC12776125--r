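test_that("gamete_dosage_pmf matches enumeration of tetraploid gametes", {
  # d = 3, no double reduction: C(4,2) = 6 pairs, 3 with one alt, 3 with two
  expect_equal(unname(gamete_dosage_pmf(3, 0)), c(0, 0.5, 0.5))
  # homozygous parents are degenerate whatever alpha
  expect_equal(unname(gamete_dosage_pmf(4, 0.3)), c(0, 0, 1))
  expect_equal(unname(gamete_dosage_pmf(0, 0.9)), c(1, 0, 0))
  # full double reduction of a duplex: one of 4 copies duplicated
  expect_equal(unname(gamete_dosage_pmf(2, 1)), c(0.5, 0, 0.5))
  # probabilities always sum to one
  for (d in 0:4) {
    for (a in c(0, 0.1, 0.5, 1)) {
      expect_equal(sum(gamete_dosage_pmf(d, a)), 1)
    }
  }
  expect_error(gamete_dosage_pmf(5, 0))
  expect_error(gamete_dosage_pmf(2, 1.5))
})

test_that("meiosis without crossovers returns parental haplotypes", {
  cfg <- sim_config(n_snps = 50, chrom_length = 1e6, causal_pos = 5e5,
    genetic_length = 0, seed = 2)
  set.seed(2)
  haps <- matrix(rbinom(200, 1, 0.5), nrow = 4)
  ind <- list(haps = haps, positions = sort(sample.int(1e6, 50)))
  for (i in 1:10) {
    gam <- simulate_meiosis(ind, cfg)
    for (r in 1:2) {
      matches <- apply(haps, 1, function(h) all(h == gam[r, ]))
      expect_true(any(matches))
    }
  }
  # fully homozygous parent: any gamete equals the single haplotype
  hom <- list(haps = matrix(1L, 4, 50), positions = ind$positions)
  cfg2 <- sim_config(n_snps = 50, chrom_length = 1e6, causal_pos = 5e5,
    genetic_length = 2, seed = 3)
  gam <- simulate_meiosis(hom, cfg2)
  expect_true(all(gam == 1L))
})

test_that("empirical gamete dosages of a triplex parent match the pmf", {
  cfg <- sim_config(n_snps = 1, chrom_length = 1e6, causal_pos = 5e5,
    genetic_length = 2, seed = 4)
  ind <- list(haps = matrix(c(1L, 1L, 1L, 0L), 4, 1), positions = 5e5)
  set.seed(4)
  n <- 20000
  dos <- vapply(seq_len(n), function(i) sum(simulate_meiosis(ind, cfg)),
    numeric(1))
  freq <- tabulate(dos + 1, nbins = 3) / n
  se <- sqrt(0.5 * 0.5 / n)
  expect_equal(freq[1], 0, tolerance = 1e-12)
  expect_lt(abs(freq[2] - 0.5), 3 * se)
  expect_lt(abs(freq[3] - 0.5), 3 * se)
})

test_that("selfing a triplex parent yields one quarter affected", {
  cfg <- sim_config(n_snps = 21, chrom_length = 1e6, causal_pos = 5e5,
    n_progeny = 10000, seed = 5)
  pop <- self_cross(cfg)
  frac <- mean(pop$truth$phenotype)
  expect_lt(abs(frac - 0.25), 3 * sqrt(0.25 * 0.75 / 10000))
  # recessive rule conservation: affected exactly when causal dosage 4
  expect_equal(pop$truth$phenotype, as.integer(pop$truth$causal_dosage == 4L))
  # quadriplex parent: every progeny affected
  cfg4 <- sim_config(n_snps = 11, chrom_length = 1e6, causal_pos = 5e5,
    parent_dosage = 4, n_progeny = 50, seed = 6)
  expect_true(all(self_cross(cfg4)$truth$phenotype == 1L))
})

test_that("marker-causal dosage correlation decays with genetic distance", {
  cfg <- sim_config(n_snps = 400, chrom_length = 20e6, causal_pos = 10e6,
    genetic_length = 2, n_progeny = 300, founder_het = 1, seed = 7)
  pop <- self_cross(cfg)
  causal <- pop$dosage[, pop$causal_idx]
  dist <- abs(pop$positions - cfg$causal_pos)
  r2 <- apply(pop$dosage, 2, function(x) {
    if (stats::sd(x) == 0) return(NA_real_)
    stats::cor(x, causal)^2
  })
  bins <- cut(dist, c(-1, 2e6, 6e6, 20e6))
  mean_r2 <- tapply(r2, bins, mean, na.rm = TRUE)
  expect_true(all(diff(mean_r2) < 0))
})

test_that("read simulation respects the dosage-error binomial model", {
  cfg <- sim_config(n_snps = 11, chrom_length = 1e6, causal_pos = 5e5,
    n_progeny = 30, seed = 8)
  pop <- self_cross(cfg)
  # error-free reads: alt reads are zero at dosage 0, depth at dosage 4
  counts <- simulate_reads(pop, read_model(depth = 20, error = 0, seed = 8))
  expect_true(all(counts$alt[pop$dosage == 0L] == 0))
  expect_true(all(counts$ref[pop$dosage == 4L] == 0))
  # bulks must be disjoint and non-empty
  ids <- pop$truth$sample
  expect_error(simulate_reads(pop, read_model(seed = 1),
    bulks = list(mut = ids[1:3], wt = ids[3:5])), "disjoint")
  expect_error(simulate_reads(pop, read_model(seed = 1),
    bulks = list(mut = character(), wt = ids[1:2])))
  # pooled counts sum member reads
  bulks <- list(mut = ids[1:10], wt = ids[11:30])
  pooled <- simulate_reads(pop, read_model(depth = 20, error = 0, seed = 9),
    bulks = bulks)
  expect_equal(nrow(pooled), ncol(pop$dosage))
  expect_true(all(pooled$mut_ref + pooled$mut_alt >= 0))
})

test_that("a high-depth affected bulk shows the expected causal frequency", {
  cfg <- sim_config(n_snps = 11, chrom_length = 1e6, causal_pos = 5e5,
    n_progeny = 400, seed = 10)
  pop <- self_cross(cfg)
  aff <- pop$truth$sample[pop$truth$phenotype == 1]
  pooled <- simulate_reads(pop, read_model(depth = 10, error = 0.01, seed = 10),
    bulks = list(mut = aff, wt = setdiff(pop$truth$sample, aff)))
  at_causal <- pooled[pooled$pos == cfg$causal_pos, ]
  depth <- at_causal$mut_ref + at_causal$mut_alt
  af <- at_causal$mut_alt / depth
  se <- sqrt(0.99 * 0.01 / depth)
  expect_lt(abs(af - 0.99), 3 * se)
})

test_that("simulation outputs are deterministic given the seed", {
  cfg <- sim_config(n_snps = 31, chrom_length = 1e6, causal_pos = 5e5,
    n_progeny = 15, seed = 11)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    pop <- self_cross(cfg)
    counts <- simulate_reads(pop, read_model(depth = 8, seed = 11))
    sim_export(pop, d, counts = counts)
  }
  for (f in c("population.vcf", "phenotypes.tsv", "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("export writes tetraploid GT, truth rows and round-trips dosage", {
  cfg <- sim_config(n_snps = 15, chrom_length = 1e6, causal_pos = 5e5,
    n_progeny = 12, seed = 12)
  pop <- self_cross(cfg)
  d <- withr::local_tempdir()
  paths <- sim_export(pop, d)
  truth <- readLines(paths[["truth"]])
  expect_match(truth[1], "causal_pos=500000")
  expect_equal(length(truth), 12 + 2) # header comment + column row + progeny
  v <- read_vcf(paths[["vcf"]])
  wide <- tidyr::pivot_wider(
    dplyr::select(v, "pos", "sample", "dosage"),
    names_from = "sample", values_from = "dosage"
  )
  got <- as.matrix(wide[match(pop$positions, wide$pos), pop$truth$sample])
  expect_equal(unname(t(got)), unname(pop$dosage))
  # quadriplex progeny at the causal site are written as 1/1/1/1
  aff <- pop$truth$sample[pop$truth$causal_dosage == 4L]
  if (length(aff) > 0) {
    lines <- readLines(paths[["vcf"]])
    causal_line <- grep(paste0("\t", as.integer(cfg$causal_pos), "\t"), lines,
      value = TRUE)
    expect_match(causal_line, "1/1/1/1")
  }
})

test_that("the IBD panel generator produces the descent structure it claims", {
  panel <- sim_ibd_panel(n_affected = 4, n_unaffected = 4,
    chrom_length = 2e6, causal_pos = 1e6, snps_per_mb = 500, seed = 13)
  causal_col <- match(1e6, panel$positions)
  # affected samples are quadriplex for the causal allele, carriers are not
  expect_true(all(panel$dosage[1:4, causal_col] == 4L))
  expect_true(all(panel$dosage[5:8, causal_col] %in% 1:3))
  # same seed reproduces byte-identical variants
  panel2 <- sim_ibd_panel(n_affected = 4, n_unaffected = 4,
    chrom_length = 2e6, causal_pos = 1e6, snps_per_mb = 500, seed = 13)
  expect_identical(panel$variants, panel2$variants)
  expect_error(sim_ibd_panel(n_affected = 0))
})
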