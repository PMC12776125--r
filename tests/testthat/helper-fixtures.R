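# in-code fixtures shared across test files

# a small tetraploid VCF: 5 biallelic SNPs, 1 indel, 1 multiallelic record
write_fixture_vcf <- function(path) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", "S1", "S2", sep = "\t"),
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT:AD\t0/0/0/1:28,9\t1/1/1/1:0,30",
    "chr1\t200\t.\tC\tG\t.\tPASS\t.\tGT:AD\t./././.:.\t0/0/1/1:14,15",
    "chr1\t300\t.\tG\tA\t.\tPASS\t.\tGT:AD\t0/1/1/1:7,21\t0/0/0/0:33,0",
    "chr1\t400\t.\tAT\tA\t.\tPASS\t.\tGT:AD\t0/0/0/0:30,0\t0/0/0/0:30,0",
    "chr1\t500\t.\tT\tC,G\t.\tPASS\t.\tGT:AD\t0/0/0/1:20,5\t0/0/0/2:20,5",
    "chr1\t600\t.\tT\tC\t.\tPASS\t.\tGT:AD\t0/0/1/1:12,13\t0/1/1/1:6,20",
    "chr1\t700\t.\tG\tT\t.\tPASS\t.\tGT:AD\t1/1/1/1:0,29\t0/0/0/1:22,8"
  ), path)
  path
}

# long dosage tibble from a named matrix (samples x sites)
dosage_tibble <- function(dosage, positions, chrom = "chr1") {
  ids <- rownames(dosage)
  tibble::tibble(
    chrom = chrom,
    pos = rep(positions, times = nrow(dosage)),
    sample = rep(ids, each = length(positions)),
    dosage = as.integer(t(dosage))
  )
}

# published counts of trichome rating x prickle phenotype over a
# 332-accession Rubus diversity panel
trichome_prickle_counts <- function() {
  m <- matrix(
    c(
      42, 6, 0, 0,
      17, 17, 132, 17,
      0, 1, 63, 21,
      0, 1, 3, 12
    ),
    nrow = 4, byrow = TRUE,
    dimnames = list(
      c("hairy", "short_glandular", "short_elongated_sparse",
        "short_elongated_abundant"),
      c("smooth", "bristles", "prickles", "prickles_bristles")
    )
  )
  storage.mode(m) <- "integer"
  m
}

# brute-force window membership count (oracle for bsa_scan / het_profile)
brute_force_window_counts <- function(pos, windows) {
  vapply(seq_len(nrow(windows)), function(i) {
    sum(pos - 1 >= windows$start[i] & pos - 1 < windows$end[i])
  }, numeric(1))
}

# exact two-sided 2x2 p-value by full enumeration over tables with the
# observed margins (oracle for marker_test)
enumerate_exact_p <- function(tab) {
  m <- sum(tab[2, ]); n <- sum(tab[1, ]); k <- sum(tab[, 2])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[2, 2], m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}
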