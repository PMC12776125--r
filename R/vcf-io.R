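#' Read tetraploid genotypes from a VCF
#'
#' Parses a VCF (v4.2+) with polyploid `GT` calls (e.g. `0/0/0/1`) and
#' optional `AD` allele depths into a long, one-row-per-sample-per-site
#' tibble. Only biallelic SNPs are retained: multiallelic records and indels
#' are skipped and counted in the skip report, as are records whose `GT`
#' arity differs from `ploidy` (with a warning). Dosage is the count of
#' alternate alleles in the genotype and is missing when any allele call is
#' missing; depths are missing when `AD` is absent.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param ploidy Expected number of alleles per genotype (default 4).
#'
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt`, `sample`,
#'   `dosage`, `ad_ref`, `ad_alt`, carrying attributes `samples` (ordered
#'   sample ids) and `skip_report` (named counts of skipped records).
#' @export
read_vcf <- function(path, ploidy = 4) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  samples <- colnames(v@gt)[-1]
  if (is.null(samples) || length(samples) == 0) abort("VCF contains no samples")

  alt <- fix$ALT
  ref <- fix$REF
  multi <- grepl(",", alt, fixed = TRUE)
  indel <- !multi & (nchar(ref) != 1 | nchar(alt) != 1 |
    !ref %in% c("A", "C", "G", "T") | !alt %in% c("A", "C", "G", "T"))
  keep <- !multi & !indel

  gt <- vcfR::extract.gt(v, element = "GT")
  ad <- if (any(grepl("AD", v@gt[, "FORMAT"]))) {
    vcfR::extract.gt(v, element = "AD")
  } else {
    NULL
  }

  gt <- gt[keep, , drop = FALSE]
  ad <- if (!is.null(ad)) ad[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]

  # dosage from GT strings; records with wrong arity are skipped
  alleles <- strsplit(gsub("|", "/", as.vector(gt), fixed = TRUE), "/", fixed = TRUE)
  arity <- lengths(alleles)
  dosage <- vapply(alleles, function(a) {
    if (length(a) == 0 || anyNA(a) || any(a == ".")) return(NA_integer_)
    sum(a == "1")
  }, integer(1))
  dosage_mat <- matrix(dosage, nrow = nrow(gt))
  arity_mat <- matrix(arity, nrow = nrow(gt))
  called <- !is.na(dosage_mat)
  bad_arity_site <- apply(arity_mat != ploidy & called, 1, any)
  if (any(bad_arity_site)) {
    warn(sprintf(
      "%d record(s) skipped: GT arity differs from ploidy %d",
      sum(bad_arity_site), ploidy
    ))
  }

  if (!is.null(ad)) {
    ad_split <- strsplit(as.vector(ad), ",", fixed = TRUE)
    ad_ref <- suppressWarnings(vapply(ad_split, function(x) as.integer(x[1]), integer(1)))
    ad_alt <- suppressWarnings(vapply(ad_split, function(x) as.integer(x[2]), integer(1)))
    ad_ref_mat <- matrix(ad_ref, nrow = nrow(gt))
    ad_alt_mat <- matrix(ad_alt, nrow = nrow(gt))
  } else {
    ad_ref_mat <- ad_alt_mat <- matrix(NA_integer_, nrow(gt), ncol(gt))
  }

  ok <- !bad_arity_site
  n_site <- sum(ok)
  out <- tibble(
    chrom = rep(fix$CHROM[ok], times = length(samples)),
    pos = rep(as.integer(fix$POS[ok]), times = length(samples)),
    ref = rep(fix$REF[ok], times = length(samples)),
    alt = rep(fix$ALT[ok], times = length(samples)),
    sample = rep(samples, each = n_site),
    dosage = as.integer(dosage_mat[ok, , drop = FALSE]),
    ad_ref = as.integer(ad_ref_mat[ok, , drop = FALSE]),
    ad_alt = as.integer(ad_alt_mat[ok, , drop = FALSE])
  ) %>%
    arrange(.data$chrom, .data$pos, match(.data$sample, samples))
  attr(out, "samples") <- samples
  attr(out, "skip_report") <- c(
    multiallelic = sum(multi),
    indel = sum(indel),
    bad_arity = sum(bad_arity_site)
  )
  out
}

#' Write tetraploid genotypes to a VCF
#'
#' Emits a minimal VCF v4.2 with unphased polyploid `GT` (alt-allele copies
#' from the dosage) and `AD` where depths are present. Round-trips through
#' [read_vcf()]: chromosome, position, alleles, dosage and depths are
#' preserved.
#'
#' @param variants Long variant tibble as returned by [read_vcf()] or the
#'   simulator export.
#' @param path Output file path.
#' @param layout Optional [genome_layout()] used to write contig headers.
#'
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, layout = NULL) {
  samples <- attr(variants, "samples")
  if (is.null(samples)) samples <- unique(variants$sample)
  has_ad <- any(!is.na(variants$ad_ref))
  gt_strings <- c("0/0/0/0", "0/0/0/1", "0/0/1/1", "0/1/1/1", "1/1/1/1")
  wide <- variants %>%
    mutate(
      gtad = paste0(
        ifelse(is.na(.data$dosage), "./././.",
          gt_strings[.data$dosage + 1L]
        ),
        if (has_ad) {
          ifelse(is.na(.data$ad_ref) | is.na(.data$ad_alt), ":.",
            paste0(":", .data$ad_ref, ",", .data$ad_alt)
          )
        } else {
          ""
        }
      )
    ) %>%
    select("chrom", "pos", "ref", "alt", "sample", "gtad") %>%
    tidyr::pivot_wider(names_from = "sample", values_from = "gtad") %>%
    arrange(.data$chrom, .data$pos)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=tetramap",
    if (!is.null(layout)) {
      sprintf("##contig=<ID=%s,length=%d>", layout$chrom, layout$length)
    },
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (has_ad) {
      '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">'
    },
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
      samples
    ), collapse = "\t")
  )
  fmt <- if (has_ad) "GT:AD" else "GT"
  body <- paste(
    wide$chrom, wide$pos, ".", wide$ref, wide$alt, ".", "PASS", ".", fmt,
    sep = "\t"
  )
  gt_cols <- as.matrix(wide[, samples, drop = FALSE])
  body <- paste(body, apply(gt_cols, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a binary phenotype table
#'
#' Two tab-separated columns: `sample` and `status`, where status is 1 for
#' affected (here: prickleless) and 0 for unaffected (prickled).
#'
#' @param path Path to the TSV (a header line is accepted and detected).
#'
#' @return A tibble with columns `sample` (unique) and `status` (0/1 integer).
#' @export
read_phenotypes <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("sample", first, ignore.case = TRUE)
  tab <- readr::read_tsv(
    path,
    col_names = if (has_header) TRUE else c("sample", "status"),
    skip = 0, show_col_types = FALSE
  )
  names(tab)[1:2] <- c("sample", "status")
  tab <- tab %>% select("sample", "status") %>%
    mutate(sample = as.character(.data$sample), status = as.integer(.data$status))
  if (anyDuplicated(tab$sample)) abort("duplicate sample ids in phenotype table")
  if (!all(tab$status %in% c(0L, 1L))) abort("phenotype status must be 0/1")
  tab
}

#' @rdname read_phenotypes
#' @param phenotypes Tibble with `sample` and `status` columns.
#' @export
write_phenotypes <- function(phenotypes, path) {
  readr::write_tsv(phenotypes[, c("sample", "status")], path)
  invisible(path)
}
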