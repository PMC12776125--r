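#' Dominance (carrier) coding of tetraploid dosages
#'
#' The single-dose dominant ("1-dom") coding collapses the five tetraploid
#' genotype classes to carrier (1) versus non-carrier (0) of the dominant
#' allele. Ref-dominant: a sample is a carrier when it retains at least one
#' reference allele (alt dosage <= 3) — the orientation used when the
#' reference genome carries the dominant allele. Alt-dominant: carrier when
#' alt dosage >= 1.
#'
#' @param dosage Integer vector of alt dosages (0..4, `NA` allowed).
#' @param orientation `"ref"` (default) or `"alt"`.
#'
#' @return Integer 0/1 carrier indicator; `NA` where dosage is missing.
#' @export
#' @examples
#' dom_code(c(4, 3, 0), "ref") # 0 1 1
dom_code <- function(dosage, orientation = c("ref", "alt")) {
  orientation <- match.arg(orientation)
  bad <- !is.na(dosage) & !dosage %in% 0:4
  if (any(bad)) abort("dosage must be in 0..4 or NA")
  if (orientation == "ref") {
    as.integer(dosage <= 3L)
  } else {
    as.integer(dosage >= 1L)
  }
}

#' Two-sided exact test of carrier status against a binary phenotype
#'
#' Exact 2x2 test on the carrier x affected table: with margins fixed, the
#' p-value sums the hypergeometric probabilities of every table at most as
#' probable as the observed one (the two-sided exact test of independence).
#' Degenerate margins (all samples carriers, or all the same phenotype)
#' yield `NA` with a reason rather than an error.
#'
#' @param carrier Integer 0/1 carrier indicator per sample (`NA` dropped).
#' @param status Integer 0/1 phenotype per sample.
#'
#' @return A list: `p` (numeric or `NA`), `table` (2x2 counts), `reason`
#'   (`NA` or why the test was not performed).
#' @export
marker_test <- function(carrier, status) {
  keep <- !is.na(carrier) & !is.na(status)
  carrier <- carrier[keep]
  status <- status[keep]
  if (length(carrier) < 2) {
    return(list(p = NA_real_, table = NULL, reason = "fewer than 2 samples"))
  }
  tab <- table(factor(carrier, levels = 0:1), factor(status, levels = 0:1))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(p = NA_real_, table = tab, reason = "degenerate margin"))
  }
  m <- sum(tab[2, ]) # carriers
  n <- sum(tab[1, ]) # non-carriers
  k <- sum(tab[, 2]) # affected
  x <- tab[2, 2] # affected carriers
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(x, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(p = min(p, 1), table = tab, reason = NA_character_)
}

#' Dominance-coded exact-test association scan
#'
#' One exact test per site on the carrier coding, with Bonferroni-adjusted
#' p-values (`min(1, p * m)` over the `m` tested sites) and the fixed
#' genome-wide significance line `p_star` (default 5e-8) used to declare
#' the significant set.
#'
#' @param variants Long dosage tibble (`sample`, `chrom`, `pos`, `dosage`),
#'   ideally pre-filtered with [site_filters()].
#' @param phenotypes Phenotype tibble (`sample`, `status`).
#' @param orientation Dominant-allele orientation for [dom_code()].
#' @param p_star Genome-wide significance threshold on the raw p-value.
#'
#' @return A `gwas_scan` tibble sorted by position: `chrom`, `pos`,
#'   `orientation`, `p`, `p_bonf`, `neglog10p`, `significant`, `reason`.
#'   The number of tests is in attribute `n_tests`.
#' @export
genome_scan <- function(variants, phenotypes, orientation = c("ref", "alt"),
                        p_star = 5e-8) {
  orientation <- match.arg(orientation)
  dat <- variants %>%
    left_join(phenotypes, by = "sample") %>%
    mutate(carrier = dom_code(.data$dosage, orientation))
  res <- dat %>%
    group_by(.data$chrom, .data$pos) %>%
    summarise(
      test = list(marker_test(.data$carrier, .data$status)),
      .groups = "drop"
    ) %>%
    mutate(
      p = purrr::map_dbl(.data$test, "p"),
      reason = purrr::map_chr(.data$test, "reason")
    ) %>%
    select(-"test")
  m <- sum(!is.na(res$p))
  out <- res %>%
    mutate(
      orientation = orientation,
      p_bonf = pmin(1, .data$p * m),
      neglog10p = -log10(.data$p),
      significant = !is.na(.data$p) & .data$p < p_star
    ) %>%
    select("chrom", "pos", "orientation", "p", "p_bonf", "neglog10p",
      "significant", "reason") %>%
    arrange(.data$chrom, .data$pos)
  attr(out, "n_tests") <- m
  attr(out, "p_star") <- p_star
  class(out) <- c("gwas_scan", class(out))
  out
}

#' Goodness of fit of observed segregation to a tetraploid self
#'
#' For a selfed parent of causal alt dosage `d`, the expected affected
#' (nulliplex-functional) fraction is the square of the probability that a
#' gamete carries two alt copies, from [gamete_dosage_pmf()]; a triplex
#' parent (d = 3, alpha = 0) gives the 1:3 expectation. The chi-square
#' goodness-of-fit statistic on (affected, unaffected) counts has 1 degree
#' of freedom. When the expected fraction is 0 or 1, concordant
#' observations are reported as consistent and discordant ones as an exact
#' impossibility, bypassing the chi-square.
#'
#' @param affected,unaffected Observed progeny counts.
#' @param d Parent alt (non-functional) dosage at the causal locus.
#' @param alpha Double-reduction rate.
#'
#' @return A list of class `segregation_test`: `observed`, `expected`,
#'   `expected_fraction`, `chisq`, `df`, `p`, `consistent`.
#' @export
#' @examples
#' segregation_test(32, 65, d = 3) # chisq 3.302, p 0.069
segregation_test <- function(affected, unaffected, d = 3, alpha = 0) {
  if (affected < 0 || unaffected < 0) abort("counts must be non-negative")
  n <- affected + unaffected
  if (n == 0) abort("total count must be positive")
  frac <- unname(gamete_dosage_pmf(d, alpha)["2"]^2)
  if (frac %in% c(0, 1)) {
    consistent <- (frac == 1 && unaffected == 0) ||
      (frac == 0 && affected == 0)
    out <- list(
      observed = c(affected = affected, unaffected = unaffected),
      expected = c(affected = n * frac, unaffected = n * (1 - frac)),
      expected_fraction = frac,
      chisq = NA_real_, df = NA_integer_, p = NA_real_,
      consistent = consistent
    )
    return(structure(out, class = "segregation_test"))
  }
  expected <- c(affected = n * frac, unaffected = n * (1 - frac))
  chisq <- sum((c(affected, unaffected) - expected)^2 / expected)
  p <- pchisq(chisq, df = 1, lower.tail = FALSE)
  structure(
    list(
      observed = c(affected = affected, unaffected = unaffected),
      expected = expected, expected_fraction = frac,
      chisq = chisq, df = 1L, p = p, consistent = p >= 0.05
    ),
    class = "segregation_test"
  )
}

#' Cramer's V association for an r x c contingency table
#'
#' Pearson chi-square on the table (no continuity or small-sample bias
#' correction) and `V = sqrt(chisq / (N * (min(r, c) - 1)))`. Rows or
#' columns with zero margin are dropped with a warning before computation.
#' The bias-corrected variant of Bergsma is available as an option.
#'
#' @param tab Integer matrix (or table) of counts, at least 2x2 after
#'   dropping empty margins.
#' @param correct_bias If `TRUE`, apply the small-sample bias correction to
#'   both chi-square/N and the effective dimensions.
#'
#' @return A list of class `cramers_v`: `chisq`, `df`, `V`, `n`, `table`.
#' @export
#' @examples
#' cramers_v(matrix(c(10, 0, 0, 10), 2)) # V = 1
cramers_v <- function(tab, correct_bias = FALSE) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) abort("counts must be non-negative")
  zr <- rowSums(tab) == 0
  zc <- colSums(tab) == 0
  if (any(zr) || any(zc)) {
    warn("dropping zero-margin rows/columns before Cramer's V")
    tab <- tab[!zr, !zc, drop = FALSE]
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) abort("need at least a 2x2 table")
  n <- sum(tab)
  if (n == 0) abort("table total must be positive")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  chisq <- unname(ct$statistic)
  r <- nrow(tab)
  c_ <- ncol(tab)
  if (correct_bias) {
    phi2 <- max(0, chisq / n - (r - 1) * (c_ - 1) / (n - 1))
    r_ <- r - (r - 1)^2 / (n - 1)
    c2 <- c_ - (c_ - 1)^2 / (n - 1)
    v <- sqrt(phi2 / (min(r_, c2) - 1))
  } else {
    v <- sqrt(chisq / (n * (min(r, c_) - 1)))
  }
  structure(
    list(chisq = chisq, df = unname(ct$parameter), V = v, n = n, table = tab),
    class = "cramers_v"
  )
}

#' Read a labelled contingency table from CSV
#'
#' First column holds row labels; the header row holds column labels.
#'
#' @param path CSV file path.
#'
#' @return An integer matrix with dimnames.
#' @export
read_contingency_csv <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  m <- as.matrix(tab[, -1])
  rownames(m) <- as.character(tab[[1]])
  storage.mode(m) <- "integer"
  m
}
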