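#' Tidy a segregation goodness-of-fit test
#'
#' @param x A `segregation_test`.
#' @param ... Unused.
#'
#' @return One-row tibble: observed and expected counts, expected affected
#'   fraction, chi-square, df, p.
#' @export
tidy.segregation_test <- function(x, ...) {
  tibble(
    affected = unname(x$observed["affected"]),
    unaffected = unname(x$observed["unaffected"]),
    expected_affected = unname(x$expected["affected"]),
    expected_unaffected = unname(x$expected["unaffected"]),
    expected_fraction = x$expected_fraction,
    chisq = x$chisq, df = x$df, p = x$p, consistent = x$consistent
  )
}

#' @rdname tidy.segregation_test
#' @export
glance.segregation_test <- function(x, ...) {
  tibble(chisq = x$chisq, df = x$df, p = x$p, consistent = x$consistent)
}

#' @export
print.segregation_test <- function(x, ...) {
  cat("Tetraploid self segregation test\n")
  cat(sprintf("  observed: %d affected / %d unaffected\n",
    x$observed["affected"], x$observed["unaffected"]))
  cat(sprintf("  expected affected fraction: %.4f\n", x$expected_fraction))
  if (is.na(x$chisq)) {
    cat(sprintf("  degenerate expectation; consistent: %s\n", x$consistent))
  } else {
    cat(sprintf("  chisq = %.4f, df = %d, p = %.4g\n", x$chisq, x$df, x$p))
  }
  invisible(x)
}

#' Tidy a Cramer's V result
#'
#' @param x A `cramers_v` object.
#' @param ... Unused.
#'
#' @return One-row tibble with `chisq`, `df`, `n`, `V`.
#' @export
tidy.cramers_v <- function(x, ...) {
  tibble(chisq = x$chisq, df = x$df, n = x$n, V = x$V)
}

#' @rdname tidy.cramers_v
#' @export
glance.cramers_v <- function(x, ...) tidy(x)

#' @export
print.cramers_v <- function(x, ...) {
  cat(sprintf("Cramer's V = %.4f (chisq = %.3f, df = %d, N = %d)\n",
    x$V, x$chisq, x$df, x$n))
  invisible(x)
}

#' Tidy / summarise mapping results
#'
#' `tidy()` on a `gwas_scan` returns the per-site records; `glance()` the
#' scan-level summary. `glance()` on an `ibd_result` summarises the final
#' interval.
#'
#' @param x A `gwas_scan` or `ibd_result`.
#' @param ... Unused.
#' @export
tidy.gwas_scan <- function(x, ...) as_tibble(x)

#' @rdname tidy.gwas_scan
#' @export
glance.gwas_scan <- function(x, ...) {
  tibble(
    n_tests = attr(x, "n_tests"),
    p_star = attr(x, "p_star"),
    n_significant = sum(x$significant),
    min_p = suppressWarnings(min(x$p, na.rm = TRUE)),
    top_chrom = x$chrom[which.min(x$p)],
    top_pos = x$pos[which.min(x$p)]
  )
}

#' @rdname tidy.gwas_scan
#' @export
glance.ibd_result <- function(x, ...) {
  if (nrow(x$interval) == 0) {
    return(tibble(chrom = NA_character_, left = NA_real_, right = NA_real_,
      width_bp = NA_real_, width_kb = NA_real_, width_mb = NA_real_,
      n_shared = nrow(x$shared), status = "no_signal"))
  }
  mutate(as_tibble(x$interval), n_shared = nrow(x$shared),
    status = paste(x$left$status, x$right$status, sep = "/"))
}

#' @export
print.ibd_result <- function(x, ...) {
  cat("IBD homozygosity mapping\n")
  cat(sprintf("  shared homozygous intervals: %d\n", nrow(x$shared)))
  if (nrow(x$interval) == 0) {
    cat("  no shared interval (no signal)\n")
  } else {
    cat(sprintf("  final interval: %s:%.0f-%.0f (%.0f bp, %d kb, %.3g Mb)\n",
      x$interval$chrom, x$interval$left, x$interval$right,
      x$interval$width_bp, x$interval$width_kb, x$interval$width_mb))
    cat(sprintf("  boundaries: left %s, right %s\n",
      x$left$status, x$right$status))
  }
  invisible(x)
}
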