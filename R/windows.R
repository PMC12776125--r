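#' Define a genome layout
#'
#' A genome layout names the chromosomes under analysis and their lengths in
#' base pairs. All window arithmetic and interval reporting is performed
#' against a layout.
#'
#' @param chrom Character vector of chromosome names (unique).
#' @param length Positive integer vector of chromosome lengths in bp.
#'
#' @return A tibble with columns `chrom` and `length`.
#' @export
#' @examples
#' genome_layout("Ra04", 36116165)
genome_layout <- function(chrom, length) {
  if (anyDuplicated(chrom)) abort("chromosome names must be unique")
  length <- as.numeric(length)
  if (any(!is.finite(length)) || any(length <= 0)) {
    abort("chromosome lengths must be positive")
  }
  tibble(chrom = as.character(chrom), length = length)
}

#' Build a sliding-window tiling of a genome
#'
#' Windows start at 0, `step`, `2 * step`, ... while the start lies before the
#' chromosome end; each window ends at `min(start + width, length)`, so final
#' partial windows are included. Coordinates are 0-based half-open,
#' BED-style; VCF positions are converted internally when sites are assigned
#' to windows.
#'
#' @param layout A genome layout from [genome_layout()].
#' @param width Window width in bp (default 100000).
#' @param step Step between window starts in bp (default 50000); must satisfy
#'   `0 < step <= width`.
#'
#' @return A tibble with columns `chrom`, `start`, `end` (0-based half-open),
#'   ordered by chromosome then start.
#' @export
#' @examples
#' make_windows(genome_layout("chr1", 250000))
make_windows <- function(layout, width = 100000, step = 50000) {
  if (width <= 0 || step <= 0) abort("width and step must be positive")
  if (step > width) abort("step must not exceed width")
  purrr::pmap_dfr(layout, function(chrom, length) {
    starts <- seq(0, length - 1, by = step)
    starts <- starts[starts < length]
    tibble(
      chrom = chrom,
      start = starts,
      end = pmin(starts + width, length)
    )
  })
}

#' Assign positions to the windows that contain them
#'
#' Returns the (site, window) containment pairs for overlapping sliding
#' windows; with `step < width` a site falls in up to `ceiling(width / step)`
#' windows.
#'
#' @param chrom,pos Vectors of chromosome and 1-based position per site.
#' @param windows Window tibble from [make_windows()].
#'
#' @return A tibble with columns `site` (index into `pos`) and `window`
#'   (row index into `windows`).
#' @export
window_membership <- function(chrom, pos, windows) {
  if (length(pos) == 0) return(tibble(site = integer(), window = integer()))
  out <- vector("list", 0L)
  for (ch in unique(windows$chrom)) {
    w_idx <- which(windows$chrom == ch)
    s_idx <- which(chrom == ch)
    if (length(s_idx) == 0 || length(w_idx) == 0) next
    # VCF pos is 1-based; windows are 0-based half-open
    q <- IRanges::IRanges(start = pos[s_idx], width = 1L)
    subj <- IRanges::IRanges(
      start = windows$start[w_idx] + 1L,
      end = windows$end[w_idx]
    )
    hits <- IRanges::findOverlaps(q, subj)
    out[[length(out) + 1L]] <- tibble(
      site = s_idx[S4Vectors::queryHits(hits)],
      window = w_idx[S4Vectors::subjectHits(hits)]
    )
  }
  if (length(out) == 0) return(tibble(site = integer(), window = integer()))
  arrange(bind_rows(out), .data$site, .data$window)
}

#' Width of a genomic interval in Mb or kb
#'
#' Reports interval width the way mapping papers print it: megabases as the
#' exact quotient, kilobases floored to an integer.
#'
#' @param start,end Interval bounds in bp with `end > start`.
#' @param unit `"Mb"`, `"kb"`, or `"bp"`.
#'
#' @return Numeric width in the requested unit.
#' @export
#' @examples
#' interval_width(32950000, 34250000, "Mb") # 1.3
#' interval_width(30482969, 30807700, "kb") # 324
interval_width <- function(start, end, unit = c("Mb", "kb", "bp")) {
  unit <- match.arg(unit)
  if (any(end <= start)) abort("end must exceed start")
  w <- end - start
  switch(unit,
    Mb = w / 1e6,
    kb = floor(w / 1e3),
    bp = w
  )
}
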