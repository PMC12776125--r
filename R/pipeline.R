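#' Default run configuration
#'
#' All tunable parameters of the mapping stages with their standard
#' defaults: 100 kb windows with a 50 kb step; recessive-BSA bulk
#' frequency cutoffs 0.95 / 0.85; dosage filters min depth 2, max missing
#' 0.05, min minor-carrier count 5; 20 kb breakpoint scan with 3-SNP
#' confirmation; genome-wide significance line 5e-8; double reduction 0.
#'
#' @return Named list of defaults.
#' @export
default_run_config <- function() {
  list(
    command = "full",
    vcf = NULL, phenotypes = NULL, counts_tsv = NULL,
    contingency_csv = NULL, out_dir = ".",
    chrom = "chr04", chrom_length = 40e6,
    window_size = 100000, step = 50000,
    af_mut_min = 0.95, af_wt_max = 0.85, min_bulk_depth = 10,
    min_dp = 2, max_missing = 0.05, min_minor = 5,
    h_max = 1, scan_bp = 20000, n_confirm = 3,
    orientation = "ref", p_star = 5e-8,
    genetic_length = 2, n_snps = 20000, causal_pos = 33.7e6,
    parent_dosage = 3, alpha = 0, n_progeny = 97, founder_het = 0.8,
    depth = 30, error = 0.005,
    affected = NULL, unaffected = NULL,
    seed = 1L
  )
}

#' Read a run configuration from a YAML key-value file
#'
#' Unknown keys are rejected; missing keys take the defaults from
#' [default_run_config()].
#'
#' @param path YAML file path.
#'
#' @return A named configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  defaults <- default_run_config()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    abort(paste("unknown config keys:", paste(unknown, collapse = ", ")))
  }
  utils::modifyList(defaults, user)
}

#' @rdname read_run_config
#' @param config Configuration list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# write via a temp file in the same directory, then rename: no partial
# outputs on failure
write_atomic <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

write_bed <- function(intervals, path, name = "interval") {
  lines <- if (nrow(intervals) == 0) {
    character()
  } else {
    sprintf("%s\t%d\t%d\t%s", intervals[[1]], as.integer(intervals[[2]]),
      as.integer(intervals[[3]]), name)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Run a configured analysis
#'
#' Dispatches on `config$command`: `"simulate"` (write a selfed population
#' as VCF + phenotype + truth tables), `"bsa"` (bulk scan to a window
#' profile TSV, enriched-interval BED and metadata JSON), `"ibd"`
#' (homozygosity mapping to metric TSV, interval BED and provenance TSV),
#' `"gwas"` (dominance exact-test scan TSV and significant-site BED),
#' `"stats_segregation"`, `"stats_cramers_v"`, or `"full"` (simulate, then
#' BSA, GWAS and the segregation test on the simulated data). Every run
#' writes a `manifest.json` recording the configuration, package version,
#' seed, input checksums and per-stage row counts; outputs are written
#' atomically. An empty result (no enriched window, empty intersection) is
#' a success with an explicit empty output file.
#'
#' @param config Configuration list from [read_run_config()] /
#'   [default_run_config()], or a path to a YAML config.
#'
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  defaults <- default_run_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    abort(paste("unknown config keys:", paste(unknown, collapse = ", ")))
  }
  config <- utils::modifyList(defaults, config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    tool = "tetramap",
    version = as.character(utils::packageVersion("tetramap")),
    command = config$command,
    seed = config$seed,
    config = config[order(names(config))],
    inputs = list(),
    row_counts = list(),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  inputs <- c(config$vcf, config$phenotypes, config$counts_tsv,
    config$contingency_csv)
  if (length(inputs) > 0) {
    missing <- inputs[!file.exists(inputs)]
    if (length(missing) > 0) {
      abort(paste("missing input file(s):", paste(missing, collapse = ", ")))
    }
    manifest$inputs <- as.list(tools::md5sum(inputs))
  }

  manifest <- switch(config$command,
    simulate = run_simulate(config, manifest),
    bsa = run_bsa(config, manifest),
    ibd = run_ibd(config, manifest),
    gwas = run_gwas(config, manifest),
    stats_segregation = run_segregation(config, manifest),
    stats_cramers_v = run_cramers(config, manifest),
    full = run_full(config, manifest),
    abort(paste("unknown command:", config$command))
  )
  write_atomic(file.path(config$out_dir, "manifest.json"), function(p) {
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  })
  invisible(manifest)
}

run_simulate <- function(config, manifest) {
  cfg <- sim_config(
    chrom = config$chrom, chrom_length = config$chrom_length,
    genetic_length = config$genetic_length, n_snps = config$n_snps,
    causal_pos = config$causal_pos, parent_dosage = config$parent_dosage,
    alpha = config$alpha, n_progeny = config$n_progeny,
    founder_het = config$founder_het, seed = config$seed
  )
  pop <- self_cross(cfg)
  counts <- simulate_reads(pop,
    read_model(depth = config$depth, error = config$error,
      seed = config$seed))
  paths <- sim_export(pop, config$out_dir, counts = counts)
  manifest$row_counts$progeny <- nrow(pop$dosage)
  manifest$row_counts$sites <- ncol(pop$dosage)
  manifest$outputs <- as.list(paths)
  manifest
}

run_bsa <- function(config, manifest) {
  counts <- if (!is.null(config$counts_tsv)) {
    read_bulk_counts(config$counts_tsv, "tsv")
  } else if (!is.null(config$vcf)) {
    read_bulk_counts(config$vcf, "vcf")
  } else {
    abort("bsa requires counts_tsv or a two-sample vcf")
  }
  layout <- genome_layout(unique(counts$chrom),
    vapply(split(counts$pos, counts$chrom)[unique(counts$chrom)], max,
      numeric(1)))
  layout$length <- pmax(layout$length, config$chrom_length)
  windows <- make_windows(layout, config$window_size, config$step)
  thr <- bsa_thresholds(config$af_mut_min, config$af_wt_max,
    config$min_bulk_depth)
  profile <- bsa_scan(counts, windows, thr)
  interval <- call_enriched_interval(profile)
  write_atomic(file.path(config$out_dir, "bsa_profile.tsv"), function(p) {
    readr::write_tsv(as_tibble(profile), p)
  })
  write_atomic(file.path(config$out_dir, "bsa_interval.bed"), function(p) {
    write_bed(interval[, c("chrom", "start", "end")], p, "bsa_enriched")
  })
  write_atomic(file.path(config$out_dir, "bsa_metadata.json"), function(p) {
    jsonlite::write_json(
      list(thresholds = unclass(thr),
        interval_rule = attr(interval, "rule"),
        n_sites = nrow(counts), n_windows = nrow(profile),
        no_signal = nrow(interval) == 0),
      p, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  })
  manifest$row_counts$sites <- nrow(counts)
  manifest$row_counts$windows <- nrow(profile)
  manifest$row_counts$intervals <- nrow(interval)
  manifest
}

run_ibd <- function(config, manifest) {
  if (is.null(config$vcf) || is.null(config$phenotypes)) {
    abort("ibd requires vcf and phenotypes")
  }
  variants <- read_vcf(config$vcf)
  phen <- read_phenotypes(config$phenotypes)
  if (!any(phen$status == 1L)) abort("ibd requires at least one affected sample")
  layout <- genome_layout(unique(variants$chrom),
    vapply(split(variants$pos, variants$chrom)[unique(variants$chrom)], max,
      numeric(1)))
  windows <- make_windows(layout, config$window_size, config$step)
  res <- ibd_map(variants, phen, windows, h_max = config$h_max,
    l_scan = config$scan_bp, n_confirm = config$n_confirm)
  write_atomic(file.path(config$out_dir, "ibd_metric.tsv"), function(p) {
    readr::write_tsv(as_tibble(res$het), p)
  })
  write_atomic(file.path(config$out_dir, "ibd_intervals.bed"), function(p) {
    iv <- res$interval
    write_bed(iv[, c("chrom", "left", "right")], p, "ibd_interval")
  })
  write_atomic(file.path(config$out_dir, "ibd_provenance.tsv"), function(p) {
    prov <- attr(res$interval, "provenance")
    if (is.null(prov)) prov <- tibble(side = character(),
      sample = character(), pos = numeric())
    readr::write_tsv(prov, p)
  })
  manifest$row_counts$affected <- sum(phen$status == 1L)
  manifest$row_counts$windows <- nrow(res$het) / length(unique(res$het$sample))
  manifest$row_counts$intervals <- nrow(res$interval)
  manifest
}

run_gwas <- function(config, manifest) {
  if (is.null(config$vcf) || is.null(config$phenotypes)) {
    abort("gwas requires vcf and phenotypes")
  }
  variants <- read_vcf(config$vcf)
  phen <- read_phenotypes(config$phenotypes)
  filt <- site_filters(variants,
    dosage_filter_config(config$min_dp, config$max_missing, config$min_minor))
  scan <- genome_scan(filt, phen, orientation = config$orientation,
    p_star = config$p_star)
  write_atomic(file.path(config$out_dir, "gwas_scan.tsv"), function(p) {
    readr::write_tsv(as_tibble(scan), p)
  })
  write_atomic(file.path(config$out_dir, "gwas_significant.bed"), function(p) {
    sig <- scan %>% filter(.data$significant) %>%
      mutate(start = .data$pos - 1, end = .data$pos)
    write_bed(sig[, c("chrom", "start", "end")], p, "significant")
  })
  manifest$row_counts$sites_tested <- attr(scan, "n_tests")
  manifest$row_counts$significant <- sum(scan$significant)
  manifest$note <-
    "association test is a dominance-coded two-sided exact 2x2 test (no kinship/structure covariates)"
  manifest
}

run_segregation <- function(config, manifest) {
  if (is.null(config$affected) || is.null(config$unaffected)) {
    abort("stats_segregation requires affected and unaffected counts")
  }
  st <- segregation_test(config$affected, config$unaffected,
    d = config$parent_dosage, alpha = config$alpha)
  write_atomic(file.path(config$out_dir, "segregation.tsv"), function(p) {
    readr::write_tsv(tidy(st), p)
  })
  manifest$row_counts$progeny <- config$affected + config$unaffected
  manifest
}

run_cramers <- function(config, manifest) {
  if (is.null(config$contingency_csv)) {
    abort("stats_cramers_v requires contingency_csv")
  }
  tab <- read_contingency_csv(config$contingency_csv)
  cv <- cramers_v(tab)
  write_atomic(file.path(config$out_dir, "cramers_v.tsv"), function(p) {
    readr::write_tsv(tidy(cv), p)
  })
  manifest$row_counts$cells <- length(tab)
  manifest
}

run_full <- function(config, manifest) {
  manifest <- run_simulate(config, manifest)
  truth <- read_phenotypes(file.path(config$out_dir, "phenotypes.tsv"))
  # pooled bulks from the simulated per-sample VCF depths
  variants <- read_vcf(file.path(config$out_dir, "population.vcf"))
  mut_ids <- truth$sample[truth$status == 1L]
  wt_ids <- truth$sample[truth$status == 0L]
  counts <- variants %>%
    group_by(.data$chrom, .data$pos) %>%
    summarise(
      mut_ref = sum(.data$ad_ref[.data$sample %in% mut_ids], na.rm = TRUE),
      mut_alt = sum(.data$ad_alt[.data$sample %in% mut_ids], na.rm = TRUE),
      wt_ref = sum(.data$ad_ref[.data$sample %in% wt_ids], na.rm = TRUE),
      wt_alt = sum(.data$ad_alt[.data$sample %in% wt_ids], na.rm = TRUE),
      .groups = "drop"
    )
  counts_path <- file.path(config$out_dir, "bulk_counts.tsv")
  write_atomic(counts_path, function(p) readr::write_tsv(counts, p))
  bsa_config <- config
  bsa_config$counts_tsv <- counts_path
  manifest <- run_bsa(bsa_config, manifest)
  gwas_config <- config
  gwas_config$vcf <- file.path(config$out_dir, "population.vcf")
  gwas_config$phenotypes <- file.path(config$out_dir, "phenotypes.tsv")
  manifest <- run_gwas(gwas_config, manifest)
  seg_config <- config
  seg_config$affected <- sum(truth$status == 1L)
  seg_config$unaffected <- sum(truth$status == 0L)
  manifest <- run_segregation(seg_config, manifest)
  manifest
}
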