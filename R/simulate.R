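#' Simulation configuration for an autotetraploid self or cross
#'
#' Defines one simulated chromosome segregating a recessive causal allele.
#' Defaults describe a selfed blackberry line triplex for the recessive
#' allele (parent alt dosage 3, so one functional copy), a 40 Mb chromosome
#' with a 2 Morgan map, 20,000 segregating SNPs, the causal locus at
#' 33.7 Mb, and 97 progeny — the family structure under which a recessive
#' prickleless locus segregates 1 affected : 3 unaffected.
#'
#' @param chrom Chromosome name.
#' @param chrom_length Chromosome length in bp.
#' @param genetic_length Genetic map length in Morgans.
#' @param n_snps Number of segregating SNPs (the causal site is one of them).
#' @param causal_pos Position (bp) of the causal SNP; the alternate allele is
#'   the non-functional (recessive) allele.
#' @param parent_dosage Parent alt dosage at the causal locus (0..4;
#'   3 = triplex for the recessive allele).
#' @param alpha Double-reduction rate used by [gamete_dosage_pmf()]; the
#'   haplotype-level meiosis simulator models bivalent pairing only
#'   (effectively alpha = 0).
#' @param n_progeny Number of progeny.
#' @param founder_het Fraction of SNPs heterozygous (dosage 1..3) in the
#'   parent; the remainder are homozygous.
#' @param seed Integer random seed.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(chrom = "chr04", chrom_length = 40e6,
                       genetic_length = 2, n_snps = 20000,
                       causal_pos = 33.7e6, parent_dosage = 3,
                       alpha = 0, n_progeny = 97,
                       founder_het = 0.8, seed = 1L) {
  if (alpha < 0 || alpha > 1) abort("alpha must be in [0, 1]")
  if (!parent_dosage %in% 0:4) abort("parent_dosage must be in 0..4")
  if (causal_pos < 1 || causal_pos > chrom_length) {
    abort("causal_pos must lie on the chromosome")
  }
  if (n_progeny <= 0) abort("n_progeny must be positive")
  structure(
    list(
      chrom = chrom, chrom_length = chrom_length,
      genetic_length = genetic_length, n_snps = n_snps,
      causal_pos = causal_pos, parent_dosage = parent_dosage,
      alpha = alpha, n_progeny = n_progeny,
      founder_het = founder_het, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Gamete dosage distribution under multisomic inheritance
#'
#' Probability that a diploid gamete from a tetraploid parent of alt dosage
#' `d` carries 0, 1 or 2 alternate alleles. With probability `1 - alpha` the
#' gamete is a random draw of 2 of the 4 homologous copies (hypergeometric);
#' with probability `alpha` (double reduction) one copy is drawn uniformly
#' and duplicated.
#'
#' @param d Parent alt dosage (0..4).
#' @param alpha Double-reduction rate in \[0, 1\].
#'
#' @return Named numeric vector of probabilities over gamete dosages
#'   `c("0", "1", "2")`, summing to 1.
#' @export
#' @examples
#' gamete_dosage_pmf(3, 0) # 0, 0.5, 0.5
gamete_dosage_pmf <- function(d, alpha = 0) {
  if (!d %in% 0:4) abort("d must be an integer in 0..4")
  if (alpha < 0 || alpha > 1) abort("alpha must be in [0, 1]")
  hyper <- dhyper(0:2, m = d, n = 4 - d, k = 2)
  dr <- c(`0` = (4 - d) / 4, `1` = 0, `2` = d / 4)
  setNames((1 - alpha) * hyper + alpha * dr, c("0", "1", "2"))
}

# one meiosis of a tetraploid individual under bivalent pairing:
# haplotypes paired into two bivalents uniformly over the three pairings;
# crossovers per bivalent ~ Poisson(genetic length in Morgans), positions
# uniform along the chromosome; the gamete receives one recombinant product
# from each bivalent.
.meiosis_gamete <- function(haps, positions, chrom_length, genetic_length) {
  pairings <- list(c(1L, 2L, 3L, 4L), c(1L, 3L, 2L, 4L), c(1L, 4L, 2L, 3L))
  p <- pairings[[sample.int(3L, 1L)]]
  gam <- matrix(0L, nrow = 2, ncol = length(positions))
  for (b in 1:2) {
    a <- haps[p[2 * b - 1], ]
    bb <- haps[p[2 * b], ]
    n_xo <- rpois(1, genetic_length)
    if (n_xo == 0) {
      gam[b, ] <- if (runif(1) < 0.5) a else bb
    } else {
      xo <- sort(runif(n_xo, 0, chrom_length))
      seg <- findInterval(positions, xo)
      start_a <- runif(1) < 0.5
      from_a <- (seg %% 2 == 0) == start_a
      gam[b, ] <- ifelse(from_a, a, bb)
    }
  }
  gam
}

#' Simulate one meiosis of a tetraploid individual
#'
#' Homolog-level model of multisomic inheritance: the four homologs are
#' paired into two bivalents uniformly at random over the three possible
#' pairings; each bivalent receives a Poisson number of crossovers (mean =
#' genetic length in Morgans) at uniform positions, applied between the two
#' paired sequences; the gamete receives one product per bivalent.
#'
#' @param individual A list with element `haps`, a 4 x n_snps 0/1 matrix,
#'   such as the `parent` element of [self_cross()] output.
#' @param cfg A [sim_config()] (provides map length and chromosome length).
#' @param positions SNP positions in bp (defaults to `individual$positions`).
#'
#' @return A 2 x n_snps 0/1 matrix: the gamete's two haplotypes.
#' @export
simulate_meiosis <- function(individual, cfg, positions = individual$positions) {
  .meiosis_gamete(individual$haps, positions, cfg$chrom_length, cfg$genetic_length)
}

# founder individual: causal site at parent_dosage with alt on the first
# `parent_dosage` haplotypes; other sites heterozygous with prob founder_het
# (dosage uniform on 1..3, copies on random haplotypes), else homozygous.
.make_founder <- function(cfg) {
  n <- cfg$n_snps
  positions <- sort(sample.int(cfg$chrom_length, n - 1L))
  positions <- sort(unique(c(positions, as.integer(cfg$causal_pos))))
  while (length(positions) < n) {
    extra <- sample.int(cfg$chrom_length, n - length(positions))
    positions <- sort(unique(c(positions, extra)))
  }
  causal_idx <- match(as.integer(cfg$causal_pos), positions)
  m <- length(positions)
  het <- runif(m) < cfg$founder_het
  dos <- integer(m)
  dos[het] <- sample(1:3, sum(het), replace = TRUE)
  dos[!het] <- sample(c(0L, 4L), sum(!het), replace = TRUE)
  dos[causal_idx] <- cfg$parent_dosage
  haps <- matrix(0L, 4, m)
  rnk <- apply(matrix(runif(4 * m), 4, m), 2, rank, ties.method = "random")
  haps[] <- as.integer(rnk <= rep(dos, each = 4))
  haps[, causal_idx] <- c(rep(1L, cfg$parent_dosage), rep(0L, 4 - cfg$parent_dosage))
  list(haps = haps, positions = positions, causal_idx = causal_idx)
}

#' Self a tetraploid parent segregating a recessive allele
#'
#' Generates `n_progeny` selfed offspring of a simulated founder, each the
#' union of two independent meioses ([simulate_meiosis()]). The phenotype is
#' recessive: an individual is affected (e.g. prickleless) exactly when it
#' carries zero functional copies at the causal locus, i.e. causal alt
#' dosage 4.
#'
#' @param cfg A [sim_config()].
#'
#' @return A list of class `sim_population` with elements `cfg`, `parent`
#'   (founder haplotypes and SNP positions), `dosage` (n_progeny x n_snps
#'   integer matrix of alt dosages), `positions`, `causal_idx`, and `truth`,
#'   a tibble with `sample`, `causal_dosage`, `phenotype`.
#' @export
self_cross <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  founder <- .make_founder(cfg)
  m <- length(founder$positions)
  dosage <- matrix(0L, cfg$n_progeny, m)
  for (i in seq_len(cfg$n_progeny)) {
    g1 <- .meiosis_gamete(founder$haps, founder$positions,
      cfg$chrom_length, cfg$genetic_length)
    g2 <- .meiosis_gamete(founder$haps, founder$positions,
      cfg$chrom_length, cfg$genetic_length)
    dosage[i, ] <- colSums(g1) + colSums(g2)
  }
  causal_dosage <- dosage[, founder$causal_idx]
  phenotype <- as.integer(causal_dosage == 4L) # zero functional copies
  ids <- sprintf("P%03d", seq_len(cfg$n_progeny))
  structure(
    list(
      cfg = cfg, parent = founder, dosage = dosage,
      positions = founder$positions, causal_idx = founder$causal_idx,
      truth = tibble(
        sample = ids, causal_dosage = causal_dosage, phenotype = phenotype
      )
    ),
    class = "sim_population"
  )
}

#' Sequencing read model
#'
#' Per-individual per-site depth is Poisson(`depth`); alternate-read counts
#' are Binomial(depth, p) with p = (dosage/4)(1 - error) + (1 - dosage/4)
#' error. Bulk counts are sums over the bulk's members, so a bulk sequenced
#' to ~300x corresponds to `depth = 300 / n_members` per individual.
#'
#' @param depth Mean read depth per individual per site (> 0).
#' @param error Per-read miscall rate in \[0, 0.5).
#' @param seed Integer seed.
#'
#' @return A list of class `read_model`.
#' @export
read_model <- function(depth = 30, error = 0.005, seed = 1L) {
  if (depth <= 0) abort("depth must be positive")
  if (error < 0 || error >= 0.5) abort("error must be in [0, 0.5)")
  structure(list(depth = depth, error = error, seed = as.integer(seed)),
    class = "read_model")
}

#' Simulate read counts for a population, per sample or pooled into bulks
#'
#' @param pop A [self_cross()] population (or any list with a `dosage`
#'   matrix, `positions`, and `cfg`).
#' @param model A [read_model()].
#' @param bulks Optional named list of two disjoint character vectors of
#'   sample ids, `list(mut = ..., wt = ...)`; when given, counts are pooled
#'   by bulk.
#'
#' @return Without bulks: a list with `ref` and `alt` integer matrices
#'   (samples x sites). With bulks: a tibble of pooled counts with columns
#'   `chrom`, `pos`, `mut_ref`, `mut_alt`, `wt_ref`, `wt_alt`.
#' @export
simulate_reads <- function(pop, model = read_model(), bulks = NULL) {
  set.seed(model$seed)
  dos <- pop$dosage
  p_alt <- (dos / 4) * (1 - model$error) + (1 - dos / 4) * model$error
  depth <- matrix(rpois(length(dos), model$depth), nrow = nrow(dos))
  alt <- matrix(rbinom(length(dos), as.vector(depth), as.vector(p_alt)),
    nrow = nrow(dos))
  ref <- depth - alt
  rownames(ref) <- rownames(alt) <- pop$truth$sample
  if (is.null(bulks)) return(list(ref = ref, alt = alt))
  if (length(bulks) != 2 || any(lengths(bulks) == 0)) {
    abort("bulks must be two non-empty sample sets")
  }
  if (length(intersect(bulks[[1]], bulks[[2]])) > 0) {
    abort("bulk members must be disjoint")
  }
  tibble(
    chrom = pop$cfg$chrom,
    pos = pop$positions,
    mut_ref = colSums(ref[bulks[[1]], , drop = FALSE]),
    mut_alt = colSums(alt[bulks[[1]], , drop = FALSE]),
    wt_ref = colSums(ref[bulks[[2]], , drop = FALSE]),
    wt_alt = colSums(alt[bulks[[2]], , drop = FALSE])
  )
}

#' Export a simulated population to VCF, phenotype TSV and truth TSV
#'
#' Writes the progeny genotypes as an unphased tetraploid VCF (with `AD`
#' taken from simulated per-sample read counts when supplied), the binary
#' phenotype table, and a truth table recording the causal position and each
#' progeny's causal dosage.
#'
#' @param pop A [self_cross()] population.
#' @param dir Output directory (created if needed).
#' @param counts Optional per-sample counts from [simulate_reads()] without
#'   bulks.
#'
#' @return Named character vector of the three file paths, invisibly.
#' @export
sim_export <- function(pop, dir, counts = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- nrow(pop$dosage)
  m <- ncol(pop$dosage)
  ids <- pop$truth$sample
  variants <- tibble(
    chrom = rep(pop$cfg$chrom, m * n),
    pos = rep(pop$positions, times = n),
    ref = "A", alt = "T",
    sample = rep(ids, each = m),
    dosage = as.integer(t(pop$dosage)),
    ad_ref = if (is.null(counts)) NA_integer_ else as.integer(t(counts$ref)),
    ad_alt = if (is.null(counts)) NA_integer_ else as.integer(t(counts$alt))
  )
  attr(variants, "samples") <- ids
  layout <- genome_layout(pop$cfg$chrom, pop$cfg$chrom_length)
  paths <- c(
    vcf = file.path(dir, "population.vcf"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_vcf(variants, paths[["vcf"]], layout = layout)
  write_phenotypes(
    tibble(sample = ids, status = pop$truth$phenotype), paths[["phenotypes"]]
  )
  truth_lines <- c(
    sprintf("# causal_chrom=%s causal_pos=%d", pop$cfg$chrom,
      as.integer(pop$cfg$causal_pos)),
    "sample\tcausal_dosage\tphenotype",
    sprintf("%s\t%d\t%d", pop$truth$sample, pop$truth$causal_dosage,
      pop$truth$phenotype)
  )
  writeLines(truth_lines, paths[["truth"]])
  invisible(paths)
}

#' Simulate a panel of relatives sharing an ancestral causal haplotype
#'
#' Synthetic descent model for identity-by-descent homozygosity mapping. An
#' ancestral haplotype carrying the recessive causal allele is eroded by
#' recombination: each homolog descended from it retains the ancestral
#' sequence in an interval around the causal locus whose endpoints are
#' exponentially distributed with rate `n_meioses * recomb rate`, and is an
#' independent background haplotype outside it. Affected individuals carry
#' four such descended homologs (hence are homozygous across the shared
#' segment); unaffected carriers carry one to three. This reproduces the
#' block of shared homozygosity around a recessive locus in a cultivar
#' panel without modelling an explicit pedigree.
#'
#' @param n_affected,n_unaffected Panel sizes.
#' @param chrom Chromosome name.
#' @param chrom_length Chromosome length in bp.
#' @param causal_pos Causal-locus position in bp.
#' @param snps_per_mb SNP density (default 2000 per Mb).
#' @param cm_per_mb Recombination rate (default 1.5 cM/Mb, a genome-wide average for Rubus linkage maps).
#' @param n_meioses Independent meioses separating each homolog from the
#'   ancestor (more meioses = narrower shared segment).
#' @param maf Background minor-allele frequency for haplotype alleles.
#' @param seed Integer seed.
#'
#' @return A list of class `ibd_panel`: `dosage` matrix (samples x sites),
#'   `positions`, `causal_pos`, `chrom`, `chrom_length`, `phenotypes`
#'   tibble, and `variants`, the long dosage tibble consumed by the IBD
#'   mapping functions.
#' @export
sim_ibd_panel <- function(n_affected = 8, n_unaffected = 8,
                          chrom = "chr04", chrom_length = 4e6,
                          causal_pos = 2e6, snps_per_mb = 2000,
                          cm_per_mb = 1.5, n_meioses = 8,
                          maf = 0.3, seed = 1L) {
  if (n_affected < 1) abort("need at least one affected sample")
  set.seed(seed)
  m <- round(snps_per_mb * chrom_length / 1e6)
  positions <- sort(sample.int(chrom_length, m))
  positions <- sort(unique(c(positions, as.integer(causal_pos))))
  m <- length(positions)
  causal_idx <- match(as.integer(causal_pos), positions)
  anc <- as.integer(runif(m) < maf)
  anc[causal_idx] <- 1L # ancestral haplotype carries the causal (alt) allele
  rate <- n_meioses * cm_per_mb / 100 / 1e6 # per bp
  draw_homolog <- function(from_anc) {
    bg <- as.integer(runif(m) < maf)
    bg[causal_idx] <- 0L
    if (!from_anc) return(bg)
    left <- causal_pos - stats::rexp(1, rate)
    right <- causal_pos + stats::rexp(1, rate)
    inside <- positions >= left & positions <= right
    ifelse(inside, anc, bg)
  }
  n <- n_affected + n_unaffected
  dosage <- matrix(0L, n, m)
  n_anc <- c(rep(4L, n_affected),
    sample(1:3, n_unaffected, replace = TRUE))
  for (i in seq_len(n)) {
    homs <- vapply(seq_len(4), function(h) draw_homolog(h <= n_anc[i]),
      integer(m))
    dosage[i, ] <- rowSums(homs)
  }
  ids <- c(sprintf("AFF%02d", seq_len(n_affected)),
    sprintf("CAR%02d", seq_len(n_unaffected)))
  rownames(dosage) <- ids
  phenotypes <- tibble(
    sample = ids,
    status = c(rep(1L, n_affected), rep(0L, n_unaffected))
  )
  variants <- tibble(
    chrom = chrom,
    pos = rep(positions, times = n),
    ref = "A", alt = "T",
    sample = rep(ids, each = m),
    dosage = as.integer(t(dosage))
  )
  attr(variants, "samples") <- ids
  structure(
    list(
      dosage = dosage, positions = positions, causal_pos = causal_pos,
      chrom = chrom, chrom_length = chrom_length,
      phenotypes = phenotypes, variants = variants
    ),
    class = "ibd_panel"
  )
}
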