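---
title: "Fine mapping a recessive locus in an autotetraploid: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fine mapping a recessive locus in an autotetraploid: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetramap)
library(dplyr)
```

# The problem

Prickle-free canes are a long-standing breeding target in blackberry
(*Rubus*, autotetraploid). Pricklelessness behaves as a recessive trait at
a single locus: a plant is smooth only when all four homologous copies
carry the non-functional allele. Mapping such a locus in a tetraploid
outcrossing crop combines three classic strategies, and `tetramap`
implements all three over a common variant model, together with a
population and read simulator so each stage can be validated against known
truth:

* a **bulked-segregant analysis (BSA)**: pool DNA of the affected and
  unaffected progeny of one segregating family, sequence the two pools,
  and scan for the genomic region where pooled allele frequencies match
  recessive expectations;
* **identity-by-descent (IBD) homozygosity mapping**: affected cultivars
  descending from a common mutant ancestor share a homozygous haplotype
  block around the locus; intersecting windows of depressed
  heterozygosity across affected samples localises it, and diagnostic
  SNPs refine the block's borders;
* a **dominance-coded association scan** over a diversity panel, with
  supporting segregation and contingency statistics.

# Genotype model

All stages work on biallelic SNPs with *allele dosage* genotypes: the
count (0–4) of alternate-allele copies among the four homologs
(nulliplex to quadriplex). "Heterozygous" in this package always means
dosage 1–3 and "homozygous" dosage 0 or 4 — the only reading under which
a diagnostic SNP can be "homozygous in the affected cultivars and no more
than heterozygous in the prickled ones". Dosage is read from tetraploid
`GT` fields (`read_vcf()`), or called from allele-depth ratios
(`call_dosage()`) by nearest expected frequency k/4 with ties broken
toward the lower dosage — a deterministic, conservative rule. Site
filters (`site_filters()`) follow the standard dosage-conversion
defaults: minimum depth 2 per call, at most 5% missing calls per site,
and at least 5 samples carrying the minor allele. We read `min.minor` as
a *carrier-sample* count; the alternative reading (minor-allele copy
count) differs only for sites carried almost entirely in one genotype
class.

Window arithmetic is shared by every scan: 100 kb sliding windows with a
50 kb step (`make_windows()`), 0-based half-open internally and in BED
output, 1-based in VCF. A variant contributes to every window containing
it, so overlapping windows double-count by design — this matches the
plotted statistic the scans are built on.

# The autotetraploid simulator

`sim_config()` / `self_cross()` generate the study family: a parent
triplex for the recessive allele (one functional copy) selfed to produce
97 progeny, on a 40 Mb chromosome with a 2 Morgan map and 20,000
segregating SNPs. Meiosis is modelled at the homolog level under
multisomic inheritance: the four homologs pair into two bivalents,
uniformly over the three possible pairings; each bivalent receives a
Poisson number of crossovers (mean = map length in Morgans) at uniform
positions; the gamete takes one product per bivalent. Crossover
interference is ignored — the Poisson model is the simplest one
consistent with a map length.

Double reduction (a gamete receiving two sister-derived copies, rate
`alpha`) is modelled analytically in `gamete_dosage_pmf()`:
probability `1 - alpha` of a hypergeometric draw of 2 from the 4 copies,
probability `alpha` of one copy duplicated. The haplotype simulator
itself uses bivalent pairing only (effectively `alpha = 0`): the rate is
not quantified for this crop, and zero reproduces the 1 affected : 3
unaffected selfing expectation the family shows. A triplex self then
gives gamete dosages {1, 2} with probability ½ each and an affected
(double-`ss` gamete) fraction of ¼.

Founder haplotypes are i.i.d. per site with no linkage disequilibrium
beyond physical linkage; physical linkage alone generates the block
structure the scans rely on. By default 80% of simulated SNPs are
heterozygous in the parent: a variant panel called *on a segregating
family* is ascertained to vary within that family, so most retained sites
segregate; the remainder emulate fixed differences against the reference.
The causal allele is exported as the alternate allele (the reference
genome carries the dominant, functional allele), and `polarize()` exists
to handle the opposite orientation.

Read counts follow a Poisson-depth, binomial-error model: per individual
and site, depth ~ Poisson(D) and alternate reads ~ Binomial(depth, p)
with p = (dosage/4)(1−ε) + (1−dosage/4)ε. Pooled bulks are sums over
their members, so a bulk sequenced to ~300× corresponds to D = 300 /
bulk size per member. This emulates depth and error noise but not real
libraries' GC bias, mapping artefacts, duplicated-region pile-ups, or
allele-specific amplification — passing recovery tests on these
simulations therefore demonstrates the statistical machinery, not
robustness to alignment pathology.

What the generator does *not* emulate deserves emphasis: no population
structure in the diversity-panel sense, no genotyping-batch effects, no
multiallelic or indel variation, and one chromosome per run
(multi-chromosome layouts are built by repetition with independent
seeds).

# The BSA scan

Bulk allele frequencies are computed from pooled *read* counts, never
from genotype calls — the study design pools DNA before sequencing, so
reads are the observable. Sites below a pooled-depth floor (default 10
reads in either bulk; the source protocol states no floor, so it is
documented and configurable) are excluded, then the recessive filter
keeps sites with affected-bulk causal-allele frequency ≥ 0.95 and
control-bulk frequency ≤ 0.85. The scan statistic is the count of
passing variants per window.

For the affected bulk of a triplex self, only one of a gamete's two
products can carry the functional haplotype, so the expected causal-allele
frequency at a linked marker decays like 1 − r/2 with recombination
fraction r and saturates at 0.75 for unlinked markers. The 0.95 cutoff
therefore passes essentially all tightly linked in-phase markers and a
small noise tail elsewhere; the enriched region at a 5 cM/Mb map spans
roughly ±1–2 Mb.

The enriched-interval call marks windows with count ≥
max(`min_count`, `f`·max), bridges marked runs separated by at most
`max_gap` sub-threshold windows, and reports the run with the greatest
total passing-variant mass. The defaults (`min_count = 2`, `f = 0.1`,
`max_gap = 8`) come from a sampling analysis rather than from the
half-of-maximum convention sometimes used for dense profiles: with a
sparse marker panel the per-window counts in the enriched region are
small Poisson numbers (mean ≈ 3 under the simulator's study conditions),
so a threshold placed near the typical enriched count fragments the
region at sampling zeroes, and the single maximum window is a noisy
anchor — in our replicate experiments a half-max, run-through-max rule
recovered the causal position in under a third of families at *any*
tested marker density, while the mass-selected, gap-bridged rule
recovered it in all of 60. The fraction `f` engages for dense panels
(where the absolute floor is far below the signal), tightening the call
toward the conventional behaviour; every parameter is recorded in the
run metadata. The trade-off is honest width: at 0.5 SNPs/kb the called
interval spans a few Mb, and it narrows with marker density — at the
densities of a full resequencing experiment the same rule yields
intervals on the ~1 Mb scale of published BSA results.

# IBD homozygosity mapping

For each affected sample, heterozygous calls are counted per window
(`het_profile()`), and the display metric −(count / median count) is
computed per chromosome, so typical windows sit near −1 and fully
homozygous windows at 0 (`homozygosity_metric()`). The median's scope is
configurable (per chromosome or genome-wide; per chromosome is the
default), and a zero median — a nearly fully homozygous sample — floors
the normaliser at 1 to keep the metric defined.

Runs of windows with at most `h_max` heterozygous calls (default 1,
absorbing isolated genotyping errors; the source protocol states no
tolerance) become candidate intervals, and the candidate set is
intersected across all affected samples (`shared_homozygous_intervals()`).
The widest shared interval is then refined: `diagnostic_snps()` classifies
each site (every affected homozygous for the same allele, no unaffected
homozygous for it; missing calls disqualify; sites with complete calls
that violate the rule are the *inconsistent* evidence), and
`refine_breakpoint()` scans 20 kb on each side of a candidate border,
accepting it only when at least `n_confirm = 3` diagnostic SNPs support
the interval side *and* 3 informative SNPs contradict the pattern on the
far side. When the far side is still clean — the window-grid candidate
overshoots into the shared block — the candidate slides outward one
informative SNP at a time until the contradiction appears, which is what
anchors the border at the first real recombination evidence. Three
supporting SNPs per side is a design choice: the source protocol scans
20 kb "to reduce the chance of calling a false breakpoint" without
fixing a count, and three is the smallest support immune to a single
miscalled site on each side. Boundary provenance (which sample is
heterozygous at the nearest contradicting SNP) is reported alongside.

The simulator's IBD panel (`sim_ibd_panel()`) is a *synthetic descent
model*, not a pedigree: an ancestral haplotype carrying the causal
allele is eroded by recombination so that each descended homolog retains
it in an interval around the locus with exponentially distributed
endpoints (rate = meioses × recombination rate), and is an independent
background haplotype outside. Affected samples carry four descended
homologs, unaffected carriers one to three. Defaults — 8 affected, 8
carriers, 2,000 SNPs/Mb, background minor-allele frequency 0.3, 1.5
cM/Mb (a genome-wide average for *Rubus* linkage maps), 8 meioses per
homolog — give shared blocks of a few hundred kb, the scale of published
family-based fine-mapping intervals; more meioses shrink the block as
1/(total independent recombination opportunities). Blocks much smaller
than one 100 kb window cannot be detected by the window stage at all,
which is the method's intrinsic resolution floor.

# Association and contingency statistics

The single-marker scan uses the single-dose dominant ("1-dom") coding:
carrier versus non-carrier of the dominant allele, ref-dominant by
default because the reference genome carries the functional allele. Each
site is tested with a two-sided exact 2×2 test (hypergeometric
enumeration, summing all tables at most as probable as the observed one).
This is a deliberate simplification: the package does not reimplement a
polyploid mixed model with kinship covariates — on a binary trait and a
binary coding the exact test is correct, dependency-free and
conservative, and the divergence is recorded in each run's metadata.
Bonferroni adjustment (min(1, p·m)) and the fixed genome-wide line
p = 5×10⁻⁸ are both reported, matching standard practice for these
scans. Degenerate sites (all carriers, or a constant phenotype) return
`NA` with a reason rather than failing.

`segregation_test()` checks observed affected/unaffected counts of a
self against the expectation [P(gamete dosage 2)]² from
`gamete_dosage_pmf()` — for a triplex parent, 0.25 — with a 1-df
chi-square; degenerate expectations (0 or 1) bypass the statistic and
report plain consistency. The published family's 32 affected : 65
unaffected gives χ² = 3.302, p = 0.069: not rejected at 5%.

`cramers_v()` computes the Pearson chi-square (no continuity correction)
and V = sqrt(χ² / (N·(min(r,c)−1))) on a labelled contingency table,
dropping zero-margin rows or columns with a warning; a small-sample
bias-corrected variant is available as an option because plain V on
small, unbalanced tables is upward-biased. On the bundled 4×4 trichome ×
prickle panel counts (N = 332, `inst/extdata`), the plain definition
gives V = 0.510.

```{r}
tab <- read_contingency_csv(system.file(
  "extdata", "rubus_trichome_prickle_counts.csv", package = "tetramap"))
cramers_v(tab)
segregation_test(32, 65, d = 3)
```

# Numerical and degenerate-input decisions

* Dosage-call ties break toward the lower dosage; exact-test ties use a
  (1 + 10⁻⁷) relative slack when summing "at most as probable" tables,
  the standard guard against floating-point misclassification.
* An all-zero scan profile, an empty interval intersection, or a
  degenerate test margin are explicit, typed "no signal"/`NA` results,
  never errors; pipeline runs treat them as success with empty output
  files.
* The interval caller's leftmost-run and lower-dosage tie rules make
  every stage deterministic given a seed; `run_pipeline()` outputs are
  byte-identical across reruns with equal config and seed.
* Down-sampling a variant panel (as dosage-conversion workflows do
  before filtering) is exposed as a uniform random site subsample with a
  seed (`downsample_sites()`); the original sampling scheme is not
  recoverable, so no stronger claim is made.

# Validation experiments and their problem sizes

The shipped tests validate each stage against an independent oracle
(brute-force window membership, hypergeometric enumeration, per-site rule
checks, hand chi-square arithmetic) and run two recovery experiments end
to end, sized to finish in minutes on one core: 20 selfed families of 32
affected / 65 unaffected bulked progeny at 300× pooled depth on a 40 Mb
chromosome with 20,000 SNPs for the BSA chain, and 20 synthetic descent
panels per meiosis depth (4, 8, 16) for the IBD chain — containment is
asserted at 4 meioses, where shared blocks comfortably exceed the window
resolution floor, and the three depths together give the
width-monotonicity check. Simulator calibration uses 10⁵ single-locus
meioses and 10⁴ selfed progeny. `scripts/acceptance.R` re-runs all of
these from scratch at a caller-chosen seed and writes the headline
numbers as JSON.

# Known limitations

* The exact association test ignores relatedness and population
  structure; on a structured diversity panel it will be anticonservative
  compared to a mixed model. It is the right tool for the simulated
  panels shipped here and a documented simplification elsewhere.
* The enriched-interval width at sparse marker density is intentionally
  generous (a few Mb); treat it as a region to intersect with other
  evidence, as the three-strategy design intends.
* Cross-assembly coordinate reconciliation (multiple reference genomes,
  duplicated regions) is out of scope; all positions in a run live in
  one reference's coordinates.
* The simulator's bivalent-only meiosis cannot generate double reduction
  at the haplotype level; `alpha` affects the analytic law and the
  segregation test only.
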