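---
title: "Methods: ROH, FST and selection-signature scans in rohscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ROH, FST and selection-signature scans in rohscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohscan)
```

# Scope

`rohscan` analyzes diploid autosomal SNP-array genotypes of a structured
population — the motivating design is a single dog breed whose lines are
selected for different purposes — and localizes divergent selection with
two complementary statistics: runs of homozygosity (ROH, capturing
selective sweeps and inbreeding) and per-marker Weir–Cockerham F_ST
(capturing allele-frequency differentiation). Around these sit a QC
cascade, population-structure PCA, morphometric trait statistics, gene
annotation geometry, and a simulator that generates every input with known
ground truth.

# Data model

A `GenotypePanel` couples a samples × SNPs call matrix (0/1/2 copies of the
counted allele, `NA` missing) to a map sorted by (chromosome, bp) and a
sample-metadata table. Coordinates are 1-based inclusive everywhere; BED
input is converted at the boundary. The counted allele convention differs
by source: PED/MAP input counts the minor allele observed at load (ties at
0.5 broken to the alphabetically later symbol, so the coding is
deterministic), while VCF counts ALT. `recodeToMinor()` re-establishes
minor-allele counting after QC, which keeps downstream signs
interpretable; the writers spell alleles back out, so write→read→write is
byte-stable. For a PED SNP where only one allele is observed, the counted
(minor) allele is the unseen one and all calls are 0 — PED carries no
allele information beyond observation, so this is the only lossless
convention.

# Quality control

Four filters run in fixed order, with marker statistics recomputed after
each stage: (1) drop samples with call rate < 0.95; (2) drop SNPs with
call rate < 0.95; (3) drop SNPs with minor allele frequency < 0.01;
(4) drop SNPs whose observed/expected heterozygote-frequency ratio falls
outside [0.05, 1.1]. All thresholds retain the boundary value. The HWE
screen is formulated directly on the O/E ratio (not an exact-test p-value),
and the MAF stage removes monomorphic markers first, so the ratio is never
evaluated on a zero expected frequency. Note one deliberate reading: tool
flags of the form `-geno 0.95` are sometimes (mis)written where a call
rate of 0.95 is meant; `qcPipeline` implements the call-rate semantics
(retain ≥ 0.95), and `qcConfig()` exposes the threshold so either reading
is reachable.

One property worth spelling out: tightening the *sample* screen can
legitimately change the retained SNP set in either direction, because
marker statistics are recomputed over the surviving samples. Monotonicity
holds per screen: tightening a SNP-level threshold with the sample screen
fixed only ever shrinks the SNP set.

# ROH detection

Runs are found with the consecutive-runs (windowless) method. Per
individual and chromosome, a left-to-right scan grows a candidate run; a
SNP is admissible if it is homozygous, or heterozygous/missing while the
run's budget (`maxHet = 1`, `maxMissing = 1`) is unspent, and its gap to
the previous SNP is ≤ `maxGapBp` (1000 kb). The SNP whose addition violates
a constraint closes the run, and scanning resumes *at* that SNP with fresh
budgets. Candidates are trimmed so both endpoints are homozygous
non-missing calls — het or missing calls can therefore never inflate a
run's physical length — and are emitted if they contain ≥ `minSnps` (55)
SNPs and span ≥ `minLengthBp` (1000 kb), where length is last-bp − first-bp
(no +1), matching the kb arithmetic used for L_AUTO. The "minimum window
size of 55 SNPs" of the sliding-window tradition maps to the minimum SNP
count of a run here.

Two parameter sets are exposed rather than conflated: the island-mode
defaults above, and a cluster-mode set (`rohParams(clusterMode = TRUE)`)
that adds the density criterion of at most 150 kb per SNP, used when
deriving consensus clusters. The scan core is compiled (Rcpp); the test
suite holds it equal to an independent brute-force enumeration of maximal
admissible windows under the same restart rule, and fuzz tests assert
validity and non-extendability of every emitted run. Non-extendability is
stated modulo trimming: absorbing a flanking het/missing call within
budget is possible but cannot move the homozygous anchors, so the emitted
segment is unchanged.

The restart rule deserves a note: after a run closes at a violating SNP,
scanning resumes at that SNP (not after it). For a budget violation the
violating het/missing call is then absorbed into the next candidate and
trimmed off its front, which is equivalent to resuming just after it; for
a gap violation the SNP itself anchors the next candidate. This yields
non-overlapping maximal runs and reproduces the textbook behavior that two
interior hets 1 Mb apart split a long homozygous stretch into two runs at
the second het, each judged against the emission thresholds on its own.

F_ROH is Σ L_ROH / L_AUTO with L_AUTO the mapped extent (per chromosome,
last SNP bp − first SNP bp, summed); a published constant (for the dog
autosomes, 2,201,878 kb) can be substituted via `lAutoBp`. Per-length-class
F_ROH values (classes <6, 6–12, 12–24, ≥24 Mb; half-open bins) decompose
the total exactly.

# Islands, clusters, association

Per-SNP in-ROH frequencies are computed per population over the post-QC
population size; an individual covers a SNP iff the SNP position lies
inside one of its runs (inclusive endpoints). ROH islands are maximal runs
of consecutive map SNPs with frequency ≥ 0.5 — the threshold is inclusive
("at least 50%"), and a single qualifying SNP is a (degenerate) island.
No bridging across a sub-threshold SNP happens by default; a `bridge1`
option exists but is off, because the simplest reading of a per-SNP
threshold is strict consecutiveness.

Consensus clusters use breed-wide support counts (≥ 20 individuals,
inclusive) over cluster-mode runs. Each cluster is represented by its lead
(lowest-bp) SNP; the association test cross-tabulates the binary in-ROH
state at the lead SNP against membership in two disjoint groups. The test
statistic is a Pearson chi-square with 1 df and no continuity correction
when all expected counts are ≥ 5, otherwise a two-sided Fisher exact test;
the case-control ROH comparison behind commercial implementations is not
published in detail, so the package fixes this defensible, testable
choice. Bonferroni correction uses the number of clusters tested in the
comparison, and significance means corrected p ≤ 0.05. Results carry
−log10(p) for Manhattan plotting. Single-SNP clusters are retained but
flagged; span constraints are already enforced at segment detection and
are not re-imposed.

# Weir–Cockerham F_ST

The per-site 1984 two-population estimator is computed from complete-case
per-group sample sizes, allele frequencies, and observed heterozygote
frequencies; θ = a/(a+b+c). A SNP needs ≥ 2 non-missing genotypes per
group and polymorphism across the pooled groups, otherwise its components
are `NA` (never coerced to 0). Negative per-SNP estimates are reported
as-is; genome-wide summaries use the ratio-of-sums Σa/Σ(a+b+c). The scan
designs are all pairwise contrasts and one-vs-all (union of the remaining
samples); the significance threshold θ ≥ 0.6 is inclusive. Calibration is
checked against the Balding–Nichols model, whose drift parameter F equals
the expected marker-wise differentiation: at F = 0.2 with 2 × 100
individuals and 20,000 SNPs the weighted estimate lands in [0.18, 0.22] in
at least 9 of 10 seeds, a fixed difference gives θ = 1 to 1e-12, and an
arbitrary split of a panmictic sample stays within ±0.01 of 0.

# Population structure and morphometrics

The GRM is the frequency-standardized cross-product
w = (x − 2p)/sqrt(2p(1−p)), averaged per pair over the SNPs non-missing in
both individuals (missing calls are mean-imputed, i.e. contribute zero);
zero-variance SNPs are skipped with a count. Genotype PCA takes the top-k
eigenpairs of the GRM, scales eigenvectors by sqrt(eigenvalue), and fixes
signs so the largest-magnitude entry of each component is positive.
Degenerate spectra are flagged. The test suite holds GRM PCA equal to a
direct SVD of the standardized genotype matrix.

Morphometric PCA standardizes traits to unit variance by default: the 18
canonical body measurements span roughly 4 cm (eye width) to 67 cm (chest
girth), and unscaled PCA would be girth-dominated. Because reports in this
area sometimes normalize the proportion of variance explained over only
the leading components, both conventions (λ_i/Σ all and λ_i/Σ top-k) are
emitted side by side rather than guessing.

Per-trait group statistics follow the conventional battery: Shapiro–Wilk
per group, Levene's test median-centered (delegated to `car`; it reduces
to ANOVA on absolute deviations from group medians, which the tests
cross-check), one-way ANOVA, and — when ANOVA p < 0.05 — Tukey(–Kramer)
HSD with a compact letter display at α = 0.05. The CLD is computed as the
maximal cliques of the "not significantly different" graph
(`igraph::max_cliques`), ordered by first member: groups share a letter
iff their pairwise adjusted p exceeds α, the display is reconstructible
from the significance pattern alone, and it is invariant to input order.
Constant traits short-circuit with F = 0 and a shared letter.

# Gene annotation

Distances are edge-to-point gaps in bp on 1-based inclusive spans; strand
is ignored. `nearestGene` is unbounded and breaks ties by lower gene
start, then lexicographic id; `genesWithin` uses an inclusive window
(default 1 Mb: a gene edge exactly 1 Mb away is in); `genesInRegion`
requires ≥ 1 bp overlap. Gene sources are user-supplied BED4/GFF3 files —
no remote lookups.

# The simulator: what it emulates, and what it does not

`simulatePanel` draws ancestral counted-allele frequencies uniformly from
[0.1, 0.9], population frequencies from the Balding–Nichols beta
distribution (parameter F per population), and genotypes binomially. The
default map is 10 chromosomes × 5,000 evenly spaced SNPs over 50 Mb
(≈ 1 SNP / 10 kb, commercial canine array density); the default population
design is four usage groups (35/66/92/44 individuals at F = 0.10, 0.10,
0.05, 0.08), mirroring a realistic within-breed study. Autozygosity is
planted at the genotype level: every call in a carrier's span becomes
homozygous, with one shared pattern for sweeps (so the span enters
population-level consensus) or per-carrier patterns for individual ROH.
`injectNoise` flips calls to heterozygous or missing independently
(defaults 5e-4 and 2e-3); inside planted spans flips are capped at the ROH
scan's tolerance (one het, one missing per span) so the planted truth
stays recoverable by design. The master seed fans out to per-stage
sub-seeds, so changing the noise rate never changes the drift draws, and
identical seeds give byte-identical panels. Morphometrics are independent
normal draws per trait and group at the 18-trait default table
(`tableOneParams()`), with an optional correlation matrix.

Deliberate non-realism, and what it means for the tests: there is no
linkage disequilibrium, recombination, mutation or pedigree process.
Background (non-planted) genotypes are exchangeable across SNPs, so
spontaneous 55-SNP homozygous runs essentially never occur and baseline
F_ROH is ≈ 0 — unlike real array data, where background LD and pedigree
inbreeding produce genuine short ROH. Passing recovery tests therefore
demonstrates that the detectors find what the model plants and respect
their thresholds exactly; they do not certify behavior under realistic LD
structure, array artefacts, or pedigree autozygosity. Likewise, real
headline counts from any particular study (post-QC marker counts, total
segment counts, island counts) depend on that study's data and are not
reproducible from simulation; the package treats them as regression
references only.

# Numerical conventions and degenerate inputs

- Missingness is `NA` throughout; statistics use complete cases per SNP
  (and per group where applicable).
- All thresholds named "at least"/"no more than" are inclusive: MAF 0.01
  retained, O/E bounds retained, island frequency 0.50 in, cluster support
  20 in, F_ST 0.6 significant, 1 Mb annotation window in.
- Ties: PED allele tie at 0.5 → alphabetically later symbol counted;
  nearest-gene ties → lower start, then id; CLD letters ordered by first
  group member.
- Degenerate cases are explicit: empty panels after a QC stage raise an
  error naming the stage; all-missing SNPs flag undefined MAF; monomorphic
  SNPs have undefined F_ST components and are skipped by the GRM with a
  count; identical-individual panels flag a degenerate PCA spectrum;
  min-support above the sample count warns and returns no clusters.

# Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
panels sized for a single CPU: the ROH oracle comparison uses 200
individuals × 1,000 SNPs, fuzz suites use 1,000 small panels, F_ST
calibration uses 20,000 SNPs × 200 individuals over 10 (tests) or 5
(script) seeds, island/cluster recovery uses 50–100 individuals × 2,500
SNPs over 10–20 seeds, the ANOVA type-I calibration uses 1,000–2,000
replicates, and the compact-letter recovery 50–100 replicates. These sizes
were chosen so each property is measured with comfortable statistical
margin while the whole suite completes in minutes.

# Known limitations

- PED/MAP support is the PLINK 1.9 *text* dialect; binary BED/BIM/FAM,
  phased data, and sex chromosomes are out of scope.
- The association test is the fixed 2×2 lead-SNP formulation; covariate
  adjustment and permutation p-values are not implemented.
- Windowed/smoothed F_ST and haplotype statistics (iHS, XP-EHH) are out of
  scope; the per-site estimator is deliberately the only one.
- The simulator's lack of LD means simulated marker density, not haplotype
  structure, drives ROH lengths; length-class distributions should be read
  as mechanical, not demographic.
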