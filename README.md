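# rohscan

Selection-signature and inbreeding analysis for within-breed SNP-array
panels, built around runs of homozygosity (ROH) and per-marker F_ST.

Closed breeding populations — dog breeds are the motivating case — develop
sub-structure when different lines are selected for different purposes
(conformation showing, working/sledding, companionship). `rohscan`
implements the standard analysis battery used to localize that divergent
selection on diploid autosomal genotypes:

- **Genotype I/O and QC.** PLINK-text PED/MAP and VCF readers/writers, and
  the conventional filter cascade: sample call rate ≥ 0.95, SNP call rate
  ≥ 0.95, minor allele frequency ≥ 0.01, and a Hardy–Weinberg screen on the
  observed/expected heterozygote-frequency ratio (retain 0.05 ≤ O/E ≤ 1.1).
- **ROH detection** by the consecutive-runs method: a run must span ≥ 55
  SNPs and ≥ 1000 kb, tolerate at most one heterozygous and one missing
  call, and contain no inter-SNP gap above 1000 kb; a cluster-mode variant
  additionally requires a density of ≥ 1 SNP per 150 kb. Runs are binned
  into length classes (<6, 6–12, 12–24, ≥24 Mb).
- **Genomic inbreeding** F_ROH = Σ L_ROH / L_AUTO per individual, totals and
  per length class, with L_AUTO the mapped autosomal extent (overridable by
  a published constant).
- **ROH islands**: per-population runs of consecutive SNPs that lie inside
  an ROH in at least 50% of individuals (inclusive threshold) — the
  selective-sweep signal.
- **Consensus ROH clusters** (support ≥ 20 individuals) and a genome-wide
  **homozygosity association test**: at each cluster's lead SNP the binary
  in-ROH state is cross-tabulated against two groups (chi-square with
  1 df, Fisher fallback for small expected counts) with Bonferroni
  correction over clusters.
- **Weir–Cockerham F_ST** (1984 two-population, per site):
  θ = a / (a + b + c) from the among-population (a), among-individual (b)
  and within-individual (c) variance components; genome-wide weighted
  estimate Σa / Σ(a+b+c); significance threshold θ ≥ 0.6 (inclusive);
  pairwise and one-vs-all designs.
- **Population structure**: genomic-relationship-matrix (GRM) PCA for
  genotypes, standardized PCA for morphometric traits, and per-trait
  Shapiro–Wilk / Levene / one-way ANOVA / Tukey HSD statistics with
  compact-letter displays.
- **Gene annotation geometry**: nearest gene, genes within 1 Mb of a
  marker, genes inside islands/clusters (user-supplied BED4/GFF3).
- **A synthetic-data generator**: Balding–Nichols drifted populations,
  planted individual/shared autozygous tracts, genotyping noise, and
  group-structured morphometrics — every analysis stage can be validated
  against known truth without any external data.

## Worked example

Simulate three drifted populations, plant a selective sweep carried by 70%
of the "show" group, add genotyping noise, and run the pipeline:

```r
library(rohscan)

cfg <- simConfig(seed = 11, nChrom = 4, snpsPerChrom = 2500,
                 populations = data.frame(label = c("pet", "show", "sled"),
                                          n = c(30L, 30L, 40L),
                                          F = c(0.08, 0.10, 0.05)))
sim   <- simulatePanel(cfg)
sweep <- plantedSegment(2L, 1.0e7, 1.3e7, carriers = c(show = 0.7),
                        kind = "shared_sweep")
pl    <- plantAutozygosity(sim$panel, sim$truth, sweep, seed = 11)
panel <- injectNoise(pl$panel, seed = 11, truth = pl$truth)

qc <- qcPipeline(panel)
qc$report
#>              stage   unit input removed retained
#> 1 sample_call_rate sample   100       0      100
#> 2    snp_call_rate    snp 10000       0    10000
#> 3              maf    snp 10000       1     9999
#> 4     hwe_oe_ratio    snp  9999     881     9118

roh  <- detectRoh(qc$panel)
froh <- computeFroh(roh, snpMap(qc$panel), sampleIds = sampleIds(qc$panel))
tapply(froh$f_roh_total, sub("_.*", "", froh$sample_id), median)
#>      pet     show     sled
#> 0.000000 0.015006 0.000000

groups  <- with(sampleInfo(qc$panel), setNames(group, sample_id))
freqs   <- snpRohFrequency(roh, snpMap(qc$panel), groups)
subset(detectIslands(freqs), population == "show")
#>   population chrom start_bp   end_bp n_snps peak_freq mean_freq
#> 1       show     2 10000001 13000001    146       0.7 0.6860731

scan <- fstScan(qc$panel, design = "one_vs_all")
sapply(scan, function(x) x$weighted_theta)
#>  pet_vs_rest show_vs_rest sled_vs_rest
#>   0.06001056   0.06862012   0.05026293
```

Reading the output: the HWE screen removes markers pushed out of
Hardy–Weinberg proportions by the pooled population structure; the planted
3 Mb sweep is recovered exactly as a "show" ROH island (146 SNPs, carrier
frequency 0.70, above the inclusive 50% threshold) and lifts the show
group's median F_ROH to 3 Mb / ~200 Mb ≈ 0.015; the genome-wide weighted
F_ST of each group against the rest (0.05–0.07) reflects the simulated
drift, and no single marker reaches the θ ≥ 0.6 selection threshold, as
expected without planted allelic differentiation.

## Documentation

The methods vignette (`vignettes/selection-signatures.Rmd`) describes the
models, parameter choices, numerical conventions and limitations; function
reference is in the roxygen documentation of each exported function.
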