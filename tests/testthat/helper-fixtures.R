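# fixture builders: everything is generated in code at test time

# wrap a call matrix (samples x snps) into a panel on one or more chromosomes
makePanel <- function(calls, chrom = 1L, bp = NULL, groups = NULL,
                      nAutosomes = 38L) {
  n <- nrow(calls); m <- ncol(calls)
  if (is.null(bp)) bp <- seq(100000L, by = 100000L, length.out = m)
  if (length(chrom) == 1L) chrom <- rep(chrom, m)
  if (is.null(rownames(calls))) rownames(calls) <- sprintf("s%02d", seq_len(n))
  map <- data.frame(snp_id = sprintf("m%04d", seq_len(m)), chrom = chrom,
                    bp = bp, allele1 = "A", allele2 = "B",
                    stringsAsFactors = FALSE)
  colnames(calls) <- map$snp_id
  md <- data.frame(sample_id = rownames(calls),
                   group = if (is.null(groups)) "all" else groups,
                   stringsAsFactors = FALSE)
  genotypePanel(calls, map, md, nAutosomes = nAutosomes)
}

# genotypes skewed towards homozygosity so consecutive runs actually form
randomAutozygousCalls <- function(nInd, nSnps,
                                  probs = c(hom0 = 0.50, het = 0.03,
                                            hom2 = 0.44, miss = 0.03)) {
  matrix(sample(c(0L, 1L, 2L, NA_integer_), nInd * nSnps, replace = TRUE,
                prob = probs), nInd, nSnps)
}

# 10-sample x 12-SNP QC fixture with one planted violation per filter,
# evaluated with qcFixtureConfig() (sample call rate 0.90; a 12-SNP panel
# cannot hold both a tolerated and an offending missing rate at 0.95).
# s10 misses 2/12 calls (0.833 < 0.90). After s10 is removed:
#   snp2 call rate 8/9 < 0.95, snp3 monomorphic (maf 0), snp4 all
#   heterozygous (O/E = 2 > 1.1), snp5 het-deficient (O/E = 0 < 0.05);
# every other SNP passes all filters (s1's single miss keeps 11/12 >= 0.90).
qcFixture <- function() {
  innocent <- c(0L, 0L, 0L, 1L, 1L, 1L, 1L, 2L, 2L, 2L)
  calls <- sapply(1:12, function(j) innocent)
  calls[, 2] <- c(NA, 0L, 0L, 1L, 1L, 1L, 1L, 2L, 2L, 2L)
  calls[, 3] <- rep(0L, 10)
  calls[, 4] <- rep(1L, 10)
  calls[, 5] <- c(0L, 0L, 0L, 0L, 0L, 2L, 2L, 2L, 2L, 2L)
  calls[10, 11] <- NA
  calls[10, 12] <- NA
  rownames(calls) <- sprintf("s%02d", 1:10)
  makePanel(calls)
}

qcFixtureConfig <- function() qcConfig(sampleCallRate = 0.90)

# homogeneous homozygous chromosome with optional het/missing positions
homChrom <- function(nSnps, spacingBp = 20000L, hetAt = integer(),
                     missAt = integer(), allele = 2L) {
  g <- rep(allele, nSnps)
  g[hetAt] <- 1L
  g[missAt] <- NA_integer_
  bp <- seq(1L, by = spacingBp, length.out = nSnps)
  list(g = as.integer(g), bp = bp)
}

expect_segments_equal <- function(got, want) {
  cols <- c("sample_id", "chrom", "start_bp", "end_bp", "n_snps", "n_het",
            "n_missing", "length_bp")
  got <- got[do.call(order, got[c("sample_id", "chrom", "start_bp")]),
             cols, drop = FALSE]
  want <- want[do.call(order, want[c("sample_id", "chrom", "start_bp")]),
               cols, drop = FALSE]
  rownames(got) <- rownames(want) <- NULL
  for (cl in cols) got[[cl]] <- as.vector(got[[cl]])
  for (cl in cols) want[[cl]] <- as.vector(want[[cl]])
  expect_equal(got, want)
}
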