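# shared fixture: 20 individuals, one chromosome, a 2 Mb homozygous block
# (SNPs 41..140 at 20 kb spacing) carried by a configurable subset
blockPanel <- function(nCarrier, nTotal = 20L, nSnps = 300L) {
  calls <- matrix(1L, nTotal, nSnps)  # heterozygous background: no runs
  calls[seq_len(nCarrier), 41:140] <- 2L
  makePanel(calls, bp = seq(1L, by = 20000L, length.out = nSnps))
}

test_that("in-ROH SNP frequencies match the naive per-individual scan", {
  set.seed(31)
  calls <- randomAutozygousCalls(50, 1000)
  panel <- makePanel(calls, bp = seq(1L, by = 15000L, length.out = 1000))
  segs <- detectRoh(panel, rohParams(minSnps = 20, minLengthBp = 2e5))
  groups <- stats::setNames(rep(c("g1", "g2"), each = 25), sampleIds(panel))
  freqs <- snpRohFrequency(segs, snpMap(panel), groups)
  oracle <- rohFreqOracle(segs, snpMap(panel), groups)
  for (pp in c("g1", "g2")) {
    got <- freqs$freq[freqs$population == pp]
    expect_equal(got, oracle[[pp]])
  }
  # invariance to segment ordering
  segsShuf <- segs[sample(nrow(segs)), ]
  expect_equal(snpRohFrequency(segsShuf, snpMap(panel), groups), freqs)
})

test_that("simple frequency cases: covered, uncovered, unknown sample", {
  panel <- blockPanel(10)
  segs <- detectRoh(panel)
  groups <- stats::setNames(rep("pop", 20), sampleIds(panel))
  freqs <- snpRohFrequency(segs, snpMap(panel), groups)
  expect_equal(freqs$freq[90], 0.5)   # inside the block: 10 of 20
  expect_equal(freqs$freq[200], 0)    # outside every segment
  segsBad <- segs
  segsBad$sample_id[1] <- "stranger"
  expect_error(snpRohFrequency(segsBad, snpMap(panel), groups),
               "unknown group")
})

test_that("islands use an inclusive threshold and strict consecutiveness", {
  map <- data.frame(snp_id = sprintf("m%d", 1:50), chrom = 1L,
                    bp = seq(1e5, by = 1e5, length.out = 50))
  freqs <- data.frame(snp_id = map$snp_id, chrom = 1L, bp = map$bp,
                      population = "pop", n_in_roh = 4L, n_total = 20L,
                      freq = 0.2)
  freqs$freq[11:40] <- 0.6
  isl <- detectIslands(freqs)
  expect_identical(nrow(isl), 1L)
  expect_identical(isl$n_snps, 30L)
  expect_equal(isl$start_bp, map$bp[11])
  expect_equal(isl$end_bp, map$bp[40])

  # single SNP at exactly 0.50 qualifies ("at least 50%")
  freqs$freq <- 0.2
  freqs$freq[25] <- 0.5
  isl <- detectIslands(freqs)
  expect_identical(nrow(isl), 1L)
  expect_identical(isl$n_snps, 1L)

  # a sub-threshold SNP splits an island (no bridging by default)
  freqs$freq <- 0.6
  freqs$freq[25] <- 0.49
  isl <- detectIslands(freqs)
  expect_identical(nrow(isl), 2L)
  # but bridges with bridge1 = TRUE
  expect_identical(nrow(detectIslands(freqs, bridge1 = TRUE)), 1L)

  # maximality: flanking SNPs of every island are below threshold
  for (k in seq_len(nrow(isl))) {
    i <- match(isl$start_bp[k], freqs$bp)
    j <- match(isl$end_bp[k], freqs$bp)
    if (i > 1) expect_lt(freqs$freq[i - 1], 0.5)
    if (j < nrow(freqs)) expect_lt(freqs$freq[j + 1], 0.5)
  }
})

test_that("clusters need support from at least 20 individuals", {
  panel20 <- blockPanel(20, nTotal = 40L)
  segs <- detectRoh(panel20, rohParams(clusterMode = TRUE))
  cl <- detectClusters(segs, snpMap(panel20), sampleIds(panel20))
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$support, 20L)
  expect_identical(cl$lead_snp, snpMap(panel20)$snp_id[41])

  panel19 <- blockPanel(19, nTotal = 40L)
  segs <- detectRoh(panel19, rohParams(clusterMode = TRUE))
  cl <- detectClusters(segs, snpMap(panel19), sampleIds(panel19))
  expect_identical(nrow(cl), 0L)

  expect_warning(
    detectClusters(segs, snpMap(panel19), sampleIds(panel19)[1:5],
                   minSupport = 20L),
    "exceeds")
})

test_that("two shared regions split by a below-threshold SNP give two clusters", {
  nTotal <- 30L
  calls <- matrix(1L, nTotal, 400)
  calls[1:25, 41:140] <- 2L
  calls[1:25, 142:241] <- 2L
  calls[, 141] <- 1L  # every individual heterozygous: support drops to 0
  panel <- makePanel(calls, bp = seq(1L, by = 20000L, length.out = 400))
  segs <- detectRoh(panel, rohParams(clusterMode = TRUE))
  cl <- detectClusters(segs, snpMap(panel), sampleIds(panel), minSupport = 20L)
  expect_identical(nrow(cl), 2L)
  counts <- colSums(rohscan:::inRohCounts(segs, snpMap(panel),
                                          sampleIds(panel)))
  # maximality: extending any cluster by one map SNP drops below support
  for (k in seq_len(nrow(cl))) {
    i <- match(cl$lead_snp[k], snpMap(panel)$snp_id)
    j <- i + cl$n_snps[k] - 1L
    if (i > 1) expect_lt(counts[i - 1], 20)
    if (j < 400) expect_lt(counts[j + 1], 20)
  }
})

test_that("homozygosity association: chi-square branch, null, Bonferroni", {
  # closed form on [[40,10],[5,45]]: 49.49 at 2 dp
  tab <- matrix(c(40, 10, 5, 45), 2, byrow = TRUE)
  expect_equal(round(chisqClosedForm(tab), 2), 49.49)

  # panel: block carried by 40/50 of A and 5/50 of B
  nTotal <- 100L
  calls <- matrix(1L, nTotal, 300)
  calls[c(1:40, 51:55), 41:140] <- 2L
  panel <- makePanel(calls, bp = seq(1L, by = 20000L, length.out = 300))
  segs <- detectRoh(panel, rohParams(clusterMode = TRUE))
  cl <- detectClusters(segs, snpMap(panel), sampleIds(panel))
  expect_identical(nrow(cl), 1L)
  A <- sampleIds(panel)[1:50]; B <- sampleIds(panel)[51:100]
  res <- homozygosityAssociation(cl, segs, snpMap(panel), A, B)
  expect_identical(res$method, "chisq")
  expect_equal(unname(res$statistic), chisqClosedForm(tab), tolerance = 1e-10)
  expect_equal(unname(res$statistic),
               unname(stats::chisq.test(tab, correct = FALSE)$statistic))
  # significant even after Bonferroni over 42 tests
  expect_lt(res$p_value * 42, 0.05)

  # identical in-ROH frequencies in A and B: p ~ 1, not significant
  calls2 <- matrix(1L, nTotal, 300)
  calls2[c(1:25, 51:75), 41:140] <- 2L
  panel2 <- makePanel(calls2, bp = seq(1L, by = 20000L, length.out = 300))
  segs2 <- detectRoh(panel2, rohParams(clusterMode = TRUE))
  cl2 <- detectClusters(segs2, snpMap(panel2), sampleIds(panel2))
  res2 <- homozygosityAssociation(cl2, segs2, snpMap(panel2), A, B)
  expect_gt(res2$p_value, 0.99)
  expect_false(res2$significant)

  # chi-square and Fisher agree within an order of magnitude when all
  # expected counts are large
  tabBig <- matrix(c(60, 40, 35, 65), 2, byrow = TRUE)
  pChi <- stats::chisq.test(tabBig, correct = FALSE)$p.value
  pFis <- stats::fisher.test(tabBig)$p.value
  expect_lt(abs(log10(pChi) - log10(pFis)), 1)
})

test_that("association battery runs one-vs-rest and pairwise designs", {
  nTotal <- 60L
  calls <- matrix(1L, nTotal, 300)
  calls[1:25, 41:140] <- 2L
  panel <- makePanel(calls, bp = seq(1L, by = 20000L, length.out = 300))
  segs <- detectRoh(panel, rohParams(clusterMode = TRUE))
  cl <- detectClusters(segs, snpMap(panel), sampleIds(panel))
  groups <- stats::setNames(rep(c("pet", "show", "sled"), each = 20),
                            sampleIds(panel))
  res <- associationScan(cl, segs, snpMap(panel), groups)
  expect_setequal(unique(res$comparison),
                  c("pet_vs_rest", "show_vs_rest", "sled_vs_rest",
                    "pet_vs_show", "pet_vs_sled", "show_vs_sled"))
})
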