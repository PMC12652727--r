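test_that("single-run thresholds: SNP count, physical length, all-slack case", {
  # 60 homozygous SNPs spanning 1.18 Mb (20 kb spacing): one ROH
  hc <- homChrom(60, spacingBp = 20000L)
  panel <- makePanel(matrix(hc$g, 1), bp = hc$bp)
  segs <- detectRoh(panel)
  expect_identical(nrow(segs), 1L)
  expect_identical(segs$n_snps, 60L)
  expect_identical(segs$n_het, 0L)
  expect_equal(segs$length_bp, 59 * 20000)

  # 60 homozygous SNPs spanning 0.9 Mb: below the 1000 kb floor
  hc <- homChrom(60, spacingBp = 15000L)  # span 59*15k = 885 kb
  expect_identical(nrow(detectRoh(makePanel(matrix(hc$g, 1), bp = hc$bp))), 0L)

  # 54 homozygous SNPs spanning 1.48 Mb: below the 55-SNP floor
  hc <- homChrom(54, spacingBp = 28000L)
  expect_identical(nrow(detectRoh(makePanel(matrix(hc$g, 1), bp = hc$bp))), 0L)
})

test_that("two interior hets split a run at the second het", {
  # 150 homozygous SNPs at 20 kb spacing, hets at 30 and 80 (1.0 Mb apart)
  hc <- homChrom(150, spacingBp = 20000L, hetAt = c(30L, 80L))
  panel <- makePanel(matrix(hc$g, 1), bp = hc$bp)
  segs <- detectRoh(panel)
  expect_segments_equal(segs, rohOracle(panel, rohParams()))
  expect_identical(nrow(segs), 2L)
  # first run absorbs het 30 and stops just before het 80
  expect_equal(segs$start_bp[1], hc$bp[1])
  expect_equal(segs$end_bp[1], hc$bp[79])
  expect_identical(segs$n_het[1], 1L)
  # second run restarts at the trimmed position after het 80
  expect_equal(segs$start_bp[2], hc$bp[81])
  expect_equal(segs$end_bp[2], hc$bp[150])
  expect_identical(segs$n_het[2], 0L)
})

test_that("a gap above 1000 kb breaks a run", {
  hc <- homChrom(120, spacingBp = 20000L)
  bp <- hc$bp
  bp[61:120] <- bp[61:120] + 1200000L  # 1.22 Mb gap between SNP 60 and 61
  panel <- makePanel(matrix(hc$g, 1), bp = bp)
  segs <- detectRoh(panel)
  expect_identical(nrow(segs), 2L)
  expect_equal(segs$end_bp[1], bp[60])
  expect_equal(segs$start_bp[2], bp[61])
})

test_that("runs are trimmed to homozygous non-missing endpoints", {
  hc <- homChrom(80, spacingBp = 20000L, hetAt = 1L, missAt = 80L)
  panel <- makePanel(matrix(hc$g, 1), bp = hc$bp)
  segs <- detectRoh(panel)
  expect_identical(nrow(segs), 1L)
  expect_equal(segs$start_bp, hc$bp[2])
  expect_equal(segs$end_bp, hc$bp[79])
  expect_identical(segs$n_het, 0L)
  expect_identical(segs$n_missing, 0L)
})

test_that("length classes use half-open 6/12/24 Mb bins", {
  expect_identical(classifyLength(c(5999999, 6e6, 11999999, 12e6, 24e6 - 1,
                                    24e6, 5e7, 0)),
                   c("lt6", "6to12", "6to12", "12to24", "12to24", "ge24",
                     "ge24", "lt6"))
})

test_that("F_ROH: zero, tiling, the published denominator, class additivity", {
  map <- data.frame(snp_id = sprintf("m%d", 1:200),
                    chrom = rep(1:2, each = 100),
                    bp = rep(seq(1e5, by = 1e5, length.out = 100), 2))
  # no segments -> 0
  none <- detectRoh(makePanel(matrix(1L, 1, 200), chrom = map$chrom,
                              bp = map$bp))
  fr <- computeFroh(none, map, sampleIds = "s01")
  expect_identical(fr$f_roh_total, 0)

  # tiling segments -> exactly 1
  segs <- data.frame(sample_id = "s01", chrom = 1:2, start_bp = 1e5,
                     end_bp = 100e5, n_snps = 100L, n_het = 0L,
                     n_missing = 0L, length_bp = 99e5,
                     length_class = "6to12")
  fr <- computeFroh(segs, map)
  expect_equal(fr$f_roh_total, 1.0)

  # forced division against a fixed published L_AUTO (2,201,878 kb)
  seg1 <- segs[1, ]
  seg1$length_bp <- 220187800
  seg1$length_class <- "ge24"
  fr <- computeFroh(seg1, map, lAutoBp = 2201878000)
  expect_equal(fr$f_roh_total, 0.10)
  # class decomposition sums exactly to the total
  two <- rbind(seg1, data.frame(sample_id = "s01", chrom = 2,
                                start_bp = 1e5, end_bp = 50e5,
                                n_snps = 50L, n_het = 0L, n_missing = 0L,
                                length_bp = 49e5, length_class = "lt6"))
  fr <- computeFroh(two, map, lAutoBp = 2201878000)
  expect_equal(fr$f_roh_lt6 + fr$f_roh_6to12 + fr$f_roh_12to24 +
                 fr$f_roh_ge24, fr$f_roh_total, tolerance = 1e-12)
})

test_that("scan equals the brute-force oracle on random autozygous panels", {
  set.seed(11)
  for (rep_ in 1:10) {
    calls <- randomAutozygousCalls(4, 600)
    panel <- makePanel(calls, bp = seq(1L, by = 25000L, length.out = 600))
    for (params in list(rohParams(), rohParams(clusterMode = TRUE),
                        rohParams(minSnps = 20, minLengthBp = 3e5))) {
      segs <- detectRoh(panel, params)
      expect_segments_equal(segs, rohOracle(panel, params))
    }
  }
})

test_that("emitted segments satisfy constraints and are non-extendable", {
  set.seed(23)
  params <- rohParams(minSnps = 20, minLengthBp = 3e5)
  for (rep_ in 1:30) {
    calls <- randomAutozygousCalls(2, 400)
    bp <- sort(sample(1:2e7, 400))
    panel <- makePanel(calls, bp = bp)
    segs <- detectRoh(panel, params)
    map <- snpMap(panel)
    v <- genotypeCalls(panel)
    for (k in seq_len(nrow(segs))) {
      jj <- which(map$bp >= segs$start_bp[k] & map$bp <= segs$end_bp[k])
      w <- v[segs$sample_id[k], jj]
      # validity
      expect_lte(sum(!is.na(w) & w == 1L), params@maxHet)
      expect_lte(sum(is.na(w)), params@maxMissing)
      expect_gte(length(jj), params@minSnps)
      expect_gte(segs$length_bp[k], params@minLengthBp)
      if (length(jj) > 1) expect_lte(max(diff(map$bp[jj])), params@maxGapBp)
      expect_true(w[1] %in% c(0L, 2L) && w[length(w)] %in% c(0L, 2L))
      # non-extendability modulo trimming: absorbing the flanking SNP either
      # violates a constraint or cannot move the homozygous anchor
      lo <- jj[1] - 1L; hi <- jj[length(jj)] + 1L
      if (lo >= 1) {
        g <- v[segs$sample_id[k], lo]
        grows <- !is.na(g) && g != 1L                        # new hom anchor
        gapOk <- map$bp[jj[1]] - map$bp[lo] <= params@maxGapBp
        budgetOk <- if (is.na(g)) {
          sum(is.na(w)) + 1L <= params@maxMissing
        } else if (g == 1L) sum(!is.na(w) & w == 1L) + 1L <= params@maxHet
        else TRUE
        expect_false(grows && gapOk && budgetOk)
      }
      if (hi <= nrow(map)) {
        g <- v[segs$sample_id[k], hi]
        grows <- !is.na(g) && g != 1L
        gapOk <- map$bp[hi] - map$bp[jj[length(jj)]] <= params@maxGapBp
        budgetOk <- if (is.na(g)) {
          sum(is.na(w)) + 1L <= params@maxMissing
        } else if (g == 1L) sum(!is.na(w) & w == 1L) + 1L <= params@maxHet
        else TRUE
        expect_false(grows && gapOk && budgetOk)
      }
    }
  }
})

test_that("determinism and monotonicity in minSnps / minLengthBp", {
  set.seed(5)
  calls <- randomAutozygousCalls(3, 500)
  panel <- makePanel(calls, bp = seq(1L, by = 30000L, length.out = 500))
  s1 <- detectRoh(panel)
  s2 <- detectRoh(panel)
  expect_identical(s1, s2)
  loose <- detectRoh(panel, rohParams(minSnps = 10, minLengthBp = 1e5))
  tight <- detectRoh(panel, rohParams(minSnps = 30, minLengthBp = 5e5))
  expect_lte(nrow(tight), nrow(loose))
  key <- function(s) paste(s$sample_id, s$chrom, s$start_bp, s$end_bp)
  expect_true(all(key(tight) %in% key(loose)))
})

test_that("summaries: counts, symmetry between identical groups, shares", {
  hc <- homChrom(60, spacingBp = 20000L)
  panel <- makePanel(matrix(hc$g, 1), bp = hc$bp)
  segs <- detectRoh(panel)
  sm <- summarizeRoh(segs)
  expect_equal(sum(sm$by_chrom$total), 1)
  expect_identical(sm$by_sample$n_segments, 1L)

  segs2 <- rbind(segs, segs)
  segs2$sample_id <- c("a1", "b1")
  sm2 <- summarizeRoh(segs2, groups = c(a1 = "A", b1 = "B"))
  sh <- sm2$class_share_by_group
  expect_equal(unname(unlist(sh[sh$group == "A", -1])),
               unname(unlist(sh[sh$group == "B", -1])))
})
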