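test_that("GRM equals the naive double-loop oracle", {
  set.seed(41)
  calls <- matrix(sample(c(0:2, NA), 20 * 500, replace = TRUE,
                         prob = c(.3, .35, .3, .05)), 20, 500)
  panel <- makePanel(calls, bp = seq(1e4, by = 1e4, length.out = 500))
  g <- computeGrm(panel)
  expect_lt(max(abs(g$grm - grmOracle(panel))), 1e-10)
  expect_true(isSymmetric(unname(g$grm), tol = 1e-12))
})

test_that("GRM structural identities: duplicates and 2p individuals", {
  # duplicated sample: off-diagonal pair entry equals the shared diagonal
  set.seed(43)
  calls <- matrix(sample(0:2, 10 * 200, replace = TRUE), 10, 200)
  calls[2, ] <- calls[1, ]
  g <- computeGrm(makePanel(calls))$grm
  expect_equal(g[1, 2], g[1, 1], tolerance = 1e-12)

  # an individual sitting at 2p on every SNP has zero covariance with anyone
  # overall p = 0.5 per SNP, so 2p = 1 = the first individual's calls
  calls <- rbind(rep(1L, 100),
                 matrix(rep(c(0L, 2L, 0L, 2L, 0L, 2L), 100), 6, 100))
  g <- computeGrm(makePanel(calls))$grm
  expect_lt(max(abs(g[1, -1])), 1e-12)
})

test_that("GRM PCA equals direct PCA of the standardized genotype matrix", {
  set.seed(47)
  calls <- matrix(sample(0:2, 30 * 300, replace = TRUE), 30, 300)
  panel <- makePanel(calls)
  g <- computeGrm(panel)
  pca <- pcaGenotypes(g, k = 3)
  # direct route: SVD of the standardized matrix (complete data)
  v <- genotypeCalls(panel)
  p <- colMeans(v) / 2
  keep <- p > 0 & p < 1
  w <- sweep(v[, keep], 2, 2 * p[keep], "-")
  w <- sweep(w, 2, sqrt(2 * p[keep] * (1 - p[keep])), "/")
  sv <- svd(w / sqrt(sum(keep)))
  for (j in 1:3) {
    direct <- sv$u[, j] * sv$d[j]
    expect_equal(min(max(abs(pca$scores[, j] - direct)),
                     max(abs(pca$scores[, j] + direct))), 0,
                 tolerance = 1e-8)
  }
  # scores are orthogonal across components
  cp <- crossprod(pca$scores)
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-8)
  # eigenvalues non-increasing
  expect_true(all(diff(pca$eigenvalues) <= 1e-12))
})

test_that("PC1 separates two drifted populations and is order-invariant", {
  cfg <- simConfig(seed = 101, nChrom = 2L, snpsPerChrom = 2500L,
                   populations = data.frame(
                     label = c("p1", "p2"), n = c(50L, 50L),
                     F = c(0.1, 0.1)))
  panel <- simulatePanel(cfg)$panel
  pca <- pcaGenotypes(computeGrm(panel), k = 2)
  lab <- as.integer(sampleInfo(panel)$group == "p1")
  expect_gt(abs(cor(pca$scores[, 1], lab)), 0.9)

  # permuting samples permutes scores (up to sign)
  perm <- sample(nSamples(panel))
  pca2 <- pcaGenotypes(computeGrm(panel[perm, ]), k = 2)
  s1 <- pca$scores[rownames(pca2$scores), 1]
  expect_lt(min(max(abs(s1 - pca2$scores[, 1])),
                max(abs(s1 + pca2$scores[, 1]))), 1e-6)
})

test_that("degenerate GRM of identical individuals is flagged", {
  calls <- matrix(rep(sample(0:2, 50, replace = TRUE), each = 8), 8)
  g <- computeGrm(makePanel(calls))
  expect_warning(pcaGenotypes(g, k = 2), "degenerate")
})

test_that("morphometric PCA: identity covariance, planted direction, PVE", {
  set.seed(53)
  # uncorrelated unit-variance traits: eigenvalues all ~ 1
  x <- as.data.frame(matrix(rnorm(2000 * 8), 2000, 8))
  pca <- pcaMorphometrics(x, k = 5)
  expect_true(all(abs(pca$eigenvalues - 1) < 0.15))
  expect_equal(sum(pca$eigenvalues / sum(pca$eigenvalues)), 1)
  expect_equal(sum(pca$pve_topk), 1)

  # planted dominant direction is recovered by PC1
  dirv <- rep(1 / sqrt(8), 8)
  scores <- rnorm(500, sd = 4)
  y <- outer(scores, dirv) + matrix(rnorm(500 * 8, sd = 0.5), 500, 8)
  pca <- pcaMorphometrics(as.data.frame(y), k = 3, scale. = FALSE)
  cosang <- abs(sum(pca$loadings[, 1] * dirv))
  expect_gt(cosang, 0.95)

  expect_error(pcaMorphometrics(x[1:4, ], k = 5), "fewer samples")
})

test_that("compact letter display is consistent and order-invariant", {
  pm <- matrix(1, 3, 3, dimnames = list(c("pet", "show", "sled"),
                                        c("pet", "show", "sled")))
  pm["pet", "show"] <- pm["show", "pet"] <- 0.001
  cld <- compactLetterDisplay(pm)
  # pet and show differ: no shared letter; sled shares with both
  expect_false(any(strsplit(cld["pet"], "")[[1]] %in%
                     strsplit(cld["show"], "")[[1]]))
  expect_true(any(strsplit(cld["pet"], "")[[1]] %in%
                    strsplit(cld["sled"], "")[[1]]))
  # order invariance
  perm <- c("sled", "pet", "show")
  expect_identical(compactLetterDisplay(pm[perm, perm]), cld)
  # all-distinct case
  pm0 <- matrix(0.001, 3, 3, dimnames = dimnames(pm)); diag(pm0) <- NA
  expect_identical(sort(unname(compactLetterDisplay(pm0))),
                   c("a", "b", "c"))
})

test_that("trait tests: identical groups, Levene cross-check, Table-1 recovery", {
  set.seed(59)
  # all groups identical values: F = 0, everyone shares a letter
  tr <- data.frame(x = rep(5, 30))
  res <- traitGroupTests(tr, rep(c("a", "b", "c"), each = 10))
  expect_true(res$constant)
  expect_identical(res$anova_F, 0)
  expect_match(res$cld, "a=a,b=a,c=a")

  # Levene (median-centered) equals ANOVA on absolute deviations
  y <- c(rnorm(20, sd = 1), rnorm(20, sd = 3))
  gg <- factor(rep(c("a", "b"), each = 20))
  lev <- car::leveneTest(y ~ gg, center = median)[1, "Pr(>F)"]
  z <- abs(y - ave(y, gg, FUN = median))
  direct <- summary(stats::aov(z ~ gg))[[1]][1, "Pr(>F)"]
  expect_equal(lev, direct, tolerance = 1e-10)

  # body-length generating parameters separate all three groups
  params <- tableOneParams()
  bl <- params[params$trait == "Body Length", ]
  hits <- 0L
  for (s in 1:20) {
    tr <- simulateMorphometrics(nPerGroup = c(pet = 100, show = 100,
                                              sled = 100),
                                params = params, seed = 1000 + s)
    res <- traitGroupTests(tr["Body Length"], tr$group)
    if (isTRUE(res$significant)) {
      letters_ <- sub(".*=", "", strsplit(res$cld, ",")[[1]])
      if (length(unique(letters_)) == 3L) hits <- hits + 1L
    }
  }
  expect_gte(hits, 18L)  # >= 90% of replicates
})
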