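# Independent oracles used to cross-check the package implementations.
# These deliberately use different mechanics (cumulative sums, double loops,
# closed forms) from the code under test.

# Brute-force consecutive-runs enumeration on one chromosome of one
# individual. From each restart point the maximal admissible prefix is found
# with from-scratch cumulative sums; the candidate is trimmed to homozygous
# non-missing endpoints; scanning resumes at the violating SNP.
rohOracleChrom <- function(g, bp, params) {
  n <- length(g)
  maxHet <- params@maxHet
  maxMiss <- params@maxMissing
  maxGap <- params@maxGapBp
  res <- list()
  i <- 1L
  while (i <= n) {
    singleOk <- if (is.na(g[i])) maxMiss >= 1L
                else if (g[i] == 1L) maxHet >= 1L else TRUE
    if (!singleOk) { i <- i + 1L; next }
    idx <- i:n
    hcum <- cumsum(!is.na(g[idx]) & g[idx] == 1L)
    mcum <- cumsum(is.na(g[idx]))
    gapOk <- c(TRUE, diff(bp[idx]) <= maxGap)
    ok <- hcum <= maxHet & mcum <= maxMiss & cumprod(gapOk) == 1
    jrel <- if (all(ok)) length(idx) else which(!ok)[1] - 1L
    j <- i + jrel - 1L
    hom <- which(!is.na(g[i:j]) & g[i:j] != 1L)
    if (length(hom)) {
      a <- i + hom[1] - 1L
      b <- i + hom[length(hom)] - 1L
      w <- g[a:b]
      res[[length(res) + 1L]] <- data.frame(
        start_idx = a, end_idx = b, n_snps = b - a + 1L,
        n_het = sum(!is.na(w) & w == 1L), n_missing = sum(is.na(w)),
        length_bp = as.numeric(bp[b]) - as.numeric(bp[a]))
    }
    if (j >= n) break
    i <- j + 1L
  }
  if (!length(res)) {
    return(data.frame(start_idx = integer(), end_idx = integer(),
                      n_snps = integer(), n_het = integer(),
                      n_missing = integer(), length_bp = numeric()))
  }
  out <- do.call(rbind, res)
  keep <- out$n_snps >= params@minSnps & out$length_bp >= params@minLengthBp
  if (!is.na(params@minDensityBpPerSnp)) {
    keep <- keep & out$length_bp / out$n_snps <= params@minDensityBpPerSnp
  }
  out[keep, , drop = FALSE]
}

# full-panel oracle, returns the same columns as detectRoh
rohOracle <- function(panel, params) {
  map <- snpMap(panel)
  v <- genotypeCalls(panel)
  out <- list()
  for (id in rownames(v)) {
    for (chr in unique(map$chrom)) {
      jj <- which(map$chrom == chr)
      o <- rohOracleChrom(v[id, jj], map$bp[jj], params)
      if (nrow(o)) {
        out[[length(out) + 1L]] <- data.frame(
          sample_id = id, chrom = chr,
          start_bp = map$bp[jj][o$start_idx], end_bp = map$bp[jj][o$end_idx],
          n_snps = o$n_snps, n_het = o$n_het, n_missing = o$n_missing,
          length_bp = o$length_bp, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(sample_id = character(), chrom = integer(),
                      start_bp = integer(), end_bp = integer(),
                      n_snps = integer(), n_het = integer(),
                      n_missing = integer(), length_bp = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# scalar-loop Weir-Cockerham 1984 components for one SNP
wcOracleSnp <- function(g1, g2) {
  g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
  n <- c(length(g1), length(g2))
  p <- c(sum(g1) / (2 * n[1]), sum(g2) / (2 * n[2]))
  h <- c(mean(g1 == 1), mean(g2 == 1))
  r <- 2
  nbar <- mean(n)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

# naive double-loop GRM with per-pair complete cases
grmOracle <- function(panel) {
  v <- genotypeCalls(panel)
  nObs <- colSums(!is.na(v))
  p <- colSums(v, na.rm = TRUE) / (2 * nObs)
  keep <- nObs > 0 & p > 0 & p < 1
  v <- v[, keep, drop = FALSE]; p <- p[keep]
  n <- nrow(v)
  g <- matrix(0, n, n, dimnames = list(rownames(v), rownames(v)))
  for (k in seq_len(n)) for (l in seq_len(k)) {
    num <- 0; cnt <- 0
    for (j in seq_len(ncol(v))) {
      if (!is.na(v[k, j]) && !is.na(v[l, j])) {
        num <- num + (v[k, j] - 2 * p[j]) * (v[l, j] - 2 * p[j]) /
          (2 * p[j] * (1 - p[j]))
        cnt <- cnt + 1
      }
    }
    g[k, l] <- g[l, k] <- num / cnt
  }
  g
}

# naive per-individual interval scan for in-ROH SNP frequencies
rohFreqOracle <- function(segs, map, groups) {
  pops <- sort(unique(unname(groups)))
  out <- list()
  for (pp in pops) {
    members <- names(groups)[groups == pp]
    counts <- integer(nrow(map))
    for (id in members) {
      si <- segs[segs$sample_id == id, , drop = FALSE]
      covered <- logical(nrow(map))
      for (k in seq_len(nrow(si))) {
        covered <- covered | (map$chrom == si$chrom[k] &
                                map$bp >= si$start_bp[k] &
                                map$bp <= si$end_bp[k])
      }
      counts <- counts + covered
    }
    out[[pp]] <- counts / length(members)
  }
  out
}

# closed-form 2x2 chi-square, n(ad - bc)^2 / (r1 r2 c1 c2)
chisqClosedForm <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + cc + d
  n * (a * d - b * cc)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
}
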