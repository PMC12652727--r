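#' Per-SNP Weir-Cockerham FST (two populations)
#'
#' The 1984 genotype-based per-site estimator: variance components
#' a (among populations), b (among individuals within populations) and
#' c (within individuals) from per-group complete-case sample sizes, allele
#' frequencies and observed heterozygote frequencies; theta = a/(a+b+c).
#' SNPs monomorphic across both groups, or with fewer than two non-missing
#' genotypes in either group, get undefined (NA) components. Negative
#' estimates are reported as-is, never clamped.
#'
#' @param panel GenotypePanel
#' @param groupA,groupB disjoint non-empty character vectors of sample ids.
#' @param comparison label attached to the output rows.
#' @return data.frame: snp_id, chrom, bp, comparison, n_a, n_b, p_a, p_b,
#'   a, b, c, theta.
#' @export
wcFstPerSnp <- function(panel, groupA, groupB, comparison = "A_vs_B") {
  stopifnot(length(groupA) > 0, length(groupB) > 0,
            !any(groupA %in% groupB))
  v <- genotypeCalls(panel)
  stopifnot(all(c(groupA, groupB) %in% rownames(v)))
  map <- snpMap(panel)
  comp <- wcComponents(v[groupA, , drop = FALSE], v[groupB, , drop = FALSE])
  data.frame(snp_id = map$snp_id, chrom = map$chrom, bp = map$bp,
             comparison = comparison, n_a = comp$n1, n_b = comp$n2,
             p_a = comp$p1, p_b = comp$p2,
             a = comp$a, b = comp$b, c = comp$c, theta = comp$theta,
             stringsAsFactors = FALSE, row.names = NULL)
}

# vectorized two-population Weir-Cockerham 1984 components over SNP columns
wcComponents <- function(v1, v2) {
  n1 <- colSums(!is.na(v1))
  n2 <- colSums(!is.na(v2))
  p1 <- colSums(v1, na.rm = TRUE) / (2 * n1)
  p2 <- colSums(v2, na.rm = TRUE) / (2 * n2)
  h1 <- colSums(v1 == 1L, na.rm = TRUE) / n1
  h2 <- colSums(v2 == 1L, na.rm = TRUE) / n2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  theta <- ifelse(is.finite(denom) & denom != 0, a / denom, NA_real_)
  # undefined: monomorphic across both groups, or too little data
  undef <- n1 < 2 | n2 < 2 | (pbar %in% c(0, 1))
  bad <- undef | !is.finite(denom) | denom == 0
  a[bad] <- b[bad] <- cc[bad] <- theta[bad] <- NA_real_
  list(n1 = n1, n2 = n2, p1 = p1, p2 = p2, a = a, b = b, c = cc,
       theta = theta)
}

#' Genome-wide weighted Weir-Cockerham estimate
#'
#' The ratio-of-sums estimator sum(a) / sum(a + b + c) over SNPs with
#' defined components.
#'
#' @param fst per-SNP table from \code{\link{wcFstPerSnp}}.
#' @return a single numeric value (NA when no SNP is defined).
#' @export
weightedFst <- function(fst) {
  ok <- !is.na(fst$a)
  if (!any(ok)) return(NA_real_)
  sum(fst$a[ok]) / sum(fst$a[ok] + fst$b[ok] + fst$c[ok])
}

#' Genome scan of FST across group comparisons
#'
#' Runs per-SNP Weir-Cockerham FST for a set of comparisons: all pairwise
#' group contrasts, one-vs-all contrasts (the union of the remaining samples
#' as the second population), or both. Each comparison reports the per-SNP
#' table, the genome-wide weighted estimate, and the set of SNPs at or above
#' the significance threshold (inclusive).
#'
#' @param panel GenotypePanel
#' @param groups named vector sample_id -> group label; defaults to the
#'   panel metadata.
#' @param design character subset of c("pairwise_all", "one_vs_all").
#' @param threshold significance threshold on theta, default 0.6, inclusive.
#' @return named list per comparison, each with elements \code{per_snp},
#'   \code{weighted_theta}, \code{significant} (data.frame of qualifying
#'   SNPs) and \code{threshold}.
#' @export
fstScan <- function(panel, groups = NULL,
                    design = c("pairwise_all", "one_vs_all"),
                    threshold = 0.6) {
  if (is.null(groups)) {
    md <- sampleInfo(panel)
    groups <- stats::setNames(md$group, md$sample_id)
  }
  groups <- groups[names(groups) %in% sampleIds(panel)]
  pops <- sort(unique(unname(groups)))
  if (length(pops) < 2) stop("fstScan needs at least two groups",
                             call. = FALSE)
  design <- match.arg(design, several.ok = TRUE)
  out <- list()
  runOne <- function(idsA, idsB, label) {
    tab <- wcFstPerSnp(panel, idsA, idsB, comparison = label)
    sig <- tab[!is.na(tab$theta) & tab$theta >= threshold, , drop = FALSE]
    rownames(sig) <- NULL
    out[[label]] <<- list(per_snp = tab, weighted_theta = weightedFst(tab),
                          significant = sig, threshold = threshold)
  }
  if ("one_vs_all" %in% design) {
    for (pp in pops) {
      runOne(names(groups)[groups == pp], names(groups)[groups != pp],
             paste0(pp, "_vs_rest"))
    }
  }
  if ("pairwise_all" %in% design) {
    for (i in seq_len(length(pops) - 1L)) for (j in (i + 1L):length(pops)) {
      runOne(names(groups)[groups == pops[i]],
             names(groups)[groups == pops[j]],
             paste0(pops[i], "_vs_", pops[j]))
    }
  }
  out
}
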