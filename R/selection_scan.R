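#' Per-SNP in-ROH frequency by population
#'
#' A map SNP counts as in-ROH for an individual iff its position lies inside
#' any of that individual's runs (inclusive endpoints). Frequencies are
#' reported per population over the post-QC population size.
#'
#' @param segs segment table from \code{\link{detectRoh}}.
#' @param map SNP map data.frame (snp_id, chrom, bp).
#' @param groups named character vector sample_id -> population label; every
#'   sample in \code{segs} must appear. Samples without segments still count
#'   in the denominators.
#' @return data.frame: snp_id, chrom, bp, population, n_in_roh, n_total,
#'   freq; one row per SNP per population, in map order.
#' @export
snpRohFrequency <- function(segs, map, groups) {
  if (is.null(names(groups))) stop("groups must be a named vector",
                                   call. = FALSE)
  if (nrow(segs) && !all(segs$sample_id %in% names(groups))) {
    stop("unknown group label: segment sample absent from groups",
         call. = FALSE)
  }
  counts <- inRohCounts(segs, map, names(groups))
  pops <- sort(unique(unname(groups)))
  out <- lapply(pops, function(pp) {
    members <- names(groups)[groups == pp]
    n <- if (length(members) == 1L) counts[members, ]
         else colSums(counts[members, , drop = FALSE])
    data.frame(snp_id = map$snp_id, chrom = map$chrom, bp = map$bp,
               population = pp, n_in_roh = as.integer(n),
               n_total = length(members), freq = n / length(members),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# 0/1 matrix (samples x map SNPs): is each SNP inside any run of the sample;
# segments of samples outside sampleIds are ignored
inRohCounts <- function(segs, map, sampleIds) {
  m <- matrix(0L, length(sampleIds), nrow(map),
              dimnames = list(sampleIds, map$snp_id))
  segs <- segs[segs$sample_id %in% sampleIds, , drop = FALSE]
  if (!nrow(segs)) return(m)
  for (chr in unique(segs$chrom)) {
    jj <- which(map$chrom == chr)
    if (!length(jj)) next
    bp <- map$bp[jj]
    sc <- segs[segs$chrom == chr, , drop = FALSE]
    a <- findInterval(sc$start_bp - 0.5, bp) + 1L  # first SNP >= start
    b <- findInterval(sc$end_bp + 0.5, bp)         # last SNP <= end
    for (k in seq_len(nrow(sc))) {
      if (a[k] <= b[k]) m[sc$sample_id[k], jj[a[k]:b[k]]] <- 1L
    }
  }
  m
}

#' ROH islands: frequency-thresholded consensus homozygosity regions
#'
#' Per population, islands are maximal runs of consecutive map SNPs whose
#' in-ROH frequency is at least \code{threshold} (inclusive, "at least
#' 50\%"). The island span runs from the first to the last qualifying SNP.
#'
#' @param freqs output of \code{\link{snpRohFrequency}}.
#' @param threshold inclusive frequency threshold, default 0.5.
#' @param bridge1 if TRUE, a single sub-threshold SNP between two qualifying
#'   SNPs does not break an island (off by default).
#' @return data.frame: population, chrom, start_bp, end_bp, n_snps,
#'   peak_freq, mean_freq.
#' @export
detectIslands <- function(freqs, threshold = 0.5, bridge1 = FALSE) {
  out <- list()
  for (pp in unique(freqs$population)) {
    fp <- freqs[freqs$population == pp, , drop = FALSE]
    for (chr in unique(fp$chrom)) {
      fc <- fp[fp$chrom == chr, , drop = FALSE]
      fc <- fc[order(fc$bp), , drop = FALSE]
      ok <- fc$freq >= threshold
      if (bridge1 && length(ok) > 2) {
        interior <- which(!ok[-c(1, length(ok))]) + 1L
        fill <- interior[ok[interior - 1L] & ok[interior + 1L]]
        ok[fill] <- TRUE
      }
      if (!any(ok)) next
      r <- rle(ok)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        i <- starts[k]; j <- ends[k]
        qual <- fc$freq[i:j] >= threshold
        out[[length(out) + 1L]] <- data.frame(
          population = pp, chrom = chr,
          start_bp = fc$bp[i], end_bp = fc$bp[j], n_snps = j - i + 1L,
          peak_freq = max(fc$freq[i:j][qual]),
          mean_freq = mean(fc$freq[i:j]), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(population = character(), chrom = integer(),
                      start_bp = integer(), end_bp = integer(),
                      n_snps = integer(), peak_freq = numeric(),
                      mean_freq = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$population, res$chrom, res$start_bp), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Consensus ROH clusters (support-count-thresholded)
#'
#' Breed-wide per-SNP in-ROH support counts are computed over all samples;
#' clusters are maximal runs of consecutive map SNPs supported by at least
#' \code{minSupport} individuals (default 20). The lead SNP is the
#' lowest-position SNP of the run and represents the cluster in association
#' testing. Single-SNP clusters are retained and flagged.
#'
#' @param segs segment table detected with the cluster-mode parameter set
#'   (\code{rohParams(clusterMode = TRUE)}).
#' @param map SNP map data.frame.
#' @param sampleIds all samples in the panel (denominator population).
#' @param minSupport minimum individual count, inclusive.
#' @return data.frame: cluster_id, chrom, start_bp, end_bp, n_snps, support,
#'   lead_snp, length_bp, single_snp.
#' @export
detectClusters <- function(segs, map, sampleIds, minSupport = 20L) {
  if (minSupport > length(sampleIds)) {
    warning("minSupport exceeds sample count; no cluster can qualify")
    return(data.frame(cluster_id = character(), chrom = integer(),
                      start_bp = integer(), end_bp = integer(),
                      n_snps = integer(), support = integer(),
                      lead_snp = character(), length_bp = numeric(),
                      single_snp = logical(), stringsAsFactors = FALSE))
  }
  counts <- colSums(inRohCounts(segs, map, sampleIds))
  out <- list()
  for (chr in unique(map$chrom)) {
    jj <- which(map$chrom == chr)
    ok <- counts[jj] >= minSupport
    if (!any(ok)) next
    r <- rle(as.vector(ok))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      i <- jj[starts[k]]; j <- jj[ends[k]]
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr, start_bp = map$bp[i], end_bp = map$bp[j],
        n_snps = j - i + 1L, support = as.integer(max(counts[i:j])),
        lead_snp = map$snp_id[i],
        length_bp = as.numeric(map$bp[j]) - as.numeric(map$bp[i]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(cluster_id = character(), chrom = integer(),
                      start_bp = integer(), end_bp = integer(),
                      n_snps = integer(), support = integer(),
                      lead_snp = character(), length_bp = numeric(),
                      single_snp = logical(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start_bp), , drop = FALSE]
  res <- cbind(cluster_id = sprintf("cluster%03d", seq_len(nrow(res))), res,
               single_snp = res$n_snps == 1L)
  res$cluster_id <- as.character(res$cluster_id)
  rownames(res) <- NULL
  res
}

#' Genome-wide homozygosity association test
#'
#' For each consensus cluster, the binary in-ROH state at the cluster's lead
#' SNP is cross-tabulated against membership in two disjoint sample sets
#' (one-vs-rest or pairwise designs). The test is a Pearson chi-square with
#' 1 df and no continuity correction when all expected cell counts are at
#' least 5, otherwise a two-sided Fisher exact test. P-values are Bonferroni
#' corrected over the clusters tested in the comparison; a cluster is
#' significant when the corrected p-value is at most 0.05.
#'
#' @param clusters cluster table from \code{\link{detectClusters}}.
#' @param segs segment table (cluster-mode) used to derive in-ROH states.
#' @param map SNP map data.frame.
#' @param groupA,groupB disjoint non-empty character vectors of sample ids.
#' @param comparison label for the output (e.g. "show_vs_rest").
#' @param alpha significance level after correction, default 0.05.
#' @return data.frame: cluster_id, comparison, lead_snp, chrom, bp,
#'   a_in, a_out, b_in, b_out, method, statistic, p_value, p_bonferroni,
#'   neg_log10_p, significant.
#' @export
homozygosityAssociation <- function(clusters, segs, map, groupA, groupB,
                                    comparison = "A_vs_B", alpha = 0.05) {
  stopifnot(length(groupA) > 0, length(groupB) > 0,
            !any(groupA %in% groupB))
  if (!nrow(clusters)) {
    return(data.frame())
  }
  if (!all(clusters$lead_snp %in% map$snp_id)) {
    stop("cluster lead SNP absent from map", call. = FALSE)
  }
  allIds <- c(groupA, groupB)
  state <- inRohCounts(segs, map, allIds)  # samples x snps
  nTests <- nrow(clusters)
  rows <- lapply(seq_len(nTests), function(k) {
    snp <- clusters$lead_snp[k]
    sA <- state[groupA, snp]
    sB <- state[groupB, snp]
    tab <- matrix(c(sum(sA == 1L), sum(sA == 0L),
                    sum(sB == 1L), sum(sB == 0L)),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(c("A", "B"), c("in", "out")))
    exp <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (all(exp >= 5)) {
      ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      method <- "chisq"
      statistic <- unname(ht$statistic)
      p <- ht$p.value
    } else {
      ht <- stats::fisher.test(tab)
      method <- "fisher"
      statistic <- NA_real_
      p <- ht$p.value
    }
    j <- match(snp, map$snp_id)
    data.frame(cluster_id = clusters$cluster_id[k], comparison = comparison,
               lead_snp = snp, chrom = map$chrom[j], bp = map$bp[j],
               a_in = tab[1, 1], a_out = tab[1, 2],
               b_in = tab[2, 1], b_out = tab[2, 2],
               method = method, statistic = statistic, p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_bonferroni <- pmin(1, res$p_value * nTests)
  res$neg_log10_p <- -log10(res$p_value)
  res$significant <- res$p_bonferroni <= alpha
  rownames(res) <- NULL
  res
}

#' Run the standard battery of homozygosity association comparisons
#'
#' One-vs-rest for each population plus all pairwise comparisons, mirroring
#' the seven-test design used for pet/show/sled panels.
#'
#' @param clusters,segs,map as in \code{\link{homozygosityAssociation}}.
#' @param groups named vector sample_id -> population.
#' @param designs character: any of "one_vs_all", "pairwise_all".
#' @return row-bound association results across comparisons.
#' @export
associationScan <- function(clusters, segs, map, groups,
                            designs = c("one_vs_all", "pairwise_all")) {
  pops <- sort(unique(unname(groups)))
  res <- list()
  if ("one_vs_all" %in% designs) {
    for (pp in pops) {
      res[[length(res) + 1L]] <- homozygosityAssociation(
        clusters, segs, map,
        groupA = names(groups)[groups == pp],
        groupB = names(groups)[groups != pp],
        comparison = paste0(pp, "_vs_rest"))
    }
  }
  if ("pairwise_all" %in% designs && length(pops) > 1) {
    for (i in seq_len(length(pops) - 1L)) for (j in (i + 1L):length(pops)) {
      res[[length(res) + 1L]] <- homozygosityAssociation(
        clusters, segs, map,
        groupA = names(groups)[groups == pops[i]],
        groupB = names(groups)[groups == pops[j]],
        comparison = paste0(pops[i], "_vs_", pops[j]))
    }
  }
  do.call(rbind, res)
}
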