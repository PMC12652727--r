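#' Detect runs of homozygosity (consecutive-runs method)
#'
#' Scans each individual's sorted chromosome left to right. A SNP joins the
#' growing run if it is homozygous, or heterozygous/missing while the run's
#' het/missing budget is unspent, and its gap to the previous run SNP is at
#' most \code{maxGapBp}. The SNP whose addition violates a constraint closes
#' the run and scanning resumes at that SNP with fresh budgets. Candidates
#' are trimmed so both endpoints are homozygous non-missing, then emitted if
#' they contain at least \code{minSnps} SNPs, span at least
#' \code{minLengthBp} (length = last bp - first bp) and, when the density
#' criterion is set, carry at most \code{minDensityBpPerSnp} bp per SNP.
#'
#' @param panel GenotypePanel (sorted by construction).
#' @param params \linkS4class{RohParams}.
#' @return data.frame, one row per run: sample_id, chrom, start_bp, end_bp,
#'   n_snps, n_het, n_missing, length_bp, length_class.
#' @export
detectRoh <- function(panel, params = rohParams()) {
  stopifnot(is(panel, "GenotypePanel"), is(params, "RohParams"))
  map <- snpMap(panel)
  v <- genotypeCalls(panel)
  ids <- rownames(v)
  out <- vector("list", 0L)
  for (chr in unique(map$chrom)) {
    jj <- which(map$chrom == chr)
    cand <- roh_scan_chrom(v[, jj, drop = FALSE], as.numeric(map$bp[jj]),
                           params@maxHet, params@maxMissing, params@maxGapBp)
    if (!nrow(cand)) next
    bp <- map$bp[jj]
    startBp <- bp[cand[, "start_idx"]]
    endBp <- bp[cand[, "end_idx"]]
    lenBp <- as.numeric(endBp) - as.numeric(startBp)
    keep <- cand[, "n_snps"] >= params@minSnps & lenBp >= params@minLengthBp
    if (!is.na(params@minDensityBpPerSnp)) {
      keep <- keep & lenBp / cand[, "n_snps"] <= params@minDensityBpPerSnp
    }
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      sample_id = ids[cand[keep, "sample"]],
      chrom = chr,
      start_bp = startBp[keep],
      end_bp = endBp[keep],
      n_snps = cand[keep, "n_snps"],
      n_het = cand[keep, "n_het"],
      n_missing = cand[keep, "n_missing"],
      length_bp = lenBp[keep],
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(sample_id = character(), chrom = integer(),
                      start_bp = integer(), end_bp = integer(),
                      n_snps = integer(), n_het = integer(),
                      n_missing = integer(), length_bp = numeric(),
                      length_class = character(), stringsAsFactors = FALSE))
  }
  segs <- do.call(rbind, out)
  segs <- segs[order(match(segs$sample_id, ids), segs$chrom, segs$start_bp), ,
               drop = FALSE]
  rownames(segs) <- NULL
  segs$length_class <- classifyLength(segs$length_bp)
  segs
}

#' ROH length classes
#'
#' Half-open physical-length bins: [0, 6), [6, 12), [12, 24) and [24, Inf)
#' megabases, labelled lt6, 6to12, 12to24, ge24.
#'
#' @param lengthBp numeric vector of run lengths in bp.
#' @return character vector of class labels.
#' @export
classifyLength <- function(lengthBp) {
  stopifnot(all(lengthBp >= 0))
  cut(lengthBp, breaks = c(0, 6e6, 12e6, 24e6, Inf),
      labels = c("lt6", "6to12", "12to24", "ge24"),
      right = FALSE, include.lowest = TRUE) |> as.character()
}

#' Genomic inbreeding from ROH (F_ROH)
#'
#' F_ROH = sum of an individual's ROH lengths divided by L_AUTO, the mapped
#' autosomal extent (per chromosome, last SNP bp - first SNP bp, summed).
#' Also returns the per-length-class decomposition, which sums exactly to
#' the total. Individuals present in \code{sampleIds} but without segments
#' get F_ROH = 0.
#'
#' @param segs segment table from \code{\link{detectRoh}}.
#' @param map SNP map (data.frame with chrom, bp) defining L_AUTO.
#' @param sampleIds individuals to report; default the samples in segs.
#' @param lAutoBp override for the L_AUTO denominator in bp (e.g. a
#'   published constant such as 2,201,878 kb for the dog autosomes).
#' @return data.frame: sample_id, f_roh_total, f_roh_lt6, f_roh_6to12,
#'   f_roh_12to24, f_roh_ge24, l_auto_bp.
#' @export
computeFroh <- function(segs, map, sampleIds = NULL, lAutoBp = NULL) {
  if (is.null(lAutoBp)) {
    stopifnot(is.data.frame(map), nrow(map) > 0)
    lAutoBp <- sum(vapply(split(as.numeric(map$bp), map$chrom),
                          function(b) max(b) - min(b), numeric(1)))
  }
  stopifnot(lAutoBp > 0)
  if (is.null(sampleIds)) sampleIds <- unique(segs$sample_id)
  classes <- c("lt6", "6to12", "12to24", "ge24")
  tot <- matrix(0, length(sampleIds), length(classes),
                dimnames = list(sampleIds, classes))
  if (nrow(segs)) {
    agg <- stats::aggregate(length_bp ~ sample_id + length_class, data = segs,
                            FUN = sum)
    agg <- agg[agg$sample_id %in% sampleIds, , drop = FALSE]
    tot[cbind(agg$sample_id, agg$length_class)] <- agg$length_bp
  }
  fr <- tot / lAutoBp
  data.frame(sample_id = sampleIds,
             f_roh_total = rowSums(fr),
             f_roh_lt6 = fr[, "lt6"], f_roh_6to12 = fr[, "6to12"],
             f_roh_12to24 = fr[, "12to24"], f_roh_ge24 = fr[, "ge24"],
             l_auto_bp = lAutoBp, stringsAsFactors = FALSE, row.names = NULL)
}

#' Summaries of a segment table
#'
#' Deterministic summary tables: per-chromosome run counts by length class,
#' per-sample totals (count and summed length), and per-group length-class
#' percentage shares.
#'
#' @param segs segment table from \code{\link{detectRoh}}.
#' @param groups optional named vector mapping sample_id -> group label.
#' @return list of data.frames: \code{by_chrom}, \code{by_sample},
#'   \code{class_share_by_group} (NULL when \code{groups} is missing).
#' @export
summarizeRoh <- function(segs, groups = NULL) {
  classes <- c("lt6", "6to12", "12to24", "ge24")
  if (!nrow(segs)) {
    return(list(by_chrom = data.frame(), by_sample = data.frame(),
                class_share_by_group = NULL))
  }
  segs$length_class <- factor(segs$length_class, levels = classes)
  byChrom <- as.data.frame.matrix(table(segs$chrom, segs$length_class))
  byChrom <- cbind(chrom = as.integer(rownames(byChrom)), byChrom,
                   total = rowSums(byChrom))
  rownames(byChrom) <- NULL

  bySample <- stats::aggregate(length_bp ~ sample_id, data = segs, FUN = sum)
  cnt <- as.data.frame(table(sample_id = segs$sample_id),
                       stringsAsFactors = FALSE)
  bySample <- merge(bySample, cnt, by = "sample_id")
  names(bySample) <- c("sample_id", "total_length_bp", "n_segments")
  bySample <- bySample[order(bySample$sample_id), , drop = FALSE]
  rownames(bySample) <- NULL

  share <- NULL
  if (!is.null(groups)) {
    g <- groups[segs$sample_id]
    if (anyNA(g)) stop("segment sample missing from groups", call. = FALSE)
    tb <- table(group = g, class = segs$length_class)
    share <- as.data.frame.matrix(100 * prop.table(tb, margin = 1))
    share <- cbind(group = rownames(share), share)
    rownames(share) <- NULL
  }
  list(by_chrom = byChrom, by_sample = bySample, class_share_by_group = share)
}
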