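#' Nearest gene to a marker
#'
#' Nearest by edge distance on the same chromosome (distance 0 when the
#' marker lies inside the gene). Ties are broken by lower gene start, then
#' lexicographic gene_id, so results are invariant to gene-list order.
#' Spans are 1-based inclusive; strand is ignored.
#'
#' @param snpBp marker position (bp).
#' @param snpChrom marker chromosome (integer).
#' @param genes data.frame from \code{\link{readGeneIntervals}}.
#' @param queryId id attached to the output row.
#' @return one-row data.frame (query, gene_id, relation, distance_bp), or
#'   NULL when the chromosome carries no gene.
#' @export
nearestGene <- function(snpBp, snpChrom, genes, queryId = "snp") {
  g <- genes[genes$chrom == snpChrom, , drop = FALSE]
  if (!nrow(g)) return(NULL)
  d <- pmax(g$start_bp - snpBp, snpBp - g$end_bp, 0)
  o <- order(d, g$start_bp, g$gene_id)
  i <- o[1]
  data.frame(query = queryId, gene_id = g$gene_id[i],
             relation = if (d[i] == 0) "contains" else "nearest",
             distance_bp = d[i], stringsAsFactors = FALSE)
}

#' Genes within a window of a marker
#'
#' All genes on the marker's chromosome whose edge distance is at most
#' \code{window} (inclusive; overlap counts as distance 0).
#'
#' @inheritParams nearestGene
#' @param window window size in bp, default 1 Mb.
#' @return data.frame (possibly 0 rows): query, gene_id, relation,
#'   distance_bp; sorted by distance then gene start.
#' @export
genesWithin <- function(snpBp, snpChrom, genes, window = 1e6,
                        queryId = "snp") {
  g <- genes[genes$chrom == snpChrom, , drop = FALSE]
  if (!nrow(g)) {
    return(data.frame(query = character(), gene_id = character(),
                      relation = character(), distance_bp = numeric(),
                      stringsAsFactors = FALSE))
  }
  d <- pmax(g$start_bp - snpBp, snpBp - g$end_bp, 0)
  keep <- d <= window
  g <- g[keep, , drop = FALSE]; d <- d[keep]
  if (!nrow(g)) {
    return(data.frame(query = character(), gene_id = character(),
                      relation = character(), distance_bp = numeric(),
                      stringsAsFactors = FALSE))
  }
  o <- order(d, g$start_bp, g$gene_id)
  data.frame(query = queryId, gene_id = g$gene_id[o],
             relation = ifelse(d[o] == 0, "contains", "within_window"),
             distance_bp = d[o], stringsAsFactors = FALSE, row.names = NULL)
}

#' Genes overlapping a region
#'
#' Genes overlapping [start_bp, end_bp] on the region's chromosome by at
#' least one bp (1-based inclusive spans).
#'
#' @param regionChrom,regionStart,regionEnd region coordinates.
#' @param genes data.frame of gene intervals.
#' @param queryId id attached to output rows.
#' @return data.frame: query, gene_id, relation ("contains"), distance_bp 0.
#' @export
genesInRegion <- function(regionChrom, regionStart, regionEnd, genes,
                          queryId = "region") {
  g <- genes[genes$chrom == regionChrom &
               genes$end_bp >= regionStart &
               genes$start_bp <= regionEnd, , drop = FALSE]
  if (!nrow(g)) {
    return(data.frame(query = character(), gene_id = character(),
                      relation = character(), distance_bp = numeric(),
                      stringsAsFactors = FALSE))
  }
  o <- order(g$start_bp, g$gene_id)
  data.frame(query = queryId, gene_id = g$gene_id[o], relation = "contains",
             distance_bp = 0, stringsAsFactors = FALSE, row.names = NULL)
}

#' Annotate a table of regions against a gene set
#'
#' Convenience wrapper applying \code{\link{genesInRegion}} over island or
#' cluster tables.
#'
#' @param regions data.frame with chrom, start_bp, end_bp and an id column.
#' @param genes gene intervals.
#' @param idCol name of the region id column (default first of cluster_id /
#'   population).
#' @return row-bound annotation hits.
#' @export
annotateRegions <- function(regions, genes, idCol = NULL) {
  if (is.null(idCol)) {
    idCol <- intersect(c("cluster_id", "population"), names(regions))[1]
  }
  out <- lapply(seq_len(nrow(regions)), function(i) {
    qid <- if (!is.na(idCol)) as.character(regions[[idCol]][i])
           else sprintf("region%d", i)
    genesInRegion(regions$chrom[i], regions$start_bp[i], regions$end_bp[i],
                  genes, queryId = qid)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
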