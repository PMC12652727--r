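#' Write a result table as TSV
#'
#' Deterministic column order (as given), tab-separated, with header.
#'
#' @param x data.frame.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeTsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Write genomic regions as BED
#'
#' Converts 1-based inclusive spans to BED's 0-based half-open convention.
#' Works for ROH segment, island and cluster tables (any data.frame with
#' chrom, start_bp, end_bp and an id-like column).
#'
#' @param regions data.frame with chrom, start_bp, end_bp.
#' @param path output path.
#' @param nameCol column used for the BED name field; default the first of
#'   sample_id / cluster_id / population present.
#' @return invisibly, the path.
#' @export
writeBed <- function(regions, path,
                     nameCol = intersect(c("sample_id", "cluster_id",
                                           "population"),
                                         names(regions))[1]) {
  nm <- if (!is.na(nameCol)) as.character(regions[[nameCol]])
        else sprintf("region%d", seq_len(nrow(regions)))
  bed <- data.frame(chrom = regions$chrom,
                    start = regions$start_bp - 1L,
                    end = regions$end_bp,
                    name = nm)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Manhattan-ready table from association or FST results
#'
#' @param x association result (uses neg_log10_p) or per-SNP FST table
#'   (uses theta).
#' @return data.frame chrom, bp, value.
#' @export
manhattanTable <- function(x) {
  val <- if ("neg_log10_p" %in% names(x)) x$neg_log10_p else x$theta
  data.frame(chrom = x$chrom, bp = x$bp, value = val)
}
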