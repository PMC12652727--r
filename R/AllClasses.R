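#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib rohscan, .registration = TRUE
NULL

#' GenotypePanel: a mapped autosomal SNP-array genotype panel
#'
#' Container for diploid bi-allelic genotypes of a set of individuals at
#' mapped autosomal SNPs. Calls count copies of the panel's counted allele
#' (the second allele of each marker's allele pair): 0, 1, 2, or \code{NA}
#' for a missing call. The map is kept sorted by (chromosome, position) and
#' the call matrix columns follow map order.
#'
#' @slot calls integer matrix, samples x SNPs; values in \{0, 1, 2, NA\}.
#'   Row names are sample ids, column names SNP ids.
#' @slot map data.frame with columns \code{snp_id}, \code{chrom} (integer
#'   autosome index), \code{bp} (1-based position), \code{allele1},
#'   \code{allele2} (the counted allele).
#' @slot metadata data.frame keyed by \code{sample_id} with at least a
#'   \code{group} column; optionally \code{sex} and morphometric traits.
#' @slot nAutosomes integer, size of the configured autosome set (dog: 38).
#'
#' @exportClass GenotypePanel
setClass("GenotypePanel",
  representation(
    calls      = "matrix",
    map        = "data.frame",
    metadata   = "data.frame",
    nAutosomes = "integer"
  ),
  prototype(nAutosomes = 38L)
)

setValidity("GenotypePanel", function(object) {
  msg <- character()
  m <- object@map
  need <- c("snp_id", "chrom", "bp", "allele1", "allele2")
  if (!all(need %in% names(m))) {
    return(paste("map must have columns:", paste(need, collapse = ", ")))
  }
  if (ncol(object@calls) != nrow(m)) {
    msg <- c(msg, "number of call-matrix columns must equal number of map rows")
  }
  if (!identical(colnames(object@calls), as.character(m$snp_id))) {
    msg <- c(msg, "call-matrix column names must equal map snp_id, in map order")
  }
  if (anyDuplicated(m$snp_id)) msg <- c(msg, "snp_id values must be unique")
  if (nrow(m)) {
    if (any(m$bp < 1L)) msg <- c(msg, "bp positions must be >= 1")
    if (any(m$chrom < 1L | m$chrom > object@nAutosomes)) {
      msg <- c(msg, sprintf("chrom must lie in 1..%d", object@nAutosomes))
    }
    o <- order(m$chrom, m$bp)
    if (!identical(o, seq_len(nrow(m)))) {
      msg <- c(msg, "map must be sorted by (chrom, bp)")
    }
  }
  v <- object@calls
  if (!all(v[!is.na(v)] %in% c(0L, 1L, 2L))) {
    msg <- c(msg, "calls must be 0, 1, 2 or NA")
  }
  if (nrow(object@metadata)) {
    if (!"sample_id" %in% names(object@metadata)) {
      msg <- c(msg, "metadata must have a sample_id column")
    } else if (!all(rownames(object@calls) %in% object@metadata$sample_id)) {
      msg <- c(msg, "every genotyped sample needs a metadata row")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypePanel
#'
#' Sorts the map by (chromosome, position), permutes the call-matrix columns
#' accordingly, and validates the result.
#'
#' @param calls integer matrix samples x SNPs with values in \{0,1,2,NA\}.
#' @param map data.frame with snp_id, chrom, bp, allele1, allele2.
#' @param metadata optional data.frame with sample_id (and group, ...).
#' @param nAutosomes size of the autosome set (default 38, the dog karyotype).
#' @return A \linkS4class{GenotypePanel}.
#' @export
genotypePanel <- function(calls, map, metadata = NULL, nAutosomes = 38L) {
  stopifnot(is.matrix(calls), is.data.frame(map))
  map$snp_id  <- as.character(map$snp_id)
  map$chrom   <- as.integer(map$chrom)
  map$bp      <- as.integer(map$bp)
  map$allele1 <- as.character(map$allele1)
  map$allele2 <- as.character(map$allele2)
  o <- order(map$chrom, map$bp)
  map <- map[o, , drop = FALSE]
  rownames(map) <- NULL
  storage.mode(calls) <- "integer"
  calls <- calls[, o, drop = FALSE]
  colnames(calls) <- map$snp_id
  if (is.null(metadata)) {
    metadata <- data.frame(sample_id = rownames(calls),
                           group = "all", stringsAsFactors = FALSE)
  }
  new("GenotypePanel", calls = calls, map = map,
      metadata = as.data.frame(metadata), nAutosomes = as.integer(nAutosomes))
}

setMethod("show", "GenotypePanel", function(object) {
  cat(sprintf("GenotypePanel: %d samples x %d SNPs on %d chromosome(s)\n",
              nrow(object@calls), ncol(object@calls),
              length(unique(object@map$chrom))))
  if (nrow(object@metadata) && "group" %in% names(object@metadata)) {
    tb <- table(object@metadata$group)
    cat("groups:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  }
  miss <- mean(is.na(object@calls))
  cat(sprintf("missing call fraction: %.4f\n", miss))
})

#' @rdname genotypePanel
#' @param object,x a GenotypePanel
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname genotypePanel
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))
#' @rdname genotypePanel
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))
#' @rdname genotypePanel
#' @export
setGeneric("snpMap", function(x) standardGeneric("snpMap"))
#' @rdname genotypePanel
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))
#' @rdname genotypePanel
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname genotypePanel
setMethod("nSamples", "GenotypePanel", function(x) nrow(x@calls))
#' @rdname genotypePanel
setMethod("nSnps", "GenotypePanel", function(x) ncol(x@calls))
#' @rdname genotypePanel
setMethod("genotypeCalls", "GenotypePanel", function(x) x@calls)
#' @rdname genotypePanel
setMethod("snpMap", "GenotypePanel", function(x) x@map)
#' @rdname genotypePanel
setMethod("sampleInfo", "GenotypePanel", function(x) x@metadata)
#' @rdname genotypePanel
setMethod("sampleIds", "GenotypePanel", function(x) rownames(x@calls))

#' Subset a GenotypePanel by samples and/or SNPs
#'
#' @param x GenotypePanel
#' @param i sample selector (ids, indices or logical)
#' @param j SNP selector (ids, indices or logical)
#' @param ... ignored
#' @param drop ignored, always FALSE semantics
#' @export
setMethod("[", "GenotypePanel", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@calls))
  if (missing(j)) j <- seq_len(ncol(x@calls))
  calls <- x@calls[i, j, drop = FALSE]
  map <- x@map[match(colnames(calls), x@map$snp_id), , drop = FALSE]
  rownames(map) <- NULL
  md <- x@metadata[x@metadata$sample_id %in% rownames(calls), , drop = FALSE]
  rownames(md) <- NULL
  new("GenotypePanel", calls = calls, map = map, metadata = md,
      nAutosomes = x@nAutosomes)
})

#' Recode a panel so the counted allele is the minor allele
#'
#' Recomputes per-SNP allele frequencies over non-missing calls and, wherever
#' the counted (second) allele is the major one, swaps the allele pair and
#' flips calls (0 <-> 2). Ties at frequency 0.5 are broken so the counted
#' allele is the alphabetically later symbol, making the coding deterministic.
#' Run after QC so downstream signs stay interpretable.
#'
#' @param panel GenotypePanel
#' @return GenotypePanel with minor-allele counting.
#' @export
recodeToMinor <- function(panel) {
  v <- panel@calls
  p2 <- colMeans(v, na.rm = TRUE) / 2          # frequency of counted allele
  p2[is.nan(p2)] <- 0
  a1 <- panel@map$allele1
  a2 <- panel@map$allele2
  swap <- p2 > 0.5 | (p2 == 0.5 & a2 < a1)
  if (any(swap)) {
    v[, swap] <- 2L - v[, swap, drop = FALSE]
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  map <- panel@map
  map$allele1 <- a1
  map$allele2 <- a2
  new("GenotypePanel", calls = v, map = map, metadata = panel@metadata,
      nAutosomes = panel@nAutosomes)
}

#' ROH detection parameters (consecutive-runs method)
#'
#' Defaults are the island-mode criteria used for within-breed scans of dog
#' SNP-array data: at least 55 SNPs and 1000 kb per run, at most one
#' heterozygous and one missing call, and no gap above 1000 kb between
#' consecutive SNPs. \code{minDensityBpPerSnp} is the cluster-mode extra
#' criterion (1 SNP per 150 kb); leave \code{NA} to disable.
#'
#' @slot minSnps minimum number of SNPs in a run.
#' @slot minLengthBp minimum physical span (last bp - first bp).
#' @slot maxHet maximum heterozygous calls tolerated inside a run.
#' @slot maxMissing maximum missing calls tolerated inside a run.
#' @slot maxGapBp maximum gap between consecutive SNPs inside a run.
#' @slot minDensityBpPerSnp maximum bp per SNP (density floor); NA = off.
#' @exportClass RohParams
setClass("RohParams",
  representation(
    minSnps            = "integer",
    minLengthBp        = "numeric",
    maxHet             = "integer",
    maxMissing         = "integer",
    maxGapBp           = "numeric",
    minDensityBpPerSnp = "numeric"
  ),
  prototype(minSnps = 55L, minLengthBp = 1e6, maxHet = 1L, maxMissing = 1L,
            maxGapBp = 1e6, minDensityBpPerSnp = NA_real_)
)

setValidity("RohParams", function(object) {
  ok <- object@minSnps >= 1L && object@minLengthBp > 0 &&
    object@maxHet >= 0L && object@maxMissing >= 0L && object@maxGapBp > 0 &&
    (is.na(object@minDensityBpPerSnp) || object@minDensityBpPerSnp > 0)
  if (ok) TRUE else "all RohParams values must be positive (maxHet/maxMissing >= 0)"
})

#' @rdname RohParams-class
#' @param minSnps,minLengthBp,maxHet,maxMissing,maxGapBp,minDensityBpPerSnp
#'   see slot documentation.
#' @param clusterMode if TRUE, switch on the 1 SNP / 150 kb density criterion
#'   used for consensus-cluster detection.
#' @return A \linkS4class{RohParams} object.
#' @export
rohParams <- function(minSnps = 55L, minLengthBp = 1e6, maxHet = 1L,
                      maxMissing = 1L, maxGapBp = 1e6,
                      minDensityBpPerSnp = NA_real_, clusterMode = FALSE) {
  if (clusterMode && is.na(minDensityBpPerSnp)) minDensityBpPerSnp <- 150000
  new("RohParams", minSnps = as.integer(minSnps),
      minLengthBp = as.numeric(minLengthBp), maxHet = as.integer(maxHet),
      maxMissing = as.integer(maxMissing), maxGapBp = as.numeric(maxGapBp),
      minDensityBpPerSnp = as.numeric(minDensityBpPerSnp))
}

setMethod("show", "RohParams", function(object) {
  cat(sprintf(paste0(
    "RohParams: >=%d SNPs, >=%.0f kb, <=%d het, <=%d missing, ",
    "gap <=%.0f kb, density %s\n"),
    object@minSnps, object@minLengthBp / 1000, object@maxHet,
    object@maxMissing, object@maxGapBp / 1000,
    if (is.na(object@minDensityBpPerSnp)) "off"
    else sprintf("<=%.0f kb/SNP", object@minDensityBpPerSnp / 1000)))
})
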