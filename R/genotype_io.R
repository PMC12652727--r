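#' Read a PLINK-text PED/MAP genotype panel
#'
#' Parses the PLINK 1.9 text dialect: a MAP file with columns chromosome,
#' SNP id, genetic distance, bp position and a PED file with six leading
#' columns (FID, IID, PAT, MAT, SEX, PHENO) followed by two allele columns
#' per SNP. "0 0" genotype pairs become missing calls. The counted (second)
#' allele of each SNP is the minor allele at load time, with ties at 0.5
#' broken to the alphabetically later symbol. Non-autosomal and unmapped
#' rows (chromosome outside 1..nAutosomes or bp < 1) are dropped with a
#' message; SNPs are sorted by (chrom, bp) with calls permuted accordingly.
#'
#' @param pedPath path to the PED file.
#' @param mapPath path to the MAP file.
#' @param nAutosomes size of the autosome set (default 38, dog).
#' @return A \linkS4class{GenotypePanel}; PED columns 1, 5 become the
#'   metadata \code{group} (from FID) and \code{sex} columns.
#' @export
readPedMap <- function(pedPath, mapPath, nAutosomes = 38L) {
  stopifnot(file.exists(pedPath), file.exists(mapPath))
  map <- tryCatch(
    data.table::fread(mapPath, header = FALSE, data.table = FALSE,
                      colClasses = "character"),
    error = function(e) stop("malformed MAP file '", mapPath, "': ",
                             conditionMessage(e), call. = FALSE))
  if (ncol(map) < 4L) {
    stop("MAP file must have 4 columns (chrom, snp_id, cM, bp); got ",
         ncol(map), call. = FALSE)
  }
  chrom <- suppressWarnings(as.integer(sub("^chr", "", map[[1]])))
  bp <- suppressWarnings(as.integer(map[[4]]))
  bad <- which(is.na(chrom) & !is.na(bp))
  if (length(bad)) {
    stop("MAP parse error at line ", bad[1], ": unrecognized chromosome '",
         map[bad[1], 1], "'", call. = FALSE)
  }
  mp <- data.frame(snp_id = map[[2]], chrom = chrom, bp = bp,
                   stringsAsFactors = FALSE)

  # PED is whitespace-delimited with a space inside each genotype pair, so
  # tokenize on any whitespace rather than a single separator
  pedLines <- readLines(pedPath)
  pedLines <- pedLines[nzchar(trimws(pedLines))]
  ped <- strsplit(trimws(pedLines), "[ \t]+")
  ncols <- lengths(ped)
  if (length(unique(ncols)) > 1L) {
    bad <- which(ncols != ncols[1])[1]
    stop("malformed PED file '", pedPath, "': line ", bad, " has ",
         ncols[bad], " fields, expected ", ncols[1], call. = FALSE)
  }
  nSnpCols <- ncols[1] - 6L
  if (nSnpCols < 0L || nSnpCols %% 2L != 0L) {
    stop("PED file has ", ncols[1],
         " columns; expected 6 + 2 per SNP", call. = FALSE)
  }
  if (nSnpCols / 2L != nrow(mp)) {
    stop("PED genotype columns (", nSnpCols / 2L,
         " SNPs) inconsistent with MAP rows (", nrow(mp), ")", call. = FALSE)
  }
  pedCol <- function(j) vapply(ped, `[`, character(1), j)

  keep <- !is.na(mp$chrom) & !is.na(mp$bp) & mp$bp >= 1L &
    mp$chrom >= 1L & mp$chrom <= nAutosomes
  if (any(!keep)) {
    message(sum(!keep), " non-autosomal/unmapped MAP row(s) dropped")
  }

  sampleIds <- make.unique(pedCol(2L))
  n <- length(ped)
  m <- sum(keep)
  callm <- matrix(NA_integer_, n, m)
  a1v <- character(m)
  a2v <- character(m)
  kidx <- which(keep)
  for (k in seq_len(m)) {
    jc <- kidx[k]
    al1 <- pedCol(6L + 2L * jc - 1L)
    al2 <- pedCol(6L + 2L * jc)
    obs <- c(al1, al2)
    obs <- sort(unique(obs[obs != "0"]))
    if (length(obs) > 2L) {
      stop("PED parse error: SNP ", mp$snp_id[jc], " has ", length(obs),
           " alleles; panel must be bi-allelic", call. = FALSE)
    }
    if (length(obs) <= 1L) {
      # monomorphic (or all-missing): the counted minor allele is the unseen
      # one, so every non-missing call is 0
      g <- rep(0L, n)
      g[al1 == "0" | al2 == "0"] <- NA_integer_
      callm[, k] <- g
      a1v[k] <- if (length(obs)) obs else "0"
      a2v[k] <- "0"
      next
    }
    # counted allele = minor; tie -> alphabetically later (obs is sorted)
    cnt2 <- sum(al1 == obs[2], na.rm = TRUE) + sum(al2 == obs[2], na.rm = TRUE)
    cnt1 <- sum(al1 == obs[1], na.rm = TRUE) + sum(al2 == obs[1], na.rm = TRUE)
    if (cnt2 > cnt1) obs <- rev(obs)
    counted <- obs[2]
    g <- (al1 == counted) + (al2 == counted)
    g[al1 == "0" | al2 == "0"] <- NA_integer_
    callm[, k] <- as.integer(g)
    a1v[k] <- obs[1]
    a2v[k] <- counted
  }
  rownames(callm) <- sampleIds
  mapOut <- data.frame(snp_id = mp$snp_id[keep], chrom = mp$chrom[keep],
                       bp = mp$bp[keep], allele1 = a1v, allele2 = a2v,
                       stringsAsFactors = FALSE)
  colnames(callm) <- mapOut$snp_id
  md <- data.frame(sample_id = sampleIds, group = pedCol(1L),
                   sex = pedCol(5L), stringsAsFactors = FALSE)
  genotypePanel(callm, mapOut, md, nAutosomes = nAutosomes)
}

#' Write a panel as PLINK-text PED/MAP
#'
#' Emits deterministic output: MAP rows in map order; PED rows in sample
#' order with alleles spelled from the panel's allele pair (missing as
#' "0 0"). Group labels go to the FID column, sex (if present) to column 5.
#'
#' @param panel GenotypePanel
#' @param pedPath,mapPath output paths.
#' @return invisibly, the two paths.
#' @export
writePedMap <- function(panel, pedPath, mapPath) {
  map <- snpMap(panel)
  data.table::fwrite(
    data.frame(map$chrom, map$snp_id, 0L, map$bp),
    mapPath, sep = "\t", col.names = FALSE, quote = FALSE)
  v <- genotypeCalls(panel)
  md <- sampleInfo(panel)
  grp <- md$group[match(rownames(v), md$sample_id)]
  sex <- if ("sex" %in% names(md)) md$sex[match(rownames(v), md$sample_id)] else "0"
  sex[is.na(sex) | sex == ""] <- "0"
  n <- nrow(v); m <- ncol(v)
  geno <- matrix("0 0", n, m)
  for (j in seq_len(m)) {
    a1 <- map$allele1[j]; a2 <- map$allele2[j]
    gj <- v[, j]
    geno[, j] <- c(paste(a1, a1), paste(a1, a2), paste(a2, a2))[gj + 1L]
    geno[is.na(gj), j] <- "0 0"
  }
  lines <- paste(grp, rownames(v), 0L, 0L, sex, "-9",
                 apply(geno, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, pedPath)
  invisible(c(ped = pedPath, map = mapPath))
}

#' Read genotypes from a VCF
#'
#' Reads bi-allelic records with a GT field via \pkg{vcfR}. GT "0/0" (or
#' "0|0") maps to call 0, "0/1"/"1/0" to 1, "1/1" to 2 and "./." to missing,
#' i.e. the counted allele is ALT. Multi-allelic records and records on
#' chromosomes outside the autosome set are skipped with a warning/message.
#'
#' @param vcfPath path to an (uncompressed or bgzipped) VCF.
#' @param nAutosomes size of the autosome set.
#' @return A \linkS4class{GenotypePanel} (metadata: one group "all").
#' @export
readVcfGenotypes <- function(vcfPath, nAutosomes = 38L) {
  stopifnot(file.exists(vcfPath))
  vcf <- vcfR::read.vcfR(vcfPath, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  fmt <- if ("FORMAT" %in% colnames(vcf@gt)) vcf@gt[, "FORMAT"] else NULL
  if (is.null(fmt) || !all(grepl("(^|:)GT(:|$)", fmt))) {
    stop("VCF records lack a GT FORMAT field", call. = FALSE)
  }
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic VCF record(s) skipped")
  }
  chrom <- suppressWarnings(as.integer(sub("^chr", "", fix[, "CHROM"])))
  nonAuto <- is.na(chrom) | chrom < 1L | chrom > nAutosomes
  if (any(nonAuto & !multi)) {
    message(sum(nonAuto & !multi), " non-autosomal VCF record(s) dropped")
  }
  keep <- !multi & !nonAuto
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  gt <- gt[keep, , drop = FALSE]
  gt <- gsub("|", "/", gt, fixed = TRUE)
  code <- matrix(NA_integer_, nrow(gt), ncol(gt))
  code[gt == "0/0"] <- 0L
  code[gt %in% c("0/1", "1/0")] <- 1L
  code[gt == "1/1"] <- 2L
  callm <- t(code)
  rownames(callm) <- colnames(gt)
  ids <- fix[keep, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0("snp", which(is.na(ids) | ids == "."))
  map <- data.frame(snp_id = ids, chrom = chrom[keep],
                    bp = as.integer(fix[keep, "POS"]),
                    allele1 = fix[keep, "REF"], allele2 = alt[keep],
                    stringsAsFactors = FALSE)
  colnames(callm) <- map$snp_id
  genotypePanel(callm, map, nAutosomes = nAutosomes)
}

#' Write a panel as VCFv4.2
#'
#' REF is the panel's first allele, ALT the counted (second) allele, so the
#' GT dosage equals the internal call. Calls are written unphased; missing
#' as "./.". The header documents the allele-counting convention.
#'
#' @param panel GenotypePanel
#' @param vcfPath output path.
#' @return invisibly, the path.
#' @export
writeVcfGenotypes <- function(panel, vcfPath) {
  map <- snpMap(panel)
  v <- genotypeCalls(panel)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=rohscan",
    "##INFO=<ID=CA,Number=1,Type=String,Description=\"Counted allele: ALT; GT dosage equals internal call coding\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(v)), collapse = "\t"))
  gtStr <- c("0/0", "0/1", "1/1")
  body <- vapply(seq_len(nrow(map)), function(j) {
    gj <- v[, j]
    gs <- gtStr[gj + 1L]
    gs[is.na(gj)] <- "./."
    paste(c(map$chrom[j], map$bp[j], map$snp_id[j], map$allele1[j],
            map$allele2[j], ".", "PASS", "CA=ALT", "GT", gs), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), vcfPath)
  invisible(vcfPath)
}

#' Read gene intervals from BED4 or GFF3
#'
#' BED spans (0-based half-open) are converted to 1-based inclusive; GFF3
#' spans are taken as 1-based inclusive. Output is sorted by (chrom,
#' start_bp); overlapping genes are preserved, never merged.
#'
#' @param path path to the interval file.
#' @param dialect "bed" or "gff3"; default guessed from the file extension.
#' @param nAutosomes autosome set size; rows on other chromosomes dropped
#'   with a message.
#' @return data.frame with gene_id, chrom, start_bp, end_bp.
#' @export
readGeneIntervals <- function(path, dialect = c("auto", "bed", "gff3"),
                              nAutosomes = 38L) {
  stopifnot(file.exists(path))
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE))
      "gff3" else "bed"
  }
  ln <- readLines(path)
  ln <- ln[!grepl("^#", ln) & nzchar(trimws(ln))]
  if (!length(ln)) {
    return(data.frame(gene_id = character(), chrom = integer(),
                      start_bp = integer(), end_bp = integer()))
  }
  fields <- strsplit(ln, "\t|[ ]+")
  if (dialect == "bed") {
    out <- data.frame(
      gene_id  = vapply(fields, function(f)
        if (length(f) >= 4) f[4] else NA_character_, character(1)),
      chrom    = vapply(fields, `[`, character(1), 1),
      start_bp = as.integer(vapply(fields, `[`, character(1), 2)) + 1L,
      end_bp   = as.integer(vapply(fields, `[`, character(1), 3)),
      stringsAsFactors = FALSE)
    out$gene_id[is.na(out$gene_id)] <-
      paste0("interval", which(is.na(out$gene_id)))
  } else {
    feat <- vapply(fields, `[`, character(1), 3)
    keepFeat <- feat %in% c("gene", "pseudogene") | !any(feat == "gene")
    fields <- fields[keepFeat]
    attrs <- vapply(fields, function(f) f[length(f)], character(1))
    getAttr <- function(a, key) {
      m <- regmatches(a, regexec(paste0("(?:^|;)", key, "=([^;]+)"), a))
      vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
             character(1))
    }
    gid <- getAttr(attrs, "ID")
    alt <- getAttr(attrs, "Name")
    gid[is.na(gid)] <- alt[is.na(gid)]
    gid[is.na(gid)] <- paste0("gene", which(is.na(gid)))
    out <- data.frame(
      gene_id  = gid,
      chrom    = vapply(fields, `[`, character(1), 1),
      start_bp = as.integer(vapply(fields, `[`, character(1), 4)),
      end_bp   = as.integer(vapply(fields, `[`, character(1), 5)),
      stringsAsFactors = FALSE)
  }
  out$chrom <- suppressWarnings(as.integer(sub("^chr", "", out$chrom)))
  drop <- is.na(out$chrom) | out$chrom < 1L | out$chrom > nAutosomes
  if (any(drop)) message(sum(drop), " interval(s) outside autosome set dropped")
  out <- out[!drop, , drop = FALSE]
  if (any(out$start_bp > out$end_bp)) {
    stop("gene interval with start > end after coordinate conversion",
         call. = FALSE)
  }
  out <- out[order(out$chrom, out$start_bp, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a sample-metadata table
#'
#' Tab-separated with header; must contain \code{sample_id} and
#' \code{group}; optional \code{sex} and morphometric trait columns.
#'
#' @param path path to the TSV.
#' @return data.frame.
#' @export
readSampleMetadata <- function(path) {
  md <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (!all(c("sample_id", "group") %in% names(md))) {
    stop("metadata must have sample_id and group columns", call. = FALSE)
  }
  md
}

#' @rdname readSampleMetadata
#' @param md metadata data.frame
#' @export
writeSampleMetadata <- function(md, path) {
  data.table::fwrite(md, path, sep = "\t", quote = FALSE)
  invisible(path)
}
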