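#' Per-marker quality statistics
#'
#' Call rate, minor-allele frequency, observed and expected (2p(1-p))
#' heterozygote frequency and their ratio, all computed over non-missing
#' calls only. For an all-missing SNP the call rate is 0 and maf/het fields
#' are \code{NA}; for a monomorphic SNP (exp_het = 0) oe_ratio is \code{NA}.
#'
#' @param panel GenotypePanel
#' @return data.frame: snp_id, call_rate, maf, obs_het, exp_het, oe_ratio.
#' @export
markerStats <- function(panel) {
  v <- genotypeCalls(panel)
  stopifnot(ncol(v) > 0)
  nObs <- colSums(!is.na(v))
  callRate <- nObs / nrow(v)
  p <- colSums(v, na.rm = TRUE) / (2 * nObs)  # counted-allele frequency
  p[nObs == 0] <- NA_real_
  maf <- pmin(p, 1 - p)
  obsHet <- colSums(v == 1L, na.rm = TRUE) / nObs
  obsHet[nObs == 0] <- NA_real_
  expHet <- 2 * p * (1 - p)
  oe <- ifelse(!is.na(expHet) & expHet > 0, obsHet / expHet, NA_real_)
  data.frame(snp_id = colnames(v), call_rate = callRate, maf = maf,
             obs_het = obsHet, exp_het = expHet, oe_ratio = oe,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' QC thresholds
#'
#' Defaults follow the conventional mind/geno/maf/HWE cascade for SNP-array
#' panels: sample call rate >= 0.95, SNP call rate >= 0.95, MAF >= 0.01,
#' heterozygosity observed/expected ratio within [0.05, 1.1].
#'
#' @param sampleCallRate minimum sample call rate (retain >=).
#' @param snpCallRate minimum SNP call rate (retain >=).
#' @param mafMin minimum minor allele frequency (retain >=).
#' @param hweRatioMin,hweRatioMax retained O/E heterozygosity ratio bounds
#'   (inclusive).
#' @return a named list of class "qcConfig".
#' @export
qcConfig <- function(sampleCallRate = 0.95, snpCallRate = 0.95,
                     mafMin = 0.01, hweRatioMin = 0.05, hweRatioMax = 1.1) {
  stopifnot(sampleCallRate >= 0, sampleCallRate <= 1,
            snpCallRate >= 0, snpCallRate <= 1,
            mafMin >= 0, mafMin <= 0.5,
            hweRatioMin >= 0, hweRatioMax >= hweRatioMin)
  structure(list(sample_call_rate = sampleCallRate,
                 snp_call_rate = snpCallRate, maf_min = mafMin,
                 hwe_ratio_min = hweRatioMin, hwe_ratio_max = hweRatioMax),
            class = "qcConfig")
}

#' Quality-control cascade
#'
#' Applies, in fixed order, (1) sample call-rate, (2) SNP call-rate,
#' (3) minor-allele-frequency and (4) heterozygosity O/E-ratio filters,
#' recomputing marker statistics after each stage. Thresholds are
#' retain-at-boundary: a SNP at exactly the MAF floor or at an O/E bound is
#' kept. Monomorphic SNPs (maf = 0 or all-missing) fall to the MAF stage,
#' so the HWE ratio is never evaluated on an undefined denominator.
#'
#' @param panel GenotypePanel
#' @param config a \code{\link{qcConfig}}.
#' @return list with \code{panel} (filtered GenotypePanel) and \code{report}
#'   (data.frame of per-stage attrition: stage, unit, input, removed,
#'   retained).
#' @export
qcPipeline <- function(panel, config = qcConfig()) {
  stopifnot(inherits(config, "qcConfig"))
  report <- list()
  note <- function(stage, unit, input, removed) {
    report[[length(report) + 1L]] <<- data.frame(
      stage = stage, unit = unit, input = input, removed = removed,
      retained = input - removed, stringsAsFactors = FALSE)
  }
  fail <- function(stage) {
    stop("panel empty after QC stage '", stage, "'", call. = FALSE)
  }

  # stage 1: sample call rate
  v <- genotypeCalls(panel)
  scr <- rowMeans(!is.na(v))
  keepS <- scr >= config$sample_call_rate
  note("sample_call_rate", "sample", nrow(v), sum(!keepS))
  if (!any(keepS)) fail("sample_call_rate")
  panel <- panel[keepS, ]

  # stage 2: SNP call rate
  st <- markerStats(panel)
  keep <- st$call_rate >= config$snp_call_rate
  note("snp_call_rate", "snp", nrow(st), sum(!keep))
  if (!any(keep)) fail("snp_call_rate")
  panel <- panel[, keep]

  # stage 3: MAF (removes monomorphic and all-missing SNPs when mafMin > 0)
  st <- markerStats(panel)
  keep <- !is.na(st$maf) & st$maf >= config$maf_min
  note("maf", "snp", nrow(st), sum(!keep))
  if (!any(keep)) fail("maf")
  panel <- panel[, keep]

  # stage 4: heterozygosity O/E ratio, inclusive-retain bounds
  st <- markerStats(panel)
  keep <- is.na(st$oe_ratio) |
    (st$oe_ratio >= config$hwe_ratio_min & st$oe_ratio <= config$hwe_ratio_max)
  note("hwe_oe_ratio", "snp", nrow(st), sum(!keep))
  if (!any(keep)) fail("hwe_oe_ratio")
  panel <- panel[, keep]

  list(panel = panel, report = do.call(rbind, report))
}
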