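#' Simulation configuration
#'
#' Defaults emulate a within-breed SNP-array study: a 10-chromosome map of
#' 5,000 uniformly spaced SNPs per chromosome over 50 Mb (about 1 SNP per
#' 10 kb, echoing commercial canine array density), four usage-defined
#' subpopulations with Balding-Nichols drift away from a shared ancestral
#' population, and low rates of genotyping error and missingness.
#'
#' @param seed integer master seed; every stage derives its own sub-seed
#'   from it, so e.g. changing noise rates never alters the drift draws.
#' @param nChrom number of autosomes simulated.
#' @param snpsPerChrom SNPs per chromosome.
#' @param chromLengthBp chromosome length in bp.
#' @param populations data.frame with columns label, n, F (drift parameter
#'   in [0,1); F equals the expected differentiation from the ancestral
#'   population under the Balding-Nichols model).
#' @param ancestralFreqRange range the ancestral counted-allele frequencies
#'   are drawn from (uniform).
#' @param hetErrorRate per-call heterozygote-error rate.
#' @param missingRate per-call missing rate.
#' @return list of class "simConfig".
#' @export
simConfig <- function(seed = 1L,
                      nChrom = 10L,
                      snpsPerChrom = 5000L,
                      chromLengthBp = 5e7,
                      populations = data.frame(
                        label = c("pet", "show", "sled_sprint",
                                  "sled_distance"),
                        n = c(35L, 66L, 92L, 44L),
                        F = c(0.10, 0.10, 0.05, 0.08)),
                      ancestralFreqRange = c(0.1, 0.9),
                      hetErrorRate = 0.0005,
                      missingRate = 0.002) {
  stopifnot(nChrom >= 1, snpsPerChrom >= 1, chromLengthBp > 0,
            nrow(populations) >= 1, all(populations$n >= 1),
            all(populations$F >= 0 & populations$F < 1),
            length(ancestralFreqRange) == 2,
            ancestralFreqRange[1] > 0, ancestralFreqRange[2] < 1,
            hetErrorRate >= 0, hetErrorRate <= 1,
            missingRate >= 0, missingRate <= 1)
  structure(list(seed = as.integer(seed), nChrom = as.integer(nChrom),
                 snpsPerChrom = as.integer(snpsPerChrom),
                 chromLengthBp = chromLengthBp, populations = populations,
                 ancestralFreqRange = ancestralFreqRange,
                 hetErrorRate = hetErrorRate, missingRate = missingRate),
            class = "simConfig")
}

# stage-independent sub-seed derivation (Lehmer step keeps values < 2^31)
subSeed <- function(seed, stage) {
  as.integer((as.numeric(seed) %% 2147483647) * 48271 + stage) %% 2147483647L
}

#' Simulate a genotype panel under the Balding-Nichols model
#'
#' Ancestral counted-allele frequencies are drawn uniformly from
#' \code{ancestralFreqRange}; each population's frequencies come from the
#' Balding-Nichols beta distribution with parameter F (expected marker-wise
#' differentiation from the ancestral population equals F); genotypes are
#' binomial(2, p_pop) draws. Identical seeds give byte-identical panels.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @return list: \code{panel} (GenotypePanel with group metadata) and
#'   \code{truth} (list with ancestral_freq, pop_freq matrix, planted
#'   segment table, carriers list, config).
#' @export
simulatePanel <- function(cfg = simConfig()) {
  stopifnot(inherits(cfg, "simConfig"))
  m <- cfg$nChrom * cfg$snpsPerChrom
  spacing <- cfg$chromLengthBp / cfg$snpsPerChrom
  bp1 <- as.integer(round(seq(1, by = spacing, length.out = cfg$snpsPerChrom)))
  map <- data.frame(
    snp_id = sprintf("snp_%d_%d", rep(seq_len(cfg$nChrom),
                                      each = cfg$snpsPerChrom),
                     rep(seq_len(cfg$snpsPerChrom), cfg$nChrom)),
    chrom = rep(seq_len(cfg$nChrom), each = cfg$snpsPerChrom),
    bp = rep(bp1, cfg$nChrom),
    allele1 = "A", allele2 = "B", stringsAsFactors = FALSE)

  set.seed(subSeed(cfg$seed, 1L))
  pAnc <- stats::runif(m, cfg$ancestralFreqRange[1], cfg$ancestralFreqRange[2])

  pops <- cfg$populations
  set.seed(subSeed(cfg$seed, 2L))
  popFreq <- matrix(NA_real_, nrow(pops), m,
                    dimnames = list(pops$label, map$snp_id))
  for (i in seq_len(nrow(pops))) {
    Fd <- pops$F[i]
    popFreq[i, ] <- if (Fd == 0) pAnc else {
      stats::rbeta(m, pAnc * (1 - Fd) / Fd, (1 - pAnc) * (1 - Fd) / Fd)
    }
  }

  set.seed(subSeed(cfg$seed, 3L))
  nTot <- sum(pops$n)
  calls <- matrix(NA_integer_, nTot, m)
  ids <- character(nTot)
  grp <- character(nTot)
  off <- 0L
  for (i in seq_len(nrow(pops))) {
    ni <- pops$n[i]
    calls[off + seq_len(ni), ] <- matrix(
      stats::rbinom(ni * m, 2L, rep(popFreq[i, ], each = ni)), ni, m)
    ids[off + seq_len(ni)] <- sprintf("%s_%03d", pops$label[i], seq_len(ni))
    grp[off + seq_len(ni)] <- pops$label[i]
    off <- off + ni
  }
  rownames(calls) <- ids
  colnames(calls) <- map$snp_id
  md <- data.frame(sample_id = ids, group = grp, stringsAsFactors = FALSE)
  panel <- genotypePanel(calls, map, md,
                         nAutosomes = max(38L, cfg$nChrom))
  truth <- list(ancestral_freq = pAnc, pop_freq = popFreq,
                planted = data.frame(), carriers = list(), config = cfg)
  list(panel = panel, truth = truth)
}

#' Describe a segment to plant
#'
#' @param chrom,startBp,endBp span of the segment (must cover >= 1 SNP).
#' @param carriers named numeric vector population -> carrier fraction in
#'   [0, 1].
#' @param kind "individual_roh" (each carrier gets its own homozygous
#'   pattern) or "shared_sweep" (one fixed pattern shared by all carriers,
#'   so the span enters population-level consensus).
#' @return list of class "plantedSegment".
#' @export
plantedSegment <- function(chrom, startBp, endBp, carriers,
                           kind = c("shared_sweep", "individual_roh")) {
  kind <- match.arg(kind)
  stopifnot(startBp <= endBp, all(carriers >= 0 & carriers <= 1),
            !is.null(names(carriers)))
  structure(list(chrom = chrom, start_bp = startBp, end_bp = endBp,
                 carriers = carriers, kind = kind),
            class = "plantedSegment")
}

#' Plant autozygous segments into a simulated panel
#'
#' For every carrier (sampled per population to hit the requested fraction,
#' rounded to the nearest count), all calls in the span become homozygous.
#' Shared sweeps write one fixed allele pattern into every carrier;
#' individual ROH draw a fresh pattern per carrier. The truth table records
#' realized carrier sets and per-individual planted autozygous fractions.
#'
#' @param panel GenotypePanel from \code{\link{simulatePanel}}.
#' @param truth matching truth list.
#' @param segments list of \code{\link{plantedSegment}} objects.
#' @param seed integer seed for carrier sampling and pattern draws.
#' @return list(panel, truth) with updated calls and truth.
#' @export
plantAutozygosity <- function(panel, truth, segments, seed = 1L) {
  if (inherits(segments, "plantedSegment")) segments <- list(segments)
  map <- snpMap(panel)
  v <- genotypeCalls(panel)
  md <- sampleInfo(panel)
  set.seed(subSeed(seed, 11L))
  plantedRows <- list()
  carriers <- truth$carriers
  for (k in seq_along(segments)) {
    sg <- segments[[k]]
    jj <- which(map$chrom == sg$chrom & map$bp >= sg$start_bp &
                  map$bp <= sg$end_bp)
    if (!length(jj)) stop("planted segment covers no SNPs", call. = FALSE)
    pAnc <- truth$ancestral_freq[jj]
    sharedPattern <- ifelse(stats::runif(length(jj)) < pAnc, 2L, 0L)
    segCarriers <- character()
    for (pp in names(sg$carriers)) {
      members <- md$sample_id[md$group == pp]
      if (!length(members)) stop("unknown population '", pp, "'",
                                 call. = FALSE)
      nc <- round(sg$carriers[[pp]] * length(members))
      if (nc == 0) next
      chosen <- sample(members, nc)
      for (id in chosen) {
        pat <- if (sg$kind == "shared_sweep") sharedPattern
               else ifelse(stats::runif(length(jj)) < pAnc, 2L, 0L)
        v[id, jj] <- pat
      }
      segCarriers <- c(segCarriers, chosen)
    }
    segId <- sprintf("planted%02d", length(carriers) + 1L)
    carriers[[segId]] <- segCarriers
    plantedRows[[k]] <- data.frame(
      segment_id = segId, chrom = sg$chrom, start_bp = sg$start_bp,
      end_bp = sg$end_bp, kind = sg$kind,
      n_carriers = length(segCarriers), stringsAsFactors = FALSE)
  }
  truth$carriers <- carriers
  truth$planted <- rbind(truth$planted, do.call(rbind, plantedRows))
  # realized planted autozygous fraction per individual
  lAuto <- sum(vapply(split(as.numeric(map$bp), map$chrom),
                      function(b) max(b) - min(b), numeric(1)))
  frac <- stats::setNames(numeric(nrow(md)), md$sample_id)
  for (segId in names(carriers)) {
    row <- truth$planted[truth$planted$segment_id == segId, ]
    frac[carriers[[segId]]] <- frac[carriers[[segId]]] +
      (row$end_bp - row$start_bp) / lAuto
  }
  truth$planted_fraction <- frac
  out <- genotypePanel(v, map, md, nAutosomes = panel@nAutosomes)
  list(panel = out, truth = truth)
}

#' Inject genotyping noise
#'
#' Independent per-call flips to heterozygote (genotyping error) and to
#' missing. Inside planted segment spans each carrier keeps at most
#' \code{maxHetPerSpan} heterozygote flips and \code{maxMissingPerSpan}
#' missing flips (excess flips are reverted), so planted truth remains
#' recoverable under default ROH tolerances at the documented default rates
#' (het 0.0005, missing 0.002).
#'
#' @param panel GenotypePanel.
#' @param hetErrorRate,missingRate per-call rates in [0, 1].
#' @param seed integer seed.
#' @param truth optional truth list carrying planted spans to protect.
#' @param maxHetPerSpan,maxMissingPerSpan per-span caps (default 1, the ROH
#'   scan tolerance).
#' @return GenotypePanel with noise applied.
#' @export
injectNoise <- function(panel, hetErrorRate = 0.0005, missingRate = 0.002,
                        seed = 1L, truth = NULL, maxHetPerSpan = 1L,
                        maxMissingPerSpan = 1L) {
  stopifnot(hetErrorRate >= 0, hetErrorRate <= 1,
            missingRate >= 0, missingRate <= 1)
  if (hetErrorRate == 0 && missingRate == 0) return(panel)
  v0 <- genotypeCalls(panel)
  v <- v0
  map <- snpMap(panel)
  set.seed(subSeed(seed, 21L))
  if (hetErrorRate > 0) {
    flip <- matrix(stats::runif(length(v)) < hetErrorRate, nrow(v))
    v[flip & !is.na(v0)] <- 1L
  }
  set.seed(subSeed(seed, 22L))
  if (missingRate > 0) {
    miss <- matrix(stats::runif(length(v)) < missingRate, nrow(v))
    v[miss] <- NA_integer_
  }
  if (!is.null(truth) && nrow(truth$planted)) {
    for (segId in truth$planted$segment_id) {
      row <- truth$planted[truth$planted$segment_id == segId, ]
      jj <- which(map$chrom == row$chrom & map$bp >= row$start_bp &
                    map$bp <= row$end_bp)
      for (id in truth$carriers[[segId]]) {
        newHet <- jj[!is.na(v[id, jj]) & v[id, jj] == 1L &
                       (is.na(v0[id, jj]) | v0[id, jj] != 1L)]
        if (length(newHet) > maxHetPerSpan) {
          revert <- newHet[-seq_len(maxHetPerSpan)]
          v[id, revert] <- v0[id, revert]
        }
        newMiss <- jj[is.na(v[id, jj]) & !is.na(v0[id, jj])]
        if (length(newMiss) > maxMissingPerSpan) {
          revert <- newMiss[-seq_len(maxMissingPerSpan)]
          v[id, revert] <- v0[id, revert]
        }
      }
    }
  }
  genotypePanel(v, map, sampleInfo(panel), nAutosomes = panel@nAutosomes)
}

#' Default morphometric generating parameters
#'
#' The 18 standard body measurements (cm) with per-group means and SDs for
#' pet, show and sled dogs, as used by the morphometric simulator.
#'
#' @return long-format data.frame: trait, group, mean, sd.
#' @export
tableOneParams <- function() {
  traits <- c("Eye Width", "Snout Length", "Outside Ear Length",
              "Chest Width", "Neck Girth", "Chest Girth", "Wither Height",
              "Height at Base of Tail", "Body Length", "Tail Length",
              "Upper Foreleg Length", "Lower Foreleg Length",
              "Fore Foot Length", "Fore Foot Circumference",
              "Upper Hind Leg Length", "Lower Hind Leg Length",
              "Hind Foot Length", "Hind Foot Circumference")
  pet  <- c(4.45, 9.45, 8.79, 13.94, 35.99, 67.23, 56.92, 55.32, 61.85,
            35.71, 20.04, 21.41, 13.56, 9.91, 30.51, 24.21, 21.23, 9.47)
  petSd <- c(0.53, 0.97, 1.30, 1.98, 3.81, 6.78, 3.84, 4.01, 6.68, 4.67,
             2.41, 2.03, 1.60, 0.86, 3.33, 2.92, 2.01, 0.86)
  show <- c(4.42, 9.19, 8.43, 12.29, 37.41, 62.56, 56.85, 54.03, 54.69,
            35.84, 19.10, 20.93, 12.50, 10.24, 27.30, 23.60, 20.80, 9.63)
  showSd <- c(0.64, 0.91, 0.89, 1.40, 3.86, 4.55, 3.66, 4.04, 4.52, 2.87,
              1.91, 1.55, 1.55, 1.24, 2.36, 2.24, 1.60, 1.04)
  sled <- c(4.11, 9.42, 8.38, 12.65, 36.42, 64.85, 60.22, 58.37, 57.68,
            34.42, 17.83, 21.29, 12.83, 10.13, 30.15, 22.00, 20.24, 9.68)
  sledSd <- c(0.81, 1.17, 1.22, 1.35, 3.81, 4.47, 3.43, 5.97, 4.34, 4.42,
              2.64, 1.83, 1.50, 0.86, 3.38, 3.20, 2.24, 0.86)
  rbind(
    data.frame(trait = traits, group = "pet", mean = pet, sd = petSd),
    data.frame(trait = traits, group = "show", mean = show, sd = showSd),
    data.frame(trait = traits, group = "sled", mean = sled, sd = sledSd))
}

#' Simulate group-structured morphometrics
#'
#' Independent normal draws per trait per group at the configured means and
#' SDs (defaults: the 18-trait table from \code{\link{tableOneParams}}).
#' An optional trait correlation matrix induces within-group correlation
#' via a Cholesky factor while preserving the marginal means/SDs.
#'
#' @param nPerGroup named integer vector group -> sample size.
#' @param params long-format data.frame (trait, group, mean, sd).
#' @param seed integer seed.
#' @param corMatrix optional traits x traits correlation matrix.
#' @return data.frame: sample_id, group, one numeric column per trait.
#' @export
simulateMorphometrics <- function(nPerGroup = c(pet = 35, show = 66,
                                                sled = 136),
                                  params = tableOneParams(), seed = 1L,
                                  corMatrix = NULL) {
  stopifnot(!is.null(names(nPerGroup)), all(params$sd >= 0))
  traits <- unique(params$trait)
  set.seed(subSeed(seed, 31L))
  out <- list()
  for (gp in names(nPerGroup)) {
    n <- nPerGroup[[gp]]
    pg <- params[params$group == gp, , drop = FALSE]
    stopifnot(nrow(pg) == length(traits))
    pg <- pg[match(traits, pg$trait), , drop = FALSE]
    z <- matrix(stats::rnorm(n * length(traits)), n, length(traits))
    if (!is.null(corMatrix)) z <- z %*% chol(corMatrix)
    x <- sweep(sweep(z, 2, pg$sd, "*"), 2, pg$mean, "+")
    colnames(x) <- traits
    out[[gp]] <- data.frame(sample_id = sprintf("%s_%03d", gp, seq_len(n)),
                            group = gp, x, check.names = FALSE,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
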