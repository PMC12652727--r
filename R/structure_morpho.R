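#' Genomic relationship matrix
#'
#' Centered, frequency-standardized genotype cross-product: with p_j the
#' counted-allele frequency of SNP j, w_ij = (x_ij - 2 p_j) /
#' sqrt(2 p_j (1 - p_j)); G_kl = sum_j w_kj w_lj / m_kl, where m_kl counts
#' SNPs non-missing in both individuals. Missing calls are mean-imputed per
#' SNP (contributing 0 to the numerator); SNPs with zero variance after QC
#' are skipped with a message.
#'
#' @param panel post-QC GenotypePanel.
#' @return list with \code{grm} (symmetric samples x samples matrix) and
#'   \code{n_snps} (matrix of per-pair SNP counts used).
#' @export
computeGrm <- function(panel) {
  v <- genotypeCalls(panel)
  nObs <- colSums(!is.na(v))
  p <- colSums(v, na.rm = TRUE) / (2 * nObs)
  keep <- nObs > 0 & p > 0 & p < 1
  if (any(!keep)) {
    message(sum(!keep), " zero-variance SNP(s) skipped in GRM")
  }
  v <- v[, keep, drop = FALSE]
  p <- p[keep]
  w <- sweep(v, 2, 2 * p, "-")
  w <- sweep(w, 2, sqrt(2 * p * (1 - p)), "/")
  obs <- !is.na(v)
  w[!obs] <- 0
  storage.mode(obs) <- "double"
  nPair <- tcrossprod(obs)
  g <- tcrossprod(w) / nPair
  dimnames(g) <- list(rownames(v), rownames(v))
  dimnames(nPair) <- dimnames(g)
  list(grm = g, n_snps = nPair)
}

#' Genotype PCA from a GRM
#'
#' Top-k eigenpairs of the genomic relationship matrix; scores are
#' eigenvectors scaled by the square root of their (non-negative)
#' eigenvalues. Sign convention: within each component the entry of largest
#' magnitude is positive. Degenerate panels (all eigenvalues ~ 0) are
#' flagged with a warning.
#'
#' @param grm output of \code{\link{computeGrm}} (or a bare symmetric matrix).
#' @param k number of components, default 2.
#' @return list: \code{scores} (samples x k), \code{eigenvalues} (all),
#'   \code{pve} (per retained component, over the positive spectrum).
#' @export
pcaGenotypes <- function(grm, k = 2L) {
  g <- if (is.list(grm)) grm$grm else grm
  stopifnot(isSymmetric(unname(g), tol = 1e-8))
  ev <- eigen(g, symmetric = TRUE)
  if (k > sum(ev$values > 1e-10)) {
    if (all(ev$values < 1e-10)) {
      warning("degenerate GRM: all eigenvalues are ~0")
    } else {
      stop("k exceeds the rank of the GRM", call. = FALSE)
    }
  }
  vals <- ev$values[seq_len(k)]
  vecs <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  scores <- sweep(vecs, 2, sqrt(pmax(vals, 0)), "*")
  dimnames(scores) <- list(rownames(g), paste0("PC", seq_len(k)))
  pos <- sum(ev$values[ev$values > 0])
  list(scores = scores, eigenvalues = ev$values,
       pve = if (pos > 0) vals / pos else rep(NA_real_, k))
}

#' Morphometric PCA
#'
#' Column-standardized (unit-variance) PCA of a samples x traits table via
#' \code{prcomp}. Rows with any missing trait are dropped with a message.
#' Two proportion-of-variance conventions are reported side by side: the
#' standard lambda_i / sum(all lambda), and the "top-k" convention
#' lambda_i / sum(lambda_1..lambda_k) sometimes used when only the leading
#' components are examined.
#'
#' @param traits data.frame or matrix, samples x traits (numeric columns);
#'   row names are sample ids.
#' @param k number of components to report, default 5.
#' @param scale. standardize traits to unit variance (default TRUE).
#' @return list: scores, loadings, eigenvalues, pve_standard, pve_topk.
#' @export
pcaMorphometrics <- function(traits, k = 5L, scale. = TRUE) {
  x <- as.matrix(traits)
  stopifnot(is.numeric(x))
  complete <- stats::complete.cases(x)
  if (any(!complete)) {
    message(sum(!complete), " sample(s) with incomplete traits dropped")
  }
  x <- x[complete, , drop = FALSE]
  if (nrow(x) <= k) stop("fewer samples than components", call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = scale.)
  lambda <- pc$sdev^2
  kk <- seq_len(k)
  list(scores = pc$x[, kk, drop = FALSE],
       loadings = pc$rotation[, kk, drop = FALSE],
       eigenvalues = lambda,
       pve_standard = lambda[kk] / sum(lambda),
       pve_topk = lambda[kk] / sum(lambda[kk]))
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Groups sharing a letter are not significantly different at level alpha.
#' Letters are the maximal cliques of the graph whose edges join pairs with
#' p > alpha, ordered by their first member, so the display is
#' reconstructible from the significance pattern alone and invariant to
#' input order.
#'
#' @param pmat symmetric matrix of pairwise p-values with group dimnames.
#' @param alpha significance level, default 0.05.
#' @return named character vector group -> letter string.
#' @export
compactLetterDisplay <- function(pmat, alpha = 0.05) {
  gn <- sort(rownames(pmat))
  pmat <- pmat[gn, gn, drop = FALSE]
  adj <- (pmat > alpha) | is.na(pmat)
  diag(adj) <- TRUE
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                            diag = FALSE)
  cliques <- igraph::max_cliques(gr)
  members <- lapply(cliques, function(cl) sort(gn[as.integer(cl)]))
  members <- members[order(vapply(members, function(m) match(m[1], gn),
                                  integer(1)),
                           vapply(members, paste, character(1),
                                  collapse = ""))]
  letters_ <- letters[seq_along(members)]
  out <- stats::setNames(rep("", length(gn)), gn)
  for (i in seq_along(members)) {
    out[members[[i]]] <- paste0(out[members[[i]]], letters_[i])
  }
  out
}

#' Per-trait group comparisons (Table-1-style statistics)
#'
#' For each trait: Shapiro-Wilk normality per group, Levene's test
#' (median-centered, via \pkg{car}) for homogeneity of variances, one-way
#' ANOVA, and - when ANOVA p < alpha - Tukey(-Kramer) HSD pairwise adjusted
#' p-values with a compact-letter display. Constant traits get an NA F and
#' a flag.
#'
#' @param traits data.frame samples x traits (numeric).
#' @param groups factor/character vector of group labels, length nrow(traits).
#' @param alpha significance level, default 0.05.
#' @return data.frame with one row per trait: trait, group means/SDs (as
#'   attached attribute "group_stats"), shapiro_p (minimum across groups),
#'   levene_p, anova_F, anova_p, significant, cld (comma-joined
#'   group=letters), plus attribute "tukey" (named list of pairwise tables).
#' @export
traitGroupTests <- function(traits, groups, alpha = 0.05) {
  groups <- factor(groups)
  stopifnot(nrow(traits) == length(groups), nlevels(groups) >= 2)
  if (any(table(groups) < 3)) {
    stop("each group needs at least 3 observations", call. = FALSE)
  }
  tukeyList <- list()
  statsList <- list()
  rows <- lapply(names(traits), function(tr) {
    y <- traits[[tr]]
    ok <- !is.na(y)
    yy <- y[ok]; gg <- droplevels(groups[ok])
    gstats <- do.call(rbind, lapply(levels(gg), function(l) {
      data.frame(trait = tr, group = l, n = sum(gg == l),
                 mean = mean(yy[gg == l]), sd = stats::sd(yy[gg == l]))
    }))
    statsList[[tr]] <<- gstats
    if (stats::sd(yy) == 0) {
      # all observations identical: no variance anywhere, trivially one group
      cldv <- stats::setNames(rep("a", nlevels(gg)), levels(gg))
      return(data.frame(trait = tr, shapiro_p = NA_real_, levene_p = NA_real_,
                        anova_F = 0, anova_p = NA_real_, significant = FALSE,
                        constant = TRUE,
                        cld = paste(sprintf("%s=%s", names(cldv), cldv),
                                    collapse = ","),
                        stringsAsFactors = FALSE))
    }
    shap <- vapply(levels(gg), function(l) {
      yl <- yy[gg == l]
      if (length(unique(yl)) < 3) NA_real_ else stats::shapiro.test(yl)$p.value
    }, numeric(1))
    lev <- tryCatch(
      car::leveneTest(yy ~ gg, center = stats::median)[1, "Pr(>F)"],
      error = function(e) NA_real_)
    fit <- stats::aov(yy ~ gg)
    an <- summary(fit)[[1]]
    fstat <- an[1, "F value"]
    pval <- an[1, "Pr(>F)"]
    sig <- !is.na(pval) && pval < alpha
    cldStr <- NA_character_
    if (sig) {
      tk <- stats::TukeyHSD(fit)$gg
      tukeyList[[tr]] <<- tk
      pm <- matrix(NA_real_, nlevels(gg), nlevels(gg),
                   dimnames = list(levels(gg), levels(gg)))
      prs <- strsplit(rownames(tk), "-", fixed = TRUE)
      for (i in seq_along(prs)) {
        pm[prs[[i]][1], prs[[i]][2]] <- pm[prs[[i]][2], prs[[i]][1]] <-
          tk[i, "p adj"]
      }
      cldv <- compactLetterDisplay(pm, alpha = alpha)
      cldStr <- paste(sprintf("%s=%s", names(cldv), cldv), collapse = ",")
    }
    shapMin <- if (all(is.na(shap))) NA_real_ else min(shap, na.rm = TRUE)
    data.frame(trait = tr, shapiro_p = shapMin,
               levene_p = lev, anova_F = fstat, anova_p = pval,
               significant = sig, constant = FALSE, cld = cldStr,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "group_stats") <- do.call(rbind, statsList)
  attr(res, "tukey") <- tukeyList
  res
}
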