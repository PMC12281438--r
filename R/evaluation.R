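#' Euclidean centroid distances to a reference group
#'
#' On the PC1-PC2 plane: for each non-reference group, the Euclidean
#' distance between its centroid and the reference group's centroid.
#'
#' @param pcScores Numeric matrix, samples x >= 2 components (PC1, PC2 used).
#' @param labels Group label per sample.
#' @param refLabel Reference group (e.g. non-IBD controls).
#' @return Named numeric vector of distances, one per non-reference group.
#' @export
centroidDistances <- function(pcScores, labels, refLabel) {
  labels <- as.character(labels)
  if (!refLabel %in% labels) stopf("reference group '%s' absent", refLabel)
  xy <- pcScores[, 1:2, drop = FALSE]
  ref <- colMeans(xy[labels == refLabel, , drop = FALSE])
  groups <- setdiff(unique(labels), refLabel)
  vapply(setNames(groups, groups), function(g) {
    sqrt(sum((colMeans(xy[labels == g, , drop = FALSE]) - ref)^2))
  }, numeric(1))
}

#' Random-gene-set null model for signature robustness
#'
#' For each of `nDraws` draws, samples `setSize` genes without replacement
#' from the regulated-gene pool, fits a scaled PCA on all samples, and
#' records the per-group centroid distance to the reference group on the
#' PC1-PC2 plane together with the explained variance of PC1 and PC2.
#' Draws use independent substreams of `seed`, so results do not depend on
#' evaluation order.
#'
#' @param expr Normalized log expression, genes x samples.
#' @param labels Group label per sample (column order of `expr`).
#' @param pool Gene-id pool to draw from (e.g. all IBD-regulated DEGs).
#' @param nDraws Number of random signatures (default 200).
#' @param setSize Genes per draw (default 81).
#' @param refLabel Reference group.
#' @param seed Master seed.
#' @return data.frame(draw, group, distance, pc1_var, pc2_var).
#' @export
randomSignatureNull <- function(expr, labels, pool, nDraws = 200,
                                setSize = 81, refLabel = "non-IBD",
                                seed = 1L) {
  missing <- setdiff(pool, rownames(expr))
  if (length(missing)) stopf("pool gene '%s' absent from expr", missing[1])
  if (setSize > length(pool)) stopf("setSize exceeds pool size")
  out <- vector("list", nDraws)
  for (i in seq_len(nDraws)) {
    genes <- withSeed(substreamSeed(seed, "null-draw", i),
                      sample(pool, setSize))
    pca <- suppressWarnings(fitPca(expr[genes, , drop = FALSE], scale = TRUE))
    d <- centroidDistances(pca$scores, labels, refLabel)
    out[[i]] <- data.frame(draw = i, group = names(d), distance = unname(d),
                           pc1_var = pca$explained[1],
                           pc2_var = pca$explained[2],
                           stringsAsFactors = FALSE)
  }
  if (nDraws == 0) {
    return(data.frame(draw = integer(), group = character(),
                      distance = numeric(), pc1_var = numeric(),
                      pc2_var = numeric()))
  }
  do.call(rbind, out)
}

#' One-sample Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test of `values - reference` against median zero.
#' Zero differences are dropped (count reported); the exact distribution is
#' used for n <= 25 without ties, otherwise the normal approximation with
#' continuity correction.
#'
#' @param values Numeric sample.
#' @param reference Null median.
#' @param alternative Passed to the test ("two.sided" default).
#' @return list(p, statistic, n_used, n_zero_dropped, exact).
#' @export
oneSampleWilcoxon <- function(values, reference,
                              alternative = "two.sided") {
  d <- values - reference
  nz <- d[d != 0]
  if (length(nz) == 0) stopf("all differences are zero: test undefined")
  exact <- length(nz) <= 25 && !anyDuplicated(abs(nz))
  wt <- suppressWarnings(
    wilcox.test(nz, mu = 0, alternative = alternative, exact = exact,
                correct = TRUE))
  list(p = wt$p.value, statistic = unname(wt$statistic),
       n_used = length(nz), n_zero_dropped = length(d) - length(nz),
       exact = exact)
}

#' Per-component linear mixed model validation
#'
#' For each tested principal component: a REML linear mixed model
#' `PC ~ fixed effects + (1 | patient)` via lme4, with fixed-effect t tests
#' on residual degrees of freedom and Bonferroni correction of p-values over
#' all tested components (capped at 1). The disease-status variable is
#' treated as a factor whose first level is the reference. Setting
#' `statusVar = "disease"` and dropping controls reproduces the CD-vs-UC
#' variant.
#'
#' @param pcScores Numeric matrix, samples x components (named columns or
#'   PC index used).
#' @param meta data.frame, rownames = sample ids, with the model columns.
#' @param nPcs Number of leading components to test (Bonferroni factor).
#' @param statusVar Fixed-effect of interest (factor).
#' @param refLevel Reference level of `statusVar` (used when present); the
#'   non-IBD control group by default, so coefficients read as
#'   disease-vs-control contrasts.
#' @param covariates Further fixed-effect columns.
#' @param patientVar Random-intercept grouping column.
#' @return data.frame(pc, term, estimate, se, t, df, p, padj).
#' @export
fitPcLmm <- function(pcScores, meta, nPcs = 2, statusVar = "activity",
                     covariates = c("anti_tnf", "location"),
                     patientVar = "patient", refLevel = "non-IBD") {
  meta <- meta[rownames(pcScores), , drop = FALSE]
  meta[[statusVar]] <- factor(meta[[statusVar]])
  if (refLevel %in% levels(meta[[statusVar]])) {
    meta[[statusVar]] <- stats::relevel(meta[[statusVar]], refLevel)
  }
  if (length(unique(meta[[patientVar]])) < 2) stopf("need >= 2 patients")
  for (v in c(statusVar, covariates)) {
    if (!v %in% colnames(meta)) stopf("metadata column '%s' missing", v)
    if (length(unique(meta[[v]])) < 2) {
      stopf("factor '%s' has a single level: model is singular", v)
    }
  }
  nPcs <- min(nPcs, ncol(pcScores))
  res <- list()
  for (j in seq_len(nPcs)) {
    df <- data.frame(y = pcScores[, j], meta, check.names = FALSE)
    form <- stats::as.formula(paste(
      "y ~", paste(c(statusVar, covariates), collapse = " + "),
      "+ (1 |", patientVar, ")"))
    fit <- lme4::lmer(form, data = df, REML = TRUE)
    cf <- lme4::fixef(fit)
    vc <- as.matrix(stats::vcov(fit))
    se <- sqrt(diag(vc))
    tstat <- cf / se
    # between-within df: coefficients constant within patients are tested
    # against the patient stratum, within-patient ones against the
    # observation stratum (the classic containment approximation)
    X <- stats::model.matrix(fit)
    pat <- df[[patientVar]]
    isBetween <- apply(X, 2, function(col) {
      all(tapply(col, pat, function(v) length(unique(v)) == 1))
    })
    npat <- length(unique(pat))
    dfB <- max(npat - sum(isBetween), 1)
    dfW <- max(nrow(df) - npat - sum(!isBetween), 1)
    dfs <- ifelse(isBetween, dfB, dfW)
    dfs[1] <- dfB                                  # intercept
    p <- 2 * pt(-abs(tstat), dfs)
    res[[j]] <- data.frame(pc = j, term = names(cf),
                           estimate = unname(cf), se = unname(se),
                           t = unname(tstat), df = unname(dfs),
                           p = unname(p), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$padj <- pmin(out$p * nPcs, 1)
  rownames(out) <- NULL
  out
}
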