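#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over reference genes of
#' the ratio count / geometric-mean-across-samples, using genes with strictly
#' positive counts in every sample as the reference set.
#'
#' @param counts Nonnegative integer matrix, genes x samples.
#' @return Named positive numeric vector, one factor per sample.
#' @export
computeSizeFactors <- function(counts) {
  stopifnot(is.matrix(counts))
  allPos <- rowSums(counts <= 0) == 0
  if (!any(allPos)) stopf("cannot normalize: no gene positive in all samples")
  geo <- exp(rowMeans(log(counts[allPos, , drop = FALSE])))
  factors <- apply(counts[allPos, , drop = FALSE], 2, function(col) {
    median(col / geo)
  })
  setNames(factors, colnames(counts))
}

#' Normalized log2 expression
#'
#' Divides each sample by its median-of-ratios size factor, rescales the
#' whole matrix to a common reference depth of 1e6 (the geometric mean of
#' the normalized library sizes maps to 1e6), and applies log2(x + 1). The
#' depth standardization makes the transform — and every fold-change
#' computed from it — exactly invariant to rescaling all counts by a common
#' constant. This is the expression scale used for the linear-model
#' differential test, the cross-modal network, and the PCA underlying the
#' residual-disease score.
#'
#' @inheritParams computeSizeFactors
#' @param sizeFactors Optional precomputed factors.
#' @param referenceDepth Common depth the normalized libraries are mapped
#'   to.
#' @return Numeric matrix, genes x samples.
#' @export
normalizedLogCounts <- function(counts,
                                sizeFactors = computeSizeFactors(counts),
                                referenceDepth = 1e6) {
  x <- sweep(counts, 2, sizeFactors, "/")
  geoDepth <- exp(mean(log(colSums(x))))
  log2(x / geoDepth * referenceDepth + 1)
}

#' DEG selection thresholds
#'
#' Defaults follow the selection rule |log2FC| >= 2 with BH-adjusted
#' p < 0.05, and removal of genes with total count below 5. The fold-change
#' bound is inclusive, the alpha bound strict.
#'
#' @param lfc_up,lfc_down Fold-change bounds (lfc_up > 0 > lfc_down).
#' @param alpha Adjusted-p bound in (0, 1).
#' @param min_total_count Genes with total raw count below this are dropped
#'   before testing.
#' @return list of class `DeThresholds`.
#' @export
deThresholds <- function(lfc_up = 2, lfc_down = -2, alpha = 0.05,
                         min_total_count = 5) {
  if (!(lfc_up > 0 && 0 > lfc_down)) stopf("need lfc_up > 0 > lfc_down")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  structure(list(lfc_up = lfc_up, lfc_down = lfc_down, alpha = alpha,
                 min_total_count = min_total_count),
            class = "DeThresholds")
}

# checks each covariate column for confounding with the contrast by testing
# whether adding it to the design drops rank
.checkDesign <- function(design, labels) {
  qrX <- qr(design)
  if (qrX$rank < ncol(design)) {
    aliased <- colnames(design)[qrX$pivot[(qrX$rank + 1):ncol(design)]]
    hit <- labels[vapply(labels, function(l) any(grepl(l, aliased, fixed = TRUE)),
                         logical(1))]
    stopf("singular design: covariate '%s' is confounded with the contrast",
          if (length(hit)) hit[1] else aliased[1])
  }
}

#' Covariate-adjusted differential expression test
#'
#' An ordinary linear model per gene on log2(size-factor-normalized count
#' + 1): expression ~ contrast + covariates, with the contrast coefficient
#' tested two-sided (t test on residual degrees of freedom) and BH adjustment
#' over all tested genes. This is a documented linear-model stand-in for a
#' negative-binomial engine; externally computed DE tables with the same
#' columns can be substituted anywhere downstream.
#'
#' @param counts Genes x samples integer matrix.
#' @param meta data.frame with one row per sample (rownames = sample ids).
#' @param contrast Character pair `c(level, reference)` of values in
#'   `meta[[contrastVar]]`; log2fc > 0 means higher in `level`.
#' @param covariates Character vector of metadata columns to adjust for.
#' @param contrastVar Metadata column holding the contrast labels.
#' @param thresholds A [deThresholds()]; only `min_total_count` is used here.
#' @return data.frame with columns gene, base_mean, log2fc, p, padj.
#' @export
differentialTest <- function(counts, meta, contrast,
                             covariates = c("batch", "location"),
                             contrastVar = "activity",
                             thresholds = deThresholds()) {
  stopifnot(length(contrast) == 2)
  lev <- meta[[contrastVar]]
  if (!all(contrast %in% lev)) {
    stopf("contrast level '%s' absent from metadata",
          contrast[!contrast %in% lev][1])
  }
  keepS <- lev %in% contrast
  if (min(table(lev[keepS])) < 2) stopf("each contrast level needs >= 2 samples")
  missing <- setdiff(covariates, colnames(meta))
  if (length(missing)) stopf("covariate column '%s' missing", missing[1])

  counts <- counts[, rownames(meta)[keepS], drop = FALSE]
  metaS <- meta[keepS, , drop = FALSE]
  keepG <- rowSums(counts) >= thresholds$min_total_count
  counts <- counts[keepG, , drop = FALSE]
  expr <- normalizedLogCounts(counts)

  grp <- factor(metaS[[contrastVar]], levels = rev(contrast))
  covTerms <- covariates[vapply(covariates, function(cv) {
    length(unique(metaS[[cv]])) > 1
  }, logical(1))]
  form <- if (length(covTerms)) {
    stats::as.formula(paste("~ grp +", paste(covTerms, collapse = " + ")))
  } else {
    ~grp
  }
  design <- stats::model.matrix(form, data = cbind(metaS, grp = grp))
  .checkDesign(design, covTerms)

  fit <- stats::lm.fit(design, t(expr))
  coefIdx <- which(colnames(design) == paste0("grp", contrast[1]))
  est <- fit$coefficients[coefIdx, ]
  df <- nrow(design) - fit$rank
  rss <- colSums(fit$residuals^2)
  xtxInv <- chol2inv(chol(crossprod(design)))
  se <- sqrt(rss / df * xtxInv[coefIdx, coefIdx])
  tstat <- est / se
  p <- 2 * pt(-abs(tstat), df)
  data.frame(gene = rownames(expr),
             base_mean = rowMeans(sweep(counts, 2,
                                        computeSizeFactors(counts), "/")),
             log2fc = unname(est), p = unname(p),
             padj = p.adjust(p, "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select up- and down-regulated DEGs
#'
#' Inclusive on the fold-change bounds, strict on alpha:
#' up = \{log2fc >= lfc_up and padj < alpha\},
#' down = \{log2fc <= lfc_down and padj < alpha\}.
#'
#' @param de A DE table from [differentialTest()].
#' @param thresholds A [deThresholds()].
#' @return list(up = character, down = character).
#' @export
selectDegs <- function(de, thresholds = deThresholds()) {
  up <- de$gene[de$log2fc >= thresholds$lfc_up & de$padj < thresholds$alpha]
  down <- de$gene[de$log2fc <= thresholds$lfc_down &
                    de$padj < thresholds$alpha]
  list(up = up, down = down)
}

#' Persistent gene sets by dual-contrast overlap
#'
#' Persistent genes are differentially expressed in the same direction in
#' both the active-vs-control and the EH-vs-control contrast.
#'
#' @param upActive,downActive,upEh,downEh Character gene-id sets.
#' @return list(up, down) of intersections.
#' @export
persistentSets <- function(upActive, downActive, upEh, downEh) {
  list(up = intersect(upActive, upEh), down = intersect(downActive, downEh))
}
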