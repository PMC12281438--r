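#' Abundance/prevalence filter for zOTU tables
#'
#' A zOTU is removed only if BOTH conditions hold: its relative abundance is
#' below `minRelab` in every sample AND its prevalence (fraction of samples
#' with a nonzero count) is at most `maxPrev`. The conjunctive reading keeps
#' rare-but-concentrated taxa; `conjunctive = FALSE` switches to removal on
#' either condition.
#'
#' @param counts Integer matrix, zOTUs x samples.
#' @param minRelab Relative-abundance bound (default 0.0025, i.e. 0.25%).
#' @param maxPrev Prevalence bound (default 0.10).
#' @param conjunctive Require both conditions for removal.
#' @return Filtered count matrix (taxonomy attribute, if any, subset too).
#' @export
filterZotus <- function(counts, minRelab = 0.0025, maxPrev = 0.10,
                        conjunctive = TRUE) {
  if (ncol(counts) == 0 || nrow(counts) == 0) stopf("empty zOTU table")
  relab <- sweep(counts, 2, colSums(counts), "/")
  lowAb <- apply(relab, 1, function(r) all(r < minRelab))
  lowPrev <- rowMeans(counts > 0) <= maxPrev
  remove <- if (conjunctive) lowAb & lowPrev else lowAb | lowPrev
  out <- counts[!remove, , drop = FALSE]
  tax <- attr(counts, "taxonomy")
  if (!is.null(tax)) attr(out, "taxonomy") <- tax[rownames(out)]
  out
}

#' Centered log-ratio transform
#'
#' Per sample: counts are converted to proportions; zeros are replaced by
#' half the smallest nonzero proportion of that sample and the vector is
#' renormalized; the CLR is log(proportion) minus its per-sample mean, so
#' each sample's CLR values sum to zero. The proportion-based zero
#' replacement makes the transform exactly invariant to per-sample count
#' scaling.
#'
#' @param counts Integer matrix, zOTUs x samples.
#' @return Numeric matrix of the same dimension.
#' @export
clrTransform <- function(counts) {
  tot <- colSums(counts)
  if (any(tot == 0)) {
    stopf("sample with all-zero counts: %s",
          colnames(counts)[which(tot == 0)[1]])
  }
  apply(counts, 2, function(col) {
    p <- col / sum(col)
    nzMin <- min(p[p > 0])
    p[p == 0] <- nzMin / 2
    p <- p / sum(p)
    lp <- log(p)
    lp - mean(lp)
  })
}

#' Alpha diversity: richness and Shannon effective number
#'
#' Richness is the number of zOTUs with nonzero count; the Shannon effective
#' number is exp of the Shannon entropy of the nonzero proportions (the
#' equivalent number of equally abundant taxa).
#'
#' @param counts Integer matrix, zOTUs x samples.
#' @return data.frame(sample, richness, shannon_effective).
#' @export
alphaDiversity <- function(counts) {
  if (ncol(counts) == 0) stopf("empty zOTU table")
  tot <- colSums(counts)
  if (any(tot == 0)) {
    stopf("sample with all-zero counts: %s",
          colnames(counts)[which(tot == 0)[1]])
  }
  data.frame(
    sample = colnames(counts),
    richness = colSums(counts > 0),
    shannon_effective = apply(counts, 2, function(col) {
      p <- col[col > 0] / sum(col)
      exp(-sum(p * log(p)))
    }),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Pairwise differential abundance between groups
#'
#' Per taxon and group pair: a two-sided Wilcoxon rank-sum test on relative
#' abundances (or CLR values with `useClr`), with BH adjustment over the
#' whole taxon x pair family.
#'
#' @param counts Integer matrix, zOTUs x samples.
#' @param groups Group label per sample (column order).
#' @param useClr Test CLR values instead of relative abundances.
#' @return data.frame(taxon, group1, group2, statistic, p, padj).
#' @export
differentialAbundance <- function(counts, groups, useClr = FALSE) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stopf("need >= 2 groups")
  small <- names(which(table(groups) < 2))
  if (length(small)) stopf("group with < 2 samples: %s", small[1])
  mat <- if (useClr) clrTransform(counts) else
    sweep(counts, 2, colSums(counts), "/")
  pairs <- utils::combn(levels(droplevels(groups)), 2)
  res <- list()
  for (k in seq_len(ncol(pairs))) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    for (tx in rownames(mat)) {
      wt <- suppressWarnings(
        wilcox.test(mat[tx, groups == g1], mat[tx, groups == g2]))
      res[[length(res) + 1]] <- data.frame(
        taxon = tx, group1 = g1, group2 = g2,
        statistic = unname(wt$statistic), p = wt$p.value,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  out$padj <- p.adjust(out$p, "BH")
  out
}

#' Per-patient per-phase mean relative abundances
#'
#' For each patient and disease phase (default active and EH), the
#' arithmetic mean of each taxon's relative abundance across that patient's
#' anatomical locations. Patients missing a phase are excluded with a
#' warning.
#'
#' @param counts Integer matrix, zOTUs x samples.
#' @param meta data.frame with rownames = sample ids and columns patient and
#'   `phaseVar`.
#' @param phases Phases to summarize.
#' @param phaseVar Metadata column with phase labels.
#' @return Long data.frame(patient, phase, taxon, mean_relab).
#' @export
timeseriesPatientMeans <- function(counts, meta, phases = c("active", "EH"),
                                   phaseVar = "activity") {
  relab <- sweep(counts, 2, colSums(counts), "/")
  meta <- meta[colnames(counts), , drop = FALSE]
  patients <- unique(meta$patient)
  complete <- patients[vapply(patients, function(p) {
    all(vapply(phases, function(ph) {
      any(meta$patient == p & meta[[phaseVar]] == ph)
    }, logical(1)))
  }, logical(1))]
  dropped <- setdiff(patients[vapply(patients, function(p) {
    any(meta[[phaseVar]][meta$patient == p] %in% phases)
  }, logical(1))], complete)
  if (length(dropped)) {
    warning(sprintf("excluding %d patient(s) missing a phase: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  }
  res <- list()
  for (p in complete) {
    for (ph in phases) {
      cols <- meta$patient == p & meta[[phaseVar]] == ph
      m <- rowMeans(relab[, cols, drop = FALSE])
      res[[length(res) + 1]] <- data.frame(
        patient = p, phase = ph, taxon = names(m), mean_relab = unname(m),
        stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0) {
    return(data.frame(patient = character(), phase = character(),
                      taxon = character(), mean_relab = numeric()))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
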