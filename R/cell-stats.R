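#' Per-biopsy cluster relative frequencies
#'
#' Entry (b, c) is the number of cells of cluster c in biopsy b divided by
#' the total cell count of biopsy b; clusters absent from a biopsy get 0.
#' Every row sums to 1.
#'
#' @param cells data.frame with columns cell_id, biopsy_id, cluster.
#' @return Numeric matrix, biopsies x clusters.
#' @export
clusterFrequencies <- function(cells) {
  stopifnot(all(c("biopsy_id", "cluster") %in% colnames(cells)))
  if (nrow(cells) == 0) stopf("empty cell table")
  tab <- table(cells$biopsy_id, cells$cluster)
  empty <- rownames(tab)[rowSums(tab) == 0]
  if (length(empty)) stopf("empty biopsy: %s", paste(empty, collapse = ", "))
  freq <- sweep(unclass(tab), 1, rowSums(tab), "/")
  freq[order(rownames(freq)), order(colnames(freq)), drop = FALSE]
}

#' Percentage of a group's cells belonging to one cluster
#'
#' 100 * (cells of `cluster` within `group`) / (all cells within `group`),
#' rounded half away from zero to two decimals at reporting.
#'
#' @param cells Cell table carrying a group column (e.g. activity, joined
#'   from metadata).
#' @param cluster Cluster label.
#' @param group Group label.
#' @param groupVar Column of `cells` holding group labels.
#' @param digits Reporting precision (NULL for unrounded).
#' @return Numeric percentage.
#' @export
groupClusterPercentage <- function(cells, cluster, group,
                                   groupVar = "activity", digits = 2) {
  inGroup <- cells[[groupVar]] == group
  if (!any(inGroup)) stopf("empty group: %s", group)
  pct <- 100 * sum(inGroup & cells$cluster == cluster) / sum(inGroup)
  if (is.null(digits)) pct else roundHalfUp(pct, digits)
}

# Dunn's multiple-comparison z statistics from pooled mean ranks, with the
# standard tie correction.
.dunnPosthoc <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  ties <- table(values)
  tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
  meanRanks <- tapply(r, groups, mean)
  ns <- table(groups)
  levs <- names(meanRanks)
  pairs <- utils::combn(levs, 2)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    stringsAsFactors = FALSE)
  out$z <- mapply(function(a, b) {
    (meanRanks[a] - meanRanks[b]) /
      sqrt((N * (N + 1) / 12 - tieCorr) * (1 / ns[a] + 1 / ns[b]))
  }, out$group1, out$group2)
  out$p <- 2 * pnorm(-abs(out$z))
  out
}

#' Kruskal-Wallis with Dunn post hoc on cluster frequencies
#'
#' Per cluster: a Kruskal-Wallis test of per-biopsy relative frequencies
#' across groups, followed by Dunn's pairwise mean-rank comparisons with BH
#' adjustment applied within each cluster's pairwise family.
#'
#' @param freqs Matrix from [clusterFrequencies()], biopsies x clusters.
#' @param groups Factor/character of group labels, one per biopsy row.
#' @param adjustWithin "cluster" (default) adjusts pairwise p-values within
#'   each cluster's family; "global" adjusts across all clusters jointly.
#' @return list(kw = data.frame(cluster, statistic, p),
#'   pairwise = data.frame(cluster, group1, group2, z, p, padj)).
#' @export
compareFrequencies <- function(freqs, groups, adjustWithin = c("cluster",
                                                               "global")) {
  adjustWithin <- match.arg(adjustWithin)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stopf("need >= 2 groups")
  small <- names(which(table(groups) < 2))
  if (length(small)) stopf("group with < 2 biopsies: %s", small[1])
  kw <- do.call(rbind, lapply(colnames(freqs), function(cl) {
    k <- kruskal.test(freqs[, cl], groups)
    data.frame(cluster = cl, statistic = unname(k$statistic),
               p = k$p.value, stringsAsFactors = FALSE)
  }))
  pw <- do.call(rbind, lapply(colnames(freqs), function(cl) {
    d <- .dunnPosthoc(freqs[, cl], groups)
    cbind(cluster = cl, d)
  }))
  if (adjustWithin == "cluster") {
    pw$padj <- stats::ave(pw$p, pw$cluster, FUN = function(p) p.adjust(p, "BH"))
  } else {
    pw$padj <- p.adjust(pw$p, "BH")
  }
  rownames(pw) <- NULL
  list(kw = kw, pairwise = pw)
}
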