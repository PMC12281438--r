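#' Call paired-chain clonotypes from a contig table
#'
#' A clonotype is the exact pair of alpha- and beta-chain CDR3 nucleotide
#' sequences of a cell. Cells missing either chain are dropped; when a cell
#' carries multiple contigs of one chain, the highest-UMI contig is kept
#' (ties broken by lexicographically smallest sequence). Duplicate
#' (barcode, chain, cdr3_nt) rows are collapsed with summed UMIs and a
#' warning. Non-productive contigs are excluded unless
#' `includeNonproductive`.
#'
#' @param contigs data.frame with columns barcode, chain (TRA/TRB), cdr3_nt,
#'   umis, productive.
#' @param includeNonproductive Keep contigs flagged non-productive.
#' @return data.frame with columns cell_id, clonotype_id, cdr3a_nt, cdr3b_nt,
#'   clone_size.
#' @export
callClonotypes <- function(contigs, includeNonproductive = FALSE) {
  need <- c("barcode", "chain", "cdr3_nt", "umis", "productive")
  missing <- setdiff(need, colnames(contigs))
  if (length(missing)) stopf("contig table missing column '%s'", missing[1])
  bad <- setdiff(unique(contigs$chain), c("TRA", "TRB"))
  if (length(bad)) stopf("unknown chain label '%s'", bad[1])
  if (!includeNonproductive) contigs <- contigs[contigs$productive, ]
  if (nrow(contigs) == 0) {
    return(data.frame(cell_id = character(), clonotype_id = character(),
                      cdr3a_nt = character(), cdr3b_nt = character(),
                      clone_size = integer(), stringsAsFactors = FALSE))
  }
  key <- paste(contigs$barcode, contigs$chain, contigs$cdr3_nt, sep = "\r")
  if (anyDuplicated(key)) {
    warning("duplicate (barcode, chain, cdr3_nt) rows collapsed, UMIs summed")
    umis <- tapply(contigs$umis, key, sum)
    contigs <- contigs[!duplicated(key), ]
    contigs$umis <- as.integer(umis[paste(contigs$barcode, contigs$chain,
                                          contigs$cdr3_nt, sep = "\r")])
  }
  # best contig per (cell, chain): highest UMI, tie -> smallest sequence
  o <- order(contigs$barcode, contigs$chain, -contigs$umis, contigs$cdr3_nt)
  contigs <- contigs[o, ]
  best <- contigs[!duplicated(paste(contigs$barcode, contigs$chain)), ]
  alpha <- best[best$chain == "TRA", c("barcode", "cdr3_nt")]
  beta <- best[best$chain == "TRB", c("barcode", "cdr3_nt")]
  paired <- merge(alpha, beta, by = "barcode",
                  suffixes = c("_a", "_b"))
  if (nrow(paired) == 0) {
    return(data.frame(cell_id = character(), clonotype_id = character(),
                      cdr3a_nt = character(), cdr3b_nt = character(),
                      clone_size = integer(), stringsAsFactors = FALSE))
  }
  pairKey <- paste(paired$cdr3_nt_a, paired$cdr3_nt_b, sep = "_")
  ids <- setNames(sprintf("ct%05d", seq_along(unique(pairKey))),
                  unique(pairKey))
  sizes <- table(pairKey)
  data.frame(cell_id = paired$barcode,
             clonotype_id = unname(ids[pairKey]),
             cdr3a_nt = paired$cdr3_nt_a, cdr3b_nt = paired$cdr3_nt_b,
             clone_size = as.integer(sizes[pairKey]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Clonal expansion class counts
#'
#' For each threshold t in `thresholds`, the number of cells whose clone
#' size strictly exceeds t and the number of unique clonotypes with size > t.
#'
#' @param clonotypes Output of [callClonotypes()].
#' @param thresholds Integer expansion thresholds.
#' @return data.frame(threshold, n_cells, n_clonotypes).
#' @export
expansionSummary <- function(clonotypes, thresholds = c(1, 5, 10, 20)) {
  if (nrow(clonotypes) == 0) stopf("empty clonotype table")
  uniq <- clonotypes[!duplicated(clonotypes$clonotype_id), ]
  do.call(rbind, lapply(thresholds, function(t) {
    data.frame(threshold = t,
               n_cells = sum(clonotypes$clone_size > t),
               n_clonotypes = sum(uniq$clone_size > t))
  }))
}

#' TCR coverage per cell cluster
#'
#' Percentage of each cluster's cells that carry a called paired-chain
#' clonotype.
#'
#' @param cells Cell table (cell_id, cluster).
#' @param clonotypes Output of [callClonotypes()].
#' @return data.frame(cluster, n_cells, n_tcr, percent).
#' @export
coveragePerCluster <- function(cells, clonotypes) {
  hasTcr <- cells$cell_id %in% clonotypes$cell_id
  agg <- do.call(rbind, lapply(sort(unique(cells$cluster)), function(cl) {
    inCl <- cells$cluster == cl
    data.frame(cluster = cl, n_cells = sum(inCl),
               n_tcr = sum(inCl & hasTcr),
               stringsAsFactors = FALSE)
  }))
  agg$percent <- 100 * agg$n_tcr / agg$n_cells
  agg
}

#' Clonotypes shared across groups (Venn region counts)
#'
#' For each group, takes the set of unique clonotypes with clone size
#' >= `minSize` observed in that group, then counts every intersection
#' region: a clonotype contributes to the region of exactly the set of
#' groups containing it.
#'
#' @param clonotypes Output of [callClonotypes()].
#' @param partition Named character/factor mapping cell_id to group label.
#' @param minSize Minimal clone size ("expanded" = 2, i.e. > 1 cell).
#' @return data.frame(region, n) with `region` an `&`-joined group subset;
#'   also attribute "sets" holding the per-group clonotype sets.
#' @export
sharedClonotypes <- function(clonotypes, partition, minSize = 2) {
  lab <- partition[clonotypes$cell_id]
  if (any(is.na(lab))) {
    stopf("unlabeled cell: %s",
          clonotypes$cell_id[which(is.na(lab))[1]])
  }
  keep <- clonotypes$clone_size >= minSize
  groups <- sort(unique(as.character(partition)))
  sets <- lapply(setNames(groups, groups), function(g) {
    unique(clonotypes$clonotype_id[keep & lab == g])
  })
  uniqCt <- unique(clonotypes$clonotype_id[keep])
  membership <- matrix(FALSE, length(uniqCt), length(sets),
                       dimnames = list(uniqCt, names(sets)))
  for (g in names(sets)) membership[sets[[g]], g] <- TRUE
  regions <- apply(membership, 1, function(m) {
    paste(groups[m], collapse = "&")
  })
  regions <- regions[regions != ""]
  allRegions <- unlist(lapply(seq_along(groups), function(k) {
    apply(utils::combn(groups, k), 2, paste, collapse = "&")
  }))
  counts <- table(factor(regions, levels = allRegions))
  out <- data.frame(region = allRegions, n = as.integer(counts),
                    stringsAsFactors = FALSE)
  attr(out, "sets") <- sets
  out
}
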