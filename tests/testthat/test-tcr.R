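test_that("clonotype calling enforces pairing and contig resolution rules", {
  contigs <- rbind(
    contigRow("cellA", "TRA", "AAAA"),                 # alpha only -> dropped
    contigRow("cellB", "TRA", "CCCC"),
    contigRow("cellB", "TRB", "GGGG"),
    contigRow("cellC", "TRA", "CCCC"),
    contigRow("cellC", "TRB", "GGGG"),
    contigRow("cellD", "TRA", "TTTT"),
    contigRow("cellD", "TRB", "ACGT", umis = 7),
    contigRow("cellD", "TRB", "TGCA", umis = 3))       # lower UMI discarded
  ct <- callClonotypes(contigs)
  expect_false("cellA" %in% ct$cell_id)
  expect_equal(ct$clonotype_id[ct$cell_id == "cellB"],
               ct$clonotype_id[ct$cell_id == "cellC"])
  expect_equal(ct$clone_size[ct$cell_id == "cellB"], 2L)
  expect_equal(ct$cdr3b_nt[ct$cell_id == "cellD"], "ACGT")
  # UMI tie resolves to the lexicographically smallest sequence
  tie <- rbind(contigRow("cellE", "TRA", "GGGG", umis = 5),
               contigRow("cellE", "TRA", "AAAA", umis = 5),
               contigRow("cellE", "TRB", "CCCC"))
  expect_equal(callClonotypes(tie)$cdr3a_nt, "AAAA")
  # duplicate rows collapse with summed UMIs and a warning
  dup <- rbind(contigRow("cellF", "TRA", "AAAA", umis = 2),
               contigRow("cellF", "TRA", "AAAA", umis = 3),
               contigRow("cellF", "TRA", "CCCC", umis = 4),
               contigRow("cellF", "TRB", "GGGG"))
  expect_warning(ctF <- callClonotypes(dup), "collapsed")
  expect_equal(ctF$cdr3a_nt, "AAAA")   # 2+3 UMIs beats 4
  # non-productive contigs excluded by default
  np <- rbind(contigRow("cellG", "TRA", "AAAA", productive = FALSE),
              contigRow("cellG", "TRB", "GGGG"))
  expect_equal(nrow(callClonotypes(np)), 0)
  expect_equal(nrow(callClonotypes(np, includeNonproductive = TRUE)), 1)
})

test_that("clone sizes conserve cells and calling is idempotent", {
  fx <- tinyFixture()
  ct <- callClonotypes(contigTable(fx))
  uniq <- ct[!duplicated(ct$clonotype_id), ]
  expect_equal(sum(uniq$clone_size), nrow(ct))
  # re-calling on the retained cells' contig projection is stable
  proj <- rbind(
    data.frame(barcode = ct$cell_id, chain = "TRA", cdr3_nt = ct$cdr3a_nt,
               umis = 1L, productive = TRUE),
    data.frame(barcode = ct$cell_id, chain = "TRB", cdr3_nt = ct$cdr3b_nt,
               umis = 1L, productive = TRUE))
  ct2 <- callClonotypes(proj)
  m <- match(ct$cell_id, ct2$cell_id)
  expect_false(any(is.na(m)))
  expect_identical(paste(ct$cdr3a_nt, ct$cdr3b_nt),
                   paste(ct2$cdr3a_nt, ct2$cdr3b_nt)[m])
  expect_equal(ct$clone_size, ct2$clone_size[m])
})

test_that("expansion classes use strict thresholds and match brute force", {
  uniqCt <- data.frame(cell_id = sprintf("c%d", 1:6),
                       clonotype_id = sprintf("ct%d", 1:6),
                       clone_size = rep(1L, 6))
  es <- expansionSummary(uniqCt)
  expect_equal(es$n_cells, rep(0L, 4))
  one6 <- data.frame(cell_id = sprintf("c%d", 1:6), clonotype_id = "ct1",
                     clone_size = 6L)
  es6 <- expansionSummary(one6)
  expect_equal(es6$n_cells, c(6L, 6L, 0L, 0L))      # >1 and >5, not >10
  expect_equal(es6$n_clonotypes, c(1L, 1L, 0L, 0L))
  # random fixture vs groupby-threshold oracle; monotone in threshold
  fx <- tinyFixture()
  ct <- callClonotypes(contigTable(fx))
  es <- expansionSummary(ct)
  sizes <- table(ct$clonotype_id)
  for (i in seq_len(nrow(es))) {
    t <- es$threshold[i]
    expect_equal(es$n_cells[i], sum(sizes[sizes > t]))
    expect_equal(es$n_clonotypes[i], sum(sizes > t))
  }
  expect_true(all(diff(es$n_cells) <= 0))
  expect_true(all(diff(es$n_clonotypes) <= 0))
})

test_that("per-cluster TCR coverage equals a brute-force join", {
  fx <- tinyFixture()
  cells <- cellTable(fx)
  ct <- callClonotypes(contigTable(fx))
  cov <- coveragePerCluster(cells, ct)
  for (cl in cov$cluster[1:3]) {
    inCl <- cells$cell_id[cells$cluster == cl]
    expect_equal(cov$percent[cov$cluster == cl],
                 100 * sum(inCl %in% ct$cell_id) / length(inCl))
  }
  # saturation and empty edge cases
  expect_true(all(coveragePerCluster(
    data.frame(cell_id = ct$cell_id, cluster = "c1"), ct)$percent == 100))
  none <- ct[0, ]
  expect_true(all(coveragePerCluster(cells, none)$percent == 0))
})

test_that("shared clonotype Venn regions match enumerated sets", {
  mk <- function(cell, ct, size, grp) {
    data.frame(cell_id = cell, clonotype_id = ct, clone_size = size,
               group = grp, stringsAsFactors = FALSE)
  }
  # 3 groups; clonotypes engineered to a known Venn layout
  tab <- rbind(
    mk(c("c1", "c2"), "ctA", 2, c("g1", "g1")),        # exclusive g1
    mk(c("c3", "c4"), "ctB", 2, c("g1", "g2")),        # g1 & g2
    mk(c("c5", "c6", "c7"), "ctC", 3, c("g1", "g2", "g3")),  # all three
    mk(c("c8", "c9"), "ctD", 2, c("g3", "g3")),        # exclusive g3
    mk("c10", "ctE", 1, "g2"))                         # below minSize
  part <- setNames(tab$group, tab$cell_id)
  out <- sharedClonotypes(tab[, 1:3], part, minSize = 2)
  expected <- c("g1" = 1, "g2" = 0, "g3" = 1, "g1&g2" = 1, "g1&g3" = 0,
                "g2&g3" = 0, "g1&g2&g3" = 1)
  expect_equal(setNames(out$n, out$region), expected[out$region])
  # identity partition: full overlap
  part2 <- setNames(rep("gA", 10), tab$cell_id)
  part2[] <- ifelse(seq_len(10) %% 2 == 0, "gB", "gA")
  tab2 <- tab
  tab2$clonotype_id <- "ctZ"
  tab2$clone_size <- 10
  out2 <- sharedClonotypes(tab2[, 1:3], part2, minSize = 2)
  expect_equal(out2$n[out2$region == "gA&gB"], 1L)
  expect_equal(sum(out2$n[out2$region %in% c("gA", "gB")]), 0L)
  expect_error(sharedClonotypes(tab[, 1:3], part[-1], minSize = 2),
               "unlabeled")
})
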