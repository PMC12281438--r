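test_that("design arithmetic and labeling rules hold", {
  expect_error(generateMetadata(simConfig(n_patients_ibd = 0, n_controls = 0)),
               "empty design")
  meta <- generateMetadata(simConfig(n_patients_ibd = 10, n_controls = 2))
  expect_equal(nrow(meta), 10 * 2 * 2 + 2 * 2)
  ctrl <- meta[meta$patient_type == "control", ]
  expect_true(all(ctrl$activity == "non-IBD"))
  expect_true(all(ctrl$gradient == 0))
  # matched active biopsies sit above EH biopsies on the latent gradient
  ibd <- meta[meta$patient_type == "IBD", ]
  act <- tapply(ibd$gradient[ibd$activity == "active"],
                ibd$patient[ibd$activity == "active"], min)
  eh <- tapply(ibd$gradient[ibd$activity == "EH"],
               ibd$patient[ibd$activity == "EH"], max)
  expect_true(all(act[names(eh)] > eh))
})

test_that("fixtures are deterministic given the seed and modality-order free", {
  f1 <- simulateStudy(tinyConfig(seed = 5))
  f2 <- simulateStudy(tinyConfig(seed = 5))
  expect_identical(bulkCounts(f1), bulkCounts(f2))
  expect_identical(cellTable(f1), cellTable(f2))
  expect_identical(contigTable(f1), contigTable(f2))
  expect_identical(f1@zotuCounts, f2@zotuCounts)
  # a single modality regenerated in isolation matches the full run
  cfg <- tinyConfig(seed = 5)
  meta <- generateMetadata(cfg)
  expect_identical(generateZotuTable(meta, cfg)$counts, f1@zotuCounts)
  f3 <- simulateStudy(tinyConfig(seed = 6))
  expect_false(identical(bulkCounts(f1), bulkCounts(f3)))
})

test_that("bulk counts are NB-like with the configured baseline", {
  cfg <- tinyConfig()
  meta <- generateMetadata(cfg)
  cfgBad <- cfg
  cfgBad$nb_dispersion <- 0
  expect_error(generateBulkCounts(meta, cfgBad), "nb_dispersion")
  b <- generateBulkCounts(meta, cfg)
  expect_true(all(b$counts >= 0))
  expect_true(all(b$counts == floor(b$counts)))
  # unplanted gene control-group mean tracks the configured NB mean within 3 SE
  cfgBig <- simConfig(n_patients_ibd = 0, n_controls = 25, n_genes = 300,
                      n_persistent_up = 0, n_transient_up = 0, seed = 3)
  metaB <- generateMetadata(cfgBig)
  bb <- generateBulkCounts(metaB, cfgBig)
  w <- bb$truth$baseline_mean / sum(bb$truth$baseline_mean)
  batchFold <- ifelse(metaB$batch == "b2", 2^0.2, 1)
  mu <- outer(w, bb$truth$depth * batchFold)  # expected NB mean per gene/sample
  scaled <- bb$counts / mu                # mean 1, var (1/mu + disp) per entry
  zs <- vapply(seq_len(nrow(scaled)), function(g) {
    se <- sqrt(mean(1 / mu[g, ] + cfgBig$nb_dispersion) / ncol(scaled))
    (mean(scaled[g, ]) - 1) / se
  }, numeric(1))
  expect_gt(mean(abs(zs) <= 3), 0.97)
})

test_that("null fixture yields (almost) no persistent calls", {
  hits <- vapply(1:5, function(s) {
    cfg <- simConfig(n_patients_ibd = 6, n_controls = 3, n_genes = 300,
                     lfc_persistent = 0, lfc_transient = 0,
                     n_persistent_up = 20, n_transient_up = 20, seed = s)
    meta <- generateMetadata(cfg)
    b <- generateBulkCounts(meta, cfg)
    dA <- differentialTest(b$counts, meta, c("active", "non-IBD"))
    dE <- differentialTest(b$counts, meta, c("EH", "non-IBD"))
    sA <- selectDegs(dA)
    sE <- selectDegs(dE)
    ps <- persistentSets(sA$up, sA$down, sE$up, sE$down)
    length(ps$up) + length(ps$down)
  }, numeric(1))
  expect_lte(mean(hits), 0.01 * 300)
})

test_that("cell table respects pairing and composition rules", {
  cfg <- tinyConfig(tcr_pairing_rate = 1, extra_chain_rate = 0)
  meta <- generateMetadata(cfg)
  sc <- generateCellTable(meta, cfg)
  perCell <- table(sc$contigs$barcode, sc$contigs$chain)
  expect_true(all(perCell == 1))
  expect_setequal(rownames(perCell), sc$cells$cell_id)
  freq <- clusterFrequencies(sc$cells)
  expect_equal(unname(rowSums(freq)), rep(1, nrow(freq)))
  cfgBad <- cfg
  cfgBad$cells_per_biopsy_range <- c(0, 5)
  expect_error(generateCellTable(meta, cfgBad), "lower bound")
})

test_that("strong gradient coupling inflates the Th17-like cluster", {
  wins <- vapply(1:10, function(s) {
    cfg <- simConfig(n_patients_ibd = 4, n_controls = 3, n_genes = 20,
                     n_persistent_up = 0, n_transient_up = 0,
                     gradient_coupling = 20,
                     cells_per_biopsy_range = c(100, 200), seed = s)
    meta <- generateMetadata(cfg)
    sc <- generateCellTable(meta, cfg)
    f <- clusterFrequencies(sc$cells)
    th <- sprintf("cl%02d", cfg$th17_cluster_index)
    grp <- meta[rownames(f), "activity"]
    mean(f[grp == "active", th]) > mean(f[grp == "non-IBD", th])
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("zOTU tables carry the planted richness structure", {
  cfg <- tinyConfig()
  meta <- generateMetadata(cfg)
  cfgBad <- cfg
  cfgBad$richness_deficit <- 1.5
  expect_error(generateZotuTable(meta, cfgBad), "richness_deficit")
  z <- generateZotuTable(meta, cfg)
  expect_true(all(colSums(z$counts) == cfg$zotu_depth))
  expect_true(all(lengths(strsplit(z$taxonomy, ";")) == 6))
  wins <- vapply(1:10, function(s) {
    cfg2 <- tinyConfig(seed = s, richness_deficit = 0.5)
    m2 <- generateMetadata(cfg2)
    z2 <- generateZotuTable(m2, cfg2)
    a <- alphaDiversity(z2$counts)
    median(a$richness[m2$patient_type == "IBD"]) <
      median(a$richness[m2$patient_type == "control"])
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("fixture files round-trip through the plain-text writers", {
  fx <- tinyFixture()
  dir <- withr::local_tempdir()
  paths <- writeFixture(fx, dir)
  expect_identical(readCounts(paths[["counts"]]), bulkCounts(fx))
  meta <- readMetadata(paths[["metadata"]])
  expect_identical(meta$biopsy_id, sampleMeta(fx)$biopsy_id)
  cells <- readCells(paths[["cells"]])
  expect_identical(cells$cell_id, cellTable(fx)$cell_id)
  contigs <- readContigs(paths[["contigs"]])
  expect_identical(contigs$cdr3_nt, contigTable(fx)$cdr3_nt)
  z <- readZotus(paths[["zotus"]])
  expect_identical(unclass(z)[, ], fx@zotuCounts)
  expect_identical(attr(z, "taxonomy"), fx@taxonomy)
})
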