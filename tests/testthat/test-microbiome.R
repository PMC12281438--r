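test_that("zOTU filter removes only doubly-failing taxa", {
  n <- 20
  counts <- matrix(0L, 3, n,
                   dimnames = list(c("keepAbund", "keepPrev", "drop"),
                                   sprintf("s%d", 1:n)))
  counts["keepAbund", ] <- 10000L          # dominant everywhere: retained
  counts["keepPrev", ] <- 2L               # ~0.02% but prevalence 1
  counts["drop", ] <- 0L
  counts["drop", 1] <- 1L                  # 1/20 samples, ~0.01% there
  out <- filterZotus(counts)
  expect_setequal(rownames(out), c("keepAbund", "keepPrev"))
  # disjunctive switch removes either failure
  out2 <- filterZotus(counts, conjunctive = FALSE)
  expect_setequal(rownames(out2), "keepAbund")
  # brute-force double-condition oracle on a random fixture
  set.seed(15)
  m <- matrix(rnbinom(600, mu = 4, size = 0.3), 30, 20,
              dimnames = list(sprintf("z%02d", 1:30), sprintf("s%d", 1:20)))
  m[1, ] <- 5000L
  surv <- rownames(filterZotus(m))
  relab <- sweep(m, 2, colSums(m), "/")
  for (z in rownames(m)) {
    lowAb <- all(relab[z, ] < 0.0025)
    lowPrev <- mean(m[z, ] > 0) <= 0.10
    expect_equal(z %in% surv, !(lowAb && lowPrev))
  }
  # a taxon with max relative abundance >= the bound is never removed
  expect_true(all(apply(relab[setdiff(rownames(m), surv), , drop = FALSE],
                        1, max) < 0.0025))
})

test_that("CLR rows are centered, symmetric and scale invariant", {
  counts <- matrix(c(5L, 5L, 5L, 5L,
                     8L, 0L, 2L, 6L), 4, 2,
                   dimnames = list(sprintf("z%d", 1:4), c("s1", "s2")))
  clr <- clrTransform(counts)
  expect_equal(unname(clr[, "s1"]), rep(0, 4))     # uniform sample
  expect_lt(max(abs(colSums(clr))), 1e-10)         # centering identity
  # multiplying a sample's counts by 10 leaves its CLR unchanged
  counts10 <- counts
  counts10[, "s2"] <- counts[, "s2"] * 10L
  expect_equal(clrTransform(counts10)[, "s2"], clr[, "s2"], tolerance = 1e-12)
  # independent computation of the zero-replacement transform
  p <- counts[, "s2"] / sum(counts[, "s2"])
  p[p == 0] <- min(p[p > 0]) / 2
  p <- p / sum(p)
  expect_equal(unname(clr[, "s2"]), unname(log(p) - mean(log(p))),
               tolerance = 1e-12)
  bad <- counts
  bad[, "s2"] <- 0L
  expect_error(clrTransform(bad), "all-zero")
})

test_that("alpha diversity matches the entropy definitions", {
  counts <- matrix(0L, 8, 3, dimnames = list(sprintf("z%d", 1:8),
                                             c("uniform", "single", "mix")))
  counts[, "uniform"] <- 10L
  counts["z1", "single"] <- 50L
  counts[, "mix"] <- c(40L, 30L, 20L, 10L, 0L, 0L, 0L, 0L)
  a <- alphaDiversity(counts)
  expect_equal(a$richness, c(8, 1, 4))
  expect_equal(a$shannon_effective[1], 8)
  expect_equal(a$shannon_effective[2], 1)
  orc <- oracleAlpha(counts)
  expect_equal(a$shannon_effective, unname(orc[, "shannon"]))
  # Shannon effective <= richness, equality iff uniform
  expect_true(all(a$shannon_effective <= a$richness + 1e-12))
  expect_lt(a$shannon_effective[3], a$richness[3])
})

test_that("pairwise differential abundance matches exact rank-sum", {
  x <- c(0.12, 0.30, 0.25, 0.18)
  y <- c(0.02, 0.05, 0.09, 0.01)
  counts <- matrix(2L, 2, 8, dimnames = list(c("zA", "zB"),
                                             sprintf("s%d", 1:8)))
  counts["zA", ] <- as.integer(round(c(x, y) * 100))
  counts["zB", ] <- as.integer(100 - round(c(x, y) * 100))
  groups <- rep(c("ibd", "ctl"), each = 4)
  da <- differentialAbundance(counts, groups)
  relab <- sweep(counts, 2, colSums(counts), "/")
  expect_equal(da$p[da$taxon == "zA"],
               oracleRankSumP(relab["zA", groups == "ctl"],
                              relab["zA", groups == "ibd"]),
               tolerance = 1e-12)
  expect_equal(da$padj, oracleBH(da$p), tolerance = 1e-12)
  expect_error(differentialAbundance(counts, rep(c("a", "b"), c(7, 1))),
               "< 2 samples")
})

test_that("taxa ablated across IBD patients come out significant", {
  hits <- vapply(1:10, function(s) {
    cfg <- simConfig(n_patients_ibd = 3, n_controls = 4, n_genes = 20,
                     n_persistent_up = 0, n_transient_up = 0,
                     n_zotus = 60, richness_deficit = 0.5, seed = s)
    meta <- generateMetadata(cfg)
    z <- generateZotuTable(meta, cfg)
    universal <- Reduce(intersect, z$truth$ablated)
    if (length(universal) < 2) return(NA)
    da <- differentialAbundance(z$counts, meta$patient_type)
    mean(da$padj[da$taxon %in% universal & da$group1 == "IBD"] < 0.05) > 0.5
  }, logical(1))
  expect_gte(mean(hits, na.rm = TRUE), 0.9)
})

test_that("per-patient phase means average locations correctly", {
  counts <- matrix(10L, 2, 5,
                   dimnames = list(c("zA", "zB"),
                                   c("p1_TI_a", "p1_SC_a", "p1_TI_e",
                                     "p2_TI_a", "p2_TI_e")))
  counts["zA", ] <- c(10L, 30L, 20L, 50L, 60L)
  counts["zB", ] <- c(90L, 70L, 80L, 50L, 40L)
  meta <- data.frame(patient = c("p1", "p1", "p1", "p2", "p2"),
                     activity = c("active", "active", "EH", "active", "EH"),
                     row.names = colnames(counts))
  ts <- timeseriesPatientMeans(counts, meta)
  get <- function(p, ph, tx) ts$mean_relab[ts$patient == p &
                                             ts$phase == ph & ts$taxon == tx]
  expect_equal(get("p1", "active", "zA"), mean(c(0.1, 0.3)))  # two locations
  expect_equal(get("p1", "EH", "zA"), 0.2)                    # single sample
  expect_equal(get("p2", "active", "zA"), 0.5)
  # a patient missing a phase is excluded with a warning
  meta2 <- meta
  meta2$activity[5] <- "active"
  expect_warning(ts2 <- timeseriesPatientMeans(counts, meta2), "p2")
  expect_false("p2" %in% ts2$patient)
})

test_that("null differential abundance p-values are approximately uniform", {
  ps <- c()
  for (s in 1:10) {
    cfg <- simConfig(n_patients_ibd = 5, n_controls = 4, n_genes = 20,
                     n_persistent_up = 0, n_transient_up = 0,
                     n_zotus = 30, richness_deficit = 0, seed = s)
    meta <- generateMetadata(cfg)
    z <- generateZotuTable(meta, cfg)
    grp <- ibrd:::withSeed(3000 + s, sample(rep(c("a", "b"), length.out = nrow(meta))))
    da <- differentialAbundance(z$counts, grp)
    ps <- c(ps, da$p)
  }
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})
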