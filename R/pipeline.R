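#' Run the full residual-disease analysis pipeline
#'
#' Executes the stages in dependency order on a [StudyFixture-class] (or any
#' object providing the same accessors): size-factor normalization,
#' differential expression for active-vs-control and EH-vs-control,
#' persistent-set intersection, cluster frequencies with group tests,
#' clonotype calling and expansion summary, the cross-modal Spearman
#' network with feature selection, the IBrD model fit and training-set
#' projection, the random-signature null with one-sample Wilcoxon tests,
#' per-PC mixed-model validation, and the 16S summaries. When `outDir` is
#' given, every stage table is written as TSV/JSON together with a manifest
#' (seed, stage outputs, file checksums).
#'
#' @param fixture A [StudyFixture-class].
#' @param thresholds A [deThresholds()].
#' @param networkAlpha,networkMode,minDegree Cross-modal network settings.
#' @param varianceThreshold,span,tol,maxIter IBrD settings.
#' @param nullDraws,nullSetSize Random-signature null settings.
#' @param seed Seed for the null draws.
#' @param outDir Optional output directory.
#' @return list of stage results (invisible file paths in `$manifest` when
#'   written).
#' @export
runPipeline <- function(fixture, thresholds = deThresholds(),
                        networkAlpha = 0.05, networkMode = "fdr",
                        minDegree = 1, varianceThreshold = 0.80,
                        span = 0.6, tol = 1e-3, maxIter = 10,
                        nullDraws = 200, nullSetSize = NULL, seed = 1L,
                        outDir = NULL) {
  stopifnot(methods::is(fixture, "StudyFixture"))
  t0 <- Sys.time()
  counts <- bulkCounts(fixture)
  meta <- sampleMeta(fixture)
  cells <- cellTable(fixture)

  deActive <- differentialTest(counts, meta, c("active", "non-IBD"),
                               thresholds = thresholds)
  deEh <- differentialTest(counts, meta, c("EH", "non-IBD"),
                           thresholds = thresholds)
  degActive <- selectDegs(deActive, thresholds)
  degEh <- selectDegs(deEh, thresholds)
  persistent <- persistentSets(degActive$up, degActive$down,
                               degEh$up, degEh$down)

  freqs <- clusterFrequencies(cells)
  freqGroups <- meta[rownames(freqs), "activity"]
  freqTests <- compareFrequencies(freqs, freqGroups)

  clonotypes <- callClonotypes(contigTable(fixture))
  expansion <- expansionSummary(clonotypes)

  expr <- normalizedLogCounts(counts)
  matched <- matchSamples(colnames(expr), rownames(freqs))
  sigInput <- persistent$up
  if (length(sigInput) < 2) stopf("fewer than 2 persistent genes: no signature")
  sp <- spearmanBipartite(expr[sigInput, matched, drop = FALSE],
                          t(freqs[matched, , drop = FALSE]))
  net <- thresholdNetwork(sp$rho, sp$p, mode = networkMode,
                          alpha = networkAlpha, n = length(matched))
  signature <- selectFeatures(net, "A", minDegree = minDegree)
  if (length(signature) < 2) signature <- sigInput

  model <- fitIbrd(expr, meta, signature,
                   varianceThreshold = varianceThreshold,
                   span = span, tol = tol, maxIter = maxIter)
  scores <- projectSamples(model, expr)

  pool <- unique(c(degActive$up, degActive$down, degEh$up, degEh$down))
  if (is.null(nullSetSize)) nullSetSize <- min(81, length(signature))
  nullTab <- if (length(pool) >= nullSetSize && nullDraws > 0) {
    randomSignatureNull(expr, meta$activity, pool, nDraws = nullDraws,
                        setSize = nullSetSize, seed = seed)
  } else {
    NULL
  }
  sigPca <- suppressWarnings(fitPca(expr[signature, , drop = FALSE]))
  sigDist <- centroidDistances(sigPca$scores, meta$activity, "non-IBD")
  wilcoxon <- if (!is.null(nullTab)) {
    lapply(setNames(names(sigDist), names(sigDist)), function(g) {
      oneSampleWilcoxon(nullTab$distance[nullTab$group == g], sigDist[[g]])$p
    })
  } else {
    NULL
  }
  lmm <- fitPcLmm(sigPca$scores, meta, nPcs = 2)

  zc <- filterZotus(zotuTable(fixture))
  alpha <- alphaDiversity(zc)
  clr <- clrTransform(zc)

  res <- list(de_active = deActive, de_eh = deEh, persistent = persistent,
              frequencies = freqs, freq_tests = freqTests,
              clonotypes = clonotypes, expansion = expansion,
              network = net, signature = signature, model = model,
              scores = scores, null_distances = nullTab,
              signature_distances = sigDist, wilcoxon = wilcoxon,
              lmm = lmm, zotus_filtered = zc, alpha_diversity = alpha,
              clr = clr)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    wtsv <- function(df, name) {
      f <- file.path(outDir, name)
      write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
      f
    }
    files <- c(
      wtsv(deActive, "de_active_vs_control.tsv"),
      wtsv(deEh, "de_eh_vs_control.tsv"),
      wtsv(data.frame(gene = persistent$up), "persistent_up.txt"),
      wtsv(data.frame(gene = persistent$down), "persistent_down.txt"),
      wtsv(data.frame(biopsy_id = rownames(freqs), freqs,
                      check.names = FALSE), "frequencies.tsv"),
      wtsv(freqTests$pairwise, "freq_tests.tsv"),
      wtsv(clonotypes, "clonotypes.tsv"),
      wtsv(expansion, "expansion_summary.tsv"),
      wtsv(networkEdges(net), "network.tsv"),
      wtsv(data.frame(gene = signature), "selected_features.txt"),
      wtsv(scores, "scores.tsv"),
      wtsv(lmm, "lmm_results.tsv"),
      wtsv(alpha, "alpha.tsv"))
    if (!is.null(nullTab)) files <- c(files, wtsv(nullTab, "null_distances.tsv"))
    saveIbrdModel(model, file.path(outDir, "model.json"))
    files <- c(files, file.path(outDir, "model.json"))
    manifest <- list(
      seed = seed,
      elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      outputs = basename(files),
      checksums = as.list(tools::md5sum(files)))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    res$manifest <- manifest
  }
  res
}
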