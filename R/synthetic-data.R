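#' Simulation configuration for the synthetic multi-modal cohort
#'
#' Returns a validated configuration list. Defaults emulate the study design
#' the pipeline targets: paediatric IBD patients biopsied at two sites
#' (terminal ileum TI, sigmoid colon SC) at an active baseline and an
#' endoscopically healed (EH) follow-up, plus non-IBD controls biopsied once
#' per site. A latent per-biopsy disease gradient g (controls 0, EH
#' Uniform(0.2, 0.6), active Uniform(0.6, 1.0)) couples a Th17-like cell
#' cluster to a designated subset of the planted persistent genes, which is
#' what the cross-modal network and the principal-curve score are meant to
#' recover.
#'
#' @param n_patients_ibd,n_controls Patient numbers. IBD patients contribute
#'   `length(locations) * timepoints_per_patient` biopsies; controls one
#'   biopsy per location.
#' @param locations Site labels.
#' @param timepoints_per_patient Longitudinal depth; timepoint 1 is labelled
#'   "active", later timepoints "EH".
#' @param n_genes,n_persistent_up,n_transient_up Gene-panel sizes. Persistent
#'   genes are up-regulated in active AND EH biopsies, transient genes only
#'   in active ones.
#' @param lfc_persistent,lfc_transient Planted log2 fold-changes.
#' @param coupled_fraction Fraction of persistent genes whose expression
#'   additionally scales with the latent gradient.
#' @param nb_dispersion Negative-binomial dispersion alpha
#'   (variance = mu + alpha * mu^2).
#' @param library_size_range Sequencing depth range; depths are log-uniform.
#' @param n_clusters Number of T-cell clusters.
#' @param dirichlet_base Dirichlet concentration per cluster; by default 5
#'   everywhere except 0.5 at the Th17-like cluster, keeping it rare in
#'   controls.
#' @param th17_cluster_index Index of the gradient-coupled cluster.
#' @param gradient_coupling Coupling strength: the Th17 concentration is
#'   inflated by `(1 + gradient_coupling * g)` and coupled genes gain
#'   `gradient_coupling / 4` log2 units of expression per unit gradient.
#' @param cells_per_biopsy_range Uniform range of cells per biopsy.
#' @param tcr_pairing_rate Per-chain probability that a cell yields a contig.
#' @param extra_chain_rate Probability of a spurious additional contig of a
#'   chain already present in a cell.
#' @param clone_size_tail Power-law exponent (> 1) of the clone-size
#'   distribution.
#' @param n_zotus,zotu_depth,richness_deficit zOTU panel size, fixed
#'   sequencing depth per sample, and the fraction of taxa ablated (set to
#'   zero probability) in each IBD patient, persisting across timepoints.
#' @param seed Master integer seed; all modality substreams derive from it.
#' @return A list of class `SimConfig`.
#' @export
simConfig <- function(n_patients_ibd = 13, n_controls = 4,
                      locations = c("TI", "SC"),
                      timepoints_per_patient = 2,
                      n_genes = 2000, n_persistent_up = 60,
                      n_transient_up = 60,
                      lfc_persistent = 3, lfc_transient = 3,
                      coupled_fraction = 0.5,
                      nb_dispersion = 0.1,
                      library_size_range = c(5e5, 2e6),
                      n_clusters = 12,
                      dirichlet_base = NULL,
                      th17_cluster_index = 11,
                      gradient_coupling = 8,
                      cells_per_biopsy_range = c(300, 900),
                      tcr_pairing_rate = 0.85,
                      extra_chain_rate = 0.05,
                      clone_size_tail = 2.5,
                      n_zotus = 300, zotu_depth = 20000,
                      richness_deficit = 0.3,
                      seed = 1L) {
  if (is.null(dirichlet_base)) {
    dirichlet_base <- rep(5, n_clusters)
    dirichlet_base[th17_cluster_index] <- 0.5
  }
  cfg <- list(
    n_patients_ibd = n_patients_ibd, n_controls = n_controls,
    locations = locations, timepoints_per_patient = timepoints_per_patient,
    n_genes = n_genes, n_persistent_up = n_persistent_up,
    n_transient_up = n_transient_up,
    lfc_persistent = lfc_persistent, lfc_transient = lfc_transient,
    coupled_fraction = coupled_fraction,
    nb_dispersion = nb_dispersion,
    library_size_range = library_size_range,
    n_clusters = n_clusters, dirichlet_base = dirichlet_base,
    th17_cluster_index = th17_cluster_index,
    gradient_coupling = gradient_coupling,
    cells_per_biopsy_range = cells_per_biopsy_range,
    tcr_pairing_rate = tcr_pairing_rate,
    extra_chain_rate = extra_chain_rate,
    clone_size_tail = clone_size_tail,
    n_zotus = n_zotus, zotu_depth = zotu_depth,
    richness_deficit = richness_deficit,
    seed = as.integer(seed)
  )
  counts <- c("n_patients_ibd", "n_controls", "timepoints_per_patient",
              "n_genes", "n_persistent_up", "n_transient_up", "n_clusters",
              "n_zotus")
  for (f in counts) {
    if (cfg[[f]] < 0) stopf("%s must be >= 0", f)
  }
  for (f in c("tcr_pairing_rate", "extra_chain_rate", "richness_deficit",
              "coupled_fraction")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stopf("%s must be in [0, 1]", f)
  }
  if (cfg$th17_cluster_index > cfg$n_clusters) {
    stopf("th17_cluster_index must be <= n_clusters")
  }
  if (cfg$n_persistent_up + cfg$n_transient_up > cfg$n_genes) {
    stopf("planted gene sets exceed n_genes")
  }
  if (length(cfg$dirichlet_base) != cfg$n_clusters ||
      any(cfg$dirichlet_base <= 0)) {
    stopf("dirichlet_base must give a positive value per cluster")
  }
  if (cfg$gradient_coupling < 0) stopf("gradient_coupling must be >= 0")
  if (cfg$clone_size_tail <= 1) stopf("clone_size_tail must be > 1")
  class(cfg) <- "SimConfig"
  cfg
}

#' Generate the biopsy-level study design
#'
#' One row per biopsy: IBD patients contribute one biopsy per location at
#' each timepoint (timepoint 1 "active", later "EH"); controls contribute one
#' per location, labelled "non-IBD". The latent disease gradient is drawn
#' here (per biopsy) and carried in column `gradient`; downstream modality
#' generators and the ground-truth record read it from there, while the
#' fixture writer keeps it out of the observable metadata file.
#'
#' @param config A [simConfig()] object.
#' @return data.frame with columns biopsy_id, patient, patient_type, disease,
#'   timepoint, location, activity, batch, age_bin, gender, anti_tnf,
#'   gradient.
#' @export
generateMetadata <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  if (config$n_patients_ibd == 0 && config$n_controls == 0) {
    stopf("empty design: no patients and no controls")
  }
  withSeed(substreamSeed(config$seed, "metadata"), {
    rows <- list()
    ageLevels <- c("<6", "6-12", ">12")
    mkPatient <- function(id, type) {
      list(patient = id, type = type,
           disease = if (type == "IBD") {
             sample(c("CD", "UC"), 1, prob = c(0.7, 0.3))
           } else "none",
           batch = sample(c("b1", "b2"), 1),
           age_bin = sample(ageLevels, 1, prob = c(0.15, 0.45, 0.4)),
           gender = sample(c("f", "m"), 1),
           anti_tnf = if (type == "IBD") runif(1) < 0.7 else FALSE)
    }
    for (i in seq_len(config$n_patients_ibd)) {
      p <- mkPatient(sprintf("P%02d", i), "IBD")
      for (t in seq_len(config$timepoints_per_patient)) {
        act <- if (t == 1) "active" else "EH"
        for (loc in config$locations) {
          g <- if (act == "active") runif(1, 0.6, 1.0) else runif(1, 0.2, 0.6)
          rows[[length(rows) + 1]] <- data.frame(
            biopsy_id = sprintf("%s_%s_T%d", p$patient, loc, t),
            patient = p$patient, patient_type = "IBD", disease = p$disease,
            timepoint = t, location = loc, activity = act,
            batch = p$batch, age_bin = p$age_bin, gender = p$gender,
            anti_tnf = p$anti_tnf, gradient = g,
            stringsAsFactors = FALSE)
        }
      }
    }
    for (i in seq_len(config$n_controls)) {
      p <- mkPatient(sprintf("C%02d", i), "control")
      for (loc in config$locations) {
        rows[[length(rows) + 1]] <- data.frame(
          biopsy_id = sprintf("%s_%s_T1", p$patient, loc),
          patient = p$patient, patient_type = "control", disease = "none",
          timepoint = 1, location = loc, activity = "non-IBD",
          batch = p$batch, age_bin = p$age_bin, gender = p$gender,
          anti_tnf = FALSE, gradient = 0,
          stringsAsFactors = FALSE)
      }
    }
    meta <- do.call(rbind, rows)
    rownames(meta) <- meta$biopsy_id
    meta
  })
}

#' Generate negative-binomial bulk counts with planted signal
#'
#' Gene baseline abundances are log-normal; per-sample depths log-uniform
#' over `library_size_range`. Persistent genes are multiplied by
#' `2^lfc_persistent` in active and EH biopsies, transient genes by
#' `2^lfc_transient` in active biopsies only, and the gradient-coupled subset
#' of persistent genes additionally by `2^(gradient_coupling/4 * g)`. A
#' scalar batch offset (2^0.2 for batch "b2") exercises covariate
#' correction. Counts are NB with dispersion `nb_dispersion`.
#'
#' @param meta Output of [generateMetadata()].
#' @param config A [simConfig()].
#' @param seed Integer seed (defaults to the config substream).
#' @return list(counts = integer matrix genes x biopsies, truth = list).
#' @export
generateBulkCounts <- function(meta, config,
                               seed = substreamSeed(config$seed, "bulk")) {
  stopifnot(inherits(config, "SimConfig"))
  if (nrow(meta) == 0) stopf("empty design: no biopsies")
  if (config$nb_dispersion <= 0) stopf("nb_dispersion must be > 0")
  withSeed(seed, {
    nG <- config$n_genes
    genes <- sprintf("g%04d", seq_len(nG))
    persistent <- genes[seq_len(config$n_persistent_up)]
    transient <- genes[config$n_persistent_up +
                         seq_len(config$n_transient_up)]
    nCoupled <- round(config$coupled_fraction * length(persistent))
    coupled <- persistent[seq_len(nCoupled)]

    baseline <- exp(rnorm(nG, mean = log(50), sd = 1))
    names(baseline) <- genes
    w <- baseline / sum(baseline)
    depth <- exp(runif(nrow(meta), log(config$library_size_range[1]),
                       log(config$library_size_range[2])))
    counts <- matrix(0L, nG, nrow(meta),
                     dimnames = list(genes, meta$biopsy_id))
    for (s in seq_len(nrow(meta))) {
      fold <- rep(1, nG)
      names(fold) <- genes
      act <- meta$activity[s]
      if (act %in% c("active", "EH")) {
        fold[persistent] <- fold[persistent] * 2^config$lfc_persistent
      }
      if (act == "active") {
        fold[transient] <- fold[transient] * 2^config$lfc_transient
      }
      g <- meta$gradient[s]
      if (length(coupled) && g > 0) {
        fold[coupled] <- fold[coupled] * 2^(config$gradient_coupling / 4 * g)
      }
      if (meta$batch[s] == "b2") fold <- fold * 2^0.2
      mu <- w * depth[s] * fold
      counts[, s] <- as.integer(rnbinom(nG, mu = mu,
                                        size = 1 / config$nb_dispersion))
    }
    list(counts = counts,
         truth = list(persistent_up = persistent, transient_up = transient,
                      coupled = coupled,
                      gradient = setNames(meta$gradient, meta$biopsy_id),
                      baseline_mean = baseline, depth = depth))
  })
}

# draws one clone size from a discrete power law P(s) proportional to s^-a
.rcloneSizes <- function(n, a, maxSize = 60) {
  s <- seq_len(maxSize)
  p <- s^(-a)
  sample(s, n, replace = TRUE, prob = p / sum(p))
}

.randSeq <- function(n) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), sample(30:45, 1), replace = TRUE),
          collapse = "")
  }, character(1))
}

#' Generate the single-cell annotation and TCR contig tables
#'
#' Per biopsy, the cell count is uniform over `cells_per_biopsy_range` and
#' cluster assignment is Dirichlet-multinomial with the Th17-like cluster's
#' concentration inflated by `1 + gradient_coupling * g`. Cells are grouped
#' into clones with power-law sizes; cells of a clone share alpha/beta CDR3
#' nucleotide sequences. Each chain is observed with probability
#' `tcr_pairing_rate`; spurious extra chains occur at `extra_chain_rate`.
#'
#' @inheritParams generateBulkCounts
#' @return list(cells = data.frame, contigs = data.frame,
#'   truth = list(clone_sizes)).
#' @export
generateCellTable <- function(meta, config,
                              seed = substreamSeed(config$seed, "cells")) {
  stopifnot(inherits(config, "SimConfig"))
  if (nrow(meta) == 0) stopf("empty design: no biopsies")
  if (config$cells_per_biopsy_range[1] < 1) {
    stopf("cells_per_biopsy_range lower bound must be >= 1")
  }
  withSeed(seed, {
    cellRows <- list()
    contigRows <- list()
    cloneSizes <- integer()
    clusterLabels <- sprintf("cl%02d", seq_len(config$n_clusters))
    for (s in seq_len(nrow(meta))) {
      nCells <- sample(seq(config$cells_per_biopsy_range[1],
                           config$cells_per_biopsy_range[2]), 1)
      alpha <- config$dirichlet_base
      alpha[config$th17_cluster_index] <-
        alpha[config$th17_cluster_index] *
        (1 + config$gradient_coupling * meta$gradient[s])
      gam <- rgamma(config$n_clusters, shape = alpha)
      probs <- gam / sum(gam)
      cl <- sample(clusterLabels, nCells, replace = TRUE, prob = probs)
      ids <- sprintf("%s_c%04d", meta$biopsy_id[s], seq_len(nCells))
      cellRows[[s]] <- data.frame(cell_id = ids,
                                  biopsy_id = meta$biopsy_id[s],
                                  cluster = cl, stringsAsFactors = FALSE)
      # clone structure: fill the biopsy with clones of power-law size
      sizes <- integer()
      while (sum(sizes) < nCells) {
        sizes <- c(sizes, .rcloneSizes(max(16L, nCells %/% 4L),
                                       config$clone_size_tail))
      }
      nClones <- which(cumsum(sizes) >= nCells)[1]
      sizes <- sizes[seq_len(nClones)]
      sizes[nClones] <- nCells - sum(sizes[-nClones])
      sizes <- sizes[sizes > 0]
      cloneSizes <- c(cloneSizes, sizes)
      cloneOfCell <- rep(seq_along(sizes), sizes)
      cdr3a <- .randSeq(length(sizes))
      cdr3b <- .randSeq(length(sizes))
      for (chain in c("TRA", "TRB")) {
        present <- runif(nCells) < config$tcr_pairing_rate
        if (!any(present)) next
        seqs <- if (chain == "TRA") cdr3a else cdr3b
        main <- data.frame(
          barcode = ids[present], biopsy_id = meta$biopsy_id[s],
          chain = chain, cdr3_nt = seqs[cloneOfCell[present]],
          umis = rpois(sum(present), 10) + 1L, productive = TRUE,
          stringsAsFactors = FALSE)
        contigRows[[length(contigRows) + 1]] <- main
        extra <- runif(sum(present)) < config$extra_chain_rate
        if (any(extra)) {
          contigRows[[length(contigRows) + 1]] <- data.frame(
            barcode = ids[present][extra], biopsy_id = meta$biopsy_id[s],
            chain = chain, cdr3_nt = .randSeq(sum(extra)),
            umis = rpois(sum(extra), 3) + 1L, productive = TRUE,
            stringsAsFactors = FALSE)
        }
      }
    }
    cells <- do.call(rbind, cellRows)
    contigs <- if (length(contigRows)) {
      do.call(rbind, contigRows)
    } else {
      data.frame(barcode = character(), biopsy_id = character(),
                 chain = character(), cdr3_nt = character(),
                 umis = integer(), productive = logical())
    }
    rownames(cells) <- NULL
    rownames(contigs) <- NULL
    list(cells = cells, contigs = contigs,
         truth = list(clone_sizes = cloneSizes))
  })
}

#' Generate the zOTU count table
#'
#' Taxon abundances are log-normal; each IBD patient has a fixed random
#' `richness_deficit` fraction of taxa ablated (probability zero) in all of
#' that patient's samples across timepoints. Counts are multinomial at fixed
#' depth `zotu_depth`. Taxonomy strings carry 6 semicolon-delimited ranks.
#'
#' @inheritParams generateBulkCounts
#' @return list(counts = integer matrix zOTUs x biopsies,
#'   taxonomy = named character, truth = list(ablated per patient)).
#' @export
generateZotuTable <- function(meta, config,
                              seed = substreamSeed(config$seed, "zotus")) {
  stopifnot(inherits(config, "SimConfig"))
  if (nrow(meta) == 0) stopf("empty design: no biopsies")
  if (config$richness_deficit < 0 || config$richness_deficit > 1) {
    stopf("richness_deficit must be in [0, 1]")
  }
  withSeed(seed, {
    nZ <- config$n_zotus
    ids <- sprintf("zOTU%04d", seq_len(nZ))
    base <- setNames(exp(rnorm(nZ, 0, 1.5)), ids)
    phyla <- c("Firmicutes", "Bacteroidota", "Proteobacteria",
               "Actinobacteriota", "Verrucomicrobiota")
    taxonomy <- setNames(vapply(seq_len(nZ), function(i) {
      paste(c("Bacteria", sample(phyla, 1), sprintf("Class%02d", i %% 20),
              sprintf("Order%02d", i %% 30), sprintf("Family%02d", i %% 40),
              sprintf("Genus%03d", i)), collapse = ";")
    }, character(1)), ids)
    patients <- unique(meta$patient[meta$patient_type == "IBD"])
    nAblate <- round(config$richness_deficit * nZ)
    ablated <- lapply(setNames(patients, patients), function(p) {
      sample(ids, nAblate)
    })
    counts <- matrix(0L, nZ, nrow(meta),
                     dimnames = list(ids, meta$biopsy_id))
    for (s in seq_len(nrow(meta))) {
      p <- base
      if (meta$patient_type[s] == "IBD") {
        p[ablated[[meta$patient[s]]]] <- 0
      }
      counts[, s] <- rmultinom(1, config$zotu_depth, p)[, 1]
    }
    list(counts = counts, taxonomy = taxonomy,
         truth = list(ablated = ablated))
  })
}

#' Simulate the full multi-modal study fixture
#'
#' Runs all modality generators on one design and assembles a
#' [StudyFixture-class]. Deterministic given `config$seed`; each modality
#' draws from its own named substream so generation order is immaterial.
#'
#' @param config A [simConfig()].
#' @return A `StudyFixture`.
#' @examples
#' fx <- simulateStudy(simConfig(n_patients_ibd = 2, n_controls = 1,
#'                               n_genes = 50, n_persistent_up = 5,
#'                               n_transient_up = 5, n_zotus = 40,
#'                               cells_per_biopsy_range = c(30, 60)))
#' fx
#' @export
simulateStudy <- function(config = simConfig()) {
  meta <- generateMetadata(config)
  bulk <- generateBulkCounts(meta, config)
  sc <- generateCellTable(meta, config)
  zo <- generateZotuTable(meta, config)
  metaVisible <- meta[, setdiff(colnames(meta), "gradient")]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = bulk$counts),
    colData = S4Vectors::DataFrame(metaVisible, row.names = meta$biopsy_id))
  methods::new("StudyFixture",
    bulk = se, cells = sc$cells, contigs = sc$contigs,
    zotuCounts = zo$counts, taxonomy = zo$taxonomy,
    truth = c(bulk$truth, sc$truth, zo$truth, list(config = config)))
}

#' Write a StudyFixture to plain-text files
#'
#' Emits counts.tsv (genes x samples), metadata.tsv, cells.tsv, contigs.csv,
#' zotus.tsv (first column zOTU id, last column taxonomy) and truth.json
#' under `dir`.
#'
#' @param fixture A [StudyFixture-class].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of file paths written.
#' @export
writeFixture <- function(fixture, dir) {
  stopifnot(methods::is(fixture, "StudyFixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cts <- bulkCounts(fixture)
  countsDf <- data.frame(gene_id = rownames(cts), cts, check.names = FALSE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    cells = file.path(dir, "cells.tsv"),
    contigs = file.path(dir, "contigs.csv"),
    zotus = file.path(dir, "zotus.tsv"),
    truth = file.path(dir, "truth.json"))
  write.table(countsDf, paths["counts"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sampleMeta(fixture), paths["metadata"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cellTable(fixture), paths["cells"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  utils::write.csv(contigTable(fixture), paths["contigs"], quote = FALSE,
                   row.names = FALSE)
  zc <- fixture@zotuCounts
  zotuDf <- data.frame(zotu_id = rownames(zc), zc,
                       taxonomy = fixture@taxonomy[rownames(zc)],
                       check.names = FALSE)
  write.table(zotuDf, paths["zotus"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- truthRecord(fixture)
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
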