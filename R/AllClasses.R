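#' @import methods
#' @importFrom stats median cor sd prcomp p.adjust pt rnbinom rgamma rmultinom
#'   rpois runif rnorm rbinom kruskal.test wilcox.test pnorm quantile setNames
#'   var complete.cases ks.test
#' @importFrom utils read.delim write.table read.csv head
NULL

#' StudyFixture: a synthetic multi-modal IBD cohort
#'
#' Container produced by [simulateStudy()]. Bulk counts and biopsy metadata
#' live in a [SummarizedExperiment::SummarizedExperiment] (genes x biopsies);
#' the single-cell annotation table, TCR contig table and zOTU count table are
#' plain data frames / matrices keyed by the same biopsy identifiers. The
#' `truth` list records every planted entity (persistent / transient /
#' gradient-coupled gene ids, the per-sample latent disease gradient, planted
#' clone sizes, per-patient ablated zOTUs) for parameter-recovery tests.
#'
#' @slot bulk SummarizedExperiment with assay `counts` and biopsy colData.
#' @slot cells data.frame with columns cell_id, biopsy_id, cluster.
#' @slot contigs data.frame with columns barcode, biopsy_id, chain, cdr3_nt,
#'   umis, productive.
#' @slot zotuCounts integer matrix, zOTUs x biopsies.
#' @slot taxonomy named character vector of semicolon-delimited 6-rank
#'   taxonomy strings, one per zOTU.
#' @slot truth list of planted ground truth.
#'
#' @exportClass StudyFixture
setClass("StudyFixture",
  representation(
    bulk = "ANY",
    cells = "data.frame",
    contigs = "data.frame",
    zotuCounts = "matrix",
    taxonomy = "character",
    truth = "list"
  )
)

setValidity("StudyFixture", function(object) {
  msg <- character()
  se <- object@bulk
  if (!methods::is(se, "SummarizedExperiment")) {
    return("bulk must be a SummarizedExperiment")
  }
  cts <- SummarizedExperiment::assay(se, "counts")
  if (any(cts < 0) || any(cts != floor(cts))) {
    msg <- c(msg, "bulk counts must be nonnegative integers")
  }
  ids <- colnames(se)
  if (nrow(object@cells) && !all(object@cells$biopsy_id %in% ids)) {
    msg <- c(msg, "cells reference biopsies absent from metadata")
  }
  if (ncol(object@zotuCounts) && !all(colnames(object@zotuCounts) %in% ids)) {
    msg <- c(msg, "zOTU samples absent from metadata")
  }
  g <- object@truth$gradient
  if (!is.null(g)) {
    meta <- as.data.frame(SummarizedExperiment::colData(se))
    ctrl <- meta$activity == "non-IBD"
    if (any(g[ids[ctrl]] != 0)) msg <- c(msg, "control gradient must be 0")
  }
  if (length(msg)) msg else TRUE
})

#' BipartiteNetwork: thresholded cross-modal Spearman network
#'
#' Spearman coefficient, p-value and adjusted p-value matrices between two
#' feature sets (rows = modality A features, columns = modality B features)
#' plus the adjacency matrix in which non-significant coefficients are set to
#' zero. Entries undefined because a feature was constant are NA and are
#' excluded from the multiple-testing family.
#'
#' @slot rho,p,padj,adjacency numeric matrices of identical dimension.
#' @slot mode "fdr" (zero where BH-adjusted p > alpha) or "nominal"
#'   (zero where raw p >= alpha).
#' @slot alpha significance bound.
#' @slot n number of matched samples used.
#'
#' @exportClass BipartiteNetwork
setClass("BipartiteNetwork",
  representation(
    rho = "matrix", p = "matrix", padj = "matrix", adjacency = "matrix",
    mode = "character", alpha = "numeric", n = "integer"
  )
)

setValidity("BipartiteNetwork", function(object) {
  msg <- character()
  if (!all(dim(object@rho) == dim(object@p)) ||
      !all(dim(object@rho) == dim(object@adjacency))) {
    msg <- c(msg, "matrix dimensions differ")
  }
  ok <- !is.na(object@rho)
  if (any(abs(object@rho[ok]) > 1 + 1e-12)) {
    msg <- c(msg, "|rho| must be <= 1 where defined")
  }
  okp <- !is.na(object@p) & !is.na(object@padj)
  if (any(object@padj[okp] < object@p[okp] - 1e-12)) {
    msg <- c(msg, "padj must be >= p elementwise")
  }
  nz <- !is.na(object@adjacency) & object@adjacency != 0
  if (any(object@adjacency[nz] != object@rho[nz])) {
    msg <- c(msg, "nonzero adjacency entries must equal rho")
  }
  if (!object@mode %in% c("fdr", "nominal")) msg <- c(msg, "invalid mode")
  if (length(msg)) msg else TRUE
})

#' IbrdModel: frozen principal-curve residual-disease scoring model
#'
#' Everything needed to score new samples: the signature gene list with the
#' training means/SDs used for standardization, the PCA rotation and explained
#' variance proportions, the number of components k retained (smallest number
#' explaining the variance threshold), the fitted principal-curve polyline
#' with cumulative arc-lengths, the training pseudotime extrema used for
#' min/max normalization, and the orientation flag (+1 keeps arc-length
#' direction, -1 flips so that controls score low).
#'
#' @slot geneIds character signature gene ids.
#' @slot means,sds numeric per-gene standardization parameters (training).
#' @slot rotation numeric matrix, genes x components (orthonormal columns).
#' @slot explained numeric variance proportions per component (sums to 1).
#' @slot k integer number of components used for the trajectory.
#' @slot vertices numeric matrix of polyline vertices in k-dim PC space.
#' @slot arclength numeric cumulative arc-length at each vertex.
#' @slot tMin,tMax numeric training pseudotime extrema.
#' @slot orientation +1 or -1.
#' @slot trainingScores named numeric IBrD values of the training samples.
#' @slot fitConfig list of fitting parameters (variance threshold, span,
#'   tol, max iterations).
#'
#' @exportClass IbrdModel
setClass("IbrdModel",
  representation(
    geneIds = "character", means = "numeric", sds = "numeric",
    rotation = "matrix", explained = "numeric", k = "integer",
    vertices = "matrix", arclength = "numeric",
    tMin = "numeric", tMax = "numeric", orientation = "numeric",
    trainingScores = "numeric", fitConfig = "list"
  )
)

setValidity("IbrdModel", function(object) {
  msg <- character()
  r <- object@rotation
  if (nrow(r) != length(object@geneIds)) {
    msg <- c(msg, "rotation rows must match signature genes")
  }
  if (max(abs(crossprod(r) - diag(ncol(r)))) > 1e-8) {
    msg <- c(msg, "rotation columns must be orthonormal")
  }
  if (abs(sum(object@explained) - 1) > 1e-8) {
    msg <- c(msg, "explained proportions must sum to 1")
  }
  if (any(object@sds <= 0)) msg <- c(msg, "sds must be positive")
  if (object@tMin >= object@tMax) msg <- c(msg, "tMin must be < tMax")
  if (is.unsorted(object@arclength)) {
    msg <- c(msg, "arc-lengths must be non-decreasing")
  }
  if (!object@orientation %in% c(-1, 1)) msg <- c(msg, "orientation not +-1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "StudyFixture", function(object) {
  se <- object@bulk
  cat("StudyFixture\n")
  cat(sprintf("  bulk:    %d genes x %d biopsies\n", nrow(se), ncol(se)))
  cat(sprintf("  cells:   %d cells, %d clusters\n", nrow(object@cells),
              length(unique(object@cells$cluster))))
  cat(sprintf("  contigs: %d rows\n", nrow(object@contigs)))
  cat(sprintf("  zOTUs:   %d taxa x %d samples\n", nrow(object@zotuCounts),
              ncol(object@zotuCounts)))
  cat(sprintf("  truth:   %s\n", paste(names(object@truth), collapse = ", ")))
})

setMethod("show", "BipartiteNetwork", function(object) {
  nz <- sum(object@adjacency != 0, na.rm = TRUE)
  cat(sprintf("BipartiteNetwork: %d x %d features, n = %d samples\n",
              nrow(object@rho), ncol(object@rho), object@n))
  cat(sprintf("  mode = %s, alpha = %g, %d edges retained\n",
              object@mode, object@alpha, nz))
})

setMethod("show", "IbrdModel", function(object) {
  cat(sprintf("IbrdModel: %d signature genes, k = %d components (%.1f%% var)\n",
              length(object@geneIds), object@k,
              100 * sum(object@explained[seq_len(object@k)])))
  cat(sprintf("  polyline: %d vertices, pseudotime range [%.4g, %.4g]\n",
              nrow(object@vertices), object@tMin, object@tMax))
  cat(sprintf("  orientation: %+d (controls low), %d training samples\n",
              as.integer(object@orientation), length(object@trainingScores)))
})

# ---- accessors -------------------------------------------------------------

#' @describeIn StudyFixture-accessors Bulk gene x biopsy count matrix.
#' @export
bulkCounts <- function(x) {
  stopifnot(methods::is(x, "StudyFixture"))
  SummarizedExperiment::assay(x@bulk, "counts")
}

#' Accessors for StudyFixture components
#'
#' @param x A `StudyFixture`.
#' @return The requested component.
#' @name StudyFixture-accessors
NULL

#' @describeIn StudyFixture-accessors Biopsy metadata as a data.frame.
#' @export
sampleMeta <- function(x) {
  stopifnot(methods::is(x, "StudyFixture"))
  as.data.frame(SummarizedExperiment::colData(x@bulk))
}

#' @describeIn StudyFixture-accessors Cell-level annotation table.
#' @export
cellTable <- function(x) {
  stopifnot(methods::is(x, "StudyFixture"))
  x@cells
}

#' @describeIn StudyFixture-accessors TCR contig table.
#' @export
contigTable <- function(x) {
  stopifnot(methods::is(x, "StudyFixture"))
  x@contigs
}

#' @describeIn StudyFixture-accessors zOTU counts with taxonomy attribute.
#' @export
zotuTable <- function(x) {
  stopifnot(methods::is(x, "StudyFixture"))
  structure(x@zotuCounts, taxonomy = x@taxonomy)
}

#' @describeIn StudyFixture-accessors Planted ground-truth record.
#' @export
truthRecord <- function(x) {
  stopifnot(methods::is(x, "StudyFixture"))
  x@truth
}

#' Accessors for BipartiteNetwork and IbrdModel
#'
#' `networkAdjacency()`, `networkRho()`, `networkPadj()` return the matrices
#' of a [BipartiteNetwork-class]; `signatureGenes()` and `trainingScores()`
#' read an [IbrdModel-class].
#'
#' @param x The object.
#' @name model-accessors
NULL

#' @rdname model-accessors
#' @export
networkAdjacency <- function(x) {
  stopifnot(methods::is(x, "BipartiteNetwork"))
  x@adjacency
}

#' @rdname model-accessors
#' @export
networkRho <- function(x) {
  stopifnot(methods::is(x, "BipartiteNetwork"))
  x@rho
}

#' @rdname model-accessors
#' @export
networkPadj <- function(x) {
  stopifnot(methods::is(x, "BipartiteNetwork"))
  x@padj
}

#' @rdname model-accessors
#' @export
signatureGenes <- function(x) {
  stopifnot(methods::is(x, "IbrdModel"))
  x@geneIds
}

#' @rdname model-accessors
#' @export
trainingScores <- function(x) {
  stopifnot(methods::is(x, "IbrdModel"))
  x@trainingScores
}
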