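#' Match samples across two modalities
#'
#' @param idsA,idsB Character vectors of biopsy ids (or data.frames with a
#'   `biopsy_id` column).
#' @return Sorted intersection of ids.
#' @export
matchSamples <- function(idsA, idsB) {
  pick <- function(x) if (is.data.frame(x)) x$biopsy_id else x
  m <- sort(intersect(pick(idsA), pick(idsB)))
  if (length(m) == 0) stopf("no matched samples between modalities")
  m
}

#' Bipartite Spearman correlation
#'
#' Average-rank Spearman correlation between every row of `X` and every row
#' of `Y` over matched sample columns, with two-sided p-values from the t
#' approximation t = rho * sqrt((n-2)/(1-rho^2)) on n-2 degrees of freedom.
#' Constant rows yield NA entries with a warning.
#'
#' @param X,Y Numeric matrices, features x samples, identical sample order.
#' @return list(rho, p) of featuresX x featuresY matrices.
#' @export
spearmanBipartite <- function(X, Y) {
  if (ncol(X) != ncol(Y)) stopf("sample columns differ between modalities")
  n <- ncol(X)
  if (n < 4) stopf("too few matched samples (n = %d, need >= 4)", n)
  constX <- apply(X, 1, function(r) length(unique(r)) == 1)
  constY <- apply(Y, 1, function(r) length(unique(r)) == 1)
  if (any(constX) || any(constY)) {
    warning(sprintf("%d constant feature row(s): correlations undefined (NA)",
                    sum(constX) + sum(constY)))
  }
  rX <- t(apply(X, 1, rank))
  rY <- t(apply(Y, 1, rank))
  # Pearson on average ranks == Spearman rho
  rXc <- rX - rowMeans(rX)
  rYc <- rY - rowMeans(rY)
  denom <- tcrossprod(sqrt(rowSums(rXc^2)), sqrt(rowSums(rYc^2)))
  rho <- tcrossprod(rXc, rYc) / denom
  rho[constX, ] <- NA
  rho[, constY] <- NA
  rho <- pmin(pmax(rho, -1), 1)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), n - 2)
  dimnames(rho) <- dimnames(p) <- list(rownames(X), rownames(Y))
  list(rho = rho, p = p)
}

#' Threshold a bipartite correlation matrix into a network
#'
#' In mode "fdr", BH adjustment is applied jointly over all defined feature
#' pairs and coefficients with adjusted p > alpha are set to zero (strictly
#' greater, so pairs at exactly alpha are kept). In mode "nominal",
#' coefficients with raw p >= alpha are zeroed while adjusted p-values are
#' still reported. Undefined (NA) pairs are excluded from the BH family.
#'
#' @param rho,p Matrices from [spearmanBipartite()].
#' @param mode "fdr" or "nominal".
#' @param alpha Significance bound.
#' @param n Number of matched samples (metadata for the object).
#' @return A [BipartiteNetwork-class].
#' @export
thresholdNetwork <- function(rho, p, mode = c("fdr", "nominal"),
                             alpha = 0.05, n = NA_integer_) {
  mode <- match.arg(mode)
  stopifnot(all(dim(rho) == dim(p)))
  padj <- p
  ok <- !is.na(p)
  padj[ok] <- p.adjust(p[ok], "BH")
  adjacency <- rho
  drop <- if (mode == "fdr") padj > alpha else p >= alpha
  adjacency[ok & drop] <- 0
  adjacency[!ok] <- NA
  methods::new("BipartiteNetwork", rho = rho, p = p, padj = padj,
               adjacency = adjacency, mode = mode, alpha = alpha,
               n = as.integer(n))
}

#' Select connected features from a thresholded network
#'
#' Features on one side with at least `minDegree` nonzero adjacency entries,
#' ordered by degree (descending) then maximal |rho| (descending).
#'
#' @param net A [BipartiteNetwork-class].
#' @param side "A" (rows) or "B" (columns).
#' @param minDegree Minimal number of retained edges (>= 1).
#' @return Character vector of feature names.
#' @export
selectFeatures <- function(net, side = c("A", "B"), minDegree = 1) {
  side <- match.arg(side)
  if (minDegree < 1) stopf("minDegree must be >= 1")
  adj <- networkAdjacency(net)
  if (side == "B") adj <- t(adj)
  nz <- !is.na(adj) & adj != 0
  degree <- rowSums(nz)
  maxRho <- apply(abs(adj), 1, function(r) {
    if (all(is.na(r))) 0 else max(r, na.rm = TRUE)
  })
  keep <- degree >= minDegree
  ord <- order(-degree[keep], -maxRho[keep])
  rownames(adj)[keep][ord]
}

#' Long-form edge table of a network
#'
#' @param net A [BipartiteNetwork-class].
#' @param keptOnly Drop zeroed/undefined pairs.
#' @return data.frame(feature_A, feature_B, rho, p, padj, kept).
#' @export
networkEdges <- function(net, keptOnly = FALSE) {
  rho <- networkRho(net)
  out <- data.frame(
    feature_A = rep(rownames(rho), times = ncol(rho)),
    feature_B = rep(colnames(rho), each = nrow(rho)),
    rho = as.vector(rho), p = as.vector(net@p),
    padj = as.vector(networkPadj(net)),
    kept = as.vector(!is.na(networkAdjacency(net)) &
                       networkAdjacency(net) != 0),
    stringsAsFactors = FALSE)
  if (keptOnly) out[out$kept, ] else out
}
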