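#' Scaled PCA of a signature expression matrix
#'
#' Centers (and by default scales to unit variance) each gene across samples
#' and decomposes with [stats::prcomp]. Zero-variance genes are dropped with
#' a warning before fitting.
#'
#' @param expr Numeric matrix, signature genes x samples.
#' @param scale Scale genes to unit variance.
#' @return list(geneIds, means, sds, rotation (genes x components),
#'   explained (variance proportions), scores (samples x components)).
#' @export
fitPca <- function(expr, scale = TRUE) {
  if (ncol(expr) < 3) stopf("need >= 3 samples for PCA")
  if (nrow(expr) < 2) stopf("need >= 2 genes for PCA")
  v <- apply(expr, 1, var)
  if (any(v == 0)) {
    warning(sprintf("dropping %d zero-variance gene(s)", sum(v == 0)))
    expr <- expr[v > 0, , drop = FALSE]
  }
  pc <- prcomp(t(expr), center = TRUE, scale. = scale)
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  list(geneIds = rownames(expr),
       means = setNames(pc$center, rownames(expr)),
       sds = if (scale) setNames(pc$scale, rownames(expr)) else
         setNames(rep(1, nrow(expr)), rownames(expr)),
       rotation = pc$rotation, explained = explained, scores = pc$x)
}

#' Number of components reaching a cumulative variance threshold
#'
#' @param explained Variance proportions (summing to ~1).
#' @param threshold Cumulative proportion to reach (default 0.80).
#' @return Smallest k with cumsum(explained)[k] >= threshold.
#' @export
chooseK <- function(explained, threshold = 0.80) {
  if (length(explained) == 0) stopf("empty explained-variance vector")
  which(cumsum(explained) >= threshold - 1e-12)[1]
}

# orthogonal projection of points (n x k) onto a polyline (m x k);
# returns arc-length positions, squared distances and the projected points.
# Ties across segments resolve to the smaller arc-length because strict
# improvement is required to move.
.projectToPolyline <- function(points, vertices, arclength) {
  n <- nrow(points)
  bestD2 <- rep(Inf, n)
  bestT <- numeric(n)
  bestPt <- matrix(0, n, ncol(points))
  for (i in seq_len(nrow(vertices) - 1)) {
    a <- vertices[i, ]
    d <- vertices[i + 1, ] - a
    len2 <- sum(d^2)
    if (len2 == 0) next
    rel <- sweep(points, 2, a)
    tt <- pmin(pmax((rel %*% d) / len2, 0), 1)[, 1]
    proj <- outer(tt, d) + rep(a, each = n)
    d2 <- rowSums((points - proj)^2)
    better <- d2 < bestD2 - 1e-12
    bestD2[better] <- d2[better]
    bestT[better] <- arclength[i] + tt[better] * sqrt(len2)
    bestPt[better, ] <- proj[better, , drop = FALSE]
  }
  if (nrow(vertices) == 1) {
    bestD2 <- rowSums(sweep(points, 2, vertices[1, ])^2)
    bestT <- rep(0, n)
    bestPt <- matrix(rep(vertices[1, ], each = n), n)
  }
  list(lambda = bestT, d2 = bestD2, projected = bestPt)
}

# local-linear smoother of y against x at the sample positions (lowess with
# robustness iterations off); handles duplicate x by averaging fits.
.smoothCoord <- function(x, y, span) {
  fit <- stats::lowess(x, y, f = span, iter = 0)
  # lowess returns values at sorted unique-ish x; map back to input order
  stats::approx(fit$x, fit$y, xout = x, rule = 2, ties = mean)$y
}

#' Fit a principal curve by projection-smoothing iteration
#'
#' Hastie-Stuetzle iteration: initialize pseudotimes from the first
#' principal component line, then alternate (i) smoothing each coordinate
#' against arc-length with a fixed-span local-linear smoother, (ii)
#' reparameterizing the smoothed polyline by cumulative arc-length, and
#' (iii) orthogonally projecting all points back onto it. Iteration stops
#' when the relative change of the total squared orthogonal distance falls
#' below `tol`, `maxIter` is reached, or the objective would increase (the
#' previous, better curve is then returned, so the objective is
#' non-increasing across accepted iterations).
#'
#' @param points Numeric matrix, n x k (samples in reduced space), n >= 5.
#' @param span Smoother span (fraction of points in each local fit).
#' @param tol Relative convergence tolerance on the objective.
#' @param maxIter Maximum iterations.
#' @return list(vertices, arclength, lambda (per-point pseudotime), d2
#'   (total squared orthogonal distance), iterations, objective (per
#'   accepted iteration)).
#' @export
principalCurve <- function(points, span = 0.6, tol = 1e-3, maxIter = 10) {
  points <- as.matrix(points)
  if (nrow(points) < 5) stopf("need >= 5 points for a principal curve")
  if (!all(is.finite(points))) stopf("non-finite input points")
  n <- nrow(points)

  ctr <- colMeans(points)
  centered <- sweep(points, 2, ctr)
  v1 <- svd(centered, nu = 0, nv = 1)$v[, 1]
  lambda <- centered %*% v1
  lambda <- lambda[, 1]

  makeCurve <- function(lambda) {
    o <- order(lambda)
    sm <- vapply(seq_len(ncol(points)), function(j) {
      .smoothCoord(lambda[o], points[o, j], span)
    }, numeric(n))
    if (!is.matrix(sm)) sm <- matrix(sm, nrow = n)
    # drop consecutive duplicate vertices
    keep <- c(TRUE, rowSums(abs(diff(sm))) > 1e-12)
    verts <- sm[keep, , drop = FALSE]
    seg <- sqrt(rowSums(diff(verts)^2))
    list(vertices = verts, arclength = c(0, cumsum(seg)))
  }

  curve <- makeCurve(lambda)
  pr <- .projectToPolyline(points, curve$vertices, curve$arclength)
  objective <- sum(pr$d2)
  history <- objective
  lambda <- pr$lambda
  iter <- 1L
  while (iter < maxIter) {
    cand <- makeCurve(lambda)
    prC <- .projectToPolyline(points, cand$vertices, cand$arclength)
    objC <- sum(prC$d2)
    if (objC > objective + 1e-12) break   # keep the better previous curve
    improved <- (objective - objC) / max(objective, .Machine$double.eps)
    curve <- cand
    pr <- prC
    objective <- objC
    lambda <- pr$lambda
    history <- c(history, objective)
    iter <- iter + 1L
    if (improved < tol) break
  }
  list(vertices = curve$vertices, arclength = curve$arclength,
       lambda = setNames(pr$lambda, rownames(points)),
       d2 = objective, iterations = iter, objective = history)
}

#' Fit the IBrD residual-disease scoring model
#'
#' Composes the scoring pipeline: scaled PCA on the signature genes, choice
#' of the smallest k components explaining `varianceThreshold` of the
#' variance, a principal curve through the k-dimensional scores, and
#' pseudotime min/max-normalization to [0, 1]. Orientation is flipped when
#' the control group's mean pseudotime is at the high end, so that 0 means
#' "no residual disease" and 1 "active inflammation". Training scores span
#' exactly [0, 1].
#'
#' @param expr Numeric expression matrix (genes x samples), normalized log
#'   scale.
#' @param meta data.frame with rownames = sample ids.
#' @param signature Character gene ids (must be present in `expr`).
#' @param varianceThreshold Cumulative explained-variance target for k.
#' @param span,tol,maxIter Principal-curve settings, see [principalCurve()].
#' @param controlLabel Value of `groupVar` marking controls (orientation
#'   anchor).
#' @param groupVar Metadata column holding activity labels.
#' @param orientBy Optional numeric vector (named by sample) overriding the
#'   control-based orientation: the curve is oriented so pseudotime
#'   correlates positively with it.
#' @return An [IbrdModel-class]; training scores via [trainingScores()].
#' @export
fitIbrd <- function(expr, meta, signature, varianceThreshold = 0.80,
                    span = 0.6, tol = 1e-3, maxIter = 10,
                    controlLabel = "non-IBD", groupVar = "activity",
                    orientBy = NULL) {
  missing <- setdiff(signature, rownames(expr))
  if (length(missing)) {
    stopf("signature genes missing from expression matrix: %s",
          paste(head(missing, 5), collapse = ", "))
  }
  pca <- fitPca(expr[signature, , drop = FALSE], scale = TRUE)
  k <- chooseK(pca$explained, varianceThreshold)
  crv <- principalCurve(pca$scores[, seq_len(k), drop = FALSE],
                        span = span, tol = tol, maxIter = maxIter)
  lambda <- crv$lambda
  isCtrl <- meta[colnames(expr), groupVar] == controlLabel
  orientation <- if (!is.null(orientBy)) {
    if (cor(lambda, orientBy[colnames(expr)]) >= 0) 1 else -1
  } else if (any(isCtrl) && any(!isCtrl)) {
    if (mean(lambda[isCtrl]) <= mean(lambda[!isCtrl])) 1 else -1
  } else {
    stopf("no control samples: supply orientBy to orient the trajectory")
  }
  tMin <- min(lambda)
  tMax <- max(lambda)
  if (tMin >= tMax) stopf("degenerate trajectory: all pseudotimes equal")
  scores <- (lambda - tMin) / (tMax - tMin)
  if (orientation < 0) scores <- 1 - scores
  methods::new("IbrdModel",
    geneIds = pca$geneIds, means = pca$means, sds = pca$sds,
    rotation = pca$rotation, explained = pca$explained, k = as.integer(k),
    vertices = crv$vertices, arclength = crv$arclength,
    tMin = tMin, tMax = tMax, orientation = orientation,
    trainingScores = scores,
    fitConfig = list(varianceThreshold = varianceThreshold, span = span,
                     tol = tol, maxIter = maxIter,
                     controlLabel = controlLabel))
}

#' Project new samples onto a frozen IBrD model
#'
#' New samples are standardized with the stored training means/SDs, rotated
#' with the stored rotation, truncated to the stored k components,
#' orthogonally projected onto the stored polyline (nearest point; ties to
#' the smaller arc-length) and normalized with the stored training
#' pseudotime extrema. Scores are not clamped: values outside [0, 1] are
#' reported as-is with `out_of_range = TRUE`.
#'
#' @param model An [IbrdModel-class].
#' @param exprNew Numeric matrix (genes x samples) on the training
#'   expression scale.
#' @return data.frame(sample, score, pseudotime, out_of_range).
#' @export
projectSamples <- function(model, exprNew) {
  stopifnot(methods::is(model, "IbrdModel"))
  missing <- setdiff(model@geneIds, rownames(exprNew))
  if (length(missing)) {
    stopf("model genes missing from new data: %s",
          paste(head(missing, 5), collapse = ", "))
  }
  x <- exprNew[model@geneIds, , drop = FALSE]
  if (!all(is.finite(x))) stopf("non-finite values in new expression data")
  z <- (x - model@means) / model@sds
  scoresNew <- t(z) %*% model@rotation[, seq_len(model@k), drop = FALSE]
  pr <- .projectToPolyline(scoresNew, model@vertices, model@arclength)
  s <- (pr$lambda - model@tMin) / (model@tMax - model@tMin)
  if (model@orientation < 0) s <- 1 - s
  data.frame(sample = colnames(exprNew), score = s,
             pseudotime = pr$lambda,
             out_of_range = s < 0 | s > 1,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Serialize an IBrD model to JSON
#'
#' Full-precision, lossless round trip: `readIbrdModel(saveIbrdModel(m, f))`
#' reproduces projection scores bit-identically.
#'
#' @param model An [IbrdModel-class].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
saveIbrdModel <- function(model, path) {
  stopifnot(methods::is(model, "IbrdModel"))
  obj <- list(
    gene_ids = model@geneIds,
    means = unname(model@means), sds = unname(model@sds),
    rotation = list(values = as.vector(model@rotation),
                    nrow = nrow(model@rotation),
                    ncol = ncol(model@rotation)),
    explained = model@explained, k = model@k,
    vertices = list(values = as.vector(model@vertices),
                    nrow = nrow(model@vertices),
                    ncol = ncol(model@vertices)),
    arclength = model@arclength,
    t_min = model@tMin, t_max = model@tMax,
    orientation = model@orientation,
    training_scores = as.list(model@trainingScores),
    fit_config = model@fitConfig)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname saveIbrdModel
#' @export
readIbrdModel <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  methods::new("IbrdModel",
    geneIds = o$gene_ids,
    means = setNames(o$means, o$gene_ids),
    sds = setNames(o$sds, o$gene_ids),
    rotation = matrix(o$rotation$values, o$rotation$nrow, o$rotation$ncol,
                      dimnames = list(o$gene_ids, NULL)),
    explained = o$explained, k = as.integer(o$k),
    vertices = matrix(o$vertices$values, o$vertices$nrow, o$vertices$ncol),
    arclength = o$arclength, tMin = o$t_min, tMax = o$t_max,
    orientation = o$orientation,
    trainingScores = unlist(o$training_scores),
    fitConfig = o$fit_config)
}
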