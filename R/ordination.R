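.centeredMatrix <- function(x, scaling = "none") {
  # individuals x SNPs double matrix: impute column means for missing, center
  # at twice the allele frequency (the column mean), optional scaling
  g <- t(dosages(x)) * 1.0
  mu <- colMeans(g, na.rm = TRUE)
  if (anyNA(mu)) stop("SNP with no called genotype: ",
                      colnames(g)[which(is.na(mu))[1]])
  idx <- which(is.na(g))
  if (length(idx)) g[idx] <- mu[(idx - 1) %/% nrow(g) + 1]
  g <- sweep(g, 2, mu)
  if (scaling != "none") {
    s <- switch(scaling,
                unit = apply(g, 2, sd),
                patterson = { p <- mu / 2; sqrt(p * (1 - p)) },
                stop("unknown scaling: ", scaling))
    pos <- s > 0
    g[, pos] <- sweep(g[, pos, drop = FALSE], 2, s[pos], "/")
    g[, !pos] <- 0
  }
  attr(g, "center") <- mu
  g
}

.canonicalSigns <- function(scores, loadings) {
  # axis sign fixed so the largest-magnitude loading is positive
  for (k in seq_len(ncol(loadings))) {
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  list(scores = scores, loadings = loadings)
}

#' Principal component analysis of individual genotypes
#'
#' Columns (SNPs) are centered at twice the mean allele frequency; missing
#' dosages are imputed at the column mean before centering. Eigenvalues are
#' squared singular values divided by n - 1, scores are the projections of
#' individuals, loadings the per-SNP axis weights, and variance fractions
#' eigenvalue shares of the total variance.
#'
#' @param x a GenotypePanel with >= 2 individuals and >= 1 polymorphic SNP.
#' @param scaling "none" (default), "unit" (unit variance) or "patterson"
#'   (divide by sqrt(p(1-p))).
#' @param nAxes number of axes to keep (default: all with nonzero variance).
#' @return an [OrdinationResult-class].
#' @export
pcaGenotypes <- function(x, scaling = c("none", "unit", "patterson"),
                         nAxes = NULL) {
  scaling <- match.arg(scaling)
  if (ncol(x) < 2) stop("at least two individuals are required")
  g <- .centeredMatrix(x, scaling)
  res <- .pcaCore(g, nAxes)
  new("OrdinationResult", eigenvalues = res$eigenvalues, scores = res$scores,
      loadings = res$loadings, varFraction = res$varFraction,
      center = attr(g, "center"),
      method = c("pca", scaling), extra = list())
}

.pcaCore <- function(g, nAxes = NULL) {
  n <- nrow(g)
  sv <- svd(g)
  eig <- sv$d^2 / (n - 1)
  keep <- which(eig > max(eig) * 1e-12)
  if (!is.null(nAxes)) keep <- keep[seq_len(min(nAxes, length(keep)))]
  tot <- sum(eig)
  scores <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], length(keep))
  loadings <- sv$v[, keep, drop = FALSE]
  rownames(scores) <- rownames(g)
  rownames(loadings) <- colnames(g)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_along(keep))
  cs <- .canonicalSigns(scores, loadings)
  list(eigenvalues = eig[keep], scores = cs$scores, loadings = cs$loadings,
       varFraction = eig[keep] / tot, totalVariance = tot)
}

#' Between-breed principal component analysis
#'
#' PCA of the breed-mean rows of the centered individual matrix, each breed
#' weighted by its sample size, so the axes maximize the between-breed
#' variance. The between/within/total Huygens decomposition is exact under
#' the shared n - 1 divisor, and the reported \code{variancePartition} is
#' the between-breed share of the total individual variance. Individuals
#' are projected onto the between-breed axes.
#'
#' @inheritParams pcaGenotypes
#' @return an [OrdinationResult-class]; \code{extra(variancePartition)} is
#'   the between-breed variance fraction, \code{extra(breedScores)} the
#'   breed-mean coordinates, and \code{varFraction} is per-axis share of the
#'   TOTAL variance.
#' @export
betweenBreedPca <- function(x, scaling = c("none", "unit", "patterson"),
                            nAxes = NULL) {
  scaling <- match.arg(scaling)
  br <- breeds(x)
  if (length(unique(br)) < 2) stop("at least two breeds are required")
  g <- .centeredMatrix(x, scaling)
  n <- nrow(g)
  sums <- rowsum(g, br)
  w <- as.vector(table(br)[rownames(sums)])
  means <- sums / w
  # weighted PCA of breed means: eigen of sum_b n_b m_b m_b' / (n - 1)
  sv <- svd(means * sqrt(w))
  eig <- sv$d^2 / (n - 1)
  keep <- which(eig > max(eig) * 1e-12)
  if (!is.null(nAxes)) keep <- keep[seq_len(min(nAxes, length(keep)))]
  totalVar <- sum(g^2) / (n - 1)
  betweenVar <- sum(eig)
  loadings <- sv$v[, keep, drop = FALSE]
  rownames(loadings) <- colnames(g)
  # flip signs once so the largest-magnitude loading per axis is positive
  flip <- vapply(seq_along(keep), function(k) {
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) -1 else 1
  }, numeric(1))
  loadings <- sweep(loadings, 2, flip, "*")
  scores <- g %*% loadings
  breedScores <- means %*% loadings
  rownames(scores) <- rownames(g)
  colnames(scores) <- colnames(loadings) <- colnames(breedScores) <-
    paste0("bcPC", seq_along(keep))
  new("OrdinationResult", eigenvalues = eig[keep], scores = scores,
      loadings = loadings, varFraction = eig[keep] / totalVar,
      center = attr(g, "center"), method = c("betweenBreedPca", scaling),
      extra = list(variancePartition = betweenVar / totalVar,
                   betweenVariance = betweenVar, totalVariance = totalVar,
                   breedScores = breedScores))
}

#' Absolute correlation between axes of two ordinations
#'
#' Axis-by-axis absolute Pearson correlation between the SNP loading
#' vectors of two ordinations computed on the same SNP set.
#'
#' @param a,b [OrdinationResult-class] objects with identical SNP sets.
#' @param k number of leading axes to compare.
#' @return numeric vector of length k.
#' @export
compareAxes <- function(a, b, k) {
  if (k > ncol(a@loadings) || k > ncol(b@loadings))
    stop("k exceeds the available axes")
  if (!identical(rownames(a@loadings), rownames(b@loadings)))
    stop("ordinations use different SNP sets")
  vapply(seq_len(k), function(i)
    abs(cor(a@loadings[, i], b@loadings[, i])), numeric(1))
}

#' Replace SNP columns by their short-range LD regression residuals
#'
#' Each centered SNP column is replaced by its residual from a no-intercept
#' least-squares regression on up to \code{nPred} preceding SNPs on the map,
#' each required to lie within \code{windowBp} of the focal SNP. Original
#' (uncorrected) columns serve as predictors. The first SNP of every
#' chromosome is unchanged; rank-deficient predictor sets fall back to the
#' usable subspace via a pivoted QR.
#'
#' @param x a GenotypePanel (map sorted by construction).
#' @param windowBp maximum predictor distance in base pairs.
#' @param nPred number of preceding SNPs used.
#' @return the corrected individuals x SNPs numeric matrix (centered).
#' @export
ldResidualCorrection <- function(x, windowBp = 200000, nPred = 2) {
  g <- .centeredMatrix(x, "none")
  info <- snpInfo(x)
  out <- g
  for (j in seq_len(ncol(g))) {
    prev <- which(info$chrom == info$chrom[j] & seq_len(ncol(g)) < j)
    prev <- prev[info$pos[j] - info$pos[prev] < windowBp]
    prev <- utils::tail(prev, nPred)
    if (!length(prev)) next
    Z <- g[, prev, drop = FALSE]
    qrz <- qr(Z)
    out[, j] <- qr.resid(qrz, g[, j])
  }
  attr(out, "center") <- attr(g, "center")
  out
}

#' Gaussian dispersion ellipse of 2-D scores
#'
#' Assuming the cloud is a sample from a bivariate normal, returns the
#' ellipse containing a point with probability \code{coverage}: center at
#' the mean, semi-axes sqrt(chi2_2(coverage) * eigenvalues of the sample
#' covariance), orientation from the leading eigenvector.
#'
#' @param scores2d numeric matrix with two columns, >= 3 rows.
#' @param coverage nominal coverage probability.
#' @return list(center, semiAxes, angle, cov, coverage); \code{angle} in
#'   radians from the first coordinate axis.
#' @export
dispersionEllipse <- function(scores2d, coverage = 0.9) {
  scores2d <- as.matrix(scores2d)
  if (nrow(scores2d) < 3 || ncol(scores2d) != 2)
    stop("need >= 3 points in two dimensions")
  ctr <- colMeans(scores2d)
  S <- cov(scores2d)
  if (det(S) <= 0) stop("singular covariance")
  e <- eigen(S, symmetric = TRUE)
  r2 <- qchisq(coverage, df = 2)
  list(center = ctr, semiAxes = sqrt(r2 * e$values),
       angle = atan2(e$vectors[2, 1], e$vectors[1, 1]),
       cov = S, coverage = coverage)
}

#' @rdname dispersionEllipse
#' @param points numeric matrix of 2-D points to test.
#' @param ellipse result of \code{dispersionEllipse}.
#' @return \code{ellipseCoverage}: the fraction of points inside the ellipse.
#' @export
ellipseCoverage <- function(points, ellipse) {
  md <- mahalanobis(as.matrix(points), ellipse$center, ellipse$cov)
  mean(md <= qchisq(ellipse$coverage, df = 2))
}
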