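#' @import methods
#' @importFrom stats var cov cor sd dist rbinom rbeta runif rnorm qchisq
#'   mahalanobis setNames smooth.spline predict plogis
#' @importFrom utils read.table write.table head combn
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' GenotypePanel: diploid biallelic SNP genotypes with map and breed labels
#'
#' The central data container of the package. It extends
#' \link[SummarizedExperiment]{SummarizedExperiment} with rows = SNPs and
#' columns = individuals. The single assay \code{"dosage"} holds integer
#' counts (0, 1, 2) of the designated alternate allele, with
#' \code{NA_integer_} as the missing-genotype sentinel. Row metadata carries
#' the SNP map (\code{chrom}, \code{pos}, and optionally the reference and
#' alternate allele characters); column metadata carries the breed code of
#' every individual.
#'
#' Validity requires: dosages in \{0, 1, 2, NA\}; unique SNP and sample
#' identifiers; positions strictly increasing within each chromosome (the
#' constructor sorts rows by chromosome and position); a non-missing breed
#' for every sample.
#'
#' @seealso [GenotypePanel()] for construction, [dosages()], [breeds()],
#'   [snpInfo()] for access.
#' @name GenotypePanel-class
#' @aliases GenotypePanel-class
#' @exportClass GenotypePanel
setClass("GenotypePanel", contains = "SummarizedExperiment")

setValidity("GenotypePanel", function(object) {
  msg <- character()
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    return("assay 'dosage' is required")
  d <- assay(object, "dosage")
  if (!is.integer(d))
    msg <- c(msg, "dosage assay must be integer storage")
  bad <- d[!is.na(d)]
  if (length(bad) && !all(bad %in% 0:2))
    msg <- c(msg, "dosages must be in {0, 1, 2, NA}")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "SNP ids must be unique")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique")
  rd <- rowData(object)
  if (!all(c("chrom", "pos") %in% colnames(rd))) {
    msg <- c(msg, "rowData must contain 'chrom' and 'pos'")
  } else {
    for (ch in unique(rd$chrom)) {
      p <- rd$pos[rd$chrom == ch]
      if (any(diff(p) <= 0)) {
        msg <- c(msg, sprintf(
          "positions must be strictly increasing within chromosome %s", ch))
        break
      }
    }
  }
  if (!"breed" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain 'breed'")
  else if (anyNA(colData(object)$breed))
    msg <- c(msg, "every sample must map to a breed")
  if (length(msg)) msg else TRUE
})

#' FreqTable: per-breed alternate-allele frequencies with denominators
#'
#' Holds a breeds-by-SNPs matrix of alternate-allele frequencies together
#' with the matrix of allele-count denominators (twice the number of
#' non-missing individuals). Cells where a breed has no called genotype are
#' undefined and stored as \code{NaN} with denominator 0, never as silent 0.
#'
#' @slot freq numeric matrix, breeds x SNPs, values in [0, 1] or NaN.
#' @slot nObs integer matrix of allele-count denominators, even, >= 0.
#' @seealso [computeBreedFreqs()]
#' @exportClass FreqTable
setClass("FreqTable", representation(freq = "matrix", nObs = "matrix"))

setValidity("FreqTable", function(object) {
  msg <- character()
  f <- object@freq; n <- object@nObs
  if (!identical(dim(f), dim(n)))
    msg <- c(msg, "freq and nObs must have identical dimensions")
  if (is.null(rownames(f)) || is.null(colnames(f)))
    msg <- c(msg, "freq must carry breed rownames and SNP colnames")
  ok <- !is.nan(f)
  if (any(f[ok] < 0 | f[ok] > 1))
    msg <- c(msg, "frequencies must lie in [0, 1]")
  if (any(n < 0) || any(n %% 2 != 0))
    msg <- c(msg, "nObs must be even and nonnegative")
  if (any(is.nan(f) != (n == 0)))
    msg <- c(msg, "undefined cells (NaN) must coincide with nObs == 0")
  if (length(msg)) msg else TRUE
})

#' SimConfig: configuration of the hierarchical genotype simulator
#'
#' Describes a Balding-Nichols style two-level drift design: continental
#' groups drift from a global ancestor with \code{f} (an F_ST-like
#' parameter), breeds drift from their group ancestor with their own
#' \code{f}, and hybrid breeds mix two parental breeds' allele frequencies.
#' Optional layers add missing genotypes (MCAR), SNP-chip ascertainment
#' (a minimum MAF in a designated discovery group) and spatial
#' allele-frequency clines along a coordinate axis.
#'
#' @slot nSnps number of SNPs simulated before ascertainment filtering.
#' @slot groups data.frame with columns \code{group}, \code{f}.
#' @slot breeds data.frame with columns \code{breed}, \code{group}, \code{f},
#'   \code{n}, \code{lon}, \code{lat}.
#' @slot hybrids data.frame with columns \code{breed}, \code{parentA},
#'   \code{parentB}, \code{alpha}, \code{n}, \code{lon}, \code{lat}
#'   (zero rows when absent).
#' @slot missingRate scalar in [0, 1).
#' @slot ascertainment list(group, mafMin) or empty list.
#' @slot cline list(fraction, axis, steepness) or empty list.
#' @slot seed integer master seed.
#' @seealso [simConfig()], [defaultWorldlikeConfig()], [simulatePanel()]
#' @exportClass SimConfig
setClass("SimConfig", representation(
  nSnps = "numeric", groups = "data.frame", breeds = "data.frame",
  hybrids = "data.frame", missingRate = "numeric",
  ascertainment = "list", cline = "list", seed = "numeric"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nSnps < 1) msg <- c(msg, "nSnps must be >= 1")
  g <- object@groups; b <- object@breeds; h <- object@hybrids
  if (!all(c("group", "f") %in% names(g))) msg <- c(msg, "groups needs group, f")
  if (!all(c("breed", "group", "f", "n", "lon", "lat") %in% names(b)))
    msg <- c(msg, "breeds needs breed, group, f, n, lon, lat")
  if (nrow(h) && !all(c("breed", "parentA", "parentB", "alpha", "n",
                        "lon", "lat") %in% names(h)))
    msg <- c(msg, "hybrids needs breed, parentA, parentB, alpha, n, lon, lat")
  if (any(g$f <= 0 | g$f >= 1) || any(b$f <= 0 | b$f >= 1))
    msg <- c(msg, "all drift f must lie in (0, 1)")
  if (!all(b$group %in% g$group)) msg <- c(msg, "breed group not in groups")
  if (nrow(h)) {
    if (any(h$alpha < 0 | h$alpha > 1)) msg <- c(msg, "alpha must be in [0, 1]")
    if (!all(c(h$parentA, h$parentB) %in% b$breed))
      msg <- c(msg, "hybrid parents must be pure breeds")
  }
  if (anyDuplicated(c(b$breed, if (nrow(h)) h$breed)))
    msg <- c(msg, "breed codes must be unique")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "missingRate must be in [0, 1)")
  if (length(object@ascertainment) &&
      !all(c("group", "mafMin") %in% names(object@ascertainment)))
    msg <- c(msg, "ascertainment needs group, mafMin")
  if (length(object@cline)) {
    if (!all(c("fraction", "axis", "steepness") %in% names(object@cline)))
      msg <- c(msg, "cline needs fraction, axis, steepness")
    else if (!object@cline$axis %in% c("lon", "lat"))
      msg <- c(msg, "cline axis must be 'lon' or 'lat'")
  }
  if (length(msg)) msg else TRUE
})

#' QCReport: accounting of the SNP filter cascade
#'
#' @slot nInput,nDroppedCallrate,nDroppedMonomorphic,nDroppedHwe,nRetained
#'   integer counts; input = dropped + retained.
#' @slot perSnp data.frame with one row per input SNP: id, drop stage
#'   (\code{"callrate"}, \code{"monomorphic"}, \code{"hwe"} or
#'   \code{"retained"}) and, for SNPs reaching the HWE stage, the minimum
#'   per-breed p-value and q-value.
#' @seealso [runCascade()]
#' @exportClass QCReport
setClass("QCReport", representation(
  nInput = "integer", nDroppedCallrate = "integer",
  nDroppedMonomorphic = "integer", nDroppedHwe = "integer",
  nRetained = "integer", perSnp = "data.frame"))

setValidity("QCReport", function(object) {
  tot <- object@nDroppedCallrate + object@nDroppedMonomorphic +
    object@nDroppedHwe + object@nRetained
  if (tot != object@nInput) "counts do not reconcile: input != dropped + retained"
  else TRUE
})

#' OrdinationResult: eigenvalues, scores and loadings of a PCA-type analysis
#'
#' @slot eigenvalues numeric, descending.
#' @slot scores entities x axes matrix of coordinates.
#' @slot loadings SNPs x axes matrix.
#' @slot varFraction per-axis fraction of the total variance.
#' @slot center per-SNP centering values used.
#' @slot method character record ("pca", "betweenBreedPca") with scaling.
#' @slot extra list of method-specific extras (e.g. \code{variancePartition},
#'   breed scores for a between-breed analysis).
#' @seealso [pcaGenotypes()], [betweenBreedPca()]
#' @exportClass OrdinationResult
setClass("OrdinationResult", representation(
  eigenvalues = "numeric", scores = "matrix", loadings = "matrix",
  varFraction = "numeric", center = "numeric", method = "character",
  extra = "list"))

setValidity("OrdinationResult", function(object) {
  msg <- character()
  if (any(object@eigenvalues < -1e-10))
    msg <- c(msg, "eigenvalues must be nonnegative (to 1e-10)")
  if (is.unsorted(rev(object@eigenvalues), strictly = FALSE) &&
      any(diff(object@eigenvalues) > 1e-10))
    msg <- c(msg, "eigenvalues must be in descending order")
  if (sum(object@varFraction) > 1 + 1e-10)
    msg <- c(msg, "variance fractions must sum to <= 1")
  if (length(msg)) msg else TRUE
})

#' SpatialGraph: a neighbor graph over breeds with planar coordinates
#'
#' @slot nodes breed codes.
#' @slot xy planar coordinates (after projection), one row per node.
#' @slot adjacency symmetric 0/1 matrix, zero diagonal.
#' @slot L row-normalized weight matrix: each row with neighbors sums to 1,
#'   isolated nodes have an all-zero row.
#' @seealso [gabrielGraph()], [moransI()], [spca()]
#' @exportClass SpatialGraph
setClass("SpatialGraph", representation(
  nodes = "character", xy = "matrix", adjacency = "matrix", L = "matrix"))

setValidity("SpatialGraph", function(object) {
  msg <- character()
  a <- object@adjacency
  if (!isSymmetric(a, tol = 0)) msg <- c(msg, "adjacency must be symmetric")
  if (any(diag(a) != 0)) msg <- c(msg, "no self loops")
  rs <- rowSums(object@L)
  if (any(abs(rs - round(rs)) > 1e-12) || !all(round(rs) %in% c(0, 1)))
    msg <- c(msg, "L row sums must be 0 (isolated) or 1")
  if (length(msg)) msg else TRUE
})

#' SpcaResult: spatial principal component analysis of breed frequencies
#'
#' Eigenvalues are signed: positive axes capture global spatial structure
#' (clines, patches; neighbors similar), negative axes capture local
#' structure (neighbors contrasted). For every axis the eigenvalue equals
#' the product of the score variance (divisor n) and the score's Moran's I.
#'
#' @slot eigenvalues signed, descending.
#' @slot scores breeds x axes.
#' @slot loadings SNPs x axes.
#' @slot varAxis per-axis score variance (divisor n).
#' @slot moranAxis per-axis Moran's I of the scores.
#' @slot graph the SpatialGraph used.
#' @seealso [spca()], [colorplotScores()]
#' @exportClass SpcaResult
setClass("SpcaResult", representation(
  eigenvalues = "numeric", scores = "matrix", loadings = "matrix",
  varAxis = "numeric", moranAxis = "numeric", graph = "SpatialGraph"))

#' AdmixtureResult: EM fit of the binomial admixture model
#'
#' @slot Q individuals x K ancestry fractions, rows sum to 1.
#' @slot P K x SNPs cluster allele frequencies.
#' @slot loglik numeric trace over iterations (non-decreasing).
#' @slot K,seed,nIter integers; \code{converged} logical.
#' @seealso [fitAdmixture()], [admixtureScan()], [matchClusters()]
#' @exportClass AdmixtureResult
setClass("AdmixtureResult", representation(
  Q = "matrix", P = "matrix", loglik = "numeric", K = "integer",
  seed = "integer", nIter = "integer", converged = "logical"))

setValidity("AdmixtureResult", function(object) {
  msg <- character()
  if (any(abs(rowSums(object@Q) - 1) > 1e-9))
    msg <- c(msg, "Q rows must sum to 1")
  if (any(object@Q < -1e-12 | object@Q > 1 + 1e-12))
    msg <- c(msg, "Q entries must be in [0, 1]")
  if (any(object@P < 0 | object@P > 1))
    msg <- c(msg, "P entries must be in [0, 1]")
  if (length(msg)) msg else TRUE
})
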