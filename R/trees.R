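#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (Studier-Keppler Q-criterion) of a validated
#' symmetric distance matrix. The tree is unrooted; negative branch lengths
#' are permitted (exactly additive inputs are recovered exactly) and can be
#' clamped at zero on request.
#'
#' @param d symmetric labelled distance matrix, n >= 3.
#' @param clampNegative set negative branch lengths to 0.
#' @return an \code{ape} \code{phylo} tree.
#' @export
njTree <- function(d, clampNegative = FALSE) {
  checkDistanceMatrix(d, lower = -Inf)
  if (nrow(d) < 3) stop("need at least three taxa")
  tr <- ape::nj(d)
  if (clampNegative) tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

.distanceForKind <- function(obj, kind) {
  switch(kind,
         asd = asdMatrix(obj),
         reynolds = reynoldsMatrix(obj),
         stop("unknown distance kind: ", kind))
}

.resampleSnps <- function(obj, idx) {
  if (is(obj, "GenotypePanel")) {
    d <- dosages(obj)[idx, , drop = FALSE]
    rownames(d) <- sprintf("bs%05d", seq_along(idx))
    GenotypePanel(d, chrom = rep("1", length(idx)),
                  pos = seq_along(idx), breed = breeds(obj))
  } else {
    new("FreqTable", freq = obj@freq[, idx, drop = FALSE],
        nObs = obj@nObs[, idx, drop = FALSE])
  }
}

#' Neighbor-joining tree with SNP-bootstrap node supports
#'
#' Builds the point-estimate tree from all SNPs, then resamples SNP columns
#' with replacement \code{nBoot} times, recomputes the distance matrix and
#' NJ tree per replicate, and reports for every internal edge the percentage
#' of replicates containing the same bipartition (matched by bipartition
#' identity, robust to node rotation). SNPs are the resampling unit because
#' both ASD and Reynolds trees are functions of per-SNP summaries.
#'
#' @param obj a [GenotypePanel-class] (individual-level ASD trees) or a
#'   [FreqTable-class] (breed-level Reynolds trees).
#' @param distance "asd" or "reynolds".
#' @param nBoot bootstrap replicates (>= 1).
#' @param seed integer seed.
#' @param clampNegative passed to [njTree()].
#' @return the point-estimate \code{phylo} tree with integer supports in
#'   [0, 100] as \code{node.label}.
#' @export
bootstrapSupport <- function(obj, distance = c("asd", "reynolds"),
                             nBoot = 100, seed = 1L, clampNegative = FALSE) {
  distance <- match.arg(distance)
  stopifnot(nBoot >= 1)
  pointTree <- njTree(.distanceForKind(obj, distance), clampNegative)
  L <- if (is(obj, "GenotypePanel")) nrow(obj) else ncol(obj@freq)
  set.seed(seed)
  bootTrees <- vector("list", nBoot)
  for (b in seq_len(nBoot)) {
    idx <- sample.int(L, L, replace = TRUE)
    bootTrees[[b]] <- njTree(.distanceForKind(.resampleSnps(obj, idx),
                                              distance), clampNegative)
  }
  class(bootTrees) <- "multiPhylo"
  counts <- ape::prop.clades(pointTree, bootTrees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  pointTree$node.label <- as.integer(round(100 * counts / nBoot))
  pointTree
}

#' Root a tree on an outgroup's pendant edge
#'
#' @param tree a \code{phylo} tree.
#' @param outgroup a leaf label present in the tree.
#' @return the rooted tree (leaf set unchanged).
#' @export
rootWithOutgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label)
    stop("outgroup label not in tree: ", outgroup)
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}
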