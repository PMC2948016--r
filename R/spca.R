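.projectPlanar <- function(lon, lat) {
  # equirectangular projection about the centroid; km units
  R <- 6371
  lat0 <- mean(lat)
  cbind(x = R * cos(lat0 * pi / 180) * lon * pi / 180,
        y = R * lat * pi / 180)
}

#' Gabriel neighbor graph over breed locations
#'
#' Two nodes are neighbors iff no third node lies strictly inside the open
#' disk having their segment as diameter (equivalently, iff no w satisfies
#' d2(u,w) + d2(w,v) < d2(u,v); boundary points do not block). Longitude /
#' latitude coordinates are projected to the plane by an equirectangular
#' projection about the centroid; pass \code{planar = TRUE} for
#' user-supplied planar coordinates.
#'
#' @param coords data.frame or matrix with columns lon, lat (or x, y when
#'   \code{planar}), rownames = breed codes.
#' @param planar coordinates already planar.
#' @return a [SpatialGraph-class] with a row-normalized weight matrix L.
#' @export
gabrielGraph <- function(coords, planar = FALSE) {
  coords <- as.data.frame(coords)
  nodes <- rownames(coords)
  n <- nrow(coords)
  if (n < 2) stop("need at least two nodes")
  xy <- if (planar) as.matrix(coords[, 1:2])
        else .projectPlanar(coords$lon, coords$lat)
  rownames(xy) <- nodes
  if (anyDuplicated(xy)) stop("duplicate coordinates")
  # squared distances computed directly (no sqrt round trip), so boundary
  # cases like lattice corners sitting ON a diameter disk stay exact
  d2 <- outer(xy[, 1], xy[, 1], "-")^2 + outer(xy[, 2], xy[, 2], "-")^2
  adj <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    blocked <- FALSE
    for (w in seq_len(n)) {
      if (w == i || w == j) next
      if (d2[i, w] + d2[w, j] < d2[i, j] * (1 - 1e-12)) {
        blocked <- TRUE
        break
      }
    }
    if (!blocked) adj[i, j] <- adj[j, i] <- 1
  }
  L <- adj / pmax(rowSums(adj), 1)
  new("SpatialGraph", nodes = nodes, xy = xy, adjacency = adj, L = L)
}

#' Moran's I spatial autocorrelation
#'
#' I = (n / sum(W)) * (z' W z) / (z' z) on the centered variable, with W
#' the graph's row-normalized weight matrix (so n / sum(W) = 1 when no node
#' is isolated). Expectation under random permutation is -1/(n-1).
#'
#' @param z numeric vector, one value per graph node, non-constant.
#' @param graph a [SpatialGraph-class], or a weight matrix directly.
#' @return Moran's I (scalar); NaN for a constant z.
#' @export
moransI <- function(z, graph) {
  W <- if (is(graph, "SpatialGraph")) graph@L else as.matrix(graph)
  n <- length(z)
  stopifnot(nrow(W) == n)
  zc <- z - mean(z)
  denom <- sum(zc^2)
  if (denom == 0) return(NaN)
  (n / sum(W)) * as.numeric(zc %*% W %*% zc) / denom
}

#' Spatial principal component analysis of breed allele frequencies
#'
#' Finds axes maximizing the product of genetic variance and spatial
#' autocorrelation by the eigendecomposition of H = X'(L + L')X / (2n),
#' where X is the column-centered breeds x SNPs frequency matrix and L the
#' graph's weight matrix. With this normalization every eigenvalue equals
#' the variance of its score (divisor n) times the score's Moran's I
#' exactly. Positive eigenvalues capture global spatial structure, negative
#' ones local structure; axes are ordered by decreasing eigenvalue. The
#' decomposition is carried out in the row space of X (rank <= n), so the
#' SNP dimension is never materialized as a dense p x p matrix.
#'
#' @param freqTab a [FreqTable-class]; undefined cells are imputed at the
#'   SNP's mean defined frequency.
#' @param graph a [SpatialGraph-class] over the same breeds, or NULL when
#'   \code{W} is given.
#' @param W optional weight matrix overriding the graph's L (e.g. the
#'   identity, under which sPCA reduces to PCA of X with divisor n).
#' @return an [SpcaResult-class].
#' @export
spca <- function(freqTab, graph = NULL, W = NULL) {
  f <- freqs(freqTab)
  n <- nrow(f)
  if (n < 3) stop("need at least three breeds")
  if (is.null(W)) {
    if (is.null(graph)) stop("supply a graph or a weight matrix")
    if (!identical(sort(rownames(f)), sort(graph@nodes)))
      stop("breeds in the frequency table and graph differ")
    f <- f[graph@nodes, , drop = FALSE]
    W <- graph@L
    if (any(rowSums(graph@adjacency) == 0))
      warning("graph has isolated nodes; components are analyzed jointly")
  } else {
    graph <- new("SpatialGraph", nodes = rownames(f),
                 xy = cbind(x = seq_len(n), y = rep(0, n)),
                 adjacency = matrix(0, n, n,
                                    dimnames = list(rownames(f), rownames(f))),
                 L = as.matrix(W))
  }
  # impute undefined cells at the column mean of defined cells, then center
  for (j in which(colSums(is.nan(f)) > 0)) {
    v <- f[, j]
    v[is.nan(v)] <- mean(v[!is.nan(v)])
    f[, j] <- v
  }
  X <- sweep(f, 2, colMeans(f))
  M <- W + t(W)
  sv <- svd(X)
  r <- sum(sv$d > max(sv$d) * 1e-12)
  U <- sv$u[, seq_len(r), drop = FALSE]
  D <- sv$d[seq_len(r)]
  V <- sv$v[, seq_len(r), drop = FALSE]
  B <- (D * t(U)) %*% M %*% U * rep(D, each = r) / (2 * n)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  loadings <- V %*% e$vectors
  scores <- X %*% loadings
  rownames(scores) <- rownames(f)
  rownames(loadings) <- colnames(f)
  colnames(scores) <- colnames(loadings) <- paste0("sPC", seq_len(r))
  varAxis <- colSums(scores^2) / n
  moranAxis <- apply(scores, 2, function(s) {
    zc <- s - mean(s)
    (n / sum(W)) * as.numeric(zc %*% W %*% zc) / sum(zc^2)
  })
  new("SpcaResult", eigenvalues = e$values, scores = scores,
      loadings = loadings, varAxis = varAxis, moranAxis = moranAxis,
      graph = graph)
}

#' RGB colorplot synthesis of sPCA scores
#'
#' The first k score vectors are min-max scaled to [0, 255] and assigned to
#' the red, green and blue channels in axis order; channels beyond k (and
#' constant score vectors) are fixed at 128. The scaling is invariant to
#' affine transformations of the scores.
#'
#' @param res an [SpcaResult-class].
#' @param k number of axes mapped to channels (<= 3).
#' @return integer matrix breeds x c(R, G, B).
#' @export
colorplotScores <- function(res, k = 3) {
  if (k > ncol(res@scores) || k > 3) stop("k must be <= 3 available axes")
  out <- matrix(128L, nrow(res@scores), 3,
                dimnames = list(rownames(res@scores), c("R", "G", "B")))
  for (i in seq_len(k)) {
    s <- res@scores[, i]
    rng <- range(s)
    if (diff(rng) > 0)
      out[, i] <- as.integer(round(255 * (s - rng[1]) / diff(rng)))
  }
  out
}
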