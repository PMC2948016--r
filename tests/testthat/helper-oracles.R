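# Independent oracles, deliberately implemented via different routes than
# the package code they check.

# Exact HWE p-value by direct enumeration with exact integer weights:
# weight(h) = n! * 2^h / (nAA! h! naa!); all quantities exact in double
# arithmetic for n <= 10.
hweEnumOracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  if (nA == 0 || na == 0) return(1.0)
  hs <- seq(min(nA, na) %% 2, min(nA, na), by = 2)
  w <- vapply(hs, function(h) {
    factorial(n) * 2^h /
      (factorial((nA - h) / 2) * factorial(h) * factorial((na - h) / 2))
  }, numeric(1))
  probs <- w / sum(w)
  obs <- probs[hs == nAa]
  sum(probs[probs <= obs * (1 + 1e-12)])
}

# Weir-Cockerham theta via the nested ANOVA mean-squares route (alleles
# within individuals within populations), ratio of summed variance
# components across loci. g is a list of populations' dosage matrices
# (individuals x loci, no missing values).
wcAnovaOracle <- function(gList) {
  r <- length(gList)
  ni <- vapply(gList, nrow, integer(1))
  L <- ncol(gList[[1]])
  ntot <- sum(ni)
  nc <- (ntot - sum(ni^2) / ntot) / (r - 1)
  pInd <- lapply(gList, function(g) g / 2)          # per-individual allele mean
  pPop <- t(vapply(pInd, colMeans, numeric(L)))     # r x L
  pAll <- colSums(pPop * ni) / ntot
  # sums of squares
  ssG <- Reduce(`+`, lapply(gList, function(g) colSums(g * (2 - g) / 2)))
  ssI <- Reduce(`+`, lapply(seq_len(r), function(i)
    colSums(2 * sweep(pInd[[i]], 2, pPop[i, ])^2)))
  ssP <- colSums(2 * ni * sweep(pPop, 2, pAll)^2)
  msG <- ssG / ntot
  msI <- ssI / (ntot - r)
  msP <- ssP / (r - 1)
  sG <- msG
  sI <- (msI - msG) / 2
  sP <- (msP - msI) / (2 * nc)
  sum(sP) / sum(sP + sI + sG)
}

# Maximum-likelihood r2 for a two-SNP genotype table by 1-D search over the
# free haplotype frequency pAB (coarse grid + golden-section refinement).
gridR2Oracle <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  cnt <- table(factor(g1, 0:2), factor(g2, 0:2))
  pA <- mean(g1) / 2; pB <- mean(g2) / 2
  ll <- function(pAB) {
    h <- c(pAB, pA - pAB, pB - pAB, 1 - pA - pB + pAB)
    h <- pmax(h, 1e-12)
    probs <- matrix(c(h[4]^2, 2 * h[3] * h[4], h[3]^2,
                      2 * h[2] * h[4], 2 * (h[1] * h[4] + h[2] * h[3]),
                      2 * h[1] * h[3],
                      h[2]^2, 2 * h[1] * h[2], h[1]^2),
                    3, 3, byrow = TRUE)
    sum(cnt * log(probs))
  }
  lo <- max(0, pA + pB - 1); hi <- min(pA, pB)
  grid <- seq(lo, hi, length.out = 2001)
  vals <- vapply(grid, ll, numeric(1))
  i <- which.max(vals)
  a <- grid[max(1, i - 2)]; b <- grid[min(length(grid), i + 2)]
  opt <- optimize(ll, c(a, b), maximum = TRUE, tol = 1e-12)
  pAB <- opt$maximum
  D <- pAB - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# Brute-force Delaunay edge set: (u, v) is a Delaunay edge iff the
# circumcircle of (u, v, w) is empty of all other points for some w
# (points in general position).
delaunayEdgesOracle <- function(xy) {
  n <- nrow(xy)
  circum <- function(a, b, c) {
    ax <- xy[a, 1]; ay <- xy[a, 2]; bx <- xy[b, 1]; by <- xy[b, 2]
    cx <- xy[c, 1]; cy <- xy[c, 2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) return(NULL)
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    c(ux, uy)
  }
  edges <- matrix(FALSE, n, n)
  for (u in seq_len(n - 1)) for (v in (u + 1):n) {
    for (w in seq_len(n)) {
      if (w == u || w == v) next
      ctr <- circum(u, v, w)
      if (is.null(ctr)) next
      r2c <- sum((xy[u, ] - ctr)^2)
      d2 <- rowSums(sweep(xy, 2, ctr)^2)
      if (all(d2[-c(u, v, w)] > r2c * (1 - 1e-9))) {
        edges[u, v] <- edges[v, u] <- TRUE
        break
      }
    }
  }
  edges
}
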