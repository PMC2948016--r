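.breedLocusSummaries <- function(x) {
  # per breed per SNP: n (called individuals), p (alt freq), h (obs het prop)
  d <- dosages(x)
  br <- breeds(x)
  ok <- !is.na(d)
  d0 <- d; d0[!ok] <- 0L
  n <- rowsum(t(ok) * 1L, br)                     # breeds x SNPs
  s <- rowsum(t(d0), br)
  het <- rowsum(t(ok & d == 1L) * 1L, br)
  p <- s / (2 * n)
  h <- het / n
  list(n = n, p = p, h = h)
}

#' Per-breed expected heterozygosity and MAF > 0.05 proportion
#'
#' For every SNP with at least two called alleles in the breed, the unbiased
#' expected heterozygosity \eqn{2\hat p(1-\hat p)\, n'/(n'-1)} is computed
#' with \eqn{n'} the allele count; the breed value is the average over those
#' SNPs. The proportion of SNPs with minor-allele frequency above
#' \code{mafThreshold} is reported alongside.
#'
#' @param x a GenotypePanel.
#' @param mafThreshold MAF cutoff for the polymorphism proportion.
#' @return data.frame(breed, meanHe, propMaf, nSnpsUsed).
#' @export
heterozygosityByBreed <- function(x, mafThreshold = 0.05) {
  s <- .breedLocusSummaries(x)
  nAll <- 2 * s$n
  use <- nAll >= 2
  he <- 2 * s$p * (1 - s$p) * nAll / (nAll - 1)
  he[!use] <- NA
  maf <- pmin(s$p, 1 - s$p)
  maf[!use] <- NA
  data.frame(breed = rownames(s$n),
             meanHe = rowMeans(he, na.rm = TRUE),
             propMaf = rowMeans(maf > mafThreshold, na.rm = TRUE),
             nSnpsUsed = rowSums(use),
             row.names = NULL, stringsAsFactors = FALSE)
}

.wcComponents <- function(n, p, h) {
  # Weir & Cockerham (1984) per-locus variance components for 2 alleles.
  # n, p, h: populations x loci matrices; returns a, b, c vectors per locus.
  present <- n > 0
  r <- colSums(present)
  nbar <- colSums(n) / r
  nc <- (colSums(n) - colSums(n^2) / colSums(n)) / (r - 1)
  pbar <- colSums(n * p, na.rm = TRUE) / (r * nbar)
  s2 <- colSums(n * sweep(p, 2, pbar)^2, na.rm = TRUE) / ((r - 1) * nbar)
  hbar <- colSums(n * h, na.rm = TRUE) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  usable <- r >= 2 & nbar > 1 & is.finite(a + b + cc)
  list(a = a, b = b, c = cc, usable = usable)
}

#' Weir-Cockerham F-statistics
#'
#' Estimates the fixation indices F_IT, F_ST and F_IS in the form of F,
#' theta and f from the per-locus variance components a (among populations),
#' b (among individuals within populations) and c (within individuals), with
#' multi-locus estimates as ratios of sums:
#' theta = sum(a) / sum(a+b+c), F = 1 - sum(c) / sum(a+b+c),
#' f = 1 - sum(c) / sum(b+c). Loci with a + b + c = 0 (monomorphic overall)
#' contribute nothing. The identity (1 - F) = (1 - theta)(1 - f) holds
#' exactly under these definitions.
#'
#' @param x a GenotypePanel.
#' @param breedSubset optional character vector of breed codes to restrict to.
#' @return list(F, theta, f, a, b, c, nLociUsed).
#' @export
wcFstats <- function(x, breedSubset = NULL) {
  if (!is.null(breedSubset)) x <- x[, breeds(x) %in% breedSubset]
  if (length(unique(breeds(x))) < 2)
    stop("at least two breeds are required")
  s <- .breedLocusSummaries(x)
  comp <- .wcComponents(s$n, s$p, s$h)
  tot <- comp$a + comp$b + comp$c
  use <- comp$usable & abs(tot) > 0
  if (!any(use)) stop("no usable (polymorphic) loci")
  sa <- sum(comp$a[use]); sb <- sum(comp$b[use]); sc <- sum(comp$c[use])
  list(F = 1 - sc / (sa + sb + sc),
       theta = sa / (sa + sb + sc),
       f = 1 - sc / (sb + sc),
       a = comp$a[use], b = comp$b[use], c = comp$c[use],
       nLociUsed = sum(use))
}

#' Pairwise F_ST matrix over breeds
#'
#' Weir-Cockerham theta restricted to each breed pair. Small negative pair
#' estimates are retained as computed (the matrix check therefore uses a
#' relaxed lower bound of -0.05).
#'
#' @param x a GenotypePanel.
#' @return symmetric numeric matrix with zero diagonal, breeds as labels.
#' @export
pairwiseFst <- function(x) {
  s <- .breedLocusSummaries(x)
  bn <- rownames(s$n)
  if (length(bn) < 2) stop("at least two breeds are required")
  m <- matrix(0, length(bn), length(bn), dimnames = list(bn, bn))
  for (i in seq_len(length(bn) - 1)) for (j in (i + 1):length(bn)) {
    idx <- c(i, j)
    comp <- .wcComponents(s$n[idx, , drop = FALSE], s$p[idx, , drop = FALSE],
                          s$h[idx, , drop = FALSE])
    tot <- comp$a + comp$b + comp$c
    use <- comp$usable & abs(tot) > 0
    m[i, j] <- m[j, i] <- sum(comp$a[use]) / sum(tot[use])
  }
  checkDistanceMatrix(m, lower = -0.05)
  m
}

#' Per-breed F_IS with SNP-resampling standard deviations
#'
#' F_IS for a breed is 1 minus the ratio of the SNP-averaged observed
#' heterozygosity to the SNP-averaged unbiased expected heterozygosity
#' (\code{perSnpRatio = TRUE} averages per-SNP ratios instead). Reliability
#' is assessed by recomputing the statistic over random SNP subsets (drawn
#' without replacement within each resample).
#'
#' @param x a GenotypePanel.
#' @param nResample number of SNP resamples.
#' @param snpsPerSample SNPs per resample (<= number of SNPs).
#' @param seed integer seed.
#' @param perSnpRatio average per-SNP Ho/He ratios instead of the ratio of
#'   averages.
#' @return data.frame(breed, fis, sd, nSnpsUsed); fis is NaN when every SNP
#'   is fixed in the breed.
#' @export
fisByBreed <- function(x, nResample = 100, snpsPerSample = 1000, seed = 1L,
                       perSnpRatio = FALSE) {
  s <- .breedLocusSummaries(x)
  nAll <- 2 * s$n
  he <- 2 * s$p * (1 - s$p) * nAll / pmax(nAll - 1, 1)
  he[nAll < 2] <- NA
  ho <- s$h
  ho[nAll < 2] <- NA
  if (snpsPerSample > ncol(he)) stop("snpsPerSample exceeds the SNP count")
  fisOf <- function(cols) {
    if (perSnpRatio) {
      ratio <- ho[, cols, drop = FALSE] / he[, cols, drop = FALSE]
      ratio[!is.finite(ratio)] <- NA
      1 - rowMeans(ratio, na.rm = TRUE)
    } else {
      num <- rowMeans(ho[, cols, drop = FALSE], na.rm = TRUE)
      den <- rowMeans(he[, cols, drop = FALSE], na.rm = TRUE)
      res <- 1 - num / den
      res[den == 0] <- NaN
      res
    }
  }
  point <- fisOf(seq_len(ncol(he)))
  set.seed(seed)
  draws <- replicate(nResample,
                     fisOf(sample.int(ncol(he), snpsPerSample)))
  if (is.null(dim(draws))) draws <- matrix(draws, nrow = 1)
  data.frame(breed = rownames(s$n), fis = unname(point),
             sd = apply(draws, 1, sd),
             nSnpsUsed = rowSums(nAll >= 2),
             row.names = NULL, stringsAsFactors = FALSE)
}
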