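#' Allele-sharing distance matrix between individuals
#'
#' For each pair, the per-SNP sharing score is IBS/2 (1 for identical
#' dosages, 0.5 for dosages differing by one, 0 for opposite homozygotes);
#' the proportion of alleles alike in state, x_ij, is the mean score over
#' SNPs called in both individuals, and ASD = 1 - x_ij. A pair with no
#' overlapping called SNP is an error.
#'
#' @param x a GenotypePanel.
#' @return symmetric individuals x individuals matrix, zero diagonal.
#' @export
asdMatrix <- function(x) {
  d <- dosages(x)
  if (ncol(d) < 2) stop("at least two individuals are required")
  ok <- !is.na(d)
  # |gi - gj| summed over shared SNPs via indicator cross-products:
  # contributes 1 for (0,1),(1,2) pairs and 2 for (0,2) pairs
  I0 <- t(ok & d == 0L) * 1
  I1 <- t(ok & d == 1L) * 1
  I2 <- t(ok & d == 2L) * 1
  M <- t(ok) * 1
  cross01 <- I0 %*% t(I1); cross12 <- I1 %*% t(I2); cross02 <- I0 %*% t(I2)
  sumAbs <- cross01 + t(cross01) + cross12 + t(cross12) +
    2 * (cross02 + t(cross02))
  overlap <- M %*% t(M)
  if (any(overlap[upper.tri(overlap)] == 0)) {
    idx <- which(overlap == 0 & upper.tri(overlap), arr.ind = TRUE)[1, ]
    stop("no overlapping called SNPs for pair ",
         rownames(overlap)[idx[1]], " / ", colnames(overlap)[idx[2]])
  }
  asd <- (sumAbs / 2) / overlap
  diag(asd) <- 0
  checkDistanceMatrix(asd)
  asd
}

#' Reynolds genetic distance matrix between breeds
#'
#' Coancestry-based distance for short divergence times, from allele
#' frequencies only: per pair, theta = sum over loci and both alleles of the
#' squared frequency difference, divided by twice the summed expected
#' heterozygosity complement, i.e. num = 2 * sum (p1 - p2)^2 and
#' den = 2 * sum (p1 + p2 - 2 p1 p2). SNPs where either breed's frequency is
#' undefined are skipped for that pair. \code{transform = "minuslog"}
#' returns -ln(1 - theta) instead of the linearized coancestry.
#'
#' @param freqTab a [FreqTable-class].
#' @param transform "linear" (default, PHYLIP-style) or "minuslog".
#' @return symmetric breeds x breeds matrix, zero diagonal.
#' @export
reynoldsMatrix <- function(freqTab, transform = c("linear", "minuslog")) {
  transform <- match.arg(transform)
  f <- freqs(freqTab)
  nb <- nrow(f)
  if (nb < 2) stop("at least two breeds are required")
  m <- matrix(0, nb, nb, dimnames = list(rownames(f), rownames(f)))
  for (i in seq_len(nb - 1)) for (j in (i + 1):nb) {
    p1 <- f[i, ]; p2 <- f[j, ]
    use <- !is.nan(p1) & !is.nan(p2)
    if (!any(use)) stop("no usable loci for pair ",
                        rownames(f)[i], " / ", rownames(f)[j])
    num <- 2 * sum((p1[use] - p2[use])^2)
    den <- 2 * sum(p1[use] + p2[use] - 2 * p1[use] * p2[use])
    if (den == 0) stop("all usable loci monomorphic for pair ",
                       rownames(f)[i], " / ", rownames(f)[j])
    theta <- num / den
    m[i, j] <- m[j, i] <- if (transform == "linear") theta
                          else -log(1 - min(theta, 1 - 1e-12))
  }
  checkDistanceMatrix(m)
  m
}
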